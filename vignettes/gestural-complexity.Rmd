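---
title: "Gestural complexity and its social predictors: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gestural complexity and its social predictors: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(apegest)
```

## The scientific question

Ape gestural communication is usually scored along four axes of
complexity — how many gesture types an individual (or a pair) uses out
of its species repertoire, whether signallers account for the
recipient's attentional state (especially for visual gestures, which
require a watching recipient), how flexibly a gesture type is used
across functional contexts, and how often gestures are strung into
sequences — plus one axis of effectiveness: how often a gesture elicits
a response within 5 s. The analytical question is whether these
quantities are predicted by an individual's integration in the social
network (eigenvector centrality, age) and by the quality of dyadic
relationships (maternal kinship, proximity-based bond strength).

`apegest` implements that analysis as a deterministic, fully tested
pipeline, together with a synthetic-data generator that emulates the
observational design closely enough for the whole chain — including
parameter recovery — to be verified without field data.

## Data model and conventions

Observations arrive as three flat tables. Gesture events carry a
`(session_id, time_s)` clock; observation bouts are the natural unit,
and neither the 5-s response window nor sequence chaining crosses a
session boundary. The recipient's attentional state and the response
are ternary (`true`/`false`/`unknown`): every proportion downstream is
"out of the gestures for which this could be assessed", so unknowns are
excluded from denominators and never imputed. Every event references a
recipient — recipient-less signalling is rejected by validation rather
than modelled. Validation is total: malformed rows become located
violation records, not crashes.

## Sequence segmentation

A sequence is two or more gestures by one sender to one recipient in
the same context, each within `gap_s = 5` s of the previous one.
Chaining is transitive and keyed by `(session, sender, recipient,
context)`; gestures to a different recipient interleaved in time do not
break a chain, because the rule is phrased per sender–recipient pair.
The literature is ambiguous about whether the 5-s window is anchored at
the previous gesture or at the chain's first gesture; anchoring at the
previous member is the default (it keeps chains transitive and matches
the common reading), and `anchor = "first"` is exposed so both
behaviours are testable. Singleton chains exist but are not sequences:
the `in_sequence` flag requires chain length ≥ 2, and singletons count
only in denominators.

## Social network indices

Per group, the proximity matrix counts scans in which two individuals
were within 2 m, credited from either member's focal scan. Eigenvector
centrality is the leading eigenvector of this weighted matrix, computed
by power iteration on `C + I` (the diagonal shift leaves eigenvectors
unchanged and prevents the period-2 oscillation a bipartite component
would cause; tolerance 1e-10 on the iterate, hard cap 10 000
iterations, convergence failure is an error that reports the residual).
Because the reference range [0, 1] is stated without a formula in the
field, the package fixes the convention: each connected component is
rescaled to maximum 1, and individuals with no proximity partners get
exactly 0. The tests verify equivalence with a dense
eigen-decomposition on hundreds of random matrices.

The dyadic bond index is the pair's proximity count divided by the
total focal observations of the two members, normalized by the group
mean of these ratios; its group mean is exactly 1 whenever defined, 0
marks never-associating pairs, and values above 1 mark
stronger-than-average relationships. A group with no proximity at all
yields missing bonds with a warning rather than a division by zero.

Community counting (greedy modularity on the weighted graph) is a
diagnostic only; nothing downstream consumes it. Ties between cuts of
equal modularity (within 1e-12) resolve to the coarser partition, so a
uniform clique is one community and isolates count as singletons.

## Complexity metrics

All metrics are stored as numerator/denominator pairs. The flexibility
index averages, over gesture types produced at least `min_count = 2`
times, the share of that type's occurrences falling in its most common
context; a modal-context tie needs no tie-break because tied contexts
share the maximal count, so the proportion is identical whichever is
called modal. `include_singletons = TRUE` adds once-observed types
(each contributing 1), mirroring the alternative scoring sometimes
reported. Dyadic metrics pool the gestures exchanged in both directions
of a pair — the natural unordered-dyad reading — and dyadic flexibility
is computed on the pooled stream rather than averaged over the two
senders (the other defensible choice; pooling uses the data where
per-sender type counts would often fall below `min_count`).

Accumulation curves (running count of distinct types in coding order)
are the saturation diagnostic: under the generator defaults each
group's curve plateaus well before its stream ends, the qualitative
analogue of repertoires saturating after a few hundred coded gestures.

## The M1–M5 model suite

Ten models: five response families at two levels.

| model | response | family |
|---|---|---|
| M1 | repertoire used / ethogram size | binomial |
| M2 | attended / assessed, by modality | binomial |
| M3 | flexibility | beta |
| M4 | in-sequence / total gestures | binomial |
| M5 | responded / assessed | binomial |

Individual-level predictors are z-scored centrality and age plus
species; dyad-level predictors are maternal kinship, the z-scored bond
and species. Controls: sex (individual) or absolute age difference and
sex combination (dyad), plus z-scored observational effort where the
response does not already entail it (M1, M3). M2 includes the three
two-way interactions of modality with each predictor at both levels,
since attention accounting should matter mostly for visual gestures.
M5 additionally takes the four complexity proportions as predictors
(attention in the visual modality only). Proportions enter raw;
continuous predictors and controls are z-standardized (denominator
n − 1) across the modeling table. Dyadic models consider only dyads
observed interacting — a dyad that never exchanged a gesture carries no
gestural information (and its zero count is determined by, not adjusted
for, observational effort).

Fitting is deterministic maximum likelihood: IRLS for the binomial
models (deviance tolerance 1e-10, 100 iterations, complete separation
flagged — never silently reported — when fitted logits reach ±30), and
joint BFGS ascent over `(β, log φ)` for the beta models, initialized
from a logit-scale least-squares fit, with standard errors from the
observed information and the Smithson–Verkuilen shrinkage
`y' = (y(n−1) + 0.5)/n` applied only when observations sit on the
boundary. A constant precision φ is assumed; nothing in the data model
identifies a precision submodel. With flat priors the Bayesian
posterior mode equals these ML estimates, which is the bridge that
makes ML the desk-scale stand-in for MCMC fitting; full Bayesian
estimation, LOO-based comparison and multi-membership random effects
are deliberately out of scope. In their place: AIC (plus optional
seeded k-fold deviance) against control-only comparators, fixed-effects
dyadic models with an optional dyad-level nonparametric bootstrap
(seeded, 500 resamples by default) for standard errors, and
delta-method species contrasts at covariate means on the link and
response scales. The M2 individual model drops the per-individual
random intercept of the original mixed formulation; with one
aggregated row per individual and modality, a free intercept per
individual is not identifiable under ML, and the fixed-effects
analogue is the documented approximation.

The pipeline summary mirrors a prediction ledger of 14 directional
predictions (all positive-signed: more sociality → more complexity →
more effectiveness). A prediction is "supported" when its
strongest-|z| coefficient is positive, its 95% interval excludes zero,
and the full model beats the controls-only model by AIC.

## The synthetic-data generator

The generator reproduces the observational design: seven groups
(19 chimpanzees; 9 + 7 orangutans; 4 + 4 + 5 + 5 siamangs, 53 subjects),
focal bouts of 5 min (chimpanzees, 24 sessions) or 15 min (others, 40
sessions), gesture rates sized to the reported per-individual means
(about 63/59/80 gestures), 35 scans per subject at 600-s spacing, and
ethograms of 18/17/14 abstract types with a Zipf(1) frequency law so
accumulation curves saturate within a few hundred gestures. Latent
dyadic affinities `N(−2, 0.8) + 1.5·kin` drive both scan neighbourhoods
and (at half strength, `recipient_affinity_scale = 0.5`, since
gesturing is less selective than 2-m proximity) the choice of gesture
recipients, creating the bond–interaction coupling the dyadic analyses
presume. Contexts are drawn with a 0.78 modal bias per type, which
lands flexibility indices in the 0.7–0.9 band typical of this
literature. Attention and response states are unknown with probability
0.05.

Effect sizes are planted on the logit scale of each model's response,
with defaults equal to the headline coefficients of the emulated
analysis: age → attention +0.30 with a +1.06 visual-modality
interaction; bond → dyadic repertoire +0.14; age and centrality →
sequence use −0.29 and −0.21; age → response +0.17; sequence use →
response −2.30; attention → response +1.23. Species intercepts default
to the logits of the reported species-level probabilities (e.g.
sequence-use probabilities 0.381/0.284/0.381).

Three design choices matter for interpreting recovery results:

1. **Planting on realized predictors.** Effects are planted on the
   exact covariates the pipeline later computes — z-scored age, the
   scan-based centrality and bond indices, the realized per-individual
   sequence and attention proportions — not on latent quantities. The
   fitted models are therefore correctly specified, and ML recovery is
   attenuation-free. This is a property of the verification design: it
   shows the pipeline estimates without bias what the generator
   planted; with noisy proxies of latent traits (as in nature) the same
   coefficients would be attenuated.
2. **Mean-matched dyadic repertoires.** A dyad observed `n` times can
   display at most `n` distinct types and, having interacted, at least
   one. The planted type count is drawn with a per-dyad probability
   solved (by uniroot on the clamped-binomial mean) so that the draw's
   expectation equals `E·plogis(d0 + β·z(bond))` despite the clamp.
   Binomial GLM point estimates depend only on the conditional mean, so
   the bond coefficient is recovered even though the count distribution
   is not exactly binomial. Unit allocation itself never looks at the
   planted repertoire, so a dyad's gesture count carries no information
   about its type count beyond what the social covariates explain.
3. **Where each coefficient lives.** The attention → response effect is
   planted on the sender's visual-attention proportion; its
   correctly-specified recovery model is the individual-level response
   model (whose predictor set contains exactly that proportion). The
   dyadic response model sees the pooled dyadic proportion — a mixture
   over the two senders — and recovers the effect approximately; it is
   checked for sign, not for exact magnitude.

Sequences are planted per event (`Bernoulli(plogis(s0 + β·z))`), then
flagged events are grouped into chains of 2–4 same-type repetitions
with intra-chain gaps of 0.5–4.5 s; chains and singletons are laid out
in sessions at least 6 s apart, so segmentation recovers the planted
flags essentially exactly, and the realized in-sequence proportion is
an unbiased binomial realization of the planted probability. A lone
flagged gesture (which cannot form a chain) is promoted or demoted with
equal probability, preserving the mean. Responses are drawn last, from
the realized sequence and attention proportions, with species
intercepts re-centred at documented constants (sequence proportion
0.35, attention proportion 0.92) so realized response rates stay near
their species targets. Gesture arrivals per focal are Poisson — the
observational literature reports no arrival model, so this is an
assumption, exposed in the configuration.

Every stage of generation draws from named substreams of one root seed,
so a single integer reproduces the dataset byte for byte.

## What the synthetic tests do and do not show

Passing recovery tests show that the pipeline's estimators are
consistent and calibrated for the design they claim to fit: correct
counting, correct index construction, correct likelihoods and standard
errors. They do not show that real ape data satisfy those models: real
gestures have overdispersion from unmodelled individual heterogeneity,
real centralities are noisy proxies of social experience (attenuating
coefficients), observation is unbalanced across individuals, species
ethograms are not abstract Zipf draws, and the generator plants no
spatial, temporal or weather structure. Flexibility realized at small
type counts is biased upward relative to its asymptotic value (the
modal share of few draws exceeds the modal probability), which is why
generated flexibility means sit near 0.81 with a 0.78 modal bias — the
same small-sample effect the index has on real data.

## Numerical choices and degenerate inputs

* Power iteration: shift `C + I`, tolerance 1e-10, max 10 000
  iterations; isolates centrality 0; one-member groups are valid.
* Bond: all-zero proximity gives missing bonds with a warning; the
  degenerate z-scoring of a constant bond vector is refused in the
  model tables (an error naming the column) and planted at the
  intercept in the generator.
* IRLS: fitted logits capped at ±30; separation flags the fit
  (`converged = FALSE` with diagnostics) instead of erroring, so a
  model suite can report it; rank-deficient designs error with the
  aliased terms named at the low level, while the suite drops aliased
  columns (recording them) for resilience on small fuzzed datasets.
* Beta regression: log-precision capped at 20 during optimization;
  non-finite likelihood evaluations return a large penalty.
* Chain partitioning: flagged counts of 2–4 become one chain; larger
  counts are split greedily into parts of 2–4 with a remainder fix
  that avoids leaving a lone gesture.
* k-fold comparison and the dyad bootstrap derive their seeds from the
  run seed through named substreams; re-running a configuration into a
  clean directory reproduces `summary.csv` byte for byte.

## Problem sizes used in the verification suite

The packaged tests exercise segmentation against a transitive-closure
oracle on 500 random streams of up to 20 events, centrality against
dense eigen-decompositions on 200 random matrices up to 12×12,
invariants on 100 fuzzed small colonies, and parameter recovery and
null calibration on 50 seeded replicates of the full 53-individual
design — sizes chosen so the whole suite runs in minutes on one CPU
while leaving the Monte-Carlo bands tight enough to detect biases of a
few hundredths on the logit scale.

## Known limitations

Fixed-effects ML in the dyadic models understates uncertainty from
repeated individual membership (the bootstrap is dyad-level, per the
stated approximation, not multi-membership); the beta models assume
constant precision; communities are a diagnostic, not an inferential
quantity; and the generator's planted world is intentionally cleaner
than observational data, as discussed above.
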