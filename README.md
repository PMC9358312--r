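# apegest

Analysis pipeline for the complexity and effectiveness of ape gestural
communication, and its social predictors.

Behavioural studies of great and lesser apes code gestures from
focal-animal video (sender, recipient, gesture type, modality, the
recipient's attentional state, the response within 5 s, the functional
context) and score each individual's social world from instantaneous
proximity scans. `apegest` implements the full analysis chain for such
data:

* a validated data model for individuals, gesture events and proximity
  scans (CSV in, CSV out, machine-readable validation);
* segmentation of gestures into **sequences** (≥ 2 gestures by the same
  sender to the same recipient within 5 s, in the same context);
* **social network indices** per group: eigenvector centrality (power
  iteration, per-component max-1 scaling), the dyadic bond index (a
  pair's proximity ratio divided by the group mean, so 1 = average
  relationship), maternal kinship, and a community-count diagnostic;
* **complexity metrics** per individual and dyad: repertoire size out of
  the species ethogram, attention accounting by modality, contextual
  flexibility, sequence use, response elicitation, plus cumulative
  repertoire (accumulation) curves and Cohen's kappa for coder
  reliability;
* the **M1–M5 regression families** at both levels — binomial GLMs
  (logit link, IRLS) and beta regression (constant precision, ML) — with
  z-standardized predictors, AIC and optional k-fold comparison against
  control-only models, delta-method species contrasts, and dyad-level
  bootstrap standard errors;
* a seeded **synthetic-data generator** emulating the study design
  (53 subjects in 7 groups: 19 chimpanzees, 16 orangutans, 18 siamangs;
  5- or 15-min focal bouts; 35 proximity scans per subject at 10-min
  spacing; species ethograms of 18/17/14 gesture types) with
  configurable planted effect sizes, so the whole pipeline can be
  exercised and parameter recovery verified without observational data.

The regressions model, e.g., an individual's repertoire as
`repertoire_used ~ Binomial(E, p)` with
`logit(p) = β₀ + β₁·z(centrality) + β₂·z(age) + species + controls`,
and flexibility with a beta likelihood on the logit mean scale. With
flat priors a Bayesian posterior mode coincides with these ML fits,
which is what makes deterministic ML a faithful desk-scale stand-in.

## Worked example

```r
library(apegest)

d <- generate_dataset(synthetic_config(), seed = 1)
d
#> <gesture_dataset>
#>   53 individuals in 7 groups (chimpanzee: 19, orangutan: 16, siamang: 18)
#>   3681 gesture events, 1855 proximity scans

rep <- run_pipeline(run_config("synthetic", out_dir = "run1", seed = 1,
                               boot = 0, verbose = FALSE))
rep
#> <run_report> run1
#>   53 individuals, 3681 events, 1855 scans; 10 models
#>   5/14 predictions supported

subset(rep$summary, model == "M4-Ind",
       select = c(term, estimate, lower, upper, sign))
#>    term   estimate      lower      upper sign
#>   z_age -0.3314849 -0.4036646 -0.2593051    -
```

The summary has one row per directional prediction (14 rows): the
coefficient judged, its 95% interval, its sign, and whether the full
model beat the controls-only model by AIC. In the run above the planted
age effect on sequence use is recovered as negative (−0.33, planted
−0.29 under that seed's noise). Four of the five supported rows are the
predictions planted as true (age → attention accounting, bond → dyadic
repertoire, attention → response at both levels); the fifth (kinship →
response) is the kind of single false positive expected at the 5% level
among the many null coefficients.

A thin CLI wraps the same functions:

```sh
inst/scripts/apegest simulate --seed 1 --out run1
inst/scripts/apegest analyze --individuals individuals.csv \
    --events events.csv --scans scans.csv --ethogram ethogram.yaml --out run2
inst/scripts/apegest report --run run1
```

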