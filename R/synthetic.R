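# Seeded synthetic-data generator emulating the focal/scan sampling design:
# 53 individuals in 7 groups (19 chimpanzees; 9 + 7 orangutans; 4 + 4 + 5 + 5
# siamangs), 35 proximity scans per subject at >= 10-min spacing, 5-min
# (chimpanzee) or 15-min (orangutan, siamang) focal bouts, species ethograms
# of 18/17/14 types, and configurable effect sizes planted on the logit
# scale of each model family's response.
#
# Planted effects are applied to the *realized* predictors the analysis
# pipeline itself computes (z-scored age, scan-based eigenvector centrality
# and bond indices, realized per-individual sequence and attention
# proportions), so the fitted models are correctly specified and maximum
# likelihood recovers the planted coefficients without attenuation.

substream_seed <- function(seed, name) {
  h <- sum(utf8ToInt(name) * seq_along(utf8ToInt(name)))
  as.integer((as.numeric(seed) * 10007 + h * 97) %% 2147483647)
}

#' Configuration for the synthetic-data generator
#'
#' Returns the full generator configuration with defaults matching the
#' emulated study design; every argument overrides one field. Effect sizes
#' are logit-scale coefficients on z-standardized predictors (or raw
#' proportions for the response model), directly comparable to the
#' coefficients the model suite estimates.
#'
#' @param groups data frame with `group_id`, `species`, `size`. The default
#'   seven groups total 53 individuals.
#' @param sessions named list per species of `n_sessions` and
#'   `session_length_s` (defaults: 24 x 300 s for chimpanzees, 40 x 900 s
#'   otherwise).
#' @param scan_interval_s,scans_per_individual scan design (600 s, 35).
#' @param ethogram an [`ethogram`][default_ethogram].
#' @param age_min,age_max uniform age bounds in years.
#' @param mother_min_age_gap minimum mother-offspring age gap in years.
#' @param affinity_base_logit,affinity_sd,kin_boost latent dyadic affinity
#'   model: neighbour probability per scan is
#'   `plogis(N(base, sd) + kin_boost * kin)`, fixed per dataset.
#' @param recipient_affinity_scale concentration of gesture partner choice
#'   on affinity: recipient weights are `exp(scale * affinity)`. The
#'   default 0.5 makes gesturing less selective than spatial proximity, so
#'   even weakly bonded dyads exchange a few gestures.
#' @param gesture_rate_per_min named per-species gesture rate per focal
#'   minute (defaults sized to average roughly 63/59/80 gestures per
#'   chimpanzee/orangutan/siamang).
#' @param contexts,modal_context_prob functional contexts and the
#'   probability that a gesture occurs in its type's dominant context
#'   (0.78 puts flexibility indices in the 0.7-0.9 range).
#' @param zipf_exponent gesture-type frequency law (exponent 1 saturates
#'   group accumulation curves within a few hundred gestures).
#' @param unknown_rate probability an event's attention or response could
#'   not be assessed.
#' @param chain_length_probs distribution of sequence-chain lengths
#'   (2 to 4 gestures, i.e. 1-3 follow-up repetitions within 5 s).
#' @param attention_intercept,visual_effect_attention non-visual logit
#'   intercepts per species and the visual-modality shift for the
#'   attention-accounting model.
#' @param sequence_intercept per-species logit of the sequence-use
#'   probability (defaults the logit of 0.381/0.284/0.381).
#' @param response_intercept per-species logit of the response probability
#'   at the centering constants (defaults the logit of 0.676/0.603/0.684).
#' @param response_seq_center,response_att_center centering constants for
#'   the sequence/attention terms of the response model, so the realized
#'   response probabilities stay near `plogis(response_intercept)`.
#' @param dyad_repertoire_intercept per-species logit of the dyadic
#'   repertoire probability (defaults the logit of 0.102/0.168/0.271).
#' @param beta_age_attention,beta_age_attention_visual planted age slope on
#'   attention accounting and its extra visual-modality component
#'   (defaults +0.30 and +1.06).
#' @param beta_bond_dyadrep planted bond slope on dyadic repertoire
#'   (default +0.14).
#' @param beta_age_seq,beta_centrality_seq planted age and centrality
#'   slopes on sequence use (defaults -0.29 and -0.21).
#' @param beta_age_response planted age slope on response (default +0.17).
#' @param beta_seq_response planted slope of the sender's sequence
#'   proportion on response (default -2.30).
#' @param beta_attention_response planted slope of the sender's visual
#'   attention proportion on response (default +1.23).
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(
    groups = data.frame(
      group_id = c("atlanta", "zurich", "leipzig",
                   "krefeld1", "krefeld2", "howlettsA", "howlettsB"),
      species = c("chimpanzee", "orangutan", "orangutan",
                  "siamang", "siamang", "siamang", "siamang"),
      size = c(19L, 9L, 7L, 4L, 4L, 5L, 5L),
      stringsAsFactors = FALSE),
    sessions = list(
      chimpanzee = list(n_sessions = 24L, session_length_s = 300),
      orangutan = list(n_sessions = 40L, session_length_s = 900),
      siamang = list(n_sessions = 40L, session_length_s = 900)),
    scan_interval_s = 600,
    scans_per_individual = 35L,
    ethogram = default_ethogram(),
    age_min = 2, age_max = 40,
    mother_min_age_gap = 8,
    affinity_base_logit = -2.0, affinity_sd = 0.8, kin_boost = 1.5,
    recipient_affinity_scale = 0.5,
    gesture_rate_per_min = c(chimpanzee = 0.525, orangutan = 0.0983,
                             siamang = 0.1333),
    contexts = c("play", "affiliative", "agonistic", "sexual"),
    modal_context_prob = 0.78,
    zipf_exponent = 1,
    unknown_rate = 0.05,
    chain_length_probs = c("2" = 0.5, "3" = 0.3, "4" = 0.2),
    attention_intercept = c(chimpanzee = 1.6, orangutan = 2.6, siamang = 2.0),
    visual_effect_attention = 1.2,
    sequence_intercept = stats::qlogis(c(chimpanzee = 0.381,
                                         orangutan = 0.284,
                                         siamang = 0.381)),
    response_intercept = stats::qlogis(c(chimpanzee = 0.676,
                                         orangutan = 0.603,
                                         siamang = 0.684)),
    response_seq_center = 0.35,
    response_att_center = 0.92,
    dyad_repertoire_intercept = stats::qlogis(c(chimpanzee = 0.102,
                                                orangutan = 0.168,
                                                siamang = 0.271)),
    beta_age_attention = 0.30,
    beta_age_attention_visual = 1.06,
    beta_bond_dyadrep = 0.14,
    beta_age_seq = -0.29,
    beta_centrality_seq = -0.21,
    beta_age_response = 0.17,
    beta_seq_response = -2.30,
    beta_attention_response = 1.23) {
  cfg <- list(groups = groups, sessions = sessions,
              scan_interval_s = scan_interval_s,
              scans_per_individual = as.integer(scans_per_individual),
              ethogram = ethogram, age_min = age_min, age_max = age_max,
              mother_min_age_gap = mother_min_age_gap,
              affinity_base_logit = affinity_base_logit,
              affinity_sd = affinity_sd, kin_boost = kin_boost,
              recipient_affinity_scale = recipient_affinity_scale,
              gesture_rate_per_min = gesture_rate_per_min,
              contexts = contexts, modal_context_prob = modal_context_prob,
              zipf_exponent = zipf_exponent, unknown_rate = unknown_rate,
              chain_length_probs = chain_length_probs,
              attention_intercept = attention_intercept,
              visual_effect_attention = visual_effect_attention,
              sequence_intercept = sequence_intercept,
              response_intercept = response_intercept,
              response_seq_center = response_seq_center,
              response_att_center = response_att_center,
              dyad_repertoire_intercept = dyad_repertoire_intercept,
              beta_age_attention = beta_age_attention,
              beta_age_attention_visual = beta_age_attention_visual,
              beta_bond_dyadrep = beta_bond_dyadrep,
              beta_age_seq = beta_age_seq,
              beta_centrality_seq = beta_centrality_seq,
              beta_age_response = beta_age_response,
              beta_seq_response = beta_seq_response,
              beta_attention_response = beta_attention_response)
  class(cfg) <- "synthetic_config"
  validate_config(cfg)
  cfg
}

#' Write a synthetic configuration to YAML
#'
#' Serializes every field of a [synthetic_config()] (the ethogram
#' included) so a run can be reproduced from a plain-text file.
#'
#' @param cfg a [synthetic_config()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_synthetic_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "synthetic_config"))
  out <- unclass(cfg)
  out$groups <- lapply(seq_len(nrow(cfg$groups)), function(i) {
    as.list(cfg$groups[i, , drop = FALSE])
  })
  out$ethogram <- lapply(cfg$ethogram, as.list)
  for (f in c("gesture_rate_per_min", "chain_length_probs",
              "attention_intercept", "sequence_intercept",
              "response_intercept", "dyad_repertoire_intercept")) {
    out[[f]] <- as.list(out[[f]])
  }
  yaml::write_yaml(out, path)
  invisible(path)
}

#' Read a synthetic configuration from YAML
#'
#' @param path a file written by [write_synthetic_config()] (or edited by
#'   hand); missing fields fall back to the package defaults.
#' @return A validated [synthetic_config()].
#' @export
read_synthetic_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- yaml::read_yaml(path)
  args <- list()
  if (!is.null(raw$groups)) {
    args$groups <- do.call(rbind, lapply(raw$groups, function(g) {
      data.frame(group_id = g$group_id, species = g$species,
                 size = as.integer(g$size), stringsAsFactors = FALSE)
    }))
  }
  if (!is.null(raw$ethogram)) {
    args$ethogram <- structure(lapply(raw$ethogram, unlist),
                               class = "ethogram")
  }
  if (!is.null(raw$sessions)) args$sessions <- raw$sessions
  named_num <- function(x) {
    v <- unlist(x)
    stats::setNames(as.numeric(v), names(v))
  }
  for (f in c("gesture_rate_per_min", "chain_length_probs",
              "attention_intercept", "sequence_intercept",
              "response_intercept", "dyad_repertoire_intercept")) {
    if (!is.null(raw[[f]])) args[[f]] <- named_num(raw[[f]])
  }
  scalars <- c("scan_interval_s", "scans_per_individual", "age_min",
               "age_max", "mother_min_age_gap", "affinity_base_logit",
               "affinity_sd", "kin_boost", "recipient_affinity_scale",
               "modal_context_prob", "zipf_exponent", "unknown_rate",
               "visual_effect_attention", "response_seq_center",
               "response_att_center", "beta_age_attention",
               "beta_age_attention_visual", "beta_bond_dyadrep",
               "beta_age_seq", "beta_centrality_seq", "beta_age_response",
               "beta_seq_response", "beta_attention_response")
  for (f in scalars) if (!is.null(raw[[f]])) args[[f]] <- raw[[f]]
  if (!is.null(raw$contexts)) args$contexts <- unlist(raw$contexts)
  do.call(synthetic_config, args)
}

validate_config <- function(cfg) {
  g <- cfg$groups
  if (nrow(g) < 1 || any(g$size < 1)) stop("groups must have size >= 1")
  if (!all(g$species %in% ethogram_species(cfg$ethogram))) {
    stop("group species missing from ethogram: ",
         paste(setdiff(g$species, ethogram_species(cfg$ethogram)),
               collapse = ", "))
  }
  for (sp in unique(g$species)) {
    if (is.null(cfg$sessions[[sp]])) stop("no session design for species ", sp)
    if (is.na(cfg$gesture_rate_per_min[sp])) stop("no gesture rate for species ", sp)
    for (fld in c("attention_intercept", "sequence_intercept",
                  "response_intercept", "dyad_repertoire_intercept")) {
      if (is.na(cfg[[fld]][sp])) stop("no ", fld, " for species ", sp)
    }
  }
  probs <- c(cfg$modal_context_prob, cfg$unknown_rate, cfg$chain_length_probs)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (cfg$scans_per_individual < 1) stop("scans_per_individual must be >= 1")
  if (cfg$age_min < 0 || cfg$age_max <= cfg$age_min) stop("invalid age bounds")
  if (any(cfg$gesture_rate_per_min <= 0)) stop("gesture rates must be positive")
  invisible(cfg)
}

#' @export
print.synthetic_config <- function(x, ...) {
  cat("<synthetic_config>\n")
  cat(sprintf("  %d groups, %d individuals; %d scans/individual\n",
              nrow(x$groups), sum(x$groups$size), x$scans_per_individual))
  betas <- x[grep("^beta_", names(x))]
  cat("  planted effects:",
      paste(sprintf("%s=%.2f", names(betas), unlist(betas)), collapse = ", "),
      "\n")
  invisible(x)
}

#' Generate the synthetic study population
#'
#' One row per individual: balanced-Bernoulli sexes, ages uniform in the
#' configured bounds, and 0-2 maternal families per group (each a mother at
#' least `mother_min_age_gap` years older than her 1-2 offspring).
#'
#' @param cfg a [synthetic_config()].
#' @param seed integer seed.
#' @return An individuals data frame.
#' @export
generate_population <- function(cfg, seed) {
  validate_config(cfg)
  set.seed(substream_seed(seed, "population"))
  rows <- list()
  for (gi in seq_len(nrow(cfg$groups))) {
    g <- cfg$groups[gi, ]
    n <- g$size
    ids <- sprintf("%s_%02d", g$group_id, seq_len(n))
    sex <- ifelse(stats::rbinom(n, 1, 0.5) == 1, "F", "M")
    age <- round(stats::runif(n, cfg$age_min, cfg$age_max), 1)
    mother <- rep("", n)
    n_fam <- sample(0:2, 1)
    taken <- rep(FALSE, n)
    for (f in seq_len(n_fam)) {
      mothers_ok <- which(sex == "F" & !taken &
                            age >= cfg$age_min + cfg$mother_min_age_gap)
      if (length(mothers_ok) == 0) break
      mom <- if (length(mothers_ok) == 1) mothers_ok else sample(mothers_ok, 1)
      kids_ok <- which(!taken & seq_len(n) != mom &
                         age <= age[mom] - cfg$mother_min_age_gap)
      if (length(kids_ok) == 0) next
      n_kids <- min(sample(1:2, 1), length(kids_ok))
      kids <- if (length(kids_ok) == 1) kids_ok else sample(kids_ok, n_kids)
      mother[kids] <- ids[mom]
      taken[c(mom, kids)] <- TRUE
    }
    rows[[gi]] <- data.frame(
      individual_id = ids, species = g$species, group_id = g$group_id,
      sex = sex, age_years = age, mother_id = mother,
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

#' Latent dyadic affinities
#'
#' Draws the fixed per-dataset affinity of every within-group dyad:
#' `a_ij ~ Normal(base, sd) + kin_boost * maternal_kin`. The same
#' affinities drive both scan neighbourhoods and gesture recipient choice,
#' coupling bond indices to interaction rates.
#'
#' @param individuals individuals table.
#' @param cfg a [synthetic_config()].
#' @param seed integer seed.
#' @return Data frame `id1`, `id2`, `group_id`, `affinity` (logit scale).
#' @export
generate_affinities <- function(individuals, cfg, seed) {
  set.seed(substream_seed(seed, "affinity"))
  kin <- maternal_kinship(individuals)
  aff <- stats::rnorm(nrow(kin), cfg$affinity_base_logit, cfg$affinity_sd) +
    cfg$kin_boost * kin$maternal_kin
  grp <- individuals$group_id[match(kin$id1, individuals$individual_id)]
  data.frame(id1 = kin$id1, id2 = kin$id2, group_id = grp,
             affinity = aff, maternal_kin = kin$maternal_kin,
             stringsAsFactors = FALSE)
}

affinity_lookup <- function(affinities) {
  key <- paste(affinities$id1, affinities$id2)
  stats::setNames(affinities$affinity, key)
}

dyad_key <- function(a, b) {
  paste(pmin(a, b), pmax(a, b))
}

#' Generate proximity scans
#'
#' Every individual is the focal of `scans_per_individual` scans spaced
#' `scan_interval_s` apart; each groupmate joins the neighbour set
#' independently with probability `plogis(affinity)`.
#'
#' @param individuals individuals table.
#' @param cfg a [synthetic_config()].
#' @param seed integer seed.
#' @param affinities optional affinity table from [generate_affinities()]
#'   (derived from `seed` when omitted).
#' @return A scans data frame.
#' @export
generate_scans <- function(individuals, cfg, seed, affinities = NULL) {
  if (is.null(affinities)) affinities <- generate_affinities(individuals, cfg, seed)
  set.seed(substream_seed(seed, "scans"))
  alook <- affinity_lookup(affinities)
  rows <- list()
  for (g in unique(individuals$group_id)) {
    members <- individuals$individual_id[individuals$group_id == g]
    for (f in members) {
      mates <- setdiff(members, f)
      p <- stats::plogis(alook[dyad_key(f, mates)])
      for (k in seq_len(cfg$scans_per_individual)) {
        nb <- mates[stats::rbinom(length(mates), 1, p) == 1]
        rows[[length(rows) + 1]] <- data.frame(
          scan_id = sprintf("%s_scan%03d", f, k),
          group_id = g,
          time_s = (k - 1) * cfg$scan_interval_s,
          focal_id = f,
          neighbor_ids = paste(nb, collapse = ";"),
          stringsAsFactors = FALSE)
      }
    }
  }
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

zipf_weights <- function(n, exponent) {
  w <- seq_len(n)^(-exponent)
  w / sum(w)
}

draw_clamped_repertoire <- function(E, n_units, mu) {
  # draw a type count in [1, min(E, n_units)] whose expectation equals mu
  # (the planted conditional mean), by solving for the binomial draw
  # probability under the clamp; at the boundaries the clamp itself is
  # returned (the dyad was observed too rarely to display its planted mean)
  if (n_units == 0) return(0L)
  hi <- min(E, n_units)
  clamp_mean <- function(p) {
    k <- 0:E
    sum(stats::dbinom(k, E, p) * pmin(pmax(k, 1L), hi))
  }
  if (mu <= 1) return(1L)
  if (mu >= hi) return(as.integer(hi))
  p_star <- stats::uniroot(function(p) clamp_mean(p) - mu,
                           interval = c(1e-9, 1 - 1e-9), tol = 1e-10)$root
  as.integer(pmin(pmax(stats::rbinom(1, E, p_star), 1L), hi))
}

partition_chain_sizes <- function(m, size_probs) {
  # partition m >= 2 flagged gestures into chains of length 2-4
  sizes <- as.integer(names(size_probs))
  out <- integer(0)
  r <- m
  while (r > max(sizes)) {
    s <- sample(sizes, 1, prob = size_probs)
    if (r - s == 1) s <- if (s < max(sizes)) s + 1L else s - 1L
    out <- c(out, s)
    r <- r - s
  }
  if (r > 0) out <- c(out, r)
  out
}

#' Generate gesture events with planted effects
#'
#' Builds the full event table for every focal individual. Gesture counts
#' follow a Poisson law sized by the species' focal-bout design; recipients
#' are sampled within each dyad's planted repertoire; gesture types follow
#' a Zipf frequency law within each dyad's planted type set; sequences are
#' laid down as chains of 2-4 repetitions within 5 s (singletons spaced
#' more than 5 s apart), attention follows the age/modality logistic model
#' and responses the age/sequence/attention logistic model described in
#' [synthetic_config()].
#'
#' @param individuals individuals table.
#' @param cfg a [synthetic_config()].
#' @param seed integer seed.
#' @param affinities,scans optional precomputed pieces (derived from `seed`
#'   when omitted).
#' @return A list: `events` (data frame) and `truth` (planted parameters
#'   and realized latent quantities for recovery tests).
#' @export
generate_gestures <- function(individuals, cfg, seed, affinities = NULL,
                              scans = NULL) {
  if (is.null(affinities)) affinities <- generate_affinities(individuals, cfg, seed)
  if (is.null(scans)) scans <- generate_scans(individuals, cfg, seed, affinities)

  ## realized social indices (the same quantities the pipeline estimates)
  d_tmp <- gesture_dataset(
    individuals,
    data.frame(event_id = character(), session_id = character(),
               time_s = numeric(), sender_id = character(),
               recipient_id = character(), gesture_type = character(),
               modality = character(), recipient_attentive = character(),
               responded = character(), context = character(),
               sequence_id = character(), stringsAsFactors = FALSE),
    scans, cfg$ethogram)
  indices <- sociality_indices(d_tmp)

  set.seed(substream_seed(seed, "gestures"))
  ind <- individuals
  n_ind <- nrow(ind)
  z_age <- z_standardize(ind$age_years, "age_years")
  cent <- indices$centrality$centrality[
    match(ind$individual_id, indices$centrality$individual_id)]
  z_cent <- z_standardize(cent, "centrality")
  names(z_age) <- names(z_cent) <- ind$individual_id
  sp_of <- stats::setNames(ind$species, ind$individual_id)

  ## per-individual planted probabilities
  p_att_vis <- stats::plogis(cfg$attention_intercept[sp_of] +
                               cfg$visual_effect_attention +
                               (cfg$beta_age_attention +
                                  cfg$beta_age_attention_visual) * z_age)
  p_att_nonvis <- stats::plogis(cfg$attention_intercept[sp_of] +
                                  cfg$beta_age_attention * z_age)
  p_seq <- stats::plogis(cfg$sequence_intercept[sp_of] +
                           cfg$beta_age_seq * z_age +
                           cfg$beta_centrality_seq * z_cent)
  names(p_att_vis) <- names(p_att_nonvis) <- names(p_seq) <- ind$individual_id

  bonds <- indices$bonds
  sp_dyad <- sp_of[bonds$id1]
  E_dyad <- vapply(sp_dyad, function(s) ethogram_size(cfg$ethogram, s), 1L)
  dkey <- paste(bonds$id1, bonds$id2)
  E_of_dyad <- stats::setNames(E_dyad, dkey)

  ## preferred context per gesture type (round-robin within species)
  pref_ctx <- list()
  for (sp in ethogram_species(cfg$ethogram)) {
    ty <- ethogram_types(cfg$ethogram, sp)
    pref_ctx[[sp]] <- stats::setNames(
      rep_len(cfg$contexts, length(ty)), ty)
  }

  alook <- affinity_lookup(affinities)

  ## pass 1: per-sender event counts, sequence flags, units
  sender_units <- list()   # per sender: integer vector of unit sizes
  n_events <- stats::setNames(integer(n_ind), ind$individual_id)
  n_flagged <- stats::setNames(integer(n_ind), ind$individual_id)
  for (i in seq_len(n_ind)) {
    id <- ind$individual_id[i]
    sp <- ind$species[i]
    ses <- cfg$sessions[[sp]]
    lambda <- cfg$gesture_rate_per_min[sp] * ses$n_sessions *
      ses$session_length_s / 60
    N <- stats::rpois(1, lambda)
    if (N == 0) {
      sender_units[[id]] <- integer(0)
      next
    }
    m <- stats::rbinom(1, N, p_seq[id])
    if (m == 1) {
      # single flagged gesture cannot form a chain; promote or demote one
      # event with equal probability (mean-preserving)
      m <- if (N == 1) 0L else if (stats::runif(1) < 0.5) 0L else 2L
    }
    chain_sizes <- if (m >= 2) partition_chain_sizes(m, cfg$chain_length_probs)
      else integer(0)
    units <- c(chain_sizes, rep(1L, N - m))
    sender_units[[id]] <- units[sample.int(length(units))]
    n_events[id] <- N
    n_flagged[id] <- m
  }

  ## pass 2: allocate units to recipients purely by affinity, then paint
  ## each dyad's planted type set onto its realized units. Because
  ## allocation never looks at the planted repertoire, a dyad's gesture
  ## count carries no information about its planted type count beyond what
  ## the social covariates explain. The number of distinct types a dyad can
  ## display is physically clamped between 1 (it exchanged a gesture) and
  ## its unit count; the type-count draw is therefore mean-matched: the
  ## draw probability is solved per dyad so that the clamped draw's
  ## expectation equals the planted mean E * plogis(d0 + beta * z_bond),
  ## keeping the repertoire models' conditional mean correctly specified
  ## (the binomial GLM point estimates depend on the mean function only).
  unit_rows <- list()
  dyad_units_by_g <- list()
  for (g in unique(ind$group_id)) {
    members <- ind$individual_id[ind$group_id == g]
    units_g <- list()
    dyad_units <- list()  # dyad key -> indices into units_g
    for (s in members) {
      mates <- setdiff(members, s)
      w <- exp(cfg$recipient_affinity_scale * alook[dyad_key(s, mates)])
      for (u in sender_units[[s]]) {
        r <- if (length(mates) == 1) mates else sample(mates, 1, prob = w)
        units_g[[length(units_g) + 1]] <- list(
          sender = s, recipient = r, size = u, type = NA_character_)
        k <- dyad_key(s, r)
        dyad_units[[k]] <- c(dyad_units[[k]], length(units_g))
      }
    }
    unit_rows[[g]] <- units_g
    dyad_units_by_g[[g]] <- dyad_units
  }

  ## planted dyadic repertoire: the models (and the bond z-score) consider
  ## only dyads observed interacting, so the planted conditional mean
  ## E_species * plogis(d0 + beta_bond * z_bond) is laid down over exactly
  ## that set
  interacting <- dkey[dkey %in% unlist(lapply(dyad_units_by_g, names))]
  z_bond_all <- stats::setNames(rep(NA_real_, nrow(bonds)), dkey)
  bv <- bonds$bond[match(interacting, dkey)]
  # degenerate bond distributions (a single interacting dyad, identical or
  # missing bonds) carry no bond contrast: plant at the intercept
  if (sum(is.finite(bv)) >= 2 && stats::sd(bv, na.rm = TRUE) > 0) {
    bv[!is.finite(bv)] <- mean(bv[is.finite(bv)])
    z_bond_all[interacting] <- z_standardize(bv, "bond")
  } else {
    z_bond_all[interacting] <- 0
  }
  d0 <- stats::setNames(cfg$dyad_repertoire_intercept[sp_dyad], dkey)
  p_rep <- stats::plogis(d0 + cfg$beta_bond_dyadrep * z_bond_all)
  realized_k <- stats::setNames(rep(0L, nrow(bonds)), dkey)
  for (g in names(unit_rows)) {
    units_g <- unit_rows[[g]]
    dyad_units <- dyad_units_by_g[[g]]
    for (k in names(dyad_units)) {
      idx <- dyad_units[[k]]
      E_sp <- E_of_dyad[k]
      r_d <- draw_clamped_repertoire(E_sp, length(idx), E_sp * p_rep[k])
      sp <- sp_of[units_g[[idx[1]]]$sender]
      types_sp <- ethogram_types(cfg$ethogram, sp)
      w0 <- zipf_weights(length(types_sp), cfg$zipf_exponent)
      ts_used <- sample(types_sp, r_d, prob = w0)
      realized_k[k] <- r_d
      cover <- idx[sample.int(length(idx), r_d)]
      for (j in seq_len(r_d)) units_g[[cover[j]]]$type <- ts_used[j]
      rest <- setdiff(idx, cover)
      if (length(rest) > 0) {
        wt <- zipf_weights(length(ts_used), cfg$zipf_exponent)
        draw <- sample(seq_along(ts_used), length(rest), replace = TRUE,
                       prob = wt)
        for (j in seq_along(rest)) units_g[[rest[j]]]$type <- ts_used[draw[j]]
      }
    }
    unit_rows[[g]] <- units_g
  }

  ## pass 3: lay units out in sessions and emit events
  ev_rows <- list()
  for (g in names(unit_rows)) {
    units_g <- unit_rows[[g]]
    if (length(units_g) == 0) next
    senders <- vapply(units_g, function(u) u$sender, character(1))
    for (s in unique(senders)) {
      su <- units_g[senders == s]
      su <- su[sample(length(su))]
      sp <- sp_of[s]
      ses <- cfg$sessions[[sp]]
      per_session <- max(1L, ceiling(length(su) / ses$n_sessions))
      session_no <- rep(seq_len(ceiling(length(su) / per_session)),
                        each = per_session)[seq_along(su)]
      t_cur <- 0
      last_session <- 0L
      for (ui in seq_along(su)) {
        u <- su[[ui]]
        if (session_no[ui] != last_session) {
          t_cur <- 0
          last_session <- session_no[ui]
        } else {
          t_cur <- t_cur + 6 + stats::rexp(1, 1 / 15)
        }
        ctx_pref <- unname(pref_ctx[[sp]][u$type])
        ctx <- if (stats::runif(1) < cfg$modal_context_prob) ctx_pref
          else sample(setdiff(cfg$contexts, ctx_pref), 1)
        times <- t_cur
        if (u$size > 1) {
          times <- t_cur + cumsum(c(0, stats::runif(u$size - 1, 0.5, 4.5)))
        }
        t_cur <- times[length(times)]
        modality <- ethogram_modality(cfg$ethogram, sp, u$type)
        p_att <- if (modality == "visual") p_att_vis[s] else p_att_nonvis[s]
        att <- unname(ifelse(stats::runif(u$size) < cfg$unknown_rate, "unknown",
                             ifelse(stats::runif(u$size) < p_att, "true", "false")))
        ev_rows[[length(ev_rows) + 1]] <- data.frame(
          session_id = sprintf("%s_f%03d", s, session_no[ui]),
          time_s = round(times, 1),
          sender_id = s, recipient_id = u$recipient,
          gesture_type = u$type, modality = modality,
          recipient_attentive = att,
          responded = NA_character_,
          context = ctx,
          planted_in_sequence = u$size > 1,
          stringsAsFactors = FALSE)
      }
    }
  }
  ev <- do.call(rbind, ev_rows)
  rownames(ev) <- NULL

  ## pass 4: responses planted on realized sequence/attention proportions
  seq_prop <- n_flagged / pmax(n_events, 1L)
  att_prop <- vapply(ind$individual_id, function(id) {
    sel <- ev$sender_id == id & ev$modality == "visual" &
      ev$recipient_attentive != "unknown"
    if (!any(sel)) return(unname(p_att_vis[id]))
    mean(ev$recipient_attentive[sel] == "true")
  }, numeric(1))
  r0 <- cfg$response_intercept[sp_of] -
    (cfg$beta_seq_response * cfg$response_seq_center +
       cfg$beta_attention_response * cfg$response_att_center)
  names(r0) <- ind$individual_id
  eta_resp <- r0[ev$sender_id] +
    cfg$beta_age_response * z_age[ev$sender_id] +
    cfg$beta_seq_response * seq_prop[ev$sender_id] +
    cfg$beta_attention_response * att_prop[ev$sender_id]
  p_resp <- stats::plogis(eta_resp)
  ev$responded <- ifelse(stats::runif(nrow(ev)) < cfg$unknown_rate, "unknown",
                         ifelse(stats::runif(nrow(ev)) < p_resp, "true", "false"))
  ev <- ev[order(ev$sender_id, ev$session_id, ev$time_s), , drop = FALSE]
  ev$event_id <- sprintf("e%06d", seq_len(nrow(ev)))
  ev$sequence_id <- ""
  planted_flags <- ev$planted_in_sequence
  ev$planted_in_sequence <- NULL
  ev <- ev[, c("event_id", "session_id", "time_s", "sender_id",
               "recipient_id", "gesture_type", "modality",
               "recipient_attentive", "responded", "context", "sequence_id")]
  rownames(ev) <- NULL

  truth <- list(
    betas = cfg[grep("^beta_", names(cfg))],
    intercepts = cfg[c("attention_intercept", "visual_effect_attention",
                       "sequence_intercept", "response_intercept",
                       "dyad_repertoire_intercept",
                       "response_seq_center", "response_att_center")],
    z_age = z_age, z_centrality = z_cent, centrality = stats::setNames(cent, ind$individual_id),
    z_bond = z_bond_all,
    dyad_repertoire_mean = stats::setNames(unname(E_dyad * p_rep), dkey),
    dyad_repertoire = realized_k,
    p_seq = p_seq, seq_prop = seq_prop, att_prop = att_prop,
    planted_in_sequence = stats::setNames(planted_flags, ev$event_id),
    affinities = affinities)
  list(events = ev, truth = truth)
}

#' Generate a complete synthetic dataset
#'
#' Bundles [generate_population()], [generate_affinities()],
#' [generate_scans()] and [generate_gestures()] under one seed; the result
#' passes [validate_dataset()] with zero violations and carries the
#' ground-truth ledger of all planted parameters.
#'
#' @param cfg a [synthetic_config()].
#' @param seed integer seed; the single source of randomness.
#' @return A [gesture_dataset()] with an extra `truth` element.
#' @examples
#' d <- generate_dataset(synthetic_config(groups = data.frame(
#'   group_id = "g1", species = "siamang", size = 4)), seed = 1)
#' d
#' @export
generate_dataset <- function(cfg, seed) {
  validate_config(cfg)
  individuals <- generate_population(cfg, seed)
  affinities <- generate_affinities(individuals, cfg, seed)
  scans <- generate_scans(individuals, cfg, seed, affinities)
  gg <- generate_gestures(individuals, cfg, seed, affinities, scans)
  d <- gesture_dataset(individuals, gg$events, scans, cfg$ethogram)
  d$truth <- gg$truth
  d
}
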