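# Parameter-recovery utilities: run the analysis stages in memory on a
# synthetic dataset and pull out the coefficients that carry planted
# effects, for recovery and null-calibration studies.

#' Map of planted effects to suite coefficients
#'
#' Where each planted generator coefficient should reappear in the fitted
#' model suite: the configuration field, the model and the coefficient
#' term name.
#'
#' @return Data frame with `effect`, `model`, `term`.
#' @export
planted_effect_map <- function() {
  data.frame(
    effect = c("beta_age_attention", "beta_age_attention_visual",
               "beta_bond_dyadrep", "beta_age_seq", "beta_centrality_seq",
               "beta_age_response", "beta_seq_response",
               "beta_attention_response"),
    model = c("M2-Ind", "M2-Ind", "M1-Dyad", "M4-Ind", "M4-Ind",
              "M5-Ind", "M5-Ind", "M5-Ind"),
    term = c("z_age", "modalityvisual:z_age", "z_bond", "z_age",
             "z_centrality", "z_age", "seq_prop", "att_visual_prop"),
    stringsAsFactors = FALSE)
}

#' Run the analysis stages in memory
#'
#' Generates (or takes) a dataset, segments sequences, computes sociality
#' indices and metrics, and fits the model suite, without writing any
#' files. The in-memory core of [run_pipeline()], convenient for
#' simulation studies.
#'
#' @param d a [gesture_dataset()], or `NULL` to generate one from `cfg`
#'   and `seed`.
#' @param cfg a [synthetic_config()] used when `d` is `NULL`.
#' @param seed integer seed.
#' @param boot,kfold passed to [run_model_suite()].
#' @param gap_s,min_count,include_singletons stage parameters.
#' @return A list: `dataset`, `events`, `indices`, `ind_table`,
#'   `dy_table`, `suite`, `summary`.
#' @export
analyze_dataset <- function(d = NULL, cfg = synthetic_config(), seed = 1L,
                            boot = 0L, kfold = 0L, gap_s = 5.0,
                            min_count = 2L, include_singletons = FALSE) {
  if (is.null(d)) d <- generate_dataset(cfg, seed)
  ev <- assign_sequences(d$events, gap_s = gap_s)
  indices <- sociality_indices(d)
  im <- individual_metrics(ev, d$ethogram, d$individuals,
                           min_count, include_singletons)
  dm <- dyad_metrics(ev, indices, d$individuals, d$ethogram,
                     min_count, include_singletons)
  ind_table <- prepare_individual_table(im, indices$centrality)
  dy_table <- prepare_dyad_table(dm)
  suite <- run_model_suite(ind_table, dy_table, boot = boot, kfold = kfold,
                           seed = seed)
  list(dataset = d, events = ev, indices = indices, ind_table = ind_table,
       dy_table = dy_table, suite = suite, summary = summarize_suite(suite))
}

#' Estimate the planted effects from one synthetic dataset
#'
#' Runs [analyze_dataset()] and extracts, for every planted effect, the
#' corresponding fitted coefficient with its 95% interval alongside the
#' planted truth.
#'
#' @param cfg a [synthetic_config()].
#' @param seed integer seed.
#' @param boot bootstrap resamples for dyadic SEs (0 = Fisher SEs).
#' @param analysis optional precomputed [analyze_dataset()] result for this
#'   configuration and seed (avoids refitting).
#' @return Data frame with `effect`, `model`, `term`, `truth`, `estimate`,
#'   `se`, `lower`, `upper`.
#' @export
planted_effect_estimates <- function(cfg = synthetic_config(), seed = 1L,
                                     boot = 0L, analysis = NULL) {
  res <- if (is.null(analysis)) {
    analyze_dataset(cfg = cfg, seed = seed, boot = boot)
  } else {
    analysis
  }
  map <- planted_effect_map()
  rows <- lapply(seq_len(nrow(map)), function(i) {
    fit <- res$suite[[map$model[i]]]$fit
    tab <- fit$coefficients
    j <- match(map$term[i], tab$term)
    data.frame(effect = map$effect[i], model = map$model[i],
               term = map$term[i],
               truth = cfg[[map$effect[i]]],
               estimate = if (is.na(j)) NA_real_ else tab$estimate[j],
               se = if (is.na(j)) NA_real_ else tab$se[j],
               lower = if (is.na(j)) NA_real_ else tab$lower[j],
               upper = if (is.na(j)) NA_real_ else tab$upper[j],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Multi-seed parameter-recovery study
#'
#' Repeats [planted_effect_estimates()] over a set of seeds and summarizes
#' each planted effect: mean estimate, Monte-Carlo standard error of that
#' mean, coverage of the 95% intervals, and the proportion of seeds whose
#' estimate carries the planted sign.
#'
#' @param cfg a [synthetic_config()].
#' @param seeds integer vector of seeds.
#' @return Data frame with one row per planted effect: `effect`, `model`,
#'   `term`, `truth`, `mean_estimate`, `mc_se` (sd of estimates across
#'   seeds divided by sqrt of the number of seeds), `coverage`,
#'   `sign_rate`, `n_seeds`.
#' @export
recover_planted_effects <- function(cfg = synthetic_config(), seeds = 1:50) {
  per_seed <- lapply(seeds, function(s) planted_effect_estimates(cfg, s))
  map <- planted_effect_map()
  rows <- lapply(seq_len(nrow(map)), function(i) {
    est <- vapply(per_seed, function(x) x$estimate[i], numeric(1))
    lo <- vapply(per_seed, function(x) x$lower[i], numeric(1))
    hi <- vapply(per_seed, function(x) x$upper[i], numeric(1))
    truth <- cfg[[map$effect[i]]]
    ok <- is.finite(est)
    data.frame(effect = map$effect[i], model = map$model[i],
               term = map$term[i], truth = truth,
               mean_estimate = mean(est[ok]),
               mc_se = stats::sd(est[ok]) / sqrt(sum(ok)),
               coverage = mean(lo[ok] <= truth & truth <= hi[ok]),
               sign_rate = mean(sign(est[ok]) == sign(truth)),
               n_seeds = sum(ok), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
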