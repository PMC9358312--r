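# Orchestration of the M1-M5 model suite over the metrics tables.

#' Prepare the individual-level modeling table
#'
#' Joins the metrics with centrality, derives the proportion predictors
#' (`rep_prop`, `att_visual_prop`, `seq_prop`) and z-standardizes the
#' continuous predictors and controls (age, centrality, observational
#' effort) across all individuals.
#'
#' @param ind_metrics output of [individual_metrics()].
#' @param centrality the `centrality` table of [sociality_indices()].
#' @return Data frame ready for the individual-level model specs.
#' @export
prepare_individual_table <- function(ind_metrics, centrality) {
  t <- ind_metrics
  t$centrality <- centrality$centrality[
    match(t$individual_id, centrality$individual_id)]
  t$rep_prop <- t$repertoire_used / t$repertoire_possible
  t$att_visual_prop <- ifelse(t$assessed_visual > 0,
                              t$attended_visual / t$assessed_visual, NA_real_)
  t$seq_prop <- ifelse(t$sequence_assessed > 0,
                       t$in_sequence / t$sequence_assessed, NA_real_)
  t$z_age <- z_standardize(t$age_years, "age_years")
  t$z_centrality <- z_standardize(t$centrality, "centrality")
  t$z_effort <- z_standardize(t$n_gestures_observed, "n_gestures_observed")
  t$species <- factor(t$species)
  t$sex <- factor(t$sex)
  t
}

#' Prepare the dyad-level modeling table
#'
#' Restricts to dyads that exchanged at least one gesture (dyads never
#' observed interacting carry no gestural information and are excluded
#' from the dyadic models), derives the dyadic proportion predictors and
#' z-standardizes bond, age difference and observational effort across the
#' included dyads.
#'
#' @param dy_metrics output of [dyad_metrics()].
#' @param interacting_only drop dyads with zero observed gestures
#'   (default `TRUE`).
#' @return Data frame ready for the dyad-level model specs.
#' @export
prepare_dyad_table <- function(dy_metrics, interacting_only = TRUE) {
  t <- dy_metrics
  if (interacting_only) {
    t <- t[t$n_gestures_observed > 0, , drop = FALSE]
    rownames(t) <- NULL
  }
  t$rep_prop <- t$repertoire_used / t$repertoire_possible
  t$att_visual_prop <- ifelse(t$assessed_visual > 0,
                              t$attended_visual / t$assessed_visual, NA_real_)
  t$seq_prop <- ifelse(t$sequence_assessed > 0,
                       t$in_sequence / t$sequence_assessed, NA_real_)
  t$z_bond <- z_standardize(t$bond, "bond")
  t$z_age_difference <- z_standardize(t$age_difference, "age_difference")
  t$z_effort <- z_standardize(t$n_gestures_observed, "n_gestures_observed")
  t$species <- factor(t$species)
  t$sex_combination <- factor(t$sex_combination)
  t
}

to_modality_long <- function(t) {
  # one row per unit and modality, with attended/assessed counts
  long <- rbind(
    transform(t, modality = "visual", attended = t$attended_visual,
              assessed = t$assessed_visual),
    transform(t, modality = "non_visual", attended = t$attended_nonvisual,
              assessed = t$assessed_nonvisual))
  long$modality <- factor(long$modality, levels = c("non_visual", "visual"))
  long
}

prune_terms <- function(terms, data) {
  # drop formula terms involving constant columns (e.g. a single observed
  # species or sex level in a small dataset); record what was dropped
  keep <- vapply(terms, function(tm) {
    vars <- strsplit(tm, ":", fixed = TRUE)[[1]]
    all(vapply(vars, function(v) {
      x <- data[[v]]
      length(unique(x[!is.na(x)])) > 1
    }, TRUE))
  }, TRUE)
  list(terms = terms[keep], dropped = terms[!keep])
}

fit_spec_model <- function(spec, data, terms, label, case_terms = terms) {
  # complete cases are determined by case_terms (the union of the terms of
  # all comparator models) so that nested fits share one response vector
  used_cols <- unique(c(spec$response,
                        unlist(strsplit(case_terms, ":", fixed = TRUE))))
  used_cols <- intersect(used_cols, names(data))
  cc <- stats::complete.cases(data[, used_cols, drop = FALSE])
  if (spec$family == "binomial") {
    cc <- cc & data[[spec$response[2]]] > 0
  }
  d <- data[cc, , drop = FALSE]
  pruned <- prune_terms(terms, d)
  rhs <- stats::reformulate(if (length(pruned$terms) > 0) pruned$terms else "1")
  mf <- stats::model.frame(rhs, d)
  xlev <- lapply(Filter(is.factor, mf), levels)
  X <- stats::model.matrix(rhs, mf)
  aliased <- character(0)
  qr_x <- qr(X)
  if (qr_x$rank < ncol(X)) {
    aliased <- colnames(X)[qr_x$pivot[(qr_x$rank + 1):ncol(X)]]
    X <- X[, setdiff(colnames(X), aliased), drop = FALSE]
  }
  fit <- if (spec$family == "binomial") {
    fit_binomial_glm(d[[spec$response[1]]], d[[spec$response[2]]], X,
                     name = label)
  } else {
    fit_beta_regression(d[[spec$response[1]]], X, name = label)
  }
  fit$data <- d
  fit$rhs <- rhs
  fit$xlev <- xlev
  fit$dropped_terms <- pruned$dropped
  fit$aliased <- aliased
  fit
}

bootstrap_se <- function(spec, data, terms, n_boot, seed) {
  # non-parametric resampling of rows (dyads), refitting the full model
  set.seed(seed)
  est <- NULL
  for (b in seq_len(n_boot)) {
    idx <- sample.int(nrow(data), replace = TRUE)
    fb <- tryCatch(fit_spec_model(spec, data[idx, , drop = FALSE], terms,
                                  label = "boot"),
                   error = function(e) NULL)
    if (is.null(fb)) next
    e <- stats::setNames(fb$coefficients$estimate, fb$coefficients$term)
    est <- if (is.null(est)) t(e) else {
      if (!identical(colnames(est), names(e))) next
      rbind(est, e)
    }
  }
  if (is.null(est) || nrow(est) < 10) return(NULL)
  apply(est, 2, stats::sd)
}

#' Fit the full M1-M5 model suite
#'
#' Fits, for every model spec, the full model plus its control-only (and,
#' where defined, intermediate) comparator, compares them by AIC (and
#' optionally seeded k-fold deviance), and computes species contrasts for
#' full models containing a species term. Dyadic fits can replace their
#' Fisher standard errors with dyad-level non-parametric bootstrap ones.
#'
#' @param ind_table,dy_table prepared tables from
#'   [prepare_individual_table()] and [prepare_dyad_table()].
#' @param specs list of model specs (default [default_model_specs()]).
#' @param boot number of bootstrap resamples for dyad-level standard
#'   errors (0 to keep Fisher SEs).
#' @param kfold folds for cross-validated model comparison (0 to skip).
#' @param seed seed for bootstrap resampling and fold splits.
#' @return A list of class `model_suite`; one element per spec with
#'   `fit` (full model), `fits` (all comparators), `comparison`,
#'   `contrasts` and `notes`.
#' @export
run_model_suite <- function(ind_table, dy_table,
                            specs = default_model_specs(),
                            boot = 0L, kfold = 0L, seed = 1L) {
  results <- list()
  for (spec in specs) {
    data <- switch(spec$level,
                   individual = ind_table,
                   individual_modality = to_modality_long(ind_table),
                   dyad = dy_table,
                   dyad_modality = to_modality_long(dy_table),
                   stop("unknown spec level: ", spec$level))
    for (col in unique(c(spec$response,
                         unlist(strsplit(c(spec$full, spec$control), ":"))))) {
      if (!col %in% names(data)) {
        stop("model ", spec$name, " references missing column: ", col)
      }
    }
    notes <- character(0)
    all_terms <- unique(c(spec$full, spec$intermediate, spec$control))
    full <- fit_spec_model(spec, data, spec$full, paste0(spec$name, "-full"),
                           case_terms = all_terms)
    if (length(full$dropped_terms) > 0) {
      notes <- c(notes, paste0("dropped constant term(s): ",
                               paste(full$dropped_terms, collapse = ", ")))
    }
    fits <- list(control = fit_spec_model(spec, data, spec$control,
                                          paste0(spec$name, "-control"),
                                          case_terms = all_terms))
    if (!is.null(spec$intermediate)) {
      fits$intermediate <- fit_spec_model(spec, data, spec$intermediate,
                                          paste0(spec$name, "-intermediate"),
                                          case_terms = all_terms)
    }
    fits$full <- full
    comparison <- compare_models(fits, kfold = kfold,
                                 seed = substream_seed(seed, spec$name))
    if (boot > 0 && spec$level %in% c("dyad", "dyad_modality")) {
      bse <- bootstrap_se(spec, data, spec$full, boot,
                          substream_seed(seed, paste0(spec$name, "-boot")))
      if (!is.null(bse) &&
          identical(names(bse), full$coefficients$term)) {
        full$coefficients$model_se <- full$coefficients$se
        full$coefficients$se <- unname(bse)
        full$coefficients$lower <- full$coefficients$estimate - 1.96 * bse
        full$coefficients$upper <- full$coefficients$estimate + 1.96 * bse
        notes <- c(notes, sprintf("dyad bootstrap SEs (%d resamples)", boot))
      }
    }
    contrasts <- tryCatch(species_contrasts(full), error = function(e) NULL)
    results[[spec$name]] <- list(spec = spec, fit = full, fits = fits,
                                 comparison = comparison,
                                 contrasts = contrasts, notes = notes)
  }
  structure(results, class = "model_suite")
}

#' @export
print.model_suite <- function(x, ...) {
  cat(sprintf("<model_suite> %d models\n", length(x)))
  for (r in x) {
    best <- r$comparison$model[r$comparison$best][1]
    cat(sprintf("  %-8s n = %3d, AIC(full) = %8.2f, best: %s%s\n",
                r$spec$name, r$fit$n_units, r$fit$aic, best,
                if (!r$fit$converged) " [NOT CONVERGED]" else ""))
  }
  invisible(x)
}

#' Summarize a model suite as the prediction ledger
#'
#' One row per directional prediction (see [prediction_ledger()]): the
#' coefficient with the largest |z| among the prediction's terms, its
#' estimate, 95% interval and sign, whether the full model beat the
#' control-only model by AIC, and whether the prediction is supported
#' (positive estimate, interval excluding zero, full model preferred).
#'
#' @param suite a `model_suite`.
#' @return Data frame with 14 rows.
#' @export
summarize_suite <- function(suite) {
  ledger <- prediction_ledger()
  rows <- lapply(seq_len(nrow(ledger)), function(i) {
    model <- ledger$model[i]
    r <- suite[[model]]
    terms <- strsplit(ledger$terms[i], ",", fixed = TRUE)[[1]]
    tab <- r$fit$coefficients
    tab <- tab[tab$term %in% terms, , drop = FALSE]
    full_preferred <- r$comparison$best[r$comparison$model ==
                                          paste0(ledger$model[i], "-full")]
    if (nrow(tab) == 0) {
      return(data.frame(prediction = ledger$prediction[i], model = model,
                        term = NA_character_, estimate = NA_real_,
                        lower = NA_real_, upper = NA_real_,
                        sign = NA_character_, full_model_preferred = full_preferred,
                        supported = NA, stringsAsFactors = FALSE))
    }
    z <- abs(tab$estimate / tab$se)
    j <- which.max(z)
    est <- tab$estimate[j]
    sig <- tab$lower[j] > 0 | tab$upper[j] < 0
    data.frame(
      prediction = ledger$prediction[i], model = model, term = tab$term[j],
      estimate = est, lower = tab$lower[j], upper = tab$upper[j],
      sign = ifelse(est > 0, "+", "-"),
      full_model_preferred = full_preferred,
      supported = est > 0 & sig & full_preferred,
      stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}
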