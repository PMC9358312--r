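# Complexity and effectiveness metrics feeding models M1-M5.
# All proportions are stored as numerator/denominator pairs; gestures whose
# attention or response could not be assessed ("unknown") are excluded from
# the corresponding denominators.

flexibility_from_stream <- function(types, contexts, min_count = 2L,
                                    include_singletons = FALSE) {
  if (length(types) == 0) return(NA_real_)
  threshold <- if (include_singletons) 1L else as.integer(min_count)
  tab <- table(types)
  qualifying <- names(tab)[tab >= threshold]
  if (length(qualifying) == 0) return(NA_real_)
  p <- vapply(qualifying, function(ty) {
    ctx <- contexts[types == ty]
    # modal-context proportion; on a tie either modal context yields the
    # same (maximal) count, so the proportion is tie-invariant
    max(table(ctx)) / length(ctx)
  }, numeric(1))
  mean(p)
}

#' Gestural flexibility index
#'
#' For each individual and each gesture type produced at least `min_count`
#' times, finds the most common context in which the type was produced and
#' the proportion of that type's occurrences falling in it, then averages
#' these proportions (unweighted) across qualifying types. The index lies
#' in `(0, 1]`: values near 1 mean gestures are context-bound, lower values
#' mean flexible use across contexts. With `include_singletons = TRUE`
#' types observed once also qualify (each contributing a proportion of 1),
#' the alternative scoring sometimes reported alongside the default.
#'
#' Modal-context ties need no tie-break: tied contexts share the maximal
#' count, so the proportion is identical whichever is called modal.
#'
#' @param events events data frame (needs `sender_id`, `gesture_type`,
#'   `context`).
#' @param min_count minimum occurrences for a type to qualify (default 2).
#' @param include_singletons if `TRUE`, qualify all observed types.
#' @return Data frame with `individual_id` and `flexibility` (`NA` when no
#'   type qualifies).
#' @examples
#' ev <- data.frame(sender_id = "A",
#'                  gesture_type = c("a", "a", "a", "a", "b", "b", "c"),
#'                  context = c("play", "play", "play", "groom",
#'                              "play", "play", "groom"))
#' flexibility_index(ev)$flexibility  # mean(3/4, 1) = 0.875
#' @export
flexibility_index <- function(events, min_count = 2L, include_singletons = FALSE) {
  if (!is.numeric(min_count) || length(min_count) != 1 || min_count < 1) {
    stop("min_count must be an integer >= 1")
  }
  senders <- unique(events$sender_id)
  flex <- vapply(senders, function(id) {
    sel <- events$sender_id == id
    flexibility_from_stream(events$gesture_type[sel], events$context[sel],
                            min_count, include_singletons)
  }, numeric(1))
  data.frame(individual_id = senders, flexibility = unname(flex),
             stringsAsFactors = FALSE)
}

count_pairs <- function(ev) {
  # numerator/denominator families for one pooled event stream
  vis <- ev$modality == "visual"
  att_known <- ev$recipient_attentive != "unknown"
  resp_known <- ev$responded != "unknown"
  list(
    repertoire_used = length(unique(ev$gesture_type)),
    attended_visual = sum(vis & att_known & ev$recipient_attentive == "true"),
    assessed_visual = sum(vis & att_known),
    attended_nonvisual = sum(!vis & att_known & ev$recipient_attentive == "true"),
    assessed_nonvisual = sum(!vis & att_known),
    in_sequence = sum(ev$in_sequence),
    sequence_assessed = nrow(ev),
    responded = sum(resp_known & ev$responded == "true"),
    produced = sum(resp_known),
    n_gestures_observed = nrow(ev)
  )
}

#' Individual complexity metrics
#'
#' Computes, per individual, every numerator/denominator pair used by the
#' individual-level models: repertoire size out of the species ethogram,
#' attention accounting split by modality (gestures to attentive recipients
#' out of those whose attentional state could be assessed), sequence use
#' (gestures in chains of length at least two out of all gestures),
#' response elicitation (gestures responded to out of those whose response
#' could be assessed), the contextual [flexibility_index()], and
#' observational effort (total gestures coded for the individual).
#' Individuals with no gestures get zero denominators, not errors.
#'
#' @param events segmented events (from [assign_sequences()]).
#' @param ethogram the species [`ethogram`][default_ethogram].
#' @param individuals individuals data frame.
#' @param min_count,include_singletons passed to [flexibility_index()].
#' @return Data frame with one row per individual: id, species, group, sex,
#'   age, the count pairs above, and `flexibility`.
#' @export
individual_metrics <- function(events, ethogram, individuals,
                               min_count = 2L, include_singletons = FALSE) {
  if (!"in_sequence" %in% names(events)) {
    stop("events must be segmented first; run assign_sequences()")
  }
  flex <- flexibility_index(events, min_count, include_singletons)
  rows <- lapply(seq_len(nrow(individuals)), function(i) {
    id <- individuals$individual_id[i]
    ev <- events[events$sender_id == id, , drop = FALSE]
    cp <- count_pairs(ev)
    data.frame(
      individual_id = id,
      species = individuals$species[i],
      group_id = individuals$group_id[i],
      sex = individuals$sex[i],
      age_years = individuals$age_years[i],
      repertoire_used = cp$repertoire_used,
      repertoire_possible = ethogram_size(ethogram, individuals$species[i]),
      attended_visual = cp$attended_visual,
      assessed_visual = cp$assessed_visual,
      attended_nonvisual = cp$attended_nonvisual,
      assessed_nonvisual = cp$assessed_nonvisual,
      flexibility = flex$flexibility[match(id, flex$individual_id)],
      in_sequence = cp$in_sequence,
      sequence_assessed = cp$sequence_assessed,
      responded = cp$responded,
      produced = cp$produced,
      n_gestures_observed = cp$n_gestures_observed,
      stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

#' Dyadic complexity metrics
#'
#' Pools, for every unordered within-group dyad, the gestures exchanged in
#' either direction and computes the same numerator/denominator families as
#' [individual_metrics()], plus the dyad's bond score, maternal kinship,
#' absolute age difference and sex combination (`FF`/`FM`/`MM`, unordered).
#' Dyadic flexibility uses the pooled event stream under the same
#' `min_count` rule. Dyads that exchanged no gestures carry zero
#' denominators.
#'
#' @param events segmented events (from [assign_sequences()]).
#' @param indices a [sociality_indices()] result.
#' @param individuals individuals data frame.
#' @param ethogram the species [`ethogram`][default_ethogram].
#' @param min_count,include_singletons passed to the flexibility
#'   computation.
#' @return Data frame with one row per within-group dyad.
#' @export
dyad_metrics <- function(events, indices, individuals, ethogram,
                         min_count = 2L, include_singletons = FALSE) {
  if (!"in_sequence" %in% names(events)) {
    stop("events must be segmented first; run assign_sequences()")
  }
  bonds <- indices$bonds
  info <- individuals
  rownames(info) <- info$individual_id
  rows <- lapply(seq_len(nrow(bonds)), function(i) {
    a <- bonds$id1[i]
    b <- bonds$id2[i]
    ev <- events[(events$sender_id == a & events$recipient_id == b) |
                 (events$sender_id == b & events$recipient_id == a), ,
                 drop = FALSE]
    cp <- count_pairs(ev)
    sexes <- sort(c(info[a, "sex"], info[b, "sex"]))
    sp <- info[a, "species"]
    data.frame(
      id1 = a, id2 = b,
      group_id = bonds$group_id[i],
      species = sp,
      bond = bonds$bond[i],
      maternal_kin = bonds$maternal_kin[i],
      age_difference = abs(info[a, "age_years"] - info[b, "age_years"]),
      sex_combination = paste(sexes, collapse = ""),
      repertoire_used = cp$repertoire_used,
      repertoire_possible = ethogram_size(ethogram, sp),
      attended_visual = cp$attended_visual,
      assessed_visual = cp$assessed_visual,
      attended_nonvisual = cp$attended_nonvisual,
      assessed_nonvisual = cp$assessed_nonvisual,
      flexibility = flexibility_from_stream(ev$gesture_type, ev$context,
                                            min_count, include_singletons),
      in_sequence = cp$in_sequence,
      sequence_assessed = cp$sequence_assessed,
      responded = cp$responded,
      produced = cp$produced,
      n_gestures_observed = cp$n_gestures_observed,
      stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

#' Cumulative repertoire (accumulation) curve
#'
#' Running count of distinct gesture types over a group's gestures in
#' coding order (session, then time). The curve is non-decreasing, bounded
#' by the ethogram size, and its final value equals the number of distinct
#' types observed in the group; a plateau well before the end of the stream
#' indicates the group repertoire was sampled to saturation.
#'
#' @param events events data frame.
#' @param group group id (optional when `events` already holds one group).
#' @param individuals individuals table used to resolve each sender's group
#'   (required when `group` is given).
#' @return Data frame with `gestures_coded` (1..n) and `cumulative_types`.
#' @export
accumulation_curve <- function(events, group = NULL, individuals = NULL) {
  ev <- events
  if (!is.null(group)) {
    if (is.null(individuals)) stop("individuals table needed to filter by group")
    members <- individuals$individual_id[individuals$group_id == group]
    ev <- ev[ev$sender_id %in% members, , drop = FALSE]
  }
  ev <- ev[order(ev$session_id, ev$time_s), , drop = FALSE]
  n <- nrow(ev)
  if (n == 0) {
    return(data.frame(gestures_coded = integer(), cumulative_types = integer()))
  }
  cum <- cumsum(!duplicated(ev$gesture_type))
  data.frame(gestures_coded = seq_len(n), cumulative_types = cum)
}

#' Cohen's kappa for coder reliability
#'
#' Chance-corrected agreement between two coders labelling the same items:
#' `kappa = (p_o - p_e) / (1 - p_e)`, with observed agreement `p_o` and
#' chance agreement `p_e` from the product of the marginal label
#' frequencies.
#'
#' @param labels1,labels2 equal-length vectors of categorical codes.
#' @return Kappa in `[-1, 1]`. When both coders assign one identical
#'   constant label (`p_e = 1`) agreement is perfect but chance-correction
#'   is undefined; 1 is returned with a warning.
#' @examples
#' cohen_kappa(c("a", "a", "b"), c("a", "a", "b"))
#' @export
cohen_kappa <- function(labels1, labels2) {
  if (length(labels1) != length(labels2) || length(labels1) < 1) {
    stop("labels1 and labels2 must have equal length >= 1")
  }
  n <- length(labels1)
  levs <- union(unique(labels1), unique(labels2))
  f1 <- as.vector(table(factor(labels1, levels = levs))) / n
  f2 <- as.vector(table(factor(labels2, levels = levs))) / n
  p_o <- mean(labels1 == labels2)
  p_e <- sum(f1 * f2)
  if (abs(1 - p_e) < .Machine$double.eps^0.5) {
    warning("both coders used a single identical label; kappa set to 1")
    return(1.0)
  }
  (p_o - p_e) / (1 - p_e)
}

#' Write metrics tables to disk
#'
#' Writes `individual_metrics.csv`, `dyad_metrics.csv` and one
#' `accumulation_<group>.csv` per group.
#'
#' @param ind_metrics,dy_metrics outputs of [individual_metrics()] and
#'   [dyad_metrics()].
#' @param events segmented events (for the accumulation curves).
#' @param individuals individuals data frame.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_metrics <- function(ind_metrics, dy_metrics, events, individuals, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  utils::write.csv(ind_metrics, file.path(dir, "individual_metrics.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(dy_metrics, file.path(dir, "dyad_metrics.csv"),
                   row.names = FALSE, quote = FALSE)
  for (g in unique(individuals$group_id)) {
    curve <- accumulation_curve(events, g, individuals)
    utils::write.csv(curve, file.path(dir, paste0("accumulation_", g, ".csv")),
                     row.names = FALSE, quote = FALSE)
  }
  invisible(dir)
}
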