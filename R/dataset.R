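#' Gesture observation datasets
#'
#' A `gesture_dataset` bundles the three tables of a focal-animal
#' observation study plus the species ethogram:
#'
#' * `individuals`: one row per study subject (`individual_id`, `species`,
#'   `group_id`, `sex`, `age_years`, `mother_id`).
#' * `events`: one row per coded gesture (`event_id`, `session_id`, `time_s`,
#'   `sender_id`, `recipient_id`, `gesture_type`, `modality`,
#'   `recipient_attentive`, `responded`, `context`, `sequence_id`).
#'   `recipient_attentive` and `responded` take values `"true"`, `"false"`
#'   or `"unknown"`; unknowns are excluded from the corresponding
#'   denominators downstream, never imputed. Times are seconds from the
#'   start of the observation session; sequences and 5-s response windows
#'   never span sessions.
#' * `scans`: one row per proximity scan (`scan_id`, `group_id`, `time_s`,
#'   `focal_id`, `neighbor_ids`), where `neighbor_ids` is a
#'   semicolon-separated list of the individuals within 2 m of the focal
#'   (possibly empty).
#'
#' @param individuals,events,scans data frames with the columns above.
#' @param ethogram an [`ethogram`][default_ethogram] object.
#' @return An object of class `gesture_dataset`.
#' @seealso [read_dataset()], [validate_dataset()], [generate_dataset()]
#' @export
gesture_dataset <- function(individuals, events, scans, ethogram) {
  individuals <- as.data.frame(individuals, stringsAsFactors = FALSE)
  events <- as.data.frame(events, stringsAsFactors = FALSE)
  scans <- as.data.frame(scans, stringsAsFactors = FALSE)
  need <- function(df, cols, what) {
    miss <- setdiff(cols, names(df))
    if (length(miss) > 0) {
      stop(what, " table is missing column(s): ", paste(miss, collapse = ", "))
    }
  }
  need(individuals, c("individual_id", "species", "group_id", "sex",
                      "age_years", "mother_id"), "individuals")
  need(events, c("event_id", "session_id", "time_s", "sender_id",
                 "recipient_id", "gesture_type", "modality",
                 "recipient_attentive", "responded", "context"), "events")
  need(scans, c("scan_id", "group_id", "time_s", "focal_id", "neighbor_ids"),
       "scans")
  if (!"sequence_id" %in% names(events)) events$sequence_id <- ""
  events$sequence_id[is.na(events$sequence_id)] <- ""
  scans$neighbor_ids[is.na(scans$neighbor_ids)] <- ""
  individuals$mother_id[is.na(individuals$mother_id)] <- ""
  # stable sort: session, then time, then original coding order
  events <- events[order(events$session_id, events$time_s), , drop = FALSE]
  rownames(events) <- NULL
  rownames(individuals) <- NULL
  rownames(scans) <- NULL
  structure(list(individuals = individuals, events = events, scans = scans,
                 ethogram = ethogram),
            class = "gesture_dataset")
}

#' @export
print.gesture_dataset <- function(x, ...) {
  cat("<gesture_dataset>\n")
  cat(sprintf("  %d individuals in %d groups (%s)\n",
              nrow(x$individuals), length(unique(x$individuals$group_id)),
              paste(sprintf("%s: %d", names(table(x$individuals$species)),
                            table(x$individuals$species)), collapse = ", ")))
  cat(sprintf("  %d gesture events, %d proximity scans\n",
              nrow(x$events), nrow(x$scans)))
  invisible(x)
}

split_neighbors <- function(neighbor_ids) {
  strsplit(ifelse(neighbor_ids == "", NA_character_, neighbor_ids), ";",
           fixed = TRUE)
}

#' Validate a gesture dataset
#'
#' Checks every structural invariant of the data model and returns the
#' violations as data, one row per problem, rather than raising errors:
#' id uniqueness and cross-references, mother links (existing female in the
#' same dataset), non-negative ages and times, sender distinct from
#' recipient, gesture types and modalities drawn from the sender-species
#' ethogram, categorical levels of attention/response, focal absent from its
#' own neighbour set, scan membership consistent with the group, and the
#' 10-min minimum spacing between scans of the same focal.
#'
#' @param d a [gesture_dataset()].
#' @return A data frame with columns `table`, `row`, `id`, `field`, `rule`
#'   and `message`; zero rows when the dataset is valid.
#' @examples
#' d <- generate_dataset(synthetic_config(groups = data.frame(
#'   group_id = "g1", species = "siamang", size = 4)), seed = 1)
#' nrow(validate_dataset(d))
#' @export
validate_dataset <- function(d) {
  stopifnot(inherits(d, "gesture_dataset"))
  ind <- d$individuals
  ev <- d$events
  sc <- d$scans
  eth <- d$ethogram
  v <- list()
  add <- function(table, row, id, field, rule, message) {
    v[[length(v) + 1]] <<- data.frame(
      table = table, row = as.integer(row), id = as.character(id),
      field = field, rule = rule, message = message,
      stringsAsFactors = FALSE)
  }

  ## individuals
  dup <- which(duplicated(ind$individual_id))
  for (i in dup) add("individuals", i, ind$individual_id[i], "individual_id",
                     "unique_id", "duplicated individual_id")
  bad_sp <- which(!ind$species %in% ethogram_species(eth))
  for (i in bad_sp) add("individuals", i, ind$individual_id[i], "species",
                        "known_species",
                        paste0("species not in ethogram: ", ind$species[i]))
  bad_sex <- which(!ind$sex %in% c("F", "M"))
  for (i in bad_sex) add("individuals", i, ind$individual_id[i], "sex",
                         "sex_level", paste0("sex must be F or M, got ", ind$sex[i]))
  bad_age <- which(!is.finite(ind$age_years) | ind$age_years < 0)
  for (i in bad_age) add("individuals", i, ind$individual_id[i], "age_years",
                         "age_nonnegative", "age_years must be a non-negative real")
  has_mom <- which(ind$mother_id != "")
  for (i in has_mom) {
    m <- match(ind$mother_id[i], ind$individual_id)
    if (is.na(m)) {
      add("individuals", i, ind$individual_id[i], "mother_id",
          "mother_exists", paste0("mother_id not in dataset: ", ind$mother_id[i]))
    } else if (ind$sex[m] != "F") {
      add("individuals", i, ind$individual_id[i], "mother_id",
          "mother_female", paste0("mother ", ind$mother_id[i], " is not female"))
    }
  }

  ## events
  dup <- which(duplicated(ev$event_id))
  for (i in dup) add("events", i, ev$event_id[i], "event_id", "unique_id",
                     "duplicated event_id")
  sender_row <- match(ev$sender_id, ind$individual_id)
  recip_row <- match(ev$recipient_id, ind$individual_id)
  for (i in which(is.na(sender_row)))
    add("events", i, ev$event_id[i], "sender_id", "known_individual",
        paste0("unknown sender_id: ", ev$sender_id[i]))
  for (i in which(is.na(recip_row)))
    add("events", i, ev$event_id[i], "recipient_id", "known_individual",
        paste0("unknown recipient_id: ", ev$recipient_id[i]))
  for (i in which(ev$sender_id == ev$recipient_id))
    add("events", i, ev$event_id[i], "recipient_id", "self_directed",
        "sender_id equals recipient_id")
  ok <- !is.na(sender_row) & !is.na(recip_row)
  for (i in which(ok & ind$group_id[sender_row] != ind$group_id[recip_row]))
    add("events", i, ev$event_id[i], "recipient_id", "same_group",
        "sender and recipient belong to different groups")
  for (i in which(!is.na(sender_row))) {
    sp <- ind$species[sender_row[i]]
    types <- ethogram_types(eth, sp)
    if (!ev$gesture_type[i] %in% types) {
      add("events", i, ev$event_id[i], "gesture_type", "ethogram_type",
          paste0("gesture_type '", ev$gesture_type[i],
                 "' not in the ", sp, " ethogram"))
    } else if (ev$modality[i] != ethogram_modality(eth, sp, ev$gesture_type[i])) {
      add("events", i, ev$event_id[i], "modality", "ethogram_modality",
          paste0("modality disagrees with ethogram for ", ev$gesture_type[i]))
    }
  }
  for (i in which(!is.finite(ev$time_s) | ev$time_s < 0))
    add("events", i, ev$event_id[i], "time_s", "time_nonnegative",
        "time_s must be a non-negative real")
  for (i in which(!ev$recipient_attentive %in% c("true", "false", "unknown")))
    add("events", i, ev$event_id[i], "recipient_attentive", "ternary_level",
        "recipient_attentive must be true/false/unknown")
  for (i in which(!ev$responded %in% c("true", "false", "unknown")))
    add("events", i, ev$event_id[i], "responded", "ternary_level",
        "responded must be true/false/unknown")
  for (i in which(is.na(ev$context) | ev$context == ""))
    add("events", i, ev$event_id[i], "context", "context_nonempty",
        "context must be non-empty")

  ## scans
  dup <- which(duplicated(sc$scan_id))
  for (i in dup) add("scans", i, sc$scan_id[i], "scan_id", "unique_id",
                     "duplicated scan_id")
  focal_row <- match(sc$focal_id, ind$individual_id)
  for (i in which(is.na(focal_row)))
    add("scans", i, sc$scan_id[i], "focal_id", "known_individual",
        paste0("unknown focal_id: ", sc$focal_id[i]))
  for (i in which(!is.na(focal_row) & ind$group_id[focal_row] != sc$group_id))
    add("scans", i, sc$scan_id[i], "group_id", "focal_in_group",
        "focal_id does not belong to group_id")
  nb <- split_neighbors(sc$neighbor_ids)
  for (i in seq_len(nrow(sc))) {
    ids <- nb[[i]]
    if (length(ids) == 1 && is.na(ids)) next
    if (sc$focal_id[i] %in% ids)
      add("scans", i, sc$scan_id[i], "neighbor_ids", "focal_not_neighbor",
          "focal_id appears in its own neighbour set")
    unk <- setdiff(ids, ind$individual_id)
    if (length(unk) > 0)
      add("scans", i, sc$scan_id[i], "neighbor_ids", "known_individual",
          paste0("unknown neighbour id(s): ", paste(unk, collapse = ";")))
    inrow <- match(setdiff(ids, unk), ind$individual_id)
    out <- which(ind$group_id[inrow] != sc$group_id[i])
    if (length(out) > 0)
      add("scans", i, sc$scan_id[i], "neighbor_ids", "neighbor_in_group",
          paste0("neighbour(s) outside group: ",
                 paste(ind$individual_id[inrow][out], collapse = ";")))
  }
  for (i in which(!is.finite(sc$time_s) | sc$time_s < 0))
    add("scans", i, sc$scan_id[i], "time_s", "time_nonnegative",
        "time_s must be a non-negative real")
  # scans of the same focal must be >= 600 s apart
  if (nrow(sc) > 0) {
    for (f in unique(sc$focal_id)) {
      idx <- which(sc$focal_id == f)
      t <- sort(sc$time_s[idx])
      if (length(t) > 1 && any(diff(t) < 600 - 1e-9)) {
        bad <- idx[order(sc$time_s[idx])][which(diff(t) < 600 - 1e-9) + 1]
        for (i in bad)
          add("scans", i, sc$scan_id[i], "time_s", "scan_spacing",
              paste0("scans of focal ", f, " less than 600 s apart"))
      }
    }
  }

  if (length(v) == 0) {
    return(data.frame(table = character(), row = integer(), id = character(),
                      field = character(), rule = character(),
                      message = character(), stringsAsFactors = FALSE))
  }
  do.call(rbind, v)
}
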