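#' Read a gesture dataset from delimited text files
#'
#' Reads the three study tables (comma-separated, UTF-8, header row, ids
#' unquoted), assembles a [gesture_dataset()], sorts events by
#' `(session_id, time_s)` and validates every invariant. Any violation
#' aborts with a message naming the offending rows; use
#' [validate_dataset()] directly to obtain violations as data.
#'
#' @param individuals_path,events_path,scans_path paths to CSV files.
#' @param ethogram an [`ethogram`][default_ethogram] object, or a path to an
#'   ethogram YAML file.
#' @return A validated `gesture_dataset`.
#' @export
read_dataset <- function(individuals_path, events_path, scans_path, ethogram) {
  for (p in c(individuals_path, events_path, scans_path)) {
    if (!file.exists(p)) stop("input file not found: ", p)
  }
  if (is.character(ethogram)) ethogram <- read_ethogram(ethogram)
  read1 <- function(path) {
    utils::read.csv(path, stringsAsFactors = FALSE, colClasses = NA,
                    encoding = "UTF-8")
  }
  ind <- read1(individuals_path)
  ev <- read1(events_path)
  sc <- read1(scans_path)
  if ("mother_id" %in% names(ind)) ind$mother_id <- as.character(ind$mother_id)
  if ("neighbor_ids" %in% names(sc)) sc$neighbor_ids <- as.character(sc$neighbor_ids)
  if ("sequence_id" %in% names(ev)) ev$sequence_id <- as.character(ev$sequence_id)
  d <- gesture_dataset(ind, ev, sc, ethogram)
  viol <- validate_dataset(d)
  if (nrow(viol) > 0) {
    shown <- utils::head(viol, 10)
    stop("dataset validation failed with ", nrow(viol), " violation(s):\n",
         paste(sprintf("  [%s row %d, id %s] %s: %s", shown$table, shown$row,
                       shown$id, shown$rule, shown$message), collapse = "\n"),
         if (nrow(viol) > 10) "\n  ..." else "")
  }
  d
}

#' Write a gesture dataset to delimited text files
#'
#' Writes `individuals.csv`, `events.csv`, `scans.csv` and `ethogram.yaml`
#' into `dir`. The dialect is fixed (comma-separated, UTF-8, header row,
#' no quoting) so that [read_dataset()] round-trips a dataset field for
#' field.
#'
#' @param d a [gesture_dataset()].
#' @param dir output directory, created if absent.
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(d, dir) {
  stopifnot(inherits(d, "gesture_dataset"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write1 <- function(df, name) {
    utils::write.csv(df, file.path(dir, name), row.names = FALSE,
                     quote = FALSE, fileEncoding = "UTF-8")
  }
  write1(d$individuals, "individuals.csv")
  write1(d$events, "events.csv")
  write1(d$scans, "scans.csv")
  write_ethogram(d$ethogram, file.path(dir, "ethogram.yaml"))
  invisible(dir)
}
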