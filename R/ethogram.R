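#' Species ethograms
#'
#' An ethogram maps each gesture type of a species to its modality
#' (`"visual"` or `"non_visual"`). Gesture types are flat labels: structural
#' variants (one hand vs. two hands, left vs. right) are deliberately not
#' distinguished, which keeps per-species repertoires small enough for
#' accumulation curves to saturate under realistic observational effort.
#'
#' The default ethogram has 18 types for chimpanzees, 17 for orangutans and
#' 14 for siamangs, with abstract labels (`chi01` ... `sia14`); roughly 60%
#' of each species' types are visual.
#'
#' @param sizes named integer vector of ethogram sizes per species.
#' @param visual_fraction fraction of types labelled visual (rounded).
#' @return An object of class `ethogram`: a named list, one element per
#'   species, each a named character vector mapping gesture type to modality.
#' @examples
#' eth <- default_ethogram()
#' lengths(eth)
#' @export
default_ethogram <- function(sizes = c(chimpanzee = 18L, orangutan = 17L, siamang = 14L),
                             visual_fraction = 0.6) {
  stopifnot(length(sizes) >= 1, !is.null(names(sizes)), all(sizes >= 1))
  eth <- lapply(seq_along(sizes), function(i) {
    sp <- names(sizes)[i]
    n <- as.integer(sizes[[i]])
    types <- sprintf("%s%02d", substr(sp, 1, 3), seq_len(n))
    n_vis <- max(1L, round(visual_fraction * n))
    modality <- rep("non_visual", n)
    modality[seq_len(n_vis)] <- "visual"
    stats::setNames(modality, types)
  })
  names(eth) <- names(sizes)
  structure(eth, class = "ethogram")
}

#' Read an ethogram from a YAML file
#'
#' The file maps species to `{gesture_type: modality}` entries, e.g.
#' ```yaml
#' chimpanzee:
#'   chi01: visual
#'   chi02: non_visual
#' ```
#'
#' @param path path to a YAML file.
#' @return An `ethogram` object.
#' @export
read_ethogram <- function(path) {
  if (!file.exists(path)) stop("ethogram file not found: ", path)
  raw <- yaml::read_yaml(path)
  eth <- lapply(raw, function(x) unlist(x))
  bad <- unlist(lapply(eth, function(x) x[!x %in% c("visual", "non_visual")]))
  if (length(bad) > 0) {
    stop("invalid modality label(s) in ethogram: ", paste(unique(bad), collapse = ", "))
  }
  structure(eth, class = "ethogram")
}

#' Write an ethogram to a YAML file
#'
#' @param ethogram an `ethogram` object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_ethogram <- function(ethogram, path) {
  stopifnot(inherits(ethogram, "ethogram"))
  yaml::write_yaml(lapply(ethogram, as.list), path)
  invisible(path)
}

#' @export
print.ethogram <- function(x, ...) {
  cat("<ethogram> ", length(x), " species\n", sep = "")
  for (sp in names(x)) {
    n_vis <- sum(x[[sp]] == "visual")
    cat(sprintf("  %-12s %2d types (%d visual, %d non-visual)\n",
                sp, length(x[[sp]]), n_vis, length(x[[sp]]) - n_vis))
  }
  invisible(x)
}

ethogram_species <- function(ethogram) names(ethogram)

ethogram_types <- function(ethogram, species) {
  if (!species %in% names(ethogram)) stop("species not in ethogram: ", species)
  names(ethogram[[species]])
}

ethogram_modality <- function(ethogram, species, types) {
  unname(ethogram[[species]][types])
}

ethogram_size <- function(ethogram, species) length(ethogram[[species]])
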