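#' Build a weighted proximity matrix for one group
#'
#' Counts, for every pair of group members, the number of scans in which the
#' two were within 2 m of each other: `C[i, j]` accumulates scans where `i`
#' was the focal and `j` among its neighbours, plus scans where `j` was the
#' focal and `i` among its neighbours. The per-individual totals `n_i` count
#' the scans in which each individual was the focal subject.
#'
#' @param scans a scans data frame (see [gesture_dataset()]) or a
#'   `gesture_dataset`.
#' @param group group id; the matrix spans all individuals of that group
#'   (for a `gesture_dataset`), or all ids appearing in the group's scans.
#' @param individuals optional individuals table used to fix the member set
#'   when `scans` is a plain data frame.
#' @return An object of class `proximity_matrix`: list with `group_id`,
#'   symmetric integer matrix `C` (zero diagonal), named vector `n_focal`,
#'   and `n_scans`. A group with zero scans yields an all-zero matrix with
#'   `empty = TRUE` rather than an error.
#' @export
build_proximity_matrix <- function(scans, group, individuals = NULL) {
  if (inherits(scans, "gesture_dataset")) {
    individuals <- scans$individuals
    scans <- scans$scans
  }
  if (!is.null(individuals)) {
    members <- individuals$individual_id[individuals$group_id == group]
  } else {
    sc_g <- scans[scans$group_id == group, , drop = FALSE]
    members <- sort(unique(c(sc_g$focal_id,
                             unlist(split_neighbors(sc_g$neighbor_ids)))))
    members <- members[!is.na(members)]
  }
  if (length(members) == 0) stop("group has no members: ", group)
  sc <- scans[scans$group_id == group, , drop = FALSE]
  k <- length(members)
  C <- matrix(0L, k, k, dimnames = list(members, members))
  n_focal <- stats::setNames(integer(k), members)
  if (nrow(sc) > 0) {
    nb <- split_neighbors(sc$neighbor_ids)
    for (i in seq_len(nrow(sc))) {
      f <- sc$focal_id[i]
      n_focal[f] <- n_focal[f] + 1L
      ids <- nb[[i]]
      if (length(ids) == 1 && is.na(ids)) next
      for (j in ids) {
        C[f, j] <- C[f, j] + 1L
        C[j, f] <- C[j, f] + 1L
      }
    }
  }
  structure(list(group_id = group, C = C, n_focal = n_focal,
                 n_scans = nrow(sc), empty = nrow(sc) == 0),
            class = "proximity_matrix")
}

#' @export
print.proximity_matrix <- function(x, ...) {
  cat(sprintf("<proximity_matrix> group %s: %d individuals, %d scans%s\n",
              x$group_id, nrow(x$C), x$n_scans,
              if (isTRUE(x$empty)) " (empty)" else ""))
  invisible(x)
}

connected_components <- function(A) {
  # components of the graph with an edge wherever A > 0 (simple BFS)
  n <- nrow(A)
  comp <- rep(NA_integer_, n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (!is.na(comp[s])) next
    cur <- cur + 1L
    queue <- s
    comp[s] <- cur
    while (length(queue) > 0) {
      v <- queue[1]
      queue <- queue[-1]
      nbrs <- which(A[v, ] > 0 & is.na(comp))
      comp[nbrs] <- cur
      queue <- c(queue, nbrs)
    }
  }
  comp
}

#' Eigenvector centrality by power iteration
#'
#' Computes the leading eigenvector of the weighted proximity matrix on each
#' connected component separately, by power iteration on the diagonally
#' shifted matrix `C + I` (same eigenvectors; the shift rules out the
#' oscillation a bipartite component would otherwise cause). Entries are
#' non-negative and rescaled so the maximum within each component is 1;
#' individuals with no proximity partners (isolates) receive centrality 0,
#' marking the least socially integrated animals.
#'
#' @param m a `proximity_matrix` (or a bare symmetric non-negative matrix).
#' @param tol convergence tolerance on the max-norm change per iteration.
#' @param max_iter maximum number of power iterations.
#' @return A data frame with `individual_id`, `centrality` in `[0, 1]` and
#'   `component` (integer label; 0 for isolates).
#' @examples
#' C <- matrix(c(0, 5, 5, 0), 2, 2, dimnames = list(c("A", "B"), c("A", "B")))
#' eigenvector_centrality(C)$centrality
#' @export
eigenvector_centrality <- function(m, tol = 1e-10, max_iter = 10000L) {
  C <- if (inherits(m, "proximity_matrix")) m$C else as.matrix(m)
  if (nrow(C) != ncol(C) || any(C < 0) || max(abs(C - t(C))) > 1e-12) {
    stop("proximity matrix must be symmetric and non-negative")
  }
  ids <- rownames(C)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(C)))
  n <- nrow(C)
  cent <- stats::setNames(numeric(n), ids)
  comp_label <- stats::setNames(integer(n), ids)
  if (n == 0) {
    return(data.frame(individual_id = character(), centrality = numeric(),
                      component = integer(), stringsAsFactors = FALSE))
  }
  comp <- connected_components(C)
  lab <- 0L
  for (cc in sort(unique(comp))) {
    idx <- which(comp == cc)
    if (length(idx) == 1 || sum(C[idx, idx]) == 0) next  # isolate: centrality 0
    lab <- lab + 1L
    comp_label[idx] <- lab
    M <- C[idx, idx, drop = FALSE] + diag(length(idx))
    v <- rep(1 / sqrt(length(idx)), length(idx))
    converged <- FALSE
    for (it in seq_len(max_iter)) {
      w <- as.vector(M %*% v)
      w <- w / sqrt(sum(w^2))
      if (max(abs(w - v)) < tol) {
        v <- w
        converged <- TRUE
        break
      }
      v <- w
    }
    if (!converged) {
      stop(sprintf("power iteration did not converge after %d iterations (residual %.3e)",
                   max_iter, max(abs(w - v))))
    }
    v <- abs(v)  # Perron vector of a non-negative matrix, up to global sign
    cent[idx] <- v / max(v)
  }
  data.frame(individual_id = ids, centrality = unname(cent),
             component = unname(comp_label), stringsAsFactors = FALSE)
}

#' Dyadic bond index (normalized proximity ratio)
#'
#' For each unordered within-group dyad, the raw index is the number of
#' scans in which the two individuals were in proximity divided by the total
#' number of focal observations of the two (`C[i,j] / (n_i + n_j)`). Raw
#' ratios are then divided by their group mean, giving bond scores in
#' `[0, Inf)` whose group mean is exactly 1: values below 1 mark weaker than
#' average relationships, values above 1 stronger ones.
#'
#' @param m a `proximity_matrix`.
#' @return A data frame with `id1`, `id2` (id1 < id2), `count`, `raw_ratio`
#'   and `bond`. Dyads with `n_i + n_j = 0` have `NA` raw ratio and bond;
#'   if the group mean of raw ratios is zero (or no dyad is assessable) all
#'   bonds are `NA` with a warning.
#' @examples
#' m <- structure(list(group_id = "g",
#'   C = matrix(c(0, 4, 2, 4, 0, 0, 2, 0, 0), 3, 3,
#'              dimnames = list(c("A", "B", "C"), c("A", "B", "C"))),
#'   n_focal = c(A = 10, B = 10, C = 10), n_scans = 30, empty = FALSE),
#'   class = "proximity_matrix")
#' dyadic_bond_index(m)$bond
#' @export
dyadic_bond_index <- function(m) {
  stopifnot(inherits(m, "proximity_matrix"))
  ids <- rownames(m$C)
  if (length(ids) < 2) {
    return(data.frame(id1 = character(), id2 = character(), count = integer(),
                      raw_ratio = numeric(), bond = numeric(),
                      stringsAsFactors = FALSE))
  }
  pairs <- utils::combn(ids, 2)
  id1 <- pairs[1, ]
  id2 <- pairs[2, ]
  count <- mapply(function(a, b) m$C[a, b], id1, id2)
  denom <- m$n_focal[id1] + m$n_focal[id2]
  raw <- ifelse(denom > 0, count / denom, NA_real_)
  mean_raw <- mean(raw, na.rm = TRUE)
  if (!is.finite(mean_raw) || mean_raw == 0) {
    warning("group mean of raw proximity ratios is zero or undefined; ",
            "bond indices reported as missing")
    bond <- rep(NA_real_, length(raw))
  } else {
    bond <- raw / mean_raw
  }
  data.frame(id1 = id1, id2 = id2, count = as.integer(count),
             raw_ratio = unname(raw), bond = unname(bond),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Maternal kinship indicator for all dyads
#'
#' A dyad is maternal kin when one member is the other's mother, or when the
#' two share the same mother (maternal siblings).
#'
#' @param individuals an individuals data frame (see [gesture_dataset()]).
#' @return A data frame with `id1`, `id2` (id1 < id2, within-group dyads
#'   only) and logical `maternal_kin`.
#' @export
maternal_kinship <- function(individuals) {
  ind <- individuals
  out <- list()
  for (g in unique(ind$group_id)) {
    ids <- sort(ind$individual_id[ind$group_id == g])
    if (length(ids) < 2) next
    pairs <- utils::combn(ids, 2)
    mom <- stats::setNames(ind$mother_id, ind$individual_id)
    mom[is.na(mom)] <- ""
    kin <- mapply(function(a, b) {
      (mom[a] != "" && mom[a] == b) || (mom[b] != "" && mom[b] == a) ||
        (mom[a] != "" && mom[a] == mom[b])
    }, pairs[1, ], pairs[2, ])
    out[[g]] <- data.frame(id1 = pairs[1, ], id2 = pairs[2, ],
                           maternal_kin = unname(kin),
                           stringsAsFactors = FALSE)
  }
  if (length(out) == 0) {
    return(data.frame(id1 = character(), id2 = character(),
                      maternal_kin = logical(), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Count communities in a proximity network
#'
#' Diagnostic only: number of communities found by greedy modularity
#' maximization on the weighted proximity graph (fast-greedy
#' agglomeration). Individuals with no proximity partners count as
#' singleton communities.
#'
#' @param m a `proximity_matrix`.
#' @return Integer number of communities (at least 1 for a non-empty group).
#' @export
count_communities <- function(m) {
  stopifnot(inherits(m, "proximity_matrix"))
  C <- m$C
  deg <- rowSums(C)
  isolated <- sum(deg == 0)
  active <- which(deg > 0)
  if (length(active) == 0) return(as.integer(nrow(C)))
  g <- igraph::graph_from_adjacency_matrix(C[active, active, drop = FALSE],
                                           mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  cl <- igraph::cluster_fast_greedy(g, weights = igraph::E(g)$weight)
  # choose the dendrogram cut with maximal modularity; on ties (within
  # 1e-12) prefer the coarser partition, so a uniform clique is one
  # community
  ks <- seq(igraph::components(g)$no, igraph::vcount(g))
  mods <- vapply(ks, function(k) {
    igraph::modularity(g, igraph::cut_at(cl, no = k),
                       weights = igraph::E(g)$weight)
  }, numeric(1))
  best_k <- ks[min(which(mods >= max(mods) - 1e-12))]
  as.integer(best_k + isolated)
}

#' Compute all sociality indices for a dataset
#'
#' Runs [build_proximity_matrix()], [eigenvector_centrality()],
#' [dyadic_bond_index()] and [maternal_kinship()] for every group.
#'
#' @param d a [gesture_dataset()].
#' @return A list of class `sociality_indices` with elements `centrality`
#'   (individual_id, group_id, centrality, component), `bonds` (group_id,
#'   id1, id2, count, raw_ratio, bond, maternal_kin) and `matrices` (named
#'   list of `proximity_matrix` objects).
#' @export
sociality_indices <- function(d) {
  stopifnot(inherits(d, "gesture_dataset"))
  groups <- unique(d$individuals$group_id)
  kin <- maternal_kinship(d$individuals)
  cent <- list()
  bonds <- list()
  mats <- list()
  for (g in groups) {
    m <- build_proximity_matrix(d$scans, g, individuals = d$individuals)
    mats[[g]] <- m
    ce <- eigenvector_centrality(m)
    ce$group_id <- g
    cent[[g]] <- ce
    b <- dyadic_bond_index(m)
    if (nrow(b) > 0) {
      b$group_id <- g
      key <- paste(b$id1, b$id2)
      kin_g <- kin[kin$id1 %in% b$id1 | kin$id2 %in% b$id2, , drop = FALSE]
      b$maternal_kin <- kin$maternal_kin[match(key, paste(kin$id1, kin$id2))]
      bonds[[g]] <- b
    }
  }
  structure(list(
    centrality = do.call(rbind, c(cent, list(make.row.names = FALSE))),
    bonds = do.call(rbind, c(bonds, list(make.row.names = FALSE))),
    matrices = mats
  ), class = "sociality_indices")
}

#' @export
print.sociality_indices <- function(x, ...) {
  cat(sprintf("<sociality_indices> %d individuals, %d dyads, %d groups\n",
              nrow(x$centrality), nrow(x$bonds), length(x$matrices)))
  invisible(x)
}

#' Write network outputs to disk
#'
#' Writes one `network_<group>.csv` edge list (id1, id2, count, raw_ratio,
#' bond) per group and a pooled `centrality.csv` (individual_id, group_id,
#' centrality, component).
#'
#' @param indices a [sociality_indices()] result.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_network <- function(indices, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (g in names(indices$matrices)) {
    b <- indices$bonds[indices$bonds$group_id == g,
                       c("id1", "id2", "count", "raw_ratio", "bond")]
    utils::write.csv(b, file.path(dir, paste0("network_", g, ".csv")),
                     row.names = FALSE, quote = FALSE)
  }
  utils::write.csv(indices$centrality[, c("individual_id", "group_id",
                                          "centrality", "component")],
                   file.path(dir, "centrality.csv"),
                   row.names = FALSE, quote = FALSE)
  invisible(dir)
}
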