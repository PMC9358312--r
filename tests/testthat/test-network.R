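# Proximity networks, centralities, bond indices, kinship, communities.

make_pm <- function(C, n_focal) {
  structure(list(group_id = "g", C = C,
                 n_focal = n_focal, n_scans = sum(n_focal), empty = FALSE),
            class = "proximity_matrix")
}

test_that("proximity counts credit co-occurrence from either side's scan", {
  ind <- data.frame(individual_id = c("A", "B", "C"), species = "siamang",
                    group_id = "g", sex = c("F", "M", "F"),
                    age_years = c(10, 5, 3), mother_id = "")
  sc <- data.frame(scan_id = c("s1", "s2", "s3"), group_id = "g",
                   time_s = c(0, 0, 600), focal_id = c("A", "B", "A"),
                   neighbor_ids = c("B", "A", ""))
  m <- build_proximity_matrix(sc, "g", individuals = ind)
  expect_equal(m$C["A", "B"], 2)
  expect_equal(m$C["A", "C"], 0)
  expect_equal(unname(m$n_focal[c("A", "B", "C")]), c(2L, 1L, 0L))
  expect_true(isSymmetric(m$C))
  expect_true(all(diag(m$C) == 0))
})

test_that("scans with empty neighbour sets yield an all-zero matrix", {
  ind <- data.frame(individual_id = c("A", "B"), species = "siamang",
                    group_id = "g", sex = "F", age_years = 5, mother_id = "")
  sc <- data.frame(scan_id = c("s1", "s2"), group_id = "g", time_s = c(0, 0),
                   focal_id = c("A", "B"), neighbor_ids = c("", ""))
  m <- build_proximity_matrix(sc, "g", individuals = ind)
  expect_true(all(m$C == 0))
})

test_that("centrality handles pairs, stars and isolates as the theory says", {
  C <- matrix(c(0, 5, 5, 0), 2, 2, dimnames = list(c("A", "B"), c("A", "B")))
  ce <- eigenvector_centrality(C)
  expect_equal(ce$centrality, c(1, 1))

  # star: hub 1, leaves 1/sqrt(3)
  ids <- c("hub", "l1", "l2", "l3")
  C <- matrix(0, 4, 4, dimnames = list(ids, ids))
  C["hub", c("l1", "l2", "l3")] <- 1
  C[c("l1", "l2", "l3"), "hub"] <- 1
  ce <- eigenvector_centrality(C)
  expect_equal(ce$centrality[ce$individual_id == "hub"], 1)
  expect_equal(ce$centrality[ce$individual_id != "hub"],
               rep(1 / sqrt(3), 3), tolerance = 1e-8)

  # isolate gets 0 and component label 0
  C2 <- rbind(cbind(C, iso = 0), iso = 0)
  dimnames(C2) <- list(c(ids, "iso"), c(ids, "iso"))
  ce <- eigenvector_centrality(C2)
  expect_equal(ce$centrality[ce$individual_id == "iso"], 0)
  expect_equal(ce$component[ce$individual_id == "iso"], 0L)
})

test_that("power iteration matches a dense eigen-decomposition oracle", {
  for (seed in 1:60) {
    set.seed(seed)
    n <- sample(2:12, 1)
    C <- matrix(0, n, n)
    upper <- upper.tri(C)
    C[upper] <- rpois(sum(upper), 1.2) * rbinom(sum(upper), 1, 0.6)
    C <- C + t(C)
    dimnames(C) <- list(paste0("i", 1:n), paste0("i", 1:n))
    got <- eigenvector_centrality(C)
    comp <- got$component
    for (cc in setdiff(unique(comp), 0L)) {
      idx <- which(comp == cc)
      v <- abs(eigen(C[idx, idx, drop = FALSE], symmetric = TRUE)$vectors[, 1])
      expect_equal(got$centrality[idx], v / max(v), tolerance = 1e-8,
                   info = paste("seed", seed))
    }
    expect_true(all(got$centrality[comp == 0L] == 0))
  }
})

test_that("centrality is invariant to rescaling the proximity weights", {
  set.seed(42)
  C <- matrix(rpois(49, 2), 7, 7)
  C <- C * upper.tri(C)
  C <- C + t(C)
  dimnames(C) <- list(letters[1:7], letters[1:7])
  expect_equal(eigenvector_centrality(C)$centrality,
               eigenvector_centrality(C * 17.3)$centrality, tolerance = 1e-9)
})

test_that("bond indices normalize to the worked trio and to mean one", {
  C <- matrix(c(0, 4, 2, 4, 0, 0, 2, 0, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  m <- make_pm(C, c(A = 10, B = 10, C = 10))
  b <- dyadic_bond_index(m)
  expect_equal(b$raw_ratio, c(0.2, 0.1, 0.0), tolerance = 1e-12)
  expect_equal(b$bond, c(2.0, 1.0, 0.0), tolerance = 1e-12)
  expect_equal(mean(b$bond), 1, tolerance = 1e-12)

  # identical raw ratios: all bonds exactly one
  C2 <- matrix(3, 3, 3) - diag(3) * 3
  dimnames(C2) <- dimnames(C)
  b2 <- dyadic_bond_index(make_pm(C2, c(A = 6, B = 6, C = 6)))
  expect_equal(b2$bond, rep(1, 3), tolerance = 1e-12)
})

test_that("a group with no proximity at all yields missing bonds and a warning", {
  C <- matrix(0, 2, 2, dimnames = list(c("A", "B"), c("A", "B")))
  expect_warning(b <- dyadic_bond_index(make_pm(C, c(A = 5, B = 5))), "zero")
  expect_true(all(is.na(b$bond)))
})

test_that("maternal kinship covers mothers, siblings and unrelated dyads", {
  ind <- data.frame(
    individual_id = c("mom", "kid1", "kid2", "other"),
    species = "siamang", group_id = "g", sex = c("F", "M", "F", "M"),
    age_years = c(20, 5, 3, 12),
    mother_id = c("", "mom", "mom", ""))
  kin <- maternal_kinship(ind)
  get <- function(a, b) kin$maternal_kin[kin$id1 == min(a, b) & kin$id2 == max(a, b)]
  expect_true(get("mom", "kid1"))
  expect_true(get("kid1", "kid2"))
  expect_false(get("kid1", "other"))
  expect_false(get("mom", "other"))
})

test_that("community counts separate cliques and count isolates", {
  ids <- paste0("i", 1:8)
  C <- matrix(0, 8, 8, dimnames = list(ids, ids))
  C[1:4, 1:4] <- 1
  C[5:8, 5:8] <- 1
  diag(C) <- 0
  expect_equal(count_communities(make_pm(C, setNames(rep(5, 8), ids))), 2L)

  Cfull <- matrix(1, 8, 8, dimnames = list(ids, ids)) - diag(8)
  expect_equal(count_communities(make_pm(Cfull, setNames(rep(5, 8), ids))), 1L)

  C0 <- matrix(0, 5, 5, dimnames = list(ids[1:5], ids[1:5]))
  expect_equal(count_communities(make_pm(C0, setNames(rep(5, 5), ids[1:5]))), 5L)
})

test_that("sociality indices hold their normalization on generated data", {
  d <- generate_dataset(small_config(), seed = 21)
  idx <- sociality_indices(d)
  for (g in unique(idx$bonds$group_id)) {
    b <- idx$bonds$bond[idx$bonds$group_id == g]
    expect_equal(mean(b, na.rm = TRUE), 1, tolerance = 1e-12)
  }
  ce <- idx$centrality
  for (g in unique(ce$group_id)) {
    for (cc in setdiff(unique(ce$component[ce$group_id == g]), 0L)) {
      expect_equal(max(ce$centrality[ce$group_id == g & ce$component == cc]),
                   1, tolerance = 1e-12)
    }
  }
})
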