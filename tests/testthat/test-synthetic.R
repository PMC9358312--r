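# Synthetic-data generator: design constants, determinism, internal
# consistency of the planted structure.

test_that("the default design constants are honoured exactly", {
  cfg <- synthetic_config()
  ind <- generate_population(cfg, seed = 3)
  expect_equal(nrow(ind), 53L)
  expect_equal(sort(as.vector(table(ind$group_id))),
               sort(c(19L, 9L, 7L, 4L, 4L, 5L, 5L)))
  expect_equal(as.vector(table(ind$species)[c("chimpanzee", "orangutan", "siamang")]),
               c(19L, 16L, 18L))
  sc <- generate_scans(ind, cfg, seed = 3)
  expect_equal(as.vector(table(sc$focal_id)), rep(35L, 53L))
  expect_equal(lengths(cfg$ethogram),
               c(chimpanzee = 18L, orangutan = 17L, siamang = 14L))
})

test_that("the same seed reproduces the dataset exactly", {
  cfg <- small_config()
  d1 <- generate_dataset(cfg, seed = 11)
  d2 <- generate_dataset(cfg, seed = 11)
  expect_identical(d1$individuals, d2$individuals)
  expect_identical(d1$events, d2$events)
  expect_identical(d1$scans, d2$scans)
  d3 <- generate_dataset(cfg, seed = 12)
  expect_false(identical(d1$events, d3$events))
})

test_that("mothers are plausibly older and female", {
  cfg <- synthetic_config()
  ind <- generate_population(cfg, seed = 4)
  kids <- ind[ind$mother_id != "", ]
  expect_gt(nrow(kids), 0)
  moms <- ind[match(kids$mother_id, ind$individual_id), ]
  expect_true(all(moms$sex == "F"))
  expect_true(all(moms$age_years - kids$age_years >= cfg$mother_min_age_gap))
  expect_true(all(moms$group_id == kids$group_id))
})

test_that("generated datasets validate cleanly and carry a full truth ledger", {
  d <- generate_dataset(small_config(), seed = 13)
  expect_identical(nrow(validate_dataset(d)), 0L)
  expect_setequal(names(d$truth$betas),
                  c("beta_age_attention", "beta_age_attention_visual",
                    "beta_bond_dyadrep", "beta_age_seq",
                    "beta_centrality_seq", "beta_age_response",
                    "beta_seq_response", "beta_attention_response"))
  expect_length(d$truth$z_age, nrow(d$individuals))
  expect_length(d$truth$p_seq, nrow(d$individuals))
  expect_true(nrow(d$truth$affinities) > 0)
})

test_that("per-individual gesture counts sit in the study's range of tens", {
  d <- generate_dataset(synthetic_config(), seed = 6)
  counts <- table(factor(d$events$sender_id,
                         levels = d$individuals$individual_id))
  by_species <- tapply(as.vector(counts), d$individuals$species, mean)
  expect_true(all(by_species > 20 & by_species < 150))
})

test_that("segmentation recovers the planted sequence structure", {
  d <- generate_dataset(synthetic_config(), seed = 14)
  ev <- assign_sequences(d$events)
  planted <- d$truth$planted_in_sequence[ev$event_id]
  expect_gte(mean(ev$in_sequence == planted), 0.99)
})

test_that("kin dyads are tighter than non-kin dyads under the kin boost", {
  cfg <- small_config(kin_boost = 3)
  ok <- vapply(1:5, function(s) {
    d <- generate_dataset(cfg, seed = s)
    idx <- sociality_indices(d)
    b <- idx$bonds
    if (!any(b$maternal_kin)) return(NA)
    mean(b$bond[b$maternal_kin], na.rm = TRUE) >
      mean(b$bond[!b$maternal_kin], na.rm = TRUE)
  }, NA)
  expect_true(all(ok, na.rm = TRUE))
})

test_that("realized flexibility sits in the configured modal-context band", {
  d <- generate_dataset(synthetic_config(), seed = 15)
  ev <- assign_sequences(d$events)
  fl <- flexibility_index(ev)$flexibility
  expect_true(mean(fl, na.rm = TRUE) > 0.7 && mean(fl, na.rm = TRUE) < 0.9)
})

test_that("a configuration round-trips through YAML", {
  cfg <- small_config(kin_boost = 2.2, unknown_rate = 0.1)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_synthetic_config(cfg, path)
  cfg2 <- read_synthetic_config(path)
  expect_equal(cfg2$groups, cfg$groups)
  expect_equal(cfg2$kin_boost, 2.2)
  expect_equal(cfg2$unknown_rate, 0.1)
  expect_equal(cfg2$gesture_rate_per_min, cfg$gesture_rate_per_min)
  expect_equal(lapply(cfg2$ethogram, as.list), lapply(cfg$ethogram, as.list))
  # identical generation under either object
  expect_identical(generate_dataset(cfg, 3)$events,
                   generate_dataset(cfg2, 3)$events)
})

test_that("invalid configurations are rejected before generation", {
  expect_error(synthetic_config(groups = data.frame(
    group_id = "g", species = "gorilla", size = 5)), "ethogram")
  expect_error(synthetic_config(unknown_rate = 1.5), "probabilities")
  expect_error(synthetic_config(age_min = 10, age_max = 5), "age bounds")
  expect_error(synthetic_config(scans_per_individual = 0), "scans")
})
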