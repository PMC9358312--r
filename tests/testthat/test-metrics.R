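# Individual/dyadic complexity metrics, accumulation curves, kappa.

test_that("flexibility averages modal-context proportions over frequent types", {
  ev <- data.frame(
    sender_id = "A",
    gesture_type = c("a", "a", "a", "a", "b", "b", "c"),
    context = c("play", "play", "play", "groom", "play", "play", "groom"))
  expect_equal(flexibility_index(ev)$flexibility, 0.875, tolerance = 1e-12)
  # singletons included: c contributes 1
  expect_equal(flexibility_index(ev, include_singletons = TRUE)$flexibility,
               mean(c(0.75, 1, 1)), tolerance = 1e-12)

  one <- data.frame(sender_id = "A", gesture_type = "a",
                    context = "play")[rep(1, 5), ]
  expect_equal(flexibility_index(one)$flexibility, 1)

  singletons <- data.frame(sender_id = "A", gesture_type = c("a", "b"),
                           context = c("play", "groom"))
  expect_true(is.na(flexibility_index(singletons)$flexibility))
  expect_error(flexibility_index(singletons, min_count = 0), "min_count")
})

test_that("individual metrics count the numerator/denominator families", {
  eth <- default_ethogram()
  ind <- data.frame(individual_id = "A", species = "chimpanzee",
                    group_id = "g", sex = "F", age_years = 12, mother_id = "")
  ev <- make_events(seq(0, 90, by = 10), sender = "A", recipient = "B",
                    type = c("chi01", "chi02", "chi03", "chi01", "chi01",
                             "chi02", "chi01", "chi02", "chi01", "chi01"),
                    modality = "visual",
                    attentive = c(rep("true", 8), "false", "false"))
  ev$in_sequence <- rep(c(TRUE, FALSE), c(4, 6))
  ev$responded <- c(rep("true", 5), rep("false", 3), "unknown", "unknown")
  m <- individual_metrics(ev, eth, ind)
  expect_equal(m$repertoire_used, 3)
  expect_equal(m$repertoire_possible, 18)
  expect_equal(c(m$attended_visual, m$assessed_visual), c(8, 10))
  expect_equal(c(m$in_sequence, m$sequence_assessed), c(4, 10))
  expect_equal(c(m$responded, m$produced), c(5, 8))
  expect_equal(m$n_gestures_observed, 10)
})

test_that("zero-gesture individuals get zero denominators, not errors", {
  eth <- default_ethogram()
  ind <- data.frame(individual_id = c("A", "B"), species = "chimpanzee",
                    group_id = "g", sex = "F", age_years = c(12, 8),
                    mother_id = "")
  ev <- make_events(0, sender = "A", recipient = "B", type = "chi01")
  ev$in_sequence <- FALSE
  m <- individual_metrics(ev, eth, ind)
  b <- m[m$individual_id == "B", ]
  expect_equal(b$n_gestures_observed, 0)
  expect_equal(b$produced, 0)
  expect_true(is.na(b$flexibility))
})

test_that("dyad metrics pool both directions and code the dyad covariates", {
  d <- generate_dataset(small_config(), seed = 31)
  ev <- assign_sequences(d$events)
  idx <- sociality_indices(d)
  dm <- dyad_metrics(ev, idx, d$individuals, d$ethogram)
  info <- d$individuals
  i <- 5
  a <- dm$id1[i]; b <- dm$id2[i]
  sub <- ev[(ev$sender_id == a & ev$recipient_id == b) |
            (ev$sender_id == b & ev$recipient_id == a), ]
  expect_equal(dm$repertoire_used[i], length(unique(sub$gesture_type)))
  expect_equal(dm$n_gestures_observed[i], nrow(sub))
  expect_equal(dm$age_difference[i],
               abs(info$age_years[info$individual_id == a] -
                   info$age_years[info$individual_id == b]))
  expect_true(all(dm$sex_combination %in% c("FF", "FM", "MM")))
  # unordered coding: an F-M dyad is FM whichever member is id1
  sexes <- paste0(pmin(info$sex[match(dm$id1, info$individual_id)],
                       info$sex[match(dm$id2, info$individual_id)]),
                  pmax(info$sex[match(dm$id1, info$individual_id)],
                       info$sex[match(dm$id2, info$individual_id)]))
  expect_equal(dm$sex_combination, sexes)
})

test_that("dyadic counts aggregate exactly to individual counts", {
  d <- generate_dataset(small_config(), seed = 32)
  ev <- assign_sequences(d$events)
  idx <- sociality_indices(d)
  im <- individual_metrics(ev, d$ethogram, d$individuals)
  dm <- dyad_metrics(ev, idx, d$individuals, d$ethogram)
  # every gesture has exactly one recipient, so an individual's sent count
  # is recovered by summing its sent events across its dyads
  for (id in d$individuals$individual_id) {
    sel <- dm$id1 == id | dm$id2 == id
    partners <- setdiff(c(dm$id1[sel], dm$id2[sel]), id)
    by_dyad <- vapply(partners, function(p) {
      sum(ev$sender_id == id & ev$recipient_id == p)
    }, numeric(1))
    expect_equal(sum(by_dyad), sum(ev$sender_id == id))
    expect_equal(im$n_gestures_observed[im$individual_id == id],
                 sum(ev$sender_id == id))
  }
  # pooled dyadic totals equal pooled individual totals
  expect_equal(sum(dm$n_gestures_observed), sum(im$n_gestures_observed))
  expect_equal(sum(dm$responded), sum(im$responded))
  expect_equal(sum(dm$produced), sum(im$produced))
  expect_equal(sum(dm$in_sequence), sum(im$in_sequence))
})

test_that("every proportion numerator stays within its denominator", {
  d <- generate_dataset(small_config(), seed = 33)
  ev <- assign_sequences(d$events)
  idx <- sociality_indices(d)
  im <- individual_metrics(ev, d$ethogram, d$individuals)
  dm <- dyad_metrics(ev, idx, d$individuals, d$ethogram)
  for (t in list(im, dm)) {
    expect_true(all(t$repertoire_used <= t$repertoire_possible))
    expect_true(all(t$attended_visual <= t$assessed_visual))
    expect_true(all(t$attended_nonvisual <= t$assessed_nonvisual))
    expect_true(all(t$in_sequence <= t$sequence_assessed))
    expect_true(all(t$responded <= t$produced))
    fl <- t$flexibility[!is.na(t$flexibility)]
    expect_true(all(fl > 0 & fl <= 1))
  }
})

test_that("accumulation curves trace distinct types in coding order", {
  ev <- make_events(c(0, 10, 20, 30), type = c("A", "B", "A", "C"))
  ind <- data.frame(individual_id = "A", species = "siamang", group_id = "g",
                    sex = "F", age_years = 3, mother_id = "")
  curve <- accumulation_curve(ev, "g", ind)
  expect_equal(curve$gestures_coded, 1:4)
  expect_equal(curve$cumulative_types, c(1, 2, 2, 3))

  single <- accumulation_curve(make_events(0))
  expect_equal(unlist(single), c(gestures_coded = 1, cumulative_types = 1))

  stream <- random_stream(40, 77)
  curve <- accumulation_curve(stream)
  expect_true(all(diff(curve$cumulative_types) >= 0))
  expect_equal(max(curve$cumulative_types),
               length(unique(stream$gesture_type)))
})

test_that("group repertoires saturate before the stream ends on synthetic data", {
  d <- generate_dataset(synthetic_config(), seed = 5)
  ev <- assign_sequences(d$events)
  g <- "atlanta"  # the largest group, >= 600 events
  curve <- accumulation_curve(ev, g, d$individuals)
  expect_gt(nrow(curve), 600)
  final <- max(curve$cumulative_types)
  first_hit <- min(curve$gestures_coded[curve$cumulative_types == final])
  expect_lt(first_hit, nrow(curve))
  expect_lte(final, 18)
})

test_that("Cohen's kappa matches hand calculations and conventions", {
  expect_equal(cohen_kappa(c("a", "b", "c"), c("a", "b", "c")), 1.0)
  # 2x2 confusion (35, 15, 15, 35): p_o = 0.70, p_e = 0.50, kappa = 0.40
  l1 <- rep(c("x", "x", "y", "y"), c(35, 15, 15, 35))
  l2 <- rep(c("x", "y", "x", "y"), c(35, 15, 15, 35))
  expect_equal(cohen_kappa(l1, l2), 0.40, tolerance = 1e-12)
  # independent labels: kappa near zero
  set.seed(11)
  a <- sample(letters[1:4], 1e4, replace = TRUE)
  b <- sample(letters[1:4], 1e4, replace = TRUE)
  expect_lt(abs(cohen_kappa(a, b)), 0.05)
  # both coders constant and equal
  expect_warning(k <- cohen_kappa(rep("a", 5), rep("a", 5)), "single")
  expect_equal(k, 1.0)
  expect_error(cohen_kappa("a", c("a", "b")), "equal length")
})
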