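# Temporal-window segmentation of gesture events into sequences.

test_that("chaining follows the 5-second same-dyad same-context rule", {
  ev <- assign_sequences(make_events(c(0, 4, 8)))
  expect_equal(length(unique(ev$sequence_id)), 1L)
  expect_true(all(ev$in_sequence))

  ev <- assign_sequences(make_events(c(0, 6)))
  expect_equal(length(unique(ev$sequence_id)), 2L)
  expect_false(any(ev$in_sequence))

  ev <- assign_sequences(make_events(c(0, 3), context = c("play", "agonistic")))
  expect_equal(length(unique(ev$sequence_id)), 2L)
  expect_false(any(ev$in_sequence))

  # interleaved gestures to a different recipient do not break a chain
  ev <- make_events(c(0, 2, 4), recipient = c("B", "C", "B"))
  ev <- assign_sequences(ev)
  expect_true(all(ev$in_sequence[ev$recipient_id == "B"]))
  expect_false(ev$in_sequence[ev$recipient_id == "C"])
})

test_that("first-event anchoring closes the window at the chain start", {
  ev <- assign_sequences(make_events(c(0, 4, 8)), anchor = "first")
  # 8 s exceeds the window from the first event: chain of 2 plus singleton
  expect_equal(sort(table(ev$sequence_id), decreasing = TRUE)[[1]], 2L)
  expect_equal(length(unique(ev$sequence_id)), 2L)
})

test_that("segmentation rejects a non-positive window", {
  expect_error(assign_sequences(make_events(c(0, 1)), gap_s = -1), "positive")
})

test_that("segmentation matches the transitive-closure oracle on random streams", {
  for (seed in 1:80) {
    n <- sample(2:16, 1)
    ev <- random_stream(n, seed)
    got <- assign_sequences(ev)
    want <- oracle_sequences(ev)
    got <- got[match(want$event_id, got$event_id), ]
    # identical partitions (same blocks, labels may differ)
    expect_equal(as.integer(factor(got$sequence_id,
                                   levels = unique(got$sequence_id))),
                 as.integer(factor(want$component,
                                   levels = unique(want$component))),
                 info = paste("seed", seed))
    expect_equal(got$in_sequence, want$in_sequence, info = paste("seed", seed))
  }
})

test_that("every event lands in exactly one sequence", {
  ev <- random_stream(30, 999)
  got <- assign_sequences(ev)
  expect_setequal(got$event_id, ev$event_id)
  expect_false(any(duplicated(got$event_id)))
  expect_true(all(got$sequence_id != ""))
})

test_that("enlarging the window never increases the number of sequences", {
  for (seed in 101:120) {
    ev <- random_stream(12, seed)
    n_chains <- vapply(c(1, 3, 5, 10, 20), function(g) {
      length(unique(assign_sequences(ev, gap_s = g)$sequence_id))
    }, numeric(1))
    expect_true(all(diff(n_chains) <= 0), info = paste("seed", seed))
  }
})
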