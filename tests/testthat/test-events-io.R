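# Data model, readers/writers and validation.

test_that("default ethogram has the expected species repertoire sizes", {
  eth <- default_ethogram()
  expect_equal(lengths(eth),
               c(chimpanzee = 18L, orangutan = 17L, siamang = 14L))
  expect_true(all(unlist(eth) %in% c("visual", "non_visual")))
  # every type maps to exactly one modality
  expect_true(all(vapply(eth, function(x) !anyDuplicated(names(x)), TRUE)))
})

test_that("ethogram YAML round-trips", {
  eth <- default_ethogram()
  path <- withr::local_tempfile(fileext = ".yaml")
  write_ethogram(eth, path)
  eth2 <- read_ethogram(path)
  expect_equal(lapply(eth2, as.list), lapply(eth, as.list))
})

test_that("a written dataset is read back identically", {
  d <- generate_dataset(small_config(), seed = 7)
  d$truth <- NULL
  dir <- withr::local_tempdir()
  write_dataset(d, dir)
  d2 <- read_dataset(file.path(dir, "individuals.csv"),
                     file.path(dir, "events.csv"),
                     file.path(dir, "scans.csv"),
                     file.path(dir, "ethogram.yaml"))
  expect_identical(d2$individuals$individual_id, d$individuals$individual_id)
  expect_identical(d2$individuals$mother_id, d$individuals$mother_id)
  expect_equal(d2$individuals$age_years, d$individuals$age_years,
               tolerance = 1e-9)
  for (col in c("event_id", "session_id", "sender_id", "recipient_id",
                "gesture_type", "modality", "recipient_attentive",
                "responded", "context")) {
    expect_identical(d2$events[[col]], d$events[[col]])
  }
  expect_equal(d2$events$time_s, d$events$time_s, tolerance = 1e-9)
  expect_identical(d2$scans$neighbor_ids, d$scans$neighbor_ids)
})

test_that("reading fails on missing files and on broken cross-references", {
  d <- generate_dataset(small_config(), seed = 8)
  dir <- withr::local_tempdir()
  write_dataset(d, dir)
  expect_error(read_dataset(file.path(dir, "nope.csv"),
                            file.path(dir, "events.csv"),
                            file.path(dir, "scans.csv"), d$ethogram),
               "not found")
  ev <- utils::read.csv(file.path(dir, "events.csv"),
                        stringsAsFactors = FALSE)
  ev$recipient_id[1] <- "ghost"
  utils::write.csv(ev, file.path(dir, "events.csv"), row.names = FALSE,
                   quote = FALSE)
  expect_error(read_dataset(file.path(dir, "individuals.csv"),
                            file.path(dir, "events.csv"),
                            file.path(dir, "scans.csv"), d$ethogram),
               ev$event_id[1])
})

test_that("validation reports located violations instead of raising", {
  d <- generate_dataset(small_config(), seed = 9)
  expect_identical(nrow(validate_dataset(d)), 0L)

  bad <- d
  bad$individuals$age_years[2] <- -1
  v <- validate_dataset(bad)
  expect_true(any(v$rule == "age_nonnegative" & v$row == 2))

  bad <- d
  bad$scans$neighbor_ids[5] <- paste(bad$scans$focal_id[5],
                                     bad$scans$neighbor_ids[5], sep = ";")
  v <- validate_dataset(bad)
  expect_true(any(v$rule == "focal_not_neighbor" & v$row == 5))

  bad <- d
  bad$events$gesture_type[3] <- "not_a_gesture"
  v <- validate_dataset(bad)
  expect_true(any(v$rule == "ethogram_type" & v$id == bad$events$event_id[3]))

  bad <- d
  bad$events$sender_id[4] <- bad$events$recipient_id[4]
  v <- validate_dataset(bad)
  expect_true(any(v$rule == "self_directed"))
})
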