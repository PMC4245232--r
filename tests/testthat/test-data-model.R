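test_that("read_study_csv preserves rows and validates structure", {
  path <- withr::local_tempfile(fileext = ".csv")
  write_toy_csv(path)
  meta <- study_meta("toy", control_group = "control")
  ds <- read_study_csv(path, meta)
  expect_s3_class(ds, "study_dataset")
  expect_equal(nrow(ds$records), 6L)
  expect_setequal(unique(ds$records$group), c("control", "treated"))

  # missing column
  bad <- withr::local_tempfile(fileext = ".csv")
  rows <- data.frame(animal_id = paste0("a", 1:6),
                     group = rep(c("control", "treated"), each = 3),
                     mediator = 1:6)
  utils::write.csv(rows, bad, row.names = FALSE)
  expect_error(read_study_csv(bad, meta), "missing column.*outcome")

  # non-numeric outcome cites the row
  bad2 <- withr::local_tempfile(fileext = ".csv")
  rows <- data.frame(animal_id = paste0("a", 1:6),
                     group = rep(c("control", "treated"), each = 3),
                     mediator = c(10, 12, 11, 15, 16, 14),
                     outcome = c("1.0", "1.2", "0.9", "NA", "2.3", "2.0"))
  utils::write.csv(rows, bad2, row.names = FALSE)
  expect_error(read_study_csv(bad2, meta), "outcome on row 4")

  # fewer than two groups
  bad3 <- withr::local_tempfile(fileext = ".csv")
  rows <- data.frame(animal_id = paste0("a", 1:6), group = "control",
                     mediator = c(10, 12, 11, 15, 16, 14),
                     outcome = c(1, 1.2, 0.9, 2.1, 2.3, 2))
  utils::write.csv(rows, bad3, row.names = FALSE)
  expect_error(read_study_csv(bad3, meta), "at least 2 groups")
})

test_that("dataset invariants: group sizes, control presence, mediator variation", {
  meta <- study_meta("s", control_group = "control")
  rec <- data.frame(animal_id = paste0("a", 1:5),
                    group = c("control", "control", "treated", "treated",
                              "treated"),
                    mediator = c(1, 2, 3, 4, 5), outcome = c(1, 2, 3, 4, 5))
  expect_error(study_dataset(meta, rec), ">= 3 animals")

  rec6 <- rbind(rec, data.frame(animal_id = "a6", group = "control",
                                mediator = 6, outcome = 6))
  expect_s3_class(study_dataset(meta, rec6), "study_dataset")

  rec6$mediator <- 5
  expect_error(study_dataset(meta, rec6), "mediator is constant")

  meta_bad <- study_meta("s", control_group = "sham")
  rec6$mediator <- 1:6
  expect_error(study_dataset(meta_bad, rec6), "control group 'sham'")
})

test_that("logit transform matches direct evaluation and rejects the boundary", {
  expect_equal(logit_percent(50), 0)
  expect_equal(logit_percent(73), log(0.73 / 0.27))
  expect_equal(logit_percent(73), 0.9946226, tolerance = 1e-6)
  expect_error(logit_percent(0), "domain error")
  expect_error(logit_percent(100), "domain error")
  expect_error(logit_percent(c(40, 120)), "domain error")
  # clamping maps the boundary to the epsilon logit
  expect_equal(logit_percent(0, clamp = TRUE, epsilon = 0.005),
               log(0.005 / 0.995))
  # strictly increasing
  x <- sort(runif(50, 1, 99))
  expect_true(all(diff(logit_percent(x)) > 0))
})

test_that("logit and inverse logit are mutual inverses", {
  withr::local_seed(11)
  for (i in 1:20) {
    x <- runif(30, 0.01, 99.99)
    expect_equal(inv_logit_percent(logit_percent(x)), x, tolerance = 1e-10)
  }
})

test_that("standardize gives mean 0, sample SD 1, and matches hand values", {
  expect_equal(standardize(c(1, 2, 3)), c(-1, 0, 1))
  expect_equal(standardize(c(2, 4, 6, 8)),
               c(-1.1618950, -0.3872983, 0.3872983, 1.1618950),
               tolerance = 1e-6)
  expect_error(standardize(c(5, 5, 5)), "degenerate-data")

  withr::local_seed(4)
  for (i in 1:20) {
    x <- rnorm(sample(5:50, 1), mean = runif(1, -10, 10),
               sd = runif(1, 0.1, 5))
    z <- standardize(x)
    expect_equal(mean(z), 0, tolerance = 1e-10)
    expect_equal(sd(z), 1, tolerance = 1e-10)
    expect_equal(order(z), order(x))
    # idempotence
    expect_equal(standardize(z), z, tolerance = 1e-10)
  }
})

test_that("prepare_study builds a valid model-ready triplet", {
  ds <- make_seeded_study(7)
  std <- prepare_study(ds)
  expect_equal(mean(std$M), 0, tolerance = 1e-10)
  expect_equal(sd(std$M), 1, tolerance = 1e-10)
  expect_equal(mean(std$Y), 0, tolerance = 1e-10)
  expect_equal(sd(std$Y), 1, tolerance = 1e-10)
  expect_true(all(std$T %in% c(0L, 1L)))
  expect_equal(std$T, as.integer(ds$records$group != "control"))
  # count and within-animal (M, Y) pairing preserved
  expect_length(std$M, nrow(ds$records))
  expect_equal(order(std$M), order(ds$records$mediator))
  expect_equal(order(std$Y), order(ds$records$outcome))
})

test_that("percent-bounded outcomes are logit-transformed before standardisation", {
  spec <- synthetic_study_spec(outcome_scale = "percent_bounded", seed = 3)
  ds <- generate_study(spec)
  std <- prepare_study(ds)
  expect_equal(std$Y, standardize(logit_percent(ds$records$outcome)),
               tolerance = 1e-12)
})

test_that("studies with more than two groups are rejected", {
  meta <- study_meta("s3", control_group = "control")
  rec <- data.frame(
    animal_id = paste0("a", 1:9),
    group = rep(c("control", "low", "high"), each = 3),
    mediator = c(1, 2, 3, 4, 5, 6, 7, 8, 9),
    outcome = c(2, 1, 3, 5, 4, 6, 8, 7, 9))
  ds <- study_dataset(meta, rec)
  expect_error(prepare_study(ds), "unsupported-design")
})
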