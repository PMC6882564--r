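test_that("moment matching reproduces the arm moments to machine precision", {
  spec <- default_arm_spec(120, seed = 11)
  cohort <- generate_cohort(spec, moment_match = TRUE)
  enh <- compute_enhancement(cohort)
  expect_equal(mean(enh$aorta_enh_hu), 340.9, tolerance = 1e-9)
  expect_equal(sd(enh$aorta_enh_hu), 51.4, tolerance = 1e-9)
  expect_equal(mean(enh$liver_enh_hu), 57.8, tolerance = 1e-9)
  expect_equal(sd(enh$liver_enh_hu), 11.8, tolerance = 1e-9)

  spec100 <- default_arm_spec(100, seed = 12)
  enh100 <- compute_enhancement(generate_cohort(spec100))
  expect_equal(mean(enh100$aorta_enh_hu), 395.9, tolerance = 1e-9)
  expect_equal(sd(enh100$liver_enh_hu), 15.5, tolerance = 1e-9)
})

test_that("generated records keep positive enhancement and the administered dose", {
  cohort <- generate_cohort(default_arm_spec(120, seed = 3), moment_match = FALSE)
  expect_equal(nrow(cohort), 100)
  expect_true(all(cohort$aorta_hap_hu > cohort$aorta_unenh_hu))
  expect_true(all(cohort$weight_kg > 0))
  expect_true(all(cohort$administered_ml_per_kg == 2.0))
  expect_true(all(cohort$sex %in% c("M", "F")))
})

test_that("same seed gives an identical cohort; different seed does not", {
  spec <- default_arm_spec(100, seed = 21)
  a <- generate_cohort(spec)
  b <- generate_cohort(spec)
  expect_identical(a, b)
  c <- generate_cohort(default_arm_spec(100, seed = 22))
  expect_false(isTRUE(all.equal(a$aorta_hap_hu, c$aorta_hap_hu)))
})

test_that("cohort generation does not disturb the caller's RNG stream", {
  set.seed(99)
  before <- runif(1)
  set.seed(99)
  invisible(generate_cohort(default_arm_spec(120, seed = 5)))
  after <- runif(1)
  expect_identical(before, after)
})

test_that("near-degenerate spread collapses enhancements onto the mean", {
  spec <- arm_spec(120, n = 50, aorta_enh_mean = 340.9, aorta_enh_sd = 1e-6,
                   liver_enh_mean = 57.8, liver_enh_sd = 1e-6, seed = 4)
  enh <- compute_enhancement(generate_cohort(spec, moment_match = FALSE))
  expect_true(all(abs(enh$aorta_enh_hu - 340.9) < 1e-4))
  expect_true(all(abs(enh$liver_enh_hu - 57.8) < 1e-4))
})

test_that("invalid arm specifications are rejected", {
  expect_error(arm_spec(120, n = 1, aorta_enh_mean = 340, aorta_enh_sd = 51,
                        liver_enh_mean = 58, liver_enh_sd = 12), "n must be")
  expect_error(arm_spec(120, n = 10, aorta_enh_mean = 340, aorta_enh_sd = 0,
                        liver_enh_mean = 58, liver_enh_sd = 12), "SDs must be positive")
  expect_error(arm_spec(120, n = 10, aorta_enh_mean = -1, aorta_enh_sd = 51,
                        liver_enh_mean = 58, liver_enh_sd = 12), "means must be positive")
  expect_error(arm_spec(135, n = 10, aorta_enh_mean = 340, aorta_enh_sd = 51,
                        liver_enh_mean = 58, liver_enh_sd = 12), "100 or 120")
})

test_that("unmatched sample moments converge to the spec values at large n", {
  spec <- arm_spec(120, n = 10000, aorta_enh_mean = 340.9, aorta_enh_sd = 51.4,
                   liver_enh_mean = 57.8, liver_enh_sd = 11.8, seed = 31)
  enh <- compute_enhancement(generate_cohort(spec, moment_match = FALSE))
  se_mean <- 51.4 / sqrt(10000)
  expect_lt(abs(mean(enh$aorta_enh_hu) - 340.9), 3 * se_mean)
  se_sd <- 51.4 / sqrt(2 * 10000)
  expect_lt(abs(sd(enh$aorta_enh_hu) - 51.4), 3 * se_sd)
  expect_lt(abs(mean(enh$liver_enh_hu) - 57.8), 3 * 11.8 / sqrt(10000))
})

test_that("cohort CSV writing is byte-stable and round-trips exactly", {
  spec <- default_arm_spec(120, seed = 8, n = 40)
  cohort <- generate_cohort(spec)
  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_cohort_csv(cohort, f1)
  write_cohort_csv(generate_cohort(spec), f2)
  expect_identical(readLines(f1), readLines(f2))

  back <- read_cohort_csv(f1)
  expect_identical(back$patient_id, cohort$patient_id)
  for (col in names(cohort)) expect_identical(back[[col]], cohort[[col]], label = col)
})

test_that("malformed cohort files fail with a parse error naming the problem", {
  cohort <- generate_cohort(default_arm_spec(120, seed = 9, n = 5))
  f <- withr::local_tempfile(fileext = ".csv")

  bad <- cohort
  bad$protocol_kvp[3] <- 135
  write_cohort_csv(bad, f)
  expect_error(read_cohort_csv(f), "protocol_kvp.*row 3")

  lines <- readLines(write_cohort_csv(cohort, f))
  lines[4] <- sub("^P120-003,120", "P120-003,abc", lines[4])
  writeLines(lines, f)
  expect_error(read_cohort_csv(f), "non-numeric.*protocol_kvp.*row 3")

  writeLines(lines[1], f)  # header only
  expect_error(read_cohort_csv(f), "no patient rows")

  writeLines(character(0), f)  # empty file
  expect_error(read_cohort_csv(f), "parse error")

  dropped <- cohort[, setdiff(names(cohort), "aorta_hap_hu")]
  write.csv(dropped, f, row.names = FALSE)
  expect_error(read_cohort_csv(f), "missing column.*aorta_hap_hu")
})

test_that("arm specifications load from YAML and JSON config files", {
  f <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("protocol_kvp: 120", "n: 25", "aorta_enh_mean: 340.9",
               "aorta_enh_sd: 51.4", "liver_enh_mean: 57.8",
               "liver_enh_sd: 11.8", "seed: 7"), f)
  spec <- read_arm_spec(f)
  expect_s3_class(spec, "arm_spec")
  expect_equal(spec$n, 25L)
  expect_equal(spec$administered_volume, 2.0)

  j <- withr::local_tempfile(fileext = ".json")
  writeLines('{"protocol_kvp": 100, "n": 10, "aorta_enh_mean": 395.9,
    "aorta_enh_sd": 65.1, "liver_enh_mean": 73.9, "liver_enh_sd": 15.5}', j)
  expect_equal(read_arm_spec(j)$protocol_kvp, 100L)

  writeLines(c("protocol_kvp: 120", "bogus_field: 1"), f)
  expect_error(read_arm_spec(f), "unknown arm_spec field")
})
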