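# Evaluation harness: statistics, relation derivation, row profiles and
# the battery driver's report.

fake_case <- function(mA, mB, relation = "A_brighter_than_B",
                      statistic = "mean_difference") {
  structure(list(name = "fake", image = luminance_image(matrix(0.5, 8, 8)),
                 target_masks = list(A = mA, B = mB), relation = relation,
                 statistic = statistic, uniform_targets = TRUE,
                 params = list(row = 4)),
            class = "illusion_case")
}

fake_outputs <- function(values) {
  structure(list(brightness = structure(list(values = values),
                                        class = "brightness_map"),
                 on_fill = list(iterations = 1L),
                 off_fill = list(iterations = 1L)),
            class = "model_outputs")
}

test_that("evaluate_case derives relations from the statistic", {
  m <- matrix(FALSE, 8, 8)
  mA <- m; mA[2:3, 2:3] <- TRUE
  mB <- m; mB[6:7, 6:7] <- TRUE
  v <- matrix(0.5, 8, 8); v[mA] <- 0.8; v[mB] <- 0.2
  res <- evaluate_case(fake_case(mA, mB), fake_outputs(v))
  expect_equal(res$difference, 0.6)
  expect_true(res$pass)

  # identical masks give a difference of exactly zero
  res0 <- evaluate_case(fake_case(mA, mA, relation = "A_equals_B"),
                        fake_outputs(v))
  expect_identical(res0$difference, 0)
  expect_true(res0$pass)

  # below delta in the wrong direction is not a pass
  v2 <- v; v2[mA] <- 0.2; v2[mB] <- 0.8
  expect_false(evaluate_case(fake_case(mA, mB), fake_outputs(v2))$pass)

  # RMS statistic compares within-mask contrast
  vt <- matrix(0.5, 8, 8)
  vt[mB] <- c(0.1, 0.9, 0.1, 0.9)
  resc <- evaluate_case(fake_case(mA, mB,
                                  relation = "A_lower_contrast_than_B",
                                  statistic = "rms_contrast_difference"),
                        fake_outputs(vt))
  expect_true(resc$pass)

  expect_error(evaluate_case(fake_case(m, mB), fake_outputs(v)),
               "empty target mask")
})

test_that("row profiles are ordered, sized and bounds-checked", {
  v <- matrix(seq(0, 1, length.out = 36), 6, 6)
  prof <- extract_row_profile(v, 3)
  expect_equal(nrow(prof), 6)
  expect_equal(prof$value, v[3, ])
  flat <- extract_row_profile(matrix(0.5, 4, 4), 2)
  expect_true(all(flat$value == 0.5))
  expect_error(extract_row_profile(v, 9), "out of range")
})

test_that("the battery driver reports one deterministic row per case", {
  b1 <- run_battery(names = c("sbc"))
  expect_equal(nrow(b1$report), 1)
  expect_equal(b1$report$relation_observed, "A_brighter_than_B")
  b2 <- run_battery(names = c("sbc"))
  expect_identical(b1$report, b2$report)
  expect_error(run_battery(names = c("sbc", "nope")), "unknown stimuli")
})

test_that("battery reports and panels are written to disk", {
  out <- file.path(tempdir(), "cf_battery_test")
  on.exit(unlink(out, recursive = TRUE), add = TRUE)
  run_battery(names = "sbc", out_dir = out)
  expect_true(file.exists(file.path(out, "battery_report.csv")))
  expect_true(file.exists(file.path(out, "battery_summary.json")))
  expect_true(file.exists(file.path(out, "sbc", "brightness.csv")))
  expect_true(file.exists(file.path(out, "sbc", "row_profile.csv")))
  grid <- read_grid_csv(file.path(out, "sbc", "input.csv"))
  expect_equal(dim(grid), c(128, 128))
})
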