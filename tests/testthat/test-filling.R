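# Filling-in layers: boundary-gated region-max spreading, the relay
# threshold, and the ON - OFF combination.

test_that("fill_layer equals the flood-fill region-max oracle", {
  set.seed(31)
  cfg <- fill_config()
  for (i in 1:30) {
    inst <- random_fill_instance(24)
    got <- fill_layer(inst$feature, inst$mask, cfg)
    want <- oracle_region_max(inst$feature, inst$mask$H, inst$mask$V,
                              cfg$fill_threshold_frac)
    expect_true(got$converged)
    expect_equal(got$activity, want, tolerance = 1e-9)
    expect_true(all(got$activity >= inst$feature - 1e-12))  # containment
  }
})

test_that("an all-ones mask blocks every lattice edge", {
  set.seed(32)
  f <- matrix(stats::runif(100), 10, 10)
  full <- structure(list(H = matrix(TRUE, 10, 10), V = matrix(TRUE, 10, 10)),
                    class = "boundary_mask")
  expect_equal(fill_layer(f, full)$activity, f)
})

test_that("a complete outline isolates its interior from outside features", {
  n <- 20
  f <- matrix(0.4, n, n)
  f[8:12, 8:12] <- 0.6
  ring <- matrix(FALSE, n, n)
  ring[6, 6:14] <- TRUE; ring[14, 6:14] <- TRUE
  empty <- matrix(FALSE, n, n)
  vring <- matrix(FALSE, n, n)
  vring[6:14, 6] <- TRUE; vring[6:14, 14] <- TRUE
  mask <- structure(list(H = ring, V = vring), class = "boundary_mask")
  base <- fill_layer(f, mask)$activity
  f2 <- f; f2[1, 1] <- 0.99   # crank an outside feature
  alt <- fill_layer(f2, mask)$activity
  expect_equal(alt[8:12, 8:12], base[8:12, 8:12])
})

test_that("the relay threshold stops spreading over dark regions", {
  # ON layer of a real stimulus: deep-black interiors never rise above
  # their own feature input (no spurious brightening of black)
  case <- generate_stimulus("dungeon")
  out <- run_model(case$image)
  img <- unclass(case$image)
  deep_black <- erode3x3(erode3x3(erode3x3(img < 0.01)))
  expect_true(all(out$on_fill$activity[deep_black] <=
                    out$feature$on[deep_black] + 1e-9))
  deep_white <- erode3x3(erode3x3(erode3x3(img > 0.99)))
  expect_true(all(out$off_fill$activity[deep_white] <=
                    out$feature$off[deep_white] + 1e-9))
})

test_that("combine normalizes the ON - OFF difference as declared", {
  on <- matrix(0.3, 5, 5); off <- matrix(0.3, 5, 5)
  expect_equal(combine_fill(on, off)$values, matrix(0.5, 5, 5))
  on2 <- matrix(0, 2, 2); off2 <- matrix(0, 2, 2)
  on2[1, 1] <- 1; off2[2, 2] <- 1
  v <- combine_fill(on2, off2)$values
  expect_equal(v[1, 1], 1)
  expect_equal(v[2, 2], 0)
})

test_that("a uniform gray input yields a flat mid-gray brightness map", {
  out <- run_model(matrix(0.5, 64, 64))
  expect_equal(out$brightness$values, matrix(0.5, 64, 64), tolerance = 1e-9)
})

test_that("run_model is deterministic and carries every intermediate", {
  case <- generate_stimulus("sbc", list(size = 64))
  o1 <- run_model(case$image)
  o2 <- run_model(case$image)
  expect_identical(o1$brightness$values, o2$brightness$values)
  expect_s3_class(o1, "model_outputs")
  for (nm in c("contrast", "luminance", "feature", "lbd", "gbd", "mask",
               "on_fill", "off_fill", "brightness", "timing")) {
    expect_false(is.null(o1[[nm]]))
  }
})
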