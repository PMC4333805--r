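# Boundary system: oriented local detection, recurrent facilitation, and
# the binary L/G gate.

vstep <- function(left, right, n = 48) {
  m <- matrix(left, n, n)
  m[, (n / 2 + 1):n] <- right
  luminance_image(m)
}

test_that("local boundaries are oriented and contrast-graded", {
  cfg <- bcs_config()
  lbd <- local_boundaries(contrast_pathway(vstep(0, 1)), cfg)
  mid <- 24
  # V ridge along the vertical step, H silent away from the image corners
  expect_gt(max(lbd$V[24, ]), 0.05)
  expect_equal(which.max(lbd$V[24, ]), mid, tolerance = 2)
  expect_lt(max(lbd$H[20:28, 10:38]), 1e-3 * max(lbd$V))

  half <- local_boundaries(contrast_pathway(vstep(0, 0.5)), cfg)
  expect_lt(max(half$V[24, ]), max(lbd$V[24, ]))

  flat <- local_boundaries(contrast_pathway(matrix(0.5, 48, 48)), cfg)
  expect_lt(max(flat$V), 1e-9)
  expect_lt(max(flat$H), 1e-9)
})

test_that("facilitation raises weak aligned contours and never suppresses", {
  cfg <- bcs_config()
  # collinear pair: full-contrast edge above, half-contrast edge below
  img <- matrix(0, 64, 64)
  img[1:32, 33:64] <- 1
  img[33:64, 33:64] <- 0.5
  lbd <- local_boundaries(contrast_pathway(luminance_image(img)), cfg)
  gbd <- global_boundaries(lbd, cfg)
  expect_true(all(gbd$V >= lbd$V - 1e-12))
  expect_true(all(gbd$H >= lbd$H - 1e-12))
  # the weak edge's crest is raised to the strong edge's level
  weak_crest <- max(lbd$V[56, ])
  strong_crest <- max(lbd$V[8, ])
  expect_lt(weak_crest, 0.7 * strong_crest)
  # raised at least to the strong mid-crest level (the strong contour's
  # junction sites can push it slightly higher still)
  expect_gte(max(gbd$V[56, ]), strong_crest)
  expect_lte(max(gbd$V[56, ]), max(lbd$V))
  # all-zero input stays all-zero
  z <- oriented_activity_zero <- local_boundaries(
    contrast_pathway(matrix(0.5, 48, 48)), cfg)
  expect_equal(max(global_boundaries(z, cfg)$V), 0)
})

test_that("the L/G gate keeps unfacilitated and erases facilitated contours", {
  expect_silent(cal <- check_lg_calibration())
  expect_lt(cal$facilitated_ratio, bcs_config()$lg_threshold)
  expect_gte(cal$unfacilitated_ratio, bcs_config()$lg_threshold)

  # thresholds mis-set in either direction are caught by the calibrator
  expect_error(check_lg_calibration(bcs_config(lg_threshold = 0.5)),
               "does not erase")
  expect_error(check_lg_calibration(bcs_config(lg_threshold = 0.999)),
               "erases the unfacilitated")
})

test_that("the boundary mask is contrast-polarity invariant", {
  cfg <- bcs_config()
  for (nm in c("dungeon", "white", "benary")) {
    case <- generate_stimulus(nm)
    m1 <- with(list(con = contrast_pathway(case$image)), {
      lbd <- local_boundaries(con, cfg)
      lg_interaction(lbd, global_boundaries(lbd, cfg), cfg)
    })
    m2 <- with(list(con = contrast_pathway(1 - unclass(case$image))), {
      lbd <- local_boundaries(con, cfg)
      lg_interaction(lbd, global_boundaries(lbd, cfg), cfg)
    })
    expect_identical(m1$H, m2$H)
    expect_identical(m1$V, m2$V)
  }
})

test_that("dungeon masks retain strong outlines and omit gray outlines", {
  case <- generate_stimulus("dungeon")
  out <- run_model(case$image)
  msk <- out$mask
  # gray target (rows 58:69, cols 27:38): every mid-edge segment is erased
  # (the contour is open; only sub-pixel crumbs at the corners may remain,
  # where corner amplification keeps the ratio above threshold)
  expect_equal(sum(msk$V[62:65, 25:28]), 0)   # left edge mid
  expect_equal(sum(msk$V[62:65, 37:40]), 0)   # right edge mid
  expect_equal(sum(msk$H[56:59, 31:34]), 0)   # top edge mid
  expect_equal(sum(msk$H[68:71, 31:34]), 0)   # bottom edge mid
  # a black lattice square's outline is present (square rows 38:49, cols 27:38)
  expect_gt(sum(msk$V[40:47, 25:28]), 0)   # left edge crest
  expect_gt(sum(msk$H[36:39, 29:36]), 0)   # top edge crest
  # the half-border frame is present
  expect_gt(sum(msk$V[10:118, 63:66]), 100)
})
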