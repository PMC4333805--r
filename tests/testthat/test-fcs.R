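# Front-end pathways: balanced vs center-dominated kernels, shunting
# polarity, and the exact ON/OFF duality.

step_image <- function(left, right, n = 48) {
  m <- matrix(left, n, n)
  m[, (n / 2 + 1):n] <- right
  luminance_image(m)
}

test_that("balanced contrast kernels cancel on uniform fields", {
  for (level in c(0, 0.3, 1)) {
    f <- contrast_pathway(matrix(level, 40, 40))
    expect_lt(max(f$on), 1e-6)
    expect_lt(max(f$off), 1e-6)
  }
})

test_that("contrast pathway peaks on the correct side of a step", {
  f <- contrast_pathway(step_image(0, 1))
  mid <- 24
  expect_gt(max(f$on[24, (mid + 1):48]), 0.01)    # bright side responds ON
  expect_lt(max(f$on[24, 1:mid]), 1e-8)           # dark side silent in ON
  expect_gt(max(f$off[24, 1:mid]), 0.01)          # dark side responds OFF
  expect_lt(max(f$off[24, (mid + 1):48]), 1e-8)

  # lower-contrast step yields a strictly weaker ON peak
  weak <- contrast_pathway(step_image(0, 0.5))
  expect_lt(max(weak$on[24, ]), max(f$on[24, ]))
})

test_that("luminance pathway acts as an approximate luminance detector", {
  cfg <- pathway_config()
  white <- luminance_pathway(matrix(1, 40, 40), cfg)
  expect_equal(white$on[20, 20], 1 - cfg$luminance_surround_weight,
               tolerance = 1e-9)
  expect_lt(white$off[20, 20], 1e-9)

  black <- luminance_pathway(matrix(0, 40, 40), cfg)
  expect_lt(black$on[20, 20], 1e-9)

  gray <- luminance_pathway(matrix(0.5, 40, 40), cfg)
  expect_equal(gray$on, gray$off, tolerance = 1e-12)

  # monotone in the uniform-field level
  levels <- c(0.1, 0.3, 0.5, 0.8, 1)
  resp <- vapply(levels, function(l) {
    luminance_pathway(matrix(l, 40, 40), cfg)$on[20, 20]
  }, 0)
  expect_true(all(diff(resp) > 0))
})

test_that("OFF equals ON applied to the inverted image, both pathways", {
  set.seed(21)
  img <- matrix(sample(c(0, 0.25, 0.5, 0.75, 1), 40 * 40, TRUE), 40, 40)
  for (path in list(contrast_pathway, luminance_pathway)) {
    a <- path(img)
    b <- path(1 - img)
    expect_identical(a$off, b$on)
    expect_identical(a$on, b$off)
  }
})

test_that("responses are translation-equivariant away from the border", {
  set.seed(22)
  base <- matrix(stats::runif(64 * 64), 64, 64)
  shifted <- base[c(4:64, rep(64, 3)), ]  # shift up by 3 rows
  a <- contrast_pathway(base)$on
  b <- contrast_pathway(shifted)$on
  expect_equal(a[20:40, 20:44], b[17:37, 20:44], tolerance = 1e-10)
})

test_that("feature input mixes the pathways as declared", {
  img <- step_image(0, 1, 32)
  con <- contrast_pathway(img)
  lum <- luminance_pathway(img)
  only_lum <- feature_input(con, lum, pathway_config(w_contrast = 0,
                                                     w_luminance = 3))
  expect_equal(only_lum$on, 3 * lum$on)
  only_con <- feature_input(con, lum, pathway_config(w_contrast = 2,
                                                     w_luminance = 0))
  expect_lt(max(only_con$on[16, 4:8]), 1e-6)  # uniform interior carries none
  bad <- luminance_pathway(matrix(0.5, 10, 10))
  expect_error(feature_input(con, bad), "shape")
})
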