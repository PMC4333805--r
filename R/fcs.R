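# Feature Contour System front end. The Contrast Pathways compute luminance
# ratios at borders with balanced center-surround kernels and shunting
# (divisive) inhibition; the Luminance Pathways use center-dominated kernels
# and so behave as approximate luminance detectors even over uniform areas.
# The OFF member of each pair is, by construction, the ON operator applied to
# the inverted image 1 - I, which makes the ON/OFF duality of the model exact.

#' Configuration of the ON/OFF pathway front end
#'
#' @param sigma_center,sigma_surround Gaussian kernel widths in pixels;
#'   the center must be narrower than the surround. Both lobes are
#'   normalized to unit mass, so on a uniform field center and surround
#'   responses cancel exactly in the Contrast Pathway.
#' @param shunt_floor Positive decay constant of the divisive normalization
#'   (on the `[0, 1]` luminance scale); larger values make the contrast
#'   response more nearly linear in the luminance difference.
#' @param luminance_surround_weight Fraction in `[0, 1)` by which the
#'   surround lobe underweights the center in the Luminance Pathway; a
#'   uniform field of level L yields an ON response of
#'   `L * (1 - luminance_surround_weight)`.
#' @param w_contrast,w_luminance Nonnegative mixing weights of the feature
#'   sum delivered to the filling-in layers. More weight on the contrast
#'   signal strengthens brightness contrast and weakens assimilation.
#' @return A list of class `pathway_config`.
#' @export
pathway_config <- function(sigma_center = 1, sigma_surround = 3,
                           shunt_floor = 0.5,
                           luminance_surround_weight = 0.5,
                           w_contrast = 2, w_luminance = 1) {
  stopifnot(sigma_center > 0, sigma_surround > sigma_center,
            shunt_floor > 0,
            luminance_surround_weight >= 0, luminance_surround_weight < 1,
            w_contrast >= 0, w_luminance >= 0,
            w_contrast + w_luminance > 0)
  structure(list(sigma_center = sigma_center,
                 sigma_surround = sigma_surround,
                 shunt_floor = shunt_floor,
                 luminance_surround_weight = luminance_surround_weight,
                 w_contrast = w_contrast, w_luminance = w_luminance),
            class = "pathway_config")
}

feature_field <- function(on, off) {
  structure(list(on = on, off = off), class = "feature_field")
}

#' @export
print.feature_field <- function(x, ...) {
  cat(sprintf("<feature_field %d x %d, on in [%.3g, %.3g], off in [%.3g, %.3g]>\n",
              nrow(x$on), ncol(x$on), min(x$on), max(x$on),
              min(x$off), max(x$off)))
  invisible(x)
}

contrast_on <- function(m, cfg) {
  ctr <- gauss_blur(m, cfg$sigma_center)
  sur <- gauss_blur(m, cfg$sigma_surround)
  pmax(ctr - sur, 0) / (cfg$shunt_floor + ctr + sur)
}

#' ON/OFF Contrast Pathway
#'
#' Balanced center-surround shunting network. The ON map is the rectified
#' center-minus-surround response divided by `shunt_floor + center +
#' surround`; it is strong on the bright side of a luminance border and
#' vanishes on uniform regions. The OFF map is the same operator applied to
#' the inverted image, strong on the dark side of the border.
#'
#' @param image A [luminance_image()] (or numeric matrix in `[0, 1]`).
#' @param cfg A [pathway_config()].
#' @return A `feature_field` with nonnegative `on` and `off` maps.
#' @export
contrast_pathway <- function(image, cfg = pathway_config()) {
  m <- as_matrix(luminance_image(as.matrix(image)))
  feature_field(on = contrast_on(m, cfg), off = contrast_on(1 - m, cfg))
}

luminance_on <- function(m, cfg) {
  ctr <- gauss_blur(m, cfg$sigma_center)
  sur <- gauss_blur(m, cfg$sigma_surround)
  pmax(ctr - cfg$luminance_surround_weight * sur, 0)
}

#' ON/OFF Luminance Pathway
#'
#' Center-dominated kernels (the surround lobe is scaled by
#' `luminance_surround_weight < 1`), giving an approximate luminance
#' detector: the ON map increases with local luminance even over uniform
#' areas, and the OFF map is the same operator applied to `1 - I`, strongest
#' over dark regions.
#'
#' @inheritParams contrast_pathway
#' @return A `feature_field`.
#' @export
luminance_pathway <- function(image, cfg = pathway_config()) {
  m <- as_matrix(luminance_image(as.matrix(image)))
  feature_field(on = luminance_on(m, cfg), off = luminance_on(1 - m, cfg))
}

#' Feature input to the filling-in layers
#'
#' The ON (OFF) feature input is the weighted sum of the ON (OFF) Contrast
#' and Luminance Pathway activities, taken separately at each location.
#'
#' @param contrast,luminance `feature_field`s from [contrast_pathway()] and
#'   [luminance_pathway()], same shape.
#' @param cfg A [pathway_config()] supplying `w_contrast`, `w_luminance`.
#' @return A `feature_field`.
#' @export
feature_input <- function(contrast, luminance, cfg = pathway_config()) {
  if (!identical(dim(contrast$on), dim(luminance$on))) {
    stop("contrast and luminance fields must have the same shape")
  }
  feature_field(
    on  = cfg$w_contrast * contrast$on  + cfg$w_luminance * luminance$on,
    off = cfg$w_contrast * contrast$off + cfg$w_luminance * luminance$off
  )
}
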