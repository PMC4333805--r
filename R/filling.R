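# ON/OFF Filling-in Layers: threshold-gated recurrent MAX spreading among
# 4-neighbours on the stimulus lattice, blocked where the boundary gate is
# set, plus the ON - OFF combination into the normalized brightness map.
# The steady state is the boundary-and-support-connected component maximum:
# every supported node adopts the strongest feature signal reachable from it
# without crossing a gated edge; below-threshold nodes neither initiate nor
# relay spreading and simply hold their own feature value, which is what
# stops brightness assimilating across black (and darkness across white).

#' Configuration of the filling-in layers
#'
#' @param fill_threshold_frac Fraction in `(0, 1)` of the layer's maximum
#'   feature input below which a node cannot relay activity. The default
#'   0.1 places black (near-zero ON input after rectification) below and
#'   mid-gray above threshold for the default palette: the layer maximum is
#'   carried by edge contrast peaks (about twice the uniform white-level
#'   input), while a small gray target's interior input is depressed by
#'   surround inhibition to roughly 0.12-0.19 of that maximum.
#' @param tol Convergence tolerance of the fixed-point iteration.
#' @param max_iter Iteration cap.
#' @return A list of class `fill_config`.
#' @export
fill_config <- function(fill_threshold_frac = 0.1, tol = 1e-9,
                        max_iter = 100000L) {
  stopifnot(fill_threshold_frac > 0, fill_threshold_frac < 1,
            tol >= 0, max_iter >= 1)
  structure(list(fill_threshold_frac = fill_threshold_frac, tol = tol,
                 max_iter = as.integer(max_iter)),
            class = "fill_config")
}

#' Filling-in layer (boundary-gated recurrent MAX spreading)
#'
#' Builds the MAX network on the 4-neighbour lattice with feedforward equal
#' to the feature map and support `feature >= fill_threshold_frac * max`,
#' cuts the edge between vertical neighbours wherever the `H` boundary mask
#' is set at either endpoint and between horizontal neighbours wherever the
#' `V` mask is set at either endpoint (1-px contours must not leak), and
#' relaxes to the fixed point. Each supported node ends at the maximum
#' feature over its boundary-and-support-connected component; unsupported
#' nodes keep their own feature value.
#'
#' @param feature Nonnegative numeric matrix of feature input (one of the
#'   maps of [feature_input()]).
#' @param mask A `boundary_mask` from [lg_interaction()].
#' @param cfg A [fill_config()].
#' @return A list with `activity` (matrix), `iterations`, `converged`.
#' @export
fill_layer <- function(feature, mask, cfg = fill_config()) {
  stopifnot(is.matrix(feature), min(feature) >= 0,
            identical(dim(feature), dim(mask$H)))
  thr <- cfg$fill_threshold_frac * max(feature)
  support <- feature >= thr
  h <- mask$H > 0
  v <- mask$V > 0
  # passable lattice edges: from the neighbour in each direction into a cell
  ok_from_up    <- !(h | shift_mat(h,  1, 0, FALSE))  # (r-1,c) -> (r,c)
  ok_from_down  <- !(h | shift_mat(h, -1, 0, FALSE))
  ok_from_left  <- !(v | shift_mat(v, 0,  1, FALSE))
  ok_from_right <- !(v | shift_mat(v, 0, -1, FALSE))
  x <- feature
  it <- 0L
  repeat {
    it <- it + 1L
    relay <- ifelse(support, x, 0)
    cand <- pmax(
      ifelse(ok_from_up,    shift_mat(relay,  1, 0), 0),
      ifelse(ok_from_down,  shift_mat(relay, -1, 0), 0),
      ifelse(ok_from_left,  shift_mat(relay, 0,  1), 0),
      ifelse(ok_from_right, shift_mat(relay, 0, -1), 0)
    )
    xn <- ifelse(support, pmax(feature, cand), feature)
    delta <- max(abs(xn - x))
    x <- xn
    if (delta <= cfg$tol) return(list(activity = x, iterations = it,
                                      converged = TRUE))
    if (it >= cfg$max_iter) {
      warning(sprintf("filling-in hit max_iter with residual %g", delta))
      return(list(activity = x, iterations = it, converged = FALSE))
    }
  }
}

#' Combine the ON and OFF filling-in outputs into a brightness map
#'
#' Subtracts the OFF steady state from the ON steady state and min-max
#' normalizes to `[0, 1]`; a constant difference map (no edges anywhere)
#' normalizes to 0.5 everywhere by convention.
#'
#' @param on_fill,off_fill Steady-state activity matrices.
#' @return An object of class `brightness_map`: list with `values` and the
#'   two provenance fields `on`, `off`.
#' @export
combine_fill <- function(on_fill, off_fill) {
  stopifnot(identical(dim(on_fill), dim(off_fill)))
  d <- on_fill - off_fill
  rng <- range(d)
  values <- if (diff(rng) > 1e-12) (d - rng[1]) / diff(rng) else d * 0 + 0.5
  structure(list(values = values, on = on_fill, off = off_fill),
            class = "brightness_map")
}

#' @export
print.brightness_map <- function(x, ...) {
  cat(sprintf("<brightness_map %d x %d>\n", nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' Full model configuration
#'
#' Bundles the pathway, boundary and filling-in configurations. The
#' facilitation reaches scale with the grid size (defaults are stated at
#' 128 x 128: collinear 15 px, parallel 5 px).
#'
#' @param size Grid size in pixels the reaches are scaled to.
#' @param pathway A [pathway_config()].
#' @param bcs A [bcs_config()]; if omitted, one is built with reaches scaled
#'   by `size / 128`.
#' @param fill A [fill_config()].
#' @return A list of class `model_config`.
#' @export
model_config <- function(size = 128, pathway = pathway_config(),
                         bcs = NULL, fill = fill_config()) {
  if (is.null(bcs)) {
    s <- size / 128
    bcs <- bcs_config(collinear_reach = max(2, round(15 * s)),
                      parallel_reach = max(1, round(5 * s)))
  }
  structure(list(pathway = pathway, bcs = bcs, fill = fill),
            class = "model_config")
}

#' Run the complete brightness model on one image
#'
#' Executes the whole architecture: contrast and luminance pathways (ON and
#' OFF), feature combination, local then global boundary detection, the L/G
#' interaction producing the binary boundary gate, both filling-in layers
#' against that same gate, and the ON - OFF combination. Deterministic.
#'
#' @param image A [luminance_image()] or numeric matrix in `[0, 1]`.
#' @param config A [model_config()]; defaults to one scaled to the image
#'   width.
#' @param verbose Log per-stage timings and iteration counts to stderr.
#' @return An object of class `model_outputs` holding every intermediate
#'   map (`contrast`, `luminance`, `feature`, `lbd`, `gbd`, `mask`,
#'   `on_fill`, `off_fill`) plus the final `brightness` map and a `timing`
#'   data frame.
#' @export
run_model <- function(image, config = NULL, verbose = FALSE) {
  img <- luminance_image(as.matrix(image))
  if (is.null(config)) config <- model_config(size = ncol(img))
  stopifnot(inherits(config, "model_config"))
  times <- c()
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    val <- force(expr)
    times[[name]] <<- proc.time()[["elapsed"]] - t0
    if (verbose) message(sprintf("[contourfill] %-12s %6.2fs", name,
                                 times[[name]]))
    val
  }
  con <- stage("contrast",  contrast_pathway(img, config$pathway))
  lum <- stage("luminance", luminance_pathway(img, config$pathway))
  feat <- stage("feature",  feature_input(con, lum, config$pathway))
  lbd <- stage("lbd",  local_boundaries(con, config$bcs))
  gbd <- stage("gbd",  global_boundaries(lbd, config$bcs))
  msk <- stage("mask", lg_interaction(lbd, gbd, config$bcs))
  onf  <- stage("on_fill",  fill_layer(feat$on, msk, config$fill))
  offf <- stage("off_fill", fill_layer(feat$off, msk, config$fill))
  if (verbose) {
    message(sprintf("[contourfill] fill iterations: on %d, off %d",
                    onf$iterations, offf$iterations))
  }
  br <- combine_fill(onf$activity, offf$activity)
  structure(list(image = img, config = config,
                 contrast = con, luminance = lum, feature = feat,
                 lbd = lbd, gbd = gbd, mask = msk,
                 on_fill = onf, off_fill = offf,
                 brightness = br,
                 timing = data.frame(stage = names(times),
                                     seconds = as.numeric(times))),
            class = "model_outputs")
}

#' @export
print.model_outputs <- function(x, ...) {
  cat(sprintf("<model_outputs %d x %d; fill iterations on=%d off=%d>\n",
              nrow(x$image), ncol(x$image),
              x$on_fill$iterations, x$off_fill$iterations))
  invisible(x)
}
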