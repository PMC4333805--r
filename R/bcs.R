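# Boundary Contour System: oriented Local Boundary Detection (simple nodes
# with offset excitatory/inhibitory lobes, summed into polarity-invariant
# complex nodes, then a feedforward 3x3 MAX), Global Boundary Detection
# (recurrent MAX facilitation along collinear and, to a lesser reach,
# parallel directions), and the L/G Interaction that divides local by global
# and thresholds the ratio into a binary boundary gate. Facilitated
# low-contrast contours have ratio << 1 and are erased from the gate;
# unfacilitated contours keep ratio ~ 1 and survive.

#' Configuration of the boundary system
#'
#' @param lobe_offset Pixels between a simple node's excitatory and
#'   inhibitory lobes (perpendicular to the preferred contour orientation).
#' @param lobe_length Pixels of lobe elongation along the preferred
#'   orientation (odd).
#' @param collinear_reach,parallel_reach Per-step reach, in pixels, of the
#'   recurrent facilitation along the contour orientation and orthogonal to
#'   it. Collinear reach must exceed parallel reach: the extra-classical
#'   receptive field is larger in the collinear direction.
#' @param support_eps Fraction of the global LBD maximum below which a site
#'   carries no contour support: unsupported sites neither relay
#'   facilitation nor emit boundaries (there are no global-boundary signals
#'   on the empty space between contours). Support additionally requires
#'   the site to lie on the crest of its contour (an oriented local maximum
#'   perpendicular to the preferred orientation), so the smooth kernel
#'   tails that flank every contour cannot act as relay corridors between
#'   nearby contours.
#' @param lg_threshold Ratio cutoff in `(0, 1]` of the L/G Interaction. It
#'   must sit strictly between the facilitated low-contrast ratio
#'   (~0.56-0.60 for a half-contrast edge aligned with a full-contrast one
#'   under the default palette) and the smallest within-contour ratio of an
#'   unfacilitated boundary (~0.73, the mid-edge-to-corner ratio produced
#'   by corner amplification of the center-surround kernels), so that
#'   facilitated contours are erased whole while unfacilitated contours are
#'   kept whole. [check_lg_calibration()] verifies both sides on a
#'   step-edge pair.
#' @param lg_eps Absolute LBD floor, as a fraction of the global LBD
#'   maximum, below which no boundary is emitted.
#' @return A list of class `bcs_config`.
#' @export
bcs_config <- function(lobe_offset = 1, lobe_length = 3,
                       collinear_reach = 15, parallel_reach = 5,
                       support_eps = 0.15, lg_threshold = 0.65,
                       lg_eps = 0.02) {
  stopifnot(lobe_offset >= 1, lobe_length >= 1, lobe_length %% 2 == 1,
            collinear_reach >= parallel_reach, parallel_reach >= 1,
            lg_threshold > 0, lg_threshold <= 1,
            support_eps > 0, lg_eps > 0)
  structure(list(lobe_offset = as.integer(lobe_offset),
                 lobe_length = as.integer(lobe_length),
                 collinear_reach = as.integer(collinear_reach),
                 parallel_reach = as.integer(parallel_reach),
                 support_eps = support_eps, lg_threshold = lg_threshold,
                 lg_eps = lg_eps),
            class = "bcs_config")
}

oriented_activity <- function(H, V) {
  structure(list(H = H, V = V), class = "oriented_activity")
}

#' @export
print.oriented_activity <- function(x, ...) {
  cat(sprintf("<oriented_activity %d x %d, max H %.4g, max V %.4g>\n",
              nrow(x$H), ncol(x$H), max(x$H), max(x$V)))
  invisible(x)
}

# shift with replicate borders (for the lobe offset at the image edge)
shift_replicate <- function(m, dr, dc) {
  r <- max(abs(dr), abs(dc))
  mp <- pad_replicate(m, r)
  mp[(r + 1 - dr):(r + nrow(m) - dr), (r + 1 - dc):(r + ncol(m) - dc)]
}

#' Local Boundary Detection
#'
#' Simple nodes have two adjacent rectangular lobes elongated along the
#' preferred orientation and offset by `lobe_offset` perpendicular to it.
#' One lobe combines `+ON - OFF`, the other `+OFF - ON`; the two
#' opposite-polarity simple responses are rectified and summed into a
#' polarity-invariant complex response, which is then dilated by a
#' feedforward 3x3 MAX so corners and junctions are not attenuated.
#' Response magnitude grows with edge contrast.
#'
#' @param contrast A `feature_field` from [contrast_pathway()].
#' @param cfg A [bcs_config()].
#' @return An `oriented_activity` with components `H` (horizontal contours,
#'   i.e. vertical luminance gradient) and `V` (vertical contours).
#' @export
local_boundaries <- function(contrast, cfg = bcs_config()) {
  d <- contrast$on - contrast$off
  # vertical contours: elongate along rows, lobes offset across columns
  sv <- box_filter(d, cfg$lobe_length, "row")
  xv <- sv - shift_replicate(sv, 0, -cfg$lobe_offset)
  # horizontal contours: elongate along columns, lobes offset across rows
  sh <- box_filter(d, cfg$lobe_length, "col")
  xh <- sh - shift_replicate(sh, -1 * cfg$lobe_offset, 0)
  # opposite-polarity simple pair -> complex: [x]_+ + [-x]_+ = |x|
  oriented_activity(H = max3x3(abs(xh)), V = max3x3(abs(xv)))
}

# Contour support per orientation: a site supports (relays, and may emit) a
# boundary only if it exceeds the absolute floor AND lies on the crest of
# its contour -- a local maximum of the oriented response perpendicular to
# the preferred orientation. Without the crest condition, the kernel tails
# that flank every contour (smoothly decaying over ~8 px) form spurious
# relay corridors between nearby parallel contours, and facilitation leaks
# across the empty space the model says it must not cross.
contour_support <- function(lbd, cfg) {
  m <- max(max(lbd$H), max(lbd$V))
  thr <- cfg$support_eps * m
  crest <- function(x, perp_axis) {
    (x > thr) & (x >= run_max(x, 1, perp_axis) - 1e-15)
  }
  list(H = crest(lbd$H, "row"), V = crest(lbd$V, "col"))
}

# one orientation of the recurrent facilitation: window-max over supported
# sites, rectangle |d_collinear| <= cr, |d_parallel| <= pr
facilitate_orientation <- function(ff, support, cr, pr, collinear_axis) {
  par_axis <- if (collinear_axis == "row") "col" else "row"
  x <- ff
  repeat {
    y <- x
    y[!support] <- 0
    wm <- run_max(run_max(y, cr, collinear_axis), pr, par_axis)
    xn <- ifelse(support, pmax(ff, wm), ff)
    if (max(abs(xn - x)) <= 0) return(xn)
    x <- xn
  }
}

#' Global Boundary Detection
#'
#' Recurrent MAX facilitation among like-oriented supported sites: each
#' supported site is linked to supported sites within `collinear_reach`
#' along the contour direction and `parallel_reach` orthogonal to it, and
#' the lattice relaxes to the per-connected-component maximum (the fixed
#' point of the dendritic-inhibition MAX circuit on that graph). Strong
#' boundaries are unchanged; weak supported boundaries aligned with strong
#' ones are raised to the strong level. Facilitation is asymmetric: no
#' site's activity ever drops below its local boundary signal.
#'
#' @param lbd An `oriented_activity` from [local_boundaries()].
#' @param cfg A [bcs_config()].
#' @return An `oriented_activity` of facilitated (global) boundary signals.
#' @export
global_boundaries <- function(lbd, cfg = bcs_config()) {
  sup <- contour_support(lbd, cfg)
  oriented_activity(
    H = facilitate_orientation(lbd$H, sup$H, cfg$collinear_reach,
                               cfg$parallel_reach, "col"),
    V = facilitate_orientation(lbd$V, sup$V, cfg$collinear_reach,
                               cfg$parallel_reach, "row")
  )
}

boundary_mask <- function(H, V) {
  structure(list(H = H, V = V), class = "boundary_mask")
}

#' @export
print.boundary_mask <- function(x, ...) {
  cat(sprintf("<boundary_mask %d x %d, %d H sites, %d V sites>\n",
              nrow(x$H), ncol(x$H), sum(x$H), sum(x$V)))
  invisible(x)
}

#' Local/Global Interaction
#'
#' Computes, per orientation and location, the ratio of the local to the
#' global boundary signal and emits a binary gate: 1 where the ratio crosses
#' `lg_threshold` (no facilitation happened, the boundary is kept and blocks
#' filling-in), 0 where the ratio falls below it (the boundary was
#' facilitated by a stronger aligned contour and is erased). Boundaries are
#' only ever emitted on supported contour sites whose local signal exceeds
#' the absolute floor `lg_eps`, so the gate is a subset of the contour
#' support and the division is always well defined (off support,
#' `gbd = lbd` and the site is simply not gated).
#'
#' @param lbd,gbd `oriented_activity` maps from [local_boundaries()] and
#'   [global_boundaries()].
#' @param cfg A [bcs_config()].
#' @return A `boundary_mask` with logical `H` and `V` components.
#' @export
lg_interaction <- function(lbd, gbd, cfg = bcs_config()) {
  if (!identical(dim(lbd$H), dim(gbd$H))) stop("shape mismatch")
  m <- max(max(lbd$H), max(lbd$V))
  sup <- contour_support(lbd, cfg)
  gate <- function(l, g, s) {
    s & (l > cfg$lg_eps * m) & (l >= cfg$lg_threshold * g)
  }
  boundary_mask(H = gate(lbd$H, gbd$H, sup$H),
                V = gate(lbd$V, gbd$V, sup$V))
}

#' Verify the L/G threshold calibration on a step-edge pair
#'
#' Builds a calibration image holding a full-contrast step edge collinear
#' with a half-contrast step edge (black/white vs black/gray), runs the
#' boundary stages, and checks that the facilitated half-contrast edge's
#' local-to-global ratio falls strictly below `lg_threshold` while the
#' unfacilitated full-contrast edge keeps a ratio of 1 at or above it.
#'
#' @param cfg A [bcs_config()].
#' @param pcfg A [pathway_config()].
#' @param levels Palette used for the calibration edges.
#' @return Invisibly, a list with the measured facilitated ratio; errors if
#'   the threshold is outside the admissible band.
#' @export
check_lg_calibration <- function(cfg = bcs_config(), pcfg = pathway_config(),
                                 levels = c(black = 0, gray = 0.5, white = 1)) {
  # 64x64: left half black; right half white on top, gray below, so the
  # vertical black|white edge is collinear with the vertical black|gray edge.
  img <- matrix(levels[["black"]], 64, 64)
  img[1:32, 33:64] <- levels[["white"]]
  img[33:64, 33:64] <- levels[["gray"]]
  lbd <- local_boundaries(contrast_pathway(luminance_image(img), pcfg), cfg)
  gbd <- global_boundaries(lbd, cfg)
  # probe the crest of each edge segment away from corners
  strong <- lbd$V[8, ] >= 0.999 * max(lbd$V[8, ])
  ratio_strong <- min(lbd$V[8, strong] / gbd$V[8, strong])
  weak <- lbd$V[56, ] >= 0.999 * max(lbd$V[56, ])
  ratio_weak <- max(lbd$V[56, weak] / gbd$V[56, weak])
  if (!(ratio_weak < cfg$lg_threshold)) {
    stop(sprintf(paste0("lg_threshold %.3f does not erase the facilitated ",
                        "half-contrast edge (ratio %.3f)"),
                 cfg$lg_threshold, ratio_weak))
  }
  if (!(ratio_strong >= cfg$lg_threshold)) {
    stop(sprintf(paste0("lg_threshold %.3f erases the unfacilitated ",
                        "full-contrast edge (ratio %.3f)"),
                 cfg$lg_threshold, ratio_strong))
  }
  invisible(list(facilitated_ratio = ratio_weak,
                 unfacilitated_ratio = ratio_strong))
}
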