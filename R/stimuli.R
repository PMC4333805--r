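# Parametric, deterministic generators for the classic brightness-illusion
# battery. Every case is rectilinear (ring/bullseye patterns are rendered as
# nested squares, the cube illusion in its reduced corner-bracket form), uses
# a crisp palette with no anti-aliasing, and is bundled with eroded target
# masks and the predicted brightness relation. Geometry is authored on a
# 128 x 128 reference grid and scaled to the requested size.
#
# Geometry rationale (at the 128 reference): element edges that must be
# facilitated sit within the boundary system's reach -- collinear gaps are
# at most 8 px (reach 15) and parallel spacings at most 4 px (reach 5) --
# while edges that must survive keep their nearest like-oriented stronger
# contour at least 16 px away: the oriented-response tails of two contours
# closer than that can overlap into a crest ridge that relays facilitation
# across the gap. Weak edges that must be erased are >= 12 px long so they
# have a true mid-segment well below the corner-amplified level.

STIMULUS_NAMES <- c("dungeon", "cube", "grating", "rings", "bullseye",
                    "sbc", "white", "benary", "todorovic",
                    "checkerboard", "checkerboard_extended",
                    "contrast_contrast", "white_yazdanbakhsh",
                    "white_anderson", "white_howe", "white_inverted")

#' List the stimulus registry
#'
#' @return A data frame with one row per stimulus: `name`, the predicted
#'   `relation`, the evaluation `statistic`, and the default profile `row`
#'   (at the 128 reference size), in stable registry order.
#' @export
list_stimuli <- function() {
  info <- lapply(STIMULUS_NAMES, function(nm) {
    case <- generate_stimulus(nm)
    data.frame(name = nm, relation = case$relation,
               statistic = case$statistic, row = case$params$row,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, info)
}

#' Generate a battery stimulus with target masks and predicted relation
#'
#' Deterministic (seed-free): identical `name` and `params` give
#' bit-identical grids. The default palette is black = 0, gray = 0.5,
#' white = 1; the symmetric gray makes the ON and OFF networks mirror each
#' other. Target masks mark the interior of each gray target with a 1-px
#' rim excluded, so that target statistics are not contaminated by edge
#' kernels.
#'
#' @param name One of the 16 registry identifiers (see [list_stimuli()]).
#' @param params Optional list overriding generator parameters: `size`
#'   (grid side, >= 64), `levels` (named palette `black`, `gray`, `white`),
#'   and per-case extras (`offset` for the Anderson/Howe variants;
#'   `center_amp`, `surround_hi_amp`, `surround_lo_amp` for
#'   contrast-contrast).
#' @return An object of class `illusion_case`: list with `name`, `image`
#'   ([luminance_image()]), `target_masks` (named logical matrices `A`,
#'   `B`), `relation` (`A_brighter_than_B`, `A_equals_B` or
#'   `A_lower_contrast_than_B`), `statistic` (`mean_difference` or
#'   `rms_contrast_difference`), `uniform_targets` (FALSE only for the
#'   textured contrast-contrast targets) and `params`.
#' @export
generate_stimulus <- function(name, params = list()) {
  if (!is.character(name) || length(name) != 1 || !(name %in% STIMULUS_NAMES)) {
    stop("unknown stimulus name: ", paste(name, collapse = ", "))
  }
  p <- utils::modifyList(list(size = 128L,
                              levels = c(black = 0, gray = 0.5, white = 1)),
                         params)
  size <- as.integer(p$size)
  if (size < 64) stop("grid size must be at least 64")
  lv <- p$levels
  stopifnot(all(c("black", "gray", "white") %in% names(lv)),
            lv[["black"]] < lv[["gray"]], lv[["gray"]] < lv[["white"]])
  gen <- switch(name,
    dungeon = stim_dungeon, cube = stim_cube, grating = stim_grating,
    rings = stim_rings, bullseye = stim_bullseye, sbc = stim_sbc,
    white = stim_white, benary = stim_benary, todorovic = stim_todorovic,
    checkerboard = stim_checkerboard,
    checkerboard_extended = stim_checkerboard_extended,
    contrast_contrast = stim_contrast_contrast,
    white_yazdanbakhsh = stim_white_yazdanbakhsh,
    white_anderson = stim_white_anderson, white_howe = stim_white_howe,
    white_inverted = stim_white_inverted)
  out <- gen(size, lv, p)
  finalize_case(name, out, p)
}

# --- plumbing ---------------------------------------------------------------

# scale a 128-reference coordinate to the working size (1-based, clamped)
ref_scaler <- function(size) {
  u <- size / 128
  function(x) pmax(1L, pmin(size, as.integer(round(x * u))))
}

paint <- function(img, r1, r2, c1, c2, val) {
  img[r1:r2, c1:c2] <- val
  img
}

region_mask <- function(size, r1, r2, c1, c2) {
  m <- matrix(FALSE, size, size)
  m[r1:r2, c1:c2] <- TRUE
  m
}

finalize_case <- function(name, out, p) {
  img <- luminance_image(out$img)
  masks <- lapply(out$masks, function(m) erode3x3(m))
  if (any(vapply(masks, sum, 0L) == 0)) {
    stop("degenerate (zero-area) target mask for stimulus ", name)
  }
  if (sum(masks$A & masks$B) > 0) stop("target masks overlap for ", name)
  uniform <- !identical(name, "contrast_contrast")
  if (uniform) {
    for (m in masks) {
      if (length(unique(as.vector(out$img[m]))) != 1) {
        stop("target mask covers more than one luminance for ", name)
      }
    }
  }
  p$row <- out$row
  structure(list(name = name, image = img, target_masks = masks,
                 relation = out$relation, statistic = out$statistic,
                 uniform_targets = uniform, params = p),
            class = "illusion_case")
}

#' @export
print.illusion_case <- function(x, ...) {
  cat(sprintf("<illusion_case '%s' %dx%d, relation %s (%s)>\n", x$name,
              nrow(x$image), ncol(x$image), x$relation, x$statistic))
  invisible(x)
}

# --- individual generators --------------------------------------------------
# A is always the target the relation statement puts first.

stim_sbc <- function(size, lv, p) {
  s <- ref_scaler(size)
  img <- matrix(lv[["black"]], size, size)
  img <- paint(img, 1, size, s(65), size, lv[["white"]])
  img <- paint(img, s(53), s(76), s(21), s(44), lv[["gray"]])   # on black
  img <- paint(img, s(53), s(76), s(85), s(108), lv[["gray"]])  # on white
  list(img = img,
       masks = list(A = region_mask(size, s(53), s(76), s(21), s(44)),
                    B = region_mask(size, s(53), s(76), s(85), s(108))),
       relation = "A_brighter_than_B", statistic = "mean_difference",
       row = s(64))
}

stim_dungeon <- function(size, lv, p) {
  s <- ref_scaler(size)
  img <- matrix(lv[["black"]], size, size)
  img <- paint(img, 1, size, 1, s(64), lv[["white"]])
  row_starts <- c(18, 38, 58, 78, 98)      # 12-px squares, 8-px gaps
  col_starts <- list(left = c(7, 27, 47), right = c(71, 91, 111))
  mA <- matrix(FALSE, size, size); mB <- matrix(FALSE, size, size)
  for (side in names(col_starts)) {
    left <- side == "left"
    for (r0 in row_starts) {
      for (c0 in col_starts[[side]]) {
        gray_here <- r0 == 58 && c0 %in% c(27, 91)  # centre of each lattice
        val <- if (gray_here) lv[["gray"]]
               else if (left) lv[["black"]] else lv[["white"]]
        img <- paint(img, s(r0), s(r0 + 11), s(c0), s(c0 + 11), val)
        if (gray_here) {
          reg <- region_mask(size, s(r0), s(r0 + 11), s(c0), s(c0 + 11))
          if (left) mA <- mA | reg else mB <- mB | reg
        }
      }
    }
  }
  list(img = img, masks = list(A = mA, B = mB),
       relation = "A_brighter_than_B", statistic = "mean_difference",
       row = s(64))
}

stim_cube <- function(size, lv, p) {
  s <- ref_scaler(size)
  # reduced rectilinear cube: a hollow square outline (12-px bands) whose
  # corners are L-brackets and whose side middles are gray bars, separated
  # from the brackets by 8-px gaps. Bands are 12 px thick so bar edges
  # behave like plain step edges (thin strips would let the two edge
  # responses reinforce each other and resist facilitation). One cube with
  # black corners on the white half, one with white corners on the black
  # half (top/bottom halves).
  img <- matrix(lv[["black"]], size, size)
  img <- paint(img, 1, s(64), 1, size, lv[["white"]])
  half <- function(img, dy, corner, bar) {
    # outline rows 5:60 (+dy), cols 37:92; bands 12 px; brackets 14 long
    img <- paint(img, s(5 + dy), s(16 + dy), s(37), s(50), corner)   # TL h
    img <- paint(img, s(5 + dy), s(18 + dy), s(37), s(48), corner)   # TL v
    img <- paint(img, s(5 + dy), s(16 + dy), s(79), s(92), corner)   # TR h
    img <- paint(img, s(5 + dy), s(18 + dy), s(81), s(92), corner)   # TR v
    img <- paint(img, s(49 + dy), s(60 + dy), s(37), s(50), corner)  # BL h
    img <- paint(img, s(47 + dy), s(60 + dy), s(37), s(48), corner)  # BL v
    img <- paint(img, s(49 + dy), s(60 + dy), s(79), s(92), corner)  # BR h
    img <- paint(img, s(47 + dy), s(60 + dy), s(81), s(92), corner)  # BR v
    img <- paint(img, s(5 + dy), s(16 + dy), s(59), s(70), bar)      # top
    img <- paint(img, s(49 + dy), s(60 + dy), s(59), s(70), bar)     # bottom
    img <- paint(img, s(27 + dy), s(38 + dy), s(37), s(48), bar)     # left
    img <- paint(img, s(27 + dy), s(38 + dy), s(81), s(92), bar)     # right
    img
  }
  img <- half(img, 0, lv[["black"]], lv[["gray"]])
  img <- half(img, 64, lv[["white"]], lv[["gray"]])
  bars <- function(dy) {
    region_mask(size, s(5 + dy), s(16 + dy), s(59), s(70)) |
      region_mask(size, s(49 + dy), s(60 + dy), s(59), s(70)) |
      region_mask(size, s(27 + dy), s(38 + dy), s(37), s(48)) |
      region_mask(size, s(27 + dy), s(38 + dy), s(81), s(92))
  }
  list(img = img, masks = list(A = bars(0), B = bars(64)),
       relation = "A_brighter_than_B", statistic = "mean_difference",
       row = s(32))
}

stim_grating <- function(size, lv, p) {
  s <- ref_scaler(size)
  img <- matrix(lv[["black"]], size, size)
  img <- paint(img, 1, size, 1, s(64), lv[["white"]])
  for (c0 in c(5, 17, 29, 41, 53)) {   # 8-px bars, 4-px gaps
    for (dx in c(0, 64)) {
      bar <- if (dx == 0) lv[["black"]] else lv[["white"]]
      val <- if (c0 == 29) lv[["gray"]] else bar
      img <- paint(img, s(49), s(80), s(c0 + dx), s(c0 + 7 + dx), val)
    }
  }
  list(img = img,
       masks = list(A = region_mask(size, s(49), s(80), s(29), s(36)),
                    B = region_mask(size, s(49), s(80), s(93), s(100))),
       relation = "A_brighter_than_B", statistic = "mean_difference",
       row = s(64))
}

# nested-square ring painter: half-sizes and colors outside-in around a
# center (rc, cc) given in 128-reference coordinates
paint_rings <- function(img, s, rc, cc, half_sizes, cols) {
  for (i in seq_along(half_sizes)) {
    hs <- half_sizes[i]
    img <- paint(img, s(rc - hs + 1), s(rc + hs), s(cc - hs + 1), s(cc + hs),
                 cols[i])
  }
  img
}

ring_band_mask <- function(size, s, rc, cc, hs_out, hs_in) {
  region_mask(size, s(rc - hs_out + 1), s(rc + hs_out),
              s(cc - hs_out + 1), s(cc + hs_out)) &
    !region_mask(size, s(rc - hs_in + 1), s(rc + hs_in),
                 s(cc - hs_in + 1), s(cc + hs_in))
}

stim_rings <- function(size, lv, p) {
  s <- ref_scaler(size)
  img <- matrix(lv[["gray"]], size, size)
  hs <- c(26, 22, 18, 14, 10, 6)
  img <- paint_rings(img, s, 64, 32, hs,
                     c(lv[["black"]], lv[["white"]], lv[["black"]],
                       lv[["white"]], lv[["gray"]], lv[["white"]]))
  img <- paint_rings(img, s, 64, 96, hs,
                     c(lv[["white"]], lv[["black"]], lv[["white"]],
                       lv[["black"]], lv[["gray"]], lv[["black"]]))
  list(img = img,
       masks = list(A = ring_band_mask(size, s, 64, 32, 10, 6),
                    B = ring_band_mask(size, s, 64, 96, 10, 6)),
       relation = "A_brighter_than_B", statistic = "mean_difference",
       row = s(64))
}

stim_bullseye <- function(size, lv, p) {
  s <- ref_scaler(size)
  img <- matrix(lv[["gray"]], size, size)
  hs <- c(26, 22, 18, 14, 10, 6)
  img <- paint_rings(img, s, 64, 32, hs,
                     c(lv[["white"]], lv[["black"]], lv[["white"]],
                       lv[["black"]], lv[["white"]], lv[["gray"]]))
  img <- paint_rings(img, s, 64, 96, hs,
                     c(lv[["black"]], lv[["white"]], lv[["black"]],
                       lv[["white"]], lv[["black"]], lv[["gray"]]))
  list(img = img,
       masks = list(A = region_mask(size, s(59), s(70), s(27), s(38)),
                    B = region_mask(size, s(59), s(70), s(91), s(102))),
       relation = "A_brighter_than_B", statistic = "mean_difference",
       row = s(64))
}

# square-wave grating shared by the White-family stimuli: 16 bars of 8 px,
# odd bars `dark`, even bars `light`
white_grating <- function(size, s, dark, light) {
  img <- matrix(dark, size, size)
  for (k in seq(2, 16, by = 2)) {
    img <- paint(img, 1, size, s(8 * k - 7), s(8 * k), light)
  }
  img
}

stim_white <- function(size, lv, p) {
  s <- ref_scaler(size)
  img <- white_grating(size, s, lv[["black"]], lv[["white"]])
  img <- paint(img, s(53), s(76), s(33), s(40), lv[["gray"]])  # on black bar
  img <- paint(img, s(53), s(76), s(89), s(96), lv[["gray"]])  # on white bar
  list(img = img,
       masks = list(A = region_mask(size, s(53), s(76), s(33), s(40)),
                    B = region_mask(size, s(53), s(76), s(89), s(96))),
       relation = "A_brighter_than_B", statistic = "mean_difference",
       row = s(64))
}

stim_white_yazdanbakhsh <- function(size, lv, p) {
  s <- ref_scaler(size)
  img <- white_grating(size, s, lv[["black"]], lv[["white"]])
  # gap strips detach each target from its coaxial bar, so the target is
  # completely surrounded by the opposite-polarity surround
  img <- paint(img, s(49), s(52), s(33), s(40), lv[["white"]])
  img <- paint(img, s(77), s(80), s(33), s(40), lv[["white"]])
  img <- paint(img, s(53), s(76), s(33), s(40), lv[["gray"]])
  img <- paint(img, s(49), s(52), s(89), s(96), lv[["black"]])
  img <- paint(img, s(77), s(80), s(89), s(96), lv[["black"]])
  img <- paint(img, s(53), s(76), s(89), s(96), lv[["gray"]])
  list(img = img,
       masks = list(A = region_mask(size, s(53), s(76), s(33), s(40)),
                    B = region_mask(size, s(53), s(76), s(89), s(96))),
       relation = "A_brighter_than_B", statistic = "mean_difference",
       row = s(64))
}

# grating with a phase-reversal band: inside rows 53:76 every bar flips
# color except the protected bars around each target. The targets sit
# `offset` reference rows above the band. With `frame = TRUE`, a white
# stripe along the top and a black stripe along the bottom connect all
# white regions into one brightness system and all black regions into one
# darkness system, so that when every target border is erased (the Howe
# arrangement) the ON and OFF assimilation draw on identical component
# maxima and cancel exactly.
white_variant_base <- function(size, lv, s, offset, frame = FALSE) {
  img <- white_grating(size, s, lv[["black"]], lv[["white"]])
  protected <- c(4, 5, 6, 11, 12, 13)
  for (k in setdiff(1:16, protected)) {
    val <- if (k %% 2 == 1) lv[["white"]] else lv[["black"]]
    img <- paint(img, s(53), s(76), s(8 * k - 7), s(8 * k), val)
  }
  if (frame) {
    img <- paint(img, 1, s(4), 1, size, lv[["white"]])
    img <- paint(img, s(125), size, 1, size, lv[["black"]])
  }
  r1 <- 53 - offset; r2 <- 76 - offset
  img <- paint(img, s(r1), s(r2), s(33), s(40), lv[["gray"]])
  img <- paint(img, s(r1), s(r2), s(89), s(96), lv[["gray"]])
  list(img = img,
       masks = list(A = region_mask(size, s(r1), s(r2), s(33), s(40)),
                    B = region_mask(size, s(r1), s(r2), s(89), s(96))),
       row = s(round((r1 + r2) / 2)))
}

stim_white_howe <- function(size, lv, p) {
  offset <- if (is.null(p$offset)) 0 else p$offset
  out <- white_variant_base(size, lv, ref_scaler(size), offset, frame = TRUE)
  out$relation <- "A_equals_B"; out$statistic <- "mean_difference"
  out
}

stim_white_anderson <- function(size, lv, p) {
  offset <- if (is.null(p$offset)) 40 else p$offset
  if (offset < 16) {
    stop("anderson offset must move the targets clear of the reversal band")
  }
  out <- white_variant_base(size, lv, ref_scaler(size), offset)
  out$relation <- "A_brighter_than_B"; out$statistic <- "mean_difference"
  out
}

stim_white_inverted <- function(size, lv, p) {
  s <- ref_scaler(size)
  img <- white_grating(size, s, lv[["black"]], lv[["gray"]])
  # the white targets carry the highest-contrast edges themselves, so no
  # facilitation from the weaker grating can erase them: contrast direction
  img <- paint(img, s(53), s(76), s(89), s(96), lv[["white"]])  # A: gray bar
  img <- paint(img, s(53), s(76), s(33), s(40), lv[["white"]])  # B: black bar
  list(img = img,
       masks = list(A = region_mask(size, s(53), s(76), s(89), s(96)),
                    B = region_mask(size, s(53), s(76), s(33), s(40))),
       relation = "A_brighter_than_B", statistic = "mean_difference",
       row = s(64))
}

stim_benary <- function(size, lv, p) {
  s <- ref_scaler(size)
  img <- matrix(lv[["white"]], size, size)
  img <- paint(img, s(33), s(64), s(9), s(120), lv[["black"]])   # horizontal arm
  img <- paint(img, s(9), s(120), s(53), s(76), lv[["black"]])   # vertical arm
  # A sits inside the arm flush with its lower boundary, so A's bottom
  # border lies on the same line as the strong black-white arm contour
  # (erased -> brightness assimilates from the white ground). B hangs from
  # the same line on the white ground (erased -> darkness assimilates from
  # the arm). All other target borders stay >= 16 px from any strong
  # like-oriented contour and survive.
  img <- paint(img, s(49), s(64), s(93), s(104), lv[["gray"]])   # A: on cross
  img <- paint(img, s(65), s(80), s(25), s(36), lv[["gray"]])    # B: on ground
  list(img = img,
       masks = list(A = region_mask(size, s(49), s(64), s(93), s(104)),
                    B = region_mask(size, s(65), s(80), s(25), s(36))),
       relation = "A_brighter_than_B", statistic = "mean_difference",
       row = s(58))
}

stim_todorovic <- function(size, lv, p) {
  s <- ref_scaler(size)
  img <- matrix(lv[["black"]], size, size)
  img <- paint(img, 1, size, s(65), size, lv[["white"]])
  half <- function(img, dx, occluder) {
    img <- paint(img, s(49), s(80), s(17 + dx), s(48 + dx), lv[["gray"]])
    for (r0 in c(39, 71)) for (c0 in c(7, 39)) {
      img <- paint(img, s(r0), s(r0 + 19), s(c0 + dx), s(c0 + 19 + dx),
                   occluder)
    }
    img
  }
  img <- half(img, 0, lv[["white"]])
  img <- half(img, 64, lv[["black"]])
  plus_mask <- function(dx) {
    sq <- region_mask(size, s(49), s(80), s(17 + dx), s(48 + dx))
    occ <- matrix(FALSE, size, size)
    for (r0 in c(39, 71)) for (c0 in c(7, 39)) {
      occ <- occ | region_mask(size, s(r0), s(r0 + 19),
                               s(c0 + dx), s(c0 + 19 + dx))
    }
    sq & !occ
  }
  list(img = img, masks = list(A = plus_mask(0), B = plus_mask(64)),
       relation = "A_brighter_than_B", statistic = "mean_difference",
       row = s(64))
}

checkerboard_img <- function(size, check_ref, s, lo, hi) {
  check <- max(2L, as.integer(round(check_ref * size / 128)))
  idx <- function(x) ((x - 1L) %/% check)
  r <- idx(seq_len(size)); c <- idx(seq_len(size))
  par <- outer(r, c, function(a, b) (a + b) %% 2L)
  ifelse(par == 0L, hi, lo)
}

check_region <- function(size, check_ref, i, j) {
  check <- max(2L, as.integer(round(check_ref * size / 128)))
  region_mask(size, (i - 1L) * check + 1L, min(size, i * check),
              (j - 1L) * check + 1L, min(size, j * check))
}

stim_checkerboard <- function(size, lv, p) {
  img <- checkerboard_img(size, 16, ref_scaler(size), lv[["black"]],
                          lv[["white"]])
  a <- check_region(size, 16, 4, 3)   # (4+3) odd: black check, white flanks
  b <- check_region(size, 16, 4, 6)   # (4+6) even: white check, black flanks
  img[a] <- lv[["gray"]]; img[b] <- lv[["gray"]]
  list(img = img, masks = list(A = a, B = b),
       relation = "A_brighter_than_B", statistic = "mean_difference",
       row = floor(3.5 * max(2L, as.integer(round(16 * size / 128)))))
}

stim_checkerboard_extended <- function(size, lv, p) {
  img <- checkerboard_img(size, 8, ref_scaler(size), lv[["black"]],
                          lv[["white"]])
  a <- check_region(size, 8, 8, 5)    # odd sum: white flanks
  b <- check_region(size, 8, 8, 12)   # even sum: black flanks
  img[a] <- lv[["gray"]]; img[b] <- lv[["gray"]]
  list(img = img, masks = list(A = a, B = b),
       relation = "A_brighter_than_B", statistic = "mean_difference",
       row = floor(7.5 * max(2L, as.integer(round(8 * size / 128)))))
}

stim_contrast_contrast <- function(size, lv, p) {
  s <- ref_scaler(size)
  mid <- lv[["gray"]]
  ca <- if (is.null(p$center_amp)) 0.1 else p$center_amp
  sh <- if (is.null(p$surround_hi_amp)) 0.5 else p$surround_hi_amp
  sl <- if (is.null(p$surround_lo_amp)) 0.05 else p$surround_lo_amp
  stopifnot(sl < ca, ca < sh)
  # 12-px check grids; each centre patch (3x3 checks) shares its grid with
  # its own surround so the patch edges are collinear with the surround
  # edges. The right half's grid is shifted by half a check vertically so
  # its grid lines are NOT collinear with the strong left-surround lines,
  # and the right patch sits 20 px from the half border: otherwise the
  # left surround would facilitate (and erase) the right patch's edges.
  check <- max(2L, as.integer(round(12 * size / 128)))
  half_shift <- check %/% 2L
  idx <- function(x) ((x - 1L) %/% check)
  rows <- seq_len(size); cols <- seq_len(size)
  par_l <- outer(idx(rows), idx(cols), function(a, b) (a + b) %% 2L)
  par_r <- outer(idx(rows + half_shift), idx(cols),
                 function(a, b) (a + b) %% 2L)
  right <- col(par_l) > s(64)
  par <- ifelse(right, par_r, par_l)
  amp <- matrix(sl, size, size)                       # right surround
  amp[, 1:s(64)] <- sh                                # left surround
  ctr_a <- region_mask(size, 4L * check + 1L, min(size, 7L * check),
                       check + 1L, min(size, 4L * check))
  ctr_b <- region_mask(size,
                       4L * check + 1L + half_shift,
                       min(size, 7L * check + half_shift),
                       min(size, 7L * check) + 1L, min(size, 10L * check))
  amp[ctr_a | ctr_b] <- ca                            # both centre patches
  img <- mid + ifelse(par == 0L, amp, -amp)
  list(img = img, masks = list(A = ctr_a, B = ctr_b),
       relation = "A_lower_contrast_than_B",
       statistic = "rms_contrast_difference", row = s(64))
}
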