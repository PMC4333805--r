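# Low-level raster helpers shared by the pathway, boundary and filling stages.
# All fields are plain numeric matrices indexed [row, col]; row 1 is the top
# of the image so "vertical" always means along rows.

#' Construct a luminance image
#'
#' Wraps a numeric matrix of luminance values in `[0, 1]` with light
#' validation. This is the input type of the whole model; stimulus generators
#' return one inside their [illusion_case()].
#'
#' @param grid Numeric matrix with all values in `[0, 1]`.
#' @return An object of class `luminance_image` (a matrix with a class
#'   attribute); `nrow()`/`ncol()` give height and width in pixels.
#' @export
luminance_image <- function(grid) {
  if (!is.matrix(grid) || !is.numeric(grid)) {
    stop("`grid` must be a numeric matrix")
  }
  if (anyNA(grid) || min(grid) < 0 || max(grid) > 1) {
    stop("luminance values must lie in [0, 1] and contain no NA")
  }
  structure(grid, class = c("luminance_image", "matrix"))
}

#' @export
print.luminance_image <- function(x, ...) {
  cat(sprintf("<luminance_image %d x %d, levels: %s>\n",
              nrow(x), ncol(x),
              paste(format(sort(unique(as.vector(x)))), collapse = ", ")))
  invisible(x)
}

as_matrix <- function(x) {
  if (inherits(x, "luminance_image")) x <- unclass(x)
  x
}

# Shift a matrix by (dr, dc); vacated cells take `fill`.
shift_mat <- function(m, dr, dc, fill = 0) {
  h <- nrow(m); w <- ncol(m)
  out <- matrix(fill, h, w)
  rs <- max(1, 1 + dr):min(h, h + dr)
  cs <- max(1, 1 + dc):min(w, w + dc)
  if (length(rs) < 1 || length(cs) < 1) return(out)
  out[rs, cs] <- m[rs - dr, cs - dc]
  out
}

# Replicate-pad a matrix by `r` pixels on every side.
pad_replicate <- function(m, r) {
  if (r == 0) return(m)
  ri <- c(rep(1L, r), seq_len(nrow(m)), rep(nrow(m), r))
  ci <- c(rep(1L, r), seq_len(ncol(m)), rep(ncol(m), r))
  m[ri, ci]
}

# Separable 1-D convolution along rows (axis = "col" smears across columns)
# with replicate border handling. `k` is an odd-length kernel.
conv1 <- function(m, k, axis = c("row", "col")) {
  axis <- match.arg(axis)
  r <- (length(k) - 1L) %/% 2L
  h <- nrow(m); w <- ncol(m)
  mp <- pad_replicate(m, r)
  out <- matrix(0, h, w)
  for (i in seq_along(k)) {
    off <- i - 1L - r
    if (axis == "row") {
      out <- out + k[i] * mp[(r + 1 + off):(r + h + off), (r + 1):(r + w)]
    } else {
      out <- out + k[i] * mp[(r + 1):(r + h), (r + 1 + off):(r + w + off)]
    }
  }
  out
}

gaussian_kernel <- function(sigma) {
  r <- max(1L, ceiling(3.5 * sigma))
  k <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  k / sum(k)
}

# Isotropic Gaussian blur, unit-mass kernel, replicate padding.
gauss_blur <- function(m, sigma) {
  k <- gaussian_kernel(sigma)
  conv1(conv1(m, k, "row"), k, "col")
}

# Centered box filter of odd length `len` along the given axis.
box_filter <- function(m, len, axis) {
  conv1(m, rep(1 / len, len), axis)
}

# Greyscale dilation (running maximum) over offsets -k..k along an axis,
# zero-padded so image borders do not wrap.
run_max <- function(m, k, axis = c("row", "col")) {
  axis <- match.arg(axis)
  out <- m
  if (k < 1) return(out)
  for (off in seq_len(k)) {
    if (axis == "row") {
      out <- pmax(out, shift_mat(m, off, 0), shift_mat(m, -off, 0))
    } else {
      out <- pmax(out, shift_mat(m, 0, off), shift_mat(m, 0, -off))
    }
  }
  out
}

# 3x3 maximum filter (feedforward MAX of the complex nodes).
max3x3 <- function(m) run_max(run_max(m, 1, "row"), 1, "col")

# Binary erosion with a 3x3 structuring element; `m` is logical/0-1.
erode3x3 <- function(m) {
  m <- m > 0
  out <- m
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    out <- out & shift_mat(m, dr, dc, fill = FALSE)
  }
  out
}

#' Write a numeric grid as plain-text CSV
#'
#' @param grid Numeric matrix (image, activity map or mask).
#' @param path Output file path.
#' @export
write_grid_csv <- function(grid, path) {
  utils::write.table(as_matrix(grid), path, sep = ",",
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a numeric grid written by [write_grid_csv()]
#'
#' @param path CSV file path.
#' @return Numeric matrix.
#' @export
read_grid_csv <- function(path) {
  as.matrix(utils::read.table(path, sep = ",", header = FALSE))
}

#' Write a grid as an 8-bit greyscale PNG
#'
#' Uses the display convention of the activity panels: minimum activity maps
#' to black, maximum to white (min-max scaling). Requires a PNG-capable
#' graphics device; falls back with a warning if none is available.
#'
#' @param grid Numeric matrix.
#' @param path Output PNG path.
#' @param rescale Min-max scale to `[0, 1]` before writing (default `TRUE`).
#' @export
write_grid_png <- function(grid, path, rescale = TRUE) {
  m <- as_matrix(grid)
  if (rescale) {
    rng <- range(m)
    m <- if (diff(rng) > 0) (m - rng[1]) / diff(rng) else m * 0 + 0.5
  }
  m <- pmin(pmax(m, 0), 1)
  ok <- tryCatch({
    grDevices::png(path, width = ncol(m), height = nrow(m))
    graphics::par(mar = c(0, 0, 0, 0))
    graphics::image(t(m[nrow(m):1, , drop = FALSE]), col = grDevices::gray(0:255 / 255),
                    axes = FALSE, useRaster = TRUE, zlim = c(0, 1))
    grDevices::dev.off()
    TRUE
  }, error = function(e) {
    warning("PNG device unavailable: ", conditionMessage(e))
    FALSE
  })
  invisible(if (ok) path else NULL)
}
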