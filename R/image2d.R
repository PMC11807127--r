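#' 2D intensity image with axis conventions
#'
#' A light wrapper around a numeric matrix carrying the metadata all feature
#' computations need: the physical pixel size and the sign convention for the
#' y axis. Pixel coordinates are 0-based with pixel centres at integer
#' `(x, y)`; `x` is the column index, `y` the row index. `y_axis_sign = -1`
#' (the default) encodes the usual raster storage where row 0 is the top of
#' the image and y grows downward; `+1` encodes a mathematical y-up frame.
#' All reported angles are corrected by this sign so they refer to the
#' conventional counter-clockwise frame regardless of storage order.
#'
#' @param values numeric matrix of intensities (rows = y, columns = x).
#' @param pixel_size optional physical edge length of one pixel (micrometres).
#' @param y_axis_sign `+1` if the y axis points up, `-1` (default) if down.
#' @return An object of class `image2d`: the matrix with attributes
#'   `pixel_size` and `y_axis_sign`.
#' @examples
#' img <- image2d(matrix(runif(100), 10, 10), pixel_size = 0.32)
#' @export
image2d <- function(values, pixel_size = NULL, y_axis_sign = -1L) {
  values <- as.matrix(values)
  if (!is.numeric(values) || nrow(values) < 1L || ncol(values) < 1L)
    stop("'values' must be a non-empty numeric matrix")
  if (!all(is.finite(values)))
    stop("'values' must be finite everywhere")
  if (!y_axis_sign %in% c(-1, 1))
    stop("'y_axis_sign' must be +1 or -1")
  if (!is.null(pixel_size) && (!is.numeric(pixel_size) || pixel_size <= 0))
    stop("'pixel_size' must be a positive number")
  structure(values,
            pixel_size = pixel_size,
            y_axis_sign = as.integer(y_axis_sign),
            class = c("image2d", "matrix", "array"))
}

#' @export
print.image2d <- function(x, ...) {
  cat(sprintf("<image2d> %d x %d pixels", nrow(x), ncol(x)))
  ps <- attr(x, "pixel_size")
  if (!is.null(ps)) cat(sprintf(", pixel size %g um", ps))
  cat(sprintf(", y axis %s\n", if (attr(x, "y_axis_sign") > 0) "up" else "down"))
  invisible(x)
}

y_sign <- function(image) {
  s <- attr(image, "y_axis_sign")
  if (is.null(s)) -1L else as.integer(s)
}

as_mask <- function(mask) {
  m <- as.matrix(mask)
  storage.mode(m) <- "logical"
  m
}

# pixel-centre coordinate grids, 0-based; x = column, y = row
coord_x <- function(m) matrix(rep(seq_len(ncol(m)) - 1L, each = nrow(m)), nrow(m))
coord_y <- function(m) matrix(rep(seq_len(nrow(m)) - 1L, ncol(m)), nrow(m))

#' Normalise angles to a standard interval
#'
#' Directional angles live on `[0, 360)` degrees, axial angles (orientation
#' of an undirected axis) on `[0, 180)`.
#'
#' @param deg numeric vector of angles in degrees.
#' @param period `360` (directional, default) or `180` (axial).
#' @return angles reduced modulo `period` into `[0, period)`.
#' @export
normalize_angle <- function(deg, period = 360) {
  ((deg %% period) + period) %% period
}

deg2rad <- function(deg) deg * pi / 180
rad2deg <- function(rad) rad * 180 / pi

# run expr under its own seed without disturbing the caller's RNG stream
with_local_seed <- function(seed, expr) {
  if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}

# unit cue vector in raster coordinates: sigma maps the mathematical y
# component onto the stored row direction
cue_vector <- function(alpha_p_deg, sigma) {
  a <- deg2rad(alpha_p_deg)
  v <- c(cos(a), sigma * sin(a))
  # exact-degree cues (0/90/180/270) must give exact zero components, or
  # split-line pixels would be assigned by floating-point noise
  v[abs(v) < 1e-12] <- 0
  v
}
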