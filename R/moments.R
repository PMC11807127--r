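#' Raw and central image moments
#'
#' Image moments up to order 3 underlie every shape and polarity feature in
#' the package. The raw moment of order (i, j) of an intensity image I is
#' \deqn{m_{ij} = \sum_x \sum_y x^i y^j I(x, y)} summed over the (optionally
#' masked) pixels, with 0-based pixel-centre coordinates. The centre of mass
#' is \eqn{(\bar x, \bar y) = (m_{10}/m_{00}, m_{01}/m_{00})} and the central
#' moments are \deqn{\mu_{ij} = \sum (x-\bar x)^i (y-\bar y)^j I(x, y).}
#' For moments of a binary shape pass `intensity = NULL` so that I = 1 on the
#' mask.
#'
#' @param image an [image2d] or numeric matrix of intensities, or `NULL` for
#'   unit intensity on the mask.
#' @param mask optional logical matrix selecting the region; `NULL` uses the
#'   whole image.
#' @param order highest moment order (i + j) to compute, default 3.
#' @return An object of class `moment_set`: a list with matrices `raw` and
#'   `central` (entry `[i+1, j+1]` holds the order-(i, j) moment) and the
#'   `centroid` c(x, y) in pixel coordinates.
#' @examples
#' m <- image_moments(NULL, mask = matrix(TRUE, 4, 4))
#' m$centroid  # (1.5, 1.5)
#' @export
image_moments <- function(image = NULL, mask = NULL, order = 3L) {
  if (is.null(image) && is.null(mask))
    stop("need at least one of 'image' and 'mask'")
  if (is.null(image)) {
    I <- matrix(1, nrow(mask), ncol(mask))
  } else {
    I <- as.matrix(image)
  }
  if (!is.null(mask)) {
    mask <- as_mask(mask)
    if (!identical(dim(mask), dim(I)))
      stop("mask shape must equal image shape")
    if (!any(mask)) stop("empty region: mask has no pixels")
    keep <- which(mask)
  } else {
    keep <- seq_along(I)
  }
  x <- (ceiling(keep / nrow(I)) - 1)       # column index, 0-based
  y <- ((keep - 1) %% nrow(I))             # row index, 0-based
  w <- as.numeric(I[keep])
  m00 <- sum(w)
  if (m00 <= 0) stop("empty region: total intensity is zero")

  raw <- matrix(NA_real_, order + 1L, order + 1L,
                dimnames = list(paste0("i", 0:order), paste0("j", 0:order)))
  xp <- outer(x, 0:order, `^`)
  yp <- outer(y, 0:order, `^`)
  for (i in 0:order) for (j in 0:order) {
    if (i + j <= order) raw[i + 1L, j + 1L] <- sum(xp[, i + 1L] * yp[, j + 1L] * w)
  }
  cx <- raw[2, 1] / m00
  cy <- raw[1, 2] / m00
  central <- matrix(NA_real_, order + 1L, order + 1L, dimnames = dimnames(raw))
  xc <- outer(x - cx, 0:order, `^`)
  yc <- outer(y - cy, 0:order, `^`)
  for (i in 0:order) for (j in 0:order) {
    if (i + j <= order) central[i + 1L, j + 1L] <- sum(xc[, i + 1L] * yc[, j + 1L] * w)
  }
  structure(list(raw = raw, central = central, centroid = c(x = cx, y = cy),
                 order = order, n_pixels = length(keep)),
            class = "moment_set")
}

#' @export
print.moment_set <- function(x, ...) {
  cat(sprintf("<moment_set> m00 = %g, centroid = (%.3f, %.3f)\n",
              x$raw[1, 1], x$centroid[1], x$centroid[2]))
  invisible(x)
}

#' Centre of mass from a moment set
#'
#' @param moments a `moment_set` from [image_moments()].
#' @return c(x, y), 0-based pixel coordinates.
#' @export
moment_centroid <- function(moments) {
  stopifnot(inherits(moments, "moment_set"))
  if (moments$raw[1, 1] <= 0) stop("empty region: m00 = 0")
  moments$centroid
}

# convenience accessors
mu <- function(moments, i, j) moments$central[i + 1L, j + 1L]
mraw <- function(moments, i, j) moments$raw[i + 1L, j + 1L]

#' Axis lengths of the intensity-equivalent ellipse
#'
#' The eigenvalues \eqn{\lambda_1 \ge \lambda_2} of the normalised second
#' central moment matrix give the full major/minor axis lengths of the
#' ellipse with the same second moments as the region, as
#' \eqn{4\sqrt{\lambda}}.
#'
#' @param moments a `moment_set`.
#' @return c(major, minor) in pixels; minor is 0 for degenerate (collinear)
#'   regions, with a warning.
#' @export
axis_lengths <- function(moments) {
  stopifnot(inherits(moments, "moment_set"))
  m00 <- moments$raw[1, 1]
  if (m00 <= 0) stop("empty region: m00 = 0")
  u20 <- mu(moments, 2, 0) / m00
  u02 <- mu(moments, 0, 2) / m00
  u11 <- mu(moments, 1, 1) / m00
  tr <- u20 + u02
  det_ <- u20 * u02 - u11^2
  disc <- max(0, (tr / 2)^2 - det_)
  l1 <- tr / 2 + sqrt(disc)
  l2 <- max(0, tr / 2 - sqrt(disc))
  if (l2 <= .Machine$double.eps * max(1, l1))
    warning("degenerate region: minor axis length is zero")
  c(major = 4 * sqrt(l1), minor = 4 * sqrt(l2))
}

#' Eccentricity of the intensity-equivalent ellipse
#'
#' @param moments a `moment_set`.
#' @return eccentricity in `[0, 1)`; 0 for a disc.
#' @export
moment_eccentricity <- function(moments) {
  ax <- suppressWarnings(axis_lengths(moments))
  if (ax[1] <= 0) return(0)
  unname(sqrt(max(0, 1 - (ax[2] / ax[1])^2)))
}
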