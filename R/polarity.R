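#' Directed front-rear polarity angle between two centroids
#'
#' The polarity angle from a 'rear' reference point to a 'front' target
#' point, \deqn{\alpha = \sigma\,\mathrm{atan2}(\bar y_f - \bar y_r,\;
#' \bar x_f - \bar x_r) \mod 2\pi,} a directional quantity in
#' `[0, 360)` degrees. Coincident centroids carry no direction and give
#' `NA`.
#'
#' @param rear c(x, y) of the reference ('rear') centroid.
#' @param front c(x, y) of the target ('front') centroid.
#' @param sigma y-axis sign convention, `+1` y up / `-1` y down.
#' @param tol distance below which the centroids count as coincident.
#' @return directional angle in degrees `[0, 360)`, or `NA`.
#' @export
front_rear_angle <- function(rear, front, sigma = -1L, tol = 1e-9) {
  stopifnot(length(rear) == 2L, length(front) == 2L, sigma %in% c(-1, 1))
  dx <- front[1] - rear[1]
  dy <- front[2] - rear[2]
  if (sqrt(dx^2 + dy^2) < tol) return(NA_real_)
  normalize_angle(rad2deg(sigma * atan2(dy, dx)))
}

#' Nucleus-Golgi polarity angle of one cell
#'
#' Direction from the nucleus centre of mass to the organelle (Golgi)
#' centre; the classic front-rear polarity proxy for migration direction.
#' The organelle centroid is intensity-weighted over the organelle channel
#' within the organelle mask when a channel is supplied, otherwise the
#' binary-mask centroid.
#'
#' @param nucleus_mask,organelle_mask logical matrices.
#' @param organelle_channel optional intensity matrix for weighting.
#' @param sigma y-axis sign convention.
#' @return directional angle in degrees, or `NA` if either mask is empty or
#'   the centroids coincide.
#' @export
nucleus_golgi_polarity <- function(nucleus_mask, organelle_mask,
                                   organelle_channel = NULL, sigma = -1L) {
  if (is.null(organelle_mask) || !any(organelle_mask)) return(NA_real_)
  if (is.null(nucleus_mask) || !any(nucleus_mask)) return(NA_real_)
  rear <- image_moments(NULL, nucleus_mask, order = 1L)$centroid
  front <- weighted_centroid(organelle_channel, organelle_mask)
  if (anyNA(front)) return(NA_real_)
  front_rear_angle(rear, front, sigma)
}

#' Nucleus displacement angle of one cell
#'
#' Direction from the cell-shape centre of mass to the nucleus centre.
#'
#' @param cell_mask,nucleus_mask logical matrices.
#' @param sigma y-axis sign convention.
#' @return directional angle in degrees, or `NA`.
#' @export
nucleus_displacement <- function(cell_mask, nucleus_mask, sigma = -1L) {
  if (is.null(nucleus_mask) || !any(nucleus_mask)) return(NA_real_)
  rear <- image_moments(NULL, cell_mask, order = 1L)$centroid
  front <- image_moments(NULL, nucleus_mask, order = 1L)$centroid
  front_rear_angle(rear, front, sigma)
}

#' Marker polarity angle of one cell
#'
#' Direction from the geometric cell centre to the intensity-weighted
#' centre of a marker channel within the cell; sensitive to even weak
#' intracellular gradients.
#'
#' @param cell_mask logical matrix.
#' @param channel intensity matrix of the marker.
#' @param sigma y-axis sign convention.
#' @return directional angle in degrees, or `NA` when the channel carries no
#'   intensity in the cell or the weighted centre coincides with the
#'   geometric centre (uniform marker).
#' @export
marker_polarity <- function(cell_mask, channel, sigma = -1L) {
  rear <- image_moments(NULL, cell_mask, order = 1L)$centroid
  front <- weighted_centroid(channel, cell_mask)
  if (anyNA(front)) return(NA_real_)
  front_rear_angle(rear, front, sigma, tol = 1e-6)
}

weighted_centroid <- function(channel, mask) {
  mask <- as_mask(mask)
  if (!any(mask)) return(c(NA_real_, NA_real_))
  if (is.null(channel)) {
    mom <- image_moments(NULL, mask, order = 1L)
  } else {
    if (sum(as.matrix(channel)[mask]) <= 0) return(c(NA_real_, NA_real_))
    mom <- image_moments(channel, mask, order = 1L)
  }
  mom$centroid
}

#' Cue directional intensity ratio
#'
#' Splits the cell through its shape centroid perpendicular to the cue
#' direction \eqn{\alpha_p} and compares the intensity carried by the two
#' halves: \deqn{s_r = 1 - 2\,\frac{\sum_{A_l} I}{\sum_{cell} I},} where
#' \eqn{A_l} is the rear half (pixels whose displacement from the centroid
#' projects negatively onto the cue unit vector). Ranges from -1 (all
#' intensity against the cue) through 0 (balanced) to +1 (all intensity
#' along the cue). Pixels with exactly zero projection are assigned to the
#' front half.
#'
#' @param cell_mask logical matrix.
#' @param channel intensity matrix.
#' @param alpha_p cue direction in degrees.
#' @param sigma y-axis sign convention.
#' @return ratio in `[-1, 1]`, or `NA` when the cell carries no intensity.
#' @export
cue_intensity_ratio <- function(cell_mask, channel, alpha_p, sigma = -1L) {
  mask <- as_mask(cell_mask)
  if (!any(mask)) stop("empty region")
  I <- as.matrix(channel)
  keep <- which(mask)
  w <- as.numeric(I[keep])
  total <- sum(w)
  if (total <= 0) return(NA_real_)
  ctr <- image_moments(NULL, mask, order = 1L)$centroid
  x <- ceiling(keep / nrow(mask)) - 1
  y <- (keep - 1) %% nrow(mask)
  v <- cue_vector(alpha_p, sigma)
  p <- (x - ctr[1]) * v[1] + (y - ctr[2]) * v[2]
  rear_sum <- sum(w[p < 0])
  1 - 2 * rear_sum / total
}
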