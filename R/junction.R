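#' Interface region around a cell outline
#'
#' The one-pixel outer contour of the cell mask (mask pixels with a
#' 4-neighbour outside) dilated to the set of all pixels within Euclidean
#' distance `thickness` of the contour, clipped to the image bounds. The
#' band straddles both sides of the cell boundary and is deliberately not
#' clipped to the cell's own mask, since junction signal lives on both
#' sides of a shared boundary. This is the single extra parameter the
#' junction analysis needs.
#'
#' @param cell_mask logical matrix.
#' @param thickness dilation radius in pixels (>= 1).
#' @return logical matrix of the same shape.
#' @export
interface_region <- function(cell_mask, thickness = 3L) {
  stopifnot(thickness >= 1)
  mask <- as_mask(cell_mask)
  if (!any(mask)) stop("empty region")
  dilate_set(mask_contour(mask), thickness)
}

# one-pixel contour: mask pixels with at least one 4-neighbour outside the
# mask (image border counts as outside)
mask_contour <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  pad <- matrix(FALSE, nr + 2L, nc + 2L)
  pad[2:(nr + 1L), 2:(nc + 1L)] <- mask
  inner <- pad[2:(nr + 1L), 2:(nc + 1L)] &
    pad[1:nr, 2:(nc + 1L)] & pad[3:(nr + 2L), 2:(nc + 1L)] &
    pad[2:(nr + 1L), 1:nc] & pad[2:(nr + 1L), 3:(nc + 2L)]
  mask & !inner
}

#' Otsu threshold with a fixed 256-bin dialect
#'
#' Maximises the between-class variance on a 256-bin histogram spanning the
#' range of the supplied values. Otsu outcomes depend on binning, so the
#' dialect is fixed and documented. Returns `NA` for (near-)constant input,
#' where no two classes exist.
#'
#' @param values numeric vector of intensities.
#' @param n_bins number of histogram bins (default 256).
#' @return threshold value: pixels `>= threshold` form the bright class; or
#'   `NA` for constant input.
#' @export
otsu_threshold <- function(values, n_bins = 256L) {
  values <- values[is.finite(values)]
  if (length(values) == 0L) return(NA_real_)
  lo <- min(values); hi <- max(values)
  if (hi - lo <= .Machine$double.eps * max(1, abs(hi))) return(NA_real_)
  bin <- pmin(n_bins, 1L + floor((values - lo) / (hi - lo) * n_bins))
  counts <- tabulate(bin, nbins = n_bins)
  mids <- lo + (seq_len(n_bins) - 0.5) * (hi - lo) / n_bins
  w <- counts / sum(counts)
  cw <- cumsum(w)                 # class probability below cut
  cm <- cumsum(w * mids)          # class mean mass below cut
  mt <- cm[n_bins]
  valid <- cw > 0 & cw < 1
  between <- rep(-Inf, n_bins)
  between[valid] <- (mt * cw[valid] - cm[valid])^2 / (cw[valid] * (1 - cw[valid]))
  k <- which.max(between)
  # bright class starts at the first bin above the optimal cut
  lo + k * (hi - lo) / n_bins
}

#' Junction morphometrics within an interface region
#'
#' Computes the three normalised junction features on the junction channel
#' restricted to the interface band: interface occupancy (fraction of the
#' band covered by Otsu-positive junction protein), intensity per interface
#' area (mean channel intensity over the band) and cluster density (mean
#' intensity over the Otsu-positive protein area only). With constant
#' intensity in the band the Otsu split is undefined: occupancy and cluster
#' density are then missing while the mean band intensity is still
#' reported.
#'
#' @param region logical matrix, the interface band from
#'   [interface_region()].
#' @param channel intensity matrix of the junction channel.
#' @param threshold optional fixed threshold; default computes Otsu within
#'   the region.
#' @return list: `interface_area`, `protein_area`, `interface_occupancy`,
#'   `intensity_per_interface_area`, `cluster_density`, `otsu_threshold`.
#' @export
junction_stats <- function(region, channel, threshold = NULL) {
  region <- as_mask(region)
  if (!any(region)) stop("empty region")
  vals <- as.numeric(as.matrix(channel)[region])
  area <- length(vals)
  mean_int <- mean(vals)
  thr <- if (is.null(threshold)) otsu_threshold(vals) else threshold
  if (is.na(thr)) {
    return(list(interface_area = area, protein_area = NA_real_,
                interface_occupancy = NA_real_,
                intensity_per_interface_area = mean_int,
                cluster_density = NA_real_, otsu_threshold = NA_real_))
  }
  bright <- vals >= thr
  parea <- sum(bright)
  list(interface_area = area,
       protein_area = parea,
       interface_occupancy = parea / area,
       intensity_per_interface_area = mean_int,
       cluster_density = if (parea > 0) mean(vals[bright]) else NA_real_,
       otsu_threshold = thr)
}

#' Junction features for one cell
#'
#' @param cell_mask logical matrix.
#' @param channel junction channel intensity matrix.
#' @param thickness interface band radius in pixels.
#' @param threshold optional fixed (image-global) Otsu threshold; by default
#'   Otsu is computed per cell within the band.
#' @return list as in [junction_stats()].
#' @export
junction_features <- function(cell_mask, channel, thickness = 3L,
                              threshold = NULL) {
  junction_stats(interface_region(cell_mask, thickness), channel, threshold)
}
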