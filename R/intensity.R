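#' Compartmentalised intensity readouts for one cell
#'
#' Total and mean intensity of a channel in four subcellular compartments:
#' the whole cell, the nucleus, the cytosol (cell minus nucleus — the only
#' strict partition, so totals add exactly), and a membrane band of given
#' thickness around the cell contour (the same construction as the junction
#' interface region; it overlaps the cytosol and is reported separately,
#' not subtracted). The nucleus-to-cytosol ratio of mean intensities is the
#' standard readout for nuclear translocation of a reporter.
#'
#' @param cell_mask logical matrix.
#' @param nucleus_mask logical matrix or `NULL` (nucleus/cytosol readouts
#'   then missing).
#' @param channel intensity matrix.
#' @param membrane_thickness band half-width in pixels (>= 1).
#' @param ratio_mode `"mean"` (default) or `"total"`: which intensities the
#'   nucleus/cytosol ratio compares.
#' @return named list: `area_`, `total_`, `mean_` for each of `cell`,
#'   `nucleus`, `cytosol`, `membrane`, plus `ratio_nucleus_cytosol`.
#' @export
compartment_stats <- function(cell_mask, nucleus_mask, channel,
                              membrane_thickness = 2L,
                              ratio_mode = c("mean", "total")) {
  ratio_mode <- match.arg(ratio_mode)
  stopifnot(membrane_thickness >= 1)
  mask <- as_mask(cell_mask)
  if (!any(mask)) stop("empty region")
  I <- as.matrix(channel)
  stat <- function(m) {
    a <- sum(m)
    if (a == 0) return(c(area = 0, total = NA_real_, mean = NA_real_))
    tot <- sum(I[m])
    c(area = a, total = tot, mean = tot / a)
  }
  cell <- stat(mask)
  if (!is.null(nucleus_mask) && any(nucleus_mask)) {
    nuc_m <- as_mask(nucleus_mask) & mask
    cyt_m <- mask & !nuc_m
    nuc <- stat(nuc_m)
    cyt <- stat(cyt_m)
  } else {
    nuc <- cyt <- c(area = NA_real_, total = NA_real_, mean = NA_real_)
  }
  mem <- stat(interface_region(mask, membrane_thickness) & mask)
  ratio <- if (ratio_mode == "mean") {
    if (is.finite(nuc["mean"]) && is.finite(cyt["mean"]) && cyt["mean"] > 0)
      unname(nuc["mean"] / cyt["mean"]) else NA_real_
  } else {
    if (is.finite(nuc["total"]) && is.finite(cyt["total"]) && cyt["total"] > 0)
      unname(nuc["total"] / cyt["total"]) else NA_real_
  }
  list(area_cell = unname(cell["area"]), total_cell = unname(cell["total"]),
       mean_cell = unname(cell["mean"]),
       area_nucleus = unname(nuc["area"]), total_nucleus = unname(nuc["total"]),
       mean_nucleus = unname(nuc["mean"]),
       area_cytosol = unname(cyt["area"]), total_cytosol = unname(cyt["total"]),
       mean_cytosol = unname(cyt["mean"]),
       area_membrane = unname(mem["area"]), total_membrane = unname(mem["total"]),
       mean_membrane = unname(mem["mean"]),
       ratio_nucleus_cytosol = ratio)
}
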