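#' Extract the per-cell feature table of one image
#'
#' Runs the whole feature stack — localisation, morphology, polarity,
#' intensity compartments and junction morphometrics — for every retained
#' cell of an image and returns one row per cell. Cells are retained by
#' [match_and_filter()] (exactly one nucleus, not touching the border by
#' default). Which feature blocks appear depends on which channels and
#' masks are available; missing features are `NA`, never silently 0.
#'
#' All angle columns are in degrees: directed polarity angles in
#' `[0, 360)`, the axial shape orientation in `[0, 180)`, using the image's
#' y-axis sign convention.
#'
#' @param channels named list of intensity matrices; recognised names are
#'   `junction`, `nucleus`, `organelle`, `marker` (any subset).
#' @param cell_mask integer label matrix of cells.
#' @param nucleus_mask integer label matrix of nuclei, or `NULL`.
#' @param organelle_mask integer label matrix of organelles, or `NULL`; if
#'   `NULL` and an organelle channel exists it is derived with
#'   [golgi_instance_mask()].
#' @param alpha_p cue (e.g. flow) direction in degrees.
#' @param sigma y-axis sign convention.
#' @param pixel_size optional pixel edge length (micrometres).
#' @param junction_thickness interface band radius in pixels.
#' @param membrane_thickness membrane band radius in pixels.
#' @param exclude_border drop border-touching cells.
#' @param image_id identifier copied into every row.
#' @return data frame of class `feature_table`, one row per retained cell,
#'   with attribute `filter_log` (the [match_and_filter()] bookkeeping).
#' @export
extract_features <- function(channels, cell_mask, nucleus_mask = NULL,
                             organelle_mask = NULL,
                             alpha_p = 0, sigma = -1L, pixel_size = NULL,
                             junction_thickness = 3L,
                             membrane_thickness = 2L,
                             exclude_border = TRUE,
                             image_id = "image") {
  cells <- validate_label_mask(cell_mask)
  have_nuc_mask <- !is.null(nucleus_mask)
  if (have_nuc_mask) nucleus_mask <- validate_label_mask(nucleus_mask)
  if (is.null(organelle_mask) && !is.null(channels$organelle))
    organelle_mask <- golgi_instance_mask(channels$organelle, cells)
  cell_ids <- sort(unique(cells[cells > 0L]))
  if (length(cell_ids) == 0L) {
    return(empty_feature_table(image_id))
  }
  if (have_nuc_mask) {
    mf <- match_and_filter(cells, nucleus_mask, exclude_border)
    keep <- mf$retained
  } else {
    # no nucleus mask: keep all (non-border) cells, no nucleus pairing
    border <- integer(0)
    if (exclude_border) {
      nr <- nrow(cells); nc <- ncol(cells)
      border <- unique(c(cells[1, ], cells[nr, ], cells[, 1], cells[, nc]))
    }
    ids <- setdiff(cell_ids, border)
    keep <- data.frame(cell_label = ids, nucleus_label = NA_integer_)
    mf <- list(retained = keep,
               dropped = data.frame(cell_label = setdiff(cell_ids, ids),
                                    reason = "touches_border"),
               counts = c(total = length(cell_ids), retained = length(ids),
                          dropped = length(cell_ids) - length(ids)))
  }
  rows <- lapply(seq_len(nrow(keep)), function(i) {
    k <- keep$cell_label[i]
    cm <- cells == k
    nm <- if (have_nuc_mask && !is.na(keep$nucleus_label[i]))
      nucleus_mask == keep$nucleus_label[i] & cm else NULL
    om <- if (!is.null(organelle_mask)) organelle_mask == k else NULL
    if (!is.null(om) && !any(om)) om <- NULL
    cell_feature_row(k, cm, nm, om, channels, alpha_p, sigma, pixel_size,
                     junction_thickness, membrane_thickness, image_id)
  })
  out <- do.call(rbind, rows)
  attr(out, "filter_log") <- mf
  attr(out, "alpha_p") <- alpha_p
  attr(out, "sigma") <- sigma
  class(out) <- c("feature_table", "data.frame")
  out
}

cell_feature_row <- function(label, cm, nm, om, channels, alpha_p, sigma,
                             pixel_size, junction_thickness,
                             membrane_thickness, image_id) {
  ctr <- image_moments(NULL, cm, order = 1L)$centroid
  morph <- morphology_features(cm, alpha_p, sigma, pixel_size)
  nuc_ctr <- if (!is.null(nm)) image_moments(NULL, nm, order = 1L)$centroid
             else c(NA_real_, NA_real_)
  row <- data.frame(
    image_id = image_id, label = label,
    cell_x = unname(ctr[1]), cell_y = unname(ctr[2]),
    nucleus_x = unname(nuc_ctr[1]), nucleus_y = unname(nuc_ctr[2]),
    area_px2 = morph$area_px2, area_um2 = morph$area_um2,
    perimeter_px = morph$perimeter_px,
    circularity = morph$circularity, eccentricity = morph$eccentricity,
    orientation_deg = morph$orientation_deg, lwr = morph$lwr,
    symmetry_score = morph$symmetry_score,
    angle_nucleus_golgi_deg = NA_real_,
    angle_nucleus_displacement_deg = NA_real_,
    angle_marker_polarity_deg = NA_real_,
    cue_intensity_ratio = NA_real_,
    stringsAsFactors = FALSE)
  if (!is.null(nm)) {
    row$angle_nucleus_displacement_deg <- nucleus_displacement(cm, nm, sigma)
    if (!is.null(om))
      row$angle_nucleus_golgi_deg <-
        nucleus_golgi_polarity(nm, om, channels$organelle, sigma)
  }
  if (!is.null(channels$marker)) {
    row$angle_marker_polarity_deg <-
      marker_polarity(cm, channels$marker, sigma)
    row$cue_intensity_ratio <-
      cue_intensity_ratio(cm, channels$marker, alpha_p, sigma)
    cs <- compartment_stats(cm, nm, channels$marker, membrane_thickness)
    row <- cbind(row, as.data.frame(cs))
  }
  if (!is.null(channels$junction)) {
    jf <- junction_features(cm, channels$junction, junction_thickness)
    jf$otsu_threshold <- NULL
    row <- cbind(row, as.data.frame(jf))
  }
  row
}

empty_feature_table <- function(image_id) {
  out <- data.frame(image_id = character(0), label = integer(0))
  attr(out, "filter_log") <- list(counts = c(total = 0, retained = 0,
                                             dropped = 0))
  class(out) <- c("feature_table", "data.frame")
  out
}

#' @export
print.feature_table <- function(x, ...) {
  log <- attr(x, "filter_log")
  cat(sprintf("<feature_table> %d cells x %d features", nrow(x), ncol(x)))
  if (!is.null(log))
    cat(sprintf("  (retained %d of %d cells)", log$counts["retained"],
                log$counts["total"]))
  cat("\n")
  if (nrow(x)) print.data.frame(utils::head(as.data.frame(x), 6))
  invisible(x)
}

#' Collective circular summaries of a feature table
#'
#' Groups the per-cell table by image and summarises each requested angle
#' feature with [circ_summary()] and the uniformity tests. Statistical
#' inference operates at the image level — single cells within a monolayer
#' are spatially correlated, so per-cell test p-values would overstate the
#' evidence. The V-test reference is the expected polarisation direction:
#' for nucleus-Golgi polarity the expectation under a cue points opposite
#' to the cue, so that feature's reference defaults to `alpha_p + 180`.
#'
#' @param features a `feature_table` (possibly several images' rows).
#' @param alpha_p cue direction in degrees (default: the table's
#'   attribute).
#' @param angle_features named character vector of angle columns to
#'   summarise, names giving the output feature label; defaults to the
#'   standard directed and axial features present in the table.
#' @param expected_offset named numeric vector of offsets (degrees) added
#'   to `alpha_p` per feature to obtain the V-test reference direction.
#' @param level CI level.
#' @return data frame with one row per image x feature: n, mean, R, S, V,
#'   CI bounds and the four uniformity-test statistics and p-values.
#' @export
summarise_features <- function(features, alpha_p = NULL,
                               angle_features = NULL,
                               expected_offset = c(angle_nucleus_golgi_deg = 180),
                               level = 0.95) {
  if (is.null(alpha_p)) alpha_p <- attr(features, "alpha_p")
  if (is.null(alpha_p)) alpha_p <- 0
  if (is.null(angle_features)) {
    angle_features <- intersect(
      c("angle_nucleus_golgi_deg", "angle_nucleus_displacement_deg",
        "angle_marker_polarity_deg", "orientation_deg"),
      names(features))
  }
  imgs <- unique(features$image_id)
  rows <- list()
  for (img in imgs) {
    sub <- features[features$image_id == img, , drop = FALSE]
    for (feat in angle_features) {
      vals <- sub[[feat]]
      vals <- vals[is.finite(vals)]
      if (length(vals) < 2) next
      axial <- feat == "orientation_deg"
      smp <- angle_sample(vals, mode = if (axial) "axial" else "directional")
      off <- if (feat %in% names(expected_offset))
        expected_offset[[feat]] else 0
      ref <- normalize_angle(alpha_p + off, if (axial) 180 else 360)
      cs <- circ_summary(smp, alpha_p = ref, level = level)
      ray <- rayleigh_test(smp)
      vt <- v_test(smp, ref)
      wa <- watson_test(smp)
      rao <- if (smp$n >= 4) rao_spacing_test(smp) else NULL
      rows[[length(rows) + 1L]] <- data.frame(
        image_id = img, feature = feat, n = cs$n,
        mean_deg = cs$mean_deg, R = cs$R, S = cs$S, V = cs$V, c = cs$c,
        alpha_ref_deg = ref,
        ci_low_deg = cs$ci_low_deg, ci_high_deg = cs$ci_high_deg,
        rayleigh_z = unname(ray$statistic), rayleigh_p = ray$p.value,
        vtest_u = unname(vt$statistic), vtest_p = vt$p.value,
        watson_u2 = unname(wa$statistic), watson_p = wa$p.value,
        rao_u = if (is.null(rao)) NA_real_ else unname(rao$statistic),
        rao_p = if (is.null(rao)) NA_real_ else rao$p.value,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) return(data.frame())
  do.call(rbind, rows)
}
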