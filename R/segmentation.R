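#' Validate an instance label mask
#'
#' @param mask integer matrix; 0 = background, k >= 1 = instance k.
#' @return the mask as an integer matrix, invisibly checked.
#' @export
validate_label_mask <- function(mask) {
  m <- as.matrix(mask)
  if (any(!is.finite(m)) || any(m < 0) || any(m != round(m)))
    stop("label mask must contain non-negative integers")
  storage.mode(m) <- "integer"
  m
}

#' Instance segmentation dispatcher
#'
#' Delegates to a segmentation backend. The built-in `"classical"` backend
#' needs no external model; deep-learning backends (cellpose, deepcell,
#' microsam) are adapter slots — requesting one that is not plugged in is
#' an explicit error, never a silent fallback. Precomputed masks bypass
#' segmentation entirely via [validate_label_mask()].
#'
#' @param channels named list of intensity matrices (needs `nucleus` and
#'   `junction` for the classical backend).
#' @param backend backend name, default `"classical"`.
#' @param config backend parameter list (see [classical_segment()]).
#' @return list with integer matrices `cell` and `nucleus`.
#' @export
segment_cells <- function(channels, backend = "classical", config = list()) {
  if (backend == "classical") {
    need <- setdiff(c("nucleus", "junction"), names(channels))
    if (length(need))
      stop("classical backend requires channels: ", paste(need, collapse = ", "))
    return(do.call(classical_segment,
                   c(list(nucleus_channel = channels$nucleus,
                          junction_channel = channels$junction), config)))
  }
  stop(sprintf(
    "segmentation backend '%s' is not available in this installation; %s",
    backend, "supply precomputed masks or use backend = 'classical'"))
}

#' Built-in classical segmentation backend
#'
#' Nuclei are found by global Otsu thresholding of the nucleus channel,
#' hole filling and connected-component labelling (tiny components are
#' discarded). Cells are grown from the nucleus seeds over the junction
#' channel by seeded region growing (Voronoi propagation with image-based
#' metric), so bright junction ridges act as barriers between cells.
#'
#' @param nucleus_channel,junction_channel intensity matrices.
#' @param min_nucleus_area discard nucleus components smaller than this
#'   (pixels).
#' @param lambda regularisation of the propagation metric (0 = pure
#'   intensity barrier, large = pure Euclidean Voronoi).
#' @return list with integer matrices `cell` and `nucleus`.
#' @export
classical_segment <- function(nucleus_channel, junction_channel,
                              min_nucleus_area = 20L, lambda = 1e-4) {
  nuc <- as.matrix(nucleus_channel)
  thr <- otsu_threshold(as.numeric(nuc))
  if (is.na(thr)) {
    warning("no foreground after Otsu on nucleus channel; zero instances")
    z <- matrix(0L, nrow(nuc), ncol(nuc))
    return(list(cell = z, nucleus = z))
  }
  bw <- EBImage::fillHull(EBImage::Image(matrix(as.numeric(nuc >= thr),
                                                nrow(nuc))))
  lab <- EBImage::bwlabel(bw)
  sizes <- table(imageData_int(lab)[imageData_int(lab) > 0])
  small <- as.integer(names(sizes)[sizes < min_nucleus_area])
  nl <- imageData_int(lab)
  if (length(small)) nl[nl %in% small] <- 0L
  # compact relabel so labels are 1..K
  keep <- sort(unique(nl[nl > 0]))
  nl <- matrix(match(nl, keep, nomatch = 0L), nrow(nl))
  if (!any(nl > 0)) {
    warning("no nuclei retained; zero instances")
    z <- matrix(0L, nrow(nuc), ncol(nuc))
    return(list(cell = z, nucleus = z))
  }
  cells <- EBImage::propagate(EBImage::Image(as.matrix(junction_channel)),
                              EBImage::Image(nl), lambda = lambda)
  list(cell = imageData_int(cells), nucleus = nl)
}

imageData_int <- function(img) {
  m <- as.matrix(EBImage::imageData(img))
  storage.mode(m) <- "integer"
  m
}

#' Organelle (Golgi) instance mask by Otsu superposition
#'
#' Applies a global Otsu threshold to the organelle channel and gives every
#' thresholded pixel the label of the cell beneath it, so each cell's
#' organelle mask is the bright organelle signal inside that cell. A blob
#' straddling a cell boundary is split between the cells.
#'
#' @param organelle_channel intensity matrix.
#' @param cell_mask integer label matrix of cells.
#' @return integer label matrix of organelle instances (cell labels).
#' @export
golgi_instance_mask <- function(organelle_channel, cell_mask) {
  ch <- as.matrix(organelle_channel)
  cells <- validate_label_mask(cell_mask)
  thr <- otsu_threshold(as.numeric(ch))
  out <- matrix(0L, nrow(ch), ncol(ch))
  if (is.na(thr)) return(out)
  sel <- ch >= thr & cells > 0L
  out[sel] <- cells[sel]
  out
}

#' Match nuclei to cells and filter the cell population
#'
#' Each nucleus is assigned to the cell covering the majority of its area
#' (ties break to the lower cell label). Cells with zero or two or more
#' assigned nuclei are dropped, as are (by default) cells touching the
#' image border, whose truncated shapes would bias morphology and polarity
#' features. All drops are tallied so that retained + dropped reconciles
#' with the total.
#'
#' @param cell_mask,nucleus_mask integer label matrices.
#' @param exclude_border drop cells touching the image border (default
#'   TRUE).
#' @return list: `retained` data frame (`cell_label`, `nucleus_label`),
#'   `dropped` data frame (`cell_label`, `reason`), `counts` named vector.
#' @export
match_and_filter <- function(cell_mask, nucleus_mask, exclude_border = TRUE) {
  cells <- validate_label_mask(cell_mask)
  nucs <- validate_label_mask(nucleus_mask)
  stopifnot(identical(dim(cells), dim(nucs)))
  cell_ids <- sort(unique(cells[cells > 0L]))
  # majority-overlap assignment, ties -> lower cell label
  ov <- which(nucs > 0L & cells > 0L)
  assign <- integer(0)
  if (length(ov)) {
    tab <- table(nucleus = nucs[ov], cell = cells[ov])
    assign <- apply(tab, 1, function(row) {
      as.integer(colnames(tab)[which.max(row)])   # first max = lower label
    })
    names(assign) <- rownames(tab)
  }
  n_per_cell <- table(factor(assign, levels = cell_ids))
  border <- integer(0)
  if (exclude_border) {
    nr <- nrow(cells); nc <- ncol(cells)
    border <- unique(c(cells[1, ], cells[nr, ], cells[, 1], cells[, nc]))
    border <- border[border > 0L]
  }
  reason <- character(0); dropped <- integer(0)
  retained <- data.frame(cell_label = integer(0), nucleus_label = integer(0))
  for (k in cell_ids) {
    nk <- n_per_cell[as.character(k)]
    if (k %in% border) {
      dropped <- c(dropped, k); reason <- c(reason, "touches_border")
    } else if (nk == 0) {
      dropped <- c(dropped, k); reason <- c(reason, "no_nucleus")
    } else if (nk > 1) {
      dropped <- c(dropped, k); reason <- c(reason, "multiple_nuclei")
    } else {
      nuc_lab <- as.integer(names(assign)[assign == k])
      retained <- rbind(retained,
                        data.frame(cell_label = k, nucleus_label = nuc_lab[1]))
    }
  }
  counts <- c(total = length(cell_ids), retained = nrow(retained),
              dropped = length(dropped))
  list(retained = retained,
       dropped = data.frame(cell_label = dropped, reason = reason,
                            stringsAsFactors = FALSE),
       counts = counts)
}
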