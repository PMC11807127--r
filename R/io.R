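#' Read a run configuration from YAML
#'
#' Fills defaults for every omitted key and validates the result. The
#' configuration mirrors the pipeline's needs: input path and mode, channel
#' assignment (by 1-based index into the TIFF frames or by name), pixel
#' size, cue direction, axis convention, band thicknesses, segmentation
#' block, output directory and seed.
#'
#' @param path YAML file path, or a list already parsed.
#' @return validated config list of class `run_config`.
#' @export
read_run_config <- function(path) {
  cfg <- if (is.list(path)) path else yaml::read_yaml(path)
  defaults <- list(
    mode = "single",              # single | stack | folder
    input = NULL,
    channels = list(),            # e.g. junction: 1, nucleus: 2, ...
    masks = list(),               # optional precomputed cell/nucleus TIFFs
    pixel_size = NULL,
    alpha_p = 0,
    y_axis_sign = -1L,
    junction_thickness = 3L,
    membrane_thickness = 2L,
    exclude_border = TRUE,
    segmentation = list(backend = "classical", config = list()),
    output_dir = "cellpolarity_out",
    seed = 1L)
  for (k in names(defaults))
    if (is.null(cfg[[k]])) cfg[[k]] <- defaults[[k]]
  if (!cfg$mode %in% c("single", "stack", "folder"))
    stop("config key 'mode': must be single, stack or folder")
  if (!cfg$y_axis_sign %in% c(-1, 1))
    stop("config key 'y_axis_sign': must be +1 or -1")
  if (length(cfg$channels) == 0 && length(cfg$masks) == 0)
    stop("config: need at least one of 'channels' (for segmentation) or ",
         "'masks' (precomputed)")
  cfg$alpha_p <- normalize_angle(cfg$alpha_p)
  class(cfg) <- "run_config"
  cfg
}

#' Read a multi-channel (or stack) TIFF as a list of matrices
#'
#' Frames are returned in file order; channel assignment to junction,
#' nucleus, organelle or marker roles happens via the configuration's
#' `channels` block. 8/16-bit integer files arrive rescaled to `[0, 1]` by
#' the TIFF reader; features are intensity-scale invariant where they
#' should be, so no further normalisation is applied.
#'
#' @param path TIFF file.
#' @return list of numeric matrices, one per frame.
#' @export
read_image_frames <- function(path) {
  frames <- tiff::readTIFF(path, all = TRUE, as.is = FALSE)
  if (!is.list(frames)) frames <- list(frames)
  lapply(frames, function(f) {
    if (length(dim(f)) == 3L) f <- f[, , 1L]   # collapse grey-stored-as-RGB
    as.matrix(f)
  })
}

#' Write an integer label mask as TIFF
#'
#' Stored as 16-bit; labels above 65535 are not supported by the format.
#'
#' @param mask integer matrix.
#' @param path output file.
#' @export
write_label_tiff <- function(mask, path) {
  m <- validate_label_mask(mask)
  if (max(m) > 65535L) stop("more than 65535 labels cannot be stored as 16-bit TIFF")
  tiff::writeTIFF(m / 65535, path, bits.per.sample = 16L)
  invisible(path)
}

#' Read an integer label mask from TIFF
#'
#' @param path TIFF file written by [write_label_tiff()] (16-bit labels).
#' @return integer matrix.
#' @export
read_label_tiff <- function(path) {
  m <- tiff::readTIFF(path)
  if (length(dim(m)) == 3L) m <- m[, , 1L]
  validate_label_mask(round(m * 65535))
}

#' Write a feature or summary table as CSV with provenance header
#'
#' Plain UTF-8 CSV ('.' decimal, ',' separator); missing values are empty
#' cells. A comment header records the package version, the seed and a hash
#' of the resolved configuration so outputs are traceable; angle columns
#' are degrees with the conventions documented in the header.
#'
#' @param table data frame.
#' @param path output file.
#' @param config optional `run_config` for the provenance hash.
#' @param seed optional seed to record.
#' @export
write_features_csv <- function(table, path, config = NULL, seed = NULL) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(sprintf("# cellpolarity %s",
                     as.character(utils::packageVersion("cellpolarity"))), con)
  if (!is.null(seed)) writeLines(sprintf("# seed: %s", seed), con)
  if (!is.null(config)) {
    h <- substr(digest_config(config), 1, 12)
    writeLines(sprintf("# config_hash: %s", h), con)
  }
  writeLines(paste("# angles in degrees; directional [0,360),",
                   "axial [0,180); missing values empty"), con)
  utils::write.csv(as.data.frame(table), con, row.names = FALSE, na = "")
  invisible(path)
}

digest_config <- function(config) {
  # dependency-free stable hash: serialise to canonical YAML, then md5;
  # output_dir does not influence results and is excluded, so re-runs of
  # the same analysis into different directories hash identically
  cfg <- unclass(config)
  cfg$output_dir <- NULL
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(yaml::as.yaml(cfg[order(names(cfg))]), tmp)
  as.character(tools::md5sum(tmp))
}

#' Read a feature CSV written by [write_features_csv()]
#'
#' @param path CSV file.
#' @return data frame (comment header lines skipped).
#' @export
read_features_csv <- function(path) {
  utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' Export a rose plot to SVG or PDF
#'
#' @param sample an [angle_sample].
#' @param path output file ending in `.svg` or `.pdf`.
#' @param summary optional [circ_summary()] overlay.
#' @param n_bins histogram bins.
#' @export
export_rose <- function(sample, path, summary = NULL, n_bins = 24L) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "svg") grDevices::svg(path, width = 5, height = 5)
  else if (ext == "pdf") grDevices::pdf(path, width = 5, height = 5)
  else stop("unsupported rose export format: .", ext)
  on.exit(grDevices::dev.off())
  plot(rose_histogram(sample, n_bins), summary = summary)
  invisible(path)
}

#' Run the full extraction pipeline from a configuration
#'
#' Executes one of the three scenarios — a single image, a multi-image
#' stack (one TIFF whose frames are images x channels), or a folder tree
#' whose subfolders name experimental conditions — and writes per-image
#' feature CSVs, a merged CSV, a per-image circular summary CSV, a
#' human-readable log and a copy of the resolved configuration. Unreadable
#' files in folder mode are logged and skipped; the run continues.
#'
#' @param config path to a YAML configuration or a `run_config` list.
#' @return invisibly, a list with `features` (merged data frame),
#'   `summary` (per-image circular summaries) and `output_dir`.
#' @export
run_pipeline <- function(config) {
  cfg <- if (inherits(config, "run_config")) config else read_run_config(config)
  dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(cfg$output_dir, "run.log")
  logf <- function(...) {
    msg <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"), sprintf(...))
    cat(msg, "\n", sep = "", file = log_path, append = TRUE)
    message(msg)
  }
  yaml::write_yaml(unclass(cfg), file.path(cfg$output_dir, "config_resolved.yml"))
  logf("cellpolarity %s; seed %s; config hash %s",
       as.character(utils::packageVersion("cellpolarity")), cfg$seed,
       substr(digest_config(cfg), 1, 12))
  set.seed(cfg$seed)

  jobs <- discover_jobs(cfg, logf)
  all_feats <- list()
  for (j in jobs) {
    feats <- tryCatch(
      process_one_image(j, cfg, logf),
      error = function(e) {
        logf("ERROR in %s: %s (skipped)", j$image_id, conditionMessage(e))
        NULL
      })
    if (is.null(feats)) next
    if (!is.null(j$condition) && nrow(feats)) feats$condition <- j$condition
    write_features_csv(feats,
                       file.path(cfg$output_dir,
                                 paste0(j$image_id, "_features.csv")),
                       cfg, cfg$seed)
    all_feats[[j$image_id]] <- feats
  }
  merged <- if (length(all_feats)) do.call(rbind_fill, all_feats) else data.frame()
  write_features_csv(merged, file.path(cfg$output_dir, "features_merged.csv"),
                     cfg, cfg$seed)
  summ <- if (nrow(merged)) summarise_features(merged, alpha_p = cfg$alpha_p)
          else data.frame()
  write_features_csv(summ, file.path(cfg$output_dir, "summary_circular.csv"),
                     cfg, cfg$seed)
  logf("done: %d image(s), %d cells, outputs in %s", length(all_feats),
       nrow(merged), cfg$output_dir)
  invisible(list(features = merged, summary = summ,
                 output_dir = cfg$output_dir))
}

rbind_fill <- function(...) {
  dfs <- list(...)
  if (length(dfs) == 1L && is.list(dfs[[1]]) && !is.data.frame(dfs[[1]]))
    dfs <- dfs[[1]]
  cols <- unique(unlist(lapply(dfs, names)))
  do.call(rbind, lapply(dfs, function(d) {
    for (m in setdiff(cols, names(d))) d[[m]] <- NA
    d[cols]
  }))
}

discover_jobs <- function(cfg, logf) {
  if (cfg$mode == "single") {
    list(list(path = cfg$input, frame_sets = NULL, condition = NULL,
              image_id = tools::file_path_sans_ext(basename(cfg$input))))
  } else if (cfg$mode == "stack") {
    frames <- read_image_frames(cfg$input)
    n_ch <- length(cfg$channels)
    if (n_ch == 0 || length(frames) %% n_ch != 0)
      stop("stack TIFF: frame count ", length(frames),
           " is not a multiple of the ", n_ch, " configured channels")
    n_img <- length(frames) / n_ch
    logf("stack: %d frames -> %d images x %d channels", length(frames),
         n_img, n_ch)
    lapply(seq_len(n_img), function(i) {
      list(path = cfg$input,
           frame_sets = frames[((i - 1) * n_ch + 1):(i * n_ch)],
           condition = NULL,
           image_id = sprintf("%s_img%02d",
                              tools::file_path_sans_ext(basename(cfg$input)), i))
    })
  } else {                         # folder: subfolder name = condition
    subs <- list.dirs(cfg$input, recursive = FALSE)
    jobs <- list()
    for (s in subs) {
      tifs <- list.files(s, pattern = "\\.tiff?$", full.names = TRUE)
      for (tf in tifs)
        jobs[[length(jobs) + 1L]] <-
          list(path = tf, frame_sets = NULL, condition = basename(s),
               image_id = paste(basename(s),
                                tools::file_path_sans_ext(basename(tf)),
                                sep = "_"))
    }
    logf("folder: %d image(s) in %d condition(s)", length(jobs), length(subs))
    jobs
  }
}

process_one_image <- function(job, cfg, logf) {
  frames <- if (!is.null(job$frame_sets)) job$frame_sets
            else read_image_frames(job$path)
  channels <- list()
  for (nm in names(cfg$channels)) {
    idx <- cfg$channels[[nm]]
    if (idx > length(frames))
      stop("channel '", nm, "' expects frame ", idx, " but TIFF has ",
           length(frames), " frame(s)")
    channels[[nm]] <- frames[[idx]]
  }
  if (length(cfg$masks)) {
    cell <- read_label_tiff(resolve_mask_path(cfg$masks$cell, job))
    nuc <- if (!is.null(cfg$masks$nucleus))
      read_label_tiff(resolve_mask_path(cfg$masks$nucleus, job)) else NULL
    logf("%s: precomputed masks (%d cell labels)", job$image_id,
         length(unique(cell[cell > 0])))
  } else {
    seg <- segment_cells(channels, cfg$segmentation$backend,
                         cfg$segmentation$config)
    cell <- seg$cell; nuc <- seg$nucleus
    logf("%s: segmented %d cells (%s backend)", job$image_id,
         length(unique(cell[cell > 0])), cfg$segmentation$backend)
  }
  skipped <- setdiff(c("junction", "nucleus", "organelle", "marker"),
                     names(channels))
  if (length(skipped))
    logf("%s: channels absent -> features skipped: %s", job$image_id,
         paste(skipped, collapse = ", "))
  extract_features(channels, cell, nuc,
                   alpha_p = cfg$alpha_p, sigma = cfg$y_axis_sign,
                   pixel_size = cfg$pixel_size,
                   junction_thickness = cfg$junction_thickness,
                   membrane_thickness = cfg$membrane_thickness,
                   exclude_border = cfg$exclude_border,
                   image_id = job$image_id)
}

resolve_mask_path <- function(spec_path, job) {
  if (file.exists(spec_path)) return(spec_path)
  cand <- file.path(dirname(job$path), spec_path)
  if (file.exists(cand)) return(cand)
  stop("mask file not found: ", spec_path)
}
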