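# fixtures and independent oracles, all built in code

# rasterise an ellipse mask: semi-axes a, b, orientation phi_deg in the
# conventional (y-up) frame, stored with the given sigma raster convention
raster_ellipse <- function(a, b, phi_deg, sigma = -1, n = 2 * ceiling(a) + 21,
                           centre = NULL) {
  if (is.null(centre)) centre <- c((n - 1) / 2, (n - 1) / 2)
  xg <- matrix(rep(0:(n - 1), each = n), n)
  yg <- matrix(rep(0:(n - 1), n), n)
  t <- sigma * phi_deg * pi / 180
  dx <- xg - centre[1]; dy <- yg - centre[2]
  u <- dx * cos(t) + dy * sin(t)
  v <- -dx * sin(t) + dy * cos(t)
  (u / a)^2 + (v / b)^2 <= 1
}

raster_disc <- function(r, n = 2 * ceiling(r) + 11, centre = NULL) {
  raster_ellipse(r, r, 0, n = n, centre = centre)
}

# brute-force double-loop moment oracle (independent of image_moments)
brute_moments <- function(I, mask = NULL, order = 3) {
  raw <- matrix(0, order + 1, order + 1)
  for (r in seq_len(nrow(I))) for (cc in seq_len(ncol(I))) {
    if (!is.null(mask) && !mask[r, cc]) next
    x <- cc - 1; y <- r - 1
    for (i in 0:order) for (j in 0:order) {
      if (i + j <= order)
        raw[i + 1, j + 1] <- raw[i + 1, j + 1] + x^i * y^j * I[r, cc]
    }
  }
  cx <- raw[2, 1] / raw[1, 1]; cy <- raw[1, 2] / raw[1, 1]
  central <- matrix(0, order + 1, order + 1)
  for (r in seq_len(nrow(I))) for (cc in seq_len(ncol(I))) {
    if (!is.null(mask) && !mask[r, cc]) next
    x <- cc - 1; y <- r - 1
    for (i in 0:order) for (j in 0:order) {
      if (i + j <= order)
        central[i + 1, j + 1] <- central[i + 1, j + 1] +
          (x - cx)^i * (y - cy)^j * I[r, cc]
    }
  }
  list(raw = raw, central = central, centroid = c(cx, cy))
}

# smallest absolute angular difference, directional (period 360) or axial
ang_diff <- function(a, b, period = 360) {
  d <- (a - b) %% period
  pmin(d, period - d)
}

# tiny deterministic monolayer shared by several tests
small_monolayer <- function(seed = 3, ...) {
  generate_monolayer(synthetic_spec(n_cells = 16, width = 200, height = 200,
                                    seed = seed, ...))
}
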