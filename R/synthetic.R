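#' Specification for a synthetic monolayer image
#'
#' Defines every distribution the generator draws from; together with the
#' seed it fully determines the output. Cells are ellipses on a jittered
#' grid, clipped by the Voronoi partition of the seed points so regions can
#' never overlap. With `confluent = FALSE` (default) the ellipse axes are
#' capped so neighbouring cells do not touch, which keeps the parametric
#' ground truth (orientation, elongation, bearings) exact; with
#' `confluent = TRUE` cells fill their entire Voronoi polygon, emulating a
#' tightly packed monolayer for segmentation benchmarks.
#'
#' @param width,height image size in pixels.
#' @param n_cells number of cells.
#' @param orientation list: `type` (`"fixed"` or `"vonmises"`), `value` /
#'   `mu` (degrees, axial) and `kappa`.
#' @param lwr list: `mean`, `sd` of the length-to-width ratio (truncated at
#'   1.05).
#' @param fill fraction of the maximal safe semi-major axis used.
#' @param jitter_frac seed jitter as a fraction of the grid pitch.
#' @param confluent logical, see above.
#' @param nucleus list: `scale` (nucleus disc radius relative to the cell
#'   semi-minor axis), `displacement_frac` (offset of the nucleus centre
#'   relative to the cell semi-minor axis, capped so the nucleus stays
#'   inside), `bearing` (`"uniform"` or von Mises list).
#' @param organelle list: `radius` (px), `distance_frac` (offset from the
#'   nucleus centre relative to the cell semi-minor axis; the offset is
#'   raised to clear the nucleus and capped so the disc fits inside the
#'   cell), `bearing` distribution.
#' @param marker list: `model` (`"uniform"`, `"gradient"` or `"ratio"`),
#'   `base`, `slope`, `bearing`, `ratio` (nucleus:cytosol).
#' @param junction list: `width` (band half-width px), `q` (bright pixel
#'   fraction), `high`, `low` intensities.
#' @param noise_sd Gaussian noise standard deviation added to every
#'   channel.
#' @param background background intensity level.
#' @param y_axis_sign axis convention shared with the extraction modules.
#' @param seed integer seed.
#' @return object of class `synthetic_spec` (a list).
#' @export
synthetic_spec <- function(width = 300L, height = 300L, n_cells = 49L,
                           orientation = list(type = "vonmises", mu = 30,
                                              kappa = 4),
                           lwr = list(mean = 1.8, sd = 0.25),
                           fill = 0.9, jitter_frac = 0.06,
                           confluent = FALSE,
                           nucleus = list(scale = 0.35,
                                          displacement_frac = 0.45,
                                          bearing = list(type = "uniform")),
                           organelle = list(radius = 2.5,
                                            distance_frac = 0.6,
                                            bearing = list(type = "vonmises",
                                                           mu = 210,
                                                           kappa = 4)),
                           marker = list(model = "gradient", base = 0.5,
                                         slope = 0.4,
                                         bearing = list(type = "fixed",
                                                        value = 0),
                                         ratio = 3),
                           junction = list(width = 2L, q = 0.5, high = 1,
                                           low = 0.2),
                           noise_sd = 0.01, background = 0.05,
                           y_axis_sign = -1L, seed = 1L) {
  stopifnot(width >= 50, height >= 50, n_cells >= 1)
  structure(as.list(environment()), class = "synthetic_spec")
}

sample_bearing <- function(dist, n) {
  switch(dist$type,
         fixed = rep(dist$value, n),
         uniform = stats::runif(n, 0, 360),
         vonmises = rvonmises_deg(n, dist$mu, dist$kappa),
         stop("unknown bearing distribution type: ", dist$type))
}

#' Draw von Mises random angles
#'
#' Best-Fisher rejection sampler for the von Mises distribution with mean
#' `mu` (degrees) and concentration `kappa`; `kappa = 0` gives the uniform
#' distribution. With `axial = TRUE` the draws are axial (period 180):
#' sampled on the doubled scale and halved.
#'
#' @param n number of draws.
#' @param mu mean direction in degrees.
#' @param kappa concentration, >= 0.
#' @param seed optional seed (otherwise the current RNG stream is used).
#' @param axial logical.
#' @return an [angle_sample] of the draws.
#' @export
sample_von_mises <- function(n, mu, kappa, seed = NULL, axial = FALSE) {
  if (!is.null(seed)) set.seed(seed)
  if (axial) {
    deg <- rvonmises_deg(n, 2 * mu, kappa) / 2
    angle_sample(deg, mode = "axial")
  } else {
    angle_sample(rvonmises_deg(n, mu, kappa), mode = "directional")
  }
}

# raw sampler returning degrees in [0, 360)
rvonmises_deg <- function(n, mu, kappa) {
  stopifnot(kappa >= 0)
  if (kappa == 0) return(stats::runif(n, 0, 360))
  mu_r <- deg2rad(mu)
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(0)
  while (length(out) < n) {
    m <- max(16L, 2L * (n - length(out)))
    u1 <- stats::runif(m); u2 <- stats::runif(m); u3 <- stats::runif(m)
    z <- cos(pi * u1)
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    ok <- (cc * (2 - cc) - u2 > 0) | (log(cc / u2) + 1 - cc >= 0)
    th <- mu_r + sign(u3[ok] - 0.5) * acos(pmax(-1, pmin(1, f[ok])))
    out <- c(out, th)
  }
  normalize_angle(rad2deg(out[seq_len(n)]))
}

#' Generate a synthetic monolayer image stack with ground truth
#'
#' Renders a multi-channel image (junction, nucleus, organelle, marker), the
#' cell and nucleus instance label masks, and a per-cell ground-truth table
#' from a [synthetic_spec()]. All geometry is drawn once from the spec's
#' distributions with the spec's seed, so the same spec reproduces the same
#' stack bit for bit.
#'
#' @param spec a [synthetic_spec()].
#' @return list: `channels` (named list of matrices), `cell_mask`,
#'   `nucleus_mask` (integer label matrices), `truth` (data frame), `spec`.
#' @export
generate_monolayer <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  W <- spec$width; H <- spec$height
  n <- spec$n_cells
  sigma <- spec$y_axis_sign
  gc_ <- ceiling(sqrt(n * W / H)); gr_ <- ceiling(n / gc_)
  px <- W / gc_; py <- H / gr_
  pitch <- min(px, py)
  jit <- spec$jitter_frac * pitch
  slots <- expand.grid(ix = seq_len(gc_), iy = seq_len(gr_))[seq_len(n), ]
  # snap centres to the half-pixel grid: shapes rasterised about a
  # half-integer centre are point-symmetric, so binary mask centroids equal
  # the drawn centres exactly and bearings survive rasterisation
  snap <- function(v) round(2 * v) / 2
  sx <- snap((slots$ix - 0.5) * px + stats::runif(n, -jit, jit))
  sy <- snap((slots$iy - 0.5) * py + stats::runif(n, -jit, jit))

  max_a <- 0.5 * pitch - jit - 1
  if (max_a < 4) stop("infeasible packing: cells too small (", round(max_a, 1),
                      " px semi-axis); reduce n_cells or enlarge the image")
  ori <- if (spec$orientation$type == "fixed")
    rep(normalize_angle(spec$orientation$value, 180), n)
  else normalize_angle(rvonmises_deg(n, 2 * spec$orientation$mu,
                                     spec$orientation$kappa) / 2, 180)
  lwr_k <- pmax(1.05, stats::rnorm(n, spec$lwr$mean, spec$lwr$sd))
  a_k <- rep(spec$fill * max_a, n)
  b_k <- a_k / lwr_k
  if (min(b_k) < 3) stop("infeasible packing: minor semi-axis below 3 px; ",
                         "reduce lwr or n_cells")

  # Voronoi partition of the full frame (used for clipping / confluence)
  xg <- matrix(rep(seq_len(W) - 1L, each = H), H)
  yg <- matrix(rep(seq_len(H) - 1L, W), H)
  best <- matrix(Inf, H, W); vor <- matrix(0L, H, W)
  for (k in seq_len(n)) {
    d2 <- (xg - sx[k])^2 + (yg - sy[k])^2
    upd <- d2 < best
    best[upd] <- d2[upd]; vor[upd] <- k
  }

  cells <- matrix(0L, H, W)
  if (spec$confluent) {
    cells <- vor
  } else {
    for (k in seq_len(n)) {
      t <- sigma * deg2rad(ori[k])
      dx <- xg - sx[k]; dy <- yg - sy[k]
      u <- dx * cos(t) + dy * sin(t)
      v <- -dx * sin(t) + dy * cos(t)
      inside <- (u / a_k[k])^2 + (v / b_k[k])^2 <= 1 & vor == k
      cells[inside] <- k
    }
  }

  # nuclei (discs, one per cell) and organelles (discs at a bearing from
  # the nucleus centre). A circular nucleus snapped to the half-pixel grid
  # keeps the displacement bearing exact under rasterisation. The organelle
  # offset is capped so the disc stays wholly inside the cell ellipse; when
  # the sampled bearing leaves too little room (nucleus near the cell edge
  # in that direction) the nucleus displacement is shrunk - bearing
  # preserved - until a minimum organelle offset fits, so bearings are
  # never hypersensitive to sub-pixel centroid error.
  nuc_bear <- sample_bearing(spec$nucleus$bearing, n)
  org_bear <- sample_bearing(spec$organelle$bearing, n)
  orad <- spec$organelle$radius
  d_min_org <- 4
  rn_k <- spec$nucleus$scale * b_k
  if (min(b_k) < orad + d_min_org / 2 + 2)
    stop("infeasible packing: organelle radius ", orad,
         " too large for minor semi-axis ", round(min(b_k), 1))
  nuc_d <- pmin(spec$nucleus$displacement_frac * b_k, b_k - rn_k - 1.5)
  nx <- ny <- ox <- oy <- numeric(n)
  for (k in seq_len(n)) {
    t <- sigma * deg2rad(ori[k])
    u_r <- c(cos(deg2rad(org_bear[k])), sigma * sin(deg2rad(org_bear[k])))
    u1 <- u_r[1] * cos(t) + u_r[2] * sin(t)
    u2 <- -u_r[1] * sin(t) + u_r[2] * cos(t)
    A <- a_k[k] - orad - 1; B <- b_k[k] - orad - 1
    nd <- nuc_d[k]
    nb_r <- deg2rad(nuc_bear[k])
    repeat {
      n0 <- c(nd * cos(nb_r), sigma * nd * sin(nb_r))
      n1 <- n0[1] * cos(t) + n0[2] * sin(t)
      n2 <- -n0[1] * sin(t) + n0[2] * cos(t)
      al <- (u1 / A)^2 + (u2 / B)^2
      ga <- n1 * u1 / A^2 + n2 * u2 / B^2
      de <- (n1 / A)^2 + (n2 / B)^2 - 1
      d_fit <- (-ga + sqrt(max(0, ga^2 - al * de))) / al
      if (d_fit >= d_min_org || nd < 0.2) break
      nd <- 0.7 * nd
    }
    if (d_fit < 1) stop("infeasible packing: organelle does not fit ",
                        "inside cell ", k, "; reduce organelle radius or lwr")
    nx[k] <- snap(sx[k] + nd * cos(nb_r))
    ny[k] <- snap(sy[k] + sigma * nd * sin(nb_r))
    d_want <- max(spec$organelle$distance_frac * b_k[k],
                  rn_k[k] + orad + 1)
    d <- min(d_want, d_fit)
    ox[k] <- nx[k] + d * u_r[1]
    oy[k] <- ny[k] + d * u_r[2]
  }
  # record the achieved (post-snap) nucleus bearing as ground truth
  nuc_bear <- normalize_angle(rad2deg(sigma * atan2(ny - sy, nx - sx)))
  nuclei <- matrix(0L, H, W)
  for (k in seq_len(n)) {
    inside <- (xg - nx[k])^2 + (yg - ny[k])^2 <= rn_k[k]^2 & cells == k
    nuclei[inside] <- k
  }
  organelles <- matrix(0L, H, W)
  # render organelle discs with sub-pixel (4x4 supersampled) coverage so
  # the intensity-weighted centroid matches the drawn centre closely; the
  # instance mask is the >= 50% coverage core
  org_cov <- matrix(0, H, W)
  sub <- seq(-0.375, 0.375, by = 0.25)
  for (k in seq_len(n)) {
    cols <- max(1L, floor(ox[k] - orad)):min(W - 1L, ceiling(ox[k] + orad))
    rows <- max(1L, floor(oy[k] - orad)):min(H - 1L, ceiling(oy[k] + orad))
    for (cc in cols) for (rr in rows) {
      if (cells[rr + 1L, cc + 1L] != k) next
      cov <- mean(outer((cc + sub - ox[k])^2, (rr + sub - oy[k])^2, `+`) <=
                    orad^2)
      if (cov > 0) {
        org_cov[rr + 1L, cc + 1L] <- cov
        if (cov >= 0.5) organelles[rr + 1L, cc + 1L] <- k
      }
    }
  }

  # channels
  bg <- spec$background
  ch_nuc <- matrix(bg, H, W); ch_nuc[nuclei > 0L] <- 1
  ch_org <- bg + (1 - bg) * org_cov

  contour <- matrix(FALSE, H, W)
  for (k in seq_len(n)) if (any(cells == k))
    contour <- contour | mask_contour(cells == k)
  band <- dilate_set(contour, spec$junction$width)
  ch_jun <- matrix(bg, H, W)
  nb <- sum(band)
  bright <- stats::runif(nb) < spec$junction$q
  ch_jun[band] <- ifelse(bright, spec$junction$high, spec$junction$low)

  mk_bear <- sample_bearing(spec$marker$bearing, n)
  ch_mark <- matrix(bg, H, W)
  for (k in seq_len(n)) {
    sel <- cells == k
    if (!any(sel)) next
    if (spec$marker$model == "uniform") {
      ch_mark[sel] <- spec$marker$base
    } else if (spec$marker$model == "gradient") {
      brad <- deg2rad(mk_bear[k])
      proj <- ((xg[sel] - sx[k]) * cos(brad) +
                 (yg[sel] - sy[k]) * sigma * sin(brad)) / a_k[k]
      ch_mark[sel] <- pmax(0, spec$marker$base + spec$marker$slope * proj)
    } else if (spec$marker$model == "ratio") {
      ch_mark[sel] <- 1
      ch_mark[nuclei == k] <- spec$marker$ratio
    } else stop("unknown marker model: ", spec$marker$model)
  }

  if (spec$noise_sd > 0) {
    addn <- function(m) {
      out <- m + matrix(stats::rnorm(H * W, 0, spec$noise_sd), H)
      out[out < 0] <- 0
      out
    }
    ch_nuc <- addn(ch_nuc); ch_org <- addn(ch_org)
    ch_jun <- addn(ch_jun); ch_mark <- addn(ch_mark)
  }

  # the intensity-weighted centroid of a linear gradient in an ellipse is
  # pulled toward the major axis: the recoverable marker-polarity direction
  # is the gradient bearing rotated by the cell's second-moment tensor,
  # atan2 of M u with M = R(phi) diag(a^2, b^2) R(phi)', u = (cos b, sin b)
  phi_r <- deg2rad(ori); beta_r <- deg2rad(mk_bear)
  u1m <- cos(beta_r - phi_r); u2m <- sin(beta_r - phi_r)
  marker_expected <- normalize_angle(rad2deg(
    phi_r + atan2(b_k^2 * u2m, a_k^2 * u1m)))

  truth <- data.frame(
    label = seq_len(n), seed_x = sx, seed_y = sy,
    orientation_deg = ori, lwr = lwr_k,
    nucleus_bearing_deg = nuc_bear,
    organelle_bearing_deg = org_bear,
    marker_bearing_deg = mk_bear,
    marker_polarity_expected_deg = marker_expected,
    expected_sr_sign = sign(round(cos(deg2rad(marker_expected)), 12)))

  list(channels = list(junction = ch_jun, nucleus = ch_nuc,
                       organelle = ch_org, marker = ch_mark),
       cell_mask = cells, nucleus_mask = nuclei,
       organelle_mask = organelles,
       truth = truth, spec = spec)
}

# exact Euclidean dilation of a pixel set by radius t (same construction as
# interface_region, shared by the junction band renderer)
dilate_set <- function(mask, t) {
  nr <- nrow(mask); nc <- ncol(mask)
  out <- matrix(FALSE, nr, nc)
  idx <- which(mask)
  if (!length(idx)) return(out)
  r0 <- (idx - 1L) %% nr + 1L
  c0 <- (idx - 1L) %/% nr + 1L
  for (dx in -floor(t):floor(t)) {
    dymax <- floor(sqrt(t^2 - dx^2))
    for (dy in -dymax:dymax) {
      r <- r0 + dy; cc <- c0 + dx
      ok <- r >= 1L & r <= nr & cc >= 1L & cc <= nc
      out[cbind(r[ok], cc[ok])] <- TRUE
    }
  }
  out
}
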