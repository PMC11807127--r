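#' Directional or axial angle sample
#'
#' Container for a set of angles. Directional data (front and back
#' distinguishable, e.g. nucleus-Golgi polarity) have period 360 degrees;
#' axial data (undirected axes, e.g. shape orientation) have period 180
#' degrees and are analysed after the doubling transform
#' \eqn{\theta_i = 2\phi_i}, with means backtransformed by halving. Angles
#' are taken in degrees and stored in radians; `NA` entries are dropped.
#'
#' @param angles_deg numeric vector of angles in degrees.
#' @param mode `"directional"` (default) or `"axial"`.
#' @param weights optional non-negative per-observation weights.
#' @return object of class `angle_sample`.
#' @examples
#' a <- angle_sample(c(10, 50, 90))
#' circ_summary(a, alpha_p = 0)
#' @export
angle_sample <- function(angles_deg, mode = c("directional", "axial"),
                         weights = NULL) {
  mode <- match.arg(mode)
  keep <- is.finite(angles_deg)
  angles_deg <- angles_deg[keep]
  if (length(angles_deg) < 1L) stop("need at least one finite angle")
  if (!is.null(weights)) {
    weights <- weights[keep]
    stopifnot(length(weights) == length(angles_deg), all(weights >= 0))
  }
  period <- if (mode == "axial") 180 else 360
  structure(list(rad = deg2rad(normalize_angle(angles_deg, period)),
                 mode = mode, weights = weights,
                 n = length(angles_deg)),
            class = "angle_sample")
}

#' @export
print.angle_sample <- function(x, ...) {
  cat(sprintf("<angle_sample> %s, n = %d\n", x$mode, x$n))
  invisible(x)
}

# angles on the analysis scale: doubled for axial data
analysis_angles <- function(sample) {
  stopifnot(inherits(sample, "angle_sample"))
  if (sample$mode == "axial") 2 * sample$rad else sample$rad
}

# mean resultant of angles in radians (optionally weighted)
resultant <- function(theta, w = NULL) {
  if (is.null(w)) w <- rep(1, length(theta))
  W <- sum(w)
  C <- sum(w * cos(theta)) / W
  S <- sum(w * sin(theta)) / W
  list(R = sqrt(C^2 + S^2), mean = atan2(S, C))
}

#' Collective circular summary: polarity indices and confidence interval
#'
#' Computes the mean resultant vector of the sample. Its length R is the
#' polarity index (1 = perfectly aligned collective, 0 = no collective
#' direction); its direction is the circular mean. The circular variance is
#' S = 1 - R. Given a reference ("polar") direction `alpha_p`, the signed
#' polarity index is \deqn{V = R\,\cos(\bar\alpha - \alpha_p),} between -1
#' (anti-aligned) and +1 (aligned with the cue). Axial samples are doubled
#' before analysis and the mean (and its CI) halved afterwards; the
#' reference is doubled accordingly.
#'
#' @param sample an [angle_sample].
#' @param alpha_p optional reference direction in degrees (period of the
#'   sample's mode).
#' @param ci logical: compute a confidence interval for the mean direction.
#' @param level confidence level, default 0.95.
#' @param seed integer seed for the bootstrap CI fallback.
#' @return object of class `circ_summary` with fields `n`, `mean_deg`, `R`,
#'   `S`, `V`, `c`, `alpha_p`, `ci_low_deg`, `ci_high_deg`, `ci_level`,
#'   `ci_method`, `mode`.
#' @export
circ_summary <- function(sample, alpha_p = NULL, ci = TRUE, level = 0.95,
                         seed = 1L) {
  stopifnot(inherits(sample, "angle_sample"))
  theta <- analysis_angles(sample)
  res <- resultant(theta, sample$weights)
  half <- if (sample$mode == "axial") 2 else 1
  mean_deg <- normalize_angle(rad2deg(res$mean) / half, 360 / half)
  V <- cc <- ap <- NA_real_
  if (!is.null(alpha_p)) {
    ap <- normalize_angle(alpha_p, 360 / half)
    cc <- cos(res$mean - half * deg2rad(ap))
    V <- res$R * cc
  }
  ci_out <- c(NA_real_, NA_real_); ci_method <- NA_character_
  if (ci && sample$n >= 2 && res$R > 1e-12) {
    cio <- mean_ci(sample, level = level, seed = seed)
    ci_out <- c(cio$ci_low_deg, cio$ci_high_deg)
    ci_method <- cio$method
  }
  structure(list(n = sample$n, mode = sample$mode,
                 mean_deg = mean_deg, R = res$R, S = 1 - res$R,
                 V = V, c = cc, alpha_p = ap,
                 ci_low_deg = ci_out[1], ci_high_deg = ci_out[2],
                 ci_level = level, ci_method = ci_method),
            class = "circ_summary")
}

#' @export
print.circ_summary <- function(x, ...) {
  cat(sprintf("Circular summary (%s), n = %d\n", x$mode, x$n))
  cat(sprintf("  mean direction : %.2f deg\n", x$mean_deg))
  cat(sprintf("  polarity index R = %.4f  (circular variance S = %.4f)\n",
              x$R, x$S))
  if (is.finite(x$V))
    cat(sprintf("  signed polarity index V = %.4f  (alpha_p = %.1f deg)\n",
                x$V, x$alpha_p))
  if (is.finite(x$ci_low_deg))
    cat(sprintf("  %.0f%% CI of mean: [%.2f, %.2f] deg (%s)\n",
                100 * x$ci_level, x$ci_low_deg, x$ci_high_deg, x$ci_method))
  invisible(x)
}

#' Signed polarity index
#'
#' Convenience accessor for V = R cos(mean - alpha_p); see [circ_summary()].
#'
#' @inheritParams circ_summary
#' @param alpha_p reference direction in degrees.
#' @return numeric V in `[-1, 1]`.
#' @export
signed_polarity_index <- function(sample, alpha_p) {
  circ_summary(sample, alpha_p = alpha_p, ci = FALSE)$V
}

#' Confidence interval for the circular mean direction
#'
#' Large-sample interval based on the circular dispersion
#' \eqn{\hat\delta = (1 - \hat\rho_2) / (2R^2)} (with \eqn{\hat\rho_2} the
#' mean resultant length of the doubled deviations):
#' \eqn{\bar\theta \pm \arcsin(z\sqrt{\hat\delta/n})}. For small samples
#' (n < 25) or when the arcsine argument leaves [0, 1] the method falls
#' back to a seeded percentile bootstrap of the mean direction (B
#' resamples). Axial samples are handled on the doubled scale and the
#' interval halved.
#'
#' @inheritParams circ_summary
#' @param B bootstrap resamples for the fallback.
#' @return list with `ci_low_deg`, `ci_high_deg`, `method`.
#' @export
mean_ci <- function(sample, level = 0.95, B = 2000L, seed = 1L) {
  stopifnot(inherits(sample, "angle_sample"), sample$n >= 2)
  theta <- analysis_angles(sample)
  res <- resultant(theta)
  if (res$R <= 1e-12) {
    warning("resultant length ~ 0: mean direction CI is the full circle")
    return(list(ci_low_deg = NA_real_, ci_high_deg = NA_real_,
                method = "undefined"))
  }
  half <- if (sample$mode == "axial") 2 else 1
  n <- length(theta)
  z <- stats::qnorm(1 - (1 - level) / 2)
  dev <- theta - res$mean
  rho2 <- mean(cos(2 * dev))
  delta <- (1 - rho2) / (2 * res$R^2)
  arg <- z * sqrt(max(0, delta) / n)
  if (n >= 25 && arg <= 1) {
    hw <- asin(arg)
    method <- "dispersion"
  } else {
    devs <- with_local_seed(seed, vapply(seq_len(B), function(b) {
      th <- theta[sample.int(n, n, replace = TRUE)]
      d <- resultant(th)$mean - res$mean
      atan2(sin(d), cos(d))                      # wrap to (-pi, pi]
    }, numeric(1)))
    qs <- stats::quantile(devs, c((1 - level) / 2, 1 - (1 - level) / 2),
                          names = FALSE, type = 7)
    hw <- max(abs(qs))                           # symmetric envelope
    method <- "bootstrap"
  }
  lo <- rad2deg(res$mean - hw) / half
  hi <- rad2deg(res$mean + hw) / half
  list(ci_low_deg = normalize_angle(lo, 360 / half),
       ci_high_deg = normalize_angle(hi, 360 / half),
       method = method)
}

circ_test_result <- function(name, statistic, stat_name, p, n, extra = NULL) {
  out <- list(method = name,
              statistic = stats::setNames(statistic, stat_name),
              p.value = min(1, max(0, p)), n = n,
              data.name = "angle sample")
  out <- c(out, extra)
  class(out) <- c("circ_test", "htest")
  out
}

#' Rayleigh test of circular uniformity
#'
#' Tests the null of uniformity against a unimodal alternative using
#' Z = n R^2, with the standard series approximation for the p-value.
#' Axial samples are doubled first.
#'
#' @inheritParams circ_summary
#' @return an object of class `circ_test` (printable as an `htest`).
#' @export
rayleigh_test <- function(sample) {
  theta <- analysis_angles(sample)
  n <- length(theta)
  if (n < 4) warning("n < 4: Rayleigh p-value unreliable")
  R <- resultant(theta)$R
  Z <- n * R^2
  p <- exp(-Z) * (1 + (2 * Z - Z^2) / (4 * n) -
                    (24 * Z - 132 * Z^2 + 76 * Z^3 - 9 * Z^4) / (288 * n^2))
  circ_test_result("Rayleigh test of uniformity", Z, "Z", p, n,
                   list(R = R))
}

#' V-test (modified Rayleigh) for a specified direction
#'
#' Tests uniformity against a unimodal alternative concentrated at a known
#' a-priori direction `alpha_p`. The statistic is u = V sqrt(2n) with V the
#' signed polarity index; the p-value is one-sided from the normal
#' approximation. For nucleus-Golgi polarity under flow the expected
#' polarisation direction is opposite to the cue, so pass cue + 180.
#'
#' @inheritParams signed_polarity_index
#' @return `circ_test` object with fields `V` and `u`.
#' @export
v_test <- function(sample, alpha_p) {
  theta <- analysis_angles(sample)
  n <- length(theta)
  if (n < 4) warning("n < 4: V-test p-value unreliable")
  V <- signed_polarity_index(sample, alpha_p)
  u <- V * sqrt(2 * n)
  p <- stats::pnorm(u, lower.tail = FALSE)
  circ_test_result("V-test (specified direction)", u, "u", p, n,
                   list(V = V, alpha_p = alpha_p))
}

#' Watson's U2 test of circular uniformity
#'
#' Omnibus uniformity test based on the squared deviation of the empirical
#' distribution from uniformity. Uses the finite-sample modified statistic
#' and the asymptotic series for the p-value.
#'
#' @inheritParams circ_summary
#' @return `circ_test` object.
#' @export
watson_test <- function(sample) {
  theta <- analysis_angles(sample)
  n <- length(theta)
  if (n < 4) warning("n < 4: Watson p-value unreliable")
  u <- sort(theta %% (2 * pi)) / (2 * pi)
  i <- seq_len(n)
  U2 <- sum((u - (2 * i - 1) / (2 * n))^2) - n * (mean(u) - 0.5)^2 + 1 / (12 * n)
  U2m <- (U2 - 0.1 / n + 0.1 / n^2) * (1 + 0.8 / n)
  if (U2m <= 1e-8) {
    p <- 1                       # statistic at/below its lattice minimum
  } else {
    m <- 1:50
    p <- 2 * sum((-1)^(m - 1) * exp(-2 * m^2 * pi^2 * U2m))
  }
  circ_test_result("Watson's U2 test of uniformity", U2, "U2", p, n,
                   list(U2_modified = U2m))
}

.rao_cache <- new.env(parent = emptyenv())

#' Rao's spacing test of circular uniformity
#'
#' Based on the deviation of the sorted arc spacings from the uniform
#' spacing lambda = 360/n: U = (1/2) sum |T_i - lambda| (degrees). The
#' p-value comes from a seeded Monte Carlo null (uniform samples of size
#' n), cached per sample size, rather than from printed critical-value
#' tables. Ties (identical angles) reduce sensitivity but are not an
#' error.
#'
#' @inheritParams circ_summary
#' @param n_mc Monte Carlo null replicates (default 10000).
#' @param seed seed for the Monte Carlo null.
#' @return `circ_test` object; the statistic is in degrees.
#' @export
rao_spacing_test <- function(sample, n_mc = 10000L, seed = 1234L) {
  theta <- analysis_angles(sample)
  n <- length(theta)
  if (n < 4) warning("n < 4: Rao spacing p-value unreliable")
  U <- rao_statistic(theta)
  key <- sprintf("n%d_mc%d_seed%d", n, n_mc, seed)
  if (is.null(.rao_cache[[key]])) {
    .rao_cache[[key]] <- with_local_seed(seed, {
      null_u <- matrix(stats::runif(n * n_mc, 0, 2 * pi), nrow = n)
      sort(apply(null_u, 2, rao_statistic))
    })
  }
  null_dist <- .rao_cache[[key]]
  p <- (sum(null_dist >= U) + 1) / (length(null_dist) + 1)
  circ_test_result("Rao's spacing test of uniformity", U, "U (deg)", p, n)
}

rao_statistic <- function(theta) {
  deg <- sort(rad2deg(theta %% (2 * pi)))
  n <- length(deg)
  sp <- c(diff(deg), 360 - deg[n] + deg[1])
  0.5 * sum(abs(sp - 360 / n))
}

#' Circular-linear correlation coefficient
#'
#' Mardia's correlation between a circular and a linear variable:
#' \deqn{r = \sqrt{\frac{r_{xc}^2 + r_{xs}^2 - 2 r_{xc} r_{xs} r_{cs}}
#' {1 - r_{cs}^2}}} with \eqn{r_{xc} = cor(x, \cos\alpha)},
#' \eqn{r_{xs} = cor(x, \sin\alpha)}, \eqn{r_{cs} = cor(\cos\alpha,
#' \sin\alpha)}. Ranges 0 (no association) to 1.
#'
#' @param sample an [angle_sample].
#' @param x numeric vector, same length as the sample.
#' @return coefficient in `[0, 1]`, or `NA` for degenerate input.
#' @export
circ_linear_corr <- function(sample, x) {
  theta <- analysis_angles(sample)
  stopifnot(length(x) == length(theta))
  keep <- is.finite(x)
  theta <- theta[keep]; x <- x[keep]
  if (length(x) < 5 || stats::sd(x) == 0) return(NA_real_)
  cx <- cos(theta); sx <- sin(theta)
  if (stats::sd(cx) == 0 || stats::sd(sx) == 0) return(NA_real_)
  rxc <- stats::cor(x, cx); rxs <- stats::cor(x, sx)
  rcs <- stats::cor(cx, sx)
  if (abs(rcs) >= 1) return(NA_real_)
  r2 <- (rxc^2 + rxs^2 - 2 * rxc * rxs * rcs) / (1 - rcs^2)
  sqrt(max(0, min(1, r2)))
}

#' Circular-circular correlation coefficient
#'
#' Jammalamadaka-SenGupta correlation between two circular variables:
#' \deqn{\rho = \frac{\sum \sin(\alpha_i - \bar\alpha)\sin(\beta_i -
#' \bar\beta)}{\sqrt{\sum \sin^2(\alpha_i - \bar\alpha) \sum \sin^2(\beta_i
#' - \bar\beta)}}.}
#'
#' @param a,b [angle_sample] objects of equal length.
#' @return coefficient in `[-1, 1]`, or `NA` for a degenerate denominator.
#' @export
circ_circ_corr <- function(a, b) {
  ta <- analysis_angles(a); tb <- analysis_angles(b)
  stopifnot(length(ta) == length(tb))
  if (length(ta) < 5) stop("need n >= 5")
  ma <- resultant(ta)$mean; mb <- resultant(tb)$mean
  sa <- sin(ta - ma); sb <- sin(tb - mb)
  den <- sqrt(sum(sa^2) * sum(sb^2))
  if (den == 0) return(NA_real_)
  sum(sa * sb) / den
}

#' Rose (circular) histogram counts
#'
#' Counts over equal angular bins of the full circle. For axial samples the
#' data occupy `[0, 180)` and every observation is duplicated at +180
#' degrees; the duplicated half is flagged so plots can render it
#' transparent. Non-duplicated counts sum to n.
#'
#' @param sample an [angle_sample].
#' @param n_bins number of bins (>= 4, must divide 360).
#' @return object of class `rose_histogram`: data frame with `bin_start`,
#'   `bin_mid`, `bin_end` (degrees), `count`, `duplicated`.
#' @export
rose_histogram <- function(sample, n_bins = 24L) {
  stopifnot(n_bins >= 4L, 360 %% n_bins == 0)
  width <- 360 / n_bins
  deg <- normalize_angle(rad2deg(sample$rad), if (sample$mode == "axial") 180 else 360)
  if (sample$mode == "axial") deg2 <- c(deg, deg + 180) else deg2 <- deg
  idx <- pmin(n_bins, 1L + floor(deg2 / width))
  counts <- tabulate(idx, nbins = n_bins)
  dup <- rep(FALSE, n_bins)
  if (sample$mode == "axial") {
    dup_idx <- pmin(n_bins, 1L + floor((deg + 180) / width))
    dup[unique(dup_idx)] <- TRUE
  }
  out <- data.frame(bin_start = (seq_len(n_bins) - 1L) * width,
                    bin_mid = (seq_len(n_bins) - 0.5) * width,
                    bin_end = seq_len(n_bins) * width,
                    count = counts, duplicated = dup)
  attr(out, "n") <- sample$n
  attr(out, "mode") <- sample$mode
  class(out) <- c("rose_histogram", "data.frame")
  out
}

#' Plot a rose histogram with collective statistics
#'
#' Base-graphics rose plot: wedge counts, the mean-direction arrow with
#' length equal to the polarity index R, and optionally the cue direction
#' and CI whiskers. Duplicated (axial) bins are drawn lighter.
#'
#' @param x a `rose_histogram`.
#' @param summary optional [circ_summary()] of the same sample.
#' @param ... unused.
#' @return invisibly `x`.
#' @export
plot.rose_histogram <- function(x, summary = NULL, ...) {
  op <- graphics::par(mar = c(1, 1, 2, 1)); on.exit(graphics::par(op))
  graphics::plot(NA, xlim = c(-1.1, 1.1), ylim = c(-1.1, 1.1), asp = 1,
                 axes = FALSE, xlab = "", ylab = "",
                 main = sprintf("Rose plot (n = %d)", attr(x, "n")))
  maxc <- max(x$count, 1)
  for (i in seq_len(nrow(x))) {
    if (x$count[i] == 0) next
    r <- sqrt(x$count[i] / maxc)    # equal-area wedges
    a <- deg2rad(seq(x$bin_start[i], x$bin_end[i], length.out = 16))
    graphics::polygon(c(0, r * cos(a)), c(0, r * sin(a)),
                      col = if (x$duplicated[i]) grDevices::grey(0.85)
                            else grDevices::grey(0.55),
                      border = "white")
  }
  graphics::symbols(0, 0, circles = 1, inches = FALSE, add = TRUE, fg = "grey30")
  if (!is.null(summary)) {
    m <- deg2rad(summary$mean_deg)
    graphics::arrows(0, 0, summary$R * cos(m), summary$R * sin(m),
                     col = "red", lwd = 2, length = 0.08)
    if (is.finite(summary$alpha_p)) {
      a <- deg2rad(summary$alpha_p)
      graphics::arrows(0, 0, cos(a), sin(a), col = "grey40", lwd = 1,
                       length = 0.08, lty = 2)
    }
  }
  invisible(x)
}

#' Mean resultant length of the von Mises distribution
#'
#' The theoretical polarity index of a von Mises sample with concentration
#' kappa: \eqn{A(\kappa) = I_1(\kappa)/I_0(\kappa)} (ratio of modified
#' Bessel functions). Used for parameter-recovery checks.
#'
#' @param kappa concentration parameter, >= 0.
#' @return A(kappa) in `[0, 1)`.
#' @export
vonmises_resultant_length <- function(kappa) {
  stopifnot(kappa >= 0)
  if (kappa == 0) return(0)
  besselI(kappa, 1, expon.scaled = TRUE) / besselI(kappa, 0, expon.scaled = TRUE)
}
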