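test_that("resultant summary matches direct vector sums", {
  s <- circ_summary(angle_sample(rep(40, 8)), ci = FALSE)
  expect_equal(s$R, 1)
  expect_equal(s$mean_deg, 40)
  expect_equal(circ_summary(angle_sample(c(0, 90, 180, 270)), ci = FALSE)$R,
               0, tolerance = 1e-12)
  s2 <- circ_summary(angle_sample(c(0, 90)), ci = FALSE)
  expect_equal(s2$R, sqrt(2) / 2, tolerance = 1e-12)
  expect_equal(s2$mean_deg, 45)
  expect_error(angle_sample(numeric(0)))
})

test_that("signed polarity index follows V = R cos(mean - alpha_p)", {
  expect_equal(signed_polarity_index(angle_sample(rep(123, 5)), 123), 1)
  expect_equal(signed_polarity_index(angle_sample(rep(10, 5)), 190), -1)
  # R = 0.5 at 60 deg from the reference: V = 0.25
  # two angles +/- delta around m have R = cos(delta)
  delta <- acos(0.5) * 180 / pi
  s <- angle_sample(c(60 - delta, 60 + delta))
  expect_equal(signed_polarity_index(s, 0), 0.5 * cos(60 * pi / 180),
               tolerance = 1e-12)
})

test_that("circular identities hold for arbitrary samples", {
  set.seed(17)
  for (i in 1:20) {
    deg <- runif(sample(5:60, 1), 0, 360)
    ap <- runif(1, 0, 360)
    s <- circ_summary(angle_sample(deg), alpha_p = ap, ci = FALSE)
    expect_equal(s$V, s$R * cos((s$mean_deg - ap) * pi / 180),
                 tolerance = 1e-12)
    expect_equal(s$S, 1 - s$R)
    expect_lte(abs(s$V), s$R + 1e-12)
    # joint rotation leaves R and V unchanged
    rot <- runif(1, 0, 360)
    s2 <- circ_summary(angle_sample(deg + rot), alpha_p = ap + rot,
                       ci = FALSE)
    expect_equal(s2$R, s$R, tolerance = 1e-12)
    expect_equal(s2$V, s$V, tolerance = 1e-9)
  }
})

test_that("axial doubling pipeline recovers an axial mean", {
  s <- sample_von_mises(500, 37, 8, seed = 23, axial = TRUE)
  cs <- circ_summary(s, ci = FALSE)
  expect_lt(ang_diff(cs$mean_deg, 37, 180), 1)
  # axial V: all angles at the reference give 1
  expect_equal(signed_polarity_index(angle_sample(rep(140, 6), "axial"), 140),
               1, tolerance = 1e-12)
  # axial angles at reference + 90 (perpendicular) give -1
  expect_equal(signed_polarity_index(angle_sample(rep(50, 6), "axial"), 140),
               -1, tolerance = 1e-12)
})

test_that("von Mises sampling matches the Bessel-ratio resultant length", {
  expect_lt(circ_summary(sample_von_mises(1e5, 0, 0, seed = 1),
                         ci = FALSE)$R, 0.01)
  s8 <- sample_von_mises(1e4, 100, 8, seed = 2)
  expect_equal(circ_summary(s8, ci = FALSE)$R, vonmises_resultant_length(8),
               tolerance = 0.012)
  for (k in c(0.5, 2, 8)) {
    sk <- sample_von_mises(2000, 250, k, seed = 40 + k)
    expect_lt(abs(circ_summary(sk, ci = FALSE)$R -
                    vonmises_resultant_length(k)), 0.02)
  }
  # fixed seed reproducibility
  expect_identical(sample_von_mises(50, 10, 3, seed = 7)$rad,
                   sample_von_mises(50, 10, 3, seed = 7)$rad)
})

test_that("confidence intervals contain the mean and shrink to zero width", {
  s <- angle_sample(rep(77, 30))
  ci <- mean_ci(s)
  expect_equal(ci$ci_low_deg, 77, tolerance = 1e-6)
  expect_equal(ci$ci_high_deg, 77, tolerance = 1e-6)
  # dispersion and bootstrap agree at large n
  big <- sample_von_mises(1000, 60, 4, seed = 3)
  disp <- mean_ci(big)
  expect_identical(disp$method, "dispersion")
  set.seed(99)
  boot_hw <- {
    theta <- big$rad
    res <- sapply(1:2000, function(b) {
      th <- theta[sample.int(1000, 1000, replace = TRUE)]
      atan2(sum(sin(th)), sum(cos(th)))
    })
    m <- atan2(sum(sin(theta)), sum(cos(theta)))
    d <- atan2(sin(res - m), cos(res - m)) * 180 / pi
    max(abs(quantile(d, c(0.025, 0.975))))
  }
  disp_hw <- ang_diff(disp$ci_high_deg, disp$ci_low_deg) / 2
  expect_lt(abs(disp_hw - boot_hw), 2)
  # near-uniform sample: CI undefined with a warning
  expect_warning(u <- mean_ci(angle_sample(c(0, 90, 180, 270))), "full circle")
  expect_true(is.na(u$ci_low_deg))
})

test_that("CI coverage is near nominal for von Mises draws", {
  hit <- replicate(200, {
    cs <- circ_summary(sample_von_mises(500, 30, 8), ci = TRUE)
    w <- (cs$ci_high_deg - cs$ci_low_deg) %% 360
    ((30 - cs$ci_low_deg) %% 360) <= w
  })
  expect_gte(mean(hit), 0.93)
})

test_that("Rayleigh test separates concentrated from uniform samples", {
  r1 <- rayleigh_test(angle_sample(rep(25, 10)))
  expect_equal(unname(r1$statistic), 10)
  expect_lt(r1$p.value, 1e-3)
  grid <- rayleigh_test(angle_sample(seq(0, 350, by = 10)))
  expect_gt(grid$p.value, 0.99)
  expect_warning(rayleigh_test(angle_sample(c(1, 2))), "unreliable")
})

test_that("V-test statistic and one-sidedness", {
  # V = 0: u = 0, p = 0.5 (orthogonal reference)
  v0 <- suppressWarnings(v_test(angle_sample(c(45, 225)), 135))
  expect_equal(unname(v0$statistic), 0, tolerance = 1e-9)
  expect_equal(v0$p.value, 0.5)
  # anti-aligned: V < 0, p > 0.5
  vn <- v_test(angle_sample(rep(180, 20) + rnorm(20, 0, 5)), 0)
  expect_lt(vn$V, 0)
  expect_gt(vn$p.value, 0.5)
})

test_that("Watson and Rao react to equispaced and degenerate samples", {
  eq <- angle_sample(seq(0, 359, by = 10))
  rao_eq <- rao_spacing_test(eq)
  expect_equal(unname(rao_eq$statistic), 0, tolerance = 1e-9)
  expect_gt(rao_eq$p.value, 0.99)
  # all identical, n = 10: one spacing 360, nine 0 -> U = 324
  rao_id <- rao_spacing_test(angle_sample(rep(42, 10)))
  expect_equal(unname(rao_id$statistic), 324, tolerance = 1e-9)
  expect_lt(rao_id$p.value, 0.01)
  expect_lt(watson_test(angle_sample(rep(42, 10)))$p.value, 0.01)
  expect_gt(watson_test(eq)$p.value, 0.5)
})

test_that("circular-linear correlation identities", {
  a <- seq(0, 350, by = 10)
  s <- angle_sample(a)
  expect_equal(circ_linear_corr(s, cos(a * pi / 180)), 1, tolerance = 1e-9)
  # rotation invariance
  set.seed(3)
  ang <- runif(60, 0, 360); x <- rnorm(60) + cos(ang * pi / 180)
  r0 <- circ_linear_corr(angle_sample(ang), x)
  r1 <- circ_linear_corr(angle_sample(ang + 111), x)
  expect_equal(r0, r1, tolerance = 1e-9)
  expect_true(is.na(circ_linear_corr(angle_sample(ang), rep(2, 60))))
  # independent x: small coefficient in most replicates
  set.seed(5)
  nulls <- replicate(40, circ_linear_corr(angle_sample(runif(200, 0, 360)),
                                          rnorm(200)))
  expect_gte(mean(nulls < 0.15), 0.95)
})

test_that("circular-circular correlation sign algebra", {
  set.seed(6)
  a <- angle_sample(runif(50, 0, 360))
  expect_equal(circ_circ_corr(a, a), 1)
  shifted <- angle_sample(rad2deg <- a$rad * 180 / pi + 180)
  expect_equal(circ_circ_corr(a, shifted), 1, tolerance = 1e-9)
  neg <- angle_sample(-a$rad * 180 / pi)
  expect_equal(circ_circ_corr(a, neg), -1, tolerance = 1e-9)
  nulls <- replicate(40, circ_circ_corr(
    sample_von_mises(100, 0, 2), sample_von_mises(100, 90, 2)))
  expect_lt(mean(abs(nulls)), 0.1)
})

test_that("rose histogram conserves counts and duplicates axial bins", {
  s <- angle_sample(c(7.5, 22.5, 100, 200, 300))
  rh <- rose_histogram(s, 24)
  expect_equal(sum(rh$count), 5)
  ax <- angle_sample(c(10, 40, 100, 170), mode = "axial")
  rha <- rose_histogram(ax, 24)
  expect_equal(sum(rha$count), 8)           # originals + duplicates
  expect_equal(sum(rha$count[!rha$duplicated]), 4)
  first <- rha$count[1:12]; second <- rha$count[13:24]
  expect_equal(second, first)               # duplicated half mirrors
  expect_error(rose_histogram(s, 7))
})
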