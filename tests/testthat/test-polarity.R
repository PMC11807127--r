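test_that("front-rear angle follows the sign convention in all quadrants", {
  expect_equal(front_rear_angle(c(0, 0), c(1, 0), +1), 0)
  expect_equal(front_rear_angle(c(0, 0), c(0, 1), +1), 90)
  expect_equal(front_rear_angle(c(0, 0), c(0, 1), -1), 270)
  # vector-geometry oracle across all four quadrants, both sigma
  set.seed(5)
  for (i in 1:40) {
    r <- runif(2, -10, 10); f <- runif(2, -10, 10)
    for (sg in c(-1, 1)) {
      got <- front_rear_angle(r, f, sg)
      exp_ang <- (sg * atan2(f[2] - r[2], f[1] - r[1]) * 180 / pi) %% 360
      expect_equal(got, exp_ang, tolerance = 1e-9)
    }
  }
  expect_true(is.na(front_rear_angle(c(2, 3), c(2, 3))))
})

test_that("swapping front and rear shifts the angle by exactly 180", {
  set.seed(6)
  for (i in 1:10) {
    r <- runif(2, 0, 50); f <- runif(2, 0, 50)
    a <- front_rear_angle(r, f, -1); b <- front_rear_angle(f, r, -1)
    expect_equal(ang_diff(a, b + 180), 0, tolerance = 1e-9)
  }
})

test_that("nucleus-Golgi polarity recovers a placed bearing", {
  # nucleus disc at centre, organelle disc at bearing 210 (sigma = -1)
  n <- 81; ctr <- 40
  nuc <- raster_disc(6, n = n, centre = c(ctr, ctr))
  d <- 20; b <- 210 * pi / 180; sigma <- -1
  org_ctr <- c(ctr + d * cos(b), ctr + sigma * d * sin(b))
  org <- raster_disc(4, n = n, centre = org_ctr)
  got <- nucleus_golgi_polarity(nuc, org, NULL, sigma)
  expect_lt(ang_diff(got, 210), 2)
  # swap: antisymmetry
  swapped <- nucleus_golgi_polarity(org, nuc, NULL, sigma)
  expect_lt(ang_diff(swapped, 30), 2)
  # concentric: missing
  expect_true(is.na(nucleus_golgi_polarity(nuc, nuc, NULL, sigma)))
  # absent organelle: missing, no error
  expect_true(is.na(nucleus_golgi_polarity(nuc, NULL, NULL, sigma)))
})

test_that("nucleus displacement uses the cell centre as rear", {
  cell <- raster_disc(25, n = 71, centre = c(35, 35))
  nuc <- raster_disc(6, n = 71, centre = c(45, 35))   # displaced +x
  expect_lt(ang_diff(nucleus_displacement(cell, nuc, -1), 0), 1)
  nuc_up <- raster_disc(6, n = 71, centre = c(35, 25)) # smaller y = up
  expect_lt(ang_diff(nucleus_displacement(cell, nuc_up, -1), 90), 1)
  expect_true(is.na(nucleus_displacement(cell,
                                         raster_disc(6, 71, c(35, 35)), -1)))
})

test_that("marker polarity finds delta spots and gradients, misses uniform", {
  cell <- raster_disc(20, n = 51, centre = c(25, 25))
  ch <- matrix(0, 51, 51)
  spot <- c(25 + 10 * cos(pi / 4), 25 - 10 * sin(pi / 4))  # bearing 45, sigma -1
  ch[round(spot[2]) + 1, round(spot[1]) + 1] <- 5
  expect_lt(ang_diff(marker_polarity(cell, ch, -1), 45), 2)
  # uniform marker: centroids coincide
  expect_true(is.na(marker_polarity(cell, matrix(1, 51, 51), -1)))
  # linear gradient along +x
  grad <- matrix(rep(seq(0, 1, length.out = 51), each = 51), 51)
  expect_lt(ang_diff(marker_polarity(cell, grad, +1), 0), 1)
})

test_that("cue intensity ratio obeys its contract", {
  # disc centred between pixel columns: the split line carries no pixels
  cell <- raster_disc(15, n = 42, centre = c(20.5, 20))
  # uniform intensity in a symmetric cell: balanced
  expect_equal(cue_intensity_ratio(cell, matrix(1, 42, 42), 0), 0,
               tolerance = 0.02)
  # all intensity strictly in the rear half (cue +x, rear = x < centroid)
  ch <- matrix(0, 42, 42); ch[, 1:15] <- 3; ch[!cell] <- 0
  expect_equal(cue_intensity_ratio(cell, ch, 0), -1)
  # 75% of intensity in the front half -> 0.5
  ch2 <- matrix(0, 42, 42)
  ch2[cell] <- 1
  front <- col(ch2) - 1 >= 20.5
  tot_front <- sum(ch2[cell & front]); tot_rear <- sum(ch2[cell & !front])
  # scale front weights so front carries 75% of the total
  w <- 3 * tot_rear / tot_front
  ch2[cell & front] <- w
  expect_equal(cue_intensity_ratio(cell, ch2, 0), 0.5, tolerance = 1e-9)
})

test_that("cue reversal flips the ratio sign; translation leaves it fixed", {
  set.seed(9)
  cell <- raster_disc(12, n = 61, centre = c(25.5, 30.5))
  ch <- matrix(0, 61, 61)
  ch[cell] <- runif(sum(cell), 0.1, 2)
  for (ap in c(0, 33, 127)) {
    s1 <- cue_intensity_ratio(cell, ch, ap)
    s2 <- cue_intensity_ratio(cell, ch, ap + 180)
    expect_equal(s1, -s2, tolerance = 1e-9)
    expect_lte(abs(s1), 1)
  }
  # translate mask and image together
  cell2 <- matrix(FALSE, 61, 61); ch2 <- matrix(0, 61, 61)
  cell2[11:61, 6:56] <- cell[1:51, 1:51]
  ch2[11:61, 6:56] <- ch[1:51, 1:51]
  expect_equal(cue_intensity_ratio(cell2, ch2, 33),
               cue_intensity_ratio(cell, ch, 33), tolerance = 1e-9)
})

test_that("marker polarity and ratio sign agree on synthetic gradients", {
  # gradient at bearing beta in a disc: polarity = beta and
  # sign(s_r) = sign(cos(beta - alpha_p))
  n <- 61; ctr <- 30
  cell <- raster_disc(22, n = n, centre = c(ctr, ctr))
  xg <- matrix(rep(0:(n - 1), each = n), n); yg <- matrix(rep(0:(n - 1), n), n)
  sigma <- -1
  for (beta in c(20, 100, 200, 305)) {
    br <- beta * pi / 180
    proj <- (xg - ctr) * cos(br) + (yg - ctr) * sigma * sin(br)
    ch <- 1 + 0.02 * proj
    expect_lt(ang_diff(marker_polarity(cell, ch, sigma), beta), 1.5)
    for (ap in c(0, 90, 250)) {
      sr <- cue_intensity_ratio(cell, ch, ap, sigma)
      expect_equal(sign(sr), sign(cos((beta - ap) * pi / 180)),
                   tolerance = 1e-9)
    }
  }
})
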