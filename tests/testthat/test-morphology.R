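test_that("orientation of axis-aligned bars matches the axis", {
  hbar <- matrix(FALSE, 21, 21); hbar[10:12, 3:19] <- TRUE
  vbar <- matrix(FALSE, 21, 21); vbar[3:19, 10:12] <- TRUE
  expect_equal(shape_orientation(image_moments(NULL, hbar), -1), 0)
  expect_equal(shape_orientation(image_moments(NULL, vbar), -1), 90)
  expect_equal(shape_orientation(image_moments(NULL, hbar), +1), 0)
})

test_that("orientation recovery over angles and aspect ratios, both sigma", {
  for (sigma in c(-1, 1)) {
    for (ab in list(c(30, 10), c(25, 15), c(20, 6))) {
      for (ang in seq(0, 165, by = 15)) {
        mask <- raster_ellipse(ab[1], ab[2], ang, sigma = sigma, n = 81)
        got <- shape_orientation(image_moments(NULL, mask), sigma)
        expect_lt(ang_diff(got, ang, 180), 1)
      }
    }
  }
})

test_that("isotropic shapes return missing orientation", {
  sq <- matrix(FALSE, 20, 20); sq[5:14, 5:14] <- TRUE
  expect_true(is.na(shape_orientation(image_moments(NULL, sq), -1)))
  expect_true(is.na(shape_orientation(image_moments(NULL,
                                                    raster_disc(10)), -1)))
})

test_that("length-to-width ratio is exact for discs and ellipses", {
  expect_equal(lwr(image_moments(NULL, raster_disc(20))), 1, tolerance = 0.01)
  m <- image_moments(NULL, raster_ellipse(30, 10, 0, n = 81))
  expect_equal(lwr(m), 3, tolerance = 0.05 / 3)
  # rotation invariance
  l0 <- lwr(image_moments(NULL, raster_ellipse(24, 12, 10, n = 71)))
  l90 <- lwr(image_moments(NULL, raster_ellipse(24, 12, 100, n = 71)))
  expect_lt(abs(l90 / l0 - 1), 0.01)
  # degenerate: 1-pixel-wide line
  line <- matrix(FALSE, 9, 9); line[5, 2:8] <- TRUE
  expect_warning(ld <- lwr(image_moments(NULL, line)), "degenerate")
  expect_true(is.na(ld))
})

test_that("orientation and LWR are translation invariant", {
  e <- raster_ellipse(15, 7, 40, n = 45)
  big <- matrix(FALSE, 90, 90); big[5:49, 8:52] <- e
  big2 <- matrix(FALSE, 90, 90); big2[40:84, 30:74] <- e
  m1 <- image_moments(NULL, big); m2 <- image_moments(NULL, big2)
  expect_equal(shape_orientation(m1, -1), shape_orientation(m2, -1))
  expect_equal(lwr(m1), lwr(m2))
})

test_that("symmetry score is 1 for true mirror shapes, 0-1 always", {
  rect <- matrix(FALSE, 30, 30); rect[10:20, 5:25] <- TRUE
  expect_gte(shape_symmetry(rect, 0), 0.98)
  expect_equal(shape_symmetry(rect, 0), shape_symmetry(rect, 180))
  # axis-aligned ellipse: split line along either principal axis is a
  # lattice-preserving mirror
  e <- raster_ellipse(15, 8, 0, n = 45)
  expect_gte(shape_symmetry(e, 0), 0.95)
  expect_gte(shape_symmetry(e, 90), 0.95)
  # tilted mirror axis: nearest-pixel resampling loses boundary pixels to
  # rounding collisions, so the score is high but not near 1
  et <- raster_ellipse(15, 8, 30, n = 45)
  expect_gte(shape_symmetry(et, 30), 0.7)
  expect_gt(shape_symmetry(et, 30), shape_symmetry(et, 75))
  set.seed(21)
  for (i in 1:10) {
    blob <- matrix(runif(400) > 0.45, 20, 20)
    blob[10, 10] <- TRUE
    s <- shape_symmetry(blob, runif(1, 0, 360))
    expect_gte(s, 0); expect_lte(s, 1)
  }
})

test_that("symmetry equals a brute-force pixel reflection IoU", {
  # right triangle, cue along +x: split by the vertical line through the
  # centroid, reflect the rear half, IoU with the front half
  tri <- matrix(FALSE, 25, 25)
  for (r in 1:20) tri[r, 1:r] <- TRUE
  alpha <- 0; sigma <- -1
  got <- shape_symmetry(tri, alpha, sigma)
  idx <- which(tri)
  x <- (ceiling(idx / nrow(tri)) - 1); y <- (idx - 1) %% nrow(tri)
  cx <- mean(x)
  front <- x - cx > 0; rear <- x - cx < 0
  mirrored <- unique(paste(round(2 * cx - x[rear]), y[rear]))
  fr <- paste(x[front], y[front])
  expected <- length(intersect(mirrored, fr)) /
    length(union(mirrored, fr))
  expect_equal(got, expected)
})

test_that("area, perimeter and circularity behave on standard shapes", {
  sq <- matrix(FALSE, 14, 14); sq[3:12, 3:12] <- TRUE
  d <- region_descriptors(sq, pixel_size = 0.5)
  expect_equal(d$area_px2, 100)
  expect_equal(d$area_um2, 25)
  expect_equal(d$perimeter_px, 36 * 0.948) # 4 x 9 rook steps, corrected
  disc <- raster_disc(20)
  dd <- region_descriptors(disc)
  expect_gte(dd$circularity, 0.95)
  expect_lte(dd$circularity, 1)
  line <- matrix(FALSE, 5, 110); line[3, 4:104] <- TRUE
  expect_lt(region_descriptors(line)$circularity, 0.2)
  expect_error(region_descriptors(matrix(FALSE, 3, 3)), "empty")
})
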