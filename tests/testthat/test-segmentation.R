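test_that("nucleus assignment follows majority overlap with low-label ties", {
  cells <- matrix(0L, 10, 10)
  cells[2:9, 2:5] <- 1L; cells[2:9, 6:9] <- 2L
  nucs <- matrix(0L, 10, 10)
  nucs[3:4, 3:7] <- 1L               # 60% in cell 1, 40% in cell 2
  mf <- match_and_filter(cells, nucs, exclude_border = FALSE)
  expect_equal(mf$retained$cell_label, 1L)
  expect_equal(mf$dropped$reason, "no_nucleus")
  # exact tie: half in each -> lower label wins
  nucs2 <- matrix(0L, 10, 10); nucs2[6:7, 4:7] <- 1L
  mf2 <- match_and_filter(cells, nucs2, exclude_border = FALSE)
  expect_equal(mf2$retained$cell_label, 1L)
})

test_that("cells with zero or multiple nuclei are dropped and logged", {
  cells <- matrix(0L, 12, 12)
  cells[2:11, 2:6] <- 1L; cells[2:11, 7:11] <- 2L
  nucs <- matrix(0L, 12, 12)
  nucs[3:4, 3:4] <- 1L; nucs[8:9, 3:4] <- 2L   # both in cell 1
  mf <- match_and_filter(cells, nucs, exclude_border = FALSE)
  expect_equal(nrow(mf$retained), 0)
  expect_setequal(mf$dropped$reason, c("multiple_nuclei", "no_nucleus"))
  expect_equal(unname(mf$counts["total"]),
               unname(mf$counts["retained"] + mf$counts["dropped"]))
})

test_that("a five-cell toy layout retains exactly the hand count", {
  # 2 x 2 interior grid of cells + 1 border strip; border cell and the
  # nucleus-free cell drop, one cell has two nuclei -> 2 retained
  cells <- matrix(0L, 20, 20)
  cells[1:20, 1:3] <- 5L                       # touches border
  cells[4:11, 5:11] <- 1L; cells[4:11, 12:18] <- 2L
  cells[12:19, 5:11] <- 3L; cells[12:19, 12:18] <- 4L
  nucs <- matrix(0L, 20, 20)
  nucs[6:7, 7:8] <- 1L                         # cell 1
  nucs[6:7, 14:15] <- 2L                       # cell 2
  nucs[14:15, 6:7] <- 3L; nucs[17:18, 9:10] <- 4L  # both in cell 3
  mf <- match_and_filter(cells, nucs, exclude_border = TRUE)
  expect_setequal(mf$retained$cell_label, c(1L, 2L))
  expect_equal(unname(mf$counts["dropped"]), 3)
  expect_setequal(mf$dropped$reason,
                  c("touches_border", "multiple_nuclei", "no_nucleus"))
})

test_that("label renumbering changes labels, not retained regions", {
  cells <- matrix(0L, 15, 15)
  cells[3:7, 3:7] <- 1L; cells[3:7, 9:13] <- 2L; cells[9:13, 3:7] <- 3L
  nucs <- matrix(0L, 15, 15)
  nucs[4:5, 4:5] <- 1L; nucs[4:5, 10:11] <- 2L; nucs[10:11, 4:5] <- 3L
  mf1 <- match_and_filter(cells, nucs, exclude_border = FALSE)
  perm <- c(0L, 7L, 5L, 2L)                   # background, then labels+1
  cells2 <- matrix(perm[cells + 1L], 15)
  mf2 <- match_and_filter(cells2, nucs, exclude_border = FALSE)
  regions1 <- lapply(sort(mf1$retained$cell_label), function(k) which(cells == k))
  regions2 <- lapply(mf2$retained$cell_label, function(k) which(cells2 == k))
  expect_setequal(vapply(regions1, paste, collapse = ",", ""),
                  vapply(regions2, paste, collapse = ",", ""))
})

test_that("Golgi mask inherits cell labels and splits straddling blobs", {
  cells <- matrix(0L, 20, 20)
  cells[2:19, 2:10] <- 7L; cells[2:19, 11:19] <- 8L
  ch <- matrix(0.05, 20, 20)
  ch[5:7, 5:7] <- 1                            # inside cell 7
  ch[12:14, 9:13] <- 1                         # straddles 7 and 8
  om <- golgi_instance_mask(ch, cells)
  expect_setequal(unique(om[om > 0]), c(7L, 8L))
  expect_true(all(om[5:7, 5:7] == 7L))
  expect_true(all(om[12:14, 9:10] == 7L))
  expect_true(all(om[12:14, 11:13] == 8L))
  # constant channel: empty organelle mask
  expect_equal(sum(golgi_instance_mask(matrix(1, 20, 20), cells)), 0)
})

test_that("classical backend segments the synthetic monolayer accurately", {
  g <- generate_monolayer(synthetic_spec(n_cells = 25, width = 250,
                                         height = 250, seed = 7,
                                         confluent = TRUE))
  seg <- segment_cells(g$channels, "classical")
  truth_ids <- sort(unique(g$cell_mask[g$cell_mask > 0]))
  ious <- vapply(truth_ids, function(k) {
    tr <- g$cell_mask == k
    pl <- seg$cell[tr]; pl <- pl[pl > 0]
    if (!length(pl)) return(0)
    kk <- as.integer(names(which.max(table(pl))))
    pr <- seg$cell == kk
    sum(pr & tr) / sum(pr | tr)
  }, numeric(1))
  expect_gte(mean(ious), 0.9)
  expect_equal(length(unique(seg$nucleus[seg$nucleus > 0])), 25)
})

test_that("blank images and unknown backends fail loudly but cleanly", {
  blank <- list(nucleus = matrix(0, 30, 30), junction = matrix(0, 30, 30))
  expect_warning(seg <- segment_cells(blank, "classical"), "zero instances")
  expect_equal(sum(seg$cell), 0)
  ft <- extract_features(blank, seg$cell, seg$nucleus)
  expect_equal(nrow(ft), 0)
  expect_error(segment_cells(blank, "cellpose"), "not available")
  expect_error(validate_label_mask(matrix(c(-1, 0, 1, 2), 2)), "non-negative")
})
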