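test_that("fraction estimation matches hand arithmetic in both modes", {
  expect_equal(estimate_fraction(c(0.1, 0.2, 0.49)), 0)
  expect_equal(estimate_fraction(c(rep(0.9, 3), rep(0.1, 7))), 0.30)
  expect_equal(estimate_fraction(c(0.9, 0.1, 0.2), tissue_fractions = c(1, 1, 0.5),
                                 mode = "area"), 0.40)
  expect_error(estimate_fraction(numeric(0)), "at least one patch")
  expect_error(estimate_fraction(c(0.5), mode = "area"), "tissue_fractions")
})

test_that("fraction estimation is monotone and mode-consistent", {
  pathdistill:::with_seed(10, {
    for (i in 1:25) {
      n <- sample(3:30, 1)
      probs <- runif(n)
      tf <- runif(n, 0.2, 1)
      base <- estimate_fraction(probs, tf, mode = "area")
      j <- sample(n, 1)
      raised <- probs; raised[j] <- min(1, probs[j] + runif(1, 0, 1 - probs[j]))
      expect_gte(estimate_fraction(raised, tf, mode = "area"), base)
      expect_gte(estimate_fraction(raised), estimate_fraction(probs))
      # equal tissue fractions collapse area mode onto count mode
      expect_equal(estimate_fraction(probs, rep(0.7, n), mode = "area"),
                   estimate_fraction(probs))
    }
  })
})

test_that("response calls implement the pCR and MPR definitions", {
  expect_equal(unlist(call_response(0)[c("pcr", "mpr")]),
               c(pcr = TRUE, mpr = TRUE))
  expect_equal(unlist(call_response(0.10)[c("pcr", "mpr")]),
               c(pcr = FALSE, mpr = TRUE))
  expect_equal(unlist(call_response(0.101)[c("pcr", "mpr")]),
               c(pcr = FALSE, mpr = FALSE))
  expect_error(call_response(1.2), "\\[0, 1\\]")
  expect_error(call_response(-0.1), "\\[0, 1\\]")

  calls <- call_response(pathdistill:::with_seed(4, runif(500)))
  expect_true(all(!calls$pcr | calls$mpr))  # pcr implies mpr

  eps <- call_response(0.004, pcr_epsilon = 0.005)
  expect_true(eps$pcr)
})

test_that("slide assessment aggregates per slide with response calls", {
  co <- small_cohort(n_slides = 3, grid = c(3L, 4L), seed = 19, n_labeled = 14L,
                     pcr_prob = 0)
  patches <- cohort_patches(co, with_features = TRUE)
  head <- train_step1(patches[patches$label != "UNLABELED", ],
                      head_config(epochs = 30))
  est <- assess_slides(patches, head)
  expect_equal(nrow(est), 3)
  expect_true(all(est$predicted_fraction >= 0 & est$predicted_fraction <= 1))
  expect_equal(est$predicted_percent, est$predicted_fraction * 100)
  expect_true(all(!est$pcr | est$mpr))
})

test_that("probability grids and heatmaps honor the layout contract", {
  patches <- tibble::tibble(grid_row = c(0L, 0L, 1L), grid_col = c(0L, 1L, 1L),
                            prob = c(0.2, 0.8, 0.5))
  g <- prob_grid(patches)
  expect_equal(dim(g), c(2, 2))
  expect_true(is.na(g[2, 1]))
  expect_equal(g[1, 2], 0.8)

  dir <- withr::local_tempdir()
  out <- render_heatmap(g, file.path(dir, "hm.png"), cell_size = 4)
  img <- png::readPNG(out$png)
  expect_equal(dim(img)[1:2], c(8, 8))
  expect_equal(img[5, 1, 4], 0)  # outside the bed: transparent
  expect_equal(img[1, 1, 4], 1)

  back <- as.matrix(readr::read_csv(out$csv, show_col_types = FALSE))
  dimnames(back) <- NULL
  expect_identical(back, g)
})

test_that("an all-zero grid renders uniformly in the cool end of the colormap", {
  g <- matrix(0, 3, 5)
  dir <- withr::local_tempdir()
  out <- render_heatmap(g, file.path(dir, "cold.png"), cell_size = 2)
  img <- png::readPNG(out$png)
  for (ch in 1:3) expect_equal(length(unique(as.vector(img[, , ch]))), 1)
  # cool end: blue dominates red
  expect_gt(img[1, 1, 3], img[1, 1, 1])
})

test_that("extreme-patch galleries are deterministic with stated tie-breaks", {
  probs <- c(0.9, 0.1, 0.5, 0.5, 0.7)
  patches <- make_prob_patches(probs)
  sel <- top_bottom_patches(patches, k = 1)
  expect_equal(sel$prob[sel$which == "high"], 0.9)
  expect_equal(sel$prob[sel$which == "low"], 0.1)

  tied <- make_prob_patches(rep(0.4, 4))
  sel2 <- top_bottom_patches(tied, k = 2)
  hi <- sel2[sel2$which == "high", ]
  expect_equal(hi$grid_col, c(0L, 1L))  # ties -> ascending grid order

  distinct <- make_prob_patches(seq(0.1, 0.9, length.out = 8))
  sel3 <- top_bottom_patches(distinct, k = 3)
  expect_equal(nrow(dplyr::distinct(sel3, grid_row, grid_col)), 6)

  expect_error(top_bottom_patches(patches, k = 9), "exceeds")
})

test_that("thumbnails are written with the probability in the filename", {
  patches <- make_prob_patches(c(0.91, 0.2, 0.45))
  dir <- withr::local_tempdir()
  sel <- top_bottom_patches(patches, k = 1, out_dir = dir,
                            render = function(row) array(128, c(16, 16, 3)))
  expect_true(all(file.exists(sel$file)))
  expect_match(basename(sel$file[sel$which == "high"]), "p0\\.910_high\\.png")
})

test_that("RGB bin counts conserve mass and localize uniform input", {
  px <- array(128, dim = c(20, 30, 3))
  counts <- rgb_bin_counts(px, n_bins = 32)
  expect_true(all(tapply(counts$count, counts$channel, sum) == 600))
  nonzero <- counts[counts$count > 0, ]
  expect_equal(nrow(nonzero), 3)
  expect_true(all(nonzero$lower <= 128 & 128 < nonzero$upper))

  mask <- matrix(FALSE, 20, 30); mask[1:5, 1:6] <- TRUE
  expect_equal(sum(rgb_bin_counts(px, mask)$count), 3 * 30)
  expect_error(rgb_bin_counts(px, matrix(FALSE, 20, 30)), "empty")
})

test_that("cohort color shifts move the histogram peak accordingly", {
  a <- render_patch("stroma", seed = 50)
  b <- render_patch("stroma", color_shift = c(-60, 0, 0), seed = 50)
  peak_bin <- function(px) {
    counts <- rgb_bin_counts(px, n_bins = 16)
    red <- counts[counts$channel == "R", ]
    red$bin[which.max(red$count)]
  }
  expect_lt(peak_bin(b), peak_bin(a))
})
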