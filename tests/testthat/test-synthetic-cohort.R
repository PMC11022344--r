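test_that("cohort generation is deterministic given the seed", {
  spec <- cohort_spec(n_slides = 5, grid_shape_range = c(3, 5), seed = 21)
  a <- generate_cohort(spec)
  b <- generate_cohort(spec)
  expect_identical(a$slides$true_fraction, b$slides$true_fraction)
  expect_identical(a$slides$class_grid, b$slides$class_grid)
  expect_identical(a$patch_labels, b$patch_labels)
  expect_identical(render_patch("tumor", seed = 7), render_patch("tumor", seed = 7))
})

test_that("pcr_prob = 1 yields only complete responders with zero tumor patches", {
  co <- generate_cohort(cohort_spec(n_slides = 6, grid_shape_range = c(3, 4),
                                    pcr_prob = 1, seed = 2))
  expect_true(all(co$slides$true_fraction == 0))
  expect_true(all(vapply(co$slides$class_grid,
                         function(g) sum(g == "tumor"), numeric(1)) == 0))
})

test_that("realized tumor patch share matches the drawn fraction within one patch", {
  co <- generate_cohort(cohort_spec(n_slides = 20, grid_shape_range = c(4, 9),
                                    pcr_prob = 0.2, seed = 31))
  targets <- pathdistill:::with_seed(stage_seed(31L, "fraction"),
                                     stats::rbeta(20, 1.2, 3))
  is_pcr <- pathdistill:::with_seed(stage_seed(31L, "pcr"), stats::runif(20) < 0.2)
  targets[is_pcr] <- 0
  for (i in 1:20) {
    n <- length(co$slides$class_grid[[i]])
    expect_lte(abs(co$slides$true_fraction[i] - targets[i]), 1 / n)
  }
})

test_that("realized pCR count equals an independent replay of the seeded streams", {
  co <- generate_cohort(cohort_spec(n_slides = 50, pcr_prob = 0.25,
                                    grid_shape_range = c(3, 4), seed = 12))
  # direct RNG replay of the generator's seeded draws: the pCR Bernoulli
  # stream, the Beta fraction stream, and the grid-shape stream (a tiny
  # non-pCR fraction on a small grid also realizes zero tumor patches)
  is_pcr <- pathdistill:::with_seed(stage_seed(12L, "pcr"),
                                    stats::runif(50) < 0.25)
  fr <- pathdistill:::with_seed(stage_seed(12L, "fraction"),
                                stats::rbeta(50, 1.2, 3))
  fr[is_pcr] <- 0
  shp <- pathdistill:::with_seed(stage_seed(12L, "grid"),
                                 matrix(sample(3:4, 100, replace = TRUE), ncol = 2))
  expected_zero <- sum(pathdistill:::round_half_away(fr * shp[, 1] * shp[, 2]) == 0)
  expect_equal(sum(co$slides$true_fraction == 0), expected_zero)
  expect_gte(sum(co$slides$true_fraction == 0), sum(is_pcr))
})

test_that("tumor renders carry more gradient energy than stroma renders", {
  grad_idx <- c(11, 23, 35)  # per-channel gradient-energy means
  energy <- function(class, s) {
    mean(extract_features(render_patch(class, seed = s))[grad_idx])
  }
  e_tumor <- vapply(1:100, function(s) energy("tumor", s), numeric(1))
  e_stroma <- vapply(1:100, function(s) energy("stroma", s + 1000), numeric(1))
  expect_gt(mean(e_tumor), mean(e_stroma))
})

test_that("cohort color shift is additive on the un-clipped signal", {
  base <- render_patch("stroma", seed = 4, clip = FALSE)
  shifted <- render_patch("stroma", color_shift = c(20, 0, 0), seed = 4,
                          clip = FALSE)
  expect_equal(mean(shifted[, , 1]) - mean(base[, , 1]), 20, tolerance = 1e-9)
  expect_equal(shifted[, , 2], base[, , 2])
})

test_that("tumor placement is exchangeable when cluster_strength is 0", {
  # per-seed permutation test on mean nearest-neighbour distance among tumor
  # cells; the rejection rate over 200 seeds should stay near alpha = 0.01
  mean_nn <- function(pos) {
    d <- as.matrix(stats::dist(pos)); diag(d) <- Inf
    mean(apply(d, 1, min))
  }
  rows <- 8L; cols <- 8L
  cells <- as.matrix(expand.grid(r = 1:rows, c = 1:cols))
  pvals <- vapply(1:200, function(s) {
    g <- pathdistill:::with_seed(s, pathdistill:::make_class_grid(
      rows, cols, 0.3, cluster_strength = 0, necrosis_frac = 0.3))
    obs <- mean_nn(cells[g == "tumor", , drop = FALSE])
    k <- sum(g == "tumor")
    null <- pathdistill:::with_seed(s + 5000, vapply(1:99, function(j) {
      mean_nn(cells[sample(nrow(cells), k), , drop = FALSE])
    }, numeric(1)))
    (1 + sum(null <= obs)) / 100  # one-sided: clustering shrinks NN distance
  }, numeric(1))
  expect_lte(mean(pvals <= 0.01), 0.035)
})

test_that("positive cluster_strength produces spatially clustered tumor nests", {
  mean_nn <- function(pos) {
    d <- as.matrix(stats::dist(pos)); diag(d) <- Inf
    mean(apply(d, 1, min))
  }
  cells <- as.matrix(expand.grid(r = 1:12, c = 1:12))
  nn_at <- function(strength) {
    mean(vapply(1:30, function(s) {
      g <- pathdistill:::with_seed(s, pathdistill:::make_class_grid(
        12L, 12L, 0.25, cluster_strength = strength, necrosis_frac = 0.3))
      mean_nn(cells[g == "tumor", , drop = FALSE])
    }, numeric(1)))
  }
  expect_lt(nn_at(2), nn_at(0))
})

test_that("export writes the layout the readers consume, truth kept separate", {
  dir <- withr::local_tempdir()
  co <- small_cohort(n_slides = 3, grid = c(2L, 3L), seed = 8,
                     label_noise_sd = 0.04)
  paths <- export_cohort(co, dir)
  m <- read_manifest(paths$manifest)
  expect_equal(nrow(m), 3)
  expect_true(all(file.exists(file.path(dir, m$image))))
  truth <- readr::read_csv(paths$truth, show_col_types = FALSE)
  expect_equal(truth$true_fraction, co$slides$true_fraction)
  # noisy manifest labels differ from truth whenever the noise draw is nonzero
  expect_false(all(m$label_fraction == truth$true_fraction))
  lab <- read_patch_labels(paths$patch_labels)
  expect_gt(nrow(lab), 0)
  expect_error(export_cohort(co, dir), "refusing to overwrite")
})

test_that("zero label noise makes manifest labels equal the truth exactly", {
  dir <- withr::local_tempdir()
  co <- small_cohort(n_slides = 2, grid = c(2L, 2L), seed = 3,
                     label_noise_sd = 0)
  paths <- export_cohort(co, dir)
  m <- read_manifest(paths$manifest)
  expect_equal(m$label_fraction, co$slides$true_fraction)
})

test_that("cohort patch tables carry human labels only where annotated", {
  co <- small_cohort(n_slides = 3, grid = c(3L, 3L), seed = 13, n_labeled = 6L)
  patches <- cohort_patches(co)
  expect_equal(nrow(patches),
               sum(vapply(co$slides$class_grid, length, numeric(1))))
  lab <- co$patch_labels
  key <- paste(patches$slide_id, patches$grid_row, patches$grid_col)
  lkey <- paste(lab$slide_id, lab$grid_row, lab$grid_col)
  expect_equal(patches$label[match(lkey, key)], lab$label)
  expect_true(all(patches$label[!key %in% lkey] == "UNLABELED"))
  # human POS labels mark exactly the viable-tumor patches in the sample
  expect_equal(lab$label,
               ifelse(patches$class[match(lkey, key)] == "tumor", "POS", "NEG"))
})
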