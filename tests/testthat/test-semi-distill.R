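test_that("step-1 training is deterministic and separates Gaussian clouds", {
  patches <- make_gaussian_clouds(n = 200, d = 8, sep = 4, seed = 42)
  idx <- pathdistill:::with_seed(1, sample(200, 140))
  cfg <- head_config(seed = 9)
  h1 <- train_step1(patches[idx, ], cfg)
  h2 <- train_step1(patches[idx, ], cfg)
  expect_identical(h1$W1, h2$W1)
  expect_identical(h1$W2, h2$W2)

  held <- patches[-idx, ]
  acc <- mean((predict_probs(h1, held) >= 0.5) == (held$label == "POS"))
  expect_gte(acc, 0.95)

  fit <- glmnet::glmnet(patches$features[idx, ],
                        as.integer(patches$label[idx] == "POS"),
                        family = "binomial", alpha = 0, lambda = 1e-2)
  oracle_acc <- mean((as.numeric(stats::predict(fit, held$features,
                                                type = "response")) >= 0.5) ==
                       (held$label == "POS"))
  expect_gte(acc, oracle_acc - 0.03)
})

test_that("training rejects single-class and non-finite input", {
  patches <- make_gaussian_clouds(n = 40)
  only_pos <- patches[patches$label == "POS", ]
  expect_error(train_step1(only_pos), "both classes required")
  bad <- patches
  bad$features[1, 1] <- NA
  expect_error(train_step1(bad), "non-finite")
})

test_that("predicted probability pairs sum to one and are deterministic", {
  patches <- make_gaussian_clouds(n = 80, seed = 7)
  head <- train_step1(patches, head_config(epochs = 20))
  pair <- predict_probs(head, patches, type = "pair")
  expect_equal(rowSums(pair), rep(1, nrow(patches)))
  expect_true(all(pair >= 0 & pair <= 1))
  dup <- patches[c(1, 1), ]
  p <- predict_probs(head, dup)
  expect_identical(p[1], p[2])
  expect_error(predict_probs(head, matrix(0, 2, 5)), "dimension")
})

test_that("tumor patches score higher than stroma on a separable fixture", {
  co <- small_cohort(n_slides = 4, grid = c(4L, 5L), seed = 23, n_labeled = 30L,
                     pcr_prob = 0)
  patches <- cohort_patches(co, with_features = TRUE)
  human <- patches[patches$label != "UNLABELED", ]
  head <- train_step1(human, head_config(epochs = 40))
  probs <- predict_probs(head, patches)
  expect_gt(mean(probs[patches$class == "tumor"]),
            mean(probs[patches$class == "stroma"]))
})

test_that("pseudo-label assignment follows the ranking cutoff and gates", {
  cfg <- distill_config()
  p0 <- assign_pseudo_labels(make_prob_patches(runif(8)), 0, cfg)
  expect_false(any(p0$label == "PSEUDO_POS"))
  expect_equal(attr(p0, "k"), 0L)

  p1 <- assign_pseudo_labels(make_prob_patches(seq(0.85, 0.99, length.out = 6)),
                             1, cfg)
  expect_true(all(p1$label == "PSEUDO_POS"))

  # N = 10, fraction 0.3 -> k = 3; gate 0.8 admits only two of the top three
  probs <- c(0.95, 0.90, 0.70, 0.60, 0.50, 0.40, 0.15, 0.10, 0.05, 0.30)
  p3 <- assign_pseudo_labels(make_prob_patches(probs), 0.3, cfg)
  expect_equal(which(p3$label == "PSEUDO_POS"), c(1L, 2L))
  expect_equal(which(p3$label == "PSEUDO_NEG"), c(7L, 8L, 9L))
  expect_equal(attr(p3, "k"), 3L)

  # ties on probability resolved by ascending (grid_row, grid_col)
  tie <- make_prob_patches(rep(0.9, 4))
  pt <- assign_pseudo_labels(tie, 0.5, cfg)
  expect_equal(pt$label, c("PSEUDO_POS", "PSEUDO_POS", "UNLABELED", "UNLABELED"))

  # half-away-from-zero rounding of k: 0.25 * 2 = 0.5 -> k = 1
  ph <- assign_pseudo_labels(make_prob_patches(c(0.9, 0.85)), 0.25, cfg)
  expect_equal(attr(ph, "k"), 1L)
})

test_that("human labels are never reassigned", {
  probs <- c(0.99, 0.98, 0.97, 0.1, 0.05)
  patches <- make_prob_patches(probs, labels = c("NEG", "UNLABELED", "UNLABELED",
                                                 "POS", "UNLABELED"))
  out <- assign_pseudo_labels(patches, 1, distill_config())
  expect_equal(out$label[1], "NEG")
  expect_equal(out$label[4], "POS")
  expect_equal(out$label[c(2, 3)], c("PSEUDO_POS", "PSEUDO_POS"))
})

test_that("pseudo-label assignment matches exhaustive enumeration on random instances", {
  cfg_pool <- list(distill_config(),
                   distill_config(theta_pos = 0.9, theta_neg = 0.1),
                   distill_config(include_pseudo_negatives = FALSE))
  pathdistill:::with_seed(2024, {
    for (case in 1:500) {
      N <- sample(1:50, 1)
      probs <- round(runif(N), sample(c(1, 2, 6), 1))  # ties likely at 1 digit
      gr <- sample(0:6, N, replace = TRUE)
      gc <- sample(0:6, N, replace = TRUE)
      lab <- sample(c("UNLABELED", "POS", "NEG"), N, replace = TRUE,
                    prob = c(0.8, 0.1, 0.1))
      if (!any(lab == "UNLABELED")) lab[1] <- "UNLABELED"
      frac <- sample(c(0, 1, runif(1)), 1)
      cfg <- cfg_pool[[sample(3, 1)]]
      patches <- tibble::tibble(slide_id = "s", grid_row = gr, grid_col = gc,
                                prob = probs, label = lab)
      got <- assign_pseudo_labels(patches, frac, cfg)
      want <- oracle_pseudo(probs, gr, gc, lab, frac, cfg)
      expect_identical(got$label, want)
      n_unl <- sum(lab == "UNLABELED")
      expect_lte(sum(got$label == "PSEUDO_POS"),
                 pathdistill:::round_half_away(frac * n_unl))
      expect_identical(got$label[lab != "UNLABELED"], lab[lab != "UNLABELED"])
    }
  })
})

test_that("zero distillation iterations reproduce step-1 training exactly", {
  co <- small_cohort(n_slides = 4, grid = c(3L, 4L), seed = 41, n_labeled = 20L,
                     pcr_prob = 0)
  patches <- cohort_patches(co, with_features = TRUE)
  tr <- patches[patches$slide_id %in% co$slides$slide_id[co$slides$split == "train"], ]
  slides <- co$slides[co$slides$split == "train", ]
  hc <- head_config(epochs = 20, seed = 3)
  fit <- distill(tr, slides, hc, distill_config(n_iterations = 0))
  direct <- train_step1(tr[tr$label != "UNLABELED", ], hc)
  expect_identical(fit$head$W1, direct$W1)
  expect_identical(fit$head$b2, direct$b2)
  expect_equal(nrow(fit$log), 1)
})

test_that("distillation does not hurt slide-percentage recovery on noiseless labels", {
  co <- generate_cohort(cohort_spec(
    n_slides = 20, grid_shape_range = c(6L, 9L), pcr_prob = 0.2,
    label_noise_sd = 0, n_labeled_patches = 24L, seed = 77))
  patches <- cohort_patches(co, with_features = TRUE)
  train_ids <- co$slides$slide_id[co$slides$split == "train"]
  test_ids <- co$slides$slide_id[co$slides$split == "test"]
  tr <- patches[patches$slide_id %in% train_ids, ]
  te <- patches[patches$slide_id %in% test_ids, ]
  fit <- distill(tr, co$slides[co$slides$split == "train", ],
                 head_config(seed = 2), distill_config())
  truth <- co$slides$true_fraction[match(test_ids, co$slides$slide_id)]
  mae_of <- function(head) {
    est <- assess_slides(te, head)
    unname(mae_mse(truth, est$predicted_fraction[match(test_ids, est$slide_id)])["mae"])
  }
  expect_lte(mae_of(fit$head), mae_of(fit$head0) + 1e-12)
  expect_gt(fit$log$n_pseudo_pos[nrow(fit$log)], 0)
})

test_that("slides labeled 0 percent drive their patch probabilities below 0.5", {
  # human annotation comes from separable clouds; every slide in the run is a
  # complete responder, so its unlabeled (non-tumor) patches get pseudo-negatives
  anno <- make_gaussian_clouds(n = 60, d = 6, sep = 5, seed = 15)
  pathdistill:::with_seed(8, {
    neg_like <- matrix(stats::rnorm(40 * 6), ncol = 6) - 2.5
    unl <- tibble::tibble(
      slide_id = rep(c("z1", "z2"), each = 20),
      grid_row = rep(0:19, 2), grid_col = 0L, tissue_fraction = 1,
      label = "UNLABELED", features = neg_like
    )
  })
  anno$slide_id <- "z1"
  patches <- dplyr::bind_rows(anno, unl)
  slides <- tibble::tibble(slide_id = c("z1", "z2"), label_fraction = 0)
  fit <- distill(patches, slides, head_config(epochs = 30, seed = 5),
                 distill_config())
  probs <- predict_probs(fit$head, unl)
  expect_true(all(probs < 0.5))
})

test_that("an iteration with no pseudo labels falls back to step-1 with a warning", {
  patches <- make_gaussian_clouds(n = 30, sep = 4, seed = 3)
  unl <- make_gaussian_clouds(n = 10, sep = 4, seed = 4)
  unl$label <- "UNLABELED"
  unl$grid_col <- 1L
  all_p <- dplyr::bind_rows(patches, unl)
  slides <- tibble::tibble(slide_id = "fixture", label_fraction = 0)
  # fraction 0 forbids pseudo-positives; theta_neg 0 makes negatives unreachable
  expect_warning(
    fit <- distill(all_p, slides, head_config(epochs = 10),
                   distill_config(n_iterations = 1, theta_neg = 0)),
    "no pseudo labels"
  )
  expect_true(fit$log$fallback[2])
})

test_that("distill configs enforce the gate ordering", {
  expect_error(distill_config(theta_neg = 0.6), "theta_neg < 0.5 required")
  expect_error(distill_config(theta_pos = 0.4), "theta_pos")
  expect_silent(distill_config(theta_pos = 1, theta_neg = 0))
})

test_that("classifier checkpoints round trip through disk", {
  patches <- make_gaussian_clouds(n = 60, seed = 10)
  head <- train_step1(patches, head_config(epochs = 15, seed = 44))
  p <- withr::local_tempfile(fileext = ".json")
  write_classifier(head, p)
  back <- read_classifier(p)
  expect_equal(back$W1, head$W1)
  expect_equal(back$feature_mean, head$feature_mean)
  expect_equal(back$config$seed, head$config$seed)
  expect_equal(predict_probs(back, patches), predict_probs(head, patches))
})
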