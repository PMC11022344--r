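# Shared fixtures, all generated in code at test time.

# Two Gaussian feature clouds, well separated unless `sep` is small.
make_gaussian_clouds <- function(n = 200, d = 8, sep = 4, seed = 42) {
  pathdistill:::with_seed(seed, {
    n_pos <- n %/% 2
    X <- rbind(
      matrix(stats::rnorm(n_pos * d), ncol = d) + sep / 2,
      matrix(stats::rnorm((n - n_pos) * d), ncol = d) - sep / 2
    )
    tibble::tibble(
      slide_id = "fixture",
      grid_row = seq_len(n) - 1L,
      grid_col = 0L,
      tissue_fraction = 1,
      label = c(rep("POS", n_pos), rep("NEG", n - n_pos)),
      features = X
    )
  })
}

# A small patch tibble with explicit probabilities for pseudo-label tests.
make_prob_patches <- function(probs, labels = NULL) {
  n <- length(probs)
  tibble::tibble(
    slide_id = "s1",
    grid_row = as.integer((seq_len(n) - 1) %/% 5),
    grid_col = as.integer((seq_len(n) - 1) %% 5),
    prob = probs,
    label = labels %||% rep("UNLABELED", n)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Brute-force pseudo-label oracle: full enumeration of ranking and gates.
oracle_pseudo <- function(probs, grid_row, grid_col, label, fraction, cfg) {
  out <- label
  elig <- which(label == "UNLABELED")
  N <- length(elig)
  k <- as.integer(sign(fraction * N) * floor(abs(fraction * N) + 0.5))
  key <- order(-probs[elig], grid_row[elig], grid_col[elig])
  ranked <- elig[key]
  for (r in seq_along(ranked)) {
    i <- ranked[r]
    if (r <= k && probs[i] >= cfg$theta_pos) out[i] <- "PSEUDO_POS"
    if (r > k && cfg$include_pseudo_negatives && probs[i] <= cfg$theta_neg) {
      out[i] <- "PSEUDO_NEG"
    }
  }
  out
}

small_cohort <- function(n_slides = 4, grid = c(3L, 4L), seed = 5,
                         label_noise_sd = 0.03, pcr_prob = 0.25,
                         n_labeled = 12L, split_frac = c(train = 0.75, val = 0, test = 0.25)) {
  generate_cohort(cohort_spec(
    n_slides = n_slides, grid_shape_range = grid, pcr_prob = pcr_prob,
    label_noise_sd = label_noise_sd, n_labeled_patches = n_labeled,
    split_frac = split_frac, seed = seed
  ))
}
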