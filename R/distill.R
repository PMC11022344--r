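#' Distillation configuration
#'
#' Controls the percentage-guided pseudo-labeling loop. Pseudo-labels combine
#' two gates: a ranking cutoff derived from the pathologist's slide-level
#' percentage (the top `k = round(fraction * N)` patches by predicted tumor
#' probability are pseudo-positive candidates) and confidence thresholds
#' (`theta_pos` for pseudo-positives, `theta_neg` for pseudo-negatives below
#' the cutoff). Both gates must pass; everything else stays unlabeled.
#'
#' @param n_iterations Number of pseudo-label/retrain rounds after the initial
#'   supervised step (0 reproduces step-1 training exactly).
#' @param theta_pos Confidence gate for pseudo-positives, in (0.5, 1].
#' @param theta_neg Confidence gate for pseudo-negatives, in [0, 0.5).
#' @param include_pseudo_negatives Assign pseudo-negatives at all.
#' @return Object of class `distill_config`.
#' @export
distill_config <- function(n_iterations = 3L, theta_pos = 0.8, theta_neg = 0.2,
                           include_pseudo_negatives = TRUE) {
  if (!(theta_pos > 0.5 && theta_pos <= 1)) {
    stop("theta_pos must lie in (0.5, 1]", call. = FALSE)
  }
  if (!(theta_neg >= 0 && theta_neg < 0.5)) {
    stop("theta_neg < 0.5 required (and >= 0)", call. = FALSE)
  }
  stopifnot(n_iterations >= 0)
  structure(list(n_iterations = as.integer(n_iterations), theta_pos = theta_pos,
                 theta_neg = theta_neg,
                 include_pseudo_negatives = isTRUE(include_pseudo_negatives)),
            class = "distill_config")
}

#' Assign percentage-guided pseudo-labels for one slide
#'
#' Unlabeled tumor-bed patches are ranked by predicted tumor probability
#' (descending, ties broken by ascending `(grid_row, grid_col)`). With
#' `k = round(label_fraction * N)` (half away from zero, N = number of
#' unlabeled patches): ranks 1..k with probability >= `theta_pos` become
#' PSEUDO_POS; ranks > k with probability <= `theta_neg` become PSEUDO_NEG
#' (when enabled); all other patches stay UNLABELED. Human POS/NEG labels are
#' never reassigned.
#'
#' @param patches Tibble with columns `prob`, `grid_row`, `grid_col`, `label`.
#'   Rows whose `label` is not `"UNLABELED"` pass through untouched.
#' @param label_fraction The slide's pathologist-derived viable-tumor fraction
#'   in [0, 1].
#' @param cfg A [distill_config()].
#' @return `patches` with updated `label`; attribute `k` holds the ranking
#'   cutoff. The pseudo-positive count never exceeds `k`.
#' @export
assign_pseudo_labels <- function(patches, label_fraction, cfg = distill_config()) {
  assert_fraction(label_fraction)
  stopifnot(all(c("prob", "grid_row", "grid_col", "label") %in% names(patches)))
  elig <- which(patches$label == "UNLABELED")
  N <- length(elig)
  if (N < 1) stop("at least one unlabeled patch required", call. = FALSE)
  k <- as.integer(round_half_away(label_fraction * N))
  ord <- elig[order(-patches$prob[elig], patches$grid_row[elig],
                    patches$grid_col[elig])]
  new_label <- patches$label
  if (k > 0) {
    top <- ord[seq_len(k)]
    new_label[top[patches$prob[top] >= cfg$theta_pos]] <- "PSEUDO_POS"
  }
  if (cfg$include_pseudo_negatives && k < N) {
    rest <- ord[(k + 1):N]
    new_label[rest[patches$prob[rest] <= cfg$theta_neg]] <- "PSEUDO_NEG"
  }
  out <- patches
  out$label <- new_label
  attr(out, "k") <- k
  out
}

#' Iterative semi-supervised distillation
#'
#' Implements the two-step training loop. Iteration 0 trains the head on the
#' human patch labels alone ([train_step1()]). Each subsequent iteration (i)
#' scores every still-unlabeled tumor-bed patch of every training slide with
#' the current head, (ii) assigns pseudo-labels per slide from the noisy
#' slide-level percentage via [assign_pseudo_labels()] (the full unlabeled
#' pool is re-ranked each iteration), and (iii) retrains the head from scratch
#' with a fresh seeded initialization on the union of human and pseudo labels.
#' The encoder is frozen throughout and human labels are immutable. If an
#' iteration yields no pseudo-labels at all, it falls back to step-1
#' training with a warning (human labels always provide both classes, so a
#' single-class pseudo batch is still usable).
#'
#' @param patches Patch tibble for all training slides: `slide_id`,
#'   `grid_row`, `grid_col`, `features` (matrix column), `label` (POS/NEG for
#'   human-annotated patches, UNLABELED otherwise).
#' @param slides Tibble with `slide_id` and `label_fraction`.
#' @param head_cfg A [head_config()]; iteration i retrains with seed
#'   `stage_seed(head_cfg$seed, paste0("iter", i))`.
#' @param cfg A [distill_config()].
#' @param val Optional list with `patches` and `slides` (with a
#'   `true_fraction` or `label_fraction` column) used to log per-iteration
#'   validation R-squared and MAE.
#' @return Object of class `distill_fit`: the final `head`, the step-1 head
#'   (`head0`), a per-iteration `log` tibble, and the configs.
#' @export
distill <- function(patches, slides, head_cfg = head_config(),
                    cfg = distill_config(), val = NULL) {
  stopifnot(all(c("slide_id", "features", "label") %in% names(patches)))
  human <- patches$label %in% c("POS", "NEG")
  head0 <- train_step1(patches[human, ], head_cfg)

  val_metrics <- function(head) {
    if (is.null(val)) return(c(val_r2 = NA_real_, val_mae = NA_real_))
    est <- assess_slides(val$patches, head)
    ref <- val$slides
    yref <- ref$true_fraction %||% ref$label_fraction
    m <- est$predicted_fraction[match(ref$slide_id, est$slide_id)]
    c(val_r2 = r2_score(yref, m), val_mae = unname(mae_mse(yref, m)["mae"]))
  }

  vm0 <- val_metrics(head0)
  log <- tibble::tibble(iteration = 0L, n_human = sum(human),
                        n_pseudo_pos = 0L, n_pseudo_neg = 0L,
                        n_unlabeled = sum(!human),
                        fallback = FALSE,
                        val_r2 = unname(vm0["val_r2"]),
                        val_mae = unname(vm0["val_mae"]))
  head <- head0
  if (cfg$n_iterations > 0) {
    frac <- slides$label_fraction[match(patches$slide_id, slides$slide_id)]
    if (anyNA(frac)) stop("patches reference slides missing from `slides`",
                          call. = FALSE)
    for (it in seq_len(cfg$n_iterations)) {
      work <- patches
      work$prob <- predict_probs(head, patches)
      lab <- work$label
      for (sid in unique(work$slide_id)) {
        idx <- which(work$slide_id == sid)
        if (!any(work$label[idx] == "UNLABELED")) next  # fully annotated slide
        res <- assign_pseudo_labels(work[idx, ], frac[idx[1]], cfg)
        lab[idx] <- res$label
      }
      n_pp <- sum(lab == "PSEUDO_POS"); n_pn <- sum(lab == "PSEUDO_NEG")
      stopifnot(all(lab[human] == patches$label[human]))  # human labels immutable
      fallback <- (n_pp == 0 && n_pn == 0)
      it_cfg <- head_cfg
      it_cfg$seed <- stage_seed(head_cfg$seed, paste0("iter", it))
      if (fallback) {
        warning(sprintf("iteration %d produced no pseudo labels; retraining on human labels only", it),
                call. = FALSE)
        head <- train_step1(patches[human, ], it_cfg)
      } else {
        keep <- lab != "UNLABELED"
        train_set <- patches[keep, ]
        train_set$label <- lab[keep]
        head <- train_step1(train_set, it_cfg)
      }
      vm <- val_metrics(head)
      log <- dplyr::bind_rows(log, tibble::tibble(
        iteration = it, n_human = sum(human),
        n_pseudo_pos = n_pp, n_pseudo_neg = n_pn,
        n_unlabeled = sum(lab == "UNLABELED"),
        fallback = fallback,
        val_r2 = unname(vm["val_r2"]),
        val_mae = unname(vm["val_mae"])
      ))
    }
  }
  structure(list(head = head, head0 = head0, log = log,
                 head_cfg = head_cfg, cfg = cfg),
            class = "distill_fit")
}

#' @export
print.distill_fit <- function(x, ...) {
  cat(sprintf("<distill_fit> %d iteration(s), theta_pos=%.2f theta_neg=%.2f\n",
              x$cfg$n_iterations, x$cfg$theta_pos, x$cfg$theta_neg))
  print(x$log)
  invisible(x)
}

#' Per-iteration distillation log
#'
#' @param x A `distill_fit`.
#' @param ... Unused.
#' @return Tibble with one row per iteration: pseudo-label counts, fallback
#'   flag, and validation metrics when a validation set was supplied.
#' @export
tidy.distill_fit <- function(x, ...) x$log

#' One-row summary of a distillation run
#'
#' @param x A `distill_fit`.
#' @param ... Unused.
#' @export
glance.distill_fit <- function(x, ...) {
  last <- x$log[nrow(x$log), ]
  tibble::tibble(n_iterations = x$cfg$n_iterations,
                 n_human = last$n_human,
                 n_pseudo_pos = last$n_pseudo_pos,
                 n_pseudo_neg = last$n_pseudo_neg,
                 val_r2 = last$val_r2, val_mae = last$val_mae)
}
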