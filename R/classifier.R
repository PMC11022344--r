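#' Training configuration for the classifier head
#'
#' The trainable model is deliberately small: a two-layer fully connected head
#' (D -> hidden -> 2, ReLU between, softmax output) on top of the frozen
#' encoder. It is fit by mini-batch gradient descent (Adam) on class-weighted
#' cross-entropy; inverse-frequency class weights guard against the severe
#' imbalance of near-pCR slides, where positive patches are rare. Training is
#' fully deterministic given `seed` (initialization and batch shuffling).
#'
#' @param hidden Hidden layer width H.
#' @param lr Adam learning rate.
#' @param epochs Number of passes over the training set.
#' @param batch_size Mini-batch size.
#' @param weight_decay L2 penalty on weights.
#' @param seed Integer seed for initialization and shuffling.
#' @return Object of class `head_config`.
#' @export
head_config <- function(hidden = 16L, lr = 0.01, epochs = 60L, batch_size = 64L,
                        weight_decay = 1e-4, seed = 1L) {
  stopifnot(hidden >= 1, lr > 0, epochs >= 1, batch_size >= 1, weight_decay >= 0)
  structure(list(hidden = as.integer(hidden), lr = lr, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), weight_decay = weight_decay,
                 seed = as.integer(seed)),
            class = "head_config")
}

# Features from a patch tibble (matrix column `features`) or a bare matrix.
feature_matrix <- function(x) {
  X <- if (is.matrix(x)) x else {
    if (!"features" %in% names(x)) stop("patches need a `features` column", call. = FALSE)
    as.matrix(x$features)
  }
  if (!all(is.finite(X))) stop("non-finite feature values", call. = FALSE)
  X
}

#' Step-1 supervised training on human-labeled patches
#'
#' Fits the two-layer head from scratch on pathologist patch labels (POS =
#' viable tumor present, NEG = none visible). Features are standardized with
#' training-set statistics stored in the fitted object.
#'
#' @param patches Tibble with a `features` matrix column and a `label` column
#'   containing POS/NEG (pseudo states must be mapped before calling), or a
#'   feature matrix together with `labels`.
#' @param config A [head_config()].
#' @param labels Optional POS/NEG character vector when `patches` is a bare
#'   matrix.
#' @return Object of class `patch_classifier`.
#' @export
train_step1 <- function(patches, config = head_config(), labels = NULL) {
  X <- feature_matrix(patches)
  y <- labels %||% patches$label
  y <- as.character(y)
  y[y == "PSEUDO_POS"] <- "POS"
  y[y == "PSEUDO_NEG"] <- "NEG"
  if (!all(y %in% c("POS", "NEG"))) stop("labels must be POS/NEG", call. = FALSE)
  if (length(unique(y)) < 2) stop("both classes required", call. = FALSE)
  stopifnot(nrow(X) == length(y))
  y01 <- as.integer(y == "POS")

  mu <- colMeans(X)
  sdv <- apply(X, 2, stats::sd)
  sdv[sdv < 1e-12] <- 1
  Xs <- sweep(sweep(X, 2, mu), 2, sdv, "/")

  n <- nrow(Xs); d <- ncol(Xs); H <- config$hidden
  w_class <- n / (2 * c(sum(y01 == 0), sum(y01 == 1)))  # inverse frequency
  w <- w_class[y01 + 1]

  fit <- with_seed(config$seed, {
    W1 <- matrix(stats::rnorm(d * H, 0, sqrt(2 / d)), d, H)
    b1 <- numeric(H)
    W2 <- matrix(stats::rnorm(H * 2, 0, sqrt(2 / H)), H, 2)
    b2 <- numeric(2)
    params <- list(W1 = W1, b1 = b1, W2 = W2, b2 = b2)
    m <- lapply(params, function(p) p * 0)
    v <- lapply(params, function(p) p * 0)
    beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8; t_step <- 0
    loss <- NA_real_
    for (ep in seq_len(config$epochs)) {
      ord <- sample.int(n)
      for (start in seq(1, n, by = config$batch_size)) {
        idx <- ord[start:min(start + config$batch_size - 1, n)]
        Xb <- Xs[idx, , drop = FALSE]; yb <- y01[idx]; wb <- w[idx]
        A1 <- sweep(Xb %*% params$W1, 2, params$b1, "+")
        Z1 <- pmax(A1, 0)
        A2 <- sweep(Z1 %*% params$W2, 2, params$b2, "+")
        A2 <- A2 - apply(A2, 1, max)
        P <- exp(A2); P <- P / rowSums(P)
        loss <- -mean(wb * log(pmax(P[cbind(seq_along(yb), yb + 1)], 1e-12)))
        G2 <- P
        G2[cbind(seq_along(yb), yb + 1)] <- G2[cbind(seq_along(yb), yb + 1)] - 1
        G2 <- G2 * wb / length(yb)
        g <- list(
          W1 = NULL, b1 = NULL,
          W2 = crossprod(Z1, G2) + config$weight_decay * params$W2,
          b2 = colSums(G2)
        )
        G1 <- (G2 %*% t(params$W2)) * (A1 > 0)
        g$W1 <- crossprod(Xb, G1) + config$weight_decay * params$W1
        g$b1 <- colSums(G1)
        t_step <- t_step + 1
        for (k in names(params)) {
          m[[k]] <- beta1 * m[[k]] + (1 - beta1) * g[[k]]
          v[[k]] <- beta2 * v[[k]] + (1 - beta2) * g[[k]]^2
          mhat <- m[[k]] / (1 - beta1^t_step)
          vhat <- v[[k]] / (1 - beta2^t_step)
          params[[k]] <- params[[k]] - config$lr * mhat / (sqrt(vhat) + eps)
        }
      }
    }
    list(params = params, final_loss = loss)
  })

  structure(list(
    W1 = fit$params$W1, b1 = fit$params$b1,
    W2 = fit$params$W2, b2 = fit$params$b2,
    feature_mean = mu, feature_sd = sdv,
    dimension = d, config = config,
    n_train = n, class_counts = c(NEG = sum(y01 == 0), POS = sum(y01 == 1)),
    final_loss = fit$final_loss
  ), class = "patch_classifier")
}

head_forward <- function(head, X) {
  if (ncol(X) != head$dimension) {
    stop(sprintf("feature dimension %d does not match model dimension %d",
                 ncol(X), head$dimension), call. = FALSE)
  }
  Xs <- sweep(sweep(X, 2, head$feature_mean), 2, head$feature_sd, "/")
  Z1 <- pmax(sweep(Xs %*% head$W1, 2, head$b1, "+"), 0)
  A2 <- sweep(Z1 %*% head$W2, 2, head$b2, "+")
  A2 <- A2 - apply(A2, 1, max)
  P <- exp(A2)
  P / rowSums(P)
}

#' Predict per-patch viable-tumor probabilities
#'
#' @param head A fitted `patch_classifier`.
#' @param patches Patch tibble with a `features` matrix column, or a feature
#'   matrix.
#' @param type `"tumor"` (default) returns the tumor-class probability
#'   vector; `"pair"` returns the n x 2 (NEG, POS) probability matrix, rows
#'   summing to 1.
#' @return Numeric vector in [0, 1], or a matrix for `type = "pair"`;
#'   deterministic.
#' @export
predict_probs <- function(head, patches, type = c("tumor", "pair")) {
  type <- match.arg(type)
  P <- head_forward(head, feature_matrix(patches))
  if (type == "pair") P else P[, 2]
}

#' @export
print.patch_classifier <- function(x, ...) {
  cat(sprintf("<patch_classifier> D=%d -> H=%d -> 2 (frozen encoder upstream)\n",
              x$dimension, x$config$hidden))
  cat(sprintf("  trained on %d patches (NEG %d / POS %d), %d epochs, seed %d\n",
              x$n_train, x$class_counts["NEG"], x$class_counts["POS"],
              x$config$epochs, x$config$seed))
  invisible(x)
}

#' Tidy a fitted classifier head
#'
#' @param x A `patch_classifier`.
#' @param ... Unused.
#' @return A tibble with one row per weight: `layer`, `from`, `to`,
#'   `estimate`.
#' @export
tidy.patch_classifier <- function(x, ...) {
  lay <- function(W, b, name) {
    dplyr::bind_rows(
      tibble::tibble(layer = name,
                     from = rep(seq_len(nrow(W)), ncol(W)),
                     to = rep(seq_len(ncol(W)), each = nrow(W)),
                     estimate = as.vector(W)),
      tibble::tibble(layer = paste0(name, "_bias"), from = 0L,
                     to = seq_along(b), estimate = b)
    )
  }
  dplyr::bind_rows(lay(x$W1, x$b1, "hidden"), lay(x$W2, x$b2, "output"))
}

#' Glance at a fitted classifier head
#'
#' @param x A `patch_classifier`.
#' @param ... Unused.
#' @return One-row tibble with model size and training summary.
#' @export
glance.patch_classifier <- function(x, ...) {
  tibble::tibble(
    dimension = x$dimension, hidden = x$config$hidden,
    n_train = x$n_train, n_pos = unname(x$class_counts["POS"]),
    n_neg = unname(x$class_counts["NEG"]),
    epochs = x$config$epochs, final_loss = x$final_loss,
    seed = x$config$seed
  )
}

#' Save / load a classifier head
#'
#' Checkpoints are single JSON files embedding the weights, the feature
#' standardization, and the full training config including the seed.
#'
#' @param head A `patch_classifier`.
#' @param path File path.
#' @return `path` (write) or the restored `patch_classifier` (read).
#' @export
write_classifier <- function(head, path) {
  obj <- list(
    W1 = head$W1, b1 = head$b1, W2 = head$W2, b2 = head$b2,
    feature_mean = head$feature_mean, feature_sd = head$feature_sd,
    dimension = head$dimension, config = unclass(head$config),
    n_train = head$n_train, class_counts = as.list(head$class_counts),
    final_loss = head$final_loss
  )
  jsonlite::write_json(obj, path, digits = NA, matrix = "rowmajor")
  invisible(path)
}

#' @rdname write_classifier
#' @export
read_classifier <- function(path) {
  obj <- jsonlite::fromJSON(path)
  structure(list(
    W1 = as.matrix(obj$W1),
    b1 = as.numeric(obj$b1),
    W2 = as.matrix(obj$W2),
    b2 = as.numeric(obj$b2),
    feature_mean = as.numeric(obj$feature_mean),
    feature_sd = as.numeric(obj$feature_sd),
    dimension = as.integer(obj$dimension),
    config = do.call(head_config, obj$config),
    n_train = as.integer(obj$n_train),
    class_counts = c(NEG = obj$class_counts$NEG, POS = obj$class_counts$POS),
    final_loss = as.numeric(obj$final_loss)
  ), class = "patch_classifier")
}
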