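# Internal helpers shared across modules.

clip01 <- function(x) pmin(pmax(x, 0), 1)

# Round half away from zero (round() in R rounds half to even).
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Derive a stage seed from a global seed
#'
#' Every source of randomness in the pipeline draws from a stage seed computed
#' deterministically from one global seed and a stage name, so whole runs are
#' reproducible from a single integer.
#'
#' @param seed Integer global seed.
#' @param stage Character stage name (e.g. `"synth"`, `"iter2"`).
#' @return A single integer seed, strictly below 2^31.
#' @export
stage_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stage))
  h <- 0
  for (k in utf8ToInt(paste(stage, collapse = ""))) {
    h <- (h * 31 + k) %% 1000003
  }
  as.integer((abs(as.numeric(seed)) + h * 2011 + 17) %% 2147483629)
}

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = genv)
    } else if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
      rm(".Random.seed", envir = genv)
    }
  })
  set.seed(seed)
  force(expr)
}

# Separable Gaussian smoothing of a matrix with replicate edge padding.
# sigma <= 0 returns the input unchanged.
smooth_field <- function(mat, sigma) {
  if (sigma <= 0) return(mat)
  r <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(seq(-r, r), sd = sigma)
  k <- k / sum(k)
  pad_conv <- function(v) {
    n <- length(v)
    vp <- c(rep(v[1], r), v, rep(v[n], r))
    stats::filter(vp, k, sides = 2)[(r + 1):(r + n)]
  }
  m <- apply(mat, 2, pad_conv)
  t(apply(t(m), 2, pad_conv))
}

assert_fraction <- function(x, what = deparse(substitute(x))) {
  if (!is.numeric(x) || anyNA(x) || any(x < 0 | x > 1)) {
    stop(sprintf("`%s` must be in [0, 1]", what), call. = FALSE)
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
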