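#' Specify a synthetic cohort
#'
#' The synthetic cohort generator produces procedural slides with known ground
#' truth so the whole pipeline (tiling, training, distillation, assessment,
#' evaluation) can be validated end to end without real slide scans. Each
#' slide is a tumor bed tiled into a grid of 256x256 patches of three tissue
#' appearances (viable tumor, stroma, necrosis); the tumor bed is their union,
#' and the residual viable tumor fraction is the tumor share of it. A point
#' mass at zero models pathological complete responses. Slide-level labels are
#' the true fraction plus clipped Gaussian noise, mimicking pathologist
#' percentage-estimate scatter. A per-cohort additive RGB shift emulates
#' scanner color differences.
#'
#' @param n_slides Number of slides.
#' @param grid_shape_range Inclusive `c(min, max)` for grid rows and columns,
#'   drawn independently per slide.
#' @param pcr_prob Probability a slide's true fraction is exactly 0 (a pCR).
#' @param fraction_shape1,fraction_shape2 Beta parameters for non-pCR true
#'   fractions.
#' @param cluster_strength Gaussian smoothing sigma (in patch units) of the
#'   random field whose upper quantile becomes tumor; 0 gives spatially
#'   exchangeable tumor placement, larger values give contiguous tumor nests.
#' @param necrosis_frac Fraction of non-tumor patches rendered as necrosis.
#' @param label_noise_sd Standard deviation, on the fraction scale, of the
#'   additive noise on the pathologist slide label.
#' @param color_shift Length-3 additive RGB offset (0-255 scale) applied to
#'   every rendered pixel of the cohort.
#' @param cohort Cohort tag.
#' @param split_frac Named fractions for train/val/test; slides are assigned
#'   in blocks (first train, then val, then test).
#' @param n_labeled_patches Number of patches sampled from training slides and
#'   exported with human-style POS/NEG labels (tumor -> POS, else NEG),
#'   emulating sparse pathologist patch annotation.
#' @param seed Integer seed; all generation is deterministic given it.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_slides = 50L,
                        grid_shape_range = c(10L, 20L),
                        pcr_prob = 0.25,
                        fraction_shape1 = 1.2,
                        fraction_shape2 = 3,
                        cluster_strength = 2,
                        necrosis_frac = 0.3,
                        label_noise_sd = 0.05,
                        color_shift = c(0, 0, 0),
                        cohort = "C1",
                        split_frac = c(train = 0.8, val = 0, test = 0.2),
                        n_labeled_patches = 120L,
                        seed = 1L) {
  stopifnot(n_slides >= 1, length(grid_shape_range) == 2,
            grid_shape_range[1] >= 1, grid_shape_range[2] >= grid_shape_range[1],
            fraction_shape1 > 0, fraction_shape2 > 0,
            cluster_strength >= 0, label_noise_sd >= 0,
            length(color_shift) == 3, n_labeled_patches >= 0,
            necrosis_frac >= 0, necrosis_frac <= 1)
  assert_fraction(pcr_prob)
  if (abs(sum(split_frac) - 1) > 1e-9) stop("split_frac must sum to 1", call. = FALSE)
  structure(list(
    n_slides = as.integer(n_slides),
    grid_shape_range = as.integer(grid_shape_range),
    pcr_prob = pcr_prob,
    fraction_shape1 = fraction_shape1,
    fraction_shape2 = fraction_shape2,
    cluster_strength = cluster_strength,
    necrosis_frac = necrosis_frac,
    label_noise_sd = label_noise_sd,
    color_shift = as.numeric(color_shift),
    cohort = cohort,
    split_frac = split_frac,
    n_labeled_patches = as.integer(n_labeled_patches),
    seed = as.integer(seed)
  ), class = "cohort_spec")
}

patch_render_seed <- function(slide_seed, grid_row, grid_col) {
  stage_seed(slide_seed, sprintf("patch-%d-%d", grid_row, grid_col))
}

#' Generate a synthetic cohort
#'
#' Slide patch-class grids come from thresholding a Gaussian-smoothed random
#' field at the quantile matching the target tumor fraction, so the realized
#' tumor patch count is exactly `round(fraction * n_patches)` (within one
#' patch of the target) and tumor patches form contiguous nests. A second
#' smoothed field places necrosis among the non-tumor patches. Necrosis counts
#' toward the tumor bed but never toward viable tumor.
#'
#' @param spec A [cohort_spec()].
#' @return An object of class `synthetic_cohort`: a list with
#'   `slides` (a tibble with one row per slide, including `true_fraction` and
#'   a `class_grid` list-column of character matrices), `patch_labels`
#'   (human-style POS/NEG labels for a random subset of training patches), and
#'   `spec`.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- spec$n_slides
  is_pcr <- with_seed(stage_seed(spec$seed, "pcr"), stats::runif(n) < spec$pcr_prob)
  fracs <- with_seed(stage_seed(spec$seed, "fraction"),
                     stats::rbeta(n, spec$fraction_shape1, spec$fraction_shape2))
  fracs[is_pcr] <- 0
  noise <- with_seed(stage_seed(spec$seed, "labelnoise"),
                     stats::rnorm(n, 0, spec$label_noise_sd))
  shapes <- with_seed(stage_seed(spec$seed, "grid"), {
    lo <- spec$grid_shape_range[1]; hi <- spec$grid_shape_range[2]
    matrix(sample(seq(lo, hi), 2 * n, replace = TRUE), ncol = 2)
  })

  n_train <- round_half_away(n * spec$split_frac[["train"]])
  n_val <- round_half_away(n * spec$split_frac[["val"]])
  split <- c(rep("train", n_train), rep("val", n_val),
             rep("test", n - n_train - n_val))

  slide_seed <- vapply(seq_len(n),
                       function(i) stage_seed(spec$seed, sprintf("slide-%d", i)),
                       integer(1))

  class_grid <- vector("list", n)
  true_fraction <- numeric(n)
  for (i in seq_len(n)) {
    g <- with_seed(slide_seed[i],
                   make_class_grid(shapes[i, 1], shapes[i, 2], fracs[i],
                                   spec$cluster_strength, spec$necrosis_frac))
    class_grid[[i]] <- g
    true_fraction[i] <- mean(g == "tumor")
    if (abs(true_fraction[i] - fracs[i]) > 1 / length(g)) {
      stop(sprintf("grid too small to realize fraction %.3f for slide %d",
                   fracs[i], i), call. = FALSE)
    }
  }

  slides <- tibble::tibble(
    slide_id = sprintf("%s_s%03d", spec$cohort, seq_len(n)),
    label_fraction = clip01(true_fraction + noise),
    cohort = spec$cohort,
    split = split,
    magnification = "20x",
    true_fraction = true_fraction,
    grid_rows = shapes[, 1],
    grid_cols = shapes[, 2],
    class_grid = class_grid,
    slide_seed = slide_seed
  )

  patch_labels <- sample_patch_labels(slides, spec)
  structure(list(slides = slides, patch_labels = patch_labels, spec = spec),
            class = "synthetic_cohort")
}

# Tumor = top-k cells of a smoothed Gaussian field (k matches the target
# fraction exactly); necrosis = top share of a second field among non-tumor.
make_class_grid <- function(rows, cols, fraction, cluster_strength, necrosis_frac) {
  npix <- rows * cols
  field <- smooth_field(matrix(stats::rnorm(npix), rows, cols), cluster_strength)
  nfield <- smooth_field(matrix(stats::rnorm(npix), rows, cols), cluster_strength)
  k <- as.integer(round_half_away(fraction * npix))
  g <- matrix("stroma", rows, cols)
  if (k > 0) g[order(field, decreasing = TRUE)[seq_len(k)]] <- "tumor"
  non_tumor <- which(g != "tumor")
  kn <- as.integer(round_half_away(necrosis_frac * length(non_tumor)))
  if (kn > 0) {
    g[non_tumor[order(nfield[non_tumor], decreasing = TRUE)[seq_len(kn)]]] <- "necrosis"
  }
  g
}

sample_patch_labels <- function(slides, spec) {
  train <- slides[slides$split == "train", ]
  if (nrow(train) == 0 || spec$n_labeled_patches == 0) {
    return(tibble::tibble(slide_id = character(), grid_row = integer(),
                          grid_col = integer(), label = character()))
  }
  pool <- dplyr::bind_rows(lapply(seq_len(nrow(train)), function(i) {
    g <- train$class_grid[[i]]
    idx <- which(g == g, arr.ind = TRUE)  # all cells
    tibble::tibble(slide_id = train$slide_id[i],
                   grid_row = as.integer(idx[, 1] - 1L),
                   grid_col = as.integer(idx[, 2] - 1L),
                   class = g[idx])
  }))
  n_take <- min(spec$n_labeled_patches, nrow(pool))
  sel <- with_seed(stage_seed(spec$seed, "labels"), sample(nrow(pool), n_take))
  out <- pool[sort(sel), ]
  tibble::tibble(slide_id = out$slide_id, grid_row = out$grid_row,
                 grid_col = out$grid_col,
                 label = ifelse(out$class == "tumor", "POS", "NEG"))
}

# Bilinearly upscaled coarse Gaussian noise (cells x cells control points).
coarse_noise <- function(size, cells = 8) {
  g <- matrix(stats::rnorm((cells + 1)^2), cells + 1, cells + 1)
  pos <- (seq_len(size) - 0.5) / size * cells
  i0 <- pmin(floor(pos), cells - 1); t <- pos - i0
  a <- g[i0 + 1, , drop = FALSE] * (1 - t) + g[i0 + 2, , drop = FALSE] * t
  a[, i0 + 1, drop = FALSE] * rep(1 - t, each = size) +
    a[, i0 + 2, drop = FALSE] * rep(t, each = size)
}

draw_ellipses <- function(img, cx, cy, a, b, theta, color, alpha_scale = 1) {
  size <- dim(img)[1]
  for (i in seq_along(cx)) {
    r <- max(a[i], b[i]) + 2
    xs <- max(1, floor(cx[i] - r)):min(size, ceiling(cx[i] + r))
    ys <- max(1, floor(cy[i] - r)):min(size, ceiling(cy[i] + r))
    if (length(xs) == 0 || length(ys) == 0) next
    dx <- outer(rep(1, length(ys)), xs - cx[i])
    dy <- outer(ys - cy[i], rep(1, length(xs)))
    ct <- cos(theta[i]); st <- sin(theta[i])
    q <- ((dx * ct + dy * st) / a[i])^2 + ((-dx * st + dy * ct) / b[i])^2
    alpha <- pmin(1, pmax(0, (1.15 - q) / 0.3)) * alpha_scale
    for (ch in 1:3) {
      img[ys, xs, ch] <- img[ys, xs, ch] * (1 - alpha) + color[ch] * alpha
    }
  }
  img
}

#' Render one synthetic patch
#'
#' Procedural textures on the 0-255 RGB scale: viable tumor patches carry many
#' small dark elliptical nuclei-like blobs (high local gradient energy) on a
#' pink background; stroma patches are smooth oriented fiber stripes; necrosis
#' patches are low-saturation gray mottle. Appearance parameters (nuclear
#' density, stripe orientation and contrast) are jittered per patch so classes
#' overlap slightly, as real tissue does. The textures are statistical stand-ins
#' for histology, not simulated H&E stains.
#'
#' @param class One of `"tumor"`, `"stroma"`, `"necrosis"`.
#' @param color_shift Length-3 additive RGB offset applied to all pixels.
#' @param seed Optional integer; when given, rendering is a pure function of
#'   `(class, color_shift, seed)`.
#' @param clip Clamp the result to [0, 255] (set `FALSE` to inspect the
#'   pre-clip signal).
#' @param size Patch edge length in pixels.
#' @return A `size x size x 3` numeric array on the 0-255 scale.
#' @export
render_patch <- function(class = c("tumor", "stroma", "necrosis"),
                         color_shift = c(0, 0, 0), seed = NULL, clip = TRUE,
                         size = 256L) {
  class <- match.arg(class)
  do_render <- function() {
    img <- array(0, dim = c(size, size, 3))
    if (class == "tumor") {
      z <- coarse_noise(size, 8)
      base <- c(216, 172, 200) + stats::rnorm(3, 0, 5)
      for (ch in 1:3) img[, , ch] <- base[ch] + 5 * z
      n_nuc <- stats::rpois(1, stats::runif(1, 28, 85))
      if (n_nuc > 0) {
        img <- draw_ellipses(img,
          cx = stats::runif(n_nuc, 1, size), cy = stats::runif(n_nuc, 1, size),
          a = stats::runif(n_nuc, 2.5, 6), b = stats::runif(n_nuc, 2.5, 6),
          theta = stats::runif(n_nuc, 0, pi),
          color = c(72, 34, 104) + stats::rnorm(3, 0, 6))
      }
    } else if (class == "stroma") {
      z <- coarse_noise(size, 8)
      base <- c(235, 205, 218) + stats::rnorm(3, 0, 4)
      th <- stats::runif(1, 0, pi); lam <- stats::runif(1, 35, 70)
      amp <- stats::runif(1, 4, 10); phase <- stats::runif(1, 0, 2 * pi)
      xy <- outer(seq_len(size) * sin(th), rep(1, size)) +
        outer(rep(1, size), seq_len(size) * cos(th))
      s <- amp * sin(2 * pi * xy / lam + phase)
      img[, , 1] <- base[1] + 4 * z - 0.4 * s
      img[, , 2] <- base[2] + 4 * z - 1.0 * s
      img[, , 3] <- base[3] + 4 * z - 0.6 * s
      n_fib <- stats::rpois(1, 1.2)
      if (n_fib > 0) {
        img <- draw_ellipses(img,
          cx = stats::runif(n_fib, 1, size), cy = stats::runif(n_fib, 1, size),
          a = stats::runif(n_fib, 8, 22), b = stats::runif(n_fib, 1, 2.5),
          theta = rep(th, n_fib) + stats::rnorm(n_fib, 0, 0.2),
          color = c(150, 95, 135), alpha_scale = 0.35)
      }
    } else {
      z <- coarse_noise(size, 6)
      base <- c(172, 168, 162) + stats::rnorm(1, 0, 4)
      for (ch in 1:3) img[, , ch] <- base[ch] + 22 * z
    }
    fine <- matrix(stats::rnorm(size * size, 0, 2), size, size)
    for (ch in 1:3) img[, , ch] <- img[, , ch] + fine + color_shift[ch]
    if (clip) img <- pmin(pmax(img, 0), 255)
    img
  }
  if (is.null(seed)) do_render() else with_seed(seed, do_render())
}

#' Patch table for a synthetic cohort
#'
#' Expands each slide's patch-class grid into the tabular patch form the rest
#' of the pipeline consumes (one row per 256x256 tile), optionally rendering
#' each patch and extracting its feature vector on the fly so whole-slide
#' rasters are never materialized.
#'
#' @param cohort A `synthetic_cohort`.
#' @param with_features Compute the `features` matrix column by rendering each
#'   patch (deterministic per patch) and applying `encoder`.
#' @param encoder Encoder used when `with_features = TRUE`.
#' @return A tibble with columns `slide_id`, `grid_row`, `grid_col`,
#'   `origin_x`, `origin_y`, `tissue_fraction`, `class` (ground truth),
#'   `label` (human POS/NEG where annotated, else UNLABELED), and optionally a
#'   `features` matrix column.
#' @export
cohort_patches <- function(cohort, with_features = FALSE,
                           encoder = builtin_encoder()) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  sl <- cohort$slides
  patches <- dplyr::bind_rows(lapply(seq_len(nrow(sl)), function(i) {
    g <- sl$class_grid[[i]]
    idx <- expand.grid(grid_row = seq_len(nrow(g)) - 1L,
                       grid_col = seq_len(ncol(g)) - 1L)
    tibble::tibble(
      slide_id = sl$slide_id[i],
      grid_row = as.integer(idx$grid_row),
      grid_col = as.integer(idx$grid_col),
      origin_x = as.integer(idx$grid_col * 256L),
      origin_y = as.integer(idx$grid_row * 256L),
      tissue_fraction = 1,
      class = g[cbind(idx$grid_row + 1L, idx$grid_col + 1L)],
      slide_seed = sl$slide_seed[i]
    )
  }))
  lab <- cohort$patch_labels
  patches <- dplyr::left_join(
    patches,
    dplyr::mutate(lab, .human = label),
    by = c("slide_id", "grid_row", "grid_col")
  )
  patches$label <- ifelse(is.na(patches$.human), "UNLABELED", patches$.human)
  patches$.human <- NULL
  if (with_features) {
    shift <- cohort$spec$color_shift
    feats <- vapply(seq_len(nrow(patches)), function(j) {
      px <- render_patch(patches$class[j], color_shift = shift,
                         seed = patch_render_seed(patches$slide_seed[j],
                                                  patches$grid_row[j],
                                                  patches$grid_col[j]))
      extract_features(px, encoder)
    }, numeric(encoder$dimension))
    patches$features <- t(feats)
  }
  patches$slide_seed <- NULL
  patches
}

#' Export a synthetic cohort to disk
#'
#' Writes exactly the layout the readers consume: one PNG image and one
#' full-extent mask PNG per slide, `manifest.csv` with the noisy percentage
#' labels, `patch_labels.csv`, and ground truth kept separate in `truth.csv`
#' (per slide) and `patch_truth.csv` (per patch). Slide rasters are assembled
#' in memory, so this is intended for small fixture-sized grids.
#'
#' @param cohort A `synthetic_cohort`.
#' @param out_dir Output directory (created if needed).
#' @return Named list of written paths, invisibly.
#' @export
export_cohort <- function(cohort, out_dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  sl <- cohort$slides
  img_paths <- file.path(out_dir, paste0("slide_", sl$slide_id, ".png"))
  mask_paths <- file.path(out_dir, paste0("mask_", sl$slide_id, ".png"))
  clash <- c(img_paths, mask_paths)[file.exists(c(img_paths, mask_paths))]
  if (length(clash) > 0) {
    stop(sprintf("refusing to overwrite existing slide files: %s",
                 paste(basename(clash), collapse = ", ")), call. = FALSE)
  }
  shift <- cohort$spec$color_shift
  for (i in seq_len(nrow(sl))) {
    g <- sl$class_grid[[i]]
    h <- nrow(g) * 256L; w <- ncol(g) * 256L
    img <- array(0, dim = c(h, w, 3))
    for (r in seq_len(nrow(g))) {
      for (cc in seq_len(ncol(g))) {
        px <- render_patch(g[r, cc], color_shift = shift,
                           seed = patch_render_seed(sl$slide_seed[i], r - 1L, cc - 1L))
        img[((r - 1) * 256 + 1):(r * 256), ((cc - 1) * 256 + 1):(cc * 256), ] <- px
      }
    }
    png::writePNG(img / 255, img_paths[i])
    write_mask(matrix(TRUE, h, w), mask_paths[i])
  }
  manifest <- tibble::tibble(
    slide_id = sl$slide_id,
    image = basename(img_paths),
    tumor_bed = basename(mask_paths),
    label_fraction = sl$label_fraction,
    cohort = sl$cohort,
    split = sl$split,
    magnification = sl$magnification
  )
  paths <- list(
    manifest = file.path(out_dir, "manifest.csv"),
    patch_labels = file.path(out_dir, "patch_labels.csv"),
    truth = file.path(out_dir, "truth.csv"),
    patch_truth = file.path(out_dir, "patch_truth.csv"),
    images = img_paths, masks = mask_paths
  )
  write_manifest(manifest, paths$manifest)
  write_patch_labels(cohort$patch_labels, paths$patch_labels)
  readr::write_csv(sl[c("slide_id", "true_fraction")], paths$truth, progress = FALSE)
  pt <- cohort_patches(cohort)[c("slide_id", "grid_row", "grid_col", "class")]
  readr::write_csv(pt, paths$patch_truth, progress = FALSE)
  invisible(paths)
}
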