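#' Estimate a slide's residual viable tumor fraction
#'
#' Aggregates patch probabilities into the slide-level estimate: predicted
#' positive patches divided by the total tumor bed. Two denominators are
#' offered because "tumor bed area" can be read as patch count or as tissue
#' area: `count` mode is `(#patches with prob >= threshold) / N`; `area` mode
#' weights every patch by its `tissue_fraction`, so border slivers count in
#' proportion to the tissue they contain. The two agree exactly when all
#' tissue fractions are equal.
#'
#' @param probs Numeric vector of per-patch tumor probabilities.
#' @param tissue_fractions Per-patch tissue fractions (required for `area`
#'   mode).
#' @param mode `"count"` (default) or `"area"`.
#' @param threshold Patch positivity threshold on the probability (default
#'   0.5).
#' @return A single fraction in [0, 1].
#' @export
estimate_fraction <- function(probs, tissue_fractions = NULL,
                              mode = c("count", "area"), threshold = 0.5) {
  mode <- match.arg(mode)
  if (length(probs) == 0) stop("at least one patch required", call. = FALSE)
  assert_fraction(probs, "probs")
  pos <- probs >= threshold
  if (mode == "count") {
    mean(pos)
  } else {
    if (is.null(tissue_fractions) || length(tissue_fractions) != length(probs)) {
      stop("area mode requires tissue_fractions aligned with probs", call. = FALSE)
    }
    sum(tissue_fractions[pos]) / sum(tissue_fractions)
  }
}

#' Call pathological response from a viable-tumor fraction
#'
#' pCR (pathological complete response) is the absence of viable residual
#' tumor: the fraction is exactly 0 (with an optional epsilon band for
#' continuous estimators, off by default). MPR (major pathological response)
#' is at most 10 percent viable residual tumor. pCR implies MPR for every
#' input.
#'
#' @param fraction Numeric vector of fractions in [0, 1].
#' @param pcr_epsilon Call pCR when `fraction <= pcr_epsilon` (default 0:
#'   zero positive patches required).
#' @return Tibble with columns `fraction`, `pcr`, `mpr`.
#' @export
call_response <- function(fraction, pcr_epsilon = 0) {
  if (!is.numeric(fraction) || anyNA(fraction) || any(fraction < 0 | fraction > 1)) {
    stop("fraction must lie in [0, 1]", call. = FALSE)
  }
  tibble::tibble(fraction = fraction,
                 pcr = fraction <= pcr_epsilon,
                 mpr = fraction <= 0.10)
}

#' Assess slides from patch probabilities
#'
#' @param patches Patch tibble with `slide_id`, a `features` matrix column,
#'   and `tissue_fraction`.
#' @param head A fitted `patch_classifier`.
#' @param mode,threshold Passed to [estimate_fraction()].
#' @param pcr_epsilon Passed to [call_response()].
#' @return Tibble, one row per slide: `slide_id`, `n_patches`,
#'   `predicted_fraction`, `predicted_percent`, `pcr`, `mpr`,
#'   `decision_threshold`.
#' @export
assess_slides <- function(patches, head, mode = "count", threshold = 0.5,
                          pcr_epsilon = 0) {
  probs <- predict_probs(head, patches)
  out <- dplyr::summarise(
    dplyr::group_by(tibble::tibble(slide_id = patches$slide_id, prob = probs,
                                   tissue_fraction = patches$tissue_fraction),
                    .data$slide_id),
    n_patches = dplyr::n(),
    predicted_fraction = estimate_fraction(.data$prob, .data$tissue_fraction,
                                           mode = mode, threshold = threshold),
    .groups = "drop"
  )
  calls <- call_response(out$predicted_fraction, pcr_epsilon = pcr_epsilon)
  out$predicted_percent <- out$predicted_fraction * 100
  out$pcr <- calls$pcr
  out$mpr <- calls$mpr
  out$decision_threshold <- threshold
  out
}

#' Probability grid for one slide
#'
#' @param patches Patch tibble (one slide) with `grid_row`, `grid_col`,
#'   `prob`; cells absent from the table (outside the tumor bed) become `NA`.
#' @return Numeric matrix of dimension `max(grid_row)+1 x max(grid_col)+1`.
#' @export
prob_grid <- function(patches) {
  stopifnot(all(c("grid_row", "grid_col", "prob") %in% names(patches)))
  g <- matrix(NA_real_, max(patches$grid_row) + 1L, max(patches$grid_col) + 1L)
  g[cbind(patches$grid_row + 1L, patches$grid_col + 1L)] <- patches$prob
  g
}

heatmap_palette <- function(n = 256) {
  grDevices::colorRamp(c("#2c2c7c", "#00a0c6", "#f3ef55", "#e8321e"))(
    seq(0, 1, length.out = n)) / 255
}

#' Render a tumor-likelihood heatmap
#'
#' Writes a PNG visualizing per-patch tumor probabilities on a fixed
#' cool-to-hot colormap (dark blue at 0 through cyan and yellow to red at 1);
#' cells outside the tumor bed (NA) are fully transparent. A paired numeric
#' matrix CSV (same path with extension `.csv`) is always written and
#' round-trips the probabilities exactly.
#'
#' @param grid Probability matrix from [prob_grid()]; `NA` allowed.
#' @param path Output PNG path.
#' @param cell_size Output pixels per grid cell.
#' @return Invisibly, a list with `png` and `csv` paths.
#' @export
render_heatmap <- function(grid, path, cell_size = 8L) {
  stopifnot(is.matrix(grid))
  pal <- heatmap_palette()
  idx <- pmin(pmax(round(grid * 255) + 1, 1), 256)
  h <- nrow(grid); w <- ncol(grid)
  img <- array(0, dim = c(h, w, 4))
  ok <- !is.na(grid)
  for (ch in 1:3) {
    plane <- matrix(0, h, w)
    plane[ok] <- pal[idx[ok], ch]
    img[, , ch] <- plane
  }
  img[, , 4][ok] <- 1
  big <- array(0, dim = c(h * cell_size, w * cell_size, 4))
  one <- matrix(1, cell_size, cell_size)
  for (ch in 1:4) big[, , ch] <- kronecker(img[, , ch], one)
  png::writePNG(big, path)
  csv <- sub("\\.png$", ".csv", path, ignore.case = TRUE)
  if (identical(csv, path)) csv <- paste0(path, ".csv")
  readr::write_csv(tibble::as_tibble(as.data.frame(grid), .name_repair = "minimal"),
                   csv, progress = FALSE)
  invisible(list(png = path, csv = csv))
}

#' Plot a probability grid with ggplot2
#'
#' @param grid Probability matrix (`NA` = outside tumor bed).
#' @return A ggplot object (tiles colored on the same fixed cool-to-hot
#'   scale as [render_heatmap()]).
#' @export
plot_heatmap <- function(grid) {
  df <- tidyr::expand_grid(grid_row = seq_len(nrow(grid)) - 1L,
                           grid_col = seq_len(ncol(grid)) - 1L)
  df$prob <- grid[cbind(df$grid_row + 1L, df$grid_col + 1L)]
  ggplot2::ggplot(df[!is.na(df$prob), ],
                  ggplot2::aes(x = .data$grid_col, y = .data$grid_row,
                               fill = .data$prob)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradientn(
      colours = c("#2c2c7c", "#00a0c6", "#f3ef55", "#e8321e"),
      limits = c(0, 1), name = "P(tumor)") +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "grid column", y = "grid row") +
    ggplot2::theme_minimal()
}

#' Select the k most and least tumor-like patches
#'
#' Deterministic selection for gallery figures: ordering is by probability
#' (descending for the high set, ascending for the low set) with ties broken
#' by ascending `(grid_row, grid_col)`. When `out_dir` and a `pixels`
#' list-column (or `render` function) are available, thumbnails are written
#' with the probability embedded in the filename.
#'
#' @param patches Patch tibble with `prob`, `grid_row`, `grid_col`,
#'   `slide_id`.
#' @param k Number of patches per extreme; must not exceed `nrow(patches)`.
#' @param out_dir Optional directory for thumbnail PNGs.
#' @param render Optional `function(row)` returning an RGB array on the 0-255
#'   scale for a patch row, used to produce thumbnails.
#' @return Tibble of `2k` rows (when probabilities are distinct and
#'   `N >= 2k`) with `which` (`"high"`/`"low"`) and `rank` columns; a `file`
#'   column when thumbnails were written.
#' @export
top_bottom_patches <- function(patches, k, out_dir = NULL, render = NULL) {
  n <- nrow(patches)
  if (k > n) stop(sprintf("k = %d exceeds the %d available patches", k, n),
                  call. = FALSE)
  hi <- patches[order(-patches$prob, patches$grid_row, patches$grid_col), ][seq_len(k), ]
  lo <- patches[order(patches$prob, patches$grid_row, patches$grid_col), ][seq_len(k), ]
  hi$which <- "high"; lo$which <- "low"
  hi$rank <- seq_len(k); lo$rank <- seq_len(k)
  out <- dplyr::bind_rows(hi, lo)
  if (!is.null(out_dir) && !is.null(render)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    out$file <- vapply(seq_len(nrow(out)), function(i) {
      row <- out[i, ]
      f <- file.path(out_dir, sprintf("%s_r%d_c%d_p%.3f_%s.png", row$slide_id,
                                      row$grid_row, row$grid_col, row$prob,
                                      row$which))
      png::writePNG(render(row) / 255, f)
      f
    }, character(1))
  }
  out
}

#' RGB bin counts within the tumor bed
#'
#' Scanner and staining differences between cohorts show up as shifted
#' channel histograms; this quality-control summary counts pixels per channel
#' in equal-width bins over [0, 256), restricted to the tumor-bed mask.
#'
#' @param pixels `H x W x 3` array on the 0-255 scale.
#' @param mask Logical `H x W` matrix; `NULL` uses every pixel.
#' @param n_bins Number of equal-width bins.
#' @return Tibble with `channel` (`"R"/"G"/"B"`), `bin` (1-based), `lower`,
#'   `upper` (half-open bin edges), `count`. Counts per channel sum to the
#'   masked pixel count.
#' @export
rgb_bin_counts <- function(pixels, mask = NULL, n_bins = 32L) {
  stopifnot(length(dim(pixels)) == 3, dim(pixels)[3] == 3, n_bins >= 1)
  if (is.null(mask)) mask <- matrix(TRUE, dim(pixels)[1], dim(pixels)[2])
  if (!any(mask)) stop("empty tumor bed mask", call. = FALSE)
  width <- 256 / n_bins
  dplyr::bind_rows(lapply(1:3, function(ch) {
    v <- pixels[, , ch][mask]
    b <- pmin(pmax(floor(v / width), 0), n_bins - 1) + 1L
    tibble::tibble(channel = c("R", "G", "B")[ch],
                   bin = seq_len(n_bins),
                   lower = (seq_len(n_bins) - 1) * width,
                   upper = seq_len(n_bins) * width,
                   count = tabulate(b, nbins = n_bins))
  }))
}

#' Plot per-channel bin counts
#'
#' @param counts Output of [rgb_bin_counts()], optionally with an extra
#'   `cohort` column for side-by-side comparison.
#' @return A ggplot object.
#' @export
plot_rgb_bins <- function(counts) {
  p <- ggplot2::ggplot(counts, ggplot2::aes(x = .data$lower, y = .data$count)) +
    ggplot2::geom_col(width = counts$upper[1] - counts$lower[1]) +
    ggplot2::labs(x = "channel value", y = "pixel count") +
    ggplot2::theme_minimal()
  if ("cohort" %in% names(counts)) {
    p + ggplot2::facet_grid(cohort ~ channel)
  } else {
    p + ggplot2::facet_wrap(~channel)
  }
}
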