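#' Encoder specification
#'
#' Patch features are produced by a frozen, deterministic encoder: the same
#' patch always maps to the same vector, and the encoder is never updated
#' during training — only the two-layer classifier head learns. The default is
#' the built-in hand-crafted extractor ([builtin_encoder()]); any external
#' deep feature extractor can be plugged in by supplying its function and
#' output dimension.
#'
#' @param name Encoder name.
#' @param dimension Output feature dimension D.
#' @param fun Function mapping a 256x256x3 array (0-255 scale) to a numeric
#'   vector of length `dimension`.
#' @return An object of class `encoder_spec`.
#' @export
encoder_spec <- function(name, dimension, fun) {
  stopifnot(is.character(name), dimension >= 1, is.function(fun))
  structure(list(name = name, dimension = as.integer(dimension),
                 frozen = TRUE, fun = fun),
            class = "encoder_spec")
}

#' Built-in patch feature extractor
#'
#' A desk-scale stand-alone encoder: per RGB channel it computes an 8-bin
#' normalized intensity histogram on [0, 256), the channel mean and standard
#' deviation, and the mean and standard deviation of the per-pixel gradient
#' energy (sum of squared horizontal and vertical finite differences), giving
#' D = 3 x 12 = 36 features. Color statistics separate tissue appearances and
#' scanner shifts; gradient energy separates nuclei-dense viable tumor from
#' smooth stroma.
#'
#' @return An `encoder_spec` with `dimension = 36`.
#' @export
builtin_encoder <- function() {
  encoder_spec("builtin", 36L, builtin_features)
}

builtin_features <- function(pixels) {
  feats <- numeric(0)
  breaks <- seq(0, 256, by = 32)
  for (ch in 1:3) {
    v <- pixels[, , ch]
    h <- tabulate(pmin(floor(pmax(v, 0) / 32) + 1L, 8L), nbins = 8L)
    gx <- v[, -1] - v[, -ncol(v)]
    gy <- v[-1, ] - v[-nrow(v), ]
    e <- gx[-nrow(gx), ]^2 + gy[, -ncol(gy)]^2
    feats <- c(feats, h / length(v), mean(v), stats::sd(v), mean(e), stats::sd(e))
  }
  feats
}

#' Extract features from one patch
#'
#' @param pixels A 256x256x3 numeric array on the 0-255 scale (any square
#'   RGB raster is accepted; the built-in extractor is size-agnostic).
#' @param encoder An [encoder_spec()]; default [builtin_encoder()].
#' @return Numeric vector of length `encoder$dimension`; finite,
#'   deterministic.
#' @export
extract_features <- function(pixels, encoder = builtin_encoder()) {
  if (!(is.array(pixels) && length(dim(pixels)) == 3 && dim(pixels)[3] == 3)) {
    stop("pixels must be an H x W x 3 RGB array", call. = FALSE)
  }
  f <- encoder$fun(pixels)
  if (length(f) != encoder$dimension || !all(is.finite(f))) {
    stop(sprintf("encoder '%s' returned %d values (expected %d finite)",
                 encoder$name, length(f), encoder$dimension), call. = FALSE)
  }
  f
}

#' Tile a tumor bed into non-overlapping 256x256 patches
#'
#' The patch grid is anchored at the origin of the tumor-bed bounding box (not
#' the slide origin), so re-cropping the same bed reproduces identical patch
#' identities. Tiling is exhaustive over the bounding box: a
#' `ceil(h/256) x ceil(w/256)` grid, each cell a half-open 256-pixel extent.
#' A cell is kept iff the fraction of its 256^2 pixels lying inside the mask
#' (`tissue_fraction`) is at least `min_tissue_fraction`; the default 0.5
#' drops edge slivers.
#'
#' @param mask Logical `height x width` tumor-bed mask (see
#'   [read_tumor_bed()]).
#' @param slide_id Slide identifier carried into the patch table.
#' @param min_tissue_fraction Admission threshold in [0, 1]; 0 keeps every
#'   bounding-box cell.
#' @param patch Patch edge length in pixels.
#' @return Tibble with columns `slide_id`, `grid_row`, `grid_col` (0-based),
#'   `origin_x`, `origin_y` (0-based slide coordinates of the patch top-left),
#'   `tissue_fraction`, `label = "UNLABELED"`. The bed bounding box is
#'   attached as attribute `bed_bbox` (`c(x0, y0, width, height)`).
#' @export
tile_tumor_bed <- function(mask, slide_id = "slide", min_tissue_fraction = 0.5,
                           patch = 256L) {
  stopifnot(is.matrix(mask))
  if (!any(mask)) stop("empty tumor bed", call. = FALSE)
  assert_fraction(min_tissue_fraction)
  rows_any <- which(rowSums(mask) > 0)
  cols_any <- which(colSums(mask) > 0)
  y0 <- rows_any[1] - 1L; x0 <- cols_any[1] - 1L
  bh <- rows_any[length(rows_any)] - y0; bw <- cols_any[length(cols_any)] - x0
  n_r <- as.integer(ceiling(bh / patch)); n_c <- as.integer(ceiling(bw / patch))

  # integral image for fast per-cell mask sums
  sub <- mask[rows_any[1]:nrow(mask), cols_any[1]:ncol(mask), drop = FALSE]
  ii <- apply(apply(sub, 2, cumsum), 1, cumsum)  # transposed integral
  cell_sum <- function(r, cc) {
    # half-open cell [r*patch, (r+1)*patch) x [cc*patch, ...) in bed coords
    y1 <- r * patch; y2 <- min((r + 1) * patch, nrow(sub))
    x1 <- cc * patch; x2 <- min((cc + 1) * patch, ncol(sub))
    if (y2 <= y1 || x2 <= x1) return(0)
    s <- ii[x2, y2]
    if (y1 > 0) s <- s - ii[x2, y1]
    if (x1 > 0) s <- s - ii[x1, y2]
    if (y1 > 0 && x1 > 0) s <- s + ii[x1, y1]
    s
  }
  grid <- expand.grid(grid_row = seq_len(n_r) - 1L, grid_col = seq_len(n_c) - 1L)
  tf <- mapply(cell_sum, grid$grid_row, grid$grid_col) / patch^2
  out <- tibble::tibble(
    slide_id = slide_id,
    grid_row = as.integer(grid$grid_row),
    grid_col = as.integer(grid$grid_col),
    origin_x = as.integer(x0 + grid$grid_col * patch),
    origin_y = as.integer(y0 + grid$grid_row * patch),
    tissue_fraction = as.numeric(tf),
    label = "UNLABELED"
  )
  out <- out[out$tissue_fraction >= min_tissue_fraction, ]
  if (nrow(out) == 0) {
    stop(sprintf("tumor bed too small: no patch reached tissue fraction %.2f (bed bbox %dx%d at (%d, %d))",
                 min_tissue_fraction, bw, bh, x0, y0), call. = FALSE)
  }
  out <- out[order(out$grid_row, out$grid_col), ]
  attr(out, "bed_bbox") <- c(x0 = x0, y0 = y0, width = bw, height = bh)
  out
}

#' Crop a patch's pixels from a slide raster
#'
#' @param image `H x W x 3` array on the 0-255 scale.
#' @param origin_x,origin_y 0-based top-left corner.
#' @param patch Edge length; regions beyond the image are zero-padded (they
#'   lie outside the tumor bed by construction).
#' @return `patch x patch x 3` array.
#' @export
crop_patch <- function(image, origin_x, origin_y, patch = 256L) {
  out <- array(0, dim = c(patch, patch, 3))
  ys <- (origin_y + 1):min(origin_y + patch, dim(image)[1])
  xs <- (origin_x + 1):min(origin_x + patch, dim(image)[2])
  out[seq_along(ys), seq_along(xs), ] <- image[ys, xs, , drop = FALSE]
  out
}

#' Add feature vectors to a patch table from a slide raster
#'
#' @param patches Patch tibble from [tile_tumor_bed()].
#' @param image Slide raster (`H x W x 3`, 0-255 scale).
#' @param encoder An [encoder_spec()].
#' @return `patches` with a `features` matrix column.
#' @export
add_patch_features <- function(patches, image, encoder = builtin_encoder()) {
  feats <- vapply(seq_len(nrow(patches)), function(i) {
    extract_features(crop_patch(image, patches$origin_x[i], patches$origin_y[i]),
                     encoder)
  }, numeric(encoder$dimension))
  patches$features <- t(feats)
  patches
}
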