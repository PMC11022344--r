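#' Read a slide manifest
#'
#' A manifest is the cohort-level table of slides entering the pipeline: one
#' row per slide with its image, tumor-bed annotation, the pathologist's
#' slide-level residual-viable-tumor percentage, and cohort/split tags.
#' Percentages are stored on disk on the 0-100 scale pathologists report and
#' held in memory as fractions in [0, 1].
#'
#' @param path Path to a CSV with columns
#'   `slide_id,image,tumor_bed,label_percent,cohort,split` (and optionally
#'   `magnification`, defaulting to `"20x"`).
#' @return A tibble with columns `slide_id`, `image`, `tumor_bed`,
#'   `label_fraction`, `cohort`, `split`, `magnification`, row order as on
#'   disk.
#' @export
#' @examples
#' p <- tempfile(fileext = ".csv")
#' writeLines(c("slide_id,image,tumor_bed,label_percent,cohort,split",
#'              "s1,img.png,mask.png,30,C1,train"), p)
#' read_manifest(p)
read_manifest <- function(path) {
  df <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                        progress = FALSE)
  required <- c("slide_id", "image", "tumor_bed", "label_percent", "cohort", "split")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    stop(sprintf("manifest is missing required column(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  pct <- suppressWarnings(as.numeric(df$label_percent))
  bad <- which(is.na(pct) | pct < 0 | pct > 100)
  if (length(bad) > 0) {
    stop(sprintf("label_percent outside [0, 100] for slide(s): %s",
                 paste(df$slide_id[bad], collapse = ", ")), call. = FALSE)
  }
  if (anyDuplicated(paste(df$cohort, df$slide_id))) {
    stop("duplicate slide_id within a cohort", call. = FALSE)
  }
  bad_split <- setdiff(unique(df$split), c("train", "val", "test"))
  if (length(bad_split) > 0) {
    stop(sprintf("split must be one of train/val/test, got: %s",
                 paste(bad_split, collapse = ", ")), call. = FALSE)
  }
  tibble::tibble(
    slide_id = df$slide_id,
    image = df$image,
    tumor_bed = df$tumor_bed,
    label_fraction = pct / 100,
    cohort = df$cohort,
    split = df$split,
    magnification = if ("magnification" %in% names(df)) df$magnification else "20x"
  )
}

#' Write a slide manifest
#'
#' Inverse of [read_manifest()]: `label_fraction` is written back as
#' `label_percent` on the 0-100 scale. The round trip is lossless.
#'
#' @param manifest A tibble as returned by [read_manifest()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(manifest, path) {
  assert_fraction(manifest$label_fraction, "label_fraction")
  out <- tibble::tibble(
    slide_id = manifest$slide_id,
    image = manifest$image,
    tumor_bed = manifest$tumor_bed,
    label_percent = manifest$label_fraction * 100,
    cohort = manifest$cohort,
    split = manifest$split,
    magnification = manifest$magnification %||% "20x"
  )
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Read human patch labels
#'
#' Patch-level binary annotations made by pathologists: POS if viable tumor
#' cells are present anywhere in the 256x256 patch, NEG if none are visible.
#' Human annotation never contains pseudo states.
#'
#' @param path CSV with columns `slide_id,grid_row,grid_col,label`.
#' @return Tibble with those columns; `grid_row`/`grid_col` integer (0-based),
#'   `label` in `{"POS","NEG"}`.
#' @export
read_patch_labels <- function(path) {
  df <- readr::read_csv(path, col_types = readr::cols(
    slide_id = readr::col_character(),
    grid_row = readr::col_integer(),
    grid_col = readr::col_integer(),
    label = readr::col_character()
  ), progress = FALSE)
  bad <- setdiff(unique(df$label), c("POS", "NEG"))
  if (length(bad) > 0) {
    stop(sprintf("patch labels must be POS or NEG, got: %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  if (anyDuplicated(df[c("slide_id", "grid_row", "grid_col")])) {
    stop("duplicate (slide_id, grid_row, grid_col) in patch labels", call. = FALSE)
  }
  if (any(df$grid_row < 0 | df$grid_col < 0)) {
    stop("grid indices must be non-negative", call. = FALSE)
  }
  tibble::as_tibble(df)
}

#' @rdname read_patch_labels
#' @param labels Tibble of patch labels.
#' @param path Output CSV path.
#' @export
write_patch_labels <- function(labels, path) {
  stopifnot(all(c("slide_id", "grid_row", "grid_col", "label") %in% names(labels)))
  readr::write_csv(labels[c("slide_id", "grid_row", "grid_col", "label")], path,
                   progress = FALSE)
  invisible(path)
}

#' Read a tumor-bed annotation as a binary mask
#'
#' Tumor beds are delineated by pathologists and are required input for every
#' slide; the pipeline never segments them automatically. The annotation is
#' either a binary mask image covering the slide extent (any nonzero pixel is
#' bed) or a polygon file in image pixel coordinates, rasterized with the
#' even-odd fill rule by a pixel-center test.
#'
#' Pixel coordinates are 0-based with half-open extents; the center of pixel
#' `(x, y)` is `(x + 0.5, y + 0.5)`.
#'
#' @param annotation_ref Path to a mask PNG, a polygon JSON file, or a logical
#'   matrix (passed through after validation).
#' @param image_extent `c(width, height)` in pixels; required for polygon
#'   input, checked against mask input when supplied.
#' @return A logical matrix of dimension `height x width`; `[y + 1, x + 1]`
#'   indexes pixel `(x, y)`.
#' @export
read_tumor_bed <- function(annotation_ref, image_extent = NULL) {
  if (is.matrix(annotation_ref)) {
    mask <- annotation_ref
    storage.mode(mask) <- "logical"
  } else if (grepl("\\.png$", annotation_ref, ignore.case = TRUE)) {
    img <- png::readPNG(annotation_ref)
    mask <- if (length(dim(img)) == 3) apply(img, c(1, 2), max) > 0 else img > 0
    if (!is.null(image_extent) &&
        !identical(dim(mask), as.integer(c(image_extent[2], image_extent[1])))) {
      stop("mask extent does not match the stated image extent", call. = FALSE)
    }
  } else if (grepl("\\.(geo)?json$", annotation_ref, ignore.case = TRUE)) {
    if (is.null(image_extent)) {
      stop("image_extent is required for polygon annotations", call. = FALSE)
    }
    rings <- read_polygon_rings(annotation_ref)
    mask <- rasterize_polygons(rings, width = image_extent[1], height = image_extent[2])
  } else {
    stop("unrecognised tumor-bed annotation format (expect .png or .json)",
         call. = FALSE)
  }
  if (!any(mask)) stop("empty tumor bed", call. = FALSE)
  mask
}

# Polygon files: either GeoJSON Polygon/MultiPolygon geometry or
# {"polygons": [[[x, y], ...], ...]}. Returns a list of n x 2 matrices (rings).
read_polygon_rings <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  to_ring <- function(m) {
    m <- as.matrix(m)
    if (ncol(m) != 2 || nrow(m) < 3) stop("polygon ring needs >= 3 (x, y) vertices",
                                          call. = FALSE)
    m
  }
  rings <- if (!is.null(doc$polygons)) {
    lapply(if (is.list(doc$polygons)) doc$polygons else list(doc$polygons), to_ring)
  } else if (identical(doc$type, "Polygon")) {
    lapply(if (is.list(doc$coordinates)) doc$coordinates else list(doc$coordinates), to_ring)
  } else if (identical(doc$type, "MultiPolygon")) {
    lapply(unlist(doc$coordinates, recursive = FALSE), to_ring)
  } else {
    stop("unrecognised polygon file structure", call. = FALSE)
  }
  if (length(rings) == 0) stop("empty tumor bed", call. = FALSE)
  rings
}

#' Rasterize polygon rings to a binary mask
#'
#' Even-odd fill over all rings (so holes subtract); a pixel belongs to the
#' polygon iff its center lies inside. Vertices outside the image extent are
#' clipped to it with a warning.
#'
#' @param rings List of n x 2 matrices of (x, y) vertices, 0-based image
#'   coordinates, rings closed implicitly.
#' @param width,height Image extent in pixels.
#' @return Logical `height x width` matrix.
#' @export
rasterize_polygons <- function(rings, width, height) {
  stopifnot(width >= 1, height >= 1)
  rings <- lapply(rings, function(r) {
    if (any(r[, 1] < 0 | r[, 1] > width | r[, 2] < 0 | r[, 2] > height)) {
      warning("polygon vertices outside image extent were clipped", call. = FALSE)
      r[, 1] <- pmin(pmax(r[, 1], 0), width)
      r[, 2] <- pmin(pmax(r[, 2], 0), height)
    }
    r
  })
  yc <- seq_len(height) - 0.5
  # Crossing-parity accumulator: D[r, 1:m] += 1 encoded as difference array,
  # one prefix range per (edge, scanline) crossing.
  D <- matrix(0L, nrow = height, ncol = width + 1L)
  for (ring in rings) {
    n <- nrow(ring)
    for (i in seq_len(n)) {
      j <- if (i == n) 1L else i + 1L
      x1 <- ring[i, 1]; y1 <- ring[i, 2]
      x2 <- ring[j, 1]; y2 <- ring[j, 2]
      if (y1 == y2) next
      hit <- which((y1 > yc) != (y2 > yc))
      if (length(hit) == 0) next
      xint <- x1 + (yc[hit] - y1) * (x2 - x1) / (y2 - y1)
      # pixel centers xc = col - 0.5 strictly left of the intersection
      m <- pmin(width, pmax(0L, floor(xint + 0.5)))
      keep <- m > 0
      if (any(keep)) {
        idx <- cbind(hit[keep], 1L)
        D[idx] <- D[idx] + 1L
        idx2 <- cbind(hit[keep], m[keep] + 1L)
        D[idx2] <- D[idx2] - 1L
      }
    }
  }
  counts <- t(apply(D, 1, cumsum))[, seq_len(width), drop = FALSE]
  counts %% 2 == 1
}

#' Write a tumor-bed mask as a PNG
#'
#' @param mask Logical matrix (`height x width`).
#' @param path Output path.
#' @export
write_mask <- function(mask, path) {
  png::writePNG(matrix(as.numeric(mask), nrow = nrow(mask)), path)
  invisible(path)
}
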