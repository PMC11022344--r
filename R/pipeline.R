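#' Validate and normalize a run configuration
#'
#' A run configuration drives [run_e2e()]: one global `seed` (every stage
#' derives its own seed from it via [stage_seed()]), a data source (either a
#' `cohort` section for synthetic runs or a `manifest`/`patch_labels` pair for
#' real slides), and optional `head`, `distill`, `assessment` and `metrics`
#' sections. All defaults are filled in and echoed back; unknown keys are
#' rejected. Violations are reported together, one message per problem.
#'
#' @param x A YAML file path or a nested list.
#' @return A normalized object of class `run_config`.
#' @export
validate_config <- function(x) {
  if (inherits(x, "run_config")) return(x)
  if (is.character(x) && length(x) == 1) x <- yaml::read_yaml(x) %||% list()
  if (!is.list(x)) stop("config must be a YAML file or a list", call. = FALSE)
  errors <- character()
  note <- function(msg) errors <<- c(errors, msg)

  known <- c("seed", "out", "cohort", "manifest", "patch_labels", "truth",
             "head", "distill", "assessment", "metrics")
  for (k in setdiff(names(x), known)) note(sprintf("unknown config key `%s`", k))

  if (is.null(x$seed)) {
    note("`seed` is required")
  } else if (!is.numeric(x$seed) || length(x$seed) != 1) {
    note("`seed` must be a single integer")
  }

  if (is.null(x$cohort) && is.null(x$manifest)) {
    note("either a `cohort` section (synthetic run) or a `manifest` path is required")
  }
  if (!is.null(x$cohort) && !is.null(x$manifest)) {
    note("give either `cohort` or `manifest`, not both")
  }

  take_section <- function(section, builder, drop = character()) {
    sec <- x[[section]] %||% list()
    ok_keys <- setdiff(names(formals(builder)), drop)
    for (k in setdiff(names(sec), ok_keys)) {
      note(sprintf("unknown key `%s` in `%s` section", k, section))
    }
    sec <- sec[intersect(names(sec), ok_keys)]
    tryCatch(do.call(builder, sec),
             error = function(e) {
               note(sprintf("in `%s`: %s", section, conditionMessage(e)))
               do.call(builder, list())
             })
  }

  cohort <- if (!is.null(x$cohort)) take_section("cohort", cohort_spec, drop = "seed")
  head_cfg <- take_section("head", head_config, drop = "seed")
  distill_cfg <- take_section("distill", distill_config)

  assessment <- x$assessment %||% list()
  for (k in setdiff(names(assessment), c("mode", "threshold", "pcr_epsilon"))) {
    note(sprintf("unknown key `%s` in `assessment` section", k))
  }
  assessment <- list(mode = assessment$mode %||% "count",
                     threshold = assessment$threshold %||% 0.5,
                     pcr_epsilon = assessment$pcr_epsilon %||% 0)
  if (!assessment$mode %in% c("count", "area")) {
    note("assessment mode must be 'count' or 'area'")
  }
  if (!is.numeric(assessment$threshold) || assessment$threshold < 0 ||
      assessment$threshold > 1) {
    note("assessment threshold must lie in [0, 1]")
  }

  metrics <- x$metrics %||% list()
  for (k in setdiff(names(metrics), "tolerances")) {
    note(sprintf("unknown key `%s` in `metrics` section", k))
  }
  tolerances <- as.numeric(metrics$tolerances %||% c(0.1, 0.3))
  if (any(tolerances <= 0 | tolerances > 1) ||
      is.unsorted(tolerances, strictly = TRUE)) {
    note("metric tolerances must be ascending unique values in (0, 1]")
  }

  if (length(errors) > 0) {
    stop(paste0("invalid run config:\n", paste0("  - ", errors, collapse = "\n")),
         call. = FALSE)
  }
  structure(list(
    seed = as.integer(x$seed), out = x$out,
    cohort = cohort, manifest = x$manifest, patch_labels = x$patch_labels,
    truth = x$truth, head = head_cfg, distill = distill_cfg,
    assessment = assessment, metrics = list(tolerances = tolerances)
  ), class = "run_config")
}

log_line <- function(stage, ...) {
  jsonlite::toJSON(c(list(stage = stage), list(...)), auto_unbox = TRUE,
                   digits = NA)
}

read_slide_image <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 2) img <- array(rep(img, 3), dim = c(dim(img), 3))
  img[, , 1:3, drop = FALSE] * 255
}

# Load a real-slide manifest into the in-memory patch/slide form.
load_manifest_inputs <- function(cfg) {
  manifest <- read_manifest(cfg$manifest)
  root <- dirname(cfg$manifest)
  labels <- if (!is.null(cfg$patch_labels)) read_patch_labels(cfg$patch_labels) else {
    tibble::tibble(slide_id = character(), grid_row = integer(),
                   grid_col = integer(), label = character())
  }
  encoder <- builtin_encoder()
  patches <- dplyr::bind_rows(lapply(seq_len(nrow(manifest)), function(i) {
    img <- read_slide_image(file.path(root, manifest$image[i]))
    mask <- read_tumor_bed(file.path(root, manifest$tumor_bed[i]))
    p <- tile_tumor_bed(mask, slide_id = manifest$slide_id[i])
    add_patch_features(p, img, encoder)
  }))
  patches <- dplyr::left_join(patches, dplyr::rename(labels, .human = "label"),
                              by = c("slide_id", "grid_row", "grid_col"))
  patches$label <- ifelse(is.na(patches$.human), "UNLABELED", patches$.human)
  patches$.human <- NULL
  truth <- if (!is.null(cfg$truth)) {
    readr::read_csv(cfg$truth, col_types = readr::cols(
      slide_id = readr::col_character(), true_fraction = readr::col_double()),
      progress = FALSE)
  }
  list(slides = manifest, patches = patches, truth = truth)
}

#' Run the pipeline end to end
#'
#' Executes synthesize (or load) -> tile/extract -> two-step distillation
#' training -> slide assessment -> evaluation, with every stage seeded from
#' the single global seed. Test-split slides are held out of training and
#' scored both with the final distilled head and with the step-1-only head,
#' so the contribution of distillation is always visible in the summary.
#' Identical config and seed give byte-identical summary JSON.
#'
#' @param config A [validate_config()] input (path, list, or `run_config`).
#' @param out Output directory (overrides `config$out`); when given, writes
#'   `summary.json`, `slides.csv` (per-slide estimates and response calls),
#'   `report.json`, per-slide heatmaps under `heatmaps/`, and a line-oriented
#'   JSON `run.log`.
#' @return Invisibly, a list of class `e2e_run`: `summary` (the JSON-stable
#'   result list), `estimates`, `fit` (the `distill_fit`), `log_lines`.
#' @export
run_e2e <- function(config, out = NULL) {
  cfg <- validate_config(config)
  out <- out %||% cfg$out
  lines <- character()
  say <- function(...) lines <<- c(lines, as.character(log_line(...)))

  if (!is.null(cfg$cohort)) {
    spec <- cfg$cohort
    spec$seed <- stage_seed(cfg$seed, "synth")
    cohort <- generate_cohort(spec)
    slides <- cohort$slides
    truth_col <- "true_fraction"
    say("synth", n_slides = nrow(slides), n_pcr = sum(slides$true_fraction == 0),
        seed = spec$seed)
    patches <- cohort_patches(cohort, with_features = TRUE)
  } else {
    inputs <- load_manifest_inputs(cfg)
    slides <- inputs$slides
    patches <- inputs$patches
    if (!is.null(inputs$truth)) {
      slides <- dplyr::left_join(slides, inputs$truth, by = "slide_id")
      truth_col <- "true_fraction"
    } else {
      truth_col <- "label_fraction"
    }
    say("load", n_slides = nrow(slides), n_patches = nrow(patches))
  }
  say("tile", n_patches = nrow(patches),
      n_labeled = sum(patches$label %in% c("POS", "NEG")))

  train_ids <- slides$slide_id[slides$split == "train"]
  test_ids <- slides$slide_id[slides$split == "test"]
  if (length(train_ids) == 0 || length(test_ids) == 0) {
    stop("config requires at least one train and one test slide", call. = FALSE)
  }
  tr_patches <- patches[patches$slide_id %in% train_ids, ]
  te_patches <- patches[patches$slide_id %in% test_ids, ]

  head_cfg <- cfg$head
  head_cfg$seed <- stage_seed(cfg$seed, "train")
  fit <- distill(tr_patches, slides[slides$split == "train", ],
                 head_cfg = head_cfg, cfg = cfg$distill)
  for (i in seq_len(nrow(fit$log))) {
    r <- fit$log[i, ]
    say("train", iteration = r$iteration, n_human = r$n_human,
        n_pseudo_pos = r$n_pseudo_pos, n_pseudo_neg = r$n_pseudo_neg,
        n_unlabeled = r$n_unlabeled, n_patches = nrow(tr_patches))
  }

  assess_with <- function(head) {
    assess_slides(te_patches, head, mode = cfg$assessment$mode,
                  threshold = cfg$assessment$threshold,
                  pcr_epsilon = cfg$assessment$pcr_epsilon)
  }
  est <- assess_with(fit$head)
  est0 <- assess_with(fit$head0)
  say("assess", n_slides = nrow(est))

  ref <- slides[match(est$slide_id, slides$slide_id), ][[truth_col]]
  rep_distilled <- evaluation_report(ref, est$predicted_fraction,
                                     tolerances = cfg$metrics$tolerances,
                                     slide_id = est$slide_id, source = "distilled")
  rep_step1 <- evaluation_report(ref, est0$predicted_fraction,
                                 tolerances = cfg$metrics$tolerances,
                                 slide_id = est0$slide_id, source = "step1_only")
  say("evaluate", n_slides = rep_distilled$n, reference = truth_col)

  summary <- list(
    seed = cfg$seed,
    n_train_slides = length(train_ids),
    n_test_slides = length(test_ids),
    n_patches = nrow(patches),
    reference = truth_col,
    distill_log = fit$log[c("iteration", "n_human", "n_pseudo_pos",
                            "n_pseudo_neg", "n_unlabeled", "fallback")],
    metrics = list(distilled = tidy.evaluation_report(rep_distilled),
                   step1_only = tidy.evaluation_report(rep_step1)),
    config = list(
      head = unclass(cfg$head), distill = unclass(cfg$distill),
      assessment = cfg$assessment, metrics = cfg$metrics,
      cohort = if (!is.null(cfg$cohort)) unclass(cfg$cohort)
    )
  )

  if (!is.null(out)) {
    dir.create(out, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(summary, file.path(out, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         na = "null")
    readr::write_csv(est, file.path(out, "slides.csv"), progress = FALSE)
    write_report(rep_distilled, file.path(out, "report.json"))
    hm_dir <- file.path(out, "heatmaps")
    dir.create(hm_dir, showWarnings = FALSE)
    te <- te_patches
    te$prob <- predict_probs(fit$head, te_patches)
    for (sid in test_ids) {
      g <- prob_grid(te[te$slide_id == sid, ])
      render_heatmap(g, file.path(hm_dir, paste0(sid, ".png")))
    }
    writeLines(lines, file.path(out, "run.log"))
  }

  invisible(structure(list(summary = summary, estimates = est,
                           estimates_step1 = est0, fit = fit,
                           reports = list(distilled = rep_distilled,
                                          step1_only = rep_step1),
                           log_lines = lines),
                      class = "e2e_run"))
}

#' @export
print.e2e_run <- function(x, ...) {
  cat(sprintf("<e2e_run> %d train / %d test slides, %d patches\n",
              x$summary$n_train_slides, x$summary$n_test_slides,
              x$summary$n_patches))
  print(dplyr::bind_rows(x$summary$metrics$distilled,
                         x$summary$metrics$step1_only))
  invisible(x)
}
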