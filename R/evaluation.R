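#' Coefficient of determination against a reference
#'
#' `1 - sum((y - yhat)^2) / sum((y - mean(y))^2)`, computed against the stated
#' reference (e.g. the senior-pathologist consensus), not a symmetric
#' correlation. May be negative for predictors worse than the reference mean.
#'
#' @param y_true Reference fractions.
#' @param y_pred Predicted fractions.
#' @return A single real value.
#' @export
r2_score <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred)) stop("length mismatch", call. = FALSE)
  if (length(y_true) < 2) stop("need at least 2 observations", call. = FALSE)
  ss_tot <- sum((y_true - mean(y_true))^2)
  if (ss_tot == 0) stop("R-squared undefined: y_true is constant", call. = FALSE)
  1 - sum((y_true - y_pred)^2) / ss_tot
}

#' Mean absolute and mean squared error
#'
#' @param y_true,y_pred Equal-length numeric vectors.
#' @return Named numeric vector `c(mae = , mse = )`. Always
#'   `mae <= sqrt(mse)`.
#' @export
mae_mse <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred)) stop("length mismatch", call. = FALSE)
  if (length(y_true) < 1) stop("need at least 1 observation", call. = FALSE)
  d <- y_true - y_pred
  c(mae = mean(abs(d)), mse = mean(d^2))
}

#' Robust accuracy at tolerance tau
#'
#' The fraction of slides whose predicted value lies within `tau` of the
#' reference, on the fraction scale: `tau = 0.1` means within 10 percentage
#' points. The band edge is inclusive (`|y - yhat| <= tau`). Non-decreasing
#' in `tau`, and exactly 1 whenever `tau >= 1` for fractions in [0, 1].
#'
#' @param y_true,y_pred Equal-length fraction vectors.
#' @param tau Tolerance, `tau > 0`.
#' @return A value in [0, 1].
#' @export
robust_accuracy <- function(y_true, y_pred, tau) {
  if (length(y_true) != length(y_pred)) stop("length mismatch", call. = FALSE)
  if (length(y_true) < 1) stop("need at least 1 observation", call. = FALSE)
  if (!is.numeric(tau) || length(tau) != 1 || tau <= 0) {
    stop("tau must be a single value > 0", call. = FALSE)
  }
  mean(abs(y_true - y_pred) <= tau)
}

concordance_counts <- function(ref_call, pred_call) {
  c(tp = sum(pred_call & ref_call), fp = sum(pred_call & !ref_call),
    fn = sum(!pred_call & ref_call), tn = sum(!pred_call & !ref_call))
}

#' Build an evaluation report for one prediction set
#'
#' Bundles the agreement metrics (R-squared, MAE, MSE, robust accuracy at
#' each tolerance) with pCR/MPR response-call concordance (predicted vs
#' reference 2x2 counts) and the underlying scatter data.
#'
#' @param y_true Reference fractions (one per slide).
#' @param y_pred Predicted fractions, aligned with `y_true`.
#' @param tolerances Robust-accuracy tolerances, ascending unique values in
#'   (0, 1]; defaults 0.1 and 0.3.
#' @param slide_id Optional slide identifiers for the scatter data.
#' @param source Label for the prediction source.
#' @return Object of class `evaluation_report` with fields `n`, `r2`, `mae`,
#'   `mse`, `racc` (named by tolerance), `concordance` (`$pcr`, `$mpr`),
#'   `warning` (non-`NA` for degenerate input), `source`, and `data`.
#' @export
evaluation_report <- function(y_true, y_pred, tolerances = c(0.1, 0.3),
                              slide_id = NULL, source = "model") {
  stopifnot(length(y_true) == length(y_pred))
  if (is.unsorted(tolerances, strictly = TRUE)) {
    stop("tolerances must be ascending and unique", call. = FALSE)
  }
  if (any(tolerances <= 0 | tolerances > 1)) {
    stop("tolerances must lie in (0, 1]", call. = FALSE)
  }
  n <- length(y_true)
  slide_id <- slide_id %||% if (n > 0) sprintf("s%03d", seq_len(n)) else character()
  warn <- NA_character_
  if (n == 0) {
    r2 <- NA_real_; err <- c(mae = NA_real_, mse = NA_real_)
    racc <- stats::setNames(rep(NA_real_, length(tolerances)),
                            format(tolerances, trim = TRUE))
    warn <- "empty prediction set: metrics undefined"
    conc <- list(pcr = concordance_counts(logical(0), logical(0)),
                 mpr = concordance_counts(logical(0), logical(0)))
  } else {
    r2 <- if (n >= 2 && stats::var(y_true) > 0) r2_score(y_true, y_pred) else {
      warn <- "R-squared undefined for constant or single reference"
      NA_real_
    }
    err <- mae_mse(y_true, y_pred)
    racc <- stats::setNames(
      vapply(tolerances, function(t) robust_accuracy(y_true, y_pred, t), numeric(1)),
      format(tolerances, trim = TRUE))
    ref <- call_response(y_true); prd <- call_response(y_pred)
    conc <- list(pcr = concordance_counts(ref$pcr, prd$pcr),
                 mpr = concordance_counts(ref$mpr, prd$mpr))
  }
  structure(list(
    n = n, r2 = r2, mae = unname(err["mae"]), mse = unname(err["mse"]),
    racc = racc, concordance = conc, warning = warn, source = source,
    data = tibble::tibble(slide_id = slide_id, y_true = y_true, y_pred = y_pred,
                          source = source)
  ), class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("<evaluation_report> source=%s n=%d\n", x$source, x$n))
  cat(sprintf("  R2 = %s  MAE = %s  MSE = %s\n",
              format(x$r2), format(x$mae), format(x$mse)))
  for (nm in names(x$racc)) cat(sprintf("  RAcc_%s = %s\n", nm, format(x$racc[[nm]])))
  if (!is.na(x$warning)) cat("  warning:", x$warning, "\n")
  invisible(x)
}

#' Tidy an evaluation report
#'
#' @param x An `evaluation_report`.
#' @param ... Unused.
#' @return One-row tibble: `source`, `n`, `r2`, `mae`, `mse`, one
#'   `racc_<tau>` column per tolerance, and pCR/MPR concordance counts
#'   (`pcr_tp` = both call pCR, `pcr_fp` = predicted-only, `pcr_fn` =
#'   reference-only, `pcr_tn` = neither; likewise `mpr_*`).
#' @export
tidy.evaluation_report <- function(x, ...) {
  row <- tibble::tibble(source = x$source, n = x$n, r2 = x$r2,
                        mae = x$mae, mse = x$mse)
  for (nm in names(x$racc)) row[[paste0("racc_", nm)]] <- x$racc[[nm]]
  for (cl in c("pcr", "mpr")) {
    for (cell in c("tp", "fp", "fn", "tn")) {
      row[[paste0(cl, "_", cell)]] <- unname(x$concordance[[cl]][cell])
    }
  }
  row
}

#' @rdname tidy.evaluation_report
#' @export
glance.evaluation_report <- function(x, ...) tidy.evaluation_report(x)

#' Write / read an evaluation report as JSON
#'
#' The round trip is lossless: numbers are serialized at full precision and
#' `racc` keys are the tolerance values as strings (e.g. `"0.1"`, `"0.3"`).
#' A degenerate report (n = 0 or constant reference) carries `null` metrics
#' plus a `warning` field.
#'
#' @param report An `evaluation_report`.
#' @param path JSON file path.
#' @return `path` (write) / the restored `evaluation_report` (read).
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "evaluation_report"))
  obj <- list(
    n = report$n, r2 = report$r2, mae = report$mae, mse = report$mse,
    racc = as.list(report$racc),
    concordance = lapply(report$concordance, as.list),
    warning = report$warning, source = report$source,
    data = report$data
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, na = "null",
                       null = "null")
  invisible(path)
}

#' @rdname write_report
#' @export
read_report <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  as_counts <- function(l) vapply(c("tp", "fp", "fn", "tn"),
                                  function(k) as.integer(l[[k]]), integer(1))
  structure(list(
    n = as.integer(obj$n),
    r2 = if (is.null(obj$r2)) NA_real_ else as.numeric(obj$r2),
    mae = if (is.null(obj$mae)) NA_real_ else as.numeric(obj$mae),
    mse = if (is.null(obj$mse)) NA_real_ else as.numeric(obj$mse),
    racc = unlist(lapply(obj$racc, function(v) if (is.null(v)) NA_real_ else as.numeric(v))) %||%
      stats::setNames(numeric(0), character(0)),
    concordance = list(pcr = as_counts(obj$concordance$pcr),
                       mpr = as_counts(obj$concordance$mpr)),
    warning = if (is.null(obj$warning)) NA_character_ else as.character(obj$warning),
    source = obj$source,
    data = tibble::as_tibble(obj$data)
  ), class = "evaluation_report")
}

#' Compare prediction sources against a reference
#'
#' The observer-comparison report: every prediction set (model, individual
#' pathologists, ...) is scored against the same reference labels with the
#' full metric suite plus response-call concordance, one row per source, and
#' the aligned scatter data is kept for plotting.
#'
#' @param reference Tibble with `slide_id` and `fraction` (the consensus
#'   reference).
#' @param predictions Tibble with `slide_id`, `source`, `fraction`; one or
#'   more sources, each covering exactly the reference slides.
#' @param tolerances Robust-accuracy tolerances.
#' @return Object of class `observer_report`: `table` (one tidy row per
#'   source) and `data` (scatter rows). `tidy()` returns the table;
#'   `autoplot()` draws predicted-vs-reference scatter panels.
#' @export
observer_report <- function(reference, predictions, tolerances = c(0.1, 0.3)) {
  stopifnot(all(c("slide_id", "fraction") %in% names(reference)),
            all(c("slide_id", "source", "fraction") %in% names(predictions)))
  reports <- lapply(split(predictions, predictions$source), function(p) {
    extra <- setdiff(p$slide_id, reference$slide_id)
    missing <- setdiff(reference$slide_id, p$slide_id)
    if (length(extra) > 0 || length(missing) > 0) {
      stop(sprintf("slide_id mismatch for source '%s': missing [%s], unexpected [%s]",
                   p$source[1], paste(missing, collapse = ", "),
                   paste(extra, collapse = ", ")), call. = FALSE)
    }
    yp <- p$fraction[match(reference$slide_id, p$slide_id)]
    evaluation_report(reference$fraction, yp, tolerances = tolerances,
                      slide_id = reference$slide_id, source = p$source[1])
  })
  structure(list(
    table = dplyr::bind_rows(lapply(reports, tidy.evaluation_report)),
    data = dplyr::bind_rows(lapply(reports, function(r) r$data)),
    reports = reports
  ), class = "observer_report")
}

#' @export
print.observer_report <- function(x, ...) {
  cat("<observer_report>\n")
  print(x$table)
  invisible(x)
}

#' @rdname observer_report
#' @param x An `observer_report`.
#' @param ... Unused.
#' @export
tidy.observer_report <- function(x, ...) x$table

#' Scatter panels of predicted vs reference fractions
#'
#' @param object An `observer_report`.
#' @param ... Unused.
#' @return A ggplot object, one panel per source, identity line dashed.
#' @export
autoplot.observer_report <- function(object, ...) {
  ggplot2::ggplot(object$data,
                  ggplot2::aes(x = .data$y_true, y = .data$y_pred)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey50") +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::facet_wrap(~source) +
    ggplot2::coord_equal(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(x = "reference viable tumor fraction",
                  y = "predicted viable tumor fraction") +
    ggplot2::theme_minimal()
}

#' Write an observer report as CSV + JSON
#'
#' @param x An `observer_report`.
#' @param stem Output path stem; writes `<stem>.csv` (the per-source table)
#'   and `<stem>.json` (table plus scatter data).
#' @return Invisibly, the written paths.
#' @export
write_observer_report <- function(x, stem) {
  stopifnot(inherits(x, "observer_report"))
  csv <- paste0(stem, ".csv"); json <- paste0(stem, ".json")
  readr::write_csv(x$table, csv, progress = FALSE)
  jsonlite::write_json(list(table = x$table, data = x$data), json,
                       auto_unbox = TRUE, digits = NA, na = "null")
  invisible(list(csv = csv, json = json))
}
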