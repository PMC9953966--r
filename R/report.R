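new_eval_report <- function(per_rep, model_name, task, positive, n, seed,
                            fitted = NULL, holdout_scores = NULL) {
  summary <- per_rep |>
    dplyr::group_by(.data$dataset) |>
    dplyr::summarise(
      accuracy_mean = mean(.data$accuracy), accuracy_sd = sd(.data$accuracy),
      sensitivity_mean = mean(.data$sensitivity),
      sensitivity_sd = sd(.data$sensitivity),
      specificity_mean = mean(.data$specificity),
      specificity_sd = sd(.data$specificity),
      auc_median = median(.data$auc),
      auc_q25 = quantile(.data$auc, 0.25, names = FALSE),
      auc_q75 = quantile(.data$auc, 0.75, names = FALSE),
      .groups = "drop"
    )
  structure(list(
    model = model_name, task = task, positive = positive,
    per_rep = per_rep, summary = summary, n = n, seed = seed,
    fitted = fitted, holdout_scores = holdout_scores
  ), class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> model '%s', task %s vs %s (positive: %s)\n",
              x$model, x$task[1], x$task[2], x$positive))
  cat(sprintf("  subjects: %s\n",
              paste(names(x$n), as.integer(x$n), sep = "=", collapse = ", ")))
  s <- x$summary
  for (i in seq_len(nrow(s))) {
    cat(sprintf(
      "  %-10s accuracy %5.1f +/- %4.1f%%  sens %5.1f%%  spec %5.1f%%  AUC %0.3f (%0.3f-%0.3f)\n",
      s$dataset[i], 100 * s$accuracy_mean[i], 100 * s$accuracy_sd[i],
      100 * s$sensitivity_mean[i], 100 * s$specificity_mean[i],
      s$auc_median[i], s$auc_q25[i], s$auc_q75[i]))
  }
  invisible(x)
}

#' Per-repetition metrics of an evaluation report
#'
#' @param x An `eval_report`.
#' @param ... Unused.
#' @return Tibble with one row per (dataset, repetition): accuracy,
#'   sensitivity, specificity, AUC.
#' @export
tidy.eval_report <- function(x, ...) {
  dplyr::mutate(x$per_rep, model = x$model, .before = 1)
}

#' One-row summary of an evaluation report
#'
#' Mean +/- SD accuracy/sensitivity/specificity and median (IQR) AUC per
#' dataset, flattened into a single row with `cv_` / `validation_` / `test_`
#' prefixes.
#'
#' @param x An `eval_report`.
#' @param ... Unused.
#' @return A one-row tibble.
#' @export
glance.eval_report <- function(x, ...) {
  long <- tidyr::pivot_longer(x$summary, -"dataset")
  wide <- tidyr::pivot_wider(
    long, names_from = c("dataset", "name"), values_from = "value",
    names_glue = "{dataset}_{name}")
  dplyr::bind_cols(tibble::tibble(model = x$model,
                                  task = paste(x$task, collapse = "_vs_")),
                   wide)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Summary table across several evaluation reports
#'
#' @param ... `eval_report` objects (or one list of them).
#' @return Tibble mirroring the classic results-table layout: one row per
#'   model and dataset with accuracy/sensitivity/specificity mean +/- SD and
#'   AUC median (IQR).
#' @export
report_table <- function(...) {
  reports <- list(...)
  if (length(reports) == 1 && !inherits(reports[[1]], "eval_report")) {
    reports <- reports[[1]]
  }
  dplyr::bind_rows(purrr::map(reports, function(r) {
    dplyr::mutate(r$summary, model = r$model,
                  task = paste(r$task, collapse = "_vs_"), .before = 1)
  }))
}

#' Box plots of per-repetition metrics
#'
#' @param object An `eval_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.eval_report <- function(object, ...) {
  df <- tidyr::pivot_longer(object$per_rep,
                            c("accuracy", "sensitivity", "specificity",
                              "auc"),
                            names_to = "metric")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$dataset, y = .data$value)) +
    ggplot2::geom_boxplot(outlier.size = 0.5) +
    ggplot2::facet_wrap(~metric) +
    ggplot2::labs(
      title = sprintf("%s: %s vs %s", object$model, object$task[1],
                      object$task[2]),
      x = NULL, y = NULL
    ) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' ROC curve points for a holdout set
#'
#' Computes the ROC polyline of each repetition's averaged decision values on
#' the requested holdout set.
#'
#' @param report An `eval_report` with holdout scores.
#' @param dataset `"validation"` (default) or `"test"`.
#' @return Tibble `rep`, `fpr`, `tpr`.
#' @export
roc_points <- function(report, dataset = "validation") {
  hs <- report$holdout_scores[[dataset]]
  if (is.null(hs)) stop("no scores stored for dataset ", dataset,
                        call. = FALSE)
  pos <- report$positive
  dplyr::bind_rows(purrr::map(seq_len(ncol(hs$scores)), function(i) {
    s <- hs$scores[, i]
    ord <- order(s, decreasing = TRUE)
    is_pos <- hs$labels[ord] == pos
    tibble::tibble(
      rep = i,
      fpr = c(0, cumsum(!is_pos) / sum(!is_pos)),
      tpr = c(0, cumsum(is_pos) / sum(is_pos))
    )
  }))
}

#' Plot per-repetition ROC curves of one or more models
#'
#' @param ... Named `eval_report` objects.
#' @param dataset Holdout set to plot (default `"validation"`).
#' @return A ggplot object.
#' @export
plot_roc <- function(..., dataset = "validation") {
  reports <- list(...)
  if (is.null(names(reports)) || any(names(reports) == "")) {
    names(reports) <- vapply(reports, function(r) r$model, character(1))
  }
  df <- dplyr::bind_rows(purrr::imap(reports, function(r, nm) {
    dplyr::mutate(roc_points(r, dataset), model = nm)
  }))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$fpr, y = .data$tpr,
                                   group = interaction(.data$model,
                                                       .data$rep),
                                   colour = .data$model)) +
    ggplot2::geom_step(alpha = 0.15) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey50") +
    ggplot2::labs(x = "False positive rate", y = "True positive rate") +
    ggplot2::theme_minimal()
}

#' Write an evaluation report to disk
#'
#' JSON summary + per-repetition CSV.
#'
#' @param report An `eval_report`.
#' @param stem Output path stem (writes `<stem>.json`, `<stem>_reps.csv`).
#' @return `stem`, invisibly.
#' @export
write_eval_report <- function(report, stem) {
  jsonlite::write_json(
    list(model = report$model, task = report$task,
         positive = report$positive, seed = report$seed,
         n = as.list(setNames(as.integer(report$n), names(report$n))),
         summary = report$summary),
    paste0(stem, ".json"), auto_unbox = TRUE, pretty = TRUE, digits = NA)
  readr::write_csv(report$per_rep, paste0(stem, "_reps.csv"))
  invisible(stem)
}
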