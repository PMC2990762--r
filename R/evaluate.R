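#' One-vs-rest confusion counts for a compartment
#'
#' For a compartment c, a protein is a true positive when c is both called
#' and true, a false positive when called but not true, a false negative when
#' true but not called, and a true negative otherwise. Tie calls contribute
#' each called compartment. Proteins without usable Pfam data (status
#' `no_pfam` / `no_data`) are excluded from the tally by default and reported
#' as coverage; set `include_uncovered = TRUE` to count them as all-negative
#' calls.
#'
#' @param calls Tibble from [predict_localization()] (needs `protein_id`,
#'   `compartments`, `status`).
#' @param truth Tibble (`protein_id`, `compartment`): multi-label ground
#'   truth, one row per true membership.
#' @param compartment Compartment name to tally.
#' @param include_uncovered Count proteins without Pfam data as negative
#'   calls instead of excluding them (default FALSE).
#' @return A one-row tibble: `compartment`, `tp`, `fp`, `tn`, `fn`,
#'   `n_evaluated`, `n_uncovered`.
#' @export
confusion_counts <- function(calls, truth, compartment, include_uncovered = FALSE) {
  missing <- setdiff(calls$protein_id, truth$protein_id)
  if (length(missing) > 0) {
    abort(paste0("proteins absent from truth table: ",
                 paste(head(missing, 5), collapse = ", "),
                 if (length(missing) > 5) ", ..."))
  }
  uncovered <- calls$status %in% c("no_pfam", "no_data")
  n_uncovered <- sum(uncovered)
  if (!include_uncovered) calls <- calls[!uncovered, ]
  true_set <- unique(truth$protein_id[truth$compartment == compartment])
  called <- vapply(calls$compartments, function(x) compartment %in% x, logical(1))
  is_true <- calls$protein_id %in% true_set
  tibble(
    compartment = compartment,
    tp = sum(called & is_true),
    fp = sum(called & !is_true),
    tn = sum(!called & !is_true),
    fn = sum(!called & is_true),
    n_evaluated = nrow(calls),
    n_uncovered = n_uncovered
  )
}

#' Sensitivity and specificity from confusion counts
#'
#' Sensitivity = tp / (tp + fn); specificity = tn / (tn + fp). A zero
#' denominator yields `NA` (undefined), never a silent 0.
#'
#' @param counts Tibble of confusion counts (columns `tp`, `fp`, `tn`, `fn`;
#'   one or more rows).
#' @return `counts` with `sensitivity` and `specificity` columns appended.
#' @export
performance_metrics <- function(counts) {
  dplyr::mutate(
    counts,
    sensitivity = ifelse(.data$tp + .data$fn > 0, .data$tp / (.data$tp + .data$fn), NA_real_),
    specificity = ifelse(.data$tn + .data$fp > 0, .data$tn / (.data$tn + .data$fp), NA_real_)
  )
}

#' Per-compartment performance report
#'
#' One-vs-rest sensitivity and specificity across compartments, in the
#' layout of a compartment-by-metric benchmark table. By default the ten
#' reporting compartments are used (cell plate excluded).
#'
#' @inheritParams confusion_counts
#' @param compartments Compartments to report (default
#'   [reporting_compartments()]).
#' @param label Predictor label recorded in the report (default "pfam").
#' @return A tibble with one row per compartment: counts plus `sensitivity`,
#'   `specificity` and `predictor`.
#' @export
performance_report <- function(calls, truth,
                               compartments = reporting_compartments(),
                               include_uncovered = FALSE, label = "pfam") {
  purrr::map_dfr(compartments, function(cmp) {
    confusion_counts(calls, truth, cmp, include_uncovered = include_uncovered)
  }) %>%
    performance_metrics() %>%
    dplyr::mutate(predictor = label)
}

#' Threshold-swept ROC curve for one compartment
#'
#' At each threshold t on the grid \{0, step, 2*step, ..., 1\} a protein is
#' called for compartment c iff its score for c is at least t *and* c is
#' among the protein's (tied) top-scoring compartments. The true- and
#' false-positive rates are tallied one-vs-rest at each threshold; the area
#' under the curve is computed by the trapezoid rule on the (FPR, TPR)
#' points sorted by FPR.
#'
#' @param scored Long score tibble (`protein_id`, `compartment`, `score`)
#'   from [score_proteins()].
#' @param truth Tibble (`protein_id`, `compartment`) ground truth.
#' @param compartment Compartment to sweep.
#' @param step Threshold grid spacing in (0, 1\] (default 0.01).
#' @param tie_tolerance Tolerance for the argmax tie test (default 1e-9).
#' @return A `pfantom_roc` tibble (`threshold`, `tpr`, `fpr`) with
#'   attributes `auc` and `compartment`. TPR and FPR are non-increasing in
#'   the threshold.
#' @export
roc_sweep <- function(scored, truth, compartment, step = 0.01, tie_tolerance = 1e-9) {
  if (step <= 0 || step > 1) abort("step must be in (0, 1]")
  per_protein <- scored %>%
    dplyr::group_by(.data$protein_id) %>%
    dplyr::summarise(
      top = max(.data$score),
      score = .data$score[.data$compartment == !!compartment][1],
      .groups = "drop"
    ) %>%
    dplyr::mutate(is_argmax = .data$top - .data$score <= tie_tolerance)
  true_set <- unique(truth$protein_id[truth$compartment == compartment])
  is_true <- per_protein$protein_id %in% true_set
  n_pos <- sum(is_true)
  n_neg <- sum(!is_true)
  thresholds <- seq(0, 1, by = step)
  if (thresholds[length(thresholds)] < 1) thresholds <- c(thresholds, 1)
  pts <- purrr::map_dfr(thresholds, function(t) {
    called <- per_protein$is_argmax & per_protein$score >= t
    tibble(
      threshold = t,
      tpr = if (n_pos > 0) sum(called & is_true) / n_pos else NA_real_,
      fpr = if (n_neg > 0) sum(called & !is_true) / n_neg else NA_real_
    )
  })
  auc <- trapezoid_auc(pts$fpr, pts$tpr)
  structure(pts, class = c("pfantom_roc", class(tibble())),
            auc = auc, compartment = compartment)
}

# Trapezoid-rule AUC on (fpr, tpr) points, anchored at (0,0) and (1,1).
trapezoid_auc <- function(fpr, tpr) {
  ok <- !is.na(fpr) & !is.na(tpr)
  x <- c(0, fpr[ok], 1)
  y <- c(0, tpr[ok], 1)
  o <- order(x, y)
  x <- x[o]; y <- y[o]
  sum(diff(x) * (head(y, -1) + y[-1]) / 2)
}

#' @exportS3Method
glance.pfantom_roc <- function(x, ...) {
  tibble(compartment = attr(x, "compartment"), auc = attr(x, "auc"),
         n_thresholds = nrow(x))
}

#' Plot an ROC curve
#'
#' @param object A `pfantom_roc` from [roc_sweep()].
#' @param ... Unused.
#' @return A ggplot: TPR against FPR with the chance diagonal dotted.
#' @exportS3Method
autoplot.pfantom_roc <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object), ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dotted", colour = "grey50") +
    ggplot2::geom_path() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::coord_equal(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(
      x = "False positive rate", y = "True positive rate",
      title = paste0(attr(object, "compartment"),
                     " (AUC = ", formatC(attr(object, "auc"), format = "f", digits = 3), ")")
    ) +
    ggplot2::theme_minimal()
}

#' Plot a per-compartment performance report
#'
#' @param report Tibble from [performance_report()].
#' @return A ggplot bar chart of sensitivity and specificity per compartment.
#' @export
plot_performance <- function(report) {
  long <- tidyr::pivot_longer(report, c("sensitivity", "specificity"),
                              names_to = "metric", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$compartment, y = .data$value,
                                     fill = .data$metric)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = NULL, y = "Fraction", fill = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
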