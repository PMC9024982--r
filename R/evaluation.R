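# Evaluation: accuracy at a threshold, ROC/AUC, per-case tables and
# genuine/imposter score summaries.

# Pairwise (Mann-Whitney) AUC: P(score_pos > score_neg) + 0.5 P(tie),
# computed from ranks so it is exact for ties.
auc_pairwise <- function(scores, labels) {
  pos <- labels == 1
  n1 <- sum(pos)
  n0 <- sum(!pos)
  r <- rank(scores, ties.method = "average")
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Trapezoidal area under the ROC curve, from first principles.
auc_trapezoid <- function(scores, labels) {
  roc <- roc_points(scores, labels)
  sum(diff(roc$fpr) * (head(roc$tpr, -1) + tail(roc$tpr, -1)) / 2)
}

#' ROC curve points
#'
#' @param scores Numeric scores (higher = more likely real/positive).
#' @param labels Binary labels (1 = positive).
#' @return A tibble (`threshold`, `fpr`, `tpr`) ordered from (0, 0) to
#'   (1, 1).
#' @export
roc_points <- function(scores, labels) {
  ord <- order(scores, decreasing = TRUE)
  lab <- labels[ord] == 1
  sc <- scores[ord]
  tp <- cumsum(lab)
  fp <- cumsum(!lab)
  keep <- c(sc[-1] != sc[-length(sc)], TRUE)  # last point per threshold
  tibble(
    threshold = c(Inf, sc[keep]),
    fpr = c(0, fp[keep] / max(1, sum(!lab))),
    tpr = c(0, tp[keep] / max(1, sum(lab)))
  )
}

#' Evaluate predictions: accuracy, AUC, per-case table
#'
#' Accuracy is the fraction of correct decisions at threshold `tau` (ties
#' count as positive: `decision = score >= tau`), reported in percent. AUC is
#' the probability that a random positive outscores a random negative (ties
#' counted half), identical to the trapezoidal area under the ROC curve. When
#' `attack_kind`/`profile` columns are present, a per-case accuracy table
#' (class x device profile) is included.
#'
#' @param predictions Tibble with columns `score` and `label` (1 = real);
#'   optional `attack_kind`, `profile`.
#' @param tau Decision threshold (default 0.5).
#' @return A list of class `eval_report`: `accuracy` (%), `auc`, `n`,
#'   `confusion` tibble, `per_case` tibble (or NULL), `scores` tibble,
#'   `tau`.
#' @export
evaluate_predictions <- function(predictions, tau = 0.5) {
  stopifnot(all(c("score", "label") %in% names(predictions)))
  sc <- predictions$score
  y <- predictions$label
  if (length(sc) == 0) stop_pg("No predictions to evaluate.", "pg_data_error")
  dec <- sc >= tau
  accuracy <- 100 * mean(dec == (y == 1))
  if (length(unique(y)) < 2) {
    warn("AUC undefined for single-class input; reporting accuracy only.")
    auc <- NA_real_
  } else {
    auc <- auc_pairwise(sc, y)
  }
  confusion <- tibble(
    truth = rep(c("real", "attack"), each = 2),
    decision = rep(c("real", "attack"), 2),
    n = c(sum(y == 1 & dec), sum(y == 1 & !dec),
          sum(y == 0 & dec), sum(y == 0 & !dec))
  )
  per_case <- NULL
  if (all(c("attack_kind", "profile") %in% names(predictions))) {
    per_case <- predictions |>
      mutate(correct = (.data$score >= tau) == (.data$label == 1)) |>
      group_by(.data$attack_kind, .data$profile) |>
      summarise(n = n(), accuracy = 100 * mean(.data$correct),
                .groups = "drop")
  }
  structure(list(
    accuracy = accuracy, auc = auc, n = length(sc), tau = tau,
    confusion = confusion, per_case = per_case,
    scores = tibble(score = sc, label = y)
  ), class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> n=%d  accuracy=%.4f%%  AUC=%s  (tau=%g)\n",
              x$n, x$accuracy,
              if (is.na(x$auc)) "NA" else sprintf("%.6f", x$auc), x$tau), ...)
  if (!is.null(x$per_case)) print(x$per_case)
  invisible(x)
}

#' @rdname evaluate_predictions
#' @param x An `eval_report`.
#' @param ... Unused.
#' @export
tidy.eval_report <- function(x, ...) {
  if (is.null(x$per_case)) x$confusion else x$per_case
}

#' @rdname evaluate_predictions
#' @export
glance.eval_report <- function(x, ...) {
  tibble(n = x$n, accuracy = x$accuracy, auc = x$auc, tau = x$tau)
}

#' @rdname evaluate_predictions
#' @param object An `eval_report`.
#' @export
autoplot.eval_report <- function(object, ...) {
  roc <- roc_points(object$scores$score, object$scores$label)
  ggplot2::ggplot(roc, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         color = "grey60") +
    ggplot2::geom_step(linewidth = 0.8, color = "#2166ac") +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "False positive rate", y = "True positive rate",
      title = sprintf("ROC (AUC = %.4f)", object$auc)
    ) +
    ggplot2::theme_minimal()
}

#' Genuine/imposter score histogram
#'
#' @param report An `eval_report`.
#' @param bins Histogram bins.
#' @return A ggplot object.
#' @export
plot_score_histogram <- function(report, bins = 30) {
  d <- mutate(report$scores,
              class = ifelse(.data$label == 1, "genuine", "imposter"))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$score, fill = .data$class)) +
    ggplot2::geom_histogram(bins = bins, alpha = 0.6,
                            position = "identity") +
    ggplot2::geom_vline(xintercept = report$tau, linetype = "dashed") +
    ggplot2::scale_fill_manual(values = c(genuine = "#2166ac",
                                          imposter = "#b2182b")) +
    ggplot2::labs(x = "Classifier score", y = "Clips", fill = NULL) +
    ggplot2::theme_minimal()
}
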