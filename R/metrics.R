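check_pred_truth <- function(predictions, truths, labels) {
  if (length(predictions) != length(truths)) {
    stop(sprintf("%d predictions but %d truths", length(predictions),
                 length(truths)), call. = FALSE)
  }
  if (length(predictions) == 0L) stop("no cases to evaluate", call. = FALSE)
  bad <- !truths %in% as.character(labels)
  if (any(bad)) {
    stop("truth label(s) outside the label set: ",
         paste(unique(truths[bad]), collapse = ", "), call. = FALSE)
  }
  invisible(TRUE)
}

# 1-based rank of the true label in the descending sort, ties by label order.
true_rank <- function(p, truth, labels) {
  match(truth, rank_classes(validate_prob_vector(p, labels), labels))
}

#' Top-k accuracy
#'
#' Fraction of cases whose true label appears among the `k` highest
#' probability classes of the prediction (deterministic tie-break by label
#' order). Non-decreasing in `k`; equals 1 when `k` covers the label set.
#'
#' @param predictions List of probability vectors.
#' @param truths Character vector of true labels, same length.
#' @param k Positive integer, at most the number of classes.
#' @inheritParams validate_prob_vector
#' @return A proportion in `[0, 1]`.
#' @export
top_k_accuracy <- function(predictions, truths, k = 1L,
                           labels = retinal_labels()) {
  check_pred_truth(predictions, truths, labels)
  if (k < 1L || k > length(labels)) {
    stop(sprintf("k must lie in 1..%d", length(labels)), call. = FALSE)
  }
  ranks <- mapply(true_rank, predictions, truths,
                  MoreArgs = list(labels = labels))
  mean(ranks <= k)
}

#' Mean reciprocal rank
#'
#' Average of `1/rank(true)` over cases, ranks 1-based in the descending
#' sort (ties by label order), so MRR lies in `(0, 1]` and is bounded below
#' by top-1 accuracy.
#'
#' @inheritParams top_k_accuracy
#' @return MRR in `(0, 1]`.
#' @export
mean_reciprocal_rank <- function(predictions, truths,
                                 labels = retinal_labels()) {
  check_pred_truth(predictions, truths, labels)
  ranks <- mapply(true_rank, predictions, truths,
                  MoreArgs = list(labels = labels))
  mean(1 / ranks)
}

#' Expected calibration error
#'
#' A case's confidence is its top-1 predicted probability. Cases are
#' assigned to `M` equal-width bins over `[0, 1]` — half-open
#' `[m/M, (m+1)/M)` with the last bin closed — and the bin-weighted absolute
#' gaps between empirical top-1 accuracy and mean confidence are summed:
#' \deqn{ECE = \sum_m \frac{|B_m|}{N} \left| acc(B_m) - conf(B_m) \right|.}
#' Empty bins contribute 0.
#'
#' @inheritParams top_k_accuracy
#' @param bins Number of bins `M` (default 10).
#' @return ECE in `[0, 1]`; lower is better.
#' @export
expected_calibration_error <- function(predictions, truths, bins = 10L,
                                       labels = retinal_labels()) {
  check_pred_truth(predictions, truths, labels)
  if (bins < 1L) stop("bins must be >= 1", call. = FALSE)
  conf <- vapply(predictions, function(p) {
    max(validate_prob_vector(p, labels))
  }, numeric(1))
  correct <- vapply(seq_along(predictions), function(i) {
    argmax_label(predictions[[i]], labels) == truths[[i]]
  }, logical(1))
  bin <- pmin(floor(conf * bins), bins - 1L) + 1L   # last bin closed at 1
  n <- length(conf)
  ece <- 0
  for (b in unique(bin)) {
    in_b <- bin == b
    ece <- ece + sum(in_b) / n * abs(mean(correct[in_b]) - mean(conf[in_b]))
  }
  ece
}

#' Multiclass Brier score
#'
#' Mean over cases of the full-vector squared error between the predicted
#' distribution and the one-hot truth,
#' \eqn{\frac{1}{N}\sum_i \sum_c (\hat p_{i,c} - 1\{y_i = c\})^2}
#' — the literal multiclass form without the halving convention, so its
#' algebraic range is `[0, 2]`. Lower is better.
#'
#' @inheritParams top_k_accuracy
#' @return Brier score in `[0, 2]`.
#' @export
brier_score <- function(predictions, truths, labels = retinal_labels()) {
  check_pred_truth(predictions, truths, labels)
  per_case <- vapply(seq_along(predictions), function(i) {
    p <- validate_prob_vector(predictions[[i]], labels)
    onehot <- as.numeric(as.character(labels) == truths[[i]])
    sum((p - onehot)^2)
  }, numeric(1))
  mean(per_case)
}

#' Evaluation configuration
#'
#' @param k_values Integer vector of `k` for top-k accuracy (default
#'   `c(1, 3)`).
#' @param ece_bins Number of ECE bins (default 10).
#' @return A list of class `evaluation_config`.
#' @export
evaluation_config <- function(k_values = c(1L, 3L), ece_bins = 10L) {
  if (any(k_values < 1L)) stop("k values must be positive", call. = FALSE)
  if (ece_bins < 1L) stop("ece_bins must be >= 1", call. = FALSE)
  structure(list(k_values = as.integer(k_values),
                 ece_bins = as.integer(ece_bins)),
            class = "evaluation_config")
}

#' Evaluate one method's predictions with the full metric suite
#'
#' @inheritParams top_k_accuracy
#' @param cfg An [evaluation_config()].
#' @return A list with `top_k` (named by k), `mrr`, `ece`, `brier`, `n`.
#' @export
evaluate_predictions <- function(predictions, truths,
                                 cfg = evaluation_config(),
                                 labels = retinal_labels()) {
  check_pred_truth(predictions, truths, labels)
  if (any(cfg$k_values > length(labels))) {
    stop("k values cannot exceed the number of classes", call. = FALSE)
  }
  top_k <- vapply(cfg$k_values, function(k) {
    top_k_accuracy(predictions, truths, k, labels)
  }, numeric(1))
  list(top_k = stats::setNames(top_k, paste0("top_", cfg$k_values)),
       mrr = mean_reciprocal_rank(predictions, truths, labels),
       ece = expected_calibration_error(predictions, truths, cfg$ece_bins,
                                        labels),
       brier = brier_score(predictions, truths, labels),
       n = length(predictions))
}
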