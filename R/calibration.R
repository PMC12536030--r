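#' Seeded split configuration
#'
#' The corpus is partitioned once, under a fixed seed, into a small
#' calibration subset (used solely to estimate submodel reliability), a
#' development portion, and a held-out test set. With the defaults on a
#' 200-case corpus this yields 20 / 120 / 60 cases.
#'
#' @param seed Integer seed for the shuffle.
#' @param calibration_size Number of calibration cases (default 20, the
#'   reliability-estimation budget).
#' @param test_fraction Fraction of all cases held out for testing, in
#'   (0, 1); default 0.3.
#' @return A list of class `split_config`.
#' @export
split_config <- function(seed = 1L, calibration_size = 20L,
                         test_fraction = 0.3) {
  if (calibration_size < 1L) stop("calibration_size must be positive",
                                  call. = FALSE)
  if (!is.numeric(test_fraction) || test_fraction <= 0 || test_fraction >= 1) {
    stop("test_fraction must lie strictly between 0 and 1", call. = FALSE)
  }
  structure(list(seed = as.integer(seed),
                 calibration_size = as.integer(calibration_size),
                 test_fraction = test_fraction),
            class = "split_config")
}

#' Partition labeled cases into calibration / development / test
#'
#' Uniform seeded shuffle (no stratification; class counts in the intended
#' corpora are moderately balanced, so stratification is left to the caller).
#' Partitions are disjoint, exhaustive, and byte-identical across runs with
#' the same seed. Unlabeled cases are rejected: every partition feeds either
#' reliability estimation or accuracy measurement, both of which need truth.
#'
#' @param cases List of labeled [case_record()]s.
#' @param cfg A [split_config()].
#' @return A list of class `dataset_split` with elements `calibration`,
#'   `development`, `test` (lists of case records), and the `config`.
#' @export
split_dataset <- function(cases, cfg = split_config()) {
  n <- length(cases)
  unlabeled <- vapply(cases, function(x) is.null(x$label), logical(1))
  if (any(unlabeled)) {
    stop("unlabeled case(s): ",
         paste(vapply(cases[unlabeled], `[[`, character(1), "case_id"),
               collapse = ", "), call. = FALSE)
  }
  n_test <- floor(cfg$test_fraction * n)
  if (cfg$calibration_size + n_test >= n) {
    stop(sprintf("cannot draw %d calibration + %d test cases from %d total",
                 cfg$calibration_size, n_test, n), call. = FALSE)
  }
  perm <- with_seed(cfg$seed, sample.int(n))
  cal_idx <- perm[seq_len(cfg$calibration_size)]
  test_idx <- perm[seq.int(n - n_test + 1L, n)]
  dev_idx <- perm[seq.int(cfg$calibration_size + 1L, n - n_test)]
  structure(list(calibration = cases[cal_idx],
                 development = cases[dev_idx],
                 test = cases[test_idx],
                 config = cfg),
            class = "dataset_split")
}

#' Reliability profile constructor
#'
#' Per-submodel reliability `alpha` — the top-1 match rate on the calibration
#' subset — plus the provenance needed to audit it.
#'
#' @param alpha Named numeric vector in `[0, 1]`, one entry per submodel.
#' @param n_calibration Number of calibration cases the rates were computed
#'   on.
#' @param seed Optional split seed, recorded for provenance.
#' @return A list of class `reliability_profile`.
#' @export
reliability_profile <- function(alpha, n_calibration, seed = NA_integer_) {
  if (!is.numeric(alpha) || is.null(names(alpha)) ||
      any(alpha < 0 | alpha > 1)) {
    stop("alpha must be a named numeric vector with values in [0, 1]",
         call. = FALSE)
  }
  structure(list(alpha = alpha, n_calibration = as.integer(n_calibration),
                 seed = seed),
            class = "reliability_profile")
}

#' @export
print.reliability_profile <- function(x, ...) {
  cat(sprintf("<reliability_profile: %d submodel(s), n_calibration = %d>\n",
              length(x$alpha), x$n_calibration))
  print(round(x$alpha, 4))
  invisible(x)
}

#' Estimate per-submodel reliability on the calibration subset
#'
#' `alpha_i` is the fraction of calibration cases on which submodel `i`'s
#' most probable class (deterministic argmax, ties to label order) equals the
#' true label. Every submodel must have exactly one output per calibration
#' case — a missing output is an error naming the submodel and case, never a
#' silent imputation. When `calibration_ids` is supplied, outputs for any
#' other case are rejected, enforcing that reliability is never computed on
#' development or test cases.
#'
#' @param outputs List of [submodel_output()] records covering the
#'   calibration cases (possibly several submodels).
#' @param truths Named character vector mapping case_id to true label.
#' @param calibration_ids Optional character vector of the calibration
#'   case_ids; defaults to `names(truths)`.
#' @param seed Recorded in the profile for provenance.
#' @inheritParams validate_prob_vector
#' @return A [reliability_profile()].
#' @export
estimate_reliability <- function(outputs, truths, calibration_ids = NULL,
                                 seed = NA_integer_,
                                 labels = retinal_labels()) {
  calibration_ids <- calibration_ids %||% names(truths)
  if (is.null(names(truths)) || !all(calibration_ids %in% names(truths))) {
    stop("truths must be named by case_id and cover the calibration cases",
         call. = FALSE)
  }
  out_cases <- vapply(outputs, `[[`, character(1), "case_id")
  stray <- setdiff(out_cases, calibration_ids)
  if (length(stray) > 0L) {
    stop("outputs include non-calibration case(s): ",
         paste(utils::head(stray, 5L), collapse = ", "),
         " - reliability must be estimated on the calibration split only",
         call. = FALSE)
  }
  ids <- vapply(outputs, `[[`, character(1), "submodel_id")
  n_cal <- length(calibration_ids)
  alpha <- vapply(split(seq_along(outputs), ids), function(idx) {
    have <- out_cases[idx]
    miss <- setdiff(calibration_ids, have)
    if (length(miss) > 0L) {
      stop(sprintf("submodel '%s' has no output for calibration case(s): %s",
                   ids[idx[1L]], paste(utils::head(miss, 5L), collapse = ", ")),
           call. = FALSE)
    }
    if (anyDuplicated(have)) {
      stop(sprintf("submodel '%s' has duplicate outputs for a calibration case",
                   ids[idx[1L]]), call. = FALSE)
    }
    hits <- vapply(idx, function(j) {
      argmax_label(outputs[[j]]$probs, labels) ==
        truths[[outputs[[j]]$case_id]]
    }, logical(1))
    sum(hits) / n_cal
  }, numeric(1))
  reliability_profile(alpha, n_calibration = n_cal, seed = seed)
}
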