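#' Pseudo-loss confidence configuration
#'
#' The ensemble elicits one free-text response per disease candidate and
#' treats the response length as a loss surrogate: shorter, more decisive
#' responses score higher. `pseudo_loss = length / length_divisor` and
#' `confidence = 1 / (pseudo_loss + epsilon)`.
#'
#' @param epsilon Small positive guard so zero-length responses remain
#'   finite. Default `1e-9`: small enough not to distort any realistic
#'   length, large enough to keep an empty reply legal.
#' @param length_divisor Positive scale applied to raw lengths; default 10.
#' @param length_unit `"characters"` (default, raw string length) or
#'   `"tokens"`; recorded for provenance, not used in arithmetic.
#' @return A list of class `confidence_config`.
#' @export
confidence_config <- function(epsilon = 1e-9, length_divisor = 10.0,
                              length_unit = c("characters", "tokens")) {
  length_unit <- match.arg(length_unit)
  if (!is.numeric(epsilon) || length(epsilon) != 1L || epsilon <= 0) {
    stop("epsilon must be a positive number", call. = FALSE)
  }
  if (!is.numeric(length_divisor) || length(length_divisor) != 1L ||
      length_divisor <= 0) {
    stop("length_divisor must be a positive number", call. = FALSE)
  }
  structure(list(epsilon = epsilon, length_divisor = length_divisor,
                 length_unit = length_unit),
            class = "confidence_config")
}

check_lengths <- function(length) {
  if (!is.numeric(length) || any(!is.finite(length)) || any(length < 0)) {
    stop("response lengths must be finite and nonnegative", call. = FALSE)
  }
  length
}

#' Pseudo-loss of a response
#'
#' @param length Nonnegative response length(s).
#' @param cfg A [confidence_config()].
#' @return `length / length_divisor` (vectorized).
#' @export
#' @examples
#' pseudo_loss(10) # 1
pseudo_loss <- function(length, cfg = confidence_config()) {
  check_lengths(length) / cfg$length_divisor
}

#' Length-based confidence of a response
#'
#' Strictly decreasing in length; a zero-length response yields `1/epsilon`.
#'
#' @inheritParams pseudo_loss
#' @return `1 / (pseudo_loss(length) + epsilon)` (vectorized).
#' @export
length_confidence <- function(length, cfg = confidence_config()) {
  1 / (pseudo_loss(length, cfg) + cfg$epsilon)
}

#' Per-candidate response lengths to a five-way distribution
#'
#' Converts one response length per disease candidate (in label-set order)
#' into a probability distribution: confidence per candidate, then
#' normalization across the candidates. Shorter responses receive higher
#' probability.
#'
#' @param lengths Nonnegative integer vector, one length per class.
#' @inheritParams pseudo_loss
#' @inheritParams validate_prob_vector
#' @return A named probability vector.
#' @export
#' @examples
#' lengths_to_distribution(c(10, 20, 40, 40, 40))
lengths_to_distribution <- function(lengths, cfg = confidence_config(),
                                    labels = retinal_labels()) {
  if (length(lengths) != length(labels)) {
    stop(sprintf("expected one length per class (%d), got %d",
                 length(labels), length(lengths)), call. = FALSE)
  }
  normalize_scores(length_confidence(lengths, cfg), labels)
}
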