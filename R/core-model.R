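#' The default five-way retinal label set
#'
#' Ordered class names shared by every probability vector in the package:
#' no diabetic retinopathy, mild and severe diabetic retinopathy, glaucoma,
#' and age-related macular degeneration. Label order is load-bearing — it is
#' the deterministic tie-break for argmax and ranking — so every function
#' takes the label set explicitly and defaults to this one.
#'
#' @param labels Character vector of unique class names (at least two).
#' @return A character vector of class `retfuse_labels`.
#' @export
#' @examples
#' retinal_labels()
retinal_labels <- function(labels = c("NoDR", "MildDR", "SevereDR",
                                      "Glaucoma", "AMD")) {
  if (!is.character(labels) || length(labels) < 2L) {
    stop("a label set needs at least two character class names", call. = FALSE)
  }
  if (anyDuplicated(labels)) {
    stop("label set contains duplicated class names", call. = FALSE)
  }
  structure(labels, class = "retfuse_labels")
}

# Tolerance for "sums to 1" at I/O boundaries; vectors produced internally by
# floating-point arithmetic are renormalized instead of rejected.
PROB_SUM_TOL <- 1e-9

#' Validate a probability vector against a label set
#'
#' Checks length, non-negativity, finiteness and unit sum (tolerance `1e-9`).
#'
#' @param p Numeric vector of probabilities in label-set order.
#' @param labels Label set (see [retinal_labels()]).
#' @return `p`, invisibly, named by the labels.
#' @export
validate_prob_vector <- function(p, labels = retinal_labels()) {
  if (!is.numeric(p) || length(p) != length(labels)) {
    stop(sprintf("probability vector must be numeric of length %d",
                 length(labels)), call. = FALSE)
  }
  if (any(!is.finite(p))) stop("probability vector has non-finite entries",
                               call. = FALSE)
  if (any(p < 0)) stop("probability vector has negative entries",
                       call. = FALSE)
  if (abs(sum(p) - 1) > PROB_SUM_TOL) {
    stop(sprintf("probabilities sum to %.10f, not 1 (tolerance %g)",
                 sum(p), PROB_SUM_TOL), call. = FALSE)
  }
  invisible(stats::setNames(as.numeric(p), as.character(labels)))
}

#' Normalize nonnegative scores to a probability vector
#'
#' Divides by the total; an all-zero score vector falls back to the uniform
#' distribution with a warning (an ensemble of exactly uniform submodels can
#' legitimately produce all-zero fused scores, and the system must still
#' return a distribution).
#'
#' @param raw_scores Numeric vector of nonnegative finite scores, one per
#'   class in label-set order.
#' @inheritParams validate_prob_vector
#' @return A named probability vector summing to 1.
#' @export
#' @examples
#' normalize_scores(c(2, 1, 1, 0, 0))
normalize_scores <- function(raw_scores, labels = retinal_labels()) {
  if (!is.numeric(raw_scores) || length(raw_scores) != length(labels)) {
    stop(sprintf("expected %d scores, got %d", length(labels),
                 length(raw_scores)), call. = FALSE)
  }
  if (any(!is.finite(raw_scores))) stop("scores must be finite",
                                        call. = FALSE)
  if (any(raw_scores < 0)) stop("scores must be nonnegative", call. = FALSE)
  total <- sum(raw_scores)
  if (total == 0) {
    warning("all scores are zero; falling back to the uniform distribution",
            call. = FALSE)
    p <- rep(1 / length(labels), length(labels))
  } else {
    p <- raw_scores / total
  }
  stats::setNames(as.numeric(p), as.character(labels))
}

#' Most probable class of a distribution
#'
#' Ties are broken by label-set order (lowest index), so results are
#' reproducible; `which.max()` already implements exactly this rule.
#'
#' @inheritParams validate_prob_vector
#' @return A single class name.
#' @export
#' @examples
#' argmax_label(c(0.1, 0.6, 0.1, 0.1, 0.1))
argmax_label <- function(p, labels = retinal_labels()) {
  p <- validate_prob_vector(p, labels)
  as.character(labels)[which.max(p)]
}

#' Construct a case record
#'
#' One patient case: an identifier, an optional free-text narrative (PDF
#' derived text folded in), an optional precomputed image-evidence
#' distribution, and an optional ground-truth label. At least one of
#' narrative and image distribution must be present.
#'
#' @param case_id Unique case identifier (string).
#' @param text Optional narrative string.
#' @param image_probs Optional numeric probability vector from the image
#'   branch, aligned to `labels`.
#' @param label Optional true class name, a member of `labels`.
#' @inheritParams validate_prob_vector
#' @return A list of class `case_record`.
#' @export
case_record <- function(case_id, text = NULL, image_probs = NULL,
                        label = NULL, labels = retinal_labels()) {
  if (!is.character(case_id) || length(case_id) != 1L || !nzchar(case_id)) {
    stop("case_id must be a non-empty string", call. = FALSE)
  }
  if (is.null(text) && is.null(image_probs)) {
    stop(sprintf("case '%s': at least one of text/image_probs required",
                 case_id), call. = FALSE)
  }
  if (!is.null(image_probs)) {
    image_probs <- as.numeric(validate_prob_vector(image_probs, labels))
  }
  if (!is.null(label) && !label %in% as.character(labels)) {
    stop(sprintf("case '%s': label '%s' is not in the label set (labels are exact strings)",
                 case_id, label), call. = FALSE)
  }
  structure(list(case_id = case_id, text = text, image_probs = image_probs,
                 label = label),
            class = "case_record")
}

#' Construct a submodel output record
#'
#' One submodel's five-way distribution for one case, with provenance. Text
#' submodels may additionally carry the per-candidate response lengths that
#' induced the distribution through the pseudo-loss transform.
#'
#' @param submodel_id,case_id Identifiers (strings).
#' @param probs Numeric probability vector in label-set order.
#' @param modality `"text"` or `"image"`.
#' @param response_lengths Optional nonnegative integer vector, one per class.
#' @inheritParams validate_prob_vector
#' @return A list of class `submodel_output`.
#' @export
submodel_output <- function(submodel_id, case_id, probs,
                            modality = c("text", "image"),
                            response_lengths = NULL,
                            labels = retinal_labels()) {
  modality <- match.arg(modality)
  probs <- as.numeric(validate_prob_vector(probs, labels))
  if (!is.null(response_lengths)) {
    if (length(response_lengths) != length(labels) ||
        any(response_lengths < 0) ||
        any(response_lengths != round(response_lengths))) {
      stop(sprintf("submodel '%s', case '%s': response_lengths must be %d nonnegative integers",
                   submodel_id, case_id, length(labels)), call. = FALSE)
    }
    response_lengths <- as.integer(response_lengths)
  }
  structure(list(submodel_id = submodel_id, case_id = case_id, probs = probs,
                 modality = modality, response_lengths = response_lengths),
            class = "submodel_output")
}

#' Construct a fused diagnosis
#'
#' Internal constructor used by the fusion methods; bundles the fused
#' distribution with its ranked hypotheses and per-submodel diagnostics
#' (effective weight and entropy in nats) for auditability.
#'
#' @param probs Fused probability vector.
#' @param per_submodel_weight Named numeric vector of effective weights.
#' @param per_submodel_entropy Named numeric vector of entropies (nats).
#' @param method Fusion method name.
#' @inheritParams validate_prob_vector
#' @return A list of class `fused_diagnosis` with elements `probs`,
#'   `ranking`, `per_submodel_weight`, `per_submodel_entropy`,
#'   `contributing`, and `method`.
#' @keywords internal
new_fused_diagnosis <- function(probs, per_submodel_weight,
                                per_submodel_entropy, method,
                                labels = retinal_labels()) {
  probs <- validate_prob_vector(probs, labels)
  ranking <- rank_classes(probs, labels)
  structure(list(probs = probs, ranking = ranking,
                 per_submodel_weight = per_submodel_weight,
                 per_submodel_entropy = per_submodel_entropy,
                 contributing = names(per_submodel_weight),
                 method = method),
            class = "fused_diagnosis")
}

# Classes sorted by descending probability; ties broken by label order.
rank_classes <- function(p, labels = retinal_labels()) {
  as.character(labels)[order(-p, seq_along(p))]
}

#' @export
print.fused_diagnosis <- function(x, ...) {
  cat(sprintf("<fused_diagnosis: %s, %d submodel(s)>\n", x$method,
              length(x$contributing)))
  print(round(x$probs, 4))
  cat("ranking:", paste(x$ranking, collapse = " > "), "\n")
  invisible(x)
}
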