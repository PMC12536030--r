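#' Shannon entropy of a distribution, in nats
#'
#' \eqn{H(p) = -\sum_c p_c \ln p_c} with the convention
#' \eqn{0 \cdot \ln 0 = 0}. For a valid distribution over `k` classes the
#' result lies in `[0, ln k]`; the upper bound `ln k` (`ln 5` for the retinal
#' set) is the reference against which the fusion entropy penalty is scaled.
#'
#' @inheritParams validate_prob_vector
#' @return Entropy in nats.
#' @export
#' @examples
#' shannon_entropy(rep(0.2, 5)) # ln 5
shannon_entropy <- function(p, labels = retinal_labels()) {
  p <- validate_prob_vector(p, labels)
  pos <- p > 0
  -sum(p[pos] * log(p[pos]))
}

check_fusion_inputs <- function(outputs) {
  if (length(outputs) == 0L) {
    stop("fusion requires at least one submodel output", call. = FALSE)
  }
  ids <- vapply(outputs, `[[`, character(1), "submodel_id")
  if (anyDuplicated(ids)) {
    stop("duplicate submodel_id in fusion inputs: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  cases <- unique(vapply(outputs, `[[`, character(1), "case_id"))
  if (length(cases) > 1L) {
    stop("fusion inputs mix case_ids: ", paste(cases, collapse = ", "),
         call. = FALSE)
  }
  ids
}

#' Rank-based fusion baseline
#'
#' For each submodel, classes are ranked by descending probability (ties by
#' label order); the class at 0-based rank `r` accrues a fractional weight
#' `1/(r + 1)`, so the top class of each submodel contributes 1, the runner-up
#' 1/2, and so on down the harmonic sequence. Accumulated scores are
#' normalized. Submodel quality is deliberately ignored — this is the
#' transparent reference the reliability-aware aggregator is compared
#' against.
#'
#' @param outputs List of [submodel_output()] records for one case.
#' @inheritParams validate_prob_vector
#' @return A `fused_diagnosis`.
#' @export
rank_fusion <- function(outputs, labels = retinal_labels()) {
  ids <- check_fusion_inputs(outputs)
  k <- length(labels)
  scores <- numeric(k)
  entropies <- numeric(length(outputs))
  for (j in seq_along(outputs)) {
    p <- validate_prob_vector(outputs[[j]]$probs, labels)
    ord <- order(-p, seq_len(k))     # descending, ties to lower label index
    r <- integer(k); r[ord] <- seq_len(k) - 1L
    scores <- scores + 1 / (r + 1)
    entropies[j] <- shannon_entropy(p, labels)
  }
  new_fused_diagnosis(normalize_scores(scores, labels),
                      per_submodel_weight = stats::setNames(rep(1, length(ids)), ids),
                      per_submodel_entropy = stats::setNames(entropies, ids),
                      method = "rank", labels = labels)
}

#' Reliability- and entropy-weighted fusion
#'
#' Each submodel `j` contributes its distribution `p_j` with effective weight
#' \deqn{w_j = \alpha_j \left(1 - H_j / H_{\max}\right),}
#' where \eqn{\alpha_j} is the submodel's reliability (top-1 match rate on a
#' disjoint calibration split) and \eqn{H_j} its Shannon entropy with
#' \eqn{H_{\max} = \ln k}. The fused score of class `d` is
#' \eqn{\sum_j w_j\, p_j(d)}, normalized over classes. Reliable, low-entropy
#' submodels dominate; a submodel emitting the exactly uniform distribution
#' (or one with reliability 0) contributes nothing but is retained in the
#' diagnostics with weight 0. If every weight is zero the fused distribution
#' falls back to uniform with a warning.
#'
#' @param outputs List of [submodel_output()] records for one case.
#' @param reliabilities A [reliability_profile()] or a named numeric vector
#'   of reliabilities in `[0, 1]`; must cover every submodel in `outputs`.
#' @inheritParams validate_prob_vector
#' @return A `fused_diagnosis` recording per-submodel weights and entropies.
#' @export
reliability_entropy_fusion <- function(outputs, reliabilities,
                                       labels = retinal_labels()) {
  ids <- check_fusion_inputs(outputs)
  alpha <- as_alpha(reliabilities)
  missing <- setdiff(ids, names(alpha))
  if (length(missing) > 0L) {
    stop("no reliability estimate for submodel(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  h_max <- log(length(labels))
  k <- length(labels)
  scores <- numeric(k)
  w <- h <- stats::setNames(numeric(length(ids)), ids)
  for (j in seq_along(outputs)) {
    id <- ids[j]
    p <- validate_prob_vector(outputs[[j]]$probs, labels)
    h[id] <- shannon_entropy(p, labels)
    # clamp: the uniform distribution can land an ulp above h_max
    w[id] <- alpha[[id]] * max(0, 1 - h[id] / h_max)
    scores <- scores + w[id] * p
  }
  probs <- suppressWarnings(normalize_scores(scores, labels))
  if (sum(scores) == 0) {
    warning("all effective fusion weights are zero; returning uniform",
            call. = FALSE)
  }
  new_fused_diagnosis(probs, per_submodel_weight = w,
                      per_submodel_entropy = h,
                      method = "reliability_entropy", labels = labels)
}

as_alpha <- function(reliabilities) {
  if (inherits(reliabilities, "reliability_profile")) {
    return(reliabilities$alpha)
  }
  if (is.numeric(reliabilities) && !is.null(names(reliabilities))) {
    if (any(reliabilities < 0 | reliabilities > 1)) {
      stop("reliabilities must lie in [0, 1]", call. = FALSE)
    }
    return(reliabilities)
  }
  stop("reliabilities must be a reliability_profile or a named numeric vector",
       call. = FALSE)
}

#' Fuse the available evidence for one case
#'
#' Dispatches to the chosen fusion method using only the submodels that
#' actually produced output for the case. A missing modality (typically the
#' image branch: most records are text-only) is simply excluded and the
#' remaining weights renormalize, so absence of an evidence source changes
#' nothing beyond its removal — fusion neutrality. Zero available submodels
#' is an explicit error, never a silent uniform.
#'
#' @param case A [case_record()].
#' @param outputs List of [submodel_output()] records (any cases; filtered to
#'   `case$case_id`).
#' @param method `"reliability_entropy"` (default) or `"rank"`.
#' @param reliabilities Required for `"reliability_entropy"`; see
#'   [reliability_entropy_fusion()].
#' @inheritParams validate_prob_vector
#' @return A `fused_diagnosis`.
#' @export
fuse_case <- function(case, outputs,
                      method = c("reliability_entropy", "rank"),
                      reliabilities = NULL, labels = retinal_labels()) {
  method <- match.arg(method)
  available <- Filter(function(o) identical(o$case_id, case$case_id), outputs)
  if (length(available) == 0L) {
    stop(sprintf("case '%s': no submodel evidence available", case$case_id),
         call. = FALSE)
  }
  switch(method,
         rank = rank_fusion(available, labels),
         reliability_entropy = {
           if (is.null(reliabilities)) {
             stop("reliability_entropy fusion needs a reliability profile",
                  call. = FALSE)
           }
           reliability_entropy_fusion(available, reliabilities, labels)
         })
}
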