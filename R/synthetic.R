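#' Specification of one synthetic submodel
#'
#' The simulator emulates an ensemble of diagnostic submodels of
#' heterogeneous quality: each emits a five-way distribution whose argmax
#' equals the true label with probability `target_accuracy` (errors uniform
#' over the remaining classes) and whose concentration is governed by
#' `sharpness`.
#'
#' @param submodel_id Unique identifier.
#' @param target_accuracy Probability that the emitted distribution's argmax
#'   is the true label, in `[0, 1]`.
#' @param sharpness Positive concentration `kappa`; the emitted distribution
#'   is a symmetric simplex draw sharpened toward the mode (Dirichlet with
#'   `kappa` on the mode and 1 elsewhere), so higher `kappa` means lower
#'   entropy.
#' @param modality `"text"` or `"image"`. Text submodels also materialize
#'   per-candidate response lengths, and their distribution is recomputed
#'   through the pseudo-loss transform so that path is exercised end to end.
#' @param coverage Fraction of cases the submodel emits output for, in
#'   `[0, 1]`; models the minority subset of cases with usable images.
#' @param wrong_sharpness_factor Multiplier in `(0, 1]` applied to
#'   `sharpness` when the emitted mode is wrong (default 1/3). Real
#'   diagnostic submodels are flatter when they are wrong than when they are
#'   right, and this confidence-correctness link is precisely the per-case
#'   signal the entropy penalty consumes; without it (factor 1, a
#'   correctness-independent generator) entropy carries no information about
#'   correctness and no entropy-aware aggregator can beat the best single
#'   submodel.
#' @return A list of class `submodel_spec`.
#' @export
submodel_spec <- function(submodel_id, target_accuracy, sharpness = 6,
                          modality = c("text", "image"), coverage = 1.0,
                          wrong_sharpness_factor = 1 / 3) {
  modality <- match.arg(modality)
  if (target_accuracy < 0 || target_accuracy > 1) {
    stop("target_accuracy must lie in [0, 1]", call. = FALSE)
  }
  if (sharpness <= 0) stop("sharpness must be positive", call. = FALSE)
  if (coverage < 0 || coverage > 1) {
    stop("coverage must lie in [0, 1]", call. = FALSE)
  }
  if (wrong_sharpness_factor <= 0 || wrong_sharpness_factor > 1) {
    stop("wrong_sharpness_factor must lie in (0, 1]", call. = FALSE)
  }
  structure(list(submodel_id = submodel_id,
                 target_accuracy = target_accuracy,
                 sharpness = sharpness, modality = modality,
                 coverage = coverage,
                 wrong_sharpness_factor = wrong_sharpness_factor),
            class = "submodel_spec")
}

#' A synthetic ensemble scenario
#'
#' Bundles the corpus size, class balance, submodel roster and master seed.
#' The default roster mirrors the regime the fusion methods are designed
#' for: six text submodels with top-1 accuracies spanning roughly 0.22-0.56
#' (targets 0.45, 0.60, 0.35, 0.30, 0.30, 0.40) and heterogeneous sharpness,
#' plus one image submodel covering a 30% minority of cases, over a
#' moderately balanced 200-case corpus.
#'
#' @param n_cases Number of cases (default 200).
#' @param class_weights Probability vector of class prevalences (default
#'   uniform).
#' @param submodels List of [submodel_spec()]s.
#' @param seed Master seed; every submodel draws from its own substream so
#'   adding one never perturbs another's output.
#' @inheritParams validate_prob_vector
#' @return A list of class `ensemble_scenario`.
#' @export
ensemble_scenario <- function(n_cases = 200L,
                              class_weights = NULL,
                              submodels = default_submodel_roster(),
                              seed = 1L,
                              labels = retinal_labels()) {
  class_weights <- class_weights %||% rep(1 / length(labels), length(labels))
  class_weights <- as.numeric(validate_prob_vector(class_weights, labels))
  if (n_cases < 3L) stop("n_cases must be at least 3", call. = FALSE)
  ids <- vapply(submodels, `[[`, character(1), "submodel_id")
  if (anyDuplicated(ids)) stop("submodel ids must be unique", call. = FALSE)
  structure(list(n_cases = as.integer(n_cases),
                 class_weights = class_weights,
                 submodels = submodels, seed = as.integer(seed),
                 labels = labels),
            class = "ensemble_scenario")
}

#' @rdname ensemble_scenario
#' @param include_image Include the 30%-coverage image submodel (default
#'   TRUE).
#' @export
default_submodel_roster <- function(include_image = TRUE) {
  acc <- c(0.45, 0.60, 0.35, 0.30, 0.30, 0.40)
  kappa <- c(6, 8, 4, 3, 5, 6)
  roster <- lapply(seq_along(acc), function(i) {
    submodel_spec(paste0("text-", i), target_accuracy = acc[i],
                  sharpness = kappa[i], modality = "text", coverage = 1.0)
  })
  if (include_image) {
    roster <- c(roster, list(
      submodel_spec("image-1", target_accuracy = 0.55, sharpness = 7,
                    modality = "image", coverage = 0.3)))
  }
  roster
}

#' Generate synthetic labeled cases
#'
#' Labels are drawn from the scenario's class weights; narratives are
#' label-free placeholder stubs (deliberately: generated text must never
#' leak label tokens into anything a downstream text model could read).
#'
#' @param scenario An [ensemble_scenario()].
#' @return List of [case_record()]s, reproducible per seed.
#' @export
generate_cases <- function(scenario) {
  labels <- scenario$labels
  lab <- with_seed(substream_seed(scenario$seed, 0L), {
    sample(as.character(labels), scenario$n_cases, replace = TRUE,
           prob = scenario$class_weights)
  })
  lapply(seq_len(scenario$n_cases), function(i) {
    case_record(case_id = sprintf("case-%04d", i),
                text = sprintf("synthetic ophthalmic narrative, record %04d", i),
                label = lab[i], labels = labels)
  })
}

# One sharpened simplex draw with its maximum guaranteed at `mode`:
# Dirichlet(kappa at mode, 1 elsewhere) via the gamma-ratio construction,
# then the largest coordinate is swapped into the mode position.
sharpened_simplex_draw <- function(mode, kappa, k) {
  a <- rep(1, k); a[mode] <- kappa
  g <- stats::rgamma(k, shape = a, rate = 1)
  p <- g / sum(g)
  top <- which.max(p)
  if (top != mode) { tmp <- p[mode]; p[mode] <- p[top]; p[top] <- tmp }
  p
}

#' Generate one submodel's outputs over a case list
#'
#' For each covered case the emitted mode equals the true label with
#' probability `target_accuracy`, otherwise a uniformly drawn other class;
#' the distribution is a symmetric simplex draw sharpened toward the mode,
#' with the concentration reduced by `wrong_sharpness_factor` on wrong-mode
#' draws (uncertain-when-wrong behavior).
#' Text submodels convert the draw to per-candidate response lengths (the
#' inverse pseudo-loss transform) and re-derive their probabilities through
#' [lengths_to_distribution()], so the reported distribution is exactly what
#' the confidence-scoring path produces; after integer quantization the
#' mode's length is nudged to remain the strict minimum, preserving the
#' argmax guarantee. Uncovered cases emit nothing.
#'
#' @param cases List of labeled [case_record()]s.
#' @param spec A [submodel_spec()].
#' @param seed Substream seed for this submodel.
#' @param cfg [confidence_config()] used for the length round-trip.
#' @inheritParams validate_prob_vector
#' @return List of [submodel_output()]s (length <= `length(cases)`).
#' @export
generate_submodel_outputs <- function(cases, spec, seed,
                                      cfg = confidence_config(),
                                      labels = retinal_labels()) {
  k <- length(labels)
  lab_chr <- as.character(labels)
  with_seed(seed, {
    out <- lapply(cases, function(case) {
      if (stats::runif(1) > spec$coverage) return(NULL)
      truth_idx <- match(case$label, lab_chr)
      correct <- stats::runif(1) <= spec$target_accuracy
      mode <- if (correct) truth_idx else {
        others <- setdiff(seq_len(k), truth_idx)
        others[sample.int(k - 1L, 1L)]
      }
      kappa <- spec$sharpness *
        if (correct) 1 else spec$wrong_sharpness_factor
      p <- sharpened_simplex_draw(mode, kappa, k)
      lengths <- NULL
      if (spec$modality == "text") {
        lengths <- distribution_to_lengths(p, cfg)
        # keep the mode's response strictly shortest after rounding
        ties <- which(lengths == min(lengths))
        if (!identical(ties, mode)) {
          lengths[mode] <- min(lengths) - 1L
        }
        p <- as.numeric(lengths_to_distribution(lengths, cfg, labels))
      }
      submodel_output(spec$submodel_id, case$case_id, p,
                      modality = spec$modality,
                      response_lengths = lengths, labels = labels)
    })
    Filter(Negate(is.null), out)
  })
}

#' Invert a distribution into per-candidate response lengths
#'
#' Produces integer lengths whose pseudo-loss confidences renormalize back
#' to approximately `p` (total-variation error well under 0.02 for any
#' distribution with entries >= 0.05): `length_c = round(base / p_c)`, so
#' likelier candidates get shorter responses. A zero entry is unreachable by
#' a finite length and raises an error.
#'
#' @inheritParams validate_prob_vector
#' @param cfg A [confidence_config()].
#' @param base_length Length scale of the shortest responses (default 100
#'   characters).
#' @return Integer vector of positive lengths.
#' @export
#' @examples
#' distribution_to_lengths(c(0.4, 0.3, 0.1, 0.1, 0.1))
distribution_to_lengths <- function(p, cfg = confidence_config(),
                                    base_length = 100,
                                    labels = retinal_labels()) {
  p <- validate_prob_vector(p, labels)
  if (any(p == 0)) {
    stop("cannot represent a zero probability with a finite response length",
         call. = FALSE)
  }
  as.integer(pmax(1, round(base_length / (p / max(p)))))
}

#' Generate the full ensemble for a scenario
#'
#' @param scenario An [ensemble_scenario()].
#' @param cases Optionally, pre-generated cases (defaults to
#'   [generate_cases()] on the scenario).
#' @param cfg [confidence_config()] for text submodels.
#' @return A list with `cases` and `outputs` (flat list of
#'   [submodel_output()]s across all submodels).
#' @export
generate_ensemble <- function(scenario, cases = NULL,
                              cfg = confidence_config()) {
  cases <- cases %||% generate_cases(scenario)
  outputs <- list()
  for (i in seq_along(scenario$submodels)) {
    spec <- scenario$submodels[[i]]
    outputs <- c(outputs,
                 generate_submodel_outputs(cases, spec,
                                           substream_seed(scenario$seed, i),
                                           cfg, scenario$labels))
  }
  list(cases = cases, outputs = outputs)
}
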