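#' Triage policy
#'
#' Maps fused probabilities to application-aligned actions. The tiers are
#' screening (low-to-moderate yet non-negligible probability), monitoring
#' (intermediate probability suggesting progression risk) and referral (high
#' probability implicating optic-nerve or macular involvement). The default
#' thresholds 0.15 / 0.35 / 0.60 are documented, non-clinical defaults — the
#' mapping is decision support, not a validated clinical endpoint — and every
#' piece is configurable. By default the no-disease class `NoDR` cannot
#' trigger any tier, and only `SevereDR`, `Glaucoma` and `AMD` can trigger a
#' referral.
#'
#' @param screening_min,monitoring_min,referral_min Strictly increasing
#'   thresholds in `[0, 1]`.
#' @param eligible Classes allowed to trigger any action tier (default: all
#'   but `NoDR`).
#' @param referral_classes Classes allowed to trigger the referral tier.
#' @inheritParams validate_prob_vector
#' @return A list of class `triage_policy`.
#' @export
triage_policy <- function(screening_min = 0.15, monitoring_min = 0.35,
                          referral_min = 0.60,
                          eligible = NULL,
                          referral_classes = c("SevereDR", "Glaucoma", "AMD"),
                          labels = retinal_labels()) {
  th <- c(screening_min, monitoring_min, referral_min)
  if (any(!is.finite(th)) || any(th < 0) || any(th > 1) ||
      !(screening_min < monitoring_min && monitoring_min < referral_min)) {
    stop("thresholds must satisfy 0 <= screening < monitoring < referral <= 1",
         call. = FALSE)
  }
  eligible <- eligible %||% setdiff(as.character(labels), "NoDR")
  if (!all(eligible %in% as.character(labels)) ||
      !all(referral_classes %in% as.character(labels))) {
    stop("policy classes must belong to the label set", call. = FALSE)
  }
  structure(list(screening_min = screening_min,
                 monitoring_min = monitoring_min,
                 referral_min = referral_min,
                 eligible = eligible,
                 referral_classes = referral_classes),
            class = "triage_policy")
}

#' Map a fused diagnosis to a triage action
#'
#' The highest tier reached by any eligible class wins
#' (referral > monitoring > screening > none); within a tier, ties go to the
#' higher probability, then label order. The full distribution always rides
#' along with the action — uncertainty is preserved, never collapsed into
#' the action label.
#'
#' @param diag A `fused_diagnosis` (or a bare probability vector).
#' @param policy A [triage_policy()].
#' @inheritParams validate_prob_vector
#' @return A list of class `triage_action`: `action` (one of `"referral"`,
#'   `"monitoring"`, `"screening"`, `"none"`), `class` and `probability` of
#'   the triggering class (NA for `"none"`), and the untouched `probs`.
#' @export
map_to_action <- function(diag, policy = triage_policy(),
                          labels = retinal_labels()) {
  probs <- if (inherits(diag, "fused_diagnosis")) diag$probs else
    validate_prob_vector(diag, labels)
  lab <- as.character(labels)
  tier <- function(class, p) {
    if (!class %in% policy$eligible) return(0L)
    if (p >= policy$referral_min && class %in% policy$referral_classes) {
      return(3L)
    }
    if (p >= policy$monitoring_min) return(2L)
    if (p >= policy$screening_min) return(1L)
    0L
  }
  tiers <- vapply(seq_along(lab), function(i) tier(lab[i], probs[[i]]),
                  integer(1))
  best <- max(tiers)
  if (best == 0L) {
    action <- list(action = "none", class = NA_character_,
                   probability = NA_real_, probs = probs)
  } else {
    cand <- which(tiers == best)
    trig <- cand[order(-probs[cand], cand)][1L]
    action <- list(action = c("screening", "monitoring", "referral")[best],
                   class = lab[trig], probability = unname(probs[[trig]]),
                   probs = probs)
  }
  structure(action, class = "triage_action")
}

#' @export
print.triage_action <- function(x, ...) {
  if (x$action == "none") {
    cat("<triage_action: none>\n")
  } else {
    cat(sprintf("<triage_action: %s, triggered by %s at %.4f>\n",
                x$action, x$class, x$probability))
  }
  invisible(x)
}
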