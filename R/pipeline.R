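#' Run a full synthetic-ensemble study in memory
#'
#' Generates the scenario's cases and submodel outputs, partitions the cases
#' (calibration / development / test), estimates per-submodel reliability on
#' the calibration subset only, fuses every test case with the rank baseline
#' and the reliability-plus-entropy aggregator, and scores all single
#' submodels and both fusion methods on the held-out test set with the full
#' metric suite. This is the function the command-line `run-all` command and
#' the acceptance analysis are built on.
#'
#' @param scenario An [ensemble_scenario()].
#' @param split_cfg A [split_config()]; its seed defaults to the scenario
#'   seed.
#' @param eval_cfg An [evaluation_config()].
#' @param cfg A [confidence_config()].
#' @return A list of class `retfuse_report`: `seed`, `config_hash`,
#'   `generated_at`, `reliability` (alpha block + n_calibration),
#'   `per_method` (metrics per single submodel and per fusion method), and
#'   `splits` (case-id lists).
#' @export
run_scenario <- function(scenario,
                         split_cfg = split_config(seed = scenario$seed),
                         eval_cfg = evaluation_config(),
                         cfg = confidence_config()) {
  labels <- scenario$labels
  ens <- generate_ensemble(scenario, cfg = cfg)
  split <- split_dataset(ens$cases, split_cfg)

  case_ids <- function(part) vapply(part, `[[`, character(1), "case_id")
  truth_of <- function(part) {
    stats::setNames(vapply(part, `[[`, character(1), "label"), case_ids(part))
  }
  cal_ids <- case_ids(split$calibration)
  cal_truth <- truth_of(split$calibration)

  out_case <- vapply(ens$outputs, `[[`, character(1), "case_id")
  out_sub <- vapply(ens$outputs, `[[`, character(1), "submodel_id")

  # reliability on fully-covering submodels only; partial-coverage submodels
  # (the image branch) are calibrated on the calibration cases they cover
  profile <- estimate_reliability_with_coverage(
    ens$outputs[out_case %in% cal_ids], cal_truth, cal_ids,
    seed = split_cfg$seed, labels = labels,
    all_submodel_ids = unique(out_sub))

  test_truth <- truth_of(split$test)
  test_ids <- names(test_truth)

  per_method <- list()
  # single submodels, each on the covered subset of the test set
  for (sid in unique(out_sub)) {
    sel <- which(out_sub == sid & out_case %in% test_ids)
    if (length(sel) == 0L) next
    preds <- lapply(ens$outputs[sel], `[[`, "probs")
    truths <- unname(test_truth[out_case[sel]])
    per_method[[sid]] <- evaluate_predictions(preds, truths, eval_cfg, labels)
  }
  # fusion methods on every test case
  test_outputs <- ens$outputs[out_case %in% test_ids]
  for (method in c("rank", "reliability_entropy")) {
    fused <- lapply(split$test, function(case) {
      fuse_case(case, test_outputs, method = method,
                reliabilities = profile, labels = labels)
    })
    preds <- lapply(fused, `[[`, "probs")
    per_method[[method]] <-
      evaluate_predictions(preds, unname(test_truth), eval_cfg, labels)
  }

  structure(list(
    seed = scenario$seed,
    config_hash = config_hash(list(scenario = scenario, split = split_cfg,
                                   eval = eval_cfg, confidence = cfg)),
    generated_at = format(Sys.time(), tz = "UTC", usetz = TRUE),
    reliability = list(alpha = as.list(profile$alpha),
                       n_calibration = profile$n_calibration),
    per_method = per_method,
    splits = list(calibration = cal_ids,
                  development = case_ids(split$development),
                  test = test_ids)),
    class = "retfuse_report")
}

# Reliability for a mixed-coverage ensemble: each submodel's alpha is its
# top-1 match rate over the calibration cases it actually covers. A submodel
# with zero calibration coverage has unknown reliability and gets alpha 0
# (it then contributes nothing to fusion), with a warning.
estimate_reliability_with_coverage <- function(cal_outputs, cal_truth,
                                               cal_ids, seed, labels,
                                               all_submodel_ids = NULL) {
  ids <- vapply(cal_outputs, `[[`, character(1), "submodel_id")
  alphas <- lapply(split(seq_along(cal_outputs), ids), function(idx) {
    covered <- vapply(cal_outputs[idx], `[[`, character(1), "case_id")
    estimate_reliability(cal_outputs[idx], cal_truth[covered],
                         calibration_ids = covered, seed = seed,
                         labels = labels)
  })
  alpha <- vapply(alphas, function(p) unname(p$alpha), numeric(1))
  alpha <- stats::setNames(alpha, names(alphas))
  uncovered <- setdiff(all_submodel_ids, names(alpha))
  if (length(uncovered) > 0L) {
    warning("submodel(s) with no calibration coverage get reliability 0: ",
            paste(uncovered, collapse = ", "), call. = FALSE)
    alpha[uncovered] <- 0
  }
  reliability_profile(alpha, n_calibration = length(cal_ids), seed = seed)
}

# Small deterministic FNV-1a hash of the deparsed configuration; provenance
# only, not cryptographic.
config_hash <- function(x) {
  s <- paste(deparse(x, control = "all"), collapse = "")
  h <- 2166136261
  for (b in utf8ToInt(s)) {
    h <- bitwXor(as.integer(h %% 2147483647), b) * 16777619
    h <- h %% 4294967296
  }
  sprintf("%08x", as.integer(h %% 2147483647))
}

#' @export
print.retfuse_report <- function(x, ...) {
  cat(sprintf("<retfuse_report: seed %d, config %s>\n", x$seed,
              x$config_hash))
  cat("reliability (calibration, n =", x$reliability$n_calibration, "):\n")
  print(round(unlist(x$reliability$alpha), 4))
  cat("test metrics:\n")
  for (m in names(x$per_method)) {
    r <- x$per_method[[m]]
    cat(sprintf("  %-20s top1 %.4f  mrr %.4f  ece %.4f  brier %.4f  (n=%d)\n",
                m, r$top_k[["top_1"]], r$mrr, r$ece, r$brier, r$n))
  }
  invisible(x)
}
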