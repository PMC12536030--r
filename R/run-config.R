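#' Read a run configuration from YAML
#'
#' One structured document drives every pipeline stage; all seeds live here
#' so any artifact is reproducible from (config, seed). Recognized top-level
#' keys (all optional, defaults in parentheses):
#' `seed` (1), `labels` (the retinal five), `scenario`
#' (`n_cases`, `class_weights`, `submodels:` list of
#' `{id, target_accuracy, sharpness, modality, coverage}`), `split`
#' (`calibration_size` 20, `test_fraction` 0.3), `confidence` (`epsilon`,
#' `length_divisor`, `length_unit`), `evaluation` (`k_values`, `ece_bins`),
#' `triage` (`screening_min`, `monitoring_min`, `referral_min`, `eligible`,
#' `referral_classes`), and `methods` (both fusion methods).
#'
#' @param path YAML file path.
#' @param seed_override Optional integer replacing the config seed (the
#'   command line's `--seed`).
#' @return A list of class `run_config` with fully-constructed component
#'   configs.
#' @export
read_run_config <- function(path, seed_override = NULL) {
  raw <- if (is.null(path)) list() else yaml::read_yaml(path)
  build_run_config(raw, seed_override)
}

build_run_config <- function(raw, seed_override = NULL) {
  seed <- as.integer(seed_override %||% raw$seed %||% 1L)
  labels <- retinal_labels(unlist(raw$labels) %||%
                             c("NoDR", "MildDR", "SevereDR", "Glaucoma",
                               "AMD"))
  sc <- raw$scenario %||% list()
  submodels <- if (is.null(sc$submodels)) default_submodel_roster() else {
    lapply(sc$submodels, function(s) {
      submodel_spec(s$id, s$target_accuracy,
                    sharpness = s$sharpness %||% 6,
                    modality = s$modality %||% "text",
                    coverage = s$coverage %||% 1.0,
                    wrong_sharpness_factor = s$wrong_sharpness_factor %||%
                      (1 / 3))
    })
  }
  scenario <- ensemble_scenario(
    n_cases = sc$n_cases %||% 200L,
    class_weights = unlist(sc$class_weights) %||% NULL,
    submodels = submodels, seed = seed, labels = labels)
  sp <- raw$split %||% list()
  co <- raw$confidence %||% list()
  ev <- raw$evaluation %||% list()
  tr <- raw$triage %||% list()
  structure(list(
    seed = seed, labels = labels, scenario = scenario,
    split = split_config(seed = seed,
                         calibration_size = sp$calibration_size %||% 20L,
                         test_fraction = sp$test_fraction %||% 0.3),
    confidence = confidence_config(
      epsilon = co$epsilon %||% 1e-9,
      length_divisor = co$length_divisor %||% 10.0,
      length_unit = co$length_unit %||% "characters"),
    evaluation = evaluation_config(
      k_values = unlist(ev$k_values) %||% c(1L, 3L),
      ece_bins = ev$ece_bins %||% 10L),
    triage = triage_policy(
      screening_min = tr$screening_min %||% 0.15,
      monitoring_min = tr$monitoring_min %||% 0.35,
      referral_min = tr$referral_min %||% 0.60,
      eligible = unlist(tr$eligible) %||% NULL,
      referral_classes = unlist(tr$referral_classes) %||%
        c("SevereDR", "Glaucoma", "AMD"),
      labels = labels),
    methods = unlist(raw$methods) %||% c("rank", "reliability_entropy")),
    class = "run_config")
}
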