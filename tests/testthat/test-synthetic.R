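test_that("case generation is seeded, sized, and respects class weights", {
  sc <- ensemble_scenario(n_cases = 200L, seed = 77)
  cases <- generate_cases(sc)
  expect_length(cases, 200L)
  expect_identical(cases, generate_cases(sc))
  counts <- table(vapply(cases, `[[`, character(1), "label"))
  # uniform weights: counts within multinomial 99% bounds of 40 each
  bounds <- qbinom(c(0.005, 0.995), 200, 0.2)
  expect_true(all(counts >= bounds[1] & counts <= bounds[2]))
  # degenerate weights force a single class
  deg <- ensemble_scenario(n_cases = 50L,
                           class_weights = c(1, 0, 0, 0, 0), seed = 3)
  expect_true(all(vapply(generate_cases(deg), `[[`, character(1),
                         "label") == "NoDR"))
})

test_that("synthetic narratives never contain label tokens", {
  cases <- generate_cases(ensemble_scenario(n_cases = 50L, seed = 5))
  texts <- vapply(cases, `[[`, character(1), "text")
  for (lab in as.character(retinal_labels())) {
    expect_false(any(grepl(lab, texts, fixed = TRUE)))
  }
})

test_that("submodel outputs hit the target accuracy within binomial bounds", {
  sc <- ensemble_scenario(n_cases = 1500L, seed = 8)
  cases <- generate_cases(sc)
  spec <- submodel_spec("m", target_accuracy = 0.6, sharpness = 6)
  outs <- generate_submodel_outputs(cases, spec, seed = 42)
  expect_length(outs, 1500L)
  truth <- setNames(vapply(cases, `[[`, character(1), "label"),
                    vapply(cases, `[[`, character(1), "case_id"))
  hits <- vapply(outs, function(o) {
    argmax_label(o$probs) == truth[[o$case_id]]
  }, logical(1))
  bounds <- qbinom(c(0.005, 0.995), 1500, 0.6)
  expect_gte(sum(hits), bounds[1])
  expect_lte(sum(hits), bounds[2])
  # every emitted distribution is valid and lengths round-trip exactly
  for (o in outs[1:50]) {
    expect_silent(validate_prob_vector(o$probs))
    expect_equal(o$probs,
                 as.numeric(lengths_to_distribution(o$response_lengths)),
                 tolerance = 1e-12)
  }
})

test_that("coverage controls the fraction of cases with output", {
  sc <- ensemble_scenario(n_cases = 1000L, seed = 12)
  cases <- generate_cases(sc)
  spec <- submodel_spec("img", 0.5, modality = "image", coverage = 0.3)
  outs <- generate_submodel_outputs(cases, spec, seed = 9)
  bounds <- qbinom(c(0.005, 0.995), 1000, 0.3)
  expect_gte(length(outs), bounds[1])
  expect_lte(length(outs), bounds[2])
  expect_null(outs[[1]]$response_lengths)  # image branch has no responses
})

test_that("perfect accuracy with extreme sharpness approaches a delta on the truth", {
  sc <- ensemble_scenario(n_cases = 30L, seed = 2)
  cases <- generate_cases(sc)
  spec <- submodel_spec("m", 1.0, sharpness = 1e6, modality = "image")
  outs <- generate_submodel_outputs(cases, spec, seed = 1)
  truth <- setNames(vapply(cases, `[[`, character(1), "label"),
                    vapply(cases, `[[`, character(1), "case_id"))
  for (o in outs) {
    expect_identical(argmax_label(o$probs), truth[[o$case_id]])
    expect_gt(max(o$probs), 0.99)
  }
})

test_that("wrong-mode draws are flatter than correct ones on average", {
  sc <- ensemble_scenario(n_cases = 1200L, seed = 19)
  cases <- generate_cases(sc)
  spec <- submodel_spec("m", 0.5, sharpness = 6, modality = "image")
  outs <- generate_submodel_outputs(cases, spec, seed = 4)
  truth <- setNames(vapply(cases, `[[`, character(1), "label"),
                    vapply(cases, `[[`, character(1), "case_id"))
  h <- vapply(outs, function(o) shannon_entropy(o$probs), numeric(1))
  hit <- vapply(outs, function(o) {
    argmax_label(o$probs) == truth[[o$case_id]]
  }, logical(1))
  expect_gt(mean(h[!hit]), mean(h[hit]))
})

test_that("distribution_to_lengths inverts the pseudo-loss transform", {
  expect_true(length(unique(distribution_to_lengths(rep(0.2, 5)))) == 1L)
  lens <- distribution_to_lengths(c(4, 2, 1, 1, 1) / 9)
  expect_equal(lens / lens[1], c(1, 2, 4, 4, 4), tolerance = 0.01)
  expect_error(distribution_to_lengths(c(0.5, 0.5, 0, 0, 0)),
               "zero probability")
  tv <- function(p, q) 0.5 * sum(abs(p - q))
  set.seed(61)
  for (i in 1:100) {
    p <- random_prob()
    p <- (p + 0.06) / sum(p + 0.06)  # keep entries comfortably above 0.05
    back <- lengths_to_distribution(distribution_to_lengths(p))
    expect_lte(tv(p, as.numeric(back)), 0.02)
  }
})

test_that("adding a submodel does not perturb the other submodels' draws", {
  roster <- default_submodel_roster(include_image = FALSE)
  sc1 <- ensemble_scenario(n_cases = 40L, submodels = roster, seed = 23)
  sc2 <- ensemble_scenario(n_cases = 40L,
                           submodels = c(roster,
                                         list(submodel_spec("extra", 0.5))),
                           seed = 23)
  e1 <- generate_ensemble(sc1)
  e2 <- generate_ensemble(sc2)
  sub_of <- function(e, id) {
    Filter(function(o) o$submodel_id == id, e$outputs)
  }
  for (id in paste0("text-", 1:6)) {
    expect_identical(sub_of(e1, id), sub_of(e2, id))
  }
})

test_that("scenarios validate their inputs", {
  expect_error(submodel_spec("m", 1.2), "target_accuracy")
  expect_error(submodel_spec("m", 0.5, sharpness = 0), "sharpness")
  expect_error(submodel_spec("m", 0.5, coverage = 2), "coverage")
  expect_error(submodel_spec("m", 0.5, wrong_sharpness_factor = 0),
               "wrong_sharpness_factor")
  expect_error(ensemble_scenario(submodels = list(submodel_spec("a", 0.5),
                                                  submodel_spec("a", 0.4))),
               "unique")
  expect_error(ensemble_scenario(class_weights = c(0.5, 0.5, 0.2, 0, 0)),
               "sum to")
})
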