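test_that("shannon entropy matches hand-computed values and bounds", {
  expect_equal(shannon_entropy(c(1, 0, 0, 0, 0)), 0)
  expect_equal(shannon_entropy(rep(0.2, 5)), log(5))
  expect_equal(shannon_entropy(c(0.7, 0.1, 0.1, 0.05, 0.05)),
               1.00976270671, tolerance = 1e-9)
  set.seed(31)
  for (i in 1:30) {
    p <- random_prob()
    h <- shannon_entropy(p)
    expect_gte(h, 0)
    expect_lte(h, log(5) + 1e-12)
    expect_equal(h, oracle_entropy(p), tolerance = 1e-12)
  }
})

test_that("rank fusion of one submodel yields the normalized harmonic profile", {
  out <- submodel_output("m1", "c1", c(0.4, 0.3, 0.15, 0.1, 0.05))
  fd <- rank_fusion(list(out))
  expect_equal(unname(fd$probs), (1 / (1:5)) / (137 / 60), tolerance = 1e-12)
  expect_identical(fd$ranking,
                   c("NoDR", "MildDR", "SevereDR", "Glaucoma", "AMD"))
})

test_that("rank fusion symmetries: swapped top pair ties, identical rankings rescale", {
  a <- submodel_output("a", "c1", c(0.5, 0.3, 0.1, 0.06, 0.04))
  b <- submodel_output("b", "c1", c(0.3, 0.5, 0.1, 0.06, 0.04))
  fd <- rank_fusion(list(a, b))
  expect_equal(fd$probs[[1]], fd$probs[[2]], tolerance = 1e-12)
  # three submodels with identical rankings equal the single-submodel profile
  c1 <- submodel_output("c", "c1", c(0.45, 0.25, 0.15, 0.1, 0.05))
  fd3 <- rank_fusion(list(a, c1, submodel_output("d", "c1",
                                                 c(0.9, 0.05, 0.03, 0.015,
                                                   0.005))))
  expect_equal(unname(fd3$probs), unname(rank_fusion(list(a))$probs),
               tolerance = 1e-12)
})

test_that("rank fusion breaks probability ties by label order", {
  out <- submodel_output("m", "c1", c(0.25, 0.25, 0.25, 0.2, 0.05))
  fd <- rank_fusion(list(out))
  # first three classes get ranks 0,1,2 in label order
  expect_identical(fd$ranking[1:3], c("NoDR", "MildDR", "SevereDR"))
  expect_gt(fd$probs[[1]], fd$probs[[2]])
})

test_that("reliability-plus-entropy fusion reproduces the two-submodel worked example", {
  a <- submodel_output("A", "c1", c(0.7, 0.1, 0.1, 0.05, 0.05))
  b <- submodel_output("B", "c1", c(0.1, 0.6, 0.1, 0.1, 0.1))
  fd <- reliability_entropy_fusion(list(a, b), c(A = 0.6, B = 0.3))
  expect_equal(unname(fd$probs), c(0.5551, 0.2208, 0.1000, 0.0621, 0.0621),
               tolerance = 1e-3)
  expect_equal(unname(fd$per_submodel_weight[["A"]]), 0.2236,
               tolerance = 1e-3)
  expect_equal(unname(fd$per_submodel_weight[["B"]]), 0.0712,
               tolerance = 1e-3)
  expect_equal(unname(fd$per_submodel_entropy[["A"]]), 1.0098,
               tolerance = 1e-3)
})

test_that("a single weighted submodel passes through; a uniform one contributes nothing", {
  p <- c(0.5, 0.2, 0.15, 0.1, 0.05)
  solo <- reliability_entropy_fusion(
    list(submodel_output("A", "c1", p)), c(A = 0.42))
  expect_equal(unname(solo$probs), p, tolerance = 1e-12)
  both <- reliability_entropy_fusion(
    list(submodel_output("A", "c1", p),
         submodel_output("U", "c1", rep(0.2, 5))),
    c(A = 0.42, U = 0.99))
  expect_equal(unname(both$probs), p, tolerance = 1e-12)
  expect_equal(unname(both$per_submodel_weight[["U"]]), 0)
  expect_true("U" %in% both$contributing)
})

test_that("all-zero effective weights fall back to uniform with a warning", {
  outs <- list(submodel_output("A", "c1", rep(0.2, 5)),
               submodel_output("B", "c1", c(0.6, 0.1, 0.1, 0.1, 0.1)))
  expect_warning(fd <- reliability_entropy_fusion(outs, c(A = 0.5, B = 0)),
                 "zero")
  expect_equal(unname(fd$probs), rep(0.2, 5))
})

test_that("fusion validates its inputs", {
  expect_error(rank_fusion(list()), "at least one")
  a <- submodel_output("A", "c1", rep(0.2, 5))
  a2 <- submodel_output("A", "c1", rep(0.2, 5))
  expect_error(rank_fusion(list(a, a2)), "duplicate submodel_id")
  b <- submodel_output("B", "c2", rep(0.2, 5))
  expect_error(rank_fusion(list(a, b)), "mix case_ids")
  expect_error(reliability_entropy_fusion(list(a), c(Z = 0.4)),
               "no reliability estimate for submodel\\(s\\): A")
  expect_error(reliability_entropy_fusion(list(a), c(A = 1.4)), "\\[0, 1\\]")
})

test_that("both fusion methods match naive loop oracles on random ensembles", {
  set.seed(33)
  for (i in 1:200) {
    n_sub <- sample(1:6, 1)
    outs <- random_outputs(n_sub)
    probs <- lapply(outs, `[[`, "probs")
    alpha <- setNames(runif(n_sub), paste0("m", seq_len(n_sub)))
    expect_equal(unname(rank_fusion(outs)$probs), oracle_rank_fusion(probs),
                 tolerance = 1e-12)
    expect_equal(unname(reliability_entropy_fusion(outs, alpha)$probs),
                 oracle_rel_entropy_fusion(probs, unname(alpha)),
                 tolerance = 1e-12)
  }
})

test_that("normalizing scores equals renormalizing the weights first", {
  set.seed(34)
  for (i in 1:50) {
    n_sub <- sample(2:6, 1)
    outs <- random_outputs(n_sub)
    alpha <- setNames(runif(n_sub, 0.05, 1), paste0("m", seq_len(n_sub)))
    fd <- reliability_entropy_fusion(outs, alpha)
    w <- fd$per_submodel_weight / sum(fd$per_submodel_weight)
    renorm <- Reduce(`+`, lapply(seq_len(n_sub), function(j) {
      w[[j]] * outs[[j]]$probs
    }))
    expect_equal(unname(fd$probs), renorm, tolerance = 1e-12)
  }
})

test_that("fusion is invariant to submodel order and equivariant to label relabeling", {
  set.seed(35)
  labels <- retinal_labels()
  for (i in 1:25) {
    outs <- random_outputs(4)
    alpha <- setNames(runif(4), paste0("m", 1:4))
    perm_sub <- sample(4)
    expect_equal(unname(rank_fusion(outs[perm_sub])$probs),
                 unname(rank_fusion(outs)$probs), tolerance = 1e-12)
    expect_equal(unname(reliability_entropy_fusion(outs[perm_sub],
                                                   alpha)$probs),
                 unname(reliability_entropy_fusion(outs, alpha)$probs),
                 tolerance = 1e-12)
    # relabeling classes relabels the fused output identically; permute with
    # distinct probabilities so rank tie-breaks cannot differ across orders
    perm_lab <- sample(5)
    relab <- lapply(outs, function(o) {
      submodel_output(o$submodel_id, o$case_id, o$probs[perm_lab])
    })
    expect_equal(unname(rank_fusion(relab)$probs),
                 unname(rank_fusion(outs)$probs)[perm_lab],
                 tolerance = 1e-12)
    expect_equal(unname(reliability_entropy_fusion(relab, alpha)$probs),
                 unname(reliability_entropy_fusion(outs, alpha)$probs)[perm_lab],
                 tolerance = 1e-12)
  }
})

test_that("raising reliability raises the fused share of that submodel's top class", {
  pa <- c(0.6, 0.2, 0.1, 0.05, 0.05)
  pb <- c(0.1, 0.6, 0.1, 0.1, 0.1)[c(2, 1, 3, 4, 5)] # same entropy as pa? no:
  # use the same vector permuted so entropies are exactly equal
  pb <- pa[c(2, 1, 3, 4, 5)]
  outs <- list(submodel_output("A", "c1", pa), submodel_output("B", "c1", pb))
  prev <- -Inf
  for (aA in seq(0.1, 0.9, by = 0.2)) {
    fd <- reliability_entropy_fusion(outs, c(A = aA, B = 0.5))
    expect_gte(fd$probs[["NoDR"]], prev)
    prev <- fd$probs[["NoDR"]]
  }
})

test_that("a higher-entropy distribution with the same argmax gets a lower weight", {
  sharp <- c(0.8, 0.1, 0.05, 0.03, 0.02)
  flat <- c(0.4, 0.2, 0.15, 0.15, 0.1)  # same argmax, strictly higher entropy
  expect_gt(shannon_entropy(flat), shannon_entropy(sharp))
  other <- submodel_output("B", "c1", c(0.1, 0.4, 0.3, 0.1, 0.1))
  w_sharp <- reliability_entropy_fusion(
    list(submodel_output("A", "c1", sharp), other),
    c(A = 0.5, B = 0.5))$per_submodel_weight[["A"]]
  w_flat <- reliability_entropy_fusion(
    list(submodel_output("A", "c1", flat), other),
    c(A = 0.5, B = 0.5))$per_submodel_weight[["A"]]
  expect_lt(w_flat, w_sharp)
})

test_that("fuse_case uses only the case's available submodels", {
  case <- case_record("c1", text = "t", label = "AMD")
  outs <- c(random_outputs(3, "c1"), random_outputs(2, "c2"))
  alpha <- setNames(runif(5), paste0("m", 1:5))
  fd <- fuse_case(case, outs, method = "reliability_entropy",
                  reliabilities = alpha)
  expect_setequal(fd$contributing, c("m1", "m2", "m3"))
  direct <- reliability_entropy_fusion(outs[1:3], alpha)
  expect_equal(fd$probs, direct$probs, tolerance = 1e-15)
  expect_error(fuse_case(case_record("c9", text = "t"), outs,
                         reliabilities = alpha),
               "no submodel evidence")
})

test_that("consensus delta distributions fuse to the same delta under both methods", {
  delta <- c(0, 0, 1, 0, 0)
  outs <- lapply(1:3, function(j) {
    submodel_output(paste0("m", j), "c1", delta)
  })
  case <- case_record("c1", text = "t")
  alpha <- c(m1 = 0.4, m2 = 0.6, m3 = 0.2)
  fd_re <- fuse_case(case, outs, "reliability_entropy", alpha)
  expect_equal(unname(fd_re$probs), delta, tolerance = 1e-12)
  expect_identical(fd_re$ranking[1], "SevereDR")
  fd_rk <- fuse_case(case, outs, "rank", alpha)
  expect_identical(fd_rk$ranking[1], "SevereDR")
})
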