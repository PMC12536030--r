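# Independent, deliberately naive reference implementations used as oracles.
# These share no code with the package paths they check.

oracle_entropy <- function(p) {
  s <- 0
  for (x in p) if (x > 0) s <- s - x * log(x)
  s
}

# rank fusion by explicit sorting, one class at a time
oracle_rank_fusion <- function(prob_list) {
  k <- length(prob_list[[1]])
  score <- numeric(k)
  for (p in prob_list) {
    ord <- order(-p, seq_len(k))
    for (pos in seq_len(k)) {
      score[ord[pos]] <- score[ord[pos]] + 1 / pos
    }
  }
  score / sum(score)
}

oracle_rel_entropy_fusion <- function(prob_list, alpha) {
  k <- length(prob_list[[1]])
  hmax <- log(k)
  score <- numeric(k)
  for (j in seq_along(prob_list)) {
    p <- prob_list[[j]]
    w <- alpha[j] * (1 - oracle_entropy(p) / hmax)
    for (c in seq_len(k)) score[c] <- score[c] + w * p[c]
  }
  if (sum(score) == 0) rep(1 / k, k) else score / sum(score)
}

oracle_true_rank <- function(p, truth_idx) {
  ord <- order(-p, seq_along(p))
  which(ord == truth_idx)
}

oracle_top_k <- function(prob_list, truth_idx, k) {
  mean(vapply(seq_along(prob_list), function(i) {
    oracle_true_rank(prob_list[[i]], truth_idx[i]) <= k
  }, logical(1)))
}

oracle_mrr <- function(prob_list, truth_idx) {
  mean(vapply(seq_along(prob_list), function(i) {
    1 / oracle_true_rank(prob_list[[i]], truth_idx[i])
  }, numeric(1)))
}

oracle_brier <- function(prob_list, truth_idx) {
  total <- 0
  for (i in seq_along(prob_list)) {
    for (c in seq_along(prob_list[[i]])) {
      y <- if (c == truth_idx[i]) 1 else 0
      total <- total + (prob_list[[i]][c] - y)^2
    }
  }
  total / length(prob_list)
}

# random distribution over k classes (uniform on the simplex)
random_prob <- function(k = 5) {
  g <- -log(runif(k))
  g / sum(g)
}

random_outputs <- function(n_sub, case_id = "c1", k = 5,
                           labels = retinal_labels()) {
  lapply(seq_len(n_sub), function(j) {
    submodel_output(paste0("m", j), case_id, random_prob(k), labels = labels)
  })
}
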