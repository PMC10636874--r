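# Shared fixture builders and independent oracles used across test files.

# random connected symmetric nonnegative adjacency (guaranteed connected by
# laying down a random spanning tree first)
random_connected_adjacency <- function(n, extra_edge_prob = 0.15) {
  G <- matrix(0, n, n)
  for (i in 2:n) {
    j <- sample.int(i - 1, 1)
    w <- runif(1, 0.1, 1)
    G[i, j] <- w; G[j, i] <- w
  }
  extra <- which(upper.tri(G) & G == 0)
  pick <- extra[runif(length(extra)) < extra_edge_prob]
  w <- runif(length(pick), 0.1, 1)
  G[pick] <- w
  G <- pmax(G, t(G))
  G
}

# scalar-loop PPMI oracle, independent of the vectorized implementation
ppmi_oracle <- function(P, log_base = exp(1)) {
  total <- sum(P)
  r <- rowSums(P); cs <- colSums(P)
  X <- matrix(0, nrow(P), ncol(P))
  for (i in seq_len(nrow(P))) for (j in seq_len(ncol(P))) {
    if (P[i, j] > 0)
      X[i, j] <- max(0, log(P[i, j] * total / (r[i] * cs[j]), base = log_base))
  }
  X
}

# brute-force Fmax scan built only on per_gene_pr
fmax_oracle <- function(predictions, truth, grid) {
  best <- -Inf; best_t <- NA
  for (t in grid) {
    prec <- numeric(0); rec <- numeric(0)
    for (id in names(truth$terms)) {
      p_i <- if (id %in% rownames(predictions))
        colnames(predictions)[predictions[id, ] >= t] else character(0)
      pr <- per_gene_pr(p_i, truth$terms[[id]])
      if (length(p_i) > 0) prec <- c(prec, pr[["precision"]])
      rec <- c(rec, pr[["recall"]])
    }
    if (length(prec) == 0) next
    Pr <- mean(prec); Rc <- mean(rec)
    f <- if (Pr + Rc > 0) 2 * Pr * Rc / (Pr + Rc) else 0
    if (f > best) { best <- f; best_t <- t }
  }
  list(fmax = best, t_star = best_t)
}

# random prediction matrix + truth set over a small term universe
random_eval_instance <- function(max_lnc = 10, max_terms = 8) {
  n_l <- sample(2:max_lnc, 1)
  n_t <- sample(2:max_terms, 1)
  terms <- sprintf("GO:%07d", seq_len(n_t))
  lnc <- sprintf("LNC%02d", seq_len(n_l))
  scores <- matrix(round(runif(n_l * n_t), 2), n_l, n_t,
                   dimnames = list(lnc, terms))
  tr <- lapply(lnc, function(i) sample(terms, sample.int(n_t, 1)))
  names(tr) <- lnc
  list(predictions = scores, truth = truth_set(tr))
}

# small bundle for fast end-to-end tests
tiny_bundle <- function(seed = 7, ...) {
  generate_bundle(synth_config(n_l = 12, n_p = 24, n_m = 6, g = 2,
                               p_in = 0.4, p_out = 0.05, terms_per_group = 2,
                               seed = seed, ...))
}

fast_pipeline_config <- function(seed = 7, ...) {
  pipeline_config(sdae_widths = c(16, 8), epochs = 60, min_positives = 5,
                  seed = seed, ...)
}
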