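ann_df <- function(...) {
  rows <- list(...)
  annotation_table(data.frame(
    protein_id = vapply(rows, `[`, "", 1),
    go_term = vapply(rows, `[`, "", 2),
    evidence = vapply(rows, `[`, "", 3),
    stringsAsFactors = FALSE))
}

test_that("annotation_table validates GO ids and collapses duplicates", {
  expect_error(ann_df(c("p1", "GO:12", "EXP")), "malformed")
  tab <- ann_df(c("p1", "GO:0000001", "EXP"), c("p1", "GO:0000001", "EXP"))
  expect_equal(nrow(tab), 1)
})

test_that("filter_non_iea removes only proteins with IEA-only annotations", {
  tab <- ann_df(c("only_iea", "GO:0000001", "IEA"),
                c("only_iea", "GO:0000002", "IEA"),
                c("mixed", "GO:0000001", "EXP"),
                c("mixed", "GO:0000003", "IEA"),
                c("manual", "GO:0000002", "IDA"))
  out <- filter_non_iea(tab)
  expect_false("only_iea" %in% out$protein_id)
  # mixed-evidence protein keeps ALL its records, including the IEA one
  expect_equal(sum(out$protein_id == "mixed"), 2)
  expect_true("manual" %in% out$protein_id)
  empty <- tab[0, , drop = FALSE]
  expect_equal(nrow(filter_non_iea(empty)), 0)
})

test_that("propagation follows is_a/part_of ancestry when enabled", {
  tab <- ann_df(c("p1", "GO:0000003", "EXP"))
  chain <- data.frame(child = c("GO:0000003", "GO:0000002"),
                      parent = c("GO:0000002", "GO:0000001"))
  # disabled (default) is the identity
  expect_identical(propagate_annotations(tab, chain), tab)
  out <- propagate_annotations(tab, chain, enabled = TRUE)
  expect_setequal(out$go_term,
                  c("GO:0000001", "GO:0000002", "GO:0000003"))

  # diamond DAG matches brute-force reachability
  diamond <- data.frame(
    child = c("GO:0000004", "GO:0000004", "GO:0000002", "GO:0000003"),
    parent = c("GO:0000002", "GO:0000003", "GO:0000001", "GO:0000001"))
  tab2 <- ann_df(c("p1", "GO:0000004", "EXP"))
  out2 <- propagate_annotations(tab2, diamond, enabled = TRUE)
  # independent oracle: iterate edge relation to a fixed point
  reach <- "GO:0000004"
  repeat {
    nxt <- unique(c(reach, diamond$parent[diamond$child %in% reach]))
    if (length(nxt) == length(reach)) break
    reach <- nxt
  }
  expect_setequal(out2$go_term, reach)

  cyc <- data.frame(child = c("GO:0000001", "GO:0000002"),
                    parent = c("GO:0000002", "GO:0000001"))
  expect_error(propagate_annotations(tab, cyc, enabled = TRUE), "cycle")
})

toy_embeddings <- function(n, d = 4, seed = 1, prefix = "P") {
  set.seed(seed)
  m <- matrix(runif(n * d), n, d)
  rownames(m) <- sprintf("%s%03d", prefix, seq_len(n))
  m
}

test_that("term training sets are balanced, disjoint and seeded", {
  emb <- toy_embeddings(100)
  tab <- annotation_table(data.frame(
    protein_id = rownames(emb)[1:10], go_term = "GO:0000001",
    evidence = "EXP"))
  ts <- build_term_training_set("GO:0000001", tab, emb, seed = 5)
  expect_length(ts$negatives, 10)
  expect_length(intersect(ts$positives, ts$negatives), 0)
  ts2 <- build_term_training_set("GO:0000001", tab, emb, seed = 5)
  expect_identical(ts$negatives, ts2$negatives)
  ts3 <- build_term_training_set("GO:0000001", tab, emb, seed = 6)
  expect_false(identical(ts$negatives, ts3$negatives))

  # below min_positives the term is skipped
  small <- annotation_table(tab[1:2, ])
  expect_null(build_term_training_set("GO:0000001", small, emb,
                                      min_positives = 10))
  # not enough candidate negatives
  expect_null(build_term_training_set("GO:0000001", tab, emb[1:15, ],
                                      min_positives = 5))
})

separable_ts <- function(seed = 1, n = 20, margin = 3) {
  set.seed(seed)
  x <- rbind(matrix(rnorm(n * 2), n, 2) + margin,
             matrix(rnorm(n * 2), n, 2) - margin)
  rownames(x) <- sprintf("P%03d", seq_len(2 * n))
  structure(list(term = "GO:0000001",
                 positives = rownames(x)[1:n],
                 negatives = rownames(x)[(n + 1):(2 * n)],
                 x = x,
                 y = factor(rep(c("pos", "neg"), each = n),
                            levels = c("neg", "pos")),
                 seed = seed),
            class = "term_training_set")
}

test_that("a separable toy problem is classified perfectly with calibrated scores", {
  ts <- separable_ts()
  clf <- train_term_classifier(ts, seed = 3)
  p <- predict_term_scores(clf, ts$x)
  expect_true(all(p >= 0 & p <= 1))
  expect_equal(mean((p > 0.5) == (ts$y == "pos")), 1)
})

test_that("permuted labels give chance-level cross-validated accuracy", {
  set.seed(77)
  n <- 30
  x <- matrix(rnorm(2 * n * 4), 2 * n, 4)
  rownames(x) <- sprintf("P%03d", seq_len(2 * n))
  y <- factor(sample(rep(c("pos", "neg"), n)), levels = c("neg", "pos"))
  folds <- rep(1:5, length.out = 2 * n)
  acc <- numeric(5)
  for (k in 1:5) {
    ts <- structure(list(term = "GO:0000001",
                         positives = rownames(x)[folds != k & y == "pos"],
                         negatives = rownames(x)[folds != k & y == "neg"],
                         x = x[folds != k, ], y = y[folds != k], seed = k),
                    class = "term_training_set")
    clf <- train_term_classifier(ts, seed = k)
    p <- predict_term_scores(clf, x[folds == k, ])
    acc[k] <- mean((p > 0.5) == (y[folds == k] == "pos"))
  }
  expect_lt(abs(mean(acc) - 0.5), 0.15)
})

test_that("degenerate features are rejected", {
  ts <- separable_ts()
  ts$x <- matrix(1, nrow(ts$x), 2, dimnames = dimnames(ts$x))
  expect_error(train_term_classifier(ts), "degenerate")
})

test_that("prediction matrices have the right shape, range and width checks", {
  ts <- separable_ts()
  clf <- train_term_classifier(ts, seed = 3)
  lnc <- ts$x[1:5, ]
  rownames(lnc) <- paste0("LNC", 1:5)
  pm <- predict_lncrna_functions(list("GO:0000001" = clf), lnc)
  expect_equal(dim(pm), c(5, 1))
  expect_true(all(pm >= 0 & pm <= 1))
  # an lncRNA whose embedding matches a strong positive scores high
  expect_gt(pm[1, "GO:0000001"], 0.5)

  empty <- predict_lncrna_functions(list(), lnc)
  expect_equal(dim(empty), c(5, 0))

  expect_error(predict_term_scores(clf, lnc[, 1, drop = FALSE]), "width")
})

test_that("training uses proteins only: no lncRNA id can enter a training set", {
  b <- tiny_bundle()
  emb <- toy_embeddings(b$config$n_p, seed = 2)
  rownames(emb) <- b$index$ids$protein
  for (tm in unique(b$annotations$go_term)) {
    ts <- build_term_training_set(tm, b$annotations, emb, seed = 1,
                                  min_positives = 2)
    ids <- c(ts$positives, ts$negatives)
    expect_true(all(ids %in% b$index$ids$protein))
    expect_false(any(ids %in% b$index$ids$lncrna))
  }
})

test_that("planted structure yields informative held-out term classifiers", {
  # embeddings from the real pipeline on a structured bundle; each modeled
  # term's held-out AUROC should clear chance by 3 standard errors for at
  # least 80% of terms
  b <- generate_bundle(synth_config(seed = 19))
  gn <- assemble_global(b$L, b$P, b$M, b$LP, b$LM, b$PM, b$index)
  X <- ppmi(rwr(transition_matrix(gn), alpha = 0.5))
  st <- train_sdae(X, sdae_config(c(nrow(X), 32, 16), epochs = 100,
                                  learning_rate = 1e-2, seed = 19))
  emb <- encode(st, X)
  prot <- b$index$ids$protein
  pe <- emb[global_index(b$index, prot), , drop = FALSE]
  rownames(pe) <- prot
  terms <- unique(b$annotations$go_term)
  set.seed(19)
  hold <- sample(prot, 20)
  train_ann <- annotation_table(
    b$annotations[!b$annotations$protein_id %in% hold, , drop = FALSE])
  ok <- 0; modeled <- 0
  for (tm in terms) {
    ts <- build_term_training_set(tm, train_ann, pe[setdiff(prot, hold), ],
                                  seed = derive_seed(19, tm),
                                  min_positives = 5)
    if (is.null(ts)) next
    modeled <- modeled + 1
    clf <- train_term_classifier(ts, seed = derive_seed(19, tm))
    p <- predict_term_scores(clf, pe[hold, ])
    truth_pos <- hold %in% b$annotations$protein_id[b$annotations$go_term == tm]
    n1 <- sum(truth_pos); n0 <- sum(!truth_pos)
    if (n1 == 0 || n0 == 0) { modeled <- modeled - 1; next }
    auc <- (sum(rank(p)[truth_pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
    se <- sqrt((n1 + n0 + 1) / (12 * n1 * n0))  # Wilcoxon null SE
    if (auc > 0.5 + 3 * se) ok <- ok + 1
  }
  expect_gt(modeled, 0)
  expect_gte(ok / modeled, 0.8)
})
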