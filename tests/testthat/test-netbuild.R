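test_that("pcc_similarity reproduces pairwise Pearson correlations", {
  # identical profiles correlate perfectly
  expr <- rbind(a = c(1, 2, 3, 4), b = c(1, 2, 3, 4), c = c(4, 1, 3, 2))
  net <- pcc_similarity(expr)
  e <- net$edges
  ab <- e[e$id_a == "a" & e$id_b == "b", ]
  expect_equal(ab$weight, 1.0)

  # perfectly anticorrelated pair is clipped away
  expr2 <- rbind(x = c(1, 2, 3), y = c(3, 2, 1))
  expect_equal(n_edges(pcc_similarity(expr2)), 0)
  expect_equal(n_edges(pcc_similarity(expr2, clip_negative = FALSE)), 1)

  # random matrix matches a brute-force per-pair recomputation
  set.seed(11)
  m <- matrix(rnorm(40), 5, 8, dimnames = list(paste0("e", 1:5), NULL))
  net3 <- pcc_similarity(m)
  for (i in 1:4) for (j in (i + 1):5) {
    r <- cor(m[i, ], m[j, ])
    row <- net3$edges[net3$edges$id_a == paste0("e", i) &
                        net3$edges$id_b == paste0("e", j), ]
    if (r > 0) expect_equal(row$weight, r) else expect_equal(nrow(row), 0)
  }
  # no self-similarity edges
  expect_false(any(net3$edges$id_a == net3$edges$id_b))
})

test_that("pcc_similarity is invariant to positive per-row affine transforms", {
  set.seed(3)
  m <- matrix(rnorm(48), 6, 8, dimnames = list(paste0("e", 1:6), NULL))
  m2 <- sweep(sweep(m, 1, runif(6, 0.5, 3), "*"), 1, rnorm(6), "+")
  rownames(m2) <- rownames(m)
  n1 <- pcc_similarity(m); n2 <- pcc_similarity(m2)
  expect_equal(n1$edges$weight, n2$edges$weight, tolerance = 1e-10)
  expect_equal(n1$edges$id_a, n2$edges$id_a)
})

test_that("pcc_similarity rejects degenerate input, naming the entity", {
  expr <- rbind(good = c(1, 2, 3), flat = c(5, 5, 5))
  expect_error(pcc_similarity(expr), "flat")
  expect_error(pcc_similarity(rbind(a = 1, b = 2)), "samples")
  expect_error(pcc_similarity(rbind(a = c(1, 2))), "entities")
})

test_that("fuse_scores applies the noisy-OR rule after dropping negatives", {
  one <- function(...) {
    src <- lapply(list(...), function(s)
      data.frame(id_a = "l1", id_b = "p1", score = s))
    out <- fuse_scores(src)
    if (nrow(out) == 0) NA_real_ else out$weight
  }
  expect_equal(one(0.8), 0.8)                      # single source identity
  expect_equal(one(0.5, 0.5), 0.75)
  expect_equal(one(0.6, -0.3, 0.2), 1 - 0.4 * 0.8) # 0.68, negatives removed
  expect_true(is.na(one(-0.5, -0.1)))              # no positive score: absent
  expect_error(one(1.2), "probability-like")
})

test_that("fusion is monotone and bounded by each positive source", {
  set.seed(5)
  for (rep in 1:20) {
    k <- sample(1:4, 1)
    s <- runif(k, 0.01, 0.99)
    srcs <- lapply(s, function(v) data.frame(id_a = "l", id_b = "p", score = v))
    fused <- fuse_scores(srcs)$weight
    expect_gte(fused, max(s) - 1e-12)
    expect_lte(fused, 1)
    # adding a positive source never decreases the fused score
    extra <- runif(1, 0.01, 0.99)
    fused2 <- fuse_scores(c(srcs, list(
      data.frame(id_a = "l", id_b = "p", score = extra))))$weight
    expect_gte(fused2, fused - 1e-12)
  }
})

test_that("binarize_interactions builds unit-weight networks with set semantics", {
  idx <- entity_index(paste0("l", 1:4), paste0("p", 1:4), character())
  pairs <- data.frame(id_a = c("l1", "l2", "l3"), id_b = c("p1", "p2", "p3"))
  net <- binarize_interactions(pairs, idx, "lncrna", "protein")
  expect_equal(n_edges(net), 3)
  expect_true(all(net$edges$weight == 1))

  expect_equal(n_edges(binarize_interactions(
    data.frame(id_a = character(), id_b = character()), idx,
    "lncrna", "protein")), 0)

  dup <- data.frame(id_a = c("l1", "l1"), id_b = c("p1", "p1"))
  expect_equal(n_edges(binarize_interactions(dup, idx, "lncrna", "protein")), 1)

  bad <- data.frame(id_a = "l1", id_b = "zz9")
  expect_error(binarize_interactions(bad, idx, "lncrna", "protein"), "zz9")
})

empty_net <- function(ka, kb) component_network(NULL, ka, kb)

test_that("assemble_global lays out blocks with exact symmetry", {
  idx <- entity_index(c("l1", "l2"), c("p1", "p2"), "m1")
  # all-empty components give the zero matrix of the right dimension
  gn0 <- assemble_global(empty_net("lncrna", "lncrna"),
                         empty_net("protein", "protein"),
                         empty_net("mirna", "mirna"),
                         empty_net("lncrna", "protein"),
                         empty_net("lncrna", "mirna"),
                         empty_net("protein", "mirna"), idx)
  expect_equal(dim(gn0$G), c(5, 5))
  expect_equal(Matrix::nnzero(gn0$G), 0)

  # hand placement: LP edge (l1, p2, 0.5) lands at rows/cols (1, 4)
  lp <- component_network(data.frame(id_a = "l1", id_b = "p2", weight = 0.5),
                          "lncrna", "protein")
  gn <- assemble_global(empty_net("lncrna", "lncrna"),
                        empty_net("protein", "protein"),
                        empty_net("mirna", "mirna"), lp,
                        empty_net("lncrna", "mirna"),
                        empty_net("protein", "mirna"), idx)
  G <- as.matrix(gn$G)
  expect_equal(G[1, 4], 0.5)
  expect_equal(G[4, 1], 0.5)
  expect_equal(sum(G != 0), 2)
})

test_that("assembled global networks are symmetric and nonnegative on random fixtures", {
  for (s in 1:5) {
    b <- generate_bundle(synth_config(n_l = 10, n_p = 15, n_m = 5, g = 2,
                                      seed = s))
    gn <- assemble_global(b$L, b$P, b$M, b$LP, b$LM, b$PM, b$index)
    expect_equal(max(abs(gn$G - Matrix::t(gn$G))), 0)
    expect_gte(min(gn$G@x, 0), 0)
    expect_equal(nrow(gn$G), 30)
  }
})

test_that("block extraction recovers each component network bit-exactly", {
  b <- generate_bundle(synth_config(n_l = 10, n_p = 15, n_m = 5, g = 2,
                                    seed = 42))
  gn <- assemble_global(b$L, b$P, b$M, b$LP, b$LM, b$PM, b$index)
  for (spec in list(list("L", "lncrna", "lncrna"),
                    list("P", "protein", "protein"),
                    list("M", "mirna", "mirna"),
                    list("LP", "lncrna", "protein"),
                    list("LM", "lncrna", "mirna"),
                    list("PM", "protein", "mirna"))) {
    got <- network_block(gn, spec[[2]], spec[[3]])$edges
    want <- b[[spec[[1]]]]$edges
    ord <- function(e) e[order(e$id_a, e$id_b), ]
    g <- ord(got); w <- ord(want)
    expect_identical(g$id_a, w$id_a)
    expect_identical(g$weight, w$weight)
  }
})

test_that("assemble_global rejects invalid components", {
  idx <- entity_index(c("l1", "l2"), c("p1", "p2"), "m1")
  wrong_kind <- component_network(
    data.frame(id_a = "l1", id_b = "l2", weight = 1), "lncrna", "lncrna")
  expect_error(
    assemble_global(empty_net("lncrna", "lncrna"),
                    empty_net("protein", "protein"),
                    empty_net("mirna", "mirna"),
                    wrong_kind,  # an L-type network in the LP slot
                    empty_net("lncrna", "mirna"),
                    empty_net("protein", "mirna"), idx),
    "kinds")
  neg <- component_network(
    data.frame(id_a = "l1", id_b = "l2", weight = -0.2), "lncrna", "lncrna",
    allow_negative = TRUE)
  expect_error(
    assemble_global(neg, empty_net("protein", "protein"),
                    empty_net("mirna", "mirna"),
                    empty_net("lncrna", "protein"),
                    empty_net("lncrna", "mirna"),
                    empty_net("protein", "mirna"), idx),
    "nonnegative")
})

test_that("duplicate undirected records must agree in weight", {
  e <- data.frame(id_a = c("a", "b"), id_b = c("b", "a"),
                  weight = c(0.5, 0.5))
  net <- component_network(e, "lncrna", "lncrna")
  expect_equal(n_edges(net), 1)
  e$weight <- c(0.5, 0.6)
  expect_error(component_network(e, "lncrna", "lncrna"), "conflicting")
})

test_that("merge_max_weight keeps experimental certainty", {
  fused <- data.frame(id_a = c("l1", "l2"), id_b = c("p1", "p2"),
                      weight = c(0.4, 0.9))
  binary <- data.frame(id_a = "l1", id_b = "p1", weight = 1)
  m <- merge_max_weight(fused, binary)
  expect_equal(m$weight[m$id_a == "l1"], 1)
  expect_equal(m$weight[m$id_a == "l2"], 0.9)
})
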