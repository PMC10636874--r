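#' Component networks
#'
#' A component network is a sparse weighted edge list between two entity
#' kinds. Intra-kind networks (`kind_a == kind_b`) are undirected with no
#' self-loops; only strictly positive weights are stored (confidence-like
#' similarity or association scores).
#'
#' @param edges A data.frame with columns `id_a`, `id_b`, `weight` (zero rows
#'   allowed). Duplicate records of the same undirected pair must agree in
#'   weight within 1e-9.
#' @param kind_a,kind_b Entity kinds, each one of `"lncrna"`, `"protein"`,
#'   `"mirna"`.
#' @param allow_negative Keep edges with negative weight (used only when a
#'   caller explicitly opts out of clipping; such networks cannot enter the
#'   global network, which must be nonnegative).
#' @return An object of class `component_network`.
#' @export
component_network <- function(edges, kind_a, kind_b, allow_negative = FALSE) {
  kind_a <- match.arg(kind_a, index_kinds)
  kind_b <- match.arg(kind_b, index_kinds)
  if (is.null(edges) || nrow(edges) == 0) {
    edges <- data.frame(id_a = character(), id_b = character(),
                        weight = numeric(), stringsAsFactors = FALSE)
  }
  stopifnot(all(c("id_a", "id_b", "weight") %in% names(edges)))
  edges <- data.frame(id_a = as.character(edges$id_a),
                      id_b = as.character(edges$id_b),
                      weight = as.numeric(edges$weight),
                      stringsAsFactors = FALSE)
  if (anyNA(edges$weight)) stop("non-numeric edge weight")
  if (!allow_negative && any(edges$weight <= 0))
    stop("component networks store strictly positive weights; got ",
         sum(edges$weight <= 0), " non-positive edge(s)")
  intra <- kind_a == kind_b
  if (intra && any(edges$id_a == edges$id_b))
    stop("self-loops are not allowed in intra-kind networks")
  if (nrow(edges) > 0) {
    # canonical orientation: intra-kind pairs sorted lexicographically so
    # duplicate (a,b)/(b,a) records collapse onto one key
    if (intra) {
      flip <- edges$id_a > edges$id_b
      tmp <- edges$id_a[flip]
      edges$id_a[flip] <- edges$id_b[flip]
      edges$id_b[flip] <- tmp
    }
    key <- paste(edges$id_a, edges$id_b, sep = "\r")
    if (anyDuplicated(key)) {
      rng <- tapply(edges$weight, key, function(w) diff(range(w)))
      bad <- names(rng)[rng > 1e-9]
      if (length(bad) > 0)
        stop("conflicting duplicate edge weights for pair(s): ",
             paste(gsub("\r", "--", bad), collapse = ", "))
      edges <- edges[!duplicated(key), , drop = FALSE]
    }
    rownames(edges) <- NULL
  }
  structure(list(edges = edges, kind_a = kind_a, kind_b = kind_b),
            class = "component_network")
}

#' @export
print.component_network <- function(x, ...) {
  cat("component_network", x$kind_a, "-", x$kind_b, ":", nrow(x$edges),
      "edges\n")
  invisible(x)
}

#' Number of edges in a component network
#' @param net A [component_network()].
#' @export
n_edges <- function(net) nrow(net$edges)

#' Pearson co-expression similarity network
#'
#' Computes the Pearson correlation coefficient (PCC) between every pair of
#' entities from their expression profiles and stores the positive
#' correlations as an intra-kind similarity network. Negative and zero
#' correlations are absent by default (the global network must stay
#' nonnegative for the walk probabilities to be well formed); the diagonal is
#' always excluded.
#'
#' @param expr Numeric matrix, rows = entities (rownames are ids),
#'   columns = samples. At least 2 entities and 2 samples; every row must
#'   have nonzero variance.
#' @param kind Entity kind of the rows.
#' @param clip_negative If `TRUE` (default) pairs with PCC <= 0 are absent;
#'   if `FALSE`, negative correlations are kept as (non-assemblable) signed
#'   edges.
#' @return A [component_network()] with `kind_a == kind_b == kind`.
#' @export
pcc_similarity <- function(expr, kind = "lncrna", clip_negative = TRUE) {
  expr <- as.matrix(expr)
  if (is.null(rownames(expr))) stop("expression matrix must have row ids")
  if (anyDuplicated(rownames(expr))) stop("duplicate entity ids in expression matrix")
  if (nrow(expr) < 2) stop("need at least 2 entities for pairwise correlation")
  if (ncol(expr) < 2) stop("need at least 2 samples for correlation")
  v <- apply(expr, 1, stats::var)
  if (any(v == 0))
    stop("zero-variance expression profile for: ",
         paste(rownames(expr)[v == 0], collapse = ", "))
  cc <- stats::cor(t(expr))
  ut <- which(upper.tri(cc), arr.ind = TRUE)
  w <- cc[ut]
  keep <- if (clip_negative) w > 0 else w != 0
  edges <- data.frame(id_a = rownames(expr)[ut[keep, 1]],
                      id_b = rownames(expr)[ut[keep, 2]],
                      weight = w[keep], stringsAsFactors = FALSE)
  component_network(edges, kind, kind, allow_negative = !clip_negative)
}

#' Fuse per-source correlation scores into one confidence score
#'
#' Combines the correlation scores of several expression sources for each
#' (lncRNA, protein) pair into a single score by the noisy-OR style rule
#' S = 1 - prod(1 - S_n), taken over the positive source scores only;
#' negative correlation scores are removed first. Pairs with no positive
#' score are absent from the result.
#'
#' @param sources A list of data.frames, each with columns `id_a`, `id_b`,
#'   `score`; scores must be <= 1 (probability-like).
#' @return A data.frame `id_a, id_b, weight` with fused scores in (0, 1].
#' @examples
#' fuse_scores(list(data.frame(id_a = "l1", id_b = "p1", score = 0.5),
#'                  data.frame(id_a = "l1", id_b = "p1", score = 0.5)))
#' # weight 0.75
#' @export
fuse_scores <- function(sources) {
  if (!is.list(sources) || length(sources) < 1)
    stop("need at least one score source")
  if (is.data.frame(sources)) sources <- list(sources)
  all <- do.call(rbind, lapply(sources, function(s) {
    stopifnot(all(c("id_a", "id_b", "score") %in% names(s)))
    data.frame(id_a = as.character(s$id_a), id_b = as.character(s$id_b),
               score = as.numeric(s$score), stringsAsFactors = FALSE)
  }))
  if (any(all$score > 1))
    stop("source scores must be probability-like (<= 1); got max ",
         max(all$score))
  pos <- all[all$score > 0, , drop = FALSE]
  if (nrow(pos) == 0)
    return(data.frame(id_a = character(), id_b = character(),
                      weight = numeric(), stringsAsFactors = FALSE))
  key <- paste(pos$id_a, pos$id_b, sep = "\r")
  fused <- tapply(pos$score, key, function(s) 1 - prod(1 - s))
  parts <- strsplit(names(fused), "\r", fixed = TRUE)
  out <- data.frame(id_a = vapply(parts, `[`, "", 1),
                    id_b = vapply(parts, `[`, "", 2),
                    weight = as.numeric(fused), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out[order(out$id_a, out$id_b), , drop = FALSE]
}

#' Binary interaction network from a pair list
#'
#' Experimentally verified interaction pairs get weight 1; everything else is
#' absent. Duplicate pairs collapse to a single edge.
#'
#' @param pairs data.frame with columns `id_a`, `id_b`.
#' @param index An [entity_index()]; every id must be known.
#' @param kind_a,kind_b Entity kinds of the two columns.
#' @return A [component_network()].
#' @export
binarize_interactions <- function(pairs, index, kind_a, kind_b) {
  if (is.null(pairs) || nrow(pairs) == 0) {
    return(component_network(NULL, kind_a, kind_b))
  }
  ids <- unique(c(as.character(pairs$id_a), as.character(pairs$id_b)))
  known <- unlist(index$ids, use.names = FALSE)
  bad <- setdiff(ids, known)
  if (length(bad) > 0)
    stop("interaction pairs reference unknown ids: ",
         paste(bad, collapse = ", "))
  edges <- data.frame(id_a = as.character(pairs$id_a),
                      id_b = as.character(pairs$id_b),
                      weight = 1, stringsAsFactors = FALSE)
  component_network(edges, kind_a, kind_b)
}

#' Merge two edge tables for the same kind pair, taking the maximum weight
#'
#' Used when the same pair carries both a fused co-expression score and a
#' binary experimental interaction: both are confidence-like in \[0, 1\] and
#' the maximum preserves experimental certainty.
#'
#' @param a,b data.frames with `id_a`, `id_b`, `weight`.
#' @return A merged data.frame.
#' @export
merge_max_weight <- function(a, b) {
  all <- rbind(a[, c("id_a", "id_b", "weight")], b[, c("id_a", "id_b", "weight")])
  key <- paste(all$id_a, all$id_b, sep = "\r")
  mx <- tapply(all$weight, key, max)
  first <- all[!duplicated(key), c("id_a", "id_b"), drop = FALSE]
  first$weight <- as.numeric(mx[paste(first$id_a, first$id_b, sep = "\r")])
  rownames(first) <- NULL
  first
}

block_spec <- list(L = c("lncrna", "lncrna"), P = c("protein", "protein"),
                   M = c("mirna", "mirna"), LP = c("lncrna", "protein"),
                   LM = c("lncrna", "mirna"), PM = c("protein", "mirna"))

#' Assemble the global heterogeneous network
#'
#' Stacks the six component networks into one symmetric nonnegative block
#' adjacency matrix over all nodes, in fixed block order lncRNA, protein,
#' miRNA:
#' \preformatted{
#'       [ L    LP   LM ]
#'   G = [ LP'  P    PM ]
#'       [ LM'  PM'  M  ]
#' }
#' Off-diagonal blocks are mirrored by their transpose so G is exactly
#' symmetric.
#'
#' @param L,P,M Intra-kind similarity networks (lncRNA, protein, miRNA).
#' @param LP,LM,PM Inter-kind association networks.
#' @param index An [entity_index()] resolving every edge endpoint.
#' @return An object of class `global_network` with elements `index` and `G`
#'   (a sparse symmetric `Matrix::dgCMatrix`).
#' @export
assemble_global <- function(L, P, M, LP, LM, PM, index) {
  comps <- list(L = L, P = P, M = M, LP = LP, LM = LM, PM = PM)
  n <- index$n_total
  ii <- integer(0); jj <- integer(0); ww <- numeric(0)
  for (nm in names(comps)) {
    comp <- comps[[nm]]
    if (!inherits(comp, "component_network"))
      stop("component ", nm, " is not a component_network")
    want <- block_spec[[nm]]
    if (!identical(c(comp$kind_a, comp$kind_b), want))
      stop("component ", nm, " has kinds (", comp$kind_a, ", ", comp$kind_b,
           "); expected (", want[1], ", ", want[2], ")")
    e <- comp$edges
    if (nrow(e) == 0) next
    if (any(e$weight < 0))
      stop("component ", nm, " has negative weights; the global network must be nonnegative")
    ka <- entity_kind(index, e$id_a)
    kb <- entity_kind(index, e$id_b)
    ok <- (ka == want[1] & kb == want[2]) | (ka == want[2] & kb == want[1])
    if (!all(ok))
      stop("component ", nm, " has edges whose endpoint kinds do not match its block")
    # orient inter-kind edges so id_a always carries the block's row kind,
    # then collapse duplicates (both orientations supplied must agree)
    flip <- ka == want[2] & kb == want[1] & want[1] != want[2]
    if (any(flip)) {
      tmp <- e$id_a[flip]
      e$id_a[flip] <- e$id_b[flip]
      e$id_b[flip] <- tmp
    }
    key <- paste(e$id_a, e$id_b, sep = "\r")
    if (anyDuplicated(key)) {
      rng <- tapply(e$weight, key, function(w) diff(range(w)))
      bad <- names(rng)[rng > 1e-9]
      if (length(bad) > 0)
        stop("component ", nm, " has conflicting duplicate edges: ",
             paste(gsub("\r", "--", bad), collapse = ", "))
      e <- e[!duplicated(key), , drop = FALSE]
    }
    i <- global_index(index, e$id_a)
    j <- global_index(index, e$id_b)
    # place each edge and its mirror; intra-kind diagonals were excluded at
    # component construction
    ii <- c(ii, i, j); jj <- c(jj, j, i); ww <- c(ww, e$weight, e$weight)
  }
  G <- Matrix::sparseMatrix(i = ii, j = jj, x = ww, dims = c(n, n),
                            dimnames = list(index_ids(index), index_ids(index)))
  structure(list(index = index, G = G), class = "global_network")
}

#' @export
print.global_network <- function(x, ...) {
  cat("global_network:", nrow(x$G), "nodes,", Matrix::nnzero(x$G),
      "nonzero entries\n")
  invisible(x)
}

#' Extract one block of the global network as a component network
#'
#' @param gn A `global_network`.
#' @param kind_a,kind_b The block to extract.
#' @return A [component_network()] (upper-triangle edges for intra-kind
#'   blocks).
#' @export
network_block <- function(gn, kind_a, kind_b) {
  idx <- gn$index
  rows <- global_index(idx, idx$ids[[kind_a]])
  cols <- global_index(idx, idx$ids[[kind_b]])
  B <- gn$G[rows, cols, drop = FALSE]
  tb <- Matrix::summary(methods::as(B, "TsparseMatrix"))
  keep <- tb$x != 0
  if (kind_a == kind_b) keep <- keep & tb$i < tb$j
  edges <- data.frame(id_a = idx$ids[[kind_a]][tb$i[keep]],
                      id_b = idx$ids[[kind_b]][tb$j[keep]],
                      weight = tb$x[keep], stringsAsFactors = FALSE)
  component_network(edges, kind_a, kind_b)
}

#' Drop the miRNA block from a global network (ablation)
#'
#' Removes every miRNA row and column, leaving the lncRNA and protein blocks
#' bit-identical — the "network without miRNAs" ablation configuration.
#'
#' @param gn A `global_network`.
#' @return A `global_network` over lncRNA and protein nodes only.
#' @export
drop_mirna <- function(gn) {
  idx <- gn$index
  new_idx <- entity_index(idx$ids$lncrna, idx$ids$protein, character())
  keep <- seq_len(idx$offsets[["mirna"]])
  structure(list(index = new_idx, G = gn$G[keep, keep, drop = FALSE]),
            class = "global_network")
}
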