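#' Transition matrix of the global network
#'
#' Normalizes the global adjacency by node degree:
#' `A[i, j] = G[i, j] / sum_k G[k, i]`, the weight of the edge divided by the
#' total weight incident to the walker's current node i. G is required to be
#' symmetric, so the normalizing sum over column i equals the sum over row i
#' and every **row** of A is a probability distribution over the walker's next
#' position — which is what makes each row of the diffusion state a
#' distribution over the graph. Rows/columns of isolated (zero-degree) nodes
#' get a unit diagonal entry: a walker starting there stays put, which keeps
#' A stochastic without perturbing the connected components.
#'
#' @param gn A `global_network`, or a symmetric nonnegative matrix.
#' @return An object of class `transition_matrix`: list with `A` (sparse
#'   row-stochastic matrix) and `isolated` (integer indices of zero-degree
#'   nodes).
#' @export
transition_matrix <- function(gn) {
  G <- if (inherits(gn, "global_network")) gn$G else gn
  G <- methods::as(methods::as(Matrix::Matrix(G, sparse = TRUE), "generalMatrix"),
                   "CsparseMatrix")
  if (any(G@x < 0)) stop("adjacency must be nonnegative")
  if (!Matrix::isSymmetric(G, tol = 1e-12)) stop("adjacency must be symmetric")
  deg <- Matrix::colSums(G)  # = rowSums by symmetry
  isolated <- which(deg == 0)
  scale <- ifelse(deg > 0, 1 / deg, 0)
  A <- Matrix::Diagonal(x = scale) %*% G
  if (length(isolated) > 0) {
    A <- A + Matrix::sparseMatrix(i = isolated, j = isolated,
                                  x = rep(1, length(isolated)),
                                  dims = dim(G))
  }
  dimnames(A) <- dimnames(G)
  structure(list(A = methods::as(A, "CsparseMatrix"), isolated = isolated),
            class = "transition_matrix")
}

#' @export
print.transition_matrix <- function(x, ...) {
  cat("transition_matrix:", nrow(x$A), "nodes,", length(x$isolated),
      "isolated\n")
  invisible(x)
}

#' Random walk with restart over the global network
#'
#' Iterates the recurrence `P_k = alpha * P_{k-1} %*% A + (1 - alpha) * P_0`
#' with `P_0` the identity, until the maximum per-row L1 change drops below
#' `tol` or `max_iter` is reached. Row i of the converged matrix (the
#' "diffusion state") is the stationary visiting distribution of a walker
#' that starts at node i, follows edges with weight `alpha`, and restarts at
#' i with weight `1 - alpha`.
#'
#' Note on conventions: `alpha` here multiplies the walk term exactly as in
#' the defining recurrence, so `1 - alpha` is the restart weight; some
#' descriptions call the restart weight itself alpha. At the usual operating
#' point `alpha = 0.5` the two readings coincide.
#'
#' @param A A `transition_matrix` (or a row-stochastic matrix).
#' @param alpha Walk-continuation weight in \[0, 1\] (`1 - alpha` = restart).
#' @param tol Convergence tolerance on the max per-row L1 change.
#' @param max_iter Iteration cap.
#' @param state_mode `"converged"` returns the plateau distribution;
#'   `"accumulated"` returns the sum of the per-step matrices `P_1 + ... + P_K`
#'   (the alternative construction used by some graph-representation methods).
#' @return An object of class `diffusion_state`: list with `P` (dense
#'   matrix), `iterations`, `converged`, `alpha`, `state_mode`.
#' @export
rwr <- function(A, alpha = 0.5, tol = 1e-6, max_iter = 100,
                state_mode = c("converged", "accumulated")) {
  state_mode <- match.arg(state_mode)
  if (!is.numeric(alpha) || length(alpha) != 1 || alpha < 0 || alpha > 1)
    stop("alpha must be a single value in [0, 1]")
  if (tol <= 0) stop("tol must be > 0")
  if (max_iter < 1) stop("max_iter must be >= 1")
  Am <- if (inherits(A, "transition_matrix")) A$A else A
  n <- nrow(Am)
  P0 <- diag(n)
  P <- P0
  acc <- matrix(0, n, n)
  converged <- FALSE
  k <- 0L
  while (k < max_iter) {
    k <- k + 1L
    Pnew <- alpha * as.matrix(P %*% Am) + (1 - alpha) * P0
    acc <- acc + Pnew
    delta <- max(rowSums(abs(Pnew - P)))
    P <- Pnew
    if (delta < tol) { converged <- TRUE; break }
  }
  out <- if (state_mode == "converged") P else acc
  dimnames(out) <- dimnames(Am)
  structure(list(P = out, iterations = k, converged = converged,
                 alpha = alpha, state_mode = state_mode),
            class = "diffusion_state")
}

#' @export
print.diffusion_state <- function(x, ...) {
  cat("diffusion_state:", nrow(x$P), "nodes, alpha =", x$alpha, ",",
      x$iterations, "iterations,",
      if (x$converged) "converged" else "NOT converged", "\n")
  invisible(x)
}

#' Positive pointwise mutual information re-weighting
#'
#' Treats the diffusion state as a co-occurrence table and re-weights each
#' entry by how much more mass it carries than independence of its row and
#' column marginals would predict:
#' `X[i, j] = max(0, log(P[i, j] * total / (r_i * c_j)))`, where `total` is
#' the grand sum and `r_i`, `c_j` the marginals. Zeros of P stay zero. The
#' result is invariant to scaling P by a positive constant.
#'
#' @param P A `diffusion_state` or a nonnegative matrix with positive total
#'   mass.
#' @param log_base Base of the logarithm (natural log by default; the zero
#'   pattern is base-invariant).
#' @return A nonnegative matrix of class `ppmi_matrix`.
#' @export
ppmi <- function(P, log_base = exp(1)) {
  Pm <- if (inherits(P, "diffusion_state")) P$P else as.matrix(P)
  if (any(Pm < 0)) stop("diffusion state must be nonnegative")
  total <- sum(Pm)
  if (total <= 0) stop("diffusion state has zero total mass")
  r <- rowSums(Pm)
  cs <- colSums(Pm)
  ratio <- Pm * total / (r %o% cs)
  X <- matrix(0, nrow(Pm), ncol(Pm), dimnames = dimnames(Pm))
  pos <- Pm > 0
  X[pos] <- pmax(0, log(ratio[pos], base = log_base))
  class(X) <- c("ppmi_matrix", class(X))
  X
}
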