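#' Protein GO annotation table
#'
#' @param df data.frame with columns `protein_id`, `go_term`, `evidence`.
#'   GO term ids must match `GO:` + 7 digits. Exact duplicate records are
#'   collapsed.
#' @return A validated data.frame of class `annotation_table`.
#' @export
annotation_table <- function(df) {
  stopifnot(all(c("protein_id", "go_term", "evidence") %in% names(df)))
  df <- data.frame(protein_id = as.character(df$protein_id),
                   go_term = as.character(df$go_term),
                   evidence = as.character(df$evidence),
                   stringsAsFactors = FALSE)
  bad <- !grepl("^GO:\\d{7}$", df$go_term)
  if (any(bad))
    stop("malformed GO term id(s): ",
         paste(utils::head(unique(df$go_term[bad]), 5), collapse = ", "))
  df <- df[!duplicated(df), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("annotation_table", "data.frame")
  df
}

#' Drop proteins that have only electronically inferred annotations
#'
#' A protein is kept only if at least one of its records carries a manually
#' assigned (non-IEA) evidence code; retained proteins keep all their
#' records, including the IEA ones.
#'
#' @param table An [annotation_table()].
#' @return A filtered [annotation_table()].
#' @export
filter_non_iea <- function(table) {
  if (nrow(table) == 0) return(table)
  has_manual <- tapply(table$evidence != "IEA", table$protein_id, any)
  keep_ids <- names(has_manual)[has_manual]
  annotation_table(table[table$protein_id %in% keep_ids, , drop = FALSE])
}

#' Read a minimal OBO ontology
#'
#' Parses only `[Term]` stanzas with `id:`, `is_a:` and
#' `relationship: part_of` lines — enough to propagate annotations up the
#' GO graph. Obsolete terms are kept (their edges are whatever the file
#' states).
#'
#' @param path Path to an OBO file.
#' @return A list with `terms` (character vector) and `edges` (data.frame
#'   `child`, `parent`, `relation`).
#' @export
read_obo <- function(path) {
  lines <- readLines(path, warn = FALSE)
  terms <- character(0)
  child <- character(0); parent <- character(0); rel <- character(0)
  cur <- NA_character_
  in_term <- FALSE
  for (ln in lines) {
    ln <- trimws(ln)
    if (ln == "[Term]") { in_term <- TRUE; cur <- NA_character_; next }
    if (grepl("^\\[", ln)) { in_term <- FALSE; next }
    if (!in_term || ln == "") next
    if (grepl("^id:", ln)) {
      cur <- trimws(sub("^id:", "", ln))
      terms <- c(terms, cur)
    } else if (grepl("^is_a:", ln) && !is.na(cur)) {
      p <- trimws(sub("!.*$", "", sub("^is_a:", "", ln)))
      child <- c(child, cur); parent <- c(parent, p); rel <- c(rel, "is_a")
    } else if (grepl("^relationship:\\s*part_of", ln) && !is.na(cur)) {
      p <- trimws(sub("!.*$", "", sub("^relationship:\\s*part_of", "", ln)))
      child <- c(child, cur); parent <- c(parent, p); rel <- c(rel, "part_of")
    }
  }
  list(terms = unique(terms),
       edges = data.frame(child = child, parent = parent, relation = rel,
                          stringsAsFactors = FALSE))
}

#' Propagate annotations to ancestor terms (true-path rule)
#'
#' When enabled, each protein annotated to a term is also annotated to every
#' ancestor of that term along `is_a`/`part_of` edges (evidence code carried
#' over). Disabled by default: propagation is an optional convention of
#' CAFA-like evaluations, not part of the core transfer method.
#'
#' @param table An [annotation_table()].
#' @param ontology A list as returned by [read_obo()], or a data.frame of
#'   `child`, `parent` edges.
#' @param enabled Apply propagation? Default `FALSE` returns the table
#'   unchanged.
#' @return An [annotation_table()].
#' @export
propagate_annotations <- function(table, ontology = NULL, enabled = FALSE) {
  if (!enabled) return(table)
  edges <- if (is.data.frame(ontology)) ontology else ontology$edges
  if (is.null(edges) || nrow(edges) == 0) return(table)
  g <- igraph::graph_from_data_frame(edges[, c("child", "parent")],
                                     directed = TRUE)
  if (!igraph::is_dag(g)) stop("ontology graph contains a cycle")
  anc <- lapply(igraph::V(g)$name, function(v)
    setdiff(names(igraph::subcomponent(g, v, mode = "out")), v))
  names(anc) <- igraph::V(g)$name
  extra <- do.call(rbind, lapply(seq_len(nrow(table)), function(i) {
    a <- anc[[table$go_term[i]]]
    if (is.null(a) || length(a) == 0) return(NULL)
    data.frame(protein_id = table$protein_id[i], go_term = a,
               evidence = table$evidence[i], stringsAsFactors = FALSE)
  }))
  annotation_table(rbind(as.data.frame(table), extra))
}

#' Balanced training set for one GO term
#'
#' Positives are all embedded proteins annotated to the term; negatives are a
#' uniform random sample, without replacement and of equal size, from the
#' embedded proteins not annotated to the term. Returns `NULL` (term skipped)
#' when there are fewer than `min_positives` positives or not enough
#' candidate negatives.
#'
#' @param term GO term id.
#' @param annotations An [annotation_table()] (already filtered/propagated).
#' @param protein_embeddings Numeric matrix, rownames = protein ids. Every
#'   annotated protein must have an embedding row.
#' @param seed Integer seed for the negative sample.
#' @param min_positives Minimum positives required to model the term.
#' @return A list of class `term_training_set` (`term`, `positives`,
#'   `negatives`, `x`, `y`, `seed`) or `NULL`.
#' @export
build_term_training_set <- function(term, annotations, protein_embeddings,
                                    seed = 1, min_positives = 10) {
  emb_ids <- rownames(protein_embeddings)
  ann_ids <- unique(annotations$protein_id)
  missing <- setdiff(ann_ids, emb_ids)
  if (length(missing) > 0)
    stop("no embedding for annotated protein(s): ",
         paste(utils::head(missing, 5), collapse = ", "))
  positives <- sort(unique(annotations$protein_id[annotations$go_term == term]))
  if (length(positives) < min_positives) return(NULL)
  candidates <- sort(setdiff(emb_ids, positives))
  if (length(candidates) < length(positives)) return(NULL)
  set.seed(seed)
  negatives <- sort(sample(candidates, length(positives)))
  x <- protein_embeddings[c(positives, negatives), , drop = FALSE]
  y <- factor(rep(c("pos", "neg"), c(length(positives), length(negatives))),
              levels = c("neg", "pos"))
  structure(list(term = term, positives = positives, negatives = negatives,
                 x = x, y = y, seed = seed),
            class = "term_training_set")
}

median_heuristic_gamma <- function(x) {
  d2 <- as.numeric(stats::dist(x))^2
  med <- stats::median(d2[d2 > 0])
  if (!is.finite(med) || med <= 0) return(1 / max(1, ncol(x)))
  1 / med
}

#' Train a calibrated SVM for one GO term
#'
#' RBF-kernel support vector machine with Platt-style sigmoid probability
#' calibration (internal cross-validation), so emitted scores are
#' probabilities in \[0, 1\]. The kernel width defaults to the median
#' heuristic on the training features.
#'
#' @param ts A [build_term_training_set()] result.
#' @param cost SVM cost parameter C.
#' @param gamma RBF kernel width; `NULL` uses the median heuristic.
#' @param seed Seed for the calibration folds.
#' @return An object of class `term_classifier`.
#' @export
train_term_classifier <- function(ts, cost = 1, gamma = NULL, seed = 1) {
  stopifnot(inherits(ts, "term_training_set"))
  if (!all(is.finite(ts$x))) stop("training features must be finite")
  if (nrow(unique(ts$x)) == 1)
    stop("degenerate training features: all rows identical for term ", ts$term)
  if (is.null(gamma)) gamma <- median_heuristic_gamma(ts$x)
  set.seed(seed)
  fit <- e1071::svm(ts$x, ts$y, kernel = "radial", cost = cost, gamma = gamma,
                    probability = TRUE, scale = FALSE)
  structure(list(term = ts$term, fit = fit, gamma = gamma, cost = cost,
                 n_pos = length(ts$positives), n_neg = length(ts$negatives),
                 seed = seed),
            class = "term_classifier")
}

#' Positive-class probability from a term classifier
#' @param clf A `term_classifier`.
#' @param x Feature matrix with the training width.
#' @return Numeric vector of probabilities in \[0, 1\].
#' @export
predict_term_scores <- function(clf, x) {
  x <- as.matrix(x)
  if (ncol(x) != ncol(clf$fit$SV))
    stop("feature width ", ncol(x), " does not match training width ",
         ncol(clf$fit$SV))
  pred <- stats::predict(clf$fit, x, probability = TRUE)
  p <- attr(pred, "probabilities")[, "pos"]
  unname(pmin(1, pmax(0, p)))
}

#' Train classifiers for every modellable GO term
#'
#' @param annotations An [annotation_table()].
#' @param protein_embeddings Matrix with protein ids as rownames.
#' @param seed Base seed; each term uses a seed derived from it and the term
#'   id, so adding or removing terms does not reshuffle the others.
#' @param min_positives Terms with fewer positives are skipped.
#' @param cost,gamma Passed to [train_term_classifier()].
#' @return Named list of `term_classifier` objects (possibly empty).
#' @export
train_go_classifiers <- function(annotations, protein_embeddings, seed = 1,
                                 min_positives = 10, cost = 1, gamma = NULL) {
  terms <- sort(unique(annotations$go_term))
  out <- list()
  for (tm in terms) {
    s <- derive_seed(seed, tm)
    ts <- build_term_training_set(tm, annotations, protein_embeddings,
                                  seed = s, min_positives = min_positives)
    if (is.null(ts)) next
    out[[tm]] <- train_term_classifier(ts, cost = cost, gamma = gamma,
                                       seed = s)
  }
  out
}

#' Score lncRNAs against every trained GO term classifier
#'
#' @param classifiers Named list from [train_go_classifiers()].
#' @param lncrna_embeddings Matrix with lncRNA ids as rownames, same feature
#'   width as training.
#' @return A `prediction_matrix`: numeric matrix lncRNAs x GO terms with
#'   scores in \[0, 1\].
#' @export
predict_lncrna_functions <- function(classifiers, lncrna_embeddings) {
  lncrna_embeddings <- as.matrix(lncrna_embeddings)
  scores <- matrix(numeric(0), nrow(lncrna_embeddings), 0,
                   dimnames = list(rownames(lncrna_embeddings), NULL))
  if (length(classifiers) > 0) {
    cols <- lapply(classifiers, predict_term_scores, x = lncrna_embeddings)
    scores <- do.call(cbind, cols)
    dimnames(scores) <- list(rownames(lncrna_embeddings), names(classifiers))
  }
  class(scores) <- c("prediction_matrix", class(scores))
  scores
}
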