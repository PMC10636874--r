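#' Read an identifier list (one id per line)
#' @param path Plain-text file, UTF-8, no header; blank lines ignored.
#' @return Character vector.
#' @export
read_id_list <- function(path) {
  ids <- readLines(path, warn = FALSE, encoding = "UTF-8")
  ids <- trimws(ids)
  ids[ids != ""]
}

#' @rdname read_id_list
#' @param ids Character vector to write.
#' @export
write_id_list <- function(ids, path) {
  writeLines(as.character(ids), path, useBytes = TRUE)
  invisible(path)
}

parse_tsv_lines <- function(path, n_cols) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  keep <- !grepl("^\\s*#", lines) & trimws(lines) != ""
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0)
    return(list(fields = matrix(character(0), 0, n_cols), lineno = integer(0)))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  lens <- lengths(parts)
  if (any(lens != n_cols))
    stop("malformed line ", lineno[which(lens != n_cols)[1]], " in ", path,
         ": expected ", n_cols, " tab-separated columns, got ",
         lens[which(lens != n_cols)[1]])
  list(fields = matrix(unlist(parts), ncol = n_cols, byrow = TRUE),
       lineno = lineno)
}

#' Read a weighted edge list
#'
#' Three tab-separated columns `id_a`, `id_b`, `weight`, no header; lines
#' starting with `#` are comments. Unknown ids (when an index is supplied)
#' and malformed lines raise errors naming the offence.
#'
#' @param path TSV file path.
#' @param kind_a,kind_b Entity kinds of the two id columns.
#' @param index Optional [entity_index()]; when given, every id must resolve.
#' @return A [component_network()].
#' @export
read_edge_list <- function(path, kind_a, kind_b, index = NULL) {
  p <- parse_tsv_lines(path, 3)
  if (nrow(p$fields) == 0) return(component_network(NULL, kind_a, kind_b))
  w <- suppressWarnings(as.numeric(p$fields[, 3]))
  if (anyNA(w))
    stop("malformed line ", p$lineno[which(is.na(w))[1]], " in ", path,
         ": non-numeric weight '", p$fields[which(is.na(w))[1], 3], "'")
  edges <- data.frame(id_a = p$fields[, 1], id_b = p$fields[, 2], weight = w,
                      stringsAsFactors = FALSE)
  if (!is.null(index)) {
    known <- index_ids(index)
    bad <- setdiff(unique(c(edges$id_a, edges$id_b)), known)
    if (length(bad) > 0)
      stop("unknown ids in ", path, ": ", paste(bad, collapse = ", "))
  }
  component_network(edges, kind_a, kind_b)
}

#' @rdname read_edge_list
#' @param net A [component_network()] to write.
#' @export
write_edge_list <- function(net, path) {
  e <- net$edges
  lines <- sprintf("%s\t%s\t%.17g", e$id_a, e$id_b, e$weight)
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Read an expression matrix
#'
#' TSV with a header row of sample ids; first column holds entity ids.
#'
#' @param path TSV file path.
#' @return Numeric matrix, entities in rows.
#' @export
read_expression <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (anyDuplicated(df[[1]])) stop("duplicate entity ids in ", path)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  m
}

#' Read / write a protein annotation table
#'
#' Three tab-separated columns `protein_id`, `go_term`, `evidence_code`, no
#' header (a GAF-like projection); `#` comments allowed.
#'
#' @param path TSV file path.
#' @return An [annotation_table()].
#' @export
read_annotations <- function(path) {
  p <- parse_tsv_lines(path, 3)
  annotation_table(data.frame(protein_id = p$fields[, 1],
                              go_term = p$fields[, 2],
                              evidence = p$fields[, 3],
                              stringsAsFactors = FALSE))
}

#' @rdname read_annotations
#' @param table An [annotation_table()] to write.
#' @export
write_annotations <- function(table, path) {
  writeLines(sprintf("%s\t%s\t%s", table$protein_id, table$go_term,
                     table$evidence), path, useBytes = TRUE)
  invisible(path)
}

#' Read / write a truth set
#'
#' Two tab-separated columns `lncrna_id`, `go_term`, no header.
#'
#' @param path TSV file path.
#' @return A [truth_set()].
#' @export
read_truth <- function(path) {
  p <- parse_tsv_lines(path, 2)
  if (nrow(p$fields) == 0) stop("truth file ", path, " is empty")
  truth_set(split(p$fields[, 2], p$fields[, 1]))
}

#' @rdname read_truth
#' @param truth A [truth_set()] to write.
#' @export
write_truth <- function(truth, path) {
  lines <- unlist(lapply(names(truth$terms), function(id)
    sprintf("%s\t%s", id, truth$terms[[id]])))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Read / write predictions as a long TSV
#'
#' Three tab-separated columns `lncrna_id`, `go_term`, `score`, no header.
#'
#' @param path TSV file path.
#' @return A `prediction_matrix` (absent pairs score 0).
#' @export
read_predictions <- function(path) {
  p <- parse_tsv_lines(path, 3)
  s <- as.numeric(p$fields[, 3])
  lnc <- sort(unique(p$fields[, 1])); terms <- sort(unique(p$fields[, 2]))
  m <- matrix(0, length(lnc), length(terms), dimnames = list(lnc, terms))
  m[cbind(match(p$fields[, 1], lnc), match(p$fields[, 2], terms))] <- s
  class(m) <- c("prediction_matrix", class(m))
  m
}

#' @rdname read_predictions
#' @param predictions A `prediction_matrix` to write.
#' @export
write_predictions <- function(predictions, path) {
  lnc <- rownames(predictions); terms <- colnames(predictions)
  lines <- unlist(lapply(seq_along(lnc), function(i)
    sprintf("%s\t%s\t%.17g", lnc[i], terms, predictions[i, ])))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Persist a matrix as MatrixMarket with a node-index sidecar
#'
#' The sidecar (`<path>.index.tsv`) maps row number to `(kind, id)` so a
#' persisted global network, diffusion state or PPMI matrix can be
#' reconstructed with its entity index.
#'
#' @param m Matrix (sparse or dense) with rownames equal to the index ids.
#' @param index An [entity_index()].
#' @param path Output `.mtx` path.
#' @return `path`, invisibly.
#' @export
write_indexed_matrix <- function(m, index, path) {
  Matrix::writeMM(methods::as(Matrix::Matrix(m, sparse = TRUE),
                              "CsparseMatrix"), path)
  ids <- index_ids(index)
  kinds <- entity_kind(index, ids)
  writeLines(sprintf("%d\t%s\t%s", seq_along(ids), kinds, ids),
             paste0(path, ".index.tsv"), useBytes = TRUE)
  invisible(path)
}

#' @rdname write_indexed_matrix
#' @return For the reader: a list with `matrix` (sparse) and `index`.
#' @export
read_indexed_matrix <- function(path) {
  m <- methods::as(Matrix::readMM(path), "CsparseMatrix")
  p <- parse_tsv_lines(paste0(path, ".index.tsv"), 3)
  ord <- order(as.integer(p$fields[, 1]))
  kinds <- p$fields[ord, 2]; ids <- p$fields[ord, 3]
  idx <- entity_index(ids[kinds == "lncrna"], ids[kinds == "protein"],
                      ids[kinds == "mirna"])
  dimnames(m) <- list(ids, ids)
  list(matrix = m, index = idx)
}

#' Write embeddings as TSV (id column + one column per dimension)
#' @param emb Numeric matrix with rownames.
#' @param path Output path.
#' @export
write_embeddings <- function(emb, path) {
  df <- data.frame(id = rownames(emb), emb, check.names = FALSE)
  colnames(df) <- c("id", paste0("d", seq_len(ncol(emb))))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_embeddings
#' @export
read_embeddings <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}
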