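#' Entity index for the global heterogeneous network
#'
#' Fixes the row/column layout of the global network: blocks are always
#' ordered lncRNA, then protein, then miRNA. The global index of an entity is
#' its kind's offset plus its within-kind position.
#'
#' @param lncrna,protein,mirna Character vectors of entity identifiers, one
#'   per entity. Any of them may be empty, but identifiers must be unique
#'   across all three kinds.
#' @return An object of class `entity_index` with elements `ids` (named list
#'   of id vectors per kind), `offsets` (named integer vector of 0-based
#'   block offsets) and `n_total`.
#' @examples
#' idx <- entity_index(c("l1", "l2"), c("p1", "p2"), "m1")
#' global_index(idx, "p2") # 4: proteins start after the 2 lncRNAs
#' @export
entity_index <- function(lncrna = character(), protein = character(),
                         mirna = character()) {
  ids <- list(lncrna = as.character(lncrna),
              protein = as.character(protein),
              mirna = as.character(mirna))
  for (k in names(ids)) {
    if (anyDuplicated(ids[[k]]))
      stop("duplicate ", k, " identifiers: ",
           paste(unique(ids[[k]][duplicated(ids[[k]])]), collapse = ", "))
  }
  all_ids <- unlist(ids, use.names = FALSE)
  if (anyDuplicated(all_ids))
    stop("identifiers shared across kinds: ",
         paste(unique(all_ids[duplicated(all_ids)]), collapse = ", "))
  n <- vapply(ids, length, integer(1))
  offsets <- c(lncrna = 0L, protein = n[["lncrna"]],
               mirna = n[["lncrna"]] + n[["protein"]])
  structure(list(ids = ids, offsets = offsets, n_total = sum(n)),
            class = "entity_index")
}

#' @export
print.entity_index <- function(x, ...) {
  n <- vapply(x$ids, length, integer(1))
  cat("entity_index:", n[["lncrna"]], "lncRNA,", n[["protein"]], "protein,",
      n[["mirna"]], "miRNA (", x$n_total, "nodes )\n")
  invisible(x)
}

index_kinds <- c("lncrna", "protein", "mirna")

#' Global (whole-matrix) index of entities
#'
#' @param index An [entity_index()].
#' @param ids Character vector of identifiers (any kind).
#' @return Integer vector of 1-based row/column positions in the global
#'   network; errors on unknown ids.
#' @export
global_index <- function(index, ids) {
  stopifnot(inherits(index, "entity_index"))
  out <- rep(NA_integer_, length(ids))
  for (k in index_kinds) {
    pos <- match(ids, index$ids[[k]])
    hit <- !is.na(pos)
    out[hit] <- index$offsets[[k]] + pos[hit]
  }
  if (anyNA(out))
    stop("unknown identifiers: ", paste(unique(ids[is.na(out)]), collapse = ", "))
  out
}

#' Kind of each identifier
#' @inheritParams global_index
#' @return Character vector in `c("lncrna", "protein", "mirna")`.
#' @export
entity_kind <- function(index, ids) {
  out <- rep(NA_character_, length(ids))
  for (k in index_kinds) out[ids %in% index$ids[[k]]] <- k
  if (anyNA(out))
    stop("unknown identifiers: ", paste(unique(ids[is.na(out)]), collapse = ", "))
  out
}

#' All identifiers in global order
#' @param index An [entity_index()].
#' @return Character vector of length `index$n_total`.
#' @export
index_ids <- function(index) {
  unlist(index$ids, use.names = FALSE)
}
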