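#' Configuration of the synthetic heterogeneous-network generator
#'
#' The generator plants functional modules: every entity (lncRNA, protein,
#' miRNA) belongs to one of `g` groups; edges inside a group appear with
#' probability `p_in`, between groups with `p_out`, in all six component
#' networks; each group owns `terms_per_group` GO terms; every protein is
#' annotated with its group's terms, and a held-out fraction of lncRNAs'
#' group terms forms the evaluation truth set. Guilt-by-association holds by
#' construction, so a working pipeline must recover the held-out labels.
#'
#' @param n_l,n_p,n_m Entity counts per kind (miRNAs may be 0 for the
#'   without-miRNA ablation).
#' @param g Number of function groups, `g <= min(n_l, n_p)`.
#' @param p_in,p_out Intra-/inter-group edge probabilities, `p_in > p_out >= 0`
#'   (equal values are allowed for null-model checks).
#' @param noise Gaussian sd added to the base edge weight 0.5 (weights are
#'   clipped into (0, 1\]).
#' @param terms_per_group GO terms owned by each group.
#' @param holdout_frac Fraction of lncRNAs whose group terms become truth.
#' @param binary_lp Make the lncRNA-protein network binary (weight 1),
#'   mirroring experimentally verified interaction sets.
#' @param seed Integer seed; the bundle is a deterministic function of the
#'   config.
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(n_l = 30, n_p = 60, n_m = 10, g = 3, p_in = 0.3,
                         p_out = 0.02, noise = 0.1, terms_per_group = 3,
                         holdout_frac = 0.5, binary_lp = FALSE, seed = 1) {
  if (p_in < p_out || p_out < 0 || p_in > 1)
    stop("need 1 >= p_in >= p_out >= 0")
  if (n_l < 1 || n_p < 1 || n_m < 0 || g < 1) stop("invalid entity counts")
  if (g > min(n_l, n_p)) stop("g must be <= min(n_l, n_p)")
  if (holdout_frac <= 0 || holdout_frac > 1) stop("holdout_frac in (0, 1]")
  structure(as.list(environment()), class = "synth_config")
}

synth_pair_edges <- function(ids_a, ids_b, grp_a, grp_b, p_in, p_out, noise,
                             intra, binary = FALSE) {
  if (length(ids_a) == 0 || length(ids_b) == 0)
    return(data.frame(id_a = character(), id_b = character(),
                      weight = numeric(), stringsAsFactors = FALSE))
  if (intra) {
    pr <- which(upper.tri(matrix(0, length(ids_a), length(ids_b))),
                arr.ind = TRUE)
  } else {
    pr <- as.matrix(expand.grid(seq_along(ids_a), seq_along(ids_b)))
  }
  same <- grp_a[pr[, 1]] == grp_b[pr[, 2]]
  p <- ifelse(same, p_in, p_out)
  present <- stats::runif(nrow(pr)) < p
  w <- if (binary) rep(1, sum(present)) else
    pmin(1, pmax(0.01, 0.5 + stats::rnorm(sum(present), 0, noise)))
  data.frame(id_a = ids_a[pr[present, 1]], id_b = ids_b[pr[present, 2]],
             weight = w, stringsAsFactors = FALSE)
}

#' Generate a synthetic bundle with planted functional structure
#'
#' @param cfg A [synth_config()].
#' @return A list of class `synth_bundle`: `index`, the six
#'   [component_network()]s (`L`, `P`, `M`, `LP`, `LM`, `PM`), `annotations`
#'   (proteins only), `truth` (held-out lncRNAs), `groups` (named integer
#'   vector of ground-truth group assignments), `terms_by_group`, and `config`.
#' @export
generate_bundle <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  set.seed(cfg$seed)
  l_ids <- sprintf("LNC%04d", seq_len(cfg$n_l))
  p_ids <- sprintf("PROT%04d", seq_len(cfg$n_p))
  m_ids <- if (cfg$n_m > 0) sprintf("MIR%04d", seq_len(cfg$n_m)) else character()
  idx <- entity_index(l_ids, p_ids, m_ids)
  # uniform group assignment; the first g lncRNAs and proteins cover every
  # group so no group is empty where it matters
  grp_l <- c(seq_len(cfg$g),
             sample.int(cfg$g, cfg$n_l - cfg$g, replace = TRUE))
  grp_p <- c(seq_len(cfg$g),
             sample.int(cfg$g, cfg$n_p - cfg$g, replace = TRUE))
  grp_m <- if (cfg$n_m > 0) sample.int(cfg$g, cfg$n_m, replace = TRUE) else integer()
  groups <- stats::setNames(c(grp_l, grp_p, grp_m), c(l_ids, p_ids, m_ids))

  L <- component_network(synth_pair_edges(l_ids, l_ids, grp_l, grp_l,
                                          cfg$p_in, cfg$p_out, cfg$noise, TRUE),
                         "lncrna", "lncrna")
  P <- component_network(synth_pair_edges(p_ids, p_ids, grp_p, grp_p,
                                          cfg$p_in, cfg$p_out, cfg$noise, TRUE),
                         "protein", "protein")
  M <- component_network(synth_pair_edges(m_ids, m_ids, grp_m, grp_m,
                                          cfg$p_in, cfg$p_out, cfg$noise, TRUE),
                         "mirna", "mirna")
  LP <- component_network(synth_pair_edges(l_ids, p_ids, grp_l, grp_p,
                                           cfg$p_in, cfg$p_out, cfg$noise,
                                           FALSE, binary = cfg$binary_lp),
                          "lncrna", "protein")
  LM <- component_network(synth_pair_edges(l_ids, m_ids, grp_l, grp_m,
                                           cfg$p_in, cfg$p_out, cfg$noise, FALSE),
                          "lncrna", "mirna")
  PM <- component_network(synth_pair_edges(p_ids, m_ids, grp_p, grp_m,
                                           cfg$p_in, cfg$p_out, cfg$noise, FALSE),
                          "protein", "mirna")

  terms_by_group <- lapply(seq_len(cfg$g), function(gi)
    sprintf("GO:%07d", (gi - 1) * cfg$terms_per_group +
              seq_len(cfg$terms_per_group)))
  ann <- do.call(rbind, lapply(seq_along(p_ids), function(i)
    data.frame(protein_id = p_ids[i], go_term = terms_by_group[[grp_p[i]]],
               evidence = "EXP", stringsAsFactors = FALSE)))
  annotations <- annotation_table(ann)

  n_hold <- max(1L, round(cfg$holdout_frac * cfg$n_l))
  held <- sort(sample(l_ids, n_hold))
  truth <- truth_set(stats::setNames(
    lapply(held, function(id) terms_by_group[[groups[[id]]]]), held))

  structure(list(index = idx, L = L, P = P, M = M, LP = LP, LM = LM, PM = PM,
                 annotations = annotations, truth = truth, groups = groups,
                 terms_by_group = terms_by_group, config = cfg),
            class = "synth_bundle")
}

#' @export
print.synth_bundle <- function(x, ...) {
  cat("synth_bundle:", x$config$n_l, "lncRNA,", x$config$n_p, "protein,",
      x$config$n_m, "miRNA in", x$config$g, "groups;",
      x$truth$n_test, "held-out truth lncRNAs\n")
  invisible(x)
}

bundle_files <- c(lncrna_ids = "lncrna_ids.txt", protein_ids = "protein_ids.txt",
                  mirna_ids = "mirna_ids.txt", L = "lncrna_similarity.tsv",
                  P = "protein_interactions.tsv", M = "mirna_similarity.tsv",
                  LP = "lncrna_protein.tsv", LM = "lncrna_mirna.tsv",
                  PM = "protein_mirna.tsv", annotations = "annotations.tsv",
                  truth = "truth.tsv")

#' Write a synthetic bundle to a directory
#'
#' Emits the three ID lists, the six edge-list TSVs, the annotation TSV and
#' the truth TSV in exactly the dialects the package's readers consume, plus
#' a `manifest.json` listing the files and the generator seed.
#'
#' @param bundle A `synth_bundle`.
#' @param dir Output directory (created if needed).
#' @return Named character vector of the written paths, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, bundle_files)
  names(paths) <- names(bundle_files)
  write_id_list(bundle$index$ids$lncrna, paths[["lncrna_ids"]])
  write_id_list(bundle$index$ids$protein, paths[["protein_ids"]])
  write_id_list(bundle$index$ids$mirna, paths[["mirna_ids"]])
  for (nm in c("L", "P", "M", "LP", "LM", "PM"))
    write_edge_list(bundle[[nm]], paths[[nm]])
  write_annotations(bundle$annotations, paths[["annotations"]])
  write_truth(bundle$truth, paths[["truth"]])
  manifest <- list(seed = bundle$config$seed,
                   files = as.list(stats::setNames(basename(paths), names(paths))))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(paths)
}

#' Read a bundle directory written by [write_bundle()]
#'
#' @param dir Directory containing the bundle files.
#' @return A list with `index`, the six component networks, `annotations`
#'   and `truth` (group assignments are not persisted: they are generator
#'   ground truth, not pipeline input).
#' @export
read_bundle <- function(dir) {
  paths <- file.path(dir, bundle_files)
  names(paths) <- names(bundle_files)
  idx <- entity_index(read_id_list(paths[["lncrna_ids"]]),
                      read_id_list(paths[["protein_ids"]]),
                      read_id_list(paths[["mirna_ids"]]))
  kinds <- list(L = c("lncrna", "lncrna"), P = c("protein", "protein"),
                M = c("mirna", "mirna"), LP = c("lncrna", "protein"),
                LM = c("lncrna", "mirna"), PM = c("protein", "mirna"))
  nets <- lapply(names(kinds), function(nm)
    read_edge_list(paths[[nm]], kinds[[nm]][1], kinds[[nm]][2], idx))
  names(nets) <- names(kinds)
  c(list(index = idx), nets,
    list(annotations = read_annotations(paths[["annotations"]]),
         truth = read_truth(paths[["truth"]])))
}
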