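#' Derive a stage seed from a global seed and a stage name
#'
#' One global seed drives the whole pipeline; each stochastic stage gets a
#' deterministic seed derived from the global seed and the stage's name, so
#' an ablation that removes a stage does not reshuffle the others.
#'
#' @param seed Integer global seed.
#' @param stage Stage name (any string).
#' @return A positive integer below 2^31.
#' @export
derive_seed <- function(seed, stage) {
  h <- 0
  for (code in utf8ToInt(stage)) h <- (h * 131 + code) %% 2147483647
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483647 + 1)
}

#' Pipeline configuration
#'
#' @param alpha Walk-continuation weight of the random walk with restart
#'   (`1 - alpha` = restart probability weight); 0.5 by default, the usual
#'   operating point.
#' @param tol,max_iter Convergence controls of [rwr()].
#' @param state_mode `"converged"` or `"accumulated"` diffusion state.
#' @param log_base PPMI logarithm base.
#' @param sdae_widths Hidden layer widths **excluding** the input width (the
#'   input width is the node count, known only at run time); the last entry
#'   is the bottleneck dimension. Default `c(48, 16)`, a reduced-scale
#'   analogue of the deep full-scale stack.
#' @param corruption,epochs,learning_rate,batch_size,fine_tune,scale_input
#'   SDAE controls (see [sdae_config()]).
#' @param min_positives,svm_cost,svm_gamma Classifier controls (see
#'   [train_go_classifiers()]).
#' @param propagate Apply true-path annotation propagation (needs `ontology`).
#' @param ontology Optional [read_obo()] result.
#' @param grid Evaluation threshold grid.
#' @param drop_mirna Run the without-miRNA ablation: miRNA rows/columns are
#'   removed from the global network before diffusion.
#' @param seed Global seed; every stochastic stage derives its own seed from
#'   it.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(alpha = 0.5, tol = 1e-6, max_iter = 100,
                            state_mode = "converged", log_base = exp(1),
                            sdae_widths = c(48, 16), corruption = 0.2,
                            epochs = 150, learning_rate = 1e-2,
                            batch_size = 32, fine_tune = FALSE,
                            scale_input = FALSE, min_positives = 10,
                            svm_cost = 1, svm_gamma = NULL, propagate = FALSE,
                            ontology = NULL, grid = seq(0, 1, by = 0.01),
                            drop_mirna = FALSE, seed = 1) {
  structure(as.list(environment()), class = "pipeline_config")
}

#' Run the full prediction pipeline on a bundle
#'
#' Chains the stages: assemble the global network, column-normalize, run the
#' random walk with restart, convert the diffusion state to PPMI, train the
#' stacked denoising autoencoder and extract bottleneck embeddings, train
#' per-GO-term SVMs on the protein embeddings and annotations, score the
#' lncRNAs, and (when the bundle carries a truth set) evaluate with the Fmax
#' protocol.
#'
#' @param bundle A `synth_bundle` or the list returned by [read_bundle()]:
#'   must carry `index`, the six component networks `L`, `P`, `M`, `LP`,
#'   `LM`, `PM`, `annotations`, and optionally `truth`.
#' @param cfg A [pipeline_config()].
#' @param out_dir Optional directory; when given, each stage's artifact is
#'   persisted there (MTX + index sidecar for matrices, TSV for embeddings
#'   and predictions, JSON for the manifest).
#' @return A list of class `run_manifest`: per-stage counts and timings, the
#'   `global_network`, `embeddings`, `classifiers`, `predictions`, and (if
#'   truth was present) `curve`, `summary` and `coverage`.
#' @export
run_pipeline <- function(bundle, cfg = pipeline_config(), out_dir = NULL) {
  stopifnot(inherits(cfg, "pipeline_config"))
  stages <- list()
  tick <- function(expr, name) {
    t0 <- proc.time()[["elapsed"]]
    val <- force(expr)
    stages[[name]] <<- list(seconds = proc.time()[["elapsed"]] - t0)
    val
  }

  gn <- tick(assemble_global(bundle$L, bundle$P, bundle$M, bundle$LP,
                             bundle$LM, bundle$PM, bundle$index), "build")
  if (cfg$drop_mirna) gn <- drop_mirna(gn)
  stages$build$nodes <- nrow(gn$G)
  stages$build$edges <- Matrix::nnzero(gn$G)

  A <- tick(transition_matrix(gn), "normalize")
  ds <- tick(rwr(A, alpha = cfg$alpha, tol = cfg$tol, max_iter = cfg$max_iter,
                 state_mode = cfg$state_mode), "diffuse")
  stages$diffuse$iterations <- ds$iterations
  stages$diffuse$converged <- ds$converged
  X <- tick(ppmi(ds, log_base = cfg$log_base), "ppmi")

  n <- nrow(X)
  widths <- c(n, pmin(cfg$sdae_widths, n))
  scfg <- sdae_config(widths, corruption = cfg$corruption,
                      epochs = cfg$epochs, learning_rate = cfg$learning_rate,
                      batch_size = cfg$batch_size,
                      seed = derive_seed(cfg$seed, "embed"),
                      fine_tune = cfg$fine_tune, scale_input = cfg$scale_input)
  state <- tick(train_sdae(X, scfg), "embed")
  emb <- encode(state, X)
  stages$embed$dimension <- ncol(emb)

  idx <- gn$index
  ann <- filter_non_iea(bundle$annotations)
  if (cfg$propagate)
    ann <- propagate_annotations(ann, cfg$ontology, enabled = TRUE)
  ann <- annotation_table(ann[ann$protein_id %in% idx$ids$protein, ,
                              drop = FALSE])
  prot_emb <- emb[global_index(idx, idx$ids$protein), , drop = FALSE]
  rownames(prot_emb) <- idx$ids$protein
  classifiers <- tick(
    train_go_classifiers(ann, prot_emb, seed = derive_seed(cfg$seed, "train"),
                         min_positives = cfg$min_positives,
                         cost = cfg$svm_cost, gamma = cfg$svm_gamma),
    "train")
  stages$train$terms_modeled <- length(classifiers)

  lnc_emb <- emb[global_index(idx, idx$ids$lncrna), , drop = FALSE]
  rownames(lnc_emb) <- idx$ids$lncrna
  predictions <- tick(predict_lncrna_functions(classifiers, lnc_emb),
                      "predict")
  stages$predict$lncrnas_scored <- nrow(predictions)

  curve <- NULL; summary <- NULL; coverage <- NULL
  if (!is.null(bundle$truth)) {
    curve <- tick(pr_curve(predictions, bundle$truth, grid = cfg$grid),
                  "evaluate")
    summary <- fmax(curve)
    coverage <- count_correct(predictions, bundle$truth, summary$t_star)
    stages$evaluate$fmax <- summary$fmax
    stages$evaluate$coverage <- coverage
  }

  manifest <- structure(
    list(config = cfg, stages = stages, network = gn, embeddings = emb,
         classifiers = classifiers, predictions = predictions, curve = curve,
         summary = summary, coverage = coverage),
    class = "run_manifest")

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_indexed_matrix(gn$G, idx, file.path(out_dir, "global_network.mtx"))
    write_embeddings(emb, file.path(out_dir, "embeddings.tsv"))
    if (ncol(predictions) > 0)
      write_predictions(predictions, file.path(out_dir, "predictions.tsv"))
    if (!is.null(curve))
      utils::write.table(cbind(curve,
                               F = ifelse(is.na(curve$precision), NA,
                                          ifelse(curve$precision + curve$recall > 0,
                                                 2 * curve$precision * curve$recall /
                                                   (curve$precision + curve$recall), 0))),
                         file.path(out_dir, "pr_curve.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
    js <- list(seed = cfg$seed,
               stages = lapply(stages, function(s) s[!vapply(s, is.null, TRUE)]))
    if (!is.null(summary))
      js$summary <- list(fmax = summary$fmax, t_star = summary$t_star,
                         precision = summary$precision,
                         recall = summary$recall, coverage = coverage)
    jsonlite::write_json(js, file.path(out_dir, "run_manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  manifest
}

#' @export
print.run_manifest <- function(x, ...) {
  cat("run_manifest:\n")
  for (nm in names(x$stages)) {
    s <- x$stages[[nm]]
    info <- s[setdiff(names(s), "seconds")]
    cat(sprintf("  %-9s %6.2fs  %s\n", nm, s$seconds,
                paste(names(info), unlist(info), sep = "=", collapse = ", ")))
  }
  if (!is.null(x$summary)) print(x$summary)
  invisible(x)
}
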