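# lncfun

Predicting Gene Ontology (GO) functions for long non-coding RNAs (lncRNAs)
from a global heterogeneous network.

Most lncRNAs have no experimentally characterized function, while proteins
carry rich curated GO annotation. `lncfun` transfers annotation from proteins
to lncRNAs by guilt-by-association over one global network of three node
kinds — lncRNA, protein, miRNA — assembled from six component networks
(lncRNA co-expression similarity, protein–protein interaction, miRNA
co-expression, lncRNA–protein, lncRNA–miRNA and protein–miRNA associations)
into the symmetric block adjacency

```
      [ L    LP   LM ]
  G = [ LP'  P    PM ]
      [ LM'  PM'  M  ]
```

The pipeline then:

1. **diffuses** the network with a random walk with restart,
   `P_k = α P_{k−1} A + (1−α) P_0` with `A = D⁻¹G` and restart weight
   `1 − α` (default `α = 0.5`), giving each node a stationary visiting
   distribution over the whole graph;
2. **re-weights** the diffusion state as a positive pointwise mutual
   information (PPMI) matrix, `X_ij = max(0, log(P_ij·ΣP / (r_i·c_j)))`;
3. **compresses** the PPMI rows with a stacked denoising autoencoder (SDAE)
   and takes the bottleneck layer as each node's embedding;
4. **trains** one RBF-kernel SVM per GO term on protein embeddings
   (balanced negative sampling, Platt-calibrated probabilities), after
   dropping proteins that have only IEA-evidence annotations;
5. **scores** every lncRNA against every modeled term and **evaluates**
   against a truth set with the CAFA-style `Fmax` protocol: averaged
   precision over the `m(t)` lncRNAs with a nonempty prediction set,
   averaged recall over all `N` evaluated lncRNAs, maximized over a score
   threshold grid.

A seeded synthetic-network generator with planted functional modules makes
the whole pipeline testable end to end without any external downloads.

## Worked example

Generate a synthetic bundle with three planted function groups and run the
full pipeline:

```r
library(lncfun)

bundle <- generate_bundle(synth_config(seed = 7))
bundle
#> synth_bundle: 30 lncRNA, 60 protein, 10 miRNA in 3 groups; 15 held-out truth lncRNAs

run <- run_pipeline(bundle, pipeline_config(seed = 7))
run
#> run_manifest:
#>   build       0.99s  nodes=100, edges=1158
#>   normalize   0.03s
#>   diffuse     0.01s  iterations=15, converged=1
#>   ppmi        0.00s
#>   embed       0.62s  dimension=16
#>   train       0.04s  terms_modeled=9
#>   predict     0.00s  lncrnas_scored=30
#>   evaluate    0.04s  fmax=1, coverage=15
#> Fmax = 1.000 at t* = 0.58 (precision 1.000, recall 1.000)
```

The 100-node network (30 lncRNAs + 60 proteins + 10 miRNAs) is embedded into
16 dimensions; 9 GO terms (3 per group) get classifiers; all 30 lncRNAs are
scored. On the 15 held-out lncRNAs the predictions reach `Fmax = 1.0` at
threshold 0.58 — every held-out lncRNA's group terms are recovered
(`coverage = 15` of 15). The planted structure here is deliberately clean;
the interesting comparison is against chance:

```r
base <- permuted_truth_fmax(run$predictions, bundle$truth,
                            seed = derive_seed(7, "permute"))
sprintf("permuted-truth baseline Fmax = %.3f", base$fmax)
#> "permuted-truth baseline Fmax = 0.667"
```

Randomly reassigning the truth sets among the same lncRNAs still yields
`Fmax ≈ 0.67` (with 3 groups, a permuted lncRNA keeps its own group's terms
a third of the time), so the pipeline's margin over chance — not the raw
`Fmax` — is the meaningful signal.

Real data enter through plain-text files: ID lists (one per line), 3-column
edge-list TSVs, a `protein_id / go_term / evidence` annotation TSV and a
`lncrna_id / go_term` truth TSV; see `read_bundle()`, `read_edge_list()`,
`read_annotations()`, `read_truth()`. A thin command-line wrapper
(`exec/lncfun`) exposes `simulate`, `run-all` and `evaluate` subcommands.

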