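---
title: "Predicting lncRNA functions from a heterogeneous network: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting lncRNA functions from a heterogeneous network: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lncfun)
```

## The problem

Most long non-coding RNAs (lncRNAs) have no experimentally characterized
function, while proteins carry rich, curated Gene Ontology (GO) annotation.
`lncfun` transfers function from proteins to lncRNAs by
guilt-by-association: entities that interact, or are co-expressed, tend to
share function. The package builds one global heterogeneous network over
three node kinds (lncRNA, protein, miRNA), learns a low-dimensional embedding
of every node from the network's diffusion structure, trains one calibrated
SVM per GO term on the protein embeddings, and scores every lncRNA against
every modeled term.

## The model, stage by stage

### Global network assembly

Six component networks enter: three intra-kind similarity networks
(lncRNA co-expression, protein–protein interaction, miRNA co-expression) and
three inter-kind association networks (lncRNA–protein, lncRNA–miRNA,
protein–miRNA). They are stacked into a block matrix over all nodes in fixed
order lncRNA → protein → miRNA:

$$G = \begin{pmatrix} L & LP & LM \\ LP^T & P & PM \\ LM^T & PM^T & M \end{pmatrix}$$

Off-diagonal blocks are mirrored by their transpose, so $G$ is exactly
symmetric and nonnegative — both properties are asserted, not assumed,
because the walk probabilities below require them.

Co-expression similarities are Pearson correlations between expression
profiles (`pcc_similarity()`). Negative correlations are clipped to absent by
default: $G$ must stay nonnegative, and a negative correlation is weak
evidence of shared function. When several expression sources score the same
lncRNA–protein pair, the per-source scores $S_n \in (0,1]$ are combined by a
noisy-OR rule after discarding the non-positive ones
(`fuse_scores()`):

$$S = 1 - \prod_{n} (1 - S_n), \qquad S_n > 0.$$

This is monotone (adding a source never lowers the fused score) and bounded
by 1, which is what one wants of accumulating independent evidence.
Experimentally verified interaction pairs are binary
(`binarize_interactions()`, weight 1); when a pair carries both a fused
co-expression score and a binary interaction, the maximum is taken
(`merge_max_weight()`) — both are confidence-like in $[0,1]$ and experimental
certainty should not be diluted.

Self-similarities are excluded (a self-loop only inflates restart mass), and
duplicate undirected edge records must agree in weight within $10^{-9}$ or
the constructor refuses the input.

### Diffusion: random walk with restart

The adjacency is degree-normalized into a transition matrix,

$$A_{ij} = \frac{G_{ij}}{\sum_k G_{ki}},$$

i.e. each edge weight divided by the total weight incident to the walker's
current node $i$; since $G$ is symmetric this makes every **row** of $A$ a
probability distribution over the next step. (Descriptions of this
construction vary in whether they phrase the normalization over rows or
columns; for a symmetric $G$ the formula above is the one that makes each row
of the diffusion state a distribution, which is the property the rest of the
pipeline relies on.) Zero-degree nodes get a unit diagonal entry — the walker
stays put — which keeps $A$ stochastic without touching other components.

Starting from $P_0 = I$, the walk iterates

$$P_k = \alpha\, P_{k-1} A + (1 - \alpha)\, P_0$$

until the largest per-row L1 change falls below a tolerance (default
$10^{-6}$, cap 100 iterations). Here $\alpha$ multiplies the walk term, so
$1-\alpha$ is the restart weight; some texts attach the name $\alpha$ to the
restart probability instead, and at the default operating point
$\alpha = 0.5$ the two readings coincide — which is the value used
throughout. The converged matrix (the *diffusion state*) has row $i$ equal to
the stationary visiting distribution of a walker restarting at node $i$; the
fixed point satisfies $P = (1-\alpha) P_0 (I - \alpha A)^{-1}$, and the test
suite checks the iterative solution against that closed form to $10^{-8}$.
An `accumulated` mode returning $\sum_{k\ge 1} P_k$ is also provided, since
the underlying graph-representation construction is sometimes run that way;
`converged` is the default.

### PPMI re-weighting

Raw diffusion rows are dominated by hub nodes. Treating the diffusion state
as a co-occurrence table, each entry is re-weighted by positive pointwise
mutual information:

$$X_{ij} = \max\!\left(0,\; \log \frac{P_{ij} \cdot \sum_{kl} P_{kl}}
{\left(\sum_j P_{ij}\right)\left(\sum_i P_{ij}\right)} \right),$$

which keeps only associations stronger than the independence of their
marginals would predict. Zeros of $P$ stay zero, the result is invariant to
scaling $P$ by a positive constant, and the log base (natural by default)
only rescales nonzero values.

### SDAE embedding

The PPMI matrix is high-dimensional (one column per node), so a stacked
denoising autoencoder compresses it. Each greedy stage corrupts its input by
masking noise (each entry zeroed independently with probability 0.2 by
default), maps it through a logistic-sigmoid hidden layer of the next
configured width, reconstructs the *clean* input with a linear decoder, and
minimizes squared reconstruction error; the stage's hidden representation of
the clean input feeds the next stage. The bottleneck (last) layer is the
embedding. Optimization is Adam (step size defaults: $10^{-3}$ generally,
$10^{-2}$ in the reduced-scale pipeline default where inputs are ~100
columns), minibatch 32. Squared loss pairs naturally with a linear
reconstruction output; the hidden activation is the conventional bounded
squashing choice. An optional end-to-end fine-tuning pass over the unrolled
stack is available (off by default), as is per-column min-max input scaling
for data whose PPMI values are large enough to saturate the sigmoid.

Everything is a deterministic function of (seed, config, data): weight
initialization, minibatch order and corruption masks all draw from one
seeded stream, and the test suite asserts bit-identical reruns.

The full-scale width schedule for a 36,863-node network is
`[36863, 10000, 3000, 1000, 512]` with a 512-dimensional bottleneck; that is
a configuration default only. The package's own pipeline default is the
reduced-scale `[n, 48, 16]` (bottleneck 16) used on the ~100-node synthetic
study networks, with 150 epochs per stage — small enough that the entire
pipeline runs in seconds while still separating planted modules cleanly.

### Annotation transfer via per-term SVMs

Protein annotations are first filtered: a protein whose *every* record is
evidence code IEA (the only code not assigned by a curator) is dropped
entirely; a protein with at least one manually assigned term keeps all its
records. Optional true-path propagation (annotate each protein to all
`is_a`/`part_of` ancestors of its terms, via a minimal OBO reader) is
provided but off by default — the core transfer method does not require it,
and whether to apply it is an evaluation-protocol convention.

For each GO term with at least `min_positives` annotated proteins (default
10), a balanced training set is built: all positives, plus an equal-size
uniform random sample (without replacement, seeded) of embedded proteins not
annotated to the term. An RBF-kernel SVM ($C = 1$, kernel width by the median
heuristic on the training features) is fitted with Platt-style sigmoid
probability calibration on internal cross-validation folds, so every emitted
score is a probability in $[0,1]$. lncRNAs never enter any training set —
training uses proteins only; lncRNA embeddings are scored at prediction time.

### Evaluation: the Fmax protocol

For a score threshold $t$, each evaluated lncRNA's prediction set $P_i(t)$
contains the terms scoring $\ge t$ (boundary included). With truth sets
$T_i$:

- per-gene precision $= |P_i(t) \cap T_i| / |P_i(t)|$, undefined when
  $P_i(t)$ is empty;
- per-gene recall $= |P_i(t) \cap T_i| / |T_i|$.

Averaged precision at $t$ is taken over only the $m(t)$ lncRNAs with a
nonempty prediction set — that is exactly why the $m(t)$ convention exists —
while averaged recall is taken over all $N$ evaluated lncRNAs, an empty
prediction set contributing recall 0. Then

$$F_{max} = \max_t \frac{2\,Pr(t)\,Rc(t)}{Pr(t) + Rc(t)},$$

searched over a grid of 101 evenly spaced thresholds by default, skipping
thresholds where $Pr$ is undefined, with $F = 0$ where $Pr + Rc = 0$ and ties
resolved to the smallest threshold. Truth and predictions are compared as
flat term sets (exact match, no ontology-aware partial credit). The
*coverage* count is the number of lncRNAs with at least one true positive
term at the $F_{max}$ threshold; the threshold is an explicit argument
because "annotated correctly" admits other readings.

## The synthetic generator: what it does and does not emulate

`generate_bundle()` plants functional modules: every entity belongs to one of
`g` groups; in all six component networks an edge appears with probability
`p_in` inside a group and `p_out` between groups, with confidence-like
weights $\mathrm{clip}_{(0,1]}(0.5 + \mathcal{N}(0, 0.1))$ (binary mode
available for the interaction-style network). Each group owns
`terms_per_group` GO terms (3 by default); every protein is annotated with
its group's terms (evidence `EXP`), and for a held-out fraction of lncRNAs
(50% by default) the group terms become the evaluation truth set.

Defaults (`n_l = 30`, `n_p = 60`, `n_m = 10`, `g = 3`, `p_in = 0.3`,
`p_out = 0.02`) are the package's standing study conditions: large enough
that each group has ~20 proteins (so balanced training sets exist at
`min_positives = 10`), small enough that the full pipeline runs in a few
seconds. The no-signal control sets `p_in = p_out = 0.15`, the signal
configuration's approximate mean edge rate, so total edge density is held
roughly constant while the group labels carry no information.

What passing tests on this generator show: the pipeline recovers planted
guilt-by-association structure far above a permuted-truth chance baseline,
and degrades to chance when the structure is removed. What they do not show:
performance on real data, whose degree distributions are heavy-tailed, whose
GO term frequencies span orders of magnitude, whose truth sets are sparse
and biased toward well-studied genes, and whose component networks disagree
with each other. The generator is a statistical test harness, not a mimic of
real interaction databases.

## Numerical and design choices

- **Transition normalization.** $A = D^{-1} G$ (rows stochastic), per the
  formula above; asserted against a per-entry oracle. Symmetry of $G$ is
  checked first because the construction is only meaningful for undirected
  networks.
- **Isolated nodes** stay put rather than being rejected; this keeps ablation
  configurations (e.g. a kind with no edges) runnable.
- **Convergence.** Max-row L1 tolerance $10^{-6}$, 100 iterations by default;
  the geometric contraction rate is $\alpha$, so at $\alpha = 0.5$ this is
  ample. Tests that compare against the closed form tighten the tolerance
  instead of loosening the comparison.
- **PPMI log base** natural by default; configurable, since only the nonzero
  magnitudes change.
- **Seeding.** One global seed; each stochastic stage (SDAE, per-term
  negative sampling, calibration folds, permutation baseline) derives its own
  seed by hashing the stage name (`derive_seed()`), so removing one stage or
  term never reshuffles another. All derived seeds stay below $2^{31}$.
- **Degenerate inputs** fail loudly and early: zero-variance expression rows
  name the offending entity, malformed TSV lines name the line number,
  unknown identifiers are listed, all-identical training features are
  rejected, non-finite SDAE losses cite stage and epoch.
- **Sparse storage.** Networks are sparse end-to-end (`Matrix`); only the
  diffusion state and PPMI matrix are dense, which is intrinsic — diffusion
  fills in zeros — and acceptable at the node counts the package targets.

## Known limitations

- The diffusion state is materialized densely, so networks beyond a few
  thousand nodes need more memory than the defaults assume; the full-scale
  width schedule is provided as configuration but training it is a
  cluster-scale job, not a package default.
- SVM probability calibration on small balanced sets (tens of examples) is
  noisy; scores are well-ordered long before they are well-calibrated.
- The evaluation gives no partial credit for predicting a parent of a true
  term unless propagation is switched on for both predictions' training
  annotations and the truth.
- miRNA nodes carry no annotations and are never scored; they contribute
  connectivity only.
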