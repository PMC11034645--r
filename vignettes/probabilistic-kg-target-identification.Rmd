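---
title: "Probabilistic knowledge graphs for disease target identification: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Probabilistic knowledge graphs for disease target identification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(probkg)
```

# The problem

Target identification asks which proteins, when activated or inhibited, have a
therapeutic effect on a disease. Heterogeneous biological networks — drug–drug
and protein–protein interactions, drug–protein interactions, drug–disease and
protein–disease associations, drug–side-effect associations — encode much of
what is known, but as *binary* edges: an observed association says nothing
about the strength of its evidence, and an absent edge is not a negative
(the *exposure bias* problem familiar from recommendation systems).

`probkg` addresses both issues by building a **probabilistic knowledge graph**:
edges carry probabilities derived from how often the two entities co-occur in
a literature corpus, a graph-embedding model reconstructs the weighted graph,
and the reconstructed protein–disease scores rank candidate targets.

# The model

## Edge probabilities

Entities come in four types, $T = \{\mathrm{drug}, \mathrm{protein},
\mathrm{disease}, \mathrm{side\ effect}\}$. Relations split into three groups:

* $R_c$ — literature-weighted associations (drug–protein, drug–disease,
  protein–disease), whose evidence strength is the co-occurrence count
  $C_r[i,j]$: the number of documents mentioning both entities;
* $R_s$ — two *dense* similarity relations (drug structural similarity via
  Dice on Morgan fingerprints, protein sequence similarity via normalized
  Smith–Waterman scores), where every pair carries its similarity score;
* the remaining associations/interactions, which stay binary.

An observed edge $e = (i, j, r)$ receives probability

$$p(e) = \big(\sigma(C_r[i,j] + \alpha) - 1\big)\,\mathbb{1}_{R_c}(r) + 1,$$

with $\sigma$ the logistic function: a literature-weighted edge with zero
co-occurrence evidence floors at $\sigma(\alpha)$ and approaches 1
monotonically with its count; non-$R_c$ association edges are exactly 1;
similarity edges carry their similarity value; unobserved pairs are 0.
The hyperparameters $\alpha$ (probability floor) and $\beta$ (weight floor,
below) default to 0 — so a zero-evidence observed edge has probability 0.5 —
and are exposed on every constructor, since no canonical values exist.

## Embedding and reconstruction

For each relation the aggregation adjacency is
$A_r = P_r$ if $r \in R_s$, else the binarization $I(P_r > 0)$, followed by
**row-wise Euclidean normalization** $\hat A_r$. Each entity type $a$
aggregates over every relation touching it (using $\hat A_r^\top$ when $a$ is
the target side):

$$Y_a = \sum_{r \in R^a} \hat A_r X_b W_r, \qquad
  \tilde Z_a = \mathrm{ReLU}([Y_a \,|\, X_a]\, W^1), \qquad
  Z_a = \mathrm{rownorm}(\tilde Z_a),$$

with learnable initial embeddings $X_a$ ($n_a \times d_0$), per-relation
weights $W_r$, and a shared projection $W^1$. The training objective
reconstructs every relation through a projection pair $G_r, H_r$:

$$\min_\Theta \sum_r \big\| (Z_a G_r H_r^\top Z_b^\top - P_r) \odot M_r
  \big\|_F^2 + \lambda \sum_{\theta \in \Theta} \|\theta\|_F^2,$$

where the loss weight
$M_r[i,j] = \frac{\sigma(C_r+\beta)-1}{\sigma(C_r+\alpha)} P_r[i,j]\,
\mathbb{1}_{R_c}(r) + 1$
up-weights well-evidenced edges: when $P_r$ came from the probability map it
collapses algebraically to $\sigma(C_r[i,j]+\beta)$, so weights live in
$[\sigma(\beta), 1)$ on observed literature edges and are exactly 1 elsewhere.
For symmetric relations (both similarity networks, drug–drug and
protein–protein interaction) the tie $G_r = H_r$ enforces symmetric
reconstructions.

## Ablation controls

Four control objectives nullify the literature evidence: `og` reconstructs
the unweighted binarized graph; `rp` replaces observed literature
probabilities by cached uniform draws $u_1 \in [\sigma(\alpha), 1)$ (the
exact range the count map can produce); `rw` replaces weights by independent
draws $u_2 \in [\sigma(\beta), 1)$; `rpw` does both. Draws are made once
("offline") and cached, so a control model trains against a fixed randomized
graph. If the full model beats `rpw`, the counts — not merely the weighting
scheme — carry signal.

# Numerical and design choices

Where the method's description left genuine freedom, this package decides as
follows (each is a package-level choice, not something inherited verbatim):

* **Normalization.** The bare $\|\cdot\|_2$ on $A_r$ and $\tilde Z_a$ is read
  as *row-wise* Euclidean normalization: each node's neighborhood and
  embedding is scaled independently, which yields unit-norm embeddings and
  scale-free aggregation. A whole-matrix Frobenius alternative is available
  via `train_config(norm = "frobenius")`. Zero rows stay zero in both modes.
* **One pass.** Aggregation + projection runs once per forward pass; the
  description is of a single convolution round, and a configurable round
  count was dropped (it would buy nothing tested here).
* **Optimizer.** No autograd framework is assumed: gradients are derived by
  hand (verified against central finite differences to 1e-5 in the test
  suite) and optimized with full-batch Adam. Defaults: `lr = 2e-3`,
  `epochs = 1000` with early stopping on validation AUPR (patience 50),
  `lambda = 1e-4`, dimensions $d_0 = 128$, $d_1 = 64$, $k = 64$, Gaussian
  initialization at scale $1/\sqrt{d}$. The learning rate was tuned once on a
  synthetic world (seed 101, disjoint from any seed used in the tests): 1e-3
  converged too slowly for the 500-epoch training-sanity budget while 2e-3
  through 5e-3 all reached $\le 8.6\%$ of the initial loss with held-out
  AUROC $\ge 0.95$; 2e-3 is the most conservative of those.
* **Loss support.** Unobserved entries of association relations are included
  with weight 1 (the objective is written over full grids); dense similarity
  relations contribute every entry, including the unit diagonal. Entries
  masked with `mask_entries()` are removed from *both* the target and the
  loss (weight 0): leaving held-out positives in the loss as forced zeros
  would train against the test labels.
* **Similarity relations under controls.** Read literally, the randomized
  probability formula would set similarity edges to 1; since similarity
  edges' probabilities are defined as similarity scores (overriding the
  count-based map), the controls leave similarity grids unchanged.
* **Smith–Waterman.** Exact affine-gap DP with BLOSUM50 (via Biostrings'
  table); a gap of length $L$ costs $\mathrm{open} + \mathrm{ext}(L-1)$
  with EMBOSS-water defaults open 10, ext 0.5. Raw local-alignment scores
  are unbounded, so the similarity grid divides by the geometric mean of the
  self-alignment scores, $SW(i,j)/\sqrt{SW(i,i)\,SW(j,j)}$, giving a
  symmetric unit-diagonal grid in $[0,1]$ (raw scores via
  `normalize = FALSE`).
* **Literature matching.** Case-insensitive *substring* matching through an
  Aho–Corasick automaton, counted at the *document* level (a document
  contributes at most 1 to any pair, however often either name occurs).
  Substring semantics can overmatch very short names, so synonyms shorter
  than `min_length = 3` characters are dropped. The automaton is required to
  behave identically to a naive per-synonym scan; a brute-force oracle
  enforces this in the tests.
* **Statistics conventions.** Significant entries per row are those strictly
  above $\mu + 2\sigma$ with the *population* standard deviation; Spearman
  correlations use average ranks for ties and report `NA` (never 0) when a
  rank variance is zero; AUROC uses the tie-corrected Mann–Whitney form and
  AUPR the step-interpolated sweep with tied scores grouped; empty or
  single-class evaluation subsets are reported as undefined, not zero.
* **Cross-validation.** Entry-wise folds stratify individual matrix entries
  (per-fold positive counts within 1 of exact). Cluster-wise folds cluster
  disease columns by average-linkage agglomerative clustering on
  $1 - \mathrm{Jaccard}$, then assign whole clusters largest-first to the
  currently smallest fold; a cluster larger than $1/k$ of the columns is
  split at a lower dendrogram level with a warning. Linkage and the size cap
  are package choices — the underlying description names neither. Validation
  entries are a stratified 10% of the non-test entries.
* **Graph construction.** Duplicate edges deduplicate; conflicting
  similarity values keep the maximum (conservative and deterministic);
  similarity diagonals are fixed at 1 and participate in the loss; entity
  identifiers are opaque strings (no MeSH/UniProt normalization — that is
  curation, not method).

# The synthetic world

`generate_prob_kg()` plants a rank-4 latent factor structure over
60 entities per type: a pair is a true link when its factor inner product
exceeds the relation's density-calibrated quantile (density 0.15, between the
sparse and dense regimes of real target–disease matrices). Co-occurrence
counts are two-rate Poisson — mean $\lambda_1 = 8$ on true links,
$\lambda_0 = 0.5$ elsewhere — the minimal model that makes literature
evidence informative, which the ablation comparison requires. Similarity
grids are cosine similarities of the latent factors mapped affinely to
$[0,1]$. A 10% fraction of true target–disease links is withheld: removed
from the observed graph, counts zeroed, and (in `recovery_experiment()`)
masked out of the loss.

What a green recovery test **does** establish: the pipeline recovers planted
low-rank structure from held-out entries well above chance, with informative
counts helping. What it does **not** establish: performance on real
databases, whose degree distributions are heavy-tailed and far larger, whose
entity naming is noisy, and whose "negatives" are unlabeled — none of which
the generator emulates. Note also that in the recovery experiment only
held-out *positives* are masked; unobserved negatives remain in the loss with
weight 1, which inflates held-out separability relative to a fully masked
test fold. For honest evaluation on real data, mask entire test folds from
`entrywise_folds()` / `clusterwise_folds()` with `mask_entries()`.

```{r, eval = FALSE}
reps <- recovery_experiment(synthetic_spec(seed = 1),
                            train_config(epochs = 500, seed = 1),
                            variants = c("full", "rpw"))
reps$full
```

# Known limitations

* Dense matrices throughout: designed for desk-scale catalogs (thousands of
  entities), not the full real-data graphs.
* The Smith–Waterman DP is exact and quadratic; no BLAST-style heuristics.
* Substring name matching does no disambiguation or abbreviation expansion.
* Exposure-bias diagnostics (`subset_performance()`,
  `maxscore_degree_correlation()`) quantify the bias; nothing in the model
  explicitly corrects it.
* Symmetric relations are reconstructed through a tied projection
  $G_r G_r^\top$, which constrains the reconstruction to be positive
  semi-definite in the embedding inner product; zero-diagonal interaction
  networks therefore retain an irreducible fitting error.
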