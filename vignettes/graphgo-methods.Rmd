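---
title: "graphgo: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{graphgo: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Most proteins have no experimentally verified function. Automated Gene
Ontology (GO) annotation is a multilabel classification problem: given a
protein, score every term of a GO namespace (molecular function MFO,
biological process BPO, cellular component CCO). `graphgo` implements a
multimodal predictor at desk scale: protein *structure* enters as a
residue contact graph processed by a hierarchical graph neural network,
protein *sequence* enters as a global embedding vector, and the two are
fused and decoded into per-term probabilities.

# The model, stage by stage

## Contact graphs

A predicted structure (PDB file) is reduced to its C-alpha trace. Nodes
are residues; an edge joins residues whose C-alpha atoms are strictly
closer than 10 Å (the threshold is a parameter; the strict inequality is
deliberate, so a pair at exactly 10 Å is not in contact). Self-loops are
added for the graph convolution, whose propagation rule is

$$H^{(l+1)} = \sigma\!\left(\tilde D^{-1/2}\tilde A\,\tilde D^{-1/2} H^{(l)} W^{(l)}\right),$$

with $\tilde A$ the adjacency with self-loops and $\tilde D$ its degree
matrix. Residues without a C-alpha atom are dropped and indices
compacted; the first model, chain and alternate location are taken when
a file contains several, because single-chain predicted models are the
intended input.

## Structural node embeddings

Per-residue features come from biased second-order random walks trained
with skip-gram and negative sampling. Stepping from node $v$ with
predecessor $t$, a neighbor $x$ receives unnormalized weight
$\alpha_{pq}(t,x)\,W_{vx}$ where $\alpha$ is $1/p$ if $x = t$, $1$ if
$x$ is adjacent to $t$, and $1/q$ otherwise. Defaults $p = 0.8$,
$q = 1.2$ give a mildly outward-biased walk. Design choices:

* **Self-loops are excluded from the walk graph** — a self-step carries
  no structural information and makes the distance classification of
  $\alpha$ ill-posed. They stay in the GNN adjacency.
* The distance case is computed locally ($d = 0$ iff $x = t$, $1$ iff
  adjacency$(t,x)$, else $2$), exact for neighbors of $v$.
* The first step of a walk, which has no predecessor, samples neighbors
  proportional to edge weight.
* Walk and skip-gram sizes are not fixed by any reference; the defaults
  (10 walks per node, length 80, dimension 30, window 10, 5 negatives,
  5 epochs) are conventional settings, all exposed in `walk_config()`.
  Dimension 30 keeps desk-scale graphs (tens of nodes) from being
  overparameterized.
* Training is single-threaded with a self-contained xorshift RNG, so an
  embedding table is a pure function of (graph, config, seed).

## Sequence features

Two kinds: (i) per-residue one-hot encodings over the 20 standard
residues plus `X` (alphabetical column order, `X` last), optionally
concatenated to the structural node features; (ii) a global per-protein
vector `h_global`. Real protein-language-model embeddings are
precomputed offline and loaded through `load_plm_embeddings()` — the
adapter infers the dimension from the file and hard-codes nothing,
because published model variants disagree with some reported widths.
For self-contained runs, `mock_embed()` provides a deterministic
stand-in: a seeded random projection of the sequence's 3-mer count
profile, so identical sequences map to identical vectors and
near-identical sequences to nearby ones. It is a *test double*, not a
language model: it has no evolutionary knowledge and its similarity
structure is purely compositional.

## GO labels

`parse_obo()` reads OBO 1.2, keeps non-obsolete terms and `is_a` edges
only (`part_of`/`regulates` are ignored — the conservative CAFA-style
default), checks namespace consistency and acyclicity. Annotations are
propagated by the true-path rule (a protein annotated with a term is
annotated with every ancestor), then rare terms are dropped: the default
`min_proteins = 25` is configurable since published frequency thresholds
are data-dependent. Namespace roots are excluded from vocabularies —
after propagation they are annotated to everything. The label matrix
therefore satisfies column-wise hierarchy: a child column never exceeds
its parent's.

## The network

Six stacked **ConvPoolBlocks**, each: a 3-layer graph convolution stack
(ReLU), **self-attention graph pooling** — two independent single-layer
attention passes $z_k = \tanh(\tilde D^{-1/2}\tilde A \tilde D^{-1/2} X
\theta_k)$ averaged into per-node scores $y$, the top $\lceil 0.75 N
\rceil$ nodes kept (ties broken toward lower node index for
determinism), features gated by $y$, adjacency reduced to the induced
subgraph — and a **mixed readout** concatenating the node-wise mean and
elementwise max. Where the textual description ("sum pooling") and the
formula (a $1/N$ term) of the readout disagree, the formula (mean) is
implemented.

Open points resolved as package design choices:

* **Per-block readout aggregation** is a sum over the six blocks (the
  standard hierarchical-pooling readout; keeps the fused width
  independent of depth). `readout_agg = "concat"` is available.
* **Blocks do not share parameters**; the hidden width defaults to 64.
* **Transformer input**: a transformer needs tokens. The fused
  representation is presented as three role tokens — a learned
  classification token, the projected graph readout, the projected
  sequence embedding — encoded by a 3-layer, 8-head encoder (post-layer-
  norm, 4x feedforward width). Tokens are role-specific, so no
  positional encoding is required; the classification token's output
  feeds a 3-layer fully connected head with sigmoid outputs.
* **Loss/optimizer** (unstated in any reference): elementwise binary
  cross-entropy and Adam at 1e-3 — the standard multilabel choices.
* Initialization is Glorot-uniform from a seeded stream; dropout
  (default 0.2) applies to attention output, feedforward output and
  between classifier layers, in training mode only.

The whole network is implemented in base R with hand-written
backpropagation (no GPU framework exists in the target environment); a
finite-difference gradient check over *every* parameter tensor is part
of the test suite, which is a stronger correctness guarantee than
trusting an autograd.

## Evaluation

Protein-centric Fmax over a 101-point threshold grid: at threshold
$\tau$, precision is averaged over the $m(\tau)$ proteins predicting at
least one term, recall over all evaluable proteins, and Fmax is the
maximum harmonic mean. Proteins with zero true labels are excluded from
recall averaging with a warning (the definition leaves them unspecified;
excluding is the conservative choice). AUC and AUPR are micro-averaged
over all protein-term cells by default (`average = "macro"` gives
by-term averaging): AUC by the rank/Mann-Whitney estimator with
midranks, AUPR by step interpolation over descending distinct scores.
Training uses a 7:2:1 random split (largest-remainder rounding, so 10
proteins give exactly 7/2/1), early stopping on validation Fmax with
patience 10, and per-namespace defaults of dropout 0.2 / batch 32 (MFO,
CCO) and 0.3 / 64 (BPO).

# The synthetic world

`generate_dataset()` emits a complete toy dataset: PDB structures,
FASTA, a miniature `is_a` ontology, and annotations. Chains are
ideal-geometry C-alpha traces — α-helix (2.3 Å radius, 100° turn,
1.5 Å rise), extended strand (collinear 3.8 Å), or a self-avoiding
random coil (3.8 Å steps) — so contact density separates folds cleanly:
an extended chain only contacts $|i-j| \le 2$ neighbors while a helix
contacts out to $|i-j| \approx 7$. Labels are planted from **both**
modalities, mirroring the multimodal claim under test: four sequence
motifs (prevalence 0.35 each), two contact-density bands (mean degree
< 4.5 and ≥ 8.5, hit by extended and helical folds respectively), a
coil-fold term and a hydrophobic-composition term, each flipped
independently with probability 0.05. Defaults: 200 proteins of 30–80
residues, 12 terms in a 3-level ontology, seed-reproducible to the byte.

What a green end-to-end test establishes: the pipeline can extract
planted sequence and structure signal and beat both a shuffled-label
control and the all-positive baseline. What it does **not** establish:
performance on real proteomes — real structures are not ideal traces,
real GO vocabularies are orders of magnitude larger and imbalanced, and
a real language model is not a k-mer hash.

# Numerical and budget choices

* Contact threshold comparisons are strict (`<`); top-k ties break
  toward lower node index; Fmax threshold ties toward the lower
  threshold; the max-pool subgradient routes to the first maximal row.
* All randomness flows through explicit integer seeds; derived stage
  seeds are hashed into the 32-bit range R accepts.
* The acceptance suite scales two things down for a 1-CPU budget, both
  stated in the test file: criterion 5 trains on the full default world
  but with a reduced walk corpus (5×40 walks, 3 skip-gram epochs), and
  criterion 7 verifies byte-identical pipeline reruns on a 24-protein
  world — determinism is scale-independent.
* Degenerate inputs: a single-residue chain yields a self-loop-only
  graph; an isolated node truncates its walks and receives a zero
  embedding with a warning; `N = 1` pooling keeps the node (gated);
  an empty vocabulary after rare-term filtering is an error advising a
  lower threshold.

# Known limitations

* No mmCIF, multi-chain complexes, all-atom contact definitions or
  pLDDT filtering; first model/chain/altloc only.
* Only `is_a` propagation; no evidence codes, no full GAF parsing.
* The transformer tokenization of the fused vector is one reasonable
  reading of an under-specified design; alternatives (e.g. per-block
  readout tokens) exist.
* Training is CPU-bound R; it is meant for hundreds of proteins and
  tens of terms, not proteome-scale runs.
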