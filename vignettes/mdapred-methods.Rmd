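---
title: "Methods: graph-regularized NMF for miRNA-disease association prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: graph-regularized NMF for miRNA-disease association prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mdapred)
```

## The problem

Most experimentally confirmed miRNA-disease associations cover a small
corner of the full miRNA x disease grid, and wet-lab validation of a
candidate association is slow and expensive. The goal of this package is
to rank the unobserved cells of the binary association matrix
$A \in \{0,1\}^{N_m \times N_d}$ so that true but not-yet-observed
associations concentrate at the top of each disease's candidate list.

Three kinds of side information are available beyond $A$ itself:

* a miRNA-miRNA functional similarity matrix $M$ (computable from the
  disease sets of the miRNAs, see below),
* a disease-disease similarity matrix $D$ with entries in $[0,1]$
  (consumed as an input; semantic/phenotype similarity computation from
  MeSH terms is upstream of this package),
* a sparse binary node-attribute matrix
  $C \in \{0,1\}^{N_m \times (N_f+N_c)}$ recording miRNA family and
  genomic-cluster membership. miRNAs in one family share a seed region
  and hence plausibly share targets and diseases; miRNAs within ~20 kb
  on the genome are typically co-transcribed, with the same consequence.

## The model

The predicted score matrix $U \ge 0$ minimizes

$$
\mathcal{L}(U,X,Y,Z) \;=\; \|U-A\|_F^2
\;+\; \alpha_1\|U - MX(DY)^T\|_F^2
\;+\; \alpha_2\|U - CZ(DY)^T\|_F^2
\;+\; \alpha_3\,\mathrm{Tr}(U^T L U)
\;+\; \alpha_4\|U\|_1
$$

over nonnegative $U, X, Y, Z$. The projections $X$ ($N_m \times c$),
$Y$ ($N_d \times c$) and $Z$ ($(N_f+N_c) \times c$) place miRNAs
(through their similarities), diseases (through theirs) and miRNA node
attributes in one shared $c$-dimensional space; the products
$MX(DY)^T$ and $CZ(DY)^T$ are low-rank reconstructions of the score
matrix from edges and from node attributes respectively. $L = W - S$ is
the Laplacian of the miRNA k-nearest-neighbour graph, so the trace term
penalizes score differences between similar miRNAs
($\mathrm{Tr}(U^TLU) = \tfrac12\sum_{ij} S_{ij}\|U_{i\cdot}-U_{j\cdot}\|^2$
for symmetric $S$). The $\ell_1$ penalty encodes that a disease is
associated with a limited number of miRNAs.

Assumptions worth stating explicitly: associations are generated by a
low-rank mechanism expressible in the similarity/attribute bases;
unobserved cells are predominantly true negatives (they enter the fit
term as zeros); and similarity neighbourhoods are informative about
shared disease spectra.

### Solver

The objective is non-convex jointly, so it is split into four
subproblems solved cyclically (U, then X, Y, Z) by multiplicative
updates, each derived by splitting the subproblem gradient into its
positive and negative parts and rescaling the factor by their ratio,
e.g.

$$
U \leftarrow U \odot
\frac{2A + 2\alpha_1 MX(DY)^T + 2\alpha_2 CZ(DY)^T + 2\alpha_3 SU}
     {2U + 2\alpha_1 U + 2\alpha_2 U + 2\alpha_3 WU + \alpha_4 B},
$$

with $B$ all ones. Starting from positive factors, every iterate stays
nonnegative by construction. The objective is recorded once per full
cycle; iteration stops when the difference between two adjacent cycles
falls below $\varepsilon$ or after `max_iter` cycles. Monotonicity of
these rules is *not* proven for this composite objective; the test
suite checks it empirically (20 seeded runs, non-increase in at least
99% of recorded cycles) rather than assuming it. Correctness of each
rule is verified two independent ways: elementwise substitution
oracles, and finite-difference agreement of the implied gradient of
each subproblem, because the intermediate trace algebra one would
otherwise transcribe contains typographical corruption in its source.

### Numerical choices

* **Initialization** (unspecified in the original description).
  Default `warm_start_from_A`: $U_0 = A + 0.1\,\overline{A}\,\mathrm{Unif}(0,1)$
  — strictly positive so the multiplicative rules can move every entry,
  while starting at the data; $X_0, Y_0, Z_0 \sim 0.01\,\mathrm{Unif}(0,1)$.
  A `uniform_random` scheme is available. All draws are seeded.
* **Denominator guard.** Each update denominator gets an additive floor
  $\delta = 10^{-12}$; the rules are undefined at zero and this is
  standard NMF practice.
* **Convergence.** Absolute difference below $\varepsilon = 10^{-6}$ by
  default, as published; since an absolute threshold is scale-dependent,
  a relative mode is available (`convergence = "relative"`).
* **Empty attribute matrix.** When $N_f + N_c = 0$ the attribute term is
  dropped entirely (treated as "no information") rather than evaluated
  as $\alpha_2\|U\|^2$, which would absurdly shrink all scores just
  because no annotation file was supplied. All-zero *rows* of a nonempty
  $C$ need no special case: $(CZ)_{i\cdot} = 0$ for such miRNAs.
* **Ties** in the kNN selection are broken by ascending index, making
  graphs and hence fits reproducible.

### Tunable parameters

| parameter | default | meaning / provenance |
|---|---|---|
| $\alpha_1..\alpha_4$ | 0.1 | term weights; best value on a $\{0.01,0.1,1,10\}$ CV grid over the real data in the original study |
| $c$ | 15 | shared latent dimension; never reported originally — this package's choice, swept in the test suite |
| $k$ | 5 | neighbour count of the miRNA graph; never reported originally — this package's choice |
| $\varepsilon$ | $10^{-6}$ | objective-difference stopping threshold |
| `max_iter` | 100 | cycle cap, as published |

## Similarity and graph construction

`mirna_functional_similarity()` scores two miRNAs by best-match
averaging of their disease sets over $D$: each disease of one set is
matched to its most similar disease in the other set, and the matches
are averaged over both directions. miRNAs with empty disease sets get
similarity 0 (no information), and self-similarity is 1 otherwise.

The published neighbour rule ("$S_{ij}=1$ if miRNA $i$ is one of the
similar neighbours of miRNA $j$") yields a *directed* graph; by default
this package symmetrizes it with $\max(S, S^T)$ so that
$\mathrm{Tr}(U^TLU)$ is the standard nonnegative smoothness penalty.
The raw directed variant remains available (`symmetrize_graph = FALSE`)
since the $U$ update uses $S$ and $W$ directly and is well-defined
either way; whether the original experiments symmetrized is not stated.

During cross-validation, if $M$ is itself derived from the
associations, recomputing it from the *training* fold only
(`recompute_mirna_sim = TRUE`) avoids leaking held-out labels through
the similarity network. Whether the original experiments did so is not
stated; leakage-free is the defensible default when applicable, and the
naive variant is reproducible by passing a fixed precomputed $M$.

## Evaluation protocol

All known positives are split uniformly at random into five near-equal
folds. Per fold, the held-out positives are set to 0 in the training
matrix, the model is refit, and each evaluated disease's candidate
miRNAs are ranked by its score column — the fold's positives are the
positive class, never-observed pairs the negative class, and training
positives are excluded from the ranking. Design points the source
leaves open, fixed here:

* masked positives are excluded from the negative pool (they are not
  "unobserved");
* per-disease metrics are averaged over the folds in which the disease
  has held-out positives; report averages are arithmetic means over
  diseases; only a disease's own column cells are its negatives;
* the PR area uses the trapezoid rule on the threshold-swept curve
  anchored at recall 0 (the step-function average-precision estimator
  is a flag); ROC/PR curves are vertically averaged across folds on a
  fixed 1000-point grid;
* "common diseases" are selected by a minimum-positives predicate
  (default 80, matching the 15-disease selection on the real data)
  rather than a hard-coded list. At synthetic scale the cutoff must be
  scaled with the miRNA universe — 200 synthetic miRNAs versus roughly
  a thousand in the real data gives a cutoff of 16 — otherwise the
  predicate selects nothing.

A pooled mode and a paired t-test on per-disease AUCs (for method
comparison) complete the protocol.

## The synthetic world

`generate_synthetic()` states a world with 200 miRNAs in 20 families
and 30 clusters, 40 diseases, a planted rank-6 nonnegative latent
structure, 8% association density, similarity noise of sd 0.05 and a 2%
independent label-flip probability. Free choices and why:

* family/cluster structure is *tied to the latent factors* (each
  miRNA's latent row = its family prototype + half its cluster
  prototype + half-normal noise of sd 0.1), so the attribute projection
  genuinely predicts associations — otherwise the $\alpha_2$ code path
  would be untestable for effect;
* ~10 members per family makes family membership informative without
  making families trivially separable; cluster prototypes at half
  weight reflect that co-transcription is a weaker functional tie than
  shared seed regions;
* similarities are cosine similarities of the latent rows (any
  nonnegative kernel satisfies the type contract) with symmetric
  truncated Gaussian noise, sd 0.05 — mild measurement noise;
* the association threshold quantile is *compensated for flips*
  ($d_0 = (\text{density} - f)/(1 - 2f)$) so the realized post-flip
  density matches the target in expectation.

What the generator does **not** emulate: MeSH DAG topology, genomic
coordinates, the heavy-tailed disease-degree distribution of real
association databases, or their identifier universe. A green synthetic
recovery test therefore establishes that the implementation extracts
planted low-rank/attribute/neighbour signal under label noise — not
that the model attains any particular performance on real curated data.

## Known limitations

* The label-flip noise bounds attainable ranking quality: a flipped-in
  positive carries no signal, so even an oracle scoring with the true
  planted probabilities cannot rank it above genuine negatives. At the
  default density and flip rate, roughly a fifth of all positives are
  such noise cells, and sparsely annotated diseases are hit hardest —
  per-disease AUC over *all* diseases has a markedly lower ceiling than
  over common diseases. Recovery results in the test suite must be read
  against this ceiling, not against 1.0.
* At the stated weights the data-fidelity term (weight 1) dominates the
  side-information terms (weight 0.1 each): held-out cells are scored
  by a conservative blend in which the attribute projection — the
  strongest single signal on the synthetic world — is diluted. The
  weights are kept as published; re-weighting toward the attribute term
  is a research question, not a default.
* Multiplicative updates stall at exact zeros: an entry that reaches 0
  can never leave it. The strictly positive initialization avoids
  starting there, but the $\ell_1$ term drives weakly supported entries
  toward 0, producing ties at the bottom of candidate rankings.
* The solver finds a stationary point of a non-convex objective;
  different seeds give (mildly) different fits. All randomness is
  seeded and the cross-validation refits per fold with distinct derived
  seeds.
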