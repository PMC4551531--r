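---
title: "Methods: downward random walks for missing GO annotations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: downward random walks for missing GO annotations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(drwgo)
```

## The problem

Gene Ontology (GO) annotations of most proteins are incomplete: a protein
known to perform a general function (say, protein glycosylation) often
lacks the more specific descendant terms that actually describe its
biology. Because of the true path rule — annotation with a term implies
annotation with all of its ancestors — the *missing* functions of a
partially annotated protein are, by construction, descendants of the
terms it already carries. `drwgo` exploits exactly this: it walks
downward from a protein's known terms through the GO DAG and ranks the
unannotated descendants it reaches.

Two families of missing functions matter. A *first kind* term is missing
for one protein but annotated to others; neighbour-based classifiers can
transfer it. A *second kind* term is present in the ontology but
annotated to **no** protein in the dataset; frequency- and
neighbour-based methods are structurally blind to it, while a walk on
the ontology itself is not. This distinction drives most design choices
below.

## The model

### Term similarity

Lin similarity between terms \(t_1, t_2\):

\[ \mathrm{sim}(t_1,t_2) = \frac{2\,IC(t^\ast)}{IC(t_1)+IC(t_2)}, \]

where \(t^\ast\) is the most informative common ancestor (each term
counting as its own ancestor, so a subsumer is its own MICA). The
default information content is **structural**:

\[ IC(t) = 1 - \frac{\log(1+|\mathrm{desc}(t)|)}{\log |\mathcal T|}, \]

which depends only on the DAG: leaves get 1, the root gets exactly 0.
The **corpus** alternative (`corpus_ic()`) uses annotation frequency,
\(IC(t) = \log(f_t/N)/\log(1/N)\), on the same \([0,1]\) scale; a
zero-frequency term then has \(IC=0\) and similarity 0 to every *other*
term — precisely the bias that motivates the structural default, and
the mechanism behind the dRW-Corpus comparison variant.

Two degenerate cases are resolved by convention and worth knowing:

* `sim(t, t) = 1` for identical terms even when \(IC(t) = 0\). The
  formula is 0/0 at the root under structure IC; taking self-similarity
  as maximal keeps every shared term its own reciprocal match in the
  protein similarity below, so `psim(i, i) = 1` holds for all annotated
  proteins.
* Because \(IC(\mathrm{root}) = 0\) exactly, every edge leaving the root
  has filtered similarity 0; the transition matrix falls back to a
  uniform distribution over parents for such columns (with a warning).
  This is the rule rather than the exception at the root, and the
  uniform fallback coincides there with the equal-weight (dRW-E)
  variant.

### The downward walk

Transitions are restricted to parent→child edges
(\(f\mathrm{sim}(t_1,t_2) = \mathrm{sim}(t_1,t_2) A(t_1,t_2)\)) and each
child's incoming edges are normalized to a probability column:

\[ W(t_1,t_2) = \frac{f\mathrm{sim}(t_1,t_2)}{\sum_t f\mathrm{sim}(t,t_2)}. \]

From a start term \(t\), with restart parameter \(\eta\):

\[ R_{s+1}(t,v) = \eta \sum_{u \in t\,\cup\,\mathrm{desc}(t)} R_s(t,u)\,W(u,v)
   + (1-\eta)\,\mathbf e_t, \qquad R_0 = \mathbf e_t . \]

Since no term is its own descendant, \(R_s(t,t) = 1-\eta\) exactly for
every \(s \ge 1\), and probability decays with depth, so direct children
outrank deeper descendants. On a single-parent chain the converged
profile has the closed form \((1-\eta)\,\eta^d\) at distance \(d\); the
test suite pins the implementation to this and to a dense full-matrix
iteration oracle at \(10^{-10}\).

Defaults: \(\eta = 0.5\) (equal probability of staying vs descending —a
deliberately uninformative choice) and **10 iterations**. GO's maximum
depth is 15, so a fixed iteration count reaches a near-stationary
profile; we use a fixed count rather than a convergence test for bitwise
reproducibility. Note a literal reading of the recursion at \(\eta = 0\)
collapses the profile to the start vector; the implementation follows
the formula as written.

### Scoring, dRW

For protein \(i\) with term set \(\mathcal T_i\) and candidate
\(v \notin \mathcal T_i\):

\[ \mathcal L(i,v) = \sum_{t \in \mathcal T_i} \tilde R(t,v)
   \;\; \text{s.t.} \;\; \tilde R(t,v) > \theta . \]

\(\theta\) is adaptive: the mean of all **nonzero off-start** entries
pooled over the profiles of \(\mathcal T_i\). Two documented readings
existed; we pool across start terms (one \(\theta\) per protein) and
exclude the constant diagonal entries \(\tilde R(t,t) = 1-\eta\), which
are never candidates and would otherwise dominate the mean on shallow
hierarchies and filter out nearly everything. The inequality is strict.

### dRW-kNN

Protein similarity follows the reciprocal best-match construction: a
pair \((t_1 \in \mathcal T_i, t_2 \in \mathcal T_j)\) counts when each
is the other's most similar term (argmax ties broken by lexicographic
term id; a term may be the mutual best of several partners), and

\[ \mathrm{psim}(i,j) = \frac{2 \sum_{(t_1,t_2)\in\mathcal P}
   \mathrm{sim}(t_1,t_2)}{|\mathcal T_i| + |\mathcal T_j|} . \]

The kNN fusion averages neighbour beliefs:

\[ \tilde{\mathcal L}(i,v) = \frac{1}{k} \sum_{j \in \mathcal N_k(i)}
   \mathrm{psim}(i,j)\, \mathcal L(j,v), \]

with \(\mathcal L(j,v) = 1\) when \(v\) is annotated to \(j\).
\(\mathcal N_k(i)\) always contains \(i\); since
\(\mathrm{psim}(i,i)=1\), **k = 1 reproduces dRW entry-wise**, which the
acceptance suite asserts exactly. Neighbour ties at the k-th rank break
to the smaller protein index. The default `k = 10` is this package's
own choice (the source protocol's k is not available); every run echoes
it in the output header.

Baselines: `itss_baseline()` is the same fusion with binary neighbour
belief only (no walk), hence blind to second-kind terms;
`naive_predict()` scores every candidate by its annotation frequency
\(f_v/N\), identically across proteins.

## Experiment protocol

`mask_annotations()` simulates missingness: per protein with ≥ 2 terms
it iteratively removes `m` uniformly drawn *protein-specific leaves*,
recomputing the frontier after each removal (a parent becomes maskable
once its in-set children are gone — removal without replacement), and
never strips the last term. Masked sets therefore remain upward-closed,
and re-adding the masked pairs restores the original table exactly —
both are acceptance properties. Completely masked terms are recorded as
second-kind terms but stay in the candidate universe.

`run_masking_experiment()` repeats mask-and-evaluate (defaults
`m ∈ {1,3,5}`, 10 repeats, sub-seed = seed + repeat index) and reports
mean ± sd per metric. `rollback_compare()` implements the
release-rollback check: global top-`top_n` candidate pairs (ties
lexicographic) called positive, a call counting as a true positive when
present in the newer release only; with `apply_tpr` the calls are first
closed upward. Root terms are excluded from candidate universes by
default and retained with `include_root = TRUE`, which rollback-style
analyses conventionally need.

## Evaluation metrics

The canonical definitions of the six reported metrics live in the
source protocol's supplementary material, which is not available; this
package adopts the standard multi-label definitions and documents them
as its own stand-ins (they are also printed in `?evaluate_predictions`):
midrank per-term AUC averaged into AvgROC; the pairwise ranking-loss
complement (ties 0.5) averaged per protein; Zhang–Zhou-style Coverage
(rank depth to retrieve all masked terms, minus one, unnormalized);
CAFA-style protein-centric Fmax over a threshold sweep (all unique
scores, down-sampled to 512 quantiles beyond that); and MacroF1 /
RAccuracy after rank-based binarization in which each protein's top-r
candidates are called positive with r equal to its masked count — the
masking protocol makes r known, so no threshold needs tuning. All
ranking metrics are invariant under strictly monotone score transforms,
and the binarized ones inherit that by construction; the suite tests
this. Per-protein candidate ranking ties break lexicographically by
term id, so outputs are deterministic across platforms.

## The synthetic world

`generate_dag()` grows a single-rooted DAG: each new term draws a level
in `1..max_depth` and 1–`max_parents` parents from strictly shallower
terms — acyclic by construction, depth-bounded, a tree when
`max_parents = 1`. `generate_annotations()` draws a Poisson
(`mean_leaf_annotations`, default 3) number of DAG leaves per protein
and closes upward, mirroring how association files record the most
detailed terms and the true path rule supplies ancestors. With the
default settings most leaf terms stay in the sparse (< 10 proteins)
strata and a realistic fraction of proteins is unannotated, emulating
the published annotation-support statistics at desk scale.

What the generator does **not** emulate: real GO topology statistics
(branching skew, cross-namespace structure, term depth distribution),
evidence-code mixtures, or annotation bias toward well-studied proteins.
A green test therefore establishes correctness of the algorithms and
protocol on a faithful miniature world, not reproduction of published
benchmark values — those depend on dated external GO/GOA releases,
which the harness can consume (`parse_obo()`, `parse_gaf()`) but does
not ship.

## Known limitations

* The walk is solved by fixed-count iteration, not an exact linear
  solve; this matches the source protocol and is reproducible, but
  profiles on very deep chains are truncated at the iteration horizon.
* `protein_similarity_matrix()` is quadratic in proteins with a
  quadratic-in-terms inner loop; fine at experiment scale (hundreds of
  proteins), not tuned for full-proteome runs.
* Only `is_a` and `part_of` edges are traversed (switchable to `is_a`
  alone); `regulates`-type relations and cross-namespace links are out
  of scope.
* RAccuracy and the binarization rule are documented stand-ins for
  definitions not published in the available text.
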