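---
title: "Benchmarking GO evaluation metrics with artificial dilution series"
author: "adsgo"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Benchmarking GO evaluation metrics with artificial dilution series}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(adsgo)
```

## The problem

Automated function prediction (AFP) assigns Gene Ontology (GO) terms to
genes, and an *evaluation metric* (EvM) decides which predictor is best.
GO makes that decision hard: the label space is a DAG with strong
parent–child correlations, class sizes are wildly imbalanced, genes carry
varying numbers of labels, and true negatives are ill-defined.  Metrics
borrowed from flat machine-learning settings can be fooled by all of
these.  `adsgo` turns the tables and benchmarks the metrics themselves.

The idea is an **artificial dilution series (ADS)**: starting from a
trusted annotation table `T` (gene, term pairs), generate artificial
prediction sets (AP sets) whose fraction of correct annotations — the
*signal level* — is controlled exactly, plus decoy *false-positive (FP)
sets* that carry no gene-specific information at all.  A useful metric
must (a) rank AP sets by their signal and (b) give decoys the score of a
no-signal set.  Both properties are summarised per metric by

* **RC** — the Spearman rank correlation between all AP-set scores
  (`Output[i, j] = Metric(T, APS_ij)` over replicates `i` and signal
  levels `j`, pooled) and their signal levels, and
* **FPS** — each FP set's score is converted to a signal estimate by
  intersecting it with the piecewise-linear curve of per-level median
  scores (clipped to `[0, 1]`); FPS is the maximum over the FP sets,
  i.e. the worst decoy.

## How an AP set is built

1. **Signal model — shifting to semantic neighbours.**  A random number
   `N_shift ~ U{0..|P|}` of rows have their term replaced by a uniform
   draw from the term's `k` nearest non-root ancestors (`k = 3` by
   default; ties in path distance break lexicographically).  Real
   classifiers tend to predict slightly too-general neighbour terms; a
   benchmark without this step would reward metrics that ignore the
   ontology structure.  Roots are never shift targets — they carry no
   information.
2. **Noise model — annotation permutation.**  Pairs of rows with distinct
   genes and terms exchange their terms.  A swap is accepted only when
   each incoming term has ancestor-Jaccard similarity below `th_noise`
   (default 0.2) against *every* genuine (pre-permutation) annotation of
   the receiving gene, so injected errors are unambiguously wrong.
   Swapping continues until `ceiling((1 - signal) * |P|)` rows are
   permuted.  Because swaps only exchange terms between genes, the term
   multiset and every gene's annotation count are invariant: class sizes,
   annotation depths and densities stay fixed across the whole series,
   so metrics cannot be separated by side effects.
3. **Negative set.**  Every gene receives `neg_per_gene = 4` uniformly
   sampled non-root terms, each subject to the same distance constraint.
4. **Scores.**  Positive rows draw `sc ~ N(1, 0.5)`, negative rows
   `sc ~ N(-1, 0.5)` (optionally squashed through a sigmoid).  Noise
   embedded in the positive set therefore cannot be removed by a score
   threshold, while the negative set can — exactly the two error regimes
   a metric has to cope with.

The default series spans signal 1.0 down to 0.0 in steps of 0.1 with
`N = 3` replicates per level; child seeds derive deterministically from
the master seed, so a series is byte-reproducible.

### Degenerate cases and termination

Random pair sampling stalls near complete permutation (signal 0): the
last free rows may belong to one gene or carry terms near every remaining
partner.  After a stall the generator switches to a deterministic
endgame — an exhaustive scan over free pairs, then rescue exchanges with
already-permuted rows (the replacement term is checked against the
recipient's true terms like any other swap).  A residual shortfall of at
most two rows (one unpairable swap) is accepted and recorded in the
realised noise fraction; anything larger raises an infeasibility error
rather than silently under-noising.

## The decoy (FP) sets

* **naive** — every gene gets the same `n` most frequent terms, scored by
  their frequency (the CAFA naive/base-rate predictor);
* **small** — the `n` least frequent terms at score 1 (the all-positive
  set: floods of specific false positives);
* **random** — one shared random sample of `n` terms at score 1.

The published construction uses `n = 800` terms per gene against the full
GO.  On the package's 500-term synthetic ontology the same rule is
applied with `n = 300`: large relative to a gene's true annotation set,
while leaving room in the term pool (the exact 800-term rule is exercised
on a larger synthetic ontology in the test suite).  Term frequencies
default to the truth set itself; an external frequency table (e.g.
GOA-derived) can be supplied to mirror the published setting.

## The metric battery

Thirty-seven metrics in three families, all returned as
higher-is-better:

* **Rank-based:** AUC-ROC and AUC-PR, each unstructured (US, pooled
  gene–term pairs), gene-centric (GC, averaged per gene) and term-centric
  (TC, averaged per term).  The candidate universe is truth genes × terms
  seen in truth or predictions (the full ontology is available via
  `universe = "ontology"`); missing pairs rank below all explicit scores,
  and ties are midranked (Mann–Whitney equivalence).  AUC-PR integrates
  the precision–recall curve by right-continuous steps, avoiding the
  known interpolation bias, and by default scores 0 when every candidate
  score is identical — a degenerate "curve" of one point carries no
  information (`zero_when_constant = FALSE` restores the historical
  one-rectangle behaviour).
* **Group-based:** `F_max` (CAFA convention: precision averaged over
  genes with predictions, recall over all truth genes), unweighted
  Jaccard (US/GC), SimGIC (gene-centric IC-weighted Jaccard), SimGIC2
  (its pooled unstructured form) and `S_min1`/`S_min2` (Euclidean
  combination of IC-weighted remaining uncertainty and misinformation,
  unstructured / gene-centric).  `S_min` is lower-better by nature and is
  sign-flipped at the metric boundary so the meta-evaluation is
  orientation-free.
* **Semantic:** Resnik (IC of the most informative common ancestor), Lin
  (`2 ic(MICA) / (ic(t1) + ic(t2))`) and ancestor-Jaccard, each collapsed
  per gene from the predicted-versus-correct similarity matrix by one of
  six summation methods: A mean of the matrix, B mean of column maxima,
  C mean of row maxima, D mean of B and C, E min of B and C, F mean of
  the concatenated row and column maxima.  Semantic metrics consume
  *direct* (unpropagated) predictions — relatedness across terms is the
  measure's own job.

Group and rank metrics see ancestor-propagated inputs: a truth table is
closed under ancestry, and predicted scores propagate to ancestors by
maximum, so a term counts as predicted at a threshold exactly when any
descendant does.  Thresholded metrics sweep every distinct score
descending and keep the best value; `n_bins` caps the sweep at an evenly
spaced subset of the observed scores (100 in the shipped examples) when
runtimes matter.

Two information-content variants are exposed: `ic(t) = -log2 freq(t)`
(marginal) and `ic2(t) = -log2(freq(t) / min_p freq(p))` (accretion —
information conditional on the direct parents).  Frequencies of terms
unseen in the evaluation set are floored at `1 / (2 n_genes)` so their
IC stays finite.  Which variant a metric uses is part of its registry
entry, and both appear in the battery.

## The synthetic world

So that the whole pipeline runs with no downloads, `adsgo` generates
GO-like ontologies and truth sets:

* terms are arranged in levels of geometrically growing width below a
  single root (depth 8, growth 1.6, level widths floored at 5% of the
  term count) — GO fans out quickly below its roots;
* the upper half of the DAG is tree-like; extra parents (up to 3, with
  probability 0.05 per extra slot) appear only in the deeper half.  This
  keeps top branches well separated, which is what makes random GO term
  pairs nearly disjoint in their ancestor sets; without it the
  ancestor-Jaccard noise constraint is unsatisfiable;
* each gene draws a right-skewed (log-normal, meanlog 1.5, sdlog 0.6)
  number of direct annotations and samples them from one or two anchor
  branches with a `1.5^depth` bias towards specific terms — gene
  functions are semantically clustered, and independent scattering would
  let heavily annotated genes block the permutation entirely.

What the generator does **not** emulate: the sheer size of GO (tens of
thousands of terms, depth ~15), real annotation sparsity (~1% of the
gene × term matrix versus ~6% here), multiple namespace roots and
evidence-code structure.  Consequently, absolute decoy signals of
rank-based metrics are attenuated relative to the published full-scale
experiments — at full scale the naive predictor leaves most of the
vocabulary unpredicted and rides a frequency gradient spanning five
orders of magnitude, both of which push its AUC towards the perfect-set
level.  On the 500-term world the qualitative ordering reproduces
clearly (US/GC AUC-ROC are by far the most decoy-prone metrics; the
IC-weighted Jaccard family and TC structurings are robust), but the
absolute FPS of US AUC-ROC saturates well below 1.  Passing tests
demonstrate the correctness of the machinery and the direction of every
published effect, not real-data metric rankings.

## Numerical and design choices

* Ancestor closures include the term itself, so `term_jaccard(t, t) = 1`
  and propagation is a plain union.
* `is_a` edges always; `part_of` by default (common GO practice), other
  relations ignored; namespaces are processed jointly unless restricted.
* Duplicate prediction rows keep the maximum score — consistent with the
  threshold-sweep semantics.
* GC averages for group metrics run over all truth genes; `F_max`
  follows the CAFA precision convention (genes with predictions only).
  Per-unit AUCs skip units lacking both classes and log the count.
* The FP signal takes the *largest* crossing with the median curve
  (worst case for the metric) when the curve is non-monotone.
* A metric failure on a single series cell is recorded as missing and
  logged; more than 10% missing cells aborts the evaluation.
* RC pools all cells rather than averaging per-replicate correlations;
  Kendall is available as an option.
* Shipped problem sizes: the packaged demonstrations and tests use a
  500-term / depth-8 DAG with 100 genes, 11 signal levels × 3
  replicates, 300-term FP sets and 100 threshold bins — small enough to
  run on a laptop in minutes, large enough for every construction rule
  to bind.

## Limitations

Beyond the scale caveats above: the signal and noise models are the two
published ones (semantic shift + distant permutation); the architecture
keeps them pluggable but ships no alternatives.  The exact composition
of the original 37-metric battery is not fully enumerable from the
published text; the registry reproduces the documented structure and
adds the ic2-weighted variants of the two recommended semantic
combinations to complete the count, and nothing in the package depends
on the battery's exact size.
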