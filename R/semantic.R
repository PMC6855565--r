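# Semantic-similarity metrics: Resnik, Lin and ancestor-Jaccard term-pair
# similarities, the A-F matrix summation methods and the per-gene,
# threshold-swept semantic evaluation.  These metrics operate on the direct
# (unpropagated) annotations: relatedness between distinct terms is
# captured by the similarity measure itself, so ancestor propagation of the
# predictions is deliberately omitted.

#' Pairwise semantic similarity between two terms
#'
#' `resnik` is the information content of the most informative common
#' ancestor (MICA); `lin` is `2 ic(MICA) / (ic(t1) + ic(t2))` (0 when the
#' denominator is 0); `ajacc` is the Jaccard index of the two ancestor
#' closures.  Resnik is used unnormalised: rank-based summaries are scale
#' free.
#'
#' @param g an `ads_ontology`.
#' @param ic_table an `ads_ic` table with IC filled (unused by `ajacc`).
#' @param measure `"resnik"`, `"lin"` or `"ajacc"`.
#' @param t1,t2 term ids.
#' @param ic_variant IC column used by `resnik`/`lin`.
#' @return a similarity (`lin`, `ajacc` in `[0, 1]`; `resnik >= 0`).
#' @export
pairwise_similarity <- function(g, ic_table, measure = c("resnik", "lin", "ajacc"),
                                t1, t2, ic_variant = "ic") {
  measure <- match.arg(measure)
  i <- term_index(g, t1); j <- term_index(g, t2)
  if (measure == "ajacc") return(jacc_idx(g, i, j))
  w <- ic_lookup(ic_table, ic_variant)
  ic_g <- unname(w[g$ids])
  mica <- max(ic_g[intersect(g$anc[[i]], g$anc[[j]])])
  if (measure == "resnik") return(mica)
  den <- ic_g[[i]] + ic_g[[j]]
  if (den <= 0) 0 else 2 * mica / den
}

#' Collapse a predicted-vs-correct similarity matrix to one score
#'
#' Rows of `M` are predicted terms, columns are correct terms.  Methods:
#' `A` mean of all entries; `B` mean of column maxima (best hit per correct
#' term); `C` mean of row maxima (best hit per predicted term); `D`
#' `(B + C) / 2`; `E` `min(B, C)`; `F` mean of the concatenated row and
#' column maxima.  `B` ignores false positives and `C` ignores false
#' negatives; `E` and `F` combine both directions robustly.
#'
#' @param M numeric matrix (`|S_pred| x |S_corr|`).
#' @param method one of `"A"` to `"F"`.
#' @return a single score; 0 for a matrix with no rows (nothing predicted).
#' @export
summarize_matrix <- function(M, method = c("A", "B", "C", "D", "E", "F")) {
  method <- match.arg(method)
  if (is.null(dim(M))) M <- matrix(M, nrow = 1L)
  if (nrow(M) == 0L || ncol(M) == 0L) return(0)
  rmax <- apply(M, 1L, max)
  cmax <- apply(M, 2L, max)
  switch(method,
         A = mean(M),
         B = mean(cmax),
         C = mean(rmax),
         D = (mean(cmax) + mean(rmax)) / 2,
         E = min(mean(cmax), mean(rmax)),
         F = mean(c(rmax, cmax)))
}

#' Semantic-similarity evaluation metric
#'
#' For each threshold over the descending distinct prediction scores, each
#' gene's predicted-above-threshold terms are compared against its correct
#' terms in a pairwise similarity matrix, the matrix is collapsed with the
#' chosen summation method, scores are averaged over truth genes (a gene
#' with nothing predicted contributes 0) and the maximum over thresholds is
#' returned.  Inputs are direct annotations; no ancestor propagation is
#' applied.
#'
#' @param g an `ads_ontology`.
#' @param truth truth table (direct annotations).
#' @param pred prediction set (direct predictions).
#' @param measure `"resnik"`, `"lin"` or `"ajacc"`.
#' @param method summation method `"A"`-`"F"`.
#' @param ic_table an `ads_ic` table (needed by `resnik`/`lin`).
#' @param ic_variant IC column for `resnik`/`lin`.
#' @param n_bins optional threshold-sweep cap.
#' @return a single score.
#' @export
semantic_metric <- function(g, truth, pred,
                            measure = c("resnik", "lin", "ajacc"),
                            method = c("A", "B", "C", "D", "E", "F"),
                            ic_table = NULL, ic_variant = "ic",
                            n_bins = NULL) {
  measure <- match.arg(measure)
  method <- match.arg(method)
  if (isTRUE(attr(pred, "propagated"))) {
    stop("semantic metrics expect unpropagated predictions")
  }
  if (measure != "ajacc" && is.null(ic_table)) {
    stop("ic_table required for measure ", measure)
  }
  genes <- sort(unique(truth$gene))
  th <- threshold_grid(pred$score, n_bins)
  if (length(th) == 0L) return(0)

  ic_g <- if (measure == "ajacc") NULL else {
    w <- ic_lookup(ic_table, ic_variant)
    unname(w[g$ids])
  }
  sim_pair <- function(i, j) {
    if (measure == "ajacc") return(jacc_idx(g, i, j))
    mica <- max(ic_g[intersect(g$anc[[i]], g$anc[[j]])])
    if (measure == "resnik") return(mica)
    den <- ic_g[[i]] + ic_g[[j]]
    if (den <= 0) 0 else 2 * mica / den
  }
  cache <- new.env(parent = emptyenv())
  sim_cached <- function(i, j) {
    key <- if (i <= j) paste0(i, ":", j) else paste0(j, ":", i)
    v <- cache[[key]]
    if (is.null(v)) {
      v <- sim_pair(i, j)
      cache[[key]] <- v
    }
    v
  }

  truth_split <- split(term_index(g, truth$term), truth$gene)
  pred_split <- split(data.frame(ti = term_index(g, pred$term),
                                 sc = pred$score),
                      pred$gene)
  score_th <- numeric(length(th))
  per_gene <- matrix(0, length(genes), length(th))
  for (gi in seq_along(genes)) {
    gn <- genes[[gi]]
    corr <- unique(truth_split[[gn]])
    pr <- pred_split[[gn]]
    if (is.null(pr) || nrow(pr) == 0L) next
    pr <- pr[order(-pr$sc), , drop = FALSE]
    pr <- pr[!duplicated(pr$ti), , drop = FALSE]     # keep max score per term
    # full matrix once; thresholds subset rows
    Mfull <- matrix(0, nrow(pr), length(corr))
    for (a in seq_len(nrow(pr))) {
      for (b in seq_along(corr)) {
        Mfull[a, b] <- sim_cached(pr$ti[[a]], corr[[b]])
      }
    }
    for (jx in seq_along(th)) {
      nrows <- sum(pr$sc >= th[[jx]])
      if (nrows == 0L) next
      per_gene[gi, jx] <- summarize_matrix(Mfull[seq_len(nrows), , drop = FALSE],
                                           method)
    }
  }
  score_th <- colMeans(per_gene)
  max(score_th)
}
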