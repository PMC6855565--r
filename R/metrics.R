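# Evaluation metric battery: rank-based (AUC-ROC / AUC-PR x US/GC/TC),
# group-based (F_max, Jaccard, SimGIC, SimGIC2, S_min1, S_min2) and the
# shared threshold-sweep machinery.  Semantic metrics live in semantic.R.
#
# Group and rank metrics operate on ancestor-propagated truth and
# predictions; every metric sweeps the distinct prediction scores from the
# largest down (optionally subsampled to a fixed number of threshold bins)
# and reports the best value over the sweep.  All metrics are returned in
# higher-is-better orientation: the S_min family is sign-flipped.

# Descending threshold grid over the observed scores.  When n_bins is given
# and there are more distinct scores, an evenly spaced subset of the actual
# score values is used (always keeping the extremes).
threshold_grid <- function(scores, n_bins = NULL) {
  th <- sort(unique(scores[is.finite(scores)]), decreasing = TRUE)
  if (length(th) == 0L) return(numeric(0))
  if (!is.null(n_bins) && length(th) > n_bins) {
    th <- th[unique(round(seq(1L, length(th), length.out = n_bins)))]
  }
  th
}

# For rows (group, score, weight), the cumulative weight per group at each
# descending threshold: out[g, j] = sum of w over the group's rows with
# score >= th[j].  Groups is a factor; th must be descending.
cum_weight_matrix <- function(group, score, w, th, levels) {
  m <- length(th)
  G <- length(levels)
  out <- matrix(0, G, m, dimnames = list(levels, NULL))
  if (length(score) == 0L || m == 0L) return(out)
  asc <- rev(th)
  k <- findInterval(score, asc)          # number of thresholds <= score
  jfirst <- m + 1L - k                   # first descending index that includes the row
  keep <- k > 0L
  if (!any(keep)) return(out)
  gi <- match(group[keep], levels)
  key <- (jfirst[keep] - 1L) * G + gi       # column-major linear index
  s <- rowsum(w[keep], key)
  out[as.integer(rownames(s))] <- s
  if (m > 1L) {
    cs <- apply(out, 1L, cumsum)            # m x G
    out <- matrix(t(cs), G, m, dimnames = list(levels, NULL))
  }
  out
}

# Common preparation for group metrics: propagated truth and predictions,
# TP flags per prediction row, per-gene truth index.
prep_group <- function(g, truth, pred) {
  if (!isTRUE(attr(truth, "propagated"))) truth <- propagate_truth(g, truth)
  if (!isTRUE(attr(pred, "propagated"))) pred <- propagate_predictions(g, pred)
  tkey <- paste0(truth$gene, "\r", truth$term)
  pkey <- paste0(pred$gene, "\r", pred$term)
  list(truth = truth, pred = pred, is_tp = pkey %in% tkey,
       genes = sort(unique(truth$gene)))
}

#' F-max: best harmonic mean of averaged precision and recall
#'
#' Sweeps thresholds over the distinct prediction scores (descending).  At
#' each threshold, precision is averaged over genes with at least one
#' prediction at or above the threshold and recall over all truth genes
#' (the CAFA convention); the maximum F over the sweep is returned.
#'
#' @param g an `ads_ontology`.
#' @param truth truth table; propagated automatically if needed.
#' @param pred prediction set; propagated automatically if needed.
#' @param n_bins optional cap on the number of thresholds swept.
#' @return score in `[0, 1]`.
#' @export
fmax <- function(g, truth, pred, n_bins = NULL) {
  pp <- prep_group(g, truth, pred)
  if (nrow(pp$pred) == 0L) return(0)
  th <- threshold_grid(pp$pred$score, n_bins)
  all_genes <- sort(unique(c(pp$genes, unique(pp$pred$gene))))
  TP <- cum_weight_matrix(pp$pred$gene, pp$pred$score,
                          as.numeric(pp$is_tp), th, all_genes)
  NP <- cum_weight_matrix(pp$pred$gene, pp$pred$score,
                          rep(1, nrow(pp$pred)), th, all_genes)
  n_truth <- table(factor(pp$truth$gene, levels = all_genes))
  f_best <- 0
  for (j in seq_along(th)) {
    has_pred <- NP[, j] > 0
    if (!any(has_pred)) next
    p <- mean(TP[has_pred, j] / NP[has_pred, j])
    tg <- pp$genes
    r <- mean(TP[tg, j] / as.numeric(n_truth[tg]))
    f <- if (p + r > 0) 2 * p * r / (p + r) else 0
    if (f > f_best) f_best <- f
  }
  f_best
}

#' S-min: minimum Euclidean combination of remaining uncertainty and misinformation
#'
#' At each threshold, remaining uncertainty `ru` is the information content
#' of the false-negative terms and misinformation `mi` that of the
#' false-positive terms.  `S_min1` (the original, unstructured form)
#' averages `ru` and `mi` across genes first and minimises
#' `sqrt(ru^2 + mi^2)` over thresholds; `S_min2` (gene-centric) minimises
#' the across-gene average of the per-gene `sqrt(ru_g^2 + mi_g^2)`.  The
#' sweep includes the empty prediction set.  The result is returned
#' sign-flipped (`-S_min`) so that, like every other metric here, larger is
#' better and a perfect prediction scores 0.
#'
#' @inheritParams fmax
#' @param ic_table an `ads_ic` table with IC columns filled.
#' @param variant `"S_min1"` or `"S_min2"`.
#' @param ic_variant which IC column weights terms.
#' @return score `<= 0`.
#' @export
smin <- function(g, truth, pred, ic_table, variant = c("S_min1", "S_min2"),
                 ic_variant = c("ic", "ic2"), n_bins = NULL) {
  variant <- match.arg(variant)
  ic_variant <- match.arg(ic_variant)
  w <- ic_lookup(ic_table, ic_variant)
  pp <- prep_group(g, truth, pred)
  w_truth <- w[pp$truth$term]
  w_pred <- w[pp$pred$term]
  if (anyNA(w_truth) || anyNA(w_pred)) {
    bad <- unique(c(pp$truth$term[is.na(w_truth)], pp$pred$term[is.na(w_pred)]))
    stop("missing information content for term(s): ",
         paste(bad, collapse = ", "))
  }
  genes <- pp$genes
  th <- threshold_grid(pp$pred$score, n_bins)
  TPic <- cum_weight_matrix(pp$pred$gene, pp$pred$score,
                            w_pred * pp$is_tp, th, genes)
  FPic <- cum_weight_matrix(pp$pred$gene, pp$pred$score,
                            w_pred * !pp$is_tp, th, genes)
  truth_ic <- rowsum(w_truth, factor(pp$truth$gene, levels = genes))[, 1L]
  # append the empty-prediction threshold: ru = total truth IC, mi = 0
  RU <- cbind(if (length(th)) truth_ic - TPic else NULL, truth_ic)
  MI <- cbind(if (length(th)) FPic else NULL, 0)
  if (variant == "S_min1") {
    s <- sqrt(colMeans(RU)^2 + colMeans(MI)^2)
  } else {
    s <- colMeans(sqrt(RU^2 + MI^2))
  }
  -min(s)
}

#' SimGIC: information-content-weighted Jaccard between prediction and truth
#'
#' `GC` (the original SimGIC) computes, per gene, the IC-weighted Jaccard
#' between the predicted and true term sets and averages over truth genes;
#' `US` (SimGIC2) pools all (gene, term) pairs into one weighted Jaccard.
#' The threshold sweep keeps the maximum.
#'
#' @inheritParams smin
#' @param variant `"GC"` (per-gene SimGIC) or `"US"` (pooled SimGIC2).
#' @param ic_variant IC column used as weights; `"none"` gives the
#'   unweighted Jaccard.
#' @return score in `[0, 1]`.
#' @export
simgic <- function(g, truth, pred, ic_table, variant = c("GC", "US"),
                   ic_variant = c("ic", "ic2", "none"), n_bins = NULL) {
  variant <- match.arg(variant)
  ic_variant <- match.arg(ic_variant)
  w <- ic_lookup(ic_table, ic_variant)
  pp <- prep_group(g, truth, pred)
  if (nrow(pp$pred) == 0L) return(0)
  w_truth <- w[pp$truth$term]
  w_pred <- w[pp$pred$term]
  genes <- pp$genes
  th <- threshold_grid(pp$pred$score, n_bins)
  TPic <- cum_weight_matrix(pp$pred$gene, pp$pred$score,
                            w_pred * pp$is_tp, th, genes)
  FPic <- cum_weight_matrix(pp$pred$gene, pp$pred$score,
                            w_pred * !pp$is_tp, th, genes)
  truth_ic <- rowsum(w_truth, factor(pp$truth$gene, levels = genes))[, 1L]
  if (variant == "US") {
    num <- colSums(TPic)
    den <- sum(truth_ic) + colSums(FPic)
    sc <- ifelse(den > 0, num / den, 0)
  } else {
    den <- truth_ic + FPic               # recycled per column
    ratio <- ifelse(den > 0, TPic / den, 0)
    sc <- colMeans(ratio)
  }
  max(sc)
}

#' Unweighted Jaccard metric (SimUI)
#'
#' [simgic()] with all term weights equal to 1: `GC` is the gene-centric
#' SimUI, `US` its pooled unstructured form.
#'
#' @inheritParams simgic
#' @return score in `[0, 1]`.
#' @export
jaccard_metric <- function(g, truth, pred, variant = c("GC", "US"),
                           n_bins = NULL) {
  variant <- match.arg(variant)
  unit <- data.frame(term = g$ids, freq = NA_real_, stringsAsFactors = FALSE)
  class(unit) <- c("ads_ic", "data.frame")
  simgic(g, truth, pred, unit, variant = variant, ic_variant = "none",
         n_bins = n_bins)
}

# Candidate universe for AUC metrics: truth genes x (terms of truth or
# predictions), or the full ontology term set.  Returns a score matrix
# (missing predictions at -Inf) and a logical truth matrix.
candidate_universe <- function(g, truth, pred, universe = c("union", "ontology")) {
  universe <- match.arg(universe)
  genes <- sort(unique(truth$gene))
  terms <- if (universe == "ontology") g$ids else
    sort(unique(c(truth$term, pred$term)))
  S <- matrix(-Inf, length(genes), length(terms),
              dimnames = list(genes, terms))
  L <- matrix(FALSE, length(genes), length(terms),
              dimnames = list(genes, terms))
  pi <- match(pred$gene, genes)
  pj <- match(pred$term, terms)
  keep <- !is.na(pi) & !is.na(pj)
  S[cbind(pi[keep], pj[keep])] <- pred$score[keep]
  L[cbind(match(truth$gene, genes), match(truth$term, terms))] <- TRUE
  list(score = S, label = L)
}

# Mann-Whitney AUC with midrank ties; NA when one class is empty.
auc_binary <- function(score, label) {
  n1 <- sum(label); n0 <- sum(!label)
  if (n1 == 0L || n0 == 0L) return(NA_real_)
  r <- rank(score)
  (sum(r[label]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' AUC-ROC over the candidate gene-term universe
#'
#' The candidate universe is truth genes crossed with the terms occurring
#' in truth or predictions (or the whole ontology via `universe`); missing
#' predictions rank below all explicit scores.  `US` ranks all pairs
#' pooled; `GC` averages per-gene AUCs over genes with both classes; `TC`
#' averages per-term AUCs over terms with both classes.  Ties are midranked
#' (Mann-Whitney equivalence).
#'
#' @inheritParams fmax
#' @param structuring `"US"`, `"GC"` or `"TC"`.
#' @param universe `"union"` (default) or `"ontology"`.
#' @return score in `[0, 1]`.
#' @export
auc_roc <- function(g, truth, pred, structuring = c("US", "GC", "TC"),
                    universe = "union") {
  structuring <- match.arg(structuring)
  pp <- prep_group(g, truth, pred)
  u <- candidate_universe(g, pp$truth, pp$pred, universe)
  if (structuring == "US") {
    out <- auc_binary(as.vector(u$score), as.vector(u$label))
    if (is.na(out)) stop("AUC-ROC undefined: a class is empty")
    return(out)
  }
  dim_i <- if (structuring == "GC") 1L else 2L
  n <- dim(u$score)[[dim_i]]
  vals <- vapply(seq_len(n), function(i) {
    if (dim_i == 1L) auc_binary(u$score[i, ], u$label[i, ])
    else auc_binary(u$score[, i], u$label[, i])
  }, numeric(1))
  ok <- !is.na(vals)
  if (!any(ok)) stop("AUC-ROC undefined: no unit with both classes")
  if (any(!ok)) {
    message(sum(!ok), " ", if (dim_i == 1L) "gene(s)" else "term(s)",
            " without both classes skipped in ", structuring, " AUC-ROC")
  }
  mean(vals[ok])
}

# Step-wise area under the precision-recall curve for one score/label set.
# Thresholds sweep the distinct finite scores (descending); pairs never
# predicted (-Inf) stay outside the curve.  Constant-score behaviour
# follows `zero_when_constant`.
pr_area <- function(score, label, zero_when_constant = TRUE) {
  n_pos <- sum(label)
  if (n_pos == 0L) return(NA_real_)
  finite <- is.finite(score)
  if (!any(finite)) return(0)
  if (length(unique(score)) == 1L) {      # zero score range over all points
    if (zero_when_constant) return(0)
    return(n_pos / length(score))         # single PR point: recall 1, p = prevalence
  }
  s <- score[finite]; l <- label[finite]
  ord <- order(s, decreasing = TRUE)
  s <- s[ord]; l <- l[ord]
  ends <- which(!duplicated(s))           # start of each block
  ends <- c(ends[-1] - 1L, length(s))     # last index of each block
  tp <- cumsum(l)[ends]
  np <- ends
  prec <- tp / np
  rec <- tp / n_pos
  sum(diff(c(0, rec)) * prec)
}

#' AUC-PR over the candidate gene-term universe
#'
#' Area under the precision-recall curve by step-wise (right-continuous)
#' summation over descending distinct scores.  When every candidate score
#' in the analysed scope is identical the curve degenerates to a single
#' point; `zero_when_constant = TRUE` (default) scores such an
#' information-free prediction 0, `FALSE` keeps the single-point rectangle
#' (the historical behaviour this correction amends).
#'
#' @inheritParams auc_roc
#' @param zero_when_constant score 0 when the score range in scope is zero.
#' @return score in `[0, 1]`.
#' @export
auc_pr <- function(g, truth, pred, structuring = c("US", "GC", "TC"),
                   zero_when_constant = TRUE, universe = "union") {
  structuring <- match.arg(structuring)
  pp <- prep_group(g, truth, pred)
  u <- candidate_universe(g, pp$truth, pp$pred, universe)
  if (structuring == "US") {
    out <- pr_area(as.vector(u$score), as.vector(u$label), zero_when_constant)
    if (is.na(out)) stop("AUC-PR undefined: no positives in scope")
    return(out)
  }
  dim_i <- if (structuring == "GC") 1L else 2L
  n <- dim(u$score)[[dim_i]]
  vals <- vapply(seq_len(n), function(i) {
    if (dim_i == 1L) pr_area(u$score[i, ], u$label[i, ], zero_when_constant)
    else pr_area(u$score[, i], u$label[, i], zero_when_constant)
  }, numeric(1))
  ok <- !is.na(vals)
  if (!any(ok)) stop("AUC-PR undefined: no unit with positives")
  mean(vals[ok])
}

#' The metric battery
#'
#' Enumerates the default battery of 37 evaluation metrics: AUC-ROC and
#' AUC-PR in US/GC/TC structurings, F-max, unweighted Jaccard (US/GC),
#' SimGIC (GC) and SimGIC2 (US) under both IC variants, S_min1 and S_min2
#' under both IC variants, and the three semantic similarities (Resnik,
#' Lin, ancestor-Jaccard) under summation methods A-F, plus ic2-weighted
#' variants of Resnik E and Lin E.
#'
#' @return data.frame with one row per metric: `name`, `core`,
#'   `structuring`, `ic_variant`, `summation`, `orientation`,
#'   `propagate_predictions`.
#' @export
metric_registry <- function() {
  row <- function(name, core, structuring = "n/a", ic = "none",
                  summation = "n/a", orientation = "higher_better",
                  propagate = TRUE) {
    data.frame(name = name, core = core, structuring = structuring,
               ic_variant = ic, summation = summation,
               orientation = orientation, propagate_predictions = propagate,
               stringsAsFactors = FALSE)
  }
  out <- rbind(
    row("US AUC-ROC", "auc_roc", "US"),
    row("GC AUC-ROC", "auc_roc", "GC"),
    row("TC AUC-ROC", "auc_roc", "TC"),
    row("US AUC-PR", "auc_pr", "US"),
    row("GC AUC-PR", "auc_pr", "GC"),
    row("TC AUC-PR", "auc_pr", "TC"),
    row("Fmax", "fmax"),
    row("US Jacc", "jaccard", "US"),
    row("GC Jacc", "jaccard", "GC"),
    row("ic SimGIC", "simgic", "GC", "ic"),
    row("ic2 SimGIC", "simgic", "GC", "ic2"),
    row("ic SimGIC2", "simgic", "US", "ic"),
    row("ic2 SimGIC2", "simgic", "US", "ic2"),
    row("ic Smin1", "smin", "US", "ic", orientation = "lower_better"),
    row("ic2 Smin1", "smin", "US", "ic2", orientation = "lower_better"),
    row("ic Smin2", "smin", "GC", "ic", orientation = "lower_better"),
    row("ic2 Smin2", "smin", "GC", "ic2", orientation = "lower_better"))
  for (m in c("Resnik", "Lin", "AJacc")) {
    ic <- if (m == "AJacc") "none" else "ic"
    for (s in LETTERS[1:6]) {
      out <- rbind(out, row(paste(m, s), tolower(m), ic = ic, summation = s,
                            propagate = FALSE))
    }
  }
  out <- rbind(out,
               row("ic2 Resnik E", "resnik", ic = "ic2", summation = "E",
                   propagate = FALSE),
               row("ic2 Lin E", "lin", ic = "ic2", summation = "E",
                   propagate = FALSE))
  rownames(out) <- NULL
  out
}

#' Score one prediction set with one metric from the registry
#'
#' Dispatches on the registry row (or metric name): group and rank metrics
#' see ancestor-propagated inputs, semantic metrics see the direct
#' (unpropagated) annotations.  All results are higher-is-better (the
#' S_min family is sign-flipped inside [smin()]).
#'
#' @param g an `ads_ontology`.
#' @param truth truth table (direct annotations).
#' @param pred prediction set (direct predictions).
#' @param metric a row of [metric_registry()] or a metric name from it.
#' @param ic_table an `ads_ic` table (required by IC-weighted and semantic
#'   metrics).
#' @param n_bins optional threshold-sweep cap passed to sweeping metrics.
#' @param universe candidate universe for the AUC family.
#' @param zero_when_constant AUC-PR constant-score correction flag.
#' @return a single numeric score.
#' @export
score_metric <- function(g, truth, pred, metric, ic_table = NULL,
                         n_bins = NULL, universe = "union",
                         zero_when_constant = TRUE) {
  if (is.character(metric)) {
    reg <- metric_registry()
    i <- match(metric, reg$name)
    if (is.na(i)) stop("unknown metric: ", metric)
    metric <- reg[i, ]
  }
  core <- metric$core
  switch(core,
    auc_roc = auc_roc(g, truth, pred, metric$structuring, universe),
    auc_pr = auc_pr(g, truth, pred, metric$structuring, zero_when_constant,
                    universe),
    fmax = fmax(g, truth, pred, n_bins),
    jaccard = jaccard_metric(g, truth, pred, metric$structuring, n_bins),
    simgic = simgic(g, truth, pred, ic_table, metric$structuring,
                    metric$ic_variant, n_bins),
    smin = smin(g, truth, pred, ic_table,
                if (metric$structuring == "US") "S_min1" else "S_min2",
                metric$ic_variant, n_bins),
    resnik = ,
    lin = ,
    ajacc = semantic_metric(g, truth, pred, core, metric$summation,
                            ic_table = ic_table,
                            ic_variant = metric$ic_variant, n_bins = n_bins),
    stop("unknown metric core: ", core))
}
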