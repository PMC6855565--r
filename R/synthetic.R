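# Synthetic GO-like ontologies and truth sets.  The generator emulates the
# structural features the dilution machinery depends on: a rooted DAG with
# multiple parents, a skewed class-size distribution (few large shallow
# terms, many small deep ones) and a right-skewed annotations-per-gene
# count with a bias towards specific (deep) terms.

#' Configuration for the synthetic ontology / truth generator
#'
#' @param n_terms total number of terms including the root (>= 10).
#' @param max_parents maximum direct parents per term.
#' @param p_multi per-extra-parent probability; most terms keep a single
#'   parent, as in GO, so ancestor closures stay compact.
#' @param depth number of levels below the root.
#' @param growth geometric growth factor of level widths (deeper levels
#'   hold more terms, as in GO).
#' @param n_genes number of genes in the truth set (>= 2).
#' @param ann_meanlog,ann_sdlog log-normal parameters of the direct
#'   annotations-per-gene count (right-skewed).
#' @param leaf_bias base of the exponential depth weighting when sampling
#'   annotation terms; larger values bias annotation towards deep terms.
#' @param seed RNG seed.
#' @return a list of class `ads_synth_config`.
#' @export
synth_config <- function(n_terms = 500L, max_parents = 3L, p_multi = 0.05,
                         depth = 8L,
                         growth = 1.6, n_genes = 100L,
                         ann_meanlog = 1.5, ann_sdlog = 0.6,
                         leaf_bias = 1.5, seed = 1L) {
  stopifnot(n_terms >= 10L, n_genes >= 2L, depth >= 2L, max_parents >= 1L)
  structure(list(n_terms = as.integer(n_terms),
                 max_parents = as.integer(max_parents), p_multi = p_multi,
                 depth = as.integer(depth), growth = growth,
                 n_genes = as.integer(n_genes),
                 ann_meanlog = ann_meanlog, ann_sdlog = ann_sdlog,
                 leaf_bias = leaf_bias, seed = as.integer(seed)),
            class = "ads_synth_config")
}

#' Generate a synthetic GO-like DAG
#'
#' Terms are organised in levels of geometrically growing width below a
#' single root; each term draws 1 to `max_parents` parents uniformly from
#' the previous level.  Construction by levels guarantees acyclicity and a
#' controlled depth.  Deterministic per seed.
#'
#' @param cfg an [synth_config()].
#' @return an `ads_ontology`.
#' @export
make_dag <- function(cfg = synth_config()) {
  set.seed(cfg$seed)
  n_below <- cfg$n_terms - 1L
  raw <- cfg$growth^seq_len(cfg$depth)
  # at least a handful of terms per level: GO fans out quickly below the root
  width <- pmax(max(4L, round(0.05 * n_below)), round(raw / sum(raw) * n_below))
  # adjust the deepest level so the total matches exactly
  width[cfg$depth] <- width[cfg$depth] + (n_below - sum(width))
  stopifnot(all(width >= 1L))

  ids <- sprintf("ST:%07d", seq_len(cfg$n_terms))
  level_of <- c(0L, rep(seq_len(cfg$depth), times = width))
  parents <- vector("list", cfg$n_terms)
  names(parents) <- ids
  parents[[1L]] <- character()
  for (i in 2L:cfg$n_terms) {
    prev <- which(level_of == level_of[[i]] - 1L)
    # upper levels stay tree-like so top branches remain well separated
    # (random GO term pairs have near-disjoint ancestor sets); extra
    # parents appear only in the deeper half of the DAG
    np <- if (level_of[[i]] > cfg$depth / 2) {
      1L + stats::rbinom(1L, cfg$max_parents - 1L, cfg$p_multi)
    } else 1L
    np <- min(np, length(prev))
    parents[[i]] <- ids[sample(prev, np)]
  }
  nms <- sprintf("synthetic term %d (level %d)", seq_len(cfg$n_terms), level_of)
  names(nms) <- ids
  build_ontology(ids, parents, names = nms)
}

#' Generate a synthetic truth set over a DAG
#'
#' Each gene draws its direct annotation count from a right-skewed
#' log-normal.  A gene's annotations are semantically clustered, as real
#' gene functions are: the gene first picks a small number of anchor
#' branches (subtrees rooted two levels below the root) and then samples
#' its terms from those subtrees without replacement, weighted by
#' `leaf_bias^depth` so specific terms are annotated more often than broad
#' ones.  Output is unpropagated (direct annotations).  Deterministic per
#' seed.
#'
#' @param g an `ads_ontology`.
#' @param cfg an [synth_config()].
#' @param n_anchors number of annotation branches per gene.
#' @return an `ads_annotations` table with `n_genes` distinct genes.
#' @export
make_truth <- function(g, cfg = synth_config(), n_anchors = 2L) {
  set.seed(cfg$seed + 1L)
  pool <- setdiff(seq_along(g$ids), g$roots)
  anchor_lvl <- min(2L, max(g$depth))
  anchors <- which(g$depth == anchor_lvl)
  # members of each anchor subtree (descendants incl. the anchor itself)
  under <- lapply(anchors, function(a) {
    pool[vapply(g$anc[pool], function(cl) a %in% cl, logical(1))]
  })
  w_all <- cfg$leaf_bias^g$depth
  genes <- sprintf("gene%04d", seq_len(cfg$n_genes))
  counts <- pmax(1L, round(stats::rlnorm(cfg$n_genes, cfg$ann_meanlog,
                                         cfg$ann_sdlog)))
  out_gene <- character(0); out_term <- integer(0)
  for (gi in seq_len(cfg$n_genes)) {
    sel <- sample(seq_along(anchors), min(n_anchors, length(anchors)))
    cand <- unique(unlist(under[sel], use.names = FALSE))
    while (length(cand) < counts[[gi]] && length(sel) < length(anchors)) {
      sel <- c(sel, sample(setdiff(seq_along(anchors), sel), 1L))
      cand <- unique(unlist(under[sel], use.names = FALSE))
    }
    k <- min(counts[[gi]], length(cand))
    terms <- sample(cand, k, prob = w_all[cand])
    out_gene <- c(out_gene, rep(genes[[gi]], k))
    out_term <- c(out_term, terms)
  }
  new_annotations(out_gene, g$ids[out_term])
}
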