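# Shared fixtures: tiny hand-built ontologies, a mid-sized synthetic world
# and brute-force oracles.

# A (root) <- B <- C <- D
chain_ontology <- function() {
  build_ontology(c("A", "B", "C", "D"),
                 list(A = character(), B = "A", C = "B", D = "C"))
}

# A (root) <- {B, C} <- D
diamond_ontology <- function() {
  build_ontology(c("A", "B", "C", "D"),
                 list(A = character(), B = "A", C = "A", D = c("B", "C")))
}

# root R with k sibling leaves t1..tk: closures {R, ti}; useful when terms
# must behave as an unstructured label set
sibling_ontology <- function(k = 6L) {
  ids <- c("R", paste0("t", seq_len(k)))
  parents <- c(list(R = character()),
               stats::setNames(rep(list("R"), k), paste0("t", seq_len(k))))
  build_ontology(ids, parents)
}

# hand-made propagated tables that bypass ancestor closure entirely, so
# closed-form metric examples stay exact
flat_truth <- function(gene, term) {
  adsgo:::new_annotations(gene, term, propagated = TRUE)
}
flat_pred <- function(gene, term, score) {
  adsgo:::new_predictions(gene, term, score, propagated = TRUE)
}

# explicit IC table
manual_ic <- function(terms, ic, freq = NA_real_, ic2 = ic) {
  out <- data.frame(term = terms, freq = freq, ic = ic, ic2 = ic2,
                    stringsAsFactors = FALSE)
  class(out) <- c("ads_ic", "data.frame")
  out
}

# mid-sized synthetic world reused across dilution/metric tests
test_world <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- synth_config(n_terms = 300L, n_genes = 30L, seed = 42L)
      g <- make_dag(cfg)
      T_ <- make_truth(g, cfg)
      freq <- term_frequencies(g, T_)
      ict <- information_content(g, freq)
      cache <<- list(cfg = cfg, g = g, truth = T_, freq = freq, ic = ict)
    }
    cache
  }
})

# brute-force Mann-Whitney AUC: concordant pairs + half ties
brute_auc <- function(scores, labels) {
  pos <- scores[labels]; neg <- scores[!labels]
  tot <- 0
  for (p in pos) tot <- tot + sum(p > neg) + 0.5 * sum(p == neg)
  tot / (length(pos) * length(neg))
}
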