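# Closed-form examples bypass ancestor propagation via pre-propagated flat
# tables (see helpers), so the arithmetic stays exact.

test_that("F-max matches closed forms", {
  sib <- sibling_ontology(4)
  truth <- flat_truth(c("g1", "g1"), c("t1", "t2"))
  # perfect prediction
  expect_equal(fmax(sib, truth, flat_pred(c("g1", "g1"), c("t1", "t2"), 1)), 1)
  # one of two truth terms predicted: p = 1, r = 0.5, F = 2/3
  expect_equal(fmax(sib, truth, flat_pred("g1", "t1", 1)), 2 / 3,
               tolerance = 1e-12)
  # no overlap at any threshold
  expect_equal(fmax(sib, truth, flat_pred("g1", "t3", 1)), 0)
  expect_equal(fmax(sib, truth, flat_pred(character(), character(), numeric())), 0)
})

test_that("S-min matches closed forms and its variants agree on one gene", {
  sib <- sibling_ontology(4)
  ic1 <- manual_ic(c("R", paste0("t", 1:4)), ic = 1)
  truth <- flat_truth(c("g1", "g1"), c("t1", "t2"))
  perfect <- flat_pred(c("g1", "g1"), c("t1", "t2"), 1)
  expect_equal(smin(sib, truth, perfect, ic1, "S_min1"), 0, tolerance = 1e-12)
  # truth {A,B}, pred {A,C}, ic = 1: ru = 1, mi = 1, S = sqrt(2), flipped
  pred <- flat_pred(c("g1", "g1"), c("t1", "t3"), 1)
  expect_equal(smin(sib, truth, pred, ic1, "S_min1"), -sqrt(2),
               tolerance = 1e-12)
  expect_equal(smin(sib, truth, pred, ic1, "S_min1"),
               smin(sib, truth, pred, ic1, "S_min2"), tolerance = 1e-12)
  bad <- manual_ic("t1", ic = 1)
  expect_error(smin(sib, truth, pred, bad, "S_min1"), "missing information")
})

test_that("SimGIC and the Jaccard metric match weighted closed forms", {
  sib <- sibling_ontology(4)
  truth <- flat_truth(c("g1", "g1"), c("t2", "t3"))
  pred <- flat_pred(c("g1", "g1"), c("t1", "t2"), 1)
  ic1 <- manual_ic(c("R", paste0("t", 1:4)), ic = 1)
  # {A,B} vs {B,C}, unit weights: 1 / 3
  expect_equal(simgic(sib, truth, pred, ic1, "GC", "ic"), 1 / 3,
               tolerance = 1e-12)
  expect_equal(simgic(sib, truth, pred, ic1, "US", "ic"), 1 / 3,
               tolerance = 1e-12)
  expect_equal(jaccard_metric(sib, truth, pred, "GC"), 1 / 3,
               tolerance = 1e-12)
  # ic(t1) = 2, others 1: intersection {t2} = 1, union {t1,t2,t3} = 4
  ic2 <- manual_ic(c("R", paste0("t", 1:4)), ic = c(1, 2, 1, 1, 1))
  expect_equal(simgic(sib, truth, pred, ic2, "GC", "ic"), 1 / 4,
               tolerance = 1e-12)
  # perfect prediction
  expect_equal(simgic(sib, truth, flat_pred(c("g1", "g1"), c("t2", "t3"), 1),
                      ic1, "US", "ic"), 1)
  expect_equal(jaccard_metric(sib, truth, flat_pred("g1", "t4", 1), "US"), 0)
})

test_that("Jaccard metric equals SimGIC under constant weights", {
  w <- test_world()
  flat <- manual_ic(w$g$ids, ic = 1)
  set.seed(20)
  for (rep in 1:5) {
    ap <- make_ap_set(w$g, w$truth, runif(1), ads_config(),
                      seed = 500 + rep)
    for (v in c("GC", "US")) {
      expect_equal(jaccard_metric(w$g, w$truth, ap, v, n_bins = 40),
                   simgic(w$g, w$truth, ap, flat, v, "ic", n_bins = 40),
                   tolerance = 1e-12)
    }
  }
})

test_that("AUC-ROC agrees with the brute-force Mann-Whitney count", {
  sib <- sibling_ontology(10)
  terms <- paste0("t", 1:10)
  set.seed(99)
  for (i in 1:200) {
    n_true <- sample(1:9, 1)
    truth <- flat_truth("g1", sample(terms, n_true))
    n_pred <- sample(1:10, 1)
    pred <- flat_pred("g1", sample(terms, n_pred),
                      round(runif(n_pred), 2))     # rounded -> frequent ties
    # oracle over the same candidate universe, missing scored -Inf
    cand <- sort(unique(c(truth$term, pred$term)))
    sc <- rep(-Inf, length(cand))
    sc[match(pred$term, cand)] <- pred$score
    lab <- cand %in% truth$term
    if (all(lab) || !any(lab)) next
    expect_equal(auc_roc(sib, truth, pred, "US"), brute_auc(sc, lab),
                 tolerance = 1e-12)
  }
  # hand cases
  truth <- flat_truth("g1", c("t1", "t2"))
  expect_equal(auc_roc(sib, truth,
                       flat_pred("g1", c("t1", "t2", "t3"), c(0.9, 0.8, 0.7)),
                       "US"), 1)
  expect_equal(auc_roc(sib, truth,
                       flat_pred("g1", c("t1", "t2", "t3"), c(0.9, 0.6, 0.8)),
                       "US"), 0.5)
  expect_error(auc_roc(sib, flat_truth("g1", terms),
                       flat_pred("g1", "t1", 1), "US"), "undefined")
})

test_that("AUC-PR uses step summation and the constant-score correction", {
  sib <- sibling_ontology(6)
  truth <- flat_truth("g1", c("t1", "t2"))
  expect_equal(auc_pr(sib, truth,
                      flat_pred("g1", c("t1", "t2", "t3"),
                                c(0.9, 0.8, 0.7)), "US"), 1)
  # positives {0.9}, negatives {0.8, 0.7}: single PR point (r = 1, p = 1)
  truth1 <- flat_truth("g1", "t1")
  expect_equal(auc_pr(sib, truth1,
                      flat_pred("g1", c("t1", "t2", "t3"),
                                c(0.9, 0.8, 0.7)), "US"), 1)
  # constant scores: 0 under the correction, prevalence rectangle without
  const <- flat_pred("g1", c("t1", "t2", "t3"), c(0.5, 0.5, 0.5))
  expect_equal(auc_pr(sib, truth1, const, "US", zero_when_constant = TRUE), 0)
  expect_equal(auc_pr(sib, truth1, const, "US", zero_when_constant = FALSE),
               1 / 3)
  expect_error(auc_pr(sib, flat_truth("g2", "t1"),
                      flat_pred("g2", "t2", 1), "US"),
               NA)  # positives exist (t1), so no error
})

test_that("gene- and term-centric AUC average only units with both classes", {
  sib <- sibling_ontology(6)
  truth <- flat_truth(c("g1", "g1", "g2"), c("t1", "t2", "t1"))
  pred <- flat_pred(c("g1", "g1", "g2", "g2"),
                    c("t1", "t3", "t1", "t2"),
                    c(0.9, 0.2, 0.8, 0.3))
  gc <- auc_roc(sib, truth, pred, "GC")
  # g1: pos {t1:0.9, t2:-Inf}, neg {t3:0.2} -> pairs 1, 0 -> auc 0.5
  # g2: pos {t1:0.8}, neg {t2:0.3, t3:-Inf} -> auc 1
  expect_equal(gc, mean(c(0.5, 1)), tolerance = 1e-12)
  # t1 is positive for both genes and t3 negative for both (skipped);
  # t2: positive g1 unpredicted (-Inf) vs negative g2 at 0.3 -> auc 0
  expect_equal(suppressMessages(auc_roc(sib, truth, pred, "TC")), 0,
               tolerance = 1e-12)
})

test_that("pairwise similarities follow MICA arithmetic", {
  # A(root, freq 1) <- B(0.5) <- C(0.25);  D(0.5) child of A
  g <- build_ontology(c("A", "B", "C", "D"),
                      list(A = character(), B = "A", C = "B", D = "A"))
  ic <- manual_ic(c("A", "B", "C", "D"),
                  ic = -log2(c(1, 0.5, 0.25, 0.5)))
  expect_equal(pairwise_similarity(g, ic, "lin", "C", "C"), 1)
  expect_equal(pairwise_similarity(g, ic, "resnik", "C", "C"), 2)
  expect_equal(pairwise_similarity(g, ic, "resnik", "C", "D"), 0)
  expect_equal(pairwise_similarity(g, ic, "lin", "C", "D"), 0)
  expect_equal(pairwise_similarity(g, ic, "ajacc", "C", "D"), 0.25)
})

test_that("matrix summaries A-F match hand computations", {
  M1 <- matrix(c(1, 0, 0, 1), 2, 2)
  expect_equal(summarize_matrix(M1, "A"), 0.5)
  for (m in c("B", "C", "D", "E", "F")) expect_equal(summarize_matrix(M1, m), 1)

  M2 <- matrix(c(0.8, 0.2), 1, 2)      # 1 predicted, 2 correct
  expect_equal(summarize_matrix(M2, "A"), 0.5)
  expect_equal(summarize_matrix(M2, "B"), 0.5)
  expect_equal(summarize_matrix(M2, "C"), 0.8)
  expect_equal(summarize_matrix(M2, "D"), 0.65)
  expect_equal(summarize_matrix(M2, "E"), 0.5)
  expect_equal(summarize_matrix(M2, "F"), (0.8 + 0.8 + 0.2) / 3)

  # symmetric matrix: B = C implies D = E = F = B
  set.seed(1)
  S <- matrix(runif(9), 3, 3); S <- (S + t(S)) / 2
  b <- summarize_matrix(S, "B")
  for (m in c("C", "D", "E", "F")) expect_equal(summarize_matrix(S, m), b)

  # ordering properties on random matrices
  for (i in 1:20) {
    M <- matrix(runif(12), sample(3:4, 1))
    vals <- vapply(c("B", "C", "D", "E", "F"), summarize_matrix,
                   numeric(1), M = M)
    expect_lte(vals[["E"]], vals[["D"]] + 1e-12)
    expect_gte(vals[["F"]], min(vals[["B"]], vals[["C"]]) - 1e-12)
    expect_lte(vals[["F"]], max(vals[["B"]], vals[["C"]]) + 1e-12)
  }
})

test_that("the semantic metric sweeps thresholds over direct annotations", {
  sib <- sibling_ontology(6)
  # two genes so leaf frequencies are 0.5 and ic > 0
  truth <- adsgo:::new_annotations(c("g1", "g1", "g2", "g2"),
                                   c("t1", "t2", "t3", "t4"))
  ict <- information_content(sib, term_frequencies(sib, truth))
  pred <- adsgo:::new_predictions(truth$gene, truth$term, 1)
  for (m in c("B", "C", "D", "E", "F")) {
    expect_equal(semantic_metric(sib, truth, pred, "lin", m, ict), 1)
  }
  # method A averages off-diagonal dissimilar pairs, so it stays below 1
  expect_lt(semantic_metric(sib, truth, pred, "lin", "A", ict), 1)
  # single gene, single threshold reduces to summarize_matrix
  t1 <- adsgo:::new_annotations("g1", c("t1", "t2"))
  p1 <- adsgo:::new_predictions("g1", c("t1", "t3"), c(1, 1))
  M <- matrix(c(term_jaccard(sib, "t1", "t1"), term_jaccard(sib, "t3", "t1"),
                term_jaccard(sib, "t1", "t2"), term_jaccard(sib, "t3", "t2")),
              2, 2)
  expect_equal(semantic_metric(sib, t1, p1, "ajacc", "D"),
               summarize_matrix(M, "D"), tolerance = 1e-12)
  expect_error(semantic_metric(sib, t1, propagate_predictions(sib, p1),
                               "ajacc", "D"), "unpropagated")
})

test_that("the registry covers the published battery shape", {
  reg <- metric_registry()
  expect_true(all(c("TC AUC-PR", "ic2 SimGIC2", "Fmax", "Lin E", "AJacc F",
                    "ic Smin1", "US Jacc") %in% reg$name))
  sem <- reg$core %in% c("resnik", "lin", "ajacc")
  expect_true(all(!reg$propagate_predictions[sem]))
  expect_true(all(reg$propagate_predictions[!sem]))
  expect_setequal(reg$orientation[grepl("Smin", reg$name)], "lower_better")
  expect_false(any(duplicated(reg$name)))
})

test_that("every bounded metric scores the perfect prediction at its top", {
  w <- test_world()
  pt <- propagate_truth(w$g, w$truth)
  perfect <- adsgo:::new_predictions(pt$gene, pt$term, 1, propagated = TRUE)
  expect_equal(fmax(w$g, w$truth, perfect), 1)
  expect_equal(simgic(w$g, w$truth, perfect, w$ic, "US", "ic"), 1)
  expect_equal(simgic(w$g, w$truth, perfect, w$ic, "GC", "ic2"), 1)
  expect_equal(jaccard_metric(w$g, w$truth, perfect, "GC"), 1)
  expect_equal(smin(w$g, w$truth, perfect, w$ic, "S_min1"), 0,
               tolerance = 1e-9)
  expect_equal(smin(w$g, w$truth, perfect, w$ic, "S_min2"), 0,
               tolerance = 1e-9)
})

test_that("a high-scoring false-positive term never improves set metrics", {
  # flat sets: the added term brings no true ancestors with it, so the
  # penalty must be monotone
  sib <- sibling_ontology(12)
  terms <- paste0("t", 1:12)
  set.seed(12)
  ic <- manual_ic(c("R", terms), ic = c(0, runif(12, 0.5, 3)))
  for (i in 1:25) {
    truth <- flat_truth("g1", sample(terms, sample(2:4, 1)))
    pt <- sample(terms, sample(2:5, 1))
    pred <- flat_pred("g1", pt, runif(length(pt)))
    extra <- sample(setdiff(terms, union(truth$term, pred$term)), 1)
    worse <- flat_pred(c(pred$gene, "g1"), c(pred$term, extra),
                       c(pred$score, max(pred$score) + 1))
    for (f in list(
      function(p) simgic(sib, truth, p, ic, "US", "ic"),
      function(p) simgic(sib, truth, p, ic, "GC", "ic"),
      function(p) jaccard_metric(sib, truth, p, "US"),
      function(p) smin(sib, truth, p, ic, "S_min1"),
      function(p) smin(sib, truth, p, ic, "S_min2"))) {
      expect_lte(f(worse), f(pred) + 1e-12)
    }
  }
})
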