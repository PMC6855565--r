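# Artificial dilution series: signal model (shift to semantic neighbours),
# noise model (annotation permutation under an ancestor-Jaccard distance
# constraint), negative set, score sampling and the series loop, plus the
# three decoy false-positive sets.

#' Configuration for an artificial dilution series
#'
#' Defaults follow the published study conditions: signal range 100% to 0%
#' in ten-point steps, semantic neighbourhood size `k = 3`, noise acceptance
#' threshold `th_noise = 0.2`, four negative annotations per gene, positive
#' scores `Normal(1, 0.5)` and negative scores `Normal(-1, 0.5)`.
#'
#' @param signal_range descending vector of signal levels in `[0, 1]`.
#' @param replicates number of AP sets per signal level (`N`).
#' @param k semantic neighbourhood size for the shift step.
#' @param th_noise ancestor-Jaccard threshold below which a permuted or
#'   sampled term counts as unrelated to a gene's true terms.
#' @param neg_per_gene erroneous low-score annotations added per gene.
#' @param pos_score_mean,pos_score_sd positive-set score distribution.
#' @param neg_score_mean,neg_score_sd negative-set score distribution.
#' @param sigmoid_scores squash scores into `(0, 1)` with a logistic sigmoid.
#' @param master_seed seed from which per-set child seeds are derived.
#' @param max_attempts_factor the permutation gives up after
#'   `max_attempts_factor * nrow(P)` rejected draws.
#' @return a list of class `ads_config`.
#' @export
ads_config <- function(signal_range = seq(1, 0, by = -0.1),
                       replicates = 3L,
                       k = 3L,
                       th_noise = 0.2,
                       neg_per_gene = 4L,
                       pos_score_mean = 1, pos_score_sd = 0.5,
                       neg_score_mean = -1, neg_score_sd = 0.5,
                       sigmoid_scores = FALSE,
                       master_seed = 1L,
                       max_attempts_factor = 1000L) {
  stopifnot(all(diff(signal_range) < 0), all(signal_range >= 0),
            all(signal_range <= 1), replicates >= 1L, k >= 1L,
            th_noise > 0, th_noise < 1, neg_per_gene >= 0L)
  structure(list(signal_range = signal_range, replicates = as.integer(replicates),
                 k = as.integer(k), th_noise = th_noise,
                 neg_per_gene = as.integer(neg_per_gene),
                 pos_score_mean = pos_score_mean, pos_score_sd = pos_score_sd,
                 neg_score_mean = neg_score_mean, neg_score_sd = neg_score_sd,
                 sigmoid_scores = sigmoid_scores,
                 master_seed = as.integer(master_seed),
                 max_attempts_factor = as.integer(max_attempts_factor)),
            class = "ads_config")
}

#' Shift a random fraction of annotations to semantic neighbours
#'
#' Draws `N_shift` uniformly from `0..nrow(P)`, picks that many rows without
#' replacement and replaces each picked row's term with a uniform draw from
#' its `k` nearest non-root ancestors.  Rows whose term has no eligible
#' neighbour are left unchanged; duplicates created by shifting collapse.
#' This emulates a classifier predicting a slightly too general term.
#'
#' @param g an `ads_ontology`.
#' @param P an unpropagated `ads_annotations` table.
#' @param k neighbourhood size.
#' @param n_shift override the random draw (used in tests).
#' @return an `ads_annotations` table.
#' @export
shift_to_neighbours <- function(g, P, k = 3L, n_shift = NULL) {
  stopifnot(!isTRUE(attr(P, "propagated")))
  n <- nrow(P)
  if (is.null(n_shift)) n_shift <- sample(0:n, 1L)
  stopifnot(n_shift >= 0L, n_shift <= n)
  if (n_shift == 0L) return(P)
  rows <- sample.int(n, n_shift)
  term <- P$term
  for (r in rows) {
    nb <- k_nearest_parents(g, term[[r]], k)
    if (length(nb)) term[[r]] <- nb[[sample.int(length(nb), 1L)]]
  }
  new_annotations(P$gene, term)
}

#' Permute annotations between genes to inject a controlled noise fraction
#'
#' Repeatedly draws a pair of not-yet-permuted rows with distinct genes and
#' distinct terms; the terms are exchanged iff each incoming term has
#' ancestor-Jaccard `< th_noise` against *every* pre-permutation term of the
#' receiving gene (its genuine annotations; terms brought in by earlier
#' swaps are already noise and do not constrain later swaps) and is not
#' already annotated to it.  Each accepted swap marks two rows as noise; swapping
#' stops once at least `ceiling(epsilon * nrow(P))` rows are permuted.  The
#' permutation preserves the term multiset and each gene's annotation count,
#' so class sizes and annotation depths are untouched.
#'
#' If the pair search exhausts its attempt budget while the shortfall is
#' within the series tolerance (2 rows), the achieved fraction is returned;
#' a larger shortfall is an infeasibility error.
#'
#' @param g an `ads_ontology`.
#' @param P an unpropagated `ads_annotations` table.
#' @param epsilon requested noise fraction in `[0, 1]`.
#' @param th_noise acceptance threshold on ancestor-Jaccard similarity.
#' @param max_attempts rejected-draw budget (default `1000 * nrow(P)`).
#' @return an `ads_annotations` table with attributes `realised_noise`
#'   (fraction of rows permuted) and `noise` (data.frame of the permuted-in
#'   gene/term rows).
#' @export
permute_noise <- function(g, P, epsilon, th_noise = 0.2, max_attempts = NULL) {
  stopifnot(!isTRUE(attr(P, "propagated")), epsilon >= 0, epsilon <= 1)
  n <- nrow(P)
  if (n == 0L) stop("empty positive set")
  if (is.null(max_attempts)) max_attempts <- 1000L * n
  target <- ceiling(epsilon * n)

  gene <- P$gene
  term_i <- term_index(g, P$term)
  gsplit <- split(seq_len(n), gene)
  orig_terms <- lapply(gsplit, function(rows) term_i[rows])  # pre-permutation
  permuted <- logical(n)
  n_perm <- 0L

  # a<->b exchange is valid iff genes and terms differ, no duplicate row is
  # created, and each incoming term is distant from the recipient gene's
  # genuine (pre-permutation) annotations
  valid_swap <- function(a, b) {
    if (gene[[a]] == gene[[b]] || term_i[[a]] == term_i[[b]]) return(FALSE)
    cur_a <- term_i[gsplit[[gene[[a]]]]]
    cur_b <- term_i[gsplit[[gene[[b]]]]]
    if (term_i[[a]] %in% cur_b || term_i[[b]] %in% cur_a) return(FALSE)
    if (max_jacc_vs(g, term_i[[a]], orig_terms[[gene[[b]]]]) >= th_noise) return(FALSE)
    if (max_jacc_vs(g, term_i[[b]], orig_terms[[gene[[a]]]]) >= th_noise) return(FALSE)
    TRUE
  }
  do_swap <- function(a, b) {
    tmp <- term_i[[a]]; term_i[[a]] <<- term_i[[b]]; term_i[[b]] <<- tmp
  }

  # phase 1: random pair draws (fast until the free set gets sticky)
  attempts <- 0L
  stall <- 0L
  stall_limit <- 50L * n
  while (n_perm < target && attempts < max_attempts && stall < stall_limit) {
    attempts <- attempts + 1L
    free <- which(!permuted)
    if (length(free) < 2L) break
    ab <- free[sample.int(length(free), 2L)]
    if (valid_swap(ab[[1L]], ab[[2L]])) {
      do_swap(ab[[1L]], ab[[2L]])
      permuted[ab] <- TRUE
      n_perm <- n_perm + 2L
      stall <- 0L
    } else {
      stall <- stall + 1L
    }
  }

  # phase 2: deterministic endgame over the remaining rows
  while (n_perm < target) {
    free <- which(!permuted)
    progress <- FALSE
    if (length(free) >= 2L) {
      for (ai in seq_len(length(free) - 1L)) {
        for (bi in (ai + 1L):length(free)) {
          if (valid_swap(free[[ai]], free[[bi]])) {
            do_swap(free[[ai]], free[[bi]])
            permuted[c(free[[ai]], free[[bi]])] <- TRUE
            n_perm <- n_perm + 2L
            progress <- TRUE
            break
          }
        }
        if (progress) break
      }
    }
    if (progress) next
    # rescue: exchange a stuck row with an already-permuted one; the term
    # entering the permuted row's gene is checked the same way, so every
    # permuted row still carries a term distant from its gene's truth
    done <- which(permuted)
    for (a in free) {
      for (b in done) {
        if (valid_swap(a, b)) {
          do_swap(a, b)
          permuted[[a]] <- TRUE
          n_perm <- n_perm + 1L
          progress <- TRUE
          break
        }
      }
      if (progress) break
    }
    if (!progress) break
  }

  if (n_perm < target - 2L) {
    stop(sprintf(
      "noise permutation infeasible: %d of %d target rows permuted (%d short)",
      n_perm, target, target - n_perm))
  }

  out <- data.frame(gene = gene, term = g$ids[term_i],
                    stringsAsFactors = FALSE)
  out <- out[order(out$gene, out$term), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "propagated") <- FALSE
  class(out) <- c("ads_annotations", "data.frame")
  attr(out, "realised_noise") <- n_perm / n
  attr(out, "noise") <- data.frame(gene = gene[permuted],
                                   term = g$ids[term_i[permuted]],
                                   stringsAsFactors = FALSE)
  out
}

#' Build the negative prediction set
#'
#' For every distinct gene of the truth set, samples `neg_per_gene` terms
#' uniformly from the non-root ontology terms, accepting a term only if its
#' ancestor-Jaccard against every true term of that gene is below
#' `th_noise` and it was not already assigned to the gene.  These rows later
#' receive low scores, so they are separable by a score threshold.
#'
#' @param g an `ads_ontology`.
#' @param T_ an `ads_annotations` truth table (direct annotations).
#' @param cfg an [ads_config()].
#' @return an `ads_predictions` set with origin `"negative"` and `NA` scores
#'   (scores are drawn by [assign_scores()]).
#' @export
make_negative_set <- function(g, T_, cfg = ads_config()) {
  genes <- unique(T_$gene)
  stopifnot(length(genes) >= 1L)
  if (cfg$neg_per_gene == 0L) {
    return(new_predictions(character(), character(), numeric(), character()))
  }
  pool <- setdiff(seq_along(g$ids), g$roots)
  truth_split <- split(term_index(g, T_$term), T_$gene)
  out_gene <- character(0); out_term <- integer(0)
  for (gn in genes) {
    true_terms <- truth_split[[gn]]
    got <- integer(0)
    attempts <- 0L
    budget <- cfg$max_attempts_factor * cfg$neg_per_gene
    while (length(got) < cfg$neg_per_gene) {
      if (attempts >= budget) {
        stop("negative set infeasible for gene ", gn,
             ": ontology too small or shallow for th_noise = ", cfg$th_noise)
      }
      attempts <- attempts + 1L
      cand <- pool[[sample.int(length(pool), 1L)]]
      if (cand %in% got) next
      if (max_jacc_vs(g, cand, true_terms) >= cfg$th_noise) next
      got <- c(got, cand)
    }
    out_gene <- c(out_gene, rep(gn, length(got)))
    out_term <- c(out_term, got)
  }
  new_predictions(out_gene, g$ids[out_term], NA_real_, "negative")
}

#' Assign prediction scores and merge positive and negative sets
#'
#' Positive rows draw scores from `Normal(pos_score_mean, pos_score_sd)`;
#' negative rows from `Normal(neg_score_mean, neg_score_sd)`.  With
#' `sigmoid_scores` the scores are squashed into `(0, 1)`.
#'
#' @param P_pos an `ads_annotations` table (the perturbed positive set).
#' @param P_neg an `ads_predictions` set from [make_negative_set()].
#' @param cfg an [ads_config()].
#' @return the merged `ads_predictions` AP set with origin labels kept.
#' @export
assign_scores <- function(P_pos, P_neg, cfg = ads_config()) {
  sc_pos <- stats::rnorm(nrow(P_pos), cfg$pos_score_mean, cfg$pos_score_sd)
  sc_neg <- stats::rnorm(nrow(P_neg), cfg$neg_score_mean, cfg$neg_score_sd)
  if (cfg$sigmoid_scores) {
    sc_pos <- stats::plogis(sc_pos)
    sc_neg <- stats::plogis(sc_neg)
  }
  new_predictions(c(P_pos$gene, P_neg$gene),
                  c(P_pos$term, P_neg$term),
                  c(sc_pos, sc_neg),
                  c(rep("positive", nrow(P_pos)), rep("negative", nrow(P_neg))))
}

#' Generate one artificial prediction (AP) set at a given signal level
#'
#' Pipeline: copy the truth, shift a random fraction of rows to semantic
#' neighbours, permute `1 - signal` of the rows between genes, build the
#' negative set and draw scores.  Deterministic given `seed`.
#'
#' @param g an `ads_ontology`.
#' @param T_ the truth table (direct annotations).
#' @param signal signal level in `[0, 1]`; the requested noise fraction is
#'   `1 - signal`.
#' @param cfg an [ads_config()].
#' @param seed child seed for this set.
#' @return an `ads_predictions` AP set with attributes `signal`,
#'   `realised_noise`, `seed`, `noise` (permuted-in rows) and
#'   `pre_permutation` (the post-shift table the permutation started from).
#' @export
make_ap_set <- function(g, T_, signal, cfg = ads_config(), seed = NULL) {
  stopifnot(signal >= 0, signal <= 1)
  if (!is.null(seed)) set.seed(seed)
  shifted <- shift_to_neighbours(g, T_, cfg$k)
  noised <- permute_noise(g, shifted, 1 - signal, cfg$th_noise,
                          max_attempts = cfg$max_attempts_factor * nrow(shifted))
  neg <- make_negative_set(g, T_, cfg)
  ap <- assign_scores(noised, neg, cfg)
  attr(ap, "signal") <- signal
  attr(ap, "realised_noise") <- attr(noised, "realised_noise")
  attr(ap, "seed") <- seed
  attr(ap, "noise") <- attr(noised, "noise")
  attr(ap, "pre_permutation") <- shifted
  ap
}

# Deterministic child seed below 2^31 from (master seed, replicate, level).
child_seed <- function(master, i, j) {
  as.integer((as.double(master) * 1000003 + i * 10007 + j * 101) %% 2147483647)
}

#' Generate a full artificial dilution series
#'
#' `replicates` AP sets at every level of `signal_range`, each with its own
#' deterministically derived child seed.
#'
#' @param g an `ads_ontology`.
#' @param T_ the truth table (direct annotations).
#' @param cfg an [ads_config()].
#' @return an `ads_series`: list with `sets` (list indexed `[[replicate]][[level]]`),
#'   `signal_levels`, `config` and a `manifest` data.frame (set id, signal,
#'   replicate, child seed, realised noise).
#' @export
make_series <- function(g, T_, cfg = ads_config()) {
  SR <- cfg$signal_range
  N <- cfg$replicates
  sets <- vector("list", N)
  manifest <- NULL
  for (i in seq_len(N)) {
    sets[[i]] <- vector("list", length(SR))
    for (j in seq_along(SR)) {
      seed <- child_seed(cfg$master_seed, i, j)
      ap <- make_ap_set(g, T_, SR[[j]], cfg, seed = seed)
      sets[[i]][[j]] <- ap
      manifest <- rbind(manifest, data.frame(
        set_id = sprintf("AP_i%02d_s%04.2f", i, SR[[j]]),
        signal = SR[[j]], replicate = i, seed = seed,
        realised_noise = attr(ap, "realised_noise"),
        stringsAsFactors = FALSE))
    }
  }
  structure(list(sets = sets, signal_levels = SR, config = cfg,
                 manifest = manifest),
            class = "ads_series")
}

#' @export
print.ads_series <- function(x, ...) {
  cat(sprintf("ads_series: %d replicates x %d signal levels (%s..%s)\n",
              length(x$sets), length(x$signal_levels),
              format(max(x$signal_levels)), format(min(x$signal_levels))))
  invisible(x)
}

#' Write a series to a directory of prediction TSVs plus a manifest
#'
#' @param series an `ads_series`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_series <- function(series, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  m <- series$manifest
  for (r in seq_len(nrow(m))) {
    i <- m$replicate[[r]]
    j <- match(m$signal[[r]], series$signal_levels)
    write_predictions(series$sets[[i]][[j]],
                      file.path(dir, paste0(m$set_id[[r]], ".tsv")))
  }
  utils::write.table(m, file.path(dir, "manifest.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Build a decoy false-positive prediction set
#'
#' Every gene receives the same term list, carrying no gene-specific
#' information: `naive` uses the `n_terms` most frequent terms with the term
#' frequency as score (the CAFA naive predictor); `small` the `n_terms`
#' least frequent terms with score 1 (the all-positive set); `random` one
#' shared uniform sample of `n_terms` terms with score 1.
#'
#' @param g an `ads_ontology`.
#' @param genes character vector of gene ids.
#' @param freq an `ads_ic` table with the `freq` column filled.
#' @param kind `"naive"`, `"small"` or `"random"`.
#' @param n_terms number of terms per gene (default 800).
#' @return an `ads_predictions` set with origin `"fp"`.
#' @export
make_fp_set <- function(g, genes, freq, kind = c("naive", "small", "random"),
                        n_terms = 800L) {
  kind <- match.arg(kind)
  pool <- setdiff(g$ids, g$ids[g$roots])
  if (length(pool) < n_terms) {
    stop("validation error: ontology has ", length(pool),
         " non-root terms, fewer than n_terms = ", n_terms)
  }
  f <- freq$freq[match(pool, freq$term)]
  ord <- order(f, pool)                      # ascending freq, ties by id
  terms <- switch(kind,
    naive  = pool[rev(ord)][seq_len(n_terms)],
    small  = pool[ord][seq_len(n_terms)],
    random = sample(pool, n_terms))
  scores <- switch(kind,
    naive  = f[match(terms, pool)],
    small  = rep(1, n_terms),
    random = rep(1, n_terms))
  new_predictions(rep(genes, each = n_terms),
                  rep(terms, times = length(genes)),
                  rep(scores, times = length(genes)),
                  "fp")
}
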