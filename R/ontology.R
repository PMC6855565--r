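# Ontology container ----------------------------------------------------------
#
# An `ads_ontology` stores the DAG as integer-indexed adjacency lists plus the
# full ancestor closure of every term (closure includes the term itself, so
# term_jaccard(t, t) == 1 and annotation propagation is a plain union).

#' Build an ontology object from term ids and parent lists
#'
#' Validates that the parent relation forms a rooted directed acyclic graph and
#' precomputes ancestor closures and shortest root distances.
#'
#' @param ids character vector of canonical term identifiers.
#' @param parents named list mapping each term id to a character vector of its
#'   direct parent ids (may be empty for roots).
#' @param alt_ids named character vector mapping alternate ids to canonical ids.
#' @param names optional named character vector of human-readable term names.
#' @return An object of class `ads_ontology`.
#' @export
build_ontology <- function(ids, parents, alt_ids = character(), names = NULL) {
  ids <- as.character(ids)
  if (anyDuplicated(ids)) stop("duplicate term ids")
  n <- length(ids)
  if (n == 0L) stop("ontology has no terms")
  idx <- seq_len(n)
  names(idx) <- ids

  par <- vector("list", n)
  for (i in idx) {
    p <- parents[[ids[[i]]]]
    if (is.null(p) || length(p) == 0L) {
      par[[i]] <- integer()
      next
    }
    pi <- idx[as.character(p)]
    if (anyNA(pi)) {
      stop("term ", ids[[i]], " has unknown parent(s): ",
           paste(setdiff(p, ids), collapse = ", "))
    }
    par[[i]] <- sort(unique(unname(pi)))
  }

  # Kahn topological sort over child -> parent edges; leftover nodes = cycle.
  n_out <- lengths(par)                 # edges towards parents
  child <- vector("list", n)
  for (i in idx) for (p in par[[i]]) child[[p]] <- c(child[[p]], i)
  roots <- which(n_out == 0L)
  if (length(roots) == 0L) stop("ontology validation: no root term (cycle)")
  order <- integer(0)
  queue <- roots
  remaining <- n_out
  while (length(queue)) {
    v <- queue[[1L]]; queue <- queue[-1L]
    order <- c(order, v)
    for (c in child[[v]]) {
      remaining[[c]] <- remaining[[c]] - 1L
      if (remaining[[c]] == 0L) queue <- c(queue, c)
    }
  }
  if (length(order) < n) {
    stop("ontology validation: cycle detected over parent edges (",
         n - length(order), " terms unreachable from any root)")
  }

  # Closures and depths in topological order (parents are processed first).
  anc <- vector("list", n)
  depth <- integer(n)
  for (v in order) {
    if (length(par[[v]]) == 0L) {
      anc[[v]] <- v
      depth[[v]] <- 0L
    } else {
      anc[[v]] <- sort(unique(c(v, unlist(anc[par[[v]]], use.names = FALSE))))
      depth[[v]] <- min(depth[par[[v]]]) + 1L
    }
  }

  alt <- as.character(alt_ids)
  names(alt) <- names(alt_ids)
  if (length(alt) && !all(alt %in% ids)) {
    stop("alt_id target(s) not in ontology: ",
         paste(setdiff(alt, ids), collapse = ", "))
  }

  structure(
    list(ids = ids, index = idx, parents = par, children = lapply(child, sort),
         roots = sort(roots), anc = anc, depth = depth, alt = alt,
         names = names),
    class = "ads_ontology")
}

#' @export
print.ads_ontology <- function(x, ...) {
  cat(sprintf("ads_ontology: %d terms, %d roots, max depth %d\n",
              length(x$ids), length(x$roots), max(x$depth)))
  invisible(x)
}

#' Number of terms in an ontology
#' @param g an `ads_ontology`.
#' @return integer count of terms.
#' @export
n_terms <- function(g) length(g$ids)

# Resolve term ids (through alt_id map) to internal indices; errors on unknown.
term_index <- function(g, terms, allow_missing = FALSE) {
  terms <- as.character(terms)
  hit <- match(terms, names(g$alt))
  mapped <- ifelse(is.na(hit), terms, g$alt[hit])
  i <- unname(g$index[mapped])
  if (!allow_missing && anyNA(i)) {
    stop("unknown term(s): ", paste(unique(terms[is.na(i)]), collapse = ", "))
  }
  i
}

#' Ancestor closure of a term
#'
#' Returns all ancestors of `t` reachable over parent edges, including `t`
#' itself (so the closure of a root is the root alone).
#'
#' @param g an `ads_ontology`.
#' @param t a term id (alternate ids are resolved).
#' @return character vector of term ids.
#' @export
term_ancestors <- function(g, t) {
  stopifnot(length(t) == 1L)
  g$ids[g$anc[[term_index(g, t)]]]
}

# Integer-index jaccard between two closures (internal hot path).
jacc_idx <- function(g, i, j) {
  a <- g$anc[[i]]; b <- g$anc[[j]]
  ni <- length(intersect(a, b))
  ni / (length(a) + length(b) - ni)
}

# Max ancestor-jaccard of term index i against a set of term indices.
max_jacc_vs <- function(g, i, set) {
  if (length(set) == 0L) return(0)
  m <- 0
  for (j in set) {
    v <- jacc_idx(g, i, j)
    if (v > m) m <- v
  }
  m
}

#' Ancestor-set Jaccard similarity between two terms
#'
#' The Jaccard index of the two terms' ancestor closures (each closure
#' includes the term itself).  Symmetric; 1 iff the closures coincide.
#'
#' @param g an `ads_ontology`.
#' @param t1,t2 term ids.
#' @return similarity in `[0, 1]`.
#' @export
term_jaccard <- function(g, t1, t2) {
  jacc_idx(g, term_index(g, t1), term_index(g, t2))
}

#' k nearest non-root ancestors of a term
#'
#' Proper ancestors of `t` ordered by shortest parent-path distance, ties
#' broken by lexicographic term id, truncated to `k`.  Root terms are never
#' returned (they carry no information); near the top of the DAG the result
#' may hold fewer than `k` terms, and for a root it is empty.
#'
#' @param g an `ads_ontology`.
#' @param t a term id.
#' @param k maximum number of neighbours, `>= 1`.
#' @return character vector of at most `k` term ids.
#' @export
k_nearest_parents <- function(g, t, k) {
  stopifnot(k >= 1L)
  i <- term_index(g, t)
  out <- character(0)
  frontier <- g$parents[[i]]
  seen <- c(i, frontier)
  while (length(frontier) && length(out) < k) {
    lvl <- setdiff(frontier, g$roots)
    out <- c(out, sort(g$ids[lvl]))
    nxt <- unique(unlist(g$parents[frontier], use.names = FALSE))
    frontier <- setdiff(nxt, seen)
    seen <- c(seen, frontier)
  }
  out[seq_len(min(k, length(out)))]
}

# Term frequencies and information content -------------------------------------

#' Relative annotation frequencies of ontology terms
#'
#' For each ontology term, the fraction of distinct genes annotated to it
#' after ancestor propagation of the truth table.  Terms with no annotated
#' gene get frequency 0; a namespace root that every annotated gene reaches
#' gets frequency 1.
#'
#' @param g an `ads_ontology`.
#' @param annotations an annotation table (propagated or not; propagation is
#'   applied if missing).
#' @return a data.frame (class `ads_ic`) with columns `term` and `freq`,
#'   one row per ontology term; attribute `n_genes` records the gene count.
#' @export
term_frequencies <- function(g, annotations) {
  stopifnot(is.data.frame(annotations))
  if (nrow(annotations) == 0L) stop("empty annotation table")
  if (!isTRUE(attr(annotations, "propagated"))) {
    annotations <- propagate_truth(g, annotations)
  }
  genes <- unique(annotations$gene)
  ti <- term_index(g, annotations$term)
  cnt <- integer(length(g$ids))
  tab <- table(ti[!duplicated(paste0(annotations$gene, "\r", ti))])
  cnt[as.integer(names(tab))] <- as.integer(tab)
  out <- data.frame(term = g$ids, freq = cnt / length(genes),
                    stringsAsFactors = FALSE)
  attr(out, "n_genes") <- length(genes)
  class(out) <- c("ads_ic", "data.frame")
  out
}

#' Information-content weights from term frequencies
#'
#' Fills two IC variants: `ic(t) = -log2(freq(t))` (marginal information,
#' bits, with zero frequencies clamped to a floor so the weight stays
#' finite) and `ic2(t) = -log2(freq(t) / min_p freq(p))` over direct parents
#' `p` (information accretion: information conditional on the parents; for a
#' root `ic2 = ic`).
#'
#' @param g an `ads_ontology`.
#' @param ic_table output of [term_frequencies()].
#' @param floor frequency floor for unannotated terms; default
#'   `1 / (2 * n_genes)`.
#' @return `ic_table` with `ic` and `ic2` columns added.
#' @export
information_content <- function(g, ic_table, floor = NULL) {
  stopifnot(inherits(ic_table, "ads_ic"))
  if (is.null(floor)) {
    ng <- attr(ic_table, "n_genes")
    if (is.null(ng)) stop("ic_table lacks n_genes attribute; supply `floor`")
    floor <- 1 / (2 * ng)
  }
  f <- pmax(ic_table$freq[match(g$ids, ic_table$term)], floor)
  ic_table$ic <- -log2(f)[match(ic_table$term, g$ids)]
  pf <- vapply(seq_along(g$ids), function(i) {
    p <- g$parents[[i]]
    if (length(p) == 0L) 1 else min(f[p])
  }, numeric(1))
  ratio <- pmin(f / pf, 1)
  ic2 <- -log2(ratio)
  ic_table$ic2 <- ic2[match(ic_table$term, g$ids)]
  ic_table
}

# Named ic lookup vector for a given variant.
ic_lookup <- function(ic_table, variant = c("ic", "ic2", "none")) {
  variant <- match.arg(variant)
  if (variant == "none") {
    w <- rep(1, nrow(ic_table))
  } else {
    if (is.null(ic_table[[variant]])) {
      stop("ic_table has no ", variant, " column; run information_content()")
    }
    w <- ic_table[[variant]]
  }
  names(w) <- ic_table$term
  w
}

#' Write an IC table to tab-delimited text
#' @param ic_table an `ads_ic` table.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_ic_table <- function(ic_table, path) {
  utils::write.table(as.data.frame(ic_table), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an IC table written by [write_ic_table()]
#' @param path input file.
#' @param n_genes gene count to attach (used for the default IC floor).
#' @return an `ads_ic` data.frame.
#' @export
read_ic_table <- function(path, n_genes = NULL) {
  out <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
  attr(out, "n_genes") <- n_genes
  class(out) <- c("ads_ic", "data.frame")
  out
}
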