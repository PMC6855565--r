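# Truth (annotation) tables and prediction sets.
#
# Both are plain data.frames with a `propagated` attribute.  Truth tables
# have columns (gene, term); prediction sets add (score, origin) where
# origin is one of "positive", "negative", "fp".

new_annotations <- function(gene, term, propagated = FALSE) {
  out <- data.frame(gene = as.character(gene), term = as.character(term),
                    stringsAsFactors = FALSE)
  out <- unique(out)
  out <- out[order(out$gene, out$term), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "propagated") <- propagated
  class(out) <- c("ads_annotations", "data.frame")
  out
}

new_predictions <- function(gene, term, score, origin = "positive",
                            propagated = FALSE) {
  out <- data.frame(gene = as.character(gene), term = as.character(term),
                    score = as.numeric(score),
                    origin = rep(as.character(origin),
                                 length.out = length(gene)),
                    stringsAsFactors = FALSE)
  # one row per (gene, term): keep the maximum score
  out <- out[order(out$gene, out$term, -out$score, out$origin), , drop = FALSE]
  out <- out[!duplicated(out[c("gene", "term")]), , drop = FALSE]
  out <- out[order(out$gene, out$term), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "propagated") <- propagated
  class(out) <- c("ads_predictions", "data.frame")
  out
}

#' Read a truth annotation table
#'
#' Two tab-separated columns: gene id, term id.  Alternate term ids are
#' mapped to canonical ids; rows whose term is unknown to the ontology are
#' dropped with a warning.  Gzip input is read transparently.
#'
#' @param path input file.
#' @param g an `ads_ontology` used to validate and canonicalise term ids.
#' @param header does the file carry a header line?
#' @return an `ads_annotations` data.frame with columns `gene`, `term`.
#' @export
read_annotations <- function(path, g, header = FALSE) {
  raw <- utils::read.table(path, sep = "\t", header = header,
                           stringsAsFactors = FALSE, quote = "",
                           comment.char = "")
  if (ncol(raw) != 2L) {
    stop("format error: expected 2 tab-separated columns, got ", ncol(raw))
  }
  names(raw) <- c("gene", "term")
  idx <- term_index(g, raw$term, allow_missing = TRUE)
  if (anyNA(idx)) {
    warning(sum(is.na(idx)), " row(s) with unknown terms dropped")
    raw <- raw[!is.na(idx), , drop = FALSE]
    idx <- idx[!is.na(idx)]
  }
  if (nrow(raw) == 0L) stop("validation error: no rows left after term filtering")
  new_annotations(raw$gene, g$ids[idx])
}

#' Read a prediction set
#'
#' Three tab-separated columns: gene id, term id, score.  Duplicate
#' (gene, term) rows keep the maximum score.  Rows with unknown terms are
#' dropped with a warning.
#'
#' @inheritParams read_annotations
#' @return an `ads_predictions` data.frame.
#' @export
read_predictions <- function(path, g, header = FALSE) {
  raw <- utils::read.table(path, sep = "\t", header = header,
                           stringsAsFactors = FALSE, quote = "",
                           comment.char = "")
  if (ncol(raw) != 3L) {
    stop("format error: expected 3 tab-separated columns, got ", ncol(raw))
  }
  names(raw) <- c("gene", "term", "score")
  idx <- term_index(g, raw$term, allow_missing = TRUE)
  if (anyNA(idx)) {
    warning(sum(is.na(idx)), " row(s) with unknown terms dropped")
    raw <- raw[!is.na(idx), , drop = FALSE]
    idx <- idx[!is.na(idx)]
  }
  if (nrow(raw) == 0L) stop("validation error: no rows left after term filtering")
  new_predictions(raw$gene, g$ids[idx], raw$score)
}

#' Write a truth table / prediction set as tab-delimited text
#'
#' @param x an `ads_annotations` or `ads_predictions` object.
#' @param path output path (`.gz` for gzip).
#' @return `path`, invisibly.
#' @export
write_annotations <- function(x, path) {
  cols <- intersect(c("gene", "term", "score"), names(x))
  utils::write.table(as.data.frame(x)[cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_annotations
#' @export
write_predictions <- write_annotations

#' Propagate a truth table to ancestors
#'
#' Closes the table under ancestry: a gene annotated to a term is annotated
#' to every ancestor of that term.  Idempotent; output rows are sorted by
#' gene then term.
#'
#' @param g an `ads_ontology`.
#' @param t an `ads_annotations` table.
#' @return a propagated `ads_annotations` table.
#' @export
propagate_truth <- function(g, t) {
  stopifnot(is.data.frame(t))
  idx <- term_index(g, t$term)
  closures <- g$anc[idx]
  lens <- lengths(closures)
  out <- new_annotations(rep(t$gene, lens),
                         g$ids[unlist(closures, use.names = FALSE)],
                         propagated = TRUE)
  out
}

#' Propagate a prediction set to ancestors with score max-propagation
#'
#' Every ancestor of a predicted term is added with score equal to the
#' maximum score over its predicted descendants (including itself), so a
#' term counts as predicted at threshold `th` iff any of its descendants
#' does.  The origin label of the maximum-scoring contributing row is kept.
#' Idempotent.  Semantic-similarity metrics skip this step: they account
#' for term relatedness themselves.
#'
#' @param g an `ads_ontology`.
#' @param p an `ads_predictions` set.
#' @return a propagated `ads_predictions` set.
#' @export
propagate_predictions <- function(g, p) {
  stopifnot(is.data.frame(p))
  idx <- term_index(g, p$term)
  closures <- g$anc[idx]
  lens <- lengths(closures)
  out <- new_predictions(rep(p$gene, lens),
                         g$ids[unlist(closures, use.names = FALSE)],
                         rep(p$score, lens),
                         rep(p$origin, lens),
                         propagated = TRUE)
  for (a in c("signal", "realised_noise", "seed", "noise", "pre_permutation")) {
    attr(out, a) <- attr(p, a)
  }
  out
}
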