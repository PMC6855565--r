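# Minimal OBO 1.2/1.4 reader and writer.
#
# Only the fields needed for DAG construction are interpreted: id, name,
# alt_id, is_a, relationship: part_of, is_obsolete, namespace.  Cross-products
# and other relation types are ignored by design.

#' Load an ontology from an OBO file
#'
#' Parses `[Term]` stanzas, drops obsolete terms, maps alternate ids and
#' builds the DAG over `is_a` (and, by default, `part_of`) edges.  Edges to
#' obsolete or undeclared terms are dropped.  A cyclic parent relation is a
#' validation error.
#'
#' @param path path to an OBO file (plain or gzip).
#' @param use_part_of include `relationship: part_of` edges (default `TRUE`,
#'   matching common GO practice).
#' @param namespace optional namespace name; when given, only terms of that
#'   namespace are kept.
#' @return an `ads_ontology`.
#' @export
load_obo <- function(path, use_part_of = TRUE, namespace = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  term_starts <- which(lines == "[Term]")
  if (length(term_starts) == 0L) stop("OBO format error: no [Term] stanza in ", path)
  stanza_breaks <- c(which(grepl("^\\[", lines)), length(lines) + 1L)

  ids <- character(0)
  nms <- character(0)
  parents <- list()
  alt <- character(0)
  ns <- character(0)

  for (s in term_starts) {
    end <- min(stanza_breaks[stanza_breaks > s]) - 1L
    body <- lines[(s + 1L):end]
    body <- sub("\\s*!.*$", "", body)        # trailing comments
    field <- sub(":.*$", "", body)
    value <- trimws(sub("^[^:]*:\\s*", "", body))

    id <- value[field == "id"][1]
    if (is.na(id) || !nzchar(id)) stop("OBO format error: [Term] without id")
    if (any(field == "is_obsolete" & value == "true")) next

    p <- value[field == "is_a"]
    p <- sub("\\s.*$", "", p)
    if (use_part_of) {
      rel <- value[field == "relationship"]
      po <- rel[grepl("^part_of\\s", rel)]
      p <- c(p, sub("^part_of\\s+(\\S+).*$", "\\1", po))
    }
    ids <- c(ids, id)
    nm <- value[field == "name"][1]
    nms <- c(nms, if (is.na(nm)) id else nm)
    parents[[id]] <- unique(p)
    a <- value[field == "alt_id"]
    if (length(a)) alt[a] <- id
    nsv <- value[field == "namespace"][1]
    ns <- c(ns, if (is.na(nsv)) "" else nsv)
  }

  if (!is.null(namespace)) {
    keep <- ns == namespace
    ids <- ids[keep]; nms <- nms[keep]
    parents <- parents[ids]
    alt <- alt[alt %in% ids]
  }
  # drop edges to terms that were obsolete / filtered out
  parents <- lapply(parents, function(p) p[p %in% ids])
  alt <- alt[alt %in% ids]
  names(nms) <- ids
  build_ontology(ids, parents, alt_ids = alt, names = nms)
}

#' Write an ontology to an OBO file
#'
#' Emits one `[Term]` stanza per term with `id`, `name` and `is_a` lines.
#' The output round-trips through [load_obo()].
#'
#' @param g an `ads_ontology`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_obo <- function(g, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("format-version: 1.2", ""), con)
  for (i in seq_along(g$ids)) {
    nm <- if (!is.null(g$names)) unname(g$names[g$ids[[i]]]) else g$ids[[i]]
    stanza <- c("[Term]",
                paste0("id: ", g$ids[[i]]),
                paste0("name: ", nm),
                paste0("is_a: ", g$ids[g$parents[[i]]]),
                "")
    writeLines(stanza, con)
  }
  invisible(path)
}
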