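#' Ontology graphs and ancestor-set Jaccard similarity
#'
#' An `ontology_graph` stores terms of a cell-classification tree (or DAG)
#' with directed child-to-parent (`is_a`) edges. Similarity between two terms
#' is the Jaccard coefficient of their reflexive-transitive ancestor sets:
#' every hierarchical node above (and including) each term participates, so
#' exact matches score 1 and terms sharing only deep roots score near 0. This
#' replaces coarser binary schemes (1 for exact match, 0.5 for shared parent)
#' with a graded score.
#'
#' @param ids character vector of term ids.
#' @param names character vector of term names (same length).
#' @param parents list parallel to `ids`; each element a character vector of
#'   parent term ids (empty for roots).
#' @return an `ontology_graph` object.
#' @export
ontology_graph <- function(ids, names = ids, parents) {
  stopifnot(length(ids) == length(names), length(ids) == length(parents))
  if (anyDuplicated(ids)) .stopf("ontology_graph: duplicate term ids")
  parents <- lapply(parents, as.character)
  unknown <- setdiff(unlist(parents), ids)
  if (length(unknown)) {
    .stopf("ontology_graph: parent id(s) not among terms: %s",
           paste(unknown, collapse = ", "))
  }
  g <- structure(list(ids = as.character(ids), names = as.character(names),
                      parents = stats::setNames(parents, ids),
                      cache = new.env(parent = emptyenv())),
                 class = "ontology_graph")
  # cycle check: a node may never appear among its parents' ancestors
  for (id in g$ids) {
    for (p in g$parents[[id]]) {
      if (id %in% ontology_ancestors(g, p)) {
        .stopf("ontology_graph: cycle detected through '%s'", id)
      }
    }
  }
  g
}

#' @rdname ontology_graph
#' @param graph an `ontology_graph`.
#' @export
ontology_roots <- function(graph) {
  graph$ids[vapply(graph$parents, length, 1L) == 0L]
}

#' Reflexive-transitive ancestor set of a term
#' @param graph an `ontology_graph`.
#' @param term a term id present in the graph.
#' @return character vector of ancestor ids, including `term` itself.
#' @export
ontology_ancestors <- function(graph, term) {
  if (!term %in% graph$ids) .stopf("unknown ontology term: '%s'", term)
  cached <- graph$cache[[term]]
  if (!is.null(cached)) return(cached)
  seen <- character(0)
  frontier <- term
  steps <- 0L
  while (length(frontier)) {
    seen <- union(seen, frontier)
    frontier <- setdiff(unique(unlist(graph$parents[frontier])), seen)
    steps <- steps + 1L
    if (steps > length(graph$ids) + 1L) {
      .stopf("ontology_graph: cycle detected near term '%s'", term)
    }
  }
  graph$cache[[term]] <- seen
  seen
}

#' Jaccard similarity of two ontology terms
#'
#' `|ancestors(a) intersect ancestors(b)| / |ancestors(a) union ancestors(b)|`
#' over reflexive-transitive ancestor sets.
#' @param term_a,term_b term ids present in `graph`.
#' @param graph an `ontology_graph`.
#' @return similarity in \[0, 1\].
#' @export
ontology_jaccard <- function(term_a, term_b, graph) {
  aa <- ontology_ancestors(graph, term_a)
  ab <- ontology_ancestors(graph, term_b)
  length(intersect(aa, ab)) / length(union(aa, ab))
}

#' Read an OBO flat file into an ontology graph
#'
#' Parses `[Term]` stanzas, keeping `id:`, `name:` and `is_a:` lines
#' (trailing `!` comments stripped). Relationships other than `is_a` are
#' ignored; obsolete terms are kept if present.
#' @param path path to an OBO-format text file.
#' @return an `ontology_graph`.
#' @export
read_obo <- function(path) {
  lines <- readLines(path, warn = FALSE)
  ids <- character(0); nms <- character(0); parents <- list()
  cur_id <- NA_character_; cur_name <- NA_character_; cur_par <- character(0)
  in_term <- FALSE
  flush <- function() {
    if (!is.na(cur_id)) {
      ids <<- c(ids, cur_id)
      nms <<- c(nms, if (is.na(cur_name)) cur_id else cur_name)
      parents[[length(parents) + 1L]] <<- cur_par
    }
  }
  for (ln in lines) {
    ln <- trimws(ln)
    if (ln == "[Term]") {
      flush(); in_term <- TRUE
      cur_id <- NA_character_; cur_name <- NA_character_; cur_par <- character(0)
    } else if (grepl("^\\[", ln)) {
      flush(); in_term <- FALSE; cur_id <- NA_character_
    } else if (in_term) {
      if (startsWith(ln, "id:")) {
        cur_id <- trimws(sub("^id:", "", ln))
      } else if (startsWith(ln, "name:")) {
        cur_name <- trimws(sub("^name:", "", ln))
      } else if (startsWith(ln, "is_a:")) {
        v <- trimws(sub("!.*$", "", sub("^is_a:", "", ln)))
        if (nzchar(v)) cur_par <- c(cur_par, v)
      }
    }
  }
  flush()
  ontology_graph(ids, nms, parents)
}

#' Map label strings to ontology terms
#'
#' Default offline resolver: exact match on term name (after whitespace/case
#' normalization), then lookup in an optional synonym table.
#' @param labels character vector of labels.
#' @param graph an `ontology_graph`.
#' @param synonyms optional named character vector mapping label to term id.
#' @return character vector of term ids, `NA` where unresolved.
#' @export
resolve_terms <- function(labels, graph, synonyms = NULL) {
  keys <- .norm_label(labels)
  by_name <- stats::setNames(graph$ids, .norm_label(graph$names))
  out <- unname(by_name[keys])
  if (!is.null(synonyms)) {
    syn <- stats::setNames(as.character(synonyms), .norm_label(names(synonyms)))
    miss <- is.na(out)
    out[miss] <- unname(syn[keys[miss]])
  }
  out
}
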