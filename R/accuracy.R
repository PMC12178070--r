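#' Annotation accuracy against a reference labeling
#'
#' Scores each cell by the similarity between its predicted and reference
#' cell-type label, then averages either over cells (`level = "cell"`) or as
#' the unweighted mean of per-reference-group means (`level = "cluster"`,
#' each reference cell type contributing equally regardless of abundance).
#'
#' Two similarity modes are supported. `"embedding"` uses the cosine between
#' text embeddings of the two labels, clipped to \[0, 1\] (a message is
#' emitted when clipping occurs; raw cosines can be slightly negative for
#' unrelated names). `"ontology"` maps both labels to ontology terms and
#' scores the Jaccard coefficient of their ancestor sets; labels that fail to
#' map score `unmapped_score` (default 0) with a warning.
#'
#' @param predicted,reference character vectors of per-cell labels, equal
#'   length.
#' @param mode `"embedding"` or `"ontology"`.
#' @param level `"cell"` or `"cluster"`.
#' @param provider embedding provider (embedding mode).
#' @param graph an `ontology_graph` (ontology mode).
#' @param term_map named character vector label -> term id (ontology mode);
#'   labels are matched after normalization. Terms are also resolved against
#'   graph term names directly.
#' @param unmapped_score score assigned to pairs with an unmappable label.
#' @return accuracy in \[0, 1\].
#' @export
annotation_accuracy <- function(predicted, reference,
                                mode = c("embedding", "ontology"),
                                level = c("cell", "cluster"),
                                provider = hash_embedding_provider(),
                                graph = NULL, term_map = NULL,
                                unmapped_score = 0) {
  mode <- match.arg(mode)
  level <- match.arg(level)
  if (length(predicted) != length(reference)) {
    .stopf("annotation_accuracy: predicted and reference lengths differ")
  }
  scores <- annotation_pair_scores(predicted, reference, mode, provider,
                                   graph, term_map, unmapped_score)
  if (level == "cell") {
    mean(scores)
  } else {
    grp <- .norm_label(reference)
    mean(tapply(scores, grp, mean))
  }
}

# Per-cell similarity scores for (predicted, reference) label pairs.
annotation_pair_scores <- function(predicted, reference, mode, provider,
                                   graph, term_map, unmapped_score) {
  pk <- .norm_label(predicted)
  rk <- .norm_label(reference)
  if (mode == "embedding") {
    labs <- unique(c(pk, rk))
    emb <- provider$embed(labs)
    cs <- tcrossprod(.l2_normalize_rows(emb))
    raw <- cs[cbind(match(pk, labs), match(rk, labs))]
    raw[pk == rk] <- 1
    if (any(raw < 0)) {
      message(sprintf("annotation_accuracy: %d cosine value(s) below 0 clipped",
                      sum(raw < 0)))
    }
    pmin(1, pmax(0, raw))
  } else {
    if (is.null(graph)) .stopf("annotation_accuracy: ontology mode needs 'graph'")
    labs <- unique(c(pk, rk))
    terms <- resolve_terms(labs, graph, synonyms = term_map)
    if (anyNA(terms)) {
      .warnf("annotation_accuracy: unmapped label(s) scored %.3g: %s",
             unmapped_score, paste(labs[is.na(terms)], collapse = ", "))
    }
    tmap <- stats::setNames(terms, labs)
    vapply(seq_along(pk), function(i) {
      ta <- tmap[[pk[i]]]
      tb <- tmap[[rk[i]]]
      if (is.na(ta) || is.na(tb)) return(unmapped_score)
      ontology_jaccard(ta, tb, graph)
    }, numeric(1))
  }
}
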