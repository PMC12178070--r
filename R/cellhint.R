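#' Raw cell-to-type distance matrix
#'
#' Euclidean distance from every cell to every target-type centroid in a
#' shared embedding space (typically 50-dimensional PCA or the integrated
#' coordinates).
#' @param cells cells x d coordinate matrix (or `panorama_embedding`).
#' @param target_types a centroid table from [centroid_table()] or a plain
#'   types x d matrix with rownames.
#' @return cells x types distance matrix.
#' @export
cell_type_distances <- function(cells, target_types) {
  if (inherits(cells, "panorama_embedding")) cells <- cells$coords
  cent <- if (is.list(target_types)) target_types$centroids else as.matrix(target_types)
  if (is.null(cent) || nrow(cent) == 0) .stopf("cell_type_distances: empty target types")
  d <- pairwise_dist(as.matrix(cells), cent)
  colnames(d) <- rownames(cent)
  d
}

#' Convert distances to similarities
#'
#' Distances are normalized by the mean of the full cell-by-type distance
#' matrix and passed through a negated exponential: `S = exp(-D / mean(D))`.
#' An all-zero distance matrix yields all-ones similarity with a warning
#' (the formula's limit).
#' @param D non-negative distance matrix.
#' @return similarity matrix in (0, 1].
#' @export
normalize_to_similarity <- function(D) {
  if (any(D < 0)) .stopf("normalize_to_similarity: negative distances")
  m <- mean(D)
  if (m == 0) {
    .warnf("normalize_to_similarity: all-zero distances; similarity = 1")
    return(array(1, dim = dim(D), dimnames = dimnames(D)))
  }
  exp(-D / m)
}

#' Per-cell assignment uncertainty (inverted clarity)
#'
#' The cell's similarity row is normalized to a distribution over the K
#' target types; alpha is its Shannon entropy divided by `log(K)`, so alpha
#' is 1 for a perfectly ambiguous cell and 0 for a one-hot assignment.
#' Clarity is `1 - alpha`. With a single target type alpha is defined as 0.
#' @param S similarity matrix (cells x types) or a single row.
#' @return numeric vector of alpha values in \[0, 1\].
#' @export
clarity_alpha <- function(S) {
  if (is.null(dim(S))) S <- matrix(S, nrow = 1)
  K <- ncol(S)
  if (K == 1) return(rep(0, nrow(S)))
  rs <- rowSums(S)
  if (any(rs <= 0)) .stopf("clarity_alpha: row(s) with non-positive sum")
  p <- S / rs
  h <- -rowSums(ifelse(p > 0, p * log(p), 0))
  pmin(1, pmax(0, h / log(K)))
}

#' Blend expression similarity with the label prior
#'
#' Elementwise evaluation of
#' `S'_iJ = beta * ((1 - alpha_i) * S_iJ + alpha_i * M_IJ) + (1 - beta) * S_iJ`
#' where `M_IJ` is the prior similarity between cell i's source label and
#' target type J. At most a `beta`-fraction of the similarity is replaced,
#' and only in proportion to the cell's uncertainty `alpha_i` — confident
#' cells keep their expression-based similarity untouched.
#'
#' @param S cells x types similarity matrix (types named).
#' @param alphas per-cell uncertainty in \[0, 1\].
#' @param M a `prior_similarity` matrix (or NULL to return `S`).
#' @param source_labels per-cell source label.
#' @param beta prior strength in \[0, 1\], default 0.1.
#' @return adjusted similarity matrix S'.
#' @export
adjust_similarity <- function(S, alphas, M, source_labels, beta = 0.1) {
  if (!(beta >= 0 && beta <= 1)) .stopf("adjust_similarity: beta must be in [0, 1]")
  if (any(alphas < 0 | alphas > 1)) .stopf("adjust_similarity: alpha outside [0, 1]")
  if (is.null(M) || beta == 0) return(S)
  stopifnot(length(alphas) == nrow(S), length(source_labels) == nrow(S))
  m <- prior_lookup(M, source_labels, colnames(S))
  beta * ((1 - alphas) * S + alphas * m) + (1 - beta) * S
}

# Directed type-level assignment fractions from dataset A's cells onto
# dataset B's types: fraction of type-I cells whose argmax adjusted
# similarity is type J.
.assignment_fractions <- function(coords_a, labels_a, coords_b, labels_b,
                                  M, beta) {
  cent <- centroid_table(coords_b, labels_b)
  D <- cell_type_distances(coords_a, cent)
  S <- normalize_to_similarity(D)
  Sp <- adjust_similarity(S, clarity_alpha(S), M, labels_a, beta)
  hit <- colnames(Sp)[max.col(Sp, ties.method = "first")]
  src <- sort(unique(labels_a))
  tgt <- rownames(cent$centroids)
  fr <- matrix(0, length(src), length(tgt), dimnames = list(src, tgt))
  for (I in src) {
    tab <- table(factor(hit[labels_a == I], levels = tgt))
    fr[I, ] <- as.numeric(tab) / sum(tab)
  }
  fr
}

#' Harmonize cell-type labels across datasets
#'
#' Sequential pairwise alignment of per-dataset cell-type vocabularies.
#' For every ordered dataset pair the cells of one dataset are softly
#' assigned to the other's types through the prior-adjusted similarity, and
#' the per-type assignment fractions are classified by reciprocal-majority
#' rules: majority (>= `majority`) in both directions gives a one-to-one
#' edge; a single-direction majority gives a subset edge, labeled `"split"`
#' when the receiving (coarser) type absorbs several source types of that
#' dataset pair and `"merge"` otherwise; types with no accepted edge are
#' `"novel"`. Connected components of accepted edges become alignment
#' groups; the harmonized group label joins the distinct member names with
#' `" = "` in first-seen order, and per-cell labels are revised to their
#' group label.
#'
#' @param datasets list; each element either a `cell_dataset` carrying `pca`
#'   and `label_given`, a `panorama_embedding` with labels, or a list with
#'   `coords` and `labels`.
#' @param M a `prior_similarity` matrix (NULL disables the prior; identical
#'   to `beta = 0`).
#' @param beta prior strength, default 0.1.
#' @param order optional integer order of alignment; default descending
#'   dataset size.
#' @param majority assignment-fraction threshold constituting a majority.
#' @return a `harmonization` object: `table` (data.frame: group, dataset,
#'   cell_type, relationship, harmonized), `edges`, `groups`,
#'   `revised_labels` (list per dataset), `order`.
#' @export
harmonize_datasets <- function(datasets, M = NULL, beta = 0.1, order = NULL,
                               majority = 0.5) {
  embs <- lapply(seq_along(datasets), function(i) {
    x <- datasets[[i]]
    if (inherits(x, "cell_dataset")) {
      if (is.null(x$pca)) .stopf("harmonize_datasets: dataset %d has no pca; run preprocess()", i)
      list(coords = x$pca, labels = x$label_given)
    } else if (inherits(x, "panorama_embedding")) {
      list(coords = x$coords, labels = x$labels)
    } else {
      list(coords = as.matrix(x$coords), labels = as.character(x$labels))
    }
  })
  keep <- vapply(embs, function(e) nrow(e$coords) > 0, TRUE)
  if (any(!keep)) .warnf("harmonize_datasets: skipping empty dataset(s) %s",
                         paste(which(!keep), collapse = ", "))
  ds_ids <- which(keep)
  if (length(ds_ids) < 2) .stopf("harmonize_datasets: need >= 2 non-empty datasets")
  if (is.null(order)) {
    order <- ds_ids[order(vapply(embs[ds_ids], function(e) nrow(e$coords), 1L),
                          decreasing = TRUE)]
  }
  # node universe: (dataset, type)
  nodes <- do.call(rbind, lapply(order, function(i) {
    data.frame(dataset = i, cell_type = sort(unique(embs[[i]]$labels)),
               stringsAsFactors = FALSE)
  }))
  node_key <- paste(nodes$dataset, nodes$cell_type, sep = "\r")
  nn <- nrow(nodes)
  edges <- NULL
  for (ai in seq_along(order)[-length(order)]) {
    for (bi in (ai + 1):length(order)) {
      a <- order[ai]; b <- order[bi]
      fr_ab <- .assignment_fractions(embs[[a]]$coords, embs[[a]]$labels,
                                     embs[[b]]$coords, embs[[b]]$labels, M, beta)
      fr_ba <- .assignment_fractions(embs[[b]]$coords, embs[[b]]$labels,
                                     embs[[a]]$coords, embs[[a]]$labels, M, beta)
      for (I in rownames(fr_ab)) {
        for (J in colnames(fr_ab)) {
          maj_ab <- fr_ab[I, J] >= majority
          maj_ba <- fr_ba[J, I] >= majority
          if (!maj_ab && !maj_ba) next
          rel <- if (maj_ab && maj_ba) "one_to_one" else "subset"
          edges <- rbind(edges, data.frame(
            ds_a = a, type_a = I, ds_b = b, type_b = J, relationship = rel,
            frac_ab = fr_ab[I, J], frac_ba = fr_ba[J, I],
            stringsAsFactors = FALSE))
        }
      }
    }
  }
  # refine subset edges: the receiving type of a one-directional majority is
  # the coarser one; "split" when it absorbs >= 2 types of the same partner
  # dataset, "merge" otherwise
  if (!is.null(edges) && any(edges$relationship == "subset")) {
    for (r in which(edges$relationship == "subset")) {
      if (edges$frac_ab[r] >= majority) {
        recv <- c(edges$ds_b[r], edges$type_b[r]); src_ds <- edges$ds_a[r]
      } else {
        recv <- c(edges$ds_a[r], edges$type_a[r]); src_ds <- edges$ds_b[r]
      }
      n_in <- sum((edges$ds_b == recv[1] & edges$type_b == recv[2] & edges$ds_a == src_ds) |
                    (edges$ds_a == recv[1] & edges$type_a == recv[2] & edges$ds_b == src_ds))
      edges$relationship[r] <- if (n_in >= 2) "split" else "merge"
    }
  }
  uf <- .uf_new(nn)
  if (!is.null(edges)) {
    for (r in seq_len(nrow(edges))) {
      ia <- match(paste(edges$ds_a[r], edges$type_a[r], sep = "\r"), node_key)
      ib <- match(paste(edges$ds_b[r], edges$type_b[r], sep = "\r"), node_key)
      uf <- .uf_union(uf, ia, ib)
    }
  }
  root <- vapply(seq_len(nn), function(i) .uf_find(uf, i), 1L)
  group_id <- match(root, unique(root))
  # harmonized label: distinct member names, first-seen order, joined " = "
  harmonized <- vapply(seq_len(max(group_id)), function(g) {
    mem <- nodes$cell_type[group_id == g]
    paste(mem[!duplicated(.norm_label(mem))], collapse = " = ")
  }, character(1))
  node_rel <- vapply(seq_len(nn), function(i) {
    if (is.null(edges)) return("novel")
    hit <- (edges$ds_a == nodes$dataset[i] & edges$type_a == nodes$cell_type[i]) |
      (edges$ds_b == nodes$dataset[i] & edges$type_b == nodes$cell_type[i])
    if (!any(hit)) return("novel")
    rels <- edges$relationship[hit]
    if (any(rels == "one_to_one")) "one_to_one" else rels[1]
  }, character(1))
  tab <- data.frame(group = group_id, dataset = nodes$dataset,
                    cell_type = nodes$cell_type, relationship = node_rel,
                    harmonized = harmonized[group_id], stringsAsFactors = FALSE)
  tab <- tab[order(tab$group, tab$dataset, tab$cell_type), , drop = FALSE]
  rownames(tab) <- NULL
  revised <- lapply(seq_along(embs), function(i) {
    if (!keep[i]) return(character(0))
    idx <- match(paste(i, embs[[i]]$labels, sep = "\r"), node_key)
    harmonized[group_id[idx]]
  })
  structure(list(table = tab, edges = edges,
                 groups = split(node_key, group_id),
                 revised_labels = revised, order = order,
                 beta = beta, majority = majority),
            class = "harmonization")
}

#' @exportS3Method base::print
print.harmonization <- function(x, ...) {
  cat(sprintf("harmonization: %d groups over %d (dataset, type) nodes\n",
              length(x$groups), nrow(x$table)))
  for (g in unique(x$table$group)) {
    cat(sprintf("  [%d] %s\n", g, x$table$harmonized[x$table$group == g][1]))
  }
  invisible(x)
}

#' Write a harmonization table as TSV
#' @param h a `harmonization` object.
#' @param path file path.
#' @export
write_harmonization <- function(h, path) {
  utils::write.table(h$table, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
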