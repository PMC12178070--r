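#' Shared low-dimensional embedding across batches
#'
#' Builds a common embedding for several datasets: the log-normalized
#' matrices are restricted to the gene intersection (optionally to supplied
#' HVGs), rows are L2-normalized, the batches are stacked and reduced by a
#' truncated SVD to `d` dimensions (coordinates are `U * diag(s)`, the
#' singular-vector scale the downstream Gaussian smoothing kernel expects),
#' then split back per batch.
#'
#' @param datasets list of `cell_dataset` (preprocessed or raw; the log
#'   layer is computed when absent) or list of plain cells x genes matrices.
#' @param d target dimension (default 100, clamped to the data).
#' @param hvg optional character vector restricting the gene universe.
#' @param seed RNG seed (kept for interface stability; the reduction is
#'   deterministic).
#' @return list of `panorama_embedding` objects: `coords` (cells x d),
#'   `batch`, `labels`.
#' @export
reduce_dimensions <- function(datasets, d = 100L, hvg = NULL, seed = 0L) {
  mats <- lapply(datasets, function(ds) {
    if (inherits(ds, "cell_dataset")) {
      if (!is.null(ds$norm)) {
        as.matrix(ds$norm)
      } else {
        tot <- Matrix::rowSums(ds$counts)
        as.matrix(log1p(ds$counts * (1e4 / pmax(tot, 1))))
      }
    } else {
      as.matrix(ds)
    }
  })
  genes <- Reduce(intersect, lapply(mats, colnames))
  if (!is.null(hvg)) genes <- intersect(genes, hvg)
  if (length(genes) == 0) {
    .stopf("reduce_dimensions: empty gene intersection (per-dataset gene counts: %s)",
           paste(vapply(mats, ncol, 1L), collapse = ", "))
  }
  stacked <- do.call(rbind, lapply(mats, function(m) .l2_normalize_rows(m[, genes, drop = FALSE])))
  d <- min(d, nrow(stacked) - 1L, length(genes) - 1L)
  set.seed(seed)
  sv <- svd(stacked, nu = d, nv = 0)
  coords <- sv$u %*% diag(sv$d[seq_len(d)], d)
  sizes <- vapply(mats, nrow, 1L)
  ends <- cumsum(sizes)
  starts <- c(1L, utils::head(ends, -1) + 1L)
  lapply(seq_along(datasets), function(i) {
    ds <- datasets[[i]]
    lab <- if (inherits(ds, "cell_dataset")) ds$label_given else NULL
    bat <- if (inherits(ds, "cell_dataset")) ds$batch else rep(sprintf("batch%d", i), sizes[i])
    structure(list(coords = coords[starts[i]:ends[i], , drop = FALSE],
                   batch = bat, labels = lab),
              class = "panorama_embedding")
  })
}

# Coerce (embedding | cell_dataset with pca | matrix) to a panorama_embedding.
.as_panorama <- function(x, batch_id = "batch") {
  if (inherits(x, "panorama_embedding")) return(x)
  if (inherits(x, "cell_dataset")) {
    if (is.null(x$pca)) .stopf("dataset has no embedding; run preprocess() or reduce_dimensions()")
    return(structure(list(coords = x$pca, batch = x$batch, labels = x$label_given),
                     class = "panorama_embedding"))
  }
  structure(list(coords = as.matrix(x), batch = rep(batch_id, nrow(x)), labels = NULL),
            class = "panorama_embedding")
}

#' Prior-weighted mutual nearest neighbors between two batches
#'
#' Cross-batch cell distances are divided entrywise by the label-similarity
#' `M_IJ` of the two cells' types before the k-nearest-neighbor search, so
#' cells whose annotations agree are easier to match and cells with
#' dissimilar annotations must be much closer in expression to qualify.
#' Pairs mutual under the weighted distance form the match set. In
#' approximate mode the candidate pool per cell is first taken as
#' `pool_factor * k` nearest by raw distance, and the weighted re-ranking
#' selects `k` within that pool (the two-stage scheme used with approximate
#' indexes).
#'
#' @param A,B `panorama_embedding` objects (or datasets/matrices coercible
#'   to one) with per-cell `labels` when a prior is used.
#' @param M a `prior_similarity` matrix, or NULL for the neutral (all-ones)
#'   prior.
#' @param k neighbors per direction (clamped with a warning if too large).
#' @param approx use the candidate-pool two-stage search.
#' @param pool_factor candidate pool size multiplier for approximate mode.
#' @return a `mnn_matches` data.frame: `i` (cell in A), `j` (cell in B),
#'   `dist` (raw), `wdist` (weighted).
#' @export
prior_weighted_mnn <- function(A, B, M = NULL, k = 30L, approx = FALSE,
                               pool_factor = 5L) {
  A <- .as_panorama(A); B <- .as_panorama(B)
  nA <- nrow(A$coords); nB <- nrow(B$coords)
  if (k > min(nA, nB)) {
    .warnf("prior_weighted_mnn: k = %d clamped to %d", k, min(nA, nB))
    k <- min(nA, nB)
  }
  d <- pairwise_dist(A$coords, B$coords)
  w <- if (is.null(M)) d else {
    if (is.null(A$labels) || is.null(B$labels)) {
      .stopf("prior_weighted_mnn: labels required when a prior matrix is given")
    }
    d / prior_lookup(M, A$labels, B$labels)
  }
  nn_of <- function(dist_raw, dist_w, kk) {
    # row-wise k nearest under the weighted distance, optionally restricted
    # to a raw-distance candidate pool
    n <- nrow(dist_raw)
    out <- matrix(0L, n, kk)
    for (r in seq_len(n)) {
      if (approx) {
        pool <- order(dist_raw[r, ])[seq_len(min(pool_factor * kk, ncol(dist_raw)))]
        out[r, ] <- pool[order(dist_w[r, pool])[seq_len(kk)]]
      } else {
        out[r, ] <- order(dist_w[r, ])[seq_len(kk)]
      }
    }
    out
  }
  nnA <- nn_of(d, w, k)            # for each A cell: k B-neighbors
  nnB <- nn_of(t(d), t(w), k)      # for each B cell: k A-neighbors
  inB <- matrix(FALSE, nA, nB)
  inB[cbind(rep(seq_len(nA), k), as.vector(nnA))] <- TRUE
  inA <- matrix(FALSE, nB, nA)
  inA[cbind(rep(seq_len(nB), k), as.vector(nnB))] <- TRUE
  mutual <- inB & t(inA)
  idx <- which(mutual, arr.ind = TRUE)
  res <- data.frame(i = idx[, 1], j = idx[, 2],
                    dist = d[idx], wdist = w[idx])
  res <- res[order(res$i, res$j), , drop = FALSE]
  rownames(res) <- NULL
  class(res) <- c("mnn_matches", "data.frame")
  res
}

#' Pairwise batch alignment scores
#'
#' For each pair of batches, the fraction of cells of the smaller batch
#' participating in at least one mutual match — the quantity that orders the
#' greedy panorama assembly.
#' @param embeddings list of `panorama_embedding`.
#' @param M prior matrix or NULL.
#' @param k neighbors per direction.
#' @param approx,pool_factor passed to [prior_weighted_mnn()].
#' @return symmetric matrix of scores in \[0, 1\].
#' @export
alignment_scores <- function(embeddings, M = NULL, k = 30L, approx = FALSE,
                             pool_factor = 5L) {
  nb <- length(embeddings)
  if (nb < 2) .stopf("alignment_scores: need >= 2 batches")
  s <- matrix(0, nb, nb)
  for (a in seq_len(nb - 1)) {
    for (b in (a + 1):nb) {
      m <- prior_weighted_mnn(embeddings[[a]], embeddings[[b]], M, k = k,
                              approx = approx, pool_factor = pool_factor)
      nA <- nrow(embeddings[[a]]$coords); nB <- nrow(embeddings[[b]]$coords)
      small <- min(nA, nB)
      part <- if (nA <= nB) length(unique(m$i)) else length(unique(m$j))
      s[a, b] <- s[b, a] <- part / small
    }
  }
  s
}

#' Per-type centroid table
#' @param coords cells x d matrix.
#' @param labels per-cell labels.
#' @return list: `centroids` (types x d), `counts`.
#' @export
centroid_table <- function(coords, labels) {
  labels <- as.character(labels)
  types <- sort(unique(labels))
  cent <- do.call(rbind, lapply(types, function(tp) {
    colMeans(coords[labels == tp, , drop = FALSE])
  }))
  rownames(cent) <- types
  list(centroids = cent, counts = as.integer(table(labels)[types]))
}

#' Displacement field for a batch from its mutual matches
#'
#' For every matched pair (i in A, j in B) the pair displacement is the base
#' bias `v_j - v_i` plus the group-cohesion correction
#' `M_IJ * (v_i - v_I - v_j + v_J)` built from the type centroids, so that
#' cells of well-agreeing types keep their relative position within the
#' target cluster. Per-cell displacements are Gaussian-kernel smoothings of
#' the matched cells' pair biases (`exp(-dist^2 / sigma)` weights); cells
#' with no match receive the displacement of expression-similar cells of the
#' same label (top `n_share` matched same-label cells, inverse-distance
#' weighted), falling back to the global smoothing when their label has no
#' matched cells.
#'
#' @param matches `mnn_matches` from [prior_weighted_mnn()].
#' @param A,B `panorama_embedding` objects.
#' @param centroids optional list with `A`, `B` centroid tables (computed
#'   from coords/labels when NULL).
#' @param M prior matrix (or plain labeled matrix), or NULL to drop the
#'   correction term (pair bias reduces to `v_j - v_i`).
#' @param sigma Gaussian smoothing kernel width (default 15, matched to the
#'   `U * s` coordinate scale of [reduce_dimensions()]).
#' @param n_share same-label cells sharing displacement with unmatched cells.
#' @return list: `displacement` (n_A x d), `pair_bias` (one row per match),
#'   `matched` (logical per A cell).
#' @export
compute_bias <- function(matches, A, B, centroids = NULL, M = NULL,
                         sigma = 15, n_share = 10L) {
  A <- .as_panorama(A); B <- .as_panorama(B)
  nA <- nrow(A$coords); d <- ncol(A$coords)
  if (nrow(matches) == 0) {
    .warnf("compute_bias: empty match set; zero displacement")
    return(list(displacement = matrix(0, nA, d),
                pair_bias = matrix(0, 0, d), matched = rep(FALSE, nA)))
  }
  vi <- A$coords[matches$i, , drop = FALSE]
  vj <- B$coords[matches$j, , drop = FALSE]
  pair_bias <- vj - vi
  if (!is.null(M)) {
    if (is.null(A$labels) || is.null(B$labels)) {
      .stopf("compute_bias: labels required when a prior matrix is given")
    }
    if (is.null(centroids)) {
      centroids <- list(A = centroid_table(A$coords, A$labels),
                        B = centroid_table(B$coords, B$labels))
    }
    li <- A$labels[matches$i]; lj <- B$labels[matches$j]
    vI <- centroids$A$centroids[li, , drop = FALSE]
    vJ <- centroids$B$centroids[lj, , drop = FALSE]
    mij <- if (inherits(M, "prior_similarity")) {
      .prior_lookup_pairs(M, li, lj)
    } else {
      M[cbind(match(li, rownames(M)), match(lj, colnames(M)))]
    }
    pair_bias <- pair_bias + mij * (vi - vI - vj + vJ)
  }
  dimnames(pair_bias) <- NULL
  # one bias per matched A cell (mean over its pairs)
  anchor_ids <- sort(unique(matches$i))
  anchor_bias <- rowsum(pair_bias, group = matches$i) /
    as.vector(table(matches$i)[as.character(anchor_ids)])
  anchor_coords <- A$coords[anchor_ids, , drop = FALSE]

  disp <- matrix(0, nA, d)
  d2 <- pairwise_sqdist(A$coords, anchor_coords)
  wts <- exp(-d2 / sigma)
  wsum <- rowSums(wts)
  ok <- wsum > 0
  disp[ok, ] <- (wts[ok, , drop = FALSE] %*% anchor_bias) / wsum[ok]

  matched <- seq_len(nA) %in% anchor_ids
  if (!is.null(A$labels) && any(!matched)) {
    anchor_lab <- A$labels[anchor_ids]
    for (c_id in which(!matched)) {
      same <- which(anchor_lab == A$labels[c_id])
      if (length(same) == 0) next   # keep global smoothing fallback
      dd <- sqrt(d2[c_id, same])
      top <- order(dd)[seq_len(min(n_share, length(same)))]
      w <- 1 / (dd[top] + 1e-8)
      share <- disp[anchor_ids[same[top]], , drop = FALSE]
      disp[c_id, ] <- colSums(share * w) / sum(w)
    }
  }
  list(displacement = disp, pair_bias = pair_bias, matched = matched)
}

#' Prior-informed panorama integration of multiple batches
#'
#' Greedy panorama assembly: batch pairs are processed in descending
#' alignment-score order; whenever a pair connects two panoramas, the
#' smaller panorama is shifted onto the larger by the displacement field of
#' its prior-weighted mutual matches. With `M = NULL` the same code path
#' runs under the neutral all-ones prior (unweighted distances, full
#' group-cohesion coefficient), which is the package's no-prior baseline.
#'
#' @param datasets list of `cell_dataset` (reduced via
#'   [reduce_dimensions()]) or list of `panorama_embedding`.
#' @param M `prior_similarity` matrix or NULL.
#' @param k mutual-neighbor count (default 30).
#' @param sigma smoothing kernel width.
#' @param approx,pool_factor passed to [prior_weighted_mnn()].
#' @param d reduction dimension when raw datasets are given.
#' @param seed seed for the reduction.
#' @param labels optional list of per-batch label vectors overriding the
#'   embeddings' labels.
#' @return list: `coords` (all cells, input order), `batch`, `labels`,
#'   `embeddings` (per batch, corrected), `merge_log`.
#' @export
integrate_batches <- function(datasets, M = NULL, k = 30L, sigma = 15,
                              approx = FALSE, pool_factor = 5L, d = 100L,
                              seed = 0L, labels = NULL) {
  embs <- if (all(vapply(datasets, inherits, TRUE, "panorama_embedding"))) {
    datasets
  } else {
    reduce_dimensions(datasets, d = d, seed = seed)
  }
  if (!is.null(labels)) {
    for (i in seq_along(embs)) embs[[i]]$labels <- as.character(labels[[i]])
  }
  nb <- length(embs)
  if (nb < 2) .stopf("integrate_batches: need >= 2 batches")
  # The module's no-prior code path is the neutral all-ones prior: identical
  # matches (d / 1) and full group-cohesion coefficient. A label-free run
  # (embeddings without labels) additionally drops the cohesion term.
  if (is.null(M)) {
    labs <- unique(unlist(lapply(embs, `[[`, "labels")))
    if (length(labs)) M <- neutral_prior(labs)
  }
  scores <- alignment_scores(embs, M, k = k, approx = approx,
                             pool_factor = pool_factor)
  prs <- which(upper.tri(scores), arr.ind = TRUE)
  ord <- order(scores[prs], decreasing = TRUE)
  prs <- prs[ord, , drop = FALSE]
  uf <- .uf_new(nb)
  coords <- lapply(embs, `[[`, "coords")
  sizes <- vapply(coords, nrow, 1L)
  merge_log <- character(0)
  merged_any <- rep(FALSE, nb)
  for (r in seq_len(nrow(prs))) {
    a <- prs[r, 1]; b <- prs[r, 2]
    if (scores[a, b] <= 0) next
    ra <- .uf_find(uf, a); rb <- .uf_find(uf, b)
    if (ra == rb) next
    mem_a <- which(vapply(seq_len(nb), function(i) .uf_find(uf, i) == ra, TRUE))
    mem_b <- which(vapply(seq_len(nb), function(i) .uf_find(uf, i) == rb, TRUE))
    # incoming = smaller panorama (by cell count), shifted onto the reference
    if (sum(sizes[mem_a]) <= sum(sizes[mem_b])) {
      inc <- mem_a; ref <- mem_b
    } else {
      inc <- mem_b; ref <- mem_a
    }
    pano <- function(members) {
      structure(list(coords = do.call(rbind, coords[members]),
                     batch = unlist(lapply(embs[members], `[[`, "batch")),
                     labels = if (all(vapply(embs[members], function(e) !is.null(e$labels), TRUE)))
                       unlist(lapply(embs[members], `[[`, "labels"))),
                class = "panorama_embedding")
    }
    Ain <- pano(inc); Bref <- pano(ref)
    mm <- prior_weighted_mnn(Ain, Bref, M, k = k, approx = approx,
                             pool_factor = pool_factor)
    cb <- compute_bias(mm, Ain, Bref, M = M, sigma = sigma)
    shifted <- Ain$coords + cb$displacement
    offs <- 0L
    for (m_i in inc) {
      coords[[m_i]] <- shifted[(offs + 1L):(offs + sizes[m_i]), , drop = FALSE]
      offs <- offs + sizes[m_i]
    }
    uf <- .uf_union(uf, ra, rb)
    merged_any[c(inc, ref)] <- TRUE
    merge_log <- c(merge_log, sprintf(
      "merged panorama {%s} into {%s} (score %.3f, %d matches)",
      paste(inc, collapse = ","), paste(ref, collapse = ","),
      scores[a, b], nrow(mm)))
  }
  if (any(!merged_any)) {
    .warnf("integrate_batches: batch(es) %s had no positive alignment; left uncorrected",
           paste(which(!merged_any), collapse = ", "))
  }
  out_embs <- lapply(seq_len(nb), function(i) {
    e <- embs[[i]]; e$coords <- coords[[i]]; e
  })
  list(coords = do.call(rbind, coords),
       batch = unlist(lapply(embs, `[[`, "batch")),
       labels = if (all(vapply(embs, function(e) !is.null(e$labels), TRUE)))
         unlist(lapply(embs, `[[`, "labels")),
       embeddings = out_embs, merge_log = merge_log,
       alignment = scores)
}
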