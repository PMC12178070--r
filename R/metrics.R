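#' KMeans Adjusted Rand Index
#'
#' KMeans with k equal to the number of ground-truth types (seeded,
#' multi-restart), scored by the adjusted Rand index of the clustering
#' against the labels and truncated at 0 (chance-level or worse scores 0).
#' @param embedding cells x d matrix.
#' @param true_labels per-cell labels (>= 2 distinct).
#' @param seed RNG seed.
#' @param nstart kmeans restarts.
#' @return score in \[0, 1\].
#' @export
kmeans_ari <- function(embedding, true_labels, seed = 0L, nstart = 10L) {
  embedding <- as.matrix(embedding)
  k <- length(unique(true_labels))
  if (k < 2) .stopf("kmeans_ari: need >= 2 true labels")
  if (nrow(embedding) < k) .stopf("kmeans_ari: fewer cells than clusters")
  set.seed(seed)
  km <- stats::kmeans(embedding, centers = k, nstart = nstart, iter.max = 100)
  max(0, mclust::adjustedRandIndex(km$cluster, true_labels))
}

#' Silhouette score on labels
#'
#' Mean silhouette coefficient of the labeling, mapped from \[-1, 1\] to
#' \[0, 1\] via `(s + 1) / 2`. Cells in singleton classes contribute 0 width
#' (the `cluster` package convention).
#' @param embedding cells x d matrix.
#' @param true_labels per-cell labels (>= 2 distinct).
#' @return score in \[0, 1\].
#' @export
silhouette_label <- function(embedding, true_labels) {
  f <- factor(true_labels)
  if (nlevels(f) < 2) .stopf("silhouette_label: need >= 2 labels")
  s <- cluster::silhouette(as.integer(f), stats::dist(as.matrix(embedding)))
  (mean(s[, 3]) + 1) / 2
}

#' Integration Local Inverse Simpson's Index (iLISI)
#'
#' Per cell, the inverse Simpson index of the batch composition among its k
#' nearest neighbors, with Gaussian distance weights (bandwidth the cell's
#' mean neighbor distance), averaged over cells and rescaled to \[0, 1\] by
#' `(LISI - 1) / (B - 1)` for B batches. 1 means neighborhoods reproduce a
#' perfect batch mixture, 0 means single-batch neighborhoods. A single
#' batch scores 1 by convention.
#' @param embedding cells x d matrix.
#' @param batch_ids per-cell batch labels.
#' @param k neighborhood size (default 90, clamped to n - 1).
#' @return score in \[0, 1\].
#' @export
ilisi <- function(embedding, batch_ids, k = 90L) {
  embedding <- as.matrix(embedding)
  b <- as.character(batch_ids)
  B <- length(unique(b))
  if (B == 1) return(1)
  n <- nrow(embedding)
  k <- min(k, n - 1L)
  d2 <- pairwise_sqdist(embedding, embedding)
  diag(d2) <- Inf
  nn <- .knn_from_dist(d2, k)
  lisi <- numeric(n)
  for (i in seq_len(n)) {
    dd <- sqrt(d2[i, nn[i, ]])
    sig <- mean(dd)
    w <- if (sig > 0) exp(-dd^2 / (2 * sig^2)) else rep(1, length(dd))
    w <- w / sum(w)
    p <- tapply(w, b[nn[i, ]], sum)
    lisi[i] <- 1 / sum(p^2)
  }
  score <- (mean(lisi) - 1) / (B - 1)
  min(1, max(0, score))
}

#' kBET-style acceptance rate
#'
#' For a sample of cells, a chi-squared test compares the batch composition
#' of the cell's k-neighborhood with the global batch proportions; the
#' score is the fraction of tests not rejected at `alpha`. Neighborhoods
#' whose expected counts fall below 5 are skipped (recorded in the
#' `n_skipped` attribute). A single batch scores 1.
#' @param embedding cells x d matrix.
#' @param batch_ids per-cell batch labels.
#' @param k neighborhood size.
#' @param n_samples cells sampled for testing.
#' @param seed sampling seed.
#' @param alpha rejection level.
#' @return acceptance rate in \[0, 1\].
#' @export
kbet_acceptance <- function(embedding, batch_ids, k = 50L, n_samples = 200L,
                            seed = 0L, alpha = 0.05) {
  embedding <- as.matrix(embedding)
  b <- factor(batch_ids)
  B <- nlevels(b)
  if (B == 1) return(1)
  n <- nrow(embedding)
  k <- min(k, n - 1L)
  glob <- as.numeric(table(b)) / n
  if (any(k * glob < 5)) {
    k <- min(n - 1L, ceiling(5 / min(glob)))
  }
  set.seed(seed)
  idx <- if (n <= n_samples) seq_len(n) else sort(sample.int(n, n_samples))
  d2 <- pairwise_sqdist(embedding[idx, , drop = FALSE], embedding)
  d2[cbind(seq_along(idx), idx)] <- Inf
  accept <- 0L; tested <- 0L; skipped <- 0L
  for (r in seq_along(idx)) {
    nb <- order(d2[r, ])[seq_len(k)]
    obs <- as.numeric(table(b[nb]))
    expd <- k * glob
    if (any(expd < 5)) { skipped <- skipped + 1L; next }
    stat <- sum((obs - expd)^2 / expd)
    p <- stats::pchisq(stat, df = B - 1, lower.tail = FALSE)
    tested <- tested + 1L
    if (p > alpha) accept <- accept + 1L
  }
  if (tested == 0) {
    .warnf("kbet_acceptance: no testable neighborhoods (expected counts < 5)")
    return(NA_real_)
  }
  structure(accept / tested, n_skipped = skipped)
}

#' Aggregate integration metrics
#'
#' `batch_score = mean(ilisi, kbet)`, `bio_score = mean(kmeans_ari,
#' silhouette)`, `overall = 0.4 * batch_score + 0.6 * bio_score` — the
#' benchmark convention weighting biological conservation above batch
#' removal.
#' @param kmeans_ari,silhouette_label,ilisi,kbet_acceptance component scores
#'   in \[0, 1\].
#' @param params optional list of parameters to record.
#' @return a `metrics_report` (list with components, `batch_score`,
#'   `bio_score`, `overall`).
#' @export
aggregate_metrics <- function(kmeans_ari, silhouette_label, ilisi,
                              kbet_acceptance, params = list()) {
  batch <- mean(c(ilisi, kbet_acceptance))
  bio <- mean(c(kmeans_ari, silhouette_label))
  structure(list(kmeans_ari = as.numeric(kmeans_ari),
                 silhouette_label = as.numeric(silhouette_label),
                 ilisi = as.numeric(ilisi),
                 kbet_acceptance = as.numeric(kbet_acceptance),
                 batch_score = batch, bio_score = bio,
                 overall = 0.4 * batch + 0.6 * bio, params = params),
            class = "metrics_report")
}

#' @exportS3Method base::print
print.metrics_report <- function(x, ...) {
  cat(sprintf(paste0("metrics_report: kmeans_ari=%.3f silhouette=%.3f ",
                     "ilisi=%.3f kbet=%.3f | batch=%.3f bio=%.3f overall=%.3f\n"),
              x$kmeans_ari, x$silhouette_label, x$ilisi, x$kbet_acceptance,
              x$batch_score, x$bio_score, x$overall))
  invisible(x)
}

#' Benchmark one embedding
#'
#' Computes all four component metrics and their aggregate for an embedding
#' with per-cell type and batch labels.
#' @param embedding cells x d matrix.
#' @param labels per-cell type labels.
#' @param batch per-cell batch ids.
#' @param k_ilisi,k_kbet neighborhood sizes.
#' @param n_samples kBET sample size.
#' @param seed RNG seed.
#' @return a `metrics_report`.
#' @export
benchmark_embedding <- function(embedding, labels, batch, k_ilisi = 90L,
                                k_kbet = 50L, n_samples = 200L, seed = 0L) {
  aggregate_metrics(
    kmeans_ari = kmeans_ari(embedding, labels, seed = seed),
    silhouette_label = silhouette_label(embedding, labels),
    ilisi = ilisi(embedding, batch, k = k_ilisi),
    kbet_acceptance = as.numeric(kbet_acceptance(embedding, batch, k = k_kbet,
                                                 n_samples = n_samples,
                                                 seed = seed)),
    params = list(k_ilisi = k_ilisi, k_kbet = k_kbet, n_samples = n_samples,
                  seed = seed))
}
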