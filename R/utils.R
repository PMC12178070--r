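# Internal numerical helpers shared across modules.

# Normalize a label for keying: trim, collapse whitespace, lowercase.
# Original casing is kept separately for display.
.norm_label <- function(x) {
  tolower(gsub("[[:space:]]+", " ", trimws(as.character(x))))
}

# Squared Euclidean distances between rows of a and rows of b.
pairwise_sqdist <- function(a, b) {
  a <- as.matrix(a)
  b <- as.matrix(b)
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
  d2[d2 < 0] <- 0
  d2
}

pairwise_dist <- function(a, b) sqrt(pairwise_sqdist(a, b))

# Row indices of the k smallest entries per row of a distance matrix.
# Returns an n x k integer matrix.
.knn_from_dist <- function(d, k) {
  k <- min(k, ncol(d))
  t(apply(d, 1L, function(r) order(r)[seq_len(k)]))
}

# Minimal union-find over 1..n.
.uf_new <- function(n) seq_len(n)
.uf_find <- function(uf, i) {
  while (uf[i] != i) i <- uf[i]
  i
}
.uf_union <- function(uf, i, j) {
  ri <- .uf_find(uf, i)
  rj <- .uf_find(uf, j)
  if (ri != rj) uf[ri] <- rj
  uf
}

# L2-normalize matrix rows; zero rows stay zero.
.l2_normalize_rows <- function(x) {
  n <- sqrt(rowSums(x^2))
  n[n == 0] <- 1
  x / n
}

.stopf <- function(...) stop(sprintf(...), call. = FALSE)
.warnf <- function(...) warning(sprintf(...), call. = FALSE)
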