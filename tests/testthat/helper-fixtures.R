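# Shared fixtures, built in code at test time.

# Gaussian blobs: n_per cells around each center row; returns coords + labels.
make_blobs <- function(n_per, centers, sd = 0.1, seed = 1) {
  set.seed(seed)
  centers <- as.matrix(centers)
  k <- nrow(centers)
  coords <- do.call(rbind, lapply(seq_len(k), function(i) {
    matrix(stats::rnorm(n_per * ncol(centers), sd = sd), n_per) +
      matrix(centers[i, ], n_per, ncol(centers), byrow = TRUE)
  }))
  list(coords = coords, labels = rep(rownames(centers) %||%
                                       paste0("type", seq_len(k)), each = n_per))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# A tiny embedding provider with hand-set unit vectors, for forcing exact
# cosine values in tests.
fixed_provider <- function(vectors) {
  structure(list(
    id = "fixed", dim = ncol(vectors),
    embed = function(labels) {
      out <- vectors[labels, , drop = FALSE]
      rownames(out) <- labels
      out
    }), class = "embedding_provider")
}

# Prior-similarity matrix with explicit entries (bypassing embeddings).
manual_prior <- function(m, floor = 0.05) {
  structure(m, keys = tolower(rownames(m)), floor = floor,
            class = c("prior_similarity", "matrix"))
}

# Small default simulation shared by several tests.
small_batches <- function(n_batches = 3, cells = 150, genes = 120, seed = 7,
                          ...) {
  generate_batches(sim_config(n_batches = n_batches, cells_per_batch = cells,
                              n_genes = genes, seed = seed, ...))
}
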