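test_that("shared reduction captures the dense-SVD variance and respects duplication", {
  set.seed(6)
  x <- matrix(stats::rnorm(200 * 50, mean = 2), 200, 50)
  x[x < 0] <- 0
  colnames(x) <- paste0("G", 1:50)
  emb <- reduce_dimensions(list(x), d = 10)
  # oracle: eigenvalues of the Gram matrix of the row-normalized data
  xn <- x / sqrt(rowSums(x^2))
  ev <- eigen(crossprod(xn), symmetric = TRUE, only.values = TRUE)$values
  expect_equal(sum(emb[[1]]$coords^2), sum(ev[1:10]), tolerance = 0.01)

  # duplicated dataset: duplicate rows land on identical coordinates
  emb2 <- reduce_dimensions(list(x, x), d = 10)
  expect_equal(emb2[[1]]$coords, emb2[[2]]$coords, tolerance = 1e-8)

  # determinism
  emb3 <- reduce_dimensions(list(x), d = 10)
  expect_identical(emb[[1]]$coords, emb3[[1]]$coords)

  colnames(x) <- paste0("H", 1:50)
  expect_error(reduce_dimensions(list(x, matrix(1, 2, 3))), "gene intersection")
})

test_that("weighted MNN matches the hand-computed toy case", {
  # d(a1,b1) = 1 with same label (M = 1); d(a1,b2) = 0.8 with M = 0.5 so the
  # weighted distance 1.6 loses despite being closer in expression
  A <- structure(list(coords = matrix(0), batch = "A", labels = "x"),
                 class = "panorama_embedding")
  B <- structure(list(coords = matrix(c(1, -0.8), 2), batch = c("B", "B"),
                      labels = c("x", "y")),
                 class = "panorama_embedding")
  M <- manual_prior(matrix(c(1, 0.5, 0.5, 1), 2,
                           dimnames = list(c("x", "y"), c("x", "y"))))
  m <- suppressWarnings(prior_weighted_mnn(A, B, M, k = 1))
  expect_equal(m$i, 1)
  expect_equal(m$j, 1)
  expect_equal(m$dist, 1)
  expect_equal(m$wdist, 1)
})

test_that("an all-ones prior reproduces the unweighted match set", {
  b <- make_blobs(40, centers = rbind(c(0, 0), c(4, 0)), sd = 0.5, seed = 2)
  A <- structure(list(coords = b$coords, batch = "A", labels = b$labels),
                 class = "panorama_embedding")
  b2 <- make_blobs(40, centers = rbind(c(0.5, 0), c(4.5, 0)), sd = 0.5, seed = 3)
  B <- structure(list(coords = b2$coords, batch = "B", labels = b2$labels),
                 class = "panorama_embedding")
  M1 <- neutral_prior(c("type1", "type2"))
  m_prior <- prior_weighted_mnn(A, B, M1, k = 10)
  m_plain <- prior_weighted_mnn(A, B, NULL, k = 10)
  expect_identical(m_prior[, c("i", "j")], m_plain[, c("i", "j")])
  expect_equal(m_prior$wdist, m_plain$dist)
})

test_that("lowering a label pair's similarity never increases its match count", {
  b <- make_blobs(50, centers = rbind(c(0, 0), c(2, 0)), sd = 0.8, seed = 5)
  A <- structure(list(coords = b$coords, batch = "A", labels = b$labels),
                 class = "panorama_embedding")
  b2 <- make_blobs(50, centers = rbind(c(0.3, 0.3), c(2.3, 0.3)), sd = 0.8,
                   seed = 6)
  B <- structure(list(coords = b2$coords, batch = "B", labels = b2$labels),
                 class = "panorama_embedding")
  cross <- function(mval) {
    M <- manual_prior(matrix(c(1, mval, mval, 1), 2,
                             dimnames = list(c("type1", "type2"),
                                             c("type1", "type2"))))
    m <- prior_weighted_mnn(A, B, M, k = 15)
    sum(A$labels[m$i] != B$labels[m$j])
  }
  counts <- vapply(c(1, 0.7, 0.5, 0.3, 0.1), cross, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("approximate candidate-pool search recovers the exact match set", {
  ds <- small_batches(n_batches = 2, cells = 250, genes = 100, seed = 13)
  emb <- reduce_dimensions(ds, d = 20)
  M <- build_prior_matrix(embed_labels(unique(ds[[1]]$label_true)))
  exact <- prior_weighted_mnn(emb[[1]], emb[[2]], M, k = 10)
  approx <- prior_weighted_mnn(emb[[1]], emb[[2]], M, k = 10, approx = TRUE,
                               pool_factor = 5)
  key <- function(m) paste(m$i, m$j)
  overlap <- length(intersect(key(exact), key(approx))) /
    max(length(key(exact)), length(key(approx)))
  expect_gte(overlap, 0.95)
})

test_that("alignment scores are symmetric, 1 for duplicates, low for disjoint types", {
  ds <- small_batches(n_batches = 2, cells = 120, genes = 100, seed = 19)
  emb <- reduce_dimensions(list(ds[[1]], ds[[1]]), d = 15)
  s <- alignment_scores(emb, NULL, k = 10)
  expect_equal(s[1, 2], 1)
  expect_identical(s, t(s))

  # disjoint label sets at floor similarity, far apart in the embedding
  bA <- make_blobs(50, centers = rbind(c(0, 0), c(3, 0)), sd = 0.5, seed = 3)
  bB <- make_blobs(50, centers = rbind(c(20, 20), c(23, 20)), sd = 0.5, seed = 4)
  embd <- list(
    structure(list(coords = bA$coords, batch = "A",
                   labels = c("t1", "t2")[match(bA$labels, c("type1", "type2"))]),
              class = "panorama_embedding"),
    structure(list(coords = bB$coords, batch = "B",
                   labels = c("t3", "t4")[match(bB$labels, c("type1", "type2"))]),
              class = "panorama_embedding"))
  Mf <- manual_prior(matrix(c(1, .05, .05, .05,
                              .05, 1, .05, .05,
                              .05, .05, 1, .05,
                              .05, .05, .05, 1), 4,
                            dimnames = list(c("t1", "t2", "t3", "t4"),
                                            c("t1", "t2", "t3", "t4"))))
  sd2 <- alignment_scores(embd, Mf, k = 5)
  expect_lt(sd2[1, 2], 0.3)
})

test_that("pair bias evaluates the centroid-correction equation exactly", {
  # 1-D toy: v_i = 2 (centroid v_I = 1), v_j = 5 (centroid v_J = 3), M = 0.5
  A <- structure(list(coords = matrix(c(2, 0)), batch = c("A", "A"),
                      labels = c("I", "I")), class = "panorama_embedding")
  B <- structure(list(coords = matrix(c(5, 1)), batch = c("B", "B"),
                      labels = c("J", "J")), class = "panorama_embedding")
  M <- manual_prior(matrix(c(1, 0.5, 0.5, 1), 2,
                           dimnames = list(c("I", "J"), c("I", "J"))))
  matches <- structure(data.frame(i = 1L, j = 1L, dist = 3, wdist = 6),
                       class = c("mnn_matches", "data.frame"))
  cb <- compute_bias(matches, A, B, M = M, sigma = 15)
  expect_equal(as.numeric(cb$pair_bias), 3 + 0.5 * (2 - 1 - 5 + 3))

  # algebraic cancellation: cells sitting on their centroids get the raw bias
  A2 <- structure(list(coords = matrix(2), batch = "A", labels = "I"),
                  class = "panorama_embedding")
  B2 <- structure(list(coords = matrix(5), batch = "B", labels = "J"),
                  class = "panorama_embedding")
  cb2 <- compute_bias(matches, A2, B2, M = M, sigma = 15)
  expect_equal(as.numeric(cb2$pair_bias), 3)

  # an all-zero similarity removes the correction term entirely
  Mz <- matrix(0, 2, 2, dimnames = list(c("I", "J"), c("I", "J")))
  cbz <- compute_bias(matches, A, B, M = Mz, sigma = 15)
  cb0 <- compute_bias(matches, A, B, M = NULL, sigma = 15)
  expect_identical(cbz$pair_bias, cb0$pair_bias)
  expect_identical(cbz$displacement, cb0$displacement)

  # empty match set: zero displacement with a warning
  empty <- structure(data.frame(i = integer(0), j = integer(0),
                                dist = numeric(0), wdist = numeric(0)),
                     class = c("mnn_matches", "data.frame"))
  expect_warning(cbe <- compute_bias(empty, A, B, M = NULL), "empty")
  expect_true(all(cbe$displacement == 0))
})

test_that("the neutral prior and the no-prior code path integrate identically", {
  ds <- small_batches(n_batches = 3, cells = 100, genes = 100, seed = 41)
  labs <- unique(unlist(lapply(ds, `[[`, "label_true")))
  res_ones <- integrate_batches(ds, M = neutral_prior(labs), k = 10, d = 20)
  res_null <- integrate_batches(ds, M = NULL, k = 10, d = 20)
  expect_lt(max(abs(res_ones$coords - res_null$coords)), 1e-6)
})

test_that("integration pulls same-type cross-batch centroids together", {
  ds <- small_batches(n_batches = 3, cells = 150, genes = 120, seed = 7,
                      batch_effect_sd = 0.5)
  emb <- reduce_dimensions(ds, d = 30)
  M <- build_prior_matrix(embed_labels(unique(ds[[1]]$label_true)))
  res <- integrate_batches(emb, M = M, k = 10)
  centroid_gaps <- function(coords_list) {
    out <- numeric(0)
    for (a in 1:2) for (b in (a + 1):3) {
      ca <- centroid_table(coords_list[[a]], ds[[a]]$label_true)
      cb <- centroid_table(coords_list[[b]], ds[[b]]$label_true)
      shared <- intersect(rownames(ca$centroids), rownames(cb$centroids))
      out <- c(out, sqrt(rowSums((ca$centroids[shared, , drop = FALSE] -
                                    cb$centroids[shared, , drop = FALSE])^2)))
    }
    out
  }
  pre <- centroid_gaps(lapply(emb, `[[`, "coords"))
  post <- centroid_gaps(lapply(res$embeddings, `[[`, "coords"))
  expect_gte(mean(post < pre), 0.9)
})

test_that("integration is equivariant to permuting cells within a batch", {
  ds <- small_batches(n_batches = 2, cells = 80, genes = 100, seed = 51)
  emb <- reduce_dimensions(ds, d = 15)
  M <- build_prior_matrix(embed_labels(unique(ds[[1]]$label_true)))
  res <- integrate_batches(emb, M = M, k = 8)
  set.seed(9)
  perm <- sample(80)
  emb_p <- emb
  emb_p[[2]]$coords <- emb[[2]]$coords[perm, , drop = FALSE]
  emb_p[[2]]$labels <- emb[[2]]$labels[perm]
  emb_p[[2]]$batch <- emb[[2]]$batch[perm]
  res_p <- integrate_batches(emb_p, M = M, k = 8)
  expect_equal(res_p$embeddings[[2]]$coords,
               res$embeddings[[2]]$coords[perm, , drop = FALSE],
               tolerance = 1e-9)
  expect_equal(res_p$embeddings[[1]]$coords, res$embeddings[[1]]$coords,
               tolerance = 1e-9)
})

test_that("high-similarity aliases barely move the corrected embedding", {
  ds <- small_batches(n_batches = 3, cells = 120, genes = 100, seed = 61)
  emb <- reduce_dimensions(ds, d = 20)
  types <- unique(unlist(lapply(ds, `[[`, "label_true")))
  aliases <- stats::setNames(paste0(types, "s"), types)   # plural variants
  # precondition: the aliases really are near-synonymous to the provider
  sims <- vapply(types, function(tp) label_cosine(tp, aliases[tp]), numeric(1))
  expect_true(all(sims >= 0.8))

  run <- function(embs) {
    labs <- unique(unlist(lapply(embs, `[[`, "labels")))
    M <- build_prior_matrix(embed_labels(labs))
    integrate_batches(embs, M = M, k = 10)$coords
  }
  clean <- run(emb)
  emb_alias <- emb
  emb_alias[[2]]$labels <- unname(aliases[emb[[2]]$labels])
  aliased <- run(emb_alias)
  scale <- mean(sqrt(rowSums((clean - do.call(rbind, lapply(emb, `[[`, "coords")))^2)))
  drift <- mean(sqrt(rowSums((aliased - clean)^2)))
  expect_lt(drift, 0.05 * max(scale, 1e-12) + 0.05)
})

test_that("mislabeled cells land between clusters under biased corruption", {
  # one type's cells in one batch mislabeled as another existing type
  ds <- small_batches(n_batches = 2, cells = 200, genes = 120, seed = 71,
                      batch_effect_sd = 0.4)
  emb <- reduce_dimensions(ds, d = 20)
  lab2 <- emb[[2]]$labels
  mis <- lab2 == "alpha cell"
  lab2[mis] <- "beta cell"
  emb[[2]]$labels <- lab2
  M <- build_prior_matrix(embed_labels(unique(c(emb[[1]]$labels, lab2))))
  res <- integrate_batches(emb, M = M, k = 15)
  co2 <- res$embeddings[[2]]$coords
  ref <- res$embeddings[[1]]$coords
  cents <- centroid_table(ref, emb[[1]]$labels)$centroids
  dist_to <- function(cells, type) {
    sqrt(rowSums((cells - matrix(cents[type, ], nrow(cells), ncol(cents),
                                 byrow = TRUE))^2))
  }
  mindist <- pmin(dist_to(co2, "alpha cell"), dist_to(co2, "beta cell"))
  ok_alpha <- ds[[2]]$label_true == "alpha cell" & !mis
  expect_gt(mean(mindist[mis]),
            mean(pmin(dist_to(co2[ds[[2]]$label_true == "beta cell", , drop = FALSE], "alpha cell"),
                      dist_to(co2[ds[[2]]$label_true == "beta cell", , drop = FALSE], "beta cell"))))
})
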