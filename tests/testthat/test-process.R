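# Toy dataset where cell i expresses exactly n_i distinct genes once.
qc_toy <- function(genes_detected, n_genes = 1200) {
  counts <- matrix(0, length(genes_detected), n_genes)
  for (i in seq_along(genes_detected)) counts[i, seq_len(genes_detected[i])] <- 1
  cell_dataset(counts, batch = "b1")
}

test_that("gene-count filter keeps boundary cells and skips null rules", {
  ds <- qc_toy(c(100, 300, 400, 50, 1000))
  cfg <- processing_config(min_genes_per_cell = 300, min_cells_per_gene = 0)
  res <- apply_qc_filters(ds, cfg)
  expect_equal(res$report$n_cells_out, 3L)          # 300 kept (>= rule)
  expect_equal(res$report$removed_min_genes, 2L)

  # a high mito fraction is ignored while the threshold is NULL
  counts <- matrix(5, 4, 400)
  colnames(counts) <- c(paste0("MT-", 1:100), paste0("G", 1:300))
  dsm <- cell_dataset(counts, batch = "b", mito_genes = paste0("MT-", 1:100))
  expect_equal(dsm$qc$mito_frac[1], 0.25)
  cfg0 <- processing_config(min_genes_per_cell = 0, min_cells_per_gene = 0)
  expect_equal(apply_qc_filters(dsm, cfg0)$report$n_cells_out, 4L)
  cfg1 <- processing_config(min_genes_per_cell = 0, min_cells_per_gene = 0,
                            max_mito_frac = 0.2)
  expect_error(apply_qc_filters(dsm, cfg1), "all 4 cells removed")

  expect_error(apply_qc_filters(ds, processing_config(min_genes_per_cell = 2000)),
               "review thresholds")
})

test_that("a planted low-depth subpopulation is removed at the planted rate", {
  set.seed(14)
  n <- 1000
  low <- stats::runif(n) < 0.05
  genes_det <- ifelse(low, sample(50:250, n, TRUE), sample(350:900, n, TRUE))
  ds <- qc_toy(genes_det)
  res <- apply_qc_filters(ds, processing_config(min_genes_per_cell = 300,
                                                min_cells_per_gene = 0))
  removed_frac <- 1 - res$report$n_cells_out / n
  expect_lt(abs(removed_frac - mean(low)), 0.02)
})

test_that("normalization targets row sums and constant genes are never HVGs", {
  ds <- small_batches(n_batches = 1, cells = 80, genes = 100)[[1]]
  # plant a constant gene
  ds$counts[, 60] <- 7
  cfg <- processing_config(min_genes_per_cell = 0, min_cells_per_gene = 0,
                           n_hvg = 50, n_pcs = 10, n_neighbors = 10)
  pp <- preprocess(ds, cfg)
  expect_equal(as.numeric(Matrix::rowSums(pp$norm_pre)),
               rep(1e4, nrow(ds$counts)), tolerance = 1e-6)
  expect_false(colnames(ds$counts)[60] %in% pp$hvg)
})

test_that("the first PC separates two well-separated planted types", {
  cfg <- sim_config(n_batches = 1, cells_per_batch = 200, n_genes = 100,
                    cell_types = data.frame(name = c("t1", "t2"),
                                            prop = c(0.5, 0.5)),
                    markers = list(1:8, 9:16), fold = 8,
                    batch_effect_sd = 0, seed = 2)
  ds <- generate_batches(cfg)[[1]]
  pp <- preprocess(ds, processing_config(min_genes_per_cell = 0,
                                         min_cells_per_gene = 0, n_hvg = 50,
                                         n_pcs = 10, n_neighbors = 10))
  r <- stats::cor(pp$pca[, 1], as.integer(ds$label_true == "t1"))
  expect_gt(abs(r), 0.9)
})

test_that("resolution bisection reaches planted cluster numbers deterministically", {
  blobs <- make_blobs(60, centers = rbind(c(0, 0), c(8, 0), c(0, 8)), sd = 0.3,
                      seed = 4)
  g <- knn_graph(blobs$coords, k = 10)
  res <- cluster_to_target(g, method = "leiden", target_k = 3, seed = 1)
  expect_true(res$reached)
  expect_equal(res$k, 3L)
  expect_equal(mclust::adjustedRandIndex(res$labels, blobs$labels), 1)

  res2 <- cluster_to_target(g, method = "leiden", target_k = 3, seed = 1)
  expect_identical(res$labels, res2$labels)

  # a connected clique collapses to one cluster at the lower resolution bound
  gk <- igraph::make_full_graph(30)
  res1 <- cluster_to_target(gk, method = "louvain", target_k = 1, seed = 1)
  expect_equal(res1$k, 1L)
})

test_that("rank_markers agrees with wilcox.test and finds exclusive genes", {
  set.seed(8)
  n <- 60
  x <- matrix(stats::rnorm(n * 20, mean = 5), n, 20)
  colnames(x) <- paste0("G", 1:20)
  labels <- rep(c("A", "B"), each = n / 2)
  x[labels == "A", 3] <- x[labels == "A", 3] + 10   # exclusive-ish marker
  mk <- rank_markers(x, labels, n_top = 5)
  expect_equal(mk$A$gene[1], "G3")

  # statistic cross-check against stats::wilcox.test (normal approximation)
  w <- stats::wilcox.test(x[labels == "A", 7], x[labels == "B", 7],
                          exact = FALSE, correct = FALSE)
  g7 <- which(colnames(x) == "G7")
  full <- rank_markers(x, labels, n_top = 20)
  expect_equal(full$A$p[full$A$gene == "G7"], w$p.value, tolerance = 1e-8)
})

test_that("label permutation destroys marker enrichment", {
  cfg <- sim_config(n_batches = 1, cells_per_batch = 300, n_genes = 120,
                    batch_effect_sd = 0, seed = 17)
  ds <- generate_batches(cfg)[[1]]
  pp <- preprocess(ds, processing_config(min_genes_per_cell = 0,
                                         min_cells_per_gene = 0, n_hvg = 100,
                                         n_pcs = 10, n_neighbors = 10))
  planted <- lapply(seq_len(6), function(i) paste0("G", ((i - 1) * 8 + 1):(i * 8)))
  names(planted) <- sort(unique(ds$label_true))[order(sort(unique(ds$label_true)))]
  types <- cfg$cell_types$name
  mk_true <- rank_markers(pp, ds$label_true, n_top = 10)
  hit_true <- mean(vapply(seq_along(types), function(i) {
    mean(paste0("G", ((i - 1) * 8 + 1):(i * 8)) %in% mk_true[[types[i]]]$gene)
  }, numeric(1)))
  set.seed(1)
  perm <- sample(ds$label_true)
  mk_perm <- rank_markers(pp, perm, n_top = 10)
  hit_perm <- mean(vapply(seq_along(types), function(i) {
    mean(paste0("G", ((i - 1) * 8 + 1):(i * 8)) %in% mk_perm[[types[i]]]$gene)
  }, numeric(1)))
  expect_gt(hit_true, 0.9)
  expect_lt(hit_perm, 0.3)
})

test_that("identical clusters yield no significant markers after correction", {
  ok <- 0L
  for (s in 1:5) {
    set.seed(100 + s)
    x <- matrix(stats::rpois(200 * 50, 3), 200, 50)
    colnames(x) <- paste0("G", 1:50)
    labels <- rep(c("A", "B"), each = 100)
    mk <- rank_markers(log1p(x), labels, n_top = 50)
    padj <- stats::p.adjust(mk$A$p, "BH")
    if (!any(padj < 0.01)) ok <- ok + 1L
  }
  expect_gte(ok, 4L)
})

test_that("mock annotation maps marker dictionaries with graded confidence", {
  dict <- list("T cell" = c("CD3D", "CD3E"), "B cell" = c("MS4A1", "CD79A"))
  ann <- mock_annotator(dict)
  markers <- list(
    c1 = data.frame(gene = c("CD3D", "CD3E", paste0("X", 1:8))),
    c2 = data.frame(gene = c("MS4A1", paste0("X", 1:9))),
    c3 = data.frame(gene = paste0("X", 1:10)))
  recs <- annotate_clusters(markers, "", ann)
  expect_equal(recs$cell_type, c("T cell", "B cell", "Unknown"))
  expect_equal(recs$confidence, c("high", "medium", "low"))

  # annotator failure falls back to Unknown rather than aborting
  broken <- structure(list(annotate = function(...) stop("boom")),
                      class = "annotator")
  expect_warning(fb <- annotate_clusters(markers, "", broken), "failed")
  expect_equal(unique(fb$cell_type), "Unknown")
})

test_that("config decisions are parsed from context tokens", {
  ann <- mock_annotator(list())
  dec <- ann$decide_config("article mentions min_genes=500 and target_k=6")
  expect_equal(dec$config$min_genes_per_cell, 500)
  expect_equal(dec$config$target_k, 6)
  expect_true(any(grepl("min_genes_per_cell = 500", dec$log)))
})

test_that("expression summaries discretize and flag missing genes", {
  x <- matrix(c(0, 0, 0, 0,  1, 2, 3, 8), ncol = 2,
              dimnames = list(NULL, c("Gzero", "Gvar")))
  labels <- c("c1", "c1", "c2", "c2")
  s <- summarize_expression(x, labels, c("Gzero", "Gvar", "Gmissing"))
  expect_true(all(s[, "Gzero"] == "absent"))
  expect_true(all(s[, "Gmissing"] == "not detected"))
  expect_true(all(s[, "Gvar"] %in% c("low", "medium", "high")))
})

test_that("re-annotation splits a planted subtype on a queried gene", {
  # two subtypes share the dictionary markers G1..G6 (differential against a
  # third type); subtype B additionally expresses the query gene G40
  cfg <- sim_config(n_batches = 1, cells_per_batch = 450, n_genes = 100,
                    cell_types = data.frame(name = c("ic A", "ic B", "other"),
                                            prop = rep(1 / 3, 3)),
                    markers = list(c(1:6, 30:33), c(1:6, 40:43), 50:57),
                    fold = 10, batch_effect_sd = 0, nb_dispersion = 5,
                    seed = 23)
  ds <- generate_batches(cfg)[[1]]
  pp <- preprocess(ds, processing_config(min_genes_per_cell = 0,
                                         min_cells_per_gene = 0, n_hvg = 60,
                                         n_pcs = 10, n_neighbors = 10))
  dict <- list("intercalated cell" = paste0("G", 1:6),
               "other cell" = paste0("G", 50:57))
  rules <- list(list(target_type = "intercalated cell", gene = "G40",
                     high_label = "type B intercalated cell",
                     low_label = "type A intercalated cell"))
  ann <- mock_annotator(dict, reannotation_rules = rules)
  cl <- cluster_to_target(pp$graph, target_k = 3, seed = 1)
  labels <- paste0("c", cl$labels)
  mk <- rank_markers(pp, labels, n_top = 10)
  recs <- annotate_clusters(mk, "", ann)
  expect_equal(sum(recs$cell_type == "intercalated cell"), 2L)
  re <- reannotate_clusters(pp, labels, recs, ann)
  got <- re$records$cell_type[match(labels, re$records$cluster)]
  ic <- ds$label_true %in% c("ic A", "ic B")
  agree <- mean((got[ic] == "type B intercalated cell") ==
                  (ds$label_true[ic] == "ic B"))
  expect_gt(max(agree, 1 - agree), 0.95)

  # no queried genes: records unchanged
  ann0 <- mock_annotator(dict)
  re0 <- reannotate_clusters(pp, labels, recs, ann0)
  expect_identical(re0$records, recs)
})

test_that("the full pipeline is reproducible and logs every decision", {
  ds <- small_batches(n_batches = 1, cells = 450, genes = 120, seed = 31,
                      fold = 8, nb_dispersion = 5)[[1]]
  # marker blocks follow the order of cfg$cell_types
  dict <- lapply(stats::setNames(seq_len(6), c("alpha cell", "beta cell",
                                               "delta cell", "acinar cell",
                                               "ductal cell", "endothelial cell")),
                 function(i) paste0("G", ((i - 1) * 8 + 1):(i * 8)))
  ann <- mock_annotator(dict)
  r1 <- process_dataset(ds, ann, context = "min_genes=0 min_cells=0 target_k=6",
                        seed = 2)
  r2 <- process_dataset(ds, ann, context = "min_genes=0 min_cells=0 target_k=6",
                        seed = 2)
  expect_identical(r1$records, r2$records)
  expect_identical(r1$dataset$label_given, r2$dataset$label_given)
  expect_identical(r1$log, r2$log)

  # log covers config decisions, qc, clustering and annotation rationale
  expect_true(any(grepl("decide_config", r1$log)))
  expect_true(any(grepl("qc:", r1$log)))
  expect_true(any(grepl("cluster:", r1$log)))
  expect_true(any(grepl("annotate:", r1$log)))

  # with the right target, cluster annotations recover the planted types
  acc <- annotation_accuracy(r1$dataset$label_given, r1$dataset$label_true,
                             mode = "embedding", level = "cluster")
  expect_gt(acc, 0.95)
})

test_that("confidence orders accuracy on constructed annotations", {
  dict <- list("T cell" = c("CD3D", "CD3E"), "B cell" = c("MS4A1", "CD79A"))
  ann <- mock_annotator(dict)
  markers <- list(
    good = data.frame(gene = c("CD3D", "CD3E", paste0("X", 1:8))),
    weak = data.frame(gene = c("MS4A1", paste0("Y", 1:9))))
  recs <- annotate_clusters(markers, "", ann)
  truth <- c(good = "T cell", weak = "T cell")  # the weak cluster is wrong
  acc <- as.numeric(recs$cell_type == truth[recs$cluster])
  expect_gte(mean(acc[recs$confidence == "high"]),
             mean(acc[recs$confidence %in% c("low", "medium")]))
})
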