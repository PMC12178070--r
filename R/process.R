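#' Processing configuration
#'
#' Parameters of the per-dataset processing pipeline. Optional thresholds
#' (`max_genes_per_cell`, `max_mito_frac`, `max_ribo_frac`) default to `NULL`
#' and the corresponding filter is then skipped entirely — the convention
#' being that such filters are only applied when a source explicitly
#' specifies them. `min_genes_per_cell = 300` is the preset for common
#' droplet-based datasets.
#'
#' @param min_genes_per_cell minimum genes detected per cell (kept if >=).
#' @param max_genes_per_cell optional upper bound on genes per cell.
#' @param min_cells_per_gene genes expressed in fewer cells are dropped.
#' @param max_mito_frac,max_ribo_frac optional per-cell fraction caps.
#' @param n_hvg number of highly variable genes.
#' @param n_neighbors kNN graph neighborhood size.
#' @param n_pcs number of principal components.
#' @param batch_correct whether to invoke the external batch-correction hook.
#' @param cluster_method `"leiden"` or `"louvain"`.
#' @param target_k optional target number of clusters.
#' @param norm_target library-size normalization target (counts per cell).
#' @return a `processing_config` list.
#' @export
processing_config <- function(min_genes_per_cell = 300L, max_genes_per_cell = NULL,
                              min_cells_per_gene = 3L, max_mito_frac = NULL,
                              max_ribo_frac = NULL, n_hvg = 2000L,
                              n_neighbors = 15L, n_pcs = 50L,
                              batch_correct = FALSE,
                              cluster_method = c("leiden", "louvain"),
                              target_k = NULL, norm_target = 1e4) {
  cluster_method <- match.arg(cluster_method)
  num <- c(min_genes_per_cell, min_cells_per_gene, n_hvg, n_neighbors, n_pcs)
  if (any(num < 0)) .stopf("processing_config: thresholds must be non-negative")
  structure(list(min_genes_per_cell = min_genes_per_cell,
                 max_genes_per_cell = max_genes_per_cell,
                 min_cells_per_gene = min_cells_per_gene,
                 max_mito_frac = max_mito_frac, max_ribo_frac = max_ribo_frac,
                 n_hvg = n_hvg, n_neighbors = n_neighbors, n_pcs = n_pcs,
                 batch_correct = batch_correct, cluster_method = cluster_method,
                 target_k = target_k, norm_target = norm_target),
            class = "processing_config")
}

#' Apply quality-control filters
#'
#' Removes cells failing the gene-count, mito-fraction and ribo-fraction
#' rules of the config (boundary values kept: a cell with exactly
#' `min_genes_per_cell` genes survives), then genes expressed in fewer than
#' `min_cells_per_gene` of the surviving cells. Rules whose threshold is
#' `NULL` are skipped.
#'
#' @param ds a `cell_dataset` with a counts layer.
#' @param cfg a `processing_config`.
#' @return list with `dataset` (filtered) and `report` (cells/genes removed
#'   per rule).
#' @export
apply_qc_filters <- function(ds, cfg) {
  n0 <- nrow(ds$counts)
  keep <- rep(TRUE, n0)
  report <- list(n_cells_in = n0, n_genes_in = ncol(ds$counts))
  drop_rule <- function(bad, name) {
    report[[name]] <<- sum(bad & keep)
    keep <<- keep & !bad
  }
  drop_rule(ds$qc$n_genes < cfg$min_genes_per_cell, "removed_min_genes")
  if (!is.null(cfg$max_genes_per_cell)) {
    drop_rule(ds$qc$n_genes > cfg$max_genes_per_cell, "removed_max_genes")
  }
  if (!is.null(cfg$max_mito_frac)) {
    drop_rule(ds$qc$mito_frac > cfg$max_mito_frac, "removed_mito")
  }
  if (!is.null(cfg$max_ribo_frac)) {
    ribo <- grepl("^RP[SL]", colnames(ds$counts))
    rf <- if (any(ribo)) {
      as.numeric(Matrix::rowSums(ds$counts[, ribo, drop = FALSE]) /
                   pmax(ds$qc$total_counts, 1))
    } else rep(0, n0)
    drop_rule(rf > cfg$max_ribo_frac, "removed_ribo")
  }
  if (!any(keep)) {
    .stopf("apply_qc_filters: all %d cells removed; review thresholds", n0)
  }
  counts <- ds$counts[keep, , drop = FALSE]
  gkeep <- Matrix::colSums(counts > 0) >= cfg$min_cells_per_gene
  report$removed_low_coverage_genes <- sum(!gkeep)
  counts <- counts[, gkeep, drop = FALSE]
  out <- cell_dataset(counts, batch = ds$batch[keep],
                      label_true = if (!is.null(ds$label_true)) ds$label_true[keep],
                      label_given = if (!is.null(ds$label_given)) ds$label_given[keep],
                      mito_genes = ds$mito_genes)
  report$n_cells_out <- nrow(counts)
  report$n_genes_out <- ncol(counts)
  list(dataset = out, report = report)
}

#' Normalize, select HVGs, compute PCA and the kNN graph
#'
#' Per-cell total-count normalization to `norm_target` followed by log1p;
#' highly variable genes by binned normalized dispersion (variance/mean of
#' the normalized layer, z-scored within 20 mean bins; zero-variance genes
#' are never selected); PCA on the centered, unit-variance (clipped at 10)
#' HVG submatrix; symmetric unweighted kNN graph on the PC coordinates.
#' `batch_correct = TRUE` calls `hook(pca, batch)` if a hook function is
#' supplied, otherwise warns — batch correction itself lives in the
#' integration module.
#'
#' @param ds a filtered `cell_dataset`.
#' @param cfg a `processing_config`.
#' @param hook optional function `(pca, batch) -> corrected pca` used when
#'   `cfg$batch_correct` is TRUE.
#' @return the dataset with `norm`, `hvg`, `pca` and `graph` filled in.
#' @export
preprocess <- function(ds, cfg, hook = NULL) {
  counts <- ds$counts
  tot <- Matrix::rowSums(counts)
  if (any(tot == 0)) .stopf("preprocess: cell(s) with zero counts; filter first")
  sf <- cfg$norm_target / tot
  norm_pre <- Matrix::Diagonal(x = sf) %*% counts   # pre-log, rows sum to target
  norm_pre <- as(norm_pre, "CsparseMatrix")
  lognorm <- norm_pre
  lognorm@x <- log1p(lognorm@x)
  dimnames(lognorm) <- dimnames(counts)
  dimnames(norm_pre) <- dimnames(counts)

  mu <- Matrix::colMeans(norm_pre)
  ex2 <- Matrix::colMeans(norm_pre^2)
  v <- pmax(ex2 - mu^2, 0) * nrow(norm_pre) / max(1, nrow(norm_pre) - 1)
  disp <- ifelse(mu > 0, v / mu, 0)
  eligible <- which(v > 0)
  n_hvg <- min(cfg$n_hvg, length(eligible))
  if (n_hvg < 2) .stopf("preprocess: fewer than 2 variable genes")
  bins <- cut(rank(mu[eligible], ties.method = "first"),
              breaks = min(20L, length(eligible)), labels = FALSE)
  zd <- disp[eligible]
  for (b in unique(bins)) {
    i <- bins == b
    s <- stats::sd(zd[i])
    zd[i] <- if (is.na(s) || s == 0) 0 else (zd[i] - mean(zd[i])) / s
  }
  hvg <- colnames(counts)[eligible[order(zd, decreasing = TRUE)[seq_len(n_hvg)]]]

  x <- as.matrix(lognorm[, hvg, drop = FALSE])
  x <- scale(x)
  x[is.na(x)] <- 0
  x[x > 10] <- 10; x[x < -10] <- -10
  n_pcs <- cfg$n_pcs
  if (n_pcs >= min(nrow(x), ncol(x))) {
    .stopf("preprocess: n_pcs = %d must be < min(cells, HVGs) = %d",
           n_pcs, min(nrow(x), ncol(x)))
  }
  sv <- svd(sweep(x, 2, colMeans(x)), nu = n_pcs, nv = 0)
  pca <- sv$u %*% diag(sv$d[seq_len(n_pcs)], n_pcs)
  rownames(pca) <- rownames(counts)
  if (isTRUE(cfg$batch_correct)) {
    if (is.function(hook)) pca <- hook(pca, ds$batch)
    else .warnf("preprocess: batch_correct requested but no hook supplied; skipped")
  }
  ds$norm <- lognorm
  ds$norm_pre <- norm_pre
  ds$hvg <- hvg
  ds$pca <- pca
  ds$graph <- knn_graph(pca, cfg$n_neighbors)
  ds
}

#' Symmetric kNN graph from embedding coordinates
#' @param coords cells x d matrix.
#' @param k neighbors per cell.
#' @return an undirected `igraph` graph (union of directed kNN edges).
#' @export
knn_graph <- function(coords, k) {
  n <- nrow(coords)
  k <- min(k, n - 1L)
  d <- pairwise_sqdist(coords, coords)
  diag(d) <- Inf
  nn <- .knn_from_dist(d, k)
  edges <- cbind(rep(seq_len(n), each = k), as.vector(t(nn)))
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  igraph::simplify(g)
}

#' Cluster a graph to a target number of clusters
#'
#' Monotone bisection on the community-detection resolution parameter until
#' the achieved cluster count equals `target_k` or `max_iter` evaluations are
#' spent; on failure the labels nearest in count are returned (preferring the
#' lower resolution) with `reached = FALSE`. The community detection is run
#' under a fixed seed, so results are reproducible.
#'
#' @param graph an `igraph` graph.
#' @param method `"leiden"` (modularity objective) or `"louvain"`.
#' @param target_k desired number of clusters (>= 1).
#' @param resolution_bounds search interval.
#' @param max_iter maximum community-detection evaluations.
#' @param seed RNG seed for the community detection.
#' @return list: `labels` (integer per vertex), `resolution`, `k`, `reached`.
#' @export
cluster_to_target <- function(graph, method = c("leiden", "louvain"),
                              target_k = NULL, resolution_bounds = c(0.1, 3),
                              max_iter = 20L, seed = 0L) {
  method <- match.arg(method)
  if (is.null(target_k) || target_k < 1) .stopf("cluster_to_target: target_k >= 1 required")
  run <- function(r) {
    set.seed(seed)
    comm <- if (method == "leiden") {
      igraph::cluster_leiden(graph, objective_function = "modularity",
                             resolution = r, n_iterations = 3)
    } else {
      igraph::cluster_louvain(graph, resolution = r)
    }
    as.integer(igraph::membership(comm))
  }
  lo <- resolution_bounds[1]; hi <- resolution_bounds[2]
  best <- NULL
  consider <- function(best, labels, r) {
    k <- length(unique(labels))
    cand <- list(labels = labels, resolution = r, k = k)
    if (is.null(best)) return(cand)
    db <- abs(best$k - target_k); dc <- abs(k - target_k)
    if (dc < db || (dc == db && r < best$resolution)) cand else best
  }
  l_lo <- run(lo); best <- consider(best, l_lo, lo)
  k_lo <- length(unique(l_lo))
  if (k_lo != target_k) {
    l_hi <- run(hi); best <- consider(best, l_hi, hi)
  }
  it <- 2L
  while (best$k != target_k && it < max_iter && (hi - lo) > 1e-4) {
    mid <- (lo + hi) / 2
    l_mid <- run(mid); best <- consider(best, l_mid, mid)
    k_mid <- length(unique(l_mid))
    if (k_mid < target_k) lo <- mid else hi <- mid
    it <- it + 1L
  }
  reached <- best$k == target_k
  if (!reached) {
    .warnf("cluster_to_target: target %d not reached; returning nearest count %d",
           target_k, best$k)
  }
  c(best, list(reached = reached))
}

#' Rank one-vs-rest marker genes by Wilcoxon rank-sum
#'
#' For each cluster, a one-vs-rest rank-sum test per gene on the log
#' normalized layer, computed from a single tie-corrected ranking per gene
#' with the normal approximation for the test statistic (equivalent to
#' `wilcox.test(correct = FALSE)` z-scores). Genes are ranked by the
#' z statistic (upregulation first), ties broken by mean log fold-change.
#' Clusters with fewer than 2 cells are skipped with a warning.
#'
#' @param norm cells x genes log-normalized matrix (dense or sparse), or a
#'   preprocessed `cell_dataset` (its `norm` layer is used).
#' @param labels per-cell cluster labels.
#' @param n_top markers returned per cluster.
#' @return named list: per cluster a data.frame `gene`, `z`, `p`, `lfc`.
#' @export
rank_markers <- function(norm, labels, n_top = 10L) {
  if (inherits(norm, "cell_dataset")) {
    if (is.null(norm$norm)) .stopf("rank_markers: run preprocess() first")
    norm <- norm$norm
  }
  x <- as.matrix(norm)
  N <- nrow(x)
  stopifnot(length(labels) == N)
  labels <- as.character(labels)
  sizes <- table(labels)
  use <- names(sizes)[sizes >= 2]
  if (length(use) < length(sizes)) {
    .warnf("rank_markers: skipping cluster(s) with < 2 cells: %s",
           paste(setdiff(names(sizes), use), collapse = ", "))
  }
  if (length(use) < 2) .stopf("rank_markers: need >= 2 clusters of size >= 2")
  ranks <- apply(x, 2, rank)             # average ranks, ties handled
  tie_term <- apply(x, 2, function(col) {
    t <- table(col)
    sum(t^3 - t)
  })
  out <- list()
  for (cl in use) {
    inc <- labels == cl
    n1 <- sum(inc); n2 <- N - n1
    R1 <- colSums(ranks[inc, , drop = FALSE])
    U <- R1 - n1 * (n1 + 1) / 2
    mu <- n1 * n2 / 2
    sig2 <- n1 * n2 / 12 * ((N + 1) - tie_term / (N * (N - 1)))
    z <- ifelse(sig2 > 0, (U - mu) / sqrt(sig2), 0)
    p <- 2 * stats::pnorm(-abs(z))
    lfc <- colMeans(x[inc, , drop = FALSE]) - colMeans(x[!inc, , drop = FALSE])
    ord <- order(-z, -lfc)
    top <- ord[seq_len(min(n_top, length(ord)))]
    out[[cl]] <- data.frame(gene = colnames(x)[top], z = z[top], p = p[top],
                            lfc = lfc[top], row.names = NULL)
  }
  out
}

#' Deterministic mock annotator
#'
#' A pure-function implementation of the annotator contract used to drive
#' the processing pipeline offline. Decisions a language model would take
#' from an article are replaced by explicit rules: `decide_config` parses
#' `key=value` tokens out of the free-text context (e.g. `"min_genes=500
#' target_k=6"`); `annotate` maps each cluster's top markers against a
#' marker dictionary, assigning the best-matching type with confidence given
#' by the fraction of that type's dictionary markers hit (all -> high,
#' >= half -> medium, some -> low, none -> "Unknown"/low); `reannotate`
#' applies optional gene-level rules that split or rename a type according
#' to the discretized expression summary of queried genes.
#'
#' @param marker_dict named list: cell type -> character vector of marker
#'   genes.
#' @param reannotation_rules optional list of rules, each a list with
#'   `target_type`, `gene`, `high_label`, `low_label`: clusters annotated as
#'   `target_type` become `high_label` when the queried gene's discretized
#'   level is medium/high, else `low_label`.
#' @param tissue,disease,stage constants copied into every record.
#' @return an `annotator` object (list of pure functions).
#' @export
mock_annotator <- function(marker_dict, reannotation_rules = NULL,
                           tissue = "synthetic tissue", disease = "healthy",
                           stage = "adult") {
  decide_config <- function(context = "") {
    cfg <- processing_config()
    log <- c("decide_config: starting from package defaults")
    toks <- regmatches(context, gregexpr("[A-Za-z_]+=[-0-9.]+", context))[[1]]
    map <- c(min_genes = "min_genes_per_cell", max_genes = "max_genes_per_cell",
             min_cells = "min_cells_per_gene", max_mito = "max_mito_frac",
             max_ribo = "max_ribo_frac", n_hvg = "n_hvg",
             n_neighbors = "n_neighbors", n_pcs = "n_pcs",
             target_k = "target_k")
    for (tk in toks) {
      kv <- strsplit(tk, "=", fixed = TRUE)[[1]]
      fld <- unname(map[kv[1]])
      if (!is.na(fld)) {
        cfg[[fld]] <- as.numeric(kv[2])
        log <- c(log, sprintf("decide_config: context sets %s = %s", fld, kv[2]))
      }
    }
    list(config = cfg, log = log)
  }
  annotate <- function(markers, context = "") {
    recs <- lapply(names(markers), function(cl) {
      top <- markers[[cl]]$gene
      frac <- vapply(marker_dict, function(g) mean(g %in% top), numeric(1))
      hit <- if (length(frac)) max(frac) else 0
      if (hit == 0) {
        type <- "Unknown"; conf <- "low"
        why <- "no dictionary markers among top genes"
      } else {
        cand <- names(marker_dict)[frac == hit]
        type <- sort(cand)[1]
        conf <- if (hit >= 0.999) "high" else if (hit >= 0.5) "medium" else "low"
        why <- sprintf("%.0f%% of '%s' dictionary markers in top genes",
                       100 * hit, type)
      }
      data.frame(cluster = cl, cell_type = type, confidence = conf,
                 tissue = tissue, disease = disease, stage = stage,
                 rationale = why, stringsAsFactors = FALSE)
    })
    do.call(rbind, recs)
  }
  select_query_genes <- function(records, context = "") {
    if (is.null(reannotation_rules)) return(character(0))
    hits <- vapply(reannotation_rules, function(r) {
      r$target_type %in% records$cell_type
    }, logical(1))
    unique(vapply(reannotation_rules[hits], `[[`, character(1), "gene"))
  }
  reannotate <- function(records, summary) {
    if (is.null(reannotation_rules)) return(records)
    for (r in reannotation_rules) {
      if (!r$gene %in% colnames(summary)) next
      idx <- which(records$cell_type == r$target_type)
      for (i in idx) {
        lev <- summary[records$cluster[i], r$gene]
        new <- if (lev %in% c("medium", "high")) r$high_label else r$low_label
        if (!identical(new, records$cell_type[i])) {
          records$rationale[i] <- sprintf(
            "%s; revised from '%s' (query gene %s: %s)",
            records$rationale[i], records$cell_type[i], r$gene, lev)
          records$cell_type[i] <- new
        }
      }
    }
    records
  }
  structure(list(decide_config = decide_config, annotate = annotate,
                 select_query_genes = select_query_genes,
                 reannotate = reannotate),
            class = "annotator")
}

#' Annotate clusters through an annotator
#'
#' One record per cluster; an annotator failure falls back to
#' "Unknown"/low-confidence records rather than aborting the pipeline.
#' @param markers output of [rank_markers()].
#' @param context free-text context passed through to the annotator.
#' @param annotator an annotator (see [mock_annotator()]).
#' @return data.frame of annotation records.
#' @export
annotate_clusters <- function(markers, context = "", annotator) {
  tryCatch(annotator$annotate(markers, context), error = function(e) {
    .warnf("annotate_clusters: annotator failed (%s); labeling Unknown",
           conditionMessage(e))
    do.call(rbind, lapply(names(markers), function(cl) {
      data.frame(cluster = cl, cell_type = "Unknown", confidence = "low",
                 tissue = "", disease = "", stage = "",
                 rationale = "annotator failure fallback",
                 stringsAsFactors = FALSE)
    }))
  })
}

#' Summarize cluster-level expression into discrete levels
#'
#' Cluster means of the queried genes on the log-normalized layer are binned
#' across clusters into `absent` (exact zero) / `low` / `medium` / `high`
#' by quartiles of the per-gene cluster means. Queried genes absent from the
#' matrix are reported as `"not detected"`.
#' @param norm log-normalized matrix or preprocessed `cell_dataset`.
#' @param labels per-cell cluster labels.
#' @param genes genes to summarize.
#' @return character matrix clusters x genes of levels.
#' @export
summarize_expression <- function(norm, labels, genes) {
  if (inherits(norm, "cell_dataset")) norm <- norm$norm
  cls <- sort(unique(as.character(labels)))
  out <- matrix("not detected", nrow = length(cls), ncol = length(genes),
                dimnames = list(cls, genes))
  for (g in genes) {
    if (!g %in% colnames(norm)) next
    m <- vapply(cls, function(cl) mean(norm[labels == cl, g]), numeric(1))
    qs <- stats::quantile(m, c(0.25, 0.5, 0.75), names = FALSE)
    idx <- findInterval(m, qs, left.open = TRUE) + 1L
    lev <- c("low", "low", "medium", "high")[idx]
    lev[m == 0] <- "absent"
    out[, g] <- lev
  }
  out
}

#' Second-round re-annotation through queried gene expression
#'
#' Lets the annotator pick query genes, summarizes their cluster-level
#' expression into natural-language-like discrete levels, and lets the
#' annotator revise labels. With no queried genes, records pass through
#' unchanged.
#' @param norm log-normalized matrix or preprocessed `cell_dataset`.
#' @param labels per-cell cluster labels.
#' @param records first-round annotation records.
#' @param annotator an annotator.
#' @param context free-text context.
#' @return list: `records` (possibly revised), `summary`, `log`.
#' @export
reannotate_clusters <- function(norm, labels, records, annotator, context = "") {
  genes <- annotator$select_query_genes(records, context)
  if (length(genes) == 0) {
    return(list(records = records, summary = NULL,
                log = "reannotate: no genes queried; records unchanged"))
  }
  summ <- summarize_expression(norm, labels, genes)
  new <- annotator$reannotate(records, summ)
  log <- c(sprintf("reannotate: queried gene(s) %s", paste(genes, collapse = ", ")),
           sprintf("reannotate: cluster %s -> '%s' (%s)",
                   new$cluster, new$cell_type, new$confidence))
  list(records = new, summary = summ, log = log)
}

#' Run the full per-dataset processing pipeline
#'
#' filter -> preprocess -> cluster-to-target-k -> annotate -> re-annotate,
#' with every parameter decision and annotation rationale accumulated in a
#' plain-text log. Deterministic for a fixed seed and mock annotator.
#'
#' @param ds a `cell_dataset` with raw counts.
#' @param annotator an annotator (see [mock_annotator()]).
#' @param context free-text context handed to the annotator's decisions.
#' @param seed seed for clustering.
#' @param n_top_markers markers per cluster passed to annotation.
#' @return list: `dataset` (processed, `label_given` revised to cluster
#'   annotations), `clusters`, `records`, `config`, `markers`, `log`.
#' @export
process_dataset <- function(ds, annotator, context = "", seed = 0L,
                            n_top_markers = 10L) {
  dec <- annotator$decide_config(context)
  cfg <- dec$config
  log <- dec$log
  fl <- apply_qc_filters(ds, cfg)
  log <- c(log, sprintf("qc: %s", paste(names(fl$report), unlist(fl$report),
                                        sep = "=", collapse = ", ")))
  d <- fl$dataset
  cfg$n_hvg <- min(cfg$n_hvg, ncol(d$counts))
  cfg$n_pcs <- min(cfg$n_pcs, min(dim(d$counts)) - 1L, cfg$n_hvg - 1L)
  d <- preprocess(d, cfg)
  log <- c(log, sprintf("preprocess: n_hvg=%d n_pcs=%d n_neighbors=%d",
                        length(d$hvg), ncol(d$pca), cfg$n_neighbors))
  tk <- cfg$target_k %||% 8L
  cl <- cluster_to_target(d$graph, method = cfg$cluster_method, target_k = tk,
                          seed = seed)
  log <- c(log, sprintf(
    "cluster: method=%s target_k=%d achieved_k=%d resolution=%.4f reached=%s",
    cfg$cluster_method, tk, cl$k, cl$resolution, cl$reached))
  labels <- paste0("c", cl$labels)
  mk <- rank_markers(d, labels, n_top = n_top_markers)
  recs <- annotate_clusters(mk, context, annotator)
  log <- c(log, sprintf("annotate: cluster %s -> '%s' (%s): %s",
                        recs$cluster, recs$cell_type, recs$confidence,
                        recs$rationale))
  re <- reannotate_clusters(d, labels, recs, annotator, context)
  recs <- re$records
  log <- c(log, re$log)
  d$label_given <- recs$cell_type[match(labels, recs$cluster)]
  list(dataset = d, clusters = labels, records = recs, config = cfg,
       markers = mk, log = log)
}
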