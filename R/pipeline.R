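#' Two-step prior-informed integration
#'
#' The stepwise process: (1) build an initial label-similarity prior from
#' the raw per-dataset annotations; (2) harmonize the annotations across
#' datasets with the uncertainty-modulated prior; (3) rebuild the prior on
#' the harmonized labels (aliases that were grouped now share a label and
#' hence similarity 1); (4) integrate the batches with the rebuilt prior.
#' All intermediates are returned.
#'
#' @param datasets list of `cell_dataset` (raw or preprocessed).
#' @param annotations optional list of per-dataset per-cell labels
#'   overriding `label_given`.
#' @param provider embedding provider for the priors.
#' @param beta harmonization prior strength.
#' @param knn mutual-neighbor count for integration.
#' @param sigma smoothing width for integration.
#' @param d shared-embedding dimension.
#' @param floor prior similarity floor.
#' @param seed seed for the reduction.
#' @return list: `embedding` (integration result), `harmonization`,
#'   `prior_initial`, `prior_rebuilt`, `revised_labels`, `reduced`.
#' @export
two_step_integrate <- function(datasets, annotations = NULL,
                               provider = hash_embedding_provider(),
                               beta = 0.1, knn = 30L, sigma = 15, d = 100L,
                               floor = 0.05, seed = 0L) {
  if (length(datasets) < 2) {
    .warnf("two_step_integrate: single dataset; identity passthrough")
    emb <- reduce_dimensions(datasets, d = d, seed = seed)
    return(list(embedding = list(coords = emb[[1]]$coords, batch = emb[[1]]$batch,
                                 labels = emb[[1]]$labels),
                harmonization = NULL, prior_initial = NULL,
                prior_rebuilt = NULL,
                revised_labels = list(emb[[1]]$labels), reduced = emb))
  }
  embs <- reduce_dimensions(datasets, d = d, seed = seed)
  if (!is.null(annotations)) {
    for (i in seq_along(embs)) embs[[i]]$labels <- as.character(annotations[[i]])
  }
  raw_labels <- unique(unlist(lapply(embs, `[[`, "labels")))
  M1 <- build_prior_matrix(embed_labels(raw_labels, provider), floor = floor)
  harm <- harmonize_datasets(embs, M = M1, beta = beta)
  hembs <- embs
  for (i in seq_along(hembs)) hembs[[i]]$labels <- harm$revised_labels[[i]]
  harm_labels <- unique(unlist(harm$revised_labels))
  M2 <- build_prior_matrix(embed_labels(harm_labels, provider), floor = floor)
  integ <- integrate_batches(hembs, M = M2, k = knn, sigma = sigma)
  list(embedding = integ, harmonization = harm, prior_initial = M1,
       prior_rebuilt = M2, revised_labels = harm$revised_labels,
       reduced = embs)
}

#' Consensus cluster annotation by fuzzy majority voting
#'
#' Within each cluster, source labels whose pairwise embedding cosine
#' reaches `fuzzy_threshold` pool their votes (connected components of the
#' label similarity graph); the group with most votes wins and its most
#' frequent member string becomes the cluster label (ties broken by larger
#' raw count, then lexicographically). A threshold above 1 disables merging
#' and reduces to strict string majority voting.
#'
#' @param cluster_labels per-cell cluster ids.
#' @param source_annotations per-cell labels to vote over.
#' @param fuzzy_threshold cosine threshold for pooling near-synonymous
#'   labels (default 0.85).
#' @param provider embedding provider.
#' @return a `consensus` object: `clusters` (data.frame: cluster, label,
#'   votes, vote_fraction, group_members), `cell_labels` (per-cell revised).
#' @export
major_vote <- function(cluster_labels, source_annotations,
                       fuzzy_threshold = 0.85,
                       provider = hash_embedding_provider()) {
  stopifnot(length(cluster_labels) == length(source_annotations))
  cl <- as.character(cluster_labels)
  ann <- as.character(source_annotations)
  ulab <- unique(ann)
  keys <- .norm_label(ulab)
  merged_group <- seq_along(ulab)
  if (fuzzy_threshold <= 1 && length(ulab) > 1) {
    emb <- provider$embed(unique(keys))
    cs <- tcrossprod(.l2_normalize_rows(emb))
    kidx <- match(keys, unique(keys))
    uf <- .uf_new(length(ulab))
    for (a in seq_along(ulab)[-1]) {
      for (b in seq_len(a - 1)) {
        if (cs[kidx[a], kidx[b]] >= fuzzy_threshold) uf <- .uf_union(uf, a, b)
      }
    }
    merged_group <- vapply(seq_along(ulab), function(i) .uf_find(uf, i), 1L)
  }
  rows <- list(); cell_labels <- ann
  for (c_id in sort(unique(cl))) {
    inc <- cl == c_id
    if (!any(inc)) next
    counts <- table(ann[inc])
    gids <- merged_group[match(names(counts), ulab)]
    gvotes <- tapply(as.numeric(counts), gids, sum)
    top_count <- vapply(names(gvotes), function(g) {
      max(counts[gids == as.integer(g)])
    }, numeric(1))
    ord <- order(-gvotes, -top_count, names(gvotes))
    win <- as.integer(names(gvotes)[ord[1]])
    members <- names(counts)[gids == win]
    mc <- counts[members]
    label <- members[order(-as.numeric(mc), members)][1]
    rows[[length(rows) + 1]] <- data.frame(
      cluster = c_id, label = label, votes = sum(mc),
      vote_fraction = sum(mc) / sum(counts),
      group_members = paste(members, collapse = " | "),
      stringsAsFactors = FALSE)
    cell_labels[inc] <- label
  }
  structure(list(clusters = do.call(rbind, rows), cell_labels = cell_labels),
            class = "consensus")
}

#' Label corruption specification
#'
#' The three corruption schemes of the robustness experiments: `fuzzy`
#' replaces a type name by an alias (similar naming, high embedding
#' similarity); `unbiased` replaces it by a novel token absent from the
#' label vocabulary (default `"unknown"`); `biased` replaces it by a
#' different existing type name (a plausible but wrong annotation).
#'
#' @param scheme `"fuzzy"`, `"unbiased"` or `"biased"`.
#' @param target_types types whose cells are corrupted.
#' @param replacement named character vector target -> replacement. Default:
#'   fuzzy uses [alias_table()]; unbiased uses `"unknown"`; biased must be
#'   supplied.
#' @param fraction fraction of each target type's cells corrupted (default
#'   1: the whole type is renamed).
#' @param datasets indices of the datasets whose labels are modified when the
#'   spec drives a multi-dataset experiment (default 1: one selected
#'   dataset, leaving the others as uncorrupted references).
#' @param seed sampling seed.
#' @return a `corruption_spec`.
#' @export
corruption_spec <- function(scheme = c("fuzzy", "unbiased", "biased"),
                            target_types, replacement = NULL, fraction = 1,
                            datasets = 1L, seed = 1L) {
  scheme <- match.arg(scheme)
  if (!(fraction > 0 && fraction <= 1)) .stopf("corruption_spec: fraction in (0, 1]")
  structure(list(scheme = scheme, target_types = as.character(target_types),
                 replacement = replacement, fraction = fraction,
                 datasets = as.integer(datasets), seed = as.integer(seed)),
            class = "corruption_spec")
}

#' Apply a label corruption
#'
#' For each target type, a seeded sample of the stated fraction of its cells
#' receives the scheme's replacement label; the change mask is returned.
#' @param labels per-cell labels.
#' @param spec a `corruption_spec`.
#' @return list: `labels` (corrupted), `mask` (logical), `map` (the
#'   replacement map used).
#' @export
corrupt_labels <- function(labels, spec) {
  labels <- as.character(labels)
  present <- unique(labels)
  missing <- setdiff(spec$target_types, present)
  if (length(missing)) {
    .stopf("corrupt_labels: target type(s) absent: %s", paste(missing, collapse = ", "))
  }
  map <- spec$replacement
  if (is.null(map)) {
    map <- switch(spec$scheme,
                  fuzzy = alias_table(spec$target_types),
                  unbiased = stats::setNames(rep("unknown", length(spec$target_types)),
                                             spec$target_types),
                  biased = .stopf("corrupt_labels: biased scheme needs an explicit replacement"))
  }
  if (is.null(names(map))) names(map) <- spec$target_types
  if (spec$scheme == "biased") {
    bad <- !(unname(map) %in% present) | unname(map) == names(map)
    if (any(bad)) {
      .stopf("corrupt_labels: biased replacement must be a different existing label (%s)",
             paste(names(map)[bad], collapse = ", "))
    }
  }
  if (spec$scheme == "unbiased" && any(unname(map) %in% present)) {
    .stopf("corrupt_labels: unbiased replacement collides with existing labels")
  }
  out <- labels
  mask <- rep(FALSE, length(labels))
  set.seed(spec$seed)
  for (tp in spec$target_types) {
    idx <- which(labels == tp)
    take <- if (spec$fraction >= 1) idx else {
      sample(idx, size = max(1L, round(spec$fraction * length(idx))))
    }
    out[take] <- unname(map[tp])
    mask[take] <- TRUE
  }
  list(labels = out, mask = mask, map = map)
}

#' Label-corruption robustness experiment
#'
#' Corrupts the working annotations of the selected datasets under one
#' scheme, runs
#' each requested integration variant, and evaluates on the corrupted
#' (masked) cells only: silhouette/ARI/NMI of an unsupervised Leiden
#' clustering (resolution 0.7 by default) against the ground-truth types,
#' plus a confusion matrix of majority-voted consensus labels versus truth.
#' Variants: `"two_step"` (harmonize then integrate with the rebuilt
#' prior), `"prior"` (prior-weighted integration on the corrupted labels,
#' no harmonization), `"none"` (label-free integration baseline). A variant
#' that errors is recorded as a failed row and the experiment continues.
#'
#' @param datasets list of `cell_dataset` with `label_true` set.
#' @param spec a `corruption_spec`.
#' @param methods subset of `c("two_step", "prior", "none")`.
#' @param beta,knn,sigma,d integration parameters.
#' @param resolution Leiden resolution for the evaluation clustering.
#' @param fuzzy_threshold consensus-vote merge threshold.
#' @param provider embedding provider.
#' @param seed seed for reduction/clustering.
#' @return a data.frame of per-method metrics with attribute `confusion`
#'   (named list of voted-vs-true tables) and `mask_size`.
#' @export
corruption_experiment <- function(datasets, spec,
                                  methods = c("two_step", "prior", "none"),
                                  beta = 0.1, knn = 30L, sigma = 15, d = 100L,
                                  resolution = 0.7, fuzzy_threshold = 0.85,
                                  provider = hash_embedding_provider(),
                                  seed = 0L) {
  stopifnot(all(vapply(datasets, function(x) !is.null(x$label_true), TRUE)))
  corr <- lapply(seq_along(datasets), function(i) {
    sp <- spec
    sp$seed <- spec$seed + i - 1L
    present <- intersect(sp$target_types, unique(datasets[[i]]$label_given))
    if (!(i %in% spec$datasets) || length(present) == 0) {
      return(list(labels = datasets[[i]]$label_given,
                  mask = rep(FALSE, nrow(datasets[[i]]$counts))))
    }
    sp$target_types <- present
    if (!is.null(sp$replacement)) sp$replacement <- sp$replacement[present]
    corrupt_labels(datasets[[i]]$label_given, sp)
  })
  labels_corr <- lapply(corr, `[[`, "labels")
  mask <- unlist(lapply(corr, `[[`, "mask"))
  truth <- unlist(lapply(datasets, `[[`, "label_true"))
  if (!any(mask)) {
    .warnf("corruption_experiment: no cells corrupted (targets absent?); evaluating all cells")
    mask <- rep(TRUE, length(mask))
  }
  rows <- list(); confusion <- list()
  for (m in methods) {
    res <- tryCatch({
      emb <- switch(m,
        two_step = two_step_integrate(datasets, annotations = labels_corr,
                                      provider = provider, beta = beta,
                                      knn = knn, sigma = sigma, d = d,
                                      seed = seed)$embedding,
        prior = {
          red <- reduce_dimensions(datasets, d = d, seed = seed)
          for (i in seq_along(red)) red[[i]]$labels <- labels_corr[[i]]
          M <- build_prior_matrix(
            embed_labels(unique(unlist(labels_corr)), provider))
          integrate_batches(red, M = M, k = knn, sigma = sigma)
        },
        none = {
          red <- reduce_dimensions(datasets, d = d, seed = seed)
          for (i in seq_along(red)) red[[i]]$labels <- NULL
          integrate_batches(red, M = NULL, k = knn, sigma = sigma)
        },
        .stopf("unknown method '%s'", m))
      coords <- emb$coords
      g <- knn_graph(coords, k = 15L)
      set.seed(seed)
      cl <- igraph::cluster_leiden(g, objective_function = "modularity",
                                   resolution = resolution, n_iterations = 3)
      clusters <- as.integer(igraph::membership(cl))
      sil <- if (length(unique(truth[mask])) >= 2 && sum(mask) > 2) {
        mean(cluster::silhouette(as.integer(factor(truth[mask])),
                                 stats::dist(coords[mask, , drop = FALSE]))[, 3])
      } else NA_real_
      ari <- mclust::adjustedRandIndex(clusters[mask], truth[mask])
      nmi <- igraph::compare(as.integer(factor(clusters[mask])),
                             as.integer(factor(truth[mask])), method = "nmi")
      vote <- major_vote(clusters, unlist(labels_corr),
                         fuzzy_threshold = fuzzy_threshold, provider = provider)
      confusion[[m]] <- table(voted = vote$cell_labels[mask], true = truth[mask])
      data.frame(method = m, n_masked = sum(mask), silhouette = sil,
                 ari = ari, nmi = nmi, failed = FALSE, stringsAsFactors = FALSE)
    }, error = function(e) {
      .warnf("corruption_experiment: method '%s' failed: %s", m,
             conditionMessage(e))
      data.frame(method = m, n_masked = sum(mask), silhouette = NA_real_,
                 ari = NA_real_, nmi = NA_real_, failed = TRUE,
                 stringsAsFactors = FALSE)
    })
    rows[[m]] <- res
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "confusion") <- confusion
  attr(out, "mask_size") <- sum(mask)
  out
}
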