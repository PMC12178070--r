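#' Simulation configuration for multi-batch single-cell data
#'
#' Defines the generative model used throughout the package's tests and
#' experiments: cells of known types drawn per batch by fixed proportions,
#' negative-binomial counts whose gene means combine a log-normal baseline,
#' type-specific marker fold-changes, a gene-wise multiplicative batch effect
#' (log-normal, sd `batch_effect_sd`) and a per-cell library-size factor
#' (log-normal, sd `libsize_sd`). Batch-private types can be added per batch.
#'
#' @param n_batches number of batches.
#' @param cells_per_batch single integer or vector of length `n_batches`.
#' @param n_genes total genes; must accommodate all marker blocks.
#' @param cell_types data.frame with columns `name` and `prop` (proportions,
#'   renormalized per batch); defaults to six equally sized pancreas-style
#'   types.
#' @param markers list (parallel to `cell_types` rows) of marker gene
#'   indices; default: disjoint blocks of `markers_per_type` genes.
#' @param fold marker fold-change (scalar or per-type). Default 6.
#' @param markers_per_type block size used when `markers` is NULL.
#' @param batch_effect_sd sd of the gene-wise log-normal batch factor.
#' @param nb_dispersion negative-binomial size parameter (variance =
#'   mu + mu^2/size); `Inf` gives Poisson counts.
#' @param libsize_sd sd of the per-cell log-normal depth factor.
#' @param private_types named list batch-index -> character vector of extra
#'   type names private to that batch (each takes proportion
#'   `private_prop`, shared types renormalized).
#' @param private_prop proportion given to each private type.
#' @param n_mito_genes number of genes named `MT-*` contributing to the QC
#'   mito fraction (0 disables).
#' @param seed integer seed fixing the full output bitwise.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_batches = 3L, cells_per_batch = 500L, n_genes = 200L,
                       cell_types = NULL, markers = NULL, fold = 6,
                       markers_per_type = 8L,
                       batch_effect_sd = 0.5, nb_dispersion = 2,
                       libsize_sd = 0.3, private_types = NULL,
                       private_prop = 0.1, n_mito_genes = 0L, seed = 1L) {
  if (is.null(cell_types)) {
    cell_types <- data.frame(
      name = c("alpha cell", "beta cell", "delta cell",
               "acinar cell", "ductal cell", "endothelial cell"),
      prop = rep(1 / 6, 6))
  }
  k <- nrow(cell_types)
  if (abs(sum(cell_types$prop) - 1) > 1e-9) {
    .stopf("sim_config: type proportions must sum to 1")
  }
  if (is.null(markers)) {
    markers <- lapply(seq_len(k), function(i) {
      ((i - 1L) * markers_per_type + 1L):(i * markers_per_type)
    })
  }
  if (max(unlist(markers)) > n_genes) {
    .stopf("sim_config: marker indices exceed n_genes = %d", n_genes)
  }
  fold <- rep_len(fold, k)
  cells_per_batch <- rep_len(as.integer(cells_per_batch), n_batches)
  structure(list(n_batches = as.integer(n_batches),
                 cells_per_batch = cells_per_batch, n_genes = as.integer(n_genes),
                 cell_types = cell_types, markers = markers, fold = fold,
                 markers_per_type = as.integer(markers_per_type),
                 batch_effect_sd = batch_effect_sd, nb_dispersion = nb_dispersion,
                 libsize_sd = libsize_sd, private_types = private_types,
                 private_prop = private_prop, n_mito_genes = as.integer(n_mito_genes),
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Generate synthetic multi-batch datasets
#'
#' Draws one `cell_dataset` per batch under the model described in
#' [sim_config()]. With the same config (including seed) the output is
#' bitwise identical across calls. `label_given` starts equal to
#' `label_true`; corruption and harmonization operate on `label_given`.
#'
#' @param config a `sim_config`.
#' @return list of `cell_dataset`, one per batch.
#' @export
generate_batches <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  G <- config$n_genes
  gene_names <- sprintf("G%d", seq_len(G))
  if (config$n_mito_genes > 0) {
    mi <- seq_len(config$n_mito_genes)
    gene_names[G - mi + 1L] <- sprintf("MT-%d", mi)
  }
  baseline <- exp(stats::rnorm(G, mean = log(0.5), sd = 1))

  shared <- config$cell_types
  k_shared <- nrow(shared)
  # private types get fresh marker blocks after the shared ones (wrapping if
  # n_genes is exhausted would be a config error)
  priv_names <- unique(unlist(config$private_types))
  all_names <- c(shared$name, priv_names)
  markers <- config$markers
  fold <- config$fold
  if (length(priv_names)) {
    nxt <- max(unlist(markers))
    for (pn in priv_names) {
      blk <- (nxt + 1L):(nxt + config$markers_per_type)
      if (max(blk) > G) .stopf("generate_batches: not enough genes for private type markers")
      markers <- c(markers, list(blk))
      nxt <- max(blk)
    }
    fold <- c(fold, rep(mean(config$fold), length(priv_names)))
  }
  type_mu <- sapply(seq_along(all_names), function(ti) {
    mu <- baseline
    mu[markers[[ti]]] <- mu[markers[[ti]]] * fold[ti]
    mu
  })  # genes x types

  out <- vector("list", config$n_batches)
  for (b in seq_len(config$n_batches)) {
    nb <- config$cells_per_batch[b]
    batch_fac <- exp(stats::rnorm(G, 0, config$batch_effect_sd))
    pt <- character(0)
    if (!is.null(config$private_types)) {
      v <- config$private_types[[as.character(b)]]
      if (is.null(v) && is.null(names(config$private_types)) &&
          b <= length(config$private_types)) {
        v <- config$private_types[[b]]
      }
      pt <- v %||% character(0)
    }
    tnames <- c(shared$name, pt)
    props <- c(shared$prop * (1 - length(pt) * config$private_prop),
               rep(config$private_prop, length(pt)))
    props <- props / sum(props)
    types <- sample(tnames, nb, replace = TRUE, prob = props)
    lib <- exp(stats::rnorm(nb, 0, config$libsize_sd))
    counts <- matrix(0L, nrow = nb, ncol = G)
    for (ci in seq_len(nb)) {
      mu <- type_mu[, match(types[ci], all_names)] * batch_fac * lib[ci]
      counts[ci, ] <- if (is.infinite(config$nb_dispersion)) {
        stats::rpois(G, mu)
      } else {
        stats::rnbinom(G, mu = mu, size = config$nb_dispersion)
      }
    }
    colnames(counts) <- gene_names
    rownames(counts) <- sprintf("b%d_c%d", b, seq_len(nb))
    out[[b]] <- cell_dataset(counts, batch = sprintf("batch%d", b),
                             label_true = types,
                             mito_genes = grep("^MT-", gene_names, value = TRUE))
  }
  out
}

#' Generate a toy ontology tree
#'
#' A perfect tree with `branching^d` nodes at depth `d`, with deterministic
#' ids (`N`, `N.1`, `N.1.2`, ...), as a fixture for ancestor-set similarity.
#' @param depth tree depth (0 gives a single root).
#' @param branching children per internal node.
#' @return an `ontology_graph`.
#' @export
generate_ontology <- function(depth, branching) {
  stopifnot(depth >= 0, branching >= 1)
  ids <- "N"
  parents <- list(character(0))
  frontier <- "N"
  d <- 0L
  while (d < depth) {
    nxt <- character(0)
    for (p in frontier) {
      kids <- paste0(p, ".", seq_len(branching))
      ids <- c(ids, kids)
      parents <- c(parents, rep(list(p), branching))
      nxt <- c(nxt, kids)
    }
    frontier <- nxt
    d <- d + 1L
  }
  ontology_graph(ids, names = ids, parents = parents)
}

# Curated synonym dictionary keyed by normalized label. Small on purpose:
# covers common immune/stromal names; everything else falls back to a
# deterministic case variant.
.alias_dictionary <- c(
  "t cell" = "T lymphocyte",
  "b cell" = "B lymphocyte",
  "nk cell" = "natural killer cell",
  "natural killer cell" = "NK cell",
  "macrophage" = "histiocyte",
  "dendritic cell" = "DC",
  "fibroblast" = "stromal fibroblast",
  "keratinocyte" = "epidermal keratinocyte"
)

#' Deterministic alias table for cell-type names
#'
#' Maps each type name to an alternative spelling: a curated synonym when the
#' name is in the built-in dictionary, otherwise a case variant (first
#' alphabetic character toggled). Aliases are always string-unequal to the
#' original. Used by the fuzzy label-corruption scheme.
#' @param types character vector of type names.
#' @param seed unused placeholder kept for interface stability (the mapping
#'   is fully deterministic).
#' @return named character vector original -> alias.
#' @export
alias_table <- function(types, seed = 0L) {
  if (length(types) == 0) .stopf("alias_table: 'types' must be non-empty")
  out <- vapply(types, function(tp) {
    hit <- unname(.alias_dictionary[.norm_label(tp)])
    if (!is.na(hit) && hit != tp) return(hit)
    ch <- strsplit(tp, "")[[1]]
    i <- which(grepl("[[:alpha:]]", ch))[1]
    if (is.na(i)) return(paste0(tp, "."))
    ch[i] <- if (ch[i] %in% letters) toupper(ch[i]) else tolower(ch[i])
    alt <- paste(ch, collapse = "")
    if (identical(alt, tp)) paste0(tp, ".") else alt
  }, character(1))
  stats::setNames(out, types)
}
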