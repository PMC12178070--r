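#' Deterministic offline label-embedding provider
#'
#' Builds an embedding provider that maps a cell-type label to a unit vector
#' by feature-hashing character n-grams of the lowercased, whitespace-collapsed
#' label into a fixed-dimension vector. The hash is pure integer arithmetic,
#' so the same label always yields a bitwise-identical vector in every R
#' session and on every platform. This stands in for commercial text-embedding
#' services in fully offline, reproducible analyses: labels that share most of
#' their character n-grams (spelling and punctuation variants, plural forms)
#' receive high cosine similarity, unrelated names receive low similarity.
#'
#' @param dim embedding dimension (number of hash buckets).
#' @param ngram integer vector of n-gram lengths to hash.
#' @return an object of class `embedding_provider` with elements `id`, `dim`
#'   and `embed`, a function mapping a character vector of normalized labels
#'   to a matrix of unit-norm row vectors.
#' @examples
#' p <- hash_embedding_provider()
#' e <- p$embed(c("t cell", "b cell"))
#' rowSums(e^2)
#' @export
hash_embedding_provider <- function(dim = 256L, ngram = 2:4) {
  dim <- as.integer(dim)
  stopifnot(dim >= 8L, all(ngram >= 1L))
  embed <- function(labels) {
    out <- matrix(0, nrow = length(labels), ncol = dim)
    for (li in seq_along(labels)) {
      s <- paste0(" ", labels[li], " ")  # boundary-marked
      codes <- utf8ToInt(s)
      v <- numeric(dim)
      for (n in ngram) {
        if (length(codes) < n) next
        for (start in seq_len(length(codes) - n + 1L)) {
          gram <- codes[start:(start + n - 1L)]
          h1 <- 7
          h2 <- 5381
          for (cc in gram) {
            h1 <- (h1 * 31 + cc) %% 2147483647
            h2 <- (h2 * 131 + cc) %% 2147483629
          }
          idx <- (h1 %% dim) + 1L
          sgn <- if (h2 %% 2 == 0) 1 else -1
          v[idx] <- v[idx] + sgn
        }
      }
      nv <- sqrt(sum(v^2))
      if (nv > 0) v <- v / nv
      out[li, ] <- v
    }
    rownames(out) <- labels
    out
  }
  structure(list(id = sprintf("hash-ngram-%d", dim), dim = dim, embed = embed),
            class = "embedding_provider")
}

#' Embed cell-type labels
#'
#' Maps each distinct (whitespace-normalized, case-folded) label to a
#' unit-norm embedding vector through the given provider. Labels that differ
#' only in case or internal whitespace collapse onto one embedding.
#'
#' @param labels character vector of cell-type names (non-empty strings).
#' @param provider an `embedding_provider`; defaults to the bundled offline
#'   n-gram hashing provider.
#' @return a `label_embeddings` object: a matrix with one unit-norm row per
#'   distinct normalized label (rownames are the normalized keys), with
#'   attributes `display` (first-seen original spelling per key) and
#'   `provider` (the provider used, kept so downstream builders can embed
#'   derived strings such as "label: description").
#' @export
embed_labels <- function(labels, provider = hash_embedding_provider()) {
  if (length(labels) == 0) .stopf("embed_labels: 'labels' must be non-empty")
  keys <- .norm_label(labels)
  if (any(keys == "")) {
    .stopf("embed_labels: empty label after normalization at position %d",
           which(keys == "")[1])
  }
  first <- !duplicated(keys)
  ukeys <- keys[first]
  disp <- as.character(labels)[first]
  mat <- provider$embed(ukeys)
  nrm <- sqrt(rowSums(mat^2))
  if (any(abs(nrm - 1) > 1e-6)) {
    .stopf("embedding provider '%s' returned non-unit vectors", provider$id)
  }
  structure(mat, display = stats::setNames(disp, ukeys), provider = provider,
            class = c("label_embeddings", "matrix"))
}

#' Cosine similarity between two labels under a provider
#' @param a,b label strings.
#' @param provider embedding provider.
#' @return cosine similarity in \[-1, 1\].
#' @export
label_cosine <- function(a, b, provider = hash_embedding_provider()) {
  e <- provider$embed(.norm_label(c(a, b)))
  sum(e[1, ] * e[2, ])
}

#' Build a cell-type prior-similarity matrix
#'
#' Pairwise cosine similarities between label embeddings, floored at a small
#' positive constant so the similarity can safely divide distances, with an
#' exact unit diagonal. Typical inter-type naming distances under general text
#' embeddings exceed 0.3, so the floor only catches pathological pairs.
#'
#' @param embeddings a `label_embeddings` object from [embed_labels()], or a
#'   character vector of labels (embedded with `provider`).
#' @param floor minimum off-diagonal similarity, in (0, 1). Default 0.05.
#' @param descriptions optional named character vector mapping labels to
#'   free-text descriptions; when given, similarity is computed on embeddings
#'   of `"label: description"` strings.
#' @param provider provider used when `embeddings` is a character vector.
#' @return a `prior_similarity` object: symmetric matrix in (0, 1] with unit
#'   diagonal, dimnames the display labels, attributes `keys` (normalized
#'   labels) and `floor`.
#' @export
build_prior_matrix <- function(embeddings, floor = 0.05, descriptions = NULL,
                               provider = hash_embedding_provider()) {
  if (!(is.numeric(floor) && length(floor) == 1 && floor > 0 && floor < 1)) {
    .stopf("build_prior_matrix: 'floor' must be a single value in (0, 1)")
  }
  if (is.character(embeddings)) {
    keys <- .norm_label(embeddings)
    if (anyDuplicated(keys)) {
      .warnf("build_prior_matrix: duplicate labels after normalization collapsed")
    }
    embeddings <- embed_labels(embeddings, provider)
  }
  stopifnot(inherits(embeddings, "label_embeddings"))
  keys <- rownames(embeddings)
  disp <- attr(embeddings, "display")
  prov <- attr(embeddings, "provider")
  if (!is.null(descriptions)) {
    dkeys <- .norm_label(names(descriptions))
    txt <- vapply(seq_along(keys), function(i) {
      j <- match(keys[i], dkeys)
      if (is.na(j)) keys[i] else paste0(keys[i], ": ", .norm_label(descriptions[[j]]))
    }, character(1))
    mat <- prov$embed(txt)
  } else {
    mat <- unclass(embeddings)
  }
  cs <- tcrossprod(.l2_normalize_rows(mat))
  m <- pmax(cs, floor)
  diag(m) <- 1
  m <- (m + t(m)) / 2
  dimnames(m) <- list(unname(disp), unname(disp))
  structure(m, keys = keys, floor = floor, class = c("prior_similarity", "matrix"))
}

#' Neutral (all-ones) prior-similarity matrix
#'
#' Every label pair has similarity 1; used as the no-prior reference code
#' path of the integration module.
#' @param labels character vector of labels.
#' @return a `prior_similarity` object of ones.
#' @export
neutral_prior <- function(labels) {
  keys <- unique(.norm_label(labels))
  disp <- unique(labels)[!duplicated(.norm_label(unique(labels)))]
  m <- matrix(1, length(keys), length(keys), dimnames = list(disp, disp))
  structure(m, keys = keys, floor = 1,
            class = c("prior_similarity", "matrix"))
}

# Look up M for arbitrary (possibly unseen) label pairs; unseen labels fall
# back to the floor similarity (with one warning) so partially annotated
# inputs remain usable. Same normalized label always gives 1.
#' Look up prior similarities for label pairs
#' @param M a `prior_similarity` matrix.
#' @param labels_a,labels_b character vectors; result is
#'   `length(labels_a) x length(labels_b)`.
#' @return matrix of similarities in (0, 1].
#' @export
prior_lookup <- function(M, labels_a, labels_b) {
  keys <- attr(M, "keys")
  fl <- attr(M, "floor")
  if (is.null(fl)) fl <- 0.05
  ka <- .norm_label(labels_a)
  kb <- .norm_label(labels_b)
  ia <- match(ka, keys)
  ib <- match(kb, keys)
  if (anyNA(ia) || anyNA(ib)) {
    miss <- unique(c(ka[is.na(ia)], kb[is.na(ib)]))
    .warnf("prior_lookup: label(s) not in prior matrix, using floor %.3g: %s",
           fl, paste(miss, collapse = ", "))
  }
  out <- matrix(fl, nrow = length(ka), ncol = length(kb))
  ok_a <- !is.na(ia)
  ok_b <- !is.na(ib)
  if (any(ok_a) && any(ok_b)) {
    out[ok_a, ok_b] <- unclass(M)[ia[ok_a], ib[ok_b], drop = FALSE]
  }
  same <- outer(ka, kb, "==")
  out[same] <- 1
  out
}

# Elementwise prior lookup for two parallel label vectors (one similarity
# per pair), avoiding the full cross matrix.
.prior_lookup_pairs <- function(M, labels_a, labels_b) {
  stopifnot(length(labels_a) == length(labels_b))
  keys <- attr(M, "keys")
  fl <- attr(M, "floor")
  if (is.null(fl)) fl <- 0.05
  ka <- .norm_label(labels_a)
  kb <- .norm_label(labels_b)
  ia <- match(ka, keys)
  ib <- match(kb, keys)
  out <- rep(fl, length(ka))
  ok <- !is.na(ia) & !is.na(ib)
  if (any(ok)) out[ok] <- unclass(M)[cbind(ia[ok], ib[ok])]
  if (any(!ok)) {
    .warnf("prior lookup: label(s) not in prior matrix, using floor %.3g", fl)
  }
  out[ka == kb] <- 1
  out
}

#' Write / read a prior-similarity matrix as TSV
#'
#' Labels form the header row and first column; values are written in full
#' double precision.
#' @param M a `prior_similarity` object.
#' @param path file path.
#' @export
write_prior_matrix <- function(M, path) {
  df <- data.frame(label = rownames(M), unclass(M), check.names = FALSE)
  colnames(df) <- c("label", colnames(M))
  utils::write.table(format(df, digits = 17, scientific = FALSE, trim = TRUE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_prior_matrix
#' @param floor floor recorded on the re-read matrix.
#' @export
read_prior_matrix <- function(path, floor = 0.05) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE)
  labs <- df[[1]]
  m <- as.matrix(df[, -1, drop = FALSE])
  dimnames(m) <- list(labs, labs)
  structure(m, keys = .norm_label(labs), floor = floor,
            class = c("prior_similarity", "matrix"))
}
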