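#' Embedding backends
#'
#' A backend turns an amino-acid sequence into an L x D matrix with one
#' row per residue.  Three backends are known:
#' \describe{
#'   \item{mock}{deterministic, dependency-free; any dimension.  Used by
#'     the test-suite and the synthetic pipeline.}
#'   \item{esm2}{the `esm2_t33_650M_UR50D` protein language model,
#'     D = 1280.  Requires an external runtime and is reported as
#'     unavailable in installations without one.}
#'   \item{protbert}{the `prot_bert_bfd` model, D = 1024.  Same
#'     availability contract as `esm2`.}
#' }
#' Live backends never fall back silently: embedding through an
#' unavailable backend is an error.  Special tokens (BOS/EOS/padding)
#' emitted by live models are excluded from the residue rows, so the
#' matrix always has exactly L rows.
#'
#' @param name one of `"mock"`, `"esm2"`, `"protbert"`.
#' @param dim embedding dimension (mock backend only).
#' @param seed integer seed fixing the mock backend's residue table.
#' @return an object of class `qs_backend` with fields `name`, `dim`,
#'   `available`.
#' @export
embedding_backend <- function(name = c("mock", "esm2", "protbert"),
                              dim = 16, seed = 1) {
  name <- match.arg(name)
  if (name == "mock") return(mock_backend(dim, seed))
  dim <- switch(name, esm2 = 1280L, protbert = 1024L)
  structure(list(name = name, dim = dim, available = FALSE),
            class = "qs_backend")
}

#' Deterministic mock embedding backend
#'
#' Maps (residue identity, position, seed) to a row vector through
#' fixed per-letter vectors modulated by position, so that the same
#' sequence always produces the same matrix while distinct sequences
#' (including permutations of one another) almost surely differ.
#'
#' @param dim embedding dimension, >= 1.
#' @param seed integer seed for the letter and position tables.
#' @return a `qs_backend`.
#' @export
mock_backend <- function(dim = 16, seed = 1) {
  stopifnot(dim >= 1, is.finite(seed))
  letters21 <- c(.qs_standard_aa, "X")
  tabs <- .qs_with_seed(seed, {
    V <- matrix(rnorm(length(letters21) * dim), length(letters21), dim,
                dimnames = list(letters21, NULL))
    P <- matrix(rnorm(32 * dim, sd = 0.1), 32, dim)
    list(V = V, P = P)
  })
  structure(list(name = sprintf("mock_d%d_s%d", dim, as.integer(seed)),
                 dim = as.integer(dim), available = TRUE,
                 seed = as.integer(seed),
                 letter_table = tabs$V, position_table = tabs$P),
            class = "qs_backend")
}

#' @export
print.qs_backend <- function(x, ...) {
  cat(sprintf("embedding backend '%s' (D = %d, %s)\n", x$name, x$dim,
              if (isTRUE(x$available)) "available" else "not available"))
  invisible(x)
}

#' Embed one sequence into a per-residue matrix
#'
#' @param sequence amino-acid string (standard letters plus X).
#' @param backend a `qs_backend`, see [embedding_backend()].
#' @return a `residue_embedding`: list with `matrix` (L x D) and
#'   `backend_name`.
#' @export
embed_sequence <- function(sequence, backend) {
  stopifnot(inherits(backend, "qs_backend"))
  if (!isTRUE(backend$available)) {
    stop(sprintf(
      "embedding backend '%s' is not available in this installation; %s",
      backend$name,
      "install its runtime or precompute an embedding cache"))
  }
  sequence <- clean_sequences(sequence)
  ch <- strsplit(sequence, "")[[1]]
  L <- length(ch)
  pos <- seq_len(L)
  # per-letter vector scaled by position so permuted sequences differ,
  # plus a small periodic positional component
  M <- backend$letter_table[ch, , drop = FALSE] * (1 + 0.1 * sin(pos)) +
    backend$position_table[((pos - 1L) %% 32L) + 1L, , drop = FALSE]
  dimnames(M) <- NULL
  structure(list(matrix = M, backend_name = backend$name),
            class = "residue_embedding")
}

#' Mean-pool a per-residue embedding matrix
#'
#' Averages the L x D matrix over the residue dimension, producing one
#' length-D vector per protein.
#'
#' @param x a `residue_embedding` or a plain numeric matrix with one row
#'   per residue.
#' @return numeric vector of length D.
#' @export
mean_pool <- function(x) {
  M <- if (inherits(x, "residue_embedding")) x$matrix else x
  stopifnot(is.matrix(M), is.numeric(M))
  if (nrow(M) < 1) stop("cannot pool an empty embedding matrix")
  colMeans(M)
}

#' Construct an embedded dataset
#'
#' The central container for pooled embeddings: aligned ids, vectors,
#' qs labels and optional family / homology-cluster assignments.
#'
#' @param ids character vector of unique record ids.
#' @param vectors numeric matrix, one row per id, common dimension D.
#' @param labels integer qs labels, one per id.
#' @param family optional character vector of family ids.
#' @param cluster optional character vector of homology cluster ids.
#' @param backend name of the backend that produced the vectors.
#' @return an object of class `qs_embedded`.
#' @export
embedded_dataset <- function(ids, vectors, labels, family = NULL,
                             cluster = NULL, backend = "unknown") {
  vectors <- as.matrix(vectors)
  n <- length(ids)
  stopifnot(nrow(vectors) == n, length(labels) == n)
  if (anyDuplicated(ids)) stop("ids must be unique")
  if (!all(is.finite(vectors))) stop("embedding vectors must be finite")
  if (any(labels < 1)) stop("qs labels must be >= 1")
  rownames(vectors) <- ids
  structure(list(
    ids = as.character(ids),
    vectors = vectors,
    labels = as.integer(labels),
    family = if (is.null(family)) rep(NA_character_, n) else as.character(family),
    cluster = if (is.null(cluster)) rep(NA_character_, n) else as.character(cluster),
    backend = backend,
    dim = ncol(vectors)
  ), class = "qs_embedded")
}

#' @export
print.qs_embedded <- function(x, ...) {
  cat(sprintf("qs_embedded: %d records, D = %d, %d qs labels, backend '%s'\n",
              length(x$ids), x$dim, length(unique(x$labels)), x$backend))
  invisible(x)
}

#' @export
`[.qs_embedded` <- function(x, i, ...) {
  if (is.character(i)) i <- match(i, x$ids)
  embedded_dataset(x$ids[i], x$vectors[i, , drop = FALSE], x$labels[i],
                   x$family[i], x$cluster[i], x$backend)
}

#' @export
length.qs_embedded <- function(x) length(x$ids)

#' Embed and pool every record of a labeled dataset
#'
#' Runs [embed_sequence()] + [mean_pool()] over all records, with an
#' optional on-disk cache keyed by the backend name so repeated runs do
#' not recompute vectors.
#'
#' @param dataset a `qs_dataset`.
#' @param backend a `qs_backend`.
#' @param cache optional path to a TSV cache (id column + D numeric
#'   columns); read when present, (re)written after embedding.
#' @return a `qs_embedded` dataset.
#' @export
embed_dataset <- function(dataset, backend, cache = NULL) {
  stopifnot(inherits(dataset, "qs_dataset"))
  rec <- dataset$records
  if (!is.null(cache) && file.exists(cache)) {
    emb <- read_embedding_cache(cache)
    if (ncol(emb$vectors) == backend$dim && all(rec$id %in% emb$ids)) {
      X <- emb$vectors[rec$id, , drop = FALSE]
      dimnames(X) <- NULL
      return(embedded_dataset(rec$id, X, rec$qs_label, rec$family_id,
                              rec$cluster_id, backend$name))
    }
    .qs_msg("cache %s does not cover the dataset; re-embedding", cache)
  }
  X <- t(vapply(rec$sequence,
                function(s) mean_pool(embed_sequence(s, backend)),
                numeric(backend$dim), USE.NAMES = FALSE))
  out <- embedded_dataset(rec$id, X, rec$qs_label, rec$family_id,
                          rec$cluster_id, backend$name)
  if (!is.null(cache)) write_embedding_cache(out, cache)
  out
}

#' Read / write a pooled-embedding cache
#'
#' The cache is a TSV with an `id` column followed by D numeric
#' columns.  Labels, family and cluster assignments are not part of the
#' cache; [read_embedding_cache()] returns them as missing.
#'
#' @param path TSV path.
#' @return for `read_embedding_cache`, a list with `ids` and `vectors`.
#' @export
read_embedding_cache <- function(path) {
  tab <- data.table::fread(path, header = TRUE, data.table = FALSE)
  if (names(tab)[1] != "id") stop("embedding cache must start with an 'id' column")
  X <- as.matrix(tab[, -1, drop = FALSE])
  rownames(X) <- as.character(tab$id)
  list(ids = as.character(tab$id), vectors = X)
}

#' @param x a `qs_embedded` dataset (or list with `ids` and `vectors`).
#' @rdname read_embedding_cache
#' @export
write_embedding_cache <- function(x, path) {
  df <- data.frame(id = x$ids, x$vectors, row.names = NULL,
                   check.names = FALSE)
  names(df) <- c("id", paste0("d", seq_len(ncol(x$vectors))))
  data.table::fwrite(df, path, sep = "\t")
  invisible(path)
}
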