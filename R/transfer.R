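# Nearest-neighbour annotation transfer: assign a query the qs of its
# most similar annotated neighbour, by embedding cosine similarity or
# by sequence identity from a local alignment.

#' Cosine similarity between two vectors
#'
#' @param u,v numeric vectors of equal length and nonzero norm.
#' @return `dot(u, v) / (|u| |v|)`, in `[-1, 1]` up to rounding.
#' @export
cosine_similarity <- function(u, v) {
  stopifnot(is.numeric(u), is.numeric(v))
  if (length(u) != length(v)) stop("vectors must have equal length")
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0) stop("cosine similarity undefined for zero-norm vector")
  sum(u * v) / (nu * nv)
}

#' Annotation transfer by embedding cosine similarity
#'
#' Each query receives the qs label of the reference record with the
#' highest cosine similarity.  With `exclude_same_cluster = TRUE`,
#' references sharing the query's homology cluster are masked before
#' the maximum is taken, emulating prediction without any homolog
#' information.  Ties are broken towards the lexicographically smallest
#' reference id; queries whose references are all masked get an absent
#' prediction (`NA`).
#'
#' @param query a `qs_embedded` of query records.
#' @param reference a non-empty `qs_embedded` of annotated records with
#'   the same dimension.
#' @param exclude_same_cluster mask references in the query's cluster.
#' @return data.frame with columns `query_id`, `mode`, `neighbor_id`,
#'   `similarity`, `predicted_qs` (NA when no admissible neighbour).
#' @export
transfer_embedding <- function(query, reference, exclude_same_cluster = FALSE) {
  stopifnot(inherits(query, "qs_embedded"), inherits(reference, "qs_embedded"))
  if (length(reference) == 0) stop("reference dataset is empty")
  if (query$dim != reference$dim) {
    stop(sprintf("dimension mismatch: query D = %d, reference D = %d",
                 query$dim, reference$dim))
  }
  rord <- order(reference$ids)              # ties resolve to smallest id
  ref <- reference[rord]
  qn <- query$vectors / sqrt(rowSums(query$vectors^2))
  rn <- ref$vectors / sqrt(rowSums(ref$vectors^2))
  if (!all(is.finite(qn)) || !all(is.finite(rn))) {
    stop("cosine similarity undefined for zero-norm vector")
  }
  S <- qn %*% t(rn)
  if (exclude_same_cluster) {
    same <- outer(query$cluster, ref$cluster,
                  function(a, b) !is.na(a) & !is.na(b) & a == b)
    S[same] <- -Inf
  }
  best <- max.col(S, ties.method = "first")
  sim <- S[cbind(seq_len(nrow(S)), best)]
  none <- !is.finite(sim)
  data.frame(
    query_id = query$ids,
    mode = "embedding",
    neighbor_id = ifelse(none, NA_character_, ref$ids[best]),
    similarity = ifelse(none, NA_real_, sim),
    predicted_qs = ifelse(none, NA_integer_, ref$labels[best]),
    stringsAsFactors = FALSE
  )
}

# local alignment identity and coverage for one candidate pair
.qs_blosum_env <- new.env(parent = emptyenv())
.qs_blosum62 <- function() {
  if (is.null(.qs_blosum_env$mat)) {
    data("BLOSUM62", package = "Biostrings", envir = .qs_blosum_env)
    .qs_blosum_env$mat <- get("BLOSUM62", envir = .qs_blosum_env)
  }
  .qs_blosum_env$mat
}

.qs_align_identity <- function(query, subject) {
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(query), Biostrings::AAString(subject),
    substitutionMatrix = .qs_blosum62(), gapOpening = 10,
    gapExtension = 0.5, type = "local")
  len <- Biostrings::nchar(aln)
  if (len == 0) return(c(identity = 0, coverage = 0))
  ident <- Biostrings::nmatch(aln) / len
  shorter <- min(nchar(query), nchar(subject))
  cov <- len / shorter
  c(identity = ident, coverage = min(cov, 1))
}

#' Annotation transfer by sequence identity
#'
#' Each query receives the qs label of the reference sequence with the
#' highest local-alignment identity, provided identity and coverage of
#' the shorter sequence meet the thresholds; otherwise the query is
#' left unpredicted (the "0-predicted" bin).  Identity is
#' matches / alignment-length of a local BLOSUM62 alignment.  For
#' tractability candidates are pre-screened with the same k-mer
#' identity estimate used by [cluster_sequences()]; sequences far below
#' the identity threshold never reach the aligner.
#'
#' @param query data.frame with `id` and `sequence` columns (or a
#'   `qs_dataset`).
#' @param reference data.frame with `id`, `sequence` and `qs_label`
#'   columns (or a `qs_dataset`); must be non-empty.
#' @param min_identity minimum identity for a transfer, default 0.30.
#' @param min_coverage minimum coverage of the shorter sequence.
#' @param exclude_self drop reference records whose id equals the
#'   query's (for reference sets that contain the queries themselves).
#' @param max_candidates alignments attempted per query, best k-mer
#'   candidates first.
#' @return data.frame with columns `query_id`, `mode`, `neighbor_id`,
#'   `similarity` (identity in `[0, 1]`), `predicted_qs`.
#' @export
transfer_sequence <- function(query, reference, min_identity = 0.30,
                              min_coverage = 0.30, exclude_self = TRUE,
                              max_candidates = 25L) {
  if (inherits(query, "qs_dataset")) query <- query$records
  if (inherits(reference, "qs_dataset")) reference <- reference$records
  stopifnot(nrow(reference) > 0,
            all(c("id", "sequence") %in% names(query)),
            all(c("id", "sequence", "qs_label") %in% names(reference)))
  k <- 5L
  ref <- reference[order(reference$id), , drop = FALSE]
  km_ref <- lapply(ref$sequence, .qs_kmers, k = k)
  index <- new.env(parent = emptyenv())
  for (j in seq_along(km_ref)) {
    for (kr in unique(km_ref[[j]])) index[[kr]] <- c(index[[kr]], j)
  }
  res <- lapply(seq_len(nrow(query)), function(i) {
    qid <- query$id[i]; qseq <- query$sequence[i]
    km_q <- .qs_kmers(qseq, k)
    cand <- unique(unlist(lapply(unique(km_q), function(kr)
      if (!is.null(index[[kr]])) index[[kr]]), use.names = FALSE))
    if (exclude_self) cand <- cand[ref$id[cand] != qid]
    if (length(cand) > 0) {
      est <- vapply(cand, function(j)
        .qs_kmer_compare(km_q, km_ref[[j]], k)[1], numeric(1))
      # generous screen: the k-mer estimate is noisy near the threshold
      cand <- cand[est >= 0.5 * min_identity]
      est <- est[est >= 0.5 * min_identity]
      if (length(cand) > max_candidates) {
        keep <- order(-est)[seq_len(max_candidates)]
        cand <- cand[keep]
      }
    }
    best_j <- NA_integer_; best_ident <- -1
    for (j in cand[order(ref$id[cand])]) {
      sc <- .qs_align_identity(qseq, ref$sequence[j])
      if (sc[["identity"]] >= min_identity &&
          sc[["coverage"]] >= min_coverage &&
          sc[["identity"]] > best_ident) {
        best_j <- j; best_ident <- sc[["identity"]]
      }
    }
    if (is.na(best_j)) {
      data.frame(query_id = qid, mode = "sequence",
                 neighbor_id = NA_character_, similarity = NA_real_,
                 predicted_qs = NA_integer_, stringsAsFactors = FALSE)
    } else {
      data.frame(query_id = qid, mode = "sequence",
                 neighbor_id = ref$id[best_j], similarity = best_ident,
                 predicted_qs = as.integer(ref$qs_label[best_j]),
                 stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Does similarity separate correct from incorrect transfers?
#'
#' For every actual qs class, compares the similarity values of correct
#' and incorrect transfers with a one-sided ("greater") rank-sum test:
#' a small p-value means correct transfers come with systematically
#' higher similarity, so the similarity can serve as a confidence
#' score.  Classes lacking correct or incorrect results are reported as
#' skipped.  P-values are not corrected for multiple testing.
#'
#' @param results transfer results from [transfer_embedding()] or
#'   [transfer_sequence()].
#' @param truth integer vector of true qs labels aligned with
#'   `results` rows.
#' @return data.frame with one row per class: `qs`, `n_correct`,
#'   `n_incorrect`, `statistic`, `p_value`, `skipped`.
#' @export
confidence_separation <- function(results, truth) {
  stopifnot(nrow(results) == length(truth))
  correct <- !is.na(results$predicted_qs) & results$predicted_qs == truth
  .qs_confidence_table(results$similarity, correct, truth)
}

# shared core for similarity- and probability-based confidence reports
.qs_confidence_table <- function(values, correct, truth) {
  out <- lapply(sort(unique(truth)), function(q) {
    sel <- truth == q
    x <- values[sel & correct]
    y <- values[sel & !correct]
    x <- x[!is.na(x)]; y <- y[!is.na(y)]
    if (length(x) == 0 || length(y) == 0) {
      .qs_msg("class qs=%d skipped: needs >= 1 correct and >= 1 incorrect", q)
      data.frame(qs = q, n_correct = length(x), n_incorrect = length(y),
                 statistic = NA_real_, p_value = NA_real_, skipped = TRUE)
    } else {
      ts <- rank_sum_test(x, y, alternative = "greater")
      data.frame(qs = q, n_correct = length(x), n_incorrect = length(y),
                 statistic = ts$statistic, p_value = ts$p.value,
                 skipped = FALSE)
    }
  })
  out <- do.call(rbind, out)
  attr(out, "note") <- "p-values are uncorrected for multiple testing"
  out
}
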