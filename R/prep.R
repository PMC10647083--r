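# Homology clustering, leakage-free splitting, folds, rebalancing.

# k-mer screen for the built-in clusterer and the sequence-transfer
# prefilter.  Identity between two related sequences is estimated by
# inverting k-mer containment: if a fraction C of the shorter
# sequence's k-mers occurs in the longer one, the per-position
# identity is approximately C^(1/k).  The estimate is a screen only;
# borderline calls are settled by an actual local alignment.
.qs_kmers <- function(seq, k) {
  n <- nchar(seq)
  if (n < k) return(character(0))
  substring(seq, 1:(n - k + 1), k:n)
}

.qs_kmer_compare <- function(km_a, km_b, k) {
  # returns c(est_identity, coverage_of_shorter); positions taken on the
  # sequence with fewer k-mers.  Fewer than 3 shared k-mers (unless the
  # shorter sequence has fewer than 3 altogether) is treated as chance
  # co-occurrence: inverting containment from a single shared k-mer
  # would otherwise report ~0.37 identity for unrelated sequences.
  if (length(km_a) == 0 || length(km_b) == 0) return(c(0, 0))
  if (length(km_a) <= length(km_b)) { short <- km_a; other <- km_b }
  else { short <- km_b; other <- km_a }
  hit <- which(short %in% other)
  if (length(hit) < min(3L, length(short))) return(c(0, 0))
  contain <- length(hit) / length(short)
  span <- (hit[length(hit)] + k - 1) - hit[1] + 1
  c(contain^(1 / k), span / (length(short) + k - 1))
}

#' Cluster sequences by approximate identity
#'
#' Groups records into homology clusters at the given identity and
#' coverage thresholds.  When an `mmseqs` binary is found on the PATH
#' (and `method` is `"auto"` or `"mmseqs"`) clustering is delegated to
#' `mmseqs easy-cluster` with the matching parameters; otherwise a
#' built-in greedy centroid clusterer is used: sequences are visited
#' longest-first, candidate representatives are screened by a shared
#' k-mer identity estimate, and a sequence joins the representative
#' with the highest local-alignment identity among those meeting the
#' identity and coverage-of-shorter thresholds, else it founds a new
#' cluster.  Cluster ids are named after their representative record,
#' so the assignment is invariant to input order.
#'
#' @param records a `qs_dataset`, or a data.frame with `id` and
#'   `sequence` columns.
#' @param min_identity minimum pairwise identity (fraction), default 0.30.
#' @param min_coverage minimum coverage of the shorter sequence, default 0.30.
#' @param method `"auto"` (external tool when installed), `"builtin"`,
#'   or `"mmseqs"` (error if the binary is absent or fails).
#' @param k k-mer size of the built-in identity estimate.
#' @return a `cluster_assignment`: data.frame with columns `id`,
#'   `cluster_id`; parameters and representatives in attributes.
#' @export
cluster_sequences <- function(records, min_identity = 0.30,
                              min_coverage = 0.30,
                              method = c("auto", "builtin", "mmseqs"),
                              k = 5L) {
  method <- match.arg(method)
  if (inherits(records, "qs_dataset")) records <- records$records
  stopifnot(is.data.frame(records), nrow(records) >= 1,
            all(c("id", "sequence") %in% names(records)))
  have_mmseqs <- nzchar(Sys.which("mmseqs"))
  if (method == "mmseqs" || (method == "auto" && have_mmseqs)) {
    if (!have_mmseqs) stop("mmseqs binary not found on PATH")
    return(.qs_cluster_mmseqs(records, min_identity, min_coverage))
  }
  .qs_cluster_builtin(records, min_identity, min_coverage, k)
}

.qs_cluster_builtin <- function(records, min_identity, min_coverage, k) {
  ord <- order(-nchar(records$sequence), records$id)
  ids <- records$id[ord]
  seqs <- records$sequence[ord]
  km <- lapply(seqs, .qs_kmers, k = k)
  index <- new.env(parent = emptyenv())     # kmer -> rep indices
  rep_of <- integer(length(ids))            # member -> rep position
  reps <- integer(0)
  for (i in seq_along(ids)) {
    # k-mer screen proposes representatives; membership is decided by
    # the local alignment, whose identity/coverage semantics the k-mer
    # statistic only approximates (poorly so at high divergence)
    cand <- unique(unlist(lapply(unique(km[[i]]), function(kr)
      if (!is.null(index[[kr]])) index[[kr]]), use.names = FALSE))
    if (length(cand) > 0) {
      est <- vapply(cand, function(r)
        .qs_kmer_compare(km[[i]], km[[r]], k)[1], numeric(1))
      cand <- cand[est > 0][order(-est[est > 0])]
    }
    best <- 0L; best_sc <- -1
    for (r in cand) {
      sc <- .qs_align_identity(seqs[i], seqs[r])
      if (sc[["identity"]] >= min_identity &&
          sc[["coverage"]] >= min_coverage && sc[["identity"]] > best_sc) {
        best <- r; best_sc <- sc[["identity"]]
      }
    }
    if (best > 0L) {
      rep_of[i] <- best
    } else {
      rep_of[i] <- i
      reps <- c(reps, i)
      for (kr in unique(km[[i]])) index[[kr]] <- c(index[[kr]], i)
    }
  }
  out <- data.frame(id = ids, cluster_id = paste0("C_", ids[rep_of]),
                    stringsAsFactors = FALSE)
  out <- out[match(records$id, out$id), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("cluster_assignment", "data.frame"),
            min_identity = min_identity, min_coverage = min_coverage,
            representatives = ids[reps], method = "builtin")
}

.qs_cluster_mmseqs <- function(records, min_identity, min_coverage) {
  tmp <- tempfile("mmseqs_")
  dir.create(tmp)
  fas <- file.path(tmp, "input.fasta")
  write_fasta(records$id, records$sequence, fas)
  pref <- file.path(tmp, "session")
  res <- suppressWarnings(system2(
    "mmseqs",
    c("easy-cluster", fas, pref, file.path(tmp, "work"),
      "--min-seq-id", format(min_identity), "-c", format(min_coverage),
      "-s", "8", "--max-seqs", "1000", "--cluster-mode", "1",
      "--cluster-reassign"),
    stdout = TRUE, stderr = TRUE))
  status <- attr(res, "status")
  if (!is.null(status) && status != 0) {
    stop("mmseqs easy-cluster failed (exit ", status, "):\n",
         paste(utils::tail(res, 20), collapse = "\n"))
  }
  tab <- utils::read.table(paste0(pref, "_cluster.tsv"), sep = "\t",
                           col.names = c("rep", "member"),
                           stringsAsFactors = FALSE)
  out <- data.frame(id = tab$member, cluster_id = paste0("C_", tab$rep),
                    stringsAsFactors = FALSE)
  out <- out[match(records$id, out$id), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("cluster_assignment", "data.frame"),
            min_identity = min_identity, min_coverage = min_coverage,
            representatives = unique(tab$rep), method = "mmseqs")
}

# shared greedy assignment: clusters (largest first, ties shuffled by
# seed) go to the bin whose chi-square-style deviation from the target
# label composition shrinks most
.qs_cluster_table <- function(ids, labels, cluster_of) {
  cl <- cluster_of[ids]
  labs <- sort(unique(labels))
  counts <- table(factor(cl), factor(labels, levels = labs))
  storage.mode(counts) <- "integer"
  counts
}

#' Cluster-atomic stratified hold-out split
#'
#' Assigns every record to `"train"` or `"holdout"` such that no
#' homology cluster spans both partitions, while keeping the hold-out
#' share of every qs label as close to `holdout_fraction` as the
#' cluster-atomicity constraint allows.  Clusters are visited largest
#' first (ties shuffled by `seed`) and a cluster joins the hold-out when
#' that lowers the summed squared deviation of per-label hold-out counts
#' from their targets.
#'
#' @param dataset a `qs_embedded` or `qs_dataset`.
#' @param clusters a `cluster_assignment` covering all ids.
#' @param holdout_fraction target hold-out share, default 0.10.
#' @param seed integer seed for tie shuffling.
#' @return a `split_assignment`: data.frame with columns `id`,
#'   `partition` (`"train"`/`"holdout"`).
#' @export
make_holdout_split <- function(dataset, clusters, holdout_fraction = 0.10,
                               seed = 1) {
  ids <- .qs_ids(dataset); labels <- .qs_labels(dataset)
  ord <- order(ids); ids <- ids[ord]; labels <- labels[ord]
  cluster_of <- setNames(clusters$cluster_id, clusters$id)
  if (!all(ids %in% clusters$id)) stop("clusters do not cover all ids")
  counts <- .qs_cluster_table(ids, labels, cluster_of)
  n_l <- colSums(counts)
  target <- holdout_fraction * n_l
  sizes <- rowSums(counts)
  if (max(sizes) > ceiling(holdout_fraction * sum(sizes))) {
    warning("a cluster exceeds the hold-out target size; ",
            "the hold-out share may deviate from the requested fraction")
  }
  cl_names <- rownames(counts)
  visit <- .qs_with_seed(seed, sample(length(cl_names)))
  visit <- visit[order(-sizes[visit])]      # stable: ties stay shuffled
  ho <- numeric(ncol(counts))
  in_holdout <- logical(length(cl_names))
  cost <- function(v) sum((v - target)^2 / (target + 1))
  for (i in visit) {
    if (cost(ho + counts[i, ]) < cost(ho)) {
      in_holdout[i] <- TRUE
      ho <- ho + counts[i, ]
    }
  }
  part <- ifelse(in_holdout[match(cluster_of[ids], cl_names)],
                 "holdout", "train")
  structure(data.frame(id = ids, partition = part, stringsAsFactors = FALSE),
            class = c("split_assignment", "data.frame"),
            holdout_fraction = holdout_fraction, seed = seed)
}

#' Cluster-atomic stratified cross-validation folds
#'
#' Partitions the given (training) ids into `k` folds of near-equal
#' size and label composition, never splitting a homology cluster
#' across folds.  Each fold later serves once as the held-out 20% in a
#' 5-fold cross-validation.
#'
#' @param ids character vector of training record ids.
#' @param clusters a `cluster_assignment` covering `ids`.
#' @param labels integer qs labels aligned with `ids`.
#' @param k number of folds, >= 2.
#' @param seed integer seed for tie shuffling.
#' @return data.frame with columns `id`, `fold` (1..k).
#' @export
make_cv_folds <- function(ids, clusters, labels, k = 5, seed = 1) {
  stopifnot(length(ids) == length(labels), k >= 2)
  ord <- order(ids); ids <- ids[ord]; labels <- labels[ord]
  cluster_of <- setNames(clusters$cluster_id, clusters$id)
  if (!all(ids %in% clusters$id)) stop("clusters do not cover all ids")
  counts <- .qs_cluster_table(ids, labels, cluster_of)
  if (k > nrow(counts)) {
    stop(sprintf("k = %d exceeds the number of clusters (%d)", k, nrow(counts)))
  }
  target <- colSums(counts) / k
  size_target <- sum(counts) / k
  sizes <- rowSums(counts)
  visit <- .qs_with_seed(seed, sample(nrow(counts)))
  visit <- visit[order(-sizes[visit])]
  fold_counts <- matrix(0, k, ncol(counts))
  fold_sizes <- numeric(k)
  fold_of_cluster <- integer(nrow(counts))
  for (i in visit) {
    delta <- vapply(seq_len(k), function(f) {
      sum(((fold_counts[f, ] + counts[i, ] - target)^2 -
             (fold_counts[f, ] - target)^2) / (target + 1)) +
        ((fold_sizes[f] + sizes[i] - size_target)^2 -
           (fold_sizes[f] - size_target)^2) / (size_target + 1)
    }, numeric(1))
    f <- which.min(delta)
    fold_of_cluster[i] <- f
    fold_counts[f, ] <- fold_counts[f, ] + counts[i, ]
    fold_sizes[f] <- fold_sizes[f] + sizes[i]
  }
  fold <- fold_of_cluster[match(cluster_of[ids], rownames(counts))]
  data.frame(id = ids, fold = as.integer(fold), stringsAsFactors = FALSE)
}

#' Randomly under-sample over-represented classes
#'
#' For each target class with `n` members, retains `floor(n / factor)`
#' members chosen uniformly at random without replacement; all other
#' classes are untouched.  The default reduces monomers (qs 1) and
#' dimers (qs 2) to a third, the rebalancing used for training.
#'
#' @param labels integer qs labels.
#' @param targets classes to down-sample, default `c(1, 2)`.
#' @param factor down-sampling factor, >= 1.
#' @param seed integer seed.
#' @return sorted integer vector of retained indices into `labels`.
#' @export
downsample_classes <- function(labels, targets = c(1, 2), factor = 3,
                               seed = 1) {
  stopifnot(factor >= 1)
  idx <- seq_along(labels)
  .qs_with_seed(seed, {
    kept <- lapply(split(idx, labels), function(ii) {
      if (labels[ii[1]] %in% targets) {
        m <- floor(length(ii) / factor)
        sort(sample(ii, m))
      } else ii
    })
    sort(unlist(kept, use.names = FALSE))
  })
}

#' Exclude classes too rare to train on
#'
#' Classes with fewer than `min_count` members are removed from the
#' trainable dataset; their records are returned separately so they can
#' still be scored (as never-predictable) at evaluation time.
#'
#' @param dataset a `qs_embedded` dataset.
#' @param min_count minimum class size to keep, >= 1.
#' @return list with `kept` (a `qs_embedded`), `removed` (a
#'   `qs_embedded`, possibly empty) and `removed_labels`.
#' @export
drop_rare_classes <- function(dataset, min_count = 10) {
  stopifnot(inherits(dataset, "qs_embedded"), min_count >= 1)
  cnt <- table(dataset$labels)
  removed_labels <- as.integer(names(cnt)[cnt < min_count])
  if (length(removed_labels) == length(cnt)) {
    stop("min_count removes every class")
  }
  drop <- dataset$labels %in% removed_labels
  list(kept = dataset[!drop],
       removed = if (any(drop)) dataset[drop] else NULL,
       removed_labels = removed_labels)
}

# accessors tolerated by both container types
.qs_ids <- function(x) {
  if (inherits(x, "qs_embedded")) x$ids
  else if (inherits(x, "qs_dataset")) x$records$id
  else stop("expected a qs_embedded or qs_dataset")
}
.qs_labels <- function(x) {
  if (inherits(x, "qs_embedded")) x$labels
  else if (inherits(x, "qs_dataset")) x$records$qs_label
  else stop("expected a qs_embedded or qs_dataset")
}

#' Write a split or fold assignment as a two-column TSV
#'
#' @param assignment data.frame from [make_holdout_split()] or
#'   [make_cv_folds()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_assignment <- function(assignment, path) {
  data.table::fwrite(as.data.frame(assignment), path, sep = "\t")
  invisible(path)
}
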