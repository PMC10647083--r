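# Synthetic pooled-embedding datasets with family structure,
# class-conditional signal and multi-qs families, plus companion
# sequences, so the full pipeline runs offline.

#' Configuration of the synthetic dataset generator
#'
#' The default world: ~2,400 records in 800 sequence families of 2-4
#' members; 12 quaternary states with a skew mirroring real homomer
#' surveys (monomers > dimers > tetramers > trimers ~ hexamers > rare
#' states, rarest at 2-3% so every class stays learnable); embedding
#' dimension 16; class signal 3x the within-class noise and family
#' spread a quarter of it, the regime in which embeddings carry
#' assembly-state information beyond family identity.
#'
#' @param n_families number of sequence families.
#' @param members_range integer range (lo, hi) of members per family.
#' @param class_labels qs labels available to families.
#' @param class_proportions target share of records per label; sums to 1.
#' @param dim embedding dimension D (>= number of classes for
#'   orthonormal class directions).
#' @param family_spread sigma_b: scale of the isotropic family centers.
#' @param within_noise sigma_w: scale of the per-record isotropic noise.
#' @param class_signal s: length of the class direction added to each
#'   record (default 3 * within_noise).
#' @param multi_qs_fraction share of families that harbour a second,
#'   rare quaternary state.
#' @param mutation_rate per-site substitution probability of a member
#'   sequence relative to its family consensus.
#' @param seq_length consensus sequence length.
#' @param seed integer seed; fixed seed gives byte-identical output.
#' @return an object of class `synthetic_config`.
#' @export
synthetic_config <- function(
    n_families = 800,
    members_range = c(2L, 4L),
    class_labels = c(1L, 2L, 3L, 4L, 5L, 6L, 7L, 8L, 10L, 12L, 14L, 24L),
    class_proportions = c(0.24, 0.18, 0.09, 0.12, 0.045, 0.08,
                          0.04, 0.06, 0.04, 0.04, 0.035, 0.03),
    dim = 16L,
    family_spread = 0.25,
    within_noise = 1.0,
    class_signal = 3.0,
    multi_qs_fraction = 0.15,
    mutation_rate = 0.05,
    seq_length = 150L,
    seed = 1L) {
  stopifnot(length(class_labels) == length(class_proportions),
            abs(sum(class_proportions) - 1) < 1e-8,
            all(class_proportions > 0),
            family_spread >= 0, within_noise >= 0, class_signal >= 0,
            multi_qs_fraction >= 0, multi_qs_fraction <= 1,
            mutation_rate >= 0, mutation_rate <= 1,
            length(members_range) == 2, members_range[1] >= 1,
            members_range[2] >= members_range[1],
            n_families >= length(class_labels))
  if (any(.qs_apportion(n_families, class_proportions) < 1)) {
    stop("class proportions leave some class without a family; ",
         "increase n_families or rebalance proportions")
  }
  structure(list(
    n_families = as.integer(n_families),
    members_range = as.integer(members_range),
    class_labels = as.integer(class_labels),
    class_proportions = class_proportions,
    dim = as.integer(dim),
    family_spread = family_spread, within_noise = within_noise,
    class_signal = class_signal,
    multi_qs_fraction = multi_qs_fraction,
    mutation_rate = mutation_rate, seq_length = as.integer(seq_length),
    seed = as.integer(seed)), class = "synthetic_config")
}

# orthonormal class directions (falls back to random unit vectors when
# D < C, with a warning: separability is then not guaranteed)
.qs_class_directions <- function(D, C) {
  if (D >= C) {
    qr.Q(qr(matrix(rnorm(D * C), D, C)))
  } else {
    warning("dim < number of classes; class directions are not orthogonal")
    M <- matrix(rnorm(D * C), D, C)
    sweep(M, 2, sqrt(colSums(M^2)), "/")
  }
}

#' Generate a synthetic embedded dataset with companion sequences
#'
#' Every family gets an isotropic Gaussian center (scale
#' `family_spread`) and one quaternary state (a `multi_qs_fraction` of
#' families also carries a second, rare state on about a quarter of
#' their members).  A member's vector is
#' `center + class_signal * u(qs) + noise` with fixed orthonormal class
#' directions `u` and isotropic noise of scale `within_noise`; its
#' sequence is the family consensus with independent per-site
#' substitutions at `mutation_rate`.  Output is deterministic in the
#' seed.
#'
#' @param config a [synthetic_config()].
#' @return a `qs_simulation`: list with `dataset` (a `qs_embedded`),
#'   `records` (data.frame incl. sequences), `truth` (id, qs,
#'   family_id) and `config`.
#' @export
generate_dataset <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  .qs_with_seed(config$seed, {
    C <- length(config$class_labels)
    U <- .qs_class_directions(config$dim, C)
    fam_counts <- .qs_apportion(config$n_families, config$class_proportions)
    fam_class <- sample(rep.int(seq_len(C), fam_counts))
    members <- sample(seq(config$members_range[1], config$members_range[2]),
                      config$n_families, replace = TRUE)
    n_multi <- round(config$multi_qs_fraction * config$n_families)
    multi_fams <- if (n_multi > 0)
      sample(which(members >= 2), min(n_multi, sum(members >= 2)))
    else integer(0)
    fam_id <- sprintf("F%04d", seq_len(config$n_families))
    centers <- matrix(rnorm(config$n_families * config$dim,
                            sd = config$family_spread),
                      config$n_families, config$dim)
    aa <- .qs_standard_aa
    consensus <- vapply(seq_len(config$n_families), function(f)
      paste(sample(aa, config$seq_length, replace = TRUE), collapse = ""),
      character(1))
    rows <- vector("list", config$n_families)
    for (f in seq_len(config$n_families)) {
      m <- members[f]
      cls <- rep.int(fam_class[f], m)
      if (f %in% multi_fams) {
        others <- setdiff(seq_len(C), fam_class[f])
        second <- others[sample.int(length(others), 1,
                                    prob = config$class_proportions[others])]
        n_rare <- max(1L, floor(m / 4))
        cls[sample(m, n_rare)] <- second
      }
      base <- strsplit(consensus[f], "")[[1]]
      seqs <- vapply(seq_len(m), function(j) {
        mut <- runif(config$seq_length) < config$mutation_rate
        if (any(mut)) {
          repl <- vapply(base[mut], function(b) sample(setdiff(aa, b), 1),
                         character(1))
          base2 <- base; base2[mut] <- repl
          paste(base2, collapse = "")
        } else paste(base, collapse = "")
      }, character(1))
      noise <- matrix(rnorm(m * config$dim, sd = config$within_noise),
                      m, config$dim)
      vec <- matrix(centers[f, ], m, config$dim, byrow = TRUE) +
        config$class_signal * t(U[, cls, drop = FALSE]) + noise
      rows[[f]] <- list(fam = fam_id[f], cls = cls, seqs = seqs, vec = vec)
    }
    labels <- config$class_labels[unlist(lapply(rows, `[[`, "cls"))]
    family <- rep(fam_id, members)
    sequences <- unlist(lapply(rows, `[[`, "seqs"))
    X <- do.call(rbind, lapply(rows, `[[`, "vec"))
    ids <- sprintf("P%05d", seq_along(labels))
    dataset <- embedded_dataset(ids, X, labels, family = family,
                                backend = "synthetic")
    records <- data.frame(id = ids, sequence = sequences,
                          qs_label = labels, family_id = family,
                          cluster_id = NA_character_,
                          stringsAsFactors = FALSE)
    structure(list(dataset = dataset, records = records,
                   truth = records[, c("id", "qs_label", "family_id")],
                   config = config),
              class = "qs_simulation")
  })
}

#' @export
print.qs_simulation <- function(x, ...) {
  cat(sprintf("qs_simulation: %d records, %d families, %d qs labels, D = %d\n",
              nrow(x$records), x$config$n_families,
              length(unique(x$records$qs_label)), x$config$dim))
  invisible(x)
}

#' Decouple sequences from labels
#'
#' Permutes the sequence-to-record mapping while vectors and labels
#' stay fixed: sequence-based signal is destroyed, embedding-based
#' signal untouched.  Used to demonstrate that embeddings carry
#' label information beyond sequence identity.
#'
#' @param sim a `qs_simulation`.
#' @param seed integer seed of the permutation.
#' @return the permuted `qs_simulation`.
#' @export
label_shuffle <- function(sim, seed = 1) {
  stopifnot(inherits(sim, "qs_simulation"))
  perm <- .qs_with_seed(seed, sample(nrow(sim$records)))
  sim$records$sequence <- sim$records$sequence[perm]
  sim$shuffled <- TRUE
  sim
}

#' Write a simulation to disk in the pipeline's file formats
#'
#' Writes `sequences.fasta`, `labels.tsv` (id, qs_label, family_id) and
#' `embeddings.tsv` (pooled-embedding cache) into `dir`.
#'
#' @param sim a `qs_simulation`.
#' @param dir output directory (created if missing).
#' @return the directory, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  stopifnot(inherits(sim, "qs_simulation"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_fasta(sim$records$id, sim$records$sequence,
              file.path(dir, "sequences.fasta"))
  data.table::fwrite(sim$truth, file.path(dir, "labels.tsv"), sep = "\t")
  write_embedding_cache(sim$dataset, file.path(dir, "embeddings.tsv"))
  invisible(dir)
}
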