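# shared fixtures and independent oracles, built in code at test time

# a small, fast synthetic world for structural tests (not the default
# acceptance world)
small_sim <- function(seed = 1, n_families = 60, dim = 8,
                      class_labels = c(1L, 2L, 3L, 4L, 6L),
                      class_proportions = c(0.3, 0.25, 0.15, 0.2, 0.1),
                      ...) {
  generate_dataset(synthetic_config(
    n_families = n_families, dim = dim, class_labels = class_labels,
    class_proportions = class_proportions, seed = seed, ...))
}

random_aa <- function(n, len, seed = NULL) {
  aa <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
  gen <- function() paste(sample(aa, len, replace = TRUE), collapse = "")
  if (!is.null(seed)) set.seed(seed)
  vapply(seq_len(n), function(i) gen(), character(1))
}

mutate_seq <- function(seq, rate, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  aa <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
  ch <- strsplit(seq, "")[[1]]
  mut <- runif(length(ch)) < rate
  ch[mut] <- vapply(ch[mut], function(b) sample(setdiff(aa, b), 1),
                    character(1))
  paste(ch, collapse = "")
}

# identity oracle: matches / alignment length of a local BLOSUM62
# alignment, plus coverage of the shorter sequence
oracle_identity <- function(a, b) {
  data("BLOSUM62", package = "Biostrings", envir = environment())
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b),
    substitutionMatrix = get("BLOSUM62"), gapOpening = 10,
    gapExtension = 0.5, type = "local")
  len <- Biostrings::nchar(aln)
  c(identity = if (len == 0) 0 else Biostrings::nmatch(aln) / len,
    coverage = if (len == 0) 0 else min(1, len / min(nchar(a), nchar(b))))
}

# brute-force metric oracles (independent of the package implementation)
oracle_balanced_accuracy <- function(truth, predicted) {
  accs <- c()
  for (q in unique(truth)) {
    sel <- which(truth == q)
    ok <- 0
    for (i in sel) {
      if (!is.na(predicted[i]) && predicted[i] == truth[i]) ok <- ok + 1
    }
    accs <- c(accs, ok / length(sel))
  }
  mean(accs)
}

oracle_confusion_counts <- function(truth, predicted, classes) {
  cols <- c(as.character(classes), "none")
  M <- matrix(0L, length(classes), length(cols),
              dimnames = list(as.character(classes), cols))
  for (i in seq_along(truth)) {
    p <- if (is.na(predicted[i])) "none" else as.character(predicted[i])
    M[as.character(truth[i]), p] <- M[as.character(truth[i]), p] + 1L
  }
  M
}

oracle_prf <- function(truth, predicted, q) {
  tp <- fp <- fn <- 0
  for (i in seq_along(truth)) {
    pred_q <- !is.na(predicted[i]) && predicted[i] == q
    if (truth[i] == q && pred_q) tp <- tp + 1
    if (truth[i] != q && pred_q) fp <- fp + 1
    if (truth[i] == q && !pred_q) fn <- fn + 1
  }
  c(tp = tp, fp = fp, fn = fn)
}

# exact one-sided ("greater") rank-sum p by direct enumeration over
# which observations belong to x, using the Mann-Whitney pair count
oracle_exact_ranksum_p <- function(x, y) {
  vals <- c(x, y)
  n1 <- length(x); n <- length(vals)
  u_stat <- function(xi) {
    xs <- vals[xi]; ys <- vals[-xi]
    tot <- 0
    for (a in xs) for (b in ys) tot <- tot + (a > b) + 0.5 * (a == b)
    tot
  }
  obs <- u_stat(seq_len(n1))
  sets <- combn(n, n1)
  mean(apply(sets, 2, u_stat) >= obs - 1e-9)
}
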