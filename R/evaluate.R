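# Metrics, confusion matrices, confidence analyses, family diversity.
# Absent predictions (NA) always count as incorrect and are tallied in
# a dedicated "none" bin of the confusion matrix.

#' Balanced accuracy
#'
#' Unweighted mean over the classes present in `truth` of the per-class
#' recall.  Absent predictions (`NA`) are incorrect.
#'
#' @param truth integer vector of true qs labels.
#' @param predicted integer vector of predicted qs labels, `NA` for no
#'   prediction.
#' @return balanced accuracy in `[0, 1]`.
#' @export
balanced_accuracy <- function(truth, predicted) {
  stopifnot(length(truth) == length(predicted))
  if (length(truth) == 0) stop("empty input")
  hit <- !is.na(predicted) & predicted == truth
  mean(tapply(hit, truth, mean))
}

#' Chance-corrected (adjusted) balanced accuracy
#'
#' Rescales balanced accuracy so that random prediction scores 0 and
#' perfect prediction scores 1: `(BA - 1/C) / (1 - 1/C)` with `C` the
#' number of classes.  Used for model selection during hyperparameter
#' search; reports quote the unadjusted value.
#'
#' @inheritParams balanced_accuracy
#' @param n_classes number of classes `C`; defaults to the classes
#'   present in `truth`.
#' @return adjusted balanced accuracy (can be negative).
#' @export
adjusted_balanced_accuracy <- function(truth, predicted, n_classes = NULL) {
  C <- if (is.null(n_classes)) length(unique(truth)) else n_classes
  if (C < 2) stop("adjusted balanced accuracy needs >= 2 classes")
  ba <- balanced_accuracy(truth, predicted)
  (ba - 1 / C) / (1 - 1 / C)
}

#' Per-class precision and recall with aggregate F1
#'
#' Precision is `TP / (TP + FP)`, recall `TP / (TP + FN)`.  The
#' aggregate F1 is the support-weighted mean of per-class F1 over the
#' classes present in `truth` (macro F1 is also returned).  A class
#' that is neither observed nor predicted has undefined metrics and is
#' reported as `NA`; a class with truth support but no predictions gets
#' precision `NA` and F1 0.
#'
#' @inheritParams balanced_accuracy
#' @return list with `per_class` (data.frame `qs`, `support`,
#'   `precision`, `recall`, `f1`), `f1_weighted`, `f1_macro`.
#' @export
f1_and_pr <- function(truth, predicted) {
  stopifnot(length(truth) == length(predicted))
  if (length(truth) == 0) stop("empty input")
  classes <- sort(unique(c(truth, predicted[!is.na(predicted)])))
  per <- lapply(classes, function(q) {
    tp <- sum(truth == q & !is.na(predicted) & predicted == q)
    fp <- sum(truth != q & !is.na(predicted) & predicted == q)
    fn <- sum(truth == q & (is.na(predicted) | predicted != q))
    support <- tp + fn
    precision <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
    recall <- if (support > 0) tp / support else NA_real_
    f1 <- if (support == 0 && tp + fp == 0) NA_real_
          else if (tp == 0) 0
          else 2 * precision * recall / (precision + recall)
    data.frame(qs = q, support = support, precision = precision,
               recall = recall, f1 = f1)
  })
  per <- do.call(rbind, per)
  obs <- per$support > 0
  list(per_class = per,
       f1_weighted = sum(per$f1[obs] * per$support[obs]) / sum(per$support[obs]),
       f1_macro = mean(per$f1[obs]))
}

#' Confusion matrix with an absent-prediction bin
#'
#' Rows are actual classes, columns predicted classes, both in
#' ascending qs order; the last column (`"none"`) counts records
#' without a prediction.  Frequencies are row-normalized (all-zero rows
#' stay zero).
#'
#' @inheritParams balanced_accuracy
#' @return a `qs_confusion`: list with `classes`, `counts`, `freq`.
#' @export
confusion <- function(truth, predicted) {
  stopifnot(length(truth) == length(predicted))
  classes <- sort(unique(c(truth, predicted[!is.na(predicted)])))
  pr <- ifelse(is.na(predicted), "none", as.character(predicted))
  counts <- table(factor(truth, levels = classes),
                  factor(pr, levels = c(as.character(classes), "none")))
  counts <- unclass(counts)
  storage.mode(counts) <- "integer"
  rs <- rowSums(counts)
  freq <- counts / ifelse(rs == 0, 1, rs)
  structure(list(classes = classes, counts = counts, freq = freq),
            class = "qs_confusion")
}

#' @export
print.qs_confusion <- function(x, digits = 2, ...) {
  cat("confusion matrix (rows = actual, columns = predicted):\n")
  print(x$counts)
  invisible(x)
}

#' Write a confusion matrix as CSV
#'
#' @param x a `qs_confusion`.
#' @param path output path prefix; writes `<path>_counts.csv` and
#'   `<path>_freq.csv`.
#' @return the two paths, invisibly.
#' @export
write_confusion <- function(x, path) {
  p1 <- paste0(path, "_counts.csv"); p2 <- paste0(path, "_freq.csv")
  utils::write.csv(x$counts, p1)
  utils::write.csv(round(x$freq, 6), p2)
  invisible(c(p1, p2))
}

#' One-sided rank-sum (Wilcoxon/Mann-Whitney) test
#'
#' Tests whether values in `x` are stochastically greater than values
#' in `y` (alternative `"greater"`; `"less"` and `"two.sided"` are also
#' supported).  For combined sample sizes up to `exact_max_n` the
#' p-value is computed by exhaustive enumeration of rank assignments;
#' above that, by the normal approximation of the rank-sum statistic
#' with tie correction and no continuity correction.
#'
#' @param x,y non-empty numeric samples.
#' @param alternative `"greater"` (default), `"less"` or `"two.sided"`.
#' @param exact_max_n maximum combined size for the exact path.
#' @return list with `statistic` (z value), `p.value`, `method`.
#' @export
rank_sum_test <- function(x, y, alternative = c("greater", "less", "two.sided"),
                          exact_max_n = 12L) {
  alternative <- match.arg(alternative)
  stopifnot(length(x) > 0, length(y) > 0,
            all(is.finite(x)), all(is.finite(y)))
  n1 <- length(x); n2 <- length(y); n <- n1 + n2
  r <- rank(c(x, y))                       # midranks for ties
  W <- sum(r[seq_len(n1)])
  mu <- n1 * (n + 1) / 2
  ties <- table(r)
  sigma2 <- n1 * n2 / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
  z <- if (sigma2 > 0) (W - mu) / sqrt(sigma2) else 0
  if (n <= exact_max_n) {
    sets <- combn(n, n1)
    Wperm <- colSums(matrix(r[sets], nrow = n1))
    p <- switch(alternative,
      greater = mean(Wperm >= W - 1e-9),
      less = mean(Wperm <= W + 1e-9),
      two.sided = min(1, 2 * min(mean(Wperm >= W - 1e-9),
                                 mean(Wperm <= W + 1e-9))))
    return(list(statistic = z, p.value = p, method = "exact"))
  }
  p <- switch(alternative,
    greater = pnorm(z, lower.tail = FALSE),
    less = pnorm(z),
    two.sided = 2 * pnorm(abs(z), lower.tail = FALSE))
  list(statistic = z, p.value = p, method = "normal")
}

#' Do correct predictions come with higher probability?
#'
#' For every actual class, compares the top predicted probability of
#' correct and incorrect predictions with the one-sided rank-sum test:
#' significant separation means the model's probability is a usable
#' confidence score.  Shares its test core with
#' [confidence_separation()]; p-values are uncorrected.
#'
#' @param predictions a data.frame from [predict_proba()] (columns
#'   `id`, `predicted_qs`, `top_prob`).
#' @param truth integer vector of true qs labels aligned with
#'   `predictions` rows.
#' @return data.frame as in [confidence_separation()].
#' @export
probability_confidence <- function(predictions, truth) {
  stopifnot(nrow(predictions) == length(truth),
            all(c("predicted_qs", "top_prob") %in% names(predictions)))
  correct <- !is.na(predictions$predicted_qs) &
    predictions$predicted_qs == truth
  .qs_confidence_table(predictions$top_prob, correct, truth)
}

#' Quaternary-state diversity within families
#'
#' Summarizes, per family, how many distinct qs its members adopt in
#' truth and in prediction, and classifies every record into the
#' subgroups used for family-level accuracy reporting: members of
#' single-qs families, members carrying the dominant qs of a multi-qs
#' family, and members carrying a rare (non-dominant) qs.  The dominant
#' qs is the family's most frequent one, ties resolved towards the
#' smaller qs.  Single-member families and records without a family id
#' are reported separately, never dropped.
#'
#' @inheritParams balanced_accuracy
#' @param family character vector of family ids (NA allowed).
#' @return list with `families` (per-family counts), `records`
#'   (per-record subgroup), `accuracy` (per qs x subgroup accuracy).
#' @export
family_diversity <- function(truth, predicted, family) {
  stopifnot(length(truth) == length(predicted),
            length(truth) == length(family))
  hit <- !is.na(predicted) & predicted == truth
  has_fam <- !is.na(family)
  fams <- sort(unique(family[has_fam]))
  fam_rows <- lapply(fams, function(f) {
    sel <- has_fam & family == f
    tq <- truth[sel]
    cnt <- table(tq)
    dom <- min(as.integer(names(cnt)[cnt == max(cnt)]))
    data.frame(family_id = f, n_members = sum(sel),
               n_qs_actual = length(unique(tq)),
               n_qs_predicted = length(unique(predicted[sel][!is.na(predicted[sel])])),
               dominant_qs = dom,
               single_member = sum(sel) == 1)
  })
  fam_df <- do.call(rbind, fam_rows)
  dom_of <- setNames(fam_df$dominant_qs, fam_df$family_id)
  multi_of <- setNames(fam_df$n_qs_actual > 1, fam_df$family_id)
  single_of <- setNames(fam_df$single_member, fam_df$family_id)
  subgroup <- character(length(truth))
  subgroup[!has_fam] <- "no_family"
  fi <- family[has_fam]
  subgroup[has_fam] <- ifelse(single_of[fi], "singleton",
    ifelse(!multi_of[fi], "single_qs",
      ifelse(truth[has_fam] == dom_of[fi], "multi_dominant", "multi_rare")))
  rec_df <- data.frame(truth = truth, predicted = predicted,
                       family_id = family, subgroup = subgroup,
                       correct = hit)
  groups <- c("single_qs", "multi_dominant", "multi_rare", "singleton",
              "no_family")
  acc_rows <- list()
  for (q in sort(unique(truth))) {
    for (g in c("overall", groups)) {
      sel <- truth == q & (g == "overall" | subgroup == g)
      if (any(sel)) {
        acc_rows[[length(acc_rows) + 1]] <-
          data.frame(qs = q, subgroup = g, n = sum(sel),
                     accuracy = mean(hit[sel]))
      }
    }
  }
  list(families = fam_df, records = rec_df,
       accuracy = do.call(rbind, acc_rows))
}
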