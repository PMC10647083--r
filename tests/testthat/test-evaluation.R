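test_that("balanced accuracy matches counted recalls", {
  expect_equal(balanced_accuracy(c(1, 1, 2, 2), c(1, 1, 2, 2)), 1.0)
  expect_equal(balanced_accuracy(c(1, 1, 2, 2), c(1, 2, 2, 2)), 0.75)
  expect_equal(balanced_accuracy(c(1, 1, 2, 2), c(1, 1, 1, 1)), 0.5)
  expect_equal(balanced_accuracy(c(1, 2), c(NA, 2)), 0.5)  # NA is wrong
  expect_error(balanced_accuracy(integer(0), integer(0)), "empty")
})

test_that("adjusted balanced accuracy is zero at chance, one at perfection", {
  truth <- rep(1:4, each = 5)
  expect_equal(adjusted_balanced_accuracy(truth, truth), 1.0)
  expect_equal(adjusted_balanced_accuracy(truth, rep(1L, 20)), 0.0)
  expect_equal(adjusted_balanced_accuracy(c(1, 1, 2, 2), c(1, 2, 2, 2)),
               (0.75 - 0.5) / 0.5)
})

test_that("precision/recall/F1 match direct TP/FP/FN counting", {
  truth <- c(1, 1, 2, 2); pred <- c(1, 2, 2, 2)
  out <- f1_and_pr(truth, pred)
  expect_equal(out$per_class$precision, c(1, 2 / 3))
  expect_equal(out$per_class$recall, c(0.5, 1))
  expect_equal(out$f1_weighted, 11 / 15)

  perfect <- f1_and_pr(truth, truth)
  expect_equal(perfect$f1_weighted, 1.0)
  expect_equal(perfect$per_class$precision, c(1, 1))

  none_right <- f1_and_pr(c(1, 2), c(2, 1))
  expect_equal(none_right$f1_weighted, 0)

  set.seed(40)
  truth2 <- sample(1:4, 60, TRUE)
  pred2 <- sample(c(1:4, NA), 60, TRUE)
  out2 <- f1_and_pr(truth2, pred2)
  for (r in seq_len(nrow(out2$per_class))) {
    q <- out2$per_class$qs[r]
    o <- oracle_prf(truth2, pred2, q)
    if (o["tp"] + o["fp"] > 0) {
      expect_equal(out2$per_class$precision[r],
                   unname(o["tp"] / (o["tp"] + o["fp"])))
    }
    if (o["tp"] + o["fn"] > 0) {
      expect_equal(out2$per_class$recall[r],
                   unname(o["tp"] / (o["tp"] + o["fn"])))
    }
  }
})

test_that("confusion counts equal exhaustive pair tallies", {
  perfect <- confusion(c(1, 2, 4), c(1, 2, 4))
  expect_equal(unname(diag(perfect$counts[, 1:3])), c(1L, 1L, 1L))
  expect_equal(sum(perfect$counts), 3)

  swapped <- confusion(c(1, 2), c(2, 1))
  expect_equal(unname(diag(swapped$counts[, 1:2])), c(0L, 0L))

  set.seed(41)
  truth <- sample(c(1:5, 7), 50, TRUE)
  pred <- sample(c(1:5, 7, NA), 50, TRUE)
  cm <- confusion(truth, pred)
  expect_equal(unname(cm$counts),
               unname(oracle_confusion_counts(truth, pred, cm$classes)))
  expect_equal(sum(cm$counts), 50)                 # conserves n
  rs <- rowSums(cm$freq)
  expect_true(all(abs(rs - 1) < 1e-9 | rs == 0))
})

test_that("balanced accuracy equals the mean diagonal confusion frequency", {
  set.seed(42)
  for (rep in 1:50) {
    n <- sample(10:60, 1)
    truth <- sample(1:5, n, TRUE)
    pred <- sample(c(1:5, NA), n, TRUE)
    cm <- confusion(truth, pred)
    present <- cm$classes %in% truth
    diag_freq <- diag(cm$freq[, seq_along(cm$classes), drop = FALSE])
    expect_equal(balanced_accuracy(truth, pred),
                 mean(diag_freq[present]), tolerance = 1e-12)
  }
})

test_that("metrics ignore record order", {
  set.seed(43)
  truth <- sample(1:4, 40, TRUE); pred <- sample(c(1:4, NA), 40, TRUE)
  perm <- sample(40)
  expect_equal(balanced_accuracy(truth, pred),
               balanced_accuracy(truth[perm], pred[perm]))
  expect_equal(f1_and_pr(truth, pred)$f1_weighted,
               f1_and_pr(truth[perm], pred[perm])$f1_weighted)
  expect_equal(confusion(truth, pred)$counts,
               confusion(truth[perm], pred[perm])$counts)
})

test_that("rank-sum test: exact enumeration below n = 12, else normal", {
  out <- rank_sum_test(c(10, 11, 12), c(1, 2, 3))
  expect_equal(out$method, "exact")
  expect_equal(out$p.value, 1 / 20)          # the single extreme arrangement

  # exact path agrees with the independent enumeration oracle, with ties
  set.seed(44)
  for (rep in 1:10) {
    x <- sample(1:6, sample(3:5, 1), TRUE)
    y <- sample(1:6, sample(3:5, 1), TRUE)
    expect_equal(rank_sum_test(x, y)$p.value, oracle_exact_ranksum_p(x, y),
                 tolerance = 1e-12)
  }

  # identical samples on the normal path: z = 0, p = 0.5
  z <- rank_sum_test(rep(1:5, 2), rep(1:5, 2))
  expect_equal(z$method, "normal")
  expect_equal(z$p.value, 0.5)

  # swap symmetry in the continuous case
  set.seed(45)
  x <- rnorm(10); y <- rnorm(12)
  expect_equal(rank_sum_test(x, y)$p.value,
               1 - rank_sum_test(y, x)$p.value, tolerance = 1e-12)
})

test_that("normal-path rank-sum matches wilcox.test without continuity", {
  set.seed(46)
  for (rep in 1:10) {
    x <- round(rnorm(15), 1); y <- round(rnorm(18, 0.3), 1)  # some ties
    mine <- rank_sum_test(x, y)
    ref <- stats::wilcox.test(x, y, alternative = "greater",
                              exact = FALSE, correct = FALSE)
    expect_equal(mine$p.value, unname(ref$p.value), tolerance = 1e-10)
  }
})

test_that("probability confidence separates correct from incorrect", {
  set.seed(47)
  pred <- data.frame(
    id = sprintf("p%02d", 1:50),
    predicted_qs = c(rep(2L, 25), rep(4L, 25)),
    top_prob = c(rnorm(25, 0.9, 0.03), rnorm(25, 0.3, 0.05)))
  truth <- rep(2L, 50)                       # first 25 correct
  out <- probability_confidence(pred, truth)
  expect_lt(out$p_value, 0.01)

  # interleaved identical values: no separation
  pred$top_prob <- rep(0.5, 50)
  out2 <- probability_confidence(pred, truth)
  expect_equal(out2$p_value, 0.5)
})

test_that("family diversity report matches brute-force tallies", {
  truth <- c(2, 2, 2, 4,   6, 6,   3,   1, 1)
  pred <- c(2, 2, 4, 4,   6, 2,   3,   1, 2)
  fam <- c("A", "A", "A", "A", "B", "B", "C", NA, NA)
  fd <- family_diversity(truth, pred, fam)

  a <- fd$families[fd$families$family_id == "A", ]
  expect_equal(a$n_members, 4)
  expect_equal(a$n_qs_actual, 2)             # {2, 4}
  expect_equal(a$n_qs_predicted, 2)          # {2, 4}
  expect_equal(a$dominant_qs, 2)             # 3 of 4 members
  cc <- fd$families[fd$families$family_id == "C", ]
  expect_true(cc$single_member)

  rec <- fd$records
  expect_equal(rec$subgroup[4], "multi_rare")      # qs 4 in family A
  expect_equal(rec$subgroup[1], "multi_dominant")
  expect_equal(rec$subgroup[5], "single_qs")
  expect_equal(rec$subgroup[7], "singleton")
  expect_equal(rec$subgroup[8], "no_family")

  acc2 <- fd$accuracy[fd$accuracy$qs == 2 & fd$accuracy$subgroup == "overall", ]
  expect_equal(acc2$accuracy, 2 / 3)

  # dominant-qs tie resolves to the smaller qs
  fd2 <- family_diversity(c(2, 4), c(2, 4), c("Z", "Z"))
  expect_equal(fd2$families$dominant_qs, 2)
})
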