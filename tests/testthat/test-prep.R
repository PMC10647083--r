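test_that("identical sequences collapse to one cluster, unrelated stay apart", {
  recs <- data.frame(id = sprintf("s%d", 1:5),
                     sequence = rep(strrep("MKVLAWHRED", 5), 5))
  cl <- cluster_sequences(recs, method = "builtin")
  expect_equal(length(unique(cl$cluster_id)), 1)

  set.seed(10)
  recs2 <- data.frame(id = c("a", "b"), sequence = random_aa(2, 200))
  cl2 <- cluster_sequences(recs2, method = "builtin")
  expect_equal(length(unique(cl2$cluster_id)), 2)
})

test_that("a mutated family plus an outlier gives two clusters, matching alignment", {
  set.seed(21)
  consensus <- random_aa(1, 120)
  family <- vapply(1:6, function(i) mutate_seq(consensus, 0.2), character(1))
  outlier <- random_aa(1, 120)
  recs <- data.frame(id = sprintf("s%d", 1:7), sequence = c(family, outlier))
  cl <- cluster_sequences(recs, method = "builtin")
  expect_equal(length(unique(cl$cluster_id)), 2)
  expect_equal(length(unique(cl$cluster_id[1:6])), 1)

  # all-pairs alignment oracle agrees: every family pair qualifies at
  # the 30% identity / 30% coverage rule, no outlier pair does (local
  # alignments of unrelated sequences give short, low-coverage hits)
  for (i in 1:5) {
    sc <- oracle_identity(family[i], family[i + 1])
    expect_true(sc[["identity"]] >= 0.3 && sc[["coverage"]] >= 0.3)
  }
  for (i in 1:6) {
    sc <- oracle_identity(family[i], outlier)
    expect_false(sc[["identity"]] >= 0.3 && sc[["coverage"]] >= 0.3)
  }
})

test_that("cluster assignment is invariant to record order", {
  sim <- small_sim(seed = 9, n_families = 12)
  recs <- sim$records
  cl1 <- cluster_sequences(recs, method = "builtin")
  perm <- sample(nrow(recs))
  cl2 <- cluster_sequences(recs[perm, ], method = "builtin")
  m <- match(cl1$id, cl2$id)
  expect_identical(cl1$cluster_id, cl2$cluster_id[m])
})

test_that("hold-out split is cluster-atomic and near the target share", {
  # 800 singleton clusters: the share must land within 10% +/- 2%
  set.seed(5)
  n <- 800
  ds <- embedded_dataset(sprintf("r%03d", 1:n), matrix(rnorm(n * 4), n, 4),
                         sample(1:4, n, TRUE))
  cl <- structure(data.frame(id = ds$ids, cluster_id = paste0("C", 1:n)),
                  class = c("cluster_assignment", "data.frame"))
  sp <- make_holdout_split(ds, cl, holdout_fraction = 0.10, seed = 2)
  share <- mean(sp$partition == "holdout")
  expect_gte(share, 0.08); expect_lte(share, 0.12)
})

test_that("per-class hold-out share stays within 5 points on balanced classes", {
  set.seed(6)
  n <- 1200
  labels <- rep(1:6, each = 200)
  ds <- embedded_dataset(sprintf("r%04d", 1:n), matrix(rnorm(n * 4), n, 4),
                         labels)
  # clusters of size 2 within class so the group constraint bites
  cl <- structure(data.frame(id = ds$ids,
                             cluster_id = paste0("C", rep(1:(n / 2), each = 2))),
                  class = c("cluster_assignment", "data.frame"))
  sp <- make_holdout_split(ds, cl, holdout_fraction = 0.10, seed = 3)
  ho <- sp$partition[match(ds$ids, sp$id)] == "holdout"
  for (q in 1:6) {
    share <- mean(ho[labels == q])
    expect_gte(share, 0.05); expect_lte(share, 0.15)
  }
})

test_that("one giant cluster ends up whole in a single partition, with warning", {
  n <- 50
  ds <- embedded_dataset(sprintf("r%02d", 1:n), matrix(rnorm(n * 3), n, 3),
                         rep(1:2, 25))
  cl <- structure(data.frame(id = ds$ids, cluster_id = "C1"),
                  class = c("cluster_assignment", "data.frame"))
  expect_warning(sp <- make_holdout_split(ds, cl, 0.10, seed = 1),
                 "hold-out")
  expect_equal(length(unique(sp$partition)), 1)
})

test_that("cv folds are cluster-atomic, exhaustive, near-equal", {
  set.seed(8)
  n <- 100
  ids <- sprintf("r%03d", 1:n)
  labels <- sample(1:4, n, TRUE)
  cl <- structure(data.frame(id = ids, cluster_id = paste0("C", 1:n)),
                  class = c("cluster_assignment", "data.frame"))
  folds <- make_cv_folds(ids, cl, labels, k = 5, seed = 4)
  expect_setequal(folds$id, ids)
  expect_equal(as.integer(table(folds$fold)), rep(20L, 5))  # singletons: exact

  # clustered case: fold-size deviation bounded by the largest cluster
  sizes <- sample(1:8, 40, TRUE)
  ids2 <- sprintf("q%03d", 1:sum(sizes))
  cl2 <- structure(data.frame(id = ids2,
                              cluster_id = rep(paste0("K", 1:40), sizes)),
                   class = c("cluster_assignment", "data.frame"))
  labels2 <- sample(1:3, sum(sizes), TRUE)
  folds2 <- make_cv_folds(ids2, cl2, labels2, k = 5, seed = 4)
  cl_of <- setNames(cl2$cluster_id, cl2$id)
  for (f in 1:5) {
    in_f <- unique(cl_of[folds2$id[folds2$fold == f]])
    out_f <- unique(cl_of[folds2$id[folds2$fold != f]])
    expect_length(intersect(in_f, out_f), 0)
  }
  fs <- table(folds2$fold)
  expect_lte(max(fs) - min(fs), max(sizes) + 1)

  expect_error(make_cv_folds(ids2, cl2, labels2, k = 60), "exceeds")
})

test_that("splits and folds are reproducible and order-invariant", {
  sim <- small_sim(seed = 12, n_families = 30)
  cl <- cluster_sequences(sim$records, method = "builtin")
  sp1 <- make_holdout_split(sim$dataset, cl, seed = 9)
  sp2 <- make_holdout_split(sim$dataset, cl, seed = 9)
  expect_identical(sp1, sp2)

  perm <- sample(length(sim$dataset))
  sp3 <- make_holdout_split(sim$dataset[perm], cl, seed = 9)
  expect_identical(sp1$partition[match(sp3$id, sp1$id)], sp3$partition)

  sp4 <- make_holdout_split(sim$dataset, cl, seed = 10)
  expect_false(identical(sp1$partition, sp4$partition))
})

test_that("downsampling retains floor(n/factor) of targets, others untouched", {
  labels <- c(rep(1L, 300), rep(2L, 10), rep(4L, 25), rep(6L, 7))
  keep <- downsample_classes(labels, targets = c(1, 2), factor = 3, seed = 1)
  expect_equal(sum(labels[keep] == 1), 100)        # 300 / 3
  expect_equal(sum(labels[keep] == 2), 3)          # floor(10 / 3)
  expect_equal(sum(labels[keep] == 4), 25)
  expect_equal(sum(labels[keep] == 6), 7)
  # non-target multiset preserved exactly
  expect_identical(labels[keep][labels[keep] %in% c(4, 6)],
                   labels[labels %in% c(4, 6)])

  expect_identical(downsample_classes(labels, factor = 1, seed = 1),
                   seq_along(labels))
})

test_that("drop_rare_classes removes exactly the under-counted classes", {
  labels <- c(rep(1L, 50), rep(2L, 40), rep(7L, 2))
  n <- length(labels)
  ds <- embedded_dataset(sprintf("r%02d", 1:n), matrix(rnorm(n * 3), n, 3),
                         labels)
  out <- drop_rare_classes(ds, min_count = 5)
  expect_equal(out$removed_labels, 7L)
  expect_equal(length(out$kept), 90)
  expect_equal(length(out$removed), 2)

  # brute-force count filter agrees
  cnt <- table(labels)
  expect_equal(out$removed_labels,
               as.integer(names(cnt)[cnt < 5]))

  all_kept <- drop_rare_classes(ds, min_count = 1)
  expect_equal(length(all_kept$kept), n)
  expect_error(drop_rare_classes(ds, min_count = 100), "every class")
})
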