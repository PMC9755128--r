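test_that("fold splits are near-equal, exhaustive and seed-deterministic", {
  pos5 <- cbind(1:5, 1)
  expect_equal(sort(tabulate(kfold_split(pos5, 5, seed = 2))), rep(1L, 5))
  pos407 <- cbind(rep(1:37, each = 11), rep(1:11, 37))[1:407, ]
  f <- kfold_split(pos407, 5, seed = 9)
  sizes <- tabulate(f, 5)
  expect_equal(sum(sizes), 407)
  expect_lte(max(sizes) - min(sizes), 1)
  expect_identical(f, kfold_split(pos407, 5, seed = 9))
  expect_false(identical(f, kfold_split(pos407, 5, seed = 10)))
  expect_error(kfold_split(pos5, 6), "exceeds")
  expect_error(kfold_split(pos5, 1), "folds")
})

test_that("rank-based AUC handles the textbook cases and ties by midranks", {
  expect_equal(roc_auc(c(0.9, 0.8, 0.3), c(1, 0, 1)), 0.5)
  expect_equal(roc_auc(c(0.9, 0.8, 0.3, 0.2), c(1, 1, 0, 0)), 1)
  expect_equal(roc_auc(rep(0.4, 10), c(rep(1, 4), rep(0, 6))), 0.5)
  expect_error(roc_auc(c(1, 2), c(1, 1)), "both classes")
})

test_that("AUC equals the brute concordant-pair fraction and is rank-invariant", {
  set.seed(51)
  for (rep in 1:25) {
    n <- sample(10:50, 1)
    scores <- sample(seq(0, 1, 0.05), n, replace = TRUE)  # force ties
    labels <- rbinom(n, 1, 0.4)
    if (sum(labels) %in% c(0, n)) next
    a <- roc_auc(scores, labels)
    expect_equal(a, brute_auc(scores, labels))
    # strictly monotone transforms leave AUC unchanged
    expect_equal(roc_auc(exp(3 * scores) - 0.2, labels), a)
  }
})

test_that("AUC agrees with pROC on random data", {
  skip_if_not_installed("pROC")
  set.seed(52)
  scores <- runif(200)
  labels <- rbinom(200, 1, 0.3)
  expect_equal(roc_auc(scores, labels),
               as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                              direction = "<"))),
               tolerance = 1e-12)
})

test_that("AUPR covers the boundary cases and matches the threshold-walk oracle", {
  expect_equal(pr_aupr(c(0.9, 0.8, 0.3, 0.2), c(1, 1, 0, 0)), 1)
  expect_equal(pr_aupr(c(0.9, 0.1, 0.1, 0.1), c(1, 0, 0, 0)), 1)
  set.seed(53)
  for (rep in 1:25) {
    n <- sample(10:40, 1)
    scores <- sample(seq(0, 1, 0.1), n, replace = TRUE)
    labels <- rbinom(n, 1, 0.4)
    if (sum(labels) == 0) next
    expect_equal(pr_aupr(scores, labels), brute_aupr(scores, labels))
  }
  expect_error(pr_aupr(c(1, 2), c(0, 0)), "positive")
})

test_that("AUPR of uninformative scores approaches prevalence", {
  set.seed(54)
  n <- 1e5
  labels <- rbinom(n, 1, 0.02)
  scores <- runif(n)
  expect_equal(pr_aupr(scores, labels), mean(labels), tolerance = 0.15)
})

test_that("confusion metrics behave at fixed thresholds and degenerate inputs", {
  # one cell in each confusion quadrant
  m <- classification_metrics(c(0.9, 0.9, 0.1, 0.1), c(1, 0, 1, 0),
                              threshold = 0.5)
  expect_equal(m$accuracy, 0.5)
  expect_equal(m$mcc, 0)
  p <- classification_metrics(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0),
                              threshold = 0.5)
  for (f in c("accuracy", "sensitivity", "specificity", "precision", "mcc")) {
    expect_equal(p[[f]], 1)
  }
  # nothing predicted positive: precision (and MCC) degrade to 0, with warnings
  ws <- capture_warnings(
    q <- classification_metrics(c(0.1, 0.2, 0.3), c(0, 1, 0), threshold = 0.9))
  expect_true(any(grepl("precision: zero denominator", ws)))
  expect_equal(q$precision, 0)
  expect_equal(q$mcc, 0)
})

test_that("the Youden threshold maximizes TPR - FPR over distinct scores", {
  set.seed(55)
  scores <- round(runif(60), 2)
  labels <- rbinom(60, 1, 0.5)
  m <- classification_metrics(scores, labels, "youden")
  j_at <- function(th) {
    tpr <- mean(scores[labels == 1] >= th)
    fpr <- mean(scores[labels == 0] >= th)
    tpr - fpr
  }
  best <- max(sapply(unique(scores), j_at))
  expect_equal(j_at(m$threshold), best)
})

test_that("run_fold masks without leaking into the similarities", {
  nets <- tiny_networks()
  al <- align_vocabularies(nets$ld, nets$ml, nets$md)
  y <- as.matrix(al$ld)
  pos <- which(y == 1, arr.ind = TRUE)
  held <- pos[1:3, , drop = FALSE]
  cfg <- dmwnn_config(k = 5, lambda = 0.1, layers = 2)
  r <- run_fold(al$ld, al$ml, al$md, held, cfg)
  expect_equal(length(r$scores), 3 + sum(y == 0))
  expect_equal(sum(r$labels), 3)
  # leakage check: the fold's similarity equals similarity of the masked Y,
  # and differs from similarity of the full Y
  y_masked <- y
  y_masked[held] <- 0
  pr_masked <- build_profiles(adjacency(y_masked), al$ml, al$md)
  pr_full <- build_profiles(al$ld, al$ml, al$md)
  sm <- fused_similarity_matrix(pr_masked$lmd, 0.1)
  sf <- fused_similarity_matrix(pr_full$lmd, 0.1)
  i <- held[1, 1]
  expect_false(isTRUE(all.equal(sm[i, ], sf[i, ])))
  # empty holdout: every known positive scores 1, evaluation set = zeros only
  r0 <- run_fold(al$ld, al$ml, al$md, pos[0, , drop = FALSE], cfg)
  expect_equal(length(r0$scores), sum(y == 0))
  expect_true(all(r0$prediction$scores[y == 1] == 1))
  expect_error(run_fold(al$ld, al$ml, al$md, which(y == 0, arr.ind = TRUE)[1, , drop = FALSE], cfg),
               "not known positives")
})

test_that("held-out positives outscore random unknown pairs on planted data", {
  nets <- tiny_networks(seed = 8)
  al <- align_vocabularies(nets$ld, nets$ml, nets$md)
  y <- as.matrix(al$ld)
  pos <- which(y == 1, arr.ind = TRUE)
  held <- pos[kfold_split(pos, 5, seed = 4) == 1, , drop = FALSE]
  r <- run_fold(al$ld, al$ml, al$md, held, dmwnn_config(k = 5, layers = 2))
  expect_gt(mean(r$scores[r$labels == 1]), mean(r$scores[r$labels == 0]))
})

test_that("k-fold cross-validation is reproducible and summarized correctly", {
  nets <- tiny_networks(seed = 3)
  cfg <- dmwnn_config(k = 5, layers = 2)
  e1 <- kfold_cv(nets$ld, nets$ml, nets$md, cfg, folds = 4, seed = 6)
  e2 <- kfold_cv(nets$ld, nets$ml, nets$md, cfg, folds = 4, seed = 6)
  expect_identical(e1$per_fold, e2$per_fold)
  expect_equal(nrow(e1$per_fold), 4)
  expect_equal(e1$mean[["auc"]], mean(e1$per_fold$auc))
  expect_equal(e1$sd[["auc"]], stats::sd(e1$per_fold$auc))
  expect_true(all(e1$per_fold$auc >= 0 & e1$per_fold$auc <= 1))
  # serialization round trip
  f <- tempfile(fileext = ".json")
  write_eval_report(e1, f, "json")
  back <- jsonlite::read_json(f, simplifyVector = TRUE)
  expect_equal(back$mean$auc, e1$mean[["auc"]])
  ftsv <- tempfile(fileext = ".tsv")
  write_eval_report(e1, ftsv, "tsv")
  expect_equal(nrow(utils::read.delim(ftsv)), 4)
})

test_that("LOOCV scores a perfectly separable toy at AUC 1", {
  # l1 and l2 share their miRNA profile and the disease d1; masking either
  # (l, d1) association leaves the other to vote it back through the shared
  # profile, while l3 (no interactions) and d2 (no associations) stay at 0
  ld <- adjacency(matrix(c(1, 1, 0, 0, 0, 0), 3, 2,
                         dimnames = list(c("l1", "l2", "l3"), c("d1", "d2"))))
  ml <- adjacency(matrix(c(1, 1, 0, 1, 1, 0), 3, 2,
                         dimnames = list(c("l1", "l2", "l3"), c("m1", "m2"))),
                  "lncRNA", "miRNA")
  md <- adjacency(matrix(c(1, 1, 0, 0), 2, 2,
                         dimnames = list(c("m1", "m2"), c("d1", "d2"))),
                  "miRNA", "disease")
  cfg <- dmwnn_config(k = 1, lambda = 1, layers = 1)
  ev <- loocv(ld, ml, md, cfg)
  expect_equal(ev$auc, 1)
  expect_equal(ev$n_positives, 2)
  # pooled aggregation also reports an AUPR
  evp <- loocv(ld, ml, md, cfg, aggregate = "pooled")
  expect_equal(evp$auc, 1)
  expect_true(!is.null(evp$aupr))
})

test_that("candidate ranking excludes known pairs and orders deterministically", {
  nets <- tiny_networks(seed = 5)
  pred <- dmwnn_predict(nets$ld, nets$ml, nets$md, dmwnn_config(k = 5))
  y <- as.matrix(nets$ld)
  dis <- colnames(y)[which.max(colSums(y))]
  tab <- rank_candidates(pred, dis, top_n = 10)
  expect_lte(nrow(tab), 10)
  known <- rownames(y)[y[, dis] == 1]
  expect_false(any(tab$lncRNA %in% known))
  expect_true(all(diff(tab$score) <= 0))
  # ties broken by ascending identifier
  tied <- tab$score[1:(nrow(tab) - 1)] == tab$score[2:nrow(tab)]
  if (any(tied)) {
    i <- which(tied)[1]
    expect_true(tab$lncRNA[i] < tab$lncRNA[i + 1])
  }
  expect_error(rank_candidates(pred, "no such disease"), "nearest matches")
})
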