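test_that("the 10-fold 8:2 split reproduces the reference counts exactly", {
  man <- synthetic_manifest()                 # 30/16/16 subjects x 60 images
  plans <- make_splits(man, "diagnosis", seed = 5)
  expect_length(plans, 10)
  for (pl in plans) {
    healthy <- pl$label == 0; depressed <- pl$label == 1
    in_test <- pl$set == "test"
    expect_equal(sum(healthy & !in_test), 1440)   # 80% of 1800
    expect_equal(sum(healthy & in_test), 360)     # 20% of 1800
    expect_equal(sum(depressed & !in_test), 1536) # 80% of 1920
    expect_equal(sum(depressed & in_test), 384)   # 20% of 1920
    # internal 8:2 division of the training pool: 64/16 overall
    expect_equal(sum(healthy & pl$set == "train"), 1152)
    expect_equal(sum(healthy & pl$set == "validation"), 288)
  }
  sev <- make_splits(man, "severity", seed = 5)
  for (pl in sev) {
    for (cl in 0:1) {
      expect_equal(sum(pl$label == cl & pl$set != "test"), 768)
      expect_equal(sum(pl$label == cl & pl$set == "test"), 192)
    }
  }
})

test_that("every image is tested exactly twice across the 10 folds", {
  man <- synthetic_manifest(c(healthy = 5, non_major = 3, major = 2),
                            images_per_subject = 10)
  plans <- make_splits(man, "diagnosis", seed = 9)
  test_count <- integer(nrow(man))
  for (pl in plans) {
    te <- pl$idx[pl$set == "test"]
    test_count[te] <- test_count[te] + 1L
    # partition within each fold: sets are disjoint and exhaustive
    expect_equal(length(pl$idx), nrow(man))
    expect_false(anyNA(pl$set))
  }
  expect_true(all(test_count == 2L))
})

test_that("subject-level splitting keeps each subject's images together", {
  man <- synthetic_manifest(c(healthy = 12, non_major = 6, major = 6),
                            images_per_subject = 4)
  plans <- make_splits(man, "diagnosis", unit = "subject", seed = 3)
  for (pl in plans) {
    per_subject <- tapply(as.character(pl$set), man$subject_id[pl$idx],
                          function(s) length(unique(s)))
    expect_true(all(per_subject == 1))
  }
})

test_that("severity task drops healthy subjects", {
  man <- synthetic_manifest(c(healthy = 4, non_major = 3, major = 3),
                            images_per_subject = 5)
  tl <- task_labels(man, "severity")
  expect_equal(length(tl$idx), 30)
  expect_true(all(man$group[tl$idx] != "healthy"))
  expect_equal(sum(tl$label), 15)              # major = positive class
})

test_that("confusion counts ties as positive predictions", {
  labels <- c(1, 1, 0, 0, 1)
  scores <- c(0.9, 0.5, 0.5, 0.1, 0.2)
  cm <- confusion(labels, scores)
  expect_equal(cm, list(TP = 2, TN = 1, FP = 1, FN = 1))
  expect_error(confusion(numeric(0), numeric(0)), "empty")
  expect_error(confusion(c(1, 0), 0.5), "mismatch")
})

test_that("metric formulas reproduce their defining identities", {
  cm <- list(TP = 166, TN = 328, FP = 32, FN = 218)
  m <- metrics(cm)
  expect_equal(round(100 * m$accuracy, 2), 66.40)
  expect_equal(round(100 * m$precision, 2), 83.84)
  expect_equal(round(100 * m$recall, 2), 43.23)
  expect_equal(round(100 * m$f1, 2), 57.04)
  expect_equal(m$f1, f1_from_pr(m$precision, m$recall))
  # zero denominators give NA, not errors
  m0 <- metrics(list(TP = 0, TN = 5, FP = 0, FN = 0))
  expect_true(is.na(m0$precision) && is.na(m0$recall) && is.na(m0$f1))
  expect_equal(m0$accuracy, 1)
})

test_that("AUC equals brute-force pair counting, with ties at one half", {
  brute_auc <- function(labels, scores) {
    sp <- scores[labels == 1]; sn <- scores[labels == 0]
    tot <- 0
    for (a in sp) for (b in sn)
      tot <- tot + (a > b) + 0.5 * (a == b)
    tot / (length(sp) * length(sn))
  }
  # hand-checkable case: 3 of 4 pairs concordant
  expect_equal(roc_auc(c(1, 1, 0, 0), c(0.9, 0.6, 0.7, 0.2), n_boot = 0)$auc,
               0.75)
  # randomized cross-check incl. heavy ties, n up to 200
  set.seed(31)
  for (rep in 1:5) {
    n <- sample(10:200, 1)
    labels <- rbinom(n, 1, 0.5)
    if (length(unique(labels)) < 2) labels[1:2] <- c(0, 1)
    scores <- round(runif(n), 1)                # many exact ties
    expect_equal(roc_auc(labels, scores, n_boot = 0)$auc,
                 brute_auc(labels, scores))
  }
  # perfect and inverted separation
  expect_equal(roc_auc(c(0, 0, 1, 1), c(0.1, 0.2, 0.8, 0.9), n_boot = 0)$auc, 1)
  expect_equal(roc_auc(c(1, 1, 0, 0), c(0.1, 0.2, 0.8, 0.9), n_boot = 0)$auc, 0)
})

test_that("AUC agrees with the reference implementation", {
  skip_if_not_installed("pROC")
  set.seed(17)
  labels <- rbinom(150, 1, 0.4); labels[1:2] <- c(0, 1)
  scores <- round(rnorm(150, labels, 1.2), 2)
  ref <- as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                        direction = "<")))
  expect_equal(roc_auc(labels, scores, n_boot = 0)$auc, ref)
})

test_that("the ROC curve runs from (0,0) to (1,1) and is monotone", {
  set.seed(23)
  labels <- rep(0:1, each = 30)
  scores <- rnorm(60, labels)
  roc <- roc_auc(labels, scores, n_boot = 0)$roc
  expect_equal(roc$fpr[1], 0); expect_equal(roc$tpr[1], 0)
  expect_equal(roc$fpr[nrow(roc)], 1); expect_equal(roc$tpr[nrow(roc)], 1)
  expect_true(all(diff(roc$fpr) >= 0))
  expect_true(all(diff(roc$tpr) >= 0))
})

test_that("the bootstrap CI brackets the point estimate deterministically", {
  set.seed(29)
  labels <- rep(0:1, each = 40)
  scores <- rnorm(80, labels)
  a <- roc_auc(labels, scores, n_boot = 300, seed = 8)
  b <- roc_auc(labels, scores, n_boot = 300, seed = 8)
  expect_identical(a$ci, b$ci)
  expect_lte(a$ci[1], a$auc); expect_gte(a$ci[2], a$auc)
})

test_that("a full evaluation run produces coherent pooled results", {
  # tiny but complete: the CNN sees trivially separable images whose mean
  # intensity encodes the class, so pooled test AUC must be high
  man <- synthetic_manifest(c(healthy = 4, non_major = 2, major = 2),
                            images_per_subject = 6)
  toy <- toy_images(n_per_class = nrow(man) / 2, size = 50, seed = 3)
  images <- vector("list", nrow(man))
  images[man$group == "healthy"] <- toy$images[toy$labels == 0][1:24]
  images[man$group != "healthy"] <- toy$images[toy$labels == 1][1:24]
  cfg <- cnn_config_reduced(input = 50, kernel = c(5, 3, 3),
                            stride = c(2, 1, 1), epochs = 6, batch = 8,
                            dropout = 0)
  ev <- evaluate_task(man, images, "diagnosis", cfg, seed = 13, n_boot = 50)
  expect_equal(nrow(ev$scores), 2 * nrow(man))   # each image tested twice
  expect_gt(ev$pooled$auc, 0.9)
  expect_equal(nrow(ev$per_fold), 10)
  expect_true(all(ev$per_fold$n_test > 0))
})
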