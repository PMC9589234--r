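task_labels <- function(manifest, task) {
  task <- match.arg(task, c("diagnosis", "severity"))
  grp <- manifest$group
  if (!all(grp %in% c("healthy", "non_major", "major")))
    stop("unknown group labels in manifest")
  if (task == "diagnosis") {
    list(idx = seq_len(nrow(manifest)),
         label = as.integer(grp != "healthy"))
  } else {
    idx <- which(grp %in% c("non_major", "major"))
    list(idx = idx, label = as.integer(grp[idx] == "major"))
  }
}

# split m units into 10 shards whose sizes differ by at most 1, in a
# seeded random order (uses the caller's RNG state)
shard10 <- function(m) {
  sample(rep_len(1:10, m))
}

#' Build the 10-fold 64/16/20 split plans
#'
#' Each class (stratified) is partitioned into 10 shards; fold k uses two
#' consecutive shards (k and k+1, cyclic) as the 20% test set and the
#' remaining eight as the 80% training pool, which is then divided 8:2 into
#' the internal training (64%) and internal validation (16%) sets. With the
#' default image-level unit this reproduces the reference arithmetic
#' (e.g. 1800 healthy + 1920 depression images give 1440/360 and 1536/384
#' train/test per fold); the subject-level unit keeps all images of a
#' subject in the same set, preventing within-subject leakage at the cost
#' of those exact counts.
#'
#' @param manifest data.frame with `subject_id` and `group` columns, one row
#'   per image.
#' @param task `"diagnosis"` (healthy vs depression) or `"severity"`
#'   (non-major vs major depression; healthy rows are dropped).
#' @param unit `"image"` (default) or `"subject"`.
#' @param seed integer seed.
#' @return list of 10 split plans; each has `fold`, `idx` (manifest row
#'   indices), `label` (0/1) and `set` (factor train/validation/test).
#' @export
make_splits <- function(manifest, task = "diagnosis", unit = c("image", "subject"),
                        seed = 1L) {
  unit <- match.arg(unit)
  tl <- task_labels(manifest, task)
  if (length(unique(tl$label)) < 2) stop("need two classes to split")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(derive_seed(seed, paste0("split:", task, ":", unit)))

  # shard assignment per image, stratified by class
  shard <- integer(length(tl$idx))
  for (cl in c(0L, 1L)) {
    rows <- which(tl$label == cl)
    if (unit == "image") {
      shard[rows] <- shard10(length(rows))
    } else {
      subs <- unique(manifest$subject_id[tl$idx[rows]])
      sshard <- shard10(length(subs))
      names(sshard) <- subs
      shard[rows] <- sshard[manifest$subject_id[tl$idx[rows]]]
    }
  }

  plans <- vector("list", 10)
  for (k in 1:10) {
    test_shards <- c(k, k %% 10 + 1)
    set <- rep("train", length(tl$idx))
    set[shard %in% test_shards] <- "test"
    # inner 8:2 stratified train/validation split of the training pool
    for (cl in c(0L, 1L)) {
      pool <- which(set == "train" & tl$label == cl)
      if (unit == "image") {
        val <- sample(pool, round(length(pool) / 5))
      } else {
        subs <- unique(manifest$subject_id[tl$idx[pool]])
        vs <- sample(subs, round(length(subs) / 5))
        val <- pool[manifest$subject_id[tl$idx[pool]] %in% vs]
      }
      set[val] <- "validation"
    }
    plans[[k]] <- list(fold = k, idx = tl$idx, label = tl$label,
                       set = factor(set, c("train", "validation", "test")))
  }
  plans
}

#' Confusion matrix at a score threshold
#'
#' A score greater than or equal to the threshold predicts the positive
#' class (ties count as positive).
#'
#' @param labels 0/1 vector; @param scores numeric vector, same length.
#' @param threshold decision threshold (default 0.5).
#' @return list with TP, TN, FP, FN counts.
#' @export
confusion <- function(labels, scores, threshold = 0.5) {
  if (length(labels) == 0) stop("empty input")
  if (length(labels) != length(scores)) stop("labels/scores length mismatch")
  pred <- scores >= threshold
  pos <- labels == 1
  list(TP = sum(pred & pos), TN = sum(!pred & !pos),
       FP = sum(pred & !pos), FN = sum(!pred & pos))
}

#' Classification metrics from a confusion matrix
#'
#' Accuracy = (TP+TN)/(TP+FN+TN+FP), Precision = TP/(TP+FP),
#' Recall = TP/(TP+FN), F1 = 2TP/(2TP+FP+FN). A metric whose denominator
#' is zero is returned as NA rather than raising an error.
#'
#' @param cm list with TP, TN, FP, FN (see [confusion()]).
#' @return list with accuracy, precision, recall, f1 (fractions in \[0,1\]).
#' @export
metrics <- function(cm) {
  with(cm, {
    n <- TP + FN + TN + FP
    list(
      accuracy = if (n > 0) (TP + TN) / n else NA_real_,
      precision = if (TP + FP > 0) TP / (TP + FP) else NA_real_,
      recall = if (TP + FN > 0) TP / (TP + FN) else NA_real_,
      f1 = if (2 * TP + FP + FN > 0) 2 * TP / (2 * TP + FP + FN) else NA_real_)
  })
}

#' F1 from precision and recall
#' @param precision,recall fractions.
#' @return 2PR/(P+R).
#' @export
f1_from_pr <- function(precision, recall) {
  2 * precision * recall / (precision + recall)
}

#' ROC AUC with a stratified bootstrap confidence interval
#'
#' The AUC is the Mann-Whitney concordance probability (ties counted 1/2),
#' computed by the rank formula. The 95% CI resamples positives and
#' negatives separately (percentile method, seeded).
#'
#' @param labels 0/1 vector; @param scores numeric vector.
#' @param n_boot bootstrap resamples (default 2000; 0 skips the CI).
#' @param seed integer seed for the bootstrap.
#' @return list with `auc`, `ci` (length-2 vector or NULL) and `roc`
#'   (data.frame of FPR/TPR points).
#' @export
roc_auc <- function(labels, scores, n_boot = 2000, seed = 1L) {
  pos <- which(labels == 1); neg <- which(labels == 0)
  if (length(pos) == 0 || length(neg) == 0)
    stop("both classes must be present")
  auc_of <- function(sp, sn) {
    r <- rank(c(sp, sn))
    np <- length(sp)
    (sum(r[seq_len(np)]) - np * (np + 1) / 2) / (np * length(sn))
  }
  auc <- auc_of(scores[pos], scores[neg])
  ci <- NULL
  if (n_boot > 0) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old))
    set.seed(as.integer(seed))
    bs <- numeric(n_boot)
    sp <- scores[pos]; sn <- scores[neg]
    for (b in seq_len(n_boot)) {
      bs[b] <- auc_of(sp[sample.int(length(sp), replace = TRUE)],
                      sn[sample.int(length(sn), replace = TRUE)])
    }
    ci <- unname(stats::quantile(bs, c(0.025, 0.975), type = 7))
  }
  # ROC points at every distinct threshold
  thr <- sort(unique(scores), decreasing = TRUE)
  roc <- data.frame(
    fpr = vapply(thr, function(t) mean(scores[neg] >= t), 0),
    tpr = vapply(thr, function(t) mean(scores[pos] >= t), 0))
  roc <- rbind(data.frame(fpr = 0, tpr = 0), roc)
  list(auc = auc, ci = ci, roc = roc)
}

#' Train and evaluate one task over the 10 cross-validation folds
#'
#' For every fold the CNN is trained on the internal training set, the
#' optimal iteration is chosen from the train/validation accuracy history,
#' and the test images are scored with that model. Test scores are pooled
#' across folds into a single report; per-fold metrics are retained.
#'
#' @param manifest image manifest (`subject_id`, `group`, one row per image).
#' @param images list of pixel matrices parallel to the manifest rows.
#' @param task `"diagnosis"` or `"severity"`.
#' @param config a `cnn_config` (its `seed` is re-derived per fold).
#' @param seed master seed for splitting and per-fold training.
#' @param unit split unit, `"image"` or `"subject"`.
#' @param n_boot bootstrap resamples for the pooled AUC CI.
#' @return list with `pooled` (metrics + auc + ci), `per_fold` data.frame,
#'   `scores` (pooled test scores with manifest row, fold, label) and
#'   `plans`.
#' @export
evaluate_task <- function(manifest, images, task = "diagnosis",
                          config = cnn_config_reduced(), seed = 1L,
                          unit = "image", n_boot = 2000) {
  plans <- make_splits(manifest, task, unit = unit, seed = seed)
  all_scores <- list(); per_fold <- list()
  for (k in seq_along(plans)) {
    pl <- plans[[k]]
    tr <- pl$idx[pl$set == "train"]; trl <- pl$label[pl$set == "train"]
    va <- pl$idx[pl$set == "validation"]; val <- pl$label[pl$set == "validation"]
    te <- pl$idx[pl$set == "test"]; tel <- pl$label[pl$set == "test"]
    cfg <- config
    cfg$seed <- derive_seed(seed, paste0("fold:", task, ":", k))
    model <- build_model(cfg)
    model <- train_model(model, images[tr], trl, images[va], val)
    best <- select_best_epoch(model$history, cfg$select)
    model <- restore_epoch(model, best)
    sc <- predict_ai_score(model, images[te])
    cmk <- confusion(tel, sc)
    mk <- metrics(cmk)
    per_fold[[k]] <- data.frame(fold = k, best_epoch = best,
                                n_test = length(te),
                                auc = roc_auc(tel, sc, n_boot = 0)$auc,
                                accuracy = mk$accuracy,
                                precision = mk$precision,
                                recall = mk$recall, f1 = mk$f1)
    all_scores[[k]] <- data.frame(row = te, fold = k, label = tel, score = sc)
  }
  scores <- do.call(rbind, all_scores)
  cm <- confusion(scores$label, scores$score)
  pooled <- metrics(cm)
  ra <- roc_auc(scores$label, scores$score, n_boot = n_boot,
                seed = derive_seed(seed, paste0("boot:", task)))
  list(pooled = c(pooled, list(auc = ra$auc, auc_ci = ra$ci,
                               confusion = cm)),
       per_fold = do.call(rbind, per_fold),
       scores = scores, roc = ra$roc, plans = plans)
}
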