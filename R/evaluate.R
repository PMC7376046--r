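# Leakage-safe five-fold cross-validation and metrics: confusion matrices,
# F-score, ROC/AUC (pooled and mean), learning curves, t-SNE.

#' Stratified fold assignment for original crops
#'
#' Shuffles originals within each class (seeded) and deals them round-robin
#' into `k` folds, so folds are disjoint, cover all originals, differ in
#' size by at most one, and keep both classes represented in every fold's
#' complement. Only unaugmented crops may be assigned.
#'
#' @param crops labeled original `cell_crop`s (`origin_id == crop_id`).
#' @param k number of folds (default 5).
#' @param seed shuffle seed.
#' @return a `fold_plan`: `k`, named integer vector `assignments`
#'   (crop id -> fold), `seed`.
#' @export
make_folds <- function(crops, k = 5L, seed = 1L) {
  ids <- vapply(crops, `[[`, "", "crop_id")
  if (any(ids != origin_ids(crops)))
    stop_ctc("ctcscope_parameter_error",
             "folds must be made from original (unaugmented) crops")
  labs <- crop_labels(crops)
  if (any(labs == "UNLABELED"))
    stop_ctc("ctcscope_parameter_error", "fold crops must be labeled")
  if (length(crops) < k)
    stop_ctc("ctcscope_parameter_error",
             "%d originals cannot fill %d folds", length(crops), k)
  with_seed(seed, {
    ordered <- unlist(lapply(CLASS_LEVELS, function(cls) {
      cl_ids <- ids[labs == cls]
      if (length(cl_ids)) sample(cl_ids) else character(0)
    }))
    fold <- ((seq_along(ordered) - 1L) %% k) + 1L
    names(fold) <- ordered
    structure(list(k = as.integer(k), assignments = fold,
                   seed = as.integer(seed)),
              class = "fold_plan")
  })
}

#' F-score from a 2x2 confusion matrix
#'
#' `precision = TP / (TP + FP)`, `recall = TP / (TP + FN)`,
#' `F = 2 P R / (P + R)` — the harmonic mean weighting precision and recall
#' equally. Degenerate cases (P + R = 0, or no true/predicted positives)
#' return 0 with attribute `degenerate = TRUE`.
#'
#' @param cm 2x2 matrix, rows = truth, cols = prediction, order
#'   `c("WBC", "CTC")`.
#' @param positive positive class (default `"CTC"`).
#' @return F-score with attributes `precision`, `recall`, `degenerate`.
#' @export
f_score <- function(cm, positive = "CTC") {
  stopifnot(all(dim(cm) == c(2, 2)))
  if (sum(cm) == 0) stop_ctc("ctcscope_parameter_error", "empty confusion matrix")
  i <- match(positive, CLASS_LEVELS)
  tp <- cm[i, i]; fp <- sum(cm[-i, i]); fn <- sum(cm[i, -i])
  p <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  r <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  degen <- is.na(p) || is.na(r) || (p + r) == 0
  f <- if (degen) 0 else 2 * p * r / (p + r)
  structure(f, precision = p, recall = r, degenerate = degen)
}

#' ROC curve and AUC
#'
#' Threshold sweep over the unique scores (ties grouped), trapezoidal AUC;
#' numerically identical to the normalized Mann-Whitney U statistic.
#'
#' @param scores per-item probability of the positive (CTC) class.
#' @param truths class labels (`"WBC"`/`"CTC"` or factor).
#' @param positive positive class.
#' @return list with `roc` (data.frame `fpr`, `tpr`, `threshold`) and `auc`.
#' @export
roc_auc <- function(scores, truths, positive = "CTC") {
  truths <- as.character(truths)
  pos <- truths == positive
  n_pos <- sum(pos); n_neg <- sum(!pos)
  if (n_pos == 0 || n_neg == 0)
    stop_ctc("ctcscope_undefined_auc_error",
             "AUC undefined: only one class present in truths")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; p <- pos[ord]
  uniq_last <- c(diff(s) != 0, TRUE)      # last index of each tied group
  tp <- cumsum(p)[uniq_last]
  fp <- cumsum(!p)[uniq_last]
  roc <- data.frame(fpr = c(0, fp / n_neg), tpr = c(0, tp / n_pos),
                    threshold = c(Inf, s[uniq_last]))
  auc <- sum(diff(roc$fpr) * (head(roc$tpr, -1) + roc$tpr[-1]) / 2)
  list(roc = roc, auc = auc)
}

#' Pooled and mean AUC over folds
#'
#' The pooled AUC concatenates all folds' scores and truths before a single
#' ROC computation; the mean AUC averages per-fold AUCs. Both aggregations
#' are reported and labelled explicitly. A single-class fold is skipped from
#' the mean with a warning.
#'
#' @param scores_list,truths_list per-fold score and truth vectors.
#' @return list with `pooled_auc`, `mean_auc`, `per_fold_auc`.
#' @export
pooled_and_mean_auc <- function(scores_list, truths_list) {
  stopifnot(length(scores_list) == length(truths_list), length(scores_list) >= 1)
  per <- vapply(seq_along(scores_list), function(i) {
    tryCatch(roc_auc(scores_list[[i]], truths_list[[i]])$auc,
             ctcscope_undefined_auc_error = function(e) {
               warning(sprintf("fold %d skipped from mean AUC: %s",
                               i, conditionMessage(e)))
               NA_real_
             })
  }, 0)
  pooled <- roc_auc(unlist(scores_list), unlist(truths_list))$auc
  list(pooled_auc = pooled, mean_auc = mean(per, na.rm = TRUE),
       per_fold_auc = per)
}

confusion_2x2 <- function(truths, preds) {
  cm <- matrix(0, 2, 2, dimnames = list(truth = CLASS_LEVELS,
                                        pred = CLASS_LEVELS))
  for (i in 1:2) for (j in 1:2)
    cm[i, j] <- sum(truths == CLASS_LEVELS[i] & preds == CLASS_LEVELS[j])
  cm
}

# split augmented crops 80/20 train/validation at the origin level,
# stratified by class, seeded; no origin contributes to both sides
split_by_origin <- function(aug, frac_val = 0.2, seed = 1L) {
  origs <- origin_ids(aug)
  labs <- crop_labels(aug)
  with_seed(seed, {
    val_origins <- unlist(lapply(CLASS_LEVELS, function(cls) {
      o <- unique(origs[labs == cls])
      n_val <- max(1L, round(frac_val * length(o)))
      if (n_val >= length(o)) n_val <- length(o) - 1L
      sample(o, n_val)
    }))
  })
  in_val <- origs %in% val_origins
  list(train = aug[!in_val], val = aug[in_val])
}

#' Run leakage-safe k-fold cross-validation
#'
#' For each fold: the other folds' originals are augmented to the
#' `aug_spec` target, the augmented set is split 80/20 into train/validation at the
#' origin level, the model is trained, and predictions are made on the held
#' fold's ORIGINAL crops only — no crop derived from a test original ever
#' enters training or validation. That disjointness is asserted at runtime
#' and any violation is a hard error.
#'
#' @param originals labeled, normalized original crops.
#' @param plan a [make_folds()] plan over exactly these crops.
#' @param aug_spec an [augment_spec()]; per-fold seeds are derived from it.
#' @param config a [train_config()].
#' @return an `eval_report`: per-fold confusion matrices and metrics
#'   (accuracy, precision, recall, F-score, AUC), pooled confusion matrix
#'   and ROC, pooled and mean AUC, mean learning history, and the per-crop
#'   predictions.
#' @export
run_cv <- function(originals, plan, aug_spec = augment_spec(),
                   config = train_config()) {
  stopifnot(inherits(plan, "fold_plan"))
  ids <- vapply(originals, `[[`, "", "crop_id")
  asg <- plan$assignments
  if (anyDuplicated(names(asg)))
    stop_ctc("ctcscope_leakage_error",
             "fold plan assigns a crop to more than one fold")
  if (!setequal(names(asg), ids))
    stop_ctc("ctcscope_parameter_error",
             "fold plan does not cover exactly the given originals")
  k <- plan$k
  per_fold <- vector("list", k)
  all_scores <- vector("list", k); all_truths <- vector("list", k)
  pred_rows <- NULL
  histories <- vector("list", k)
  for (f in seq_len(k)) {
    test_ids <- names(asg)[asg == f]
    train_ids <- names(asg)[asg != f]
    if (length(intersect(test_ids, train_ids)))
      stop_ctc("ctcscope_leakage_error",
               "fold %d shares origins between train and test", f)
    test_crops <- originals[ids %in% test_ids]
    train_orig <- originals[ids %in% train_ids]
    spec_f <- aug_spec
    spec_f$seed <- aug_spec$seed + f
    aug <- augment_crops(train_orig, spec_f)
    # zero-leakage assertion: nothing in the augmented pool derives from a
    # test original
    leak <- intersect(origin_ids(aug), test_ids)
    if (length(leak))
      stop_ctc("ctcscope_leakage_error",
               "fold %d: augmented crops derive from test originals: %s",
               f, paste(head(leak, 5), collapse = ", "))
    sp <- split_by_origin(aug, 0.2, seed = spec_f$seed + 1000L)
    cfg_f <- config
    cfg_f$seed <- config$seed + f
    model <- build_model(cfg_f)
    model <- train_model(model, sp$train, sp$val, cfg_f)
    pred <- predict(model, test_crops)
    truth <- crop_labels(test_crops)
    cm <- confusion_2x2(truth, pred$label)
    fs <- f_score(cm)
    auc_f <- tryCatch(roc_auc(pred$p_ctc, truth)$auc,
                      ctcscope_undefined_auc_error = function(e) NA_real_)
    per_fold[[f]] <- list(fold = f, cm = cm,
                          accuracy = sum(diag(cm)) / sum(cm),
                          precision = attr(fs, "precision"),
                          recall = attr(fs, "recall"),
                          f_score = as.numeric(fs), auc = auc_f,
                          n_test = length(test_crops))
    all_scores[[f]] <- pred$p_ctc
    all_truths[[f]] <- truth
    histories[[f]] <- model$history
    pred_rows <- rbind(pred_rows,
                       cbind(pred, truth = truth, fold = f))
  }
  pooled_cm <- Reduce(`+`, lapply(per_fold, `[[`, "cm"))
  pooled <- roc_auc(unlist(all_scores), unlist(all_truths))
  aucs <- pooled_and_mean_auc(all_scores, all_truths)
  n_ep <- min(vapply(histories, nrow, 0L))
  mean_hist <- Reduce(`+`, lapply(histories, function(h) h[seq_len(n_ep), ])) / k
  mean_hist$epoch <- seq_len(n_ep)
  structure(list(per_fold = per_fold, pooled_cm = pooled_cm,
                 pooled_roc = pooled$roc, pooled_auc = aucs$pooled_auc,
                 mean_auc = aucs$mean_auc,
                 pooled_accuracy = sum(diag(pooled_cm)) / sum(pooled_cm),
                 pooled_f_score = as.numeric(f_score(pooled_cm)),
                 mean_history = mean_hist, predictions = pred_rows,
                 plan = plan),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("%d-fold cross-validation on %d original crops\n",
              length(x$per_fold), sum(x$pooled_cm)))
  cat(sprintf("pooled accuracy %.3f | F-score (CTC) %.3f | pooled AUC %.3f | mean AUC %.3f\n",
              x$pooled_accuracy, x$pooled_f_score, x$pooled_auc, x$mean_auc))
  cat("pooled confusion matrix (rows = truth, cols = predicted):\n")
  print(x$pooled_cm)
  invisible(x)
}

# --- t-SNE -----------------------------------------------------------------

# perplexity calibration: binary search of the Gaussian bandwidth per point
tsne_p_matrix <- function(D2, perplexity) {
  n <- nrow(D2)
  target <- log(perplexity)
  P <- matrix(0, n, n)
  for (i in seq_len(n)) {
    beta <- 1; lo <- -Inf; hi <- Inf
    di <- D2[i, -i]
    for (iter in 1:50) {
      w <- exp(-di * beta)
      sw <- sum(w)
      H <- log(sw) + beta * sum(di * w) / sw
      if (abs(H - target) < 1e-5) break
      if (H > target) { lo <- beta; beta <- if (is.finite(hi)) (beta + hi) / 2 else beta * 2 }
      else            { hi <- beta; beta <- if (is.finite(lo)) (beta + lo) / 2 else beta / 2 }
    }
    P[i, -i] <- w / sw
  }
  P <- (P + t(P)) / (2 * n)
  pmax(P, 1e-12)
}

#' t-SNE embedding of crop pixel vectors
#'
#' Exact (non-Barnes-Hut) t-SNE with perplexity calibration, early
#' exaggeration and momentum gradient descent. Defaults follow the standard
#' visualization setting for this dataset family: perplexity 50, learning
#' rate 100. Stochastic by nature — the contract is output shape and seeded
#' reproducibility, not specific geometry.
#'
#' @param X numeric matrix, one row per item.
#' @param perplexity effective neighbourhood size; requires
#'   `nrow(X) >= 3 * perplexity`.
#' @param learning_rate gradient step scale.
#' @param seed integer seed.
#' @param n_iter gradient-descent iterations.
#' @return `nrow(X)` x 2 coordinate matrix.
#' @export
tsne_embed <- function(X, perplexity = 50, learning_rate = 100, seed = 1L,
                       n_iter = 400L) {
  n <- nrow(X)
  if (n < 3 * perplexity)
    stop_ctc("ctcscope_parameter_error",
             "t-SNE needs at least 3 * perplexity = %g points, got %d",
             3 * perplexity, n)
  D2 <- as.matrix(dist(X))^2
  P <- tsne_p_matrix(D2, perplexity)
  with_seed(seed, {
    Y <- matrix(rnorm(n * 2, 0, 1e-4), n, 2)
    inc <- matrix(0, n, 2)
    momentum <- 0.5
    for (it in seq_len(n_iter)) {
      Pe <- if (it <= 100) P * 4 else P
      num <- 1 / (1 + as.matrix(dist(Y))^2)
      diag(num) <- 0
      Q <- pmax(num / sum(num), 1e-12)
      W <- (Pe - Q) * num
      grad <- 4 * (diag(rowSums(W)) - W) %*% Y
      if (it == 250) momentum <- 0.8
      inc <- momentum * inc - learning_rate * grad
      Y <- Y + inc
      Y <- sweep(Y, 2, colMeans(Y))
    }
    Y
  })
}

#' t-SNE scatter of an augmented training set
#'
#' Embeds flattened normalized crop pixels to 2-D and draws a class-colored
#' scatter (WBC green, CTC red) on the current device.
#'
#' @param crops labeled `cell_crop`s.
#' @inheritParams tsne_embed
#' @param draw draw the scatter (default TRUE).
#' @return invisibly, a list with `embedding` (n x 2) and `labels`.
#' @export
tsne_plot <- function(crops, perplexity = 50, learning_rate = 100, seed = 1L,
                      draw = TRUE) {
  X <- t(vapply(crops, function(cr) as.numeric(cr$pixels),
                numeric(length(crops[[1]]$pixels))))
  Y <- tsne_embed(X, perplexity, learning_rate, seed)
  labs <- crop_labels(crops)
  if (draw) {
    cols <- ifelse(labs == "CTC", "#d62728", "#2ca02c")
    graphics::plot(Y[, 1], Y[, 2], col = cols, pch = 19, cex = 0.6,
                   xlab = "t-SNE 1", ylab = "t-SNE 2",
                   main = "t-SNE of single-cell crops")
    graphics::legend("topright", legend = c("WBC", "CTC"),
                     col = c("#2ca02c", "#d62728"), pch = 19, bty = "n")
  }
  invisible(list(embedding = Y, labels = labs))
}

#' Diagnostic plots for an evaluation report
#'
#' `plot_roc` draws the pooled ROC curve with the chance diagonal;
#' `plot_learning_curves` the mean train/validation loss and accuracy per
#' epoch.
#'
#' @param report an `eval_report` from [run_cv()].
#' @return invisibly, the report.
#' @export
plot_roc <- function(report) {
  graphics::plot(report$pooled_roc$fpr, report$pooled_roc$tpr, type = "l",
                 lwd = 2, col = "#1f77b4", xlab = "False positive rate",
                 ylab = "True positive rate",
                 main = sprintf("Pooled ROC (AUC = %.3f, mean AUC = %.3f)",
                                report$pooled_auc, report$mean_auc))
  graphics::abline(0, 1, lty = 2, col = "grey50")
  invisible(report)
}

#' @rdname plot_roc
#' @export
plot_learning_curves <- function(report) {
  h <- report$mean_history
  old <- graphics::par(mfrow = c(1, 2)); on.exit(graphics::par(old))
  graphics::plot(h$epoch, h$train_loss, type = "l", lwd = 2, col = "#1f77b4",
                 ylim = range(c(h$train_loss, h$val_loss)),
                 xlab = "epoch", ylab = "cross-entropy", main = "Loss")
  graphics::lines(h$epoch, h$val_loss, lwd = 2, col = "#ff7f0e")
  graphics::plot(h$epoch, h$train_acc, type = "l", lwd = 2, col = "#1f77b4",
                 ylim = c(0, 1), xlab = "epoch", ylab = "accuracy",
                 main = "Accuracy")
  graphics::lines(h$epoch, h$val_acc, lwd = 2, col = "#ff7f0e")
  graphics::legend("bottomright", legend = c("train", "validation"),
                   col = c("#1f77b4", "#ff7f0e"), lwd = 2, bty = "n")
  invisible(report)
}
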