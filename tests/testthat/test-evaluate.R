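test_that("make_folds is a stratified, seeded partition with near-equal sizes", {
  toy <- make_toy_crops(60)          # 120 originals
  plan <- make_folds(toy, k = 5, seed = 1)
  expect_s3_class(plan, "fold_plan")
  sizes <- tabulate(plan$assignments, 5)
  expect_true(max(sizes) - min(sizes) <= 1)
  expect_setequal(names(plan$assignments), vapply(toy, `[[`, "", "crop_id"))
  expect_identical(plan$assignments, make_folds(toy, 5, seed = 1)$assignments)

  # the study's size: 95 originals in 5 folds of exactly 19
  orig95 <- c(make_toy_crops(32)[33:64], make_toy_crops(63)[1:63])
  orig95 <- lapply(seq_along(orig95), function(i) {
    cr <- orig95[[i]]
    cr$crop_id <- cr$origin_id <- sprintf("s%02d", i)
    cr
  })
  plan95 <- make_folds(orig95, k = 5, seed = 2)
  expect_identical(unname(tabulate(plan95$assignments, 5)), rep(19L, 5))

  expect_error(make_folds(toy[1:3], k = 5), class = "ctcscope_parameter_error")
})

test_that("f_score matches direct arithmetic on every small matrix", {
  cm <- matrix(c(90, 1, 1, 8), 2, 2, byrow = TRUE,
               dimnames = list(c("WBC", "CTC"), c("WBC", "CTC")))
  # rows truth [WBC, CTC]: TP=8, FP=1, FN=1
  f <- f_score(cm)
  expect_equal(as.numeric(f), 8 / 9, tolerance = 1e-12)
  expect_equal(attr(f, "precision"), 8 / 9)

  perfect <- matrix(c(5, 0, 0, 5), 2, 2)
  expect_equal(as.numeric(f_score(perfect)), 1)

  degen <- matrix(c(10, 0, 5, 0), 2, 2, byrow = TRUE)
  fd <- f_score(degen)
  expect_equal(as.numeric(fd), 0)
  expect_true(attr(fd, "degenerate"))

  for (tn in 0:6) for (fp in 0:6) for (fn in 0:6) for (tp in 0:6) {
    if (tn + fp + fn + tp == 0) next
    cmx <- matrix(c(tn, fp, fn, tp), 2, 2, byrow = TRUE)
    expect_equal(as.numeric(f_score(cmx)), oracle_f_score(tp, fp, fn),
                 tolerance = 1e-12)
  }
})

test_that("roc_auc matches the pair-counting oracle and handles edge cases", {
  sep <- roc_auc(c(0.1, 0.2, 0.8, 0.9), c("WBC", "WBC", "CTC", "CTC"))
  expect_equal(sep$auc, 1)
  flat <- roc_auc(rep(0.5, 10), rep(c("WBC", "CTC"), 5))
  expect_equal(flat$auc, 0.5)
  expect_error(roc_auc(runif(5), rep("CTC", 5)),
               class = "ctcscope_undefined_auc_error")

  set.seed(4)
  for (i in 1:100) {
    n <- sample(4:30, 1)
    truths <- c("WBC", "CTC", sample(c("WBC", "CTC"), n - 2, replace = TRUE))
    scores <- round(runif(n), sample(1:3, 1))   # induce ties
    expect_equal(roc_auc(scores, truths)$auc, oracle_auc(scores, truths),
                 tolerance = 1e-9)
  }

  # ROC endpoints
  r <- roc_auc(runif(20), sample(c("WBC", "CTC"), 20, replace = TRUE))$roc
  expect_equal(r$fpr[1], 0); expect_equal(r$tpr[1], 0)
  expect_equal(r$fpr[nrow(r)], 1); expect_equal(r$tpr[nrow(r)], 1)
})

test_that("pooled and mean AUC aggregate as defined", {
  s1 <- c(0.1, 0.9, 0.2, 0.8); t1 <- c("WBC", "CTC", "WBC", "CTC")
  same <- pooled_and_mean_auc(list(s1, s1), list(t1, t1))
  expect_equal(same$pooled_auc, same$mean_auc)

  s2 <- c(0.5, 0.5, 0.5, 0.5)
  two <- pooled_and_mean_auc(list(s1, s2), list(t1, t1))
  expect_equal(two$mean_auc, 0.75)

  direct <- roc_auc(c(s1, s2), c(t1, t1))$auc
  expect_equal(two$pooled_auc, direct)

  expect_warning(
    skipped <- pooled_and_mean_auc(list(s1, c(0.3, 0.6)),
                                   list(t1, c("CTC", "CTC"))),
    "skipped")
  expect_equal(skipped$mean_auc, 1)
})

test_that("run_cv is leakage-safe and exact on toy separable classes", {
  toy <- make_toy_crops(10)
  plan <- make_folds(toy, k = 5, seed = 3)
  idspec <- augment_spec(target_per_class = 16, rotation_range_deg = 0,
                         shear_range = 0, allow_hflip = FALSE,
                         allow_vflip = FALSE, seed = 1)
  cfg <- toy_train_config(max_epochs = 10)
  rep <- run_cv(toy, plan, idspec, cfg)
  expect_s3_class(rep, "eval_report")
  expect_length(rep$per_fold, 5)
  expect_equal(rep$pooled_accuracy, 1)
  expect_equal(sum(rep$pooled_cm), 20)
  # confusion-matrix conservation: row sums = class counts
  expect_equal(unname(rowSums(rep$pooled_cm)), c(10, 10))
  expect_equal(rep$pooled_auc, 1)

  # a corrupted plan that assigns one crop to two folds is refused
  bad <- plan
  bad$assignments <- c(bad$assignments, setNames(2L, names(bad$assignments)[1]))
  expect_error(run_cv(toy, bad, idspec, cfg), class = "ctcscope_leakage_error")

  # a plan over different crops is refused
  other <- make_toy_crops(10, prefix = "other")
  expect_error(run_cv(other, plan, idspec, cfg),
               class = "ctcscope_parameter_error")
})

test_that("t-SNE embeds with seeded determinism and separates distinct classes", {
  expect_error(tsne_embed(matrix(rnorm(20), 10), perplexity = 50),
               class = "ctcscope_parameter_error")

  set.seed(6)
  X <- rbind(matrix(rnorm(90 * 16), 90), matrix(rnorm(90 * 16, mean = 5), 90))
  Y <- tsne_embed(X, perplexity = 30, learning_rate = 100, seed = 9,
                  n_iter = 250)
  expect_equal(dim(Y), c(180, 2))
  expect_identical(Y, tsne_embed(X, perplexity = 30, learning_rate = 100,
                                 seed = 9, n_iter = 250))
  sil <- cluster::silhouette(rep(1:2, each = 90), dist(Y))
  expect_gt(mean(sil[, 3]), 0.3)
})

test_that("roc_auc agrees with an established implementation", {
  set.seed(12)
  scores <- runif(60)
  truths <- sample(c("WBC", "CTC"), 60, replace = TRUE)
  ours <- roc_auc(scores, truths)$auc
  ref <- as.numeric(pROC::auc(pROC::roc(
    response = factor(truths, levels = c("WBC", "CTC")),
    predictor = scores, quiet = TRUE, direction = "<")))
  expect_equal(ours, ref, tolerance = 1e-9)
})
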