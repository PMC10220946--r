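test_that("confusion_metrics formulas and algebraic identity", {
  m <- confusion_metrics(0, 10, 10, 0)
  expect_equal(unname(m[1:4]), c(0, 100, 0, 50))
  expect_error(confusion_metrics(0, 0, 5, 5), "class")

  set.seed(3)
  for (i in 1:50) {
    k <- sample(0:40, 4, replace = TRUE) + c(1, 0, 1, 0)
    m <- confusion_metrics(k[1], k[2], k[3], k[4])
    P <- k[1] + k[2]; N <- k[3] + k[4]
    expect_equal(m[["accuracy"]],
                 (m[["sensitivity"]] * P + m[["specificity"]] * N) / (P + N))
  }
})

test_that("headline consistency: (38, 9, 142, 19) rounds to the study's rates", {
  m <- confusion_metrics(38, 9, 142, 19)
  expect_equal(round(unname(m[1:4]), 1), c(80.9, 88.2, 66.7, 86.5))
})

test_that("cost tree: perfect split, cap enforcement, determinism", {
  set.seed(5)
  X <- cbind(sig = c(rnorm(30, 0), rnorm(12, 6)), noise = rnorm(42))
  y <- rep(c("healthy", "glaucoma"), c(30, 12))
  tr <- fit_cost_tree(X, y, mns = 1)
  expect_equal(tr$n_splits, 1)
  expect_equal(mean(predict(tr, X) == y), 1)

  # noisy data: the cap bounds the number of internal splits
  Xn <- matrix(rnorm(200 * 4), 200)
  yn <- rep(c("healthy", "glaucoma"), 100)
  t3 <- fit_cost_tree(Xn, yn, mns = 3)
  expect_lte(t3$n_splits, 3)
  tun <- fit_cost_tree(Xn, yn, mns = Inf)
  expect_gt(tun$n_splits, 3)
  expect_equal(mean(predict(tun, Xn) == yn), 1)  # grows to purity

  expect_error(fit_cost_tree(Xn, yn, mns = 0), "mns")
  expect_identical(fit_cost_tree(Xn, yn, mns = 5),
                   fit_cost_tree(Xn, yn, mns = 5))
})

test_that("raising C(FN) never shrinks the predicted-positive set (tree)", {
  set.seed(9)
  X <- cbind(x = c(rnorm(40, 1), rnorm(80, 0)))  # overlapping classes
  y <- rep(c("glaucoma", "healthy"), c(40, 80))
  npos <- vapply(c(1, 1.5, 2, 3, 4.5, 8), function(cf) {
    tr <- fit_cost_tree(X, y, mns = 1, cost_fn = cf)
    sum(predict(tr, X) == "glaucoma")
  }, 0)
  expect_true(all(diff(npos) >= 0))
  expect_gt(npos[6], npos[1])  # the shift is real, not flat
})

test_that("cost SVM: separable accuracy, cost shift, degenerate input", {
  set.seed(13)
  X <- scale(cbind(c(rnorm(25, -3, 0.5), rnorm(25, 3, 0.5)), rnorm(50)))
  y <- rep(c("healthy", "glaucoma"), each = 25)
  sv <- fit_cost_svm(X, y)
  expect_equal(mean(predict(sv, X) == y), 1)
  expect_error(fit_cost_svm(X, rep("healthy", 50)), "both classes")
  expect_error(fit_cost_svm(X, y, kernel = "rbf"), "linear")

  # overlapping classes: recall of the positive class non-decreasing in cost
  Xo <- scale(cbind(c(rnorm(60, -0.5), rnorm(30, 0.5)), rnorm(90)))
  yo <- rep(c("healthy", "glaucoma"), c(60, 30))
  rec <- vapply(c(1, 2, 4, 8), function(cf) {
    m <- fit_cost_svm(Xo, yo, cost_fn = cf)
    mean(predict(m, Xo)[yo == "glaucoma"] == "glaucoma")
  }, 0)
  expect_true(all(diff(rec) >= 0))

  # all-identical rows must not crash
  Xc <- matrix(1, 20, 2)
  yc <- rep(c("healthy", "glaucoma"), 10)
  expect_no_error(predict(fit_cost_svm(Xc, yc), Xc))
})

test_that("stratified CV: partition conservation and pooled marginals", {
  set.seed(17)
  X <- matrix(rnorm(208 * 3), 208)
  y <- rep(c("healthy", "glaucoma"), c(161, 47))
  cv <- stratified_kfold_cv(model_spec("tree", seed = 17), X, y)
  expect_equal(sum(cv$per_fold$n_test), 208)
  expect_equal(unname(cv$counts["tp"] + cv$counts["fn"]), 47)
  expect_equal(unname(cv$counts["tn"] + cv$counts["fp"]), 161)
  # metrics recomputable from the pooled matrix
  expect_equal(as.numeric(cv$metrics),
               as.numeric(confusion_metrics(cv$counts[["tp"]],
                                            cv$counts[["fn"]],
                                            cv$counts[["tn"]],
                                            cv$counts[["fp"]])))

  # separable features: perfect pooled metrics, both families
  Xs <- cbind(as.numeric(y == "glaucoma") * 4 + rnorm(208, 0, 0.1),
              rnorm(208))
  for (fam in c("tree", "svm")) {
    cvs <- stratified_kfold_cv(model_spec(fam, seed = 1), Xs, y)
    expect_equal(unname(cvs$metrics[["sensitivity"]]), 100)
    expect_equal(unname(cvs$metrics[["specificity"]]), 100)
  }

  # label permutation: accuracy near the majority-class rate
  set.seed(19)
  yp <- sample(y)
  cvp <- stratified_kfold_cv(model_spec("tree", seed = 19), X, yp)
  expect_lt(abs(cvp$metrics[["accuracy"]] - 100 * 161 / 208), 15)
})

test_that("CV is reproducible and errors on undersized classes", {
  X <- matrix(rnorm(40 * 2), 40)
  y <- rep(c("healthy", "glaucoma"), c(30, 10))
  a <- stratified_kfold_cv(model_spec("tree", seed = 7), X, y)
  b <- stratified_kfold_cv(model_spec("tree", seed = 7), X, y)
  expect_identical(a$counts, b$counts)
  expect_error(stratified_kfold_cv(model_spec("tree", k_folds = 11, seed = 1),
                                   X, y), "fewer members")
})

test_that("feature_relevance: dominant feature, noise null, determinism", {
  set.seed(23)
  y <- rep(c("healthy", "glaucoma"), each = 30)
  X <- cbind(labelcopy = as.numeric(y == "glaucoma"),
             matrix(rnorm(60 * 3), 60,
                    dimnames = list(NULL, c("n1", "n2", "n3"))))
  rep1 <- feature_relevance(X, y, n_reps = 50, seed = 29)
  expect_gt(rep1$relevance[["labelcopy"]], 0.99)
  expect_equal(sum(rep1$relevance), 1)

  # pure noise: approximately uniform relevance at n_reps = 1000
  Xn <- matrix(rnorm(60 * 5), 60,
               dimnames = list(NULL, paste0("f", 1:5)))
  repn <- feature_relevance(Xn, y, n_reps = 1000, seed = 31)
  expect_lt(max(repn$relevance), 2 / 5)

  expect_identical(feature_relevance(Xn, y, n_reps = 20, seed = 5),
                   feature_relevance(Xn, y, n_reps = 20, seed = 5))
})

test_that("select_msp: top-k with canonical sector tie-break", {
  rep_ <- structure(list(relevance = c(absrel_G = 0.4, absrel_TS = 0.2,
                                       absrel_TI = 0.2, absrel_NI = 0.15,
                                       absrel_N = 0.05),
                         n_reps = 10, seed = 1), class = "importance_report")
  expect_setequal(select_msp(rep_, 4),
                  c("absrel_G", "absrel_TS", "absrel_TI", "absrel_NI"))
  # tie between TS and TI resolved by canonical order (TS before TI)
  expect_equal(select_msp(rep_, 2), c("absrel_G", "absrel_TS"))
  expect_length(select_msp(rep_, 5), 5)
  expect_error(select_msp(rep_, 6), "exceeds")

  # planted signal: only G and TS carry information
  set.seed(37)
  y <- rep(c("healthy", "glaucoma"), each = 40)
  sig <- as.numeric(y == "glaucoma")
  X <- cbind(absrel_G = sig * 2 + rnorm(80, 0, 0.5),
             absrel_TS = sig * 1.5 + rnorm(80, 0, 0.5),
             absrel_N = rnorm(80), absrel_T = rnorm(80))
  r <- feature_relevance(X, y, n_reps = 100, seed = 41)
  expect_setequal(select_msp(r, 2), c("absrel_G", "absrel_TS"))
})

test_that("sweep_cv shares folds across the grid", {
  set.seed(43)
  X <- matrix(rnorm(80 * 2), 80)
  X[1:20, 1] <- X[1:20, 1] + 2
  y <- rep(c("glaucoma", "healthy"), c(20, 60))
  single <- stratified_kfold_cv(model_spec("tree", mns = 2, seed = 47), X, y)
  sw <- sweep_cv(model_spec("tree", seed = 47), "mns", 2, X, y)
  expect_equal(sw$reports[[1]]$counts, single$counts)
  expect_error(sweep_cv(model_spec("tree"), "mns", numeric(), X, y), "empty")

  sw2 <- sweep_cv(model_spec("tree", mns = 4, seed = 47), "cost_fn",
                  c(1, 2, 4), X, y)
  expect_equal(nrow(sw2$summary), 3)
  expect_true(all(sw2$summary$sensitivity >= 0 &
                  sw2$summary$sensitivity <= 100))
})
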