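# Cost-sensitive classification protocol.
#
# Glaucoma is the positive class throughout. False negatives (glaucoma
# classified healthy) may be penalized by a cost C(FN) >= 1 while C(FP)
# stays at 1; costs are realized as observation weights on the positive
# class, both in the impurity of the decision trees and in the penalty of
# the SVM. Trees are grown best-first (largest weighted-Gini decrease
# first) so the "maximum number of splits" cap MNS bounds the number of
# internal nodes, matching the semantics of the hyperparameter swept in
# the study protocol.

POSITIVE_CLASS <- "glaucoma"

#' Classifier run specification
#'
#' @param family `"tree"` or `"svm"`.
#' @param mns maximum number of splits for trees (`Inf` = unlimited).
#' @param cost_fn cost of a false negative, with C(FP) fixed at 1.
#' @param kernel SVM kernel; only `"linear"` is implemented.
#' @param k_folds folds of the stratified cross-validation.
#' @param seed integer driving fold assignment (and any resampling).
#' @param positive label of the positive (disease) class.
#' @return list of class `model_spec`.
#' @export
model_spec <- function(family = c("tree", "svm"), mns = Inf, cost_fn = 1,
                       kernel = "linear", k_folds = 5, seed = 1L,
                       positive = POSITIVE_CLASS) {
  family <- match.arg(family)
  if (!identical(mns, Inf) && (mns < 1 || mns != round(mns)))
    stop("mns must be a positive integer or Inf")
  if (cost_fn < 0) stop("cost_fn must be non-negative")
  if (k_folds < 2) stop("k_folds must be >= 2")
  structure(list(family = family, mns = mns, cost_fn = cost_fn,
                 kernel = kernel, k_folds = as.integer(k_folds),
                 seed = as.integer(seed), positive = positive),
            class = "model_spec")
}

#' Sensitivity, specificity, precision and accuracy from a confusion matrix
#'
#' Glaucoma (positive) convention: sensitivity = TP/(TP+FN), specificity =
#' TN/(TN+FP), precision = TP/(TP+FP) (0 when nothing is predicted
#' positive), accuracy = (TP+TN)/total. Values are percentages at full
#' precision; the print method rounds to one decimal.
#'
#' @param tp,fn,tn,fp non-negative integer counts; `tp + fn > 0` and
#'   `tn + fp > 0`.
#' @return named numeric of class `confusion_metrics` with the four
#'   percentages; the counts are kept in the `"counts"` attribute.
#' @export
confusion_metrics <- function(tp, fn, tn, fp) {
  counts <- c(tp = tp, fn = fn, tn = tn, fp = fp)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers")
  if (tp + fn == 0 || tn + fp == 0)
    stop("each class must have at least one observation")
  out <- c(sensitivity = 100 * tp / (tp + fn),
           specificity = 100 * tn / (tn + fp),
           precision = if (tp + fp == 0) 0 else 100 * tp / (tp + fp),
           accuracy = 100 * (tp + tn) / sum(counts))
  structure(out, counts = counts, class = "confusion_metrics")
}

#' @export
print.confusion_metrics <- function(x, ...) {
  cat(sprintf(
    "sensitivity %.1f%%  specificity %.1f%%  precision %.1f%%  accuracy %.1f%%\n",
    x["sensitivity"], x["specificity"], x["precision"], x["accuracy"]))
  invisible(x)
}

# --- decision tree ---------------------------------------------------------

# weighted Gini impurity mass of a node: n * 2 p (1-p) on weights
gini_mass <- function(wpos, wneg) {
  tot <- wpos + wneg
  if (tot <= 0) return(0)
  2 * wpos * wneg / tot
}

# best split of the rows `idx` of X; deterministic tie-breaks: larger gain,
# then lower feature index, then lower threshold
best_split <- function(X, ypos, w, idx) {
  if (length(idx) < 2) return(NULL)
  wpos_t <- sum(w[idx][ypos[idx]]); wneg_t <- sum(w[idx][!ypos[idx]])
  parent <- gini_mass(wpos_t, wneg_t)
  if (parent <= 0) return(NULL)
  best <- NULL
  for (j in seq_len(ncol(X))) {
    xv <- X[idx, j]
    o <- order(xv)
    xs <- xv[o]
    wp <- cumsum(ifelse(ypos[idx][o], w[idx][o], 0))
    wn <- cumsum(ifelse(ypos[idx][o], 0, w[idx][o]))
    cut_ok <- which(diff(xs) > 0)          # split between distinct values
    if (length(cut_ok) == 0) next
    child <- gini_mass_vec(wp[cut_ok], wn[cut_ok]) +
      gini_mass_vec(wpos_t - wp[cut_ok], wneg_t - wn[cut_ok])
    gains <- parent - child
    k <- which.max(gains)                  # first max: lowest threshold
    if (gains[k] > 1e-12 &&
        (is.null(best) || gains[k] > best$gain + 1e-12)) {
      ci <- cut_ok[k]
      best <- list(feature = j, threshold = (xs[ci] + xs[ci + 1]) / 2,
                   gain = gains[k])
    }
  }
  best
}

gini_mass_vec <- function(wpos, wneg) {
  tot <- wpos + wneg
  out <- numeric(length(tot))
  nz <- tot > 0
  out[nz] <- 2 * wpos[nz] * wneg[nz] / tot[nz]
  out
}

#' Fit a cost-sensitive classification tree
#'
#' Binary CART with weighted Gini impurity, grown best-first: at each step
#' the frontier leaf whose best split yields the largest impurity decrease
#' is split, until `mns` internal splits are reached or no split improves.
#' The false-negative cost is applied as an observation weight `cost_fn` on
#' the positive class; leaves predict the cost-weighted majority class
#' (ties go to the positive class). Fully deterministic.
#'
#' @param X numeric feature matrix or data.frame.
#' @param y labels (factor/character); `positive` marks the disease class.
#' @param mns maximum number of splits (`Inf` = grow to purity).
#' @param cost_fn false-negative cost, C(FP) = 1.
#' @param seed kept for interface symmetry; the fit is deterministic.
#' @param positive positive class label.
#' @return object of class `cost_tree` with `nodes`, `importance` (named
#'   impurity-decrease totals) and `n_splits`.
#' @export
fit_cost_tree <- function(X, y, mns = Inf, cost_fn = 1, seed = NULL,
                          positive = POSITIVE_CLASS) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  if (!identical(mns, Inf) && mns < 1) stop("mns must be >= 1 or Inf")
  y <- as.character(y)
  ypos <- y == positive
  if (!any(ypos) || all(ypos))
    stop("training data must contain both classes")
  negative <- unique(y[!ypos])
  if (length(negative) != 1) stop("y must be binary")
  w <- ifelse(ypos, cost_fn, 1)
  nodes <- list()
  new_node <- function(idx, depth) {
    wpos <- sum(w[idx][ypos[idx]]); wneg <- sum(w[idx][!ypos[idx]])
    list(idx = idx, depth = depth, leaf = TRUE, wpos = wpos, wneg = wneg,
         pred = if (wpos >= wneg) positive else negative,
         feature = NA_integer_, threshold = NA_real_,
         left = NA_integer_, right = NA_integer_)
  }
  nodes[[1]] <- new_node(seq_len(nrow(X)), 0L)
  frontier <- list()  # node id -> candidate split
  cand <- best_split(X, ypos, w, nodes[[1]]$idx)
  if (!is.null(cand)) frontier[["1"]] <- cand
  n_splits <- 0L
  importance <- setNames(numeric(ncol(X)),
                         colnames(X) %||% paste0("V", seq_len(ncol(X))))
  while (n_splits < mns && length(frontier) > 0) {
    gains <- vapply(frontier, function(s) s$gain, 0)
    pick_id <- names(frontier)[order(-gains, as.integer(names(frontier)))][1]
    nd <- as.integer(pick_id)
    sp <- frontier[[pick_id]]
    frontier[[pick_id]] <- NULL
    idx <- nodes[[nd]]$idx
    go_left <- X[idx, sp$feature] < sp$threshold
    li <- length(nodes) + 1L; ri <- length(nodes) + 2L
    nodes[[li]] <- new_node(idx[go_left], nodes[[nd]]$depth + 1L)
    nodes[[ri]] <- new_node(idx[!go_left], nodes[[nd]]$depth + 1L)
    nodes[[nd]]$leaf <- FALSE
    nodes[[nd]]$feature <- sp$feature
    nodes[[nd]]$threshold <- sp$threshold
    nodes[[nd]]$left <- li; nodes[[nd]]$right <- ri
    importance[sp$feature] <- importance[sp$feature] + sp$gain
    n_splits <- n_splits + 1L
    for (ch in c(li, ri)) {
      cs <- best_split(X, ypos, w, nodes[[ch]]$idx)
      if (!is.null(cs)) frontier[[as.character(ch)]] <- cs
    }
  }
  structure(list(nodes = nodes, importance = importance,
                 n_splits = n_splits, positive = positive,
                 negative = negative, features = colnames(X),
                 cost_fn = cost_fn),
            class = "cost_tree")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
predict.cost_tree <- function(object, newdata, ...) {
  X <- as.matrix(newdata)
  out <- character(nrow(X))
  for (i in seq_len(nrow(X))) {
    nd <- 1L
    while (!object$nodes[[nd]]$leaf) {
      n <- object$nodes[[nd]]
      nd <- if (X[i, n$feature] < n$threshold) n$left else n$right
    }
    out[i] <- object$nodes[[nd]]$pred
  }
  out
}

#' @export
print.cost_tree <- function(x, ...) {
  cat(sprintf("<cost_tree %d splits, C(FN)=%g>\n", x$n_splits, x$cost_fn))
  invisible(x)
}

# --- SVM -------------------------------------------------------------------

#' Fit a cost-sensitive linear SVM
#'
#' Linear margin classifier trained in the primal with a squared hinge
#' loss: 0.5 ||w||^2 + C sum_i c_i max(0, 1 - y_i f(x_i))^2, with
#' per-observation penalty c_i = `cost_fn` for the positive class and 1
#' otherwise, minimized by BFGS from a zero start (deterministic). Features
#' are expected to be standardized (the CV driver standardizes on the
#' training folds).
#'
#' @param X numeric feature matrix (standardized).
#' @param y labels; `positive` marks the disease class.
#' @param cost_fn false-negative penalty ratio C(FN):C(FP).
#' @param kernel only `"linear"` is implemented.
#' @param C soft-margin penalty scale (default 1).
#' @param seed kept for interface symmetry; the fit is deterministic.
#' @param positive positive class label.
#' @return object of class `cost_svm` with weights `w` and intercept `b`.
#' @export
fit_cost_svm <- function(X, y, cost_fn = 1, kernel = "linear", C = 1,
                         seed = NULL, positive = POSITIVE_CLASS) {
  if (kernel != "linear")
    stop("only the linear kernel is implemented")
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  y <- as.character(y)
  ypm <- ifelse(y == positive, 1, -1)
  if (length(unique(ypm)) < 2)
    stop("training data must contain both classes")
  negative <- unique(y[ypm < 0])
  if (length(negative) != 1) stop("y must be binary")
  ci <- ifelse(ypm > 0, cost_fn, 1)
  p <- ncol(X)
  obj <- function(par) {
    wv <- par[1:p]; b <- par[p + 1]
    m <- pmax(0, 1 - ypm * (X %*% wv + b))
    0.5 * sum(wv^2) + C * sum(ci * m^2)
  }
  grd <- function(par) {
    wv <- par[1:p]; b <- par[p + 1]
    m <- pmax(0, 1 - ypm * (as.vector(X %*% wv) + b))
    g <- -2 * C * ci * m * ypm
    c(wv + as.vector(t(X) %*% g), sum(g))
  }
  fit <- stats::optim(rep(0, p + 1), obj, grd, method = "BFGS",
                      control = list(maxit = 1000, reltol = 1e-12))
  structure(list(w = fit$par[1:p], b = fit$par[p + 1],
                 positive = positive, negative = negative, cost_fn = cost_fn,
                 converged = fit$convergence == 0,
                 features = colnames(X)),
            class = "cost_svm")
}

#' @export
predict.cost_svm <- function(object, newdata, ...) {
  f <- as.vector(as.matrix(newdata) %*% object$w + object$b)
  ifelse(f >= 0, object$positive, object$negative)
}

# --- cross-validation ------------------------------------------------------

# deterministic stratified fold assignment
stratified_folds <- function(y, k, seed) {
  set.seed(seed)
  fold <- integer(length(y))
  for (cl in unique(as.character(y))) {
    i <- which(as.character(y) == cl)
    if (length(i) < k) stop("class '", cl, "' has fewer members than folds")
    fold[i] <- sample(rep(seq_len(k), length.out = length(i)))
  }
  fold
}

#' Stratified k-fold cross-validation of a cost-sensitive model
#'
#' Folds are stratified by class and derived deterministically from the
#' spec's seed. One model per fold is trained on the remaining folds; test
#' predictions are pooled into a single confusion matrix (micro-average),
#' from which the performance metrics are computed. For SVMs, features are
#' standardized with training-fold means/SDs only.
#'
#' @param spec a [model_spec()].
#' @param X feature matrix or data.frame (numeric columns).
#' @param y labels aligned with the rows of `X`.
#' @return object of class `cv_report`: pooled `counts` (tp, fn, tn, fp),
#'   `metrics` ([confusion_metrics()]), `per_fold` data.frame and `spec`.
#' @export
stratified_kfold_cv <- function(spec, X, y) {
  stopifnot(inherits(spec, "model_spec"))
  X <- as.matrix(X)
  y <- as.character(y)
  fold <- stratified_folds(y, spec$k_folds, spec$seed)
  tp <- fn <- tn <- fp <- 0L
  per_fold <- list()
  for (f in seq_len(spec$k_folds)) {
    tr <- fold != f; te <- !tr
    Xtr <- X[tr, , drop = FALSE]; Xte <- X[te, , drop = FALSE]
    if (length(unique(y[tr])) < 2) stop("class absent from training fold ", f)
    if (spec$family == "tree") {
      m <- fit_cost_tree(Xtr, y[tr], mns = spec$mns, cost_fn = spec$cost_fn,
                         positive = spec$positive)
      pred <- predict(m, Xte)
    } else {
      mu <- colMeans(Xtr)
      sd_ <- apply(Xtr, 2, stats::sd)
      sd_[sd_ == 0 | is.na(sd_)] <- 1
      sc <- function(A) sweep(sweep(A, 2, mu), 2, sd_, "/")
      m <- fit_cost_svm(sc(Xtr), y[tr], cost_fn = spec$cost_fn,
                        kernel = spec$kernel, positive = spec$positive)
      pred <- predict(m, sc(Xte))
    }
    pos <- y[te] == spec$positive
    ppos <- pred == spec$positive
    tp <- tp + sum(pos & ppos); fn <- fn + sum(pos & !ppos)
    tn <- tn + sum(!pos & !ppos); fp <- fp + sum(!pos & ppos)
    per_fold[[f]] <- data.frame(fold = f, n_test = sum(te),
                                tp = sum(pos & ppos), fn = sum(pos & !ppos),
                                tn = sum(!pos & !ppos), fp = sum(!pos & ppos))
  }
  structure(list(counts = c(tp = tp, fn = fn, tn = tn, fp = fp),
                 metrics = confusion_metrics(tp, fn, tn, fp),
                 per_fold = do.call(rbind, per_fold), spec = spec),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("<cv_report %s, k=%d, MNS=%s, C(FN)=%g>\n", x$spec$family,
              x$spec$k_folds, format(x$spec$mns), x$spec$cost_fn))
  cat(sprintf("  pooled: TP=%d FN=%d TN=%d FP=%d\n", x$counts["tp"],
              x$counts["fn"], x$counts["tn"], x$counts["fp"]))
  cat("  "); print(x$metrics)
  invisible(x)
}

#' Average feature relevance over repeated decision trees
#'
#' Trains `n_reps` trees, each on an independent stratified random
#' subsample (default 80% per class), and averages each feature's
#' normalized split-gain relevance. Seeded and reproducible.
#'
#' @param X feature matrix or data.frame.
#' @param y labels.
#' @param n_reps number of trees (default 1000).
#' @param seed integer seed.
#' @param subsample per-class fraction drawn for each tree.
#' @param mns,cost_fn tree parameters (defaults: unlimited growth, cost 1).
#' @param positive positive class label.
#' @return object of class `importance_report`: `relevance` (named, sums
#'   to 1), `n_reps`, `seed`.
#' @export
feature_relevance <- function(X, y, n_reps = 1000, seed = 1L,
                              subsample = 0.8, mns = Inf, cost_fn = 1,
                              positive = POSITIVE_CLASS) {
  stopifnot(n_reps >= 1)
  X <- as.matrix(X)
  y <- as.character(y)
  set.seed(seed)
  p <- ncol(X)
  acc <- setNames(numeric(p), colnames(X) %||% paste0("V", 1:p))
  by_class <- split(seq_along(y), y)
  for (r in seq_len(n_reps)) {
    idx <- unlist(lapply(by_class, function(i)
      sample(i, max(2, floor(subsample * length(i))))), use.names = FALSE)
    tr <- fit_cost_tree(X[idx, , drop = FALSE], y[idx], mns = mns,
                        cost_fn = cost_fn, positive = positive)
    tot <- sum(tr$importance)
    acc <- acc + if (tot > 0) tr$importance / tot else rep(1 / p, p)
  }
  structure(list(relevance = acc / sum(acc), n_reps = n_reps, seed = seed),
            class = "importance_report")
}

#' @export
print.importance_report <- function(x, ...) {
  cat(sprintf("<importance_report over %d trees>\n", x$n_reps))
  print(round(sort(x$relevance, decreasing = TRUE), 4))
  invisible(x)
}

#' Select the most significant parameters (MSP)
#'
#' Top-k features by mean relevance. Ties are broken by the canonical
#' sector order (TS, T, TI, NS, N, NI, G) of the feature's sector suffix,
#' then alphabetically.
#'
#' @param report an [feature_relevance()] result.
#' @param k number of features to keep.
#' @return character vector of feature names, most relevant first.
#' @export
select_msp <- function(report, k = 4) {
  rel <- report$relevance
  if (k > length(rel)) stop("k exceeds the number of features")
  sec <- sub("^.*_", "", names(rel))
  canon <- match(sec, SECTORS_G, nomatch = length(SECTORS_G) + 1)
  ord <- order(-rel, canon, names(rel))
  names(rel)[ord][seq_len(k)]
}

#' Hyperparameter sweep with shared folds
#'
#' Re-runs [stratified_kfold_cv()] over a grid of one hyperparameter
#' (`"mns"` or `"cost_fn"`), holding the fold assignment fixed (same seed)
#' so the resulting curves are comparable point to point.
#'
#' @param spec template [model_spec()].
#' @param param `"mns"` or `"cost_fn"`.
#' @param values numeric grid.
#' @param X,y data as in [stratified_kfold_cv()].
#' @return object of class `cv_sweep`: list of `cv_report`s plus a summary
#'   data.frame (one row per grid point).
#' @export
sweep_cv <- function(spec, param = c("mns", "cost_fn"), values, X, y) {
  param <- match.arg(param)
  if (length(values) == 0) stop("empty grid")
  reports <- lapply(values, function(v) {
    s <- spec; s[[param]] <- v
    stratified_kfold_cv(s, X, y)
  })
  summary <- do.call(rbind, lapply(seq_along(values), function(i) {
    m <- reports[[i]]$metrics
    data.frame(value = values[i], sensitivity = m[["sensitivity"]],
               specificity = m[["specificity"]],
               precision = m[["precision"]], accuracy = m[["accuracy"]])
  }))
  names(summary)[1] <- param
  structure(list(param = param, reports = reports, summary = summary,
                 spec = spec), class = "cv_sweep")
}

#' @export
print.cv_sweep <- function(x, ...) {
  cat(sprintf("<cv_sweep over %s (%d points)>\n", x$param,
              nrow(x$summary)))
  print(transform(x$summary,
                  sensitivity = round(sensitivity, 1),
                  specificity = round(specificity, 1),
                  precision = round(precision, 1),
                  accuracy = round(accuracy, 1)), row.names = FALSE)
  invisible(x)
}
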