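#' Two-class linear discriminant with posterior scores
#'
#' Shared-covariance Gaussian classes with equal priors.  The posterior
#' probability of the positive class is the logistic of the linear
#' discriminant score.  A singular pooled covariance is ridge-regularized
#' with lambda = 1e-6 * trace / d (with a warning).
#'
#' @param x numeric matrix, examples x features.
#' @param y logical (or 0/1) labels; TRUE = positive class.
#' @return list of class \code{lda_binary}: w, bias.
#' @export
lda_binary <- function(x, y) {
  x <- as.matrix(x); y <- as.logical(y)
  if (length(unique(y)) < 2) stop("labels constant: need both classes")
  mu1 <- colMeans(x[y, , drop = FALSE])
  mu0 <- colMeans(x[!y, , drop = FALSE])
  c1 <- x[y, , drop = FALSE]; c0 <- x[!y, , drop = FALSE]
  S <- (crossprod(sweep(c1, 2, mu1)) + crossprod(sweep(c0, 2, mu0))) /
    max(nrow(x) - 2, 1)
  w <- tryCatch(solve(S, mu1 - mu0), error = function(e) NULL)
  if (is.null(w) || any(!is.finite(w))) {
    lam <- 1e-6 * sum(diag(S)) / ncol(x)
    if (!is.finite(lam) || lam <= 0) lam <- 1e-6
    warning("singular pooled covariance: ridge-regularized")
    w <- solve(S + diag(lam, ncol(x)), mu1 - mu0)
  }
  structure(list(w = as.numeric(w),
                 bias = -sum(w * (mu0 + mu1)) / 2), class = "lda_binary")
}

#' Posterior of the positive class under a fitted discriminant
#'
#' @param model an \code{\link{lda_binary}} fit.
#' @param x numeric matrix of examples.
#' @return posterior probabilities in (0, 1).
#' @export
lda_posterior <- function(model, x) {
  plogis(as.numeric(as.matrix(x) %*% model$w) + model$bias)
}

# stratified fold assignment, seeded
stratified_folds <- function(y, folds, seed) {
  set.seed(seed)
  fold <- integer(length(y))
  for (cl in unique(y)) {
    idx <- sample(which(y == cl))
    fold[idx] <- rep_len(seq_len(folds), length(idx))
  }
  fold
}

#' Cross-validated linear classifier with out-of-fold posteriors
#'
#' Trains a linear discriminant per training fold and emits, for every
#' example, the posterior score from the fold in which it was held out.
#' These out-of-fold posteriors are what the fusion stage may consume
#' without information leak.
#'
#' @param x numeric matrix, examples x features.
#' @param y logical labels.
#' @param folds number of folds; default 10.
#' @param seed fold-assignment seed.
#' @return list of class \code{posterior_model}: oof_posterior, fold,
#'   accuracy (out-of-fold, threshold 0.5), model (full-data fit).
#' @export
train_linear_posterior <- function(x, y, folds = 10, seed = 1) {
  x <- as.matrix(x); y <- as.logical(y)
  if (length(unique(y)) < 2) stop("labels constant: need both classes")
  if (min(table(y)) < folds)
    stop("need at least `folds` examples per class")
  fold <- stratified_folds(y, folds, seed)
  post <- numeric(length(y))
  for (f in seq_len(folds)) {
    m <- lda_binary(x[fold != f, , drop = FALSE], y[fold != f])
    post[fold == f] <- lda_posterior(m, x[fold == f, , drop = FALSE])
  }
  structure(list(oof_posterior = post, fold = fold,
                 accuracy = 100 * mean((post > 0.5) == y),
                 model = lda_binary(x, y), folds = folds, seed = seed),
            class = "posterior_model")
}

#' Train the three-stage late-fusion classifier
#'
#' Stage 1: linear classifier on base features; stage 2: linear
#' classifier on symmetry features; stage 3: linear classifier on the
#' two posterior scores.  The fusion stage is trained only on posteriors
#' produced out-of-fold, and all three stages are evaluated on an outer
#' held-out split that no training stage ever touches.
#'
#' @param x_base base feature matrix (e.g. network activations).
#' @param x_sym symmetry feature matrix (multi-axis symmetry scores).
#' @param y logical labels.
#' @param folds inner folds for the posterior stages; default 10.
#' @param holdout outer held-out fraction; default 0.2.
#' @param seed seed for splits and folds.
#' @return list of class \code{fusion_model}: the three fitted
#'   classifiers, the held-out index set, and held-out accuracies
#'   (base, symmetry, fused, in percent).
#' @export
train_fusion <- function(x_base, x_sym, y, folds = 10, holdout = 0.2,
                         seed = 1) {
  x_base <- as.matrix(x_base); x_sym <- as.matrix(x_sym)
  y <- as.logical(y)
  if (nrow(x_base) != length(y) || nrow(x_sym) != length(y))
    stop("misaligned features and labels")
  if (length(unique(y)) < 2) stop("labels constant: need both classes")
  set.seed(seed)
  held <- sort(unlist(lapply(split(seq_along(y), y), function(idx)
    sample(idx, max(1, round(holdout * length(idx)))))))
  tr <- setdiff(seq_along(y), held)
  base_cv <- train_linear_posterior(x_base[tr, , drop = FALSE], y[tr],
                                    folds, seed)
  sym_cv <- train_linear_posterior(x_sym[tr, , drop = FALSE], y[tr],
                                   folds, seed + 1)
  fusion <- lda_binary(cbind(base_cv$oof_posterior, sym_cv$oof_posterior),
                       y[tr])
  model <- structure(list(base = base_cv$model, symmetry = sym_cv$model,
                          fusion = fusion, held_out = held,
                          folds = folds, seed = seed),
                     class = "fusion_model")
  model$held_out_accuracy <- unlist(evaluate_fusion(
    model, x_base[held, , drop = FALSE], x_sym[held, , drop = FALSE],
    y[held])[c("base_accuracy", "symmetry_accuracy", "fused_accuracy")])
  model
}

#' Evaluate a fusion model on held-out data
#'
#' @param model a \code{\link{train_fusion}} fit.
#' @param x_base,x_sym held-out feature matrices (disjoint from all
#'   training folds).
#' @param y held-out logical labels.
#' @return list: base_accuracy, symmetry_accuracy, fused_accuracy (in
#'   percent), improvement (fused - base, percentage points), n.
#' @export
evaluate_fusion <- function(model, x_base, x_sym, y) {
  y <- as.logical(y)
  if (length(y) == 0) stop("empty held-out set")
  pb <- lda_posterior(model$base, x_base)
  ps <- lda_posterior(model$symmetry, x_sym)
  pf <- lda_posterior(model$fusion, cbind(pb, ps))
  acc <- function(p) 100 * mean((p > 0.5) == y)
  list(base_accuracy = acc(pb), symmetry_accuracy = acc(ps),
       fused_accuracy = acc(pf),
       improvement = acc(pf) - acc(pb), n = length(y))
}

#' Early-fusion baseline: single classifier on concatenated features
#'
#' Each feature (base and symmetry alike) is z-scored across images, the
#' matrices are concatenated, and one linear classifier is trained with
#' the same outer held-out split as \code{\link{train_fusion}} -- the
#' early-versus-late fusion comparison.
#'
#' @param x_base,x_sym feature matrices.
#' @param y logical labels.
#' @param holdout outer held-out fraction; default 0.2.
#' @param seed split seed (use the fusion model's seed for a matched
#'   comparison).
#' @return list: concat_accuracy (percent, held out), n.
#' @export
feature_concat_baseline <- function(x_base, x_sym, y, holdout = 0.2,
                                    seed = 1) {
  x_base <- as.matrix(x_base); x_sym <- as.matrix(x_sym)
  y <- as.logical(y)
  if (nrow(x_base) != length(y) || nrow(x_sym) != length(y))
    stop("misaligned features and labels")
  zs <- function(x) {
    sds <- apply(x, 2, sd)
    sds[sds == 0] <- 1
    scale(x, center = TRUE, scale = sds)
  }
  xx <- cbind(zs(x_base), zs(x_sym))
  set.seed(seed)
  held <- sort(unlist(lapply(split(seq_along(y), y), function(idx)
    sample(idx, max(1, round(holdout * length(idx)))))))
  tr <- setdiff(seq_along(y), held)
  m <- lda_binary(xx[tr, , drop = FALSE], y[tr])
  p <- lda_posterior(m, xx[held, , drop = FALSE])
  list(concat_accuracy = 100 * mean((p > 0.5) == y[held]),
       n = length(held))
}

#' Per-category fusion benchmark (one-vs-rest)
#'
#' For each category, positives are that category's examples and an
#' equal number of negatives is sampled (seeded) from the remaining
#' categories; the three-stage fusion pipeline is trained and evaluated
#' on its outer held-out split.  Improvements across categories are
#' compared by a two-sided rank-sum test.
#'
#' @param x_base base feature matrix for all examples.
#' @param x_sym symmetry feature matrix for all examples.
#' @param categories category label per example.
#' @param folds,holdout,seed as in \code{\link{train_fusion}}.
#' @return data.frame of class \code{category_report}: one row per
#'   category with base/symmetry/fused accuracy, improvement and mean
#'   symmetry score of the category's positives; attributes
#'   \code{ranksum_p} (fused vs base across categories) and
#'   \code{improvement_vs_base_r} (Pearson r of improvement against base
#'   accuracy).
#' @export
fusion_category_benchmark <- function(x_base, x_sym, categories,
                                      folds = 10, holdout = 0.2, seed = 1) {
  categories <- as.character(categories)
  cats <- sort(unique(categories))
  rows <- lapply(seq_along(cats), function(k) {
    cat_k <- cats[k]
    pos <- which(categories == cat_k)
    set.seed(seed + k)
    neg <- sample(which(categories != cat_k), length(pos))
    idx <- c(pos, neg)
    y <- c(rep(TRUE, length(pos)), rep(FALSE, length(neg)))
    fm <- train_fusion(x_base[idx, , drop = FALSE],
                       x_sym[idx, , drop = FALSE], y,
                       folds = folds, holdout = holdout, seed = seed + k)
    acc <- fm$held_out_accuracy
    data.frame(category = cat_k, n_pos = length(pos),
               base_accuracy = acc[["base_accuracy"]],
               symmetry_accuracy = acc[["symmetry_accuracy"]],
               fused_accuracy = acc[["fused_accuracy"]],
               improvement = acc[["fused_accuracy"]] - acc[["base_accuracy"]],
               mean_symmetry = mean(rowMeans(x_sym[pos, , drop = FALSE])),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "ranksum_p") <-
    wilcox.test(out$fused_accuracy, out$base_accuracy,
                exact = FALSE)$p.value
  attr(out, "improvement_vs_base_r") <-
    if (sd(out$base_accuracy) > 0 && sd(out$improvement) > 0)
      cor(out$improvement, out$base_accuracy) else NA_real_
  class(out) <- c("category_report", class(out))
  out
}
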