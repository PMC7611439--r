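#' Construct a pair table of observed dissimilarities
#'
#' A pair table is a data.frame with at least image_a, image_b and
#' dissimilarity (units 1/seconds, strictly positive).  Optional columns:
#' n_trials, subject_id, rt_seconds, experiment_id and pair covariates.
#' Unordered pairs must be unique within an experiment.
#'
#' @param df data.frame with the required columns.
#' @return the validated data.frame with class \code{pair_table}.
#' @export
pair_table <- function(df) {
  need <- c("image_a", "image_b", "dissimilarity")
  if (!all(need %in% names(df)))
    stop("pair table needs columns: ", paste(need, collapse = ", "))
  if (any(!is.finite(df$dissimilarity)) || any(df$dissimilarity <= 0))
    stop("dissimilarities must be finite and > 0")
  key <- paste(pmin(df$image_a, df$image_b), pmax(df$image_a, df$image_b))
  if ("experiment_id" %in% names(df)) key <- paste(key, df$experiment_id)
  if (!"subject_id" %in% names(df) && anyDuplicated(key))
    stop("duplicate unordered pair within an experiment")
  class(df) <- unique(c("pair_table", class(df)))
  df
}

#' Construct a feature table
#'
#' Images x features numeric matrix with image ids as rownames and a
#' provenance tag ("raw", "pca:<d>" or "concat").
#'
#' @param x numeric matrix (or data.frame of numerics).
#' @param ids image ids; default rownames(x).
#' @param provenance provenance tag.
#' @return numeric matrix with rownames and a "provenance" attribute.
#' @export
feature_table <- function(x, ids = rownames(x), provenance = "raw") {
  x <- as.matrix(x)
  if (!is.numeric(x) || any(!is.finite(x)))
    stop("feature table must be finite numeric")
  if (is.null(ids)) stop("feature table needs image ids")
  if (anyDuplicated(ids)) stop("image ids must be unique")
  rownames(x) <- ids
  attr(x, "provenance") <- provenance
  x
}

as_feature_matrix <- function(x) {
  if (is.null(dim(x))) stop("expected a feature matrix")
  as.matrix(x)
}

#' Convert reaction times to a dissimilarity
#'
#' Perceptual dissimilarity is the reciprocal of the mean correct-trial
#' search time, in 1/seconds.
#'
#' @param reaction_times vector of correct-trial reaction times (s, > 0).
#' @return dissimilarity in 1/seconds.
#' @export
rt_to_dissimilarity <- function(reaction_times) {
  rt <- reaction_times[is.finite(reaction_times)]
  if (length(rt) == 0 || any(rt <= 0))
    stop("invalid input: need at least one positive reaction time")
  1 / mean(rt)
}

#' Split-half reliability of per-subject dissimilarities
#'
#' Subjects are split into two random halves; per-pair mean
#' dissimilarities of the halves are correlated across pairs (Pearson).
#' The mean split correlation r over \code{n_splits} random splits is
#' corrected with the Spearman-Brown formula r_c = 2r / (1 + r), the
#' ceiling against which model fits are judged.
#'
#' @param per_subject data.frame: image_a, image_b, subject_id and either
#'   dissimilarity or rt_seconds (converted per subject x pair via
#'   \code{\link{rt_to_dissimilarity}}).
#' @param n_splits number of random subject splits; default 20.
#' @param seed integer seed.
#' @return list of class \code{reliability_estimate}: split_half_r,
#'   corrected_rc, per-split r values, n_splits, seed.
#' @export
split_half_reliability <- function(per_subject, n_splits = 20, seed = 1) {
  df <- per_subject
  if (!"dissimilarity" %in% names(df)) {
    if (!"rt_seconds" %in% names(df))
      stop("need dissimilarity or rt_seconds column")
    agg <- aggregate(rt_seconds ~ image_a + image_b + subject_id, df, mean)
    agg$dissimilarity <- 1 / agg$rt_seconds
    df <- agg
  }
  df$pair <- paste(pmin(df$image_a, df$image_b),
                   pmax(df$image_a, df$image_b), sep = "|")
  nsub <- tapply(df$subject_id, df$pair, function(s) length(unique(s)))
  bad <- names(nsub)[nsub < 2]
  if (length(bad) == length(nsub))
    stop("no pair has >= 2 subjects")
  if (length(bad) > 0) {
    warning(length(bad), " pair(s) with < 2 subjects excluded")
    df <- df[!df$pair %in% bad, , drop = FALSE]
  }
  subjects <- unique(df$subject_id)
  if (length(subjects) < 2) stop("need >= 2 subjects")
  set.seed(seed)
  rs <- numeric(n_splits)
  for (s in seq_len(n_splits)) {
    half <- sample(subjects, floor(length(subjects) / 2))
    m1 <- tapply(df$dissimilarity[df$subject_id %in% half],
                 df$pair[df$subject_id %in% half], mean)
    m2 <- tapply(df$dissimilarity[!df$subject_id %in% half],
                 df$pair[!df$subject_id %in% half], mean)
    common <- intersect(names(m1), names(m2))
    rs[s] <- cor(m1[common], m2[common])
  }
  r <- mean(rs)
  structure(list(split_half_r = r, corrected_rc = 2 * r / (1 + r),
                 split_r = rs, n_splits = n_splits, seed = seed),
            class = "reliability_estimate")
}

#' Spearman-Brown correction
#'
#' @param r split-half correlation in (-1, 1].
#' @return corrected reliability 2r / (1 + r).
#' @export
spearman_brown <- function(r) 2 * r / (1 + r)

#' Reduce a feature table by principal component analysis
#'
#' Centered (unscaled) PCA projection onto the top d components.
#' Component signs are fixed so the largest-magnitude loading of each
#' component is positive, making the reduction deterministic.
#'
#' @param features a \code{\link{feature_table}}.
#' @param d number of components; default 100.
#' @return feature table of scores (images x d), provenance "pca:<d>".
#' @export
pca_reduce <- function(features, d = 100) {
  x <- as_feature_matrix(features)
  if (d > min(nrow(x), ncol(x)))
    stop("invalid parameter: d exceeds min(n_images, n_features)")
  p <- prcomp(x, center = TRUE, scale. = FALSE)
  rot <- p$rotation[, seq_len(d), drop = FALSE]
  flip <- vapply(seq_len(d), function(k) {
    v <- rot[, k]
    sign(v[which.max(abs(v))])
  }, numeric(1))
  rot <- sweep(rot, 2, flip, "*")
  scores <- sweep(x, 2, p$center, "-") %*% rot
  feature_table(scores, rownames(x), provenance = paste0("pca:", d))
}

# least squares, falling back to the minimum-norm solution for
# rank-deficient designs (with a warning)
solve_ls <- function(X, y) {
  qr_x <- qr(X)
  if (qr_x$rank < ncol(X)) {
    warning("rank-deficient design: using least-norm solution")
    sv <- svd(X)
    pos <- sv$d > max(sv$d) * 1e-10
    return(as.numeric(sv$v[, pos, drop = FALSE] %*%
      ((t(sv$u[, pos, drop = FALSE]) %*% y) / sv$d[pos])))
  }
  as.numeric(qr.coef(qr_x, y))
}

# repeated random train/test splits over pair rows
cv_splits <- function(n, n_reps, test_frac, seed) {
  set.seed(seed)
  lapply(seq_len(n_reps), function(r) {
    test <- sort(sample(n, max(1, round(test_frac * n))))
    list(train = setdiff(seq_len(n), test), test = test)
  })
}

fit_ls_cv <- function(X, y, n_reps, test_frac, seed, method) {
  folds <- cv_splits(length(y), n_reps, test_frac, seed)
  fold_r <- vapply(folds, function(f) {
    w <- solve_ls(X[f$train, , drop = FALSE], y[f$train])
    cor(as.numeric(X[f$test, , drop = FALSE] %*% w), y[f$test])
  }, numeric(1))
  structure(list(weights = solve_ls(X, y),
                 fold_r = fold_r, mean_r = mean(fold_r),
                 sd_r = sd(fold_r), folds = folds,
                 n_pairs = length(y), method = method, seed = seed),
            class = "symperc_fit")
}

#' @export
print.symperc_fit <- function(x, ...) {
  cat("symperc_fit (", x$method, "): ", length(x$weights), " weights, ",
      x$n_pairs, " pairs; cross-validated r = ",
      sprintf("%.3f +/- %.3f", x$mean_r, x$sd_r), "\n", sep = "")
  invisible(x)
}

# per-pair design matrix of absolute component differences
pair_design <- function(features, observed) {
  x <- as_feature_matrix(features)
  ids <- rownames(x)
  ia <- match(observed$image_a, ids); ib <- match(observed$image_b, ids)
  if (anyNA(ia) || anyNA(ib))
    stop("pair table references image ids missing from the feature table")
  abs(x[ia, , drop = FALSE] - x[ib, , drop = FALSE])
}

#' Fit weighted principal-component distances to observed dissimilarity
#'
#' Models the observed distance between two images as a weighted sum of
#' absolute per-component feature differences,
#' \deqn{y_{12} = \sum_k w_k |x_{1,k} - x_{2,k}|,}
#' solved by ordinary least squares (no intercept).  Cross-validation uses
#' repeated random 80/20 train/test splits of the pairs; the reported
#' r is the Pearson correlation between predicted and observed distances
#' on held-out pairs.
#'
#' @param features a \code{\link{feature_table}} (typically PCA-reduced).
#' @param observed a \code{\link{pair_table}}.
#' @param n_reps number of random splits; default 10.
#' @param test_frac held-out fraction per split; default 0.2.
#' @param seed integer seed for the splits.
#' @param nonneg if TRUE, constrain weights to be non-negative
#'   (projected-gradient NNLS); off by default.
#' @return a \code{symperc_fit}: full-data weights, per-fold test r,
#'   mean/sd of test r.
#' @export
fit_weighted_pc_distances <- function(features, observed, n_reps = 10,
                                      test_frac = 0.2, seed = 1,
                                      nonneg = FALSE) {
  X <- pair_design(features, observed)
  y <- observed$dissimilarity
  if (nrow(X) < ncol(X) + 1)
    warning("fewer training pairs than recommended (d + 1)")
  if (!nonneg) return(fit_ls_cv(X, y, n_reps, test_frac, seed,
                                "weighted_pc_distances"))
  folds <- cv_splits(length(y), n_reps, test_frac, seed)
  fold_r <- vapply(folds, function(f) {
    w <- nnls_pg(X[f$train, , drop = FALSE], y[f$train])
    cor(as.numeric(X[f$test, , drop = FALSE] %*% w), y[f$test])
  }, numeric(1))
  structure(list(weights = nnls_pg(X, y), fold_r = fold_r,
                 mean_r = mean(fold_r), sd_r = sd(fold_r), folds = folds,
                 n_pairs = length(y), method = "weighted_pc_distances_nnls",
                 seed = seed),
            class = "symperc_fit")
}

# projected gradient non-negative least squares
nnls_pg <- function(X, y, iters = 2000) {
  w <- pmax(solve_ls(X, y), 0)
  lip <- sum(X^2)
  for (i in seq_len(iters)) {
    g <- crossprod(X, as.numeric(X %*% w) - y)
    w_new <- pmax(w - as.numeric(g) / lip, 0)
    if (max(abs(w_new - w)) < 1e-12) { w <- w_new; break }
    w <- w_new
  }
  w
}

#' Predict pair dissimilarities from a fitted model
#'
#' @param fit a \code{symperc_fit} from
#'   \code{\link{fit_weighted_pc_distances}} or \code{\link{fit_comb2}}.
#' @param features feature table (for weighted-PC fits) or model-distance
#'   matrix (for comb2 fits), aligned as at fitting time.
#' @param observed pair table giving the pairs to predict.
#' @return numeric vector of predicted dissimilarities.
#' @export
predict_dissimilarity <- function(fit, features, observed = NULL) {
  X <- if (startsWith(fit$method, "weighted_pc")) {
    pair_design(features, observed)
  } else as.matrix(features)
  as.numeric(X %*% fit$weights)
}

#' Percent variance explained relative to the reliability ceiling
#'
#' \deqn{\%\ var = 100 (r_m / r_c)^2}
#' with r_m the model-data correlation and r_c the Spearman-Brown
#' corrected split-half reliability.
#'
#' @param r_m model correlation with the observed data.
#' @param rc corrected split-half reliability (> 0).
#' @return percent variance explained.
#' @export
variance_explained <- function(r_m, rc) {
  if (!is.finite(rc) || rc <= 0) stop("invalid input: rc must be > 0")
  100 * (r_m / rc)^2
}

#' Fit a weighted combination of per-model distances (comb2)
#'
#' Solves y = X b by least squares, where X holds one column of
#' (unweighted) pair distances per candidate model and y the observed
#' dissimilarities; b gives each model's contribution and is reported for
#' inspection.
#'
#' @param model_distances numeric matrix, pairs x models (column names =
#'   model names).
#' @param observed a \code{\link{pair_table}} row-aligned with the matrix.
#' @param n_reps,test_frac,seed cross-validation controls as in
#'   \code{\link{fit_weighted_pc_distances}}.
#' @return a \code{symperc_fit}; weights carry model names.
#' @export
fit_comb2 <- function(model_distances, observed, n_reps = 10,
                      test_frac = 0.2, seed = 1) {
  X <- as.matrix(model_distances)
  if (nrow(X) != nrow(observed))
    stop("model-distance matrix not aligned with observed pairs")
  fit <- fit_ls_cv(X, observed$dissimilarity, n_reps, test_frac, seed,
                   "comb2")
  names(fit$weights) <- colnames(X)
  fit
}

#' Concatenate z-scored feature tables and reduce by PCA (comb1)
#'
#' Each feature is z-scored across images, all tables are concatenated
#' column-wise over the common image set, and the result is reduced to d
#' principal components.  Zero-variance features are dropped with a
#' warning.
#'
#' @param tables list of feature tables over identical image sets.
#' @param d output dimensionality; default 100.
#' @return feature table of PCA scores, provenance "concat".
#' @export
comb1_concat <- function(tables, d = 100) {
  ids <- rownames(as_feature_matrix(tables[[1]]))
  zs <- lapply(tables, function(tb) {
    x <- as_feature_matrix(tb)
    if (!setequal(rownames(x), ids))
      stop("alignment error: tables cover different image sets")
    x <- x[ids, , drop = FALSE]
    sds <- apply(x, 2, sd)
    if (any(sds == 0)) {
      warning(sum(sds == 0), " zero-variance feature(s) dropped")
      x <- x[, sds > 0, drop = FALSE]
      sds <- sds[sds > 0]
    }
    scale(x, center = TRUE, scale = sds)
  })
  out <- pca_reduce(feature_table(do.call(cbind, zs), ids), d)
  attr(out, "provenance") <- "concat"
  out
}

#' Leave-one-experiment-out generalization
#'
#' For each experiment group, fits the model on all other groups and
#' tests on the held-out group, reporting the test correlation and, when
#' a reliability is supplied, the percent variance explained against that
#' group's own (or a pooled) ceiling.
#'
#' @param x feature table (mode "features") or pairs x models distance
#'   matrix (mode "distances").
#' @param observed pair table with an experiment_id column.
#' @param mode "features" (weighted-PC model) or "distances" (comb2).
#' @param rc pooled corrected reliability, or a named vector per group.
#' @param min_test_pairs warn for groups with fewer test pairs; default 20.
#' @return data.frame: experiment_id, n_test, test_r,
#'   percent_variance_explained (NA without rc).
#' @export
leave_one_group_out <- function(x, observed, mode = c("features", "distances"),
                                rc = NULL, min_test_pairs = 20) {
  mode <- match.arg(mode)
  if (!"experiment_id" %in% names(observed))
    stop("observed pairs need an experiment_id column")
  groups <- unique(observed$experiment_id)
  if (length(groups) < 2) stop("need >= 2 experiment groups")
  X <- if (mode == "features") pair_design(x, observed) else as.matrix(x)
  y <- observed$dissimilarity
  res <- lapply(groups, function(g) {
    test <- which(observed$experiment_id == g)
    if (length(test) < min_test_pairs)
      warning("experiment ", g, " has only ", length(test), " test pairs")
    w <- solve_ls(X[-test, , drop = FALSE], y[-test])
    r <- cor(as.numeric(X[test, , drop = FALSE] %*% w), y[test])
    rc_g <- if (is.null(rc)) NA_real_
            else if (!is.null(names(rc)) && g %in% names(rc)) rc[[g]]
            else unname(rc[1])
    data.frame(experiment_id = g, n_test = length(test), test_r = r,
               percent_variance_explained =
                 if (is.na(rc_g)) NA_real_ else variance_explained(r, rc_g),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}
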