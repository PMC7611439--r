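#' Signed residual errors of a dissimilarity model
#'
#' residual = observed - predicted, in 1/seconds.  Pairs whose residual
#' lies more than one standard deviation above (below) the residual mean
#' are flagged "under" ("over") -- the model under- or over-estimated
#' their dissimilarity.  When the residual sd is zero no pair is flagged.
#' Covariate columns present in the observed table (sym_strength,
#' area_ratio, n_shared_parts, relation) are carried through.
#'
#' @param observed a \code{\link{pair_table}}.
#' @param predicted numeric vector aligned with the observed rows.
#' @return data.frame of class \code{residual_table} with columns
#'   image_a, image_b, observed, predicted, residual, flag
#'   ("under"/"over"/"within") plus any covariates.
#' @export
residual_errors <- function(observed, predicted) {
  if (length(predicted) != nrow(observed))
    stop("predicted values not aligned with observed pairs")
  res <- observed$dissimilarity - predicted
  s <- sd(res); m <- mean(res)
  flag <- rep("within", length(res))
  if (is.finite(s) && s > 0) {
    flag[res > m + s] <- "under"
    flag[res < m - s] <- "over"
  }
  out <- data.frame(image_a = observed$image_a, image_b = observed$image_b,
                    observed = observed$dissimilarity, predicted = predicted,
                    residual = res, flag = flag, stringsAsFactors = FALSE)
  for (cv in intersect(c("sym_strength", "area_ratio", "n_shared_parts",
                         "relation"), names(observed)))
    out[[cv]] <- observed[[cv]]
  class(out) <- c("residual_table", class(out))
  out
}

#' Correlate residual errors with a pair covariate
#'
#' Pearson correlation between the signed residual and a covariate
#' column, with a two-sided p-value; optionally a bootstrap standard
#' deviation and percentile confidence interval over pairs.
#'
#' @param residuals a \code{residual_table}.
#' @param covariate covariate column name (e.g. "sym_strength",
#'   "area_ratio").
#' @param n_boot bootstrap replicates (0 = none).
#' @param seed bootstrap seed.
#' @param conf confidence level for the percentile interval.
#' @return list: r, p, n, and (if bootstrapped) boot_sd, ci (2-vector).
#' @export
correlate_residuals <- function(residuals, covariate, n_boot = 0,
                                seed = 1, conf = 0.95) {
  if (!covariate %in% names(residuals))
    stop("unknown covariate: ", covariate)
  x <- residuals[[covariate]]; y <- residuals$residual
  if (length(y) < 10) stop("need >= 10 pairs")
  if (sd(x) == 0) stop("undefined correlation: constant covariate")
  ct <- cor.test(x, y, method = "pearson")
  out <- list(r = unname(ct$estimate), p = ct$p.value, n = length(y))
  if (n_boot > 0) {
    set.seed(seed)
    reps <- vapply(seq_len(n_boot), function(b) {
      k <- sample.int(length(y), replace = TRUE)
      if (sd(x[k]) == 0 || sd(y[k]) == 0) return(NA_real_)
      cor(x[k], y[k])
    }, numeric(1))
    reps <- reps[is.finite(reps)]
    a <- (1 - conf) / 2
    out$boot_sd <- sd(reps)
    out$ci <- unname(quantile(reps, c(a, 1 - a)))
    out$replicates <- reps
  }
  out
}

#' Mean residual error by number of shared parts
#'
#' @param residuals a \code{residual_table} with an n_shared_parts column.
#' @return data.frame with one row per bin (2, 1, 0): mean, sd, n; empty
#'   bins are reported with n = 0 and NA statistics.
#' @export
bin_residuals_by_shared_parts <- function(residuals) {
  if (!"n_shared_parts" %in% names(residuals))
    stop("residual table lacks n_shared_parts")
  do.call(rbind, lapply(c(2L, 1L, 0L), function(b) {
    r <- residuals$residual[residuals$n_shared_parts == b]
    data.frame(n_shared_parts = b, n = length(r),
               mean_residual = if (length(r)) mean(r) else NA_real_,
               sd_residual = if (length(r) > 1) sd(r) else NA_real_)
  }))
}

#' Metric multidimensional scaling of a dissimilarity matrix
#'
#' Metric stress MDS (SMACOF/Guttman iterations) with seeded restarts:
#' one start from classical scaling plus random starts, keeping the
#' lowest-stress solution.  Missing entries (NA) are tolerated up to 20%
#' of the off-diagonal cells and imputed by column means with a warning.
#'
#' @param distances symmetric non-negative matrix with zero diagonal.
#' @param dim embedding dimensionality; default 2.
#' @param seed integer seed for the random restarts.
#' @param n_restarts number of starts (first is classical scaling).
#' @param max_iter,tol SMACOF iteration controls.
#' @return list of class \code{mds_embedding}: coordinates (n x dim
#'   matrix), stress, embedding_r (Pearson r between embedded and input
#'   distances).
#' @export
mds_embed <- function(distances, dim = 2, seed = 1, n_restarts = 10,
                      max_iter = 500, tol = 1e-10) {
  D <- as.matrix(distances)
  n <- nrow(D)
  if (n != ncol(D) || any(abs(D - t(D)) > 1e-8, na.rm = TRUE))
    stop("need a symmetric square matrix")
  diag(D) <- 0
  off <- D[upper.tri(D)]
  if (any(off < 0, na.rm = TRUE)) stop("distances must be non-negative")
  miss <- mean(is.na(off))
  if (miss > 0.2) stop("more than 20% of distances missing")
  if (miss > 0) {
    warning("imputing ", round(100 * miss, 1), "% missing distances")
    cm <- colMeans(D, na.rm = TRUE)
    for (j in seq_len(n)) D[is.na(D[, j]), j] <- cm[j]
    D <- (D + t(D)) / 2; diag(D) <- 0
  }
  smacof <- function(X) {
    prev <- Inf
    for (it in seq_len(max_iter)) {
      E <- as.matrix(dist(X))
      stress <- sum((E[upper.tri(E)] - D[upper.tri(D)])^2)
      if (prev - stress < tol * max(prev, 1)) break
      prev <- stress
      B <- -D / (E + (E == 0))   # guard zero embedded distances
      B[E == 0] <- 0
      diag(B) <- -rowSums(B)
      X <- B %*% X / n
    }
    list(X = X, stress = stress)
  }
  set.seed(seed)
  starts <- c(list(cmdscale(D, k = dim)),
              lapply(seq_len(max(0, n_restarts - 1)), function(i)
                matrix(rnorm(n * dim), n, dim) * mean(D) / 2))
  best <- NULL
  for (X0 in starts) {
    if (ncol(X0) < dim)  # cmdscale may return fewer columns
      X0 <- cbind(X0, matrix(0, n, dim - ncol(X0)))
    fit <- smacof(X0)
    if (is.null(best) || fit$stress < best$stress) best <- fit
  }
  E <- as.matrix(dist(best$X))
  r <- cor(E[upper.tri(E)], D[upper.tri(D)])
  structure(list(coordinates = best$X, stress = best$stress,
                 embedding_r = r, dim = dim, seed = seed),
            class = "mds_embedding")
}

#' @export
print.mds_embedding <- function(x, ...) {
  cat("mds_embedding:", nrow(x$coordinates), "points in", x$dim,
      "dims; stress =", signif(x$stress, 4),
      "; embedding r =", sprintf("%.3f", x$embedding_r), "\n")
  invisible(x)
}

#' Full pairwise dissimilarity matrix from a pair table
#'
#' @param pairs a \code{\link{pair_table}}.
#' @param ids image ids fixing the row order; default all ids present.
#' @return symmetric matrix with NA for unmeasured pairs, 0 diagonal.
#' @export
pair_matrix <- function(pairs, ids = NULL) {
  if (is.null(ids)) ids <- sort(unique(c(pairs$image_a, pairs$image_b)))
  n <- length(ids)
  M <- matrix(NA_real_, n, n, dimnames = list(ids, ids))
  ia <- match(pairs$image_a, ids); ib <- match(pairs$image_b, ids)
  M[cbind(ia, ib)] <- pairs$dissimilarity
  M[cbind(ib, ia)] <- pairs$dissimilarity
  diag(M) <- 0
  M
}
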