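test_that("reaction times convert to reciprocal-mean dissimilarity", {
  expect_equal(rt_to_dissimilarity(c(0.5, 0.5)), 2)
  expect_equal(rt_to_dissimilarity(1), 1)
  expect_equal(rt_to_dissimilarity(c(0.8, 1.2)), 1)
  expect_error(rt_to_dissimilarity(numeric(0)), "reaction time")
  expect_error(rt_to_dissimilarity(c(1, -2)), "positive")
})

test_that("Spearman-Brown correction behaves as documented", {
  expect_equal(spearman_brown(0.5), 2 / 3)
  expect_equal(spearman_brown(0), 0)
  expect_equal(spearman_brown(1), 1)
  r <- seq(-0.9, 1, by = 0.05)
  expect_true(all(diff(spearman_brown(r)) > 0))  # monotone on (-1, 1]
})

test_that("split-half reliability handles duplicates, exclusions, errors", {
  base <- data.frame(image_a = sprintf("a%02d", 1:30),
                     image_b = sprintf("b%02d", 1:30),
                     dissimilarity = seq(0.5, 2, length.out = 30))
  # two identical subjects -> every split correlates perfectly
  dup <- rbind(transform(base, subject_id = "s1"),
               transform(base, subject_id = "s2"))
  rel <- split_half_reliability(dup, n_splits = 4, seed = 1)
  expect_equal(rel$split_half_r, 1)
  expect_equal(rel$corrected_rc, 1)
  # single-subject pairs are excluded with a warning
  extra <- data.frame(image_a = "z1", image_b = "z2",
                      dissimilarity = 1, subject_id = "s1")
  expect_warning(split_half_reliability(rbind(dup, extra), 2, 1),
                 "excluded")
  expect_error(split_half_reliability(transform(base, subject_id = "s1"),
                                      2, 1), "2 subjects")
  # rt input path: per-subject 1/mean(rt)
  rtdf <- rbind(transform(base, subject_id = "s1",
                          rt_seconds = 1 / dissimilarity),
                transform(base, subject_id = "s2",
                          rt_seconds = 1 / dissimilarity))
  rtdf$dissimilarity <- NULL
  expect_equal(split_half_reliability(rtdf, 2, 1)$split_half_r, 1)
})

test_that("PCA reduction is an isometry at full rank with fixed signs", {
  set.seed(8)
  x <- feature_table(matrix(rnorm(60 * 10), 60, 10),
                     sprintf("im%02d", 1:60))
  s <- pca_reduce(x, 10)
  xc <- scale(unclass(x), center = TRUE, scale = FALSE)
  expect_equal(as.matrix(dist(s)), as.matrix(dist(xc)), tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_identical(unclass(pca_reduce(x, 5)), unclass(pca_reduce(x, 5)))
  expect_error(pca_reduce(x, 11), "exceeds")
  # rank-2 data keep all variance in 2 components
  y <- feature_table(matrix(rnorm(40), 20, 2) %*% matrix(rnorm(10), 2, 5),
                     sprintf("r%02d", 1:20))
  s2 <- pca_reduce(y, 2)
  expect_equal(sum(apply(s2, 2, var)),
               sum(apply(y, 2, var)), tolerance = 1e-8)
})

test_that("weighted PC-distance fits recover generative weights", {
  big <- compose_two_part_objects(make_part_library(7, 64, seed = 2))
  # noise-free: exact recovery, perfect held-out correlation
  w0 <- make_sim_world(big, d = 10, seed = 21,
                       weights = c(5:1, rep(0.2, 5)) / 5)
  fit0 <- fit_weighted_pc_distances(w0$features, w0$pairs, seed = 1)
  expect_lt(max(abs(fit0$weights - w0$model$weights)) /
              max(w0$model$weights), 1e-6)
  expect_equal(fit0$mean_r, 1, tolerance = 1e-9)
  # noisy at ~1,000 pairs: weight correlation with truth > 0.95
  wn <- make_sim_world(big, d = 10, noise_sd = 0.1, seed = 22,
                       weights = c(5:1, rep(0.2, 5)) / 5)
  fitn <- fit_weighted_pc_distances(wn$features, wn$pairs, seed = 2)
  expect_gt(cor(fitn$weights, wn$model$weights), 0.95)
  # null: observed distances independent of features
  set.seed(23)
  null_pairs <- wn$pairs
  null_pairs$dissimilarity <- runif(nrow(null_pairs), 0.5, 2)
  fit_null <- fit_weighted_pc_distances(wn$features, null_pairs, seed = 3)
  expect_lt(abs(fit_null$mean_r), 0.1)
  # cross-validation never scores training pairs
  for (f in fit0$folds)
    expect_length(intersect(f$train, f$test), 0)
})

test_that("non-negative fitting recovers non-negative truth", {
  w0 <- make_sim_world(fix_set, d = 4, seed = 31, weights = c(2, 1, 0.5, 0))
  fit <- fit_weighted_pc_distances(w0$features, w0$pairs, seed = 1,
                                   nonneg = TRUE)
  expect_true(all(fit$weights >= 0))
  expect_equal(fit$weights, c(2, 1, 0.5, 0), tolerance = 1e-4)
})

test_that("variance explained follows the squared correlation ratio", {
  expect_equal(variance_explained(0.5, 0.5), 100)
  expect_equal(variance_explained(0, 0.9), 0)
  # printed headline recomputation from rounded inputs
  expect_equal(variance_explained(0.74, spearman_brown(0.81)), 68.358,
               tolerance = 1e-3)
  expect_error(variance_explained(0.5, 0), "rc")
})

test_that("comb2 recovers model-combination weights", {
  set.seed(41)
  n <- 300
  pt <- pair_table(data.frame(image_a = sprintf("a%03d", 1:n),
                              image_b = sprintf("b%03d", 1:n),
                              dissimilarity = runif(n, 0.5, 2)))
  # single column equal to y
  f1 <- fit_comb2(cbind(m1 = pt$dissimilarity), pt, seed = 1)
  expect_equal(unname(f1$weights), 1, tolerance = 1e-10)
  expect_equal(f1$mean_r, 1, tolerance = 1e-10)
  # exact two-model combination
  X <- cbind(m1 = runif(n, 0, 1), m2 = runif(n, 0, 1))
  pt2 <- pair_table(transform(pt,
    dissimilarity = 2 * X[, 1] + 3 * X[, 2] + 0.01))
  f2 <- fit_comb2(cbind(X, intercept = 1), pt2, seed = 1)
  expect_equal(unname(f2$weights[1:2]), c(2, 3), tolerance = 1e-8)
  # permuted response carries no signal
  set.seed(42)
  pt3 <- pair_table(transform(pt2,
    dissimilarity = sample(dissimilarity)))
  f3 <- fit_comb2(cbind(X, intercept = 1), pt3, seed = 1)
  expect_lt(abs(f3$mean_r), 0.15)
})

test_that("comb1 concatenation z-scores, aligns and reduces", {
  set.seed(51)
  ids <- sprintf("im%02d", 1:30)
  t1 <- feature_table(matrix(rnorm(30 * 6), 30, 6), ids)
  # one table: identical to PCA of its z-scored self
  single <- comb1_concat(list(t1), d = 4)
  direct <- pca_reduce(feature_table(scale(unclass(t1)), ids), 4)
  expect_equal(unclass(single), unclass(direct), ignore_attr = TRUE)
  # duplicating the table preserves the distance ordering
  dup <- comb1_concat(list(t1, t1), d = 4)
  d1 <- dist(single); d2 <- dist(dup)
  expect_equal(cor(as.numeric(d1), as.numeric(d2), method = "spearman"), 1)
  # zero-variance features dropped with warning
  t2 <- feature_table(cbind(unclass(t1), const = 1), ids)
  expect_warning(comb1_concat(list(t2), d = 4), "zero-variance")
  # disjoint image sets fail
  t3 <- feature_table(matrix(rnorm(30 * 6), 30, 6), paste0("x", 1:30))
  expect_error(comb1_concat(list(t1, t3)), "alignment")
})

test_that("leave-one-experiment-out isolates a mismatched group", {
  big <- compose_two_part_objects(make_part_library(6, 64, seed = 6))
  w <- make_sim_world(big, d = 6, noise_sd = 0.05, seed = 61)
  pairs <- w$pairs
  set.seed(62)
  pairs$experiment_id <- sample(c("e1", "e2", "e3"), nrow(pairs), TRUE)
  # one group carries a symmetry bonus the features cannot express
  bump <- pairs$experiment_id == "e3"
  pairs$dissimilarity[bump] <-
    pairs$dissimilarity[bump] + 0.6 * pairs$sym_strength[bump]
  res <- leave_one_group_out(w$features, pairs, mode = "features", rc = 0.95)
  expect_equal(nrow(res), 3)
  expect_equal(res$experiment_id[which.min(res$percent_variance_explained)],
               "e3")
  expect_true(all(res$percent_variance_explained[res$experiment_id != "e3"] >
                    res$percent_variance_explained[res$experiment_id == "e3"]))
  expect_error(leave_one_group_out(w$features,
                                   transform(pairs, experiment_id = "e1")),
               "2 experiment groups")
})
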