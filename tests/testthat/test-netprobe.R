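# small trained network over separable Gaussian classes
make_toy_world <- function(n = 400, p = 12, k = 3, seed = 1) {
  set.seed(seed)
  mu <- matrix(rnorm(k * p) * 3, k, p)
  cls <- sample(seq_len(k), n, TRUE)
  x <- matrix(rnorm(n * p), n, p) + mu[cls, ]
  list(x = x, cls = as.character(cls))
}

test_that("toy networks are deterministic, calibrated softmax machines", {
  w <- make_toy_world(seed = 2)
  net <- make_toy_network(w$x[1:300, ], w$cls[1:300], n_units = 32, seed = 3)
  net2 <- make_toy_network(w$x[1:300, ], w$cls[1:300], n_units = 32, seed = 3)
  expect_identical(net$W1, net2$W1)
  expect_identical(net$W2, net2$W2)
  P <- probe_probs(net, w$x[301:400, ])
  expect_lt(max(abs(rowSums(P) - 1)), 1e-12)
  acc <- mean(net$classes[max.col(P)] == w$cls[301:400])
  expect_gt(acc, 0.9)
  expect_error(make_toy_network(w$x, rep("a", nrow(w$x))), "degenerate")
  expect_error(make_toy_network(w$x, w$cls, n_units = 1024), "512")
})

test_that("ablation importance matches a brute-force rebuilt-head oracle", {
  w <- make_toy_world(seed = 4)
  net <- make_toy_network(w$x, w$cls, n_units = 24, seed = 5)
  imp <- unit_importance(net, w$x, w$cls, n_images = 20, seed = 1)
  # oracle: rebuild the head without the unit and re-run the forward pass
  A <- probe_activations(net, w$x[imp$images_used, ])
  ci <- match(w$cls[imp$images_used], net$classes)
  P0 <- probe_probs(net, w$x[imp$images_used, ])
  p_o <- P0[cbind(seq_along(ci), ci)]
  for (u in seq_len(24)) {
    Z <- A[, -u, drop = FALSE] %*% net$W2[-u, , drop = FALSE] +
      matrix(net$b2, nrow(A), length(net$b2), byrow = TRUE)
    Pm <- exp(Z - apply(Z, 1, max)); Pm <- Pm / rowSums(Pm)
    delta_oracle <- mean(abs(p_o - Pm[cbind(seq_along(ci), ci)]))
    expect_lt(abs(imp$delta[u] - delta_oracle), 1e-10)
  }
  # a unit with zero outgoing weights has zero importance
  net0 <- net; net0$W2[7, ] <- 0
  imp0 <- unit_importance(net0, w$x, w$cls, n_images = 20, seed = 1)
  expect_equal(imp0$delta[7], 0)
  expect_length(imp$top, imp$k)
  expect_length(imp$bottom, imp$k)
  expect_equal(imp$k, round(24 / 10))
  expect_error(probe_probs(net, w$x, ablate_unit = 99), "out of range")
})

test_that("unit-subset distances are Euclidean and monotone in the subset", {
  # hand-built network: identity extractor exposes inputs as activations
  net <- structure(list(W1 = diag(4), b1 = rep(0, 4),
                        W2 = matrix(0, 4, 2), b2 = c(0, 0),
                        classes = c("a", "b"), input_dim = 4),
                   class = "probe_network")
  x <- rbind(c(1, 0, 0, 0), c(0, 1, 0, 0), c(1, 0, 0, 0))
  d <- unit_set_distances(net, x)
  expect_equal(d$distance[d$i == 1 & d$j == 2], sqrt(2))
  expect_equal(d$distance[d$i == 1 & d$j == 3], 0)
  set.seed(6)
  xr <- matrix(abs(rnorm(20)), 5, 4)
  full <- unit_set_distances(net, xr)$distance
  sub <- unit_set_distances(net, xr, units = c(1, 3))$distance
  expect_true(all(sub <= full + 1e-12))
  expect_error(unit_set_distances(net, xr, units = integer(0)), "empty")
})

test_that("SMI follows its contrast definition and simulation signs", {
  pr <- data.frame(distance = c(3, 3, 1, 1, 1),
                   relation = c("symmetric_symmetric", "symmetric_symmetric",
                                rep("disjoint_asymmetric", 3)))
  expect_equal(smi(pr)$smi, 0.5)        # (3 - 1)/(3 + 1)
  pr$distance <- rep(2, 5)
  expect_equal(smi(pr)$smi, 0)
  expect_error(smi(data.frame(distance = 1,
                              relation = "symmetric_symmetric")),
               "disjoint_asymmetric")
  # symmetry-bonus world: positive SMI; neutral world: small SMI
  big6 <- compose_two_part_objects(make_part_library(6, 64, seed = 6))
  wb <- make_sim_world(big6, d = 4, beta_sym = 0.6, noise_sd = 0.05,
                       seed = 81, weights = rep(0.1, 4))
  expect_gt(smi(wb$pairs)$smi, 0.05)
  wn <- make_sim_world(big6, d = 4, noise_sd = 0.05, seed = 82,
                       weights = rep(0.1, 4))
  expect_lt(abs(smi(wn$pairs)$smi), 0.1)
  # bounds on arbitrary non-negative distances
  set.seed(83)
  prr <- data.frame(distance = abs(rnorm(441)),
                    relation = c(rep("symmetric_symmetric", 21),
                                 rep("disjoint_asymmetric", 420)))
  s <- smi(prr)$smi
  expect_gte(s, -1); expect_lte(s, 1)
})

test_that("bootstrap SMI is seeded, consistent and degenerate-safe", {
  wb <- make_sim_world(fix_set, d = 4, beta_sym = 0.6, noise_sd = 0.05,
                       seed = 84)
  b1 <- bootstrap_smi(wb$pairs, n_boot = 500, seed = 9)
  b2 <- bootstrap_smi(wb$pairs, n_boot = 500, seed = 9)
  expect_identical(b1$replicates, b2$replicates)
  expect_lt(abs(b1$mean - b1$plugin), 2 * b1$sd)
  # constant distances: all replicates identical, sd = 0
  pc <- wb$pairs; pc$dissimilarity <- 1
  pc$relation <- wb$pairs$relation
  bc <- bootstrap_smi(pc, n_boot = 200, seed = 1)
  expect_equal(bc$sd, 0)
  expect_true(all(bc$replicates == 0))
  expect_warning(bootstrap_smi(wb$pairs, n_boot = 50, seed = 1), "noisy")
})

test_that("spatial-frequency modulation uses the canonical groups", {
  # identity-extractor network with 6 units; craft activations by giving
  # each image a constant intensity so unit activations track frequency
  bank <- gabor_bank(size = 24)
  w <- make_toy_world(n = 200, p = 24 * 24, k = 2, seed = 7)
  net <- make_toy_network(w$x, w$cls, n_units = 16, seed = 8)
  sf <- sf_modulation(net, bank)
  # independent re-derivation from raw activations
  A <- probe_activations(net, bank)
  freqs <- bank$meta$spatial_frequency
  for (u in c(1, 5, 9)) {
    af <- tapply(A[, u], freqs, mean)
    ah <- mean(af[c("0.25", "0.33", "0.5")])
    al <- mean(af[c("0.06", "0.09", "0.17")])
    expect_equal(sf$mi[u], (ah - al) / (ah + al), tolerance = 1e-12)
  }
  ok <- !is.na(sf$mi)
  expect_true(all(sf$mi[ok] >= -1 & sf$mi[ok] <= 1))
  # hand values: A_hsf = 2, A_lsf = 1 -> 1/3; only-high -> 1; equal -> 0
  expect_equal((2 - 1) / (2 + 1), 1 / 3)
  bank_bad <- bank
  bank_bad$meta$spatial_frequency[bank_bad$meta$spatial_frequency == 0.5] <-
    0.45
  expect_error(sf_modulation(net, bank_bad), "span")
})

test_that("mirror-augmented training strengthens the symmetry advantage", {
  # desk-scale analogue of flip augmentation: the two-part object set is
  # closed under mirroring, so the augmented net trains on all n^2
  # objects (canonical images plus their mirrors) while the
  # no-augmentation net sees only the canonical orderings (left <= right);
  # labels are the unordered part pair, i.e. mirror-invariant classes.
  lib <- make_part_library(5, 40, seed = 1)
  set <- compose_two_part_objects(lib)
  x <- flatten_set(set)
  lab <- apply(set$meta[, c("left_part", "right_part")], 1,
               function(v) paste(sort(v), collapse = "-"))
  canon <- which(set$meta$left_part <= set$meta$right_part)
  seeds <- 1:5
  smi_aug <- numeric(length(seeds)); smi_no <- numeric(length(seeds))
  for (k in seq_along(seeds)) {
    na <- make_toy_network(x, lab, n_units = 32, seed = seeds[k],
                           iters = 400, lr = 0.05, train_extractor = TRUE)
    nn <- make_toy_network(x[canon, ], lab[canon], n_units = 32,
                           seed = seeds[k], iters = 400, lr = 0.05,
                           train_extractor = TRUE)
    smi_aug[k] <- smi(unit_set_distances(na, set))$smi
    smi_no[k] <- smi(unit_set_distances(nn, set))$smi
  }
  # every seed shows the contrast (sign test p = 2^-5 < 0.05)
  expect_true(all(smi_aug > smi_no))
  expect_gt(mean(smi_aug), mean(smi_no))
})
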