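#' Build a desk-scale probe network
#'
#' A stand-in for a deep network's final stages: a fixed random
#' projection with rectification as feature extractor, and a softmax
#' head (units x classes weight matrix plus bias) trained here by
#' full-batch gradient descent.  The object satisfies the probe-network
#' contract used by \code{\link{unit_importance}},
#' \code{\link{unit_set_distances}} and \code{\link{sf_modulation}}:
#' penultimate activations are exposed, and ablating unit i means
#' zeroing row i of the outgoing weight matrix while leaving the
#' extractor untouched.  Adapters for real pretrained networks can
#' supply their own \code{extract} function and head weights in the same
#' structure.
#'
#' @param x training inputs, examples x input-dim (e.g. flattened
#'   images).
#' @param y training class labels (factor/character/integer).
#' @param n_units penultimate width (<= 512).
#' @param seed seed for the projection and training.
#' @param iters,lr gradient-descent controls.
#' @param train_extractor if TRUE, the hidden layer is trained by
#'   backpropagation along with the head, so the penultimate
#'   representation depends on the training set (needed to study
#'   training-dependent effects such as mirror augmentation); if FALSE
#'   (default) the extractor is a fixed random projection and only the
#'   head is trained.
#' @return list of class \code{probe_network}: W1 (projection), b1, W2
#'   (units x classes), b2, classes, input_dim.
#' @export
make_toy_network <- function(x, y, n_units = 64, seed = 1,
                             iters = 300, lr = 0.5,
                             train_extractor = FALSE) {
  x <- as.matrix(x)
  if (n_units > 512) stop("invalid parameter: n_units must be <= 512")
  classes <- sort(unique(as.character(y)))
  if (length(classes) < 2 || nrow(x) < length(classes))
    stop("degenerate training data")
  set.seed(seed)
  W1 <- matrix(rnorm(ncol(x) * n_units), ncol(x), n_units) / sqrt(ncol(x))
  b1 <- numeric(n_units)
  sc <- max(sd(pmax(x %*% W1, 0)), 1e-8)
  if (!train_extractor) W1 <- W1 / sc
  yi <- match(as.character(y), classes)
  Y <- matrix(0, nrow(x), length(classes))
  Y[cbind(seq_len(nrow(x)), yi)] <- 1
  W2 <- matrix(0, n_units, length(classes))
  b2 <- numeric(length(classes))
  n <- nrow(x)
  for (it in seq_len(iters)) {   # full-batch GD, cross-entropy + ridge
    A <- pmax(sweep(x %*% W1, 2, b1, "+"), 0)
    P <- softmax_rows(A %*% W2 + matrix(b2, n, length(b2), byrow = TRUE))
    G <- (P - Y) / n
    if (train_extractor) {
      dA <- (G %*% t(W2)) * (A > 0)
      W1 <- W1 - lr * (crossprod(x, dA) + 1e-5 * W1)
      b1 <- b1 - lr * colSums(dA)
    }
    W2 <- W2 - lr * (crossprod(A, G) + 1e-4 * W2)
    b2 <- b2 - lr * colSums(G)
  }
  structure(list(W1 = W1, b1 = b1, W2 = W2, b2 = b2,
                 classes = classes, input_dim = ncol(x), seed = seed),
            class = "probe_network")
}

softmax_rows <- function(Z) {
  Z <- Z - apply(Z, 1, max)
  E <- exp(Z)
  E / rowSums(E)
}

#' @export
print.probe_network <- function(x, ...) {
  cat("probe_network:", ncol(x$W1), "units,", length(x$classes),
      "classes, input dim", x$input_dim, "\n")
  invisible(x)
}

# flatten a stimulus set (or accept a plain matrix of inputs)
probe_inputs <- function(net, images) {
  if (inherits(images, "stimulus_set"))
    images <- t(vapply(images$images, as.numeric,
                       numeric(net$input_dim)))
  as.matrix(images)
}

#' Penultimate activations of a probe network
#'
#' @param net a \code{probe_network}.
#' @param images a \code{stimulus_set} (flattened) or input matrix.
#' @return matrix, examples x units (non-negative).
#' @export
probe_activations <- function(net, images) {
  pmax(sweep(probe_inputs(net, images) %*% net$W1, 2, net$b1, "+"), 0)
}

#' Class probabilities of a probe network, optionally with a unit ablated
#'
#' Ablation zeroes the outgoing weights of the unit (one row of the
#' head's weight matrix); the extractor is untouched and the original
#' network is never modified.
#'
#' @param net a \code{probe_network}.
#' @param images inputs as in \code{\link{probe_activations}}.
#' @param ablate_unit optional unit index to ablate.
#' @return matrix, examples x classes; rows sum to 1.
#' @export
probe_probs <- function(net, images, ablate_unit = NULL) {
  A <- probe_activations(net, images)
  W <- net$W2
  if (!is.null(ablate_unit)) {
    if (ablate_unit < 1 || ablate_unit > nrow(W))
      stop("unit index out of range")
    W[ablate_unit, ] <- 0
  }
  P <- softmax_rows(A %*% W + matrix(net$b2, nrow(A), length(net$b2),
                                     byrow = TRUE))
  colnames(P) <- net$classes
  P
}

#' Unit importance by outgoing-weight ablation
#'
#' For each unit n_i, the importance is
#' \deqn{\delta(n_i) = \frac{1}{n}\sum_j |p_o(c_j) - p_m(c_j)|}
#' where p_o is the true-class probability of the intact network for
#' probe image j and p_m the same probability with unit i's outgoing
#' weights zeroed.  Probe images are drawn (seeded) from correctly
#' classified examples, preferring distinct classes.
#'
#' @param net a \code{probe_network}.
#' @param images candidate probe inputs.
#' @param true_classes true class label per input.
#' @param n_images number of probe images; default 20.
#' @param k size of the top/bottom unit sets; default
#'   max(1, round(n_units / 10)), the scaled-down analogue of the
#'   top-100/bottom-100 convention for 4096-unit layers.
#' @param seed selection seed.
#' @return list of class \code{unit_importance}: delta (per unit),
#'   ranking (decreasing), top, bottom, images_used.
#' @export
unit_importance <- function(net, images, true_classes, n_images = 20,
                            k = NULL, seed = 1) {
  X <- probe_inputs(net, images)
  cls <- as.character(true_classes)
  P0 <- probe_probs(net, X)
  pred <- net$classes[max.col(P0)]
  correct <- which(pred == cls)
  if (length(correct) == 0) stop("no correctly classified probe images")
  set.seed(seed)
  # prefer one image per distinct class, then fill at random
  pick <- unlist(lapply(split(correct, cls[correct]), function(ix)
    ix[sample.int(length(ix), 1)]))
  if (length(pick) > n_images) pick <- sample(pick, n_images)
  remaining <- setdiff(correct, pick)
  if (length(pick) < n_images && length(remaining) > 0)
    pick <- c(pick, sample(remaining,
                           min(n_images - length(pick), length(remaining))))
  pick <- sort(unname(pick))
  Xs <- X[pick, , drop = FALSE]
  ci <- match(cls[pick], net$classes)
  p_o <- probe_probs(net, Xs)[cbind(seq_along(pick), ci)]
  n_units <- nrow(net$W2)
  delta <- vapply(seq_len(n_units), function(u) {
    p_m <- probe_probs(net, Xs, ablate_unit = u)[cbind(seq_along(pick), ci)]
    mean(abs(p_o - p_m))
  }, numeric(1))
  if (is.null(k)) k <- max(1L, round(n_units / 10))
  ord <- order(delta, decreasing = TRUE)
  structure(list(delta = delta, ranking = ord,
                 top = ord[seq_len(k)], bottom = rev(ord)[seq_len(k)],
                 k = k, images_used = pick),
            class = "unit_importance")
}

#' Pairwise activation distances restricted to a unit subset
#'
#' Euclidean distances between penultimate activation vectors restricted
#' to the given units, for all unordered image pairs of the set.
#'
#' @param net a \code{probe_network}.
#' @param set a \code{stimulus_set} (relation tags are attached when part
#'   metadata is present) or input matrix.
#' @param units unit indices; default all.
#' @return data.frame: i, j, image_a, image_b, distance, and relation
#'   when available.
#' @export
unit_set_distances <- function(net, set, units = NULL) {
  A <- probe_activations(net, set)
  if (is.null(units)) units <- seq_len(ncol(A))
  if (length(units) == 0) stop("empty unit subset")
  D <- as.matrix(dist(A[, units, drop = FALSE]))
  if (inherits(set, "stimulus_set") && "left_part" %in% names(set$meta)) {
    pr <- enumerate_pairs(set, "all")
    pr$distance <- D[cbind(pr$i, pr$j)]
    sym_i <- set$meta$is_symmetric[pr$i]
    sym_j <- set$meta$is_symmetric[pr$j]
    pr$relation <- ifelse(pr$both_symmetric, "symmetric_symmetric",
                   ifelse(!sym_i & !sym_j & pr$n_shared_parts == 0L,
                          "disjoint_asymmetric", "other"))
    return(pr)
  }
  idx <- combn(nrow(A), 2)
  ids <- if (inherits(set, "stimulus_set")) set$meta$image_id
         else as.character(seq_len(nrow(A)))
  data.frame(i = idx[1, ], j = idx[2, ],
             image_a = ids[idx[1, ]], image_b = ids[idx[2, ]],
             distance = D[t(idx)], stringsAsFactors = FALSE)
}

#' Symmetry modulation index
#'
#' \deqn{SMI = \frac{d_{sym} - d_{asym}}{d_{sym} + d_{asym}}}
#' where d_sym and d_asym are the mean distances of
#' symmetric-symmetric and disjoint-asymmetric pairs.
#'
#' @param pairs data.frame with distance and relation columns (from
#'   \code{\link{unit_set_distances}} or a \code{pair_table} whose
#'   dissimilarity is used as the distance).
#' @return list: smi, d_sym, d_asym, n_sym, n_asym.
#' @export
smi <- function(pairs) {
  d <- if ("distance" %in% names(pairs)) pairs$distance
       else pairs$dissimilarity
  ds <- d[pairs$relation == "symmetric_symmetric"]
  da <- d[pairs$relation == "disjoint_asymmetric"]
  if (length(ds) == 0 || length(da) == 0)
    stop("need both symmetric_symmetric and disjoint_asymmetric pairs")
  d_sym <- mean(ds); d_asym <- mean(da)
  if (d_sym + d_asym == 0) stop("undefined SMI: zero mean distances")
  list(smi = (d_sym - d_asym) / (d_sym + d_asym),
       d_sym = d_sym, d_asym = d_asym,
       n_sym = length(ds), n_asym = length(da))
}

#' Bootstrap distribution of the symmetry modulation index
#'
#' Resamples the symmetric and asymmetric pair sets with replacement
#' (keeping each set's own count, e.g. 21 and 420 for the 49-object
#' set) and recomputes the SMI per replicate.
#'
#' @param pairs as in \code{\link{smi}}.
#' @param n_boot replicates; default 10000.
#' @param seed resampling seed.
#' @param conf confidence level for the percentile interval.
#' @return list: mean, sd, ci, replicates, plugin (the full-sample SMI).
#' @export
bootstrap_smi <- function(pairs, n_boot = 10000, seed = 1, conf = 0.95) {
  if (n_boot < 100) warning("n_boot < 100: bootstrap sd will be noisy")
  d <- if ("distance" %in% names(pairs)) pairs$distance
       else pairs$dissimilarity
  ds <- d[pairs$relation == "symmetric_symmetric"]
  da <- d[pairs$relation == "disjoint_asymmetric"]
  if (length(ds) == 0 || length(da) == 0)
    stop("need both symmetric_symmetric and disjoint_asymmetric pairs")
  set.seed(seed)
  reps <- vapply(seq_len(n_boot), function(b) {
    s <- mean(ds[sample.int(length(ds), replace = TRUE)])
    a <- mean(da[sample.int(length(da), replace = TRUE)])
    (s - a) / (s + a)
  }, numeric(1))
  alpha <- (1 - conf) / 2
  list(mean = mean(reps), sd = sd(reps),
       ci = unname(quantile(reps, c(alpha, 1 - alpha))),
       replicates = reps,
       plugin = (mean(ds) - mean(da)) / (mean(ds) + mean(da)))
}

#' Spatial-frequency modulation index per unit
#'
#' Each unit's activation is averaged across orientations for every
#' spatial frequency; A_hsf is the mean over the high-frequency group
#' (0.25, 0.33, 0.5 cycles/pixel) and A_lsf over the low-frequency group
#' (0.06, 0.09, 0.17).  The index is
#' \deqn{MI = \frac{A_{hsf} - A_{lsf}}{A_{hsf} + A_{lsf}},}
#' NA for units with no Gabor response.
#'
#' @param net a \code{probe_network}.
#' @param bank a Gabor \code{stimulus_set} (see \code{\link{gabor_bank}})
#'   whose meta has orientation and spatial_frequency; must span both
#'   frequency groups.
#' @param hsf,lsf frequency groups in cycles/pixel.
#' @return list: mi (per unit, NA where undefined), A_hsf, A_lsf,
#'   by_frequency (units x frequencies mean-activation matrix).
#' @export
sf_modulation <- function(net, bank,
                          hsf = c(0.25, 0.33, 0.5),
                          lsf = c(0.06, 0.09, 0.17)) {
  if (!all(c("orientation", "spatial_frequency") %in% names(bank$meta)))
    stop("bank metadata needs orientation and spatial_frequency")
  freqs <- sort(unique(bank$meta$spatial_frequency))
  if (!all(hsf %in% freqs) || !all(lsf %in% freqs))
    stop("bank must span both the high and low spatial-frequency groups")
  A <- probe_activations(net, bank)
  by_freq <- vapply(freqs, function(f)
    colMeans(A[bank$meta$spatial_frequency == f, , drop = FALSE]),
    numeric(ncol(A)))
  colnames(by_freq) <- as.character(freqs)
  a_h <- rowMeans(by_freq[, as.character(hsf), drop = FALSE])
  a_l <- rowMeans(by_freq[, as.character(lsf), drop = FALSE])
  mi <- ifelse(a_h + a_l == 0, NA_real_, (a_h - a_l) / (a_h + a_l))
  list(mi = mi, A_hsf = a_h, A_lsf = a_l, by_frequency = by_freq)
}
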