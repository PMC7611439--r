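#' Generate a library of random part silhouettes
#'
#' Parts are smooth random blobs obtained by thresholding a low-pass
#' filtered white-noise field, with a small tab forcing contact with the
#' stem.  Each part is stored in canonical left-end orientation: its right
#' edge abuts the left end of a horizontal stem.  Composing parts at both
#' ends of the stem (\code{\link{compose_two_part_objects}}) yields the
#' part-composable object sets used throughout the package; seven parts
#' give the canonical 49-object set.
#'
#' @param n_parts number of distinct parts (>= 2).
#' @param canvas side of the square canvas in pixels (>= 32); default 140.
#' @param seed integer seed; the library is deterministic given the seed.
#' @return an object of class \code{part_library}: list with \code{parts}
#'   (list of binary part-box masks), \code{canvas}, stem geometry and
#'   placement offsets.
#' @export
make_part_library <- function(n_parts = 7, canvas = 140, seed = 1) {
  if (n_parts < 2) stop("invalid parameter: n_parts must be >= 2")
  if (canvas < 32) stop("invalid parameter: canvas must be >= 32 pixels")
  pb <- floor(canvas * 0.30)            # part bounding box (pb x pb)
  stem_len <- 2 * floor(canvas * 0.15)  # even length, flip-symmetric columns
  stem_th <- max(3L, 2 * floor(canvas / 40) + 1L)
  a <- floor((canvas - stem_len) / 2) + 1L   # first stem column
  if (a - pb < 1L)
    stop("invalid parameter: canvas too small to hold a part beside the stem")
  r0 <- floor((canvas - pb) / 2) + 1L        # top row of the part box
  sr0 <- floor((canvas - stem_th) / 2) + 1L  # top row of the stem

  set.seed(seed)
  sig <- pb / 6
  khw <- ceiling(3 * sig)
  kern <- exp(-((-khw:khw)^2) / (2 * sig^2))
  kern <- kern / sum(kern)
  blur1d <- function(m) {  # separable Gaussian blur, replicate-padded
    pad <- function(v) c(rep(v[1], khw), v, rep(v[length(v)], khw))
    apply(m, 2, function(v) stats::filter(pad(v), kern, sides = 2)[(khw + 1):(khw + length(v))])
  }
  stem_rows_in_box <- (sr0:(sr0 + stem_th - 1L)) - r0 + 1L
  make_part <- function() {
    field <- matrix(rnorm(pb * pb), pb, pb)
    field <- t(blur1d(t(blur1d(field))))
    mask <- (field >= quantile(field, 0.68)) * 1
    # tab: guarantee attachment to the stem at the right edge of the box
    mask[stem_rows_in_box, (pb - 2L):pb] <- 1
    mask
  }
  parts <- vector("list", n_parts)
  keys <- character(n_parts)
  for (i in seq_len(n_parts)) {
    for (try in 1:100) {
      p <- make_part()
      key <- paste(which(p > 0), collapse = ",")
      if (!key %in% keys[seq_len(i - 1)]) break
    }
    if (key %in% keys[seq_len(i - 1)])
      stop("failed to generate distinct parts")
    parts[[i]] <- p
    keys[i] <- key
  }
  structure(list(parts = parts, canvas = canvas, part_box = pb,
                 stem_col0 = a, stem_len = stem_len,
                 stem_row0 = sr0, stem_thickness = stem_th,
                 part_row0 = r0, seed = seed),
            class = "part_library")
}

#' @export
print.part_library <- function(x, ...) {
  cat("part_library:", length(x$parts), "parts on a", x$canvas, "x",
      x$canvas, "canvas (seed", paste0(x$seed, ")"), "\n")
  invisible(x)
}

# stem raster on the full canvas; its column set {a .. W+1-a} is invariant
# under the left-right flip, so composed AA objects are exactly symmetric
stem_raster <- function(lib) {
  m <- matrix(0, lib$canvas, lib$canvas)
  cols <- lib$stem_col0:(lib$canvas + 1L - lib$stem_col0)
  rows <- lib$stem_row0:(lib$stem_row0 + lib$stem_thickness - 1L)
  m[rows, cols] <- 1
  m
}

# place a canonical part mask at the left end of the stem
place_left <- function(lib, mask) {
  m <- matrix(0, lib$canvas, lib$canvas)
  pb <- lib$part_box
  m[lib$part_row0:(lib$part_row0 + pb - 1L),
    (lib$stem_col0 - pb):(lib$stem_col0 - 1L)] <- mask
  m
}

#' Compose all two-part objects from a part library
#'
#' Every ordered pair (left part, right part) yields one object: the left
#' part in canonical orientation, the right part as the horizontal mirror
#' of its canonical form, joined by a centered horizontal stem.  Objects
#' with the same part at both ends are therefore pixel-exact mirror
#' symmetric about the vertical axis.
#'
#' @param library a \code{part_library}.
#' @return an object of class \code{stimulus_set}: list with \code{images}
#'   (list of binary canvases) and \code{meta} (data.frame with image_id,
#'   left_part, right_part, orientation, is_symmetric).
#' @export
compose_two_part_objects <- function(library) {
  if (!inherits(library, "part_library")) stop("need a part_library")
  n <- length(library$parts)
  stem <- stem_raster(library)
  placed <- lapply(library$parts, function(p) place_left(library, p))
  images <- vector("list", n * n)
  meta <- expand.grid(right_part = seq_len(n), left_part = seq_len(n))
  meta <- meta[, c("left_part", "right_part")]
  for (k in seq_len(nrow(meta))) {
    i <- meta$left_part[k]; j <- meta$right_part[k]
    images[[k]] <- pmax(stem, placed[[i]], flip_cols(placed[[j]]))
  }
  meta$image_id <- sprintf("obj_%02d_%02d", meta$left_part, meta$right_part)
  meta$orientation <- "horizontal"
  meta$is_symmetric <- meta$left_part == meta$right_part
  rownames(meta) <- NULL
  structure(list(images = images,
                 meta = meta[, c("image_id", "left_part", "right_part",
                                 "orientation", "is_symmetric")]),
            class = "stimulus_set")
}

#' @export
print.stimulus_set <- function(x, ...) {
  cat("stimulus_set:", length(x$images), "images,",
      sum(x$meta$is_symmetric), "symmetric\n")
  invisible(x)
}

#' Rotate every image in a stimulus set by a right angle
#'
#' Rotation is lossless (pixel permutation).  A 90 or 270 degree turn
#' swaps the orientation tag, mapping vertical-axis symmetry onto the
#' horizontal axis.
#'
#' @param set a \code{stimulus_set}.
#' @param angle one of 90, 180, 270 (degrees counter-clockwise).
#' @return the rotated \code{stimulus_set}.
#' @export
rotate_set <- function(set, angle) {
  if (!angle %in% c(90, 180, 270))
    stop("invalid parameter: angle must be 90, 180 or 270")
  k <- angle / 90
  set$images <- lapply(set$images, rot90ccw, k = k)
  if (angle %in% c(90, 270)) {
    swap <- c(horizontal = "vertical", vertical = "horizontal")
    set$meta$orientation <- unname(swap[set$meta$orientation])
  }
  set
}

# multiset intersection size of the two part pairs
shared_part_count <- function(l1, r1, l2, r2) {
  a <- c(l1, r1); b <- c(l2, r2)
  n <- 0L
  for (p in unique(a))
    n <- n + min(sum(a == p), sum(b == p))
  n
}

#' Enumerate unordered image pairs of a stimulus set by relation
#'
#' Relations are defined on the part metadata: \code{symmetric_symmetric}
#' selects pairs of two (distinct) symmetric objects;
#' \code{disjoint_asymmetric} selects the "AB-CD" pairs, both objects
#' asymmetric and sharing no part; \code{share_one_part} and
#' \code{share_two_parts} select by multiset part overlap.
#'
#' @param set a \code{stimulus_set} with part metadata.
#' @param relation one of "all", "symmetric_symmetric",
#'   "disjoint_asymmetric", "share_one_part", "share_two_parts".
#' @return data.frame with columns i, j (indices, i < j), image_a, image_b,
#'   n_shared_parts, both_symmetric.
#' @export
enumerate_pairs <- function(set, relation = "all") {
  rels <- c("all", "symmetric_symmetric", "disjoint_asymmetric",
            "share_one_part", "share_two_parts")
  if (!relation %in% rels)
    stop("invalid parameter: unknown relation tag '", relation, "'")
  m <- set$meta
  idx <- combn(nrow(m), 2)
  i <- idx[1, ]; j <- idx[2, ]
  ns <- mapply(shared_part_count, m$left_part[i], m$right_part[i],
               m$left_part[j], m$right_part[j])
  both_sym <- m$is_symmetric[i] & m$is_symmetric[j]
  out <- data.frame(i = i, j = j,
                    image_a = m$image_id[i], image_b = m$image_id[j],
                    n_shared_parts = as.integer(ns),
                    both_symmetric = both_sym,
                    stringsAsFactors = FALSE)
  keep <- switch(relation,
    all = rep(TRUE, nrow(out)),
    symmetric_symmetric = both_sym,
    disjoint_asymmetric = !m$is_symmetric[i] & !m$is_symmetric[j] & ns == 0L,
    share_one_part = ns == 1L,
    share_two_parts = ns == 2L)
  out[keep, , drop = FALSE]
}

#' Specify a Gabor patch
#'
#' @param orientation grating orientation in degrees, [0, 180).
#' @param spatial_frequency carrier frequency in cycles/pixel (> 0).
#' @param phase carrier phase in degrees.
#' @param size image side in pixels.
#' @param envelope_sigma Gaussian envelope sigma in pixels (default size/5).
#' @return a \code{gabor_spec} list.
#' @export
gabor_spec <- function(orientation, spatial_frequency, phase = 0,
                       size = 140, envelope_sigma = size / 5) {
  if (spatial_frequency <= 0) stop("invalid parameter: spatial_frequency must be > 0")
  if (size <= 0) stop("invalid parameter: size must be > 0")
  structure(list(orientation = orientation,
                 spatial_frequency = spatial_frequency,
                 phase = phase, size = size,
                 envelope_sigma = envelope_sigma),
            class = "gabor_spec")
}

#' Render a Gabor patch
#'
#' Sinusoidal grating under a circular Gaussian envelope, rescaled to
#' [0, 1].  Orientation 0 gives vertical stripes (modulation along x);
#' orientation 90 is the transpose up to phase convention.
#'
#' @param spec a \code{\link{gabor_spec}}.
#' @return numeric matrix (size x size) in [0, 1].
#' @export
make_gabor <- function(spec) {
  s <- spec$size
  c0 <- (s + 1) / 2
  dy <- matrix(seq_len(s) - c0, s, s)
  dx <- matrix(seq_len(s) - c0, s, s, byrow = TRUE)
  th <- spec$orientation * pi / 180
  xp <- dx * cos(th) + dy * sin(th)
  g <- exp(-(dx^2 + dy^2) / (2 * spec$envelope_sigma^2)) *
    cos(2 * pi * spec$spatial_frequency * xp + spec$phase * pi / 180)
  (g - min(g)) / (max(g) - min(g))
}

#' Build a Gabor bank as a stimulus set
#'
#' Defaults follow the canonical probing bank: 8 orientations uniformly
#' sampled over [0, 180) crossed with 6 spatial frequencies
#' (0.06, 0.09, 0.17, 0.25, 0.33, 0.5 cycles/pixel).
#'
#' @param orientations vector of orientations in degrees.
#' @param frequencies vector of spatial frequencies in cycles/pixel.
#' @param size image side in pixels.
#' @param ... further arguments to \code{\link{gabor_spec}}.
#' @return a \code{stimulus_set}; meta holds orientation and
#'   spatial_frequency per image.
#' @export
gabor_bank <- function(orientations = seq(0, 180, length.out = 9)[1:8],
                       frequencies = c(0.06, 0.09, 0.17, 0.25, 0.33, 0.5),
                       size = 140, ...) {
  grid <- expand.grid(spatial_frequency = frequencies,
                      orientation = orientations)
  images <- lapply(seq_len(nrow(grid)), function(k)
    make_gabor(gabor_spec(grid$orientation[k], grid$spatial_frequency[k],
                          size = size, ...)))
  meta <- data.frame(
    image_id = sprintf("gabor_o%03d_f%0.2f", round(grid$orientation),
                       grid$spatial_frequency),
    orientation = grid$orientation,
    spatial_frequency = grid$spatial_frequency,
    stringsAsFactors = FALSE)
  structure(list(images = images, meta = meta), class = "stimulus_set")
}

#' Specify a synthetic dissimilarity model
#'
#' The generator writes, for each image pair (i, j),
#' \deqn{d_{ij} = \sum_k w_k |x_{ik} - x_{jk}| + \beta_{sym} S_{ij}
#'   + \beta_{area} \log AR_{ij} + \epsilon,}
#' where S is the pair symmetry strength, AR the area ratio and epsilon
#' Gaussian noise, clipped below at \code{floor}.  Units are 1/seconds
#' throughout.  The defaults emulate the structure of measured search
#' dissimilarity: a symmetry bonus that makes symmetric-pair distances
#' exceed disjoint asymmetric-pair distances by roughly 0.2 1/s, trial
#' noise of 0.1 1/s, and a small positive floor.
#'
#' @param weights per-feature weights w_k.
#' @param beta_sym symmetry-bonus coefficient (1/s per unit strength).
#' @param beta_area area-ratio coefficient (1/s per log unit).
#' @param noise_sd Gaussian noise sd in 1/s (>= 0).
#' @param floor lower clip for generated dissimilarities (1/s).
#' @param seed integer seed.
#' @return a \code{dissim_model} list.
#' @export
dissim_model <- function(weights, beta_sym = 0.5, beta_area = 0.1,
                         noise_sd = 0.1, floor = 0.05, seed = 1) {
  if (noise_sd < 0) stop("invalid parameter: noise_sd must be >= 0")
  structure(list(weights = weights, beta_sym = beta_sym,
                 beta_area = beta_area, noise_sd = noise_sd,
                 floor = floor, seed = seed),
            class = "dissim_model")
}

#' Simulate a dissimilarity table over a stimulus set
#'
#' @param set a \code{stimulus_set}.
#' @param features a \code{\link{feature_table}} row-aligned with the set.
#' @param model a \code{\link{dissim_model}} whose weights match the
#'   feature dimensionality.
#' @param pairs optional precomputed pair frame from
#'   \code{\link{enumerate_pairs}}; defaults to all pairs.
#' @return a \code{\link{pair_table}} with the generated dissimilarities
#'   and pair covariates (sym_strength, area_ratio, n_shared_parts,
#'   relation).
#' @export
simulate_dissimilarities <- function(set, features, model,
                                     pairs = enumerate_pairs(set, "all")) {
  x <- as_feature_matrix(features)
  if (nrow(x) != length(set$images))
    stop("invalid parameter: features not row-aligned with stimulus set")
  if (length(model$weights) != ncol(x))
    stop("invalid parameter: weight/feature dimension mismatch")
  i <- pairs$i; j <- pairs$j
  feat_d <- abs(x[i, , drop = FALSE] - x[j, , drop = FALSE]) %*% model$weights
  sym <- numeric(nrow(pairs)); ar <- numeric(nrow(pairs))
  sv <- vapply(set$images, symmetry_score, numeric(1), axis_angle = 0)
  sh <- vapply(set$images, symmetry_score, numeric(1), axis_angle = 90)
  areas <- vapply(set$images, object_area, numeric(1))
  sym <- pmax((sv[i] + sv[j]) / 2, (sh[i] + sh[j]) / 2)
  ar <- pmax(areas[i], areas[j]) / pmin(areas[i], areas[j])
  set.seed(model$seed)
  d <- as.numeric(feat_d) + model$beta_sym * sym +
    model$beta_area * log(ar) + rnorm(nrow(pairs), 0, model$noise_sd)
  d <- pmax(d, model$floor)
  rel <- ifelse(pairs$both_symmetric, "symmetric_symmetric",
         ifelse(!set$meta$is_symmetric[i] & !set$meta$is_symmetric[j] &
                pairs$n_shared_parts == 0L, "disjoint_asymmetric", "other"))
  pair_table(data.frame(
    image_a = pairs$image_a, image_b = pairs$image_b,
    dissimilarity = d, n_trials = 1L,
    sym_strength = sym, area_ratio = ar,
    n_shared_parts = pairs$n_shared_parts, relation = rel,
    stringsAsFactors = FALSE))
}
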