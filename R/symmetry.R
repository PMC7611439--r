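#' Mirror an image about an in-plane axis through its center
#'
#' Axis angle 0 is the vertical axis (left-right mirror, exact column
#' permutation); 90 is the horizontal axis (top-bottom mirror, exact).
#' For oblique angles the image is rotated so the axis becomes vertical,
#' flipped, and rotated back, using bilinear interpolation with zero fill.
#'
#' @param image numeric matrix, intensities >= 0.
#' @param axis_angle axis angle in degrees, [0, 180); 0 = vertical axis,
#'   increasing counter-clockwise.
#' @return reflected image, same size.
#' @export
reflect <- function(image, axis_angle = 0) {
  image_grid(image)
  if (length(image) == 0) stop("invalid input: empty image")
  a <- axis_angle %% 180
  if (a == 0) return(flip_cols(image))
  if (a == 90) return(flip_rows(image))
  rotate_bilinear(flip_cols(rotate_bilinear(image, -a)), a)
}

#' Strength of planar reflection symmetry about an axis
#'
#' The score is
#' \deqn{S = 1 - \frac{\sum |A - R|}{\sum (A + R)}}
#' with R the reflection of A about the given center axis and sums over
#' all pixels.  It is 1 when the image equals its reflection in every
#' pixel, and 0 when image and reflection have disjoint support.
#'
#' @param image numeric matrix with nonzero total intensity.
#' @param axis_angle axis angle in degrees; 0 = vertical axis.
#' @return score in [0, 1].
#' @export
symmetry_score <- function(image, axis_angle = 0) {
  image_grid(image)
  s <- sum(image)
  if (s == 0) stop("undefined score: all-zero image (zero denominator)")
  r <- reflect(image, axis_angle)
  1 - sum(abs(image - r)) / sum(image + r)
}

#' Multi-axis symmetry profile of an image
#'
#' Scores symmetry about \code{n_axes} axes at k * 180/n_axes degrees,
#' k = 0 .. n_axes - 1, with 0 = vertical.  The 8-axis profile is the
#' standard symmetry feature vector for classifier augmentation.
#'
#' @param image numeric matrix.
#' @param n_axes number of axes (>= 1); default 8.
#' @return a \code{symmetry_profile} list: axis_angles, scores, S_v, S_h.
#' @export
symmetry_profile <- function(image, n_axes = 8) {
  if (n_axes < 1) stop("invalid parameter: n_axes must be >= 1")
  angles <- (seq_len(n_axes) - 1) * 180 / n_axes
  scores <- vapply(angles, function(a) symmetry_score(image, a), numeric(1))
  sv <- if (0 %in% angles) scores[angles == 0] else symmetry_score(image, 0)
  sh <- if (90 %in% angles) scores[angles == 90] else symmetry_score(image, 90)
  structure(list(axis_angles = angles, scores = scores,
                 S_v = unname(sv), S_h = unname(sh)),
            class = "symmetry_profile")
}

#' Pair-level symmetry strength
#'
#' Vertical-axis scores are averaged over the two images, likewise the
#' horizontal-axis scores; the pair strength is the larger of the two
#' means.
#'
#' @param a,b images (numeric matrices).
#' @return value in [0, 1].
#' @export
pair_symmetry_strength <- function(a, b) {
  max((symmetry_score(a, 0) + symmetry_score(b, 0)) / 2,
      (symmetry_score(a, 90) + symmetry_score(b, 90)) / 2)
}

# pixel area above a binarization threshold (0.5 of max intensity)
object_area <- function(image, threshold_frac = 0.5) {
  m <- max(image)
  if (m == 0) stop("invalid input: empty object (no support)")
  sum(image > threshold_frac * m)
}

#' Area ratio of an image pair
#'
#' Ratio of the larger to the smaller object area, where area counts
#' pixels above half the image's maximum intensity (unambiguous on
#' silhouettes).  Symmetric in its arguments and always >= 1.
#'
#' @param a,b images with nonzero support.
#' @return area ratio >= 1.
#' @export
area_ratio <- function(a, b) {
  aa <- object_area(a); ab <- object_area(b)
  max(aa, ab) / min(aa, ab)
}

#' Symmetry profiles for a whole stimulus set
#'
#' @param set a \code{stimulus_set}.
#' @param n_axes number of axes per image.
#' @return data.frame: image_id, angle_<k> columns, S_v, S_h.
#' @export
symmetry_profile_table <- function(set, n_axes = 8) {
  profs <- lapply(set$images, symmetry_profile, n_axes = n_axes)
  sc <- do.call(rbind, lapply(profs, function(p) p$scores))
  colnames(sc) <- paste0("angle_", seq_len(n_axes) - 1)
  data.frame(image_id = set$meta$image_id, sc,
             S_v = vapply(profs, function(p) p$S_v, numeric(1)),
             S_h = vapply(profs, function(p) p$S_h, numeric(1)),
             stringsAsFactors = FALSE)
}
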