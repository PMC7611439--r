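#' Construct and validate an image grid
#'
#' An image grid is a plain numeric matrix of non-negative, finite pixel
#' intensities, normally in [0, 1], with rows running top to bottom.  Most
#' functions in the package accept any such matrix; this constructor just
#' validates and returns it.
#'
#' @param pixels numeric matrix of intensities.
#' @param require_object if TRUE, require at least one nonzero pixel.
#' @return the validated matrix.
#' @export
image_grid <- function(pixels, require_object = FALSE) {
  if (!is.matrix(pixels) || !is.numeric(pixels))
    stop("image must be a numeric matrix")
  if (any(!is.finite(pixels)))
    stop("image contains non-finite pixels")
  if (any(pixels < 0))
    stop("image contains negative intensities")
  if (require_object && sum(pixels) == 0)
    stop("object image must contain at least one nonzero pixel")
  pixels
}

# left-right mirror: column c -> W + 1 - c (axis between middle columns for
# even width, through the middle column for odd width)
flip_cols <- function(m) m[, ncol(m):1, drop = FALSE]

# top-bottom mirror: row r -> H + 1 - r
flip_rows <- function(m) m[nrow(m):1, , drop = FALSE]

#' Rotate a matrix by a multiple of 90 degrees (lossless)
#'
#' @param m numeric matrix.
#' @param k number of counter-clockwise quarter turns.
#' @return rotated matrix.
#' @export
rot90ccw <- function(m, k = 1L) {
  k <- as.integer(k) %% 4L
  for (i in seq_len(k)) m <- flip_rows(t(m))
  m
}

#' Rotate an image about its center by an arbitrary angle
#'
#' Inverse-mapped bilinear interpolation with zero fill outside the frame.
#' The center of rotation is ((H+1)/2, (W+1)/2), consistent with the mirror
#' line used by \code{\link{reflect}}.  Rotations by exact multiples of 90
#' degrees on square images reduce to pixel permutations.
#'
#' @param img numeric matrix.
#' @param angle_deg rotation angle in degrees (counter-clockwise).
#' @return rotated matrix of the same size.
#' @export
rotate_bilinear <- function(img, angle_deg) {
  h <- nrow(img); w <- ncol(img)
  th <- angle_deg * pi / 180
  ct <- cos(th); st <- sin(th)
  cy <- (h + 1) / 2; cx <- (w + 1) / 2
  # destination grid offsets
  dy <- matrix(seq_len(h) - cy, h, w)
  dx <- matrix(seq_len(w) - cx, h, w, byrow = TRUE)
  # source offsets: rotate destination by -angle
  sx <- ct * dx + st * dy + cx
  sy <- -st * dx + ct * dy + cy
  x0 <- floor(sx); y0 <- floor(sy)
  fx <- sx - x0; fy <- sy - y0
  out <- matrix(0, h, w)
  # accumulate the four bilinear taps, dropping taps outside the frame
  for (corner in list(c(0, 0), c(1, 0), c(0, 1), c(1, 1))) {
    xi <- x0 + corner[1]; yi <- y0 + corner[2]
    wt <- (if (corner[1] == 0) 1 - fx else fx) *
          (if (corner[2] == 0) 1 - fy else fy)
    ok <- xi >= 1 & xi <= w & yi >= 1 & yi <= h & wt > 0
    if (any(ok))
      out[ok] <- out[ok] + wt[ok] * img[cbind(yi[ok], xi[ok])]
  }
  out
}
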