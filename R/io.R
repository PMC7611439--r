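#' Write a stimulus set to disk as 8-bit grayscale PNGs
#'
#' Intensities are quantized to 8 bits before writing (max round-trip
#' error 1/255); metadata is persisted in a sidecar \code{manifest.csv}
#' (image_id, file, and every metadata column).
#'
#' @param set a \code{stimulus_set}.
#' @param directory output directory (created if needed).
#' @return invisibly, the manifest data.frame.
#' @export
write_images <- function(set, directory) {
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  files <- paste0(set$meta$image_id, ".png")
  for (k in seq_along(set$images)) {
    q <- round(pmin(pmax(set$images[[k]], 0), 1) * 255) / 255
    png::writePNG(q, file.path(directory, files[k]))
  }
  manifest <- cbind(data.frame(file = files, stringsAsFactors = FALSE),
                    set$meta)
  write.csv(manifest, file.path(directory, "manifest.csv"),
            row.names = FALSE)
  invisible(manifest)
}

#' Read a stimulus set written by \code{\link{write_images}}
#'
#' @param directory directory holding PNGs and \code{manifest.csv}.
#' @return a \code{stimulus_set}; round-trips written sets pixel-exactly.
#' @export
read_images <- function(directory) {
  mf <- file.path(directory, "manifest.csv")
  if (!file.exists(mf)) stop("I/O error: missing manifest ", mf)
  manifest <- read.csv(mf, stringsAsFactors = FALSE)
  images <- lapply(manifest$file, function(f) {
    path <- file.path(directory, f)
    if (!file.exists(path)) stop("I/O error: missing image file ", path)
    img <- tryCatch(png::readPNG(path),
                    error = function(e)
                      stop("I/O error: cannot read PNG ", path, ": ",
                           conditionMessage(e), call. = FALSE))
    if (length(dim(img)) == 3) {
      if (dim(img)[3] >= 3 &&
          !(all(img[, , 1] == img[, , 2]) && all(img[, , 1] == img[, , 3])))
        stop("I/O error: non-grayscale image ", path)
      img <- img[, , 1]
    }
    img
  })
  meta <- manifest[, setdiff(names(manifest), "file"), drop = FALSE]
  structure(list(images = images, meta = meta), class = "stimulus_set")
}

#' Read a feature table from CSV
#'
#' Expected layout: an image_id column followed by numeric feature
#' columns.
#'
#' @param path CSV path.
#' @return a \code{\link{feature_table}}.
#' @export
read_feature_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (!"image_id" %in% names(df)) stop("feature CSV needs image_id column")
  feature_table(as.matrix(df[, setdiff(names(df), "image_id"),
                             drop = FALSE]), df$image_id)
}

#' Read a pair table from CSV
#'
#' @param path CSV path with at least image_a, image_b, dissimilarity.
#' @return a \code{\link{pair_table}}.
#' @export
read_pair_csv <- function(path) {
  pair_table(read.csv(path, stringsAsFactors = FALSE))
}

# fixed-precision CSV writer (9 significant digits) so that reruns with
# identical seeds produce byte-identical files
write_csv_fixed <- function(df, path) {
  for (j in seq_along(df))
    if (is.double(df[[j]]))
      df[[j]] <- formatC(df[[j]], digits = 9, format = "g")
  write.csv(df, path, row.names = FALSE, quote = FALSE)
}
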