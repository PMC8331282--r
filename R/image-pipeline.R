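#' Image volume container
#'
#' Light wrapper around a 2-D matrix or 3-D array of intensities, carrying
#' optional voxel spacing and a provenance string (source path, or
#' \code{"synthetic"} for generated phantoms).
#'
#' @param intensities 2-D or 3-D numeric array.
#' @param spacing optional numeric vector of per-axis physical sizes.
#' @param provenance character; where the data came from.
#' @return object of class \code{image_volume}.
#' @export
image_volume <- function(intensities, spacing = NULL, provenance = "synthetic") {
  intensities <- unclass(intensities)
  attributes(intensities) <- list(dim = dim(intensities))
  if (!is.numeric(intensities) || is.null(dim(intensities)) ||
      !(length(dim(intensities)) %in% c(2L, 3L))) {
    stop("intensities must be a 2-D matrix or 3-D array", call. = FALSE)
  }
  if (!all(is.finite(intensities))) {
    stop("intensities contain non-finite values", call. = FALSE)
  }
  structure(list(intensities = intensities, spacing = spacing,
                 provenance = provenance),
            class = "image_volume")
}

#' @export
print.image_volume <- function(x, ...) {
  cat("image_volume:", paste(dim(x$intensities), collapse = " x "),
      "| range", paste(signif(range(x$intensities), 4), collapse = "-"),
      "|", x$provenance, "\n")
  invisible(x)
}

#' Load a grayscale image or volume
#'
#' Reads PNG or TIFF for 2-D images and NIfTI (\code{.nii}/\code{.nii.gz})
#' for 3-D volumes.  RGB(A) images are converted to grayscale by averaging the
#' color channels; 8- and 16-bit integer data arrive scaled to [0, 1] (the
#' readers' native convention).
#'
#' @param path file path.
#' @return an \code{\link{image_volume}}.
#' @export
load_image <- function(path) {
  if (!file.exists(path)) stop("cannot read image: ", path, call. = FALSE)
  lower <- tolower(path)
  if (grepl("\\.png$", lower)) {
    img <- png::readPNG(path)
  } else if (grepl("\\.tiff?$", lower)) {
    img <- tiff::readTIFF(path)
  } else if (grepl("\\.nii(\\.gz)?$", lower)) {
    vol <- RNifti::readNifti(path)
    arr <- as.array(vol)
    pd <- tryCatch(RNifti::pixdim(vol), error = function(e) NULL)
    return(image_volume(arr, spacing = pd, provenance = path))
  } else {
    stop("unsupported image format: ", path, call. = FALSE)
  }
  if (length(dim(img)) == 3L) {
    nch <- dim(img)[3]
    if (nch == 2L || nch == 4L) img <- img[, , -nch, drop = FALSE] # drop alpha
    img <- apply(img, c(1, 2), mean)
  }
  image_volume(as.matrix(img), provenance = path)
}

#' Min-max intensity normalization
#'
#' Rescales intensities affinely to [0, 1].  A constant image cannot be
#' rescaled; it is returned as all zeros with a warning.
#'
#' @param image an \code{\link{image_volume}}.
#' @return normalized \code{\link{image_volume}}.
#' @export
normalize_image <- function(image) {
  v <- image$intensities
  r <- range(v)
  if (r[1] == r[2]) {
    warning("constant image: normalization returns all zeros")
    v[] <- 0
  } else {
    v <- (v - r[1]) / (r[2] - r[1])
  }
  image_volume(v, spacing = image$spacing, provenance = image$provenance)
}

# 3x3 neighborhood mean with edge replication; per-slice for 3-D input.
neighborhood_mean <- function(v) {
  if (length(dim(v)) == 3L) {
    out <- v
    for (s in seq_len(dim(v)[3])) out[, , s] <- neighborhood_mean(v[, , s])
    return(out)
  }
  h <- nrow(v); w <- ncol(v)
  p <- v[c(1, seq_len(h), h), c(1, seq_len(w), w)] # replicate-pad
  acc <- matrix(0, h, w)
  for (di in 0:2) for (dj in 0:2) {
    acc <- acc + p[di + seq_len(h), dj + seq_len(w)]
  }
  acc / 9
}

#' Extract a per-pixel feature matrix
#'
#' Turns the in-mask pixels of an image into a sample matrix for clustering:
#' one row per pixel, in the array's natural (column-major) linear order.
#' Features are the intensity alone (d = 1) or intensity plus the mean of the
#' 3x3 neighborhood with replicated edges (d = 2), which adds some robustness
#' to pixel noise.
#'
#' @param image an \code{\link{image_volume}}.
#' @param mask optional logical array of the image's shape; NULL = all pixels.
#' @param neighborhood_mean add the 3x3 local-mean feature? (default FALSE)
#' @return list with \code{features} (n x d matrix), \code{index} (linear
#'   indices of the in-mask pixels), \code{shape} (image dimensions) and
#'   \code{mask}.
#' @export
extract_features <- function(image, mask = NULL, neighborhood_mean = FALSE) {
  v <- image$intensities
  if (is.null(mask)) {
    mask <- array(TRUE, dim(v))
  } else if (!identical(dim(mask), dim(v))) {
    stop("mask shape does not match image shape", call. = FALSE)
  }
  idx <- which(mask)
  if (length(idx) == 0L) stop("empty mask: no pixels to extract", call. = FALSE)
  feats <- matrix(v[idx], ncol = 1)
  if (isTRUE(neighborhood_mean)) {
    nm <- neighborhood_mean(v)
    feats <- cbind(feats, nm[idx])
  }
  list(features = feats, index = idx, shape = dim(v), mask = mask)
}

#' Scatter cluster labels back into a segmentation map
#'
#' Inverse of \code{\link{extract_features}}: places each pixel's cluster
#' label (1..c) at its original position; out-of-mask pixels get the reserved
#' background label 0.
#'
#' @param labels integer vector of cluster labels, one per feature row.
#' @param index linear indices from \code{\link{extract_features}}.
#' @param shape image dimensions.
#' @return integer array of the given shape with values in 0..c.
#' @export
labels_to_map <- function(labels, index, shape) {
  if (length(labels) != length(index)) {
    stop("labels length (", length(labels), ") does not match index length (",
         length(index), ")", call. = FALSE)
  }
  out <- array(0L, shape)
  out[index] <- as.integer(labels)
  out
}

#' Write a segmentation label map
#'
#' 2-D maps are written as grayscale PNG (label value k stored as intensity
#' k/255, so up to 255 classes round-trip exactly); 3-D maps as integer NIfTI.
#'
#' @param map integer label array (values 0..c).
#' @param path output path (\code{.png} for 2-D, \code{.nii}/\code{.nii.gz}
#'   for 3-D).
#' @return the path, invisibly.
#' @export
save_segmentation <- function(map, path) {
  if (max(map) > 255 || min(map) < 0) {
    stop("label values must lie in 0..255 for serialization", call. = FALSE)
  }
  if (length(dim(map)) == 2L) {
    if (!grepl("\\.png$", tolower(path))) {
      stop("2-D segmentation maps are written as PNG; got ", path, call. = FALSE)
    }
    png::writePNG(map / 255, path)
  } else if (length(dim(map)) == 3L) {
    if (!grepl("\\.nii(\\.gz)?$", tolower(path))) {
      stop("3-D segmentation maps are written as NIfTI; got ", path, call. = FALSE)
    }
    RNifti::writeNifti(array(as.integer(map), dim(map)), path,
                       datatype = "int16")
  } else {
    stop("map must be 2-D or 3-D", call. = FALSE)
  }
  invisible(path)
}

#' Read back a segmentation label map
#'
#' @param path path written by \code{\link{save_segmentation}}.
#' @return integer label array.
#' @export
load_segmentation <- function(path) {
  lower <- tolower(path)
  if (grepl("\\.png$", lower)) {
    v <- png::readPNG(path)
    if (length(dim(v)) == 3L) v <- v[, , 1]
    arr <- round(v * 255)
    storage.mode(arr) <- "integer"
    arr
  } else if (grepl("\\.nii(\\.gz)?$", lower)) {
    arr <- as.array(RNifti::readNifti(path))
    storage.mode(arr) <- "integer"
    arr
  } else {
    stop("unsupported segmentation format: ", path, call. = FALSE)
  }
}

#' Segment an image by fuzzy clustering
#'
#' Convenience pipeline: normalize, mask the background by an intensity
#' threshold, extract features, fit the clustering, and scatter the hard
#' labels back into a segmentation map.
#'
#' @param image an \code{\link{image_volume}} (or a path, which is loaded).
#' @param n_clusters number of tissue classes.
#' @param mask optional logical array; if NULL, pixels with normalized
#'   intensity > \code{background_threshold} are used.
#' @param background_threshold intensity threshold defining the foreground
#'   when no mask is given (default 0.01).
#' @param neighborhood_mean add the 3x3 local-mean feature?
#' @param supervision optional \code{\link{supervision_info}} over the
#'   in-mask pixels (column-major order).
#' @param ... further arguments to \code{\link{ssfcm}} (mode, alpha, epsilon,
#'   max_iter, seed).
#' @return list with \code{map} (the label array), \code{fit} (the
#'   \code{ssfcm_fit}) and \code{extraction} (features/index/mask).
#' @export
segment_image <- function(image, n_clusters, mask = NULL,
                          background_threshold = 0.01,
                          neighborhood_mean = FALSE, supervision = NULL, ...) {
  if (is.character(image)) image <- load_image(image)
  img <- normalize_image(image)
  if (is.null(mask)) {
    mask <- img$intensities > background_threshold
  }
  ex <- extract_features(img, mask = mask, neighborhood_mean = neighborhood_mean)
  fit <- ssfcm(ex$features, n_clusters, supervision = supervision, ...)
  map <- labels_to_map(hard_labels(fit$memberships), ex$index, ex$shape)
  list(map = map, fit = fit, extraction = ex)
}
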