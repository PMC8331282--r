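#' Synthetic phantom specification
#'
#' Describes a 2-D brain-like phantom: nested elliptical tissue regions with
#' distinct mean intensities, additive Gaussian pixel noise, and an optional
#' smooth multiplicative bias field emulating coil inhomogeneity.
#'
#' @param shape integer vector (rows, cols); default 128 x 128.
#' @param n_classes number of tissue classes (default 3).
#' @param class_intensities strictly increasing values in (0, 1), one per
#'   class (default 0.3, 0.55, 0.8).
#' @param noise_sigma SD of the additive Gaussian noise (default 0.05).
#' @param bias_amplitude amplitude of the multiplicative low-frequency bias
#'   field \eqn{1 + a \cdot g(x, y)} (default 0 = off).
#' @param seed integer seed; the phantom is fully determined by its spec.
#' @return object of class \code{phantom_spec}.
#' @export
phantom_spec <- function(shape = c(128L, 128L), n_classes = 3L,
                         class_intensities = c(0.3, 0.55, 0.8),
                         noise_sigma = 0.05, bias_amplitude = 0,
                         seed = 1L) {
  shape <- as.integer(shape)
  if (length(shape) != 2L || any(shape < 16L)) {
    stop("shape must be two dimensions of at least 16 pixels", call. = FALSE)
  }
  if (length(class_intensities) != n_classes) {
    stop("need one class intensity per class", call. = FALSE)
  }
  if (any(diff(class_intensities) <= 0)) {
    stop("class intensities must be strictly increasing", call. = FALSE)
  }
  if (any(class_intensities <= 0) || any(class_intensities >= 1)) {
    stop("class intensities must lie in (0, 1)", call. = FALSE)
  }
  if (noise_sigma < 0) stop("noise_sigma must be nonnegative", call. = FALSE)
  structure(list(shape = shape, n_classes = as.integer(n_classes),
                 class_intensities = class_intensities,
                 noise_sigma = noise_sigma, bias_amplitude = bias_amplitude,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

# Ground-truth geometry: concentric ellipses with shrinking semi-axes; the
# innermost region (highest class) is a slightly off-center blob, echoing the
# concentric cortex / white-matter / deep-gray arrangement of an axial brain
# slice.  Deterministic: depends only on shape and n_classes.
phantom_truth <- function(shape, n_classes) {
  h <- shape[1]; w <- shape[2]
  row <- matrix(seq_len(h), h, w)
  col <- matrix(seq_len(w), h, w, byrow = TRUE)
  u <- (col - (w + 1) / 2) / (w / 2)
  v <- (row - (h + 1) / 2) / (h / 2)
  truth <- array(0L, dim = shape)
  rx <- seq(0.88, 0.26, length.out = n_classes)
  ry <- rx * 0.80
  for (j in seq_len(n_classes)) {
    du <- u; dv <- v
    if (j == n_classes && n_classes > 1) { # offset central blob
      du <- u - 0.10
      dv <- v + 0.06
    }
    inside <- (du / rx[j])^2 + (dv / ry[j])^2 <= 1
    truth[inside] <- j
  }
  truth
}

#' Generate a ground-truthed synthetic phantom
#'
#' Builds the tissue-label geometry, paints each class at its nominal
#' intensity, adds seeded Gaussian noise and the optional bias field to the
#' in-brain pixels, and clips to [0, 1].  Background pixels stay at exactly 0.
#'
#' @param spec a \code{\link{phantom_spec}}.
#' @return object of class \code{phantom}: list with \code{image} (an
#'   \code{\link{image_volume}}), \code{truth} (integer label array, 0 =
#'   background) and \code{spec}.
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  truth <- phantom_truth(spec$shape, spec$n_classes)
  brain <- truth > 0L
  n_brain <- sum(brain)
  counts <- tabulate(truth[brain], nbins = spec$n_classes)
  if (any(counts < 0.01 * n_brain)) {
    stop("phantom geometry leaves class ",
         paste(which(counts < 0.01 * n_brain), collapse = ", "),
         " below 1% of in-brain pixels", call. = FALSE)
  }
  img <- array(0, dim = spec$shape)
  img[brain] <- spec$class_intensities[truth[brain]]
  with_seed(spec$seed, {
    if (spec$noise_sigma > 0) {
      img[brain] <- img[brain] + stats::rnorm(n_brain, 0, spec$noise_sigma)
    }
  })
  if (spec$bias_amplitude != 0) {
    h <- spec$shape[1]; w <- spec$shape[2]
    g <- outer(sin(pi * seq_len(h) / h), cos(pi * seq_len(w) / w))
    img[brain] <- img[brain] * (1 + spec$bias_amplitude * g[brain])
  }
  img <- pmin(pmax(img, 0), 1)
  dim(img) <- spec$shape
  structure(list(image = image_volume(img, provenance = "synthetic"),
                 truth = truth, spec = spec),
            class = "phantom")
}

#' @export
print.phantom <- function(x, ...) {
  cat("synthetic phantom:", paste(x$spec$shape, collapse = " x "),
      "|", x$spec$n_classes, "classes | noise sigma", x$spec$noise_sigma,
      "| seed", x$spec$seed, "\n")
  invisible(x)
}

#' Sample partial supervision from a ground-truth map
#'
#' Selects \code{ceiling(fraction * n)} in-brain pixels, stratified per class
#' with proportional (largest-remainder) allocation and at least one pixel
#' per class, and gives each a crisp prior at its true class.  The resulting
#' \code{\link{supervision_info}} is ordered like the rows produced by
#' \code{\link{extract_features}} with \code{mask = truth > 0}.
#'
#' @param truth integer label array (0 = background).
#' @param fraction fraction of in-brain pixels to label, in (0, 1].
#' @param seed integer seed for the pixel draw.
#' @return a \code{\link{supervision_info}} over the in-brain pixels, with
#'   attribute \code{"pixel_index"} giving the labeled pixels' linear indices
#'   in the image array.
#' @export
sample_supervision <- function(truth, fraction, seed = 1L) {
  if (!is.numeric(fraction) || fraction <= 0 || fraction > 1) {
    stop("fraction must lie in (0, 1]", call. = FALSE)
  }
  idx <- which(truth > 0L)
  n <- length(idx)
  cls <- truth[idx]
  n_classes <- max(cls)
  counts <- tabulate(cls, nbins = n_classes)
  if (any(counts == 0L)) {
    stop("every class must occupy at least one pixel", call. = FALSE)
  }
  m <- ceiling(fraction * n)
  m <- max(m, n_classes)
  # proportional allocation, largest remainder, floor of 1 per class
  quota_real <- m * counts / n
  quota <- pmax(floor(quota_real), 1)
  rem <- m - sum(quota)
  if (rem > 0) {
    ord <- order(quota_real - floor(quota_real), decreasing = TRUE)
    for (j in ord) {
      if (rem == 0) break
      if (quota[j] < counts[j]) { quota[j] <- quota[j] + 1; rem <- rem - 1 }
    }
  } else if (rem < 0) {
    ord <- order(quota_real - floor(quota_real))
    for (j in ord) {
      if (rem == 0) break
      if (quota[j] > 1) { quota[j] <- quota[j] - 1; rem <- rem + 1 }
    }
  }
  labels <- rep(NA_integer_, n)
  with_seed(seed, {
    for (j in seq_len(n_classes)) {
      pool <- which(cls == j)
      take <- pool[sample.int(length(pool), min(quota[j], length(pool)))]
      labels[take] <- j
    }
  })
  sup <- supervision_info(labels, n_classes)
  attr(sup, "pixel_index") <- idx[!is.na(labels)]
  sup
}
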