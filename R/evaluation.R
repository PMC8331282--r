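# All permutations of 1..k (k <= 8 in practice: 8! = 40320 rows).
all_permutations <- function(k) {
  if (k == 1L) return(matrix(1L, 1, 1))
  sub <- all_permutations(k - 1L)
  out <- matrix(0L, k * nrow(sub), k)
  r <- 0L
  for (pos in seq_len(k)) {
    blk <- cbind(sub[, seq_len(pos - 1), drop = FALSE], k,
                 sub[, seq.int(pos, k - 1)[seq_len(k - pos)], drop = FALSE])
    out[r + seq_len(nrow(sub)), ] <- blk
    r <- r + nrow(sub)
  }
  out
}

# Minimum-cost assignment (Hungarian algorithm, potentials formulation,
# O(k^3)); returns for each row the assigned column.  Used when the class
# count makes exhaustive permutation search impractical.
hungarian_assignment <- function(cost) {
  k <- nrow(cost)
  stopifnot(ncol(cost) == k)
  INF <- sum(abs(cost)) + 1
  u <- numeric(k + 1)
  v <- numeric(k + 1)
  p <- integer(k + 1)      # p[j+1] = row assigned to column j
  way <- integer(k + 1)
  for (i in seq_len(k)) {
    p[1] <- i
    j0 <- 0L
    minv <- rep(INF, k + 1)
    used <- rep(FALSE, k + 1)
    repeat {
      used[j0 + 1] <- TRUE
      i0 <- p[j0 + 1]
      delta <- INF
      j1 <- 0L
      for (j in seq_len(k)) {
        if (!used[j + 1]) {
          cur <- cost[i0, j] - u[i0 + 1] - v[j + 1]
          if (cur < minv[j + 1]) {
            minv[j + 1] <- cur
            way[j + 1] <- j0
          }
          if (minv[j + 1] < delta) {
            delta <- minv[j + 1]
            j1 <- j
          }
        }
      }
      for (j in 0:k) {
        if (used[j + 1]) {
          u[p[j + 1] + 1] <- u[p[j + 1] + 1] + delta
          v[j + 1] <- v[j + 1] - delta
        } else {
          minv[j + 1] <- minv[j + 1] - delta
        }
      }
      j0 <- j1
      if (p[j0 + 1] == 0L) break
    }
    repeat {
      j1 <- way[j0 + 1]
      p[j0 + 1] <- p[j1 + 1]
      j0 <- j1
      if (j0 == 0L) break
    }
  }
  assign <- integer(k)
  for (j in seq_len(k)) if (p[j + 1] > 0L) assign[p[j + 1]] <- j
  assign
}

# Confusion matrix over in-truth-mask pixels, padded square to k classes.
confusion_counts <- function(predicted, truth, k) {
  mask <- truth > 0L
  p <- predicted[mask]
  t <- truth[mask]
  conf <- matrix(0, k, k)
  keep <- p > 0L & p <= k
  tab <- table(factor(p[keep], levels = seq_len(k)),
               factor(t[keep], levels = seq_len(k)))
  conf + as.matrix(tab)
}

#' Optimal cluster-to-class label matching
#'
#' Cluster indices produced by an unsupervised fit are arbitrary; this finds
#' the cluster -> class assignment that maximizes total pixel agreement with
#' the ground truth (background excluded).  Exhaustive over all permutations
#' for up to 8 classes, Hungarian assignment beyond that.  A class-count
#' mismatch is handled by padding the confusion matrix with empty classes.
#'
#' @param predicted,truth integer label arrays of identical shape
#'   (0 = background).
#' @return integer vector \code{perm} with \code{perm[i]} = the truth class
#'   assigned to predicted cluster i.
#' @export
match_labels <- function(predicted, truth) {
  if (!identical(dim(predicted), dim(truth))) {
    stop("segmentation maps differ in shape", call. = FALSE)
  }
  k <- max(max(predicted), max(truth), 1L)
  conf <- confusion_counts(predicted, truth, k)
  if (k <= 8L) {
    perms <- all_permutations(k)
    scores <- apply(perms, 1, function(p) sum(conf[cbind(seq_len(k), p)]))
    as.integer(perms[which.max(scores), ])
  } else {
    hungarian_assignment(-conf)
  }
}

#' Permutation-matched segmentation accuracy
#'
#' Percent of in-brain pixels (truth > 0) whose predicted cluster, after
#' optimal cluster-to-class matching, equals the ground-truth class.
#'
#' @param predicted,truth integer label arrays of identical shape.
#' @param matching optional precomputed matching from
#'   \code{\link{match_labels}}.
#' @return accuracy in percent (0..100).
#' @export
segmentation_accuracy <- function(predicted, truth, matching = NULL) {
  if (!identical(dim(predicted), dim(truth))) {
    stop("segmentation maps differ in shape", call. = FALSE)
  }
  mask <- truth > 0L
  if (!any(mask)) stop("empty in-brain region in truth", call. = FALSE)
  if (is.null(matching)) matching <- match_labels(predicted, truth)
  p <- predicted[mask]
  mapped <- ifelse(p > 0L, matching[pmax(p, 1L)], 0L)
  100 * mean(mapped == truth[mask])
}

#' Dice overlap coefficient for one class
#'
#' \eqn{2 |P \cap T| / (|P| + |T|)} between the predicted region of a class
#' (after cluster-to-class matching) and its ground-truth region.
#'
#' @param predicted,truth integer label arrays of identical shape.
#' @param class_id the truth class to score.
#' @param matching optional precomputed matching.
#' @return value in [0, 1]; NA (with a warning) if the class is absent from
#'   the truth.
#' @export
dice_coefficient <- function(predicted, truth, class_id, matching = NULL) {
  if (!identical(dim(predicted), dim(truth))) {
    stop("segmentation maps differ in shape", call. = FALSE)
  }
  Tset <- truth == class_id
  if (!any(Tset)) {
    warning("class ", class_id, " absent from truth; Dice undefined")
    return(NA_real_)
  }
  if (is.null(matching)) matching <- match_labels(predicted, truth)
  cluster <- which(matching == class_id)
  Pset <- if (length(cluster)) predicted == cluster else array(FALSE, dim(truth))
  2 * sum(Pset & Tset) / (sum(Pset) + sum(Tset))
}

#' Benchmark algorithm variants on replicated phantoms
#'
#' For each replicate, generates a phantom, samples one shared supervision
#' set, runs every configuration on identical inputs, and scores the
#' resulting segmentations.  Mirrors a mode-by-mode comparison table of
#' accuracy and iteration counts (runtime deliberately omitted: it is
#' hardware-dependent).
#'
#' @param spec a \code{\link{phantom_spec}}; its seed field is replaced by
#'   per-replicate seeds derived from \code{seed}.
#' @param configs list of \code{\link{fit_config}} objects.
#' @param supervision_fraction fraction of in-brain pixels labeled for the
#'   semisupervised modes (default 0.05).
#' @param replicates number of phantom replicates (default 10).
#' @param seed base seed.
#' @return data.frame with columns mode, accuracy_mean, accuracy_sd,
#'   dice_mean, iterations_mean, replicates, seed; one row per config.
#' @export
run_comparison <- function(spec, configs, supervision_fraction = 0.05,
                           replicates = 10L, seed = 1L) {
  stopifnot(inherits(spec, "phantom_spec"))
  if (length(configs) < 1L) stop("need at least one config", call. = FALSE)
  if (replicates < 1L) stop("replicates must be positive", call. = FALSE)
  if (inherits(configs, "fit_config")) configs <- list(configs)
  nm <- vapply(configs, function(cf) cf$mode, character(1))
  acc <- matrix(NA_real_, replicates, length(configs))
  dice <- matrix(NA_real_, replicates, length(configs))
  iters <- matrix(NA_real_, replicates, length(configs))
  for (r in seq_len(replicates)) {
    rseed <- (seed + 7919L * r) %% .Machine$integer.max
    sp <- spec
    sp$seed <- rseed
    ph <- generate_phantom(sp)
    mask <- ph$truth > 0L
    ex <- extract_features(ph$image, mask = mask)
    sup <- sample_supervision(ph$truth, supervision_fraction, seed = rseed)
    for (j in seq_along(configs)) {
      cf <- configs[[j]]
      fit <- ssfcm(ex$features, sp$n_classes, mode = cf$mode,
                   supervision = if (cf$mode == "fcm") NULL else sup,
                   alpha = cf$alpha, epsilon = cf$epsilon,
                   max_iter = cf$max_iter, seed = rseed)
      map <- labels_to_map(hard_labels(fit$memberships), ex$index, ex$shape)
      m <- match_labels(map, ph$truth)
      acc[r, j] <- segmentation_accuracy(map, ph$truth, matching = m)
      dice[r, j] <- mean(vapply(seq_len(sp$n_classes), function(k) {
        dice_coefficient(map, ph$truth, k, matching = m)
      }, numeric(1)), na.rm = TRUE)
      iters[r, j] <- fit$iterations
    }
  }
  data.frame(mode = nm,
             accuracy_mean = colMeans(acc),
             accuracy_sd = apply(acc, 2, stats::sd),
             dice_mean = colMeans(dice),
             iterations_mean = colMeans(iters),
             replicates = replicates,
             seed = seed,
             stringsAsFactors = FALSE)
}
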