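#' Squared Euclidean distances between cluster centers and samples
#'
#' Computes the c x n matrix of squared Euclidean distances D_ik^2 between
#' each cluster center B_i and each sample x_k.
#'
#' @param data numeric n x d matrix of samples (rows = samples).
#' @param centers numeric c x d matrix of cluster centers (rows = centers).
#' @return c x n matrix with entry (i, k) = sum over dimensions of
#'   (B_i - x_k)^2; all entries are nonnegative.
#' @export
squared_distances <- function(data, centers) {
  data <- as.matrix(data)
  centers <- as.matrix(centers)
  if (ncol(data) != ncol(centers)) {
    stop("dimensionality mismatch: data has ", ncol(data),
         " feature(s) but centers have ", ncol(centers), call. = FALSE)
  }
  if (!all(is.finite(data)) || !all(is.finite(centers))) {
    stop("non-finite values in data or centers", call. = FALSE)
  }
  cc <- nrow(centers)
  d2 <- matrix(0, cc, nrow(data))
  tx <- t(data)
  for (i in seq_len(cc)) {
    d2[i, ] <- colSums((tx - centers[i, ])^2)
  }
  d2
}

# Classic fuzzifier-2 FCM membership term A_ik = 1 / sum_j (D_ik^2 / D_jk^2),
# with the zero-distance convention: a sample at zero distance from one or
# more centers splits its membership uniformly over those centers.
fcm_term <- function(dist_sq) {
  cc <- nrow(dist_sq)
  n <- ncol(dist_sq)
  U <- matrix(0, cc, n)
  zero <- dist_sq <= 0
  any_zero <- colSums(zero) > 0L
  if (any(!any_zero)) {
    inv <- 1 / dist_sq[, !any_zero, drop = FALSE]
    U[, !any_zero] <- sweep(inv, 2, colSums(inv), "/")
  }
  if (any(any_zero)) {
    z <- zero[, any_zero, drop = FALSE] + 0
    U[, any_zero] <- sweep(z, 2, colSums(z), "/")
  }
  U
}

#' Fuzzy membership update (plain and semisupervised)
#'
#' Computes the c x n membership matrix from squared distances, optionally
#' blending in prior memberships for labeled samples.  Three update rules are
#' available:
#' \describe{
#'   \item{\code{fcm}}{the classic fuzzifier-2 update
#'     \eqn{A_{ik} = 1 / \sum_j (D_{ik}^2 / D_{jk}^2)}; supervision ignored.}
#'   \item{\code{ssfcm}}{a simplified semisupervised update
#'     \eqn{A'_{ik} = \frac{1}{1+\alpha}\left[A_{ik} + \alpha f_{ik} b_k\right]}
#'     followed by column renormalization.  This rule omits the correction
#'     factor of the standard closed form, so renormalization is required to
#'     restore column sums of 1.  Default.}
#'   \item{\code{pedrycz}}{the standard semisupervised closed form of
#'     Pedrycz & Waletzky,
#'     \eqn{A'_{ik} = \frac{1}{1+\alpha}\left[(1 + \alpha(1 - b_k \sum_j f_{jk}))
#'     A_{ik} + \alpha f_{ik} b_k\right]}, whose columns sum to 1 by
#'     construction.}
#' }
#' With \code{alpha = 0}, or with no labeled samples, all three rules coincide.
#'
#' @param dist_sq c x n matrix of squared distances (from
#'   \code{\link{squared_distances}}).
#' @param supervision a \code{\link{supervision_info}} object, or NULL for
#'   fully unsupervised data.
#' @param alpha nonnegative supervision weight.
#' @param mode one of \code{"ssfcm"}, \code{"fcm"}, \code{"pedrycz"}.
#' @return c x n membership matrix; every entry in [0, 1], every column sums
#'   to 1.
#' @export
update_membership <- function(dist_sq, supervision = NULL, alpha = 1,
                              mode = c("ssfcm", "fcm", "pedrycz")) {
  mode <- match.arg(mode)
  if (any(dist_sq < 0)) stop("negative squared distances", call. = FALSE)
  if (alpha < 0) stop("alpha must be nonnegative", call. = FALSE)
  U <- fcm_term(dist_sq)
  if (mode == "fcm" || is.null(supervision)) {
    return(U)
  }
  check_supervision(supervision, nrow(dist_sq), ncol(dist_sq))
  b <- supervision$labeled
  f <- supervision$priors
  # with alpha = 0 or no labeled samples both rules collapse exactly onto the
  # FCM term; return it unchanged so the reduction is bit-exact
  if (alpha == 0 || !any(b > 0)) {
    return(U)
  }
  fb <- sweep(f, 2, b, "*")
  if (mode == "ssfcm") {
    U <- (U + alpha * fb) / (1 + alpha)
    U <- sweep(U, 2, colSums(U), "/")
  } else { # pedrycz
    corr <- 1 + alpha * (1 - b * colSums(f))
    U <- (sweep(U, 2, corr, "*") + alpha * fb) / (1 + alpha)
  }
  U
}

#' Cluster center update
#'
#' Recomputes each center as the membership-squared weighted mean of the
#' samples, \eqn{B_i = \sum_k A_{ik}^2 x_k / \sum_k A_{ik}^2} (fuzzifier 2).
#'
#' @param memberships c x n membership matrix.
#' @param data n x d sample matrix.
#' @return c x d matrix of centers; each coordinate lies within the data's
#'   bounding box (the update is a convex combination of the samples).
#' @export
update_centers <- function(memberships, data) {
  data <- as.matrix(data)
  if (ncol(memberships) != nrow(data)) {
    stop("memberships have ", ncol(memberships), " columns but data has ",
         nrow(data), " rows", call. = FALSE)
  }
  W <- memberships^2
  mass <- rowSums(W)
  bad <- which(mass <= 0)
  if (length(bad)) {
    stop("degenerate cluster: zero membership mass for cluster ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  (W %*% data) / mass
}

# Prototype update of the standard Pedrycz semisupervised algorithm:
# B_i = sum_k [A_ik^2 + alpha (A_ik - f_ik b_k)^2] x_k /
#       sum_k [A_ik^2 + alpha (A_ik - f_ik b_k)^2].
# This is the exact minimizer of the Pedrycz objective in the centers, so the
# alternation with the pedrycz membership update is a true coordinate descent
# and the objective is non-increasing.  With alpha = 0 or no labeled samples
# the weights collapse to (a multiple of) A^2 and the update coincides with
# update_centers().
update_centers_supervised <- function(memberships, data, supervision, alpha) {
  fb <- sweep(supervision$priors, 2, supervision$labeled, "*")
  W <- memberships^2 + alpha * (memberships - fb)^2
  mass <- rowSums(W)
  bad <- which(mass <= 0)
  if (length(bad)) {
    stop("degenerate cluster: zero membership mass for cluster ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  (W %*% data) / mass
}

#' Convergence check on successive membership matrices
#'
#' The iteration stops when the Chebyshev norm (maximum absolute elementwise
#' difference) between successive membership matrices falls below epsilon.
#'
#' @param current,previous membership matrices of identical shape.
#' @param epsilon positive tolerance.
#' @return list with \code{converged} (logical) and \code{delta} (the norm).
#' @export
check_convergence <- function(current, previous, epsilon) {
  if (!identical(dim(current), dim(previous))) {
    stop("membership matrices differ in shape", call. = FALSE)
  }
  delta <- max(abs(current - previous))
  list(converged = delta < epsilon, delta = delta)
}

#' Hard cluster labels from a membership matrix
#'
#' @param memberships c x n membership matrix.
#' @return integer vector of length n; entry k is the index (1..c) of the
#'   cluster with maximal membership, ties broken toward the lowest index.
#' @export
hard_labels <- function(memberships) {
  max.col(t(memberships), ties.method = "first")
}

#' Partial supervision for semisupervised clustering
#'
#' Builds the labeled-indicator vector b and prior-membership matrix f used by
#' the semisupervised update rules.  Labeled samples carry a crisp prior (1 at
#' their class); unlabeled samples have an all-zero prior column.
#'
#' @param labels integer vector of length n: class index in 1..n_clusters for
#'   labeled samples, NA for unlabeled ones.
#' @param n_clusters number of clusters c.
#' @return object of class \code{supervision_info}: list with \code{labeled}
#'   (length-n 0/1 vector) and \code{priors} (c x n matrix).
#' @export
supervision_info <- function(labels, n_clusters) {
  n <- length(labels)
  lab <- !is.na(labels)
  if (any(lab) && (any(labels[lab] < 1) || any(labels[lab] > n_clusters))) {
    stop("labels must lie in 1..", n_clusters, call. = FALSE)
  }
  priors <- matrix(0, n_clusters, n)
  if (any(lab)) priors[cbind(labels[lab], which(lab))] <- 1
  structure(list(labeled = as.numeric(lab), priors = priors),
            class = "supervision_info")
}

# Validates shapes and the prior-column invariants.
check_supervision <- function(supervision, n_clusters, n) {
  if (!inherits(supervision, "supervision_info")) {
    stop("supervision must be a supervision_info object", call. = FALSE)
  }
  if (length(supervision$labeled) != n ||
      !identical(dim(supervision$priors), as.integer(c(n_clusters, n)))) {
    stop("supervision shape does not match data (n = ", n,
         ", c = ", n_clusters, ")", call. = FALSE)
  }
  cs <- colSums(supervision$priors)
  lab <- supervision$labeled > 0
  if (any(abs(cs[lab] - 1) > 1e-9)) {
    stop("prior columns of labeled samples must sum to 1", call. = FALSE)
  }
  if (any(cs[!lab] != 0)) {
    stop("prior columns of unlabeled samples must be zero", call. = FALSE)
  }
  invisible(TRUE)
}

#' Fit configuration helper
#'
#' Bundles the tunable clustering parameters so that several algorithm
#' variants can be benchmarked side by side (see \code{\link{run_comparison}}).
#'
#' @param mode update rule, see \code{\link{update_membership}}.
#' @param alpha supervision weight (default 1).
#' @param epsilon convergence tolerance on the membership Chebyshev norm
#'   (default 1e-5).
#' @param max_iter iteration cap (default 100).
#' @return list of class \code{fit_config}.
#' @export
fit_config <- function(mode = c("ssfcm", "fcm", "pedrycz"), alpha = 1,
                       epsilon = 1e-5, max_iter = 100L) {
  mode <- match.arg(mode)
  stopifnot(alpha >= 0, epsilon > 0, max_iter >= 1)
  structure(list(mode = mode, alpha = alpha, epsilon = epsilon,
                 max_iter = as.integer(max_iter)),
            class = "fit_config")
}

# Runs expr under a temporary RNG stream seeded with `seed`, restoring the
# caller's RNG state afterwards so fits do not perturb the session.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (had) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    })
    set.seed(seed)
  }
  expr
}

#' Semisupervised fuzzy c-means clustering
#'
#' Iterative fuzzy clustering with fuzzifier 2: memberships and centers are
#' updated in alternation until the Chebyshev norm of the membership change
#' falls below \code{epsilon} or \code{max_iter} is reached.  Partial labels
#' (\code{\link{supervision_info}}) pull the memberships of labeled samples
#' toward their priors with weight \code{alpha}.  Modes \code{fcm} and
#' \code{ssfcm} use the plain membership-squared center update
#' (\code{\link{update_centers}}); mode \code{pedrycz} pairs its membership
#' rule with the matching supervised prototype update, so that the iteration
#' is an exact coordinate descent on the Pedrycz objective
#' (\code{\link{pedrycz_objective}}), which is then non-increasing.
#'
#' Initialization: unlabeled membership columns are drawn from a flat
#' Dirichlet using the seeded generator; labeled columns start at their prior;
#' the initial centers are then computed from that membership matrix.
#'
#' @param data n x d numeric matrix (or vector, taken as n x 1) of samples.
#' @param n_clusters number of clusters c (requires n >= c).
#' @param mode update rule, see \code{\link{update_membership}}.
#' @param supervision optional \code{\link{supervision_info}}; ignored in
#'   \code{mode = "fcm"}; absent supervision in the semisupervised modes is
#'   treated as all-unlabeled.
#' @param alpha supervision weight (>= 0).
#' @param epsilon convergence tolerance (> 0).
#' @param max_iter iteration cap.
#' @param seed integer seed for the reproducible initialization.
#' @return object of class \code{ssfcm_fit}: list with \code{memberships}
#'   (c x n), \code{centers} (c x d), \code{iterations}, \code{converged},
#'   \code{delta_trace}, and the resolved parameters.
#' @examples
#' x <- matrix(c(rnorm(30, 0, 0.1), rnorm(30, 5, 0.1)), ncol = 1)
#' fit <- ssfcm(x, 2, mode = "fcm", seed = 1)
#' sort(fit$centers[, 1])
#' @export
ssfcm <- function(data, n_clusters, mode = c("ssfcm", "fcm", "pedrycz"),
                  supervision = NULL, alpha = 1, epsilon = 1e-5,
                  max_iter = 100L, seed = NULL) {
  mode <- match.arg(mode)
  data <- as.matrix(data)
  if (!all(is.finite(data))) stop("data contains non-finite values", call. = FALSE)
  n <- nrow(data)
  if (n_clusters < 1) stop("n_clusters must be positive", call. = FALSE)
  if (n < n_clusters) {
    stop("fewer samples (", n, ") than clusters (", n_clusters, ")",
         call. = FALSE)
  }
  if (alpha < 0) stop("alpha must be nonnegative", call. = FALSE)
  if (epsilon <= 0) stop("epsilon must be positive", call. = FALSE)
  if (mode == "fcm") supervision <- NULL
  if (!is.null(supervision)) check_supervision(supervision, n_clusters, n)
  # alpha = 0 switches supervision off entirely (updates and initialization),
  # so the semisupervised modes reduce exactly to plain FCM
  if (alpha == 0) supervision <- NULL

  U <- with_seed(seed, {
    g <- matrix(stats::rgamma(n_clusters * n, shape = 1), n_clusters, n)
    sweep(g, 2, colSums(g), "/")
  })
  centers <- NULL
  if (!is.null(supervision)) {
    lab <- supervision$labeled > 0
    if (any(lab)) {
      U[, lab] <- supervision$priors[, lab]
      # Labeled samples define which cluster is which class.  When every
      # cluster has labeled mass, anchor the initial centers at the labeled
      # class means so the iteration cannot permute cluster identities away
      # from the priors; a random-membership start leaves identity to chance
      # and can make the supervision penalty fight the data.
      lab_mass <- rowSums(U[, lab, drop = FALSE]^2)
      if (all(lab_mass > 0)) {
        W <- U[, lab, drop = FALSE]^2
        centers <- (W %*% data[lab, , drop = FALSE]) / rowSums(W)
      }
    }
  }
  if (is.null(centers)) centers <- update_centers(U, data)

  delta_trace <- numeric(0)
  converged <- FALSE
  iterations <- 0L
  pedrycz_centers <- mode == "pedrycz" && !is.null(supervision) && alpha > 0
  for (t in seq_len(max_iter)) {
    d2 <- squared_distances(data, centers)
    U_new <- update_membership(d2, supervision, alpha, mode)
    centers <- if (pedrycz_centers) {
      update_centers_supervised(U_new, data, supervision, alpha)
    } else {
      update_centers(U_new, data)
    }
    if (!all(is.finite(U_new)) || !all(is.finite(centers))) {
      stop("numerical failure: non-finite values during iteration ", t,
           call. = FALSE)
    }
    conv <- check_convergence(U_new, U, epsilon)
    delta_trace <- c(delta_trace, conv$delta)
    U <- U_new
    iterations <- t
    if (conv$converged) {
      converged <- TRUE
      break
    }
  }

  structure(list(memberships = U, centers = centers,
                 iterations = iterations, converged = converged,
                 delta_trace = delta_trace, mode = mode, alpha = alpha,
                 epsilon = epsilon, n_clusters = as.integer(n_clusters),
                 seed = seed),
            class = "ssfcm_fit")
}

#' @export
print.ssfcm_fit <- function(x, ...) {
  cat("Fuzzy c-means fit (mode =", x$mode, ")\n")
  cat("  clusters:  ", x$n_clusters, "\n")
  cat("  samples:   ", ncol(x$memberships), "\n")
  cat("  iterations:", x$iterations,
      if (x$converged) "(converged)" else "(not converged)", "\n")
  cat("  centers:\n")
  print(round(x$centers, 4))
  invisible(x)
}

# Pedrycz semisupervised objective
# J = sum_ik A_ik^2 D_ik^2 + alpha * sum_ik (A_ik - f_ik b_k)^2 D_ik^2.
# Exposed for monotonicity diagnostics.
#' Semisupervised clustering objective
#'
#' Evaluates the Pedrycz objective for a given membership matrix, center set
#' and supervision; used to monitor the monotone descent of the
#' \code{pedrycz} update rule.
#'
#' @param memberships c x n membership matrix.
#' @param data n x d sample matrix.
#' @param centers c x d center matrix.
#' @param supervision optional \code{\link{supervision_info}}.
#' @param alpha supervision weight.
#' @return scalar objective value.
#' @export
pedrycz_objective <- function(memberships, data, centers,
                              supervision = NULL, alpha = 1) {
  d2 <- squared_distances(as.matrix(data), centers)
  J <- sum(memberships^2 * d2)
  if (!is.null(supervision) && alpha > 0) {
    fb <- sweep(supervision$priors, 2, supervision$labeled, "*")
    J <- J + alpha * sum((memberships - fb)^2 * d2)
  }
  J
}
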