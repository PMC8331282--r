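# Independent scalar-loop oracles for the clustering formulas.  These stay
# deliberately naive (double loops, no vectorization) so they cannot share a
# code path with the implementation they check.

oracle_squared_distances <- function(data, centers) {
  cc <- nrow(centers); n <- nrow(data); d <- ncol(data)
  out <- matrix(0, cc, n)
  for (i in seq_len(cc)) {
    for (k in seq_len(n)) {
      s <- 0
      for (j in seq_len(d)) s <- s + (centers[i, j] - data[k, j])^2
      out[i, k] <- s
    }
  }
  out
}

# scalar evaluation of the three membership rules, including the
# zero-distance convention and (for ssfcm) the column renormalization
oracle_membership <- function(d2, sup, alpha, mode) {
  cc <- nrow(d2); n <- ncol(d2)
  U <- matrix(0, cc, n)
  for (k in seq_len(n)) {
    zeros <- which(d2[, k] == 0)
    fcm <- numeric(cc)
    if (length(zeros)) {
      fcm[zeros] <- 1 / length(zeros)
    } else {
      for (i in seq_len(cc)) {
        s <- 0
        for (j in seq_len(cc)) s <- s + d2[i, k] / d2[j, k]
        fcm[i] <- 1 / s
      }
    }
    if (mode == "fcm" || is.null(sup)) {
      U[, k] <- fcm
      next
    }
    b <- sup$labeled[k]
    f <- sup$priors[, k]
    if (mode == "ssfcm") {
      raw <- (fcm + alpha * f * b) / (1 + alpha)
      U[, k] <- raw / sum(raw)
    } else {
      corr <- 1 + alpha * (1 - b * sum(f))
      U[, k] <- (corr * fcm + alpha * f * b) / (1 + alpha)
    }
  }
  U
}

oracle_centers <- function(U, data) {
  cc <- nrow(U); n <- nrow(data); d <- ncol(data)
  out <- matrix(0, cc, d)
  for (i in seq_len(cc)) {
    den <- 0
    num <- numeric(d)
    for (k in seq_len(n)) {
      w <- U[i, k]^2
      den <- den + w
      num <- num + w * data[k, ]
    }
    out[i, ] <- num / den
  }
  out
}

oracle_max_abs_diff <- function(a, b) {
  m <- 0
  for (i in seq_along(a)) m <- max(m, abs(a[i] - b[i]))
  m
}

# random small clustering instance with optional partial labels
random_instance <- function(n = NULL, cc = NULL, d = NULL, labeled_frac = 0.3) {
  if (is.null(n)) n <- sample(4:10, 1)
  if (is.null(cc)) cc <- sample(2:3, 1)
  if (is.null(d)) d <- sample(1:3, 1)
  data <- matrix(stats::runif(n * d), n, d)
  labels <- rep(NA_integer_, n)
  nl <- max(1L, round(labeled_frac * n))
  labels[sample(n, nl)] <- sample(cc, nl, replace = TRUE)
  list(data = data, n = n, cc = cc, d = d,
       sup = supervision_info(labels, cc))
}

# random valid membership matrix (columns sum to 1)
random_membership <- function(cc, n) {
  g <- matrix(stats::rgamma(cc * n, 1), cc, n)
  sweep(g, 2, colSums(g), "/")
}

# Replays the pedrycz-mode fit loop step by step (same seeded initialization
# as ssfcm()) recording the objective after every iteration, so tests can
# assert monotone descent along the exact trajectory the fit follows.
replay_pedrycz <- function(data, cc, sup, alpha, seed, max_iter = 60L,
                           epsilon = 1e-5) {
  data <- as.matrix(data)
  n <- nrow(data)
  set.seed(seed)
  g <- matrix(stats::rgamma(cc * n, 1), cc, n)
  U <- sweep(g, 2, colSums(g), "/")
  lab <- sup$labeled > 0
  U[, lab] <- sup$priors[, lab]
  W <- U[, lab, drop = FALSE]^2
  centers <- if (all(rowSums(W) > 0)) {
    (W %*% data[lab, , drop = FALSE]) / rowSums(W)
  } else {
    update_centers(U, data)
  }
  fb <- sweep(sup$priors, 2, sup$labeled, "*")
  J <- numeric(0)
  for (t in seq_len(max_iter)) {
    d2 <- squared_distances(data, centers)
    U_new <- update_membership(d2, sup, alpha, "pedrycz")
    Wc <- U_new^2 + alpha * (U_new - fb)^2
    centers <- (Wc %*% data) / rowSums(Wc)
    J <- c(J, pedrycz_objective(U_new, data, centers, sup, alpha))
    conv <- check_convergence(U_new, U, epsilon)
    U <- U_new
    if (conv$converged) break
  }
  list(U = U, J = J)
}

# small phantom for pipeline tests (cheap but non-trivial geometry)
small_phantom <- function(noise = 0.05, seed = 7, shape = c(48L, 48L)) {
  generate_phantom(phantom_spec(shape = shape, noise_sigma = noise,
                                seed = seed))
}
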