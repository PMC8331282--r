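test_that("squared distances: zero at coincident points, hand-checked 1-D case", {
  x <- matrix(c(0, 4), ncol = 1)
  ctr <- matrix(c(0, 4), ncol = 1)
  expect_equal(squared_distances(x, ctr),
               matrix(c(0, 16, 16, 0), 2, 2))
  expect_equal(squared_distances(matrix(1:3, 1), matrix(1:3, 1)),
               matrix(0, 1, 1))
  expect_error(squared_distances(matrix(0, 2, 2), matrix(0, 2, 3)),
               "dimensionality")
})

test_that("squared distances match the scalar-loop oracle on random instances", {
  set.seed(11)
  for (trial in 1:10) {
    data <- matrix(runif(15), 5, 3)
    ctr <- matrix(runif(6), 2, 3)
    expect_equal(squared_distances(data, ctr),
                 oracle_squared_distances(data, ctr), tolerance = 1e-12)
  }
})

test_that("membership update: symmetry, zero-distance and alpha = 0 contracts", {
  # equidistant sample splits evenly in every mode
  d2 <- matrix(c(2, 2), 2, 1)
  sup0 <- supervision_info(NA_integer_, 2)
  for (md in c("fcm", "ssfcm", "pedrycz")) {
    expect_equal(update_membership(d2, sup0, 1, md),
                 matrix(c(0.5, 0.5), 2, 1))
  }
  # sample coincident with center 1 gets crisp membership there
  expect_equal(update_membership(matrix(c(0, 3), 2, 1), mode = "fcm"),
               matrix(c(1, 0), 2, 1))
  # alpha = 0 collapses the semisupervised rules onto FCM
  set.seed(21)
  d2 <- matrix(runif(12, 0.1, 2), 3, 4)
  sup <- supervision_info(c(1L, NA, 3L, NA), 3)
  base <- update_membership(d2, mode = "fcm")
  expect_equal(update_membership(d2, sup, 0, "ssfcm"), base, tolerance = 1e-12)
  expect_equal(update_membership(d2, sup, 0, "pedrycz"), base, tolerance = 1e-12)
})

test_that("membership update matches the scalar formula oracle in all modes", {
  set.seed(31)
  for (trial in 1:12) {
    inst <- random_instance()
    ctr <- matrix(runif(inst$cc * inst$d), inst$cc, inst$d)
    d2 <- squared_distances(inst$data, ctr)
    for (md in c("fcm", "ssfcm", "pedrycz")) {
      for (alpha in c(0.5, 1, 2)) {
        got <- update_membership(d2, inst$sup, alpha, md)
        expect_equal(got, oracle_membership(d2, inst$sup, alpha, md),
                     tolerance = 1e-10)
        expect_true(all(got >= 0 & got <= 1))
        expect_equal(colSums(got), rep(1, inst$n), tolerance = 1e-9)
      }
    }
  }
})

test_that("center update: crisp and uniform memberships reduce to plain means", {
  x <- matrix(c(0, 1, 10, 12, 14, 5), ncol = 1)
  crisp <- matrix(0, 2, 6)
  crisp[1, 1:2] <- 1
  crisp[2, 3:6] <- 1
  expect_equal(update_centers(crisp, x),
               matrix(c(mean(x[1:2]), mean(x[3:6])), 2, 1))
  unif <- matrix(1 / 3, 3, 6)
  expect_equal(update_centers(unif, x),
               matrix(mean(x), 3, 1))
  # all-zero membership mass is a hard error naming the cluster
  bad <- crisp
  bad[2, ] <- 0
  expect_error(update_centers(bad, x), "degenerate cluster.*2")
})

test_that("center update matches the loop oracle and stays in the bounding box", {
  set.seed(41)
  for (trial in 1:10) {
    inst <- random_instance(n = 6)
    U <- random_membership(inst$cc, inst$n)
    B <- update_centers(U, inst$data)
    expect_equal(B, oracle_centers(U, inst$data), tolerance = 1e-10)
    for (j in seq_len(inst$d)) {
      expect_true(all(B[, j] >= min(inst$data[, j]) - 1e-12))
      expect_true(all(B[, j] <= max(inst$data[, j]) + 1e-12))
    }
  }
})

test_that("convergence check implements the Chebyshev norm", {
  U <- random_membership(3, 5)
  expect_equal(check_convergence(U, U, 1e-8),
               list(converged = TRUE, delta = 0))
  V <- U
  V[2, 3] <- V[2, 3] + 0.01
  res <- check_convergence(V, U, 0.001)
  expect_false(res$converged)
  expect_equal(res$delta, 0.01)
  set.seed(51)
  for (trial in 1:5) {
    A <- random_membership(3, 6)
    B <- random_membership(3, 6)
    expect_equal(check_convergence(A, B, 1)$delta, oracle_max_abs_diff(A, B))
  }
  expect_error(check_convergence(U, U[, 1:3], 1e-3), "shape")
})

test_that("hard labels take the column argmax with lowest-index tie-break", {
  expect_equal(hard_labels(matrix(c(0.7, 0.3), 2, 1)), 1L)
  expect_equal(hard_labels(matrix(c(0.5, 0.5), 2, 1)), 1L)
  set.seed(61)
  U <- random_membership(4, 20)
  scan <- vapply(seq_len(20), function(k) {
    best <- 1L
    for (i in 2:4) if (U[i, k] > U[best, k]) best <- i
    best
  }, integer(1))
  expect_equal(hard_labels(U), scan)
})

test_that("fit recovers well-separated blobs and handles degenerate inputs", {
  set.seed(71)
  x <- matrix(c(rnorm(50, 0, 0.01), rnorm(50, 10, 0.01)), ncol = 1)
  fit <- ssfcm(x, 2L, mode = "fcm", seed = 5)
  expect_true(fit$converged)
  ctr <- sort(fit$centers[, 1])
  expect_lt(abs(ctr[1] - mean(x[1:50])), 0.1)
  expect_lt(abs(ctr[2] - mean(x[51:100])), 0.1)
  # cross-check against an independent FCM implementation
  if (requireNamespace("e1071", quietly = TRUE)) {
    cm <- e1071::cmeans(x, centers = 2, m = 2)
    expect_equal(ctr, unname(sort(cm$centers[, 1])), tolerance = 0.05)
  }
  # n identical points, one cluster
  same <- matrix(rep(3.5, 8), ncol = 1)
  fit1 <- ssfcm(same, 1L, mode = "fcm", seed = 1)
  expect_equal(fit1$centers[1, 1], 3.5)
  expect_true(fit1$converged)
  expect_lte(fit1$iterations, 2L)
  # fewer samples than clusters is a hard error
  expect_error(ssfcm(matrix(1:2, ncol = 1), 3L), "fewer samples")
})

test_that("fit is deterministic for identical data, config and seed", {
  set.seed(81)
  inst <- random_instance(n = 10, cc = 3)
  a <- ssfcm(inst$data, 3L, mode = "ssfcm", supervision = inst$sup, seed = 99)
  b <- ssfcm(inst$data, 3L, mode = "ssfcm", supervision = inst$sup, seed = 99)
  expect_identical(a, b)
  expect_lte(a$iterations, 100L)
  if (a$converged) expect_lt(a$delta_trace[a$iterations], a$epsilon)
})

test_that("semisupervised trajectories reduce to FCM without effective supervision", {
  set.seed(91)
  inst <- random_instance(n = 10, cc = 3)
  ref <- ssfcm(inst$data, 3L, mode = "fcm", seed = 7)
  # alpha = 0
  for (md in c("ssfcm", "pedrycz")) {
    fit <- ssfcm(inst$data, 3L, mode = md, supervision = inst$sup,
                 alpha = 0, seed = 7)
    expect_equal(fit$memberships, ref$memberships, tolerance = 1e-12)
    expect_equal(fit$delta_trace, ref$delta_trace, tolerance = 1e-12)
  }
  # no labeled samples
  none <- supervision_info(rep(NA_integer_, inst$n), 3)
  for (md in c("ssfcm", "pedrycz")) {
    fit <- ssfcm(inst$data, 3L, mode = md, supervision = none,
                 alpha = 1, seed = 7)
    expect_equal(fit$memberships, ref$memberships, tolerance = 1e-12)
  }
})

test_that("pedrycz mode monotonically decreases its objective", {
  set.seed(101)
  for (trial in 1:8) {
    inst <- random_instance(n = sample(8:25, 1))
    alpha <- sample(c(0.5, 1, 2), 1)
    # replay the fit loop to record the objective after every iteration
    fit <- ssfcm(inst$data, inst$cc, mode = "pedrycz",
                 supervision = inst$sup, alpha = alpha, seed = trial,
                 max_iter = 60L)
    traj <- replay_pedrycz(inst$data, inst$cc, inst$sup, alpha, seed = trial,
                           max_iter = 60L)
    expect_equal(traj$U, fit$memberships, tolerance = 1e-12)
    expect_true(all(diff(traj$J) <= 1e-10))
  }
})

test_that("supervision constructor validates its invariants", {
  sup <- supervision_info(c(1L, NA, 2L), 2)
  expect_equal(sup$labeled, c(1, 0, 1))
  expect_equal(colSums(sup$priors), c(1, 0, 1))
  expect_error(supervision_info(c(3L, NA), 2), "labels must lie")
  # shape mismatch against data is caught at fit time
  expect_error(ssfcm(matrix(runif(8), ncol = 1), 2L, mode = "ssfcm",
                     supervision = sup), "shape")
})
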