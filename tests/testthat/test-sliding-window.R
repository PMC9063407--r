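# Tapered sliding-window connectivity

test_that("taper weights are normalised, symmetric, and reduce to uniform", {
  for (spec in list(window_spec(), window_spec(30, 2, 1.5))) {
    w <- build_taper(spec)
    expect_length(w, spec$length_tr)
    expect_equal(sum(w), 1, tolerance = 1e-12)
    expect_equal(w, rev(w))
    expect_true(all(w > 0))
  }
  w0 <- build_taper(window_spec(60, 1, 1e-4))
  expect_lt(max(abs(w0 - 1 / 60)), 1e-6)

  # oracle: explicit convolution sum for the default taper
  L <- 60; sigma <- 3; half <- ceiling(3 * sigma)
  kern <- dnorm(seq(-half, half), sd = sigma); kern <- kern / sum(kern)
  manual <- sapply(seq_len(L), function(i) {
    sum(kern[pmax(1, i - L + half + 1):min(2 * half + 1, i + half)])
  })
  manual <- manual / sum(manual)
  w <- build_taper(window_spec(60, 1, 3))
  expect_equal(w, manual, tolerance = 1e-10)
  expect_gt(w[30], w[1])
  expect_gt(w[1], 0)
})

test_that("window enumeration covers the series with the documented count", {
  expect_length(enumerate_windows(770, window_spec()), 711)
  expect_equal(enumerate_windows(60, window_spec(60)), 0L)
  expect_equal(enumerate_windows(5, window_spec(3, 1, 1)), c(0L, 1L, 2L))
  expect_error(enumerate_windows(50, window_spec(60)), "shorter")
})

test_that("weighted window covariance matches the direct sum", {
  expect_equal(weighted_window_covariance(matrix(3, 100, 4), 0, rep(1 / 60, 60)),
               matrix(0, 4, 4))

  set.seed(5)
  X <- matrix(rnorm(200 * 3), 200, 3)
  X[, 2] <- X[, 1] * 0.8 + X[, 2] * 0.2
  # uniform weights = population-normalised sample covariance
  S_unif <- weighted_window_covariance(X, 10, rep(1 / 60, 60))
  rows <- X[11:70, ]
  expect_equal(S_unif, cov(rows) * 59 / 60, tolerance = 1e-12)

  # direct-sum oracle with a non-uniform taper
  w <- build_taper(window_spec(60, 1, 3))
  S <- weighted_window_covariance(X, 25, w)
  rows <- X[26:85, ]
  mu <- colSums(rows * w)
  S_manual <- matrix(0, 3, 3)
  for (t in 1:60) {
    d <- rows[t, ] - mu
    S_manual <- S_manual + w[t] * tcrossprod(d)
  }
  expect_equal(S, S_manual, tolerance = 1e-12)
  expect_true(isSymmetric(S))
  expect_gte(min(eigen(S, only.values = TRUE)$values), -1e-12)
})

test_that("graphical lasso solves the penalised log-det problem", {
  set.seed(2)
  X <- matrix(rnorm(300 * 5), 300, 5)
  S <- cov(X)

  # lambda = 0: unpenalised MLE
  expect_equal(glasso_precision(S, 0), solve(S), tolerance = 1e-6,
               ignore_attr = TRUE)

  # identity input: exactly diagonal solution
  th <- glasso_precision(diag(5), 0.1)
  expect_true(all(th[upper.tri(th)] == 0))

  # KKT oracle: W - S = lambda * sign(theta) on the support,
  # |W - S| <= lambda off the support
  lam <- 0.08
  th <- glasso_precision(S, lam)
  W <- solve(th)
  off <- upper.tri(S)
  expect_lt(max(abs(W - S)[off]) - lam, 1e-4)
  nz <- which(off & abs(th) > 1e-7)
  if (length(nz)) {
    expect_lt(max(abs((W - S)[nz] - lam * sign(th[nz]))), 1e-4)
  }

  # sparsity is monotone in lambda
  zero_counts <- sapply(c(0.01, 0.05, 0.1, 0.3, 0.6), function(l) {
    th <- glasso_precision(S, l)
    sum(abs(th[upper.tri(th)]) < 1e-10)
  })
  expect_true(all(diff(zero_counts) >= 0))
})

test_that("precision path is continuous across adjacent grid penalties", {
  set.seed(3)
  X <- matrix(rnorm(400 * 6), 400, 6)
  S <- cov(X)
  grid <- 10^seq(-3, 0, length.out = 10)
  sols <- lapply(grid, function(l) glasso_precision(S, l))
  for (i in seq_len(length(grid) - 1)) {
    gap <- max(abs(sols[[i + 1]] - sols[[i]]))
    expect_lt(gap, 10 * (grid[i + 1] - grid[i]) + 0.5)
  }
})

test_that("penalty selection recovers a sparse truth and honours fixed_lambda", {
  cfg_fixed <- glasso_config(fixed_lambda = 0.1)
  expect_equal(select_lambda(matrix(rnorm(100 * 3), 100, 3),
                             window_spec(20, 5, 3), cfg_fixed), 0.1)
  expect_error(select_lambda(matrix(rnorm(100 * 3), 100, 3),
                             window_spec(20, 5, 3),
                             glasso_config(lambda_grid = numeric(0))),
               "empty lambda grid")

  # simulate from a sparse precision: a chain graph
  C <- 8
  theta_true <- diag(2, C)
  for (i in 1:(C - 1)) theta_true[i, i + 1] <- theta_true[i + 1, i] <- -0.9
  sigma_true <- solve(theta_true)
  ch <- chol(sigma_true)
  cfg <- glasso_config(lambda_grid = c(0.001, 0.1, 10), n_cv_folds = 5)
  wsp <- window_spec(30, 10, 3)
  hits <- 0
  for (s in 1:10) {
    set.seed(100 + s)
    X <- matrix(rnorm(400 * C), 400, C) %*% ch
    lam <- select_lambda(X, wsp, cfg, seed = s)
    if (lam == 0.1) hits <- hits + 1
  }
  expect_gte(hits, 9)

  # same data, same seed -> same selection
  set.seed(1); X <- matrix(rnorm(400 * C), 400, C) %*% ch
  expect_identical(as.numeric(select_lambda(X, wsp, cfg, seed = 42)),
                   as.numeric(select_lambda(X, wsp, cfg, seed = 42)))
})

test_that("precision-to-correlation and Fisher z follow their closed forms", {
  expect_equal(precision_to_correlation(diag(4)), diag(4))
  expect_equal(precision_to_correlation(diag(c(2, 5, 9))), diag(3))
  th <- matrix(c(2, -1, -1, 2), 2)
  R <- precision_to_correlation(th)
  expect_equal(R[1, 2], 0.5, tolerance = 1e-12)   # Sigma = [[2/3,1/3],[1/3,2/3]]
  expect_error(precision_to_correlation(matrix(c(1, 2, 2, 1), 2)),
               "positive definite")

  expect_equal(fisher_z(0), 0)
  expect_equal(fisher_z(0.5), 0.5493, tolerance = 1e-4)
  r <- seq(0.1, 0.9, by = 0.1)
  expect_equal(fisher_z(-r), -fisher_z(r))
  expect_equal(fisher_z_inv(fisher_z(r)), r, tolerance = 1e-9)
  expect_true(is.finite(fisher_z(1)))             # clipped, not Inf
})

test_that("pair counting and vectorisation round-trip", {
  expect_equal(n_pairs(33), 528L)
  expect_equal(n_pairs(2), 1L)
  expect_equal(n_pairs(5), 10L)
  expect_error(n_pairs(1))

  set.seed(8)
  A <- matrix(rnorm(36), 6); A <- A + t(A); diag(A) <- 0
  v <- vectorize_pairs(A)
  expect_length(v, 15)
  expect_equal(v[1:5], A[1, 2:6], ignore_attr = TRUE)   # row-major i<j order
  expect_equal(unvectorize_pairs(v), A)
  expect_equal(vectorize_pairs(unvectorize_pairs(v)), v, ignore_attr = TRUE)
})

test_that("windowed_fc composes the declared per-window chain", {
  co <- small_two_state_cohort(C = 4, T_points = 120, n_per_group = 1)
  tc <- co$subjects[[1]]
  wsp <- window_spec(40, 10, 3)
  cfg <- glasso_config(fixed_lambda = 0.05)
  wfc <- windowed_fc(tc, wsp, cfg)
  expect_s3_class(wfc, "windowed_fc")
  expect_equal(nrow(wfc$z), length(enumerate_windows(120, wsp)))
  expect_equal(ncol(wfc$z), n_pairs(4))

  taper <- build_taper(wsp)
  for (wi in c(1, 5, 9)) {
    S <- weighted_window_covariance(tc$data, wfc$window_starts[wi], taper)
    th <- glasso_precision(S, 0.05)
    z_manual <- fisher_z(vectorize_pairs(precision_to_correlation(th)))
    expect_equal(wfc$z[wi, ], z_manual, tolerance = 1e-4, ignore_attr = TRUE)
  }
})

test_that("across-window mean connectivity recovers a fixed generating correlation", {
  C <- 8
  part <- stats::setNames(rep(c("SMN", "VN"), each = 4), sprintf("C%02d", 1:8))
  sc <- make_state_covariances(C, part, "within_dominant", 0.5)
  spec <- cohort_spec(
    groups = list(G = list(n_subjects = 1, markov = markov_params(1))),
    states = list(sc), T_points = 770, C = C, noise_sd = 0.2,
    network_partition = part, seed = 3)
  co <- simulate_cohort(spec)
  wfc <- windowed_fc(co$subjects[[1]], window_spec(),
                     glasso_config(fixed_lambda = 0.01))
  r_mean <- fisher_z_inv(colMeans(wfc$z))
  # attenuation from additive noise: var 1 + 0.04
  target <- vectorize_pairs(sc$matrix) / 1.04
  expect_lt(max(abs(r_mean - target)), 0.05)
})
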