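# Independent oracles and fixture builders shared across tests.

# lower median (tie -> lower of the two central order statistics)
lower_median_r <- function(v) sort(v)[(length(v) - 1) %/% 2 + 1]

# exhaustive global optimum of 2-cluster L1 k-means with lower-median
# centroids: enumerates every bipartition with two non-empty parts
exhaustive_l1_kmeans2 <- function(X) {
  n <- nrow(X)
  best <- Inf
  for (code in 1:(2^(n - 1) - 1)) {       # fix point 1 in cluster 1
    lab <- c(1L, as.integer(intToBits(code))[1:(n - 1)] + 1L)
    if (length(unique(lab)) < 2) next
    obj <- 0
    for (c in 1:2) {
      sub <- X[lab == c, , drop = FALSE]
      cen <- apply(sub, 2, lower_median_r)
      obj <- obj + sum(abs(sweep(sub, 2, cen)))
    }
    if (obj < best) best <- obj
  }
  best
}

# accuracy of a label sequence against ground truth up to the best
# permutation of 2 labels
perm2_accuracy <- function(labels, truth) {
  max(mean(labels == truth), mean((3 - labels) == truth))
}

# majority ground-truth state of each sliding window
window_truth <- function(states, starts, len) {
  vapply(starts, function(s) {
    win <- states[(s + 1):(s + len)]
    as.integer(names(which.max(table(win))))
  }, integer(1))
}

# z-matrix whose per-window variance across pairs equals a target series
z_with_row_variance <- function(v) {
  x <- sqrt(v / 2)
  cbind(x, -x)
}

# steady-state amplitude of a sinusoid in a filtered signal, by projection
# onto the sin/cos pair at that frequency over the central samples
fitted_amplitude <- function(y, freq_hz, TR, trim = 100) {
  n <- length(y)
  idx <- (trim + 1):(n - trim)
  tt <- (idx - 1) * TR
  d <- cbind(sin(2 * pi * freq_hz * tt), cos(2 * pi * freq_hz * tt))
  cf <- qr.coef(qr(d), y[idx])
  sqrt(sum(cf^2))
}

# fast generation of a small 2-state cohort for clustering tests
small_two_state_cohort <- function(C = 6, T_points = 400, n_per_group = 2,
                                   seed = 1, stay = c(0.98, 0.98),
                                   noise_sd = 0.1) {
  groups <- list(
    A = list(n_subjects = n_per_group, markov = markov_params(stay)),
    B = list(n_subjects = n_per_group, markov = markov_params(stay)))
  spec <- cohort_spec(groups = groups,
                      states = default_state_covariances(
                        C, strength_inter = 0.5, strength_within = 0.6),
                      T_points = T_points, C = C, seed = seed,
                      noise_sd = noise_sd)
  simulate_cohort(spec)
}
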