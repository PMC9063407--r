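# Connectivity-state clustering

test_that("exemplar windows sit at strict local variance maxima, with fallback", {
  z <- z_with_row_variance(c(1, 3, 2, 5, 4))
  expect_equal(select_exemplar_windows(z), c(2L, 4L))

  z_const <- z_with_row_variance(rep(2, 47))
  idx <- select_exemplar_windows(z_const)
  expect_length(idx, ceiling(47 / 10))

  # monotone series: no strict interior maximum, endpoint not counted
  z_mono <- z_with_row_variance(seq(1, 5, length.out = 30))
  expect_length(select_exemplar_windows(z_mono), ceiling(30 / 10))
})

test_that("city-block k-means finds the known optimum with documented tie-breaks", {
  X <- matrix(c(0, 1, 10, 11), 4, 1)
  fit <- kmeans_cityblock(X, 2, n_replicates = 10, seed = 1)
  expect_equal(fit$objective, 2)
  expect_length(unique(fit$labels[1:2]), 1)
  expect_length(unique(fit$labels[3:4]), 1)
  expect_false(fit$labels[1] == fit$labels[3])
  # lower-median centroids
  expect_equal(sort(as.numeric(fit$centroids)), c(0, 10))

  # k = n gives a zero objective
  expect_equal(kmeans_cityblock(X, 4, n_replicates = 5, seed = 1)$objective, 0)

  # objective is non-increasing within a run
  set.seed(3)
  Y <- matrix(rnorm(200 * 4), 200, 4)
  fit2 <- kmeans_cityblock(Y, 3, n_replicates = 1, seed = 2)
  expect_true(all(diff(fit2$obj_trace) <= 1e-12))

  # the returned replicate is at least as good as forced single runs
  set.seed(11)
  best <- kmeans_cityblock(Y, 3, n_replicates = 20, seed = 7)$objective
  singles <- sapply(1:10, function(s) {
    kmeans_cityblock(Y, 3, n_replicates = 1, seed = s)$objective
  })
  expect_true(all(best <= singles + 1e-9))

  # determinism under a fixed seed
  expect_identical(kmeans_cityblock(Y, 3, n_replicates = 5, seed = 9)$labels,
                   kmeans_cityblock(Y, 3, n_replicates = 5, seed = 9)$labels)

  # far-away initial centroid leaves an empty cluster that gets re-seeded
  init <- matrix(c(0, 1e6), 2, 1)
  Z <- matrix(c(0, 0.5, 1, 8, 9, 9.5), 6, 1)
  fit3 <- kmeans_cityblock(Z, 2, init = init)
  expect_equal(sort(unique(fit3$labels)), c(1L, 2L))
})

test_that("k-means matches the exhaustive optimum on a quick sweep", {
  set.seed(21)
  for (i in 1:60) {
    n <- sample(4:8, 1)
    P <- sample(1:3, 1)
    X <- matrix(rnorm(n * P), n, P)
    opt <- exhaustive_l1_kmeans2(X)
    fit <- kmeans_cityblock(X, 2, exhaustive_init = TRUE)
    expect_equal(fit$objective, opt, tolerance = 1e-9)
  }
})

test_that("silhouette matches hand arithmetic and the reference implementation", {
  # two tight, far-separated pairs
  X <- matrix(c(0, 0.1, 10, 10.1), 4, 1)
  s <- silhouette_cityblock(X, c(1, 1, 2, 2))
  expect_gt(as.numeric(s), 0.95)

  # hand computation for 1-D {0,1,10,11}
  X2 <- matrix(c(0, 1, 10, 11), 4, 1)
  s2 <- silhouette_cityblock(X2, c(1, 1, 2, 2))
  a <- c(1, 1, 1, 1)
  b <- c((10 + 11) / 2, (9 + 10) / 2, (10 + 9) / 2, (11 + 10) / 2)
  expect_equal(attr(s2, "widths"), (b - a) / pmax(a, b), tolerance = 1e-12)

  # identical points split arbitrarily -> 0 by the a = b convention
  X3 <- matrix(1, 6, 2)
  expect_equal(as.numeric(silhouette_cityblock(X3, rep(1:2, 3))), 0)

  expect_error(silhouette_cityblock(matrix(rnorm(6), 3), 1:3), "singleton")

  skip_if_not_installed("cluster")
  set.seed(4)
  X4 <- matrix(rnorm(40 * 3), 40, 3)
  lab <- kmeans_cityblock(X4, 3, n_replicates = 5, seed = 1)$labels
  ref <- cluster::silhouette(lab, dist(X4, method = "manhattan"))
  expect_equal(as.numeric(silhouette_cityblock(X4, lab)),
               mean(ref[, "sil_width"]), tolerance = 1e-10)
})

test_that("gap statistic prefers the true blob count and handles degeneracy", {
  mu <- rbind(rep(0, 4), rep(4, 4))
  hits <- 0
  for (s in 1:3) {
    set.seed(s)
    X <- mu[rep(1:2, each = 100), ] + matrix(rnorm(200 * 4), 200, 4)
    g <- gap_criterion(X, 2:6, B = 5, seed = s, n_replicates = 3)
    if (attr(g, "chosen_k") == 2) hits <- hits + 1
  }
  expect_gte(hits, 2)

  # unstructured data: small k chosen
  set.seed(9)
  U <- matrix(runif(200 * 4), 200, 4)
  gu <- gap_criterion(U, 2:6, B = 5, seed = 2, n_replicates = 3)
  expect_lte(attr(gu, "chosen_k"), 3)

  # fully degenerate data: references identical, se = 0 handled
  D <- matrix(1, 12, 2)
  gd <- gap_criterion(D, 2:3, B = 3, seed = 1, n_replicates = 2)
  expect_true(all(gd$se == 0))
  expect_false(any(is.na(gd$gap)))
})

test_that("choose_k resolves agreement, disagreement, and overrides", {
  gt <- structure(data.frame(k = 2:4, logW = 0, gap = c(1, 0.5, 0.2),
                             se = 0.01), chosen_k = 2L)
  expect_equal(choose_k(gt, c(0.8, 0.5, 0.3)), 2L)
  expect_warning(k <- choose_k(structure(gt, chosen_k = 3L), c(0.8, 0.5, 0.3)),
                 "silhouette")
  expect_equal(k, 2L)
  expect_equal(choose_k(gt, c(0.8, 0.5, 0.3), override = 4), 4L)
})

test_that("full-window assignment recovers planted states and is deterministic", {
  co <- small_two_state_cohort(C = 6, T_points = 400, n_per_group = 2, seed = 13)
  wsp <- window_spec(60, 4, 3)
  cfg <- glasso_config(fixed_lambda = 0.05)
  wfc <- lapply(co$subjects, function(tc) windowed_fc(tc, wsp, cfg))
  model <- suppressWarnings(
    cluster_validity(wfc, k_range = 2:4, B = 4, n_replicates = 10,
                     validity_replicates = 3, max_n = 400, seed = 2))
  asg <- assign_all_windows(wfc, model)
  expect_equal(length(asg$labels), sum(sapply(wfc, function(w) nrow(w$z))))
  expect_named(asg$sequences, names(co$subjects))

  if (model$k == 2) {
    truth <- unlist(lapply(names(co$subjects), function(sid) {
      window_truth(co$truth[[sid]], wfc[[sid]]$window_starts, 60)
    }))
    expect_gt(perm2_accuracy(asg$labels, truth), 0.9)
  }

  asg2 <- assign_all_windows(wfc, model)
  expect_identical(asg$labels, asg2$labels)

  # degenerate: every window identical to centroid 1 -> all labels 1
  z_const <- matrix(rep(model$centroids[1, ], each = 5), 5)
  wf_const <- structure(list(subject_id = "x", z = z_const,
                             window_starts = 0:4,
                             pair_index = pair_index(6)), class = "windowed_fc")
  asg3 <- assign_all_windows(list(wf_const),
                             structure(list(k = model$k,
                                            centroids = model$centroids,
                                            metric = "cityblock"),
                                       class = "state_model"))
  expect_true(all(asg3$labels == 1))
})

test_that("state medians, occurrences, and ordering behave as documented", {
  z <- rbind(c(1, 2, 3), c(4, 5, 6))
  med <- state_medians(z, c(1, 2), 2)
  expect_equal(med$medians, z)
  expect_equal(sum(med$percent), 100, tolerance = 1e-9)

  set.seed(6)
  z2 <- rbind(matrix(rnorm(30, 0), 10), matrix(rnorm(30, 5), 10),
              matrix(rnorm(30, 5), 10))
  lab <- rep(c(1, 2, 2), each = 10)
  med2 <- state_medians(z2, lab, 2, groups = rep(c("A", "B", "A"), each = 10))
  expect_equal(med2$counts, c(10L, 20L))
  expect_equal(med2$percent, c(100 / 3, 200 / 3), tolerance = 1e-9)
  expect_named(med2$by_group, c("A", "B"))
  expect_error(state_medians(z2, rep(1, 30), 2), "empty state")

  # occurrence ordering puts the most frequent state first
  fake <- list(model = structure(list(k = 2,
                                      centroids = rbind(c(1, 1, 1), c(9, 9, 9)),
                                      metric = "cityblock"),
                                 class = "state_model"),
               sequences = list(s1 = c(1, 1, 2, 1)),
               labels = c(1, 1, 2, 1), subject = rep("s1", 4))
  # state 1 already dominant: unchanged
  ord <- order_states(fake)
  expect_equal(ord$labels, c(1, 1, 2, 1))
  fake$labels <- c(2, 2, 1, 2); fake$sequences$s1 <- c(2, 2, 1, 2)
  ord2 <- order_states(fake)
  expect_equal(ord2$labels, c(1, 1, 2, 1))
  expect_equal(ord2$model$centroids[1, ], c(9, 9, 9))
})
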