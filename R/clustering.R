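# Connectivity-state identification: exemplar windows, city-block k-means,
# silhouette and gap-statistic cluster-number validity, full-data
# assignment, and state medians.

#' Select exemplar windows
#'
#' Exemplars are the windows at strict local maxima of the per-window
#' variance of connectivity across pairs (interior points only). When a
#' subject has no strict local maximum (e.g. constant or monotone variance),
#' every 10th window is taken instead, giving `ceiling(W/10)` fallback
#' windows.
#'
#' @param z W x P Fisher-z matrix or `windowed_fc` object.
#' @return 1-based integer window indices.
#' @export
select_exemplar_windows <- function(z) {
  if (inherits(z, "windowed_fc")) z <- z$z
  z <- as.matrix(z)
  W <- nrow(z)
  stopifnot(W >= 3)
  v <- apply(z, 1, stats::var)
  interior <- 2:(W - 1)
  is_max <- v[interior] > v[interior - 1] & v[interior] > v[interior + 1]
  idx <- interior[is_max]
  if (length(idx) == 0) idx <- seq.int(1L, W, by = 10L)
  as.integer(idx)
}

#' k-means clustering under the city-block metric
#'
#' Alternates nearest-centroid assignment (L1 distance, ties to the lowest
#' centroid index) with component-wise median updates (even cluster sizes
#' use the lower median), which is the exact L1 minimiser, so the objective
#' `sum_i ||x_i - c(x_i)||_1` is non-increasing. Without explicit starting
#' centroids, `n_replicates` runs are seeded k-means++-style under L1 and
#' the lowest-objective run is returned. Empty clusters are re-seeded at the
#' point farthest from its centroid.
#'
#' @param X n x P data matrix.
#' @param k number of clusters (`k <= n`).
#' @param n_replicates number of random restarts (default 100).
#' @param seed optional integer seed.
#' @param init optional k x P starting centroids (single run, no restarts).
#' @param max_iter iteration cap per run.
#' @param exhaustive_init for `k = 2` on small inputs: deterministically
#'   restart from every distinct pair of data points instead of random
#'   k-means++ seeding (no RNG consumed).
#' @return list with `labels` (1..k), `centroids` (k x P), `objective`,
#'   `obj_trace` (objective after each iteration of the returned run).
#' @export
kmeans_cityblock <- function(X, k, n_replicates = 100, seed = NULL,
                             init = NULL, max_iter = 100,
                             exhaustive_init = FALSE) {
  X <- as.matrix(X)
  stopifnot(k >= 1, nrow(X) >= k, n_replicates >= 1)
  if (!is.null(seed)) set.seed(seed)
  if (!is.null(init)) {
    init <- as.matrix(init)
    stopifnot(nrow(init) == k, ncol(init) == ncol(X))
  }
  if (exhaustive_init && is.null(init)) {
    if (k != 2) stop("exhaustive_init is implemented for k = 2 only")
    n <- nrow(X)
    lower_med <- function(v) sort(v)[(length(v) - 1) %/% 2 + 1]
    part_obj <- function(lab) {
      o <- 0
      for (c in 1:2) {
        sub <- X[lab == c, , drop = FALSE]
        if (nrow(sub) == 0) return(Inf)
        cen <- apply(sub, 2, lower_med)
        o <- o + sum(abs(sweep(sub, 2, cen)))
      }
      o
    }
    # Lloyd alone cannot always reach the best median-centroid partition
    # (the optimum need not be assignment-stable), so each restart is
    # finished with a Hartigan-style best-improvement reassignment descent.
    refine <- function(lab) {
      cur <- part_obj(lab)
      repeat {
        objs <- vapply(seq_len(n), function(p) {
          lab2 <- lab
          lab2[p] <- 3L - lab2[p]
          part_obj(lab2)
        }, numeric(1))
        if (min(objs) >= cur - 1e-12) break
        p <- which.min(objs)
        lab[p] <- 3L - lab[p]
        cur <- objs[p]
      }
      list(labels = lab, objective = cur)
    }
    best <- NULL
    for (a in 1:(n - 1)) {
      for (b in (a + 1):n) {
        fit <- kmeans_l1_cpp(X, 2L, 1L, as.integer(max_iter),
                             X[c(a, b), , drop = FALSE])
        r <- refine(as.integer(fit$labels))
        if (is.null(best) || r$objective < best$objective) best <- r
      }
    }
    cen <- rbind(apply(X[best$labels == 1, , drop = FALSE], 2, lower_med),
                 apply(X[best$labels == 2, , drop = FALSE], 2, lower_med))
    return(list(labels = best$labels, centroids = cen,
                objective = best$objective, obj_trace = best$objective))
  }
  fit <- kmeans_l1_cpp(X, as.integer(k), as.integer(n_replicates),
                       as.integer(max_iter), init)
  fit$labels <- as.integer(fit$labels)
  fit
}

#' Mean silhouette under city-block distances
#'
#' Standard silhouette width with L1 distances: `a(i)` the mean distance to
#' the point's own cluster, `b(i)` the smallest mean distance to another
#' cluster, `s(i) = (b - a)/max(a, b)`; `s(i) = 0` for singletons and for
#' degenerate `a = b = 0`.
#'
#' @param X n x P matrix; @param labels cluster labels in 1..k.
#' @return mean silhouette; per-point widths in attribute `"widths"`.
#' @export
silhouette_cityblock <- function(X, labels) {
  X <- as.matrix(X)
  labels <- as.integer(labels)
  k <- max(labels)
  stopifnot(length(labels) == nrow(X), k >= 2, all(labels >= 1))
  sizes <- tabulate(labels, k)
  if (any(sizes == 0)) stop("every cluster must be non-empty")
  if (all(sizes == 1)) stop("silhouette undefined for singleton-only clustering")
  res <- silhouette_l1_cpp(X, labels, k)
  structure(res$mean, widths = as.numeric(res$widths))
}

#' Gap statistic for cluster-number selection
#'
#' `Gap(k) = E*[log W_k] - log W_k`, where `W_k` is the within-cluster L1
#' dispersion (the k-means objective) and the expectation is estimated from
#' `B` reference datasets drawn uniformly over the feature-wise bounding box
#' of `X`. The standard error includes the usual `sqrt(1 + 1/B)` factor. The
#' chosen k is the smallest with `Gap(k) >= Gap(k+1) - se(k+1)` (the last
#' candidate if none qualifies).
#'
#' @param X n x P matrix.
#' @param k_range candidate cluster numbers (default 2:10).
#' @param B number of reference datasets (default 10, must be >= 2).
#' @param seed integer seed; @param n_replicates k-means restarts per fit.
#' @return data.frame `(k, logW, gap, se)` with attribute `"chosen_k"`.
#' @export
gap_criterion <- function(X, k_range = 2:10, B = 10, seed = 1L,
                          n_replicates = 5) {
  X <- as.matrix(X)
  stopifnot(B >= 2, nrow(X) >= max(k_range))
  set.seed(seed)
  lo <- apply(X, 2, min)
  hi <- apply(X, 2, max)
  logW <- function(M, k) {
    log(max(kmeans_cityblock(M, k, n_replicates = n_replicates)$objective,
            .Machine$double.xmin))
  }
  ref_logW <- matrix(NA_real_, B, length(k_range))
  for (b in seq_len(B)) {
    R <- matrix(stats::runif(length(X)), nrow(X), ncol(X))
    R <- sweep(sweep(R, 2, hi - lo, "*"), 2, lo, "+")
    for (ki in seq_along(k_range)) ref_logW[b, ki] <- logW(R, k_range[ki])
  }
  obs_logW <- vapply(k_range, function(k) logW(X, k), numeric(1))
  gap <- colMeans(ref_logW) - obs_logW
  se <- apply(ref_logW, 2, stats::sd) * sqrt(1 + 1 / B)
  chosen <- k_range[length(k_range)]
  for (ki in seq_along(k_range)[-length(k_range)]) {
    if (gap[ki] >= gap[ki + 1] - se[ki + 1]) { chosen <- k_range[ki]; break }
  }
  structure(data.frame(k = k_range, logW = obs_logW, gap = gap, se = se),
            chosen_k = chosen)
}

#' Choose the number of states from both validity criteria
#'
#' Returns the gap-chosen k when it agrees with the silhouette argmax;
#' otherwise returns the silhouette argmax with a warning. An explicit
#' `override` wins unconditionally.
#'
#' @param gap_table result of [gap_criterion()].
#' @param silhouettes named or plain numeric vector of mean silhouettes per
#'   k (aligned with `gap_table$k`).
#' @param override optional fixed k.
#' @return chosen k.
#' @export
choose_k <- function(gap_table, silhouettes, override = NULL) {
  if (!is.null(override)) return(as.integer(override))
  stopifnot(length(silhouettes) == nrow(gap_table))
  k_gap <- attr(gap_table, "chosen_k")
  k_sil <- gap_table$k[which.max(silhouettes)]
  if (k_gap != k_sil) {
    warning("gap criterion chose k = ", k_gap, ", silhouette chose k = ",
            k_sil, "; using the silhouette choice")
  }
  as.integer(k_sil)
}

#' Cluster-number validity analysis on exemplar windows
#'
#' Pools every subject's exemplar windows, optionally subsamples them to
#' `max_n` rows (for tractable reference clustering), then computes the gap
#' statistic and mean silhouette for each candidate k and picks k via
#' [choose_k()]. The exemplar state model is then fit at the chosen k on the
#' full exemplar pool.
#'
#' @param wfc_list list of `windowed_fc` objects.
#' @param k_range candidate ks; @param B gap reference draws.
#' @param n_replicates restarts for the final exemplar fit (default 100).
#' @param validity_replicates restarts inside the validity curves.
#' @param max_n subsample cap for the validity curves.
#' @param seed integer seed; @param override optional fixed k.
#' @return object of class `state_model`: `k`, `centroids`, `metric`,
#'   `validity` (data.frame k/logW/gap/se/silhouette), `chosen_k_rule`,
#'   `exemplar_index` (subject/window of each exemplar).
#' @export
cluster_validity <- function(wfc_list, k_range = 2:10, B = 10,
                             n_replicates = 100, validity_replicates = 5,
                             max_n = 1000, seed = 1L, override = NULL) {
  stopifnot(length(wfc_list) >= 1)
  ex_rows <- list()
  ex_index <- list()
  for (w in wfc_list) {
    idx <- select_exemplar_windows(w)
    ex_rows[[w$subject_id]] <- w$z[idx, , drop = FALSE]
    ex_index[[w$subject_id]] <- data.frame(subject = w$subject_id, window = idx)
  }
  X <- do.call(rbind, ex_rows)
  ex_index <- do.call(rbind, ex_index)
  set.seed(seed)
  Xv <- X
  if (nrow(X) > max_n) Xv <- X[sort(sample.int(nrow(X), max_n)), , drop = FALSE]
  k_range <- k_range[k_range <= nrow(Xv)]

  sil <- vapply(k_range, function(k) {
    fit <- kmeans_cityblock(Xv, k, n_replicates = validity_replicates)
    if (length(unique(fit$labels)) < 2) return(NA_real_)
    as.numeric(silhouette_cityblock(Xv, fit$labels))
  }, numeric(1))
  gap_tab <- gap_criterion(Xv, k_range, B = B, seed = derive_seed(seed, 2),
                           n_replicates = validity_replicates)
  k <- choose_k(gap_tab, sil, override = override)

  set.seed(derive_seed(seed, 3))
  fit <- kmeans_cityblock(X, k, n_replicates = n_replicates)
  validity <- gap_tab
  validity$silhouette <- sil
  structure(list(k = k, centroids = fit$centroids, metric = "cityblock",
                 validity = validity,
                 chosen_k_rule = if (!is.null(override)) "override"
                                 else "gap+silhouette",
                 exemplar_index = ex_index),
            class = "state_model")
}

#' @export
print.state_model <- function(x, ...) {
  cat("state_model: k =", x$k, "(", x$chosen_k_rule, "), metric =",
      x$metric, ",", ncol(x$centroids), "pairs\n")
  invisible(x)
}

#' Assign every window of every subject to a state
#'
#' A single k-means pass over the stacked windows of all subjects,
#' initialised at the exemplar centroids, yields the final centroids and
#' per-subject state sequences (window order preserved).
#'
#' @param wfc_list list of `windowed_fc` objects.
#' @param model exemplar `state_model`.
#' @return list with `model` (final `state_model`), `sequences` (named list
#'   of per-subject integer label vectors), `labels` (stacked), `z_all`
#'   (stacked windows), `subject` (stacked subject ids).
#' @export
assign_all_windows <- function(wfc_list, model) {
  stopifnot(inherits(model, "state_model"))
  P <- ncol(model$centroids)
  for (w in wfc_list) {
    if (ncol(w$z) != P) stop("pair-dimension mismatch between windows and centroids")
  }
  z_all <- do.call(rbind, lapply(wfc_list, `[[`, "z"))
  subject <- rep(vapply(wfc_list, `[[`, character(1), "subject_id"),
                 vapply(wfc_list, function(w) nrow(w$z), integer(1)))
  fit <- kmeans_cityblock(z_all, model$k, init = model$centroids)
  sequences <- split(fit$labels, factor(subject, levels = unique(subject)))
  final <- model
  final$centroids <- fit$centroids
  list(model = final, sequences = sequences, labels = fit$labels,
       z_all = z_all, subject = subject)
}

#' Reorder state labels
#'
#' Relabels states (default: by descending total occurrence, so state 1 is
#' the most frequent). Returns the permutation applied plus relabelled
#' sequences and centroids.
#'
#' @param assignment result of [assign_all_windows()].
#' @param order_by `"by_occurrence_desc"` (default) or `"none"`.
#' @return `assignment` with relabelled `labels`/`sequences` and permuted
#'   centroid rows; attribute `"state_order"` gives old -> new mapping.
#' @export
order_states <- function(assignment, order_by = c("by_occurrence_desc", "none")) {
  order_by <- match.arg(order_by)
  if (order_by == "none") return(assignment)
  k <- assignment$model$k
  counts <- tabulate(assignment$labels, k)
  perm <- order(counts, decreasing = TRUE)       # perm[new] = old
  relabel <- integer(k)
  relabel[perm] <- seq_len(k)                    # relabel[old] = new
  assignment$labels <- relabel[assignment$labels]
  assignment$sequences <- lapply(assignment$sequences, function(s) relabel[s])
  assignment$model$centroids <- assignment$model$centroids[perm, , drop = FALSE]
  attr(assignment, "state_order") <- relabel
  assignment
}

#' State medians and occurrence summaries
#'
#' Component-wise median of the Fisher-z windows assigned to each state
#' (the state's connectivity pattern), with occurrence counts and
#' percentages of total windows; optionally split by group.
#'
#' @param z_all stacked W_total x P window matrix.
#' @param labels stacked state labels.
#' @param k number of states.
#' @param groups optional per-window group labels for a per-group variant.
#' @return list with `medians` (k x P), `matrices` (list of C x C median
#'   matrices), `counts`, `percent`; when `groups` is given, `by_group` is a
#'   named list of the same structure.
#' @export
state_medians <- function(z_all, labels, k, groups = NULL) {
  z_all <- as.matrix(z_all)
  labels <- as.integer(labels)
  stopifnot(length(labels) == nrow(z_all), all(labels >= 1), all(labels <= k))
  counts <- tabulate(labels, k)
  if (any(counts == 0)) stop("empty state: ", paste(which(counts == 0), collapse = ", "))
  med <- t(vapply(seq_len(k), function(s) {
    apply(z_all[labels == s, , drop = FALSE], 2, stats::median)
  }, numeric(ncol(z_all))))
  out <- list(medians = med,
              matrices = lapply(seq_len(k), function(s) unvectorize_pairs(med[s, ])),
              counts = counts,
              percent = 100 * counts / sum(counts))
  if (!is.null(groups)) {
    stopifnot(length(groups) == length(labels))
    out$by_group <- lapply(split(seq_along(labels), groups), function(idx) {
      sub_counts <- tabulate(labels[idx], k)
      sub_med <- t(vapply(seq_len(k), function(s) {
        rows <- idx[labels[idx] == s]
        if (length(rows) == 0) return(rep(NA_real_, ncol(z_all)))
        apply(z_all[rows, , drop = FALSE], 2, stats::median)
      }, numeric(ncol(z_all))))
      list(medians = sub_med, counts = sub_counts,
           percent = 100 * sub_counts / max(sum(sub_counts), 1))
    })
  }
  out
}
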