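# Tapered sliding-window dynamic connectivity: window enumeration, taper
# construction, weighted window covariance, graphical-lasso precision,
# implied correlations and Fisher z pair vectors.

#' Sliding-window specification
#'
#' @param length_tr window length in TRs (default 60, about 44 s at
#'   TR = 0.720 s).
#' @param step_tr step between window starts in TRs (default 1).
#' @param taper_sigma_tr SD of the Gaussian the rectangle is convolved with
#'   (default 3 TRs).
#' @return object of class `window_spec`.
#' @export
window_spec <- function(length_tr = 60, step_tr = 1, taper_sigma_tr = 3.0) {
  stopifnot(length_tr >= 1, step_tr >= 1, taper_sigma_tr > 0)
  structure(list(length_tr = as.integer(length_tr),
                 step_tr = as.integer(step_tr),
                 taper_sigma_tr = taper_sigma_tr),
            class = "window_spec")
}

#' Build the tapered window weights
#'
#' Convolves a rectangle of width `length_tr` with a Gaussian kernel of SD
#' `taper_sigma_tr` (truncated at +/- 3 SD), crops the result back to
#' `length_tr` samples and normalises it to sum 1. The result is symmetric,
#' strictly positive, and tends to the uniform window as the SD tends to 0.
#'
#' @param spec `window_spec`.
#' @return numeric weight vector of length `length_tr`.
#' @export
build_taper <- function(spec) {
  L <- spec$length_tr
  sigma <- spec$taper_sigma_tr
  half <- max(1L, ceiling(3 * sigma))
  kern <- stats::dnorm(seq(-half, half), sd = sigma)
  kern <- kern / sum(kern)
  full <- as.numeric(stats::convolve(rep(1, L), rev(kern), type = "open"))
  w <- full[(half + 1):(half + L)]
  w <- (w + rev(w)) / 2          # enforce exact symmetry
  pmax(w, .Machine$double.xmin) / sum(w)
}

#' Enumerate window start indices
#'
#' @param T_points number of time points.
#' @param spec `window_spec`.
#' @return integer vector of 0-based start indices, windows half-open
#'   `[start, start + length)`; count is `floor((T - length)/step) + 1`.
#' @export
enumerate_windows <- function(T_points, spec) {
  if (T_points < spec$length_tr) {
    stop("T (", T_points, ") shorter than window length (", spec$length_tr, ")")
  }
  seq.int(0L, T_points - spec$length_tr, by = spec$step_tr)
}

#' Weighted window covariance
#'
#' Taper-weighted sample covariance of one window:
#' `S = sum_t w_t (x_t - mu)(x_t - mu)'` with `mu` the weighted mean and
#' `sum(w) = 1`.
#'
#' @param data T x C matrix.
#' @param start 0-based window start.
#' @param taper weight vector (window length), summing to 1.
#' @return C x C symmetric PSD matrix.
#' @export
weighted_window_covariance <- function(data, start, taper) {
  data <- as.matrix(data)
  stopifnot(start >= 0, start + length(taper) <= nrow(data),
            all(is.finite(data)))
  weighted_cov_cpp(data, as.integer(start), taper / sum(taper))
}

#' Graphical-lasso configuration
#'
#' @param lambda_grid ascending positive penalty grid for cross-validated
#'   selection (default 10 log-spaced points in `[1e-3, 1]`).
#' @param n_cv_folds number of random window folds (default 5).
#' @param max_iter maximum outer coordinate-descent sweeps.
#' @param tol convergence tolerance on the maximum entry change of the
#'   covariance estimate.
#' @param fixed_lambda optional fixed penalty bypassing cross-validation.
#' @return object of class `glasso_config`.
#' @export
glasso_config <- function(lambda_grid = 10^seq(-3, 0, length.out = 10),
                          n_cv_folds = 5, max_iter = 200, tol = 1e-5,
                          fixed_lambda = NULL) {
  stopifnot(tol > 0, max_iter >= 1, n_cv_folds >= 2)
  if (length(lambda_grid)) {
    stopifnot(all(lambda_grid > 0), !is.unsorted(lambda_grid))
  }
  structure(list(lambda_grid = lambda_grid, n_cv_folds = n_cv_folds,
                 max_iter = as.integer(max_iter), tol = tol,
                 fixed_lambda = fixed_lambda),
            class = "glasso_config")
}

#' Graphical-lasso precision matrix
#'
#' Maximises `log det(Theta) - tr(S Theta) - lambda * ||Theta||_1(off-diag)`
#' by blockwise coordinate descent. At `lambda = 0` the solution is the
#' unpenalised MLE `S^-1`, computed directly.
#'
#' @param S symmetric PSD covariance matrix.
#' @param lambda non-negative L1 penalty.
#' @param cfg `glasso_config` (controls `max_iter` and `tol`).
#' @param warm_start optional covariance estimate from a previous, similar
#'   problem.
#' @return precision matrix with attributes `"converged"`, `"iterations"`,
#'   and `"w"` (the implied covariance estimate).
#' @export
glasso_precision <- function(S, lambda, cfg = glasso_config(),
                             warm_start = NULL) {
  S <- as.matrix(S)
  stopifnot(isSymmetric(S, tol = 1e-8), lambda >= 0)
  S <- 0.5 * (S + t(S))
  if (lambda == 0) {
    theta <- tryCatch(chol2inv(chol(S)),
                      error = function(e) stop("S is singular at lambda = 0: ",
                                               conditionMessage(e)))
    attr(theta, "converged") <- TRUE
    attr(theta, "iterations") <- 0L
    attr(theta, "w") <- S
    return(theta)
  }
  fit <- glasso_cpp(S, lambda, cfg$max_iter, cfg$tol, warm_start)
  if (!fit$converged) {
    stop("graphical lasso did not converge in ", cfg$max_iter,
         " sweeps (lambda = ", lambda, ", tol = ", cfg$tol, ")")
  }
  theta <- fit$theta
  attr(theta, "converged") <- fit$converged
  attr(theta, "iterations") <- fit$iterations
  attr(theta, "w") <- fit$w
  theta
}

#' Cross-validated penalty selection
#'
#' Splits a subject's windows into random folds. For each fold and grid
#' penalty, the graphical lasso is fitted to individual training-window
#' covariances (the window is the estimation unit the pipeline applies the
#' penalty to downstream) and each fit is scored against the pooled
#' held-out covariance by the Gaussian log-likelihood
#' `log det(Theta) - tr(S_holdout Theta)`. The grid value with the highest
#' mean held-out score wins (ties go to the smaller penalty);
#' `fixed_lambda` in the config bypasses the search.
#'
#' @param data T x C matrix (post-processed time courses).
#' @param wspec `window_spec`; @param cfg `glasso_config`.
#' @param seed integer seed controlling the fold split.
#' @param max_train_windows per-fold cap on fitted training windows (keeps
#'   the search affordable on step-1 window grids).
#' @return selected penalty, with attribute `"cv_scores"` unless fixed.
#' @export
select_lambda <- function(data, wspec = window_spec(), cfg = glasso_config(),
                          seed = 1L, max_train_windows = 20) {
  if (!is.null(cfg$fixed_lambda)) return(cfg$fixed_lambda)
  if (length(cfg$lambda_grid) == 0) stop("empty lambda grid")
  data <- as.matrix(data)
  starts <- enumerate_windows(nrow(data), wspec)
  if (length(starts) < 2 * cfg$n_cv_folds) {
    stop("need at least ", 2 * cfg$n_cv_folds, " windows for CV")
  }
  taper <- build_taper(wspec)
  covs <- lapply(starts, function(s) weighted_window_covariance(data, s, taper))
  set.seed(seed)
  fold <- sample(rep_len(seq_len(cfg$n_cv_folds), length(covs)))
  scores <- matrix(0, cfg$n_cv_folds, length(cfg$lambda_grid))
  for (f in seq_len(cfg$n_cv_folds)) {
    hold <- which(fold == f)
    train <- which(fold != f)
    if (length(train) > max_train_windows) {
      train <- sort(sample(train, max_train_windows))
    }
    S_hold <- Reduce(`+`, covs[hold]) / length(hold)
    for (w in train) {
      warm <- NULL
      for (li in rev(seq_along(cfg$lambda_grid))) {  # large-to-small, warm-started
        theta <- glasso_precision(covs[[w]], cfg$lambda_grid[li], cfg,
                                  warm_start = warm)
        warm <- attr(theta, "w")
        scores[f, li] <- scores[f, li] +
          (determinant(theta, logarithm = TRUE)$modulus -
             sum(S_hold * theta)) / length(train)
      }
    }
  }
  mean_scores <- colMeans(scores)
  lambda <- cfg$lambda_grid[which.max(mean_scores)]
  attr(lambda, "cv_scores") <- stats::setNames(mean_scores,
                                               signif(cfg$lambda_grid, 4))
  lambda
}

#' Correlation matrix implied by a precision matrix
#'
#' Inverts the precision matrix to the implied covariance and normalises to
#' a correlation matrix: `R[i,j] = Sigma[i,j] / sqrt(Sigma[i,i] Sigma[j,j])`.
#'
#' @param theta symmetric positive-definite precision matrix.
#' @return correlation matrix with unit diagonal.
#' @export
precision_to_correlation <- function(theta) {
  theta <- as.matrix(theta)
  sigma <- tryCatch(chol2inv(chol(0.5 * (theta + t(theta)))),
                    error = function(e) stop("precision matrix not positive definite"))
  d <- 1 / sqrt(diag(sigma))
  R <- sigma * tcrossprod(d)
  diag(R) <- 1
  R
}

#' Fisher z-transform
#'
#' `z = atanh(r)` with inputs clipped to `+/-(1 - 1e-7)`.
#'
#' @param r correlations.
#' @return z-scores.
#' @export
fisher_z <- function(r) {
  atanh(pmin(pmax(r, -(1 - 1e-7)), 1 - 1e-7))
}

#' Inverse Fisher z-transform
#' @param z z-scores.
#' @return correlations (`tanh(z)`).
#' @export
fisher_z_inv <- function(z) tanh(z)

#' Number of component pairs
#' @param C number of components (>= 2).
#' @return `C (C - 1) / 2` (528 for 33 components).
#' @export
n_pairs <- function(C) {
  stopifnot(C >= 2)
  as.integer(C * (C - 1) / 2)
}

#' Pair index table
#'
#' Fixed pair ordering used everywhere in the package: `(i, j)` with
#' `i < j`, `i` outermost (row-major upper triangle).
#'
#' @param C number of components.
#' @param network_of optional component-to-network map; adds network columns.
#' @return data.frame with columns `pair`, `i`, `j` (and `network_i`,
#'   `network_j`, `block` when `network_of` is given).
#' @export
pair_index <- function(C, network_of = NULL) {
  idx <- which(upper.tri(matrix(0, C, C)), arr.ind = TRUE)
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  out <- data.frame(pair = seq_len(nrow(idx)), i = idx[, 1], j = idx[, 2])
  if (!is.null(network_of)) {
    out$network_i <- unname(network_of[out$i])
    out$network_j <- unname(network_of[out$j])
    out$block <- paste(pmin(out$network_i, out$network_j),
                       pmax(out$network_i, out$network_j), sep = "-")
  }
  out
}

#' Vectorise / reconstruct a symmetric matrix over pairs
#'
#' @param R symmetric C x C matrix.
#' @return length-P vector in [pair_index()] order.
#' @export
vectorize_pairs <- function(R) {
  R <- as.matrix(R)
  stopifnot(nrow(R) == ncol(R), nrow(R) >= 2)
  t(R)[lower.tri(R)]
}

#' @rdname vectorize_pairs
#' @param v length-P pair vector.
#' @param diag_value value placed on the diagonal (default 0).
#' @return symmetric C x C matrix.
#' @export
unvectorize_pairs <- function(v, diag_value = 0) {
  P <- length(v)
  C <- (1 + sqrt(1 + 8 * P)) / 2
  if (C != round(C)) stop("length is not a valid pair count")
  idx <- pair_index(C)
  M <- matrix(diag_value, C, C)
  M[cbind(idx$i, idx$j)] <- v
  M[cbind(idx$j, idx$i)] <- v
  M
}

#' Windowed dynamic connectivity for one subject
#'
#' Runs the full per-subject dynamic-connectivity chain: tapered sliding
#' windows, weighted window covariance, graphical-lasso precision (penalty
#' either fixed or selected by [select_lambda()]), implied correlations,
#' Fisher z-transform and pair vectorisation. Adjacent windows warm-start
#' each other's graphical lasso.
#'
#' @param tc `component_timecourses` (or T x C matrix).
#' @param wspec `window_spec`; @param cfg `glasso_config`.
#' @param seed seed for the penalty cross-validation.
#' @return object of class `windowed_fc`: `subject_id`, `z` (W x P matrix),
#'   `window_starts` (0-based), `pair_index`, `lambda`, `wspec`,
#'   `network_of`.
#' @export
windowed_fc <- function(tc, wspec = window_spec(), cfg = glasso_config(),
                        seed = 1L) {
  X <- tc_matrix(tc)
  sid <- if (inherits(tc, "component_timecourses")) tc$subject_id else "subject"
  network_of <- if (inherits(tc, "component_timecourses")) tc$network_of else NULL
  starts <- enumerate_windows(nrow(X), wspec)
  taper <- build_taper(wspec)
  lambda <- select_lambda(X, wspec, cfg, seed)
  Z <- windowed_zfc_cpp(X, as.integer(starts), taper, as.numeric(lambda),
                        cfg$max_iter, cfg$tol)
  if (any(!is.finite(Z))) stop("non-finite connectivity values")
  structure(list(subject_id = sid, z = Z, window_starts = starts,
                 pair_index = pair_index(ncol(X), network_of),
                 lambda = as.numeric(lambda), wspec = wspec,
                 network_of = network_of),
            class = "windowed_fc")
}

#' Write a windowed-FC series to disk
#'
#' One TSV matrix (W rows x P columns) of Fisher-z values plus a JSON
#' sidecar holding the window starts, pair index, selected penalty and
#' window specification.
#'
#' @param wfc `windowed_fc` object; @param dir output directory.
#' @return the TSV path, invisibly.
#' @export
write_windowed_fc <- function(wfc, dir) {
  stopifnot(inherits(wfc, "windowed_fc"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fp <- file.path(dir, paste0(wfc$subject_id, "_zfc.tsv"))
  z <- wfc$z
  colnames(z) <- paste0("p", wfc$pair_index$i, "_", wfc$pair_index$j)
  write_tsv_matrix(z, fp)
  side <- list(subject_id = wfc$subject_id,
               window_starts = wfc$window_starts,
               pair_index = wfc$pair_index[, c("i", "j")],
               lambda = wfc$lambda,
               window = unclass(wfc$wspec))
  jsonlite::write_json(side, file.path(dir, paste0(wfc$subject_id, "_zfc.json")),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(fp)
}

#' @export
print.windowed_fc <- function(x, ...) {
  cat("windowed_fc:", x$subject_id, "-", nrow(x$z), "windows x",
      ncol(x$z), "pairs, lambda =", signif(x$lambda, 4), "\n")
  invisible(x)
}
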