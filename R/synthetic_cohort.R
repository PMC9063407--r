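# Hidden-Markov multivariate-Gaussian cohort simulator.
#
# Subjects are simulated as ICA-style component time courses that switch
# between whole-brain connectivity states: a first-order Markov chain picks
# the active state at every time point and the signal at that time point is
# drawn from a zero-mean multivariate normal with the state's covariance.
# Ground truth (state sequences, generating parameters) is returned so the
# downstream windowing/clustering pipeline can be validated quantitatively.

#' Canonical network partition of components
#'
#' Maps components to the nine intrinsic connectivity networks used
#' throughout the package (CB, DAN, DMN, FPN, LIM, SC, SMN, VAN, VN). For
#' `C = 33` the canonical network sizes are used (CB 1, DAN 1, DMN 5, FPN 3,
#' LIM 6, SC 6, SMN 3, VAN 2, VN 6); for other `C` the components are
#' distributed over the nine labels as evenly as possible, preserving order.
#'
#' @param C number of components.
#' @return named character vector of length `C`; names are component ids
#'   (`"C01"`, ...), values are network labels.
#' @export
default_network_partition <- function(C = 33) {
  stopifnot(C >= 1)
  labels <- c("CB", "DAN", "DMN", "FPN", "LIM", "SC", "SMN", "VAN", "VN")
  if (C == 33) {
    sizes <- c(CB = 1, DAN = 1, DMN = 5, FPN = 3, LIM = 6, SC = 6,
               SMN = 3, VAN = 2, VN = 6)
  } else {
    n_net <- min(C, length(labels))
    base <- C %/% n_net
    extra <- C %% n_net
    sizes <- rep(base, n_net) + c(rep(1, extra), rep(0, n_net - extra))
    names(sizes) <- labels[seq_len(n_net)]
  }
  part <- rep(names(sizes), times = sizes)
  names(part) <- sprintf("C%02d", seq_len(C))
  part
}

# nearest-PSD repair: clip eigenvalues at a small floor, rebuild, rescale to
# unit diagonal
nearest_psd_correlation <- function(M, eig_floor = 1e-6) {
  e <- eigen(M, symmetric = TRUE)
  if (min(e$values) >= 0) return(M)
  vals <- pmax(e$values, eig_floor)
  R <- e$vectors %*% (vals * t(e$vectors))
  d <- 1 / sqrt(diag(R))
  R <- R * tcrossprod(d)
  0.5 * (R + t(R))
}

#' Construct a block-structured state covariance
#'
#' Builds a correlation-scale covariance matrix for one connectivity state.
#' `within_dominant` places correlation `strength` between components of the
#' same network and ~0 elsewhere; `inter_dominant` places `strength` between
#' components of *different* networks within the designated set
#' `inter_networks` and ~0 elsewhere. If the raw block pattern is indefinite
#' it is repaired to the nearest unit-diagonal PSD matrix by eigenvalue
#' clipping, which preserves the dominant block structure.
#'
#' @param C number of components.
#' @param network_partition named character vector mapping components to
#'   networks (see [default_network_partition()]).
#' @param style `"within_dominant"` or `"inter_dominant"`.
#' @param strength block correlation magnitude in `(0, 1)`; `0` yields the
#'   identity.
#' @param inter_networks networks whose mutual (cross-network) connectivity
#'   carries the signal for `inter_dominant`.
#' @param label 1-based state index stored on the result.
#' @return object of class `state_cov` with fields `label`, `matrix`,
#'   `description`.
#' @export
make_state_covariances <- function(C, network_partition,
                                   style = c("within_dominant", "inter_dominant"),
                                   strength,
                                   inter_networks = c("SMN", "VN", "DAN", "VAN"),
                                   label = 1L) {
  style <- match.arg(style)
  stopifnot(C >= 2, length(network_partition) == C,
            strength >= 0, strength < 1)
  net <- unname(network_partition)
  M <- diag(C)
  if (strength > 0) {
    same_net <- outer(net, net, "==")
    if (style == "within_dominant") {
      M[same_net & !diag(C)] <- strength
    } else {
      in_set <- net %in% inter_networks
      cross <- outer(in_set, in_set, "&") & !same_net
      M[cross] <- strength
    }
  }
  M <- nearest_psd_correlation(M)
  ev <- eigen(M, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8) {
    stop("state covariance not PSD after repair; eigenvalues: ",
         paste(signif(ev, 4), collapse = ", "))
  }
  structure(list(label = as.integer(label), matrix = M,
                 description = style),
            class = "state_cov")
}

#' Default two-state covariance set
#'
#' The package's default generative states: State 1 is inter-network
#' dominant (positive connectivity between SMN, VN, DAN and VAN), State 2 is
#' within-network dominant (positive connectivity inside every network
#' block). Strengths are chosen for recoverability by the windowed pipeline,
#' not to match any empirical connectivity values.
#'
#' @param C number of components.
#' @param network_partition component-to-network map.
#' @param strength_inter,strength_within block correlation magnitudes.
#' @return list of two `state_cov` objects.
#' @export
default_state_covariances <- function(C = 33,
                                      network_partition = default_network_partition(C),
                                      strength_inter = 0.35,
                                      strength_within = 0.5) {
  list(
    make_state_covariances(C, network_partition, "inter_dominant",
                           strength_inter, label = 1L),
    make_state_covariances(C, network_partition, "within_dominant",
                           strength_within, label = 2L)
  )
}

#' Markov chain parameters for the hidden state process
#'
#' @param stay_prob per-state self-transition probability in `(0, 1]`; the
#'   number of states is `length(stay_prob)`. Off-diagonal mass is spread
#'   uniformly, so the expected dwell time of state `s` is
#'   `1 / (1 - stay_prob[s])`.
#' @param transition_matrix optional explicit row-stochastic k x k matrix
#'   overriding the uniform off-diagonal construction.
#' @param initial_dist optional initial distribution; defaults to the
#'   stationary distribution of the chain.
#' @return object of class `markov_params`.
#' @export
markov_params <- function(stay_prob, transition_matrix = NULL, initial_dist = NULL) {
  k <- length(stay_prob)
  stopifnot(k >= 1, all(stay_prob > 0), all(stay_prob <= 1))
  if (is.null(transition_matrix)) {
    P <- diag(stay_prob, k)
    if (k > 1) {
      for (s in seq_len(k)) {
        off <- (1 - stay_prob[s]) / (k - 1)
        P[s, -s] <- off
      }
    } else {
      P <- matrix(1, 1, 1)
    }
  } else {
    P <- transition_matrix
    stopifnot(nrow(P) == k, ncol(P) == k)
  }
  if (any(P < 0) || any(abs(rowSums(P) - 1) > 1e-12)) {
    stop("transition matrix is not row-stochastic")
  }
  if (is.null(initial_dist)) {
    # stationary distribution: left eigenvector of P for eigenvalue 1
    e <- eigen(t(P))
    i <- which.min(abs(e$values - 1))
    v <- abs(Re(e$vectors[, i]))
    initial_dist <- v / sum(v)
  }
  stopifnot(length(initial_dist) == k, all(initial_dist >= 0),
            abs(sum(initial_dist) - 1) < 1e-8)
  structure(list(k_states = k, stay_prob = stay_prob,
                 transition_matrix = P,
                 initial_dist = initial_dist / sum(initial_dist)),
            class = "markov_params")
}

#' Cohort specification for the synthetic generator
#'
#' Holds everything that determines a simulated cohort: group definitions
#' (name, size, Markov dynamics), the state covariances, acquisition
#' geometry (`T`, `C`, `TR`), the white-noise level, artifact options, and
#' the master seed. The same spec (including seed) always produces the same
#' cohort.
#'
#' @param groups named list: each element a list with `n_subjects` and
#'   `markov` (a [markov_params()] object); names are group labels
#'   (conventionally HC/SF/NSF).
#' @param states list of `state_cov` objects (all `C` x `C`).
#' @param T_points time points per subject (default 770, i.e. 788 acquired
#'   volumes minus 18 discarded).
#' @param C components (default 33).
#' @param TR repetition time in seconds (default 0.720).
#' @param noise_sd additive white-noise SD relative to unit signal variance.
#' @param artifact_options list with `spike_rate` (per-sample probability),
#'   `spike_amplitude` (in robust-SD units), `drift_coef` (polynomial
#'   coefficients on scaled time, or NULL), `motion_coupling` (gain on
#'   shared motion regressors). All default off.
#' @param network_partition component-to-network map.
#' @param seed master integer seed.
#' @return object of class `cohort_spec`.
#' @export
cohort_spec <- function(groups, states, T_points = 770, C = 33, TR = 0.720,
                        noise_sd = 0.2,
                        artifact_options = list(spike_rate = 0,
                                                spike_amplitude = 6,
                                                drift_coef = NULL,
                                                motion_coupling = 0),
                        network_partition = default_network_partition(C),
                        seed = 1L) {
  stopifnot(length(groups) >= 1)
  if (is.null(names(groups)) || any(!nzchar(names(groups)))) {
    stop("groups must be a named list")
  }
  if (anyDuplicated(names(groups))) stop("duplicate group names")
  k_set <- unique(vapply(groups, function(g) g$markov$k_states, integer(1)))
  if (length(k_set) != 1) stop("all groups must share k_states")
  if (length(states) != k_set) stop("number of states must match k_states")
  for (s in states) stopifnot(inherits(s, "state_cov"), nrow(s$matrix) == C)
  stopifnot(T_points >= 1, C >= 2, TR > 0, noise_sd >= 0,
            length(network_partition) == C)
  defaults <- list(spike_rate = 0, spike_amplitude = 6, drift_coef = NULL,
                   motion_coupling = 0)
  artifact_options <- utils::modifyList(defaults, artifact_options)
  structure(list(groups = groups, states = states, T_points = T_points,
                 C = C, TR = TR, noise_sd = noise_sd,
                 artifact_options = artifact_options,
                 network_partition = network_partition,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Default three-group cohort specification
#'
#' Default study conditions: groups HC (n = 51), SF (n = 39) and NSF
#' (n = 16), T = 770 time points, C = 33 components at TR = 0.720 s,
#' two generative states (inter- vs within-network dominant), white noise
#' SD 0.2. Group dynamics differ only in state persistence: NSF is the most
#' State-2-dominant, HC the least, mirroring the direction of the group
#' effect the pipeline is designed to detect.
#'
#' @param C components; @param T_points time points; @param seed master seed.
#' @param n_per_group optional single size overriding all three group sizes.
#' @param stay_probs named list of per-group length-2 stay-probability
#'   vectors.
#' @param noise_sd white-noise SD.
#' @return `cohort_spec` object.
#' @export
default_cohort_spec <- function(C = 33, T_points = 770, seed = 1L,
                                n_per_group = NULL,
                                stay_probs = list(HC = c(0.97, 0.98),
                                                  SF = c(0.96, 0.985),
                                                  NSF = c(0.95, 0.99)),
                                noise_sd = 0.2) {
  sizes <- if (is.null(n_per_group)) {
    c(HC = 51L, SF = 39L, NSF = 16L)[names(stay_probs)]
  } else {
    stats::setNames(rep(as.integer(n_per_group), length(stay_probs)),
                    names(stay_probs))
  }
  groups <- lapply(names(stay_probs), function(g) {
    list(n_subjects = unname(sizes[[g]]), markov = markov_params(stay_probs[[g]]))
  })
  names(groups) <- names(stay_probs)
  cohort_spec(groups = groups,
              states = default_state_covariances(C),
              T_points = T_points, C = C, seed = seed, noise_sd = noise_sd)
}

#' Simulate a hidden Markov state sequence
#'
#' @param params [markov_params()] object.
#' @param T_points sequence length.
#' @param seed optional integer seed (set before drawing).
#' @return integer vector of length `T_points` with labels in `1..k`.
#' @export
simulate_state_sequence <- function(params, T_points, seed = NULL) {
  stopifnot(inherits(params, "markov_params"), T_points >= 1)
  if (!is.null(seed)) set.seed(seed)
  k <- params$k_states
  s <- integer(T_points)
  s[1] <- sample.int(k, 1, prob = params$initial_dist)
  if (T_points > 1) {
    u <- stats::runif(T_points - 1)
    cum <- t(apply(params$transition_matrix, 1, cumsum))
    for (t in 2:T_points) {
      s[t] <- findInterval(u[t - 1], cum[s[t - 1], ]) + 1L
    }
  }
  s
}

#' Simulate one subject's component time courses
#'
#' Draws the subject's hidden state sequence, then at each time point draws
#' the `C`-vector signal from a zero-mean multivariate normal with the
#' active state's covariance, adds white noise, and applies any configured
#' artifacts (spikes, polynomial drift, motion coupling).
#'
#' @param spec `cohort_spec`.
#' @param group group name (must exist in `spec$groups`).
#' @param seed integer seed for this subject.
#' @param subject_id subject identifier.
#' @return list with `tc` (a [component_timecourses()] object), `states`
#'   (ground-truth sequence), `motion` (T x 6 matrix or NULL).
#' @export
simulate_subject <- function(spec, group, seed, subject_id = group) {
  stopifnot(inherits(spec, "cohort_spec"), group %in% names(spec$groups))
  set.seed(seed)
  Tn <- spec$T_points
  C <- spec$C
  states <- simulate_state_sequence(spec$groups[[group]]$markov, Tn)
  chol_list <- lapply(spec$states, function(s) chol(s$matrix + 1e-10 * diag(C)))
  E <- matrix(stats::rnorm(Tn * C), Tn, C)
  X <- matrix(0, Tn, C)
  for (s in seq_along(chol_list)) {
    rows <- which(states == s)
    if (length(rows)) X[rows, ] <- E[rows, , drop = FALSE] %*% chol_list[[s]]
  }
  if (spec$noise_sd > 0) X <- X + spec$noise_sd * matrix(stats::rnorm(Tn * C), Tn, C)

  ao <- spec$artifact_options
  motion <- NULL
  if (isTRUE(ao$motion_coupling > 0)) {
    motion <- apply(matrix(stats::rnorm(Tn * 6, sd = 0.02), Tn, 6), 2, cumsum)
    X <- X + ao$motion_coupling * motion %*% matrix(stats::rnorm(6 * C, sd = 1), 6, C)
  }
  if (!is.null(ao$drift_coef) && length(ao$drift_coef) > 0) {
    tt <- seq(0, 1, length.out = Tn)
    drift <- rowSums(sapply(seq_along(ao$drift_coef),
                            function(p) ao$drift_coef[p] * tt^p))
    X <- X + drift
  }
  if (isTRUE(ao$spike_rate > 0)) {
    hits <- which(matrix(stats::runif(Tn * C), Tn, C) < ao$spike_rate)
    X[hits] <- X[hits] + ao$spike_amplitude * sign(stats::rnorm(length(hits)))
  }

  tc <- component_timecourses(subject_id = subject_id, data = X, TR = spec$TR,
                              network_of = spec$network_partition)
  list(tc = tc, states = states, motion = motion)
}

#' Simulate a whole cohort
#'
#' Applies [simulate_subject()] per subject with per-subject seeds derived
#' deterministically from the cohort seed, so the cohort is a pure function
#' of its spec.
#'
#' @param spec `cohort_spec`.
#' @return object of class `dfnc_cohort`: list with `subjects` (named list
#'   of `component_timecourses`), `truth` (per-subject ground-truth state
#'   sequences and group labels), `groups` (named character vector
#'   subject -> group), `spec`.
#' @export
simulate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (length(spec$groups) == 0) stop("empty group list")
  subjects <- list()
  truth <- list()
  groups <- character(0)
  idx <- 0L
  for (g in names(spec$groups)) {
    n <- spec$groups[[g]]$n_subjects
    stopifnot(n >= 1)
    for (i in seq_len(n)) {
      idx <- idx + 1L
      sid <- sprintf("%s%02d", g, i)
      if (sid %in% names(subjects)) stop("duplicate subject id: ", sid)
      sim <- simulate_subject(spec, g, seed = derive_seed(spec$seed, idx),
                              subject_id = sid)
      subjects[[sid]] <- sim$tc
      truth[[sid]] <- sim$states
      groups[sid] <- g
    }
  }
  structure(list(subjects = subjects, truth = truth, groups = groups,
                 spec = spec),
            class = "dfnc_cohort")
}

#' @export
print.dfnc_cohort <- function(x, ...) {
  cat("dfnc_cohort:", length(x$subjects), "subjects,",
      x$spec$T_points, "time points x", x$spec$C, "components, TR",
      x$spec$TR, "s\n")
  print(table(x$groups))
  invisible(x)
}

#' Write a cohort to disk
#'
#' One TSV matrix (T x C, header = component ids) per subject, one
#' ground-truth state-sequence TSV per subject, and a JSON manifest with the
#' spec summary, seeds and file list.
#'
#' @param cohort `dfnc_cohort`; @param dir output directory.
#' @return the manifest path, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- list()
  for (sid in names(cohort$subjects)) {
    tc <- cohort$subjects[[sid]]
    fp <- file.path(dir, paste0(sid, "_timecourses.tsv"))
    m <- tc$data
    colnames(m) <- tc$component_ids
    write_tsv_matrix(m, fp)
    gp <- file.path(dir, paste0(sid, "_states.tsv"))
    utils::write.table(data.frame(state = cohort$truth[[sid]]), gp,
                       sep = "\t", quote = FALSE, row.names = FALSE)
    files[[sid]] <- list(timecourses = basename(fp), states = basename(gp),
                         group = unname(cohort$groups[[sid]]))
  }
  manifest <- list(
    T_points = cohort$spec$T_points, C = cohort$spec$C, TR = cohort$spec$TR,
    noise_sd = cohort$spec$noise_sd, seed = cohort$spec$seed,
    network_partition = as.list(cohort$spec$network_partition),
    subjects = files)
  mp <- file.path(dir, "cohort_manifest.json")
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(mp)
}

#' Simulate per-subject state-mean connectivity vectors directly
#'
#' A light-weight generator operating at the level `group_stats` consumes:
#' each subject's per-state mean Fisher-z connectivity vector is the state's
#' base pattern plus independent subject-level noise, with an optional
#' additive z-shift on selected pairs for one group (for power studies).
#' Identical `shift = NULL` across groups gives exchangeable (null) groups.
#'
#' @param patterns k x P matrix of base state patterns (Fisher-z units).
#' @param n_per_group named integer vector of group sizes.
#' @param noise_sd subject-level between-subject SD per pair.
#' @param shift optional list(`group`, `state`, `pairs`, `delta`).
#' @param seed integer seed.
#' @return list with `fc` (list per state: n_subjects x P matrix) and
#'   `groups` (factor of length n_subjects).
#' @export
simulate_state_fc_cohort <- function(patterns, n_per_group, noise_sd = 0.2,
                                     shift = NULL, seed = 1L) {
  set.seed(seed)
  k <- nrow(patterns)
  P <- ncol(patterns)
  n_tot <- sum(n_per_group)
  groups <- factor(rep(names(n_per_group), times = n_per_group),
                   levels = names(n_per_group))
  fc <- lapply(seq_len(k), function(s) {
    M <- matrix(rep(patterns[s, ], each = n_tot), n_tot, P) +
      matrix(stats::rnorm(n_tot * P, sd = noise_sd), n_tot, P)
    rownames(M) <- paste0(as.character(groups), seq_len(n_tot))
    M
  })
  if (!is.null(shift)) {
    rows <- which(groups == shift$group)
    fc[[shift$state]][rows, shift$pairs] <-
      fc[[shift$state]][rows, shift$pairs] + shift$delta
  }
  list(fc = fc, groups = groups)
}
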