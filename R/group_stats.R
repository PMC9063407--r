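# Group statistics: pooled two-sample t, one-way ANOVA with gated post hoc
# t-tests, Pearson chi-square without continuity correction, BH-FDR, and
# the per-pair connectivity-strength comparison across groups.

#' Two-sample t-test
#'
#' Pooled-variance Student t by default (Welch with `equal_var = FALSE`),
#' two-sided. Zero combined variance returns the `t = 0, p = 1` convention
#' with a `degenerate` flag.
#'
#' @param x,y numeric samples (each n >= 2).
#' @param equal_var pooled-variance assumption (default TRUE).
#' @return list with `t`, `df`, `p`, `degenerate`.
#' @export
two_sample_t <- function(x, y, equal_var = TRUE) {
  stopifnot(length(x) >= 2, length(y) >= 2)
  if (stats::var(x) + stats::var(y) == 0) {
    return(list(t = 0, df = length(x) + length(y) - 2, p = 1,
                degenerate = TRUE))
  }
  ht <- stats::t.test(x, y, var.equal = equal_var)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value, degenerate = FALSE)
}

#' One-way ANOVA with gated post hoc t-tests
#'
#' Standard between/within decomposition across `length(groups)` levels.
#' Post hoc pairwise (pooled) t-tests are computed only when the omnibus p
#' is below `alpha`. All-identical data returns the `F = 0, p = 1`
#' convention.
#'
#' @param groups list of numeric samples (each n >= 2).
#' @param alpha significance gate for the post hoc tests (default 0.05).
#' @param posthoc run pairwise t-tests when the omnibus is significant.
#' @return list with `F`, `df1`, `df2`, `p`, and (when gated in) `posthoc`,
#'   a data.frame of pairwise comparisons.
#' @export
one_way_anova <- function(groups, alpha = 0.05, posthoc = TRUE) {
  if (length(groups) < 2) stop("need at least 2 groups")
  stopifnot(all(vapply(groups, length, integer(1)) >= 2))
  if (is.null(names(groups))) names(groups) <- paste0("g", seq_along(groups))
  y <- unlist(groups, use.names = FALSE)
  g <- factor(rep(names(groups), times = vapply(groups, length, integer(1))),
              levels = names(groups))
  df1 <- nlevels(g) - 1
  df2 <- length(y) - nlevels(g)
  if (stats::var(y) == 0) {
    return(list(F = 0, df1 = df1, df2 = df2, p = 1, degenerate = TRUE))
  }
  ht <- stats::oneway.test(y ~ g, var.equal = TRUE)
  out <- list(F = unname(ht$statistic), df1 = unname(ht$parameter[1]),
              df2 = unname(ht$parameter[2]), p = ht$p.value,
              degenerate = FALSE)
  if (posthoc && out$p < alpha) {
    combs <- utils::combn(names(groups), 2)
    ph <- apply(combs, 2, function(pr) {
      tt <- two_sample_t(groups[[pr[1]]], groups[[pr[2]]])
      data.frame(group1 = pr[1], group2 = pr[2], t = tt$t, p = tt$p)
    })
    out$posthoc <- do.call(rbind, ph)
  }
  out
}

#' Pearson chi-square test
#'
#' `X^2 = sum (O - E)^2 / E` with expected counts from the margins and
#' `df = (r-1)(c-1)`; no continuity correction. Rows or columns with zero
#' margins are dropped with a warning.
#'
#' @param table r x c matrix of non-negative counts.
#' @return list with `x2`, `df`, `p`.
#' @export
pearson_chi_square <- function(table) {
  table <- as.matrix(table)
  stopifnot(all(table >= 0), sum(table) > 0)
  zr <- rowSums(table) == 0
  zc <- colSums(table) == 0
  if (any(zr) || any(zc)) {
    warning("dropping ", sum(zr), " zero-margin row(s) and ", sum(zc),
            " zero-margin column(s)")
    table <- table[!zr, !zc, drop = FALSE]
  }
  if (nrow(table) < 2 || ncol(table) < 2) stop("need a 2x2 or larger table")
  ht <- suppressWarnings(stats::chisq.test(table, correct = FALSE))
  list(x2 = unname(ht$statistic), df = unname(ht$parameter), p = ht$p.value)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values: sort ascending, `adj_(i) = min_{j>=i}
#' (p_(j) * m / j)` capped at 1, original order restored.
#'
#' @param p_values raw p-values in `[0, 1]`.
#' @return adjusted p-values, same order.
#' @export
bh_fdr <- function(p_values) {
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(p_values, method = "BH")
}

#' Per-pair connectivity-strength comparison across groups
#'
#' For each state and each connectivity pair, compares the per-subject
#' state-mean Fisher-z values across groups: three-or-more groups use the
#' one-way ANOVA, two groups the pooled t-test. Raw p-values are BH-FDR
#' adjusted within each state's family of P pairs; post hoc pairwise
#' t-tests are run for pairs whose adjusted p survives `alpha`. Subjects
#' appear in a state's comparison only if they entered the state; a state
#' with fewer than 2 subjects in any group is skipped with a warning.
#'
#' @param fc_by_state list per state: n_subjects x P matrix of state-mean
#'   Fisher-z vectors (rows = subjects entering the state).
#' @param groups_by_state list per state: factor of group labels aligned
#'   with the rows of `fc_by_state[[s]]` (a single factor is recycled when
#'   all subjects enter every state).
#' @param alpha significance level (default 0.05).
#' @param pair_table optional [pair_index()] data.frame with network
#'   columns; adds network-block labels to the output.
#' @return list per state: data.frame with per-pair statistic, raw and
#'   adjusted p, significance flag, per-group means and n, plus a `posthoc`
#'   attribute (data.frame of pairwise t-tests for surviving pairs).
#' @export
pairwise_state_strength_comparison <- function(fc_by_state, groups_by_state,
                                               alpha = 0.05,
                                               pair_table = NULL) {
  if (is.factor(groups_by_state)) {
    groups_by_state <- rep(list(groups_by_state), length(fc_by_state))
  }
  stopifnot(length(fc_by_state) == length(groups_by_state))
  out <- vector("list", length(fc_by_state))
  names(out) <- paste0("state", seq_along(fc_by_state))
  for (s in seq_along(fc_by_state)) {
    M <- as.matrix(fc_by_state[[s]])
    g <- droplevels(as.factor(groups_by_state[[s]]))
    stopifnot(nrow(M) == length(g))
    sizes <- table(g)
    if (length(sizes) < 2 || any(sizes < 2)) {
      warning("state ", s, ": fewer than 2 subjects in some group; skipped")
      next
    }
    P <- ncol(M)
    two_groups <- nlevels(g) == 2
    stat <- raw_p <- numeric(P)
    for (q in seq_len(P)) {
      vals <- split(M[, q], g)
      if (two_groups) {
        tt <- two_sample_t(vals[[1]], vals[[2]])
        stat[q] <- tt$t; raw_p[q] <- tt$p
      } else {
        av <- one_way_anova(vals, posthoc = FALSE)
        stat[q] <- av$F; raw_p[q] <- av$p
      }
    }
    adj_p <- bh_fdr(raw_p)
    res <- data.frame(pair = seq_len(P), statistic = stat, p = raw_p,
                      p_adj = adj_p, significant = adj_p < alpha)
    if (!is.null(pair_table)) {
      res <- cbind(res, pair_table[, setdiff(names(pair_table), "pair"),
                                   drop = FALSE])
    }
    for (lev in levels(g)) {
      res[[paste0("mean_", lev)]] <- colMeans(M[g == lev, , drop = FALSE])
      res[[paste0("n_", lev)]] <- sum(g == lev)
    }
    ph <- NULL
    if (any(res$significant) && !two_groups) {
      combs <- utils::combn(levels(g), 2)
      ph <- do.call(rbind, lapply(which(res$significant), function(q) {
        vals <- split(M[, q], g)
        do.call(rbind, apply(combs, 2, function(pr) {
          tt <- two_sample_t(vals[[pr[1]]], vals[[pr[2]]])
          data.frame(pair = q, group1 = pr[1], group2 = pr[2],
                     t = tt$t, p = tt$p)
        }))
      }))
    }
    attr(res, "posthoc") <- ph
    out[[s]] <- res
  }
  out
}

#' Per-subject state-mean connectivity vectors
#'
#' Averages each subject's Fisher-z windows within each assigned state,
#' producing the inputs of [pairwise_state_strength_comparison()].
#'
#' @param wfc_list list of `windowed_fc` objects.
#' @param sequences named list of per-subject state label sequences.
#' @param k number of states.
#' @param groups named character vector subject -> group.
#' @return list with `fc_by_state` (per state: matrix of subjects entering
#'   it) and `groups_by_state` (per state: aligned group factor).
#' @export
subject_state_mean_fc <- function(wfc_list, sequences, k, groups) {
  glev <- unique(unname(groups))
  fc_by_state <- vector("list", k)
  groups_by_state <- vector("list", k)
  for (s in seq_len(k)) {
    rows <- list()
    gs <- character(0)
    for (w in wfc_list) {
      sid <- w$subject_id
      seq_s <- sequences[[sid]]
      sel <- which(seq_s == s)
      if (length(sel) == 0) next
      rows[[sid]] <- colMeans(w$z[sel, , drop = FALSE])
      gs <- c(gs, unname(groups[[sid]]))
    }
    fc_by_state[[s]] <- do.call(rbind, rows)
    groups_by_state[[s]] <- factor(gs, levels = glev)
  }
  list(fc_by_state = fc_by_state, groups_by_state = groups_by_state)
}

#' Group comparison of temporal properties
#'
#' Applies the ANOVA -> post hoc -> FDR pattern to each temporal metric
#' (per-state fractional windows, per-state mean dwell time, number of
#' transitions, directional transition counts) across groups. Dwell-time
#' comparisons drop subjects that never entered the state.
#'
#' @param tbl cohort table from [cohort_temporal_table()].
#' @param alpha significance level.
#' @return data.frame: metric, F (or t), raw p, BH-adjusted p across the
#'   metric family, significance flag.
#' @export
compare_temporal_properties <- function(tbl, alpha = 0.05) {
  metrics <- setdiff(names(tbl), c("subject", "group"))
  g <- factor(tbl$group)
  rows <- lapply(metrics, function(m) {
    vals <- split(tbl[[m]], g)
    vals <- lapply(vals, function(v) v[!is.na(v)])
    if (any(vapply(vals, length, integer(1)) < 2)) {
      return(data.frame(metric = m, statistic = NA, p = NA))
    }
    if (length(vals) == 2) {
      tt <- two_sample_t(vals[[1]], vals[[2]])
      data.frame(metric = m, statistic = tt$t, p = tt$p)
    } else {
      av <- one_way_anova(vals, posthoc = FALSE)
      data.frame(metric = m, statistic = av$F, p = av$p)
    }
  })
  out <- do.call(rbind, rows)
  out$p_adj <- NA_real_
  ok <- !is.na(out$p)
  out$p_adj[ok] <- bh_fdr(out$p[ok])
  out$significant <- !is.na(out$p_adj) & out$p_adj < alpha
  out
}
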