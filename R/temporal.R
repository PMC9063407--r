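# Per-subject state temporal properties: fractional windows, mean dwell
# time, transition counts, and the per-group state-entry table.

check_labels <- function(seq, k) {
  seq <- as.integer(seq)
  if (length(seq) < 1) stop("empty state sequence")
  if (any(seq < 1 | seq > k)) stop("labels outside 1..k")
  seq
}

#' Fractional windows per state
#'
#' Proportion of a subject's windows spent in each state.
#'
#' @param seq state label sequence; @param k number of states.
#' @return named numeric vector of length k summing to 1.
#' @export
fractional_windows <- function(seq, k) {
  seq <- check_labels(seq, k)
  stats::setNames(tabulate(seq, k) / length(seq), paste0("state", seq_len(k)))
}

# maximal constant runs of a sequence: data.frame(state, length)
state_runs <- function(seq) {
  r <- rle(as.integer(seq))
  data.frame(state = r$values, length = r$lengths)
}

#' Mean dwell time per state
#'
#' Mean length (in windows) of the maximal constant runs of each state;
#' `NA` for states the subject never enters (the dwell time of an unvisited
#' state is undefined, not zero). Multiply by `step * TR` for seconds.
#'
#' @param seq state label sequence; @param k number of states.
#' @return named numeric vector of length k (NA where unentered).
#' @export
mean_dwell_time <- function(seq, k) {
  seq <- check_labels(seq, k)
  runs <- state_runs(seq)
  out <- rep(NA_real_, k)
  agg <- tapply(runs$length, factor(runs$state, levels = seq_len(k)), mean)
  out[!is.na(agg)] <- agg[!is.na(agg)]
  stats::setNames(out, paste0("state", seq_len(k)))
}

#' Transition counts
#'
#' Total number of consecutive-window state changes plus the directional
#' k x k count matrix (`[i, j]` = number of i -> j changes, zero diagonal).
#'
#' @param seq state label sequence; @param k number of states (default
#'   `max(seq)`).
#' @return list with `total` and `directional` (k x k integer matrix).
#' @export
count_transitions <- function(seq, k = max(seq)) {
  seq <- check_labels(seq, k)
  D <- matrix(0L, k, k)
  if (length(seq) > 1) {
    from <- seq[-length(seq)]
    to <- seq[-1]
    chg <- from != to
    if (any(chg)) {
      tab <- table(factor(from[chg], levels = seq_len(k)),
                   factor(to[chg], levels = seq_len(k)))
      D <- matrix(as.integer(tab), k, k)
    }
  }
  list(total = sum(D), directional = D)
}

#' All temporal properties for one subject
#'
#' @param seq state label sequence; @param k number of states.
#' @param TR repetition time in seconds; @param step window step in TRs.
#' @param subject_id identifier carried into the result.
#' @return object of class `temporal_properties`: `fractional_windows`,
#'   `mean_dwell` (windows), `mean_dwell_seconds`, `n_transitions`,
#'   `directional_counts`, `entered` (logical per state).
#' @export
temporal_properties <- function(seq, k, TR = 0.720, step = 1,
                                subject_id = "subject") {
  seq <- check_labels(seq, k)
  tr_counts <- count_transitions(seq, k)
  dwell <- mean_dwell_time(seq, k)
  structure(list(subject_id = subject_id,
                 fractional_windows = fractional_windows(seq, k),
                 mean_dwell = dwell,
                 mean_dwell_seconds = dwell * step * TR,
                 n_transitions = tr_counts$total,
                 directional_counts = tr_counts$directional,
                 entered = tabulate(seq, k) > 0),
            class = "temporal_properties")
}

#' Cohort temporal-property table
#'
#' One row per subject with group, per-state fractional windows and mean
#' dwell times (windows), total transitions, and directional counts.
#'
#' @param sequences named list of per-subject state sequences.
#' @param groups named character vector subject -> group.
#' @param k number of states; @param TR,step timing parameters.
#' @return data.frame.
#' @export
cohort_temporal_table <- function(sequences, groups, k, TR = 0.720, step = 1) {
  rows <- lapply(names(sequences), function(sid) {
    tp <- temporal_properties(sequences[[sid]], k, TR, step, sid)
    row <- data.frame(subject = sid, group = unname(groups[[sid]]),
                      n_transitions = tp$n_transitions)
    for (s in seq_len(k)) {
      row[[paste0("frac_state", s)]] <- tp$fractional_windows[s]
      row[[paste0("dwell_state", s)]] <- tp$mean_dwell[s]
    }
    for (i in seq_len(k)) for (j in seq_len(k)) {
      if (i != j) row[[paste0("trans_", i, "_to_", j)]] <- tp$directional_counts[i, j]
    }
    row
  })
  do.call(rbind, rows)
}

#' Per-group state-entry table
#'
#' For each group and state: how many subjects entered the state (had at
#' least one window in it) and the percentage of the group, rounded half-up
#' to one decimal.
#'
#' @param sequences named list of per-subject state sequences.
#' @param groups named character vector subject -> group.
#' @param k number of states.
#' @return data.frame with columns `group`, `state`, `n_entered`, `n_group`,
#'   `pct`.
#' @export
state_entry_table <- function(sequences, groups, k) {
  stopifnot(length(sequences) >= 1, all(names(sequences) %in% names(groups)))
  glev <- unique(unname(groups[names(sequences)]))
  rows <- list()
  for (g in glev) {
    sids <- names(sequences)[unname(groups[names(sequences)]) == g]
    for (s in seq_len(k)) {
      n_ent <- sum(vapply(sids, function(sid) any(sequences[[sid]] == s),
                          logical(1)))
      rows[[length(rows) + 1]] <- data.frame(
        group = g, state = s, n_entered = n_ent, n_group = length(sids),
        pct = round_half_up(100 * n_ent / length(sids), 1))
    }
  }
  do.call(rbind, rows)
}
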