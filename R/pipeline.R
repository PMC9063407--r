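# Pipeline orchestration: configuration validation and the end-to-end
# simulate -> postprocess -> windowed FC -> cluster -> temporal metrics ->
# group stats run with TSV/JSON outputs and a manifest.

default_pipeline_config <- function() {
  list(
    TR = 0.720,
    n_discard = 18L,
    window_length = 60L,
    window_step = 1L,
    taper_sigma = 3.0,
    lambda_grid = 10^seq(-3, 0, length.out = 10),
    fixed_lambda = NULL,
    n_cv_folds = 5L,
    k_min = 2L,
    k_max = 10L,
    k_override = NULL,
    replicates = 100L,
    validity_replicates = 5L,
    validity_max_n = 1000L,
    gap_B = 10L,
    alpha = 0.05,
    seed = 1L,
    # synthetic-cohort stage
    simulate = TRUE,
    n_per_group = NULL,      # NULL = default group sizes (HC 51, SF 39, NSF 16)
    C = 33L,
    T_points = 770L,
    noise_sd = 0.2,
    input_dir = NULL,
    output_dir = NULL,
    stages = c("simulate", "postprocess", "dfnc", "cluster", "metrics", "stats")
  )
}

#' Validate a pipeline configuration
#'
#' Reads a JSON (or YAML, by extension) config file or takes a list, fills
#' unset keys with the package defaults (TR = 0.720 s, 18 discarded
#' volumes, window length 60 TRs, step 1, taper SD 3 TRs, k in 2..10,
#' 100 clustering replicates, gap B = 10, alpha = 0.05), and reports all
#' violations at once.
#'
#' @param config path to a config file, a list, or NULL for pure defaults.
#' @return validated config list of class `pipeline_config`.
#' @export
validate_config <- function(config = NULL) {
  if (is.character(config)) {
    raw <- if (file.info(config)$size == 0) {
      list()
    } else if (grepl("\\.ya?ml$", config)) {
      if (!requireNamespace("yaml", quietly = TRUE)) {
        stop("the 'yaml' package is required for YAML configs")
      }
      yaml::read_yaml(config)
    } else {
      jsonlite::read_json(config, simplifyVector = TRUE)
    }
  } else if (is.null(config)) {
    raw <- list()
  } else {
    raw <- config
  }
  cfg <- utils::modifyList(default_pipeline_config(), raw, keep.null = TRUE)

  v <- character(0)
  chk <- function(cond, msg) if (!isTRUE(cond)) v <<- c(v, msg)
  chk(is_scalar_number(cfg$TR) && cfg$TR > 0, "TR must be a positive number")
  chk(is_scalar_number(cfg$n_discard) && cfg$n_discard >= 0,
      "n_discard must be non-negative")
  chk(is_scalar_number(cfg$window_length) && cfg$window_length >= 2,
      "window_length must be >= 2")
  chk(is_scalar_number(cfg$window_step) && cfg$window_step >= 1,
      "window_step must be >= 1")
  chk(is_scalar_number(cfg$taper_sigma) && cfg$taper_sigma > 0,
      "taper_sigma must be positive")
  chk(is_scalar_number(cfg$T_points) && cfg$T_points >= cfg$window_length,
      "window_length must not exceed T_points")
  chk(is_scalar_number(cfg$k_min) && is_scalar_number(cfg$k_max) &&
        cfg$k_min >= 2 && cfg$k_max <= 10 && cfg$k_min <= cfg$k_max,
      "k range must lie within [2, 10]")
  chk(is_scalar_number(cfg$replicates) && cfg$replicates >= 1,
      "replicates must be >= 1")
  chk(is_scalar_number(cfg$gap_B) && cfg$gap_B >= 2, "gap_B must be >= 2")
  chk(is_scalar_number(cfg$alpha) && cfg$alpha > 0 && cfg$alpha < 1,
      "alpha must be in (0, 1)")
  chk(is_scalar_number(cfg$seed) && cfg$seed >= 0 &&
        cfg$seed == round(cfg$seed), "seed must be a non-negative integer")
  chk(is_scalar_number(cfg$noise_sd) && cfg$noise_sd >= 0,
      "noise_sd must be non-negative")
  if (!cfg$simulate) {
    chk(!is.null(cfg$input_dir), "input_dir required when simulate is FALSE")
  }
  stop_if_violations(v)
  class(cfg) <- "pipeline_config"
  cfg
}

read_cohort <- function(dir) {
  mp <- file.path(dir, "cohort_manifest.json")
  if (!file.exists(mp)) stop("cohort manifest not found: ", mp)
  man <- jsonlite::read_json(mp, simplifyVector = TRUE)
  part <- unlist(man$network_partition)
  subjects <- list()
  truth <- list()
  groups <- character(0)
  for (sid in names(man$subjects)) {
    entry <- man$subjects[[sid]]
    fp <- file.path(dir, entry$timecourses)
    if (!file.exists(fp)) stop("missing input file: ", fp)
    X <- read_tsv_matrix(fp)
    subjects[[sid]] <- component_timecourses(sid, X, man$TR, network_of = part)
    gp <- file.path(dir, entry$states)
    if (file.exists(gp)) truth[[sid]] <- utils::read.delim(gp)$state
    groups[sid] <- entry$group
  }
  structure(list(subjects = subjects, truth = truth, groups = groups,
                 spec = NULL),
            class = "dfnc_cohort")
}

write_stage <- function(obj, path) {
  if (is.matrix(obj) || is.data.frame(obj)) {
    utils::write.table(obj, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    jsonlite::write_json(obj, path, auto_unbox = TRUE, pretty = TRUE,
                         digits = NA, force = TRUE)
  }
  path
}

#' Run the full DFNC pipeline
#'
#' Executes the enabled stages in order — simulate (or load input),
#' post-process, windowed connectivity, state clustering, temporal metrics,
#' group statistics — writing each stage's tabular outputs (TSV) and
#' metadata (JSON) under `output_dir`, and returns a manifest with the
#' config echo, per-output MD5 hashes, package version, wall-clock time and
#' collected warnings. Identical config and seed give identical outputs.
#'
#' Simulated cohorts are generated at post-discard length (`T_points`), so
#' the initial-volume discard applies only to cohorts loaded from
#' `input_dir`.
#'
#' @param config a `pipeline_config`, config file path, list, or NULL.
#' @return object of class `run_manifest` (invisibly also written to
#'   `manifest.json` under `output_dir`).
#' @export
run_pipeline <- function(config = NULL) {
  cfg <- if (inherits(config, "pipeline_config")) config else validate_config(config)
  t0 <- Sys.time()
  out_dir <- cfg$output_dir
  if (is.null(out_dir)) out_dir <- tempfile("dfnc_run_")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  outputs <- character(0)
  warnings_log <- character(0)
  log_warn <- function(w) {
    warnings_log <<- c(warnings_log, conditionMessage(w))
    invokeRestart("muffleWarning")
  }
  stages_run <- character(0)
  wrap_stage <- function(stage, expr) {
    stages_run <<- c(stages_run, stage)
    withCallingHandlers(
      tryCatch(expr, error = function(e) {
        stop("stage '", stage, "' failed: ", conditionMessage(e), call. = FALSE)
      }),
      warning = log_warn)
  }

  # --- simulate / load -------------------------------------------------
  cohort <- wrap_stage("simulate", {
    if (cfg$simulate && "simulate" %in% cfg$stages) {
      spec <- default_cohort_spec(C = cfg$C, T_points = cfg$T_points,
                                  seed = cfg$seed,
                                  n_per_group = cfg$n_per_group,
                                  noise_sd = cfg$noise_sd)
      co <- simulate_cohort(spec)
      outputs <- c(outputs, write_cohort(co, file.path(out_dir, "cohort")))
      co
    } else {
      read_cohort(cfg$input_dir)
    }
  })
  discard <- if (cfg$simulate) 0L else cfg$n_discard

  # --- postprocess ------------------------------------------------------
  if ("postprocess" %in% cfg$stages) {
    cohort$subjects <- wrap_stage("postprocess", {
      lapply(cohort$subjects, function(tc) {
        postprocess_timecourses(tc, n_discard = discard)
      })
    })
  }

  # --- windowed connectivity -------------------------------------------
  wspec <- window_spec(cfg$window_length, cfg$window_step, cfg$taper_sigma)
  gcfg <- glasso_config(lambda_grid = cfg$lambda_grid,
                        n_cv_folds = cfg$n_cv_folds,
                        fixed_lambda = cfg$fixed_lambda)
  wfc_list <- wrap_stage("dfnc", {
    res <- lapply(seq_along(cohort$subjects), function(i) {
      windowed_fc(cohort$subjects[[i]], wspec, gcfg,
                  seed = derive_seed(cfg$seed, 10000 + i))
    })
    names(res) <- names(cohort$subjects)
    fp <- file.path(out_dir, "lambda_selected.tsv")
    write_stage(data.frame(subject = names(res),
                           lambda = vapply(res, `[[`, numeric(1), "lambda")), fp)
    outputs <- c(outputs, fp)
    res
  })

  # --- clustering -------------------------------------------------------
  assignment <- wrap_stage("cluster", {
    model <- cluster_validity(wfc_list,
                              k_range = seq.int(cfg$k_min, cfg$k_max),
                              B = cfg$gap_B, n_replicates = cfg$replicates,
                              validity_replicates = cfg$validity_replicates,
                              max_n = cfg$validity_max_n,
                              seed = derive_seed(cfg$seed, 20000),
                              override = cfg$k_override)
    asg <- assign_all_windows(wfc_list, model)
    asg <- order_states(asg)
    fp1 <- file.path(out_dir, "validity_curve.tsv")
    write_stage(model$validity, fp1)
    fp2 <- file.path(out_dir, "state_centroids.tsv")
    write_stage(asg$model$centroids, fp2)
    fp3 <- file.path(out_dir, "state_sequences.tsv")
    write_stage(data.frame(subject = asg$subject, label = asg$labels), fp3)
    outputs <- c(outputs, fp1, fp2, fp3)
    asg
  })
  k <- assignment$model$k

  # --- temporal metrics -------------------------------------------------
  metrics <- wrap_stage("metrics", {
    tbl <- cohort_temporal_table(assignment$sequences, cohort$groups, k,
                                 TR = cfg$TR, step = cfg$window_step)
    entry <- state_entry_table(assignment$sequences, cohort$groups, k)
    fp1 <- file.path(out_dir, "temporal_properties.tsv")
    fp2 <- file.path(out_dir, "state_entry.tsv")
    write_stage(tbl, fp1); write_stage(entry, fp2)
    outputs <- c(outputs, fp1, fp2)
    list(table = tbl, entry = entry)
  })

  # --- group statistics -------------------------------------------------
  stats_out <- wrap_stage("stats", {
    med <- state_medians(assignment$z_all, assignment$labels, k,
                         groups = cohort$groups[assignment$subject])
    sm <- subject_state_mean_fc(wfc_list, assignment$sequences, k,
                                cohort$groups)
    ptab <- wfc_list[[1]]$pair_index
    pairs <- pairwise_state_strength_comparison(sm$fc_by_state,
                                                sm$groups_by_state,
                                                alpha = cfg$alpha,
                                                pair_table = ptab)
    tprop <- compare_temporal_properties(metrics$table, alpha = cfg$alpha)
    fps <- character(0)
    for (s in seq_along(pairs)) {
      if (is.null(pairs[[s]])) next
      fp <- file.path(out_dir, sprintf("pairwise_state%d.tsv", s))
      write_stage(pairs[[s]], fp)
      fps <- c(fps, fp)
    }
    fp <- file.path(out_dir, "temporal_comparisons.tsv")
    write_stage(tprop, fp)
    fps <- c(fps, fp)
    fp <- file.path(out_dir, "state_occurrence.tsv")
    write_stage(data.frame(state = seq_len(k), count = med$counts,
                           percent = med$percent), fp)
    outputs <- c(outputs, fps, fp)
    list(pairwise = pairs, temporal = tprop, medians = med)
  })

  # --- manifest ---------------------------------------------------------
  all_files <- list.files(out_dir, recursive = TRUE, full.names = TRUE)
  all_files <- setdiff(all_files, file.path(out_dir, "manifest.json"))
  hashes <- tools::md5sum(all_files)
  manifest <- structure(list(
    config = cfg[setdiff(names(cfg), "output_dir")],
    stages = stages_run,
    outputs = stats::setNames(as.list(unname(hashes)),
                              sub(paste0(out_dir, "/?"), "", names(hashes))),
    package_version = as.character(utils::packageVersion("dfncstates")),
    wall_clock_sec = as.numeric(difftime(Sys.time(), t0, units = "secs")),
    warnings = warnings_log,
    chosen_k = k,
    output_dir = out_dir),
    class = "run_manifest")
  jsonlite::write_json(unclass(manifest), file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       force = TRUE)
  manifest$results <- list(metrics = metrics, stats = stats_out,
                           assignment = assignment)
  invisible(manifest)
}

#' @export
print.run_manifest <- function(x, ...) {
  cat("dfnc pipeline run:", length(x$stages), "stages,",
      length(x$outputs), "outputs, k =", x$chosen_k, "\n")
  cat("  output_dir:", x$output_dir, "\n")
  cat("  wall clock:", round(x$wall_clock_sec, 1), "s;",
      length(x$warnings), "warning(s)\n")
  invisible(x)
}
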