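.default_run_config <- function() {
  list(
    simulator = list(),          # simulator_config() arguments
    pipeline = list(
      modes = c("driver_independent", "driver_dependent"),
      groups = c("extreme", "medium"),
      feature_sets = c("global", "local", "both"),
      windows = c(5, 10, 15),
      preprocess = c("none", "zscore", "pica"),
      variance_levels = seq(50, 100, by = 10),
      classifiers = .classifiers,
      alpha = 0.05,
      cfs_fraction = 0.5,
      repeats = 4,
      folds = 5,
      n_perm = 0,
      paper_faithful = FALSE
    ),
    out_dir = "mindwander_run",
    seed = 1L
  )
}

#' Validate a pipeline run configuration
#'
#' Accepts a YAML file path or a nested list with sections `simulator`
#' (arguments of [simulator_config()]), `pipeline` (grid and
#' cross-validation settings), plus `out_dir` and `seed`. Unknown keys are
#' rejected to guard against typos; missing keys are filled with the default
#' full study design. Non-standard window lengths are accepted with a
#' warning.
#'
#' @param config file path or list; `NULL` or an empty file yields the full
#'   default design.
#' @return an object of class `mw_run_config`.
#' @export
validate_config <- function(config = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  config <- config %||% list()
  if (!is.list(config)) stop("config must be a list or a YAML file")
  defaults <- .default_run_config()
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(defaults, config)

  sim_ok <- names(formals(simulator_config))
  unknown <- setdiff(names(cfg$simulator), sim_ok)
  if (length(unknown))
    stop("unknown simulator key(s): ", paste(unknown, collapse = ", "))
  pipe_ok <- names(defaults$pipeline)
  unknown <- setdiff(names(cfg$pipeline), pipe_ok)
  if (length(unknown))
    stop("unknown pipeline key(s): ", paste(unknown, collapse = ", "))

  cfg$simulator$seed <- cfg$simulator$seed %||% stage_seed(cfg$seed, "simulate")
  # constructing the simulator config applies all its invariant checks
  sim <- do.call(simulator_config, cfg$simulator)
  if (!all(cfg$pipeline$windows %in% c(5, 10, 15)))
    warning("non-standard window length(s): ",
            paste(setdiff(cfg$pipeline$windows, c(5, 10, 15)), collapse = ", "))
  stopifnot(cfg$pipeline$folds >= 2, cfg$pipeline$repeats >= 1,
            cfg$pipeline$alpha > 0, cfg$pipeline$alpha < 1,
            cfg$pipeline$cfs_fraction > 0, cfg$pipeline$cfs_fraction <= 1)
  cfg$simulator_config <- sim
  class(cfg) <- "mw_run_config"
  cfg
}

#' Run the full experiment pipeline
#'
#' Simulate the cohort, write the session files, assign MW-proportion
#' groups, run the requested driver-independent and driver-dependent grids,
#' and write the result tables plus a JSON manifest. Stage seeds are derived
#' from the master seed by [stage_seed()], so every output is reproducible
#' from the manifest alone.
#'
#' @param config an `mw_run_config` from [validate_config()], or anything
#'   that function accepts.
#' @return the output directory, invisibly; result tables are written under
#'   `<out_dir>/reports/`.
#' @export
run_experiment <- function(config = NULL) {
  if (!inherits(config, "mw_run_config")) config <- validate_config(config)
  out <- config$out_dir
  dir.create(file.path(out, "reports"), recursive = TRUE, showWarnings = FALSE)

  cohort <- generate_cohort(config$simulator_config)
  write_sessions(cohort, file.path(out, "sessions"))
  groups <- assign_groups(cohort)
  utils::write.csv(groups, file.path(out, "reports", "groups.csv"),
                   row.names = FALSE)

  pp <- config$pipeline
  summary <- list()
  if ("driver_independent" %in% pp$modes) {
    for (grp in pp$groups) {
      if (!any(groups$group == grp)) next
      for (fs in pp$feature_sets) {
        res <- run_grid(cohort, "driver_independent", group = grp,
                        feature_set = fs, windows = pp$windows,
                        preprocess = pp$preprocess,
                        variance_levels = pp$variance_levels,
                        classifiers = pp$classifiers, alpha = pp$alpha,
                        paper_faithful = pp$paper_faithful,
                        n_perm = pp$n_perm,
                        seed = stage_seed(config$seed, paste0("fit-", grp, "-", fs)))
        rep <- build_report(res, "driver_independent")
        tag <- paste0("independent_", grp, "_", fs)
        utils::write.csv(res$evals,
                         file.path(out, "reports", paste0(tag, "_grid.csv")),
                         row.names = FALSE)
        summary[[tag]] <- list(
          best = as.list(rep$best),
          friedman = rep$friedman[c("chisq", "df", "p")],
          best_beats_others = rep$best_beats_others,
          sign_test_p = rep$sign_test_p,
          median_kappa = rep$median_kappa)
      }
    }
  }
  if ("driver_dependent" %in% pp$modes) {
    res <- run_grid(cohort, "driver_dependent", group = "medium",
                    windows = pp$windows, preprocess = pp$preprocess,
                    variance_levels = pp$variance_levels,
                    fraction = pp$cfs_fraction, repeats = pp$repeats,
                    folds = pp$folds, n_perm = pp$n_perm,
                    seed = stage_seed(config$seed, "fit-dependent"))
    if (length(res)) {
      rep <- build_report(res, "driver_dependent")
      utils::write.csv(rep$best,
                       file.path(out, "reports", "dependent_best.csv"),
                       row.names = FALSE)
      utils::write.csv(rep$mean,
                       file.path(out, "reports", "dependent_mean.csv"),
                       row.names = FALSE)
      summary$driver_dependent <- list(
        mean = as.list(rep$mean),
        sign_test_p = as.list(rep$sign_test_p),
        median_kappa = as.list(rep$median_kappa))
    }
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("mindwander")),
    seed = config$seed,
    simulator = unclass(config$simulator_config),
    pipeline = pp)
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  jsonlite::write_json(summary, file.path(out, "reports", "summary.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(out)
}
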