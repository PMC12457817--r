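# Configuration, batch execution and fixture generation. The exported
# functions here are the programmatic CLI surface; inst/cli/drcfit.R is a
# thin Rscript wrapper over them.

#' Read and validate a run configuration
#'
#' Configurations are YAML with fields `mode` (simulate | calibrate |
#' analyze | summarize), `out_dir`, `base_seed`, `workers`, an optional
#' `calibrate` block (`reps`, `target_power`) and a `scenarios` list whose
#' entries hold `dgm_name`, `n` and optionally `method`, `folds`, `library`,
#' `n_reps`. The configuration round-trips losslessly through YAML.
#'
#' @param path YAML file path, or a list already in configuration shape.
#' @return A validated `run_config` object.
#' @export
read_run_config <- function(path) {
  config <- if (is.character(path)) yaml::read_yaml(path) else path
  defaults <- list(
    mode = "simulate", out_dir = "drcfit-results", base_seed = 1L,
    workers = 1L, verbose = TRUE,
    calibrate = list(enabled = FALSE, reps = 400, target_power = 0.80),
    scenarios = list()
  )
  # modifyList recurses into (unnamed) scenario lists and would drop their
  # entries; splice the scenarios back in verbatim
  scenarios <- config$scenarios %||% list()
  config$scenarios <- NULL
  config <- utils::modifyList(defaults, config)
  config$scenarios <- scenarios
  if (!config$mode %in% c("simulate", "calibrate", "analyze", "summarize")) {
    abort_config("mode: must be simulate, calibrate, analyze or summarize")
  }
  assert_scalar_number(config$base_seed, "base_seed")
  assert_scalar_number(config$workers, "workers")
  for (i in seq_along(config$scenarios)) {
    sc <- config$scenarios[[i]]
    for (field in c("dgm_name", "n")) {
      if (is.null(sc[[field]])) {
        abort_config("scenarios[", i, "]$", field, ": field is required")
      }
    }
    if (!sc$dgm_name %in% dgm_names()) {
      abort_config(
        "scenarios[", i, "]$dgm_name: '", sc$dgm_name, "' is not one of ",
        paste(dgm_names(), collapse = ", ")
      )
    }
  }
  structure(config, class = "run_config")
}

#' Write a run configuration to YAML
#' @param config a `run_config` (or plain list).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

scenario_from_config <- function(sc, base_seed) {
  scenario_spec(
    dgm_name = sc$dgm_name, n = sc$n,
    method = sc$method %||% "tmle",
    folds = sc$folds %||% "none",
    library = sc$library %||% "reduced",
    n_reps = sc$n_reps %||% 200,
    base_seed = sc$base_seed %||% base_seed,
    v_folds = sc$v_folds %||% 10
  )
}

scenario_label <- function(spec) {
  sprintf(
    "%s_n%d_%s_%s_%s",
    spec$dgm_name, spec$n, spec$method,
    if (identical(spec$folds, "none")) "cfnone" else paste0("cf", spec$folds),
    if (is.character(spec$library)) spec$library else "custom"
  )
}

#' Run the simulation scenarios of a configuration
#'
#' Executes [run_scenario()] for every scenario entry, optionally calibrating
#' the exposure effect first, computes the empirical truth, writes one
#' replicate-level CSV per scenario plus a long-format summary CSV, and logs
#' per-scenario timing, exclusion counts and seeds.
#'
#' @param config path to a YAML configuration or a `run_config` object.
#' @param truth_n sample size for the empirical truth computation (the full
#'   design uses 1e6; smoke runs may lower it).
#' @return Invisibly, a list with the summary tibble and the output paths.
#' @export
cli_simulate <- function(config, truth_n = 1e6) {
  config <- if (inherits(config, "run_config")) config else read_run_config(config)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_msg <- function(...) if (isTRUE(config$verbose)) message(sprintf(...))
  paths <- character(0)
  perf_rows <- list()
  ids <- list()
  for (sc in config$scenarios) {
    spec <- scenario_from_config(sc, config$base_seed)
    label <- scenario_label(spec)
    t0 <- Sys.time()
    params <- dgm_params(spec$dgm_name)
    if (isTRUE(config$calibrate$enabled)) {
      params <- calibrate_effect(
        params, spec$n,
        target_power = config$calibrate$target_power,
        reps = config$calibrate$reps, seed = config$base_seed,
        n_cal_intercept = max(truth_n, 1e5)
      )
      log_msg(
        "[%s] calibrated beta_x = %.4f (power %.3f)", label,
        params$outcome$beta_x, attr(params, "calibration")$achieved_power
      )
    }
    truth <- true_ace(params, n_truth = truth_n, seed = config$base_seed)
    results <- run_scenario(spec, params, workers = config$workers)
    filt <- if (spec$method == "aipw") {
      stability_filter(results)
    } else {
      list(kept = results[is.na(results$error), , drop = FALSE], n_excluded = 0L)
    }
    perf <- performance(filt$kept, truth$theta, n_excluded = filt$n_excluded)
    path <- file.path(config$out_dir, paste0(label, "_replicates.csv"))
    utils::write.csv(results, path, row.names = FALSE)
    paths <- c(paths, path)
    perf_rows[[label]] <- perf
    ids[[label]] <- tibble::tibble(
      scenario = label, dgm_name = spec$dgm_name, n = spec$n,
      method = spec$method, folds = as.character(spec$folds),
      library = if (is.character(spec$library)) spec$library else "custom",
      theta = truth$theta, base_seed = spec$base_seed
    )
    log_msg(
      "[%s] %d reps, %d excluded, %d failed, %.1fs (seed %d)",
      label, spec$n_reps, filt$n_excluded, sum(!is.na(results$error)),
      as.numeric(difftime(Sys.time(), t0, units = "secs")), spec$base_seed
    )
  }
  summary <- summarize_grid(perf_rows, id = dplyr::bind_rows(ids))
  summary_path <- file.path(config$out_dir, "summary.csv")
  utils::write.csv(summary, summary_path, row.names = FALSE)
  invisible(list(summary = summary, paths = c(paths, summary_path)))
}

#' Analyse a CSV dataset from the command line
#'
#' Thin wrapper over [analyze()]: reads `y, x, w*` CSV data, estimates the
#' ACE, and emits a JSON record with the estimate, 95% CI and
#' propensity-score overlap summary.
#'
#' @param path CSV file path.
#' @param method `"aipw"` or `"tmle"`.
#' @param folds `"none"` or a fold count.
#' @param library library preset name.
#' @param seed integer seed.
#' @param out optional path to write the JSON record to.
#' @return The JSON string, invisibly; also printed to standard output.
#' @export
cli_analyze <- function(path, method = "tmle", folds = "none",
                        library = "reduced", seed = 1, out = NULL) {
  folds_arg <- if (identical(folds, "none")) NULL else as.integer(folds)
  res <- analyze(path, method = method, folds = folds_arg, library = library,
                 seed = seed)
  est <- res$estimate
  record <- list(
    method = est$method,
    folds = if (is.null(est$folds)) "none" else est$folds,
    library = est$library,
    psi = est$psi, se = est$se, ci_low = est$ci_low, ci_high = est$ci_high,
    n = est$n, seed = est$seed,
    ps_by_exposure = res$ps_summary
  )
  json <- jsonlite::toJSON(record, auto_unbox = TRUE, digits = NA)
  cat(json, "\n")
  if (!is.null(out)) writeLines(json, out)
  invisible(json)
}

#' Regenerate the packaged toy fixtures
#'
#' Writes the small plain-text fixtures used across the unit tests: the
#' 6-record AIPW oracle table, the zero-residual 2-record set, and a demo
#' dataset drawn from the `simple-1` mechanism, plus a checksum manifest.
#' Regeneration with the default seed is byte-idempotent.
#'
#' @param dir output directory (default: the package's `extdata` source dir).
#' @param seed integer seed (default 1, the versioned fixture seed).
#' @return Named character vector of md5 checksums, invisibly.
#' @export
make_fixtures <- function(dir = "inst/extdata", seed = 1) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  # 6-record randomized AIPW oracle table
  toy <- with_seed(child_seed(seed, 1L, stream = 50L), data.frame(
    y = round(rnorm(6), 6),
    x = rbinom(6, 1, 0.5),
    e1 = round(rnorm(6, 0.3), 6),
    e0 = round(rnorm(6, -0.2), 6),
    g = round(runif(6, 0.2, 0.8), 6)
  ))
  utils::write.csv(toy, file.path(dir, "aipw_oracle_6.csv"), row.names = FALSE)
  # zero-residual two-record set (Y = E_X exactly, g = 0.5)
  zero <- data.frame(
    y = c(1, 0), x = c(1, 0), e1 = c(1, 1), e0 = c(0, 0), g = c(0.5, 0.5)
  )
  utils::write.csv(zero, file.path(dir, "zero_residual.csv"), row.names = FALSE)
  # demo analysis dataset from the small simple mechanism
  demo <- generate_dataset(dgm_params("simple-1"), 200, child_seed(seed, 2L, stream = 50L))
  df <- as.data.frame(demo)
  df$y <- round(df$y, 6)
  df[-(1:2)] <- lapply(df[-(1:2)], round, 6)
  utils::write.csv(df, file.path(dir, "demo_simple1.csv"), row.names = FALSE)
  files <- file.path(dir, c("aipw_oracle_6.csv", "zero_residual.csv", "demo_simple1.csv"))
  sums <- tools::md5sum(files)
  names(sums) <- basename(names(sums))
  jsonlite::write_json(
    as.list(sums), file.path(dir, "manifest.json"),
    auto_unbox = TRUE, pretty = TRUE
  )
  invisible(sums)
}
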