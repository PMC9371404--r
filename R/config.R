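#' Read and validate a run configuration file
#'
#' A run configuration is a YAML file describing one simulation: the model
#' tag, an optional parameter block (defaults come from the published
#' tables), an optional initial state, a protocol (either inline pulses or
#' a named factory with overrides), integrator settings and classifier
#' tolerances. Unknown keys anywhere in the file are rejected.
#'
#' ```yaml
#' model: fd
#' params: {alpha_ux: 0.45}
#' protocol:
#'   factory: fd_fig3b          # or: pulses/horizon/labels inline
#'   overrides: {duration: 4}
#' integrator: {method: euler, dt: 0.01}
#' tolerances: {tol: 0.05, baseline_eps: 0.05}
#' ```
#'
#' @param path Path to the YAML file.
#' @return A validated `run_config` list with components `model`,
#'   `params`, `state0`, `protocol`, `settings`, `tol`, `baseline_eps`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop_config("config file not found: %s", path)
  raw <- tryCatch(yaml::read_yaml(path), error = function(e) {
    stop_config("could not parse YAML in %s: %s", path, conditionMessage(e))
  })
  validate_run_config(raw)
}

validate_run_config <- function(raw) {
  if (!is.list(raw)) stop_config("run config must be a YAML mapping")
  known <- c("model", "params", "state0", "protocol", "integrator",
             "tolerances")
  bad <- setdiff(names(raw), known)
  if (length(bad) > 0) {
    stop_config("unknown config field(s): %s", paste(bad, collapse = ", "))
  }
  if (is.null(raw$model)) stop_config("config must name a `model`")
  info <- model_info(raw$model)
  params <- params_from_config(raw$params, raw$model)

  prot_cfg <- raw$protocol
  if (is.null(prot_cfg)) stop_config("config must contain a `protocol` block")
  prot <- if (!is.null(prot_cfg$factory)) {
    extra <- setdiff(names(prot_cfg), c("factory", "overrides"))
    if (length(extra) > 0) {
      stop_config("unknown protocol field(s): %s", paste(extra, collapse = ", "))
    }
    factories <- protocol_factories()
    fac <- factories[[prot_cfg$factory]]
    if (is.null(fac)) {
      stop_config("unknown protocol factory `%s` (expected one of: %s)",
                  prot_cfg$factory, paste(names(factories), collapse = ", "))
    }
    overrides <- prot_cfg$overrides
    if (is.null(overrides)) overrides <- list()
    bad_ov <- setdiff(names(overrides), names(formals(fac)))
    if (length(bad_ov) > 0) {
      stop_config("unknown override(s) for factory `%s`: %s",
                  prot_cfg$factory, paste(bad_ov, collapse = ", "))
    }
    if (!is.null(overrides$widened_gaps)) {
      overrides$widened_gaps <- unlist(overrides$widened_gaps)
    }
    do.call(fac, overrides)
  } else {
    protocol_from_config(prot_cfg)
  }
  if (nrow(prot$events) == 0) {
    stop_config("protocol must contain at least one stimulation event")
  }
  if (!setequal(prot$channels, info$channels)) {
    stop_config("protocol channels (%s) do not match model `%s` channels (%s)",
                paste(prot$channels, collapse = ","), raw$model,
                paste(info$channels, collapse = ","))
  }

  state0 <- if (is.null(raw$state0)) {
    default_initial_state(raw$model, params)
  } else {
    s <- unlist(raw$state0)
    # YAML 1.1 resolves a bare `y` key to boolean TRUE; map it back to the
    # response variable so `state0: {y: 0, u: 0, v: 5}` works unquoted
    names(s)[names(s) == "TRUE"] <- "y"
    bad_s <- setdiff(names(s), info$states)
    if (length(bad_s) > 0 || length(s) != length(info$states)) {
      stop_config("`state0` must name exactly the state variables: %s",
                  paste(info$states, collapse = ", "))
    }
    s <- s[info$states]
    if (!all(is.finite(s)) || any(s < 0)) {
      stop_config("`state0` must be finite and non-negative")
    }
    s
  }

  icfg <- raw$integrator
  if (is.null(icfg)) icfg <- list()
  bad_i <- setdiff(names(icfg), c("method", "dt", "record_stride"))
  if (length(bad_i) > 0) {
    stop_config("unknown integrator field(s): %s", paste(bad_i, collapse = ", "))
  }
  settings <- do.call(integrator_settings, icfg)

  tcfg <- raw$tolerances
  if (is.null(tcfg)) tcfg <- list()
  bad_t <- setdiff(names(tcfg), c("tol", "baseline_eps"))
  if (length(bad_t) > 0) {
    stop_config("unknown tolerance field(s): %s", paste(bad_t, collapse = ", "))
  }
  tol <- if (is.null(tcfg$tol)) 0.05 else tcfg$tol
  baseline_eps <- if (is.null(tcfg$baseline_eps)) 0.05 else tcfg$baseline_eps
  check_positive_scalar(tol, "tol", strict = FALSE)
  check_positive_scalar(baseline_eps, "baseline_eps")

  structure(list(model = raw$model, params = params, state0 = state0,
                 protocol = prot, settings = settings,
                 tol = tol, baseline_eps = baseline_eps),
            class = "run_config")
}

#' Run a validated configuration
#'
#' Integrates, extracts the spike table and classifies, logging the full
#' run description (model, parameters, protocol summary, integrator
#' settings, tolerances) through [message()] so a run is auditable from
#' its log.
#'
#' @param config A `run_config` from [read_run_config()].
#' @return List with `trajectory`, `spikes`, `report`.
#' @export
run_simulation <- function(config) {
  if (!inherits(config, "run_config")) {
    stop_config("`config` must come from read_run_config()")
  }
  info <- model_info(config$model)
  message(sprintf("model: %s", config$model))
  message(sprintf("params: %s",
                  paste(names(config$params), unlist(config$params),
                        sep = "=", collapse = ", ")))
  message(sprintf("protocol: %d pulses, %d events, horizon %g",
                  nrow(config$protocol$pulses), nrow(config$protocol$events),
                  config$protocol$horizon))
  message(sprintf("integrator: %s, dt = %g, record_stride = %d",
                  config$settings$method, config$settings$dt,
                  config$settings$record_stride))
  message(sprintf("tolerances: tol = %g, baseline_eps = %g",
                  config$tol, config$baseline_eps))
  run_and_classify(config$model, config$params, config$protocol,
                   state0 = config$state0, settings = config$settings,
                   tol = config$tol, baseline_eps = config$baseline_eps)
}

#' Command back-ends: simulate, reproduce, sweep
#'
#' The functions behind the command-line interface (see
#' `system.file("cli", "assoclearn.R", package = "assoclearn")`). Each
#' writes its outputs (TSV trajectories and spike tables, key-value
#' behaviour reports) into `out_dir` and returns the written paths
#' invisibly. Configuration problems raise `assoclearn_config_error`
#' (CLI exit code 2); numerical failures raise
#' `assoclearn_numeric_error` (exit code 3).
#'
#' @param config_path Path to a YAML run configuration
#'   ([read_run_config()]).
#' @param out_dir Output directory (created if missing).
#' @name cli-commands
NULL

#' @rdname cli-commands
#' @export
cmd_simulate <- function(config_path, out_dir) {
  config <- read_run_config(config_path)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  res <- run_simulation(config)
  paths <- c(
    trajectory = write_trajectory(res$trajectory,
                                  file.path(out_dir, "trajectory.tsv")),
    spikes = write_spike_table(res$spikes, file.path(out_dir, "spikes.tsv")),
    report = write_behavior_report(res$report,
                                   file.path(out_dir, "report.txt"))
  )
  invisible(paths)
}

#' @rdname cli-commands
#' @param scenario Scenario name (see [reproduce_scenario()]).
#' @param settings An [integrator_settings()].
#' @export
cmd_reproduce <- function(scenario, out_dir,
                          settings = integrator_settings()) {
  res <- reproduce_scenario(scenario, settings = settings)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character()
  if (res$kind == "simulation") {
    paths <- c(
      write_trajectory(res$trajectory,
                       file.path(out_dir, paste0(scenario, "_trajectory.tsv"))),
      write_spike_table(res$spikes,
                        file.path(out_dir, paste0(scenario, "_spikes.tsv"))),
      write_behavior_report(res$report,
                            file.path(out_dir, paste0(scenario, "_report.txt")))
    )
  } else if (res$kind == "sweep") {
    paths <- write_spike_table(res$table,
                               file.path(out_dir, paste0(scenario, "_sweep.tsv")))
  } else {
    pc <- res$result
    p1 <- file.path(out_dir, paste0(scenario, "_peaks.tsv"))
    write_spike_table(pc$peaks, p1)
    p2 <- file.path(out_dir, paste0(scenario, "_report.txt"))
    write_behavior_report(pc$perturbed$report, p2)
    p3 <- file.path(out_dir, paste0(scenario, "_base_report.txt"))
    write_behavior_report(pc$base$report, p3)
    paths <- c(p1, p2, p3)
  }
  invisible(paths)
}

#' @rdname cli-commands
#' @export
cmd_sweep <- function(config_path, out_dir) {
  if (!file.exists(config_path)) {
    stop_config("config file not found: %s", config_path)
  }
  raw <- tryCatch(yaml::read_yaml(config_path), error = function(e) {
    stop_config("could not parse YAML in %s: %s", config_path,
                conditionMessage(e))
  })
  grid <- raw$grid
  if (is.null(grid) || !is.list(grid) || length(grid) == 0) {
    stop_config("sweep config must contain a non-empty `grid` block")
  }
  raw$grid <- NULL
  base <- validate_run_config(raw)
  bad <- setdiff(names(grid), names(base$params))
  if (length(bad) > 0) {
    stop_config("grid over unknown parameter(s): %s",
                paste(bad, collapse = ", "))
  }
  grid_df <- expand.grid(lapply(grid, unlist), KEEP.OUT.ATTRS = FALSE)
  if (nrow(grid_df) == 0) stop_config("sweep grid is empty")
  rows <- lapply(seq_len(nrow(grid_df)), function(i) {
    cfg <- params_to_config(base$params)
    for (nm in names(grid_df)) cfg[[nm]] <- grid_df[i, nm]
    p <- params_from_config(cfg, base$model)
    res <- run_and_classify(base$model, p, base$protocol,
                            state0 = base$state0, settings = base$settings,
                            tol = base$tol, baseline_eps = base$baseline_eps)
    rep <- res$report
    cbind(grid_df[i, , drop = FALSE],
          data.frame(learning_formed = rep$learning_formed,
                     reinforced = rep$reinforced,
                     forced_dissociation = rep$forced_dissociation,
                     baseline_return = rep$baseline_return,
                     conditioning_dominant = rep$conditioning_dominant,
                     desirable = is_desirable(rep),
                     max_response = max(res$spikes$peak)))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  path <- file.path(out_dir, "sweep.tsv")
  write_spike_table(out, path)
  invisible(path)
}
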