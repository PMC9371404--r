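#' Extract per-event response peaks from a trajectory
#'
#' Each stimulation event owns the half-open time window from its onset to
#' the next event's onset (the final event extends to the horizon). Within
#' each window, the peak is the maximum of the response variable over the
#' recorded samples, and the baseline is the response value at the window
#' start — so the baseline measures how far the system had relaxed before
#' the event fired. Window maxima on disjoint windows make the extraction
#' deterministic; no prominence heuristics are involved.
#'
#' @param trajectory A `circuit_trajectory` produced under `protocol`.
#' @param protocol The [protocol()] that drove the run (it supplies the
#'   event onsets and labels).
#' @param response Which state variable is the response: a column name or
#'   index into the trajectory states (default: the first column).
#' @return A `spike_table`: data frame with one row per event and columns
#'   `event`, `label`, `start`, `peak`, `peak_time`, `baseline`.
#' @export
detect_response_peaks <- function(trajectory, protocol, response = 1L) {
  if (!inherits(trajectory, "circuit_trajectory")) {
    stop_config("`trajectory` must be a circuit_trajectory")
  }
  if (!inherits(protocol, "protocol")) {
    stop_config("`protocol` must be a protocol object")
  }
  ev <- protocol$events
  if (nrow(ev) == 0) {
    stop_config("protocol has no stimulation events")
  }
  if (is.character(response)) {
    response <- match(response, colnames(trajectory$states))
    if (is.na(response)) stop_config("unknown response variable")
  }
  y <- trajectory$states[, response]
  times <- trajectory$times
  bounds <- c(ev$start, max(times) + 1e-9)
  rows <- lapply(seq_len(nrow(ev)), function(i) {
    in_win <- which(times >= bounds[i] - 1e-12 & times < bounds[i + 1L])
    if (length(in_win) == 0) {
      stop_config("event %d window contains no trajectory samples", i)
    }
    k <- in_win[which.max(y[in_win])]
    data.frame(event = ev$event[i], label = ev$label[i], start = ev$start[i],
               peak = y[k], peak_time = times[k],
               baseline = y[in_win[1L]], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "response") <- colnames(trajectory$states)[response]
  class(out) <- c("spike_table", "data.frame")
  out
}

#' Classify the qualitative learning behaviours of a run
#'
#' Turns a [detect_response_peaks()] spike table into boolean verdicts on
#' the qualitative phenomena of interest, with the graded amplitudes kept
#' alongside so that every verdict is auditable:
#'
#' * `learning_formed` — the first conditioned-stimulus (CS) probe after
#'   the first pairing exceeds the pre-conditioning CS response by more
#'   than the relative tolerance.
#' * `reinforced` — the CS probe after the second pairing exceeds the one
#'   after the first by more than the tolerance (the learned response
#'   grows with repeated conditioning).
#' * `forced_dissociation` — the final CS probe has fallen back to the
#'   pre-conditioning CS level (no more than `1 + tol` times it).
#' * `baseline_return` — the response has relaxed below `baseline_eps` at
#'   the start of every event window after the first.
#' * `conditioning_dominant` — every paired (conditioning) peak is at
#'   least `1 - tol` times the unconditioned-stimulus peak, i.e. the
#'   response during conditioning is no less significant than to the
#'   unconditioned stimulus alone.
#'
#' The pre-conditioning CS response is the first `CS_only` event; the
#' learned responses are the first `CS_only` event after each `paired`
#' event. With no pairings in the protocol, `learning_formed` and
#' `reinforced` are `FALSE` and `conditioning_dominant` is `NA`.
#'
#' @param spikes A `spike_table` with event labels.
#' @param tol Relative tolerance for "same amplitude" / strict-inequality
#'   margins (default 0.05).
#' @param baseline_eps Absolute dimensionless response level counted as
#'   "returned to baseline" (default 0.05; see the package vignette for
#'   the calibration).
#' @return A `behavior_report`: list of verdicts, the tolerances used and
#'   the supporting amplitudes.
#' @export
classify <- function(spikes, tol = 0.05, baseline_eps = 0.05) {
  if (!inherits(spikes, "spike_table")) {
    stop_config("`spikes` must be a spike_table from detect_response_peaks()")
  }
  if (any(is.na(spikes$label))) {
    stop_config("spike table has unlabelled events; build the protocol with channel roles or labels")
  }
  check_positive_scalar(tol, "tol", strict = FALSE)
  check_positive_scalar(baseline_eps, "baseline_eps")

  cs <- which(spikes$label == "CS_only")
  us <- which(spikes$label == "US_only")
  paired <- which(spikes$label == "paired")
  if (length(cs) == 0) {
    stop_config("classification requires at least one CS_only event")
  }
  pre_cs_peak <- spikes$peak[cs[1L]]
  final_cs_peak <- spikes$peak[cs[length(cs)]]
  learned_idx <- vapply(paired, function(pi) {
    nxt <- cs[cs > pi]
    if (length(nxt) == 0) NA_integer_ else nxt[1L]
  }, integer(1))
  learned_idx <- unique(learned_idx[!is.na(learned_idx)])
  learned_peaks <- spikes$peak[learned_idx]

  learning_formed <- length(learned_peaks) >= 1L &&
    learned_peaks[1L] > pre_cs_peak * (1 + tol)
  reinforced <- length(learned_peaks) >= 2L &&
    learned_peaks[2L] > learned_peaks[1L] * (1 + tol)
  forced_dissociation <- final_cs_peak <= pre_cs_peak * (1 + tol)
  baseline_return <- all(spikes$baseline[-1L] < baseline_eps)
  us_peak <- if (length(us) > 0) spikes$peak[us[1L]] else NA_real_
  conditioning_dominant <- if (length(paired) == 0 || is.na(us_peak)) {
    NA
  } else {
    all(spikes$peak[paired] > us_peak * (1 - tol))
  }

  structure(list(
    learning_formed = learning_formed,
    reinforced = reinforced,
    forced_dissociation = forced_dissociation,
    baseline_return = baseline_return,
    conditioning_dominant = conditioning_dominant,
    tolerances = list(tol = tol, baseline_eps = baseline_eps),
    amplitudes = list(
      pre_cs_peak = pre_cs_peak,
      learned_peaks = learned_peaks,
      final_cs_peak = final_cs_peak,
      us_peak = us_peak,
      paired_peaks = spikes$peak[paired],
      max_baseline_after_first = if (nrow(spikes) > 1L)
        max(spikes$baseline[-1L]) else NA_real_
    )
  ), class = "behavior_report")
}

#' Is a report fully "desirable"?
#'
#' The conjunction used for the Hill-coefficient robustness sweeps of the
#' forced-dissociation circuit: learning formed, reinforced, forced
#' dissociation achieved, and conditioning dominant. `NA` verdicts count
#' as failures.
#'
#' @param report A `behavior_report`.
#' @return Single logical.
#' @export
is_desirable <- function(report) {
  if (!inherits(report, "behavior_report")) {
    stop_config("`report` must be a behavior_report")
  }
  isTRUE(report$learning_formed) && isTRUE(report$reinforced) &&
    isTRUE(report$forced_dissociation) &&
    isTRUE(report$conditioning_dominant)
}

#' @export
print.behavior_report <- function(x, ...) {
  cat("<behavior_report>\n")
  for (nm in c("learning_formed", "reinforced", "forced_dissociation",
               "baseline_return", "conditioning_dominant")) {
    cat(sprintf("  %-22s %s\n", nm, format(x[[nm]])))
  }
  a <- x$amplitudes
  cat(sprintf("  pre-conditioning CS peak %.4g; learned peaks %s; final CS peak %.4g\n",
              a$pre_cs_peak,
              paste(sprintf("%.4g", a$learned_peaks), collapse = ", "),
              a$final_cs_peak))
  cat(sprintf("  tolerances: tol = %g, baseline_eps = %g\n",
              x$tolerances$tol, x$tolerances$baseline_eps))
  invisible(x)
}

run_and_classify <- function(model, params, protocol, state0 = NULL,
                             settings = integrator_settings(),
                             tol = 0.05, baseline_eps = 0.05) {
  info <- model_info(model)
  if (is.null(state0)) state0 <- default_initial_state(model, params)
  traj <- integrate_circuit(info$rhs, state0, protocol, settings,
                            params = params, model = model)
  spikes <- detect_response_peaks(traj, protocol, info$response)
  report <- classify(spikes, tol = tol, baseline_eps = baseline_eps)
  list(trajectory = traj, spikes = spikes, report = report)
}

#' Hill-coefficient sweep
#'
#' Re-runs one scenario over a grid of Hill coefficients, keeping all other
#' parameters fixed, and classifies each run — the robustness analysis
#' asking which cooperativities preserve the learning phenotype.
#'
#' @param model Model tag (see [model_info()]).
#' @param protocol The stimulus [protocol()] to use at every grid point.
#' @param params Base parameter set; its `a` (and `b`) are overridden.
#' @param a_values Integer vector of Hill coefficients to try.
#' @param b_values For the weight circuit: either a single fixed `b`,
#'   `"a"` to tie `b = a` at every grid point, or `NULL` to keep the base
#'   `b`. Ignored for the single-coefficient circuits.
#' @param state0 Optional initial state (default: the model's calibrated
#'   default).
#' @param settings An [integrator_settings()].
#' @param tol,baseline_eps Classifier tolerances (see [classify()]).
#' @return Data frame with one row per grid point: the coefficients, the
#'   five verdicts, `desirable`, and the supporting amplitudes
#'   (`pre_cs_peak`, `learned_peak_1`, `learned_peak_2`, `final_cs_peak`,
#'   `max_response`). The reports themselves are attached as the
#'   `"reports"` attribute.
#' @export
hill_sweep <- function(model, protocol, params = NULL, a_values,
                       b_values = NULL, state0 = NULL,
                       settings = integrator_settings(),
                       tol = 0.05, baseline_eps = 0.05) {
  info <- model_info(model)
  if (is.null(params)) params <- info$params()
  if (!is.numeric(a_values) || length(a_values) == 0) {
    stop_config("`a_values` must be a non-empty numeric vector")
  }
  has_b <- "b" %in% names(params)
  grid <- lapply(a_values, function(a) {
    b <- if (!has_b) NULL
    else if (is.null(b_values)) params$b
    else if (identical(b_values, "a")) a
    else b_values
    c(list(a = a), if (!is.null(b)) list(b = b))
  })
  rows <- list()
  reports <- list()
  for (g in grid) {
    p <- params
    p$a <- g$a
    if (!is.null(g$b)) p$b <- g$b
    p <- params_from_config(params_to_config(p), model_tag_of(params))
    res <- run_and_classify(model, p, protocol, state0, settings,
                            tol, baseline_eps)
    rep <- res$report
    amp <- rep$amplitudes
    rows[[length(rows) + 1L]] <- data.frame(
      a = g$a, b = if (is.null(g$b)) NA_integer_ else g$b,
      learning_formed = rep$learning_formed,
      reinforced = rep$reinforced,
      forced_dissociation = rep$forced_dissociation,
      baseline_return = rep$baseline_return,
      conditioning_dominant = rep$conditioning_dominant,
      desirable = is_desirable(rep),
      pre_cs_peak = amp$pre_cs_peak,
      learned_peak_1 = if (length(amp$learned_peaks) >= 1)
        amp$learned_peaks[1] else NA_real_,
      learned_peak_2 = if (length(amp$learned_peaks) >= 2)
        amp$learned_peaks[2] else NA_real_,
      final_cs_peak = amp$final_cs_peak,
      max_response = max(res$spikes$peak)
    )
    reports[[length(reports) + 1L]] <- rep
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "reports") <- reports
  out
}

#' Perturb one parameter and compare the classification
#'
#' Runs a scenario at the base parameter set and again with a single named
#' parameter replaced, then reports which verdicts flipped and which
#' event-peak pairs became equal (within the relative tolerance) that were
#' not equal before — the parameter-sensitivity probe.
#'
#' @param model Model tag.
#' @param params Base parameter set.
#' @param name Name of the parameter to replace (must exist in `params`).
#' @param value New value.
#' @param protocol The stimulus [protocol()].
#' @inheritParams hill_sweep
#' @return List with `base` and `perturbed` (each the `trajectory` /
#'   `spikes` / `report` triple), `flipped` (names of verdicts that
#'   changed), `peaks` (per-event peak comparison data frame) and
#'   `newly_equal` (data frame of event pairs equal within `tol` after the
#'   perturbation but not before).
#' @export
perturb_and_classify <- function(model, params, name, value, protocol,
                                 state0 = NULL,
                                 settings = integrator_settings(),
                                 tol = 0.05, baseline_eps = 0.05) {
  info <- model_info(model)
  if (is.null(params)) params <- info$params()
  if (!name %in% names(params)) {
    stop_config("unknown parameter `%s` for model `%s`", name, model)
  }
  cfg <- params_to_config(params)
  cfg[[name]] <- value
  perturbed_params <- params_from_config(cfg, model_tag_of(params))

  base <- run_and_classify(model, params, protocol, state0, settings,
                           tol, baseline_eps)
  pert <- run_and_classify(model, perturbed_params, protocol, state0,
                           settings, tol, baseline_eps)

  verdicts <- c("learning_formed", "reinforced", "forced_dissociation",
                "baseline_return", "conditioning_dominant")
  flipped <- verdicts[vapply(verdicts, function(v) {
    !identical(base$report[[v]], pert$report[[v]])
  }, logical(1))]

  peaks <- data.frame(event = base$spikes$event, label = base$spikes$label,
                      base_peak = base$spikes$peak,
                      perturbed_peak = pert$spikes$peak)
  equal_within <- function(p, i, j) {
    abs(p[i] - p[j]) <= tol * max(p[i], p[j])
  }
  pairs <- utils::combn(nrow(peaks), 2L)
  newly <- list()
  for (k in seq_len(ncol(pairs))) {
    i <- pairs[1L, k]; j <- pairs[2L, k]
    if (equal_within(peaks$perturbed_peak, i, j) &&
        !equal_within(peaks$base_peak, i, j)) {
      newly[[length(newly) + 1L]] <- data.frame(event_1 = peaks$event[i],
                                                event_2 = peaks$event[j])
    }
  }
  newly_equal <- if (length(newly) > 0) do.call(rbind, newly) else
    data.frame(event_1 = integer(), event_2 = integer())

  list(base = base, perturbed = pert, flipped = flipped,
       peaks = peaks, newly_equal = newly_equal,
       perturbation = list(name = name, value = value,
                           base_value = params[[name]]))
}

#' Write a spike table or sweep result as TSV
#'
#' @param x A `spike_table` or any data frame (e.g. a [hill_sweep()]
#'   result).
#' @param path File path.
#' @export
write_spike_table <- function(x, path) {
  utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write a behaviour report as a flat key-value text block
#'
#' @param report A `behavior_report`.
#' @param path File path.
#' @export
write_behavior_report <- function(report, path) {
  if (!inherits(report, "behavior_report")) {
    stop_config("`report` must be a behavior_report")
  }
  a <- report$amplitudes
  kv <- c(
    learning_formed = format(report$learning_formed),
    reinforced = format(report$reinforced),
    forced_dissociation = format(report$forced_dissociation),
    baseline_return = format(report$baseline_return),
    conditioning_dominant = format(report$conditioning_dominant),
    tol = format(report$tolerances$tol),
    baseline_eps = format(report$tolerances$baseline_eps),
    pre_cs_peak = sprintf("%.17g", a$pre_cs_peak),
    learned_peaks = paste(sprintf("%.17g", a$learned_peaks), collapse = ","),
    final_cs_peak = sprintf("%.17g", a$final_cs_peak),
    us_peak = sprintf("%.17g", a$us_peak),
    paired_peaks = paste(sprintf("%.17g", a$paired_peaks), collapse = ",")
  )
  writeLines(paste(names(kv), kv, sep = "\t"), path)
  invisible(path)
}
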