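#' Integrator settings
#'
#' Fixed-step integration settings: the method (`"euler"` for forward
#' Euler, `"rk4"` for the classical four-stage Runge–Kutta scheme), the
#' step size `dt` (dimensionless time; 0.01 reproduces the published
#' analysis, with RK4 at the same step as the benchmark) and an optional
#' recording stride (keep every `record_stride`-th step).
#'
#' @param method `"euler"` or `"rk4"`.
#' @param dt Step size, `> 0`.
#' @param record_stride Keep every k-th sample, integer `>= 1`.
#' @return An `integrator_settings` object.
#' @export
integrator_settings <- function(method = c("euler", "rk4"), dt = 0.01,
                                record_stride = 1L) {
  method <- match.arg(method)
  check_positive_scalar(dt, "dt")
  if (!is.numeric(record_stride) || length(record_stride) != 1L ||
      !is.finite(record_stride) || record_stride < 1 ||
      record_stride != round(record_stride)) {
    stop_config("`record_stride` must be a single integer >= 1")
  }
  structure(list(method = method, dt = dt,
                 record_stride = as.integer(record_stride)),
            class = "integrator_settings")
}

#' Integrate a circuit model under a stimulus protocol
#'
#' Fixed-step integration of `d state / dt = rhs(state, inputs(t), params)`
#' over `[0, horizon]`, with the inputs read off the protocol. Forward
#' Euler uses the input levels at the step start; RK4 evaluates the inputs
#' at the stage times (`t`, `t + dt/2`, `t + dt`), which only matters at
#' pulse edges.
#'
#' State variables are never clamped: a concentration dipping below zero
#' is numerical evidence worth seeing, not something to hide. Undershoot
#' within `-1e-9` is tolerated with a warning; anything more negative, or
#' any non-finite value, aborts with the failure time.
#'
#' @param rhs Derivative function `function(state, inputs, params)`; any of
#'   the [circuit-rhs] functions, or a user-supplied one.
#' @param state0 Finite, non-negative initial state vector.
#' @param protocol A [protocol()] supplying the horizon and input channels.
#' @param settings An [integrator_settings()].
#' @param params Parameter set forwarded to `rhs`.
#' @param model Optional model tag recorded in the trajectory.
#' @return A `circuit_trajectory`: list with `times`, `states` (matrix, one
#'   column per state variable), `inputs` (matrix, one column per channel),
#'   `model` and `settings`.
#' @export
integrate_circuit <- function(rhs, state0, protocol, settings = integrator_settings(),
                              params = NULL, model = NA_character_) {
  if (!inherits(protocol, "protocol")) {
    stop_config("`protocol` must be a protocol object")
  }
  if (!inherits(settings, "integrator_settings")) {
    stop_config("`settings` must be built with integrator_settings()")
  }
  if (!is.numeric(state0) || length(state0) == 0 || !all(is.finite(state0))) {
    stop_config("`state0` must be a finite numeric vector")
  }
  if (any(state0 < 0)) {
    stop_config("`state0` must be non-negative")
  }
  dt <- settings$dt
  n_steps <- as.integer(round(protocol$horizon / dt))
  if (n_steps < 1L) {
    stop_config("horizon %g is shorter than one step of dt = %g",
                protocol$horizon, dt)
  }
  times <- dt * (0:n_steps)
  U <- input_matrix(protocol, times)
  use_rk4 <- settings$method == "rk4"
  if (use_rk4) {
    Umid <- input_matrix(protocol, times[seq_len(n_steps)] + dt / 2)
  }

  n_state <- length(state0)
  state_names <- names(state0)
  if (is.null(state_names)) state_names <- paste0("s", seq_len(n_state))
  S <- matrix(NA_real_, nrow = n_steps + 1L, ncol = n_state,
              dimnames = list(NULL, state_names))
  s <- as.numeric(state0)
  S[1L, ] <- s
  min_seen <- min(s)

  for (i in seq_len(n_steps)) {
    if (use_rk4) {
      u1 <- U[i, ]; um <- Umid[i, ]; u2 <- U[i + 1L, ]
      k1 <- rhs(s, u1, params)
      k2 <- rhs(s + dt / 2 * k1, um, params)
      k3 <- rhs(s + dt / 2 * k2, um, params)
      k4 <- rhs(s + dt * k3, u2, params)
      s <- s + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    } else {
      s <- s + dt * rhs(s, U[i, ], params)
    }
    if (!all(is.finite(s))) {
      stop_numeric("non-finite state at t = %g", times[i + 1L])
    }
    m <- min(s)
    if (m < min_seen) min_seen <- m
    if (min_seen < -1e-9) {
      stop_numeric("state fell below -1e-9 (%.3e) at t = %g",
                   min_seen, times[i + 1L])
    }
    S[i + 1L, ] <- s
  }
  if (min_seen < 0) {
    warning(sprintf("trajectory undershot zero by %.3e (within tolerance; not clamped)",
                    -min_seen))
  }

  keep <- seq(1L, n_steps + 1L, by = settings$record_stride)
  structure(list(times = times[keep],
                 states = S[keep, , drop = FALSE],
                 inputs = U[keep, , drop = FALSE],
                 model = model, settings = settings),
            class = "circuit_trajectory")
}

#' @export
print.circuit_trajectory <- function(x, ...) {
  cat(sprintf("<circuit_trajectory> %s: %d samples over [0, %g], states: %s (%s, dt = %g)\n",
              if (is.na(x$model)) "(untagged model)" else x$model,
              length(x$times), max(x$times),
              paste(colnames(x$states), collapse = ", "),
              x$settings$method, x$settings$dt))
  invisible(x)
}

#' Plot a trajectory
#'
#' Line plot of the state variables (and optionally the applied inputs,
#' rescaled to the state axis) against time.
#'
#' @param x A `circuit_trajectory`.
#' @param which State columns to draw (names or indices; default all).
#' @param show_inputs Overlay the input channels, rescaled, in grey.
#' @param ... Passed to [graphics::matplot()].
#' @export
plot.circuit_trajectory <- function(x, which = NULL, show_inputs = FALSE, ...) {
  sel <- if (is.null(which)) seq_len(ncol(x$states)) else which
  y <- x$states[, sel, drop = FALSE]
  graphics::matplot(x$times, y, type = "l", lty = 1,
                    xlab = "time (dimensionless)", ylab = "concentration", ...)
  if (show_inputs && max(x$inputs) > 0) {
    scaled <- x$inputs / max(x$inputs) * max(y)
    graphics::matlines(x$times, scaled, lty = 3, col = "grey50")
  }
  graphics::legend("topright", legend = colnames(y), lty = 1,
                   col = seq_len(ncol(y)), bty = "n")
  invisible(x)
}

#' Step-refinement convergence check
#'
#' Integrates the same scenario at a decreasing sequence of step sizes and
#' reports, for each step size, the sup-norm deviation from the
#' finest-step solution on their common time grid — the "reduce the step
#' until the result stops changing" stability check, made quantitative.
#' Every step size must be an integer multiple of the finest, and the
#' coarsest grid must be contained in all others, so the comparisons align
#' exactly.
#'
#' @inheritParams integrate_circuit
#' @param dts Numeric vector of at least two step sizes.
#' @param method `"euler"` or `"rk4"`.
#' @return Data frame with columns `dt` and `sup_deviation`, ordered by
#'   decreasing `dt`; the finest step has deviation 0 by construction.
#' @export
convergence_check <- function(rhs, state0, protocol, dts, params = NULL,
                              method = "euler") {
  if (!is.numeric(dts) || length(dts) < 2L || any(dts <= 0)) {
    stop_config("`dts` must contain at least two positive step sizes")
  }
  dts <- sort(unique(dts), decreasing = TRUE)
  finest <- dts[length(dts)]
  ratios <- dts / finest
  if (any(abs(ratios - round(ratios)) > 1e-8)) {
    stop_config("every step size must be an integer multiple of the finest (%g)",
                finest)
  }
  coarse_ratios <- dts[1] / dts
  if (any(abs(coarse_ratios - round(coarse_ratios)) > 1e-8)) {
    stop_config("the coarsest grid must be a subgrid of every finer grid")
  }
  runs <- lapply(dts, function(dt) {
    integrate_circuit(rhs, state0, protocol,
                      integrator_settings(method = method, dt = dt),
                      params = params)
  })
  ref <- runs[[length(runs)]]
  common <- runs[[1L]]$times
  idx_of <- function(traj) {
    i <- round(common / traj$settings$dt) + 1L
    i[i > length(traj$times)] <- length(traj$times)
    i
  }
  ref_states <- ref$states[idx_of(ref), , drop = FALSE]
  dev <- vapply(runs, function(traj) {
    max(abs(traj$states[idx_of(traj), , drop = FALSE] - ref_states))
  }, numeric(1))
  data.frame(dt = dts, sup_deviation = dev)
}

#' Write / read a trajectory as tab-separated values
#'
#' One row per sample: time, then the state columns, then the input
#' columns (prefixed `input.`), with a single header line. Values are
#' written with 17 significant digits so the round trip is lossless at
#' double precision.
#'
#' @param trajectory A `circuit_trajectory`.
#' @param path File path.
#' @return `write_trajectory()` returns `path` invisibly;
#'   `read_trajectory()` returns a `circuit_trajectory` (without model tag
#'   or settings, which are not part of the on-disk format).
#' @export
write_trajectory <- function(trajectory, path) {
  if (!inherits(trajectory, "circuit_trajectory")) {
    stop_config("`trajectory` must be a circuit_trajectory")
  }
  m <- cbind(time = trajectory$times, trajectory$states,
             `colnames<-`(trajectory$inputs,
                          paste0("input.", colnames(trajectory$inputs))))
  lines <- c(paste(colnames(m), collapse = "\t"),
             apply(m, 1L, function(r) paste(sprintf("%.17g", r),
                                            collapse = "\t")))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  if (names(df)[1L] != "time") {
    stop_config("`%s` is not a trajectory file (first column must be `time`)",
                path)
  }
  input_cols <- grep("^input\\.", names(df))
  states <- as.matrix(df[, setdiff(seq_along(df), c(1L, input_cols)),
                         drop = FALSE])
  inputs <- as.matrix(df[, input_cols, drop = FALSE])
  storage.mode(states) <- "double"
  storage.mode(inputs) <- "double"
  colnames(inputs) <- sub("^input\\.", "", colnames(inputs))
  structure(list(times = df$time, states = states, inputs = inputs,
                 model = NA_character_, settings = NULL),
            class = "circuit_trajectory")
}
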