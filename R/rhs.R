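#' Circuit right-hand sides
#'
#' Time-derivative functions for the five circuit models. Each takes the
#' current state, the exogenous input levels supplied by a stimulus
#' protocol, and a matching parameter set, and returns the named derivative
#' vector. They are plain functions of `(state, inputs, params)` so that
#' the fixed-step integrator ([integrate_circuit()]) — or any user code —
#' can drive them directly.
#'
#' States and inputs:
#' * `fernando_rhs()` / `fernando_dimensional_rhs()`: state `(p, w1, w2)`
#'   (response and the two weight molecules), inputs `(u1, u2)`
#'   (unconditioned and conditioned stimulus). The repressors are not state
#'   variables; they are the algebraic map `r_j = S / (1 + u_j)` (or
#'   `R / (1 + k u_j)` dimensionally) evaluated inside the derivative.
#' * `fd_rhs()` / `fd_dimensional_rhs()` / `adjusted_fd_rhs()`: state
#'   `(y, u, v)` (response, moderator, inhibitor), inputs `(x, z)`
#'   (conditioned and unconditioned stimulus).
#'
#' @param state Numeric state vector (order as above; names optional).
#' @param inputs Numeric length-2 input vector (order as above).
#' @param params Matching parameter set from [circuit-params].
#' @return Named numeric derivative vector, same length/order as `state`.
#' @name circuit-rhs
#' @examples
#' fernando_rhs(c(p = 0, w1 = 0, w2 = 0), c(u1 = 0, u2 = 0), fernando_params())
#' fd_rhs(c(y = 0, u = 0, v = 0), c(x = 1, z = 1), fd_params())
NULL

check_rhs_args <- function(state, inputs, n_state) {
  if (!is.numeric(state) || length(state) != n_state ||
      !all(is.finite(state))) {
    stop_numeric("state must be a finite numeric vector of length %d",
                 n_state)
  }
  if (!is.numeric(inputs) || length(inputs) != 2L ||
      !all(is.finite(inputs))) {
    stop_numeric("inputs must be a finite numeric vector of length 2")
  }
  invisible(TRUE)
}

#' @rdname circuit-rhs
#' @export
fernando_rhs <- function(state, inputs, params) {
  check_rhs_args(state, inputs, 3L)
  p <- state[[1L]]; w1 <- state[[2L]]; w2 <- state[[3L]]
  a <- params$a; b <- params$b
  r1 <- params$S / (1 + inputs[[1L]])
  r2 <- params$S / (1 + inputs[[2L]])
  rep1 <- .hill_rep(r1, b)
  rep2 <- .hill_rep(r2, b)
  act_p <- .hill_act(p, b)
  dp <- params$alpha * (.hill_act(w1, a) * rep1 + .hill_act(w2, a) * rep2) - p
  dw1 <- params$beta * act_p * rep1 - params$theta * w1 + params$tau1
  dw2 <- params$beta * act_p * rep2 - params$theta * w2 + params$tau2
  c(p = dp, w1 = dw1, w2 = dw2)
}

#' @rdname circuit-rhs
#' @export
fernando_dimensional_rhs <- function(state, inputs, params) {
  check_rhs_args(state, inputs, 3L)
  p <- state[[1L]]; w1 <- state[[2L]]; w2 <- state[[3L]]
  a <- params$a; b <- params$b
  r1 <- params$R / (1 + params$k * inputs[[1L]])
  r2 <- params$R / (1 + params$k * inputs[[2L]])
  rep1 <- .hill_rep(r1 / params$K_r, b)
  rep2 <- .hill_rep(r2 / params$K_r, b)
  act_p <- .hill_act(p / params$K_p, b)
  dp <- params$v_p * (.hill_act(w1 / params$K_w, a) * rep1 +
                        .hill_act(w2 / params$K_w, a) * rep2) -
    params$delta_p * p
  dw1 <- params$v_w * act_p * rep1 - params$delta_w * w1 + params$eps1
  dw2 <- params$v_w * act_p * rep2 - params$delta_w * w2 + params$eps2
  c(p = dp, w1 = dw1, w2 = dw2)
}

#' @rdname circuit-rhs
#' @export
fd_rhs <- function(state, inputs, params) {
  check_rhs_args(state, inputs, 3L)
  y <- state[[1L]]; u <- state[[2L]]; v <- state[[3L]]
  a <- params$a
  ax <- .hill_act(inputs[[1L]], a); rx <- 1 - ax
  az <- .hill_act(inputs[[2L]], a); rz <- 1 - az
  rv <- .hill_rep(v, a)
  ru <- .hill_rep(u, a)
  dy <- (params$alpha_yx * ax * rz + params$alpha_yz * rx * az +
           params$alpha_xyz * ax * az) * rv - y
  du <- params$alpha_ux * ax - params$beta_u * u
  dv <- params$alpha_vx * ax * ru * rz - params$beta_v * v
  c(y = dy, u = du, v = dv)
}

#' @rdname circuit-rhs
#' @export
fd_dimensional_rhs <- function(state, inputs, params) {
  check_rhs_args(state, inputs, 3L)
  y <- state[[1L]]; u <- state[[2L]]; v <- state[[3L]]
  a <- params$a
  ax <- .hill_act(inputs[[1L]] / params$K_x, a); rx <- 1 - ax
  az <- .hill_act(inputs[[2L]] / params$K_z, a); rz <- 1 - az
  rv <- .hill_rep(v / params$K_v, a)
  ru <- .hill_rep(u / params$K_u, a)
  dy <- (params$alpha_yx * ax * rz + params$alpha_yz * rx * az +
           params$alpha_xyz * ax * az) * rv - params$delta_y * y
  du <- params$alpha_ux * ax - params$delta_u * u
  dv <- params$alpha_vx * ax * ru * rz - params$delta_v * v
  c(y = dy, u = du, v = dv)
}

#' @rdname circuit-rhs
#' @export
adjusted_fd_rhs <- function(state, inputs, params) {
  check_rhs_args(state, inputs, 3L)
  y <- state[[1L]]; u <- state[[2L]]; v <- state[[3L]]
  a <- params$a
  ax <- .hill_act(inputs[[1L]], a)
  az <- .hill_act(inputs[[2L]], a); rz <- 1 - az
  rv <- .hill_rep(v, a)
  ru <- .hill_rep(u, a)
  dy <- params$alpha_yx * ax * rv + params$alpha_yz * az - y
  du <- params$alpha_ux * ax - params$beta_u * u
  dv <- params$alpha_vx * ax * ru * rz - params$beta_v * v
  c(y = dy, u = du, v = dv)
}

#' Model registry
#'
#' Look up the pieces associated with a model tag: its right-hand side,
#' state-variable names, input-channel names, which channel carries the
#' unconditioned (US) and conditioned (CS) stimulus, which state variable
#' is the response, and the parameter constructor.
#'
#' @param model One of `"fernando"`, `"fernando_dimensional"`, `"fd"`,
#'   `"fd_dimensional"`, `"adjusted_fd"`.
#' @return List with elements `tag`, `rhs`, `states`, `channels`,
#'   `us_channel`, `cs_channel`, `response`, `params`.
#' @export
model_info <- function(model) {
  switch(model,
    fernando = list(tag = "fernando", rhs = fernando_rhs,
                    states = c("p", "w1", "w2"), channels = c("u1", "u2"),
                    us_channel = "u1", cs_channel = "u2", response = "p",
                    params = fernando_params),
    fernando_dimensional = list(tag = "fernando_dimensional",
                    rhs = fernando_dimensional_rhs,
                    states = c("p", "w1", "w2"), channels = c("u1", "u2"),
                    us_channel = "u1", cs_channel = "u2", response = "p",
                    params = fernando_dimensional_params),
    fd = list(tag = "fd", rhs = fd_rhs,
              states = c("y", "u", "v"), channels = c("x", "z"),
              us_channel = "z", cs_channel = "x", response = "y",
              params = fd_params),
    fd_dimensional = list(tag = "fd_dimensional", rhs = fd_dimensional_rhs,
              states = c("y", "u", "v"), channels = c("x", "z"),
              us_channel = "z", cs_channel = "x", response = "y",
              params = fd_dimensional_params),
    adjusted_fd = list(tag = "adjusted_fd", rhs = adjusted_fd_rhs,
              states = c("y", "u", "v"), channels = c("x", "z"),
              us_channel = "z", cs_channel = "x", response = "y",
              params = adjusted_fd_params),
    stop_config("unknown model tag `%s`", model)
  )
}

#' Default initial conditions for a model
#'
#' The calibrated starting states used throughout the shipped scenarios:
#' the weight circuit starts with the unconditioned weight at its basal
#' fixed point `tau1 / theta` and a small conditioned weight (0.3, giving a
#' visible but modest response to the conditioned stimulus before any
#' conditioning; set it to 0 to suppress that response entirely), and the
#' forced-dissociation circuits start with the inhibitor stocked at
#' `v = 5` — the inhibitor must be abundant before an experiment, otherwise
#' the conditioned stimulus alone already overexpresses the response.
#' Dimensional models scale these by the corresponding Hill constants.
#'
#' @param model Model tag (see [model_info()]).
#' @param params Optional parameter set (defaults to the model's defaults);
#'   used for `tau1 / theta` and the Hill-constant scalings.
#' @return Named numeric state vector.
#' @export
default_initial_state <- function(model, params = NULL) {
  info <- model_info(model)
  if (is.null(params)) params <- info$params()
  switch(model,
    fernando = c(p = 0, w1 = params$tau1 / params$theta, w2 = 0.3),
    fernando_dimensional = c(p = 0, w1 = params$eps1 / params$delta_w,
                             w2 = 0.3 * params$K_w),
    fd = c(y = 0, u = 0, v = 5),
    fd_dimensional = c(y = 0, u = 0, v = 5 * params$K_v),
    adjusted_fd = c(y = 0, u = 0, v = 5)
  )
}
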