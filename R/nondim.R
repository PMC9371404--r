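#' Nondimensionalise the weight-circuit parameters
#'
#' Maps a dimensional parameter set onto the dimensionless one via the
#' scalings `w_j -> w_j / K_w`, `r_j -> r_j / K_r`, `p -> p / K_p`,
#' `t -> delta_p * t`, `u_j -> k * u_j`, which give
#' `alpha = v_p / (K_p delta_p)`, `beta = v_w / (K_w delta_p)`,
#' `theta = delta_w / delta_p`, `tau_j = eps_j / (K_w delta_p)` and
#' `S = R / K_r` (each dimensionless group follows from dividing the
#' corresponding equation by its state scale and by `delta_p`).
#'
#' Besides the parameter set, the invertible scaling maps are returned so
#' that whole simulations can be carried across: `time_fwd`/`time_inv`
#' map dimensional time to dimensionless and back, `state_fwd`/`state_inv`
#' the state vectors, `input_fwd`/`input_inv` the per-channel input levels,
#' `protocol_fwd` a dimensional [protocol()] to its dimensionless
#' counterpart, and `trajectory_fwd` a full dimensional
#' `circuit_trajectory`.
#'
#' @param params A [fernando_dimensional_params()] set.
#' @return List with `params` (a [fernando_params()]) and `maps` (named
#'   list of functions as described above).
#' @export
nondimensionalize_fernando <- function(params) {
  if (!inherits(params, "fernando_dimensional_params")) {
    stop_config("`params` must be a fernando_dimensional_params set")
  }
  dimless <- fernando_params(
    alpha = params$v_p / (params$K_p * params$delta_p),
    beta  = params$v_w / (params$K_w * params$delta_p),
    theta = params$delta_w / params$delta_p,
    tau1  = params$eps1 / (params$K_w * params$delta_p),
    tau2  = params$eps2 / (params$K_w * params$delta_p),
    S     = params$R / params$K_r,
    a = params$a, b = params$b
  )
  state_scale <- c(p = params$K_p, w1 = params$K_w, w2 = params$K_w)
  input_scale <- c(u1 = params$k, u2 = params$k)   # multiplicative: u_bar = k u
  maps <- make_scaling_maps(time_scale = params$delta_p,
                            state_scale = state_scale,
                            input_scale = input_scale)
  list(params = dimless, maps = maps)
}

#' Nondimensionalise the forced-dissociation-circuit parameters
#'
#' Scaling convention: `t -> delta_y * t`, `x -> x / K_x`, `z -> z / K_z`,
#' `u -> u / K_u`, `v -> v / K_v`, with the response `y` left unscaled
#' (nothing downstream of `y` carries a Hill constant to scale it by).
#' This yields `alpha_y. / delta_y` for the three response production
#' strengths, `alpha_ux / (K_u delta_y)`, `alpha_vx / (K_v delta_y)`,
#' `beta_u = delta_u / delta_y` and `beta_v = delta_v / delta_y`.
#'
#' @param params A [fd_dimensional_params()] set.
#' @return List with `params` (an [fd_params()]) and `maps` (see
#'   [nondimensionalize_fernando()] for the map set).
#' @export
nondimensionalize_fd <- function(params) {
  if (!inherits(params, "fd_dimensional_params")) {
    stop_config("`params` must be an fd_dimensional_params set")
  }
  dy <- params$delta_y
  dimless <- fd_params(
    alpha_yx  = params$alpha_yx / dy,
    alpha_yz  = params$alpha_yz / dy,
    alpha_xyz = params$alpha_xyz / dy,
    alpha_ux  = params$alpha_ux / (params$K_u * dy),
    alpha_vx  = params$alpha_vx / (params$K_v * dy),
    beta_u    = params$delta_u / dy,
    beta_v    = params$delta_v / dy,
    a = params$a
  )
  state_scale <- c(y = 1, u = params$K_u, v = params$K_v)
  input_scale <- c(x = 1 / params$K_x, z = 1 / params$K_z)
  maps <- make_scaling_maps(time_scale = dy,
                            state_scale = state_scale,
                            input_scale = input_scale)
  list(params = dimless, maps = maps)
}

# time_scale: t_bar = time_scale * t
# state_scale: x_bar = x / state_scale (per state, named)
# input_scale: u_bar = input_scale * u (per channel, named)
make_scaling_maps <- function(time_scale, state_scale, input_scale) {
  time_fwd <- function(t) time_scale * t
  time_inv <- function(t_bar) t_bar / time_scale
  state_fwd <- function(state) {
    s <- as.numeric(state) / state_scale
    names(s) <- names(state_scale)
    s
  }
  state_inv <- function(state_bar) {
    s <- as.numeric(state_bar) * state_scale
    names(s) <- names(state_scale)
    s
  }
  input_fwd <- function(inputs) {
    u <- as.numeric(inputs) * input_scale
    names(u) <- names(input_scale)
    u
  }
  input_inv <- function(inputs_bar) {
    u <- as.numeric(inputs_bar) / input_scale
    names(u) <- names(input_scale)
    u
  }
  protocol_fwd <- function(prot) {
    p <- prot$pulses
    pulses <- lapply(seq_len(nrow(p)), function(i) {
      sc <- input_scale[[p$channel[i]]]
      pulse(p$channel[i], start = time_fwd(p$start[i]),
            duration = time_fwd(p$duration[i]),
            amplitude = p$amplitude[i] * sc)
    })
    labels <- if (all(is.na(prot$events$label))) NULL else prot$events$label
    protocol(pulses, horizon = time_fwd(prot$horizon),
             channels = prot$channels, labels = labels,
             us_channel = prot$us_channel, cs_channel = prot$cs_channel)
  }
  protocol_inv <- function(prot) {
    p <- prot$pulses
    pulses <- lapply(seq_len(nrow(p)), function(i) {
      sc <- input_scale[[p$channel[i]]]
      pulse(p$channel[i], start = time_inv(p$start[i]),
            duration = time_inv(p$duration[i]),
            amplitude = p$amplitude[i] / sc)
    })
    labels <- if (all(is.na(prot$events$label))) NULL else prot$events$label
    protocol(pulses, horizon = time_inv(prot$horizon),
             channels = prot$channels, labels = labels,
             us_channel = prot$us_channel, cs_channel = prot$cs_channel)
  }
  trajectory_fwd <- function(traj) {
    states <- sweep(traj$states, 2L,
                    state_scale[colnames(traj$states)], `/`)
    inputs <- sweep(traj$inputs, 2L,
                    input_scale[colnames(traj$inputs)], `*`)
    structure(list(times = time_fwd(traj$times), states = states,
                   inputs = inputs, model = traj$model,
                   settings = traj$settings),
              class = "circuit_trajectory")
  }
  list(time_fwd = time_fwd, time_inv = time_inv,
       state_fwd = state_fwd, state_inv = state_inv,
       input_fwd = input_fwd, input_inv = input_inv,
       protocol_fwd = protocol_fwd, protocol_inv = protocol_inv,
       trajectory_fwd = trajectory_fwd)
}
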