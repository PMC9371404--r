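# Independent term-by-term transcriptions of the five printed equation
# systems, written directly from the equations with no shared code with the
# package internals. They serve as hand-evaluation oracles for the RHS
# implementations.

oracle_fernando <- function(state, inputs, p) {
  pp <- state[[1]]; w <- c(state[[2]], state[[3]])
  tau <- c(p$tau1, p$tau2)
  r <- p$S / (1 + c(inputs[[1]], inputs[[2]]))
  dp <- sum(p$alpha * w^p$a / (1 + w^p$a) * 1 / (1 + r^p$b)) - pp
  dw <- p$beta * pp^p$b / (1 + pp^p$b) * 1 / (1 + r^p$b) - p$theta * w + tau
  c(dp, dw)
}

oracle_fernando_dim <- function(state, inputs, p) {
  pp <- state[[1]]; w <- c(state[[2]], state[[3]])
  eps <- c(p$eps1, p$eps2)
  r <- p$R / (1 + p$k * c(inputs[[1]], inputs[[2]]))
  dp <- sum(p$v_p * w^p$a / (p$K_w^p$a + w^p$a) *
              p$K_r^p$b / (p$K_r^p$b + r^p$b)) - p$delta_p * pp
  dw <- p$v_w * pp^p$b / (p$K_p^p$b + pp^p$b) *
    p$K_r^p$b / (p$K_r^p$b + r^p$b) - p$delta_w * w + eps
  c(dp, dw)
}

oracle_fd <- function(state, inputs, p) {
  y <- state[[1]]; u <- state[[2]]; v <- state[[3]]
  x <- inputs[[1]]; z <- inputs[[2]]; a <- p$a
  dy <- p$alpha_yx * x^a / (1 + x^a) * 1 / (1 + z^a) * 1 / (1 + v^a) +
    p$alpha_yz * 1 / (1 + x^a) * z^a / (1 + z^a) * 1 / (1 + v^a) +
    p$alpha_xyz * x^a / (1 + x^a) * z^a / (1 + z^a) * 1 / (1 + v^a) - y
  du <- p$alpha_ux * x^a / (1 + x^a) - p$beta_u * u
  dv <- p$alpha_vx * x^a / (1 + x^a) * 1 / (1 + u^a) * 1 / (1 + z^a) -
    p$beta_v * v
  c(dy, du, dv)
}

oracle_fd_dim <- function(state, inputs, p) {
  y <- state[[1]]; u <- state[[2]]; v <- state[[3]]
  x <- inputs[[1]]; z <- inputs[[2]]; a <- p$a
  hx <- x^a / (p$K_x^a + x^a); rx <- p$K_x^a / (p$K_x^a + x^a)
  hz <- z^a / (p$K_z^a + z^a); rz <- p$K_z^a / (p$K_z^a + z^a)
  rv <- p$K_v^a / (p$K_v^a + v^a); ru <- p$K_u^a / (p$K_u^a + u^a)
  dy <- p$alpha_yx * hx * rz * rv + p$alpha_yz * rx * hz * rv +
    p$alpha_xyz * hx * hz * rv - p$delta_y * y
  du <- p$alpha_ux * hx - p$delta_u * u
  dv <- p$alpha_vx * hx * ru * rz - p$delta_v * v
  c(dy, du, dv)
}

oracle_adjusted_fd <- function(state, inputs, p) {
  y <- state[[1]]; u <- state[[2]]; v <- state[[3]]
  x <- inputs[[1]]; z <- inputs[[2]]; a <- p$a
  dy <- p$alpha_yx * x^a / (1 + x^a) * 1 / (1 + v^a) +
    p$alpha_yz * z^a / (1 + z^a) - y
  du <- p$alpha_ux * x^a / (1 + x^a) - p$beta_u * u
  dv <- p$alpha_vx * x^a / (1 + x^a) * 1 / (1 + u^a) * 1 / (1 + z^a) -
    p$beta_v * v
  c(dy, du, dv)
}

# random positive parameter sets / states for property tests
random_fernando_params <- function() {
  fernando_params(alpha = runif(1, 0.2, 3), beta = runif(1, 0.2, 3),
                  theta = runif(1, 0.01, 1), tau1 = runif(1, 0, 0.3),
                  tau2 = runif(1, 0, 0.3), S = runif(1, 1, 15),
                  a = sample(1:4, 1), b = sample(1:4, 1))
}

random_fernando_dim_params <- function() {
  fernando_dimensional_params(
    v_p = runif(1, 0.2, 3), v_w = runif(1, 0.2, 3),
    delta_p = runif(1, 0.3, 2), delta_w = runif(1, 0.01, 0.5),
    K_w = runif(1, 0.3, 3), K_r = runif(1, 0.3, 3), K_p = runif(1, 0.3, 3),
    R = runif(1, 1, 15), k = runif(1, 0.3, 3),
    eps1 = runif(1, 0, 0.3), eps2 = runif(1, 0, 0.3),
    a = sample(1:4, 1), b = sample(1:4, 1))
}

random_fd_params <- function() {
  fd_params(alpha_yx = runif(1, 0.2, 4), alpha_yz = runif(1, 0.2, 4),
            alpha_xyz = runif(1, 0.2, 4), alpha_ux = runif(1, 0.1, 2),
            alpha_vx = runif(1, 0.1, 2), beta_u = runif(1, 0.02, 0.5),
            beta_v = runif(1, 0.01, 0.2), a = sample(1:4, 1))
}

random_fd_dim_params <- function() {
  fd_dimensional_params(
    alpha_yx = runif(1, 0.2, 4), alpha_yz = runif(1, 0.2, 4),
    alpha_xyz = runif(1, 0.2, 4), alpha_ux = runif(1, 0.1, 2),
    alpha_vx = runif(1, 0.1, 2), delta_y = runif(1, 0.3, 2),
    delta_u = runif(1, 0.02, 0.5), delta_v = runif(1, 0.01, 0.2),
    K_x = runif(1, 0.3, 3), K_z = runif(1, 0.3, 3),
    K_v = runif(1, 0.3, 3), K_u = runif(1, 0.3, 3),
    a = sample(1:4, 1))
}

random_adjusted_fd_params <- function() {
  fd <- random_fd_params()
  adjusted_fd_params(alpha_yx = fd$alpha_yx, alpha_yz = fd$alpha_yz,
                     alpha_ux = fd$alpha_ux, alpha_vx = fd$alpha_vx,
                     beta_u = fd$beta_u, beta_v = fd$beta_v, a = fd$a)
}

random_state3 <- function() runif(3, 0, 5)
random_inputs <- function() runif(2, 0, 20)

# simple two-pulse protocol used by several numerical tests; pulse edges sit
# strictly between grid points of the step sizes used, so that rescaled time
# grids resolve the edges identically up to rounding
toy_protocol <- function(channels, amp = 10, horizon = 10) {
  protocol(list(pulse(channels[1], 1.0003, 2.0001, amp),
                pulse(channels[2], 4.0007, 2.0001, amp)),
           horizon = horizon, channels = channels,
           us_channel = channels[1], cs_channel = channels[2])
}

decay_rhs <- function(state, inputs, params) -state
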