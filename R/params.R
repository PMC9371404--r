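#' Parameter sets for the associative-learning circuits
#'
#' Constructors for the kinetic parameter sets of the five circuit models.
#' Each returns a validated named list with a class tag that the
#' right-hand-side functions, integrator helpers and configuration I/O
#' recognise. Defaults are the published simulation values for each model
#' (and, for the dimensional forms, the identity scaling that maps onto
#' them, i.e. all Hill constants and the response degradation rate equal
#' to 1).
#'
#' @name circuit-params
#' @examples
#' fernando_params()                  # Hebbian weight circuit, a = 4, b = 2
#' fd_params(a = 3)                   # forced-dissociation circuit
#' adjusted_fd_params()               # reduced forced-dissociation circuit
NULL

new_params <- function(fields, class) {
  structure(fields, class = c(class, "circuit_params"))
}

#' @describeIn circuit-params Dimensionless Hebbian weight-molecule circuit:
#'   `alpha`, `beta` are production strengths for the response and the
#'   weights, `theta` the weight degradation rate (response degradation is
#'   scaled to 1), `tau1`/`tau2` basal weight production, `S` the basal
#'   repressor level, and `a`/`b` the Hill coefficients of weight and
#'   response/repressor binding.
#' @param alpha,beta,theta,tau1,tau2,S Dimensionless kinetic parameters
#'   (see above); `theta`, `alpha`, `beta`, `S` strictly positive,
#'   `tau1`, `tau2` non-negative.
#' @param a,b Hill coefficients (single integers `>= 1`).
#' @export
fernando_params <- function(alpha = 1, beta = 0.8, theta = 0.02,
                            tau1 = 0.1, tau2 = 0, S = 10, a = 4, b = 2) {
  check_positive_scalar(alpha, "alpha")
  check_positive_scalar(beta, "beta")
  check_positive_scalar(theta, "theta")
  check_positive_scalar(tau1, "tau1", strict = FALSE)
  check_positive_scalar(tau2, "tau2", strict = FALSE)
  check_positive_scalar(S, "S")
  check_hill_coef(a, "a")
  check_hill_coef(b, "b")
  new_params(list(alpha = alpha, beta = beta, theta = theta,
                  tau1 = tau1, tau2 = tau2, S = S, a = a, b = b),
             "fernando_params")
}

#' @describeIn circuit-params Dimensional form of the weight circuit:
#'   production rates `v_p`, `v_w`, degradation rates `delta_p`, `delta_w`,
#'   Hill constants `K_w`, `K_r`, `K_p`, basal repressor concentration `R`,
#'   input-binding coefficient `k` and basal weight production `eps1`,
#'   `eps2`. Scaled onto [fernando_params()] by
#'   [nondimensionalize_fernando()].
#' @param v_p,v_w,delta_p,delta_w,K_w,K_r,K_p,R,k,eps1,eps2 Dimensional
#'   kinetic parameters; all strictly positive except `eps1`, `eps2` which
#'   may be 0.
#' @export
fernando_dimensional_params <- function(v_p = 1, v_w = 0.8, delta_p = 1,
                                        delta_w = 0.02, K_w = 1, K_r = 1,
                                        K_p = 1, R = 10, k = 1,
                                        eps1 = 0.1, eps2 = 0, a = 4, b = 2) {
  for (nm in c("v_p", "v_w", "delta_p", "delta_w", "K_w", "K_r", "K_p",
               "R", "k")) {
    check_positive_scalar(get(nm), nm)
  }
  check_positive_scalar(eps1, "eps1", strict = FALSE)
  check_positive_scalar(eps2, "eps2", strict = FALSE)
  check_hill_coef(a, "a")
  check_hill_coef(b, "b")
  new_params(list(v_p = v_p, v_w = v_w, delta_p = delta_p, delta_w = delta_w,
                  K_w = K_w, K_r = K_r, K_p = K_p, R = R, k = k,
                  eps1 = eps1, eps2 = eps2, a = a, b = b),
             "fernando_dimensional_params")
}

#' @describeIn circuit-params Dimensionless forced-dissociation circuit:
#'   `alpha_yx`, `alpha_yz`, `alpha_xyz` drive the response `y` from the
#'   conditioned input `x`, the unconditioned input `z` and their
#'   conjunction; `alpha_ux` drives the moderator `u`, `alpha_vx` the
#'   inhibitor `v`; `beta_u`, `beta_v` are their degradation rates
#'   (response degradation scaled to 1); `a` is the shared Hill coefficient.
#' @param alpha_yx,alpha_yz,alpha_xyz,alpha_ux,alpha_vx,beta_u,beta_v
#'   Dimensionless kinetic parameters, all strictly positive.
#' @export
fd_params <- function(alpha_yx = 2, alpha_yz = 4, alpha_xyz = 4,
                      alpha_ux = 0.6, alpha_vx = 1.5,
                      beta_u = 0.1, beta_v = 0.02, a = 2) {
  for (nm in c("alpha_yx", "alpha_yz", "alpha_xyz", "alpha_ux", "alpha_vx",
               "beta_u", "beta_v")) {
    check_positive_scalar(get(nm), nm)
  }
  check_hill_coef(a, "a")
  new_params(list(alpha_yx = alpha_yx, alpha_yz = alpha_yz,
                  alpha_xyz = alpha_xyz, alpha_ux = alpha_ux,
                  alpha_vx = alpha_vx, beta_u = beta_u, beta_v = beta_v,
                  a = a),
             "fd_params")
}

#' @describeIn circuit-params Dimensional form of the forced-dissociation
#'   circuit with Hill constants `K_x`, `K_z`, `K_v`, `K_u` and degradation
#'   rates `delta_y`, `delta_u`, `delta_v`. Scaled onto [fd_params()] by
#'   [nondimensionalize_fd()].
#' @param delta_y,delta_u,delta_v,K_x,K_z,K_v,K_u Dimensional degradation
#'   rates and Hill constants, all strictly positive.
#' @export
fd_dimensional_params <- function(alpha_yx = 2, alpha_yz = 4, alpha_xyz = 4,
                                  alpha_ux = 0.6, alpha_vx = 1.5,
                                  delta_y = 1, delta_u = 0.1, delta_v = 0.02,
                                  K_x = 1, K_z = 1, K_v = 1, K_u = 1, a = 2) {
  for (nm in c("alpha_yx", "alpha_yz", "alpha_xyz", "alpha_ux", "alpha_vx",
               "delta_y", "delta_u", "delta_v", "K_x", "K_z", "K_v", "K_u")) {
    check_positive_scalar(get(nm), nm)
  }
  check_hill_coef(a, "a")
  new_params(list(alpha_yx = alpha_yx, alpha_yz = alpha_yz,
                  alpha_xyz = alpha_xyz, alpha_ux = alpha_ux,
                  alpha_vx = alpha_vx, delta_y = delta_y, delta_u = delta_u,
                  delta_v = delta_v, K_x = K_x, K_z = K_z, K_v = K_v,
                  K_u = K_u, a = a),
             "fd_dimensional_params")
}

#' @describeIn circuit-params Reduced forced-dissociation circuit in which
#'   the unconditioned input acts through its own operator, removing the
#'   three-way conjunction term (`alpha_xyz` disappears and the `z` branch
#'   of the response decouples from `x` and `v`).
#' @export
adjusted_fd_params <- function(alpha_yx = 4, alpha_yz = 1,
                               alpha_ux = 0.6, alpha_vx = 1,
                               beta_u = 0.1, beta_v = 0.02, a = 2) {
  for (nm in c("alpha_yx", "alpha_yz", "alpha_ux", "alpha_vx",
               "beta_u", "beta_v")) {
    check_positive_scalar(get(nm), nm)
  }
  check_hill_coef(a, "a")
  new_params(list(alpha_yx = alpha_yx, alpha_yz = alpha_yz,
                  alpha_ux = alpha_ux, alpha_vx = alpha_vx,
                  beta_u = beta_u, beta_v = beta_v, a = a),
             "adjusted_fd_params")
}

#' @export
print.circuit_params <- function(x, ...) {
  cat(sprintf("<%s>\n", class(x)[1L]))
  vals <- vapply(unclass(x), function(v) format(v, digits = 6), character(1))
  cat(paste0("  ", format(names(vals)), " = ", vals, collapse = "\n"), "\n")
  invisible(x)
}

param_constructors <- list(
  fernando             = fernando_params,
  fernando_dimensional = fernando_dimensional_params,
  fd                   = fd_params,
  fd_dimensional       = fd_dimensional_params,
  adjusted_fd          = adjusted_fd_params
)

model_tag_of <- function(params) {
  cls <- class(params)[1L]
  sub("_params$", "", cls)
}

#' Serialise a parameter set to a flat key/value list
#'
#' The returned list uses exactly the constructor argument names as keys and
#' round-trips through YAML (see [params_from_config()]).
#'
#' @param params A parameter set built by one of the [circuit-params]
#'   constructors.
#' @return Named list of numbers.
#' @export
params_to_config <- function(params) {
  if (!inherits(params, "circuit_params")) {
    stop_config("`params` must be a circuit parameter set")
  }
  unclass(params)
}

#' Rebuild a parameter set from a flat key/value block
#'
#' Inverse of [params_to_config()]. Every key must be a known field of the
#' model's parameter set; unknown keys are rejected so that configuration
#' typos fail loudly instead of silently falling back to defaults.
#'
#' @param config Named list (e.g. a parsed YAML block) of parameter values.
#'   Missing fields take the model defaults.
#' @param model Model tag: one of `"fernando"`, `"fernando_dimensional"`,
#'   `"fd"`, `"fd_dimensional"`, `"adjusted_fd"`.
#' @return A validated parameter set.
#' @export
params_from_config <- function(config, model) {
  ctor <- param_constructors[[model]]
  if (is.null(ctor)) {
    stop_config("unknown model tag `%s` (expected one of: %s)", model,
                paste(names(param_constructors), collapse = ", "))
  }
  if (is.null(config)) config <- list()
  if (!is.list(config) ||
      (length(config) > 0 && is.null(names(config)))) {
    stop_config("parameter block for model `%s` must be a named list", model)
  }
  known <- names(formals(ctor))
  bad <- setdiff(names(config), known)
  if (length(bad) > 0) {
    stop_config("unknown parameter field(s) for model `%s`: %s", model,
                paste(bad, collapse = ", "))
  }
  do.call(ctor, config)
}
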