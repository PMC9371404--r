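test_that("parameter constructors validate their invariants", {
  expect_s3_class(fernando_params(), "fernando_params")
  expect_error(fernando_params(alpha = -1), class = "assoclearn_config_error")
  expect_error(fernando_params(a = 1.5), class = "assoclearn_config_error")
  expect_error(fd_params(beta_u = 0), class = "assoclearn_config_error")
  expect_error(adjusted_fd_params(a = 0), class = "assoclearn_config_error")
  expect_error(fernando_dimensional_params(K_w = 0),
               class = "assoclearn_config_error")
  # published defaults
  p <- fernando_params()
  expect_equal(unclass(p)[c("alpha", "beta", "theta", "tau1", "tau2", "S")],
               list(alpha = 1, beta = 0.8, theta = 0.02, tau1 = 0.1,
                    tau2 = 0, S = 10))
  q <- fd_params()
  expect_equal(unclass(q)[c("alpha_yx", "alpha_yz", "alpha_xyz", "alpha_ux",
                            "alpha_vx", "beta_u", "beta_v")],
               list(alpha_yx = 2, alpha_yz = 4, alpha_xyz = 4,
                    alpha_ux = 0.6, alpha_vx = 1.5, beta_u = 0.1,
                    beta_v = 0.02))
})

test_that("parameter sets round-trip through flat config blocks", {
  for (model in c("fernando", "fernando_dimensional", "fd",
                  "fd_dimensional", "adjusted_fd")) {
    p <- model_info(model)$params()
    cfg <- params_to_config(p)
    expect_true(all(vapply(cfg, is.numeric, TRUE)))
    expect_equal(params_from_config(cfg, model), p)
  }
  expect_error(params_from_config(list(nonsense = 1), "fd"),
               class = "assoclearn_config_error")
  expect_error(params_from_config(list(), "no_such_model"),
               class = "assoclearn_config_error")
})

test_that("weight-circuit derivatives match hand-evaluated values", {
  par <- fernando_params()  # a = 4, b = 2, tau1 = 0.1
  # all production terms vanish at the origin; only basal growth remains
  expect_equal(fernando_rhs(c(0, 0, 0), c(0, 0), par),
               c(p = 0, w1 = 0.1, w2 = 0))
  # term-by-term evaluation at p = 1, w1 = 1, w2 = 0, no input:
  # r1 = r2 = S = 10, dp = alpha * 0.5 * 1/101 - 1
  d <- fernando_rhs(c(1, 1, 0), c(0, 0), par)
  expect_equal(d[["p"]], 0.5 / 101 - 1)
  expect_equal(d[["w1"]], 0.8 * 0.5 / 101 - 0.02 + 0.1)
  # the repressor map r = S/(1+u) at zero input equals S
  expect_equal(par$S / (1 + 0), 10)
})

test_that("forced-dissociation derivatives match hand-evaluated values", {
  par <- fd_params()  # a = 2, Table values
  # x = z = 0 kills every production term
  s <- c(1.3, 0.7, 2.1)
  expect_equal(fd_rhs(s, c(0, 0), par),
               c(y = -1.3, u = -0.1 * 0.7, v = -0.02 * 2.1))
  # half-occupancy inputs at zero state
  d <- fd_rhs(c(0, 0, 0), c(1, 1), par)
  expect_equal(d[["y"]], 2 * 0.25 + 4 * 0.25 + 4 * 0.25)
  expect_equal(d[["u"]], 0.6 * 0.5)
  expect_equal(d[["v"]], 1.5 * 0.5 * 1 * 0.5)
  # adjusted variant
  da <- adjusted_fd_rhs(c(0, 0, 0), c(1, 1), adjusted_fd_params())
  expect_equal(da[["y"]], 4 * 0.5 + 1 * 0.5)
  expect_equal(da[["v"]], 1 * 0.5 * 1 * 0.5)
  expect_equal(adjusted_fd_rhs(s, c(0, 0), adjusted_fd_params()),
               c(y = -1.3, u = -0.1 * 0.7, v = -0.02 * 2.1))
})

test_that("dimensional forms reduce to the dimensionless ones under identity scaling", {
  pd <- fernando_dimensional_params()  # all K = 1, delta_p = 1, k = 1
  pn <- nondimensionalize_fernando(pd)$params
  fd_d <- fd_dimensional_params()
  fd_n <- nondimensionalize_fd(fd_d)$params
  set.seed(7)
  for (i in 1:20) {
    s <- random_state3(); u <- random_inputs()
    expect_equal(fernando_dimensional_rhs(s, u, pd), fernando_rhs(s, u, pn),
                 tolerance = 1e-12)
    expect_equal(fd_dimensional_rhs(s, u, fd_d), fd_rhs(s, u, fd_n),
                 tolerance = 1e-12)
  }
})

test_that("every RHS matches an independent term-by-term oracle on random points", {
  set.seed(101)
  for (i in 1:100) {
    s <- random_state3(); u <- random_inputs()
    expect_equal(unname(fernando_rhs(s, u, p <- random_fernando_params())),
                 oracle_fernando(s, u, p), tolerance = 1e-12)
    expect_equal(unname(fernando_dimensional_rhs(s, u, p <- random_fernando_dim_params())),
                 oracle_fernando_dim(s, u, p), tolerance = 1e-12)
    expect_equal(unname(fd_rhs(s, u, p <- random_fd_params())),
                 oracle_fd(s, u, p), tolerance = 1e-12)
    expect_equal(unname(fd_dimensional_rhs(s, u, p <- random_fd_dim_params())),
                 oracle_fd_dim(s, u, p), tolerance = 1e-12)
    expect_equal(unname(adjusted_fd_rhs(s, u, p <- random_adjusted_fd_params())),
                 oracle_adjusted_fd(s, u, p), tolerance = 1e-12)
  }
})

test_that("non-finite states or inputs are rejected by the derivatives", {
  expect_error(fernando_rhs(c(NA, 0, 0), c(0, 0), fernando_params()),
               class = "assoclearn_numeric_error")
  expect_error(fd_rhs(c(0, 0, 0), c(Inf, 0), fd_params()),
               class = "assoclearn_numeric_error")
})

test_that("moderator converges to its closed-form fixed point under saturating input", {
  # constant saturating x, z = 0: du = alpha_ux * A(x) - beta_u * u
  par <- fd_params()
  prot <- protocol(list(pulse("x", 0, 150, 1000)), horizon = 150,
                   channels = c("x", "z"))
  tr <- integrate_circuit(fd_rhs, c(y = 0, u = 0, v = 0), prot,
                          integrator_settings("rk4", 0.01), par)
  # sample one step before the horizon: the pulse window is half-open, so
  # the very last RK4 stage already sees the input switched off
  u_end <- unname(tr$states[nrow(tr$states) - 1L, "u"])
  u_star <- par$alpha_ux * hill_act(1000, par$a) / par$beta_u
  expect_equal(u_star, 6, tolerance = 1e-6)   # 0.6 / 0.1 at saturation
  expect_equal(u_end, u_star, tolerance = 1e-4)
})

test_that("with no input and no basal production every system decays to zero", {
  quiet <- function(chans, horizon) {
    protocol(list(), horizon = horizon, channels = chans)
  }
  runs <- list(
    list(rhs = fernando_rhs, par = fernando_params(tau1 = 0, tau2 = 0),
         chans = c("u1", "u2")),
    list(rhs = fernando_dimensional_rhs,
         par = fernando_dimensional_params(eps1 = 0, eps2 = 0),
         chans = c("u1", "u2")),
    list(rhs = fd_rhs, par = fd_params(), chans = c("x", "z")),
    list(rhs = fd_dimensional_rhs, par = fd_dimensional_params(),
         chans = c("x", "z")),
    list(rhs = adjusted_fd_rhs, par = adjusted_fd_params(),
         chans = c("x", "z"))
  )
  for (r in runs) {
    tr <- integrate_circuit(r$rhs, c(2, 3, 1.5), quiet(r$chans, 400),
                            integrator_settings("euler", 0.01), r$par)
    expect_true(all(diff(tr$states) <= 1e-9))         # monotone decay
    expect_lt(max(tr$states[nrow(tr$states), ]), 0.02)
  }
})

test_that("responses respect the production-sum bounds", {
  # dimensionless p is driven by two terms each at most alpha; y by three
  # terms summing to at most alpha_yx + alpha_yz + alpha_xyz
  fe <- reproduce_scenario("fig3a")
  expect_lt(max(fe$trajectory$states[, "p"]), 2 * fernando_params()$alpha * 1.01)
  fd <- reproduce_scenario("fig3b")
  q <- fd_params()
  expect_lt(max(fd$trajectory$states[, "y"]),
            (q$alpha_yx + q$alpha_yz + q$alpha_xyz) * 1.01)
})
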