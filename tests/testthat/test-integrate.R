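test_that("forward Euler and RK4 reproduce the linear-decay closed forms", {
  prot <- protocol(list(), horizon = 1, channels = "x")
  eu <- integrate_circuit(decay_rhs, c(y = 1), prot,
                          integrator_settings("euler", 0.01))
  expect_equal(eu$states[nrow(eu$states), "y"], (1 - 0.01)^100,
               tolerance = 1e-14, ignore_attr = TRUE)
  rk <- integrate_circuit(decay_rhs, c(y = 1), prot,
                          integrator_settings("rk4", 0.01))
  expect_equal(rk$states[nrow(rk$states), "y"], exp(-1),
               tolerance = 1e-8, ignore_attr = TRUE)
  # zero derivative leaves the state constant
  zero_rhs <- function(state, inputs, params) 0 * state
  cz <- integrate_circuit(zero_rhs, c(y = 2.5), prot,
                          integrator_settings("euler", 0.1))
  expect_true(all(cz$states[, "y"] == 2.5))
})

test_that("Euler error halves when the step halves (first order)", {
  prot <- protocol(list(), horizon = 1, channels = "x")
  err <- vapply(c(0.02, 0.01, 0.005), function(dt) {
    tr <- integrate_circuit(decay_rhs, c(y = 1), prot,
                            integrator_settings("euler", dt))
    abs(tr$states[nrow(tr$states), "y"] - exp(-1))
  }, numeric(1))
  expect_equal(err[1] / err[2], 2, tolerance = 0.05)
  expect_equal(err[2] / err[3], 2, tolerance = 0.05)
})

test_that("integrator input validation and failure modes are explicit", {
  prot <- protocol(list(), horizon = 1, channels = "x")
  expect_error(integrator_settings(dt = -1), class = "assoclearn_config_error")
  expect_error(integrator_settings(record_stride = 0.5),
               class = "assoclearn_config_error")
  expect_error(integrate_circuit(decay_rhs, c(y = -1), prot,
                                 integrator_settings()),
               class = "assoclearn_config_error")
  # blow-up is reported with the failure time
  blow <- function(state, inputs, params) state^2 * 1e4
  expect_error(integrate_circuit(blow, c(y = 10), prot,
                                 integrator_settings("euler", 0.1)),
               "at t = ", class = "assoclearn_numeric_error")
  # crossing below -1e-9 aborts
  down <- function(state, inputs, params) -1
  expect_error(integrate_circuit(down, c(y = 0.05), prot,
                                 integrator_settings("euler", 0.1)),
               class = "assoclearn_numeric_error")
})

test_that("record_stride thins the sampled grid without changing the solution", {
  prot <- protocol(list(), horizon = 1, channels = "x")
  full <- integrate_circuit(decay_rhs, c(y = 1), prot,
                            integrator_settings("euler", 0.01))
  thin <- integrate_circuit(decay_rhs, c(y = 1), prot,
                            integrator_settings("euler", 0.01,
                                                record_stride = 10))
  expect_equal(thin$times, full$times[seq(1, 101, by = 10)])
  expect_equal(thin$states[, "y"], full$states[seq(1, 101, by = 10), "y"])
})

test_that("step-refinement deviations shrink monotonically on a shipped scenario", {
  prot <- fd_fig3b_protocol()
  cc <- convergence_check(fd_rhs, default_initial_state("fd"), prot,
                          dts = c(0.1, 0.05, 0.01), params = fd_params())
  expect_equal(cc$dt, c(0.1, 0.05, 0.01))
  expect_true(all(diff(cc$sup_deviation) < 0))
  expect_equal(cc$sup_deviation[3], 0)
  # identical steps give zero deviation
  cc2 <- convergence_check(decay_rhs, c(y = 1),
                           protocol(list(), horizon = 1, channels = "x"),
                           dts = c(0.01, 0.01, 0.01))
  expect_true(all(cc2$sup_deviation == 0))
  # misaligned grids are a configuration error
  expect_error(convergence_check(decay_rhs, c(y = 1),
                                 protocol(list(), horizon = 1, channels = "x"),
                                 dts = c(0.1, 0.03)),
               class = "assoclearn_config_error")
})

test_that("trajectories round-trip losslessly through TSV", {
  tr <- integrate_circuit(fd_rhs, default_initial_state("fd"),
                          fd_fig3b_protocol(),
                          integrator_settings("euler", 0.05), fd_params())
  tf <- tempfile(fileext = ".tsv")
  on.exit(unlink(tf))
  write_trajectory(tr, tf)
  back <- read_trajectory(tf)
  expect_identical(back$times, tr$times)
  expect_identical(unname(back$states), unname(tr$states))
  expect_identical(colnames(back$states), colnames(tr$states))
  expect_identical(unname(back$inputs), unname(tr$inputs))
})

test_that("RK4 stage inputs see pulse edges within a step", {
  # a pulse turning on mid-step is visible to the later stages only
  prot <- protocol(list(pulse("x", 0.05, 0.95, 1)), horizon = 1,
                   channels = "x")
  track <- function(state, inputs, params) inputs[[1L]] - 0 * state
  rk <- integrate_circuit(track, c(y = 0), prot,
                          integrator_settings("rk4", 0.1))
  # first step [0, 0.1): k1 sees 0, k2/k3 (t = 0.05) and k4 (t = 0.1) see 1
  expect_equal(rk$states[2, "y"], 0.1 * (0 + 2 + 2 + 1) / 6,
               ignore_attr = TRUE)
})
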