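# build a trajectory object directly so peak extraction can be checked
# against constructed maxima
synthetic_trajectory <- function(times, y, channels = c("x", "z")) {
  structure(list(times = times,
                 states = cbind(y = y),
                 inputs = matrix(0, length(times), length(channels),
                                 dimnames = list(NULL, channels)),
                 model = "synthetic", settings = integrator_settings()),
            class = "circuit_trajectory")
}

test_that("peak extraction finds constructed window maxima", {
  prot <- protocol(list(pulse("z", 10, 2, 1), pulse("x", 30, 2, 1)),
                   horizon = 60, channels = c("x", "z"),
                   us_channel = "z", cs_channel = "x")
  times <- seq(0, 60, by = 0.5)
  # triangular bump of height 3 peaking at t = 15 inside event 1's window
  y <- pmax(0, 3 - abs(times - 15))
  spikes <- detect_response_peaks(synthetic_trajectory(times, y), prot, "y")
  expect_equal(nrow(spikes), 2L)
  expect_equal(spikes$peak[1], 3)
  expect_equal(spikes$peak_time[1], 15)
  expect_equal(spikes$baseline[1], y[times == 10])
  # second window contains only the bump's tail: peak at window start
  expect_equal(spikes$peak[2], max(y[times >= 30]))
  # constant-zero response gives all-zero peaks
  z0 <- detect_response_peaks(synthetic_trajectory(times, 0 * times), prot, "y")
  expect_true(all(z0$peak == 0))
  # protocol without events is an error
  empty <- protocol(list(), horizon = 10, channels = c("x", "z"))
  expect_error(detect_response_peaks(synthetic_trajectory(times, y), empty),
               class = "assoclearn_config_error")
})

fabricated_spikes <- function(peaks, labels, baselines = NULL) {
  out <- data.frame(event = seq_along(peaks), label = labels,
                    start = 10 * seq_along(peaks), peak = peaks,
                    peak_time = 10 * seq_along(peaks) + 1,
                    baseline = if (is.null(baselines)) rep(0, length(peaks))
                               else baselines)
  class(out) <- c("spike_table", "data.frame")
  out
}

test_that("classification verdicts follow their defining inequalities", {
  labs <- c("US_only", "CS_only", "paired", "CS_only", "paired",
            "CS_only", "CS_only")
  sp <- fabricated_spikes(c(1, 0.10, 1.2, 0.30, 1.3, 0.50, 0.09), labs)
  rep <- classify(sp)
  expect_true(rep$learning_formed)        # 0.30 > 0.10 * 1.05
  expect_true(rep$reinforced)             # 0.50 > 0.30 * 1.05
  expect_true(rep$forced_dissociation)    # 0.09 <= 0.10 * 1.05
  expect_true(rep$conditioning_dominant)  # 1.2, 1.3 > 1 * 0.95
  expect_true(rep$baseline_return)
  # raising the final probe peak destroys dissociation
  sp2 <- fabricated_spikes(c(1, 0.10, 1.2, 0.30, 1.3, 0.50, 0.45), labs)
  expect_false(classify(sp2)$forced_dissociation)
  # equal learned peaks are not reinforcement
  sp3 <- fabricated_spikes(c(1, 0.10, 1.2, 0.30, 1.3, 0.30, 0.09), labs)
  expect_false(classify(sp3)$reinforced)
  # a weak pairing response loses conditioning dominance
  sp4 <- fabricated_spikes(c(1, 0.10, 0.90, 0.30, 1.3, 0.50, 0.09), labs)
  expect_false(classify(sp4)$conditioning_dominant)
  # elevated window-start baselines lose baseline return
  sp5 <- fabricated_spikes(c(1, 0.10, 1.2, 0.30, 1.3, 0.50, 0.09), labs,
                           baselines = c(0, 0, 0.2, 0, 0, 0, 0))
  expect_false(classify(sp5)$baseline_return)
  # unlabelled spikes cannot be classified
  sp6 <- fabricated_spikes(c(1, 0.5), c(NA, NA))
  expect_error(classify(sp6), class = "assoclearn_config_error")
})

test_that("widening the tolerance only moves strict verdicts toward equality", {
  labs <- c("US_only", "CS_only", "paired", "CS_only", "paired",
            "CS_only", "CS_only")
  set.seed(20)
  for (i in 1:25) {
    sp <- fabricated_spikes(runif(7, 0, 2), labs)
    lo <- classify(sp, tol = 0.02)
    hi <- classify(sp, tol = 0.2)
    # strict verdicts can only flip TRUE -> FALSE as tol grows
    expect_true(!hi$learning_formed || lo$learning_formed)
    expect_true(!hi$reinforced || lo$reinforced)
    # the "equality-like" verdicts can only flip FALSE -> TRUE
    expect_true(!lo$forced_dissociation || hi$forced_dissociation)
    expect_true(!lo$conditioning_dominant || hi$conditioning_dominant)
  }
})

test_that("classification is deterministic and reports its tolerances", {
  res <- reproduce_scenario("fig3b")
  res2 <- reproduce_scenario("fig3b")
  expect_identical(res$report, res2$report)
  expect_identical(res$spikes, res2$spikes)
  expect_equal(res$report$tolerances, list(tol = 0.05, baseline_eps = 0.05))
})

test_that("identity perturbation reproduces the base run exactly", {
  pc <- perturb_and_classify("fd", fd_params(), "alpha_ux", 0.6,
                             fd_fig3b_protocol())
  expect_identical(pc$base$report, pc$perturbed$report)
  expect_identical(pc$base$spikes$peak, pc$perturbed$spikes$peak)
  expect_equal(length(pc$flipped), 0L)
  expect_equal(nrow(pc$newly_equal), 0L)
  expect_error(perturb_and_classify("fd", fd_params(), "no_such", 1,
                                    fd_fig3b_protocol()),
               class = "assoclearn_config_error")
})

test_that("zeroing the inhibitor supply degenerates the learned behaviour", {
  # alpha_vx -> 0: v decays from its stock and is never replenished, so the
  # conditioned pathway saturates and dissociation is lost
  pc <- perturb_and_classify("fd", fd_params(), "alpha_vx", 1e-9,
                             fd_fig3b_protocol())
  expect_true(pc$base$report$forced_dissociation)
  expect_false(pc$perturbed$report$forced_dissociation)
  expect_true("forced_dissociation" %in% pc$flipped)
  v <- pc$perturbed$trajectory$states[, "v"]
  expect_true(all(diff(v) <= 1e-12))   # pure decay of the initial stock
})

test_that("reports and spike tables serialise to flat text", {
  res <- reproduce_scenario("fig3b")
  tf1 <- tempfile(fileext = ".txt"); tf2 <- tempfile(fileext = ".tsv")
  on.exit(unlink(c(tf1, tf2)))
  write_behavior_report(res$report, tf1)
  lines <- readLines(tf1)
  expect_true(any(grepl("^forced_dissociation\tTRUE$", lines)))
  expect_true(any(grepl("^tol\t0.05$", lines)))
  write_spike_table(res$spikes, tf2)
  back <- utils::read.delim(tf2)
  expect_equal(nrow(back), nrow(res$spikes))
  expect_equal(back$peak, res$spikes$peak, tolerance = 1e-6)
})
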