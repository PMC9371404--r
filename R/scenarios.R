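#' Reproduce a shipped figure scenario
#'
#' Runs one of the package's canonical scenarios end to end with the
#' published parameter tables, the calibrated default protocols and the
#' default forward-Euler integrator (`dt = 0.01`), and returns the
#' results. All scenarios are fully deterministic.
#'
#' * `fig3a` — weight circuit, ten-event conditioning/widening protocol.
#' * `fig3b` — forced-dissociation circuit, eight-event protocol.
#' * `fig4`  — weight circuit, sweep `a = 1..4` at fixed `b = 2`.
#' * `fig5`  — weight circuit, sweep `a = b = 1..4`.
#' * `fig6a` — forced-dissociation circuit, conditioning pulses removed.
#' * `fig6b` — adjusted circuit under the matched eight-event protocol.
#' * `fig7`  — forced-dissociation circuit, sweep `a = 1..4`.
#' * `fig8`  — adjusted circuit, sweep `a = 1..4`.
#' * `fig9`  — forced-dissociation circuit with `alpha_ux` cut from 0.6 to
#'   0.45 (a 25% reduction), the parameter-sensitivity example.
#'
#' @param scenario Scenario name (see above).
#' @param settings An [integrator_settings()].
#' @param tol,baseline_eps Classifier tolerances (see [classify()]).
#' @return For single runs: list with `kind = "simulation"`, `model`,
#'   `protocol`, `trajectory`, `spikes`, `report`. For sweeps: list with
#'   `kind = "sweep"` and the [hill_sweep()] table. For `fig9`: list with
#'   `kind = "perturbation"` and the [perturb_and_classify()] result.
#' @export
reproduce_scenario <- function(scenario,
                               settings = integrator_settings(),
                               tol = 0.05, baseline_eps = 0.05) {
  known <- c("fig3a", "fig3b", "fig4", "fig5", "fig6a", "fig6b", "fig7",
             "fig8", "fig9")
  if (!is.character(scenario) || length(scenario) != 1L ||
      !scenario %in% known) {
    stop_config("unknown scenario `%s` (expected one of: %s)",
                paste(scenario, collapse = ","), paste(known, collapse = ", "))
  }
  sim <- function(model, protocol, params = NULL) {
    info <- model_info(model)
    if (is.null(params)) params <- info$params()
    res <- run_and_classify(model, params, protocol, state0 = NULL,
                            settings = settings, tol = tol,
                            baseline_eps = baseline_eps)
    c(list(kind = "simulation", scenario = scenario, model = model,
           params = params, protocol = protocol), res)
  }
  swp <- function(model, protocol, a_values, b_values = NULL) {
    table <- hill_sweep(model, protocol, params = NULL,
                        a_values = a_values, b_values = b_values,
                        settings = settings, tol = tol,
                        baseline_eps = baseline_eps)
    list(kind = "sweep", scenario = scenario, model = model,
         protocol = protocol, table = table)
  }
  switch(scenario,
    fig3a = sim("fernando", fernando_fig3a_protocol()),
    fig3b = sim("fd", fd_fig3b_protocol()),
    fig4  = swp("fernando", fernando_fig3a_protocol(), 1:4, b_values = 2),
    fig5  = swp("fernando", fernando_fig3a_protocol(), 1:4, b_values = "a"),
    fig6a = sim("fd", fd_no_conditioning_protocol()),
    fig6b = sim("adjusted_fd", fd_fig3b_protocol()),
    fig7  = swp("fd", fd_fig3b_protocol(), 1:4),
    fig8  = swp("adjusted_fd", fd_fig3b_protocol(), 1:4),
    fig9  = {
      pc <- perturb_and_classify("fd", fd_params(), "alpha_ux", 0.45,
                                 fd_fig3b_protocol(), settings = settings,
                                 tol = tol, baseline_eps = baseline_eps)
      list(kind = "perturbation", scenario = scenario, model = "fd",
           protocol = fd_fig3b_protocol(), result = pc)
    }
  )
}
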