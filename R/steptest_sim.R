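#' Simulate a step-test experiment
#'
#' Emulates the kinetic assay: at `t = 0` the input steps up, the
#' transcription factor localizes to the nucleus with a per-cell random
#' onset and first-order approach, and transcription switches on a fixed
#' delay after the TF becomes nuclear (optionally with an extra delay for
#' cells that are in G1 at that moment). Protein traces include the
#' maturation step and measurement noise; transcription rates are inferred
#' back from the running totals, so the output plugs directly into
#' [steptest_delays()].
#'
#' @param config a [sim_config()].
#' @param n_cells number of cells.
#' @param delay fixed biological delay between TF localization and
#'   transcription onset, min.
#' @param extra_delay_g1 additional delay for cells in G1 at localization,
#'   min.
#' @param loc_rate mean TF nuclear-import rate, 1/min (per-cell lognormal
#'   spread 20%).
#' @param loc_onset_sd SD of the per-cell localization onset, min.
#' @param loc_noise_sd measurement noise on the localization series, AU.
#' @param beta smoothing parameter used for the inference step.
#' @param n_cycles simulation horizon, cycles.
#' @param seed RNG seed.
#' @return list of cells for [steptest_delays()]; each element also carries
#'   `truth` (`t_loc_on`, `t_act_true`, `g1_at_onset`).
#' @export
simulate_step_test <- function(config, n_cells = 50, delay = 0,
                               extra_delay_g1 = 0, loc_rate = 0.3,
                               loc_onset_sd = 2, loc_noise_sd = 2,
                               beta = default_beta(), n_cycles = 3,
                               seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  T <- config$t_cyc
  lapply(seq_len(n_cells), function(i) {
    phase0 <- stats::runif(1, 0, T)
    t_loc_on <- abs(stats::rnorm(1, 5, loc_onset_sd))
    r <- loc_rate * stats::rlnorm(1, 0, 0.2)
    # is the cell pre-bud (G1) when the TF arrives?
    age_at <- (phase0 + t_loc_on) %% T
    g1 <- age_at < config$bud_fraction * T
    t_act_true <- t_loc_on + delay + if (g1) extra_delay_g1 else 0
    gen <- gen_step(t_act_true, config$gamma_M * config$mu)
    tr <- simulate_cell(config, gen, n_cycles = n_cycles, mode = "ode",
                        phase0 = phase0, cell_id = sprintf("cell%03d", i))
    rates <- infer_from_trace(list(times = tr$running_total$time,
                                   P = tr$running_total$P_obs,
                                   cell_id = tr$cell_id),
                              gamma_M = config$gamma_M, k_t = config$k_t,
                              beta = beta)
    loc_t <- tr$times
    loc_v <- 100 * (1 - exp(-r * pmax(loc_t - t_loc_on, 0))) +
      stats::rnorm(length(loc_t), 0, loc_noise_sd)
    list(cell_id = tr$cell_id, rates = rates,
         localization = data.frame(time = loc_t, value = loc_v),
         bud_times = tr$bud_times, division_times = tr$division_times,
         truth = list(t_loc_on = t_loc_on, t_act_true = t_act_true,
                      g1_at_onset = g1))
  })
}
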