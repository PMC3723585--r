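# shared fixtures for the suite; everything is generated in code

# canonical study conditions
study_config <- function(...) sim_config(...)

# a small, fast configuration for unit tests (unit translation rate so SSA
# protein counts stay small)
tiny_config <- function(...) {
  sim_config(k_t = 1, noise_var = 0, ...)
}

# asynchronous population of simulated traces with cycle-modulated rates
simulate_async_population <- function(cfg, n_cells, n_cycles = 3,
                                      noise = TRUE, seed = 1) {
  set.seed(seed)
  lapply(seq_len(n_cells), function(i) {
    p <- stats::runif(1, 0, cfg$t_cyc)
    gen <- gen_cycle_modulated(cfg$gamma_M * cfg$mu, cfg$pt_ratio, cfg$t_cyc,
                               cfg$bud_fraction, phase_offset = p)
    simulate_cell(cfg, gen, n_cycles = n_cycles, mode = "ode", noise = noise,
                  phase0 = p, cell_id = sprintf("c%03d", i))
  })
}

# paired ON/OFF period records for two loci sharing a Bernoulli trigger;
# q and r tune the phi coefficient: phi = r (1 - q) / (1 - q r)
simulate_locus_pair <- function(n, q, r, jitter_sd = 3) {
  z <- stats::runif(n) < q
  on_a <- z & (stats::runif(n) < r)
  on_b <- z & (stats::runif(n) < r)
  t0 <- stats::runif(n, 0, 20)
  list(a = data.frame(period = seq_len(n), on = on_a,
                      t_act = ifelse(on_a, t0 + stats::rnorm(n, 0, jitter_sd), NA)),
       b = data.frame(period = seq_len(n), on = on_b,
                      t_act = ifelse(on_b, t0 + stats::rnorm(n, 0, jitter_sd), NA)))
}

# Fig-S18-style timing study: square-pulse transcription, maturation in the
# forward model only, activation at 50% of the population steady-state rate
timing_study <- function(n_traces, seed, beta = default_beta(),
                         t_on = 100, t_off = 200) {
  cfg <- study_config()
  gen <- gen_square_pulse(t_on, t_off, cfg$gamma_M * cfg$mu)
  set.seed(seed)
  grid <- seq(0, 3 * cfg$t_cyc, by = cfg$sampling_interval)
  A_mat <- matrix(NA_real_, length(grid), n_traces)
  for (i in seq_len(n_traces)) {
    tr <- simulate_cell(cfg, gen, n_cycles = 3, mode = "ode", noise = TRUE)
    r <- infer_from_trace(list(times = tr$running_total$time,
                               P = tr$running_total$P_obs),
                          gamma_M = cfg$gamma_M, k_t = cfg$k_t, beta = beta)
    A_mat[, i] <- r$A
  }
  plateau <- grid >= t_on + 50 & grid <= t_off - 5
  thr <- 0.5 * mean(A_mat[plateau, ])
  cross <- apply(A_mat, 2, function(a) {
    i <- which(a[-1] > thr & a[-length(a)] <= thr &
                 grid[-1] > t_on - 50 & grid[-1] <= t_off - 50)
    if (!length(i)) return(NA_real_)
    i <- i[1]
    grid[i] + diff(grid[1:2]) * (thr - a[i]) / (a[i + 1] - a[i])
  })
  delay <- cross - t_on
  list(delay = delay[!is.na(delay)], n_detected = sum(!is.na(delay)),
       threshold = thr)
}
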