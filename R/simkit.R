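#' Simulation configuration
#'
#' Bundles the physical parameters of the single-cell simulator. Defaults are
#' the canonical study conditions: 5-min imaging, 100-min cycle, budding at
#' 27% of cycle progression, mRNA half-life 20 min, CFP-like maturation
#' half-life 10 min, target steady-state mRNA count 10, additive Gaussian
#' measurement noise of variance 2.4e4 AU^2 on total fluorescence, and a
#' 2:1 peak-to-trough cycle modulation of transcription. Volume growth is
#' exponential and two-phase: slow before budding (G1), twice as fast after,
#' scaled so the compartment volume doubles over one cycle.
#'
#' @param sampling_interval imaging interval, min.
#' @param t_cyc cell-cycle length, min.
#' @param bud_fraction budding point as a fraction of the cycle, in (0,1).
#' @param g1_growth_rate,sg2m_growth_rate exponential volume growth rates,
#'   1/min, for the pre- and post-bud phases.
#' @param gamma_M mRNA degradation rate, 1/min.
#' @param k_t translation rate, protein AU per mRNA per min.
#' @param k_m fluorophore maturation rate, 1/min.
#' @param mu target steady-state mRNA count (dimensionless).
#' @param pt_ratio peak-to-trough transcription-rate ratio across the cycle.
#' @param noise_var variance of additive Gaussian noise on total
#'   fluorescence, AU^2.
#' @param transition_window width of the randomized G1 to S/G2/M transition
#'   window, min.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(sampling_interval = 5,
                       t_cyc = 100,
                       bud_fraction = 0.27,
                       g1_growth_rate = log(2) / (t_cyc * (bud_fraction + 2 * (1 - bud_fraction))),
                       sg2m_growth_rate = 2 * g1_growth_rate,
                       gamma_M = log(2) / 20,
                       k_t = 20,
                       k_m = log(2) / 10,
                       mu = 10,
                       pt_ratio = 2,
                       noise_var = 2.4e4,
                       transition_window = 40) {
  cfg <- list(sampling_interval = sampling_interval, t_cyc = t_cyc,
              bud_fraction = bud_fraction,
              g1_growth_rate = g1_growth_rate,
              sg2m_growth_rate = sg2m_growth_rate,
              gamma_M = gamma_M, k_t = k_t, k_m = k_m, mu = mu,
              pt_ratio = pt_ratio, noise_var = noise_var,
              transition_window = transition_window)
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  with(cfg, {
    if (sampling_interval <= 0) stop("sampling_interval must be > 0")
    if (t_cyc <= 0) stop("t_cyc must be > 0")
    if (bud_fraction <= 0 || bud_fraction >= 1)
      stop("bud_fraction must lie strictly inside (0, 1)")
    rates <- c(g1_growth_rate, sg2m_growth_rate, gamma_M, k_t, k_m)
    if (any(rates < 0) || any(!is.finite(rates))) stop("all rates must be >= 0 and finite")
    if (gamma_M <= 0) stop("gamma_M must be > 0")
    if (k_m <= 0) stop("k_m must be > 0")
    if (mu < 0) stop("mu must be >= 0")
    if (pt_ratio < 1) stop("pt_ratio must be >= 1")
    if (noise_var < 0) stop("noise_var must be >= 0")
    if (transition_window < 0) stop("transition_window must be >= 0")
  })
  invisible(cfg)
}

#' Read or write a simulation configuration as YAML
#' @param path file path.
#' @export
read_sim_config <- function(path) {
  do.call(sim_config, yaml::read_yaml(path))
}

#' @param config a `sim_config`.
#' @rdname read_sim_config
#' @export
write_sim_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# --- linear-cascade stepping ------------------------------------------------
# state x = (M, Pi, Pm); dx/dt = B x + A(t) e1 with
#   B = [[-gamma, 0, 0], [k_t, -k_m, 0], [0, k_m, 0]]
# For constant A over a step h the update is exact:
#   x(t+h) = E(h) x(t) + A w(h),  E = expm(Bh), w = int_0^h expm(Bs) e1 ds,
# both read off the matrix exponential of an augmented 4x4 system. E and w
# are cached per step size, so integration is a chain of 3x3 multiplies.
cascade_stepper <- function(gamma, k_t, k_m) {
  B <- rbind(c(-gamma, 0, 0), c(k_t, -k_m, 0), c(0, k_m, 0))
  Baug <- rbind(cbind(B, c(1, 0, 0)), 0)
  cache <- new.env(parent = emptyenv())
  function(h) {
    key <- format(h, digits = 15)
    got <- cache[[key]]
    if (is.null(got)) {
      Eaug <- as.matrix(Matrix::expm(Baug * h))
      got <- list(E = Eaug[1:3, 1:3, drop = FALSE], w = Eaug[1:3, 4])
      cache[[key]] <- got
    }
    got
  }
}

# division / budding schedule for a cell phase0 minutes into its cycle at t=0
cycle_schedule <- function(config, t_max, phase0 = 0) {
  T <- config$t_cyc
  b <- config$bud_fraction
  stopifnot(phase0 >= 0, phase0 < T)
  cycle_starts <- seq(-phase0, t_max + T, by = T)
  divisions <- cycle_starts  # each cycle start is a division (incl. birth)
  buds <- cycle_starts + b * T
  # events of the in-progress cycle before t = 0 are kept (negative times):
  # they anchor phase assignment for observations starting mid-cycle
  list(cycle_starts = cycle_starts,
       divisions = divisions[divisions <= t_max + 1e-9],
       buds = buds[buds <= t_max + 1e-9])
}

# volume of the mother compartment (mother body + attached bud) at times t;
# resets at division when the bud (all post-budding growth) leaves
compartment_volume <- function(config, t, phase0 = 0, v0 = 1) {
  T <- config$t_cyc; b <- config$bud_fraction
  g1 <- config$g1_growth_rate; g2 <- config$sg2m_growth_rate
  age <- (t + phase0) %% T
  n_div <- floor((t + phase0) / T) - floor(phase0 / T)
  v_bud_rel <- exp(g1 * b * T)       # growth factor from division to budding
  v_start <- v0 * v_bud_rel^n_div    # mother body grows slowly across generations
  ifelse(age < b * T,
         v_start * exp(g1 * age),
         v_start * v_bud_rel * exp(g2 * (age - b * T)))
}

# fraction of compartment volume the mother keeps at division
mother_keep_fraction <- function(config) {
  exp(-config$sg2m_growth_rate * (1 - config$bud_fraction) * config$t_cyc)
}

#' Simulate a single-cell lineage
#'
#' Forward-simulates one tracked mother cell: transcription rate `A(t)` from a
#' generator, mRNA birth-death `dM/dt = A - gamma_M * M`, translation into an
#' immature protein pool at `k_t * M`, first-order maturation at `k_m`,
#' two-phase exponential volume growth, budding/division events, and additive
#' Gaussian noise on total fluorescence. In `ode` mode dynamics are the exact
#' deterministic solution (matrix-exponential stepping between generator
#' change points) and molecular content partitions by volume fraction at
#' division; in `ssa` mode all four reactions are a Gillespie jump process and
#' partitioning is binomial with the same volume-fraction probability.
#' Daughters inherit content at division and their content keeps decaying,
#' translating and maturing, but daughters do not transcribe, so the lineage
#' running total is governed by the mother's `A(t)` alone.
#'
#' @param config a [sim_config()].
#' @param generator a [generators] object giving `A(t)` in mRNA/min.
#' @param n_cycles number of cell cycles to simulate (horizon
#'   `n_cycles * t_cyc` min).
#' @param mode `"ode"` (deterministic mean dynamics) or `"ssa"` (Gillespie).
#' @param noise add measurement noise of variance `config$noise_var`?
#' @param phase0 minutes already elapsed in the current cycle at `t = 0`
#'   (use to generate asynchronous populations).
#' @param cell_id identifier stored in the trace.
#' @param seed optional RNG seed.
#' @return a `cell_trace`: sampled `times`, `volume`, `conc` (observed
#'   total fluorescence / volume) for the mother compartment, `bud_times`,
#'   `division_times`, per-sample ground truth (`truth`, lineage totals), the
#'   lineage `running_total` (observed = true mature protein + one draw of
#'   measurement noise), and `progeny` entity traces.
#' @export
simulate_cell <- function(config, generator, n_cycles = 3,
                          mode = c("ode", "ssa"), noise = TRUE,
                          phase0 = 0, cell_id = "cell1", seed = NULL) {
  mode <- match.arg(mode)
  validate_sim_config(config)
  stopifnot(n_cycles >= 1)
  if (!is.null(seed)) set.seed(seed)
  t_max <- n_cycles * config$t_cyc
  grid <- seq(0, t_max, by = config$sampling_interval)
  sched <- cycle_schedule(config, t_max, phase0)
  rate_at(generator, grid)  # validates the generator over the horizon

  lineage <- if (mode == "ode") {
    integrate_lineage(config, generator, grid, sched, phase0, stochastic = FALSE)
  } else {
    integrate_lineage(config, generator, grid, sched, phase0, stochastic = TRUE)
  }

  sd_noise <- if (noise) sqrt(config$noise_var) else 0
  add_noise <- function(x)
    x + if (sd_noise > 0) stats::rnorm(length(x), 0, sd_noise) else 0

  vol <- compartment_volume(config, grid, phase0)
  mother_obs <- add_noise(lineage$mother[, "Pm"])
  progeny <- lapply(seq_along(lineage$daughters), function(i) {
    d <- lineage$daughters[[i]]
    idx <- which(grid >= d$t_birth - 1e-9)
    dv <- d$v_birth * exp(config$g1_growth_rate * (grid[idx] - d$t_birth))
    pm <- d$series[idx, "Pm"]
    obs <- add_noise(pm)
    structure(list(cell_id = paste0(cell_id, ".d", i), mother_id = cell_id,
                   times = grid[idx], volume = dv, total_true = pm,
                   total_obs = obs, conc = obs / dv,
                   t_birth = d$t_birth),
              class = "entity_trace")
  })

  structure(list(
    cell_id = cell_id, mother_id = NA_character_,
    times = grid,
    volume = vol,
    total_true = lineage$mother[, "Pm"],
    total_obs = mother_obs,
    conc = mother_obs / vol,
    bud_times = sched$buds, division_times = sched$divisions,
    truth = data.frame(time = grid,
                       A = rate_at(generator, grid),
                       M = lineage$total[, "M"],
                       M_mother = lineage$mother[, "M"],
                       Pi_total = lineage$total[, "Pi"],
                       Pm_total = lineage$total[, "Pm"]),
    running_total = data.frame(time = grid,
                               P_obs = add_noise(lineage$total[, "Pm"]),
                               P_true = lineage$total[, "Pm"]),
    progeny = progeny,
    config = config, generator = generator, mode = mode, phase0 = phase0
  ), class = "cell_trace")
}

# Integrate the mother + daughter entities over `grid`. Deterministic path
# uses exact matrix-exponential stepping; stochastic path runs Gillespie on
# (M, Pi, Pm) with piecewise-constant A. Returns per-grid-point mother state,
# lineage totals, and per-daughter state series.
integrate_lineage <- function(config, generator, grid, sched, phase0,
                              stochastic = FALSE) {
  t_max <- max(grid)
  brk <- generator$breaks
  pts <- sort(unique(c(grid, sched$divisions,
                       brk[brk > 0 & brk < t_max])))
  pts <- pts[pts >= 0 & pts <= t_max + 1e-9]
  if (pts[1] > 1e-12) pts <- c(0, pts)
  n <- length(pts)
  keep <- vapply(grid, function(g) which.min(abs(pts - g)), integer(1))

  step_fn <- cascade_stepper(config$gamma_M, config$k_t, config$k_m)
  A0 <- rate_at(generator, 0)
  x0 <- c(M = A0 / config$gamma_M,
          Pi = config$k_t * A0 / config$gamma_M / config$k_m,
          Pm = 0)
  if (stochastic) {
    x0["M"] <- stats::rpois(1, x0["M"])
    x0["Pi"] <- stats::rpois(1, x0["Pi"])
  }
  q_keep <- mother_keep_fraction(config)

  entities <- list(list(x = x0, A_on = TRUE, t_birth = 0, v_birth = NA))
  series <- list(matrix(0, n, 3, dimnames = list(NULL, c("M", "Pi", "Pm"))))
  series[[1]][1, ] <- x0

  for (i in seq_len(n - 1)) {
    t0 <- pts[i]; t1 <- pts[i + 1]
    A_loc <- rate_at(generator, (t0 + t1) / 2)
    for (j in seq_along(entities)) {
      e <- entities[[j]]
      A_e <- if (e$A_on) A_loc else 0
      e$x <- if (stochastic) {
        ssa_cascade_step(e$x, A_e, config, t1 - t0)
      } else {
        st <- step_fn(t1 - t0)
        drop(st$E %*% e$x) + A_e * st$w
      }
      entities[[j]] <- e
    }
    if (any(abs(sched$divisions - t1) < 1e-9)) {
      v_before <- compartment_volume(config, t1 - 1e-6, phase0)
      xm <- entities[[1]]$x
      d_x <- if (stochastic) {
        dm <- c(M = stats::rbinom(1, round(xm["M"]), 1 - q_keep),
                Pi = stats::rbinom(1, round(xm["Pi"]), 1 - q_keep),
                Pm = stats::rbinom(1, round(xm["Pm"]), 1 - q_keep))
        names(dm) <- c("M", "Pi", "Pm")
        dm
      } else {
        (1 - q_keep) * xm
      }
      entities[[1]]$x <- xm - d_x
      entities[[length(entities) + 1]] <-
        list(x = d_x, A_on = FALSE, t_birth = t1,
             v_birth = (1 - q_keep) * v_before)
      series[[length(series) + 1]] <-
        matrix(0, n, 3, dimnames = list(NULL, c("M", "Pi", "Pm")))
    }
    for (j in seq_along(entities))
      series[[j]][i + 1, ] <- entities[[j]]$x
  }

  tot <- Reduce(`+`, series)
  daughters <- lapply(seq_along(entities)[-1], function(j)
    list(t_birth = entities[[j]]$t_birth, v_birth = entities[[j]]$v_birth,
         series = series[[j]][keep, , drop = FALSE]))
  list(mother = series[[1]][keep, , drop = FALSE],
       total = tot[keep, , drop = FALSE],
       daughters = daughters)
}

# Gillespie over one interval of length h with constant transcription rate A.
# Reactions: birth A; death gamma*M; translation k_t*M (Pi+1);
# maturation k_m*Pi (Pi-1, Pm+1).
ssa_cascade_step <- function(x, A, config, h) {
  M <- round(x[["M"]]); Pi <- round(x[["Pi"]]); Pm <- round(x[["Pm"]])
  t <- 0
  repeat {
    a <- c(A, config$gamma_M * M, config$k_t * M, config$k_m * Pi)
    a0 <- sum(a)
    if (a0 <= 0) break
    dt <- stats::rexp(1, a0)
    if (t + dt > h) break
    t <- t + dt
    r <- stats::runif(1) * a0
    if (r < a[1]) M <- M + 1
    else if (r < a[1] + a[2]) M <- M - 1
    else if (r < a[1] + a[2] + a[3]) Pi <- Pi + 1
    else { Pi <- Pi - 1; Pm <- Pm + 1 }
  }
  c(M = M, Pi = Pi, Pm = Pm)
}

#' Simulate a cycloheximide-chase fluorescence trace
#'
#' After translation inhibition no new immature protein is made; mature
#' fluorescence keeps rising as the existing immature pool converts at rate
#' `k_m`, while both pools are lost at rate `gamma_P` (0 for stable
#' reporters). The observed series is the mature fluorescence plus iid
#' Gaussian noise.
#'
#' @param k_m maturation rate, 1/min (`> 0`).
#' @param gamma_P protein loss rate, 1/min (`>= 0`).
#' @param duration chase length, min.
#' @param noise_sd measurement noise SD, AU.
#' @param sampling_interval min.
#' @param immature0,mature0 pool sizes at inhibition, AU.
#' @param seed optional RNG seed.
#' @return data.frame `time`, `conc` (observed), `conc_true`, with the true
#'   parameters attached as attributes.
#' @export
simulate_chase <- function(k_m, gamma_P = 0, duration = 120, noise_sd = 0,
                           sampling_interval = 5, immature0 = 500,
                           mature0 = 1000, seed = NULL) {
  stopifnot(k_m > 0, gamma_P >= 0, duration > 0)
  if (!is.null(seed)) set.seed(seed)
  t <- seq(0, duration, by = sampling_interval)
  true <- chase_model(t, k_m, gamma_P, immature0, mature0)
  obs <- true + if (noise_sd > 0) stats::rnorm(length(t), 0, noise_sd) else 0
  structure(data.frame(time = t, conc = obs, conc_true = true),
            k_m = k_m, gamma_P = gamma_P,
            immature0 = immature0, mature0 = mature0)
}

# closed form of the two-pool chase:
#   Pi' = -(k_m + gamma_P) Pi;  Pm' = k_m Pi - gamma_P Pm
chase_model <- function(t, k_m, gamma_P, immature0, mature0) {
  if (gamma_P == 0) {
    mature0 + immature0 * (1 - exp(-k_m * t))
  } else {
    exp(-gamma_P * t) * (mature0 + immature0 * (1 - exp(-k_m * t)))
  }
}
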