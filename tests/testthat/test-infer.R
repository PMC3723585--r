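test_that("running totals are continuous at division and track the truth", {
  cfg <- tiny_config()
  tr <- simulate_cell(cfg, gen_constant(cfg$gamma_M * cfg$mu),
                      n_cycles = 3, mode = "ode", noise = FALSE)
  rt <- build_running_total(tr, use_true = TRUE)
  # equals the simulated cumulative mature protein
  expect_lt(max(abs(rt$P - tr$truth$Pm_total)) /
              max(tr$truth$Pm_total), 1e-9)
  # no progeny: total is just the mother's observed total
  rt0 <- build_running_total(tr, progeny = list(), use_true = TRUE)
  expect_equal(rt0$P, tr$total_true)
  # duplicate progeny rejected
  expect_error(build_running_total(tr, progeny = c(tr$progeny, tr$progeny[1])),
               "duplicate")
})

test_that("smoothing spline reproduces polynomial data and flattens as beta grows", {
  t <- seq(0, 200, by = 5)
  P <- 2 + 0.5 * t + 0.01 * t^2   # quadratic: representable by a cubic spline
  f <- fit_smoothing_spline(list(times = t, P = P), beta = 1e-6)
  expect_lt(max(abs(predict_spline(f, t) - P)) / max(abs(P)), 1e-6)
  # beta -> infinity: least-squares line, curvature -> 0
  fbig <- fit_smoothing_spline(list(times = t, P = P), beta = 1e12)
  expect_lt(max(abs(predict_spline(fbig, t, deriv = 2))), 1e-6)
  lm_fit <- stats::lm(P ~ t)
  expect_equal(predict_spline(fbig, t), unname(stats::fitted(lm_fit)),
               tolerance = 1e-3)
  expect_error(fit_smoothing_spline(list(times = t[1:5], P = P[1:5])),
               "at least 8")
  expect_error(predict_spline(f, 300), "outside")
})

test_that("ODE inversion recovers M and A from exact traces", {
  t <- seq(0, 150, by = 5)
  # linear accumulation: P = k_t * 10 * t with k_t = 1
  f <- fit_smoothing_spline(list(times = t, P = 10 * t), beta = 1)
  r <- infer_rates(f, t, gamma_M = 0.05, k_t = 1)
  expect_equal(r$M, rep(10, length(t)), tolerance = 1e-6)
  expect_equal(r$A, rep(0.5, length(t)), tolerance = 1e-6)
  # constant P: nothing is being made
  fc <- fit_smoothing_spline(list(times = t, P = rep(7, length(t))), beta = 1)
  rc <- infer_rates(fc, t, gamma_M = 0.05, k_t = 1)
  expect_equal(rc$M, rep(0, length(t)), tolerance = 1e-8)
  expect_equal(rc$A, rep(0, length(t)), tolerance = 1e-8)
})

test_that("inference is linear in the trace scale", {
  cfg <- study_config()
  tr <- simulate_cell(cfg, gen_square_pulse(100, 200, cfg$gamma_M * cfg$mu),
                      n_cycles = 3, mode = "ode", noise = TRUE, seed = 3)
  rt <- tr$running_total
  r1 <- infer_from_trace(list(times = rt$time, P = rt$P_obs),
                         gamma_M = cfg$gamma_M, k_t = cfg$k_t)
  r3 <- infer_from_trace(list(times = rt$time, P = 3 * rt$P_obs),
                         gamma_M = cfg$gamma_M, k_t = cfg$k_t)
  expect_equal(r3$M, 3 * r1$M, tolerance = 1e-8)
  expect_equal(r3$A, 3 * r1$A, tolerance = 1e-8)
})

test_that("round trip: noiseless fast-maturation pulse recovers A within 5%", {
  # fast maturation makes the reporter effectively instantaneous, so the
  # inversion should reproduce the generator away from the pulse edges
  cfg <- sim_config(k_m = log(2) / 0.25, noise_var = 0)
  amp <- cfg$gamma_M * cfg$mu
  tr <- simulate_cell(cfg, gen_square_pulse(100, 200, amp),
                      n_cycles = 3, mode = "ode", noise = FALSE)
  rt <- tr$running_total
  r <- infer_from_trace(list(times = rt$time, P = rt$P_true),
                        gamma_M = cfg$gamma_M, k_t = cfg$k_t, beta = 1e-3)
  interior <- rt$time >= 115 & rt$time <= 185
  expect_lt(max(abs(r$A[interior] - amp)) / amp, 0.05)
})

test_that("select_beta is deterministic, order-invariant, and monotone when noiseless", {
  cfg <- study_config()
  mk_ps <- function(mu) {
    c2 <- sim_config(mu = mu)
    list(config = c2, generator_fn = function(config, phase)
      gen_cycle_modulated(config$gamma_M * config$mu, config$pt_ratio,
                          config$t_cyc, config$bud_fraction,
                          phase_offset = phase))
  }
  grid <- c(10, 100, 1000, 10000)
  ps <- list(mk_ps(10), mk_ps(30))
  r1 <- select_beta(grid, ps, n_reps = 5, seed = 42)
  r2 <- select_beta(grid, ps, n_reps = 5, seed = 42)
  expect_identical(r1$residuals, r2$residuals)
  r_rev <- select_beta(grid, rev(ps), n_reps = 5, seed = 42)
  expect_equal(r_rev$beta_star, r1$beta_star)
  expect_equal(sort(r_rev$total), sort(r1$total), tolerance = 1e-12)
  # identical parameter sets give identical residual columns
  r_dup <- select_beta(grid, list(mk_ps(10), mk_ps(10)), n_reps = 5, seed = 1)
  expect_equal(r_dup$residuals[, 1], r_dup$residuals[, 2], tolerance = 1e-12)
  # noiseless: less smoothing always helps, so the smallest beta wins
  rn <- select_beta(grid, ps[1], n_reps = 5, seed = 7, noise = FALSE)
  expect_equal(unname(which.min(rn$total)), 1L)
})

test_that("maturation rate is recovered from chase traces", {
  ch <- simulate_chase(log(2) / 10, duration = 120, noise_sd = 0)
  fit <- estimate_maturation(ch)
  expect_true(fit$converged)
  expect_equal(fit$half_life, 10, tolerance = 1e-3)
  # flat trace: flagged, not fit
  set.seed(13)
  flat <- data.frame(time = seq(0, 100, 5), conc = 1000 + rnorm(21, 0, 1))
  ffit <- estimate_maturation(flat)
  expect_false(ffit$converged)
  expect_error(estimate_maturation(data.frame(time = 1:5, conc = 1:5)),
               "at least 10")
})

test_that("post-off mRNA decay is first order at the configured rate", {
  # exact exponential input
  t <- seq(0, 100, 5)
  rates <- data.frame(time = t, M = 12 * exp(-0.04 * t))
  dc <- check_decay(rates, off_time = 0, gamma_M_expected = 0.04)
  expect_equal(dc$gamma, 0.04, tolerance = 1e-8)
  expect_true(dc$consistent)
  # constant M: gamma ~ 0, flagged inconsistent
  dc0 <- check_decay(data.frame(time = t, M = rep(5, length(t))),
                     off_time = 0, gamma_M_expected = 0.04)
  expect_lt(dc0$gamma, 1e-6)
  expect_false(dc0$consistent)
  expect_error(check_decay(rates, off_time = 95, gamma_M_expected = 0.04),
               "fewer than 4")
})

test_that("spline fits serialize to JSON", {
  t <- seq(0, 100, 5)
  f <- fit_smoothing_spline(list(times = t, P = t^2, cell_id = "x"), beta = 10)
  path <- tempfile(fileext = ".json")
  write_spline_json(f, path)
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(obj$beta, 10)
  expect_equal(length(obj$coef), length(f$fit$fit$coef))
})
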