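test_that("generators are piecewise constant, non-negative, and validated", {
  g <- gen_square_pulse(40, 90, 0.5, baseline = 0.1)
  expect_equal(rate_at(g, c(0, 39.9, 40, 89.9, 90, 200)),
               c(0.1, 0.1, 0.5, 0.5, 0.1, 0.1))
  expect_error(gen_square_pulse(90, 40, 1))
  expect_error(gen_constant(-1))
  gc <- gen_cycle_modulated(0.35, pt_ratio = 2, t_cyc = 100,
                            bud_fraction = 0.27)
  # cycle average equals the requested mean rate
  tt <- seq(0, 99.99, by = 0.01)
  expect_equal(mean(rate_at(gc, tt)), 0.35, tolerance = 1e-3)
  expect_equal(max(rate_at(gc, tt)) / min(rate_at(gc, tt)), 2)
})

test_that("constant generator at A = gamma_M * mu holds mRNA at mu", {
  cfg <- tiny_config()
  tr <- simulate_cell(cfg, gen_constant(cfg$gamma_M * cfg$mu),
                      n_cycles = 3, mode = "ode", noise = FALSE)
  expect_equal(tr$truth$M, rep(cfg$mu, length(tr$times)), tolerance = 1e-8)
})

test_that("measurement noise has the configured variance", {
  cfg <- study_config()
  gen <- gen_constant(cfg$gamma_M * cfg$mu)
  set.seed(20)
  resid <- unlist(lapply(1:100, function(i) {
    tr <- simulate_cell(cfg, gen, n_cycles = 5, mode = "ode", noise = TRUE)
    tr$running_total$P_obs - tr$running_total$P_true
  }))
  expect_gt(length(resid), 10000)
  expect_lt(abs(mean(resid)), 3 * sqrt(cfg$noise_var / length(resid)))
  expect_lt(abs(stats::var(resid) - cfg$noise_var), 0.1 * cfg$noise_var)
})

test_that("SSA and ODE modes agree on mean mRNA for a piecewise-constant rate", {
  cfg <- tiny_config()
  gen <- gen_square_pulse(50, 150, cfg$gamma_M * cfg$mu)
  ode <- simulate_cell(cfg, gen, n_cycles = 2, mode = "ode", noise = FALSE)
  set.seed(31)
  n_rep <- 40
  idx <- c(21, 31, 41)  # t = 100, 150, 200
  ssa <- replicate(n_rep, {
    tr <- simulate_cell(cfg, gen, n_cycles = 2, mode = "ssa", noise = FALSE)
    tr$truth$M[idx]
  })
  se <- apply(ssa, 1, stats::sd) / sqrt(n_rep)
  expect_true(all(abs(rowMeans(ssa) - ode$truth$M[idx]) < 3 * se + 1e-9))
})

test_that("SSA stationary mRNA is Poisson-like (mean and variance near mu)", {
  cfg <- tiny_config(t_cyc = 3000, mu = 10)   # one long cycle, no division
  tr <- simulate_cell(cfg, gen_constant(cfg$gamma_M * cfg$mu),
                      n_cycles = 1, mode = "ssa", noise = FALSE, seed = 8)
  m <- tr$truth$M_mother[-(1:60)]  # drop burn-in and pre-bud part
  # ~50 effectively independent samples at these settings
  expect_equal(mean(m), cfg$mu, tolerance = 1.5)
  expect_equal(stats::var(m), cfg$mu, tolerance = 5)
})

test_that("molecular content is conserved at division", {
  cfg <- tiny_config()
  for (mode in c("ode", "ssa")) {
    tr <- simulate_cell(cfg, gen_constant(cfg$gamma_M * cfg$mu),
                        n_cycles = 3, mode = mode, noise = FALSE, seed = 5)
    recon <- tr$total_true
    for (p in tr$progeny) {
      i <- match(p$times, tr$times)
      recon[i] <- recon[i] + p$total_true
    }
    expect_equal(recon, tr$truth$Pm_total, tolerance = 1e-9)
  }
})

test_that("population snapshot ages follow the exponential-growth density", {
  set.seed(12)
  a <- sample_ages(5000, 100)
  ks <- suppressWarnings(
    stats::ks.test(a, function(q) 2 * (1 - 2^(-q / 100))))
  expect_gt(ks$p.value, 0.01)
})

test_that("phase-homogeneous snapshot model gives equal phase means", {
  m <- model_spec(k_G1 = 0.3, f = 1, gamma_M = log(2) / 2)
  pc <- simulate_population_snapshot(m, 4000, seed = 14)
  means <- tapply(pc$count, pc$phase, mean)
  pred <- predict_model(m)$per_phase
  for (ph in pred$phase) {
    se <- stats::sd(pc$count[pc$phase == ph]) /
      sqrt(sum(pc$phase == ph))
    expect_lt(abs(means[[ph]] - pred$mean[pred$phase == ph]), 3 * se + 1e-9)
  }
})

test_that("basal model (no G1 transcription) gives a zero-peaked G1 tail", {
  # fast mRNA turnover: carryover from the previous cycle decays within G1
  m <- model_spec(k_G1 = 0, k_sgm = 0.6, gamma_M = log(2) / 5)
  pc <- simulate_population_snapshot(m, 4000, seed = 15)
  g1 <- pc$count[pc$phase == "G1"]
  expect_gt(mean(g1 == 0), 0.5)                  # zero-peaked
  expect_gt(max(g1), 0)                          # with a decaying tail
  expect_gt(mean(pc$count[pc$phase == "S3"]), mean(pc$count[pc$phase == "S1"]))
})

test_that("chase traces follow the closed-form two-pool solution", {
  k_m <- log(2) / 32
  ch <- simulate_chase(k_m, gamma_P = 0, duration = 200, noise_sd = 0,
                       immature0 = 300, mature0 = 100)
  expected <- 100 + 300 * (1 - exp(-k_m * ch$time))
  expect_lt(max(abs(ch$conc - expected)), 1e-9)
  # k_m -> large: flat at the full pool almost immediately
  ch2 <- simulate_chase(1e3, duration = 60, noise_sd = 0,
                        immature0 = 300, mature0 = 100)
  expect_lt(max(abs(ch2$conc[-1] - 400)), 1e-6)
  # half the immature pool converts in one half-life
  ch3 <- simulate_chase(log(2) / 10, duration = 60, noise_sd = 0,
                        immature0 = 300, mature0 = 0, sampling_interval = 10)
  expect_equal(ch3$conc[ch3$time == 10], 150, tolerance = 1e-9)
})

test_that("rendered spot images have the right maxima and integrated intensity", {
  blank <- render_fish_image(
    data.frame(x_px = numeric(0), y_px = numeric(0),
               multiplicity = integer(0)),
    image_shape = c(64, 64), background_level = 100)
  expect_true(all(blank == 100))

  tr <- data.frame(x_px = c(10, 30, 50, 20, 40), y_px = c(10, 20, 30, 50, 55),
                   multiplicity = 1L)
  img <- render_fish_image(tr, image_shape = c(64, 64))
  sp <- detect_spots(img, quant_params(100))
  expect_equal(nrow(sp), 5)
  hit <- vapply(seq_len(nrow(tr)), function(i)
    any(abs(sp$x_px - tr$x_px[i]) <= 1 & abs(sp$y_px - tr$y_px[i]) <= 1),
    logical(1))
  expect_true(all(hit))

  one <- render_fish_image(data.frame(x_px = 32, y_px = 32, multiplicity = 1L),
                           image_shape = c(64, 64))
  three <- render_fish_image(data.frame(x_px = 32, y_px = 32,
                                        multiplicity = 3L),
                             image_shape = c(64, 64))
  i1 <- detect_spots(one, quant_params(100))$intensity
  i3 <- detect_spots(three, quant_params(100))$intensity
  expect_equal(i3 / i1, 3, tolerance = 0.01)

  expect_error(render_fish_image(data.frame(x_px = -5, y_px = 10,
                                            multiplicity = 1L),
                                 image_shape = c(64, 64)))
})

test_that("16-bit TIFF round-trips through the tiff writer", {
  tr <- make_spot_truth(n_cells = 4, image_shape = c(96, 96), seed = 3)
  img <- render_fish_image(tr, background_noise_sd = 20, seed = 4)
  path <- tempfile(fileext = ".tif")
  write_fish_tiff(img, path)
  back <- read_fish_tiff(path)
  expect_equal(dim(back), dim(img))
  expect_lt(max(abs(back - img)), 1)  # 16-bit quantization
})

test_that("config validation rejects out-of-range parameters", {
  expect_error(sim_config(bud_fraction = 1.2))
  expect_error(sim_config(pt_ratio = 0.5))
  expect_error(sim_config(sampling_interval = 0))
  cfgf <- tempfile(fileext = ".yaml")
  write_sim_config(sim_config(mu = 25), cfgf)
  expect_equal(read_sim_config(cfgf)$mu, 25)
})
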