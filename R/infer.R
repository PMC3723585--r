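#' Build a running-total fluorescence trace
#'
#' The running total `P(t)` sums the mother compartment's observed total
#' fluorescence with, after each progeny's separation, that progeny's total.
#' For a stable reporter this is (in expectation) non-decreasing, so division
#' and dilution do not confound rate inference. Continuous at division by
#' construction on noiseless data.
#'
#' @param mother a `cell_trace` (from [simulate_cell()]) or an `entity_trace`.
#' @param progeny list of `entity_trace`s separated from the mother; defaults
#'   to `mother$progeny`.
#' @param use_true use noiseless totals (for oracle checks).
#' @return object of class `running_total`: data.frame-like list with
#'   `times`, `P`, and `cell_id`.
#' @export
build_running_total <- function(mother, progeny = mother$progeny,
                                use_true = FALSE) {
  ids <- vapply(progeny, function(p) p$cell_id, character(1))
  if (anyDuplicated(ids)) stop("duplicate progeny assignment: ", ids[duplicated(ids)][1])
  times <- mother$times
  P <- if (use_true) mother$total_true else mother$total_obs
  for (p in progeny) {
    if (!all(p$times %in% times))
      stop("progeny trace is not on the mother's sampling grid")
    idx <- match(p$times, times)
    P[idx] <- P[idx] + if (use_true) p$total_true else p$total_obs
  }
  structure(list(cell_id = mother$cell_id, times = times, P = P),
            class = "running_total")
}

#' Fit a cubic smoothing spline to a running-total trace
#'
#' Minimizes `sum (P_i - f(t_i))^2 + beta * int f''(t)^2 dt` with time in
#' minutes and fluorescence in raw AU. `beta` is mapped onto
#' [stats::smooth.spline()]'s internal penalty (which is defined on the
#' x-range scaled to unit length) via `lambda = beta / diff(range(t))^3`.
#' First and second derivatives are available through [predict_spline()].
#'
#' @param trace a `running_total`, or anything with `times` and `P` fields.
#' @param beta roughness penalty weight, `> 0`. The package default
#'   ([default_beta()]) comes from the simulation-based calibration of
#'   [select_beta()].
#' @return a `spline_fit` with the fitted `smooth.spline`, `beta`, and the
#'   fitted domain.
#' @export
fit_smoothing_spline <- function(trace, beta = default_beta()) {
  t <- trace$times %||% trace$time
  P <- trace$P
  stopifnot(beta > 0)
  if (length(t) < 8) stop("need at least 8 samples to fit a smoothing spline")
  r <- diff(range(t))
  fit <- stats::smooth.spline(t, P, lambda = beta / r^3, all.knots = TRUE,
                              keep.data = FALSE)
  structure(list(fit = fit, beta = beta, domain = range(t),
                 cell_id = trace$cell_id %||% NA_character_),
            class = "spline_fit")
}

#' Default smoothing parameter
#'
#' Calibrated once by the [select_beta()] simulation study at the canonical
#' study conditions (see the methods vignette and `analysis/02_beta_calibration.R`);
#' the value is specific to this package's penalty convention.
#' @export
default_beta <- function() 1000

#' Evaluate a fitted smoothing spline
#' @param fit a `spline_fit`.
#' @param t times, min; must lie inside the fitted domain.
#' @param deriv 0, 1 or 2.
#' @export
predict_spline <- function(fit, t, deriv = 0) {
  stopifnot(inherits(fit, "spline_fit"))
  if (any(t < fit$domain[1] - 1e-9 | t > fit$domain[2] + 1e-9))
    stop("evaluation outside the fitted domain")
  stats::predict(fit$fit, t, deriv = deriv)$y
}

#' Serialize / restore a spline fit as JSON
#' @param fit a `spline_fit`.
#' @param path file path.
#' @export
write_spline_json <- function(fit, path) {
  obj <- list(beta = fit$beta, domain = fit$domain, cell_id = fit$cell_id,
              knot = fit$fit$fit$knot, coef = fit$fit$fit$coef,
              min = fit$fit$fit$min, range = fit$fit$fit$range)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Infer mRNA level and transcription rate from a spline fit
#'
#' Inverts the transcription-translation model `dP/dt = k_t M`,
#' `dM/dt = A - gamma_M M`, giving `M(t) = P'(t) / k_t` and
#' `A(t) = (P''(t) + gamma_M P'(t)) / k_t` on the sampling grid. Negative
#' values are reported as-is; thresholding is the event module's job.
#' Derivatives within `edge_margin` samples of the trace boundary are
#' low-confidence (spline edge effects) and flagged.
#'
#' @param fit a `spline_fit`.
#' @param times evaluation grid, min.
#' @param gamma_M mRNA degradation rate, 1/min.
#' @param k_t translation rate; `k_t = 1` reports `M` and `A` in AU.
#' @param edge_margin samples flagged low-confidence at each boundary.
#' @return `expression_rates`: data.frame `time`, `M`, `A`, `edge` plus the
#'   parameters used.
#' @export
infer_rates <- function(fit, times, gamma_M, k_t = 1, edge_margin = 2) {
  stopifnot(gamma_M >= 0, k_t > 0)
  P1 <- predict_spline(fit, times, deriv = 1)
  P2 <- predict_spline(fit, times, deriv = 2)
  n <- length(times)
  edge <- seq_len(n) <= edge_margin | seq_len(n) > n - edge_margin
  structure(data.frame(time = times,
                       M = P1 / k_t,
                       A = (P2 + gamma_M * P1) / k_t,
                       edge = edge),
            gamma_M = gamma_M, k_t = k_t, beta = fit$beta,
            cell_id = fit$cell_id,
            class = c("expression_rates", "data.frame"))
}

#' One-call inference from a running-total trace
#' @inheritParams fit_smoothing_spline
#' @inheritParams infer_rates
#' @export
infer_from_trace <- function(trace, gamma_M, k_t = 1, beta = default_beta(),
                             edge_margin = 2) {
  fit <- fit_smoothing_spline(trace, beta)
  infer_rates(fit, trace$times %||% trace$time, gamma_M, k_t, edge_margin)
}

#' Calibrate the smoothing parameter by simulation
#'
#' For each parameter set, simulates `n_reps` noisy traces, infers `A(t)` at
#' every `beta` in the grid, and scores the root-mean-square residual between
#' inferred and true transcription rate (interior samples only). `beta_star`
#' minimizes the residual summed across parameter sets. Traces are
#' asynchronous: each reprun draws a uniform cycle-phase offset.
#'
#' @param beta_grid numeric grid of penalty weights.
#' @param param_sets list of lists with elements `config` (a [sim_config()])
#'   and `generator_fn`, a `function(config, phase_offset)` returning a
#'   generator (so each replicate can be desynchronized).
#' @param n_reps replicates per parameter set.
#' @param n_cycles simulation horizon per trace, cycles.
#' @param seed RNG seed.
#' @param noise simulate measurement noise?
#' @return list with `beta_star`, `residuals` (matrix beta x param set, mean
#'   RMS residual), and `beta_grid`.
#' @export
select_beta <- function(beta_grid, param_sets, n_reps = 100, n_cycles = 3,
                        seed = 1, noise = TRUE) {
  stopifnot(length(beta_grid) >= 1, n_reps >= 1)
  res <- matrix(0, length(beta_grid), length(param_sets),
                dimnames = list(format(beta_grid, trim = TRUE), NULL))
  for (s in seq_along(param_sets)) {
    ps <- param_sets[[s]]
    # per-set RNG stream derived from the set's parameter values, so the
    # result is invariant to the order of parameter sets
    key <- paste(format(unlist(ps$config), digits = 12), collapse = ",")
    set.seed(stage_seed(seed, key))
    acc <- matrix(0, length(beta_grid), n_reps)
    for (r in seq_len(n_reps)) {
      phase <- stats::runif(1, 0, ps$config$t_cyc)
      gen <- ps$generator_fn(ps$config, phase)
      tr <- simulate_cell(ps$config, gen, n_cycles = n_cycles, mode = "ode",
                          noise = noise)
      rt <- tr$running_total
      keep <- !logical(nrow(rt))
      for (b in seq_along(beta_grid)) {
        rates <- infer_from_trace(list(times = rt$time, P = rt$P_obs),
                                  gamma_M = ps$config$gamma_M,
                                  k_t = ps$config$k_t, beta = beta_grid[b])
        ok <- !rates$edge
        acc[b, r] <- sqrt(mean((rates$A[ok] - tr$truth$A[ok])^2))
      }
    }
    res[, s] <- rowMeans(acc)
  }
  total <- rowSums(res)
  list(beta_star = beta_grid[which.min(total)], residuals = res,
       beta_grid = beta_grid, total = total)
}

#' Estimate fluorophore maturation rate from a chase trace
#'
#' Nonlinear least-squares fit of the two-pool maturation model to a
#' post-inhibition fluorescence series: immature protein converts to mature
#' at `k_m` while both pools are lost at `gamma_P` (fixed at 0 for stable
#' reporters). Degenerate (flat) traces are flagged rather than fit.
#'
#' @param trace data.frame with `time` and `conc` (e.g. [simulate_chase()]).
#' @param fix_gamma_P fix `gamma_P = 0`?
#' @return a `maturation_fit`: `k_m`, `half_life = log(2)/k_m`, `gamma_P`,
#'   `residual_norm`, `converged`.
#' @export
estimate_maturation <- function(trace, fix_gamma_P = TRUE) {
  t <- trace$time; y <- trace$conc
  if (length(t) < 10) stop("need at least 10 post-inhibition samples")
  flat_result <- function(reason)
    structure(list(k_m = NA_real_, half_life = NA_real_,
                   gamma_P = if (fix_gamma_P) 0 else NA_real_,
                   residual_norm = NA_real_, converged = FALSE,
                   reason = reason),
              class = "maturation_fit")
  if (stats::sd(y) == 0)
    return(flat_result("flat trace: no resolvable immature pool"))
  rise <- max(y) - y[1]
  start <- list(k_m = log(2) / max(diff(range(t)) / 4, 1e-3),
                mature0 = y[1], immature0 = max(rise, 1e-6))
  fml <- if (fix_gamma_P) {
    conc ~ mature0 + immature0 * (1 - exp(-k_m * time))
  } else {
    start$gamma_P <- 1e-3
    conc ~ exp(-gamma_P * time) * (mature0 + immature0 * (1 - exp(-k_m * time)))
  }
  dat <- data.frame(time = t, conc = y)
  fit <- try(minpack.lm::nlsLM(fml, data = dat, start = start,
                               lower = c(k_m = 1e-6, mature0 = -Inf,
                                         immature0 = 0,
                                         if (!fix_gamma_P) c(gamma_P = 0)),
                               control = minpack.lm::nls.lm.control(maxiter = 200)),
             silent = TRUE)
  if (inherits(fit, "try-error")) {
    return(structure(list(k_m = NA_real_, half_life = NA_real_,
                          gamma_P = NA_real_, residual_norm = NA_real_,
                          converged = FALSE,
                          reason = attr(fit, "condition")$message),
                     class = "maturation_fit"))
  }
  cf <- stats::coef(fit)
  # a maturation rate is only meaningful if the model beats a constant:
  # F-test of the fitted rise against the flat-signal null
  rss1 <- sum(stats::resid(fit)^2)
  rss0 <- sum((y - mean(y))^2)
  df1 <- length(cf) - 1
  df2 <- length(y) - length(cf)
  fstat <- ((rss0 - rss1) / df1) / (rss1 / df2)
  if (df2 < 1 || !is.finite(fstat) ||
      stats::pf(fstat, df1, df2, lower.tail = FALSE) > 0.05)
    return(flat_result("no resolvable immature pool (rise within noise)"))
  structure(list(k_m = unname(cf["k_m"]),
                 half_life = log(2) / unname(cf["k_m"]),
                 gamma_P = if (fix_gamma_P) 0 else unname(cf["gamma_P"]),
                 residual_norm = sqrt(sum(stats::resid(fit)^2)),
                 converged = TRUE, reason = NULL),
            class = "maturation_fit")
}

#' First-order decay sanity check on inferred mRNA
#'
#' After transcription shuts off, `M(t)` should fall as
#' `M_0 exp(-gamma (t - off_time))`. Fits the decay rate on the post-off
#' window by nonlinear least squares and reports the relative deviation from
#' the expected degradation rate.
#'
#' @param rates an `expression_rates` (or data.frame with `time`, `M`).
#' @param off_time shut-off time, min.
#' @param gamma_M_expected configured degradation rate, 1/min.
#' @param window length of the post-off fit window, min (default: to trace end).
#' @return a `decay_check`: `gamma`, `M0`, `relative_deviation`, `consistent`
#'   (within 10%), and the window used.
#' @export
check_decay <- function(rates, off_time, gamma_M_expected, window = Inf) {
  sel <- rates$time >= off_time & rates$time <= off_time + window
  if (!is.null(rates$edge)) sel <- sel & !rates$edge
  t <- rates$time[sel] - off_time
  y <- rates$M[sel]
  if (length(t) < 4) stop("fewer than 4 post-off samples")
  m0 <- max(y[1], 1e-12)
  fit <- try(minpack.lm::nlsLM(y ~ M0 * exp(-g * t),
                               data = data.frame(t = t, y = y),
                               start = list(M0 = m0, g = gamma_M_expected),
                               lower = c(M0 = 0, g = 0)),
             silent = TRUE)
  if (inherits(fit, "try-error")) {
    # degenerate traces (e.g. constant M) make the exponential gradient
    # singular; fall back to a log-linear fit on the positive part
    pos <- y > 0
    if (sum(pos) < 4) stop("decay fit failed: ", attr(fit, "condition")$message)
    ll <- stats::lm(log(y[pos]) ~ t[pos])
    cf <- c(M0 = exp(unname(stats::coef(ll)[1])),
            g = max(0, -unname(stats::coef(ll)[2])))
  } else {
    cf <- stats::coef(fit)
  }
  dev <- abs(cf[["g"]] - gamma_M_expected) / gamma_M_expected
  structure(list(gamma = cf[["g"]], M0 = cf[["M0"]],
                 relative_deviation = dev, consistent = dev <= 0.10,
                 window = c(off_time, off_time + min(window, max(rates$time) - off_time))),
            class = "decay_check")
}
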