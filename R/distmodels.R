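#' Phase-dependent transcription model specification
#'
#' A constant transcription rate `k_G1` in G1 that changes `f`-fold at the
#' G1 to S/G2/M transition. `f = 2` corresponds to a pure gene-dosage
#' (replication) effect; large `f` approaches no G1 transcription. The
#' transition occurs either sharply at the budding boundary or at a random,
#' uniformly distributed time within a window after budding. Alternatively
#' (or additionally) `dosage_doubling` doubles the rate at a replication
#' point inside S phase. Cells divide symmetrically (binomial halving), and
#' the asynchronous exponential-growth age density is
#' `p(a) = (2 log 2 / t_cyc) 2^(-a/t_cyc)` on `[0, t_cyc]`.
#'
#' @param k_G1 G1 transcription rate, mRNA/min (`>= 0`).
#' @param f fold-change of the rate in S/G2/M (`>= 0`; 0 allowed as a limit).
#' @param k_sgm S/G2/M rate, mRNA/min; defaults to `k_G1 * f`. Set it
#'   directly (with `k_G1 = 0`) for the basal, no-G1-transcription limit.
#' @param gamma_M mRNA degradation rate, 1/min.
#' @param t_cyc cell-cycle length, min.
#' @param bud_fraction budding point as fraction of the cycle.
#' @param transition_model `"sharp"` or `"uniform_window"`.
#' @param transition_window window width W, min (used for `"uniform_window"`).
#' @param dosage_doubling double the rate at `replication_fraction`?
#' @param replication_fraction replication point as fraction of the cycle
#'   (must lie in S/G2/M).
#' @return an object of class `model_spec`.
#' @export
model_spec <- function(k_G1, f = 1, gamma_M = log(2) / 20, t_cyc = 100,
                       bud_fraction = 0.27,
                       transition_model = c("sharp", "uniform_window"),
                       transition_window = 40,
                       dosage_doubling = FALSE,
                       replication_fraction = bud_fraction + 0.05,
                       k_sgm = k_G1 * f) {
  transition_model <- match.arg(transition_model)
  stopifnot(k_G1 >= 0, f >= 0, k_sgm >= 0, gamma_M > 0, t_cyc > 0,
            bud_fraction > 0, bud_fraction < 1, transition_window >= 0)
  if (dosage_doubling &&
      (replication_fraction <= bud_fraction || replication_fraction >= 1))
    stop("replication_fraction must lie inside S/G2/M")
  f <- if (k_G1 > 0) k_sgm / k_G1 else Inf
  structure(list(k_G1 = k_G1, f = f, k_sgm = k_sgm,
                 gamma_M = gamma_M, t_cyc = t_cyc,
                 bud_fraction = bud_fraction,
                 transition_model = transition_model,
                 transition_window = transition_window,
                 dosage_doubling = dosage_doubling,
                 replication_fraction = replication_fraction),
            class = "model_spec")
}

#' Asynchronous-population age density
#'
#' `p(a) = (2 log 2 / t_cyc) 2^(-a / t_cyc)` on `[0, t_cyc]`: the age density
#' of an exponentially growing binary-fission population.
#' @param a ages, min.
#' @param t_cyc cycle length, min.
#' @export
age_density <- function(a, t_cyc) {
  ifelse(a < 0 | a > t_cyc, 0, 2 * log(2) / t_cyc * 2^(-a / t_cyc))
}

#' @rdname age_density
#' @param n number of ages to draw.
#' @export
sample_ages <- function(n, t_cyc) {
  # inverse CDF of F(a) = 2 (1 - 2^(-a/t_cyc))
  u <- stats::runif(n)
  -t_cyc * log2(1 - u / 2)
}

#' Phase labels and phase age-boundaries
#'
#' G1 is the pre-bud part of the cycle; S/G2/M is split into three
#' equal-duration thirds S1, S2, S3 (the model-side analogue of ranked
#' bud-size thirds).
#' @param model a [model_spec()].
#' @return data.frame with phase, lo, hi (ages, min).
#' @export
phase_boundaries <- function(model) {
  T <- model$t_cyc; b <- model$bud_fraction
  e <- c(0, b, b + (1 - b) / 3, b + 2 * (1 - b) / 3, 1) * T
  data.frame(phase = c("G1", "S1", "S2", "S3"),
             lo = e[1:4], hi = e[2:5], stringsAsFactors = FALSE)
}

phase_of_age <- function(age, model) {
  pb <- phase_boundaries(model)
  cut(age, breaks = c(pb$lo, pb$hi[4]), labels = pb$phase,
      include.lowest = TRUE, right = FALSE)
}

# rate at cycle age a given the transition age tau
model_rate_at <- function(model, a, tau) {
  r <- ifelse(a >= tau, model$k_sgm, model$k_G1)
  if (model$dosage_doubling)
    r <- r * ifelse(a >= model$replication_fraction * model$t_cyc, 2, 1)
  r
}

# exact mean mRNA trajectory m(a) for a piecewise-constant rate; a_grid must
# be ascending starting at 0. Change points at tau and the replication age.
model_mean_traj <- function(model, a_grid, tau, m0) {
  g <- model$gamma_M
  cuts <- sort(unique(c(tau, if (model$dosage_doubling)
    model$replication_fraction * model$t_cyc)))
  cuts <- cuts[cuts > 0 & cuts < model$t_cyc]
  pts <- sort(unique(c(a_grid, cuts)))
  m <- numeric(length(pts))
  cur <- m0
  m[1] <- if (pts[1] == 0) m0 else NA
  for (i in seq_len(length(pts) - 1)) {
    lo <- pts[i]; hi <- pts[i + 1]
    A <- model_rate_at(model, (lo + hi) / 2, tau)
    cur <- A / g + (cur - A / g) * exp(-g * (hi - lo))
    m[i + 1] <- cur
  }
  m[match(a_grid, pts)]
}

# cyclic-steady-state newborn mean, averaging over the transition time
# distribution: m0 = E_tau[C(T)] / (2 - exp(-g T)) where C(T) is the
# end-of-cycle mean started from 0.
model_newborn_mean <- function(model, taus, tau_w) {
  g <- model$gamma_M; T <- model$t_cyc
  CT <- vapply(taus, function(tau)
    model_mean_traj(model, c(0, T), tau, 0)[2], numeric(1))
  sum(tau_w * CT) / (2 - exp(-g * T))
}

# transition-time quadrature nodes/weights
transition_nodes <- function(model, n_tau = 15) {
  if (model$transition_model == "sharp" || model$transition_window == 0) {
    list(taus = model$bud_fraction * model$t_cyc, w = 1)
  } else {
    lo <- model$bud_fraction * model$t_cyc
    hi <- min(lo + model$transition_window, model$t_cyc)
    mid <- lo + (seq_len(n_tau) - 0.5) / n_tau * (hi - lo)
    list(taus = mid, w = rep(1 / n_tau, n_tau))
  }
}

#' Predict the snapshot mRNA distribution of a phase-dependent model
#'
#' The analytic method computes the snapshot law as a mixture over cell age
#' (asynchronous exponential-growth age density) and, for the randomized
#' transition, over the uniform transition time, of Poisson laws whose mean
#' solves `dm/da = A(a) - gamma_M m` with binomial halving at division
#' (Poisson is closed under both operations, so the per-age law is exactly
#' Poisson at the cyclic steady state). The `ssa` method estimates the same
#' law by Gillespie simulation ([simulate_population_snapshot()]).
#'
#' @param model a [model_spec()].
#' @param method `"analytic"` or `"ssa"`.
#' @param n_cells number of simulated cells (`ssa` only).
#' @param seed RNG seed (`ssa` only).
#' @param n_age age-quadrature points per phase (analytic).
#' @param kmax largest count carried in the pmfs (analytic; enlarged
#'   automatically if the tail mass exceeds 1e-9).
#' @return a `model_prediction`: `per_phase` (phase, mean, sd, weight),
#'   `pmf` (matrix count x phase), `aggregate` (mean, sd, pmf).
#' @export
predict_model <- function(model, method = c("analytic", "ssa"),
                          n_cells = 20000, seed = NULL, n_age = 120,
                          kmax = NULL) {
  method <- match.arg(method)
  if (method == "ssa") {
    pc <- simulate_population_snapshot(model, n_cells, seed = seed)
    return(prediction_from_counts(pc, model))
  }
  tn <- transition_nodes(model)
  m0 <- model_newborn_mean(model, tn$taus, tn$w)
  pb <- phase_boundaries(model)
  T <- model$t_cyc

  # per-phase age quadrature (midpoint), weighted by the age density
  phases <- lapply(seq_len(4), function(i) {
    lo <- pb$lo[i]; hi <- pb$hi[i]
    a <- lo + (seq_len(n_age) - 0.5) / n_age * (hi - lo)
    w <- age_density(a, T)
    w <- w / sum(w)
    list(a = a, w = w)
  })
  # phase weights in the asynchronous population
  cdf <- function(a) 2 * (1 - 2^(-a / T))
  ph_w <- diff(cdf(c(pb$lo, T)))

  # mean trajectories per transition node on the union of phase ages
  all_a <- sort(unique(c(0, unlist(lapply(phases, `[[`, "a")))))
  m_by_tau <- vapply(tn$taus, function(tau)
    model_mean_traj(model, all_a, tau, m0), numeric(length(all_a)))

  max_m <- max(m_by_tau)
  if (is.null(kmax))
    kmax <- max(10, ceiling(max_m + 8 * sqrt(max_m + 1)))
  ks <- 0:kmax

  pmf <- matrix(0, kmax + 1, 4, dimnames = list(ks, pb$phase))
  mean_ph <- sd_ph <- numeric(4)
  for (i in seq_len(4)) {
    ia <- match(phases[[i]]$a, all_a)
    w_a <- phases[[i]]$w
    m_sub <- m_by_tau[ia, , drop = FALSE]               # n_age x n_tau
    wt <- outer(w_a, tn$w)                              # joint weights
    mu1 <- sum(wt * m_sub)
    mu2 <- sum(wt * m_sub^2)
    mean_ph[i] <- mu1
    sd_ph[i] <- sqrt(mu1 + (mu2 - mu1^2))               # Poisson mixture
    p <- vapply(ks, function(k) sum(wt * stats::dpois(k, m_sub)), numeric(1))
    pmf[, i] <- p
  }
  agg_pmf <- drop(pmf %*% ph_w)
  agg_mean <- sum(ph_w * mean_ph)
  agg_var <- sum(ph_w * (sd_ph^2 + mean_ph^2)) - agg_mean^2
  structure(list(per_phase = data.frame(phase = pb$phase, mean = mean_ph,
                                        sd = sd_ph, weight = ph_w,
                                        stringsAsFactors = FALSE),
                 pmf = pmf,
                 aggregate = list(mean = agg_mean, sd = sqrt(agg_var),
                                  pmf = agg_pmf),
                 method = "analytic", model = model, newborn_mean = m0),
            class = "model_prediction")
}

prediction_from_counts <- function(phase_counts, model) {
  sp <- split(phase_counts$count, phase_counts$phase)
  pb <- phase_boundaries(model)
  sp <- sp[pb$phase]
  mean_ph <- vapply(sp, function(x) mean(x), numeric(1))
  sd_ph <- vapply(sp, function(x) stats::sd(x), numeric(1))
  n_ph <- vapply(sp, length, integer(1))
  kmax <- max(phase_counts$count)
  pmf <- vapply(sp, function(x)
    tabulate(x + 1, nbins = kmax + 1) / length(x), numeric(kmax + 1))
  rownames(pmf) <- 0:kmax
  structure(list(per_phase = data.frame(phase = pb$phase, mean = mean_ph,
                                        sd = sd_ph, weight = n_ph / sum(n_ph),
                                        n = n_ph, stringsAsFactors = FALSE),
                 pmf = pmf,
                 aggregate = list(mean = mean(phase_counts$count),
                                  sd = stats::sd(phase_counts$count),
                                  pmf = tabulate(phase_counts$count + 1,
                                                 nbins = kmax + 1) /
                                        nrow(phase_counts)),
                 method = "ssa", model = model),
            class = "model_prediction")
}

#' Simulate an asynchronous-population snapshot
#'
#' Samples cell ages from the exponential-growth age distribution, runs each
#' cell's mRNA birth-death history (Gillespie, binomial halving at division,
#' per-cycle randomized transition time) through a burn-in and to its sampled
#' age, and labels the phase by age: G1 before budding, then three
#' equal-duration S/G2/M thirds.
#'
#' @param model a [model_spec()].
#' @param n_cells number of cells (`>= 1`).
#' @param seed RNG seed.
#' @param n_burn burn-in, full cycles.
#' @return a `phase_counts` data.frame: `cell_id`, `phase`, `count`, `age`.
#' @export
simulate_population_snapshot <- function(model, n_cells, seed = NULL,
                                         n_burn = 8) {
  stopifnot(inherits(model, "model_spec"), n_cells >= 1)
  if (!is.null(seed)) set.seed(seed)
  ages <- sample_ages(n_cells, model$t_cyc)
  window <- if (model$transition_model == "uniform_window")
    model$transition_window else 0
  counts <- .ssa_snapshot_cpp(ages, model$t_cyc, model$gamma_M,
                              model$k_G1, model$k_sgm,
                              model$bud_fraction, window,
                              model$dosage_doubling,
                              model$replication_fraction, as.integer(n_burn))
  structure(data.frame(cell_id = paste0("c", seq_len(n_cells)),
                       phase = as.character(phase_of_age(ages, model)),
                       count = counts, age = ages,
                       stringsAsFactors = FALSE),
            class = c("phase_counts", "data.frame"))
}

#' Fit the fold-change f to phase-stratified counts
#'
#' Maximizes the analytic Poisson-mixture likelihood over `(k_G1, f)`: a log
#' grid in `f` with golden-ratio local refinement, profiling out `k_G1` by
#' 1-D optimization at each `f`. Reports a likelihood-ratio confidence
#' interval. If the profile keeps improving up to the top of the grid the
#' estimate is censored at the grid bound (reported as `f > bound`), the
#' reporting convention for basal expression.
#'
#' @param data a `phase_counts` data.frame (`phase`, `count`).
#' @param gamma_M,t_cyc,bud_fraction fixed model parameters.
#' @param f_grid grid of fold-changes to profile.
#' @param transition_model,transition_window passed to [model_spec()].
#' @param conf confidence level for the LR interval.
#' @return an `f_fit`: `f_hat`, `k_G1_hat`, `censored`, `ci`, `profile`
#'   (data.frame f, loglik, k_G1), `loglik`.
#' @export
fit_f <- function(data, gamma_M = log(2) / 20, t_cyc = 100,
                  bud_fraction = 0.27,
                  f_grid = c(1, 1.5, 2, 3, 5, 7, 10, 15, 20, 30, 50, 75, 100, 150),
                  transition_model = "sharp", transition_window = 40,
                  conf = 0.95) {
  stopifnot(all(c("phase", "count") %in% names(data)))
  if (!all(c("G1", "S1", "S2", "S3") %in% data$phase))
    stop("all four phases (G1, S1, S2, S3) must be represented")
  if (all(data$count == 0))
    stop("all counts are zero: f is unidentifiable")

  mk <- function(k, f) model_spec(k, f, gamma_M, t_cyc, bud_fraction,
                                  transition_model = transition_model,
                                  transition_window = transition_window)
  ll_of <- function(k, f) phase_loglik(data, mk(k, f))
  prof_k <- function(f) {
    # scale k so the model's aggregate mean matches the data mean, then
    # refine by 1-D likelihood optimization around that bracket
    mean_obs <- mean(data$count)
    m1 <- predict_model(mk(1, f), n_age = 60)$aggregate$mean
    k0 <- max(mean_obs / m1, 1e-8)
    opt <- stats::optimize(function(lk) -ll_of(exp(lk), f),
                           interval = log(k0) + c(-1.5, 1.5), tol = 1e-4)
    list(k = exp(opt$minimum), ll = -opt$objective)
  }

  prof <- lapply(f_grid, prof_k)
  ll <- vapply(prof, `[[`, numeric(1), "ll")
  kk <- vapply(prof, `[[`, numeric(1), "k")
  i_best <- which.max(ll)
  censored <- i_best == length(f_grid) &&
    (length(f_grid) < 2 || ll[i_best] > ll[i_best - 1] + 1e-6)

  f_hat <- f_grid[i_best]; k_hat <- kk[i_best]; ll_hat <- ll[i_best]
  if (!censored && i_best > 1 && i_best < length(f_grid)) {
    # golden-section refinement on log f between the flanking grid points
    gr <- (sqrt(5) - 1) / 2
    lo <- log(f_grid[i_best - 1]); hi <- log(f_grid[i_best + 1])
    x1 <- hi - gr * (hi - lo); x2 <- lo + gr * (hi - lo)
    p1 <- prof_k(exp(x1)); p2 <- prof_k(exp(x2))
    for (it in 1:8) {
      if (p1$ll > p2$ll) {
        hi <- x2; x2 <- x1; p2 <- p1
        x1 <- hi - gr * (hi - lo); p1 <- prof_k(exp(x1))
      } else {
        lo <- x1; x1 <- x2; p1 <- p2
        x2 <- lo + gr * (hi - lo); p2 <- prof_k(exp(x2))
      }
    }
    best <- if (p1$ll > p2$ll) list(f = exp(x1), p = p1) else list(f = exp(x2), p = p2)
    if (best$p$ll > ll_hat) {
      f_hat <- best$f; k_hat <- best$p$k; ll_hat <- best$p$ll
    }
  }

  crit <- stats::qchisq(conf, df = 1) / 2
  in_ci <- ll >= ll_hat - crit
  ci <- range(c(f_grid[in_ci], f_hat))  # the maximizer is always inside
  if (censored) ci[2] <- Inf
  structure(list(f_hat = f_hat, k_G1_hat = k_hat, loglik = ll_hat,
                 censored = censored, grid_bound = max(f_grid), ci = ci,
                 profile = data.frame(f = f_grid, loglik = ll, k_G1 = kk)),
            class = "f_fit")
}

# Poisson-mixture log-likelihood of phase-labelled counts under a model
phase_loglik <- function(data, model, n_age = 60) {
  pred <- predict_model(model, n_age = n_age,
                        kmax = max(data$count) + 1)
  ll <- 0
  for (ph in c("G1", "S1", "S2", "S3")) {
    k <- data$count[data$phase == ph]
    if (!length(k)) next
    p <- pred$pmf[, ph]
    p <- pmax(p, 1e-300)
    ll <- ll + sum(log(p[k + 1]))
  }
  ll
}

#' Fit a negative binomial by moments (bursting parametrization)
#'
#' Moment estimators of burst size `b = var/mean - 1` and burst frequency
#' `a = mean / b` (per mRNA lifetime), the standard-model reading of a
#' negative binomial mRNA distribution. Degenerates to Poisson (b = 0,
#' flagged) when the variance does not exceed the mean. `refine = TRUE`
#' replaces the moment estimates by the maximum-likelihood fit
#' ([MASS::fitdistr()]).
#'
#' @param counts non-negative integer vector (at least 2 distinct values).
#' @param refine refine by MLE?
#' @return an `nb_fit`: `a` (burst frequency), `b` (burst size), `mean`,
#'   `variance`, `poisson_limit` flag, `method`.
#' @export
fit_negative_binomial <- function(counts, refine = FALSE) {
  if (length(unique(counts)) < 2) stop("need at least 2 distinct count values")
  m <- mean(counts); v <- stats::var(counts)
  if (m == 0) stop("mean count is zero: fit undefined")
  b <- v / m - 1
  if (b <= 0) {
    return(structure(list(a = NA_real_, b = 0, mean = m, variance = v,
                          poisson_limit = TRUE, method = "moments"),
                     class = "nb_fit"))
  }
  a <- m / b
  method <- "moments"
  if (refine) {
    fd <- try(suppressWarnings(
      MASS::fitdistr(counts, "negative binomial")), silent = TRUE)
    if (!inherits(fd, "try-error")) {
      size <- fd$estimate[["size"]]; mu <- fd$estimate[["mu"]]
      a <- size; b <- mu / size; method <- "mle"
    }
  }
  structure(list(a = a, b = b, mean = m, variance = v,
                 poisson_limit = FALSE, method = method),
            class = "nb_fit")
}

#' Compare phase-dependent models against phase-stratified counts
#'
#' For each candidate model: predicted vs empirical per-phase mean and SD,
#' plus a chi-square distance between the pooled (aggregate) predicted and
#' empirical pmfs, mirroring the horizontal mean/SD comparison lines over
#' each distribution.
#'
#' @param data a `phase_counts` data.frame.
#' @param models list of [model_spec()]s (must share `gamma_M` and `t_cyc`).
#' @return list with `table` (per model x phase) and `goodness` (per model
#'   chi-square distance on the aggregate pmf).
#' @export
compare_models <- function(data, models) {
  g <- unique(vapply(models, `[[`, numeric(1), "gamma_M"))
  Tc <- unique(vapply(models, `[[`, numeric(1), "t_cyc"))
  if (length(g) > 1 || length(Tc) > 1)
    stop("models must share gamma_M and t_cyc")
  emp <- prediction_from_counts(data, models[[1]])
  kmax <- max(data$count)
  emp_agg <- emp$aggregate$pmf

  rows <- list(); good <- numeric(length(models))
  for (i in seq_along(models)) {
    pred <- predict_model(models[[i]], kmax = max(kmax + 5, 15))
    tab <- merge(emp$per_phase[, c("phase", "mean", "sd")],
                 pred$per_phase[, c("phase", "mean", "sd")],
                 by = "phase", suffixes = c("_obs", "_pred"))
    tab$model <- i
    rows[[i]] <- tab
    p <- pred$aggregate$pmf[seq_len(kmax + 1)]
    p <- p / sum(p)
    p <- pmax(p, 1e-12)
    good[i] <- sum((emp_agg - p)^2 / p)
  }
  list(table = do.call(rbind, rows),
       goodness = data.frame(model = seq_along(models), chisq = good))
}
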