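#' Binarize a transcription-rate series into ON/OFF states
#'
#' ON wherever `A(t)` exceeds the background threshold; ON runs shorter than
#' `min_run` samples are removed as noise, and crossing times are placed by
#' linear interpolation between the flanking samples. Edge-flagged samples
#' (spline boundary effects) are excluded from state calling.
#'
#' @param rates an `expression_rates` (or data.frame with `time`, `A`,
#'   optionally `edge`).
#' @param threshold background threshold, AU/min (`> 0`); see
#'   [background_threshold()].
#' @param min_run minimum ON run length, samples.
#' @return an `event_record`: `time`, `on` (binary per sample),
#'   `activation_times`, `deactivation_times`, `threshold`.
#' @export
binarize <- function(rates, threshold, min_run = 2) {
  stopifnot(threshold > 0, min_run >= 1)
  keep <- if (!is.null(rates$edge)) !rates$edge else !logical(nrow(rates))
  t <- rates$time[keep]; a <- rates$A[keep]
  on <- a > threshold
  # debounce: drop ON runs shorter than min_run
  r <- rle(on)
  r$values[r$values & r$lengths < min_run] <- FALSE
  on <- inverse.rle(r)
  act <- deact <- numeric(0)
  if (length(on) > 1) {
    up <- which(!on[-length(on)] & on[-1])
    dn <- which(on[-length(on)] & !on[-1])
    interp <- function(i) {
      # threshold crossing between samples i and i+1
      if (a[i + 1] == a[i]) return(t[i + 1])
      t[i] + (t[i + 1] - t[i]) * (threshold - a[i]) / (a[i + 1] - a[i])
    }
    act <- vapply(up, interp, numeric(1))
    deact <- vapply(dn, interp, numeric(1))
  }
  structure(list(cell_id = attr(rates, "cell_id"), time = t, on = on,
                 activation_times = act, deactivation_times = deact,
                 threshold = threshold),
            class = "event_record")
}

#' Robust background threshold for ON/OFF calling
#'
#' Detection floor for [binarize()]: `k` times the median absolute deviation
#' of `A(t)` over annotated OFF reference periods (or basal-strain traces),
#' centred on the reference median.
#'
#' @param a_reference inferred `A` values over known-OFF periods.
#' @param k multiplier (default 3).
#' @export
background_threshold <- function(a_reference, k = 3) {
  stats::median(a_reference) + k * stats::mad(a_reference)
}

#' Step-test configuration
#'
#' @param transcription_threshold_fraction fraction of the population
#'   steady-state transcription rate used as the activation threshold.
#' @param tau_obs observation lag, min: the time by which observable
#'   transcription trails the underlying event (fluorophore maturation plus
#'   smoothing), used to back-reference localization levels.
#' @param localization_percentile percentile of the pooled localization
#'   values that defines the effective localization threshold.
#' @param steady_window time window (min, relative to the step at t = 0)
#'   over which the population steady-state rate is measured.
#' @export
steptest_config <- function(transcription_threshold_fraction = 0.5,
                            tau_obs = 15, localization_percentile = 5,
                            steady_window = c(150, 250)) {
  stopifnot(transcription_threshold_fraction > 0,
            transcription_threshold_fraction < 1,
            localization_percentile > 0, localization_percentile < 100,
            length(steady_window) == 2, diff(steady_window) > 0)
  structure(list(transcription_threshold_fraction = transcription_threshold_fraction,
                 tau_obs = tau_obs,
                 localization_percentile = localization_percentile,
                 steady_window = steady_window),
            class = "steptest_config")
}

# first up-crossing of `thr` by series (t, y) at or after t_from, linearly
# interpolated; NA if never crossed
first_crossing <- function(t, y, thr, t_from = -Inf) {
  sel <- t >= t_from
  t <- t[sel]; y <- y[sel]
  if (!length(t)) return(NA_real_)
  if (y[1] > thr) return(t[1])
  i <- which(y[-1] > thr & y[-length(y)] <= thr)
  if (!length(i)) return(NA_real_)
  i <- i[1]
  if (y[i + 1] == y[i]) return(t[i + 1])
  t[i] + (t[i + 1] - t[i]) * (thr - y[i]) / (y[i + 1] - y[i])
}

#' Step-test response delays (5-step threshold procedure)
#'
#' Implements the five calculation steps used to time transcription
#' activation relative to transcription-factor nuclear localization after a
#' step input at `t = 0`:
#' 1. the transcription threshold is set at
#'    `transcription_threshold_fraction` (default 50%) of the population
#'    steady-state transcription rate;
#' 2. for each cell, the localization level `tau_obs` minutes before that
#'    cell's transcription threshold crossing is read off;
#' 3. those values are pooled across cells;
#' 4. the effective localization threshold is the pool's
#'    `localization_percentile` (default 5th);
#' 5. each cell's localization time is its first crossing of that threshold.
#'
#' The response delay is activation minus localization. Cells that never
#' cross the transcription threshold are censored (kept, excluded from delay
#' statistics).
#'
#' @param cells list; each element has `rates` (an `expression_rates`),
#'   `localization` (data.frame `time`, `value`), and optionally `bud_times`,
#'   `division_times` for phase annotation.
#' @param cfg a [steptest_config()].
#' @return a `steptest_result` data.frame: `cell_id`, `activation_time`,
#'   `localization_time`, `response_delay`, `phase_at_localization`,
#'   `progression_at_localization`, `progression_at_activation`, `censored`;
#'   attributes carry the two thresholds.
#' @export
steptest_delays <- function(cells, cfg = steptest_config()) {
  stopifnot(inherits(cfg, "steptest_config"))
  # step 1: population steady state and the transcription threshold
  ss <- mean(unlist(lapply(cells, function(cl) {
    r <- cl$rates
    sel <- r$time >= cfg$steady_window[1] & r$time <= cfg$steady_window[2]
    r$A[sel & !r$edge]
  })))
  thr_a <- cfg$transcription_threshold_fraction * ss

  # per-cell activation times
  t_act <- vapply(cells, function(cl) {
    r <- cl$rates
    ok <- !r$edge
    first_crossing(r$time[ok], r$A[ok], thr_a, t_from = 0)
  }, numeric(1))

  # steps 2-3: localization levels tau_obs before each activation
  loc_at <- vapply(seq_along(cells), function(i) {
    if (is.na(t_act[i])) return(NA_real_)
    l <- cells[[i]]$localization
    stats::approx(l$time, l$value, xout = t_act[i] - cfg$tau_obs, rule = 2)$y
  }, numeric(1))
  pool <- loc_at[!is.na(loc_at)]
  if (!length(pool)) stop("no cell crossed the transcription threshold")
  # step 4: effective localization threshold
  thr_loc <- stats::quantile(pool, cfg$localization_percentile / 100,
                             names = FALSE, type = 7)
  # step 5: per-cell localization times
  t_loc <- vapply(cells, function(cl) {
    l <- cl$localization
    first_crossing(l$time, l$value, thr_loc, t_from = 0)
  }, numeric(1))

  prog_at <- function(cl, tt) {
    if (is.na(tt) || is.null(cl$division_times)) return(NA_real_)
    divs <- sort(cl$division_times)
    lo <- max(divs[divs <= tt], -Inf)
    hi <- min(divs[divs > tt], Inf)
    if (!is.finite(lo) || !is.finite(hi)) return(NA_real_)
    (tt - lo) / (hi - lo)
  }
  phase_at <- function(cl, tt) {
    if (is.na(tt) || is.null(cl$bud_times)) return(NA_character_)
    divs <- sort(cl$division_times)
    lo <- max(divs[divs <= tt], -Inf)
    bud <- cl$bud_times[cl$bud_times > lo & cl$bud_times <= tt]
    if (length(bud)) "S/G2/M" else "G1"
  }

  res <- data.frame(
    cell_id = vapply(seq_along(cells), function(i)
      cells[[i]]$cell_id %||% paste0("c", i), character(1)),
    activation_time = t_act,
    localization_time = t_loc,
    response_delay = t_act - t_loc,
    phase_at_localization = vapply(seq_along(cells), function(i)
      phase_at(cells[[i]], t_loc[i]), character(1)),
    progression_at_localization = vapply(seq_along(cells), function(i)
      prog_at(cells[[i]], t_loc[i]), numeric(1)),
    progression_at_activation = vapply(seq_along(cells), function(i)
      prog_at(cells[[i]], t_act[i]), numeric(1)),
    censored = is.na(t_act),
    stringsAsFactors = FALSE)
  structure(res, transcription_threshold = thr_a,
            localization_threshold = thr_loc,
            steady_state_rate = ss,
            class = c("steptest_result", "data.frame"))
}

#' Compare pre- vs post-budding response delays
#'
#' Two-sample Kolmogorov-Smirnov test between response delays of cells whose
#' TF localized in G1 versus in S/G2/M.
#'
#' @param result a `steptest_result`.
#' @return list with the two delay vectors, medians, and the `ks` htest.
#' @export
delays_by_phase <- function(result) {
  ok <- !result$censored & !is.na(result$phase_at_localization)
  g1 <- result$response_delay[ok & result$phase_at_localization == "G1"]
  sgm <- result$response_delay[ok & result$phase_at_localization == "S/G2/M"]
  list(g1 = g1, sgm = sgm,
       median_g1 = stats::median(g1), median_sgm = stats::median(sgm),
       ks = stats::ks.test(g1, sgm))
}

#' Co-activation statistics between homologous loci
#'
#' Scores each S/G2/M period by whether each locus turned ON, builds the 2x2
#' contingency table, and reports the Pearson chi-square test (no continuity
#' correction), the phi correlation coefficient, and -- among periods where
#' both loci activate -- the fraction whose activation times fall within
#' `window` minutes of each other.
#'
#' @param records_a,records_b data.frames with one row per scored S/G2/M
#'   period: columns `period` (shared id), `on` (logical), `t_act`
#'   (activation time, NA if OFF).
#' @param window co-timing window, min.
#' @return a `coactivation_stats`: `table` (2x2), `chisq`, `p_value`, `phi`,
#'   `dual_on_within_window`, `n_dual_on`, `activation_pairs`.
#' @export
coactivation <- function(records_a, records_b, window = 15) {
  m <- merge(records_a, records_b, by = "period", suffixes = c("_a", "_b"))
  if (!nrow(m)) stop("no shared periods between the two loci")
  tab <- table(factor(m$on_a, c(FALSE, TRUE)), factor(m$on_b, c(FALSE, TRUE)),
               dnn = c("A", "B"))
  degenerate <- any(rowSums(tab) == 0) || any(colSums(tab) == 0)
  if (degenerate) {
    chi <- list(statistic = NA_real_, p.value = NA_real_)
    phi <- NA_real_
    warning("degenerate margins: a locus is never ON (or always ON); ",
            "chi-square undefined")
  } else {
    chi <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
    num <- as.numeric(tab[2, 2]) * tab[1, 1] - as.numeric(tab[1, 2]) * tab[2, 1]
    phi <- num /
      sqrt(as.numeric(prod(rowSums(tab))) * as.numeric(prod(colSums(tab))))
  }
  dual <- m$on_a & m$on_b
  dt <- abs(m$t_act_a[dual] - m$t_act_b[dual])
  structure(list(table = tab,
                 chisq = unname(chi$statistic), p_value = chi$p.value,
                 phi = phi,
                 dual_on_within_window = if (any(dual)) mean(dt <= window,
                                                             na.rm = TRUE)
                 else NA_real_,
                 n_dual_on = sum(dual),
                 n_periods = nrow(m),
                 activation_pairs = data.frame(t_a = m$t_act_a[dual],
                                               t_b = m$t_act_b[dual]),
                 window = window),
            class = "coactivation_stats")
}

#' 2D histogram of paired activation times
#' @param stats a `coactivation_stats`.
#' @param breaks bin edges, min (shared by both axes).
#' @return matrix of counts (rows = locus A bins).
#' @export
activation_histogram2d <- function(stats, breaks = seq(0, 80, by = 10)) {
  p <- stats$activation_pairs
  ba <- cut(p$t_a, breaks, include.lowest = TRUE)
  bb <- cut(p$t_b, breaks, include.lowest = TRUE)
  table(ba, bb)
}
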