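#' Segment a trace into cell cycles
#'
#' One segment per complete division-to-division interval containing exactly
#' one budding event; leading/trailing partial intervals are kept but flagged
#' incomplete (they are needed to score S/G2/M periods following an
#' unobserved G1). Segments whose bud falls outside the division interval
#' are rejected with a warning.
#'
#' @param trace a `cell_trace` ([simulate_cell()]), or a list with `times`,
#'   `bud_times`, `division_times`, and a `series` data.frame.
#' @param series data.frame of sampled quantities with a `time` column;
#'   defaults to the trace's volume/concentration series.
#' @return list of `cycle_segment`s: `cell_id`, `cycle_index`, `t_div_start`,
#'   `t_bud`, `t_div_end`, `complete`, `data` (rows of `series` in the
#'   segment).
#' @export
segment_cycles <- function(trace, series = NULL) {
  if (is.null(series))
    series <- data.frame(time = trace$times, volume = trace$volume,
                         conc = trace$conc)
  times <- series$time
  divs <- sort(unique(trace$division_times))
  buds <- sort(trace$bud_times)
  t0 <- min(times); t1 <- max(times)
  inner <- divs[divs > t0 + 1e-9 & divs < t1 - 1e-9]
  edges <- unique(c(t0, inner, t1))
  segs <- list()
  for (i in seq_len(length(edges) - 1)) {
    lo <- edges[i]; hi <- edges[i + 1]
    # complete iff both endpoints are observed division events
    complete <- any(abs(divs - lo) < 1e-9) && any(abs(divs - hi) < 1e-9)
    in_bud <- buds[buds > lo + 1e-9 & buds < hi - 1e-9]
    if (complete && length(in_bud) != 1) {
      if (length(in_bud) > 1) {
        warning("segment [", lo, ", ", hi, "] contains ", length(in_bud),
                " bud events; rejected")
        next
      }
      complete <- FALSE  # no bud observed: treat as partial
    }
    sel <- times >= lo - 1e-9 & times <= hi + 1e-9
    segs[[length(segs) + 1]] <- structure(
      list(cell_id = trace$cell_id %||% NA_character_,
           cycle_index = length(segs) + 1,
           t_div_start = lo,
           t_bud = if (length(in_bud) == 1) in_bud else NA_real_,
           t_div_end = hi,
           complete = complete,
           data = series[sel, , drop = FALSE]),
      class = "cycle_segment")
  }
  segs
}

#' Map segments to the common cell-cycle progression coordinate
#'
#' Applies the two-piece linear time map per complete segment:
#' `[t_div_start, t_bud] -> [0, b]` and `[t_bud, t_div_end] -> [b, 1]`,
#' where `b` is the population-average pre-bud fraction (or a supplied
#' value). Division maps to 0 and 1 and every bud maps to `b` exactly.
#'
#' @param segments list of `cycle_segment`s (incomplete ones are dropped).
#' @param quantity column of the segment data to carry along.
#' @param target_bud_point `"population-average"` or a fraction in (0,1).
#' @return list with `b` and `segments`, each segment gaining `progression`
#'   and `value` vectors.
#' @export
rescale_progression <- function(segments, quantity,
                                target_bud_point = "population-average") {
  segments <- Filter(function(s) isTRUE(s$complete), segments)
  if (!length(segments)) stop("no complete segments")
  pre_frac <- vapply(segments, function(s)
    (s$t_bud - s$t_div_start) / (s$t_div_end - s$t_div_start), numeric(1))
  if (any(pre_frac <= 0 | pre_frac >= 1)) stop("zero-length cycle phase")
  b <- if (identical(target_bud_point, "population-average"))
    mean(pre_frac) else as.numeric(target_bud_point)
  stopifnot(b > 0, b < 1)
  out <- lapply(seq_along(segments), function(i) {
    s <- segments[[i]]
    t <- s$data$time
    pre <- t <= s$t_bud
    prog <- numeric(length(t))
    prog[pre] <- (t[pre] - s$t_div_start) / (s$t_bud - s$t_div_start) * b
    prog[!pre] <- b + (t[!pre] - s$t_bud) / (s$t_div_end - s$t_bud) * (1 - b)
    s$progression <- prog
    s$value <- s$data[[quantity]]
    s
  })
  list(b = b, segments = out)
}

#' Population profile across cell-cycle progression
#'
#' Bins every complete cycle's samples by progression (or, with
#' `rescale = FALSE`, by time from budding in minutes), averages the per-cycle
#' bin means across cycles, and attaches bootstrap SEMs (resampling whole
#' cycles, never individual samples) and the across-cycle SD.
#'
#' @param segments list of `cycle_segment`s.
#' @param quantity column of the segment data to profile.
#' @param n_bins number of equal-width bins (`>= 2`).
#' @param n_boot bootstrap replicates (`>= 100`).
#' @param seed RNG seed for the bootstrap.
#' @param rescale use the progression coordinate (TRUE) or raw time from
#'   budding (FALSE; bins span the average pre/post-bud durations).
#' @param target_bud_point passed to [rescale_progression()].
#' @return a `cycle_profile` data.frame: `bin_lo`, `bin_hi`, `mean`,
#'   `sem_boot`, `sd`, `n`; attribute `b` is the budding progression point.
#' @export
cycle_profile <- function(segments, quantity, n_bins = 20, n_boot = 1000,
                          seed = 1, rescale = TRUE,
                          target_bud_point = "population-average") {
  stopifnot(n_bins >= 2, n_boot >= 100)
  if (rescale) {
    rs <- rescale_progression(segments, quantity, target_bud_point)
    xs <- lapply(rs$segments, `[[`, "progression")
    vs <- lapply(rs$segments, `[[`, "value")
    edges <- seq(0, 1, length.out = n_bins + 1)
    b <- rs$b
  } else {
    keep <- Filter(function(s) isTRUE(s$complete), segments)
    if (!length(keep)) stop("no complete segments")
    xs <- lapply(keep, function(s) s$data$time - s$t_bud)
    vs <- lapply(keep, function(s) s$data[[quantity]])
    pre <- mean(vapply(keep, function(s) s$t_bud - s$t_div_start, numeric(1)))
    post <- mean(vapply(keep, function(s) s$t_div_end - s$t_bud, numeric(1)))
    edges <- seq(-pre, post, length.out = n_bins + 1)
    b <- pre / (pre + post)
  }
  n_seg <- length(xs)
  # per-cycle per-bin means
  bin_means <- matrix(NA_real_, n_seg, n_bins)
  for (i in seq_len(n_seg)) {
    bi <- findInterval(xs[[i]], edges, rightmost.closed = TRUE,
                       all.inside = TRUE)
    agg <- tapply(vs[[i]], bi, mean)
    bin_means[i, as.integer(names(agg))] <- agg
  }
  n_per_bin <- colSums(!is.na(bin_means))
  mean_bin <- colMeans(bin_means, na.rm = TRUE)
  sd_bin <- apply(bin_means, 2, stats::sd, na.rm = TRUE)
  set.seed(seed)
  boot <- matrix(NA_real_, n_boot, n_bins)
  for (r in seq_len(n_boot)) {
    idx <- sample.int(n_seg, n_seg, replace = TRUE)
    boot[r, ] <- colMeans(bin_means[idx, , drop = FALSE], na.rm = TRUE)
  }
  sem <- apply(boot, 2, stats::sd)
  mean_bin[n_per_bin == 0] <- NA_real_
  structure(data.frame(bin_lo = edges[-(n_bins + 1)], bin_hi = edges[-1],
                       mean = mean_bin, sem_boot = sem, sd = sd_bin,
                       n = n_per_bin),
            b = b, rescaled = rescale,
            class = c("cycle_profile", "data.frame"))
}

#' Instantaneous volume growth rate series
#'
#' `dV/dt` from a smoothing spline on the volume series, using the same
#' penalty convention as the protein splines.
#'
#' @param trace a `cell_trace`.
#' @param beta roughness penalty.
#' @return data.frame `time`, `growth_rate` (AU/min).
#' @export
growth_rate_series <- function(trace, beta = default_beta()) {
  # volume drops discontinuously at division, so each division-to-division
  # stretch is fit separately; stretches too short for a spline give NA
  t <- trace$times
  g <- rep(NA_real_, length(t))
  divs <- sort(trace$division_times)
  edges <- unique(c(min(t), divs[divs > min(t) & divs < max(t)], max(t)))
  for (i in seq_len(length(edges) - 1)) {
    # the sample at a division carries the post-division (reset) volume, so
    # it opens the new stretch; a division on the right edge is excluded
    right_open <- i < length(edges) - 1 ||
      any(abs(divs - edges[i + 1]) < 1e-9)
    sel <- t >= edges[i] - 1e-9 &
      (if (right_open) t < edges[i + 1] - 1e-9 else t <= edges[i + 1] + 1e-9)
    if (sum(sel) < 8) next
    fit <- fit_smoothing_spline(list(times = t[sel], P = trace$volume[sel]),
                                beta = beta)
    g[sel] <- predict_spline(fit, t[sel], deriv = 1)
  }
  data.frame(time = t, growth_rate = g)
}
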