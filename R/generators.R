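#' Transcription-rate generator functions
#'
#' A generator describes the ground-truth instantaneous transcription rate
#' \eqn{A(t)} (mRNA/min) driving a simulation. All generators are piecewise
#' constant; `gen_breaks()` exposes the change points so ODE integration can
#' step exactly between them.
#'
#' @param rate,baseline,amplitude rates in mRNA/min, all `>= 0`.
#' @param t_on,t_off onset/offset times in minutes.
#' @name generators
NULL

new_generator <- function(kind, fun, breaks, params) {
  structure(list(kind = kind, fun = fun, breaks = sort(unique(breaks)),
                 params = params),
            class = "rate_generator")
}

#' @rdname generators
#' @export
gen_constant <- function(rate) {
  stopifnot(is.numeric(rate), length(rate) == 1L, rate >= 0)
  new_generator("constant", function(t) rep(rate, length(t)), numeric(0),
                list(rate = rate))
}

#' @rdname generators
#' @export
gen_step <- function(t_on, amplitude, baseline = 0) {
  stopifnot(amplitude >= 0, baseline >= 0)
  new_generator("step",
                function(t) ifelse(t >= t_on, amplitude, baseline),
                t_on, list(t_on = t_on, amplitude = amplitude, baseline = baseline))
}

#' @rdname generators
#' @export
gen_square_pulse <- function(t_on, t_off, amplitude, baseline = 0) {
  stopifnot(t_off > t_on, amplitude >= 0, baseline >= 0)
  new_generator("square_pulse",
                function(t) ifelse(t >= t_on & t < t_off, amplitude, baseline),
                c(t_on, t_off),
                list(t_on = t_on, t_off = t_off, amplitude = amplitude,
                     baseline = baseline))
}

#' Cell-cycle-modulated generator
#'
#' Transcription at a trough rate during G1 (pre-bud) and a peak rate during
#' S/G2/M (post-bud), repeating with period `t_cyc`. `pt_ratio` is the
#' peak-to-trough ratio; `mean_rate` fixes the cycle-average rate so that the
#' long-run mRNA mean is `mean_rate / gamma_M`. The pattern starts at
#' `t_start` (rate `baseline` before that, default 0, i.e. a step up into the
#' oscillating steady state); `phase_offset` (minutes into the cycle at
#' `t_start`) desynchronizes traces.
#'
#' @param mean_rate cycle-average rate, mRNA/min.
#' @param pt_ratio peak:trough rate ratio, `>= 1`.
#' @param t_cyc cycle length, min.
#' @param bud_fraction fraction of the cycle spent pre-bud (trough phase).
#' @param t_start time at which the oscillation begins, min.
#' @param phase_offset cycle phase (min, in `[0, t_cyc)`) at `t_start`.
#' @param baseline rate before `t_start`.
#' @export
gen_cycle_modulated <- function(mean_rate, pt_ratio = 2, t_cyc = 100,
                                bud_fraction = 0.27, t_start = 0,
                                phase_offset = 0, baseline = 0) {
  stopifnot(mean_rate >= 0, pt_ratio >= 1, t_cyc > 0,
            bud_fraction > 0, bud_fraction < 1,
            phase_offset >= 0, phase_offset < t_cyc, baseline >= 0)
  # trough*b + peak*(1-b) = mean with peak = pt_ratio*trough
  trough <- mean_rate / (bud_fraction + pt_ratio * (1 - bud_fraction))
  peak <- pt_ratio * trough
  fun <- function(t) {
    out <- rep(baseline, length(t))
    act <- t >= t_start
    ph <- ((t[act] - t_start + phase_offset) %% t_cyc) / t_cyc
    out[act] <- ifelse(ph < bud_fraction, trough, peak)
    out
  }
  # breaks over a generous horizon; simulate_cell intersects with its own span
  n_rep <- 60L
  ph0 <- phase_offset / t_cyc
  brk <- t_start + c(outer(c(0, bud_fraction) - ph0, seq_len(n_rep) - 1, `+`)) * t_cyc
  new_generator("cycle_modulated", fun, c(t_start, brk[brk >= t_start]),
                list(mean_rate = mean_rate, pt_ratio = pt_ratio, t_cyc = t_cyc,
                     bud_fraction = bud_fraction, t_start = t_start,
                     phase_offset = phase_offset, trough = trough, peak = peak,
                     baseline = baseline))
}

#' Evaluate a generator
#' @param gen a `rate_generator`.
#' @param t times, min.
#' @export
rate_at <- function(gen, t) {
  stopifnot(inherits(gen, "rate_generator"))
  r <- gen$fun(t)
  if (any(!is.finite(r)) || any(r < 0))
    stop("generator returned a negative or non-finite rate on the requested horizon")
  r
}

#' @export
print.rate_generator <- function(x, ...) {
  cat("<rate_generator:", x$kind, ">\n")
  str(x$params, give.attr = FALSE)
  invisible(x)
}
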