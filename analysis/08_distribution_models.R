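#!/usr/bin/env Rscript
# Phase-dependent snapshot models: predict per-phase mRNA distributions
# (analytic Poisson mixture vs Gillespie), fit the G1 -> S/G2/M fold change
# f to phase-stratified counts, fit the aggregate distribution to a
# negative binomial, and compare sharp vs randomized-transition models.

suppressMessages(library(cyclescope))
dir.create("results", showWarnings = FALSE)
seed <- 1

scenarios <- list(
  dosage_like = model_spec(k_G1 = 0.2, f = 2),
  strong      = model_spec(k_G1 = 0.05, f = 10),
  basal       = model_spec(k_G1 = 0, k_sgm = 0.6, gamma_M = log(2) / 5)
)

rows <- list(); fits <- list()
for (nm in names(scenarios)) {
  m <- scenarios[[nm]]
  pc <- simulate_population_snapshot(m, 4000,
                                     seed = stage_seed(seed, paste0("snap_", nm)))
  pred <- predict_model(m)
  emp <- tapply(pc$count, pc$phase, mean)[pred$per_phase$phase]
  rows[[nm]] <- data.frame(scenario = nm, phase = pred$per_phase$phase,
                           mean_analytic = pred$per_phase$mean,
                           mean_ssa = as.numeric(emp))
  ft <- fit_f(pc, gamma_M = m$gamma_M)
  nb <- fit_negative_binomial(pc$count)
  fits[[nm]] <- data.frame(
    scenario = nm, f_true = m$f, f_hat = ft$f_hat, censored = ft$censored,
    nb_burst_size = nb$b, nb_burst_freq = nb$a)
  message(sprintf("%-11s f_hat = %s%s | NB burst size %.2f, frequency %.2f",
                  nm, signif(ft$f_hat, 3), if (ft$censored) " (censored at grid top)" else "",
                  nb$b, nb$a))
}
write_tsv(do.call(rbind, rows), "results/phase_means.tsv",
          meta = list(seed = seed))
write_tsv(do.call(rbind, fits), "results/phase_model_fits.tsv",
          meta = list(seed = seed))

# sharp vs randomized transition on data with a randomized transition
mw <- model_spec(k_G1 = 0.05, f = 10, transition_model = "uniform_window")
ms <- model_spec(k_G1 = 0.05, f = 10, transition_model = "sharp")
pcw <- simulate_population_snapshot(mw, 4000, seed = stage_seed(seed, "window"))
cmp <- compare_models(pcw, list(mw, ms))
write_tsv(cmp$table, "results/model_comparison.tsv", meta = list(seed = seed))
message(sprintf(
  "randomized-transition data: chi-square %.3f (window model) vs %.3f (sharp)",
  cmp$goodness$chisq[1], cmp$goodness$chisq[2]))
message("overall distributions fit a negative binomial well even though the ",
        "generating process has no intrinsic bursting; the structure is in ",
        "the phase dependence")
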