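#!/usr/bin/env Rscript
# Step-test response delays: a step input at t = 0 drives TF nuclear
# localization, transcription follows after a configurable biological delay
# (longer in G1). The 5-step threshold procedure assigns per-cell
# localization and activation times; delays split by the phase at
# localization are compared by a two-sample K-S test.

suppressMessages(library(cyclescope))
dir.create("results", showWarnings = FALSE)
seed <- 1

cfg <- sim_config()
cells <- simulate_step_test(cfg, n_cells = 120, delay = 0,
                            extra_delay_g1 = 10,
                            seed = stage_seed(seed, "steptest"))
res <- steptest_delays(cells)
write_tsv(as.data.frame(res), "results/steptest_delays.tsv",
          meta = list(seed = seed,
                      transcription_threshold =
                        attr(res, "transcription_threshold"),
                      localization_threshold =
                        attr(res, "localization_threshold")))

cmp <- delays_by_phase(res)
message(sprintf("n = %d cells (%d censored)", nrow(res), sum(res$censored)))
message(sprintf("median response delay: %.1f min overall; %.1f (G1) vs %.1f (S/G2/M)",
                median(res$response_delay, na.rm = TRUE),
                cmp$median_g1, cmp$median_sgm))
message(sprintf("two-sample K-S test G1 vs S/G2/M: p = %.2g", cmp$ks$p.value))
message("the overall delay is dominated by fluorophore maturation (~10 min ",
        "half-life); cells localizing in G1 respond later by construction")
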