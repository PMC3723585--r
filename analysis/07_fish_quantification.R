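#!/usr/bin/env Rscript
# FISH spot quantification end to end: calibrate the pixel threshold on
# blank negative controls (per-cell false-positive rate < 5%), then detect,
# mode-normalize and count spots in synthetic images with known ground
# truth. Accuracy is reported for the default spot composition (15% of
# spots are unresolvable 2-3x overlaps) and for a singles-only composition,
# which isolates the effect of the 2-fold multiplicity boundary.

suppressMessages(library(cyclescope))
dir.create("results", showWarnings = FALSE)
set.seed(stage_seed(1, "fish"))
nsd <- 44   # background noise SD; spot peak ~354 AU -> SNR ~ 8

controls <- lapply(1:3, function(k) {
  tr <- make_spot_truth(n_cells = 20, mean_spots = 0, p_nascent = 0,
                        seed = 310 + k)
  list(image = render_fish_image(tr, background_noise_sd = nsd,
                                 seed = 320 + k),
       cell_mask = tr$cell_mask)
})
cal <- calibrate_threshold(controls, candidate_grid = seq(100, 350, by = 25))
message(sprintf("calibrated pixel threshold: %d (control FP rate %.1f%%)",
                cal$pixel_threshold, 100 * cal$fp_rate))

run_accuracy <- function(p_multi, label) {
  acc <- unlist(lapply(1:5, function(k) {
    truth <- make_spot_truth(n_cells = 20, p_multi = p_multi,
                             min_separation = 8, seed = 330 + k)
    img <- render_fish_image(truth, background_noise_sd = nsd,
                             seed = 340 + k)
    q <- quantify_image(img, quant_params(cal$pixel_threshold),
                        truth$cell_mask, truth$nuclear_mask)
    tc <- tapply(truth$spots$multiplicity, truth$spots$cell_id, sum)
    truecounts <- integer(20); truecounts[as.integer(names(tc))] <- tc
    got <- integer(20); got[q$counts$cell_id] <- q$counts$count
    got == truecounts
  }))
  message(sprintf("exact per-cell count matches (%s): %.0f%% of %d cells",
                  label, 100 * mean(acc), length(acc)))
  mean(acc)
}
acc_default <- run_accuracy(0.15, "15% multi-mRNA spots")
acc_singles <- run_accuracy(0, "singles + nascent only")

write_tsv(data.frame(
  pixel_threshold = cal$pixel_threshold, control_fp_rate = cal$fp_rate,
  accuracy_default = acc_default, accuracy_singles = acc_singles,
  noise_sd = nsd),
  "results/fish_accuracy.tsv", meta = list(seed = 1))
message("multi-mRNA spots sit exactly at the 2-fold counting boundary, so ",
        "their misclassification bounds the exact-match rate; see the ",
        "methods vignette")
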