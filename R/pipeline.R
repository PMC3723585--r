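#' Derive a per-stage seed from the global seed
#'
#' Stage seeds are a deterministic hash of the global seed and the stage
#' name, so toggling one stage never shifts another stage's random stream.
#' @param global_seed integer.
#' @param stage stage name.
#' @export
stage_seed <- function(global_seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(global_seed) * 7919 + h * 104729) %% 2147483647)
}

#' Run the simulate / infer / synchronize / detect pipeline
#'
#' Executes the requested stages in dependency order and writes each stage's
#' outputs plus a manifest (seeds, config, stage list) into `out_dir`.
#' Deterministic: the same config and seed give identical numeric outputs.
#'
#' @param config list (or path to a YAML file) with elements:
#'   `seed` (global seed), `stages` (character subset of
#'   `c("simulate", "infer", "profile", "events")`), `n_cells`, `n_cycles`,
#'   and an optional `sim` block of [sim_config()] overrides.
#' @param out_dir output directory (created).
#' @return invisibly, a list of stage outputs and the manifest path.
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config) && length(config) == 1)
    config <- yaml::read_yaml(config)
  stages <- config$stages %||% c("simulate", "infer", "profile", "events")
  seed <- config$seed %||% 1L
  n_cells <- config$n_cells %||% 20L
  n_cycles <- config$n_cycles %||% 3L
  cfg <- do.call(sim_config, config$sim %||% list())
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  out <- list()
  meta <- list(seed = seed)

  # simulate is the root stage; later stages re-derive it deterministically
  set.seed(stage_seed(seed, "simulate"))
  phases <- stats::runif(n_cells, 0, cfg$t_cyc)
  traces <- lapply(seq_len(n_cells), function(i)
    simulate_cell(cfg,
                  gen_cycle_modulated(cfg$gamma_M * cfg$mu, cfg$pt_ratio,
                                      cfg$t_cyc, cfg$bud_fraction,
                                      t_start = 0, phase_offset = phases[i]),
                  n_cycles = n_cycles, mode = "ode", phase0 = phases[i],
                  cell_id = sprintf("cell%03d", i)))
  if ("simulate" %in% stages) {
    write_cell_traces(traces, file.path(out_dir, "traces"), meta)
    out$traces <- traces
  }

  rates <- NULL
  if (any(c("infer", "profile", "events") %in% stages)) {
    rates <- lapply(traces, function(tr)
      infer_from_trace(list(times = tr$running_total$time,
                            P = tr$running_total$P_obs,
                            cell_id = tr$cell_id),
                       gamma_M = cfg$gamma_M, k_t = cfg$k_t))
  }
  if ("infer" %in% stages) {
    tab <- do.call(rbind, lapply(seq_along(rates), function(i)
      cbind(cell_id = traces[[i]]$cell_id, as.data.frame(rates[[i]]))))
    write_tsv(tab, file.path(out_dir, "rates.tsv"), meta)
    out$rates <- rates
  }
  if ("profile" %in% stages) {
    segs <- unlist(lapply(seq_along(traces), function(i) {
      tr <- traces[[i]]
      segment_cycles(tr, series = data.frame(time = tr$times,
                                             A = rates[[i]]$A,
                                             M = rates[[i]]$M,
                                             volume = tr$volume))
    }), recursive = FALSE)
    prof <- cycle_profile(segs, "A", n_bins = 20, n_boot = 200,
                          seed = stage_seed(seed, "profile"))
    write_profile(prof, file.path(out_dir, "profile_A.tsv"), meta)
    out$profile <- prof
  }
  if ("events" %in% stages) {
    thr <- background_threshold(unlist(lapply(rates, function(r)
      r$A[r$time < cfg$bud_fraction * cfg$t_cyc & !r$edge])))
    ev <- lapply(rates, binarize, threshold = max(thr, 1e-6))
    tab <- do.call(rbind, lapply(seq_along(ev), function(i)
      data.frame(cell_id = traces[[i]]$cell_id,
                 n_activations = length(ev[[i]]$activation_times),
                 n_deactivations = length(ev[[i]]$deactivation_times),
                 threshold = ev[[i]]$threshold)))
    write_tsv(tab, file.path(out_dir, "events.tsv"), meta)
    out$events <- ev
  }

  manifest <- list(seed = seed, stages = stages,
                   stage_seeds = lapply(stats::setNames(stages, stages),
                                        function(s) stage_seed(seed, s)),
                   n_cells = n_cells, n_cycles = n_cycles,
                   sim_config = unclass(cfg),
                   package_version = as.character(utils::packageVersion("cyclescope")))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  out$manifest <- file.path(out_dir, "manifest.json")
  invisible(out)
}
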