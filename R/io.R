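#' TSV interchange with header comments
#'
#' All tabular outputs use tab-separated files whose header may carry
#' `# key=value` comment lines (seed, parameters). Readers skip comments;
#' writers place them before the column header.
#'
#' @param x data.frame.
#' @param path file path.
#' @param meta named list written as `# key=value` lines.
#' @export
write_tsv <- function(x, path, meta = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (length(meta))
    writeLines(paste0("# ", names(meta), "=",
                      vapply(meta, format, character(1))), con)
  utils::write.table(x, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tsv
#' @export
read_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, comment.char = "#",
                    stringsAsFactors = FALSE)
}

#' Write a set of cell traces as trace + events (+ truth) TSVs
#'
#' @param traces list of `cell_trace`s.
#' @param prefix output path prefix: writes `<prefix>.tsv`,
#'   `<prefix>_events.tsv`, and `<prefix>_truth.tsv`.
#' @param meta header comments.
#' @export
write_cell_traces <- function(traces, prefix, meta = NULL) {
  tab <- do.call(rbind, lapply(traces, function(tr)
    data.frame(cell_id = tr$cell_id, mother_id = tr$mother_id,
               time_min = tr$times, volume = tr$volume, conc = tr$conc,
               P_running = tr$running_total$P_obs)))
  ev <- do.call(rbind, lapply(traces, function(tr)
    rbind(data.frame(cell_id = tr$cell_id, event = "bud",
                     time_min = tr$bud_times),
          data.frame(cell_id = tr$cell_id, event = "division",
                     time_min = tr$division_times))))
  truth <- do.call(rbind, lapply(traces, function(tr)
    cbind(cell_id = tr$cell_id, tr$truth)))
  write_tsv(tab, paste0(prefix, ".tsv"), meta)
  write_tsv(ev, paste0(prefix, "_events.tsv"), meta)
  write_tsv(truth, paste0(prefix, "_truth.tsv"), meta)
  invisible(prefix)
}

#' Write / read phase-stratified mRNA counts
#' @param counts a `phase_counts` data.frame (`cell_id`, `phase`, `count`).
#' @param path file path.
#' @param meta header comments.
#' @export
write_phase_counts <- function(counts, path, meta = NULL) {
  write_tsv(counts[, intersect(c("cell_id", "phase", "count"),
                               names(counts))], path, meta)
}

#' @rdname write_phase_counts
#' @export
read_phase_counts <- function(path) {
  x <- read_tsv(path)
  stopifnot(all(c("cell_id", "phase", "count") %in% names(x)))
  structure(x, class = c("phase_counts", "data.frame"))
}

#' Write a cycle profile as TSV
#' @param profile a `cycle_profile`.
#' @param path file path.
#' @param meta extra header comments.
#' @export
write_profile <- function(profile, path, meta = NULL) {
  write_tsv(as.data.frame(profile), path,
            c(list(budding_point = attr(profile, "b"),
                   rescaled = attr(profile, "rescaled")), meta))
}
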