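#' Spot-quantification parameters
#'
#' @param pixel_threshold minimum intensity for a pixel to belong to a spot,
#'   AU (above background).
#' @param single_mrna_intensity integrated intensity of a single mRNA spot,
#'   AU: the mode of the spot-intensity histogram (see
#'   [estimate_single_intensity()]).
#' @param nascent_fold nascent-site threshold as a multiple of the single
#'   spot intensity (the boundary of the flat region of the intensity
#'   histogram; default 4).
#' @export
quant_params <- function(pixel_threshold, single_mrna_intensity = NA,
                         nascent_fold = 4) {
  stopifnot(pixel_threshold > 0, nascent_fold > 2)
  structure(list(pixel_threshold = pixel_threshold,
                 single_mrna_intensity = single_mrna_intensity,
                 nascent_fold = nascent_fold),
            class = "quant_params")
}

# local maxima of a matrix: pixels >= all 8 neighbours and above `floor`
local_maxima <- function(img, floor_val) {
  nr <- nrow(img); nc <- ncol(img)
  pad <- matrix(-Inf, nr + 2, nc + 2)
  pad[2:(nr + 1), 2:(nc + 1)] <- img
  ok <- img > floor_val
  for (dy in -1:1) for (dx in -1:1) {
    if (dy == 0 && dx == 0) next
    ok <- ok & img >= pad[2:(nr + 1) + dy, 2:(nc + 1) + dx]
  }
  which(ok, arr.ind = TRUE)
}

#' Detect mRNA spots in a projected FISH image
#'
#' Local maxima above the pixel threshold (relative to the image background,
#' estimated as the median pixel), merged when closer than one PSF width,
#' with intensities integrated over a square neighbourhood
#' (background-subtracted). Cell and nucleus assignment from label masks.
#'
#' @param image numeric matrix (maximum projection).
#' @param params a [quant_params()].
#' @param cell_mask,nuclear_mask integer label matrices (0 = outside);
#'   optional.
#' @param merge_radius maxima closer than this (pixels) are merged into the
#'   brighter one.
#' @param box integration window edge, pixels (odd; default 7).
#' @param min_region minimum number of above-threshold pixels in the 3x3
#'   neighbourhood of a maximum (region-based thresholding: a
#'   diffraction-limited spot lights up several contiguous pixels, a noise
#'   excursion usually only one).
#' @return a `spot_table` data.frame: `x_px`, `y_px`, `intensity`
#'   (integrated, AU), `peak`, `cell_id`, `inside_nucleus`.
#' @export
detect_spots <- function(image, params, cell_mask = NULL, nuclear_mask = NULL,
                         merge_radius = 5, box = 7, min_region = 3) {
  stopifnot(inherits(params, "quant_params"), box %% 2 == 1)
  if (max(image) >= 65535) warning("image contains saturated pixels")
  bg <- stats::median(image)
  mx <- local_maxima(image, bg + params$pixel_threshold)
  if (nrow(mx) && min_region > 1) {
    nr0 <- nrow(image); nc0 <- ncol(image)
    ok <- vapply(seq_len(nrow(mx)), function(i) {
      ys <- max(1, mx[i, 1] - 1):min(nr0, mx[i, 1] + 1)
      xs <- max(1, mx[i, 2] - 1):min(nc0, mx[i, 2] + 1)
      sum(image[ys, xs] >= bg + params$pixel_threshold) >= min_region
    }, logical(1))
    mx <- mx[ok, , drop = FALSE]
  }
  if (!nrow(mx)) {
    return(structure(data.frame(x_px = numeric(0), y_px = numeric(0),
                                intensity = numeric(0), peak = numeric(0),
                                cell_id = integer(0),
                                inside_nucleus = logical(0)),
                     class = c("spot_table", "data.frame")))
  }
  peaks <- image[mx]
  ord <- order(peaks, decreasing = TRUE)
  mx <- mx[ord, , drop = FALSE]; peaks <- peaks[ord]
  # merge: keep brightest, drop maxima within merge_radius of a kept one
  keep <- logical(nrow(mx))
  for (i in seq_len(nrow(mx))) {
    if (i == 1) { keep[1] <- TRUE; next }
    kept <- mx[keep, , drop = FALSE]
    d2 <- (kept[, 1] - mx[i, 1])^2 + (kept[, 2] - mx[i, 2])^2
    keep[i] <- all(d2 > merge_radius^2)
  }
  mx <- mx[keep, , drop = FALSE]; peaks <- peaks[keep]
  half <- (box - 1) / 2
  nr <- nrow(image); nc <- ncol(image)
  intens <- vapply(seq_len(nrow(mx)), function(i) {
    ys <- max(1, mx[i, 1] - half):min(nr, mx[i, 1] + half)
    xs <- max(1, mx[i, 2] - half):min(nc, mx[i, 2] + half)
    sum(image[ys, xs] - bg)
  }, numeric(1))
  cid <- if (!is.null(cell_mask)) cell_mask[mx] else NA_integer_
  nuc <- if (!is.null(nuclear_mask)) nuclear_mask[mx] > 0 else NA
  structure(data.frame(x_px = mx[, 2], y_px = mx[, 1], intensity = intens,
                       peak = peaks, cell_id = cid, inside_nucleus = nuc),
            class = c("spot_table", "data.frame"))
}

#' Calibrate the pixel threshold on negative controls
#'
#' Chooses the smallest candidate threshold whose per-cell false-positive
#' rate (fraction of control cells containing at least one detected spot) is
#' below `fp_target` on negative-control images. If no threshold qualifies,
#' the largest grid value is returned with `ok = FALSE`.
#'
#' @param controls list of lists with `image` and `cell_mask`.
#' @param candidate_grid ascending thresholds to try, AU.
#' @param fp_target maximum tolerated false-positive rate (default 0.05).
#' @param ... passed to [detect_spots()].
#' @return list `pixel_threshold`, `fp_rate`, `ok`, `rates` (per candidate).
#' @export
calibrate_threshold <- function(controls, candidate_grid, fp_target = 0.05,
                                ...) {
  stopifnot(length(controls) >= 1, length(candidate_grid) >= 1)
  candidate_grid <- sort(candidate_grid)
  rates <- vapply(candidate_grid, function(thr) {
    n_cells <- 0L; n_fp <- 0L
    for (ctl in controls) {
      ids <- setdiff(unique(as.vector(ctl$cell_mask)), 0L)
      n_cells <- n_cells + length(ids)
      sp <- detect_spots(ctl$image, quant_params(thr), ctl$cell_mask, ...)
      n_fp <- n_fp + length(unique(sp$cell_id[!is.na(sp$cell_id) &
                                                sp$cell_id > 0]))
    }
    n_fp / n_cells
  }, numeric(1))
  ok <- rates < fp_target
  if (any(ok)) {
    i <- which(ok)[1]
    list(pixel_threshold = candidate_grid[i], fp_rate = rates[i], ok = TRUE,
         rates = data.frame(threshold = candidate_grid, fp_rate = rates))
  } else {
    list(pixel_threshold = max(candidate_grid), fp_rate = rates[length(rates)],
         ok = FALSE,
         rates = data.frame(threshold = candidate_grid, fp_rate = rates))
  }
}

#' Single-mRNA intensity from the spot-intensity histogram mode
#'
#' The mode of the spot-intensity distribution (kernel density peak over
#' sub-nascent spots) is taken as the intensity of one mRNA.
#'
#' @param spots a `spot_table`.
#' @return mode intensity, AU.
#' @export
estimate_single_intensity <- function(spots) {
  x <- spots$intensity
  if (length(x) < 3) return(stats::median(x))
  d <- stats::density(x, n = 512)
  mode1 <- d$x[which.max(d$y)]
  # refine on the single-spot cluster only, so the multi-mRNA tail does not
  # drag the bandwidth (and the mode) around
  xs <- x[x > 0.5 * mode1 & x < 1.5 * mode1]
  if (length(xs) < 3) return(mode1)
  d2 <- stats::density(xs, n = 512)
  d2$x[which.max(d2$y)]
}

#' Classify nascent transcription sites
#'
#' Flags spots brighter than `nascent_fold` times the single-mRNA intensity
#' *and* located inside the nucleus. Skipped (with a warning) if no nuclear
#' assignment is available.
#'
#' @param spots a `spot_table`.
#' @param params a [quant_params()] with `single_mrna_intensity` set.
#' @return the spot table with a `nascent` column.
#' @export
classify_nascent <- function(spots, params) {
  stopifnot(is.finite(params$single_mrna_intensity))
  if (all(is.na(spots$inside_nucleus))) {
    warning("no nuclear mask available; nascent classification skipped")
    spots$nascent <- NA
    return(spots)
  }
  thr <- params$nascent_fold * params$single_mrna_intensity
  spots$nascent <- spots$intensity > thr & spots$inside_nucleus %in% TRUE
  spots
}

#' Per-cell mRNA counts with mode-normalized multiplicities
#'
#' Spots below 2x the single-mRNA intensity count as one mRNA; brighter
#' spots count as `round(intensity / single_mrna_intensity)` overlapping
#' mRNAs. Nascent-flagged spots are included by default (same rounding) or
#' excluded with `include_nascent = FALSE`.
#'
#' @param spots a `spot_table` (with `nascent` if exclusion is wanted).
#' @param params a [quant_params()] with `single_mrna_intensity` set.
#' @param include_nascent count nascent sites into the per-cell total?
#' @return data.frame `cell_id`, `count`; the spot table with multiplicities
#'   is attached as attribute `spots`.
#' @export
count_mrna <- function(spots, params, include_nascent = TRUE) {
  stopifnot(is.finite(params$single_mrna_intensity),
            params$single_mrna_intensity > 0)
  mult <- ifelse(spots$intensity < 2 * params$single_mrna_intensity, 1L,
                 pmax(1L, as.integer(round(
                   spots$intensity / params$single_mrna_intensity))))
  spots$multiplicity <- mult
  use <- rep(TRUE, nrow(spots))
  if (!include_nascent && "nascent" %in% names(spots))
    use <- !(spots$nascent %in% TRUE)
  sel <- use & !is.na(spots$cell_id) & spots$cell_id > 0
  counts <- tapply(spots$multiplicity[sel], spots$cell_id[sel], sum)
  out <- data.frame(cell_id = as.integer(names(counts)),
                    count = as.integer(counts))
  structure(out, spots = spots)
}

#' Classify cell-cycle phase from bud sizes
#'
#' Unbudded cells (bud size 0) are G1; budded cells are ranked by bud size
#' and split into three equal-count bins S1/S2/S3 (ranked bud size as a
#' proxy for progression). Ties keep their stable input order; when the
#' count is not divisible by 3, earlier bins take the remainder.
#'
#' @param bud_sizes numeric vector, `>= 0` (0 = unbudded).
#' @return character vector of phase labels.
#' @export
classify_phase <- function(bud_sizes) {
  stopifnot(all(bud_sizes >= 0))
  out <- rep("G1", length(bud_sizes))
  budded <- which(bud_sizes > 0)
  nb <- length(budded)
  if (nb > 0) {
    rk <- rank(bud_sizes[budded], ties.method = "first")
    sizes <- c(ceiling(nb / 3),
               ceiling((nb - ceiling(nb / 3)) / 2))
    sizes <- c(sizes, nb - sum(sizes))
    bin <- cut(rk, breaks = cumsum(c(0, sizes)), labels = c("S1", "S2", "S3"))
    out[budded] <- as.character(bin)
  }
  out
}

#' End-to-end quantification of one synthetic FISH image
#'
#' Convenience wrapper: detect spots, estimate the single-mRNA intensity
#' mode (unless given), classify nascent sites, count per cell.
#'
#' @inheritParams detect_spots
#' @param include_nascent passed to [count_mrna()].
#' @return list `spots`, `counts`, `params`.
#' @export
quantify_image <- function(image, params, cell_mask, nuclear_mask = NULL,
                           include_nascent = TRUE) {
  spots <- detect_spots(image, params, cell_mask, nuclear_mask)
  if (!is.finite(params$single_mrna_intensity))
    params$single_mrna_intensity <- estimate_single_intensity(spots)
  spots <- classify_nascent(spots, params)
  counts <- count_mrna(spots, params, include_nascent = include_nascent)
  list(spots = attr(counts, "spots"), counts = counts, params = params)
}
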