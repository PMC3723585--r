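#' Synthetic FISH ground truth
#'
#' Lays out circular cells on a grid within the image, gives each a nuclear
#' disk, and scatters diffraction-limited mRNA spots inside the cells.
#' Nascent transcription sites (multiplicity >= `nascent_multiplicity`,
#' placed inside the nucleus) are added with probability `p_nascent` per
#' cell. Regular spots get multiplicity 1 except a fraction `p_multi` that
#' get 2-3 (overlapping mRNAs in the z-projection).
#'
#' @param n_cells number of cells.
#' @param image_shape c(rows, cols), pixels.
#' @param cell_radius,nucleus_radius pixels.
#' @param mean_spots mean mRNA spots per cell (Poisson).
#' @param p_multi fraction of spots with multiplicity 2-3.
#' @param p_nascent probability a cell carries a nascent site.
#' @param nascent_multiplicity mRNA equivalents at a nascent site.
#' @param min_separation minimum center-to-center spot distance within a
#'   cell, pixels (diffraction-limited spots are resolvable; overlapping
#'   mRNAs are represented by the multiplicity instead).
#' @param seed RNG seed.
#' @return a `spot_truth`: `spots` data.frame (`x_px`, `y_px`,
#'   `multiplicity`, `nascent`, `cell_id`), `cell_mask` and `nuclear_mask`
#'   label matrices, `image_shape`, and `cells` (centers, bud sizes drawn
#'   from cycle age for phase-classification tests).
#' @export
make_spot_truth <- function(n_cells = 20, image_shape = c(256, 256),
                            cell_radius = 14, nucleus_radius = 5,
                            mean_spots = 6, p_multi = 0.15, p_nascent = 0.3,
                            nascent_multiplicity = 6, min_separation = 5,
                            seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  nr <- image_shape[1]; nc <- image_shape[2]
  pitch <- 2 * cell_radius + 4
  per_row <- floor((nc - pitch) / pitch)
  stopifnot(per_row >= 1)
  centers <- t(vapply(seq_len(n_cells) - 1L, function(i) {
    c(x = pitch * (i %% per_row) + pitch / 2 + cell_radius / 2,
      y = pitch * (i %/% per_row) + pitch / 2 + cell_radius / 2)
  }, numeric(2)))
  if (max(centers[, 2]) + cell_radius >= nr)
    stop("too many cells for the requested image shape")

  cell_mask <- matrix(0L, nr, nc)
  nuc_mask <- matrix(0L, nr, nc)
  xs <- matrix(rep(seq_len(nc), each = nr), nr, nc)
  ys <- matrix(rep(seq_len(nr), nc), nr, nc)
  for (i in seq_len(n_cells)) {
    d2 <- (xs - centers[i, 1])^2 + (ys - centers[i, 2])^2
    cell_mask[d2 <= cell_radius^2] <- i
    nuc_mask[d2 <= nucleus_radius^2] <- i
  }

  spots <- list()
  ages <- sample_ages(n_cells, 100)
  draw_in_disk <- function(r_max, placed, cx, cy) {
    # rejection-sample a point >= min_separation from all placed points
    for (try in 1:200) {
      rr <- r_max * sqrt(stats::runif(1))
      th <- stats::runif(1, 0, 2 * pi)
      x <- cx + rr * cos(th); y <- cy + rr * sin(th)
      if (!nrow(placed) ||
          all((placed$x - x)^2 + (placed$y - y)^2 >= min_separation^2))
        return(c(x, y))
    }
    NULL
  }
  for (i in seq_len(n_cells)) {
    placed <- data.frame(x = numeric(0), y = numeric(0))
    cell_spots <- list()
    if (stats::runif(1) < p_nascent) {
      p <- draw_in_disk(nucleus_radius - 1, placed, centers[i, 1], centers[i, 2])
      placed <- rbind(placed, data.frame(x = p[1], y = p[2]))
      cell_spots[[1]] <- data.frame(x_px = p[1], y_px = p[2],
                                    multiplicity = as.integer(nascent_multiplicity),
                                    nascent = TRUE, cell_id = i)
    }
    n_sp <- stats::rpois(1, mean_spots)
    for (k in seq_len(n_sp)) {
      p <- draw_in_disk(cell_radius - 2, placed, centers[i, 1], centers[i, 2])
      if (is.null(p)) next  # cell too crowded to place another resolvable spot
      placed <- rbind(placed, data.frame(x = p[1], y = p[2]))
      mult <- if (stats::runif(1) < p_multi) sample(2:3, 1) else 1L
      cell_spots[[length(cell_spots) + 1]] <-
        data.frame(x_px = p[1], y_px = p[2], multiplicity = as.integer(mult),
                   nascent = FALSE, cell_id = i)
    }
    if (length(cell_spots))
      spots[[length(spots) + 1]] <- do.call(rbind, cell_spots)
  }
  spots <- if (length(spots)) do.call(rbind, spots) else
    data.frame(x_px = numeric(0), y_px = numeric(0),
               multiplicity = integer(0), nascent = logical(0),
               cell_id = integer(0))
  # bud size: monotone in cycle age past budding (0 = unbudded G1 cell)
  bud_size <- ifelse(ages > 27, (ages - 27) / 73 * cell_radius, 0)
  structure(list(spots = spots, cell_mask = cell_mask,
                 nuclear_mask = nuc_mask, image_shape = image_shape,
                 cells = data.frame(cell_id = seq_len(n_cells),
                                    x = centers[, 1], y = centers[, 2],
                                    age = ages, bud_size = bud_size)),
            class = "spot_truth")
}

#' Render a synthetic FISH image
#'
#' Each spot becomes an isotropic 2D Gaussian whose *integrated* intensity is
#' `multiplicity * single_mrna_intensity`; Gaussian background noise and a
#' constant offset are added. Values are clipped to the 16-bit range (with a
#' warning on overflow).
#'
#' @param truth a `spot_truth` (or any data.frame with `x_px`, `y_px`,
#'   `multiplicity`).
#' @param image_shape c(rows, cols); defaults to the truth's shape.
#' @param psf_sigma Gaussian sigma, pixels.
#' @param single_mrna_intensity integrated intensity of one mRNA, AU.
#' @param background_level constant offset, AU.
#' @param background_noise_sd Gaussian noise SD, AU.
#' @param seed RNG seed.
#' @return numeric matrix (rows x cols) of intensities in `[0, 65535]`.
#' @export
render_fish_image <- function(truth, image_shape = NULL, psf_sigma = 1.5,
                              single_mrna_intensity = 5000,
                              background_level = 200,
                              background_noise_sd = 0, seed = NULL) {
  spots <- if (inherits(truth, "spot_truth")) truth$spots else truth
  if (is.null(image_shape))
    image_shape <- if (inherits(truth, "spot_truth")) truth$image_shape
      else c(256, 256)
  if (!is.null(seed)) set.seed(seed)
  nr <- image_shape[1]; nc <- image_shape[2]
  if (nrow(spots) &&
      (any(spots$x_px < 1 | spots$x_px > nc | spots$y_px < 1 | spots$y_px > nr)))
    stop("spot centers must lie within the image bounds")
  img <- matrix(background_level, nr, nc)
  half <- ceiling(4 * psf_sigma)
  for (s in seq_len(nrow(spots))) {
    cx <- spots$x_px[s]; cy <- spots$y_px[s]
    xs <- max(1, floor(cx) - half):min(nc, ceiling(cx) + half)
    ys <- max(1, floor(cy) - half):min(nr, ceiling(cy) + half)
    gx <- exp(-(xs - cx)^2 / (2 * psf_sigma^2))
    gy <- exp(-(ys - cy)^2 / (2 * psf_sigma^2))
    amp <- spots$multiplicity[s] * single_mrna_intensity /
      (2 * pi * psf_sigma^2)
    img[ys, xs] <- img[ys, xs] + amp * outer(gy, gx)
  }
  if (background_noise_sd > 0)
    img <- img + matrix(stats::rnorm(nr * nc, 0, background_noise_sd), nr, nc)
  if (any(img > 65535)) {
    warning("intensities exceed the 16-bit range; clipping")
    img[img > 65535] <- 65535
  }
  img[img < 0] <- 0
  img
}

#' Write / read a 16-bit grayscale TIFF
#' @param img numeric matrix in `[0, 65535]`.
#' @param path file path.
#' @export
write_fish_tiff <- function(img, path) {
  tiff::writeTIFF(img / 65535, path, bits.per.sample = 16L)
  invisible(path)
}

#' @rdname write_fish_tiff
#' @export
read_fish_tiff <- function(path) {
  tiff::readTIFF(path) * 65535
}
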