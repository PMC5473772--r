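## Seeded synthetic fluorescence microscopy of rod-shaped bacteria.
##
## Cells are capsules (rectangle plus semicircular caps) placed without
## overlap on a square frame. Each cell carries a diffuse cytoplasmic
## photon density, an autofluorescence floor, and zero or more
## diffraction-blurred foci whose brightness comes from the occupancy
## model. The camera model is Poisson shot noise on expected photons,
## linear gain, a constant offset, additive Gaussian read noise, and
## 16-bit quantization with clipping. Exposure-time differences between
## experimental regimes are absorbed into the gain.
##
## Four construct regimes are emulated:
##   FULL_LENGTH - repressor fused to an intact fluorophore: every pool
##     molecule fluoresces, so the unbound pool produces a large diffuse
##     component and array-bound molecules a focus.
##   SPLIT      - each repressor carries half of the fluorophore: only
##     array-bound (reconstituted) pairs fluoresce, plus a small
##     spontaneously self-assembled diffuse fraction.
##   EMPTY      - no reporter: autofluorescence only.

#' Cell-size distribution for the simulator
#'
#' Rod-cell geometry in pixels. Lengths are normal, truncated below at
#' `min_length`; widths are normal, clipped to stay biologically rod-like.
#'
#' @param length_mean,length_sd cell length distribution (pixels).
#' @param width_mean,width_sd cell width distribution (pixels).
#' @param min_length lower truncation for length (pixels).
#' @return an `area_distribution` parameter list.
#' @export
area_distribution <- function(length_mean = 28, length_sd = 5,
                              width_mean = 9, width_sd = 0.5,
                              min_length = 18) {
  stopifnot(length_mean > min_length, width_mean > 2)
  structure(list(length_mean = length_mean, length_sd = length_sd,
                 width_mean = width_mean, width_sd = width_sd,
                 min_length = min_length),
            class = "area_distribution")
}

#' Optics and camera noise configuration
#'
#' @param psf_sigma isotropic Gaussian PSF standard deviation (pixels).
#' @param read_noise_sd Gaussian read noise (counts).
#' @param gain counts per photon (exposure differences are absorbed here).
#' @param offset camera bias (counts).
#' @param bit_depth output bit depth; pixels are clipped to
#'   `[0, 2^bit_depth - 1]`.
#' @param seed integer seed for the rendering substream.
#' @return an `optics_noise_config`.
#' @export
optics_noise_config <- function(psf_sigma = 1.3, read_noise_sd = 10,
                                gain = 16, offset = 100, bit_depth = 16,
                                seed = 1L) {
  stopifnot(psf_sigma > 0, read_noise_sd >= 0, gain > 0, offset >= 0,
            bit_depth %in% c(8, 12, 16))
  structure(list(psf_sigma = psf_sigma, read_noise_sd = read_noise_sd,
                 gain = gain, offset = offset, bit_depth = bit_depth,
                 seed = as.integer(seed)),
            class = "optics_noise_config")
}

# analytic capsule area: rectangle (l - w) x w plus a full disc of
# diameter w from the two end caps
capsule_area <- function(length, width) {
  width * (length - width) + pi * (width / 2)^2
}

#' Sample a synthetic cell population
#'
#' Draws cell geometries, places cells on non-overlapping grid slots with
#' random jitter and orientation, and assigns photon budgets per the
#' construct regime. Per-cell expression noise is lognormal (unit mean);
#' when `occupancy` is given as [occupancy_params()] the titration is
#' re-solved per cell with the scaled pool, so focus brightness saturates
#' honestly at the site capacity. Passing a fixed `occupancy_result`
#' instead scales bound and free counts linearly with expression.
#'
#' @param n_cells number of cells.
#' @param construct `"FULL_LENGTH"`, `"SPLIT"`, or `"EMPTY"`.
#' @param occupancy an [occupancy_params()] or `occupancy_result`;
#'   its `n_arrays` sets the number of foci per cell.
#' @param area_distribution an [area_distribution()].
#' @param seed integer seed for the sampling substream.
#' @param frame_dim frame size in pixels, `c(nx, ny)`.
#' @param brightness_per_fluorophore expected photons per fluorophore per
#'   exposure.
#' @param autofluorescence photon density of cellular autofluorescence
#'   (photons/pixel), present in every regime.
#' @param expression_sdlog lognormal sdlog of per-cell expression noise.
#' @return a `sim_population`: list with `cells` (one row per cell:
#'   `cell_id`, `cx`, `cy`, `length`, `width`, `orientation`, `area`,
#'   `construct`, `n_arrays`, `diffuse_level`, `focus_photons`,
#'   `autofluorescence`, `expression`), `foci` (`cell_id`, `x`, `y`,
#'   `photons`), and `frame_dim`.
#' @export
sample_population <- function(n_cells, construct = c("SPLIT", "FULL_LENGTH", "EMPTY"),
                              occupancy = occupancy_params(),
                              area_distribution = bifcros::area_distribution(),
                              seed = 1L, frame_dim = c(512L, 512L),
                              brightness_per_fluorophore = 50,
                              autofluorescence = 3,
                              expression_sdlog = 0.3) {
  construct <- match.arg(construct)
  stopifnot(n_cells >= 1)
  ad <- area_distribution
  set.seed(substream_seed(seed, "sample_population"))

  # grid placement: one cell per slot guarantees non-overlap for any
  # orientation, since the slot exceeds the largest bounding circle
  max_len <- ad$length_mean + 4 * ad$length_sd
  slot <- ceiling(max_len) + 4L
  margin <- 2L
  nx <- (frame_dim[1] - 2L * margin) %/% slot
  ny <- (frame_dim[2] - 2L * margin) %/% slot
  if (n_cells > nx * ny) {
    stop(sprintf(
      "placement failed: frame %dx%d holds at most %d non-overlapping cells, %d requested",
      frame_dim[1], frame_dim[2], nx * ny, n_cells))
  }
  slots <- sample(nx * ny, n_cells)
  sx <- (slots - 1L) %% nx
  sy <- (slots - 1L) %/% nx

  len <- pmax(stats::rnorm(n_cells, ad$length_mean, ad$length_sd), ad$min_length)
  len <- pmin(len, max_len)
  wid <- pmin(pmax(stats::rnorm(n_cells, ad$width_mean, ad$width_sd),
                   ad$width_mean - 2), ad$width_mean + 2)
  theta <- stats::runif(n_cells, 0, pi)
  jitter_room <- pmax((slot - len) / 2 - 1, 0)
  cx <- margin + sx * slot + slot / 2 + stats::runif(n_cells, -1, 1) * jitter_room
  cy <- margin + sy * slot + slot / 2 + stats::runif(n_cells, -1, 1) * jitter_room
  area <- capsule_area(len, wid)
  expr <- stats::rlnorm(n_cells, meanlog = -expression_sdlog^2 / 2,
                        sdlog = expression_sdlog)

  is_result <- inherits(occupancy, "occupancy_result")
  params <- if (is_result) occupancy$params else occupancy
  stopifnot(inherits(params, "occupancy_params"))
  n_arrays <- as.integer(params$n_arrays)
  b <- brightness_per_fluorophore

  diffuse <- numeric(n_cells)
  focus_photons <- numeric(n_cells)
  if (construct != "EMPTY") {
    for (i in seq_len(n_cells)) {
      if (is_result) {
        bound_per_array <- occupancy$bound_per_array * expr[i]
        total_bound <- occupancy$total_bound * expr[i]
        free_comp <- occupancy$free_complemented * expr[i]
        pool_i <- params$pool_size * expr[i]
      } else {
        p <- params
        p$pool_size <- p$pool_size * expr[i]
        r <- compute_occupancy(p)
        bound_per_array <- r$bound_per_array
        total_bound <- r$total_bound
        free_comp <- r$free_complemented
        pool_i <- p$pool_size
      }
      if (construct == "FULL_LENGTH") {
        # intact fluorophore: every unbound molecule adds diffuse signal
        diffuse[i] <- (pool_i - total_bound) * b / area[i]
        focus_photons[i] <- if (n_arrays > 0) bound_per_array * b else 0
      } else { # SPLIT
        diffuse[i] <- free_comp * b / area[i]
        focus_photons[i] <- if (n_arrays > 0) bound_per_array * b else 0
      }
    }
  }

  cells <- data.frame(
    cell_id = seq_len(n_cells), cx = cx, cy = cy, length = len, width = wid,
    orientation = theta, area = area, construct = construct,
    n_arrays = if (construct == "EMPTY") 0L else n_arrays,
    diffuse_level = diffuse, focus_photons = focus_photons,
    autofluorescence = autofluorescence, expression = expr
  )

  foci <- NULL
  if (construct != "EMPTY" && n_arrays > 0) {
    rows <- vector("list", n_cells)
    for (i in seq_len(n_cells)) {
      a <- pmax((len[i] - wid[i]) / 2 - 1, 0)
      t <- stats::runif(n_arrays, -a, a)
      rows[[i]] <- data.frame(
        cell_id = i,
        x = cx[i] + t * cos(theta[i]),
        y = cy[i] + t * sin(theta[i]),
        photons = focus_photons[i]
      )
    }
    foci <- do.call(rbind, rows)
  } else {
    foci <- data.frame(cell_id = integer(0), x = numeric(0), y = numeric(0),
                       photons = numeric(0))
  }

  structure(list(cells = cells, foci = foci, frame_dim = as.integer(frame_dim)),
            class = "sim_population")
}

#' @export
print.sim_population <- function(x, ...) {
  cat(sprintf("<sim_population> %d %s cells on a %dx%d frame, %d foci\n",
              nrow(x$cells), x$cells$construct[1], x$frame_dim[1],
              x$frame_dim[2], nrow(x$foci)))
  invisible(x)
}

# rasterize a capsule into the frame; returns integer index vector of
# pixels whose centers lie within distance width/2 of the midline segment
capsule_pixels <- function(cx, cy, length, width, theta, nx, ny) {
  r <- width / 2
  half <- length / 2 + 1
  x0 <- max(1L, floor(cx - half)); x1 <- min(nx, ceiling(cx + half))
  y0 <- max(1L, floor(cy - half)); y1 <- min(ny, ceiling(cy + half))
  xs <- x0:x1; ys <- y0:y1
  px <- rep(xs, times = length(ys))
  py <- rep(ys, each = length(xs))
  a <- (length - width) / 2
  ux <- cos(theta); uy <- sin(theta)
  # distance from pixel center to the midline segment
  dx <- px - cx; dy <- py - cy
  t <- pmin(pmax(dx * ux + dy * uy, -a), a)
  d2 <- (dx - t * ux)^2 + (dy - t * uy)^2
  keep <- d2 <= r^2
  (px[keep] - 1L) * ny + py[keep]  # column-major index with nrow = ny
}

#' Render a synthetic 16-bit fluorescence image
#'
#' Builds the expected photon image (diffuse plus autofluorescence inside
#' each cell, foci spread by a discretized Gaussian PSF normalized to
#' conserve photons), then applies Poisson shot noise, gain, offset,
#' Gaussian read noise, and quantization with clipping. Deterministic
#' given `config$seed`.
#'
#' @param population a [sample_population()] result.
#' @param config an [optics_noise_config()].
#' @param noise logical; `FALSE` disables shot and read noise (the
#'   expected photon image is passed straight through gain/offset and
#'   quantization).
#' @return a `synthetic_image`: list with `pixels` (integer matrix,
#'   row = y), `label_mask` (integer matrix, 0 = background), `truth`
#'   (the population's cell table with rasterized `area_px`), `foci`,
#'   `expected_counts` (noise-free, unquantized counts), and `config`.
#' @export
render_image <- function(population, config = optics_noise_config(),
                         noise = TRUE) {
  stopifnot(inherits(population, "sim_population"),
            inherits(config, "optics_noise_config"))
  nx <- population$frame_dim[1]; ny <- population$frame_dim[2]
  photons <- matrix(0, nrow = ny, ncol = nx)
  mask <- matrix(0L, nrow = ny, ncol = nx)
  cells <- population$cells
  area_px <- integer(nrow(cells))
  for (i in seq_len(nrow(cells))) {
    idx <- capsule_pixels(cells$cx[i], cells$cy[i], cells$length[i],
                          cells$width[i], cells$orientation[i], nx, ny)
    if (any(mask[idx] != 0L)) {
      stop("internal error: overlapping cell placements")
    }
    mask[idx] <- cells$cell_id[i]
    photons[idx] <- photons[idx] +
      cells$diffuse_level[i] + cells$autofluorescence[i]
    area_px[i] <- length(idx)
  }

  # foci: discretized Gaussian patch, renormalized so each focus deposits
  # exactly its photon budget (no leakage at patch borders)
  sig <- config$psf_sigma
  rad <- ceiling(6 * sig)
  if (nrow(population$foci) > 0) {
    for (j in seq_len(nrow(population$foci))) {
      fx <- population$foci$x[j]; fy <- population$foci$y[j]
      ph <- population$foci$photons[j]
      if (ph <= 0) next
      x0 <- max(1L, floor(fx - rad)); x1 <- min(nx, ceiling(fx + rad))
      y0 <- max(1L, floor(fy - rad)); y1 <- min(ny, ceiling(fy + rad))
      gx <- exp(-((x0:x1) - fx)^2 / (2 * sig^2))
      gy <- exp(-((y0:y1) - fy)^2 / (2 * sig^2))
      kern <- outer(gy, gx)
      photons[y0:y1, x0:x1] <- photons[y0:y1, x0:x1] + ph * kern / sum(kern)
    }
  }

  expected_counts <- config$gain * photons + config$offset
  set.seed(substream_seed(config$seed, "render_image"))
  if (noise) {
    shot <- matrix(stats::rpois(length(photons), photons),
                   nrow = ny, ncol = nx)
    counts <- config$gain * shot + config$offset +
      stats::rnorm(length(photons), 0, config$read_noise_sd)
  } else {
    counts <- expected_counts
  }
  ceiling_val <- 2^config$bit_depth - 1
  pixels <- matrix(as.integer(pmin(pmax(round(counts), 0), ceiling_val)),
                   nrow = ny, ncol = nx)

  truth <- cells
  truth$area_px <- area_px
  structure(list(pixels = pixels, label_mask = mask, truth = truth,
                 foci = population$foci, expected_counts = expected_counts,
                 config = config),
            class = "synthetic_image")
}

#' @export
print.synthetic_image <- function(x, ...) {
  cat(sprintf("<synthetic_image> %dx%d px, %d cells, max count %d\n",
              ncol(x$pixels), nrow(x$pixels), max(x$label_mask),
              max(x$pixels)))
  invisible(x)
}

#' Write a synthetic image, its label mask and its truth table to disk
#'
#' The image and mask are single-channel 16-bit little-endian grayscale
#' TIFFs; the truth table is CSV.
#'
#' @param image a `synthetic_image`.
#' @param prefix output path prefix; writes `<prefix>_image.tif`,
#'   `<prefix>_mask.tif`, `<prefix>_truth.csv`.
#' @return named character vector of the paths, invisibly.
#' @export
write_synthetic_image <- function(image, prefix) {
  stopifnot(inherits(image, "synthetic_image"))
  paths <- c(image = paste0(prefix, "_image.tif"),
             mask = paste0(prefix, "_mask.tif"),
             truth = paste0(prefix, "_truth.csv"))
  tiff::writeTIFF(image$pixels / 65535, paths["image"],
                  bits.per.sample = 16L)
  tiff::writeTIFF(image$label_mask / 65535, paths["mask"],
                  bits.per.sample = 16L)
  utils::write.csv(image$truth, paths["truth"], row.names = FALSE)
  invisible(paths)
}

#' Read a 16-bit grayscale TIFF as an integer count matrix
#'
#' @param path TIFF file path.
#' @return integer matrix of counts in `[0, 65535]`.
#' @export
read_count_tiff <- function(path) {
  m <- tiff::readTIFF(path)
  if (length(dim(m)) == 3) m <- m[, , 1]
  matrix(as.integer(round(m * 65535)), nrow = nrow(m))
}
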