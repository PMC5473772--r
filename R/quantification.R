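## Per-cell signal/background statistics and filters.
##
## For each segmented cell the pixels are ranked; the signal is the mean
## of the brightest 10% of pixels and the background is the mean of the
## dimmest 50%. Cells are retained for analysis only if their intensity
## stays below 65,000 counts (a near-saturation guard on a 16-bit camera)
## and their signal-to-background ratio exceeds fivefold (strictly).
## Fraction counts are rounded up (at least one pixel), so the statistic
## is defined for arbitrarily small cells.

#' Quantification configuration
#'
#' Defaults are the standard analysis settings for this assay family:
#' signal = top 10% of pixels, background = bottom 50%, retain cells with
#' intensities below 65,000 counts and a signal/background ratio above 5.
#'
#' @param signal_fraction fraction of brightest pixels defining the signal.
#' @param background_fraction fraction of dimmest pixels defining the
#'   background.
#' @param max_intensity retention cutoff (counts); strictly-below.
#' @param min_ratio retention cutoff on signal/background; strictly-above.
#' @param histogram_breaks bin edges (counts) for pooled pixel histograms.
#' @param intensity_filter_on `"pixel_max"` applies `max_intensity` to the
#'   cell's brightest pixel (saturation guard, default); `"cell_mean"`
#'   applies it to the whole-cell mean.
#' @return a `quant_config`.
#' @export
quant_config <- function(signal_fraction = 0.10, background_fraction = 0.50,
                         max_intensity = 65000, min_ratio = 5.0,
                         histogram_breaks = seq(0, 66000, by = 2000),
                         intensity_filter_on = c("pixel_max", "cell_mean")) {
  stopifnot(signal_fraction > 0, signal_fraction <= 1,
            background_fraction > 0, background_fraction <= 1,
            max_intensity <= 65535, min_ratio >= 0)
  structure(list(signal_fraction = signal_fraction,
                 background_fraction = background_fraction,
                 max_intensity = max_intensity, min_ratio = min_ratio,
                 histogram_breaks = histogram_breaks,
                 intensity_filter_on = match.arg(intensity_filter_on)),
            class = "quant_config")
}

#' Per-cell signal and background statistic
#'
#' Sorts the cell's pixels (stable sort, descending); the signal is the
#' mean of the top `ceiling(signal_fraction * n)` pixels and the
#' background the mean of the bottom `ceiling(background_fraction * n)`
#' pixels (each at least one pixel). The ratio is signal/background;
#' a zero background yields an infinite ratio, which is flagged rather
#' than an error.
#'
#' @param m one cell's measurement record (from [extract_measurements()]),
#'   or any list with `cell_id`, `area`, `pixel_values`.
#' @param cfg a [quant_config()].
#' @return one-row data.frame with `cell_id`, `area`, `mean_intensity`,
#'   `max_intensity`, `signal`, `background`, `ratio`, `passed_filters`
#'   (NA until [filter_cells()] runs).
#' @export
#' @examples
#' m <- list(cell_id = 1L, area = 10L, pixel_values = seq(10, 100, by = 10))
#' signal_background(m, quant_config())  # signal 100, background 30
signal_background <- function(m, cfg = quant_config()) {
  v <- m$pixel_values
  if (length(v) == 0) stop("empty pixel vector")
  n <- length(v)
  sorted <- sort(v, decreasing = TRUE, method = "radix")
  n_sig <- max(1L, ceiling(cfg$signal_fraction * n))
  n_bg <- max(1L, ceiling(cfg$background_fraction * n))
  signal <- mean(sorted[seq_len(n_sig)])
  background <- mean(sorted[seq.int(n - n_bg + 1L, n)])
  data.frame(
    cell_id = m$cell_id, area = n, mean_intensity = mean(v),
    max_intensity = max(v), signal = signal, background = background,
    ratio = if (background > 0) signal / background else Inf,
    passed_filters = NA
  )
}

#' Quantify every cell in a measurement set
#'
#' Applies [signal_background()] per cell and then [filter_cells()], so
#' the returned table carries the retention flags.
#'
#' @param measurements a `cell_measurements` object.
#' @param cfg a [quant_config()].
#' @return data.frame of per-cell quantifications (class `cell_quant`).
#' @export
quantify_cells <- function(measurements, cfg = quant_config()) {
  q <- do.call(rbind, lapply(measurements, signal_background, cfg = cfg))
  class(q) <- c("cell_quant", class(q))
  filter_cells(q, cfg, drop = FALSE)
}

#' Apply the intensity and ratio retention filters
#'
#' A cell is retained when its intensity is strictly below
#' `max_intensity` (on the brightest pixel by default) and its
#' signal/background ratio is strictly above `min_ratio`. `passed_filters`
#' is set on every input row.
#'
#' @param quants a `cell_quant` data.frame.
#' @param cfg a [quant_config()].
#' @param drop if `TRUE` (default) return only retained cells; otherwise
#'   return all rows with the flag set.
#' @return filtered/flagged `cell_quant` data.frame.
#' @export
filter_cells <- function(quants, cfg = quant_config(), drop = TRUE) {
  intensity <- switch(cfg$intensity_filter_on,
                      pixel_max = quants$max_intensity,
                      cell_mean = quants$mean_intensity)
  quants$passed_filters <- intensity < cfg$max_intensity &
    quants$ratio > cfg$min_ratio
  if (drop) quants[quants$passed_filters, , drop = FALSE] else quants
}

#' Pooled pixel-intensity histogram over retained cells
#'
#' Pools the raw pixel values of the retained cells and bins them on the
#' configured edges. The total count equals the summed areas of the
#' retained cells.
#'
#' @param measurements a `cell_measurements` object.
#' @param cfg a [quant_config()]; supplies bin edges and, via
#'   [filter_cells()], the retention rule.
#' @param retained_ids optional integer vector of cell ids to pool;
#'   defaults to the cells passing the configured filters.
#' @return data.frame with `bin_lower`, `bin_upper` (half-open bins,
#'   last bin closed), `count`.
#' @export
pixel_histogram <- function(measurements, cfg = quant_config(),
                            retained_ids = NULL) {
  if (length(measurements) == 0) stop("no cells to pool")
  if (is.null(retained_ids)) {
    q <- quantify_cells(measurements, cfg)
    retained_ids <- q$cell_id[q$passed_filters]
  }
  keep <- Filter(function(m) m$cell_id %in% retained_ids, measurements)
  if (length(keep) == 0) stop("no retained cells to pool")
  pooled <- unlist(lapply(keep, function(m) m$pixel_values))
  br <- cfg$histogram_breaks
  if (max(pooled) > max(br) || min(pooled) < min(br)) {
    stop("histogram breaks do not span the pooled pixel range")
  }
  # half-open bins [lower, upper), with the last bin closed above
  bin <- findInterval(pooled, br, rightmost.closed = TRUE)
  counts <- tabulate(bin, nbins = length(br) - 1L)
  data.frame(bin_lower = br[-length(br)], bin_upper = br[-1], count = counts)
}
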