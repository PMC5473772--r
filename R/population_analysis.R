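## Population-level procedures: area binning, control-strain background
## subtraction, signal-vs-background regression, and copy-number
## fold-change estimation.

#' Bin whole-cell mean intensities by cell area
#'
#' Groups cells by area in windows of `window` pixels and reports the
#' per-bin mean (and SD) of whole-cell mean intensities. Bins holding
#' fewer than `min_cells` cells are excluded. `"disjoint"` mode tiles the
#' area axis with non-overlapping windows aligned to multiples of
#' `window`; `"sliding"` mode moves a `window`-wide window in 1-pixel
#' steps (bins then overlap).
#'
#' @param quants a `cell_quant` data.frame (needs `area`,
#'   `mean_intensity`).
#' @param window bin width in pixels (default 10).
#' @param min_cells minimum cells per emitted bin (default 10).
#' @param mode `"disjoint"` (default) or `"sliding"`.
#' @return data.frame with `bin_lower`, `bin_upper` (half-open),
#'   `n_cells`, `mean_intensity`, `sd`. May be empty.
#' @export
bin_by_area <- function(quants, window = 10, min_cells = 10,
                        mode = c("disjoint", "sliding")) {
  mode <- match.arg(mode)
  stopifnot(window >= 1)
  if (nrow(quants) == 0) {
    return(data.frame(bin_lower = numeric(0), bin_upper = numeric(0),
                      n_cells = integer(0), mean_intensity = numeric(0),
                      sd = numeric(0)))
  }
  lowers <- if (mode == "disjoint") {
    seq(floor(min(quants$area) / window) * window, max(quants$area),
        by = window)
  } else {
    seq(floor(min(quants$area)), max(quants$area), by = 1)
  }
  rows <- lapply(lowers, function(lo) {
    sel <- quants$area >= lo & quants$area < lo + window
    n <- sum(sel)
    if (n < min_cells) return(NULL)
    data.frame(bin_lower = lo, bin_upper = lo + window, n_cells = n,
               mean_intensity = mean(quants$mean_intensity[sel]),
               sd = stats::sd(quants$mean_intensity[sel]))
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(bin_lower = numeric(0), bin_upper = numeric(0),
                      n_cells = integer(0), mean_intensity = numeric(0),
                      sd = numeric(0))
  }
  out
}

#' Subtract a control strain's mean background per cell
#'
#' The grand mean of the control population's whole-cell mean intensities
#' is subtracted from every test cell's mean intensity. Values driven
#' below zero are clamped to zero and flagged in the `clamped` column.
#'
#' @param quants test-strain `cell_quant` data.frame.
#' @param control_quants control-strain `cell_quant` data.frame (nonempty).
#' @return `quants` with adjusted `mean_intensity`, plus columns
#'   `control_mean` and `clamped`.
#' @export
subtract_control <- function(quants, control_quants) {
  if (is.null(control_quants) || nrow(control_quants) == 0) {
    stop("control population is empty")
  }
  ctrl <- mean(control_quants$mean_intensity)
  adj <- quants$mean_intensity - ctrl
  quants$clamped <- adj < 0
  quants$mean_intensity <- pmax(adj, 0)
  quants$control_mean <- ctrl
  quants
}

#' Regress per-cell background on signal
#'
#' Ordinary least squares of the background statistic (dimmest-50% mean,
#' y) on the signal statistic (brightest-10% mean, x) across cells, after
#' excluding cells above the axis caps (65,000 counts on x, 15,000 on y
#' by default). A flat slope indicates that bright cells do not drag
#' their own background up, i.e. a well-separated signal.
#'
#' @param quants a `cell_quant` data.frame (needs `signal`, `background`).
#' @param x_cap,y_cap exclusion caps: cells with `signal > x_cap` or
#'   `background > y_cap` are dropped.
#' @return a `regression_result`: list with `slope`, `intercept`,
#'   `n_points`.
#' @export
regress_signal_vs_background <- function(quants, x_cap = 65000,
                                         y_cap = 15000) {
  sel <- quants$signal <= x_cap & quants$background <= y_cap
  d <- quants[sel, , drop = FALSE]
  if (nrow(d) < 3) {
    stop(sprintf("only %d cells survive the axis caps; >= 3 required",
                 nrow(d)))
  }
  fit <- stats::lm(background ~ signal, data = d)
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 n_points = nrow(d)),
            class = "regression_result")
}

#' @export
print.regression_result <- function(x, ...) {
  cat(sprintf("<regression_result> background = %.4f * signal + %.2f (n = %d)\n",
              x$slope, x$intercept, x$n_points))
  invisible(x)
}

#' Estimate the copy-number fold change between two strains
#'
#' Optionally restricts each strain to its brightest `subset_fraction` of
#' cells (by whole-cell mean intensity), then subtracts the control
#' strain's mean background from each cell, and reports the ratio of the
#' adjusted strain means, `fold = mean(b) / mean(a)`.
#'
#' @param strain_a,strain_b `cell_quant` data.frames; `strain_a` is the
#'   denominator (reference, e.g. single-copy).
#' @param subset_fraction 1.0 (all cells, default) or 0.5 (brightest
#'   half).
#' @param control optional control-strain `cell_quant` for background
#'   subtraction (applied after subsetting).
#' @return a `fold_change`: list with `numerator_mean`,
#'   `denominator_mean`, `fold`, `subset_fraction`, `n_a`, `n_b`.
#' @export
estimate_fold_change <- function(strain_a, strain_b, subset_fraction = 1.0,
                                 control = NULL) {
  stopifnot(subset_fraction > 0, subset_fraction <= 1)
  brightest <- function(q) {
    if (subset_fraction >= 1) return(q)
    n <- max(1L, floor(nrow(q) * subset_fraction))
    q[order(q$mean_intensity, decreasing = TRUE)[seq_len(n)], , drop = FALSE]
  }
  a <- brightest(strain_a)
  b <- brightest(strain_b)
  if (nrow(a) == 0 || nrow(b) == 0) stop("empty strain after subsetting")
  if (!is.null(control)) {
    a <- subtract_control(a, control)
    b <- subtract_control(b, control)
  }
  den <- mean(a$mean_intensity)
  num <- mean(b$mean_intensity)
  if (den <= 0) stop("denominator strain mean is zero after subtraction")
  structure(list(numerator_mean = num, denominator_mean = den,
                 fold = num / den, subset_fraction = subset_fraction,
                 n_a = nrow(a), n_b = nrow(b)),
            class = "fold_change")
}

#' @export
print.fold_change <- function(x, ...) {
  cat(sprintf("<fold_change> %.3f = %.2f / %.2f (brightest %g%%, n = %d vs %d)\n",
              x$fold, x$numerator_mean, x$denominator_mean,
              100 * x$subset_fraction, x$n_b, x$n_a))
  invisible(x)
}
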