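# Shared oracles and small fixture builders. These deliberately re-derive
# quantities through independent code paths (naive scans, closed forms,
# brute-force grouping) so package results can be checked against them.

# naive sliding-window motif counter, both strands, position-deduplicated
naive_motif_count <- function(seq, motif) {
  rc <- paste(rev(chartr("ACGT", "TGCA",
                         strsplit(motif, "")[[1]])), collapse = "")
  w <- nchar(motif)
  hits <- 0L
  for (i in seq_len(nchar(seq) - w + 1L)) {
    s <- substr(seq, i, i + w - 1L)
    if (s == motif || s == rc) hits <- hits + 1L
  }
  hits
}

# wrap a pixel vector as a measurement record
make_meas <- function(v, id = 1L) {
  list(cell_id = id, area = length(v), pixel_values = v,
       mean_intensity = mean(v))
}

# minimal cell_quant table for population-analysis tests
make_quants <- function(area, mean_intensity, signal = mean_intensity,
                        background = mean_intensity / 2) {
  data.frame(cell_id = seq_along(area), area = area,
             mean_intensity = mean_intensity,
             max_intensity = signal, signal = signal,
             background = background,
             ratio = ifelse(background > 0, signal / background, Inf),
             passed_filters = TRUE)
}

# closed-form OLS slope/intercept via covariance and variance
ols_closed_form <- function(x, y) {
  slope <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  list(slope = slope, intercept = mean(y) - slope * mean(x))
}

# numeric root-bracketing oracle for the occupancy mass balance
occupancy_root_oracle <- function(pool, sites, affinity) {
  if (pool <= 0 || sites <= 0 || affinity <= 0) return(0)
  f <- function(B) B - affinity * (pool - B) * (sites - B)
  upper <- min(pool, sites)
  if (f(upper) <= 0) return(upper)
  stats::uniroot(f, c(0, upper), tol = 1e-14)$root
}

# detection recall/precision: a true cell is recovered when >= 50% of its
# pixels fall under a single predicted label; a predicted label is correct
# when >= 50% of its pixels fall inside a single true cell
match_stats <- function(truth_mask, pred_mask) {
  overlap_frac <- function(a, b) {
    ids <- sort(unique(a[a > 0L]))
    vapply(ids, function(i) {
      sel <- a == i
      tab <- table(b[sel])
      tab <- tab[names(tab) != "0"]
      if (length(tab) == 0) 0 else max(tab) / sum(sel)
    }, 1)
  }
  recall <- mean(overlap_frac(truth_mask, pred_mask) >= 0.5)
  precision <- mean(overlap_frac(pred_mask, truth_mask) >= 0.5)
  list(recall = recall, precision = precision)
}
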