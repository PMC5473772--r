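## Equilibrium titration of the split-reporter pool against array binding
## sites.
##
## Each adjacent OL1/UAS pair on a hybrid array is treated as one
## reconstitution site. A cell holds a finite pool P of functional
## reporter pairs (one cI-VN plus one Gal4-VC counts as one pair) and
## S = n_arrays * sites_per_array identical, independent sites. With a
## dimensionless association constant K the bound count B at equilibrium
## satisfies the single-class mass balance
##
##     B = K (P - B)(S - B),  0 <= B <= min(P, S),
##
## whose physical root is
##
##     B = 2 K P S / (K(P+S) + 1 + sqrt((K(P+S)+1)^2 - 4 K^2 P S)),
##
## written in the cancellation-free form. Fluorescence is proportional to
## B; unbound pairs contribute only through a small spontaneous
## self-assembly fraction. This makes the saturation argument for
## multicopy arrays quantitative: with P fixed, B is concave and
## sub-linear in the number of arrays, so whole-cell signal cannot scale
## with extreme copy numbers.

#' Occupancy model parameters
#'
#' @param pool_size functional reporter-pair count per cell
#'   (dimensionless). Default 600, an order-of-magnitude choice for an
#'   induced repressor fusion; no measured copy number exists for this
#'   system.
#' @param n_arrays hybrid-array copies per cell.
#' @param sites_per_array reconstitution sites per array (one per adjacent
#'   OL1/UAS pair); default 64.
#' @param affinity dimensionless equilibrium association constant scaling
#'   fractional occupancy; default 1 (tight binding at the default pool).
#' @param free_complementation_rate fraction of unbound pairs that
#'   spontaneously self-assemble into fluorescent complexes; default
#'   0.002, reflecting a split designed to suppress self-assembly.
#' @return an `occupancy_params` object.
#' @export
occupancy_params <- function(pool_size = 600, n_arrays = 1,
                             sites_per_array = 64, affinity = 1,
                             free_complementation_rate = 0.002) {
  vals <- c(pool_size, n_arrays, sites_per_array, free_complementation_rate)
  if (any(!is.finite(vals)) || any(vals < 0) || is.na(affinity) ||
      affinity < 0) {
    stop("occupancy parameters must be nonnegative (affinity may be Inf)")
  }
  if (n_arrays >= 1 && sites_per_array < 1) {
    stop("sites_per_array must be >= 1")
  }
  structure(list(pool_size = pool_size, n_arrays = n_arrays,
                 sites_per_array = sites_per_array, affinity = affinity,
                 free_complementation_rate = free_complementation_rate),
            class = "occupancy_params")
}

#' Solve the pool-vs-sites occupancy balance
#'
#' Closed-form solution of the single-class Langmuir-type mass balance
#' between the reporter pool and the total array sites (see the module
#' notes above). Degenerate inputs (zero pool, zero sites, zero affinity)
#' return zero occupancy rather than erroring.
#'
#' @param params an [occupancy_params()] object.
#' @return an `occupancy_result` with fields `bound_per_array`
#'   (expected occupied sites per array), `total_bound`, and
#'   `free_complemented` (spontaneously assembled fluorescent pairs).
#' @export
#' @examples
#' compute_occupancy(occupancy_params(pool_size = 600, n_arrays = 1))
compute_occupancy <- function(params) {
  stopifnot(inherits(params, "occupancy_params"))
  P <- params$pool_size
  S <- params$n_arrays * params$sites_per_array
  K <- params$affinity
  if (P <= 0 || S <= 0 || K <= 0) {
    B <- 0
  } else if (is.infinite(K)) {
    B <- min(P, S)
  } else {
    disc <- (K * (P + S) + 1)^2 - 4 * K^2 * P * S
    B <- 2 * K * P * S / (K * (P + S) + 1 + sqrt(max(disc, 0)))
  }
  structure(
    list(bound_per_array = if (params$n_arrays > 0) B / params$n_arrays else 0,
         total_bound = B,
         free_complemented = params$free_complementation_rate * (P - B),
         params = params),
    class = "occupancy_result"
  )
}

#' @export
print.occupancy_result <- function(x, ...) {
  cat(sprintf(
    "<occupancy_result> total bound %.3f (%.3f/array of %g sites); free complemented %.3f\n",
    x$total_bound, x$bound_per_array, x$params$sites_per_array,
    x$free_complemented))
  invisible(x)
}

#' Expected focus brightness from an occupancy result
#'
#' Brightness of one array focus is linear in the number of reconstituted
#' fluorophores bound to it.
#'
#' @param result an `occupancy_result`.
#' @param brightness_per_fluorophore expected photons per fluorophore per
#'   exposure (nonnegative).
#' @return expected photons per focus.
#' @export
expected_focus_brightness <- function(result, brightness_per_fluorophore) {
  stopifnot(inherits(result, "occupancy_result"),
            brightness_per_fluorophore >= 0)
  result$bound_per_array * brightness_per_fluorophore
}

#' Sweep array copy number at a fixed pool
#'
#' Convenience titration: evaluates the occupancy model over a sequence of
#' array copy numbers, holding all other parameters fixed.
#'
#' @param params an [occupancy_params()]; its `n_arrays` is ignored.
#' @param n_arrays_seq integer vector of array copy numbers.
#' @return data.frame with columns `n_arrays`, `total_bound`,
#'   `bound_per_array`, `free_complemented`.
#' @export
titrate_arrays <- function(params, n_arrays_seq = 1:20) {
  rows <- lapply(n_arrays_seq, function(n) {
    p <- params
    p$n_arrays <- n
    r <- compute_occupancy(p)
    data.frame(n_arrays = n, total_bound = r$total_bound,
               bound_per_array = r$bound_per_array,
               free_complemented = r$free_complemented)
  })
  do.call(rbind, rows)
}
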