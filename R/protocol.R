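#' Replicate waiting-time-distribution protocol for one timer setting
#'
#' Runs the desk-scale replicate protocol used throughout the package's
#' analyses: simulate the default network at reduced molecule numbers (with
#' the interaction range rescaled to preserve binding kinetics) under a
#' square-wave load, repeat over independent seeds, extract one state-label
#' count series per run, estimate each replicate's waiting-time
#' distribution, and pool the replicates into an average psi with a
#' pointwise confidence band.
#'
#' @param timer_name,timer_value activation-cycle timer to override (see
#'   [set_timer()]); \code{NULL} keeps the baseline network.
#' @param species,activation,partner state-label filters selecting the
#'   analysed count series (see [state_series()]).
#' @param seeds integer vector of simulation seeds (default 1:10).
#' @param scale count scale factor (default 1/8, see [apply_scale()]).
#' @param duration simulated seconds per replicate (default 3e4).
#' @param magnitude,period square-wave load parameters.
#' @param ... further arguments to [fit_wtd()].
#' @return list with \code{wtds} (per-replicate \code{"wtd"} objects),
#'   \code{pooled} (replicate-average \code{"wtd"}), \code{band}
#'   (\code{"wtd_band"}).
#' @export
sweep_wtd <- function(timer_name = NULL, timer_value = NULL,
                      species, activation = NULL, partner = NULL,
                      seeds = 1:10, scale = 1 / 8, duration = 3e4,
                      magnitude = 10000, period = 1000, ...) {
  cfg <- default_config(magnitude = magnitude, period = period,
                        duration = duration)
  if (scale != 1) cfg <- apply_scale(cfg, scale)
  if (!is.null(timer_name)) cfg <- set_timer(cfg, timer_name, timer_value)
  wtds <- lapply(seeds, function(s) {
    x <- simulate_cell(cfg, seed = s)
    y <- state_series(x, species = species, activation = activation,
                      partner = partner)
    fit_wtd(y, dt = cfg$dt, ...)
  })
  pooled <- pool_wtds(wtds)
  # band on the common pooled grid
  step <- pooled$params$grid_step %||% diff(pooled$tau_grid[1:2])
  padded <- lapply(wtds, function(w) {
    psi <- numeric(length(pooled$tau_grid))
    psi[seq_along(w$psi)] <- w$psi
    structure(list(tau_grid = pooled$tau_grid, psi = psi), class = "wtd")
  })
  list(wtds = wtds, pooled = pooled, band = confidence_band(padded))
}

#' Support of a waiting-time distribution
#'
#' The largest waiting time carrying non-negligible density: the upper end
#' of the tau range where psi is at least \code{floor_frac} of its maximum
#' (default 1%).
#'
#' @param w a \code{"wtd"} (or list with \code{psi}, \code{tau_grid}).
#' @param floor_frac relative density floor.
#' @return numeric scalar, seconds.
#' @export
wtd_support <- function(w, floor_frac = 0.01) {
  nz <- w$psi >= floor_frac * max(w$psi)
  max(w$tau_grid[nz])
}

#' Dominant modes of a waiting-time distribution
#'
#' Convenience around [find_modes()]: the tau locations of the (up to) two
#' highest resolved modes, sorted increasingly.
#'
#' @param w a \code{"wtd"}.
#' @return numeric vector of length 1 or 2.
#' @export
dominant_modes <- function(w) {
  md <- find_modes(w)
  if (!nrow(md)) return(numeric(0))
  md <- md[order(md$psi, decreasing = TRUE), , drop = FALSE]
  sort(md$tau[seq_len(min(2, nrow(md)))])
}
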