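#' Amplitude-weighted signal interim periods
#'
#' One (tau, weight) pair per SIP: the waiting time between two consecutive
#' critical events, weighted by the amplitude of the initiating (earlier)
#' event. The product tau * weight is the area interpretation of the
#' cumulated dispersion time of the molecules that left the state together.
#'
#' @param dp a \code{"directing_process"}.
#' @return list with numeric \code{taus} and \code{weights} (equal length,
#'   possibly zero).
#' @export
weighted_sips <- function(dp) {
  stopifnot(inherits(dp, "directing_process"))
  list(taus = as.numeric(dp$sips), weights = as.numeric(dp$amplitudes))
}

#' Weighted kernel density estimate on a waiting-time grid
#'
#' Sum of unit-mass kernels centred on the weighted samples,
#' \code{density(tau) = sum_k w_k K_w(tau - tau_k)}, evaluated on the grid.
#' The default kernel is the finite-support Epanechnikov; a Gaussian
#' truncated at 3 bandwidths is also available, and a literal one-sided
#' (forward) kernel variant is kept behind \code{one_sided = TRUE}. Mass
#' falling below tau = 0 is reflected back so none is lost at the origin.
#'
#' @param taus non-negative waiting times, seconds.
#' @param weights non-negative weights, one per waiting time.
#' @param grid increasing evaluation grid, seconds.
#' @param bandwidth kernel support/scale w in seconds.
#' @param kernel \code{"epanechnikov"} or \code{"gaussian-truncated"}.
#' @param one_sided use the forward window \code{[tau_k, tau_k + w]} instead
#'   of a symmetric kernel (biases modes by about w/2; off by default).
#' @param reflect reflect mass at tau = 0 (default TRUE).
#' @return numeric density values on \code{grid} (unnormalised).
#' @export
kde_density <- function(taus, weights, grid, bandwidth = 1,
                        kernel = c("epanechnikov", "gaussian-truncated"),
                        one_sided = FALSE, reflect = TRUE) {
  kernel <- match.arg(kernel)
  stopifnot(length(taus) == length(weights), bandwidth > 0,
            !is.unsorted(grid))
  if (any(taus < 0)) stop("waiting times must be non-negative")
  if (any(weights < 0)) stop("weights must be non-negative")
  if (length(taus) && all(weights == 0))
    warning("all-zero weights: zero density")
  K <- function(u) {
    switch(kernel,
           "epanechnikov" = ifelse(abs(u) <= 1, 0.75 * (1 - u^2), 0),
           "gaussian-truncated" = {
             z <- stats::dnorm(u) / (stats::pnorm(3) - stats::pnorm(-3))
             ifelse(abs(u) <= 3, z, 0)
           })
  }
  centers <- if (one_sided) taus + bandwidth / 2 else taus
  dens <- numeric(length(grid))
  for (k in seq_along(centers)) {
    dens <- dens + weights[k] * K((grid - centers[k]) / bandwidth) / bandwidth
    if (reflect)
      dens <- dens + weights[k] * K((grid + centers[k]) / bandwidth) /
        bandwidth
  }
  dens
}

#' Normalise an integral distribution to a probability density
#'
#' Scales the amplitude-weighted integral distribution so that its
#' trapezoidal integral over the grid equals 1, yielding the waiting-time
#' distribution psi(tau). Mode locations are unchanged.
#'
#' @param integral_dist non-negative density values on \code{tau_grid}.
#' @param tau_grid increasing grid, seconds.
#' @return normalised density \code{psi}.
#' @export
normalize_wtd <- function(integral_dist, tau_grid) {
  stopifnot(length(integral_dist) == length(tau_grid))
  if (any(integral_dist < 0)) stop("density must be non-negative")
  mass <- .trapz(tau_grid, integral_dist)
  if (mass <= 0) stop("zero total mass: cannot normalise")
  integral_dist / mass
}

.trapz <- function(x, y) sum(diff(x) * (y[-1] + y[-length(y)]) / 2)

#' Estimate the waiting-time distribution of critical events
#'
#' The package's central estimator. Runs the full inversion pipeline on one
#' molecular count series: de-trend (window \code{tau1}), compute the local
#' fluctuation amplitude (window \code{tau2}), rectify against the Hilbert
#' envelope, detect critical events (prominent peaks and quiet-region
#' boundaries), form the directing process and its amplitude-weighted SIPs,
#' smooth them with a weighted KDE and normalise to the waiting-time
#' distribution psi(tau).
#'
#' The estimate can be restricted to an epoch \code{[epoch_start,
#' epoch_start + epoch_length]} to probe ageing of the non-ergodic system;
#' the default epoch length of 10000 s balances statistics per epoch against
#' the number of distinct epoch start times available.
#'
#' @param y numeric count series (a \code{state_ts} column, see
#'   [state_series()]).
#' @param dt sampling step, seconds.
#' @param tau1,tau2 de-trending and fluctuation windows in seconds,
#'   \code{tau1 > tau2}.
#' @param kernel,bandwidth KDE kernel and support, see [kde_density()].
#' @param grid_step tau grid resolution in seconds.
#' @param tau_max upper end of the tau grid; defaults to the largest SIP
#'   plus one bandwidth.
#' @param epoch_start,epoch_length optional epoch window in seconds;
#'   \code{epoch_length = NULL} uses the whole series.
#' @param min_amplitude drop events whose rectified amplitude is below this
#'   value (default 0, no floor). For integer molecular count series a floor
#'   of 1 molecule is the natural choice: rectified maxima smaller than one
#'   molecule are ringing of the de-trending and envelope filters around
#'   single-molecule steps, not departures of a molecular cohort.
#' @param include_boundaries,predicate event-detection options, see
#'   [detect_events()]. Recurrence WTDs use peak events only by default:
#'   pooling in the quiet-region boundary events, which flank every accepted
#'   peak, would mix peak extents into the between-peak waiting times.
#' @return object of class \code{"wtd"}: \code{tau_grid},
#'   \code{integral_dist} (amplitude-weighted, unnormalised), \code{psi}
#'   (normalised), \code{raw_counts} (unweighted KDE), \code{n_events},
#'   \code{events}, \code{directing}, \code{epoch}, \code{params}.
#' @examples
#' set.seed(1)
#' y <- 100 + cumsum(rnorm(5000, sd = 0.2)) + rnorm(5000)
#' w <- fit_wtd(y, tau1 = 100, tau2 = 10)
#' w
#' @export
fit_wtd <- function(y, dt = 1, tau1 = 100, tau2 = 10,
                    kernel = "epanechnikov", bandwidth = 1,
                    grid_step = 0.25, tau_max = NULL,
                    epoch_start = 0, epoch_length = NULL,
                    include_boundaries = FALSE, predicate = "prominence",
                    prom_mult = 3, min_amplitude = 0) {
  n <- length(y)
  span <- (n - 1) * dt
  if (is.null(epoch_length)) epoch_length <- span - epoch_start
  if (epoch_start < 0 || epoch_start + epoch_length > span + 1e-9)
    stop("epoch outside the data span [0, ", span, "] s")
  fs <- filter_signal(y, dt = dt, tau1 = tau1, tau2 = tau2)
  ev <- detect_events(fs, include_boundaries = include_boundaries,
                      predicate = predicate, prom_mult = prom_mult)
  if (min_amplitude > 0)
    ev <- ev[ev$amplitude >= min_amplitude, , drop = FALSE]
  inside <- ev$time >= epoch_start & ev$time <= epoch_start + epoch_length
  ev <- ev[inside, , drop = FALSE]
  if (nrow(ev) < 2)
    stop("insufficient events: fewer than 2 critical events in the epoch")
  dp <- build_directing(ev)
  ws <- weighted_sips(dp)
  if (is.null(tau_max)) tau_max <- max(ws$taus) + bandwidth
  grid <- seq(0, tau_max, by = grid_step)
  integral <- kde_density(ws$taus, ws$weights, grid, bandwidth, kernel)
  psi <- normalize_wtd(integral, grid)
  stopifnot(abs(.trapz(grid, psi) - 1) < 1e-6, all(psi >= -1e-12))
  raw <- kde_density(ws$taus, rep(1, length(ws$taus)), grid, bandwidth,
                     kernel)
  structure(list(
    tau_grid = grid, integral_dist = integral, psi = psi, raw_counts = raw,
    n_events = nrow(ev), events = ev, directing = dp,
    epoch = c(epoch_start, epoch_start + epoch_length),
    params = list(dt = dt, tau1 = tau1, tau2 = tau2, kernel = kernel,
                  bandwidth = bandwidth, grid_step = grid_step,
                  include_boundaries = include_boundaries,
                  predicate = predicate, prom_mult = prom_mult,
                  min_amplitude = min_amplitude)
  ), class = "wtd")
}

#' Epoch-resolved waiting-time distribution
#'
#' Convenience wrapper around [fit_wtd()] for ageing analyses: estimates
#' psi_t(tau) on the epoch \code{[t0, t0 + L]}.
#'
#' @param y count series.
#' @param t0 epoch start, seconds.
#' @param L epoch length, seconds (default 10000).
#' @param ... further arguments to [fit_wtd()].
#' @return a \code{"wtd"}.
#' @export
epoch_wtd <- function(y, t0, L = 10000, ...) {
  fit_wtd(y, epoch_start = t0, epoch_length = L, ...)
}

#' Locate the modes of a waiting-time distribution
#'
#' Local maxima of psi above a relative height floor (default 10% of the
#' global maximum) and separated by at least the kernel resolution, sorted
#' by tau.
#'
#' @param w a \code{"wtd"} (or a list with \code{psi} and \code{tau_grid}).
#' @param floor_frac minimum mode height as a fraction of the global max.
#' @param min_separation minimum tau distance between reported modes;
#'   defaults to twice the KDE bandwidth, below which two maxima are not
#'   resolvable as distinct modes (of nearby maxima the highest is kept).
#' @return data.frame with \code{tau} and \code{psi} per mode.
#' @export
find_modes <- function(w, floor_frac = 0.1, min_separation = NULL) {
  psi <- w$psi
  grid <- w$tau_grid
  if (is.null(min_separation))
    min_separation <- 2 * (w$params$bandwidth %||% 1)
  idx <- .local_maxima(psi)
  # a maximum at the very ends of the grid also counts as a mode
  n <- length(psi)
  if (n >= 2 && psi[1] > psi[2]) idx <- c(1L, idx)
  if (n >= 2 && psi[n] > psi[n - 1]) idx <- c(idx, n)
  if (!length(idx)) return(data.frame(tau = numeric(0), psi = numeric(0)))
  idx <- idx[psi[idx] >= floor_frac * max(psi)]
  # maxima closer than the kernel can resolve are one mode: greedily keep
  # the highest, drop neighbours within min_separation
  idx <- idx[order(psi[idx], decreasing = TRUE)]
  kept <- integer(0)
  for (i in idx)
    if (!length(kept) || all(abs(grid[i] - grid[kept]) >= min_separation))
      kept <- c(kept, i)
  kept <- sort(kept)
  data.frame(tau = grid[kept], psi = psi[kept])
}

#' Pointwise replicate confidence band of waiting-time distributions
#'
#' Combines psi estimates from independent replicate simulations on a common
#' tau grid into a pointwise band: mean +/- 1.96 standard errors by default,
#' or the min/max envelope. Band edges are not probability densities and are
#' deliberately not re-normalised.
#'
#' @param wtds list of at least 2 \code{"wtd"} objects on identical grids.
#' @param method \code{"se"} (mean +/- 1.96 sd/sqrt(n)) or \code{"envelope"}.
#' @return object of class \code{"wtd_band"}: \code{tau_grid}, \code{mean},
#'   \code{lo}, \code{hi}, \code{n_replicates}.
#' @export
confidence_band <- function(wtds, method = c("se", "envelope")) {
  method <- match.arg(method)
  if (length(wtds) < 2) stop("need at least 2 replicates")
  grids <- lapply(wtds, `[[`, "tau_grid")
  g0 <- grids[[1]]
  same <- vapply(grids, function(g) length(g) == length(g0) &&
                   all(abs(g - g0) < 1e-9), TRUE)
  if (!all(same)) stop("mismatched tau grids across replicates")
  m <- do.call(rbind, lapply(wtds, `[[`, "psi"))
  mu <- colMeans(m)
  if (method == "se") {
    se <- apply(m, 2, stats::sd) / sqrt(nrow(m))
    lo <- mu - 1.96 * se
    hi <- mu + 1.96 * se
  } else {
    lo <- apply(m, 2, min)
    hi <- apply(m, 2, max)
  }
  structure(list(tau_grid = g0, mean = mu, lo = lo, hi = hi,
                 n_replicates = length(wtds)), class = "wtd_band")
}

#' Average replicate WTDs on a common grid
#'
#' Refits nothing: pads each psi to a shared grid end (psi is zero beyond
#' its own support) and returns a \code{"wtd"}-like object whose psi is the
#' replicate mean, renormalised.
#'
#' @param wtds list of \code{"wtd"} objects with equal grid step.
#' @return list with \code{tau_grid}, \code{psi}, \code{integral_dist},
#'   \code{n_events}; class \code{"wtd"}.
#' @export
pool_wtds <- function(wtds) {
  step <- wtds[[1]]$params$grid_step %||% diff(wtds[[1]]$tau_grid[1:2])
  tmax <- max(vapply(wtds, function(w) max(w$tau_grid), 0))
  grid <- seq(0, tmax, by = step)
  pad <- function(v) {
    out <- numeric(length(grid))
    out[seq_along(v)] <- v
    out
  }
  psis <- do.call(rbind, lapply(wtds, function(w) pad(w$psi)))
  ints <- do.call(rbind, lapply(wtds, function(w) pad(w$integral_dist)))
  psi <- normalize_wtd(colMeans(psis), grid)
  structure(list(tau_grid = grid, psi = psi,
                 integral_dist = colMeans(ints),
                 raw_counts = NULL,
                 n_events = sum(vapply(wtds, `[[`, 0, "n_events")),
                 events = NULL, directing = NULL,
                 epoch = NULL, params = wtds[[1]]$params), class = "wtd")
}

#' @export
print.wtd <- function(x, ...) {
  md <- find_modes(x)
  cat(sprintf("wtd: psi(tau) from %d critical events%s\n", x$n_events,
              if (!is.null(x$epoch))
                sprintf(" in epoch [%g, %g] s", x$epoch[1], x$epoch[2])
              else ""))
  cat(sprintf("  grid: [0, %g] s by %g s; integral = %.6f\n",
              max(x$tau_grid), diff(x$tau_grid[1:2]),
              .trapz(x$tau_grid, x$psi)))
  if (nrow(md)) {
    md <- md[order(md$psi, decreasing = TRUE), , drop = FALSE]
    shown <- utils::head(md, 4)
    shown <- shown[order(shown$tau), ]
    extra <- nrow(md) - nrow(shown)
    cat("  modes:", paste(sprintf("%.2f s (psi = %.3f)", shown$tau,
                                  shown$psi), collapse = ", "),
        if (extra > 0) sprintf("(+%d minor)", extra) else "", "\n")
  }
  invisible(x)
}

#' @export
summary.wtd <- function(object, ...) {
  ws <- if (!is.null(object$directing)) weighted_sips(object$directing)
        else NULL
  out <- list(
    n_events = object$n_events,
    modes = find_modes(object),
    epoch = object$epoch,
    mean_sip = if (!is.null(ws)) mean(ws$taus) else NA_real_,
    support = {
      nz <- object$psi >= 0.01 * max(object$psi)
      range(object$tau_grid[nz])
    },
    params = object$params
  )
  class(out) <- "summary.wtd"
  out
}

#' @export
print.summary.wtd <- function(x, ...) {
  cat(sprintf("Waiting-time distribution summary: %d events\n", x$n_events))
  if (!is.na(x$mean_sip)) cat(sprintf("  mean SIP: %.3g s\n", x$mean_sip))
  cat(sprintf("  support (psi >= 1%% of max): [%.3g, %.3g] s\n",
              x$support[1], x$support[2]))
  if (nrow(x$modes))
    cat("  modes:", paste(sprintf("%.2f s", x$modes$tau), collapse = ", "),
        "\n")
  invisible(x)
}

#' @export
plot.wtd <- function(x, band = NULL, ...) {
  graphics::plot(x$tau_grid, x$psi, type = "l", xlab = expression(tau ~ "[s]"),
                 ylab = expression(psi(tau)), ...)
  if (!is.null(band)) {
    graphics::polygon(c(band$tau_grid, rev(band$tau_grid)),
                      c(band$lo, rev(band$hi)),
                      col = grDevices::adjustcolor("steelblue", 0.3),
                      border = NA)
    graphics::lines(x$tau_grid, x$psi)
  }
  md <- find_modes(x)
  if (nrow(md)) graphics::points(md$tau, md$psi, pch = 19)
  invisible(x)
}

#' Simulate waiting times from a fitted WTD
#'
#' Draws SIPs from the fitted psi by inverse transform sampling on the tau
#' grid (linear interpolation of the cumulative trapezoidal integral).
#'
#' @param object a \code{"wtd"}.
#' @param nsim number of waiting times to draw.
#' @param seed optional seed.
#' @param ... unused.
#' @return numeric vector of \code{nsim} waiting times.
#' @export
simulate.wtd <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  g <- object$tau_grid
  p <- object$psi
  cdf <- c(0, cumsum(diff(g) * (p[-1] + p[-length(p)]) / 2))
  cdf <- cdf / cdf[length(cdf)]
  u <- stats::runif(nsim)
  stats::approx(cdf, g, xout = u, ties = "ordered", rule = 2)$y
}

#' Export a WTD (and optional band) as TSV
#'
#' Columns \code{tau_s}, \code{integral_dist}, \code{psi}, and when a band
#' is given \code{ci_lo}, \code{ci_hi}.
#'
#' @param w a \code{"wtd"}.
#' @param path output path.
#' @param band optional \code{"wtd_band"} on the same grid.
#' @return \code{path}, invisibly.
#' @export
write_wtd <- function(w, path, band = NULL) {
  df <- data.frame(tau_s = w$tau_grid, integral_dist = w$integral_dist,
                   psi = w$psi)
  if (!is.null(band)) {
    df$ci_lo <- band$lo
    df$ci_hi <- band$hi
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
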