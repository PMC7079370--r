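# internal: turn a directing/parent distribution spec into a sampler
# closure. Accepts a function(n) or a named list; directing distributions
# must have strictly positive support.
.dist_sampler <- function(spec) {
  if (is.function(spec)) return(spec)
  if (!is.list(spec) || is.null(spec$name))
    stop("distribution spec must be a function(n) or a named list")
  switch(spec$name,
    degenerate = function(n) rep(spec$value, n),
    exponential = function(n) stats::rexp(n, rate = 1 / spec$mean),
    uniform = function(n) stats::runif(n, spec$lo, spec$hi),
    gamma = function(n) stats::rgamma(n, shape = spec$shape,
                                      rate = spec$shape / spec$mean),
    normal = function(n) stats::rnorm(n, spec$mean, spec$sd),
    `gamma-mixture` = function(n) {
      k <- sample.int(length(spec$means), n, replace = TRUE,
                      prob = spec$probs %||% rep(1, length(spec$means)))
      stats::rgamma(n, shape = spec$shape,
                    rate = spec$shape / spec$means[k])
    },
    stop("unknown distribution: ", spec$name)
  )
}

#' Generate a directing-process realisation
#'
#' Draws n i.i.d. positive intervals T_j from the given distribution and
#' returns their cumulative sums: the physical times t(t*_i) of the first n
#' events of the directing process, a strictly increasing sequence.
#'
#' @param T_spec positive-support interval distribution: a \code{function(n)}
#'   or a list such as \code{list(name = "gamma", mean = 9, shape = 20)},
#'   \code{list(name = "degenerate", value = 10)},
#'   \code{list(name = "exponential", mean = 5)},
#'   \code{list(name = "gamma-mixture", means = c(4, 9), shape = 20,
#'   probs = c(0.5, 0.5))}.
#' @param n number of events (\code{>= 2}).
#' @param seed optional seed.
#' @return numeric vector of n strictly increasing physical event times.
#' @export
generate_directing <- function(T_spec, n, seed = NULL) {
  stopifnot(n >= 2)
  if (!is.null(seed)) set.seed(seed)
  draws <- .dist_sampler(T_spec)(n)
  if (any(draws <= 0))
    stop("directing distribution must have strictly positive support")
  cumsum(draws)
}

#' Generate a subordinated trajectory
#'
#' Composes a parent process x(t*) on natural time with a directing process
#' t(t*): the subordinated trajectory x(t) is piecewise constant on physical
#' time, jumping by one parent step at each directing-process event. Regions
#' dense in events appear as stretched copies of the parent trajectory and
#' sparse regions as shrunk ones.
#'
#' @param spec list with \code{directing} (see [generate_directing()]),
#'   \code{n_events}, optional \code{parent_step} (step distribution;
#'   default degenerate unit steps, making x(t) a counting process),
#'   optional \code{dt} (grid step, default 1) and \code{seed}.
#' @return list with \code{times} (uniform grid from 0 past the last
#'   event), \code{x} (trajectory), \code{event_times}, \code{steps}.
#' @export
generate_subordinated <- function(spec) {
  stopifnot(is.list(spec), !is.null(spec$directing), !is.null(spec$n_events))
  dt <- spec$dt %||% 1
  if (!is.null(spec$seed)) set.seed(spec$seed)
  ev <- generate_directing(spec$directing, spec$n_events)
  steps <- .dist_sampler(spec$parent_step %||%
                           list(name = "degenerate", value = 1))(spec$n_events)
  times <- seq(0, (ceiling(max(ev) / dt) + 1) * dt, by = dt)
  idx <- findInterval(times, ev)
  cx <- c(0, cumsum(steps))
  list(times = times, x = cx[idx + 1L], event_times = ev, steps = steps)
}

#' Synthesise a count-like signal with planted critical events
#'
#' Emulates the phenomenology of the simulated molecular count series: a
#' slow trend, stationary Gaussian noise, and asynchronous large spikes at
#' known (planted) times. Each spike is a symmetric triangular pulse; by
#' default spikes are dips below the trend (\code{sign = -1}), the direction
#' that the printed de-trending convention \code{dyI = yI - y} rectifies
#' into positive fluctuations -- a cohort of molecules abruptly departing
#' the observed state.
#'
#' @param event_times strictly increasing planted event times, seconds.
#' @param amplitudes spike peak amplitudes (recycled).
#' @param trend function of time giving the slow component, or a constant.
#' @param noise_sd white noise standard deviation.
#' @param dt sampling step, seconds.
#' @param spike_width full base width of the triangular pulse, seconds
#'   (default 3 dt; a warning is issued if two spikes are closer than twice
#'   the width).
#' @param sign +1 for spikes above the trend, -1 (default) for dips.
#' @param snap_to_grid align planted times to the sampling grid (default
#'   TRUE): the simulator this generator emulates changes counts only at
#'   whole time steps, and an off-grid pulse centre under-samples the peak
#'   by up to a third of its amplitude, probing the sampling geometry
#'   rather than the inversion. Coinciding snapped events are merged.
#' @param seed optional seed for the noise.
#' @return object of class \code{"synthetic_signal"}: \code{times},
#'   \code{values}, \code{planted} (data.frame of the as-planted, possibly
#'   snapped, time/amplitude), and the generation parameters.
#' @export
make_spiked_signal <- function(event_times, amplitudes = 10,
                               trend = 100, noise_sd = 1, dt = 0.25,
                               spike_width = 3 * dt, sign = -1,
                               snap_to_grid = TRUE, seed = NULL) {
  stopifnot(!is.unsorted(event_times, strictly = TRUE),
            all(amplitudes > 0), noise_sd >= 0)
  if (snap_to_grid) {
    event_times <- round(event_times / dt) * dt
    keep <- !duplicated(event_times)
    event_times <- event_times[keep]
    amplitudes <- rep_len(amplitudes, length(keep))[keep]
  }
  if (!is.null(seed)) set.seed(seed)
  amplitudes <- rep_len(amplitudes, length(event_times))
  if (length(event_times) > 1 && min(diff(event_times)) < 2 * spike_width)
    warning("planted spikes overlap: minimum gap below twice the width")
  tmax <- (if (length(event_times)) max(event_times) else 0) + 20 * dt
  times <- seq(0, ceiling(tmax / dt) * dt, by = dt)
  tr <- if (is.function(trend)) trend(times) else rep(trend, length(times))
  spikes <- numeric(length(times))
  half <- spike_width / 2
  for (k in seq_along(event_times)) {
    u <- abs(times - event_times[k])
    sel <- u < half
    spikes[sel] <- spikes[sel] + amplitudes[k] * (1 - u[sel] / half)
  }
  values <- tr + sign * spikes + stats::rnorm(length(times), 0, noise_sd)
  structure(list(times = times, values = values,
                 planted = data.frame(time = event_times,
                                      amplitude = amplitudes),
                 trend = tr, noise_sd = noise_sd, dt = dt,
                 spike_width = spike_width, sign = sign),
            class = "synthetic_signal")
}

#' @export
print.synthetic_signal <- function(x, ...) {
  cat(sprintf(
    "synthetic_signal: %d samples (dt = %g s), %d planted events\n",
    length(x$times), x$dt, nrow(x$planted)))
  invisible(x)
}

#' Write a synthetic signal and its truth sidecar
#'
#' The signal uses the same TSV schema as a simulated count series
#' (\code{time_s} + one value column); the planted event times/amplitudes go
#' to \code{<path>.truth.tsv} for scoring.
#'
#' @param x a \code{"synthetic_signal"}.
#' @param path output TSV path.
#' @return \code{path}, invisibly.
#' @export
write_synthetic <- function(x, path) {
  utils::write.table(
    data.frame(time_s = x$times, synthetic.value = x$values),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(x$planted, paste0(path, ".truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

# internal: greedy 1-1 matching of recovered to planted event times
.match_events <- function(planted, recovered, tol) {
  used <- logical(length(recovered))
  hits <- 0L
  for (tp in planted) {
    d <- abs(recovered - tp)
    d[used] <- Inf
    j <- which.min(d)
    if (length(j) && is.finite(d[j]) && d[j] <= tol) {
      used[j] <- TRUE
      hits <- hits + 1L
    }
  }
  list(recall = hits / max(length(planted), 1L),
       precision = sum(used) / max(length(recovered), 1L))
}

#' Ground-truth recovery experiment for the inversion pipeline
#'
#' Forward-generates signals with a known (planted) SIP distribution, runs
#' the full filtering / event-detection / WTD pipeline on them, and scores
#' the inversion: per-seed event recall and precision (greedy one-to-one
#' matching within \code{match_tol}) and the locations of the two dominant
#' recovered psi modes. Failures (e.g. at vanishing SNR no events survive)
#' are reported as failed rows, not errors.
#'
#' Event scoring uses peak events only: the planted truth contains isolated
#' pulses, and the quiet-region boundary events that flank each accepted
#' pulse would be counted as spurious duplicates of it.
#'
#' @param directing_spec planted SIP distribution (see
#'   [generate_directing()]).
#' @param n_events planted events per seed.
#' @param amplitude spike amplitude; signal-to-noise ratio is
#'   \code{amplitude / noise_sd}.
#' @param noise_sd noise standard deviation.
#' @param trend slow-trend function or constant.
#' @param dt sampling step of the synthetic signal, seconds.
#' @param n_seeds number of independent seeds.
#' @param seed_base first seed; seeds are \code{seed_base + 0:(n_seeds-1)}.
#' @param match_tol event-matching tolerance in seconds.
#' @param tau1,tau2,bandwidth,grid_step pipeline parameters (see
#'   [fit_wtd()]). The default \code{tau2 = 2} s keeps the centred sigma
#'   window between neighbouring planted pulses (waiting times of a few
#'   seconds), so the local noise floor is estimated from noise, not from
#'   the pulses themselves.
#' @return object of class \code{"recovery_report"}: per-seed data.frame
#'   (\code{seed, n_planted, n_recovered, recall, precision, mode_lo,
#'   mode_hi, failed}) plus the psi fits.
#' @export
recovery_experiment <- function(directing_spec, n_events = 500,
                                amplitude = 10, noise_sd = 1,
                                trend = function(t) 100 + 5 * sin(2 * pi * t / 2000),
                                dt = 0.25, n_seeds = 10, seed_base = 1,
                                match_tol = 1,
                                tau1 = 50, tau2 = 2, bandwidth = 1,
                                grid_step = 0.25) {
  rows <- vector("list", n_seeds)
  fits <- vector("list", n_seeds)
  for (k in seq_len(n_seeds)) {
    seed <- seed_base + k - 1L
    set.seed(seed)
    ev <- generate_directing(directing_spec, n_events)
    sig <- make_spiked_signal(ev, amplitudes = amplitude, trend = trend,
                              noise_sd = noise_sd, dt = dt)
    res <- tryCatch({
      w <- suppressWarnings(fit_wtd(sig$values, dt = dt, tau1 = tau1,
                                    tau2 = tau2, bandwidth = bandwidth,
                                    grid_step = grid_step,
                                    include_boundaries = FALSE))
      rec <- w$events$time[w$events$kind == "peak"]
      sc <- .match_events(sig$planted$time, rec, match_tol)
      md <- find_modes(w)
      md <- md[order(md$psi, decreasing = TRUE), , drop = FALSE]
      top <- sort(md$tau[seq_len(min(2, nrow(md)))])
      fits[[k]] <- w
      data.frame(seed = seed, n_planted = n_events, n_recovered = length(rec),
                 recall = sc$recall, precision = sc$precision,
                 mode_lo = top[1],
                 mode_hi = if (length(top) > 1) top[2] else top[1],
                 failed = FALSE)
    }, error = function(e) {
      data.frame(seed = seed, n_planted = n_events, n_recovered = 0L,
                 recall = 0, precision = NA_real_, mode_lo = NA_real_,
                 mode_hi = NA_real_, failed = TRUE)
    })
    rows[[k]] <- res
  }
  structure(list(per_seed = do.call(rbind, rows), fits = fits,
                 directing_spec = directing_spec,
                 params = list(n_events = n_events, amplitude = amplitude,
                               noise_sd = noise_sd, dt = dt,
                               match_tol = match_tol, tau1 = tau1,
                               tau2 = tau2, bandwidth = bandwidth)),
            class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, ...) {
  ps <- x$per_seed
  ok <- !ps$failed
  cat(sprintf("recovery_report: %d seeds (%d ok)\n", nrow(ps), sum(ok)))
  if (any(ok))
    cat(sprintf(
      "  recall %.2f | precision %.2f | modes %.2f / %.2f s (medians)\n",
      stats::median(ps$recall[ok]), stats::median(ps$precision[ok]),
      stats::median(ps$mode_lo[ok]), stats::median(ps$mode_hi[ok])))
  invisible(x)
}
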