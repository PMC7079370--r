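# internal: indices of strict local maxima of a series, with plateau
# handling (a flat run higher than both neighbours counts once, at its
# first sample)
.local_maxima <- function(x) {
  n <- length(x)
  if (n < 3) return(integer(0))
  out <- integer(0)
  i <- 2L
  while (i <= n - 1L) {
    if (x[i] > x[i - 1L]) {
      j <- i
      while (j < n && x[j + 1L] == x[i]) j <- j + 1L
      if (j < n && x[j + 1L] < x[i]) out <- c(out, i)
      i <- j + 1L
    } else i <- i + 1L
  }
  out
}

#' Detect prominent peaks as critical events
#'
#' Candidate events are the strict local maxima of the rectified series
#' \code{yIII}. A candidate at \code{t1} is accepted when the signal
#' drops, within the candidate's own topographic span (up to the next
#' candidate at least as high), significantly below the peak relative to
#' the local fluctuation amplitude: there exists \code{t2} in that span
#' with \code{yIII(t2) + prom_mult * sigma(t2) <= yIII(t1)}.
#'
#' The margin defaults to three local standard deviations, the conventional
#' significance level: Gaussian fluctuations routinely produce rectified
#' maxima one sigma above their surroundings, so a one-sigma drop keeps an
#' order of 100 spurious events per 1000 samples on pure noise, while a
#' three-sigma prominence brings the false-event rate to the percent level
#' without touching genuine molecular-cohort fluctuations (which stand many
#' sigma above the floor). The criterion is relative to sigma, so the event
#' set is invariant under joint rescaling of signal and noise. The literal
#' subtraction form \code{yIII(t2) - sigma(t2) < yIII(t1)}, which any
#' sub-peak point satisfies, is kept under \code{predicate = "literal"}.
#'
#' @param yIII rectified positive series (see [envelope_rectify()]).
#' @param sigma local fluctuation amplitude, aligned with \code{yIII}.
#' @param dt sampling step, seconds.
#' @param predicate \code{"prominence"} (default) or \code{"literal"}.
#' @param prom_mult prominence margin in units of local sigma (default 3).
#' @return data.frame of events: \code{time}, \code{amplitude},
#'   \code{kind = "peak"}.
#' @export
detect_peaks <- function(yIII, sigma, dt = 1,
                         predicate = c("prominence", "literal"),
                         prom_mult = 3) {
  predicate <- match.arg(predicate)
  stopifnot(length(yIII) == length(sigma))
  cand <- .local_maxima(yIII)
  if (!length(cand))
    return(data.frame(time = numeric(0), amplitude = numeric(0),
                      kind = character(0)))
  n <- length(yIII)
  ok <- logical(length(cand))
  # topographic-prominence horizon: search for the drop up to the next
  # candidate at least as high (or the series end), so a deep trough can
  # validate a peak only within that peak's own span
  horizon <- integer(length(cand))
  for (k in seq_along(cand)) {
    nxt <- which(yIII[cand] >= yIII[cand[k]] & seq_along(cand) > k)[1]
    horizon[k] <- if (is.na(nxt)) n else cand[nxt]
  }
  for (k in seq_along(cand)) {
    i <- cand[k]
    rng <- if (i + 1L <= horizon[k]) (i + 1L):horizon[k] else integer(0)
    ok[k] <- if (predicate == "prominence") {
      any(yIII[rng] + prom_mult * sigma[rng] <= yIII[i])
    } else {
      any(yIII[rng] - sigma[rng] < yIII[i])
    }
  }
  idx <- cand[ok]
  data.frame(time = (idx - 1) * dt, amplitude = yIII[idx],
             kind = rep("peak", length(idx)))
}

#' Detect quiet-region boundaries as critical events
#'
#' The rectified series has regions of small values; their beginnings and
#' ends are events. A boundary is a sign change of \code{yIII - sigma}: a
#' downward crossing (the signal minus one standard deviation drops below
#' zero) opens a quiet region (\code{"quiet_start"}), an upward crossing
#' closes it (\code{"quiet_end"}).
#'
#' @inheritParams detect_peaks
#' @return data.frame of events with \code{kind} in
#'   \code{"quiet_start"}/\code{"quiet_end"}; amplitude is the \code{yIII}
#'   value at the crossing sample.
#' @export
detect_quiet_boundaries <- function(yIII, sigma, dt = 1) {
  stopifnot(length(yIII) == length(sigma))
  s <- yIII - sigma
  pos <- s > 0
  flips <- which(pos[-1L] != pos[-length(pos)]) + 1L
  if (!length(flips))
    return(data.frame(time = numeric(0), amplitude = numeric(0),
                      kind = character(0)))
  kind <- ifelse(pos[flips], "quiet_end", "quiet_start")
  data.frame(time = (flips - 1) * dt, amplitude = yIII[flips], kind = kind)
}

#' Detect all critical events of a filtered signal
#'
#' Pools prominent peaks and quiet-region boundaries into one event set,
#' sorted by time. Peaks win an equal-time collision with a boundary.
#'
#' @param fs a \code{"filtered_signal"}.
#' @param include_boundaries pool quiet-region boundary events with the
#'   peaks (default) or use peaks only.
#' @param predicate peak acceptance predicate, see [detect_peaks()].
#' @param prom_mult prominence margin, see [detect_peaks()].
#' @return data.frame of events (\code{time}, \code{amplitude},
#'   \code{kind}).
#' @export
detect_events <- function(fs, include_boundaries = TRUE,
                          predicate = "prominence", prom_mult = 3) {
  stopifnot(inherits(fs, "filtered_signal"))
  ev <- detect_peaks(fs$yIII, fs$sigma, fs$dt, predicate, prom_mult)
  if (include_boundaries) {
    qb <- detect_quiet_boundaries(fs$yIII, fs$sigma, fs$dt)
    qb <- qb[!(qb$time %in% ev$time), , drop = FALSE]  # peak kind wins
    ev <- rbind(ev, qb)
  }
  ev <- ev[order(ev$time), , drop = FALSE]
  rownames(ev) <- NULL
  ev
}

#' Build the directing-process realisation from critical events
#'
#' Orders and de-duplicates the pooled event set and forms the signal
#' interim periods (SIPs) \code{tau_i = t(t*_i) - t(t*_(i-1))}: the directing
#' process is the monotone cumulative sum of the SIPs against the natural
#' time index i. Each SIP carries the amplitude of its initiating (earlier)
#' event, used later as the weight of that waiting time.
#'
#' @param events data.frame as returned by [detect_events()] (any row
#'   order; equal-time duplicates are collapsed to one event).
#' @return object of class \code{"directing_process"}: list with
#'   \code{natural_times} (0..N), \code{physical_times} (strictly
#'   increasing), \code{sips} (positive), \code{amplitudes} (initiating-event
#'   amplitudes, one per SIP).
#' @export
build_directing <- function(events) {
  if (is.null(events) || nrow(events) < 2)
    stop("insufficient events: need at least 2 critical events")
  ev <- events[order(events$time,
                     match(events$kind,
                           c("peak", "quiet_start", "quiet_end"))), ,
               drop = FALSE]
  ev <- ev[!duplicated(ev$time), , drop = FALSE]
  if (nrow(ev) < 2) stop("insufficient events: need at least 2 distinct times")
  sips <- diff(ev$time)
  structure(list(
    natural_times = seq_len(nrow(ev)) - 1L,
    physical_times = ev$time,
    sips = sips,
    amplitudes = ev$amplitude[-nrow(ev)],
    kinds = ev$kind
  ), class = "directing_process")
}

#' @export
print.directing_process <- function(x, ...) {
  cat(sprintf(
    "directing_process: %d events over [%g, %g] s\n",
    length(x$physical_times), min(x$physical_times), max(x$physical_times)))
  cat(sprintf("  SIPs: median %.3g s, range [%.3g, %.3g] s\n",
              stats::median(x$sips), min(x$sips), max(x$sips)))
  invisible(x)
}

#' Export events or a directing process as TSV
#'
#' @param x events data.frame or a \code{"directing_process"}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_events <- function(x, path) {
  if (inherits(x, "directing_process")) {
    df <- data.frame(i = x$natural_times, t_phys_s = x$physical_times,
                     sip_s = c(NA, x$sips), amplitude = c(NA, x$amplitudes))
  } else {
    df <- data.frame(time_s = x$time, amplitude = x$amplitude, kind = x$kind)
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
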