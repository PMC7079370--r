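#' Forward moving-average operator
#'
#' The time-average filter used throughout the pipeline: the mean of the
#' signal over the forward-looking window \code{[t, t + window]}. At the right
#' edge, where the full window no longer fits, the \code{"partial"} policy
#' (default) renormalises over the available samples so the output has the
#' length of the input; \code{"truncate"} returns \code{NA} there instead.
#'
#' @param y numeric series sampled every \code{dt} seconds.
#' @param window averaging window in seconds (\code{>= dt}).
#' @param dt sampling step, seconds.
#' @param edge edge policy, \code{"partial"} or \code{"truncate"}.
#' @param align \code{"forward"} window \code{[t, t+window]} (the printed
#'   convention for the trend filter) or \code{"center"} window
#'   \code{[t-window/2, t+window/2]} (the convention for the local noise
#'   amplitude).
#' @return numeric series, same length as \code{y}.
#' @examples
#' moving_average(seq(0, 99), 10)[1:5]  # ramp: t + window/2 in the interior
#' @export
moving_average <- function(y, window, dt = 1,
                           edge = c("partial", "truncate"),
                           align = c("forward", "center")) {
  edge <- match.arg(edge)
  align <- match.arg(align)
  n <- length(y)
  if (window < dt) stop("window must be at least dt")
  k <- as.integer(round(window / dt))
  if (k + 1L > n) stop("window longer than the series")
  cs <- cumsum(c(0, y))
  i <- seq_len(n)
  if (align == "forward") {
    lo <- i
    hi <- pmin(i + k, n)
    full <- i + k <= n
  } else {
    h <- as.integer(round(window / (2 * dt)))
    lo <- pmax(i - h, 1L)
    hi <- pmin(i + h, n)
    full <- (i - h >= 1L) & (i + h <= n)
  }
  out <- (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
  if (edge == "truncate") out[!full] <- NA_real_
  out
}

#' De-trend a molecular count series
#'
#' First pipeline stage: the trend is the forward moving average over the
#' slow time scale \code{tau1}, and the fluctuation series is the printed
#' difference trend minus raw, \code{dyI = yI - y}.
#'
#' @param y numeric count series.
#' @param tau1 trend window in seconds (must exceed \code{tau2} downstream).
#' @param dt sampling step, seconds.
#' @param edge edge policy passed to [moving_average()].
#' @return list with \code{yI} (trend) and \code{dyI} (fluctuations).
#' @export
detrend <- function(y, tau1, dt = 1, edge = "partial") {
  yI <- moving_average(y, tau1, dt, edge)
  list(yI = yI, dyI = yI - y)
}

#' Local fluctuation amplitude
#'
#' The second moving average \code{yII = A_tau2 dyI} (forward window, as for
#' the trend) estimates the local mean of the fluctuations; the amplitude
#' sigma(t) is the root mean square of \code{dyI - yII} over the centred
#' window \code{[t - tau2/2, t + tau2/2]}. Edges use partial windows.
#'
#' @param dyI de-trended fluctuation series.
#' @param tau2 fluctuation window in seconds, \code{tau2 < tau1}.
#' @param dt sampling step, seconds.
#' @return list with \code{yII} and \code{sigma} (both on the grid of
#'   \code{dyI}, \code{sigma >= 0}).
#' @export
local_sigma <- function(dyI, tau2, dt = 1) {
  yII <- moving_average(dyI, tau2, dt, edge = "partial")
  dev2 <- (dyI - yII)^2
  sig2 <- moving_average(dev2, tau2, dt, edge = "partial", align = "center")
  list(yII = yII, sigma = sqrt(pmax(sig2, 0)))
}

#' Discrete Hilbert transform
#'
#' Principal-value convolution with 1/(pi t), computed in the frequency
#' domain by multiplying the spectrum with -i sign(omega) (DC and Nyquist
#' components zeroed). Linear; applying it twice returns \code{-x} up to the
#' removed mean and edge leakage. For \code{x = A sin(w t)} the interior
#' result is \code{-A cos(w t)}.
#'
#' @param x finite numeric series.
#' @return numeric series of the same length.
#' @export
hilbert_transform <- function(x) {
  n <- length(x)
  if (n < 2) return(rep(0, n))
  X <- stats::fft(x)
  m <- complex(real = 0, imaginary = numeric(n))
  half <- floor(n / 2)
  if (half >= 2) {
    pos <- 2:half
    m[pos] <- complex(real = 0, imaginary = -1)
  }
  if (n %% 2 == 0) {
    m[half + 1L] <- 0
    if (half + 2L <= n) m[(half + 2L):n] <- complex(real = 0, imaginary = 1)
  } else {
    if (half + 2L <= n) m[(half + 2L):n] <- complex(real = 0, imaginary = 1)
  }
  Re(stats::fft(X * m, inverse = TRUE)) / n
}

#' Hilbert envelope and rectified positive series
#'
#' Computes the symmetric envelope of the zero-mean de-trended fluctuations,
#' \code{y_env = |H dyI|}, and subtracts it; the remainder is clipped at zero
#' so that \code{yIII = max(dyI - y_env, 0)} is a positive-defined series
#' with enhanced prominent peaks and damped valleys.
#'
#' @param dyI de-trended (approximately zero-mean) fluctuation series.
#' @return list with \code{y_env} and \code{yIII}.
#' @export
envelope_rectify <- function(dyI) {
  y_env <- abs(hilbert_transform(dyI))
  list(y_env = y_env, yIII = pmax(dyI - y_env, 0))
}

#' Full signal transformation for one state label
#'
#' Chains de-trending, local fluctuation amplitude and envelope
#' rectification, producing every derived series the event detector needs.
#' The envelope rectification (and hence event detection) operates on the
#' zero-mean de-trended fluctuations \code{dyI}; \code{yII} and
#' \code{sigma} provide the local mean and amplitude of those fluctuations
#' at the \code{tau2} scale, against which peak prominence is tested.
#'
#' @param y raw count series for one state label.
#' @param dt sampling step in seconds.
#' @param tau1 trend window, seconds.
#' @param tau2 fluctuation window, seconds; must satisfy \code{tau2 < tau1}.
#' @param edge edge policy for the trend filter.
#' @return object of class \code{"filtered_signal"}: list of aligned series
#'   \code{y, yI, dyI, yII, sigma, y_env, yIII} plus \code{dt} and the
#'   parameters.
#' @examples
#' fs <- filter_signal(rnorm(1000) + 50, tau1 = 100, tau2 = 10)
#' range(fs$yIII)
#' @export
filter_signal <- function(y, dt = 1, tau1 = 100, tau2 = 10,
                          edge = "partial") {
  if (!(tau1 > tau2 && tau2 > 0))
    stop("filter scales must satisfy tau1 > tau2 > 0")
  dtr <- detrend(y, tau1, dt, edge)
  ls <- local_sigma(dtr$dyI, tau2, dt)
  er <- envelope_rectify(dtr$dyI)
  structure(list(y = y, yI = dtr$yI, dyI = dtr$dyI, yII = ls$yII,
                 sigma = ls$sigma, y_env = er$y_env, yIII = er$yIII,
                 dt = dt, params = list(tau1 = tau1, tau2 = tau2,
                                        edge = edge)),
            class = "filtered_signal")
}

#' @export
print.filtered_signal <- function(x, ...) {
  cat(sprintf(
    "filtered_signal: n = %d (dt = %g s), tau1 = %g s, tau2 = %g s\n",
    length(x$y), x$dt, x$params$tau1, x$params$tau2))
  cat(sprintf("  sd(dyI) = %.3g, mean sigma = %.3g, max yIII = %.3g\n",
              stats::sd(x$dyI), mean(x$sigma), max(x$yIII)))
  invisible(x)
}

#' Export a filtered signal as TSV
#'
#' @param x a \code{"filtered_signal"}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_filtered <- function(x, path) {
  stopifnot(inherits(x, "filtered_signal"))
  df <- data.frame(time_s = (seq_along(x$y) - 1) * x$dt, y = x$y, yI = x$yI,
                   dyI = x$dyI, sigma = x$sigma, y_env = x$y_env,
                   yIII = x$yIII)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
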