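# brute-force forward-window mean, the oracle for the cumsum implementation
ma_oracle <- function(y, k) {
  n <- length(y)
  vapply(seq_len(n), function(i) mean(y[i:min(i + k, n)]), 0)
}

test_that("moving average: constants, ramps and the summation oracle", {
  expect_equal(moving_average(rep(3.7, 50), 10), rep(3.7, 50))
  r <- moving_average(seq(0, 99), 10)
  expect_equal(r[1:80], seq(0, 79) + 5)  # forward mean of a ramp: t + w/2
  set.seed(42)
  y <- rnorm(500)
  expect_lt(max(abs(moving_average(y, 25) - ma_oracle(y, 25))), 1e-9)
  expect_error(moving_average(y, 1000), "longer than the series")
  expect_error(moving_average(y, 0.2), "at least dt")
})

test_that("moving average is linear and supports both edge policies", {
  set.seed(7)
  x <- rnorm(200)
  y <- rnorm(200)
  expect_equal(moving_average(2 * x + 3 * y, 20),
               2 * moving_average(x, 20) + 3 * moving_average(y, 20))
  tr <- moving_average(x, 20, edge = "truncate")
  expect_true(all(is.na(tr[181:200])))
  expect_equal(tr[1:180], moving_average(x, 20)[1:180])
})

test_that("detrending removes constants, slow trends, and keeps noise", {
  d <- detrend(rep(5, 300), tau1 = 50)
  expect_equal(d$dyI, rep(0, 300))
  # white noise around a flat trend: dyI is near-zero-mean with the noise sd
  # (a drifting trend adds the forward-window bias slope * tau1 / 2, which
  # is part of the trend component, so the mean check uses a flat trend)
  set.seed(1)
  s <- 2.5
  y <- 40 + rnorm(20000, sd = s)
  d <- detrend(y, tau1 = 100)
  expect_lt(abs(mean(d$dyI[1:19800])), 0.05)
  yd <- 0.01 * seq_len(20000) + rnorm(20000, sd = s)
  dd <- detrend(yd, tau1 = 100)
  expect_lt(abs(sd(dd$dyI[1:19800] - mean(dd$dyI[1:19800])) - s) / s, 0.05)
  # slow sinusoid (period 40 tau1): attenuated well below its amplitude
  t <- seq_len(8000)
  ys <- 10 * sin(2 * pi * t / 4000)
  ds <- detrend(ys, tau1 = 100)
  expect_lt(max(abs(ds$dyI[1:7800])), 0.25 * 10)
})

test_that("local sigma matches windowed-moment oracles", {
  ls0 <- local_sigma(rep(1.2, 400), tau2 = 10)
  expect_equal(ls0$sigma, rep(0, 400))
  # alternating +-A: rms around the local mean approaches A
  A <- 3
  alt <- rep(c(A, -A), 200)
  ls1 <- local_sigma(alt, tau2 = 10)
  expect_lt(max(abs(ls1$sigma[20:380] - A)) / A, 0.1)
  # white noise: sigma estimates the noise sd within 10% for wide windows
  set.seed(2)
  wn <- rnorm(5000, sd = 1.7)
  ls2 <- local_sigma(wn, tau2 = 100)
  expect_lt(abs(median(ls2$sigma[200:4800]) - 1.7) / 1.7, 0.1)
  # sigma ignores a constant offset
  ls3 <- local_sigma(wn + 100, tau2 = 100)
  expect_equal(ls3$sigma, ls2$sigma, tolerance = 1e-9)
})

test_that("Hilbert transform: closed forms and the exact-kernel oracle", {
  n <- 2000
  t <- seq_len(n)
  x <- 4 * sin(2 * pi * t / 100)  # 20 periods
  h <- hilbert_transform(x)
  interior <- 201:1800
  expect_lt(max(abs(h[interior] + 4 * cos(2 * pi * t[interior] / 100))) / 4,
            0.01)
  expect_equal(hilbert_transform(rep(0, 64)), rep(0, 64))
  # H(H(x)) = -x up to the mean (exact for mean-free band-limited input)
  hh <- hilbert_transform(h)
  expect_lt(max(abs(hh[interior] + x[interior])) / 4, 0.01)
  # closed-form circular kernel oracle (even n): k[m] = 2/n cot(pi m / n)
  # for odd lags, 0 for even lags
  set.seed(3)
  xr <- rnorm(256)
  m <- seq_len(255)
  kern <- ifelse(m %% 2 == 1, (2 / 256) / tan(pi * m / 256), 0)
  oracle <- vapply(seq_len(256), function(i) {
    j <- ((i - 1 - m) %% 256) + 1
    sum(kern * xr[j])
  }, 0)
  expect_lt(max(abs(hilbert_transform(xr) - oracle)), 1e-6)
})

test_that("envelope rectification clips at zero and keeps sine closed form", {
  t <- seq_len(4000)
  A <- 5
  x <- A * sin(2 * pi * t / 200)
  er <- envelope_rectify(x)
  expect_true(all(er$yIII >= 0))
  peaks <- t[(t %% 200) == 50]   # sine maxima
  peaks <- peaks[peaks > 400 & peaks < 3600]
  expect_lt(max(abs(er$yIII[peaks] - A)) / A, 0.02)
  zeros <- t[(t %% 100) == 0]
  zeros <- zeros[zeros > 400 & zeros < 3600]
  expect_lt(max(er$yIII[zeros]) / A, 0.02)
  er0 <- envelope_rectify(rep(0, 100))
  expect_equal(er0$yIII, rep(0, 100))
})

test_that("spike maxima survive the envelope subtraction", {
  # planted-signal oracle: isolated dips below a flat trend become yIII
  # peaks of nearly the planted amplitude
  sig <- make_spiked_signal(seq(100, 1900, by = 100), amplitudes = 10,
                            trend = 50, noise_sd = 0, dt = 1,
                            spike_width = 3, seed = 1)
  fs <- filter_signal(sig$values, dt = 1, tau1 = 100, tau2 = 10)
  interior <- sig$planted$time <= max(sig$times) - 100  # clear of the edge
  at <- round(sig$planted$time[interior]) + 1
  expect_true(all(abs(fs$yIII[at] - 10) / 10 < 0.15))
  expect_true(all(fs$yIII >= 0))
})

test_that("filter_signal validates scales and returns aligned series", {
  expect_error(filter_signal(rnorm(100), tau1 = 5, tau2 = 10), "tau1 > tau2")
  set.seed(4)
  fs <- filter_signal(rnorm(1000) + 20, tau1 = 80, tau2 = 8)
  expect_s3_class(fs, "filtered_signal")
  for (f in c("y", "yI", "dyI", "yII", "sigma", "y_env", "yIII"))
    expect_length(fs[[f]], 1000)
  expect_true(all(fs$sigma >= 0))
  expect_true(all(fs$yIII >= 0))
})

test_that("increasing tau1 monotonically smooths the trend", {
  set.seed(5)
  y <- cumsum(rnorm(3000)) + rnorm(3000, sd = 4)
  tv <- sapply(c(20, 50, 100, 200, 400), function(tau1)
    sum(abs(diff(moving_average(y, tau1)))))
  expect_true(all(diff(tv) < 0))
})
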