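test_that("weighted SIPs carry the initiating-event amplitude", {
  dp <- build_directing(data.frame(time = c(0, 4), amplitude = c(5, 2),
                                   kind = "peak"))
  ws <- weighted_sips(dp)
  expect_equal(ws$taus, 4)
  expect_equal(ws$weights, 5)
  dp3 <- build_directing(data.frame(time = c(0, 3, 6),
                                    amplitude = c(7, 7, 7), kind = "peak"))
  ws3 <- weighted_sips(dp3)
  expect_equal(ws3$taus, c(3, 3))
  expect_equal(ws3$weights, c(7, 7))
  # area oracle: sum tau_k w_k equals the direct sum over event pairs
  set.seed(20)
  tm <- sort(runif(50, 0, 500))
  ev <- data.frame(time = tm, amplitude = runif(50, 1, 4), kind = "peak")
  ws50 <- weighted_sips(build_directing(ev))
  expect_equal(sum(ws50$taus * ws50$weights),
               sum(diff(tm) * ev$amplitude[-50]))
})

test_that("weighted KDE matches shape, linearity and the sum oracle", {
  grid <- seq(0, 30, by = 0.1)
  d1 <- kde_density(10, 1, grid, bandwidth = 2, reflect = FALSE)
  expect_equal(grid[which.max(d1)], 10)
  expect_equal(max(d1), 0.75 / 2, tolerance = 1e-6)  # Epanechnikov peak
  d2 <- kde_density(c(5, 25), c(2, 1), grid, bandwidth = 1, reflect = FALSE)
  expect_equal(d2[grid == 5] / d2[grid == 25], 2, tolerance = 0.01)
  # brute-force kernel-sum oracle
  set.seed(21)
  taus <- runif(1000, 0, 50)
  wts <- runif(1000)
  got <- kde_density(taus, wts, grid, bandwidth = 1.5)
  K <- function(u) ifelse(abs(u) <= 1, 0.75 * (1 - u^2), 0)
  oracle <- vapply(grid, function(g)
    sum(wts * (K((g - taus) / 1.5) + K((g + taus) / 1.5)) / 1.5), 0)
  expect_lt(max(abs(got - oracle)), 1e-9)
  expect_warning(kde_density(c(1, 2), c(0, 0), grid), "all-zero")
  expect_error(kde_density(-1, 1, grid), "non-negative")
})

test_that("normalisation yields a unit-mass density with intact modes", {
  grid <- seq(0, 100, by = 0.5)
  trapz <- function(x, y) sum(diff(x) * (y[-1] + y[-length(y)]) / 2)
  d <- dgamma(grid, shape = 5, rate = 1) * 42
  psi <- normalize_wtd(d, grid)
  expect_equal(trapz(grid, psi), 1, tolerance = 1e-9)
  expect_equal(which.max(psi), which.max(d))
  u <- normalize_wtd(rep(3, 201), grid)
  expect_equal(u, rep(1 / 100, 201), tolerance = 1e-12)
  expect_error(normalize_wtd(rep(0, 201), grid), "zero total mass")
})

test_that("fit_wtd returns a normalised psi and respects epochs", {
  set.seed(22)
  ev <- generate_directing(list(name = "gamma", mean = 25, shape = 15), 700)
  sig <- suppressWarnings(
    make_spiked_signal(ev, amplitudes = 10, trend = 80, noise_sd = 1,
                       dt = 1, spike_width = 3, seed = 1))
  trapz <- function(x, y) sum(diff(x) * (y[-1] + y[-length(y)]) / 2)
  w <- fit_wtd(sig$values, dt = 1, tau2 = 4)
  expect_s3_class(w, "wtd")
  expect_equal(trapz(w$tau_grid, w$psi), 1, tolerance = 1e-6)
  expect_true(all(w$psi >= 0))
  # an epoch the length of the data reproduces the whole-series estimate
  span <- (length(sig$values) - 1)
  w_full <- fit_wtd(sig$values, dt = 1, tau2 = 4, epoch_start = 0,
                    epoch_length = span)
  expect_equal(w_full$psi, w$psi)
  expect_equal(w_full$n_events, w$n_events)
  expect_error(fit_wtd(sig$values, dt = 1, epoch_start = span + 100,
                       epoch_length = 10), "outside the data span")
  # a short epoch uses only its own events
  w_ep <- epoch_wtd(sig$values, t0 = 1000, L = 5000, dt = 1, tau2 = 4)
  expect_lt(w_ep$n_events, w$n_events)
  expect_true(all(w_ep$events$time >= 1000 & w_ep$events$time <= 6000))
})

test_that("psi is invariant under joint amplitude scaling and reweighting", {
  set.seed(23)
  ev <- generate_directing(list(name = "gamma", mean = 30, shape = 10), 300)
  sig <- suppressWarnings(
    make_spiked_signal(ev, amplitudes = 8, trend = 50, noise_sd = 0.8,
                       dt = 1, spike_width = 3, seed = 2))
  w1 <- fit_wtd(sig$values, dt = 1, tau2 = 4)
  w2 <- fit_wtd(sig$values * 6, dt = 1, tau2 = 4)
  expect_equal(w2$psi, w1$psi, tolerance = 1e-9)
  expect_equal(find_modes(w2)$tau, find_modes(w1)$tau)
  # doubling all weights does not change the normalised density
  ws <- weighted_sips(w1$directing)
  grid <- w1$tau_grid
  psi_a <- normalize_wtd(kde_density(ws$taus, ws$weights, grid), grid)
  psi_b <- normalize_wtd(kde_density(ws$taus, 2 * ws$weights, grid), grid)
  expect_equal(psi_a, psi_b, tolerance = 1e-12)
})

test_that("mode finding respects the height floor and kernel resolution", {
  grid <- seq(0, 20, by = 0.25)
  psi <- dnorm(grid, 9, 1)
  md <- find_modes(list(psi = psi / sum(psi * 0.25), tau_grid = grid,
                        params = list(bandwidth = 1)))
  expect_equal(md$tau, 9, tolerance = 0.25)
  # two separated bumps, the small one above the floor
  psi2 <- dnorm(grid, 5, 1) + 0.5 * dnorm(grid, 14, 1)
  md2 <- find_modes(list(psi = psi2, tau_grid = grid,
                         params = list(bandwidth = 1)))
  expect_equal(md2$tau, c(5, 14), tolerance = 0.3)
  # flat density has no modes
  expect_equal(nrow(find_modes(list(psi = rep(1, 81), tau_grid = grid,
                                    params = NULL))), 0)
  # sub-resolution wiggles collapse onto the dominant mode
  psi3 <- dnorm(grid, 8, 2) * (1 + 0.02 * sin(2 * pi * grid))
  md3 <- find_modes(list(psi = psi3, tau_grid = grid,
                         params = list(bandwidth = 1)))
  expect_true(all(diff(md3$tau) >= 2))
})

test_that("replicate confidence bands behave and cover a stable truth", {
  grid <- seq(0, 10, by = 0.5)
  mk <- function(psi) structure(list(tau_grid = grid, psi = psi),
                                class = "wtd")
  same <- lapply(1:5, function(i) mk(dnorm(grid, 5, 1)))
  b0 <- confidence_band(same)
  expect_equal(b0$lo, b0$hi)
  expect_equal(b0$mean, dnorm(grid, 5, 1))
  set.seed(24)
  reps <- lapply(1:10, function(i) mk(dnorm(grid, 5, 1) +
                                        rnorm(length(grid), 0, 0.005)))
  b <- confidence_band(reps)
  expect_true(all(b$lo <= b$mean & b$mean <= b$hi))
  expect_equal(b$n_replicates, 10)
  env <- confidence_band(reps, method = "envelope")
  truth <- dnorm(grid, 5, 1)
  expect_gte(mean(truth >= env$lo & truth <= env$hi), 0.9)
  bad <- mk(dnorm(seq(0, 9, by = 0.5), 5, 1))
  bad$tau_grid <- seq(0, 9, by = 0.5)
  expect_error(confidence_band(list(reps[[1]], bad)), "mismatched")
})

test_that("epoch WTDs of a stationary signal agree across epochs", {
  # 10 seeds; the epoch-B mean psi must lie inside the epoch-A replicate
  # confidence band at most grid points
  was <- list(); wbs <- list()
  for (s in 1:10) {
    set.seed(400 + s)
    ev <- generate_directing(list(name = "gamma", mean = 20, shape = 10),
                             1200)
    sig <- suppressWarnings(
      make_spiked_signal(ev, amplitudes = 10, trend = 60, noise_sd = 1,
                         dt = 1, spike_width = 3, seed = 500 + s))
    was[[s]] <- fit_wtd(sig$values, dt = 1, tau2 = 4, epoch_start = 0,
                        epoch_length = 10000, tau_max = 60)
    wbs[[s]] <- fit_wtd(sig$values, dt = 1, tau2 = 4, epoch_start = 10000,
                        epoch_length = 10000, tau_max = 60)
  }
  band <- confidence_band(was, method = "envelope")
  muB <- colMeans(do.call(rbind, lapply(wbs, `[[`, "psi")))
  inside <- muB >= band$lo - 1e-12 & muB <= band$hi + 1e-12
  expect_gte(mean(inside), 0.9)
})

test_that("simulated waiting times follow the fitted density", {
  grid <- seq(0, 20, by = 0.1)
  psi <- dnorm(grid, 8, 1.5)
  w <- structure(list(tau_grid = grid, psi = psi / sum(psi * 0.1)),
                 class = "wtd")
  draws <- simulate(w, nsim = 20000, seed = 1)
  expect_lt(abs(mean(draws) - 8), 0.1)
  expect_lt(abs(sd(draws) - 1.5), 0.1)
})

test_that("wtd TSV export includes the band when given", {
  grid <- seq(0, 5, by = 0.5)
  w <- structure(list(tau_grid = grid, integral_dist = grid + 1,
                      psi = (grid + 1) / sum(grid + 1)), class = "wtd")
  b <- structure(list(tau_grid = grid, mean = w$psi, lo = w$psi * 0.9,
                      hi = w$psi * 1.1, n_replicates = 3),
                 class = "wtd_band")
  p <- withr::local_tempfile(fileext = ".tsv")
  write_wtd(w, p, band = b)
  df <- read.delim(p)
  expect_named(df, c("tau_s", "integral_dist", "psi", "ci_lo", "ci_hi"))
  expect_equal(nrow(df), length(grid))
})
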