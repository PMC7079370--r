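stim <- list(magnitude = 10000, period = 1000, phase = 0, baseline = 100)

test_that("square wave is high-first, baseline in the second half-period", {
  expect_equal(square_wave(0, stim), 10000)
  expect_equal(square_wave(600, stim), 100)
  set.seed(1)
  t <- runif(1000, 0, 1e5)
  expect_equal(square_wave(t + stim$period, stim), square_wave(t, stim))
})

test_that("timer draws are uniform with the requested mean and support", {
  expect_equal(sample_timer(5, 0), rep(0, 5))
  set.seed(1)
  d <- sample_timer(1e5, 10)
  expect_lt(abs(mean(d) - 10), 0.1)
  expect_true(all(d >= 0 & d <= 20))
  expect_error(sample_timer(1, 10, c(5, 2)), "hi >= lo")
  expect_error(sample_timer(1, 10, c(20, 30)), "inside its support")
})

test_that("initial state has the configured census and compartments", {
  cfg <- default_config(duration = 10)
  ag <- initial_state(cfg, seed = 3)
  expect_equal(nrow(ag), 8890)
  cen <- table(factor(ag$species, levels = cfg$species$name))
  expect_equal(as.vector(cen), cfg$species$count)
  r <- sqrt(ag$x^2 + ag$y^2 + ag$z^2)
  g <- cfg$geometry
  expect_true(all(abs(r[ag$species == "integrin"] - g$cell_radius) < 1e-9))
  cyto <- ag$species %in% c("RAF", "MEK", "ERK", "ribosome")
  expect_true(all(r[cyto] >= g$nucleus_radius & r[cyto] <= g$cell_radius))
  expect_true(all(r[ag$species == "ECMprotein"] >= g$cell_radius))
  # a nucleus-only species stays inside the nuclear radius
  cfg2 <- free_config(compartment = "nucleus")
  ag2 <- initial_state(cfg2, seed = 1)
  expect_true(all(sqrt(ag2$x^2 + ag2$y^2 + ag2$z^2) <=
                    cfg2$geometry$nucleus_radius))
  # deterministic given the seed
  expect_identical(initial_state(cfg, seed = 3), ag)
})

test_that("runs are seed-reproducible with duration/dt + 1 recorded rows", {
  cfg <- tiny_config(duration = 100)
  x1 <- simulate_cell(cfg, seed = 5)
  x2 <- simulate_cell(cfg, seed = 5)
  expect_identical(x1$counts, x2$counts)
  expect_equal(nrow(x1$counts), 101)
  expect_equal(x1$times, 0:100)
  x3 <- simulate_cell(cfg, seed = 6)
  expect_false(identical(x1$counts, x3$counts))
})

test_that("a null network with no load keeps every row frozen", {
  cfg <- free_config(count = 200, duration = 50, diffusion_step = 0.4)
  x <- simulate_cell(cfg, seed = 2)
  expect_true(all(apply(x$counts, 2, function(col) all(col == col[1]))))
})

test_that("zero diffusion leaves positions unchanged", {
  cfg <- free_config(count = 100, duration = 20, diffusion_step = 0)
  a0 <- initial_state(cfg, seed = 9)
  x <- simulate_cell(cfg, seed = 9, return_agents = TRUE)
  expect_equal(x$agents$x, a0$x)
  expect_equal(x$agents$y, a0$y)
})

test_that("free Brownian steps have mean-square displacement 3 k step^2", {
  # random-walk oracle in a near-unbounded compartment (radius 5000, step
  # 0.5, 100 steps: reflections are negligible)
  k <- 100
  cfg <- free_config(count = 2000, duration = k, diffusion_step = 0.5,
                     nucleus_radius = 1, cell_radius = 5000,
                     extra_radius = 5001)
  a0 <- initial_state(cfg, seed = 4)
  a1 <- simulate_cell(cfg, seed = 4, return_agents = TRUE)$agents
  msd <- mean((a1$x - a0$x)^2 + (a1$y - a0$y)^2 + (a1$z - a0$z)^2)
  expect_lt(abs(msd - 3 * k * 0.5^2) / (3 * k * 0.5^2), 0.05)
})

test_that("no agent leaves its compartment shell under heavy diffusion", {
  cfg <- free_config(count = 300, duration = 200, diffusion_step = 2,
                     compartment = "cytoplasm")
  a <- simulate_cell(cfg, seed = 7, return_agents = TRUE)$agents
  r <- sqrt(a$x^2 + a$y^2 + a$z^2)
  expect_true(all(r >= cfg$geometry$nucleus_radius - 1e-9))
  expect_true(all(r <= cfg$geometry$cell_radius + 1e-9))
})

test_that("binding requires proximity within the interaction range", {
  # all agents inside one interaction range: every B is bound by step 1
  cfg <- pair_config(nA = 20, nB = 10, duration = 2, R_inter = 30,
                     timer_mean = 1000, diffusion_step = 0)
  x <- simulate_cell(cfg, seed = 1)
  expect_equal(state_series(x, species = "B", partner = "A")[2], 10)
  # vanishing interaction range: nothing ever binds
  cfg2 <- pair_config(nA = 20, nB = 20, duration = 50, R_inter = 1e-9)
  x2 <- simulate_cell(cfg2, seed = 1)
  expect_true(all(state_series(x2, species = "B", partner = "A") == 0))
})

test_that("spatial-hash binding equals brute-force binding", {
  cfg <- tiny_config(duration = 300, scale = 1 / 60)  # ~150 agents
  xh <- simulate_cell(cfg, seed = 11, brute_force = FALSE)
  xb <- simulate_cell(cfg, seed = 11, brute_force = TRUE)
  expect_identical(xh$counts, xb$counts)
})

test_that("uniform timers give a linear survival curve hitting 0 at 2 T", {
  # analytic oracle: N complexes with U[0, 20] lifetimes -> survival
  # S(t) = N (1 - t/20), 0 beyond 20 s
  sr <- data.frame(species = "X", active = TRUE, timer_name = "off",
                   mean = 10, lo = 0, hi = 20, active_out = FALSE,
                   produce = NA, gate_compartment = NA, die = FALSE,
                   become = NA, stringsAsFactors = FALSE)
  cfg <- free_config(count = 10000, duration = 25, init_active = 10000,
                     state_rules = sr, diffusion_step = 0)
  x <- simulate_cell(cfg, seed = 8)
  act <- state_series(x, species = "X", activation = "active")
  expected <- 10000 * pmax(1 - (0:25) / 20, 0)
  expect_true(all(abs(act - expected) < 4 * sqrt(pmax(expected, 1) / 4)))
  expect_equal(act[22:26], rep(0, 5))
  # degenerate support [5, 5]: the whole cohort fires exactly at t = 5
  sr5 <- transform(sr, mean = 5, lo = 5, hi = 5)
  cfg5 <- free_config(count = 100, duration = 8, init_active = 100,
                      state_rules = sr5, diffusion_step = 0)
  a5 <- state_series(simulate_cell(cfg5, seed = 1),
                     species = "X", activation = "active")
  expect_equal(a5, c(rep(100, 5), rep(0, 4)))
})

test_that("integrin activation is off at baseline load and linear above", {
  base <- tiny_config(duration = 1000, scale = 1 / 10)
  # pinned at baseline: no activation anywhere downstream, ever
  cfg0 <- base
  cfg0$stimulus$magnitude <- cfg0$stimulus$baseline
  x0 <- simulate_cell(cfg0, seed = 2)
  for (spp in c("integrin", "MEK", "ERK", "RUNX2"))
    expect_true(all(state_series(x0, species = spp,
                                 activation = "active") == 0),
                info = spp)
  # at full load the first-step activation count is binomial(n, k_act)
  cfg1 <- base
  n_int <- cfg1$species$count[cfg1$species$name == "integrin"]
  p <- cfg1$k_act
  x1 <- simulate_cell(cfg1, seed = 3)
  first <- state_series(x1, species = "integrin", activation = "active")[2]
  expect_lt(abs(first - n_int * p), 3 * sqrt(n_int * p * (1 - p)) + 1)
  # doubling M_ref halves the activation probability at fixed load
  cfg2 <- cfg1
  cfg2$M_ref <- 2 * cfg2$M_ref
  cfg2$stimulus$magnitude <- cfg1$stimulus$magnitude
  x2 <- simulate_cell(cfg2, seed = 3)
  first2 <- state_series(x2, species = "integrin",
                         activation = "active")[2]
  expect_lt(abs(first2 - n_int * p / 2),
            3 * sqrt(n_int * p / 2 * (1 - p / 2)) + 1)
})

test_that("time-averaged integrin activity is monotone in load magnitude", {
  means <- sapply(c(1000, 5000, 10000), function(M) {
    mean(sapply(1:10, function(s) {
      cfg <- tiny_config(duration = 300, scale = 1 / 40, magnitude = M)
      mean(state_series(simulate_cell(cfg, seed = s),
                        species = "integrin", activation = "active"))
    }))
  })
  expect_true(all(diff(means) > 0))
})

test_that("the integer mass ledger is exact at every step", {
  cfg <- tiny_config(duration = 2000, scale = 1 / 20)
  x <- simulate_cell(cfg, seed = 13)
  tot <- rowSums(x$counts)
  expect_equal(diff(tot), as.numeric(x$productions - x$degradations)[-1])
  expect_gt(sum(x$productions), 0)  # the run actually produced molecules
  # and the census at t = 0 matches the configuration
  expect_equal(tot[1], sum(cfg$species$count))
})

test_that("binding ledger: one complex removes one A and one B", {
  cfg <- pair_config(nA = 30, nB = 30, duration = 100, timer_mean = 50)
  x <- simulate_cell(cfg, seed = 4)
  freeA <- state_series(x, species = "A", partner = "none")
  freeB <- state_series(x, species = "B", partner = "none")
  bound <- state_series(x, species = "A", partner = "B")
  expect_equal(freeA + bound, rep(30, 101))
  expect_equal(freeB + state_series(x, species = "B", partner = "A"),
               rep(30, 101))
  expect_equal(state_series(x, species = "B", partner = "A"), bound)
})

test_that("state series TSV round trip preserves counts", {
  cfg <- tiny_config(duration = 50)
  x <- simulate_cell(cfg, seed = 1)
  p <- withr::local_tempfile(fileext = ".tsv")
  write_state_ts(x, p)
  back <- read_state_ts(p)
  expect_equal(back$times, x$times)
  expect_equal(unname(back$counts), unname(x$counts))
  expect_equal(colnames(back$counts), colnames(x$counts))
  expect_error(state_series(x, label = "no.such.label.here"),
               "not present")
})
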