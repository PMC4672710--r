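# Tracer diffusion: walker co-simulation, D estimation, effective-medium
# prediction, and the kiss-and-run range.

test_that("free lattice walk recovers D = lambda_dif/(2d)", {
  lat <- make_lattice(32, 2, p = 1, tau = Inf, boundary = "periodic", seed = 1)
  cfg <- walker_config(lambda_dif = 1, n_walkers = 1200, t_max = 60, seed = 2)
  est <- estimate_D(simulate_walkers(lat, cfg))
  expect_lt(abs(est$D_app - 0.25) / 0.25, 0.05)

  lat3 <- make_lattice(12, 3, p = 1, tau = Inf, boundary = "periodic", seed = 1)
  cfg3 <- walker_config(lambda_dif = 1.5, n_walkers = 1000, t_max = 40, seed = 3)
  est3 <- estimate_D(simulate_walkers(lat3, cfg3))
  expect_lt(abs(est3$D_app - 1.5 / 6) / (1.5 / 6), 0.05)
})

test_that("p = 0 walkers never move", {
  lat <- make_lattice(16, 2, p = 0, tau = Inf, boundary = "periodic", seed = 1)
  cfg <- walker_config(n_walkers = 50, t_max = 20, seed = 4)
  msd <- simulate_walkers(lat, cfg)
  expect_true(all(msd$msd == 0))
})

test_that("fast flicker approaches the annealed limit D = p lambda_dif/(2d)", {
  lat <- make_lattice(48, 2, p = 0.5, tau = 0.01, boundary = "periodic", seed = 5)
  cfg <- walker_config(n_walkers = 1200, t_max = 80, seed = 6)
  est <- estimate_D(simulate_walkers(lat, cfg))
  expect_lt(abs(est$D_app - 0.125) / 0.125, 0.10)
})

test_that("msd curves are non-negative, start at zero, and grow in expectation", {
  lat <- make_lattice(24, 2, p = 0.6, tau = 1, boundary = "periodic", seed = 7)
  cfg <- walker_config(n_walkers = 400, t_max = 50, seed = 8)
  msd <- simulate_walkers(lat, cfg)
  expect_equal(msd$msd[1], 0)
  expect_true(all(msd$msd >= 0))
  expect_gt(tail(msd$msd, 1), msd$msd[2])
})

test_that("estimate_D recovers exact and synthetic slopes", {
  # exact line msd = 4 t in d = 2 -> D = 1
  curve <- data.frame(time = 0:20, msd = 4 * (0:20))
  expect_equal(estimate_D(curve, d = 2)$D_app, 1, tolerance = 1e-12)

  # plateau -> D near zero (a flat window may fit a tiny negative slope)
  plateau <- data.frame(time = 0:20, msd = c(0, rep(5, 20)))
  expect_lt(suppressWarnings(
    estimate_D(plateau, fit_window = c(5, 20), d = 2)$D_app), 1e-2)

  # noisy parameter recovery around D = 0.2
  set.seed(9)
  tt <- seq(0, 100, by = 2)
  noisy <- data.frame(time = tt, msd = 4 * 0.2 * tt + rnorm(length(tt), 0, 0.5),
                      stderr = rep(0.5, length(tt)))
  expect_lt(abs(estimate_D(noisy, fit_window = c(0, 100), d = 2)$D_app - 0.2),
            0.02)

  expect_error(estimate_D(curve, fit_window = c(30, 40), d = 2), "empty")
  expect_warning(
    est <- estimate_D(data.frame(time = 0:20, msd = 20:0), d = 2), "clipped")
  expect_equal(est$D_app, 0)
})

test_that("EMA reproduces its closed-form limits", {
  expect_equal(ema_diffusion(1, 5), 0.25)
  expect_equal(ema_diffusion(1, Inf, lambda_dif = 2, d = 3), 2 / 6)
  # static EMA at z = 4: D/D_free = 2p - 1 above 1/2, zero below
  for (p in c(0.55, 0.75, 0.9))
    expect_equal(ema_diffusion(p, Inf), (2 * p - 1) * 0.25, tolerance = 1e-12)
  expect_equal(ema_diffusion(0.5, Inf), 0)
  expect_equal(ema_diffusion(0.3, Inf), 0)
  # static EMA at z = 6: (3p - 1)/2
  expect_equal(ema_diffusion(0.6, Inf, d = 3), (3 * 0.6 - 1) / 2 * (1 / 6),
               tolerance = 1e-12)
  # fast flicker: annealed limit within 1%
  for (p in c(0.2, 0.5, 0.8))
    expect_lt(abs(ema_diffusion(p, 1e-4) - p * 0.25) / (p * 0.25), 0.01)
  expect_error(ema_diffusion(1.2, 1), "p")
  expect_error(ema_diffusion(0.5, -1), "tau")
})

test_that("EMA is monotone in p and in tau", {
  ps <- seq(0.1, 0.9, by = 0.2)
  for (tau in c(0.1, 1, 10))
    expect_true(all(diff(ema_diffusion(ps, tau)) > 0))
  for (p in c(0.3, 0.5, 0.7)) {
    vals <- vapply(c(0.05, 0.5, 5, 50), function(tau) ema_diffusion(p, tau),
                   numeric(1))
    expect_true(all(diff(vals) < 0))     # D strictly decreasing in tau
  }
})

test_that("simulation matches exact master-equation diffusion on frozen 4x4 lattices", {
  skip_if_not_installed("MASS")
  set.seed(11)
  checked <- 0
  for (seed in 1:10) {
    lat <- make_lattice(4, 2, p = 0.75, tau = Inf, boundary = "periodic",
                        seed = 100 + seed)
    D_exact <- oracle_D_static(lat)
    if (D_exact < 0.02) next              # skip non-wrapping disorder draws
    cfg <- walker_config(n_walkers = 3000, t_max = 120)
    est <- estimate_D(simulate_walkers(lat, cfg))
    expect_lt(abs(est$D_app - D_exact) / D_exact, 0.05)
    checked <- checked + 1
    if (checked >= 3) break
  }
  expect_gte(checked, 3)
})

test_that("simulated D is monotone in p and tau within noise", {
  set.seed(12)
  D_of <- function(p, tau) {
    Ds <- vapply(1:4, function(r) {
      lat <- make_lattice(48, 2, p = p, tau = tau, boundary = "periodic")
      estimate_D(simulate_walkers(lat, walker_config(n_walkers = 400,
                                                     t_max = 120)))$D_app
    }, numeric(1))
    c(mean(Ds), sd(Ds) / 2)
  }
  a <- D_of(0.3, 1); b <- D_of(0.6, 1); c3 <- D_of(0.9, 1)
  expect_gt(b[1] - a[1], -2 * sqrt(a[2]^2 + b[2]^2))
  expect_gt(c3[1] - b[1], -2 * sqrt(b[2]^2 + c3[2]^2))
  slow <- D_of(0.5, 20); fast <- D_of(0.5, 0.2)
  expect_gt(fast[1] - slow[1], -2 * sqrt(slow[2]^2 + fast[2]^2))
})

test_that("diffusion_surface produces the full grid for both methods", {
  surf <- diffusion_surface(c(0.3, 0.7), c(0.5, Inf), method = "ema")
  expect_equal(nrow(surf), 4)
  expect_true(all(surf$method == "ema"))
  # microfused with fast flicker still diffuses less than slow hyperfused
  d_micro <- ema_diffusion(0.05, 0.01)
  d_hyper <- ema_diffusion(0.8, 100)
  expect_lt(d_micro, d_hyper)

  set.seed(13)
  surf_sim <- diffusion_surface(c(0.5, 1), 0.5, method = "sim", L = 24,
                                n_walkers = 100, t_max = 40, n_rep = 2)
  expect_equal(nrow(surf_sim), 2)
  expect_true(all(surf_sim$D >= 0))
  expect_error(diffusion_surface(numeric(0), 1), "non-empty")
})

test_that("kiss-and-run range follows sqrt(2 d D t)", {
  expect_equal(kiss_and_run_range(20, 45, 3), sqrt(6 * 20 * 45))
  expect_lt(abs(kiss_and_run_range(20, 45, 3) - 73.5), 0.1)
  expect_equal(kiss_and_run_range(0, 10, 3), 0)
  expect_equal(kiss_and_run_range(1, 0.5, 1), 1)
  expect_error(kiss_and_run_range(-1, 1), "non-negative")
  expect_error(kiss_and_run_range(1, 0), "positive")
})
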