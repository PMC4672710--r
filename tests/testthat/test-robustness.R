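# Robustness models: capacitor-leak fluctuations and spin-coupled failure.

test_that("without pore events the potential sits exactly at j/g0", {
  m <- fluctuation_model(radius = 1, pore_rate_density = 0)
  res <- simulate_fluctuations(m, t_max = 50, n_reps = 3, seed = 1)
  expect_equal(res$mean_psi, 150, tolerance = 1e-10)
  expect_equal(res$sigma_rel, 0, tolerance = 1e-12)
})

test_that("added leak can only depolarise: mean psi <= j/g0", {
  for (r in c(0.25, 1, 2)) {
    m <- fluctuation_model(radius = r)
    res <- simulate_fluctuations(m, t_max = 100, n_reps = 30, seed = 2)
    expect_lte(res$mean_psi, 150 + 1e-9)
  }
})

test_that("doubling the radius halves the relative fluctuations", {
  m1 <- fluctuation_model(radius = 0.5)
  m2 <- fluctuation_model(radius = 1)
  r1 <- simulate_fluctuations(m1, t_max = 300, n_reps = 150, seed = 3)
  r2 <- simulate_fluctuations(m2, t_max = 300, n_reps = 150, seed = 4)
  ratio <- r1$sigma_rel / r2$sigma_rel
  expect_lt(abs(ratio - 2) / 2, 0.15)
})

test_that("invagination (larger capacitance) damps fluctuations", {
  m1 <- fluctuation_model(radius = 0.5, invagination = 1)
  m2 <- fluctuation_model(radius = 0.5, invagination = 4)
  r1 <- simulate_fluctuations(m1, t_max = 200, n_reps = 100, seed = 5)
  r2 <- simulate_fluctuations(m2, t_max = 200, n_reps = 100, seed = 6)
  expect_lt(r2$sigma_rel, r1$sigma_rel)
})

test_that("radius sweep reports a near -1 scaling exponent", {
  set.seed(7)
  sweep <- fluctuation_radius_sweep(c(0.25, 0.5, 1, 2), t_max = 250,
                                    n_reps = 120)
  expect_true(all(diff(sweep$table$sigma_rel) < 0))
  expect_lt(abs(sweep$exponent + 1), 0.2)
})

test_that("spin ensembles validate topology and parameters", {
  ens <- spin_ensemble(4, "complete")
  expect_equal(nrow(ens$edges), 6)
  expect_equal(nrow(spin_ensemble(4, "chain")$edges), 3)
  expect_error(spin_ensemble(0), "n_agents")
  expect_error(spin_ensemble(3, coupling = -1), "coupling")
  expect_error(spin_ensemble(3, "edges"), "edges")
  lat <- make_lattice(5, 2, p = 0.7, tau = 1, seed = 8)
  ens_lat <- spin_from_lattice(lat, coupling = 0.4)
  expect_gte(ens_lat$n_agents, 2)
  expect_error(spin_failure_probability(spin_ensemble(13), "exact"), "N <= 12")
})

test_that("Monte Carlo catastrophe probability matches the exact master equation", {
  ens <- spin_ensemble(3, "complete", coupling = 0.5, bias = 0.3,
                       beta_inv = 1, horizon = 20)
  ex <- spin_failure_probability(ens, "exact")$p
  mc <- spin_failure_probability(ens, "monte_carlo", n_reps = 4000, seed = 9)
  expect_lt(abs(mc$p - ex), 3 * mc$se)
  # metropolis dynamics: same construction, also consistent
  ex_m <- spin_failure_probability(ens, "exact", dynamics = "metropolis")$p
  mc_m <- spin_failure_probability(ens, "monte_carlo", n_reps = 4000,
                                   dynamics = "metropolis", seed = 10)
  expect_lt(abs(mc_m$p - ex_m), 3 * mc_m$se)
})

test_that("uncoupled agents reproduce the birth-death closed form", {
  for (N in c(1, 3, 5)) {
    ens <- spin_ensemble(N, "complete", coupling = 0, bias = 0.3, horizon = 15)
    ex <- spin_failure_probability(ens, "exact")$p
    cf <- spin_independent_closed_form(ens)
    expect_lt(abs(ex - cf), 1e-7)
  }
})

test_that("coupling monotonically protects against catastrophe", {
  ps <- vapply(c(0, 0.25, 0.5, 1, 2), function(J) {
    ens <- spin_ensemble(3, "complete", coupling = J, bias = 0.3, horizon = 20)
    spin_failure_probability(ens, "exact")$p
  }, numeric(1))
  expect_true(all(diff(ps) < 0))
})

test_that("stationary distribution obeys detailed balance (Boltzmann weights)", {
  for (dyn in c("glauber", "metropolis")) {
    ens <- spin_ensemble(4, "chain", coupling = 0.7, bias = 0.2, beta_inv = 1.3)
    Q <- mitonet:::spin_generator(ens, dyn, absorbing = FALSE)
    # Boltzmann weights computed independently from the energy function
    N <- 4
    E <- vapply(0:(2^N - 1), function(st) {
      s <- ifelse(bitwAnd(st, bitwShiftL(1L, 0:(N - 1))) > 0, -1, 1)
      -0.7 * sum(s[1:3] * s[2:4]) - 0.2 * sum(s)
    }, numeric(1))
    pi_b <- exp(-E / 1.3); pi_b <- pi_b / sum(pi_b)
    resid <- as.numeric(Matrix::t(Q) %*% pi_b)
    expect_lt(max(abs(resid)), 1e-12)
  }
})

test_that("group, independent and single-agent comparisons behave as expected", {
  ens <- spin_ensemble(3, "complete", coupling = 2, bias = 0.3, horizon = 20)
  cmp <- group_vs_individual(ens)
  p <- setNames(cmp$p, cmp$case)
  expect_lt(p[["group"]], p[["independent"]])       # strong coupling protects
  expect_lt(p[["independent"]], p[["single"]])      # recovery helps a group
  ens1 <- spin_ensemble(1, coupling = 0, bias = 0.3, horizon = 20)
  cmp1 <- group_vs_individual(ens1)
  expect_lt(diff(range(cmp1$p)), 1e-9)              # N = 1: all three coincide
  ens0 <- spin_ensemble(3, "complete", coupling = 0, bias = 0.3, horizon = 20)
  cmp0 <- group_vs_individual(ens0)
  expect_lt(abs(cmp0$p[1] - cmp0$p[2]), 1e-12)      # J = 0 equals independent
})

test_that("Monte Carlo error shrinks roughly as 1/sqrt(n_reps)", {
  ens <- spin_ensemble(3, "complete", coupling = 0.5, bias = 0.3, horizon = 20)
  ex <- spin_failure_probability(ens, "exact")$p
  set.seed(11)
  err <- function(n, k) mean(vapply(seq_len(k), function(i)
    abs(spin_failure_probability(ens, "monte_carlo", n_reps = n)$p - ex),
    numeric(1)))
  e_small <- err(150, 12)
  e_big <- err(2400, 12)
  expect_lt(e_big, e_small / 2)     # expect ~4x reduction; demand at least 2x
})
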