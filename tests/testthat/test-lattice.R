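# Fluctuating bond lattice: construction, exact bond dynamics, connectivity.

test_that("lattice construction derives p, tau and the bond count", {
  lat <- make_lattice(4, 2, lambda_fus = 2, lambda_fis = 2, seed = 1)
  expect_equal(lat$p, 0.5)
  expect_equal(lat$tau, 0.25)
  expect_length(lat$bonds$state, 2 * 4 * 3)        # d * L^(d-1) * (L-1)

  lat3 <- make_lattice(4, 3, p = 0.4, tau = 2, seed = 1)
  expect_length(lat3$bonds$state, 3 * 16 * 3)
  expect_equal(lat3$lambda_fus + lat3$lambda_fis, 1 / 2)

  # each bond stored once, keyed by the lexicographically smaller endpoint
  expect_true(all(lat$bonds$from < lat$bonds$to))
  expect_false(any(duplicated(paste(lat$bonds$from, lat$bonds$to))))

  # lambda_fis = 0 forces p = 1 and every bond on
  lat1 <- make_lattice(4, 2, lambda_fus = 1, lambda_fis = 0, seed = 1)
  expect_equal(lat1$p, 1)
  expect_true(all(lat1$bonds$state))

  expect_error(make_lattice(1, 2, 1, 1), "L")
  expect_error(make_lattice(4, 4, 1, 1), "d")
  expect_error(make_lattice(4, 2, -1, 1), "non-negative")
  expect_error(make_lattice(4, 2, 0, 0), "both be zero")
})

test_that("stationary initialisation has on-bond fraction near p with no drift", {
  lat <- make_lattice(64, 2, p = 0.3, tau = 1, seed = 42)
  nb <- length(lat$bonds$state)
  # time-averaged on-fraction over a long run: within 3 SE of p
  n_steps <- 50
  fr <- numeric(n_steps)
  for (i in seq_len(n_steps)) {
    lat <- step_bonds(lat, 2)      # 2 tau apart: nearly independent snapshots
    fr[i] <- mean(lat$bonds$state)
  }
  se <- sd(fr) / sqrt(n_steps)
  expect_lt(abs(mean(fr) - 0.3), 3 * se)
  # no drift over ~10 tau and beyond: slope consistent with 0 at 95%
  fit <- summary(lm(fr ~ seq_len(n_steps)))$coefficients
  expect_gt(fit["seq_len(n_steps)", "Pr(>|t|)"], 0.05)
})

test_that("step_bonds uses the exact two-state transition law", {
  # absorbing case: lambda_fis = 0 keeps every bond on
  lat <- make_lattice(16, 2, lambda_fus = 3, lambda_fis = 0, seed = 7)
  lat <- step_bonds(lat, 5)
  expect_true(all(lat$bonds$state))

  # from all-off: P(on after dt) = p (1 - exp(-dt/tau))
  set.seed(8)
  lat <- make_lattice(100, 2, p = 0.6, tau = 2)
  lat$bonds$state[] <- FALSE
  dt <- 1.5
  lat1 <- step_bonds(lat, dt)
  n <- length(lat$bonds$state)
  p_theory <- 0.6 * (1 - exp(-dt / 2))
  se <- sqrt(p_theory * (1 - p_theory) / n)
  expect_lt(abs(mean(lat1$bonds$state) - p_theory), 4 * se)

  # ensemble autocorrelation decays as exp(-dt/tau)
  set.seed(9)
  lat <- make_lattice(100, 2, p = 0.4, tau = 1)
  s0 <- lat$bonds$state
  lat1 <- step_bonds(lat, 0.7)
  rho <- cor(as.numeric(s0), as.numeric(lat1$bonds$state))
  expect_lt(abs(rho - exp(-0.7)), 4 / sqrt(n))

  expect_error(step_bonds(lat, 0), "dt")
})

test_that("two half steps have the same marginal law as one full step", {
  set.seed(10)
  lat <- make_lattice(100, 2, p = 0.35, tau = 0.8)
  lat$bonds$state[] <- FALSE              # common fixed start
  dt <- 1.2
  one <- step_bonds(lat, dt)
  two <- step_bonds(step_bonds(lat, dt / 2), dt / 2)
  n <- length(lat$bonds$state)            # ~2e4 bonds
  p1 <- mean(one$bonds$state); p2 <- mean(two$bonds$state)
  se <- sqrt(p1 * (1 - p1) / n + p2 * (1 - p2) / n)
  expect_lt(abs(p1 - p2), 4 * se)
})

test_that("connectivity stats match a breadth-first-search oracle", {
  for (seed in 1:5) {
    lat <- make_lattice(6, 2, p = runif(1, 0.2, 0.8), tau = 1, seed = seed)
    cs <- connectivity_stats(lat)
    oracle <- bfs_clusters(lat)
    expect_equal(sort(cs$cluster_sizes), sort(oracle$sizes))
    expect_equal(sum(cs$cluster_sizes), 36)       # cluster conservation
  }
  lat3 <- make_lattice(4, 3, p = 0.4, tau = 1, seed = 3)
  cs3 <- connectivity_stats(lat3)
  expect_equal(sort(cs3$cluster_sizes), sort(bfs_clusters(lat3)$sizes))
  expect_equal(sum(cs3$cluster_sizes), 64)
})

test_that("degenerate connectivity: p = 0 fully fragmented, p = 1 spanning", {
  lat0 <- make_lattice(5, 2, p = 0, tau = 1, seed = 1)
  cs0 <- connectivity_stats(lat0)
  expect_equal(cs0$n_clusters, 25)
  expect_true(all(cs0$cluster_sizes == 1))
  expect_false(cs0$spanning)

  lat1 <- make_lattice(5, 2, p = 1, tau = 1, seed = 1)
  cs1 <- connectivity_stats(lat1)
  expect_equal(cs1$n_clusters, 1)
  expect_equal(cs1$largest_fraction, 1)
  expect_true(cs1$spanning)
})

test_that("spanning frequency at p = 0.5 is near 1/2 (square-lattice self-duality)", {
  set.seed(13)
  f <- spanning_probability(64, 0.5, n_snapshots = 400)
  expect_lt(abs(f - 0.5), 1.96 * sqrt(0.25 / 400) + 0.03)  # binomial CI + finite-L
})

test_that("morphology classification covers the five regimes exactly once", {
  expect_equal(classify_morphology(0, 1)$label, "fragmented")
  expect_equal(classify_morphology(0.03, 1)$label, "microfused")
  expect_equal(classify_morphology(0.3, 1, p_c = 0.5, eps = 0.05)$label,
               "mesofused")
  expect_equal(classify_morphology(0.7, 1)$label, "dynamic_hyperfused")
  expect_equal(classify_morphology(0.99, 1)$label, "static_hyperfused")
  expect_equal(classify_morphology(0.99, 0)$label, "static_hyperfused")
  expect_equal(classify_morphology(0.6, 0)$label, "static_hyperfused")
  expect_error(classify_morphology(1.2, 1), "p")
  expect_error(classify_morphology(0.5, 1, p_c = 1.2), "p_c")
  expect_error(classify_morphology(0.5, 1, eps = 0.6), "eps")
})

test_that("GraphML export round-trips nodes and on-bonds", {
  lat <- make_lattice(5, 2, p = 0.6, tau = 1, seed = 4)
  f <- tempfile(fileext = ".graphml")
  export_graphml(lat, f)
  g <- igraph::read_graph(f, format = "graphml")
  expect_equal(igraph::vcount(g), 25)
  expect_equal(igraph::ecount(g), sum(lat$bonds$state))
  expect_equal(sort(unique(igraph::vertex_attr(g, "x"))), as.numeric(0:4))
  unlink(f)
})

test_that("cluster time series records the connectivity trajectory", {
  lat <- make_lattice(10, 2, p = 0.5, tau = 1, seed = 5)
  ts <- cluster_time_series(lat, dt = 0.5, n_steps = 4)
  expect_equal(nrow(ts), 5)
  expect_equal(ts$time, seq(0, 2, by = 0.5))
  expect_true(all(ts$n_clusters >= 1))
})
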