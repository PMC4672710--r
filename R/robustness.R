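# Two models of fusion-as-buffering:
# (a) capacitor-leak shot noise: relative membrane-potential fluctuations
#     shrink with mitochondrial radius (per-event amplitude ~ 1/r^2, event
#     rate ~ r^2, hence sigma_rel ~ 1/r);
# (b) spin-coupled agents: ferromagnetic coupling makes the all-failed state
#     harder to reach, so groups resist catastrophic loss of function better
#     than independent agents.

#' Capacitor-leak fluctuation model of a spherical mitochondrion
#'
#' All fluxes scale with the membrane surface area `A = 4 pi r^2`:
#' capacitance `C = c_m * y * A` (the invagination factor `y >= 1` models
#' cristae, which add membrane area at fixed outer radius), pump current
#' `I = j * A`, leak conductance `G = g0 * A`, and transient pore openings as
#' a Poisson process of rate `nu * A`, each adding conductance `g_p` for a
#' lifetime `t_p`. The unperturbed potential `psi0 = j / g0` is intensive
#' (radius independent); the fluctuations around it are not.
#'
#' @param radius mitochondrial radius (um).
#' @param invagination dimensionless `y >= 1`; larger for more invaginated
#'   inner membranes.
#' @param pump_density pump current per membrane area `j` (sets
#'   `psi0 = j / g0`, default 150 in mV units).
#' @param leak_density leak conductance per area `g0`.
#' @param capacitance_density membrane capacitance per area `c_m`.
#' @param pore_rate_density pore-opening events per area per time `nu`.
#' @param pore_conductance conductance of one open pore `g_p` (an intensive
#'   perturbation: a single molecular event does not scale with size).
#' @param pore_lifetime open duration `t_p`.
#' @return An object of class `fluctuation_model`.
#' @export
fluctuation_model <- function(radius = 1, invagination = 1,
                              pump_density = 150, leak_density = 1,
                              capacitance_density = 1,
                              pore_rate_density = 0.2,
                              pore_conductance = 0.5, pore_lifetime = 1) {
  vals <- c(radius, invagination, pump_density, leak_density,
            capacitance_density, pore_conductance, pore_lifetime)
  if (any(vals <= 0)) stop("physical parameters must be positive")
  if (pore_rate_density < 0) stop("`pore_rate_density` must be >= 0")
  if (invagination < 1) stop("`invagination` must be >= 1")
  structure(list(radius = radius, invagination = invagination,
                 pump_density = pump_density, leak_density = leak_density,
                 capacitance_density = capacitance_density,
                 pore_rate_density = pore_rate_density,
                 pore_conductance = pore_conductance,
                 pore_lifetime = pore_lifetime),
            class = "fluctuation_model")
}

#' Simulate membrane-potential fluctuations under transient pore openings
#'
#' Integrates `C dpsi/dt = I_pump - (G_leak + g_p N_open(t)) psi` exactly
#' (piecewise-exponential segments between pore events; time averages from
#' closed-form segment integrals). Pore openings arrive at rate
#' `nu * 4 pi r^2` and last `t_p` each.
#'
#' Because one pore's conductance is intensive while the baseline leak and
#' the event rate grow with area, the relative fluctuation amplitude scales
#' as `1/r` — larger (more fused) mitochondria damp transient
#' depolarisations. The measured scaling exponent is reported by
#' [fluctuation_radius_sweep()] rather than asserted.
#'
#' @param model a [fluctuation_model()].
#' @param t_max simulated time (should be much longer than `pore_lifetime`).
#' @param n_reps independent replicate trajectories.
#' @param burn_in initial transient discarded from the averages (default
#'   `0.1 * t_max`).
#' @param seed optional integer seed.
#' @return List with `mean_psi`, `sigma_rel` (means over replicates),
#'   `se_sigma_rel`, and the per-replicate vectors `reps_mean`, `reps_sigma`.
#' @export
simulate_fluctuations <- function(model, t_max = 200, n_reps = 100,
                                  burn_in = 0.1 * t_max, seed = NULL) {
  stopifnot(inherits(model, "fluctuation_model"))
  if (t_max <= 10 * model$pore_lifetime)
    warning("`t_max` is not large compared to the pore lifetime")
  if (n_reps < 1) stop("`n_reps` must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  A <- 4 * pi * model$radius^2
  res <- cpp_simulate_fluct(A,
                            model$capacitance_density * model$invagination * A,
                            model$pump_density * A,
                            model$leak_density * A,
                            model$pore_rate_density * A,
                            model$pore_conductance, model$pore_lifetime,
                            t_max, burn_in, as.integer(n_reps))
  list(mean_psi = mean(res$mean_psi),
       sigma_rel = mean(res$sigma_rel),
       se_sigma_rel = if (n_reps > 1) sd(res$sigma_rel) / sqrt(n_reps) else NA_real_,
       reps_mean = res$mean_psi, reps_sigma = res$sigma_rel)
}

#' Relative fluctuations across a radius grid
#'
#' Runs [simulate_fluctuations()] at each radius (all densities fixed) and
#' fits the scaling exponent of `sigma_rel` against `r` on log-log axes.
#'
#' @param radii vector of radii (um).
#' @param model template [fluctuation_model()] (its radius is replaced).
#' @param ... passed to [simulate_fluctuations()].
#' @return List with `table` (data frame `radius`, `mean_psi`, `sigma_rel`,
#'   `se`) and `exponent` (fitted slope of `log sigma_rel` vs `log r`).
#' @export
fluctuation_radius_sweep <- function(radii = c(0.25, 0.5, 1, 2),
                                     model = fluctuation_model(), ...) {
  rows <- lapply(radii, function(r) {
    m <- model; m$radius <- r
    res <- simulate_fluctuations(m, ...)
    data.frame(radius = r, mean_psi = res$mean_psi,
               sigma_rel = res$sigma_rel, se = res$se_sigma_rel)
  })
  tab <- do.call(rbind, rows)
  expo <- unname(coef(lm(log(sigma_rel) ~ log(radius), data = tab))[2])
  list(table = tab, exponent = expo)
}

#' Spin-coupled ensemble of mitochondrial agents
#'
#' Binary agents `s = +1` (functional) / `-1` (failed) with energy
#' `E = -J sum_edges s_i s_j - h sum_i s_i`: the coupling `J >= 0` makes an
#' agent prefer the state of its neighbours, the bias `h > 0` favours the
#' functional state, and `beta_inv` is the noise scale of the single-flip
#' dynamics.
#'
#' @param n_agents number of agents `N >= 1`.
#' @param topology `"complete"`, `"chain"`, or `"edges"` (supply `edges`);
#'   use [spin_from_lattice()] to couple along the largest cluster of a
#'   lattice snapshot.
#' @param coupling ferromagnetic coupling `J >= 0`.
#' @param bias field `h` favouring the functional state.
#' @param beta_inv noise parameter (> 0); larger means noisier flips.
#' @param horizon time horizon `T` for the catastrophe probability.
#' @param edges optional 2-column integer matrix of 1-based agent pairs
#'   (used with `topology = "edges"`).
#' @return An object of class `spin_ensemble`.
#' @export
spin_ensemble <- function(n_agents, topology = c("complete", "chain", "edges"),
                          coupling = 0.5, bias = 0.3, beta_inv = 1,
                          horizon = 20, edges = NULL) {
  topology <- match.arg(topology)
  if (n_agents < 1) stop("`n_agents` must be >= 1")
  if (coupling < 0) stop("`coupling` must be >= 0")
  if (beta_inv <= 0) stop("`beta_inv` must be > 0")
  if (horizon <= 0) stop("`horizon` must be > 0")
  N <- as.integer(n_agents)
  edges <- switch(topology,
    complete = if (N > 1) t(utils::combn(N, 2)) else matrix(0L, 0, 2),
    chain = if (N > 1) cbind(1:(N - 1), 2:N) else matrix(0L, 0, 2),
    edges = {
      if (is.null(edges)) stop("supply `edges` with topology = \"edges\"")
      storage.mode(edges) <- "integer"
      if (any(edges < 1 | edges > N)) stop("edge endpoints out of range")
      edges
    })
  structure(list(n_agents = N, topology = topology, coupling = coupling,
                 bias = bias, beta_inv = beta_inv, horizon = horizon,
                 edges = edges),
            class = "spin_ensemble")
}

#' Spin ensemble coupled along a lattice cluster
#'
#' Takes the largest connected cluster of the lattice snapshot and couples
#' one agent per cluster node along the cluster's on-bonds.
#'
#' @param lattice a [make_lattice()] object.
#' @param ... further arguments to [spin_ensemble()] (`coupling`, `bias`, ...).
#' @return A `spin_ensemble` with `topology = "edges"`.
#' @export
spin_from_lattice <- function(lattice, ...) {
  g <- lattice_graph(lattice, on_only = TRUE)
  comp <- igraph::components(g)
  keep <- which(comp$membership == which.max(comp$csize))
  sub <- igraph::induced_subgraph(g, keep)
  spin_ensemble(igraph::vcount(sub), topology = "edges",
                edges = igraph::as_edgelist(sub, names = FALSE), ...)
}

spin_flip_rate <- function(dE, theta, metropolis) {
  if (metropolis) pmin(1, exp(-dE / theta)) else 1 / (1 + exp(dE / theta))
}

# Sparse generator of the single-flip chain over the 2^N spin states.
# State index: bitmask + 1, bit i set = agent i failed. If `absorbing`, the
# all-failed state has no outflow.
spin_generator <- function(ens, dynamics = c("glauber", "metropolis"),
                           absorbing = TRUE) {
  dynamics <- match.arg(dynamics)
  N <- ens$n_agents
  if (N > 12) stop("exact method limited to N <= 12 (state space 2^N)")
  nst <- 2^N
  adj <- vector("list", N)
  for (i in seq_len(N)) adj[[i]] <- integer(0)
  if (nrow(ens$edges) > 0) {
    for (e in seq_len(nrow(ens$edges))) {
      a <- ens$edges[e, 1]; b <- ens$edges[e, 2]
      adj[[a]] <- c(adj[[a]], b)
      adj[[b]] <- c(adj[[b]], a)
    }
  }
  all_failed <- nst - 1L
  ii <- jj <- integer(0)
  xx <- numeric(0)
  for (st in 0:(nst - 1)) {
    if (absorbing && st == all_failed) next
    s <- ifelse(bitwAnd(st, bitwShiftL(1L, 0:(N - 1))) > 0, -1, 1)
    for (i in seq_len(N)) {
      f <- ens$bias + ens$coupling * sum(s[adj[[i]]])
      dE <- 2 * s[i] * f
      rate <- spin_flip_rate(dE, ens$beta_inv, dynamics == "metropolis")
      to <- bitwXor(st, bitwShiftL(1L, i - 1L))
      ii <- c(ii, st + 1L); jj <- c(jj, to + 1L); xx <- c(xx, rate)
    }
  }
  Q <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(nst, nst))
  Matrix::diag(Q) <- Matrix::diag(Q) - Matrix::rowSums(Q)
  Q
}

#' Probability of catastrophic loss of function
#'
#' Probability that, starting from all agents functional, every agent is in
#' the failed state at some time at or before the horizon `T`, under
#' single-flip Glauber (heat-bath) or Metropolis dynamics. The all-failed
#' state is treated as absorbing for this first-passage computation.
#'
#' `method = "exact"` solves the master equation on the full `2^N` state
#' space (N <= 12); `method = "monte_carlo"` samples trajectories and
#' reports a binomial standard error.
#'
#' @param ens a [spin_ensemble()].
#' @param method `"exact"` or `"monte_carlo"`.
#' @param n_reps Monte Carlo trajectories.
#' @param dynamics `"glauber"` (default) or `"metropolis"`; both satisfy
#'   detailed balance and agree in stationarity.
#' @param seed optional integer seed (Monte Carlo only).
#' @return List with `p` and, for Monte Carlo, `se` and `n_reps`.
#' @export
spin_failure_probability <- function(ens, method = c("exact", "monte_carlo"),
                                     n_reps = 2000,
                                     dynamics = c("glauber", "metropolis"),
                                     seed = NULL) {
  method <- match.arg(method)
  dynamics <- match.arg(dynamics)
  stopifnot(inherits(ens, "spin_ensemble"))
  N <- ens$n_agents
  if (method == "exact") {
    Q <- spin_generator(ens, dynamics, absorbing = TRUE)
    nst <- 2^N
    p0 <- numeric(nst); p0[1] <- 1          # all functional
    tQ <- Matrix::t(Q)
    out <- deSolve::ode(y = p0, times = c(0, ens$horizon),
                        func = function(t, y, parms)
                          list(as.vector(parms %*% y)),
                        parms = tQ, rtol = 1e-10, atol = 1e-12)
    list(p = unname(out[nrow(out), nst + 1]))
  } else {
    if (!is.null(seed)) set.seed(seed)
    res <- cpp_spin_mc(N, ens$edges - 1L, ens$coupling, ens$bias,
                       ens$beta_inv, ens$horizon, as.integer(n_reps),
                       dynamics == "metropolis")
    phat <- res$absorbed / res$n_reps
    list(p = phat, se = sqrt(phat * (1 - phat) / res$n_reps),
         n_reps = res$n_reps)
  }
}

#' Independent-agent catastrophe probability (closed form)
#'
#' For `J = 0` the agents are exchangeable and independent, so the number of
#' failed agents is a birth-death chain on `0..N` with up-rate
#' `(N - k) q` and down-rate `k r`, where `q` and `r` are the single-agent
#' fail and recover rates. The first-passage probability to `k = N` by the
#' horizon is computed exactly on this `(N + 1)`-state chain — an
#' independent, much smaller computation than the `2^N` master equation,
#' which the full model must reproduce at `J = 0`.
#'
#' @inheritParams spin_failure_probability
#' @return Probability of all agents failed at or before the horizon.
#' @export
spin_independent_closed_form <- function(ens,
                                         dynamics = c("glauber", "metropolis")) {
  dynamics <- match.arg(dynamics)
  N <- ens$n_agents
  metro <- dynamics == "metropolis"
  q <- spin_flip_rate(2 * ens$bias, ens$beta_inv, metro)    # functional -> failed
  r <- spin_flip_rate(-2 * ens$bias, ens$beta_inv, metro)   # failed -> functional
  Q <- matrix(0, N + 1, N + 1)
  for (k in 0:(N - 1)) Q[k + 1, k + 2] <- (N - k) * q
  for (k in 1:(N - 1)) if (N > 1) Q[k + 1, k] <- k * r
  diag(Q) <- -rowSums(Q)
  Q[N + 1, ] <- 0                      # absorbing at all failed
  p0 <- numeric(N + 1); p0[1] <- 1
  out <- deSolve::ode(y = p0, times = c(0, ens$horizon),
                      func = function(t, y, parms) list(as.vector(t(parms) %*% y)),
                      parms = Q, rtol = 1e-12, atol = 1e-14)
  unname(out[nrow(out), N + 2])
}

#' Compare the coupled group with independent agents and a single agent
#'
#' Reports the catastrophic-failure probability at identical
#' `(h, beta_inv, T)` for: the coupled group; the same agents with the
#' coupling removed (`J = 0`); and a single agent (for which the first
#' failure is the catastrophe, `P = 1 - exp(-q T)`).
#'
#' @param ens a [spin_ensemble()] with `n_agents >= 1`.
#' @param method passed to [spin_failure_probability()].
#' @param ... further arguments to [spin_failure_probability()].
#' @return Data frame with columns `case`, `p` (and `se` where applicable).
#' @export
group_vs_individual <- function(ens, method = "exact",
                                dynamics = c("glauber", "metropolis"), ...) {
  dynamics <- match.arg(dynamics)
  p_group <- spin_failure_probability(ens, method = method,
                                      dynamics = dynamics, ...)
  ens0 <- ens; ens0$coupling <- 0
  p_indep <- spin_failure_probability(ens0, method = method,
                                      dynamics = dynamics, ...)
  q <- spin_flip_rate(2 * ens$bias, ens$beta_inv, dynamics == "metropolis")
  p_single <- 1 - exp(-q * ens$horizon)
  data.frame(case = c("group", "independent", "single"),
             p = c(p_group$p, p_indep$p, p_single),
             se = c(p_group$se %||% NA_real_, p_indep$se %||% NA_real_,
                    NA_real_))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
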