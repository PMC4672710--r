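# "Blind surveillance" quality control: healthy/dysfunctional populations in
# fragmented and networked compartments, with non-selective fission,
# function-selective fusion, size-selective but function-blind mitophagy, and
# biogenesis keeping the total constant.
#
# State (population fractions): h_f, h_n, d_f, d_n
#   (healthy/dysfunctional x fragmented/networked), summing to 1.
# Default dynamics:
#   dh_n/dt =  lambda_fus * h_f - lambda_fis * h_n
#   dd_n/dt =  s * lambda_fus * d_f - lambda_fis * d_n
#   dh_f/dt =  lambda_fis * h_n - lambda_fus * h_f - delta * h_f - mu * h_f + B
#   dd_f/dt =  lambda_fis * d_n - s * lambda_fus * d_f + delta * h_f - mu * d_f
# with biogenesis B = mu * (h_f + d_f) replacing mitophagied mass as healthy
# fragments, so the total is conserved exactly. Damage (delta) acts on
# fragmented units by default; the `damage_networked` flag adds
# -delta * h_n / +delta * h_n terms to the networked pair (sensitivity
# variant).

#' Quality-control model parameters
#'
#' @param lambda_fus fusion rate of healthy fragmented units (1/time).
#' @param s fusion selectivity in `[0, 1]`: dysfunctional units fuse at
#'   `s * lambda_fus`. `s < 1` encodes "a functional mitochondrion is more
#'   likely to fuse"; `s = 1` is function-blind fusion.
#' @param lambda_fis fission rate (1/time), identical for both types
#'   (fission is blind).
#' @param mu mitophagy rate of fragmented units (1/time), identical for both
#'   types (mitophagy is size-selective but function-blind).
#' @param delta damage rate, healthy -> dysfunctional (1/time).
#' @param damage_networked if `TRUE`, networked healthy units are damaged at
#'   rate `delta` as well; by default damage manifests only in the
#'   fragmented compartment.
#' @param biogenesis `"healthy"` (default): mitophagied mass is replaced by
#'   fresh healthy fragments; `"proportional"`: replacement mass is split
#'   between healthy and dysfunctional fragments in proportion to the
#'   current population composition (a null model with no biogenesis
#'   selection).
#' @return An object of class `qc_params`.
#' @export
qc_params <- function(lambda_fus = 1, s = 0.2, lambda_fis = 0.5,
                      mu = 0.3, delta = 0.05,
                      damage_networked = FALSE,
                      biogenesis = c("healthy", "proportional")) {
  biogenesis <- match.arg(biogenesis)
  if (any(c(lambda_fus, lambda_fis, mu, delta) < 0))
    stop("rates must be non-negative")
  if (s < 0 || s > 1) stop("`s` must lie in [0, 1]")
  structure(list(lambda_fus = lambda_fus, s = s, lambda_fis = lambda_fis,
                 mu = mu, delta = delta,
                 damage_networked = damage_networked, biogenesis = biogenesis),
            class = "qc_params")
}

#' Quality-control population state
#'
#' @param h_f,h_n,d_f,d_n non-negative population fractions
#'   (healthy/dysfunctional x fragmented/networked); must sum to 1.
#' @return A named numeric vector of class `qc_state`.
#' @export
qc_state <- function(h_f, h_n, d_f, d_n) {
  x <- c(h_f = h_f, h_n = h_n, d_f = d_f, d_n = d_n)
  if (any(x < 0)) stop("state fractions must be non-negative")
  if (abs(sum(x) - 1) > 1e-8) stop("state fractions must sum to 1")
  structure(x, class = "qc_state")
}

#' Right-hand side of the quality-control ODE
#'
#' @param state named numeric with entries `h_f`, `h_n`, `d_f`, `d_n`.
#' @param params a [qc_params()].
#' @return Named derivative vector; its components sum to zero identically
#'   (total mass conserved).
#' @export
qc_rhs <- function(state, params) {
  if (any(state < -1e-9)) stop("negative state entries")
  state <- pmax(state, 0)    # absorb integrator round-off at the boundary
  h_f <- state[["h_f"]]; h_n <- state[["h_n"]]
  d_f <- state[["d_f"]]; d_n <- state[["d_n"]]
  lf <- params$lambda_fus; lfis <- params$lambda_fis
  s <- params$s; mu <- params$mu; delta <- params$delta
  dmg_n <- if (params$damage_networked) delta else 0
  B <- mu * (h_f + d_f)
  if (params$biogenesis == "healthy") {
    B_h <- B; B_d <- 0
  } else {
    H <- h_f + h_n
    B_h <- B * H; B_d <- B * (1 - H)
  }
  c(h_f = lfis * h_n - lf * h_f - delta * h_f - mu * h_f + B_h,
    h_n = lf * h_f - lfis * h_n - dmg_n * h_n,
    d_f = lfis * d_n - s * lf * d_f + delta * h_f - mu * d_f + B_d,
    d_n = s * lf * d_f - lfis * d_n + dmg_n * h_n)
}

#' Integrate the quality-control ODE
#'
#' @param params a [qc_params()].
#' @param state0 initial state (default: all healthy, split between
#'   compartments by the fusion/fission balance).
#' @param times output times (default `seq(0, 200, by = 1)`).
#' @return A `deSolve` matrix of the trajectory.
#' @export
qc_run <- function(params, state0 = NULL, times = seq(0, 200, by = 1)) {
  if (is.null(state0)) {
    phi <- params$lambda_fis / (params$lambda_fis + params$lambda_fus + 1e-12)
    state0 <- c(h_f = phi, h_n = 1 - phi, d_f = 0, d_n = 0)
  }
  deSolve::ode(y = state0[c("h_f", "h_n", "d_f", "d_n")], times = times,
               func = function(t, y, p) list(qc_rhs(y, p)), parms = params,
               rtol = 1e-10, atol = 1e-12)
}

#' Steady state of the quality-control model
#'
#' Finds the fixed point of [qc_rhs()] on the population simplex by damped
#' Newton iteration in the three free coordinates (the fourth follows from
#' mass conservation), started from several points of the simplex; falls
#' back to long ODE integration followed by Newton polishing. Multi-start
#' agreement is used as a uniqueness check.
#'
#' @param params a [qc_params()].
#' @param tol convergence tolerance on the residual (default `1e-10`).
#' @return A `qc_state` with attributes `h_star` (steady healthy fraction
#'   `h_f + h_n`), `d_frag_share` (dysfunctional share among fragmented
#'   units) and `d_net_share` (dysfunctional share among networked units).
#' @export
qc_steady_state <- function(params, tol = 1e-10) {
  free <- c("h_f", "h_n", "d_f")
  resid <- function(x3) {
    st <- c(x3, d_n = max(1 - sum(x3), 0))
    names(st) <- c(free, "d_n")
    qc_rhs(pmax(st, 0), params)[free]
  }
  newton <- function(x3) {
    for (it in 1:200) {
      r <- resid(x3)
      if (max(abs(r)) < tol) return(list(x = x3, ok = TRUE))
      J <- matrix(0, 3, 3)
      hstep <- 1e-7
      for (j in 1:3) {
        xp <- x3; xp[j] <- xp[j] + hstep
        J[, j] <- (resid(xp) - r) / hstep
      }
      dx <- tryCatch(solve(J, -r), error = function(e) NULL)
      if (is.null(dx)) return(list(x = x3, ok = FALSE))
      lam <- 1
      repeat {
        xn <- x3 + lam * dx
        if (all(xn > -1e-9) && sum(xn) < 1 + 1e-9) break
        lam <- lam / 2
        if (lam < 1e-8) break
      }
      x3 <- pmin(pmax(xn, 0), 1)
    }
    list(x = x3, ok = max(abs(resid(x3))) < tol * 100)
  }
  starts <- list(c(h_f = 0.25, h_n = 0.25, d_f = 0.25),
                 c(h_f = 0.7, h_n = 0.25, d_f = 0.02),
                 c(h_f = 0.05, h_n = 0.05, d_f = 0.5))
  sols <- list()
  for (st in starts) {
    res <- newton(st)
    if (res$ok) sols[[length(sols) + 1]] <- res$x
  }
  if (length(sols) == 0) {
    # fall back: integrate long, then polish
    traj <- qc_run(params, times = c(0, 2000, 4000))
    y <- traj[nrow(traj), c("h_f", "h_n", "d_f")]
    res <- newton(y)
    if (!res$ok) stop("steady-state search did not converge")
    sols <- list(res$x)
  }
  spread <- if (length(sols) > 1)
    max(vapply(sols, function(s) max(abs(s - sols[[1]])), numeric(1))) else 0
  if (spread > 1e-6)
    warning("multi-start solutions differ; steady state may not be unique")
  x <- sols[[1]]
  st <- qc_state(h_f = x[["h_f"]], h_n = x[["h_n"]], d_f = x[["d_f"]],
                 d_n = max(1 - sum(x), 0))
  frag <- st[["h_f"]] + st[["d_f"]]
  net <- st[["h_n"]] + st[["d_n"]]
  attr(st, "h_star") <- st[["h_f"]] + st[["h_n"]]
  attr(st, "d_frag_share") <- if (frag > 0) st[["d_f"]] / frag else NA_real_
  attr(st, "d_net_share") <- if (net > 0) st[["d_n"]] / net else NA_real_
  st
}

#' Closed-form steady state for the default configuration
#'
#' For the default model (biogenesis as healthy fragments, damage acting on
#' fragmented units) the steady state solves in closed form; the steady
#' healthy fraction is
#' `h* = 1 / (1 + (delta/mu) * (lambda_fis + s*lambda_fus) /
#'   (lambda_fis + lambda_fus))`.
#' At `s = 1` this collapses to `mu / (mu + delta)` independently of the
#' fusion rate — blind fusion confers no surveillance benefit — while for
#' `s < 1` it increases monotonically with `lambda_fus`.
#'
#' @param params a [qc_params()] with default `damage_networked = FALSE` and
#'   `biogenesis = "healthy"`; other configurations have no closed form here.
#' @return Steady healthy fraction `h*`.
#' @export
qc_steady_analytic <- function(params) {
  if (params$damage_networked || params$biogenesis != "healthy")
    stop("closed form only available for the default configuration")
  if (params$mu <= 0) {
    if (params$delta == 0) return(1)
    return(0)  # damage without removal: dysfunction absorbs everything
  }
  lf <- params$lambda_fus; lfis <- params$lambda_fis
  if (lf + lfis == 0) return(params$mu / (params$mu + params$delta))
  1 / (1 + (params$delta / params$mu) *
         (lfis + params$s * lf) / (lfis + lf))
}

#' Sweep the fusion rate and report the steady healthy fraction
#'
#' @param params a [qc_params()] (its `lambda_fus` is replaced by each grid
#'   value in turn).
#' @param lambda_fus_grid increasing vector of fusion rates.
#' @return Data frame with columns `lambda_fus`, `h_star`, `d_frag_share`,
#'   `d_net_share`.
#' @export
sweep_fusion <- function(params, lambda_fus_grid) {
  if (is.unsorted(lambda_fus_grid)) stop("`lambda_fus_grid` must be increasing")
  rows <- lapply(lambda_fus_grid, function(lf) {
    p <- params; p$lambda_fus <- lf
    st <- qc_steady_state(p)
    data.frame(lambda_fus = lf, h_star = attr(st, "h_star"),
               d_frag_share = attr(st, "d_frag_share"),
               d_net_share = attr(st, "d_net_share"))
  })
  do.call(rbind, rows)
}
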