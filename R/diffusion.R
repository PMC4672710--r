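# Tracer diffusion on the fluctuating lattice, and the dynamic
# effective-medium (mean-field) prediction of the apparent diffusion
# coefficient D(p, tau).

#' Walker simulation configuration
#'
#' @param lambda_dif total hop-attempt rate per walker (1/time). A free
#'   walker on a `d`-dimensional lattice has `D = lambda_dif / (2 d)`
#'   (lattice constant 1).
#' @param n_walkers number of walkers (>= 1).
#' @param t_max simulated time horizon.
#' @param record_times increasing times at which the mean squared
#'   displacement is recorded; default 41 equally spaced times in
#'   `[0, t_max]`.
#' @param seed optional integer seed.
#' @return An object of class `walker_config`.
#' @export
walker_config <- function(lambda_dif = 1, n_walkers = 500, t_max = 100,
                          record_times = NULL, seed = NULL) {
  if (lambda_dif <= 0) stop("`lambda_dif` must be > 0")
  if (n_walkers < 1) stop("`n_walkers` must be >= 1")
  if (t_max <= 0) stop("`t_max` must be > 0")
  if (is.null(record_times))
    record_times <- seq(0, t_max, length.out = 41)
  record_times <- sort(unique(record_times))
  if (any(record_times < 0) || any(record_times > t_max))
    stop("`record_times` must lie in [0, t_max]")
  structure(list(lambda_dif = lambda_dif, n_walkers = as.integer(n_walkers),
                 t_max = t_max, record_times = record_times, seed = seed),
            class = "walker_config")
}

#' Simulate tracer walkers on a fluctuating lattice
#'
#' Continuous-time blind-ant random walkers: each walker attempts hops at
#' total rate `lambda_dif`, choosing one of its `2 d` neighbours uniformly;
#' the hop succeeds iff the connecting bond is currently on. Bond flicker and
#' walker hops are co-simulated exactly, event by event (bond states are
#' propagated with the exact two-state transition law to each query time, so
#' there is no discretisation bias). Walkers start at uniformly random nodes
#' and track their unwrapped displacement; periodic boundaries are
#' recommended for diffusion runs.
#'
#' @param lattice a [make_lattice()] object (its current bond states seed the
#'   simulation; for `tau = Inf` the lattice stays frozen).
#' @param config a [walker_config()].
#' @return An object of class `msd_curve`: data frame with columns `time`,
#'   `msd` (lattice-constant^2 units) and `stderr`, with attributes
#'   `n_walkers`, `d` and `lambda_dif`.
#' @export
simulate_walkers <- function(lattice, config) {
  stopifnot(inherits(lattice, "network_lattice"),
            inherits(config, "walker_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  L <- lattice$L; d <- lattice$d; N <- L^d
  nb_full <- d * N
  exists <- logical(nb_full)
  state <- logical(nb_full)
  slot <- lattice$bonds$axis * N + lattice$bonds$from
  exists[slot + 1L] <- TRUE
  state[slot + 1L] <- lattice$bonds$state
  res <- cpp_simulate_walkers(L, d, exists, state,
                              lattice$p, lattice$tau, config$lambda_dif,
                              config$n_walkers, config$record_times,
                              TRUE)
  out <- data.frame(time = config$record_times, msd = res$msd,
                    stderr = res$stderr)
  attr(out, "n_walkers") <- config$n_walkers
  attr(out, "d") <- d
  attr(out, "lambda_dif") <- config$lambda_dif
  class(out) <- c("msd_curve", "data.frame")
  out
}

#' Apparent diffusion coefficient from an MSD curve
#'
#' Weighted least-squares fit of `msd ~ time` over a fit window; the apparent
#' diffusion coefficient is the slope divided by `2 d`. Points are weighted
#' by `1 / stderr^2` where standard errors are available and positive.
#' A negative fitted slope (possible for a confined walk plus noise) is
#' clipped to zero with a warning.
#'
#' @param msd an `msd_curve` from [simulate_walkers()], or any data frame
#'   with columns `time`, `msd` and optionally `stderr`.
#' @param fit_window numeric `c(t_lo, t_hi)`; default the upper half of the
#'   recorded times (late-time slope).
#' @param d lattice dimension; taken from the curve's attribute if present.
#' @return An object of class `diffusion_estimate`: list with `D_app`,
#'   `fit_window`, `r_squared`, `slope_se`.
#' @export
estimate_D <- function(msd, fit_window = NULL, d = attr(msd, "d")) {
  if (is.null(d)) stop("`d` must be supplied when the curve carries no dimension")
  tt <- msd$time
  if (is.null(fit_window)) fit_window <- c(max(tt) / 2, max(tt))
  keep <- tt >= fit_window[1] & tt <= fit_window[2]
  if (!any(keep)) stop("empty fit window")
  if (sum(keep) < 5)
    warning("fewer than 5 recorded times in the fit window")
  df <- data.frame(time = tt[keep], msd = msd$msd[keep])
  w <- NULL
  if (!is.null(msd$stderr)) {
    se <- msd$stderr[keep]
    if (all(is.finite(se)) && all(se > 0)) w <- 1 / se^2
  }
  fit <- if (is.null(w)) lm(msd ~ time, data = df)
         else lm(msd ~ time, data = df, weights = w)
  slope <- unname(coef(fit)[2])
  # an exactly linear curve makes summary()/vcov() warn about a perfect fit
  slope_se <- suppressWarnings(
    tryCatch(sqrt(diag(vcov(fit)))[2], error = function(e) NA_real_))
  r2 <- suppressWarnings(summary(fit)$r.squared)
  if (is.na(slope)) stop("fit failed: degenerate window")
  if (slope < 0) {
    warning("negative fitted slope clipped to 0")
    slope <- 0
  }
  structure(list(D_app = slope / (2 * d), fit_window = fit_window,
                 r_squared = r2, slope_se = unname(slope_se) / (2 * d)),
            class = "diffusion_estimate")
}

#' @export
print.diffusion_estimate <- function(x, ...) {
  cat(sprintf("diffusion_estimate: D_app = %.4g (window [%g, %g], R^2 = %.3f)\n",
              x$D_app, x$fit_window[1], x$fit_window[2], x$r_squared))
  invisible(x)
}

# s * Laplace transform of the return probability of a free continuous-time
# walk on the d-dimensional hypercubic lattice with per-bond rate wm:
#   P(0, t) = [exp(-2 wm t) I_0(2 wm t)]^d .
s_ptilde <- function(s, wm, d) {
  if (wm <= 0) return(1)
  # substitute u = s t so the integrand has unit scale for any s
  f <- function(u) exp(-u) * besselI(2 * wm * u / s, 0, expon.scaled = TRUE)^d
  stats::integrate(f, 0, Inf, rel.tol = 1e-10, subdivisions = 2000L)$value
}

#' Dynamic effective-medium prediction of the diffusion coefficient
#'
#' Mean-field prediction `D(p, tau)` for a tracer on a lattice whose bonds
#' are on with probability `p` and relax with time `tau`. The calculation
#' combines two standard ingredients of dynamic bond percolation theory:
#'
#' 1. The frequency-dependent single-bond effective-medium self-consistency
#'    for binary bond rates `w` in `{1, 0}` (fractions `p`, `1 - p`):
#'    `sum_w P(w) (w - w_m) / (w + (1/gamma(s) - 1) w_m) = 0`, with
#'    `gamma(s) = (2/z) (1 - s * Ptilde(0, s))`, `z = 2 d`, and
#'    `Ptilde(0, s)` the Laplace-transformed return probability of the free
#'    walk on the effective lattice. For a binary distribution this reduces
#'    to the scalar fixed point `w_m = p - (1 - p) / (1/gamma - 1)`.
#' 2. The renewal closure for dynamically rearranging bonds: the long-time
#'    diffusion coefficient of the fluctuating lattice equals the
#'    frequency-dependent effective rate of the static medium evaluated at
#'    the bond relaxation rate, `s = 1/tau`.
#'
#' Limits (all exact in the implementation): `p = 1` gives
#' `lambda_dif / (2 d)`; `tau = Inf` reduces to the static EMA
#' `(z p / 2 - 1) / (z / 2 - 1)` times the free value (i.e. `2 p - 1` for the
#' square lattice, vanishing at `p <= 1/2`); `tau -> 0` gives
#' `p * lambda_dif / (2 d)` (annealed limit: every hop attempt independently
#' finds an on-bond with probability `p`).
#'
#' @param p bond probability, in `[0, 1]` (vectorised).
#' @param tau bond relaxation time, `(0, Inf]`.
#' @param lambda_dif total hop-attempt rate of the tracer.
#' @param d lattice dimension, 2 or 3.
#' @return Predicted diffusion coefficient(s), lattice-constant^2 per time.
#' @examples
#' ema_diffusion(0.75, Inf)           # 0.5 * 0.25: static EMA, 2p - 1
#' ema_diffusion(0.5, 1e-6)           # ~ 0.5 * 0.25: fast-flicker limit
#' @export
ema_diffusion <- function(p, tau, lambda_dif = 1, d = 2) {
  if (!d %in% c(2, 3)) stop("`d` must be 2 or 3")
  if (any(p < 0 | p > 1)) stop("`p` must lie in [0, 1]")
  if (any(tau <= 0)) stop("`tau` must be positive")
  if (lambda_dif <= 0) stop("`lambda_dif` must be > 0")
  z <- 2 * d
  w_free <- lambda_dif / z       # per-bond rate of an open bond
  one <- function(p, tau) {
    if (p <= 0) return(0)
    if (p >= 1) return(lambda_dif / (2 * d))
    if (is.infinite(tau))
      return(max((z * p / 2 - 1) / (z / 2 - 1), 0) * w_free)
    s <- 1 / tau
    g <- function(W) {
      gam <- (2 / z) * (1 - s_ptilde(s, W * w_free, d))
      A <- 1 / gam - 1
      W - (p - (1 - p) / A)
    }
    # a root exists in (0, 1]: g < 0 near 0 (A -> Inf), g >= 0 at W = 1
    stats::uniroot(g, c(1e-12, 1), tol = 1e-12)$root * w_free
  }
  if (length(tau) == 1) tau <- rep(tau, length(p))
  vapply(seq_along(p), function(i) one(p[i], tau[i]), numeric(1))
}

#' Diffusion coefficient over a (p, tau) grid
#'
#' Evaluates `D(p, tau)` on a grid either by the agent-based walker
#' simulation or by the effective-medium approximation, reproducing the
#' characteristic surface: switch-like in `p` near the percolation threshold
#' for static bonds, nearly linear in `p` for fast flicker, and increasing
#' as `tau` decreases at fixed `p`.
#'
#' @param p_grid,tau_grid non-empty grids (`tau` may include `Inf`).
#' @param method `"ema"` or `"sim"`.
#' @param lambda_dif tracer hop-attempt rate.
#' @param d lattice dimension.
#' @param L lattice side for simulation (periodic boundaries).
#' @param n_walkers,t_max simulation effort per replicate lattice.
#' @param n_rep independent lattice replicates per grid cell (the estimate
#'   and its standard error are computed across replicates; essential for
#'   static lattices, whose conductivity varies between disorder
#'   realisations).
#' @param seed optional integer seed (simulation only).
#' @return Data frame with columns `p`, `tau`, `method`, `D`, `stderr`
#'   (stderr is `NA` for the EMA).
#' @export
diffusion_surface <- function(p_grid, tau_grid, method = c("ema", "sim"),
                              lambda_dif = 1, d = 2, L = 64,
                              n_walkers = 400, t_max = 200, n_rep = 4,
                              seed = NULL) {
  method <- match.arg(method)
  if (length(p_grid) == 0 || length(tau_grid) == 0) stop("grids must be non-empty")
  if (!is.null(seed)) set.seed(seed)
  grid <- expand.grid(p = p_grid, tau = tau_grid)
  out <- lapply(seq_len(nrow(grid)), function(i) {
    p <- grid$p[i]; tau <- grid$tau[i]
    if (method == "ema") {
      data.frame(p = p, tau = tau, method = "ema",
                 D = ema_diffusion(p, tau, lambda_dif, d), stderr = NA_real_)
    } else {
      Ds <- vapply(seq_len(n_rep), function(r) {
        lat <- make_lattice(L, d, p = p, tau = tau, boundary = "periodic")
        cfg <- walker_config(lambda_dif, n_walkers, t_max)
        estimate_D(simulate_walkers(lat, cfg))$D_app
      }, numeric(1))
      data.frame(p = p, tau = tau, method = "sim", D = mean(Ds),
                 stderr = if (n_rep > 1) sd(Ds) / sqrt(n_rep) else NA_real_)
    }
  })
  do.call(rbind, out)
}

#' Root-mean-squared diffusion range during a transient fusion contact
#'
#' Back-of-the-envelope range of a matrix protein during a "kiss-and-run"
#' fusion event: `sqrt(2 d D t)` in `d` dimensions. With a GFP-like matrix
#' protein (`D` around 20-30 um^2/s) and the mean contact duration of 45 s,
#' the range is tens of micrometres — ample for matrix-content equilibration
#' without large-scale fusion.
#'
#' @param D_protein diffusion coefficient (physical units, e.g. um^2/s);
#'   non-negative.
#' @param t_contact contact duration (> 0).
#' @param d spatial dimension (3 for a mitochondrion's matrix volume).
#' @return RMS displacement, in the length unit implied by `D_protein`.
#' @examples
#' kiss_and_run_range(20, 45, 3)   # ~73.5 um
#' @export
kiss_and_run_range <- function(D_protein, t_contact, d = 3) {
  if (any(D_protein < 0)) stop("`D_protein` must be non-negative")
  if (any(t_contact <= 0)) stop("`t_contact` must be positive")
  if (d < 1) stop("`d` must be >= 1")
  sqrt(2 * d * D_protein * t_contact)
}
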