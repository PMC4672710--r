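# Fluctuating bond lattice of mitochondrial units.
#
# Nodes are mitochondrial units on a d-dimensional hypercubic lattice; a bond
# between neighbouring units is "on" when the two units are fused. Each bond
# flickers independently as a two-state Markov process with on-rate lambda_fus
# and off-rate lambda_fis, so the stationary on-probability is
#   p = lambda_fus / (lambda_fus + lambda_fis)
# and the relaxation time of the flicker is
#   tau = 1 / (lambda_fus + lambda_fis).

node_index <- function(coords, L) {
  # coords: matrix with one row per node, 0-based; returns 0-based index,
  # first coordinate fastest
  as.integer(coords %*% L^(seq_len(ncol(coords)) - 1))
}

node_coords <- function(idx, L, d) {
  # inverse of node_index
  out <- matrix(0L, nrow = length(idx), ncol = d)
  rest <- as.integer(idx)
  for (k in seq_len(d)) {
    out[, k] <- rest %% L
    rest <- rest %/% L
  }
  out
}

# Bond table for a hypercubic lattice. Each bond is stored once, keyed by its
# lexicographically smaller endpoint ("from") and its axis.
bond_table <- function(L, d, boundary) {
  N <- L^d
  coords <- node_coords(0:(N - 1), L, d)
  from <- to <- axis <- integer(0)
  for (a in seq_len(d)) {
    keep <- if (boundary == "open") coords[, a] < L - 1 else rep(TRUE, N)
    nb <- coords[keep, , drop = FALSE]
    nb[, a] <- (nb[, a] + 1L) %% L
    from <- c(from, node_index(coords[keep, , drop = FALSE], L))
    to <- c(to, node_index(nb, L))
    axis <- c(axis, rep(a - 1L, sum(keep)))
  }
  list(from = from, to = to, axis = axis)
}

#' Create a fluctuating bond lattice of mitochondrial units
#'
#' Builds an `L^d` hypercubic lattice whose bonds (fusion links between
#' neighbouring mitochondrial units) are initialised in the stationary state:
#' each bond is on independently with probability
#' `p = lambda_fus / (lambda_fus + lambda_fis)`.
#'
#' Either supply both rates, or supply `p` (and optionally `tau`) directly;
#' `p` and `tau` parameterise the same two-state bond process through
#' `lambda_fus = p / tau` and `lambda_fis = (1 - p) / tau`. `tau = Inf`
#' gives a static (quenched) lattice.
#'
#' @param L side length (units per dimension), integer >= 2.
#' @param d lattice dimension, 2 or 3.
#' @param lambda_fus,lambda_fis fusion (bond on) and fission (bond off) rates
#'   per bond, in 1/time. Non-negative; not both zero unless `p` is given.
#' @param p optional stationary bond probability in `[0, 1]`; overrides the
#'   rate pair together with `tau`.
#' @param tau relaxation time of the bond flicker (only used with `p`);
#'   `Inf` for a static lattice.
#' @param boundary `"open"` (spanning is well defined) or `"periodic"`
#'   (preferred for diffusion runs).
#' @param seed optional integer seed passed to [set.seed()].
#' @return An object of class `network_lattice` with fields `L`, `d`,
#'   `boundary`, `lambda_fus`, `lambda_fis`, `p`, `tau`, `time`, and `bonds`
#'   (a list with `from`, `to`, `axis`, `state`; nodes are 0-based indices,
#'   first coordinate fastest).
#' @examples
#' lat <- make_lattice(8, 2, lambda_fus = 2, lambda_fis = 2, seed = 1)
#' lat$p    # 0.5
#' @export
make_lattice <- function(L, d = 2, lambda_fus = NULL, lambda_fis = NULL,
                         p = NULL, tau = 1,
                         boundary = c("open", "periodic"), seed = NULL) {
  boundary <- match.arg(boundary)
  if (!is.numeric(L) || length(L) != 1 || L < 2 || L != round(L))
    stop("`L` must be a single integer >= 2")
  if (!d %in% c(2, 3)) stop("`d` must be 2 or 3")
  if (!is.null(seed)) set.seed(seed)

  if (is.null(p)) {
    if (is.null(lambda_fus) || is.null(lambda_fis))
      stop("supply both `lambda_fus` and `lambda_fis`, or `p`")
    if (lambda_fus < 0 || lambda_fis < 0) stop("rates must be non-negative")
    if (lambda_fus + lambda_fis == 0)
      stop("`lambda_fus` and `lambda_fis` cannot both be zero unless `p` is supplied")
    p <- lambda_fus / (lambda_fus + lambda_fis)
    tau <- 1 / (lambda_fus + lambda_fis)
  } else {
    if (p < 0 || p > 1) stop("`p` must lie in [0, 1]")
    if (tau <= 0) stop("`tau` must be positive")
    if (is.finite(tau)) {
      lambda_fus <- p / tau
      lambda_fis <- (1 - p) / tau
    } else {
      lambda_fus <- 0
      lambda_fis <- 0
    }
  }

  bonds <- bond_table(as.integer(L), d, boundary)
  bonds$state <- runif(length(bonds$from)) < p

  structure(
    list(L = as.integer(L), d = as.integer(d), boundary = boundary,
         lambda_fus = lambda_fus, lambda_fis = lambda_fis,
         p = p, tau = tau, time = 0, bonds = bonds),
    class = "network_lattice"
  )
}

#' @export
print.network_lattice <- function(x, ...) {
  cat(sprintf("network_lattice: %d^%d nodes, %s boundaries\n",
              x$L, x$d, x$boundary))
  cat(sprintf("  p = %.4g, tau = %.4g (lambda_fus = %.4g, lambda_fis = %.4g)\n",
              x$p, x$tau, x$lambda_fus, x$lambda_fis))
  cat(sprintf("  %d bonds, %.1f%% on, time = %.4g\n",
              length(x$bonds$state), 100 * mean(x$bonds$state), x$time))
  invisible(x)
}

#' Evolve the bond flicker exactly over a time interval
#'
#' Each bond evolves independently as a two-state Markov chain with on-rate
#' `lambda_fus` and off-rate `lambda_fis`. The update uses the exact
#' transition probability of the chain,
#' `P(on at t + dt) = p + (s - p) * exp(-dt / tau)` where `s` is the current
#' state (0/1), so there is no time-discretisation error and steps compose
#' exactly.
#'
#' @param lattice a [make_lattice()] object.
#' @param dt time increment, > 0.
#' @return The lattice with updated bond states and `time` advanced by `dt`.
#' @export
step_bonds <- function(lattice, dt) {
  stopifnot(inherits(lattice, "network_lattice"))
  if (!is.numeric(dt) || length(dt) != 1 || dt <= 0) stop("`dt` must be > 0")
  if (is.finite(lattice$tau)) {
    s <- as.numeric(lattice$bonds$state)
    p_on <- lattice$p + (s - lattice$p) * exp(-dt / lattice$tau)
    lattice$bonds$state <- runif(length(s)) < p_on
  }
  lattice$time <- lattice$time + dt
  lattice
}

#' Convert a lattice snapshot to an igraph graph
#'
#' @param lattice a [make_lattice()] object.
#' @param on_only keep only bonds currently on (fused links)? Default `TRUE`.
#' @return An [igraph::graph] whose vertices carry the integer node
#'   coordinates as attributes `x`, `y` (and `z` for `d = 3`).
#' @export
lattice_graph <- function(lattice, on_only = TRUE) {
  N <- lattice$L^lattice$d
  keep <- if (on_only) lattice$bonds$state else rep(TRUE, length(lattice$bonds$from))
  g <- igraph::make_empty_graph(n = N, directed = FALSE)
  co <- node_coords(0:(N - 1), lattice$L, lattice$d)
  g <- igraph::set_vertex_attr(g, "x", value = co[, 1])
  g <- igraph::set_vertex_attr(g, "y", value = co[, 2])
  if (lattice$d == 3) g <- igraph::set_vertex_attr(g, "z", value = co[, 3])
  edges <- rbind(lattice$bonds$from[keep], lattice$bonds$to[keep]) + 1L
  igraph::add_edges(g, as.vector(edges))
}

#' Export a lattice snapshot as GraphML
#'
#' Writes the current snapshot (nodes with integer coordinates, edges = on
#' bonds) in GraphML format.
#'
#' @inheritParams lattice_graph
#' @param file output path.
#' @return `file`, invisibly.
#' @export
export_graphml <- function(lattice, file) {
  g <- lattice_graph(lattice, on_only = TRUE)
  igraph::write_graph(g, file, format = "graphml")
  invisible(file)
}

#' Connectivity statistics of a lattice snapshot
#'
#' Connected components are computed over the on-bonds only. A snapshot is
#' `spanning` when one component touches both opposite faces along axis 0
#' (the chain-of-fused-units-across-the-cell criterion); for periodic
#' lattices the same two faces of the fundamental domain are used.
#'
#' @param lattice a [make_lattice()] object.
#' @return An object of class `cluster_stats`: list with `cluster_sizes`
#'   (component sizes in units), `largest_fraction`, `spanning`,
#'   `mean_fragment_size` and `n_clusters`.
#' @export
connectivity_stats <- function(lattice) {
  stopifnot(inherits(lattice, "network_lattice"))
  N <- lattice$L^lattice$d
  g <- lattice_graph(lattice, on_only = TRUE)
  comp <- igraph::components(g)
  co_x <- node_coords(0:(N - 1), lattice$L, lattice$d)[, 1]
  left <- unique(comp$membership[co_x == 0])
  right <- unique(comp$membership[co_x == lattice$L - 1])
  structure(
    list(cluster_sizes = as.integer(comp$csize),
         largest_fraction = max(comp$csize) / N,
         spanning = length(intersect(left, right)) > 0,
         mean_fragment_size = mean(comp$csize),
         n_clusters = comp$no),
    class = "cluster_stats"
  )
}

#' @export
print.cluster_stats <- function(x, ...) {
  cat(sprintf(
    "cluster_stats: %d clusters, largest fraction %.3f, mean size %.2f, spanning: %s\n",
    x$n_clusters, x$largest_fraction, x$mean_fragment_size, x$spanning))
  invisible(x)
}

#' Classify the morphological state of the population
#'
#' Maps the stationary bond probability `p` and the fission rate onto the
#' five morphological regimes: `fragmented` (`p = 0`), `microfused`
#' (`0 < p <= eps`, rare fusion), `mesofused` (`eps < p < p_c`, fission
#' dominated), `dynamic_hyperfused` (`p_c <= p <= 1 - eps` with ongoing
#' fission), and `static_hyperfused` (`p > 1 - eps`, or `p >= p_c` with no
#' fission at all, so no quality control is possible).
#'
#' @param p stationary bond probability in `[0, 1]`.
#' @param lambda_fis fission rate (used to distinguish dynamic from static
#'   hyperfusion).
#' @param p_c percolation threshold, in `(0, 1)`; 0.5 is exact for the 2D
#'   square lattice.
#' @param eps cut-off for the "p approximately 0 / 1" regimes, in `(0, p_c)`.
#' @return An object of class `morphology_label`: list with `label` and `p_c`.
#' @examples
#' classify_morphology(0.3, lambda_fis = 1)$label   # "mesofused"
#' @export
classify_morphology <- function(p, lambda_fis, p_c = 0.5, eps = 0.05) {
  if (!is.numeric(p) || p < 0 || p > 1) stop("`p` must lie in [0, 1]")
  if (p_c <= 0 || p_c >= 1) stop("`p_c` must lie in (0, 1)")
  if (eps <= 0 || eps >= p_c) stop("`eps` must lie in (0, p_c)")
  label <-
    if (p == 0) "fragmented"
    else if (p <= eps) "microfused"
    else if (p < p_c) "mesofused"
    else if (p > 1 - eps || lambda_fis == 0) "static_hyperfused"
    else "dynamic_hyperfused"
  structure(list(label = label, p_c = p_c), class = "morphology_label")
}

#' @export
print.morphology_label <- function(x, ...) {
  cat(sprintf("morphology: %s (p_c = %g)\n", x$label, x$p_c))
  invisible(x)
}

#' Connectivity time series of a flickering lattice
#'
#' Evolves the bond flicker with [step_bonds()] and records
#' [connectivity_stats()] after each step.
#'
#' @param lattice a [make_lattice()] object.
#' @param dt time step between recorded snapshots.
#' @param n_steps number of steps.
#' @return A data frame with columns `time`, `n_clusters`, `largest_fraction`,
#'   `spanning`, `mean_fragment_size`.
#' @export
cluster_time_series <- function(lattice, dt, n_steps) {
  rows <- vector("list", n_steps + 1)
  record <- function(lat) {
    cs <- connectivity_stats(lat)
    data.frame(time = lat$time, n_clusters = cs$n_clusters,
               largest_fraction = cs$largest_fraction,
               spanning = cs$spanning,
               mean_fragment_size = cs$mean_fragment_size)
  }
  rows[[1]] <- record(lattice)
  for (i in seq_len(n_steps)) {
    lattice <- step_bonds(lattice, dt)
    rows[[i + 1]] <- record(lattice)
  }
  do.call(rbind, rows)
}

#' Spanning probability of static bond percolation
#'
#' Fraction of independent static snapshots (each bond on with probability
#' `p`) that contain a cluster spanning the lattice along axis 0.
#'
#' @param L side length.
#' @param p bond probability.
#' @param n_snapshots number of independent snapshots.
#' @param d lattice dimension.
#' @return Estimated spanning probability.
#' @export
spanning_probability <- function(L, p, n_snapshots = 200, d = 2) {
  bonds <- bond_table(as.integer(L), d, "open")
  N <- L^d
  co_x <- node_coords(0:(N - 1), L, d)[, 1]
  left_idx <- which(co_x == 0)
  right_idx <- which(co_x == L - 1)
  nb <- length(bonds$from)
  hits <- 0L
  for (i in seq_len(n_snapshots)) {
    on <- runif(nb) < p
    g <- igraph::make_empty_graph(n = N, directed = FALSE)
    g <- igraph::add_edges(g, as.vector(rbind(bonds$from[on], bonds$to[on]) + 1L))
    memb <- igraph::components(g)$membership
    if (length(intersect(unique(memb[left_idx]), unique(memb[right_idx]))) > 0)
      hits <- hits + 1L
  }
  hits / n_snapshots
}

#' Estimate the bond-percolation threshold by bisection
#'
#' Locates the bond probability at which the spanning probability crosses
#' 1/2, by bisection on [spanning_probability()]. For the 2D square lattice
#' the exact threshold is `p_c = 1/2` (self-duality), which is also where the
#' apparent diffusion coefficient of a tracer on a static lattice changes
#' abruptly.
#'
#' @param L side length (>= 64 recommended; finite-size rounding of the
#'   transition scales as a negative power of `L`).
#' @param n_snapshots snapshots per probed `p`.
#' @param d lattice dimension.
#' @param interval search interval for `p`.
#' @param n_iter bisection iterations.
#' @param seed optional integer seed.
#' @return List with `p_c` (midpoint of the final interval), `interval`,
#'   and `history` (data frame of probed `p` and spanning frequency).
#' @export
estimate_percolation_threshold <- function(L = 128, n_snapshots = 200, d = 2,
                                           interval = c(0.3, 0.7),
                                           n_iter = 9, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  lo <- interval[1]; hi <- interval[2]
  hist_p <- hist_f <- numeric(n_iter)
  for (i in seq_len(n_iter)) {
    mid <- (lo + hi) / 2
    f <- spanning_probability(L, mid, n_snapshots, d)
    hist_p[i] <- mid; hist_f[i] <- f
    if (f > 0.5) hi <- mid else lo <- mid
  }
  list(p_c = (lo + hi) / 2, interval = c(lo, hi),
       history = data.frame(p = hist_p, spanning_freq = hist_f))
}
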