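# Independent oracles used across the suite. These deliberately avoid the
# implementation paths they check: clusters by hand-rolled breadth-first
# search, static-lattice diffusion by the exact homogenisation (corrector)
# formula, and Jensen signs by direct logistic arithmetic.

# Breadth-first-search connected components over on-bonds.
bfs_clusters <- function(lattice) {
  N <- lattice$L^lattice$d
  adj <- vector("list", N)
  on <- lattice$bonds$state
  fr <- lattice$bonds$from[on] + 1L
  to <- lattice$bonds$to[on] + 1L
  for (k in seq_along(fr)) {
    adj[[fr[k]]] <- c(adj[[fr[k]]], to[k])
    adj[[to[k]]] <- c(adj[[to[k]]], fr[k])
  }
  seen <- logical(N)
  sizes <- integer(0)
  membership <- integer(N)
  comp <- 0L
  for (start in seq_len(N)) {
    if (seen[start]) next
    comp <- comp + 1L
    queue <- start
    seen[start] <- TRUE
    size <- 0L
    while (length(queue) > 0) {
      v <- queue[1]; queue <- queue[-1]
      size <- size + 1L
      membership[v] <- comp
      for (w in adj[[v]]) if (!seen[w]) { seen[w] <- TRUE; queue <- c(queue, w) }
    }
    sizes <- c(sizes, size)
  }
  list(sizes = sizes, membership = membership)
}

# Exact effective diffusion coefficient of a frozen periodic lattice, from
# the homogenisation corrector: for each axis a, solve
#   sum_j w_ij (chi_j - chi_i + dx_ij) = 0
# and form D_aa = (1/(2N)) sum_ij w_ij (dx_ij + chi_j - chi_i)^2, with
# w_ij = lambda_dif/(2d) across each on-bond in each direction. Trapped
# (non-wrapping) clusters contribute zero, matching the uniform-start
# ensemble average the walker simulation measures.
oracle_D_static <- function(lattice, lambda_dif = 1) {
  stopifnot(lattice$boundary == "periodic", is.infinite(lattice$tau))
  N <- lattice$L^lattice$d
  d <- lattice$d
  w <- lambda_dif / (2 * d)
  on <- lattice$bonds$state
  fr <- lattice$bonds$from[on] + 1L
  to <- lattice$bonds$to[on] + 1L
  ax <- lattice$bonds$axis[on] + 1L
  W <- matrix(0, N, N)
  for (k in seq_along(fr)) {
    W[fr[k], to[k]] <- W[fr[k], to[k]] + w
    W[to[k], fr[k]] <- W[to[k], fr[k]] + w
  }
  Lap <- diag(rowSums(W)) - W
  Lap_inv <- MASS::ginv(Lap)
  D_axes <- numeric(d)
  for (a in seq_len(d)) {
    b <- numeric(N)
    sel <- ax == a
    for (k in which(sel)) {
      b[fr[k]] <- b[fr[k]] + w        # + direction into from-node balance
      b[to[k]] <- b[to[k]] - w
    }
    chi <- Lap_inv %*% b
    acc <- 0
    for (k in seq_along(fr)) {         # every on-bond contributes energy
      dx <- if (ax[k] == a) 1 else 0
      flux <- dx + chi[to[k]] - chi[fr[k]]
      acc <- acc + 2 * w * flux^2      # both directions of the bond
    }
    D_axes[a] <- acc / (2 * N)
  }
  mean(D_axes)
}

# Direct logistic arithmetic for the Jensen sign oracle (equal sizes, mean
# rule): sign of 2 r((x+y)/2) - r(x) - r(y) with r the plain logistic.
oracle_jensen_sign <- function(psi1, psi2, r_max, psi_half, slope_k) {
  r <- function(x) r_max / (1 + exp(-(x - psi_half) / slope_k))
  sign(2 * r((psi1 + psi2) / 2) - r(psi1) - r(psi2))
}

# Standard-error helper for comparing two simulated values.
within_se <- function(a, b, se, k = 2) abs(a - b) <= k * se
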