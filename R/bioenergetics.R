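# Sigmoidal bioenergetics of fusion: ATP synthesis rate responds sigmoidally
# to membrane potential, so combining two mitochondria's potentials on fusion
# changes the summed synthesis rate with a sign set by the local convexity of
# the response between the two potentials (Jensen's inequality).

#' Sigmoidal response curve
#'
#' Logistic parameterisation `r(x) = r_max / (1 + exp(-(x - psi_half) /
#' slope_k))`, strictly increasing in `x`. Used both for the ATP synthesis
#' rate as a function of membrane potential (mV on the x-axis) and, re-used
#' unchanged, for calcium-dependent enzyme activation (matrix calcium on the
#' x-axis). The defaults (`psi_half = 150` mV, `slope_k = 10` mV) are
#' illustrative values chosen to exhibit an exponential regime, a steep
#' transition and a plateau within the physiological 100-200 mV range; they
#' are not fitted to data.
#'
#' @param r_max maximal response per unit size (> 0; arbitrary rate units).
#' @param psi_half x-value at half-maximum.
#' @param slope_k steepness scale (> 0; same units as the x-axis; smaller is
#'   steeper).
#' @return An object of class `sigmoid_response`.
#' @export
sigmoid_response <- function(r_max = 1, psi_half = 150, slope_k = 10) {
  if (r_max <= 0) stop("`r_max` must be > 0")
  if (slope_k <= 0) stop("`slope_k` must be > 0")
  structure(list(r_max = r_max, psi_half = psi_half, slope_k = slope_k),
            class = "sigmoid_response")
}

#' A mitochondrion's energetic state
#'
#' @param delta_psi membrane potential (mV, >= 0).
#' @param size mass in unit counts (>= 1).
#' @param cristae_factor dimensionless factor >= 1 scaling the effective
#'   membrane capacitance (a more invaginated inner membrane holds more
#'   charge at a given potential).
#' @return An object of class `energetics_unit`.
#' @export
energetics_unit <- function(delta_psi, size = 1, cristae_factor = 1) {
  if (delta_psi < 0) stop("`delta_psi` must be >= 0")
  if (size < 1) stop("`size` must be >= 1")
  if (cristae_factor < 1) stop("`cristae_factor` must be >= 1")
  structure(list(delta_psi = delta_psi, size = size,
                 cristae_factor = cristae_factor),
            class = "energetics_unit")
}

#' ATP synthesis rate at a given membrane potential
#'
#' `size * r_max / (1 + exp(-(delta_psi - psi_half) / slope_k))`: the rate is
#' extensive in mitochondrial size and sigmoidal in potential, with an
#' exponential (convex) low-potential regime and a saturating plateau.
#'
#' @param delta_psi membrane potential (mV); vectorised.
#' @param sigmoid a [sigmoid_response()].
#' @param size mitochondrial size in unit counts.
#' @return Synthesis rate(s).
#' @export
r_atp <- function(delta_psi, sigmoid, size = 1) {
  stopifnot(inherits(sigmoid, "sigmoid_response"))
  size * sigmoid$r_max *
    stats::plogis((delta_psi - sigmoid$psi_half) / sigmoid$slope_k)
}

#' Membrane potential of a fused pair
#'
#' Two combination rules for the potential of the fused product:
#' * `"mean"`: size-weighted arithmetic mean of the two potentials.
#' * `"capacitor"`: charge-conserving combination of two charged capacitors,
#'   `(C1 psi1 + C2 psi2) / (C1 + C2)` with `Ci = size_i * cristae_factor_i`;
#'   the cristae factors let inner-membrane structure skew the outcome away
#'   from the plain size-weighted mean.
#'
#' Both rules are convex combinations, so the fused potential always lies
#' between `min(psi1, psi2)` and `max(psi1, psi2)`.
#'
#' @param unit1,unit2 [energetics_unit()] objects.
#' @param rule `"mean"` or `"capacitor"`.
#' @return Fused membrane potential (mV).
#' @examples
#' a <- energetics_unit(100); b <- energetics_unit(160, cristae_factor = 3)
#' fuse_potential(a, b, "capacitor")   # 145
#' @export
fuse_potential <- function(unit1, unit2, rule = c("mean", "capacitor")) {
  rule <- match.arg(rule)
  stopifnot(inherits(unit1, "energetics_unit"),
            inherits(unit2, "energetics_unit"))
  w <- switch(rule,
    mean = c(unit1$size, unit2$size),
    capacitor = c(unit1$size * unit1$cristae_factor,
                  unit2$size * unit2$cristae_factor))
  weighted.mean(c(unit1$delta_psi, unit2$delta_psi), w)
}

#' Net change in total ATP synthesis rate on fusion
#'
#' `delta_r = r_atp(psi_fused, size1 + size2) - [r_atp(psi1, size1) +
#' r_atp(psi2, size2)]`. For equal sizes and the mean rule the sign is set by
#' Jensen's inequality on the sigmoid between the two potentials: negative
#' where the response is locally convex (both units in the exponential
#' regime), positive in mixed convex/plateau situations, and essentially
#' zero when both units sit on the plateau.
#'
#' @inheritParams fuse_potential
#' @param sigmoid a [sigmoid_response()].
#' @return Net rate change `delta_r`.
#' @export
net_rate_change <- function(unit1, unit2, sigmoid,
                            rule = c("mean", "capacitor")) {
  rule <- match.arg(rule)
  psi_f <- fuse_potential(unit1, unit2, rule)
  r_atp(psi_f, sigmoid, unit1$size + unit2$size) -
    (r_atp(unit1$delta_psi, sigmoid, unit1$size) +
       r_atp(unit2$delta_psi, sigmoid, unit2$size))
}

#' Superadditivity check for a usefulness function
#'
#' Fusion can only pay off if some mitochondrial property maps non-linearly
#' onto usefulness: a fused unit must be worth more than the sum of its
#' parts, `f(x + y) > f(x) + f(y)`. Linear `f` always fails the check
#' (additivity).
#'
#' @param f_values either a function of one argument, or a named numeric
#'   vector mapping size to usefulness (names parsed as numbers).
#' @param x,y the two sizes to combine.
#' @return `TRUE` if `f(x + y) > f(x) + f(y)`.
#' @examples
#' superadditivity_check(function(x) x^2, 1, 1)   # TRUE
#' superadditivity_check(function(x) 3 * x, 2, 5) # FALSE
#' @export
superadditivity_check <- function(f_values, x, y) {
  f <- if (is.function(f_values)) {
    f_values
  } else {
    if (is.null(names(f_values))) stop("`f_values` must be named by size")
    tab <- setNames(as.numeric(f_values), names(f_values))
    function(v) {
      key <- as.character(v)
      hit <- match(key, names(tab))
      if (is.na(hit)) {
        num_hit <- which(abs(as.numeric(names(tab)) - v) < 1e-12)
        if (length(num_hit) == 0) stop("`f_values` missing point ", v)
        hit <- num_hit[1]
      }
      tab[[hit]]
    }
  }
  unname(f(x + y) > f(x) + f(y))
}

#' Sign map of the fusion-induced rate change over a potential grid
#'
#' Evaluates [net_rate_change()] for equal-size units over all pairs of a
#' potential grid; the resulting sign map shows the convex-regime loss
#' region, the mixed-regime gain region, and the plateau's near-zero region.
#'
#' @param psi_grid vector of membrane potentials (mV).
#' @param sigmoid a [sigmoid_response()].
#' @param rule combination rule, see [fuse_potential()].
#' @param size common unit size.
#' @return Data frame with columns `psi1`, `psi2`, `delta_r`, `sign`.
#' @export
atp_sign_map <- function(psi_grid, sigmoid, rule = "mean", size = 1) {
  grid <- expand.grid(psi1 = psi_grid, psi2 = psi_grid)
  dr <- vapply(seq_len(nrow(grid)), function(i) {
    net_rate_change(energetics_unit(grid$psi1[i], size),
                    energetics_unit(grid$psi2[i], size), sigmoid, rule)
  }, numeric(1))
  grid$delta_r <- dr
  grid$sign <- sign(dr)
  grid
}
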