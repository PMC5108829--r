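#' Quantification constants for oxygen-15 modeling
#'
#' Standard literature values, all configurable: water partition
#' coefficient `p` (ml/g), brain density `rho` (g/ml), small-to-large
#' vessel hematocrit ratio `R_sl`, and arterial oxygen content `CaO2`
#' (ml O2 / ml blood). The physical decay constant of oxygen-15
#' (`log(2)/122.24` 1/s) is only used to convert measured curves; all
#' model math operates on decay-corrected data.
#'
#' @param p partition coefficient, ml/g.
#' @param rho brain density, g/ml.
#' @param R_sl small-to-large vessel hematocrit ratio.
#' @param CaO2 arterial oxygen content, ml O2/ml blood.
#' @return a `quant_constants` object.
#' @export
quant_constants <- function(p = 0.8, rho = 1.04, R_sl = 0.85, CaO2 = 0.19) {
  stopifnot(p > 0, rho > 0, R_sl > 0, CaO2 > 0)
  structure(list(p = p, rho = rho, R_sl = R_sl, CaO2 = CaO2),
    class = "quant_constants"
  )
}

#' Time-activity curve
#'
#' @param times sample times (s), strictly increasing.
#' @param values activity concentration (kBq/ml), nonnegative.
#' @param decay_corrected logical; model code requires `TRUE`.
#' @return a `tac` object (data.frame).
#' @export
tac <- function(times, values, decay_corrected = TRUE) {
  stopifnot(
    length(times) == length(values), length(times) >= 2,
    all(diff(times) > 0), all(values >= 0), all(is.finite(values))
  )
  structure(
    data.frame(time_s = times, kbq_ml = values),
    decay_corrected = decay_corrected,
    class = c("tac", "data.frame")
  )
}

#' Oxygen-15 decay constant (1/s)
#' @export
lambda_o15 <- function() log(2) / 122.24

#' Synthetic gamma-variate arterial input function
#'
#' `Ca(t) = A * (t - t0)^gamma * exp(-(t - t0)/tau)` for `t > t0`, else 0;
#' a standard analytic surrogate for a measured arterial curve (delay-free,
#' decay-corrected). The peak sits at `t0 + gamma * tau`.
#'
#' @param times sample times (s).
#' @param A amplitude scale (> 0).
#' @param t0 appearance time (s).
#' @param gamma shape exponent (>= 0).
#' @param tau decay time constant (s, > 0).
#' @return a [tac()].
#' @export
synth_aif <- function(times = seq(0, 180, by = 0.5), A = 1, t0 = 10,
                      gamma = 3, tau = 8) {
  stopifnot(A > 0, tau > 0, gamma >= 0)
  dt <- pmax(times - t0, 0)
  v <- A * dt^gamma * exp(-dt / tau)
  v[times <= t0] <- 0
  tac(times, v, decay_corrected = TRUE)
}

# resample a TAC on a uniform fine grid [0, T]
.tac_grid <- function(aif, T, dt = 0.5) {
  tt <- seq(0, T, by = dt)
  ca <- stats::approx(aif$time_s, aif$kbq_ml, xout = tt, rule = 2, yleft = 0)$y
  ca[tt < min(aif$time_s)] <- 0
  list(t = tt, ca = ca, dt = dt)
}

# one-compartment tissue curve for rate constants K1 (1/s uptake) and k2
# (1/s washout): C(t) = K1 * int_0^t Ca(u) exp(-k2 (t-u)) du, computed by
# an exact exponential-update recursion (Ca linear within each step).
.compartment_curve <- function(ca, dt, K1, k2) {
  n <- length(ca)
  C <- numeric(n)
  if (k2 <= 0) {
    # pure accumulation
    for (i in 2:n) C[i] <- C[i - 1] + K1 * (ca[i - 1] + ca[i]) / 2 * dt
    return(C)
  }
  E <- exp(-k2 * dt)
  for (i in 2:n) {
    c0 <- ca[i - 1]; c1 <- ca[i]
    sl <- (c1 - c0) / dt
    # int_0^dt (c0 + sl*u) exp(-k2 (dt-u)) du
    I <- c0 * (1 - E) / k2 + sl * (dt - (1 - E) / k2) / k2
    C[i] <- C[i - 1] * E + K1 * I
  }
  C
}

#' Accumulated tissue counts of the water autoradiographic model
#'
#' One-compartment kinetics for freely diffusible water,
#' `dC/dt = (f rho / 6000) Ca(t) - (f / (6000 p)) C`, with `f` in
#' ml/(100 g min): the scan integral `A = int_0^T C(t) dt` is the quantity
#' a static scan measures. Monotone increasing in `f` over the
#' physiological range for any realistic input function, which is what
#' makes the lookup-table inversion of [cbf_autoradiographic()] valid.
#'
#' @param f cerebral blood flow, ml/(100 g min), >= 0 (vectorized).
#' @param aif arterial input [tac()], decay-corrected.
#' @param const [quant_constants()].
#' @param T scan duration (s).
#' @param dt integration step (s).
#' @return accumulated counts (kBq s / ml), same length as `f`.
#' @export
h2o_tissue_counts <- function(f, aif, const = quant_constants(), T = 180,
                              dt = 0.5) {
  stopifnot(inherits(aif, "tac"), isTRUE(attr(aif, "decay_corrected")))
  if (any(f < 0)) stop("negative flow")
  g <- .tac_grid(aif, T, dt)
  vapply(f, function(fi) {
    if (fi == 0) return(0)
    K1 <- fi * const$rho / 6000
    k2 <- fi / (6000 * const$p)
    C <- .compartment_curve(g$ca, g$dt, K1, k2)
    sum((C[-1] + C[-length(C)]) / 2) * g$dt
  }, numeric(1))
}

#' Autoradiographic CBF from accumulated tissue counts
#'
#' Inverts [h2o_tissue_counts()] per voxel by a monotone lookup table with
#' linear interpolation. Values above the table range are clamped to the
#' maximum flow and flagged.
#'
#' @param A numeric array/vector of accumulated counts (kBq s/ml).
#' @param aif arterial input [tac()].
#' @param const [quant_constants()].
#' @param T scan duration (s).
#' @param f_grid flow grid for the lookup table, ml/(100 g min).
#' @return object with the same shape as `A`: CBF in ml/(100 g min), with
#'   attribute `clamped` (logical, same shape) marking out-of-range input.
#' @export
cbf_autoradiographic <- function(A, aif, const = quant_constants(), T = 180,
                                 f_grid = seq(0, 150, by = 1)) {
  table_A <- h2o_tissue_counts(f_grid, aif, const, T)
  if (any(diff(table_A) <= 0)) stop("lookup table is not strictly monotone")
  dims <- dim(A)
  a <- as.numeric(A)
  clamped <- a > max(table_A)
  f <- stats::approx(table_A, f_grid, xout = pmin(pmax(a, 0), max(table_A)),
    rule = 2
  )$y
  f[a <= 0] <- 0
  if (!is.null(dims)) {
    dim(f) <- dims
    dim(clamped) <- dims
  }
  structure(f, clamped = clamped)
}

#' Cerebral blood volume from the CO scan
#'
#' Ratio method for an intravascular tracer:
#' `CBV = 100 * C_pet / (rho * R_sl * C_blood)` in ml/100 g.
#'
#' @param C_pet tissue activity concentration (kBq/ml), vectorized.
#' @param C_blood arterial whole-blood activity concentration (kBq/ml).
#' @param const [quant_constants()].
#' @return CBV in ml/100 g, same shape as `C_pet`.
#' @export
cbv_from_co <- function(C_pet, C_blood, const = quant_constants()) {
  if (C_blood <= 0) stop("C_blood must be positive")
  100 * C_pet / (const$rho * const$R_sl * C_blood)
}

#' Accumulated tissue counts of the simplified oxygen model
#'
#' Forward model of the O2 scan used both by the simulator and (inverted)
#' by the estimator: extracted oxygen-water follows the same
#' one-compartment kinetics as injected water, scaled by the extraction
#' fraction, plus a purely intravascular term:
#' \deqn{A_{O2} = OEF \cdot D(f) + \frac{CBV}{100}\rho R_{sl}
#'   \int_0^T C_a(t)\,dt}
#' where `D(f)` is [h2o_tissue_counts()] evaluated on the O2-scan input
#' function. Recirculating water of metabolism is deliberately omitted
#' (documented simplification); the estimator is the exact inverse of this
#' forward model.
#'
#' @param oef oxygen extraction fraction (vectorized with `f`, `cbv`).
#' @param f CBF, ml/(100 g min).
#' @param cbv CBV, ml/100 g.
#' @param aif_o2 arterial input [tac()] of the O2 scan.
#' @param const [quant_constants()].
#' @param T scan duration (s).
#' @return accumulated counts (kBq s/ml).
#' @export
o2_tissue_counts <- function(oef, f, cbv, aif_o2, const = quant_constants(),
                             T = 180) {
  D <- h2o_tissue_counts(f, aif_o2, const, T)
  g <- .tac_grid(aif_o2, T)
  int_ca <- sum((g$ca[-1] + g$ca[-length(g$ca)]) / 2) * g$dt
  oef * D + cbv / 100 * const$rho * const$R_sl * int_ca
}

#' OEF and CMRO2 from the O2 scan
#'
#' Per-voxel linear solve of the [o2_tissue_counts()] forward model for
#' OEF given CBF and CBV maps from the preceding scans (the sequential
#' CO / O2 / H2O protocol), then
#' `CMRO2 = OEF * f * CaO2` in ml O2/(100 g min). OEF is clipped to
#' \[0, 1.5\] and clipped or insensitive voxels (f = 0) are flagged.
#'
#' @param A_o2 accumulated O2-scan counts (array/vector, kBq s/ml).
#' @param f CBF map, same shape.
#' @param cbv CBV map, same shape.
#' @param aif_o2 arterial input [tac()] of the O2 scan.
#' @param const [quant_constants()].
#' @param T scan duration (s).
#' @return list with `oef` and `cmro2` (same shape as `A_o2`), each with a
#'   `flagged` attribute.
#' @export
oef_cmro2 <- function(A_o2, f, cbv, aif_o2, const = quant_constants(),
                      T = 180) {
  dims <- dim(A_o2)
  a <- as.numeric(A_o2)
  fv <- as.numeric(f)
  cv <- as.numeric(cbv)
  stopifnot(length(fv) == length(a), length(cv) == length(a))

  g <- .tac_grid(aif_o2, T)
  int_ca <- sum((g$ca[-1] + g$ca[-length(g$ca)]) / 2) * g$dt
  intra <- cv / 100 * const$rho * const$R_sl * int_ca

  # D(f) via the same lookup-table trick as the CBF inversion (piecewise
  # linear in f, exact at grid nodes)
  f_grid <- seq(0, 150, by = 1)
  D_grid <- h2o_tissue_counts(f_grid, aif_o2, const, T)
  D <- stats::approx(f_grid, D_grid, xout = pmin(pmax(fv, 0), max(f_grid)),
    rule = 2
  )$y

  flagged <- fv <= 0 | D <= 0
  oef <- rep(0, length(a))
  oef[!flagged] <- (a[!flagged] - intra[!flagged]) / D[!flagged]
  clip <- oef < 0 | oef > 1.5
  oef <- pmin(pmax(oef, 0), 1.5)
  flagged <- flagged | clip
  cmro2 <- oef * fv * const$CaO2
  if (!is.null(dims)) {
    dim(oef) <- dims; dim(cmro2) <- dims; dim(flagged) <- dims
  }
  list(
    oef = structure(oef, flagged = flagged),
    cmro2 = structure(cmro2, flagged = flagged)
  )
}
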