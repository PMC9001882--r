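#' Kinetic and promoter kernels
#'
#' Reusable rate-law building blocks shared by both pathway models: classic
#' and bisubstrate Michaelis-Menten fluxes, a copy-number-aware Hill promoter
#' activation, and the regulatory fractions of the biosensor and controller
#' promoters.  All amounts are molecules per cell, all rates molecules per
#' minute, unless stated otherwise.
#'
#' @name kernels
NULL

.check_nonneg <- function(...) {
  vals <- list(...)
  nm <- names(vals)
  for (i in seq_along(vals)) {
    v <- vals[[i]]
    if (any(!is.finite(v)) || any(v < 0)) {
      stop(sprintf("'%s' must be finite and >= 0", nm[i]), call. = FALSE)
    }
  }
  invisible(TRUE)
}

#' Michaelis-Menten flux
#'
#' Single-substrate enzymatic flux `kcat * E * S / (Km + S)`.
#'
#' @param E enzyme amount (molecules).
#' @param S substrate amount (molecules).
#' @param kcat catalytic turnover rate (1/min).
#' @param Km Michaelis constant (molecules), strictly positive.
#' @return Flux in molecules/min; bounded above by `kcat * E` and monotone
#'   nondecreasing in `S`.
#' @examples
#' mm_flux(E = 10, S = 5, kcat = 2, Km = 5)  # half-saturation: kcat*E/2
#' @export
mm_flux <- function(E, S, kcat, Km) {
  .check_nonneg(E = E, S = S, kcat = kcat, Km = Km)
  if (any(Km <= 0)) stop("'Km' must be > 0", call. = FALSE)
  kcat * E * S / (Km + S)
}

#' Bisubstrate Michaelis-Menten flux
#'
#' Flux of a merging (two-substrate) enzymatic step,
#' `kcat * E * S1 * S2 / (Km1*Km2 + Km2*S1 + Km1*S2 + S1*S2)`.
#' Reduces to [mm_flux()] in `S1` as `S2` saturates, and stalls when either
#' substrate is absent.
#'
#' @param E enzyme amount (molecules).
#' @param S1,S2 substrate amounts (molecules).
#' @param kcat catalytic turnover rate (1/min).
#' @param Km1,Km2 Michaelis constants (molecules), strictly positive.
#' @return Flux in molecules/min, bounded above by `kcat * E`.
#' @export
bisubstrate_flux <- function(E, S1, S2, kcat, Km1, Km2) {
  .check_nonneg(E = E, S1 = S1, S2 = S2, kcat = kcat, Km1 = Km1, Km2 = Km2)
  if (any(Km1 <= 0) || any(Km2 <= 0)) stop("Michaelis constants must be > 0", call. = FALSE)
  kcat * E * S1 * S2 / (Km1 * Km2 + Km2 * S1 + Km1 * S2 + S1 * S2)
}

#' Copy-number-aware Hill promoter activation
#'
#' Production rate of a gene activated by the sigma factor through a
#' second-order Hill function, with plasmid copy number scaling both the
#' basal/induced strengths and the effective dissociation constant:
#' `CN*a0 + CN*a1 * sigma^2 / ((kd20*CN)^2 + sigma^2)`.
#'
#' @param sigma free sigma factor (molecules).
#' @param CN plasmid copy number (copies).
#' @param a0 basal expression strength (molecules/min/copy).
#' @param a1 sigma-induced expression strength (molecules/min/copy).
#' @param kd20 sigma-promoter dissociation constant (molecules).
#' @return Production rate in molecules/min, in `[CN*a0, CN*(a0 + a1))`.
#' @export
hill_activation <- function(sigma, CN, a0, a1, kd20) {
  .check_nonneg(sigma = sigma, CN = CN, a0 = a0, a1 = a1, kd20 = kd20)
  CN * a0 + CN * a1 * sigma^2 / ((kd20 * CN)^2 + sigma^2)
}

#' Product biosensor promoter fraction
#'
#' Activation fraction of the anti-sigma promoter in the simple TF-based
#' biosensor.  A constitutive transcription factor (total pool `TF`)
#' represses the promoter; binding of the product P to the TF relieves the
#' repression:
#' `CN^2 (1 + P/kdp)^2 / (CN^2 (1 + P/kdp)^2 + TF^2)`.
#'
#' @param P product amount (molecules).
#' @param CN plasmid copy number (copies).
#' @param kdp product-TF dissociation constant (molecules), > 0.
#' @param TF constitutive transcription-factor pool (molecules).
#' @return Fraction in (0, 1], increasing in `P`, decreasing in `TF`.
#' @export
biosensor_fraction <- function(P, CN, kdp, TF) {
  .check_nonneg(P = P, CN = CN, kdp = kdp, TF = TF)
  if (any(kdp <= 0)) stop("'kdp' must be > 0", call. = FALSE)
  num <- (CN * (1 + P / kdp))^2
  num / (num + TF^2)
}

#' Regulatory promoter fractions of the realistic antithetic controller
#'
#' Activation/repression fractions, each in `[0, 1]`, used in the naringenin
#' controller equations.  `f_lux` is the AHL/LuxR activation of the sigma
#' promoter, `f_qdo` the kaempferol-relieved QdoR repression of the
#' anti-sigma promoter, and `f_p20` the sigma activation of the CHS promoter.
#' Each fraction enters the production term as
#' `alpha + (1 - alpha) * f` so that `alpha` acts as promoter leakage.
#'
#' The exact grouping of the composite dissociation constants in the Hill
#' denominators is centralized here so that alternative readings are a
#' one-line change; the adopted forms are
#' `f_lux = A^2 / (kdlux*kd2*CN / R^2 + A^2)`,
#' `f_qdo = (kdq*CN^2*kdk + Ka^2) / (kdq*CN^2*kdk + Ka^2 + kdk*Q^2)`,
#' `f_p20 = sigma^2 / (kd20_n*kd_sigma*CN_h^2 + sigma^2)`.
#'
#' @param A intracellular AHL (molecules); `R` LuxR (molecules).
#' @param R LuxR amount (molecules), > 0 for a defined activation.
#' @param kdlux,kd2 AHL/LuxR promoter dissociation constants (molecules).
#' @param CN controller plasmid copy number (copies).
#' @param Ka kaempferol (molecules); `Q` QdoR repressor (molecules).
#' @param Q QdoR repressor amount (molecules).
#' @param kdq,kdk QdoR/kaempferol dissociation constants (molecules).
#' @param sigma free sigma factor (molecules).
#' @param kd20_n,kd_sigma sigma-promoter dissociation constants (molecules).
#' @param CN_h actuator plasmid copy number (copies).
#' @return A fraction in `[0, 1]`.
#' @name promoter-fractions
NULL

#' @rdname promoter-fractions
#' @export
f_lux <- function(A, R, kdlux, kd2, CN) {
  .check_nonneg(A = A, R = R, kdlux = kdlux, kd2 = kd2, CN = CN)
  if (any(R <= 0)) return(0 * A)  # no receptor, no activation
  A^2 / (kdlux * kd2 * CN / R^2 + A^2)
}

#' @rdname promoter-fractions
#' @export
f_qdo <- function(Ka, Q, kdq, kdk, CN) {
  .check_nonneg(Ka = Ka, Q = Q, kdq = kdq, kdk = kdk, CN = CN)
  base <- kdq * CN^2 * kdk + Ka^2
  base / (base + kdk * Q^2)
}

#' @rdname promoter-fractions
#' @export
f_p20 <- function(sigma, kd20_n, kd_sigma, CN_h) {
  .check_nonneg(sigma = sigma, kd20_n = kd20_n, kd_sigma = kd_sigma, CN_h = CN_h)
  sigma^2 / (kd20_n * kd_sigma * CN_h^2 + sigma^2)
}

#' Unit conversion between molecules per cell and micromolar
#'
#' Converts an intracellular concentration quoted in micromolar to molecules
#' per cell (and back) using the cell volume: `molecules = conc * 1e-6 * Av *
#' Vcell`.
#'
#' @param uM concentration in micromolar.
#' @param molecules amount in molecules per cell.
#' @param Vcell cell volume in litres (default `1.1e-15` L, an E. coli cell).
#' @param Av Avogadro's number.
#' @return The converted quantity.
#' @export
molecules_from_uM <- function(uM, Vcell = 1.1e-15, Av = 6.02214076e23) {
  uM * 1e-6 * Av * Vcell
}

#' @rdname molecules_from_uM
#' @export
uM_from_molecules <- function(molecules, Vcell = 1.1e-15, Av = 6.02214076e23) {
  molecules / (1e-6 * Av * Vcell)
}
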