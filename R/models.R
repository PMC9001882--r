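#' Species names of the two models
#'
#' @return Character vector of state-variable names in canonical order.
#' @export
merging_species <- function() c("S1", "P", "E", "sigma", "asigma", "X")

#' @rdname merging_species
#' @export
naringenin_species <- function() {
  c("Lt", "pC", "pA", "Nc", "N", "Di", "Ka", "Q", "sigma", "asigma",
    "complex_sa", "CHS", "R", "A", "Ae", "x")
}

.check_state <- function(state, species) {
  if (any(!is.finite(state))) stop("non-finite state", call. = FALSE)
  if (is.null(names(state))) {
    if (length(state) != length(species)) stop("state has wrong length", call. = FALSE)
    names(state) <- species
  }
  state[species]
}

#' Time derivative of the merging-pathway model
#'
#' Right-hand side of the simplified merging pathway under antithetic
#' feedback regulation.  The precursor S1 is taken up at a constant rate and
#' merged with the externally set secondary substrate (`S2_level`) into the
#' product P by the enzyme E, whose expression is activated by the free
#' sigma factor.  A constitutive sigma supply is annihilated by the
#' anti-sigma factor, itself expressed through a product-responsive
#' TF-based biosensor, closing the integral feedback loop.  All species are
#' additionally diluted by growth at rate `mu`; the population X grows
#' logistically.
#'
#' @param state named numeric vector with components [merging_species()].
#' @param params a [merging_params()] object.
#' @return Named numeric vector of time derivatives (molecules/min,
#'   cells/min for X).
#' @export
merging_rhs <- function(state, params) {
  s <- .check_state(state, merging_species())
  p <- params
  V <- bisubstrate_flux(s[["E"]], s[["S1"]], p$S2_level, p$kcat, p$Km_S1, p$Km_S2)
  annih <- p$gamma * s[["sigma"]] * s[["asigma"]]
  c(
    S1 = p$K_S1 - V - p$mu * s[["S1"]],
    P = V - p$mu * s[["P"]],
    E = hill_activation(s[["sigma"]], p$CN, p$a0, p$a1, p$kd20) -
      (p$d_E + p$mu) * s[["E"]],
    sigma = p$CN * p$k_sigma - annih - (p$d_sigma + p$mu) * s[["sigma"]],
    asigma = p$CN * p$k_asigma *
      biosensor_fraction(s[["P"]], p$CN, p$kdp, p$TF_total) -
      annih - (p$d_asigma + p$mu) * s[["asigma"]],
    X = p$mu * s[["X"]] * (1 - s[["X"]] / p$Xmax)
  )
}

#' Time derivative of the naringenin-pathway model
#'
#' Right-hand side of the detailed naringenin production model: the
#' five-step metabolic chain from L-tyrosine to naringenin (the CHS step
#' merges p-coumaroyl-CoA with the externally set malonyl-CoA pool
#' `Ma_level`), the extended biosensor branch (naringenin ->
#' dihydrokaempferol -> kaempferol, sensed by the QdoR repressor), the
#' realistic antithetic controller (sigma / anti-sigma / sequestration
#' complex with promoter leakage `alpha` and explicit complex unbinding),
#' the CHS actuator with a constitutive baseline, and the AHL/LuxR
#' reference block with passive membrane diffusion between one cell and the
#' shared external volume.  The population is homogeneous, so the total
#' AHL secreted by `x` cells is `x * A`.
#'
#' @param state named numeric vector with components [naringenin_species()].
#' @param params a [naringenin_params()] object.
#' @return Named numeric vector of time derivatives.
#' @export
naringenin_rhs <- function(state, params) {
  s <- .check_state(state, naringenin_species())
  met <- params$metabolic; bio <- params$biosensor; ctl <- params$controller
  act <- params$actuator; ahl <- params$ahl; glb <- params$global
  mu <- glb$mu

  ## metabolic fluxes (molecules/min)
  V0 <- met$K_Lt
  V_Lt <- mm_flux(met$TAL, s[["Lt"]], met$kcat_TAL, met$Km_Lt)
  V_pC <- mm_flux(met$FCL, s[["pC"]], met$kcat_4CL, met$Km_pC)
  V_pA <- bisubstrate_flux(s[["CHS"]], s[["pA"]], met$Ma_level,
                           met$kcat_CHS, met$Km_pA, met$Km_Ma)
  V_Nc <- mm_flux(met$CHI, s[["Nc"]], met$kcat_CHI, met$Km_Nc)
  V_N <- mm_flux(met$F3H, s[["N"]], met$kcat_F3H, met$Km_N)
  V_Di <- mm_flux(met$FLS, s[["Di"]], met$kcat_FLS, met$Km_Di)

  ## controller sequestration kinetics
  bind <- (ctl$k_minus_c / ctl$kdc) * s[["sigma"]] * s[["asigma"]]
  unbind <- ctl$k_minus_c * s[["complex_sa"]]

  ## promoter activities (leakage alpha, regulated fraction in [0,1])
  act_lux <- ctl$alpha + (1 - ctl$alpha) *
    f_lux(s[["A"]], s[["R"]], ctl$kdlux, ctl$kd2, bio$CN)
  act_qdo <- ctl$alpha + (1 - ctl$alpha) *
    f_qdo(s[["Ka"]], s[["Q"]], bio$kdq, bio$kdk, bio$CN)
  act_p20 <- ctl$alpha + (1 - ctl$alpha) *
    f_p20(s[["sigma"]], act$kd20_n, act$kd_sigma, act$CN_h)

  Vc <- ahl$Vcell / ahl$Vext

  c(
    Lt = V0 - V_Lt - mu * s[["Lt"]],
    pC = V_Lt - V_pC - mu * s[["pC"]],
    pA = V_pC - V_pA - mu * s[["pA"]],
    Nc = V_pA - V_Nc - mu * s[["Nc"]],
    N = V_Nc - V_N - mu * s[["N"]],
    Di = V_N - V_Di - mu * s[["Di"]],
    Ka = V_Di - mu * s[["Ka"]],
    Q = bio$pQ * bio$CN * bio$kQ / (bio$dmQ + mu) - (bio$dQ + mu) * s[["Q"]],
    sigma = ctl$p_sigma * bio$CN * ctl$k_sigma_n / (ctl$dm_sigma + mu) * act_lux -
      bind + unbind - (ctl$d_sigma + mu) * s[["sigma"]],
    asigma = ctl$p_asigma * ctl$CN_asigma * ctl$k_asigma_n /
      (ctl$dm_asigma + mu) * act_qdo -
      bind + unbind - (ctl$d_asigma + mu) * s[["asigma"]],
    complex_sa = bind - unbind - (ctl$d_c + mu) * s[["complex_sa"]],
    CHS = act$beta * act$p_Hc * act$CN_h * act$k_H / (act$dm_H + mu) +
      act$p_H * act$CN_h * act$k_H / (act$dm_H + mu) * act_p20 -
      (act$d_H + mu) * s[["CHS"]],
    R = ahl$p_R * bio$CN * ahl$k_R / (ahl$dm_R + mu) - (ahl$d_R + mu) * s[["R"]],
    A = ahl$D * (Vc * s[["Ae"]] - s[["A"]]) - (ahl$d_A + mu) * s[["A"]],
    Ae = ahl$D * (s[["x"]] * s[["A"]] - s[["x"]] * Vc * s[["Ae"]]) -
      ahl$d_Ae * s[["Ae"]],
    x = mu * s[["x"]] * (1 - s[["x"]] / glb$xmax)
  )
}

#' Model handles
#'
#' Bundles a model's right-hand side, species names and perturbation target
#' so that the simulation layer can treat both systems uniformly.
#'
#' @param model `"merging"` or `"naringenin"`.
#' @return A list with elements `name`, `rhs(state, params)`, `species`,
#'   and `pert_target` (the parameter field perturbations act on by
#'   default).
#' @export
get_model <- function(model = c("merging", "naringenin")) {
  model <- match.arg(model)
  if (model == "merging") {
    list(name = "merging", rhs = merging_rhs, species = merging_species(),
         pert_target = "S2_level")
  } else {
    list(name = "naringenin", rhs = naringenin_rhs,
         species = naringenin_species(), pert_target = "Ma_level")
  }
}
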