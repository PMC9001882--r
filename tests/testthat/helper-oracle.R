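# Independent right-hand-side oracles.
#
# Each model's derivative is transcribed here directly from the governing
# equations as one flat symbolic expression per state variable, evaluated
# with eval() in an environment holding the state and parameter symbols.
# This construction shares no code with the package's kernel-composed RHS
# functions, so agreement at random points checks the composition.

oracle_merging_rhs <- function(state, params) {
  env <- list2env(c(as.list(state), unclass(params)))
  exprs <- c(
    S1 = "K_S1 - kcat*E*S1*S2_level/(Km_S1*Km_S2 + Km_S2*S1 + Km_S1*S2_level + S1*S2_level) - mu*S1",
    P = "kcat*E*S1*S2_level/(Km_S1*Km_S2 + Km_S2*S1 + Km_S1*S2_level + S1*S2_level) - mu*P",
    E = "CN*a0 + CN*a1*sigma^2/(kd20^2*CN^2 + sigma^2) - (d_E + mu)*E",
    sigma = "CN*k_sigma - gamma*sigma*asigma - (d_sigma + mu)*sigma",
    asigma = paste0(
      "CN*k_asigma*(CN^2*(1 + P/kdp)^2/(CN^2*(1 + P/kdp)^2 + TF_total^2))",
      " - gamma*sigma*asigma - (d_asigma + mu)*asigma"),
    X = "mu*X*(1 - X/Xmax)"
  )
  vapply(exprs, function(e) eval(parse(text = e), env), numeric(1))
}

oracle_naringenin_rhs <- function(state, params) {
  flat <- c(params$metabolic, params$biosensor, params$controller,
            params$actuator, params$ahl, params$global)
  env <- list2env(c(as.list(state), flat))
  V <- c(
    V_Lt = "kcat_TAL*TAL*Lt/(Km_Lt + Lt)",
    V_pC = "kcat_4CL*FCL*pC/(Km_pC + pC)",
    V_pA = "kcat_CHS*CHS*pA*Ma_level/(Km_pA*Km_Ma + Km_Ma*pA + Km_pA*Ma_level + pA*Ma_level)",
    V_Nc = "kcat_CHI*CHI*Nc/(Km_Nc + Nc)",
    V_N = "kcat_F3H*F3H*N/(Km_N + N)",
    V_Di = "kcat_FLS*FLS*Di/(Km_Di + Di)"
  )
  for (nm in names(V)) assign(nm, eval(parse(text = V[[nm]]), env), envir = env)
  exprs <- c(
    Lt = "K_Lt - V_Lt - mu*Lt",
    pC = "V_Lt - V_pC - mu*pC",
    pA = "V_pC - V_pA - mu*pA",
    Nc = "V_pA - V_Nc - mu*Nc",
    N = "V_Nc - V_N - mu*N",
    Di = "V_N - V_Di - mu*Di",
    Ka = "V_Di - mu*Ka",
    Q = "pQ*CN*kQ/(dmQ + mu) - (dQ + mu)*Q",
    sigma = paste0(
      "p_sigma*CN*k_sigma_n/(dm_sigma + mu)*",
      "(alpha + (1 - alpha)*A^2/(kdlux*kd2*CN/R^2 + A^2))",
      " - (k_minus_c/kdc)*sigma*asigma + k_minus_c*complex_sa",
      " - (d_sigma + mu)*sigma"),
    asigma = paste0(
      "p_asigma*CN_asigma*k_asigma_n/(dm_asigma + mu)*",
      "(alpha + (1 - alpha)*(kdq*CN^2*kdk + Ka^2)/(kdq*CN^2*kdk + Ka^2 + kdk*Q^2))",
      " - (k_minus_c/kdc)*sigma*asigma + k_minus_c*complex_sa",
      " - (d_asigma + mu)*asigma"),
    complex_sa = paste0(
      "(k_minus_c/kdc)*sigma*asigma - k_minus_c*complex_sa",
      " - (d_c + mu)*complex_sa"),
    CHS = paste0(
      "beta*p_Hc*CN_h*k_H/(dm_H + mu) + p_H*CN_h*k_H/(dm_H + mu)*",
      "(alpha + (1 - alpha)*sigma^2/(kd20_n*kd_sigma*CN_h^2 + sigma^2))",
      " - (d_H + mu)*CHS"),
    R = "p_R*CN*k_R/(dm_R + mu) - (d_R + mu)*R",
    A = "D*((Vcell/Vext)*Ae - A) - (d_A + mu)*A",
    Ae = "D*(x*A - x*(Vcell/Vext)*Ae) - d_Ae*Ae",
    x = "mu*x*(1 - x/xmax)"
  )
  vapply(exprs, function(e) eval(parse(text = e), env), numeric(1))
}

# Random strictly positive states/parameters for property tests.

random_merging_point <- function() {
  ru <- function(lo, hi) exp(runif(1, log(lo), log(hi)))
  params <- merging_params(
    K_S1 = ru(1, 1e5), kcat = ru(0.1, 100), Km_S1 = ru(10, 1e6),
    Km_S2 = ru(10, 1e6), S2_level = ru(1, 1e6), CN = ru(1, 50),
    a0 = ru(1e-3, 10), a1 = ru(1, 500), kd20 = ru(10, 1e6),
    k_sigma = ru(1, 5e3), gamma = ru(1e-6, 1e-2), k_asigma = ru(1, 5e3),
    kdp = ru(1, 1e4), TF_total = ru(1, 1e6), d_E = ru(1e-4, 0.1),
    d_sigma = ru(1e-4, 0.1), d_asigma = ru(1e-4, 0.1),
    mu = ru(1e-3, 0.05), Xmax = ru(1e3, 1e10)
  )
  state <- sapply(c(S1 = 6, P = 6, E = 5, sigma = 6, asigma = 5, X = 9),
                  function(hi) ru(1e-2, 10^hi))
  names(state) <- merging_species()
  list(state = state, params = params)
}

random_naringenin_point <- function() {
  ru <- function(lo, hi) exp(runif(1, log(lo), log(hi)))
  flat <- unlist(naringenin_params(), recursive = TRUE)
  names(flat) <- sub("^[a-z]+\\.", "", names(flat))
  jitter <- flat * exp(runif(length(flat), log(0.2), log(5)))
  jitter["alpha"] <- runif(1, 0, 1)
  jitter["beta"] <- runif(1, 0, 1)
  jitter["Vcell"] <- ru(1e-16, 1e-14)
  jitter["Vext"] <- ru(0.1, 10)
  params <- do.call(naringenin_params, as.list(jitter))
  state <- stats::setNames(
    vapply(naringenin_species(), function(s) ru(1e-2, 1e8), numeric(1)),
    naringenin_species())
  list(state = state, params = params)
}
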