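#' Titer target error (J1)
#'
#' Absolute deviation of the achieved titer from the target:
#' `J1 = |target - K * P_T|`, where `P_T` is the unperturbed product amount
#' at the end of the experiment and `K` converts product amount to titer
#' units (g/L for naringenin via [knar_conversion()]; model units for the
#' merging example).
#'
#' @param P_T unperturbed product amount at time T (molecules).
#' @param K amount-to-titer conversion constant (> 0).
#' @param target target titer.
#' @return Nonnegative scalar `J1`.
#' @export
j1_titer_error <- function(P_T, K, target) {
  stopifnot(P_T >= 0, K > 0)
  abs(target - K * P_T)
}

#' Production loss after perturbation (J2)
#'
#' Fractional end-point production loss caused by the perturbation:
#' `J2 = (P_unp(T) - P_pert(T)) / P_unp(T)`.  Kept signed: a negative value
#' means production rose after the perturbation.
#'
#' @param P_unp_T unperturbed product amount at time T (> 0).
#' @param P_pert_T perturbed product amount at time T.
#' @return Scalar `J2` (dimensionless fraction).
#' @export
j2_production_loss <- function(P_unp_T, P_pert_T) {
  if (P_unp_T <= 0) stop("production loss undefined for P_unp(T) <= 0", call. = FALSE)
  (P_unp_T - P_pert_T) / P_unp_T
}

#' Clipped binary sigma signal
#'
#' Maps a sigma-factor time series to the clipped binary signal used for
#' mean-crossing detection: `X(k) = (sign(reference - sigma(k)) + 1) / 2`,
#' so samples below the reference give 1, above give 0 and exact ties give
#' 0.5.
#'
#' @param sigma_series numeric series of sigma amounts.
#' @param reference crossing reference; defaults to the series mean.
#' @return Vector with values in `{0, 0.5, 1}`.
#' @export
clip_binary <- function(sigma_series, reference = mean(sigma_series)) {
  stopifnot(length(sigma_series) >= 1)
  (sign(reference - sigma_series) + 1) / 2
}

#' Oscillation count of the sigma factor (J3)
#'
#' Counts mean-crossings of the (pre-perturbation) sigma series through the
#' squared increments of its clipped binary version:
#' `J3 = 1/2 * sum_k (X(k) - X(k-1))^2`.  Each crossing contributes 1/2, so
#' a full oscillation period contributes 1, and `J3` is a multiple of 1/4
#' (1/2 on tie-free series).
#'
#' @inheritParams clip_binary
#' @return Nonnegative scalar `J3`.
#' @export
j3_count_oscillations <- function(sigma_series, reference = mean(sigma_series)) {
  stopifnot(length(sigma_series) >= 2)
  X <- clip_binary(sigma_series, reference)
  sum(diff(X)^2) / 2
}

#' Naringenin amount-to-titer conversion constant
#'
#' `K_Nar = mw * x(T) / (Av * Vext)` converts a per-cell naringenin amount
#' (molecules) into a culture titer in g/L: `titer = K_Nar * N(T)`.
#'
#' @param x_T number of cells at time T (`>= 1`).
#' @param mw molecular weight of naringenin (g/mol), default 272.25.
#' @param Av Avogadro's number (1/mol).
#' @param Vext culture volume (L, > 0).
#' @return Conversion constant in g/L per molecule-per-cell.
#' @export
knar_conversion <- function(x_T, mw = 272.25, Av = 6.02214076e23, Vext = 1) {
  stopifnot(x_T >= 1, Vext > 0)
  mw * x_T / (Av * Vext)
}

#' Antithetic-controller operating constraints
#'
#' Evaluates the two controller feasibility constraints on the unperturbed
#' trajectory: (1) the free sigma factor must stay at or above
#' `sigma_min_uM` (default 4.5 uM, converted to molecules with the cell
#' volume), and (2) sigma must dominate anti-sigma, `sigma(t) >= asigma(t)`.
#' Both are checked over an evaluation window, by default the
#' pre-perturbation segment after a 10% burn-in.  The total violation is
#' the sum over the window grid of the constraint shortfalls (in uM).
#'
#' @param traj_unp unperturbed `trajectory` containing `sigma` and
#'   `asigma`.
#' @param sigma_min_uM minimum free sigma level (uM).
#' @param window numeric `c(from, to)` in minutes, or `NULL` to use
#'   `[0.1 * t_window_end, t_window_end]` where `t_window_end` is `t_pert`
#'   (when given) or the trajectory end.
#' @param t_pert perturbation time used to close the default window.
#' @param Vcell cell volume (L) for the uM conversion.
#' @return A `constraint_report`: list with `feasible`, `violation`, and
#'   per-constraint shortfalls `sigma_min` and `sigma_dominance` (uM).
#' @export
evaluate_constraints <- function(traj_unp, sigma_min_uM = 4.5, window = NULL,
                                 t_pert = NULL, Vcell = 1.1e-15) {
  t_hi <- if (!is.null(t_pert)) t_pert else max(traj_unp$times)
  if (is.null(window)) window <- c(0.1 * t_hi, t_hi)
  sig <- uM_from_molecules(
    species_series(traj_unp, "sigma", window[1], window[2]), Vcell = Vcell)
  asig <- uM_from_molecules(
    species_series(traj_unp, "asigma", window[1], window[2]), Vcell = Vcell)
  short_min <- pmax(0, sigma_min_uM - sig)
  short_dom <- pmax(0, asig - sig)
  violation <- sum(short_min) + sum(short_dom)
  structure(list(feasible = violation == 0, violation = violation,
                 sigma_min = max(short_min), sigma_dominance = max(short_dom),
                 window = window),
            class = "constraint_report")
}

#' @export
print.constraint_report <- function(x, ...) {
  cat(sprintf("<constraint_report> %s (violation = %g)\n",
              if (x$feasible) "feasible" else "infeasible", x$violation))
  cat(sprintf("  max sigma-minimum shortfall: %g uM\n", x$sigma_min))
  cat(sprintf("  max sigma-dominance shortfall: %g uM\n", x$sigma_dominance))
  invisible(x)
}

#' Decision-variable bounds
#'
#' The tunable controller/biosensor parameters of each MOP with their
#' biologically plausible lower and upper bounds.  For the merging pathway
#' these are the enzyme expression strength `a1`, the sigma-promoter
#' dissociation constant `kd20`, the anti-sigma expression strength
#' `k_asigma`, and the growth rate `mu`.  For the naringenin pathway:
#' the anti-sigma and CHS translation rates `p_asigma` and `p_H`, the
#' plasmid copy numbers `CN_asigma` and `CN_h` (integers), the complex
#' unbinding rate `k_minus_c`, the CHS-promoter dissociation constant
#' `kd20_n`, and the growth rate `mu`.
#'
#' @return A data frame with columns `name`, `lower`, `upper`, `integer`.
#' @export
merging_bounds <- function() {
  data.frame(
    name = c("a1", "kd20", "k_asigma", "mu"),
    lower = c(90, 1e5, 700, 0.005),
    upper = c(160, 3.5e5, 1500, 0.01),
    integer = FALSE
  )
}

#' @rdname merging_bounds
#' @export
naringenin_bounds <- function() {
  data.frame(
    name = c("p_asigma", "CN_asigma", "p_H", "CN_h", "k_minus_c", "kd20_n", "mu"),
    lower = c(0.1, 1, 0.1, 1, 0.01, 1e-2, 0.0069),
    upper = c(20, 15, 20, 15, 20, 1e4, 0.0231),
    integer = c(FALSE, TRUE, FALSE, TRUE, FALSE, FALSE, FALSE)
  )
}

.check_theta <- function(theta, bounds) {
  if (is.null(names(theta))) names(theta) <- bounds$name
  theta <- theta[bounds$name]
  if (any(is.na(theta))) stop("decision vector is missing components", call. = FALSE)
  if (any(theta < bounds$lower - 1e-12) || any(theta > bounds$upper + 1e-12)) {
    stop("decision vector outside its bounds", call. = FALSE)
  }
  theta[bounds$integer] <- round(theta[bounds$integer])
  theta
}

#' Evaluate the merging-pathway MOP at one decision vector
#'
#' Patches the base parameters with the decision vector
#' `(a1, kd20, k_asigma, mu)`, runs the paired perturbation protocol and
#' returns the two objectives.  The reported-only `E_max_uM` diagnostic is
#' the peak enzyme level in uM (the wet-lab design guideline caps it at
#' 180 uM); it never enters the optimization.
#'
#' @param theta named (or bounds-ordered) decision vector within
#'   [merging_bounds()].
#' @param base_params a [merging_params()] object.
#' @param protocol a [sim_protocol()] with a perturbation.
#' @param target,K MOP target titer and conversion constant; defaults from
#'   the registry MOP section.
#' @return List with `J` (named numeric `c(J1, J2)`), `violation` (0),
#'   `feasible`, and `diagnostics`.  Failed integrations yield `Inf`
#'   objectives rather than an error, so optimizer bookkeeping stays
#'   simple.
#' @export
evaluate_merging <- function(theta, base_params = merging_params(),
                             protocol = default_protocol("merging"),
                             target = NULL, K = NULL) {
  mop <- default_mop("merging")
  target <- target %||% mop$target_titer
  K <- K %||% mop$K
  theta <- .check_theta(theta, merging_bounds())
  params <- set_params(base_params, as.list(theta))
  res <- tryCatch(run_paired("merging", params, protocol), error = identity)
  if (inherits(res, "error")) {
    return(list(J = c(J1 = Inf, J2 = Inf), violation = Inf, feasible = FALSE,
                diagnostics = list(error = conditionMessage(res))))
  }
  P_u <- endpoint(res$unperturbed)[["P"]]
  P_p <- endpoint(res$perturbed)[["P"]]
  E_max <- max(res$unperturbed$states[, "E"], res$perturbed$states[, "E"])
  list(
    J = c(J1 = j1_titer_error(P_u, K, target),
          J2 = j2_production_loss(P_u, P_p)),
    violation = 0, feasible = TRUE,
    diagnostics = list(P_unp = P_u, P_pert = P_p,
                       E_max_uM = uM_from_molecules(E_max))
  )
}

#' Evaluate the naringenin-pathway MOP at one decision vector
#'
#' Patches the base parameters with the decision vector
#' `(p_asigma, CN_asigma, p_H, CN_h, k_minus_c, kd20_n, mu)` (copy numbers
#' rounded to integers), runs the paired malonyl-CoA perturbation protocol
#' and returns the three objectives plus the controller constraint report.
#' `J1` is the deviation from the target titer in g/L using
#' [knar_conversion()] at the final cell count; `J3` is computed on the
#' pre-perturbation sigma series after a 10% burn-in.
#'
#' @param theta named (or bounds-ordered) decision vector within
#'   [naringenin_bounds()].
#' @param base_params a [naringenin_params()] object.
#' @param protocol a [sim_protocol()] with a `Ma_level` perturbation.
#' @param target target titer in g/L (default from the registry).
#' @return List with `J` (named numeric `c(J1, J2, J3)`), `violation`,
#'   `feasible`, `constraints` (a `constraint_report`) and `diagnostics`.
#' @export
evaluate_naringenin <- function(theta, base_params = naringenin_params(),
                                protocol = default_protocol("naringenin"),
                                target = NULL) {
  mop <- default_mop("naringenin")
  target <- target %||% mop$target_titer
  theta <- .check_theta(theta, naringenin_bounds())
  params <- set_params(base_params, as.list(theta))
  res <- tryCatch(run_paired("naringenin", params, protocol), error = identity)
  if (inherits(res, "error")) {
    return(list(J = c(J1 = Inf, J2 = Inf, J3 = Inf), violation = Inf,
                feasible = FALSE,
                diagnostics = list(error = conditionMessage(res))))
  }
  t_pert <- protocol$perturbation$t_pert
  N_u <- endpoint(res$unperturbed)[["N"]]
  N_p <- endpoint(res$perturbed)[["N"]]
  x_T <- endpoint(res$unperturbed)[["x"]]
  K <- knar_conversion(x_T, mw = params$global$mw, Av = params$global$Av,
                       Vext = params$ahl$Vext)
  sig_pre <- species_series(res$unperturbed, "sigma",
                            from = 0.1 * t_pert, to = t_pert)
  cons <- evaluate_constraints(res$unperturbed,
                               sigma_min_uM = mop$sigma_min_uM %||% 4.5,
                               t_pert = t_pert,
                               Vcell = params$ahl$Vcell)
  list(
    J = c(J1 = j1_titer_error(N_u, K, target),
          J2 = j2_production_loss(N_u, N_p),
          J3 = j3_count_oscillations(sig_pre)),
    violation = cons$violation, feasible = cons$feasible, constraints = cons,
    diagnostics = list(N_unp = N_u, N_pert = N_p, x_T = x_T,
                       titer_unp = K * N_u)
  )
}

#' Matched static (open-loop) regulation baseline
#'
#' Builds the constitutive-expression counterpart of a closed-loop merging
#' design: feedback is disabled (`a1 = 0`) and the basal expression
#' strength `a0` is sized by root finding so that the open loop reaches the
#' same unperturbed end-point product as the closed loop.  Comparing the
#' production loss J2 of the two isolates the benefit of dynamic
#' regulation from mere expression-level differences.
#'
#' @param params closed-loop [merging_params()].
#' @param protocol a [sim_protocol()] with a perturbation.
#' @param a0_max upper bracket for the basal strength search.
#' @return A `merging_params` object with `a1 = 0` and matched `a0`.
#' @export
static_baseline_params <- function(params, protocol, a0_max = 100) {
  target_P <- endpoint(integrate_model("merging", params, protocol,
                                       perturbed = FALSE))[["P"]]
  gap <- function(a0) {
    ps <- set_params(params, list(a1 = 0, a0 = a0))
    endpoint(integrate_model("merging", ps, protocol,
                             perturbed = FALSE))[["P"]] - target_P
  }
  a0 <- stats::uniroot(gap, c(1e-6, a0_max), tol = 1e-8)$root
  set_params(params, list(a1 = 0, a0 = a0))
}
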