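#' Parameter registry
#'
#' Model parameter sets are shipped as structured YAML files (one per named
#' registry entry) under `inst/extdata/registry/`, with units recorded per
#' field.  `param_registry()` lists the available entries;
#' `registry_entry()` loads one in full (parameters, default initial state,
#' default protocol and MOP settings).
#'
#' @param entry registry entry name, e.g. `"merging-default"`.
#' @param file path to a registry YAML file (overrides `entry`).
#' @return `param_registry()` returns a character vector of entry names;
#'   `registry_entry()` the parsed registry list.
#' @export
param_registry <- function() {
  dir <- system.file("extdata", "registry", package = "antitune")
  sub("\\.yaml$", "", list.files(dir, pattern = "\\.yaml$"))
}

#' @rdname param_registry
#' @export
registry_entry <- function(entry = "merging-default", file = NULL) {
  if (is.null(file)) {
    file <- system.file("extdata", "registry", paste0(entry, ".yaml"),
                        package = "antitune")
    if (!nzchar(file)) {
      stop(sprintf("registry entry '%s' not found (available: %s)",
                   entry, paste(param_registry(), collapse = ", ")),
           call. = FALSE)
    }
  }
  if (!file.exists(file)) stop(sprintf("registry file '%s' not found", file), call. = FALSE)
  reg <- yaml::read_yaml(file)
  for (f in c("model", "params", "initial_state")) {
    if (is.null(reg[[f]])) stop(sprintf("registry file '%s' lacks field '%s'", file, f), call. = FALSE)
  }
  reg
}

.merging_fields <- c(
  "K_S1", "kcat", "Km_S1", "Km_S2", "S2_level", "CN", "a0", "a1", "kd20",
  "k_sigma", "gamma", "k_asigma", "kdp", "TF_total", "d_E", "d_sigma",
  "d_asigma", "mu", "Xmax"
)

.naringenin_groups <- list(
  metabolic = c("K_Lt", "kcat_TAL", "kcat_4CL", "kcat_CHS", "kcat_CHI",
                "kcat_F3H", "kcat_FLS", "Km_Lt", "Km_pC", "Km_pA", "Km_Ma",
                "Km_Nc", "Km_N", "Km_Di", "TAL", "FCL", "CHI", "F3H", "FLS",
                "Ma_level"),
  biosensor = c("pQ", "kQ", "dmQ", "dQ", "kdq", "kdk", "CN"),
  controller = c("p_sigma", "k_sigma_n", "dm_sigma", "d_sigma", "alpha",
                 "kdlux", "kd2", "kdc", "k_minus_c", "d_c", "p_asigma",
                 "CN_asigma", "k_asigma_n", "dm_asigma", "d_asigma"),
  actuator = c("beta", "p_Hc", "p_H", "CN_h", "k_H", "dm_H", "d_H",
               "kd20_n", "kd_sigma"),
  ahl = c("p_R", "k_R", "dm_R", "d_R", "D", "Vcell", "Vext", "d_A", "d_Ae",
          "Ae_dose"),
  global = c("mu", "xmax", "mw", "Av")
)

#' Merging-pathway model parameters
#'
#' Constructs a validated parameter set for the simplified merging-pathway
#' model.  Defaults come from the `"merging-default"` registry entry; any
#' field can be overridden by name.
#'
#' @param ... named overrides of individual parameter fields.
#' @param registry registry entry name to use for defaults.
#' @return An object of class `merging_params` (a named list).
#' @examples
#' p <- merging_params(mu = 0.006)
#' p$mu
#' @export
merging_params <- function(..., registry = "merging-default") {
  base <- registry_entry(registry)$params
  p <- utils::modifyList(base, .named_dots(...))
  missing <- setdiff(.merging_fields, names(p))
  if (length(missing)) stop("missing merging parameters: ", paste(missing, collapse = ", "), call. = FALSE)
  unknown <- setdiff(names(p), .merging_fields)
  if (length(unknown)) stop("unknown merging parameters: ", paste(unknown, collapse = ", "), call. = FALSE)
  p <- p[.merging_fields]
  vals <- unlist(p)
  if (any(!is.finite(vals)) || any(vals < 0)) stop("all merging parameters must be finite and >= 0", call. = FALSE)
  if (p$CN < 1) stop("'CN' must be >= 1", call. = FALSE)
  if (p$Xmax < 1) stop("'Xmax' must be >= 1", call. = FALSE)
  if (p$mu <= 0) stop("'mu' must be > 0", call. = FALSE)
  structure(p, class = c("merging_params", "antitune_params"))
}

#' Naringenin-pathway model parameters
#'
#' Constructs a validated, group-structured parameter set for the detailed
#' naringenin model (sub-records `metabolic`, `biosensor`, `controller`,
#' `actuator`, `ahl`, `global`).  Defaults come from the
#' `"naringenin-default"` registry entry.  Overrides are given with flat
#' field names (all field names are unique across groups), e.g.
#' `naringenin_params(p_H = 8, mu = 0.01)`.
#'
#' @param ... named overrides of individual parameter fields (flat names).
#' @param registry registry entry name to use for defaults.
#' @return An object of class `naringenin_params` (a list of group lists).
#' @export
naringenin_params <- function(..., registry = "naringenin-default") {
  p <- registry_entry(registry)$params
  dots <- .named_dots(...)
  for (nm in names(dots)) {
    grp <- .nar_group_of(nm)
    p[[grp]][[nm]] <- dots[[nm]]
  }
  for (grp in names(.naringenin_groups)) {
    missing <- setdiff(.naringenin_groups[[grp]], names(p[[grp]]))
    if (length(missing)) {
      stop(sprintf("missing naringenin parameters in group '%s': %s",
                   grp, paste(missing, collapse = ", ")), call. = FALSE)
    }
    p[[grp]] <- p[[grp]][.naringenin_groups[[grp]]]
  }
  vals <- unlist(p)
  if (any(!is.finite(vals)) || any(vals < 0)) stop("all naringenin parameters must be finite and >= 0", call. = FALSE)
  if (p$controller$alpha > 1) stop("'alpha' must be in [0, 1]", call. = FALSE)
  if (p$actuator$beta > 1) stop("'beta' must be in [0, 1]", call. = FALSE)
  if (p$ahl$Vcell >= p$ahl$Vext) stop("'Vcell' must be smaller than 'Vext'", call. = FALSE)
  structure(p, class = c("naringenin_params", "antitune_params"))
}

.nar_group_of <- function(field) {
  for (grp in names(.naringenin_groups)) {
    if (field %in% .naringenin_groups[[grp]]) return(grp)
  }
  stop(sprintf("unknown naringenin parameter '%s'", field), call. = FALSE)
}

.named_dots <- function(...) {
  dots <- list(...)
  if (length(dots) && (is.null(names(dots)) || any(!nzchar(names(dots))))) {
    stop("parameter overrides must be named", call. = FALSE)
  }
  dots
}

#' Patch a parameter set by flat field names
#'
#' Returns a copy of `params` with the named fields replaced.  Works for
#' both model families; for naringenin parameters the flat field name is
#' located in its group automatically.
#'
#' @param params a `merging_params` or `naringenin_params` object.
#' @param updates named list (or named numeric vector) of new values.
#' @return The patched, re-validated parameter object.
#' @export
set_params <- function(params, updates) {
  updates <- as.list(updates)
  if (inherits(params, "merging_params")) {
    for (nm in names(updates)) {
      if (!nm %in% .merging_fields) stop(sprintf("unknown merging parameter '%s'", nm), call. = FALSE)
      params[[nm]] <- updates[[nm]]
    }
    do.call(merging_params, c(unclass(params), list(registry = "merging-default")))
  } else if (inherits(params, "naringenin_params")) {
    flat <- list()
    for (grp in names(.naringenin_groups)) flat <- c(flat, params[[grp]])
    for (nm in names(updates)) flat[[nm]] <- updates[[nm]]
    do.call(naringenin_params, c(flat, list(registry = "naringenin-default")))
  } else {
    stop("'params' must be a merging_params or naringenin_params object", call. = FALSE)
  }
}

#' @export
print.antitune_params <- function(x, ...) {
  kind <- if (inherits(x, "merging_params")) "merging" else "naringenin"
  cat(sprintf("<%s_params>\n", kind))
  flat <- unlist(x)
  cat(sprintf("  %d parameters; e.g. mu = %g\n", length(flat),
              flat[[grep("(^|\\.)mu$", names(flat))[1]]]))
  invisible(x)
}

#' Default initial state, protocol and MOP settings for a model
#'
#' Convenience accessors for the non-kinetic sections of a registry entry.
#'
#' @param model `"merging"` or `"naringenin"`.
#' @param registry registry entry name; defaults to `"<model>-default"`.
#' @return `default_initial_state()` a named numeric vector of species
#'   amounts; `default_protocol()` a [sim_protocol()]; `default_mop()` a list
#'   of MOP settings (target titer etc.).
#' @export
default_initial_state <- function(model = c("merging", "naringenin"),
                                  registry = NULL) {
  model <- match.arg(model)
  reg <- registry_entry(registry %||% paste0(model, "-default"))
  unlist(reg$initial_state)
}

#' @rdname default_initial_state
#' @export
default_protocol <- function(model = c("merging", "naringenin"),
                             registry = NULL) {
  model <- match.arg(model)
  reg <- registry_entry(registry %||% paste0(model, "-default"))
  pr <- reg$protocol
  sim_protocol(
    t_end = pr$t_end,
    n_points = pr$n_points,
    initial_state = unlist(reg$initial_state),
    perturbation = perturbation_spec(pr$t_pert, pr$target, pr$reduction)
  )
}

#' @rdname default_initial_state
#' @export
default_mop <- function(model = c("merging", "naringenin"), registry = NULL) {
  model <- match.arg(model)
  registry_entry(registry %||% paste0(model, "-default"))$mop
}

`%||%` <- function(a, b) if (is.null(a)) b else a
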