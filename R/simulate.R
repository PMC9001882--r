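#' Perturbation specification
#'
#' A mid-course step perturbation of an externally set substrate pool: at
#' time `t_pert` the parameter `target` is replaced by
#' `(1 - reduction) * target`.
#'
#' @param t_pert perturbation time (min), `>= 0`.
#' @param target name of the perturbed parameter (`"S2_level"` for the
#'   merging model, `"Ma_level"` for the naringenin model).
#' @param reduction fractional reduction in `[0, 1]` (0.6 means the pool
#'   drops to 40% of its nominal value).
#' @return An object of class `perturbation_spec`.
#' @export
perturbation_spec <- function(t_pert, target = "S2_level", reduction = 0.6) {
  stopifnot(is.numeric(t_pert), length(t_pert) == 1, t_pert >= 0,
            is.character(target), length(target) == 1,
            is.numeric(reduction), length(reduction) == 1,
            reduction >= 0, reduction <= 1)
  structure(list(t_pert = t_pert, target = target, reduction = reduction),
            class = "perturbation_spec")
}

#' Simulation protocol
#'
#' Defines one numerical experiment: the time horizon, output grid size,
#' initial state and (optionally) a [perturbation_spec()].
#'
#' @param t_end end of the experiment (min).
#' @param n_points number of output grid points (`>= 2`).
#' @param initial_state named numeric vector of initial species amounts; if
#'   `NULL` the model's registry default is used at integration time.
#' @param perturbation a [perturbation_spec()], or `NULL` for an
#'   unperturbed run.
#' @return An object of class `sim_protocol`.
#' @export
sim_protocol <- function(t_end, n_points = 1041, initial_state = NULL,
                         perturbation = NULL) {
  stopifnot(is.numeric(t_end), t_end > 0, n_points >= 2)
  if (!is.null(perturbation)) {
    stopifnot(inherits(perturbation, "perturbation_spec"))
    if (perturbation$t_pert >= t_end) stop("'t_pert' must be < 't_end'", call. = FALSE)
  }
  structure(list(t_end = t_end, n_points = n_points,
                 initial_state = initial_state, perturbation = perturbation),
            class = "sim_protocol")
}

.traj_tol_neg <- 1e-9

.make_trajectory <- function(times, states, species, events = list()) {
  colnames(states) <- species
  if (any(!is.finite(states))) stop("integration produced non-finite states", call. = FALSE)
  low <- min(states)
  if (low < -.traj_tol_neg * max(1, max(abs(states)))) {
    warning(sprintf("trajectory dips below zero (min %g); clipping", low))
  }
  states[states < 0] <- 0
  structure(list(times = times, states = states, species = species,
                 events = events),
            class = "trajectory")
}

#' Integrate a model over a protocol
#'
#' Solves the initial-value problem with a stiff-capable implicit solver
#' (`deSolve::ode`, method `"lsoda"`).  When the protocol carries a
#' perturbation, the integration is split at `t_pert` and restarted with
#' the perturbed parameter value, matching a sudden step change in
#' substrate availability.  Small negative excursions (below `1e-9`
#' relative) are clipped to zero on output.
#'
#' @param model a model name (`"merging"`/`"naringenin"`) or a handle from
#'   [get_model()].
#' @param params the matching parameter object.
#' @param protocol a [sim_protocol()].
#' @param perturbed logical; apply the protocol's perturbation?  (Used by
#'   [run_paired()] to share one protocol between both runs.)
#' @param rtol,atol relative / absolute solver tolerances.
#' @return A `trajectory` object: `times` (min), `states`
#'   (`n_points x n_species` matrix, molecules or cells), `species`,
#'   `events` (list of `(time, description)`).
#' @export
integrate_model <- function(model, params, protocol, perturbed = TRUE,
                            rtol = 1e-8, atol = 1e-6) {
  mod <- if (is.character(model)) get_model(model) else model
  y0 <- protocol$initial_state %||% default_initial_state(mod$name)
  y0 <- .check_state(y0, mod$species)
  grid <- seq(0, protocol$t_end, length.out = protocol$n_points)
  pert <- protocol$perturbation
  events <- list()

  # lsoda may probe slightly negative states; clamp before the strict kernels
  func <- function(t, y, p) list(unname(mod$rhs(pmax(y, 0), p)))
  solve_piece <- function(times, y, p) {
    out <- deSolve::ode(y = y, times = times, func = func, parms = p,
                        method = "lsoda", rtol = rtol, atol = atol)
    if (attr(out, "istate")[1L] < 0 || nrow(out) < length(times)) {
      stop(sprintf("integration failed near t = %g min", out[nrow(out), 1]),
           call. = FALSE)
    }
    out
  }

  if (is.null(pert) || !perturbed) {
    out <- solve_piece(grid, y0, params)
    return(.make_trajectory(out[, 1], out[, -1, drop = FALSE], mod$species, events))
  }

  grid1 <- sort(unique(c(grid[grid <= pert$t_pert], pert$t_pert)))
  grid2 <- sort(unique(c(pert$t_pert, grid[grid > pert$t_pert], protocol$t_end)))
  out1 <- solve_piece(grid1, y0, params)
  p2 <- set_params(params, stats::setNames(
    list((1 - pert$reduction) * .get_param(params, pert$target)), pert$target))
  y_mid <- pmax(out1[nrow(out1), -1], 0)
  names(y_mid) <- mod$species
  out2 <- solve_piece(grid2, y_mid, p2)
  events <- list(list(
    time = pert$t_pert,
    description = sprintf("%s reduced by %g%% (to %g)", pert$target,
                          100 * pert$reduction,
                          (1 - pert$reduction) * .get_param(params, pert$target))
  ))
  times <- c(out1[, 1], out2[-1, 1])
  states <- rbind(out1[, -1, drop = FALSE], out2[-1, -1, drop = FALSE])
  .make_trajectory(times, states, mod$species, events)
}

.get_param <- function(params, field) {
  if (inherits(params, "merging_params")) return(params[[field]])
  params[[.nar_group_of(field)]][[field]]
}

#' Paired unperturbed / perturbed simulation
#'
#' Runs the protocol twice from a single shared solve of the
#' pre-perturbation segment: the perturbed run continues with the stepped
#' parameter, the unperturbed run continues with the original parameters.
#' Both trajectories are therefore identical on `[0, t_pert]`.
#'
#' @inheritParams integrate_model
#' @return A list with elements `unperturbed` and `perturbed`, both
#'   `trajectory` objects on the same time grid.
#' @export
run_paired <- function(model, params, protocol, rtol = 1e-8, atol = 1e-6) {
  if (is.null(protocol$perturbation)) {
    stop("'protocol' must carry a perturbation for a paired run", call. = FALSE)
  }
  mod <- if (is.character(model)) get_model(model) else model
  pert <- protocol$perturbation
  ## shared pre-perturbation path
  pre <- sim_protocol(t_end = protocol$t_end, n_points = protocol$n_points,
                      initial_state = protocol$initial_state,
                      perturbation = pert)
  traj_p <- integrate_model(mod, params, pre, perturbed = TRUE,
                            rtol = rtol, atol = atol)
  ## unperturbed continuation from the identical split state
  idx_split <- which(traj_p$times == pert$t_pert)[1]
  y_mid <- traj_p$states[idx_split, ]
  grid2 <- traj_p$times[traj_p$times >= pert$t_pert]
  func <- function(t, y, p) list(unname(mod$rhs(pmax(y, 0), p)))
  out2 <- deSolve::ode(y = y_mid, times = grid2, func = func, parms = params,
                       method = "lsoda", rtol = rtol, atol = atol)
  if (attr(out2, "istate")[1L] < 0 || nrow(out2) < length(grid2)) {
    stop("integration failed in the unperturbed continuation", call. = FALSE)
  }
  states_u <- rbind(traj_p$states[seq_len(idx_split - 1), , drop = FALSE],
                    out2[, -1, drop = FALSE])
  traj_u <- .make_trajectory(traj_p$times, states_u, mod$species, list())
  list(unperturbed = traj_u, perturbed = traj_p)
}

#' State at a given time
#'
#' Extracts the state vector at time `T` from a trajectory, exactly at grid
#' nodes and by linear interpolation in between.
#'
#' @param traj a `trajectory`.
#' @param T query time (min) within the stored range.
#' @return Named numeric state vector.
#' @export
endpoint <- function(traj, T = max(traj$times)) {
  stopifnot(inherits(traj, "trajectory"))
  if (T < min(traj$times) || T > max(traj$times)) {
    stop(sprintf("T = %g outside trajectory range [%g, %g]",
                 T, min(traj$times), max(traj$times)), call. = FALSE)
  }
  hit <- which(traj$times == T)
  if (length(hit)) return(stats::setNames(traj$states[hit[1], ], traj$species))
  i <- findInterval(T, traj$times)
  w <- (T - traj$times[i]) / (traj$times[i + 1] - traj$times[i])
  stats::setNames((1 - w) * traj$states[i, ] + w * traj$states[i + 1, ],
                  traj$species)
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("<trajectory> %d species x %d time points, t in [%g, %g] min\n",
              length(x$species), length(x$times), min(x$times), max(x$times)))
  for (ev in x$events) cat(sprintf("  event at t = %g: %s\n", ev$time, ev$description))
  invisible(x)
}

#' @export
as.data.frame.trajectory <- function(x, ...) {
  data.frame(time = x$times, x$states, check.names = FALSE)
}

#' Trajectory CSV export / import
#'
#' Writes a trajectory as CSV (first column `time` in minutes, one column
#' per species) and reads it back.
#'
#' @param traj a `trajectory`.
#' @param file path of the CSV file.
#' @return `write_trajectory_csv()` returns `file` invisibly;
#'   `read_trajectory_csv()` returns a `trajectory`.
#' @export
write_trajectory_csv <- function(traj, file) {
  utils::write.csv(as.data.frame(traj), file, row.names = FALSE)
  invisible(file)
}

#' @rdname write_trajectory_csv
#' @export
read_trajectory_csv <- function(file) {
  df <- utils::read.csv(file, check.names = FALSE)
  if (names(df)[1] != "time") stop("first CSV column must be 'time'", call. = FALSE)
  .make_trajectory(df[[1]], as.matrix(df[, -1, drop = FALSE]),
                   names(df)[-1], list())
}

#' Extract one species' time series
#'
#' @param traj a `trajectory`.
#' @param species species name.
#' @param from,to optional time window (min), inclusive.
#' @return Numeric vector of amounts on the stored grid.
#' @export
species_series <- function(traj, species, from = NULL, to = NULL) {
  stopifnot(species %in% traj$species)
  keep <- rep(TRUE, length(traj$times))
  if (!is.null(from)) keep <- keep & traj$times >= from
  if (!is.null(to)) keep <- keep & traj$times <= to
  traj$states[keep, species]
}
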