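#' Pareto dominance
#'
#' `a` dominates `b` iff `a <= b` componentwise with strict improvement in
#' at least one component (all objectives minimized).
#'
#' @param a,b numeric objective vectors of equal length.
#' @return Logical flag.
#' @export
dominates <- function(a, b) {
  if (length(a) != length(b)) stop("objective vectors differ in length", call. = FALSE)
  all(a <= b) && any(a < b)
}

#' Constrained pairwise preference (feasibility rules)
#'
#' Compares two evaluated individuals by the feasibility-dominance rules: a
#' feasible individual beats an infeasible one; two infeasible individuals
#' are compared by total violation; two feasible ones by Pareto dominance.
#'
#' @param a,b lists with elements `J` (objective vector) and `violation`
#'   (scalar `>= 0`).
#' @return `+1` if `a` is preferred, `-1` if `b` is preferred, `0` if
#'   neither.
#' @export
constrained_compare <- function(a, b) {
  fa <- a$violation <= 0
  fb <- b$violation <= 0
  if (fa && !fb) return(1L)
  if (!fa && fb) return(-1L)
  if (!fa && !fb) {
    if (a$violation < b$violation) return(1L)
    if (b$violation < a$violation) return(-1L)
    return(0L)
  }
  if (dominates(a$J, b$J)) return(1L)
  if (dominates(b$J, a$J)) return(-1L)
  0L
}

#' DE/rand/1/bin trial vector
#'
#' Builds a differential-evolution trial vector for target index `i`:
#' mutant `x_r1 + F * (x_r2 - x_r3)` with binomial crossover against the
#' target (at least one coordinate always taken from the mutant).  Bounds
#' are enforced by reflection (then clamping), and coordinates flagged as
#' integers (plasmid copy numbers) are rounded.  For external-archive
#' elitism, `x_r1` may be drawn from `archive_thetas`.
#'
#' @param pop numeric matrix, one row per population member.
#' @param i target row index.
#' @param F differential weight in `(0, 2]`.
#' @param CR crossover rate in `[0, 1]`.
#' @param bounds data frame with `lower`, `upper`, `integer` (as from
#'   [merging_bounds()]).
#' @param archive_thetas optional matrix of archive decision vectors used
#'   as base-vector pool.
#' @param p_archive probability of drawing the base vector from the
#'   archive.
#' @return Numeric trial vector within bounds.
#' @export
de_trial <- function(pop, i, F, CR, bounds, archive_thetas = NULL,
                     p_archive = 0.5) {
  n <- nrow(pop)
  if (n < 4) stop("DE requires a population of at least 4", call. = FALSE)
  others <- setdiff(seq_len(n), i)
  idx <- sample(others, 3)
  x1 <- pop[idx[1], ]
  if (!is.null(archive_thetas) && nrow(archive_thetas) > 0 &&
      stats::runif(1) < p_archive) {
    x1 <- archive_thetas[sample.int(nrow(archive_thetas), 1), ]
  }
  v <- x1 + F * (pop[idx[2], ] - pop[idx[3], ])
  ## reflect into the box, then clamp any residual overshoot
  lo <- bounds$lower; hi <- bounds$upper
  below <- v < lo; v[below] <- 2 * lo[below] - v[below]
  above <- v > hi; v[above] <- 2 * hi[above] - v[above]
  v <- pmin(pmax(v, lo), hi)
  j_rand <- sample.int(length(v), 1)
  take <- stats::runif(length(v)) <= CR
  take[j_rand] <- TRUE
  trial <- ifelse(take, v, pop[i, ])
  trial[bounds$integer] <- round(trial[bounds$integer])
  unname(trial)
}

#' Spherical pruning of a non-dominated archive
#'
#' Diversity preservation in objective space: objective vectors are min-max
#' normalized to the archive's ideal/nadir box, mapped to hyperspherical
#' sectors (each of the `m - 1` angular coordinates binned into `arcs`
#' uniform divisions of `[0, pi/2]`), and at most one member per sector is
#' retained -- the one with the smallest normalized Euclidean norm (closest
#' to the ideal point).
#'
#' @param J numeric matrix of objective vectors (rows = members), assumed
#'   mutually non-dominated.
#' @param arcs number of angular divisions per spherical coordinate.
#' @return Integer vector of retained row indices (in increasing order).
#' @export
spherical_prune <- function(J, arcs = 50) {
  J <- as.matrix(J)
  n <- nrow(J); m <- ncol(J)
  if (n <= 1) return(seq_len(n))
  ideal <- apply(J, 2, min)
  nadir <- apply(J, 2, max)
  span <- nadir - ideal
  Z <- sweep(J, 2, ideal)
  for (j in seq_len(m)) {
    Z[, j] <- if (span[j] > 0) Z[, j] / span[j] else 0
  }
  sector <- .spherical_sectors(Z, arcs)
  norms <- sqrt(rowSums(Z^2))
  keep <- integer(0)
  for (sec in unique(sector)) {
    members <- which(sector == sec)
    keep <- c(keep, members[which.min(norms[members])])
  }
  sort(keep)
}

## sector labels from sequential spherical angles over the positive orthant
.spherical_sectors <- function(Z, arcs) {
  n <- nrow(Z); m <- ncol(Z)
  labels <- character(n)
  for (i in seq_len(n)) {
    v <- Z[i, ]
    bins <- integer(m - 1)
    for (k in seq_len(m - 1)) {
      ang <- atan2(v[k + 1], sqrt(sum(v[seq_len(k)]^2)))  # in [0, pi/2]
      b <- floor(ang / (pi / 2) * arcs)
      bins[k] <- min(max(b, 0), arcs - 1)
    }
    labels[i] <- paste(bins, collapse = ":")
  }
  labels
}

#' Dominated hypervolume (2 or 3 objectives)
#'
#' Exact hypervolume dominated by a set of minimized objective vectors with
#' respect to a reference point.  Points not strictly better than the
#' reference in every coordinate are ignored.
#'
#' @param J numeric matrix of objective vectors (rows = points).
#' @param ref numeric reference point (componentwise upper corner).
#' @return Scalar hypervolume.
#' @export
hypervolume <- function(J, ref) {
  J <- as.matrix(J)
  J <- J[apply(J, 1, function(r) all(is.finite(r)) && all(r < ref)), , drop = FALSE]
  if (nrow(J) == 0) return(0)
  m <- ncol(J)
  if (m == 2) return(.hv2(J, ref))
  if (m == 3) {
    z <- sort(unique(J[, 3]))
    z_up <- c(z[-1], ref[3])
    total <- 0
    for (k in seq_along(z)) {
      slab <- J[J[, 3] <= z[k], c(1, 2), drop = FALSE]
      total <- total + (z_up[k] - z[k]) * .hv2(slab, ref[1:2])
    }
    return(total)
  }
  stop("hypervolume implemented for 2 or 3 objectives", call. = FALSE)
}

.hv2 <- function(J, ref) {
  ord <- order(J[, 1], J[, 2])
  J <- J[ord, , drop = FALSE]
  hv <- 0
  best2 <- ref[2]
  for (i in seq_len(nrow(J))) {
    if (J[i, 2] < best2) {
      hv <- hv + (ref[1] - J[i, 1]) * (best2 - J[i, 2])
      best2 <- J[i, 2]
    }
  }
  hv
}

## archive update under feasibility-dominance; returns the new archive
.archive_insert <- function(archive, ind) {
  if (!is.finite(ind$violation)) return(archive)  # failed-evaluation sentinel
  feas <- vapply(archive, function(a) a$violation <= 0, logical(1))
  if (ind$violation > 0) {
    if (any(feas) ) return(archive)
    if (length(archive) == 0) return(list(ind))
    best <- min(vapply(archive, `[[`, numeric(1), "violation"))
    if (ind$violation < best) return(list(ind))
    return(archive)
  }
  archive <- archive[feas]  # first feasible arrival evicts infeasibles
  for (a in archive) {
    if (dominates(a$J, ind$J) || all(a$J == ind$J)) return(archive)
  }
  keep <- vapply(archive, function(a) !dominates(ind$J, a$J), logical(1))
  c(archive[keep], list(ind))
}

#' MOEA configuration
#'
#' @param pop_size population size (`>= 4`).
#' @param generations number of DE generations.
#' @param F differential weight in `(0, 2]`.
#' @param CR crossover rate in `[0, 1]`.
#' @param seed mandatory RNG seed; recorded in all outputs.
#' @param arcs spherical-pruning resolution (angular divisions).
#' @param capacity maximum archive size.
#' @param max_evals optional cap on objective evaluations (budget);
#'   default `pop_size * (generations + 1)`.
#' @param p_archive probability that the DE base vector is drawn from the
#'   archive (external-archive elitism).
#' @param obj_caps optional numeric vector of objective caps (pertinency
#'   bounds); solutions exceeding any cap are kept out of the archive.
#' @return A list of class `moea_config`.
#' @export
moea_config <- function(pop_size = 20, generations = 15, F = 0.8, CR = 0.9,
                        seed = 1, arcs = 50, capacity = 100,
                        max_evals = NULL, p_archive = 0.5, obj_caps = NULL) {
  if (pop_size < 4) stop("DE requires a population of at least 4", call. = FALSE)
  stopifnot(generations >= 0, F > 0, F <= 2, CR >= 0, CR <= 1)
  if (is.null(seed)) stop("'seed' is mandatory", call. = FALSE)
  max_evals <- max_evals %||% (pop_size * (generations + 1))
  if (max_evals < pop_size) stop("evaluation budget must cover the initial population", call. = FALSE)
  structure(list(pop_size = pop_size, generations = generations, F = F,
                 CR = CR, seed = as.integer(seed), arcs = arcs,
                 capacity = capacity, max_evals = max_evals,
                 p_archive = p_archive, obj_caps = obj_caps),
            class = "moea_config")
}

#' Run the constrained multiobjective differential-evolution optimizer
#'
#' DE/rand/1/bin with Deb feasibility rules for parent replacement, an
#' external archive of mutually non-dominated (feasible-first) solutions,
#' external-archive elitism in the base-vector selection, and spherical
#' pruning when the archive outgrows its capacity.
#'
#' @param fn evaluation closure: `fn(theta)` must return a list with `J`
#'   (numeric objective vector, `Inf` allowed as failure sentinel) and
#'   `violation` (scalar `>= 0`).
#' @param bounds decision-variable bounds data frame (`name`, `lower`,
#'   `upper`, `integer`).
#' @param config a [moea_config()].
#' @return An object of class `moea_result`: `archive` (data frame of
#'   non-dominated solutions: `solution_id`, decision variables by name,
#'   objectives, `violation`, `feasible`), `log` (one row per evaluation),
#'   `history` (per-generation archive snapshots of objective vectors),
#'   `config` and `seed`.
#' @export
run_moea <- function(fn, bounds, config = moea_config()) {
  stopifnot(inherits(config, "moea_config"))
  set.seed(config$seed)
  n <- nrow(bounds)
  cache <- new.env(parent = emptyenv())
  evals <- 0L
  log_rows <- list()

  evaluate <- function(theta) {
    key <- paste(signif(theta, 12), collapse = "|")
    if (exists(key, envir = cache, inherits = FALSE)) {
      return(get(key, envir = cache, inherits = FALSE))
    }
    out <- fn(stats::setNames(theta, bounds$name))
    out$J <- stats::setNames(as.numeric(out$J), paste0("J", seq_along(out$J)))
    if (any(!is.finite(out$J)) || !is.finite(out$violation)) {
      out$J[] <- Inf
      out$violation <- Inf
    }
    evals <<- evals + 1L
    out$eval_id <- evals
    log_rows[[length(log_rows) + 1L]] <<- c(
      list(eval_id = evals), as.list(stats::setNames(theta, bounds$name)),
      as.list(out$J), list(violation = out$violation))
    cache[[key]] <- out
    out
  }

  rand_theta <- function() {
    th <- bounds$lower + stats::runif(n) * (bounds$upper - bounds$lower)
    th[bounds$integer] <- round(th[bounds$integer])
    th
  }

  pop <- do.call(rbind, lapply(seq_len(config$pop_size), function(i) rand_theta()))
  pop_eval <- lapply(seq_len(config$pop_size), function(i) evaluate(pop[i, ]))

  archive <- list()
  admit <- function(arch, theta, ev) {
    if (!is.null(config$obj_caps) && all(is.finite(ev$J)) &&
        any(ev$J > config$obj_caps)) return(arch)
    ind <- list(theta = theta, J = ev$J, violation = ev$violation,
                eval_id = ev$eval_id)
    .archive_insert(arch, ind)
  }
  for (i in seq_len(config$pop_size)) {
    archive <- admit(archive, pop[i, ], pop_eval[[i]])
  }

  prune <- function(arch) {
    if (length(arch) <= config$capacity) return(arch)
    J <- do.call(rbind, lapply(arch, `[[`, "J"))
    keep <- spherical_prune(J, config$arcs)
    arch <- arch[keep]
    if (length(arch) > config$capacity) {
      J <- do.call(rbind, lapply(arch, `[[`, "J"))
      Z <- sweep(J, 2, apply(J, 2, min))
      rng <- apply(J, 2, function(c) diff(range(c)))
      for (j in seq_along(rng)) if (rng[j] > 0) Z[, j] <- Z[, j] / rng[j]
      arch <- arch[order(sqrt(rowSums(Z^2)))[seq_len(config$capacity)]]
    }
    arch
  }
  archive <- prune(archive)

  history <- list(do.call(rbind, lapply(archive, `[[`, "J")))
  gen <- 0L
  while (gen < config$generations && evals < config$max_evals) {
    gen <- gen + 1L
    arch_thetas <- do.call(rbind, lapply(archive, `[[`, "theta"))
    for (i in seq_len(config$pop_size)) {
      if (evals >= config$max_evals) break
      trial <- de_trial(pop, i, config$F, config$CR, bounds,
                        archive_thetas = arch_thetas,
                        p_archive = config$p_archive)
      ev <- evaluate(trial)
      archive <- admit(archive, trial, ev)
      if (constrained_compare(ev, pop_eval[[i]]) > 0) {
        pop[i, ] <- trial
        pop_eval[[i]] <- ev
      }
    }
    archive <- prune(archive)
    history[[gen + 1L]] <- do.call(rbind, lapply(archive, `[[`, "J"))
  }

  if (length(archive) == 0) stop("all evaluations failed; empty archive", call. = FALSE)
  ord <- order(vapply(archive, `[[`, numeric(1), "eval_id"))
  archive <- archive[ord]
  arch_df <- data.frame(
    solution_id = vapply(archive, `[[`, numeric(1), "eval_id"),
    do.call(rbind, lapply(archive, function(a) stats::setNames(a$theta, bounds$name))),
    do.call(rbind, lapply(archive, function(a) {
      stats::setNames(a$J, paste0("J", seq_along(a$J)))
    })),
    violation = vapply(archive, `[[`, numeric(1), "violation")
  )
  arch_df$feasible <- arch_df$violation <= 0
  log_df <- do.call(rbind, lapply(log_rows, as.data.frame))
  structure(list(archive = arch_df, log = log_df, history = history,
                 config = config, seed = config$seed, n_evals = evals),
            class = "moea_result")
}

#' @export
print.moea_result <- function(x, ...) {
  cat(sprintf("<moea_result> %d evaluations (seed %d), archive of %d solutions\n",
              x$n_evals, x$seed, nrow(x$archive)))
  invisible(x)
}

#' Archive CSV export with JSON run metadata
#'
#' Writes the final archive (and optionally the full evaluation log) as
#' CSV with 17 significant digits, plus a JSON sidecar carrying the tool
#' version, the effective optimizer configuration, the seed and a config
#' hash, so that every artifact records how it was produced.
#'
#' @param result a `moea_result`.
#' @param file path for the archive CSV.
#' @param log_file optional path for the evaluation-log CSV.
#' @return `file`, invisibly.
#' @export
write_archive_csv <- function(result, file, log_file = NULL) {
  df <- result$archive
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(c) formatC(c, digits = 17, format = "g"))
  utils::write.csv(df, file, row.names = FALSE, quote = FALSE)
  if (!is.null(log_file)) {
    utils::write.csv(result$log, log_file, row.names = FALSE)
  }
  meta <- list(
    tool = "antitune",
    version = as.character(utils::packageVersion("antitune")),
    seed = result$seed,
    n_evals = result$n_evals,
    config = unclass(result$config),
    config_hash = sum(utf8ToInt(paste(
      names(unlist(result$config)), unlist(result$config), collapse = ";")))
  )
  jsonlite::write_json(meta, paste0(file, ".meta.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA, null = "null")
  invisible(file)
}
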