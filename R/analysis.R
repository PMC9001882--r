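#' Level-diagram norms of a Pareto front
#'
#' Min-max normalizes every objective over the front to `[0, 1]` and
#' returns the p-norm of each solution's normalized objective vector.  The
#' same y-value is used for that solution in every level-diagram panel.  A
#' degenerate objective (max = min over the front) is normalized to 0 with
#' a warning.
#'
#' @param front numeric matrix or data frame of objective vectors (rows =
#'   solutions, columns = objectives).
#' @param p norm order (`>= 1`), or `Inf` for the maximum norm.
#' @return List with `norms` (numeric, one per solution) and
#'   `normalization` (per-objective `min`/`max` used).
#' @export
pnorm_levels <- function(front, p = 2) {
  J <- as.matrix(front)
  if (nrow(J) == 0) stop("empty front", call. = FALSE)
  if (!(is.infinite(p) || p >= 1)) stop("'p' must be >= 1 or Inf", call. = FALSE)
  lo <- apply(J, 2, min)
  hi <- apply(J, 2, max)
  Z <- sweep(J, 2, lo)
  for (j in seq_len(ncol(J))) {
    span <- hi[j] - lo[j]
    if (span > 0) {
      Z[, j] <- Z[, j] / span
    } else {
      Z[, j] <- 0
      warning(sprintf("objective %d is constant over the front; normalized to 0", j))
    }
  }
  norms <- if (is.infinite(p)) {
    apply(abs(Z), 1, max)
  } else {
    rowSums(abs(Z)^p)^(1 / p)
  }
  list(norms = unname(norms), normalization = list(min = lo, max = hi, p = p))
}

#' Pareto table with level-diagram norms
#'
#' Combines an optimizer archive with its level-diagram norms into a
#' single table for reporting and export.
#'
#' @param result a `moea_result`, or a data frame shaped like its
#'   `archive` component (with `J1`, `J2`, ... columns).
#' @param p norm order passed to [pnorm_levels()].
#' @return An object of class `pareto_table`: the archive data frame with
#'   a `norm` column, carrying the normalization record as an attribute.
#' @export
pareto_table <- function(result, p = 2) {
  df <- if (inherits(result, "moea_result")) result$archive else as.data.frame(result)
  obj_cols <- grep("^J\\d+$", names(df), value = TRUE)
  if (length(obj_cols) == 0) stop("no objective columns (J1, J2, ...) found", call. = FALSE)
  lv <- pnorm_levels(df[obj_cols], p = p)
  df$norm <- lv$norms
  structure(df, class = c("pareto_table", "data.frame"),
            normalization = lv$normalization, objectives = obj_cols)
}

#' Representative solutions of a Pareto front
#'
#' Selects the per-objective extreme solutions (argmin of each objective)
#' plus the best-compromise solution (minimum level-diagram norm), the
#' standard shortlist used when presenting a design library.  Ties are
#' broken deterministically by solution id (row order).
#'
#' @param front a [pareto_table()] (or data frame with `J*` and `norm`
#'   columns).
#' @param p norm order used if `norm` is absent.
#' @return The front rows of the selected solutions, with a `role` column
#'   (`"min_J1"`, ..., `"compromise"`); a solution filling several roles
#'   appears once per role but duplicates share the same `solution_id`.
#' @export
select_representatives <- function(front, p = 2) {
  df <- as.data.frame(front)
  obj_cols <- grep("^J\\d+$", names(df), value = TRUE)
  if (!"norm" %in% names(df)) df$norm <- pnorm_levels(df[obj_cols], p = p)$norms
  picks <- c(
    stats::setNames(lapply(obj_cols, function(cn) which.min(df[[cn]])),
                    paste0("min_", obj_cols)),
    list(compromise = which.min(df$norm))
  )
  out <- df[unlist(picks), , drop = FALSE]
  out$role <- names(picks)
  rownames(out) <- NULL
  out
}

#' Trade-off summary of a Pareto front
#'
#' Spearman rank correlations between every pair of objectives over the
#' front, plus regime labels from k-means clustering of the normalized
#' objectives (a labeling convenience for discussing front zones; never
#' used in optimization).  On a strictly non-dominated bi-objective front
#' the J1-J2 correlation is exactly -1.
#'
#' @param front a [pareto_table()] or data frame with `J*` columns.
#' @param k number of regimes for the k-means labeling (clamped to the
#'   front size); `0` to skip.
#' @return List with `spearman` (correlation matrix, `NA` where an
#'   objective is degenerate), `n`, and `regimes` (integer labels or
#'   `NULL`).
#' @export
tradeoff_stats <- function(front, k = 3) {
  df <- as.data.frame(front)
  obj_cols <- grep("^J\\d+$", names(df), value = TRUE)
  J <- as.matrix(df[obj_cols])
  if (nrow(J) < 3) stop("need at least 3 solutions for trade-off statistics", call. = FALSE)
  degenerate <- apply(J, 2, function(c) diff(range(c)) == 0)
  rho <- suppressWarnings(stats::cor(J, method = "spearman"))
  rho[degenerate, ] <- NA_real_
  rho[, degenerate] <- NA_real_
  diag(rho) <- 1
  regimes <- NULL
  if (k > 0) {
    Z <- apply(J, 2, function(c) {
      s <- diff(range(c)); if (s > 0) (c - min(c)) / s else c * 0
    })
    kk <- min(k, nrow(unique(Z)))
    regimes <- stats::kmeans(Z, centers = kk, nstart = 5)$cluster
  }
  list(spearman = rho, n = nrow(J), regimes = regimes)
}

#' Pareto table CSV round trip
#'
#' Writes a [pareto_table()] as CSV with 17 significant digits (so the
#' round trip reproduces the numbers bit-exactly) and reads it back.
#'
#' @param pt a `pareto_table`.
#' @param file CSV path.
#' @return `write_pareto_csv()` returns `file` invisibly;
#'   `read_pareto_csv()` returns a `pareto_table`.
#' @export
write_pareto_csv <- function(pt, file) {
  df <- as.data.frame(pt)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(c) {
    v <- vapply(c, function(x) formatC(x, digits = 17, format = "g"), "")
    v
  })
  utils::write.csv(df, file, row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' @rdname write_pareto_csv
#' @export
read_pareto_csv <- function(file) {
  df <- utils::read.csv(file, check.names = FALSE)
  pareto_table(df[setdiff(names(df), "norm")])
}

#' Level diagrams of a Pareto front
#'
#' One panel per objective (and optionally per decision variable): the
#' x-axis is the raw objective or parameter value, the y-axis the common
#' level-diagram norm of the solution, so a given solution sits at the
#' same height in every panel.
#'
#' @param pt a [pareto_table()].
#' @param vars additional (decision-variable) columns to panel.
#' @return A ggplot object.
#' @export
level_diagram <- function(pt, vars = character(0)) {
  df <- as.data.frame(pt)
  obj_cols <- attr(pt, "objectives") %||% grep("^J\\d+$", names(df), value = TRUE)
  cols <- c(obj_cols, vars)
  long <- do.call(rbind, lapply(cols, function(cn) {
    data.frame(panel = cn, value = df[[cn]], norm = df$norm)
  }))
  long$panel <- factor(long$panel, levels = cols)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$value, y = .data$norm)) +
    ggplot2::geom_point(colour = "#2c7fb8", size = 2) +
    ggplot2::facet_wrap(~panel, scales = "free_x") +
    ggplot2::labs(x = NULL, y = "normalized p-norm of objectives") +
    ggplot2::theme_bw()
}

#' Pareto front scatter plot
#'
#' J1 against J2; with three objectives, J3 is shown as the marker size
#' (bubble plot).
#'
#' @param pt a [pareto_table()] (or archive data frame).
#' @return A ggplot object.
#' @export
plot_front <- function(pt) {
  df <- as.data.frame(pt)
  aes <- if ("J3" %in% names(df)) {
    ggplot2::aes(x = .data$J1, y = .data$J2, size = .data$J3)
  } else {
    ggplot2::aes(x = .data$J1, y = .data$J2)
  }
  ggplot2::ggplot(df, aes) +
    ggplot2::geom_point(colour = "#de2d26", alpha = 0.8) +
    ggplot2::labs(x = "J1 (titer target error)",
                  y = "J2 (production loss after perturbation)",
                  size = "J3 (oscillations)") +
    ggplot2::theme_bw()
}
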