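toy_problem <- function() {
  ## min ( theta^2, (theta-1)^2 ), theta in [-1, 2]; analytic Pareto set is
  ## [0, 1] with front J2 = (1 - sqrt(J1))^2
  list(
    fn = function(theta) {
      th <- theta[[1]]
      list(J = c(th^2, (th - 1)^2), violation = 0)
    },
    bounds = data.frame(name = "theta", lower = -1, upper = 2, integer = FALSE)
  )
}

test_that("dominance follows the componentwise definition", {
  expect_true(dominates(c(1, 1), c(2, 2)))
  expect_false(dominates(c(1, 1), c(1, 1)))
  expect_false(dominates(c(1, 3), c(3, 1)))
  expect_false(dominates(c(3, 1), c(1, 3)))
  expect_true(dominates(c(1, 2), c(1, 3)))
  expect_error(dominates(c(1, 2), c(1, 2, 3)), "length")
})

test_that("constrained comparison applies the feasibility rules", {
  mk <- function(J, v) list(J = J, violation = v)
  expect_equal(constrained_compare(mk(c(9, 9), 0), mk(c(1, 1), 0.5)), 1L)
  expect_equal(constrained_compare(mk(c(1, 1), 0.2), mk(c(0, 0), 0.5)), 1L)
  expect_equal(constrained_compare(mk(c(1, 3), 0), mk(c(3, 1), 0)), 0L)
  expect_equal(constrained_compare(mk(c(2, 2), 0), mk(c(1, 1), 0)), -1L)
})

test_that("DE trial vectors collapse to the base vector at F=0, CR=1 and respect bounds", {
  set.seed(11)
  bounds <- data.frame(name = c("a", "b"), lower = c(0, 10), upper = c(1, 20),
                       integer = c(FALSE, TRUE))
  pop <- cbind(runif(6), round(runif(6, 10, 20)))
  for (i in 1:6) {
    tr <- de_trial(pop, i, F = 0, CR = 1, bounds, p_archive = 0)
    expect_true(any(apply(pop, 1, function(r) all(r == tr))))
  }
  for (rep in 1:200) {
    tr <- de_trial(pop, 1, F = 1.5, CR = 0.5, bounds, p_archive = 0)
    expect_true(all(tr >= bounds$lower & tr <= bounds$upper))
    expect_equal(tr[2], round(tr[2]))  # integer coordinate
  }
  set.seed(42); t1 <- de_trial(pop, 2, 0.8, 0.9, bounds)
  set.seed(42); t2 <- de_trial(pop, 2, 0.8, 0.9, bounds)
  expect_identical(t1, t2)
})

test_that("spherical pruning equals a brute-force sector-assignment oracle", {
  brute_prune <- function(J, arcs) {
    ideal <- apply(J, 2, min); nadir <- apply(J, 2, max)
    Z <- sweep(J, 2, ideal)
    for (j in seq_len(ncol(J))) {
      s <- nadir[j] - ideal[j]
      Z[, j] <- if (s > 0) Z[, j] / s else 0
    }
    sec <- apply(Z, 1, function(v) {
      paste(vapply(seq_len(length(v) - 1), function(k) {
        ang <- atan2(v[k + 1], sqrt(sum(v[seq_len(k)]^2)))
        min(max(floor(ang / (pi / 2) * arcs), 0), arcs - 1)
      }, numeric(1)), collapse = ":")
    })
    nrm <- sqrt(rowSums(Z^2))
    sort(unlist(lapply(split(seq_len(nrow(J)), sec), function(ix) {
      ix[which.min(nrm[ix])]
    })), method = "radix")
  }
  rand_front <- function(n, m) {
    ## mutually non-dominated points on a simplex-like shell
    X <- matrix(abs(rnorm(n * m)), n, m)
    X / rowSums(X)
  }
  set.seed(1234)
  for (rep in 1:50) {
    J <- rand_front(sample(10:100, 1), 2)
    expect_identical(spherical_prune(J, 10), unname(brute_prune(J, 10)))
  }
  for (rep in 1:50) {
    J <- rand_front(sample(10:100, 1), 3)
    expect_identical(spherical_prune(J, 6), unname(brute_prune(J, 6)))
  }
  expect_identical(spherical_prune(matrix(c(1, 2), 1)), 1L)
  two <- rbind(c(0, 1), c(1, 0))
  expect_identical(spherical_prune(two, 10), c(1L, 2L))
})

test_that("hypervolume matches direct rectangle arithmetic", {
  expect_equal(hypervolume(rbind(c(1, 1)), ref = c(2, 2)), 1)
  expect_equal(hypervolume(rbind(c(0, 1), c(1, 0)), ref = c(2, 2)),
               2 * 1 + 1 * 1)
  expect_equal(hypervolume(rbind(c(3, 3)), ref = c(2, 2)), 0)
  ## 3-D: single point is a box
  expect_equal(hypervolume(rbind(c(0, 0, 0)), ref = c(1, 2, 3)), 6)
  expect_equal(hypervolume(rbind(c(0, 1, 0), c(1, 0, 0)), ref = c(2, 2, 1)),
               3)
})

test_that("the optimizer recovers the analytic front of the convex toy problem", {
  prob <- toy_problem()
  res <- run_moea(prob$fn, prob$bounds,
                  moea_config(pop_size = 20, generations = 99, seed = 5,
                              arcs = 50, capacity = 1e6))
  expect_lte(res$n_evals, 2000)
  arch <- res$archive
  ## Pareto set within [0 - eps, 1 + eps]
  expect_gte(min(arch$theta), -0.02)
  expect_lte(max(arch$theta), 1.02)
  ## front on the analytic curve J2 = (1 - sqrt(J1))^2
  dev <- abs(arch$J2 - (1 - sqrt(arch$J1))^2)
  expect_lt(max(dev), 0.01)
  expect_gt(nrow(arch), 10)
  ## archive mutually non-dominated at every generation (vectorized check)
  is_nondominated_set <- function(J) {
    le <- outer(J[, 1], J[, 1], "<=") & outer(J[, 2], J[, 2], "<=")
    lt <- outer(J[, 1], J[, 1], "<") | outer(J[, 2], J[, 2], "<")
    dom <- le & lt
    diag(dom) <- FALSE
    !any(dom)
  }
  expect_true(all(vapply(res$history, is_nondominated_set, logical(1))))
  ## hypervolume non-decreasing across generations
  hv <- vapply(res$history, hypervolume, numeric(1), ref = c(4.1, 4.1))
  expect_true(all(diff(hv) >= -1e-12))
})

test_that("a degenerate second objective reduces the optimizer to scalar DE", {
  prob <- list(
    fn = function(theta) list(J = c((theta[[1]] - 0.25)^2, 0), violation = 0),
    bounds = data.frame(name = "t", lower = -1, upper = 2, integer = FALSE)
  )
  res <- run_moea(prob$fn, prob$bounds,
                  moea_config(pop_size = 20, generations = 30, seed = 3))
  best <- res$archive$t[which.min(res$archive$J1)]
  expect_lt(abs(best - 0.25), 0.01)
})

test_that("identical seeds reproduce identical runs; budgets are validated", {
  prob <- toy_problem()
  cfg <- moea_config(pop_size = 10, generations = 5, seed = 77)
  r1 <- run_moea(prob$fn, prob$bounds, cfg)
  r2 <- run_moea(prob$fn, prob$bounds, cfg)
  expect_identical(r1$archive, r2$archive)
  expect_identical(r1$log, r2$log)
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  write_archive_csv(r1, f1); write_archive_csv(r2, f2)
  expect_identical(readLines(f1), readLines(f2))  # byte-identical
  expect_error(moea_config(pop_size = 3), "at least 4")
  expect_error(moea_config(pop_size = 10, max_evals = 5), "budget")
  expect_error(moea_config(seed = NULL), "seed")
})

test_that("feasibility rules steer the archive to the feasible region", {
  ## constraint: theta >= 0.5 feasible; minimize (theta^2, (theta-1)^2)
  prob <- list(
    fn = function(theta) {
      th <- theta[[1]]
      list(J = c(th^2, (th - 1)^2), violation = max(0, 0.5 - th))
    },
    bounds = data.frame(name = "t", lower = -1, upper = 2, integer = FALSE)
  )
  res <- run_moea(prob$fn, prob$bounds,
                  moea_config(pop_size = 20, generations = 25, seed = 9))
  expect_true(all(res$archive$feasible))
  expect_gte(min(res$archive$t), 0.5 - 1e-9)
})

test_that("evaluation caching never re-evaluates an identical decision vector", {
  calls <- 0
  prob <- list(
    fn = function(theta) {
      calls <<- calls + 1
      list(J = c(theta[[1]]^2, (theta[[1]] - 1)^2), violation = 0)
    },
    bounds = data.frame(name = "t", lower = 0, upper = 1, integer = TRUE)
  )
  ## integer decision variable on [0,1]: only 2 distinct values exist
  res <- run_moea(prob$fn, prob$bounds,
                  moea_config(pop_size = 6, generations = 10, seed = 2))
  expect_lte(calls, 2)
  expect_equal(res$n_evals, calls)
})
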