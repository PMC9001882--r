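test_that("logistic growth integrates to its carrying capacity", {
  p <- merging_params(K_S1 = 0, a0 = 0, a1 = 0, k_sigma = 0, k_asigma = 0)
  y0 <- setNames(c(0, 0, 0, 0, 0, 1), merging_species())
  pr <- sim_protocol(t_end = 5000, n_points = 101, initial_state = y0)
  traj <- integrate_model("merging", p, pr)
  X_end <- endpoint(traj)[["X"]]
  expect_lt(abs(X_end - p$Xmax) / p$Xmax, 1e-3)
})

test_that("without enzyme expression no product is ever formed", {
  p <- merging_params(a0 = 0, a1 = 0)
  pr <- default_protocol("merging")
  traj <- integrate_model("merging", p, pr, perturbed = FALSE)
  expect_equal(max(traj$states[, "P"]), 0)
  expect_equal(max(traj$states[, "E"]), 0)
})

test_that("linear decay reproduces its closed form", {
  ## dE/dt = -(d_E + mu) E with all production off
  p <- merging_params(K_S1 = 0, a0 = 0, a1 = 0, k_sigma = 0, k_asigma = 0,
                      d_E = 0.009, mu = 0.001)
  y0 <- setNames(c(0, 0, 100, 0, 0, 1), merging_species())
  pr <- sim_protocol(t_end = 100, n_points = 11, initial_state = y0)
  traj <- integrate_model("merging", p, pr)
  expect_equal(endpoint(traj, 100)[["E"]], 100 * exp(-1), tolerance = 1e-5)
})

test_that("paired runs share the pre-perturbation path exactly and split at t_pert", {
  p <- merging_params()
  pr <- default_protocol("merging")
  res <- run_paired("merging", p, pr)
  t_pert <- pr$perturbation$t_pert
  pre <- res$unperturbed$times <= t_pert
  expect_identical(res$unperturbed$states[pre, ], res$perturbed$states[pre, ])
  post <- res$unperturbed$times > t_pert + 200
  expect_gt(max(abs(res$unperturbed$states[post, "P"] -
                    res$perturbed$states[post, "P"])), 0)
  ev <- res$perturbed$events[[1]]
  expect_equal(ev$time, t_pert)
  expect_match(ev$description, "S2_level")
})

test_that("a null perturbation leaves the two trajectories identical", {
  p <- merging_params()
  pr0 <- default_protocol("merging")
  pr <- sim_protocol(pr0$t_end, pr0$n_points, pr0$initial_state,
                     perturbation_spec(3900, "S2_level", reduction = 0))
  res <- run_paired("merging", p, pr)
  scale <- max(abs(res$unperturbed$states))
  expect_lt(max(abs(res$unperturbed$states - res$perturbed$states)) / scale,
            1e-6)
})

test_that("a 60% reduction steps the perturbed input to 40% of nominal", {
  p <- merging_params()
  pr <- default_protocol("merging")
  expect_equal(pr$perturbation$reduction, 0.6)
  ## the step acts on the parameter, so the perturbed flux balance differs:
  res <- run_paired("merging", p, pr)
  ## reconstruct the S2 value the perturbed run used after t_pert from the
  ## S1 balance: dS1 = K_S1 - V - mu*S1 ~ 0 at steady state
  end <- endpoint(res$perturbed)
  V_end <- p$K_S1 - p$mu * end[["S1"]]
  S2_implied <- uniroot(function(S2) {
    bisubstrate_flux(end[["E"]], end[["S1"]], S2, p$kcat, p$Km_S1, p$Km_S2) - V_end
  }, c(1, p$S2_level))$root
  expect_equal(S2_implied, 0.4 * p$S2_level, tolerance = 0.02)
})

test_that("endpoint() is exact at nodes and linear in between", {
  traj <- structure(list(
    times = c(0, 10, 20),
    states = cbind(a = c(0, 10, 40), b = c(5, 5, 5)),
    species = c("a", "b"), events = list()), class = "trajectory")
  expect_equal(endpoint(traj, 10), c(a = 10, b = 5))
  expect_equal(endpoint(traj, 15), c(a = 25, b = 5))
  expect_equal(endpoint(traj, 0), c(a = 0, b = 5))
  expect_error(endpoint(traj, 21), "outside")
})

test_that("trajectory CSV round-trips through disk", {
  p <- merging_params()
  pr <- sim_protocol(t_end = 200, n_points = 21,
                     initial_state = default_initial_state("merging"))
  traj <- integrate_model("merging", p, pr)
  f <- tempfile(fileext = ".csv")
  write_trajectory_csv(traj, f)
  back <- read_trajectory_csv(f)
  expect_equal(back$times, traj$times)
  expect_equal(back$states, traj$states, tolerance = 1e-12)
  expect_identical(back$species, traj$species)
})

test_that("endpoints are stable under tolerance halving", {
  p <- merging_params()
  pr <- default_protocol("merging")
  e1 <- endpoint(integrate_model("merging", p, pr, rtol = 1e-8, atol = 1e-6))
  e2 <- endpoint(integrate_model("merging", p, pr, rtol = 5e-9, atol = 5e-7))
  rel <- abs(e1 - e2) / pmax(abs(e1), 1)
  expect_lt(max(rel), 1e-4)  # < 0.01%
})

test_that("protocol validation rejects inconsistent settings", {
  expect_error(sim_protocol(0), "t_end")
  expect_error(perturbation_spec(-5, "S2_level", 0.5))
  expect_error(perturbation_spec(10, "S2_level", 1.5))
  expect_error(sim_protocol(100, perturbation = perturbation_spec(200, "S2_level", 0.5)),
               "t_pert")
  p <- merging_params()
  pr <- sim_protocol(t_end = 100, n_points = 11,
                     initial_state = default_initial_state("merging"))
  expect_error(run_paired("merging", p, pr), "perturbation")
})
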