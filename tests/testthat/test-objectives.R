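test_that("titer target error is an absolute deviation with the stated arithmetic", {
  expect_equal(j1_titer_error(P_T = 800, K = 1e-3, target = 1.0), 0.2)
  expect_equal(j1_titer_error(P_T = 1000 / 2, K = 2e-3, target = 1.0), 0)
  expect_equal(j1_titer_error(P_T = 2000, K = 1e-3, target = 1.0), 1.0)
  ## invariance under (K, P) -> (cK, P/c)
  set.seed(7)
  for (i in 1:20) {
    P <- runif(1, 1, 1e6); K <- runif(1, 1e-7, 1e-2); c_ <- runif(1, 0.1, 10)
    expect_equal(j1_titer_error(P, K, 2), j1_titer_error(P / c_, c_ * K, 2))
  }
})

test_that("production loss is the signed fractional endpoint drop", {
  expect_equal(j2_production_loss(100, 100), 0)
  expect_equal(j2_production_loss(100, 0), 1)
  expect_equal(j2_production_loss(100, 80), 0.2)
  expect_equal(j2_production_loss(100, 120), -0.2)  # gains stay signed
  expect_error(j2_production_loss(0, 10), "undefined")
})

test_that("clipped binary signal takes values {0, 1/2, 1} with the documented tie rule", {
  expect_equal(clip_binary(c(5, 5, 5)), c(0.5, 0.5, 0.5))
  expect_equal(clip_binary(c(0, 2, 0, 2)), c(1, 0, 1, 0))  # mean = 1
  s <- c(1, 3, 2)  # mean = 2: below -> 1, above -> 0, tie -> 1/2
  expect_equal(clip_binary(s), c(1, 0, 0.5))
})

test_that("oscillation count matches hand-derived crossing cases", {
  expect_equal(j3_count_oscillations(rep(3.2, 10)), 0)
  expect_equal(j3_count_oscillations(c(0, 0, 2, 2)), 0.5)  # one crossing
  ## mean-centered sinusoids: N full periods -> 2N crossings -> J3 = N
  for (N in 1:3) {
    t <- seq(0, N, length.out = N * 64 + 1)
    expect_equal(j3_count_oscillations(sin(2 * pi * t - pi / 4)), N)
  }
})

test_that("oscillation count equals a brute-force mean-crossing counter on random series", {
  brute_crossings <- function(s) {
    d <- sign(mean(s) - s)
    d <- d[d != 0]
    sum(diff(d) != 0) / 2
  }
  set.seed(99)
  for (i in 1:1000) {
    n <- sample(5:60, 1)
    s <- rnorm(n) + cumsum(rnorm(n, sd = 0.3))
    expect_equal(j3_count_oscillations(s), brute_crossings(s))
  }
})

test_that("the naringenin titer conversion is linear in cell count with mw/Av scaling", {
  Av <- 6.02214076e23
  expect_equal(knar_conversion(x_T = Av, mw = 272.25, Av = Av, Vext = 1), 272.25)
  expect_equal(knar_conversion(2e12), 2 * knar_conversion(1e12))
  expect_equal(knar_conversion(1e12, Vext = 2), knar_conversion(1e12) / 2)
})

test_that("constraint reports flag sigma shortfalls and anti-sigma dominance", {
  mk_traj <- function(sig_uM, asig_uM, n = 50) {
    structure(list(
      times = seq(0, 1000, length.out = n),
      states = cbind(sigma = molecules_from_uM(rep(sig_uM, n)),
                     asigma = molecules_from_uM(rep(asig_uM, n))),
      species = c("sigma", "asigma"), events = list()), class = "trajectory")
  }
  ok <- evaluate_constraints(mk_traj(10, 1))
  expect_true(ok$feasible)
  expect_equal(ok$violation, 0)
  low <- evaluate_constraints(mk_traj(4.0, 1))
  expect_false(low$feasible)
  expect_equal(low$sigma_min, 0.5, tolerance = 1e-10)
  edge <- evaluate_constraints(mk_traj(6, 6))
  expect_equal(edge$sigma_dominance, 0)
  dom <- evaluate_constraints(mk_traj(6, 8))
  expect_false(dom$feasible)
  expect_equal(dom$sigma_dominance, 2, tolerance = 1e-10)
})

test_that("merging MOP evaluation is deterministic and finite at the bounds midpoint", {
  b <- merging_bounds()
  theta <- setNames((b$lower + b$upper) / 2, b$name)
  e1 <- evaluate_merging(theta)
  e2 <- evaluate_merging(theta)
  expect_identical(e1$J, e2$J)
  expect_true(all(is.finite(e1$J)))
  expect_lt(e1$J[["J2"]], 1)
  expect_gte(e1$J[["J1"]], 0)
})

test_that("J1 vanishes when the target is set to the achieved titer (self-consistency replay)", {
  b <- merging_bounds()
  theta <- setNames((b$lower + b$upper) / 2, b$name)
  mop <- default_mop("merging")
  e1 <- evaluate_merging(theta)
  achieved <- mop$K * e1$diagnostics$P_unp
  e2 <- evaluate_merging(theta, target = achieved)
  expect_equal(e2$J[["J1"]], 0, tolerance = 1e-9)
})

test_that("decision vectors outside their bounds are rejected; copy numbers are rounded", {
  expect_error(evaluate_merging(c(a1 = 1e4, kd20 = 2e5, k_asigma = 1000,
                                  mu = 0.007)), "bounds")
  b <- naringenin_bounds()
  theta <- setNames((b$lower + b$upper) / 2, b$name)
  theta["CN_asigma"] <- 4.6
  checked <- antitune:::.check_theta(theta, b)
  expect_equal(checked[["CN_asigma"]], 5)
})
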