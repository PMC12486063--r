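test_that("parameter constructors enforce their domains", {
  expect_error(ams_params(lambda = 0), "0 < lambda <= 2")
  expect_error(ams_params(lambda = 2.5), "0 < lambda <= 2")
  expect_silent(ams_params(lambda = 2))
  expect_error(sup_params(alpha = 0), "0 < alpha < 1")
  expect_error(sup_params(alpha = 1), "0 < alpha < 1")
  expect_error(sup_params(eta = 1.2), "0 < eta < 1")
  expect_error(sup_params(n_perturb = 0), "n_perturb")
})

test_that("interval projection lands on the violated boundary", {
  # interior point: no displacement
  expect_equal(project_interval_row(c(0.5, 7), c(1, 0), 0, 1), c(0, 0))
  # classic oracle case: a = (1,1), U = 1, x = (1,1) -> d = (-0.5, -0.5)
  expect_equal(project_interval_row(c(1, 1), c(1, 1), -Inf, 1), c(-0.5, -0.5))
  # violated constraints are met with equality after the step
  set.seed(21)
  for (r in 1:20) {
    n <- 6
    a <- stats::rnorm(n); x <- stats::rnorm(n)
    L <- -0.5; U <- 0.5
    d <- project_interval_row(x, a, L, U)
    t_after <- sum(a * (x + d))
    t_before <- sum(a * x)
    if (t_before > U) expect_equal(t_after, U)
    else if (t_before < L) expect_equal(t_after, L)
    else expect_equal(d, numeric(n))
  }
  expect_error(project_interval_row(c(1, 1), c(0, 0), 0, 1), "empty constraint")
})

test_that("interval projection agrees with the constrained-LSQ KKT oracle", {
  set.seed(42)
  for (r in 1:50) {
    n <- 10
    a <- stats::rnorm(n); x <- stats::rnorm(n, sd = 2)
    b <- sort(stats::rnorm(2))
    d <- project_interval_row(x, a, b[1], b[2])
    expect_lt(max(abs(d - project_oracle(x, a, b[1], b[2]))), 1e-8)
  }
})

test_that("a feasible point is a fixed point of the AMS sweep", {
  toy <- planted_toy(1)
  out <- ams_iteration(toy$x_star, toy$sys, lambda = 1)
  expect_equal(as.numeric(out), toy$x_star)
  expect_equal(attr(out, "n_violated"), 0L)
  # single-constraint system: one sweep with lambda = 1 is the exact projection
  infl <- random_influence(2, n_vox = 10, n_beam = 4)
  cs <- constraint_set(data.frame(voxel = 1, structure = "S", space = "dose",
                                  lower = 0, upper = 0.1, weight = 1,
                                  ref = 0.1))
  sys1 <- constraint_system(infl, cs)
  x <- rep(5, 4)
  stepped <- as.numeric(ams_iteration(x, sys1, lambda = 1))
  a <- as.numeric(sys1$A[1, ])
  manual <- pmax(0, x + project_interval_row(x, a, 0, 0.1))
  expect_equal(stepped, manual)
})

test_that("AMS iterates are Fejer monotone toward the planted point", {
  toy <- planted_toy(7)
  for (lam in c(0.5, 1.0, 1.9)) {
    x <- toy$x0
    dist <- sum((x - toy$x_star)^2)
    for (k in 1:200) {
      x <- as.numeric(ams_iteration(x, toy$sys, lambda = lam))
      d2 <- sum((x - toy$x_star)^2)
      expect_lte(d2, dist * (1 + 1e-12))
      dist <- d2
    }
    expect_true(all(x >= 0))
  }
})

test_that("feasibility_seek converges on planted toys and reports traces", {
  for (seed in c(3, 13, 23)) {
    toy <- planted_toy(seed)
    res <- feasibility_seek(toy$x0, toy$sys,
                            ams_params(lambda = 1, max_iterations = 500,
                                       tol = 1e-6))
    expect_true(res$converged)
    expect_lt(res$residual, 1e-6)
    expect_true(all(res$x >= 0))
    expect_equal(nrow(res$trace), res$iterations + 1L)
  }
  # already-feasible start returns unchanged with zero iterations
  toy <- planted_toy(3)
  res0 <- feasibility_seek(toy$x_star, toy$sys, ams_params())
  expect_identical(res0$iterations, 0L)
  expect_equal(res0$x, toy$x_star)
  # inconsistent system: bounded run, residual plateau, no exception
  cs_bad <- toy$cset
  half <- seq_len(nrow(cs_bad)) <= nrow(cs_bad) / 2
  cs_bad$upper[half] <- cs_bad$lower[half] <- cs_bad$lower[half] / 10
  cs_bad$upper[!half] <- pmax(cs_bad$upper[!half], 100)
  cs_bad$lower[!half] <- 99
  sys_bad <- constraint_system(toy$infl, constraint_set(cs_bad))
  res_bad <- feasibility_seek(toy$x0, sys_bad,
                              ams_params(max_iterations = 150, tol = 1e-9))
  expect_false(res_bad$converged)
  expect_identical(res_bad$iterations, 150L)
  expect_true(is.finite(res_bad$residual))
})

test_that("chi-squared objective and gradient match hand values and FD", {
  # one target voxel, w = 2, ref 74, current 73 -> chi2 = 2
  g <- voxel_grid(c(1, 1, 1))
  infl <- influence_matrix(Matrix::Matrix(73, 1, 1, sparse = TRUE),
                           Matrix::Matrix(73, 1, 1, sparse = TRUE), g)
  cs <- constraint_set(data.frame(voxel = 1, structure = "PTV",
                                  space = "dose", lower = 70, upper = 79,
                                  weight = 2, ref = 74))
  sys <- constraint_system(infl, cs)
  expect_equal(objective_chi2(1, sys), 2 * (74 - 73)^2)
  # doubling all weights doubles chi2
  expect_equal(objective_chi2(1, sys, weights = 2 * sys$w),
               2 * objective_chi2(1, sys))
  # zero at the reference point and zero gradient there
  toy <- planted_toy(5)
  expect_equal(objective_chi2(toy$x_star, toy$sys), 0)
  expect_equal(gradient_chi2(toy$x_star, toy$sys),
               numeric(length(toy$x_star)))
  # central finite differences on a random point
  x <- toy$x0
  gr <- gradient_chi2(x, toy$sys)
  h <- 1e-5
  fd <- vapply(seq_along(x), function(j) {
    xp <- x; xm <- x
    xp[j] <- x[j] + h; xm[j] <- x[j] - h
    (objective_chi2(xp, toy$sys) - objective_chi2(xm, toy$sys)) / (2 * h)
  }, numeric(1))
  expect_lt(max(abs(gr - fd)) / max(abs(gr)), 1e-5)
  # far above the references the gradient turns positive componentwise
  gr_hi <- gradient_chi2(x + 100, toy$sys)
  active <- abs(gr_hi) > 0
  expect_true(all(gr_hi[active] > 0))
})

test_that("superiorization reduces to feasibility-seeking without gradient", {
  toy <- planted_toy(17)
  # references already met: gradient == 0, trajectories identical
  sys_met <- toy$sys
  # run both from the planted point where chi2 = 0
  ams <- ams_params(lambda = 1, max_iterations = 50, tol = 0)
  fs <- feasibility_seek(toy$x_star, sys_met, ams)
  sa <- superiorize(toy$x_star, sys_met, ams, sup_params())
  expect_equal(sa$x, fs$x, tolerance = 1e-12)
  # vanishing alpha: perturbations are negligible, trajectory matches AMS
  sa_tiny <- superiorize(toy$x0, toy$sys,
                         ams_params(lambda = 1, max_iterations = 30, tol = 0),
                         sup_params(alpha = 1e-6))
  fs_ref <- feasibility_seek(toy$x0, toy$sys,
                             ams_params(lambda = 1, max_iterations = 30,
                                        tol = 0))
  expect_equal(sa_tiny$x, fs_ref$x, tolerance = 1e-6)
})

test_that("superiorization is objective-non-inferior and residual-resilient", {
  wins <- 0L
  for (seed in 1:20) {
    toy <- planted_toy(seed)
    ams <- ams_params(lambda = 1, max_iterations = 120, tol = 0)
    fs <- feasibility_seek(toy$x0, toy$sys, ams)
    sa <- superiorize(toy$x0, toy$sys, ams, sup_params())
    if (objective_chi2(sa$x, toy$sys) <=
        objective_chi2(fs$x, toy$sys) + 1e-12) wins <- wins + 1L
    # perturbation resilience: SA's feasibility residual within 10x of AMS's
    expect_lte(sa$residual, 10 * fs$residual + 1e-9)
  }
  expect_gte(wins / 20, 0.95)
})

test_that("solver state invariants hold along superiorization traces", {
  toy <- planted_toy(29)
  sa <- superiorize(toy$x0, toy$sys,
                    ams_params(max_iterations = 60, tol = 0), sup_params())
  expect_true(all(sa$x >= 0))
  # beta trace non-increasing where recorded (s never resets)
  b <- sa$trace$beta[!is.na(sa$trace$beta) & sa$trace$beta > 0]
  expect_true(all(diff(b) <= 1e-15))
  # weight decay factor is eta^k
  expect_equal(sa$trace$weight_scale[-1],
               0.99 ^ seq_len(nrow(sa$trace) - 1))
})
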