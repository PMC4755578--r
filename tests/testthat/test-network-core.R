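test_that("logistic value and derivatives are analytic and consistent", {
  l0 <- logistic(0)
  expect_equal(l0$value, 0.5)
  expect_equal(l0$deriv1, 0.25)
  expect_equal(l0$deriv2, 0)
  # derivatives agree with central finite differences across the range
  u <- seq(-6, 6, by = 0.7)
  h <- 1e-6
  expect_equal(logistic(u)$deriv1,
               (logistic(u + h)$value - logistic(u - h)$value) / (2 * h),
               tolerance = 1e-8)
  expect_equal(logistic(u)$deriv2,
               (logistic(u + h)$deriv1 - logistic(u - h)$deriv1) / (2 * h),
               tolerance = 1e-8)
  # saturates gracefully
  expect_equal(logistic(1000)$value, 1)
  expect_equal(logistic(-1000)$deriv1, 0)
  expect_equal(logistic_nonlinearity()$gamma0, 0.25)
})

test_that("network_params validates shapes and finiteness", {
  W <- matrix(rnorm(10), 5, 2)
  expect_s3_class(network_params(W), "network_params")
  expect_error(network_params(W, K = matrix(0, 4, 4)), "square")
  expect_error(network_params(t(W)), "M >= N")
  W[1] <- NA
  expect_error(network_params(W), "finite")
})

test_that("fixed point solves s = g(Wx + Ks) with small residual", {
  # no recurrence, zero input: homogeneous g(0) = 1/2
  p <- network_params(matrix(rnorm(8), 4, 2))
  fp <- solve_fixed_point(p, c(0, 0))
  expect_true(fp$converged)
  expect_equal(fp$s, rep(0.5, 4))
  # no recurrence, any input: s = g(Wx) after one effective update
  x <- c(0.7, -1.2)
  fp <- solve_fixed_point(p, x)
  expect_equal(fp$s, plogis(drop(p$W %*% x)), tolerance = 1e-8)
  # residual invariant on random subcritical networks
  for (i in 1:5) {
    pp <- random_subcritical_network(M = 6, N = 3, seed = 100 + i)
    x <- with_seed(200 + i, rnorm(3))
    fp <- solve_fixed_point(pp, x, tol = 1e-10)
    expect_true(fp$converged)
    resid <- max(abs(fp$s - pp$nl$eval(drop(pp$W %*% x + pp$K %*% fp$s))))
    expect_lt(resid, 1e-9)
    expect_true(all(fp$s > 0 & fp$s < 1))
  }
})

test_that("supercritical ring with seeded noise breaks symmetry into a hill", {
  M <- 41
  p <- network_params(build_ring(M)$W, 1.1 * optimal_ring_K(M))
  fp <- solve_fixed_point(p, c(0, 0), noise_scale = 1e-6, seed = 42,
                          max_iter = 2e5)
  expect_true(fp$converged)
  pv <- population_vector(fp$s, ring_angles(M))
  expect_gt(pv$magnitude, 0.1 * M * max(fp$s))
  # and the subcritical network stays homogeneous
  p_sub <- network_params(build_ring(M)$W, 0.9 * optimal_ring_K(M))
  fp_sub <- solve_fixed_point(p_sub, c(0, 0), noise_scale = 1e-6, seed = 42,
                              max_iter = 2e5)
  pv_sub <- population_vector(fp_sub$s, ring_angles(M))
  expect_lt(pv_sub$magnitude, 1e-3)
})

test_that("explicit integration matches the linear-ODE closed form for K=0", {
  # scalar neuron, no recurrence: linearized dynamics relax exponentially
  # with time constant tau toward g(Wx)
  p <- network_params(matrix(1, 1, 1))
  x <- 0.4
  dt <- 0.01
  traj <- integrate_dynamics(p, x, duration = 5, dt = dt, init = 0.5)
  s_inf <- plogis(0.4)
  tt <- attr(traj, "time")
  # closed form of tau*ds/dt = -s + g(Wx) when g is frozen at the drive:
  # here K = 0 so the equation is exactly linear in s
  expect_equal(as.numeric(traj), s_inf + (0.5 - s_inf) * exp(-tt),
               tolerance = 2 * dt, ignore_attr = TRUE)
})

test_that("integration and damped iteration agree on random networks", {
  for (i in 1:20) {
    p <- random_subcritical_network(M = sample(3:10, 1), N = 2,
                                    seed = 300 + i)
    x <- with_seed(400 + i, rnorm(2, sd = 0.5))
    fp <- solve_fixed_point(p, x, tol = 1e-10)
    traj <- integrate_dynamics(p, x, duration = 60, dt = 0.1)
    expect_lt(max(abs(traj[nrow(traj), ] - fp$s)), 1e-8)
  }
})

test_that("integration rejects unstable time steps and trajectories stay put at the fixed point", {
  p <- random_subcritical_network(M = 4, N = 2, seed = 1)
  expect_error(integrate_dynamics(p, c(0, 0), duration = 1, dt = 1.5),
               "dt")
  fp <- solve_fixed_point(p, c(0.1, 0.2), tol = 1e-12)
  traj <- integrate_dynamics(p, c(0.1, 0.2), duration = 1, dt = 0.05,
                             init = fp$s)
  expect_lt(max(abs(sweep(traj, 2, fp$s))), 1e-9)
})

test_that("non-convergence within max_iter is flagged, not fatal", {
  M <- 21
  p <- network_params(build_ring(M)$W, optimal_ring_K(M)) # exactly critical
  fp <- solve_fixed_point(p, c(1e-5, 0), max_iter = 50)
  expect_false(fp$converged)
  expect_identical(fp$iterations, 50L)
})

test_that("network parameter serialization round-trips at double precision", {
  p <- random_subcritical_network(M = 6, N = 3, seed = 9)
  dir <- withr::local_tempdir()
  write_network_params(p, dir)
  q <- read_network_params(dir)
  expect_identical(q$W, unname(p$W))
  expect_identical(unname(q$K), unname(p$K))
  expect_identical(q$tau, p$tau)
  expect_identical(q$nl$name, p$nl$name)
})
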