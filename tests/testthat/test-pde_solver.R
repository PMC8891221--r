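test_that("initial conditions evaluate per their defining formulas", {
  g <- grid1d(30, 0.5)
  hv <- make_ic(initial_condition("heaviside", beta = 10), g)
  expect_equal(hv$u[g$x == 0], 1)
  expect_equal(hv$u[g$x == 10], 1)   # closed on the left at x = beta
  expect_equal(hv$u[g$x == 20], 0)
  expect_true(all(hv$s == 0))
  ex <- make_ic(initial_condition("exponential", beta = 10, a = 0.5), g)
  expect_equal(ex$u[g$x == 10], 1)   # continuity at x = beta
  ex2 <- make_ic(initial_condition("exponential", beta = 10, a = 2), g)
  expect_equal(ex2$u[g$x == 10.5], exp(-1))
  expect_true(all(ex2$s == 0))
  expect_error(make_ic(initial_condition("heaviside", beta = 40), g),
               "beta")
  expect_error(initial_condition("exponential"), "decay rate")
})

test_that("spatially uniform states follow the logistic/linear closed forms", {
  # interior nodes far from the truncation boundary follow the
  # space-independent dynamics: logistic growth for u, driven linear decay
  # for s
  r1 <- 1.3; r2 <- 0.7; u0 <- 0.2
  g <- grid1d(30, 0.1)
  st0 <- field_state(0, rep(u0, g$n), numeric(g$n))
  sol <- solve_1d(model_params(r1, r2), st0, g,
                  solver_settings(dt = 1e-5, t_end = 2, store_every = 1))
  interior <- g$x <= 10
  tfin <- max(sol$times)
  u_exact <- u0 / (u0 + (1 - u0) * exp(-tfin))
  s_exact <- integrate(function(y)
    r1 * u0 / (u0 + (1 - u0) * exp(-y)) * exp(-r2 * (tfin - y)),
    0, tfin, rel.tol = 1e-12)$value
  i <- length(sol$times)
  expect_lt(max(abs(sol$u[interior, i] - u_exact)), 1e-6)
  expect_lt(max(abs(sol$s[interior, i] - s_exact)), 1e-6)
})

test_that("the empty state is an equilibrium and substrate stays bounded", {
  g <- grid1d(20, 0.1)
  st0 <- field_state(0, numeric(g$n), numeric(g$n))
  sol <- solve_1d(model_params(2, 1), st0, g,
                  solver_settings(dt = 0.01, t_end = 2, store_every = 0.5))
  expect_true(all(sol$u == 0))
  expect_true(all(sol$s == 0))
  # bounded substrate: s <= R (1 - exp(-r2 t)) whenever u <= 1, s(.,0)=0
  run <- coarse_run("heaviside", r1 = 2, r2 = 1, t_end = 20)
  R <- run$params$R
  for (i in seq_along(run$times)) {
    bound <- R * (1 - exp(-run$params$r2 * run$times[i])) + 1e-9
    expect_lt(max(run$s[, i]), bound + 1e-12)
  }
})

test_that("the invaded region relaxes to u = 1, s = R behind the front", {
  run <- coarse_run("heaviside", r1 = 2, r2 = 1, t_end = 40)
  i <- length(run$times)
  expect_lt(abs(run$s[1, i] - run$params$R), 1e-2)
  expect_lt(abs(run$u[1, i] - 1), 1e-2)
})

test_that("smooth-front speeds are insensitive to grid refinement", {
  est_a <- coarse_speed("exponential", a = 1, X = 80, dx = 0.04,
                        dt = 0.004, t_end = 40)
  est_b <- coarse_speed("exponential", a = 1, X = 80, dx = 0.02,
                        dt = 0.002, t_end = 40)
  expect_lt(abs(est_a$c - est_b$c), 0.01)
})

test_that("2D pore simulation holds boundaries, symmetry and positivity", {
  p <- dimensional_params()
  sol <- solve_2d(p, solver_settings(dt = 1e-2, t_end = 4),
                  mesh_n = 41, snapshot_times = c(2, 4))
  for (k in 1:2) {
    u <- sol$u[[k]]
    n <- nrow(u)
    # boundary nodes at carrying capacity
    expect_equal(max(abs(u[c(1, n), ] - p$Ku_hat)), 0)
    expect_equal(max(abs(u[, c(1, n)] - p$Ku_hat)), 0)
    # all 8 symmetries of the square
    expect_lt(max(abs(u - t(u))), 1e-8)
    expect_lt(max(abs(u - u[n:1, ])), 1e-8)
    expect_lt(max(abs(u - u[, n:1])), 1e-8)
    expect_true(all(u >= 0), info = "cell density non-negative")
    expect_true(all(sol$s[[k]] >= 0), info = "substrate non-negative")
  }
  # monotone filling: density never decreases and the pore keeps filling
  expect_true(all(sol$u[[2]] >= sol$u[[1]] - 1e-9))
  expect_gt(mean(sol$u[[2]]), mean(sol$u[[1]]))
})
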