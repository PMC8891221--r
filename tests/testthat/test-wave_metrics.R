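test_that("front position is located by linear interpolation", {
  g <- grid1d(20, 0.1)
  u <- pmax(0, 1 - g$x / 10)
  expect_equal(front_position(u, g, 0.5), 5)
  # translation equivariance
  d <- 3.2
  u2 <- pmax(0, 1 - (g$x - d) / 10)
  expect_equal(front_position(u2, g, 0.5), 5 + d, tolerance = 1e-10)
  # heaviside jump located within one cell
  hv <- make_ic(initial_condition("heaviside", beta = 10), g)
  expect_lt(abs(front_position(hv, g, 0.5) - 10), g$dx + 1e-12)
  expect_error(front_position(rep(0.01, g$n), g, 0.5), "below")
})

test_that("the speed estimator recovers a rigid translation exactly", {
  fx <- generate_fixture("translating-profile", speed = 0.7)
  est <- estimate_wave_speed(fx)
  expect_lt(abs(est$c - 0.7), 1e-10)
  expect_true(est$converged)
  expect_lt(est$residual, 1e-9)
  # too few snapshots refused
  short <- fx
  short$times <- fx$times[1:5]
  short$u <- fx$u[, 1:5]; short$s <- fx$s[, 1:5]
  expect_error(estimate_wave_speed(short), "10 stored snapshots")
})

test_that("converged wave-speed estimates are threshold-robust", {
  est_mid <- study_estimate("heaviside")
  sol <- attr(est_mid, "solution")
  est_low <- suppressWarnings(estimate_wave_speed(sol, level = 0.05))
  expect_lt(abs(est_mid$c - est_low$c), 0.01)
})

test_that("sharp-front speed does not depend on the occupied length beta", {
  ca <- coarse_speed("heaviside", beta = 5, dt = 0.005)
  cb <- coarse_speed("heaviside", beta = 10, dt = 0.005)
  expect_lt(abs(ca$c - cb$c), 0.005)
})

test_that("sub-critical smooth speeds are independent of the substrate rates", {
  est1 <- cached("disp_a05_r1", {
    measure_wave_speed(model_params(1, 1),
                       initial_condition("exponential", a = 0.5),
                       grid1d(100, 0.01),
                       solver_settings(dt = 1e-3, t_end = 30))
  })
  est5 <- cached("disp_a05_r5", {
    measure_wave_speed(model_params(5, 1),
                       initial_condition("exponential", a = 0.5),
                       grid1d(100, 0.01),
                       solver_settings(dt = 1e-3, t_end = 30))
  })
  expect_lt(abs(est1$c - est5$c), 0.01)
  expect_lt(abs(est1$c - 2), 0.02)  # dispersion value 1/a = 2
})

test_that("dispersion sweep reports speeds beside the 1/a prediction", {
  tab <- cached("disp_sweep", {
    dispersion_sweep(c(2), model_params(1, 1),
                     grid = grid1d(60, 0.02),
                     settings = solver_settings(dt = 0.005, t_end = 40))
  })
  expect_named(tab, c("a", "c", "dispersion", "converged"))
  expect_equal(tab$dispersion, 0.5)
  expect_lt(abs(tab$c - 0.5), 0.02)
})

test_that("the minimum-speed table rises with r1 and respects sqrt(R/2)", {
  tab <- cached("cmin_tab", {
    cmin_heatmap(r1_list = c(0.5, 1, 4), r2_list = c(1, 4),
                 grid = grid1d(40, 0.02),
                 settings = solver_settings(dt = 0.01, t_end = 40))
  })
  expect_true(all(tab$c_min >= 0))
  for (r2 in unique(tab$r2)) {
    cm <- tab$c_min[tab$r2 == r2][order(tab$r1[tab$r2 == r2])]
    expect_true(all(diff(cm) > 0),
                info = sprintf("c_min increasing in r1 at r2 = %g", r2))
  }
  # Porous-Fisher bound for every entry
  expect_true(all(tab$c_min <= sqrt((tab$r1 / tab$r2) / 2) + 0.01))
})
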