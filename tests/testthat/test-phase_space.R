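test_that("travelling-wave vector fields vanish at the equilibria", {
  p <- model_params(1, 1)
  expect_equal(tw_rhs_smooth(c(1, p$R, 0), 1, p), c(0, 0, 0))
  expect_equal(tw_rhs_desing(c(1, p$R, 0), 1, p), c(0, 0, 0))
  expect_equal(tw_rhs_desing(c(0, 0, 0), 1, p), c(0, 0, 0))
  # hand-evaluated substrate slope at an interior point
  d <- tw_rhs_smooth(c(1 / 2, p$R, -0.1), 1, p)
  expect_equal(d[2], 1 / 2)
  expect_error(tw_rhs_smooth(c(0.5, 0, -0.1), 1, p), "singular")
})

test_that("closed-form eigenvalues match numerical eigendecomposition", {
  p <- model_params(1, 1)
  # hand-checked case: smooth system, invaded point, c = 1, R = 1
  e <- equilibrium_eigenvalues("smooth", "invaded", 1, p)
  expect_equal(e$closed_form, c(1, (-1 + sqrt(5)) / 2, (-1 - sqrt(5)) / 2))
  expect_lt(max(abs(e$closed_form - e$numeric)), 1e-10)
  # non-hyperbolic origin of the desingularised system
  e0 <- equilibrium_eigenvalues("desing", "uninvaded", 0.29, p)
  expect_equal(e0$closed_form, c(0, 0, -0.29))
  expect_lt(max(abs(e0$closed_form - e0$numeric)), 1e-10)
  # the smooth system cannot be linearised at the origin
  expect_error(equilibrium_eigenvalues("smooth", "uninvaded", 1, p),
               "singular")
  # randomised oracle across the parameter cube
  set.seed(42)
  for (i in 1:50) {
    cc <- runif(1, 0.1, 10)
    pp <- model_params(runif(1, 0.1, 10), runif(1, 0.1, 10))
    for (sys in c("smooth", "desing")) {
      e <- equilibrium_eigenvalues(sys, "invaded", cc, pp)
      expect_lt(max(abs(e$closed_form - e$numeric)), 1e-10)
    }
    # Vieta: in the desingularised system the saddle pair (the two
    # eigenvalues other than the pure-substrate mode r1/c) multiplies to
    # -R; checked on the numerically computed spectrum
    e <- equilibrium_eigenvalues("desing", "invaded", cc, pp)
    i1 <- which.min(abs(e$numeric - pp$r1 / cc))
    expect_equal(prod(e$numeric[-i1]), -pp$R, tolerance = 1e-8)
  }
})

test_that("desingularised orbits reproduce smooth orbits after rescaling", {
  p <- model_params(1.5, 0.8)
  cc <- 1.2
  start <- c(U = 0.6, S = 0.9, W = -0.15)
  zspan <- seq(0, 2.5, length.out = 400)
  sm <- deSolve::ode(start, zspan,
                     function(z, y, q) list(tw_rhs_smooth(y, cc, p)),
                     NULL, method = "lsoda", rtol = 1e-10, atol = 1e-12)
  # augment the desingularised system with dz/dzeta = S to compare in z;
  # output densely so the linear interpolation below does not dominate
  dg <- suppressWarnings(
    deSolve::ode(c(start, z = 0), seq(0, 6, length.out = 24000),
                 function(zt, y, q)
                   list(c(tw_rhs_desing(y[1:3], cc, p), y[2])),
                 NULL, method = "lsoda", rtol = 1e-10, atol = 1e-12,
                 maxsteps = 1e5,
                 rootfunc = function(zt, y, q) c(y[2] - 0.015, 2.8 - y[4]),
                 events = list(root = TRUE, terminalroot = c(1, 2))))
  keep <- dg[, "S"] > 0.01 & dg[, "z"] <= max(zspan)
  for (v in c("U", "S", "W")) {
    interp <- approx(dg[keep, "z"], dg[keep, v], xout = sm[, "time"])
    ok <- !is.na(interp$y)
    expect_lt(max(abs(interp$y[ok] - sm[ok, v])), 1e-6)
  }
})

test_that("the slow manifold has the defining quadratic structure", {
  p <- model_params(1, 1)
  m <- slow_manifold(2, p)
  expect_equal(m$W(0, 0.5), 0)   # every term carries a factor U
  expect_equal(m$W(0, 5), 0)
  # r1 = c^2, r2 = 1 collapses the quadratic terms: W = -U/c
  m2 <- slow_manifold(2, model_params(4, 1))
  for (U in c(0.001, 0.01, 0.1))
    expect_equal(m2$W(U, 0.3), -U / 2)
})

test_that("the slow manifold is tangent to the flow to quadratic order", {
  p <- model_params(1.3, 0.6)
  cc <- 0.9
  m <- slow_manifold(cc, p)
  # off-manifold component of the full desingularised field at points on
  # the manifold, as the point is scaled toward the origin
  scales <- 10^seq(-2, -4, length.out = 9)
  resid <- vapply(scales, function(h) {
    U <- h; S <- h * 0.7
    W <- m$W(U, S)
    f <- tw_rhs_desing(c(U, S, W), cc, p)
    dWdU <- m$alpha_UU * 2 * U + m$alpha_US * S + m$alpha_U
    dWdS <- m$alpha_US * U
    abs(f[3] - (dWdU * f[1] + dWdS * f[2]))
  }, numeric(1))
  slope <- coef(lm(log(resid) ~ log(scales)))[2]
  expect_gte(unname(slope), 2.5)
})

test_that("the slow flow leaves the origin along the predicted branch", {
  for (pars in list(c(1, 1), c(2, 0.5))) {
    p <- model_params(pars[1], pars[2])
    cc <- 1
    expect_equal(unlist(slow_flow_rhs(0, 0, cc, p)),
                 c(dU = 0, dS = 0))
    tr <- integrate_slow_flow(c(1e-4 * (p$r2 + 1) / p$r1, 1e-4), cc, p,
                              zeta_end = -3000)
    n <- nrow(tr)
    # heteroclinic branch slope U/S -> (r2+1)/r1 near the origin
    expect_equal(tr$U[n] / tr$S[n], (p$r2 + 1) / p$r1, tolerance = 1e-3)
    # mapped back to the wave coordinate the tail decays like exp(-z/c)
    sel <- tr$U < 5e-3 & tr$U > 1e-4
    fit <- lm(log(tr$U[sel]) ~ tr$z[sel])
    expect_equal(unname(coef(fit)[2]), -1 / cc, tolerance = 0.02)
  }
})

test_that("orbit extraction reproduces analytic derivatives", {
  # constant region maps to W = 0
  g <- grid1d(30, 0.01)
  p <- model_params(1, 1)
  sol <- structure(list(
    grid = g, params = p, times = 0:19,
    u = matrix(rep(pmin(1, pmax(0, 1.5 - g$x / 10)), 20), g$n, 20),
    s = matrix(0.5, g$n, 20), meta = list()),
    class = "substrate_solution1d")
  orb <- extract_orbit(sol, 0, check = FALSE)
  flat <- g$x > 0.1 & g$x < 4.9  # interior of the u = 1 plateau
  expect_true(all(orb$W[flat] == 0))
  # sampled Porous-Fisher wave: W matches the analytic derivative to
  # O(dz^2)
  R <- 1; cmin <- sqrt(R / 2)
  pf <- porous_fisher_wave(g$x - 20, R)
  solpf <- structure(list(grid = g, params = p, times = 0:19,
                          u = matrix(pf$U, g$n, 20),
                          s = matrix(pf$S, g$n, 20), meta = list()),
                     class = "substrate_solution1d")
  orbpf <- extract_orbit(solpf, cmin, check = FALSE)
  behind <- orbpf$z < -0.1   # away from the corner at the front
  zorig <- g$x[behind] - 20  # pre-shift coordinate of the same nodes
  W_exact <- -(1 / (2 * cmin)) * exp(zorig / (2 * cmin))
  expect_lt(max(abs(orbpf$W[behind] - W_exact)), g$dx^2 * 2)
})

test_that("orbits integrated on the slow flow itself classify as smooth", {
  orbit <- generate_fixture("on-manifold-orbit", c = 1,
                            params = model_params(1, 1))
  cl <- classify_front(orbit, slow_manifold(1, model_params(1, 1)))
  expect_identical(cl$front, "smooth")
  expect_lt(cl$median_relative_deviation, 1e-6)
})

test_that("speeds below the minimum force the orbit out of the octant", {
  p <- model_params(1, 1)
  # c comfortably above c_min: the direct-entry orbit stays physical
  pr1 <- probe_subminimal_speed(1, p)
  expect_gte(pr1$min_U, -1e-6)
  expect_true(pr1$physical)
  expect_null(pr1$negative_U_zeta)
  # c well below c_min = 0.29: part of the orbit has U < 0
  pr2 <- probe_subminimal_speed(0.1, p)
  expect_lt(pr2$min_U, 0)
  expect_false(pr2$physical)
  expect_length(pr2$negative_U_zeta, 2)
})
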