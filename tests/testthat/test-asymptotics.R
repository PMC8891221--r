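test_that("the substrate integral reproduces its closed-form limits", {
  p <- model_params(1, 1)
  # saturated cell density gives the invaded substrate level R
  expect_equal(substrate_from_profile(function(z) rep(1, length(z)),
                                      1, p, 0), p$R, tolerance = 1e-8)
  p2 <- model_params(3, 2)
  expect_equal(substrate_from_profile(function(z) rep(1, length(z)),
                                      0.7, p2, -2), p2$R, tolerance = 1e-8)
  # exponential tails: S = r1 U / (b c + r2)
  b <- 2; cc <- 1
  S <- substrate_from_profile(function(z) exp(-b * z), cc, p, c(0, 0.5, 1))
  expect_equal(S, p$r1 * exp(-b * c(0, 0.5, 1)) / (b * cc + p$r2),
               tolerance = 1e-8)
  # empty profile maps to empty substrate
  expect_equal(substrate_from_profile(function(z) numeric(length(z)) ,
                                      1, p, 0), 0)
  expect_error(substrate_from_profile(function(z) exp(z), 1, p, 0),
               "decay")
})

test_that("the dispersion relation is c = 1/a on its branch", {
  expect_identical(dispersion_speed(5), 0.2)
  expect_identical(dispersion_speed(1), 1)
  a <- c(0.5, 1, 2, 4, 8)
  expect_true(all(diff(dispersion_speed(a)) < 0))
  expect_lt(dispersion_speed(1e6), 1e-5)
  expect_error(dispersion_speed(0), "positive")
  expect_error(dispersion_speed(-1), "positive")
})

test_that("the Porous-Fisher sharp wave is exact", {
  z <- seq(-30, 10, 0.01)
  for (R in c(0.5, 1, 2)) {
    w <- porous_fisher_wave(z, R)
    expect_equal(w$c_min, sqrt(R / 2))
    expect_equal(w$S, R * w$U)
    # continuity and compact support at the front
    expect_equal(w$U[z == 0], 0)
    expect_true(all(w$U[z > 0] == 0))
    expect_equal(w$U[1], 1, tolerance = exp(-30 / (2 * w$c_min)) * 1.1)
    # satisfies the substituted wave equation to round-off
    expect_lt(max(abs(porous_fisher_residual(z[z < 0], R))), 1e-12)
  }
  expect_equal(round(porous_fisher_wave(0, 1)$c_min, 2), 0.71)
})

test_that("integer-r2 substrate closed forms match quadrature", {
  zh <- seq(-10, 10, 0.25)
  for (r2 in 1:3) {
    d <- max(abs(substratewaves:::s0_closed_form(zh, 1.5, r2) - substratewaves:::s0_quadrature(zh, 1.5, r2)))
    expect_lt(d, 1e-8)
  }
  # printed special cases for r2 = 1 and r2 = 2
  r1 <- 2
  expect_equal(substratewaves:::s0_closed_form(0.3, r1, 1),
               r1 * (1 - exp(0.3) * log(exp(-0.3) + 1)))
  expect_equal(substratewaves:::s0_closed_form(-0.4, r1, 2),
               r1 * (1 / 2 - exp(-0.4) + exp(-0.8) * log(exp(0.4) + 1)))
})

test_that("perturbation profiles have the required structure", {
  p <- model_params(1, 1)
  zh <- seq(-12, 12, 0.05)
  pp <- perturbation_solution(4, p, zh)
  expect_equal(pp$U0[pp$zhat == 0], 0.5)       # normalisation
  expect_true(all(diff(pp$U0) < 0))            # monotone front
  expect_equal(pp$S0[1], p$R, tolerance = 1e-4)   # invaded limit
  expect_lt(pp$S0[nrow(pp)], 1e-4)             # uninvaded limit
  expect_lt(max(abs(pp$U1[c(1, nrow(pp))])), 1e-3)  # correction vanishes
  # non-integer r2 falls back to quadrature with a notice
  expect_message(perturbation_solution(4, model_params(1, 1.5),
                                       seq(-2, 2, 0.5)), "quadrature")
})

test_that("the perturbation residual decays at fourth order in 1/c", {
  p <- model_params(1, 1)
  resmax <- function(cc) {
    zh <- seq(-12, 12, 0.01)
    pp <- perturbation_solution(cc, p, zh)
    r <- tw_residual(zh * cc, pp$U, pp$S0, cc, p)
    max(abs(r$res_u))
  }
  ratio <- resmax(2) / resmax(4)
  expect_gt(ratio, 8)
  expect_lt(ratio, 32)
})

test_that("far-field consistency pins the speed to the tail decay rate", {
  p <- model_params(1, 1)
  expect_equal(farfield_consistency(1 / 1.7, 1.7, p)$defect, 0)
  r <- farfield_consistency(2, 1, model_params(1.3, 0.4))
  expect_equal(r$S_over_U, 1.3 / (2 + 0.4))
  expect_equal(r$W_over_U, -2)
  expect_equal(r$defect, 1)
})

test_that("extracted smooth-wave tails obey the far-field ratios", {
  est <- study_estimate("exponential", a = 1)
  cc <- est$c
  orb <- extract_orbit(attr(est, "solution"), cc, check = FALSE)
  tail <- orb[orb$U > 1e-3 & orb$U < 1e-2, ]
  b <- 1 / cc
  pred <- farfield_consistency(b, cc, model_params(1, 1))
  expect_equal(median(tail$S / tail$U), pred$S_over_U, tolerance = 0.05)
  expect_equal(median(tail$W / tail$U), pred$W_over_U, tolerance = 0.05)
  # fitted tail decay rate matches 1/c
  fit <- lm(log(tail$U) ~ tail$z)
  expect_equal(unname(coef(fit)[2]), -b, tolerance = 0.05)
})

test_that("fast substrate kinetics approach the Porous-Fisher profile", {
  est <- study_estimate("heaviside", r1 = 100, r2 = 100)
  orb <- extract_orbit(attr(est, "solution"), est$c, check = FALSE)
  # align the closed form so both profiles cross 1/2 at z = 0
  cmin <- sqrt(1 / 2)
  zc <- -2 * cmin * log(0.5)
  ref <- porous_fisher_wave(orb$z, 1, z_c = zc)
  expect_lt(max(abs(orb$U - ref$U)), 0.05)
  expect_lt(max(abs(orb$S - ref$S)), 0.05)
})
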