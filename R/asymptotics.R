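#' Substrate profile implied by a cell-density wave profile
#'
#' Given a travelling-wave cell density `U(z)`, the linear substrate
#' equation integrates exactly to
#' \deqn{S(z) = (r_1/c) e^{r_2 z / c} \int_z^\infty e^{-r_2 y / c} U(y) dy,}
#' evaluated here by adaptive quadrature with an analytic correction for
#' exponentially decaying tails.  For `U` identically 1 this recovers the
#' invaded level `S = R`; for `U = exp(-b z)` it gives
#' `S = r1 U / (b c + r2)`.
#'
#' @param U a function of `z` (vectorised) that decays as `z -> Inf`.
#' @param c wave speed (> 0).
#' @param params a [model_params()] object.
#' @param z evaluation points.
#' @param tail_rate optional known exponential decay rate of `U` for the
#'   analytic tail beyond the quadrature horizon; if `NULL` the tail is
#'   estimated from `U` itself.
#' @return `S(z)` at the requested points.
#' @export
substrate_from_profile <- function(U, c, params, z, tail_rate = NULL) {
  stopifnot(is.function(U), c > 0, inherits(params, "model_params"))
  r1 <- params$r1; r2 <- params$r2
  zmax <- max(z) + 40 * c / max(r2, 1)
  # decay check and tail estimate at the quadrature horizon
  u1 <- U(zmax - 1); u2 <- U(zmax)
  if (!is.finite(u1) || !is.finite(u2) || u2 > u1 + 1e-12)
    stop("U does not decay at large z: substrate integral diverges",
         call. = FALSE)
  b <- if (!is.null(tail_rate)) tail_rate
       else if (u2 > 0 && u1 > 0) log(u1 / u2) else Inf
  vapply(z, function(zi) {
    quad <- integrate(function(y) exp(-r2 * (y - zi) / c) * U(y),
                      zi, zmax, rel.tol = 1e-10, abs.tol = 1e-14)$value
    tail <- if (is.finite(b) && b > 0)
      U(zmax) * exp(-r2 * (zmax - zi) / c) / (b + r2 / c)
    else 0
    (r1 / c) * (quad + tail)
  }, numeric(1))
}

#' Dispersion relation for smooth-fronted waves
#'
#' A cell density decaying like `exp(-a x)` ahead of the front evolves into
#' a smooth travelling wave of speed `c = 1/a`, independent of the
#' substrate parameters.  The relation holds below the critical decay rate
#' `a_crit`; for faster-decaying initial data the measured speed plateaus
#' at the `(r1, r2)`-dependent minimum speed instead.
#'
#' @param a initial far-field decay rate (> 0), vectorised.
#' @return The predicted wave speed `1/a`.
#' @examples
#' dispersion_speed(5)  # 0.2
#' @export
dispersion_speed <- function(a) {
  if (any(!is.finite(a)) || any(a <= 0))
    stop("decay rate a must be positive", call. = FALSE)
  1 / a
}

#' Exact sharp-fronted wave of the Porous-Fisher limit
#'
#' For fast substrate production and decay (`r1, r2 -> Inf` at fixed
#' `R = r1/r2`) the substrate slaves to the cell density (`s = R u`) and
#' the model reduces to the Porous-Fisher equation with diffusivity `R u`,
#' whose sharp-fronted wave is known exactly:
#' \deqn{U(z) = 1 - e^{(z - z_c)/(2c)} \ (z < z_c), \quad 0 \ (z > z_c),
#'       \qquad S = R U, \qquad c = c_{min} = \sqrt{R/2}.}
#'
#' @param z evaluation points.
#' @param R substrate production/decay ratio.
#' @param z_c front location (default 0).
#' @return A list with `U`, `S`, `c_min`.
#' @examples
#' porous_fisher_wave(0, R = 1)$c_min  # 1/sqrt(2)
#' @export
porous_fisher_wave <- function(z, R, z_c = 0) {
  stopifnot(R > 0)
  cmin <- sqrt(R / 2)
  U <- ifelse(z < z_c, 1 - exp((z - z_c) / (2 * cmin)), 0)
  list(U = U, S = R * U, c_min = cmin)
}

# O(1) substrate term of the large-c expansion: quadrature form.
# Derived from dS0/dzhat = r2 S0 - r1 U0 with S0 -> 0 ahead of the wave:
# S0(zhat) = r1 e^{r2 zhat} int_zhat^Inf e^{-r2 y} U0(y) dy, U0 the logistic.
s0_quadrature <- function(zhat, r1, r2) {
  vapply(zhat, function(zh) {
    # substitute y = zh + v so the integrand is O(e^{-r2 v})
    f <- function(v) exp(-r2 * v) / (1 + exp(pmin(zh + v, 700)))
    r1 * integrate(f, 0, Inf, rel.tol = 1e-12, abs.tol = 1e-15)$value
  }, numeric(1))
}

# closed form for integer r2: (-1)^r2 r1 e^{r2 zhat} [log(1+e^{-zhat}) +
# sum_{n=1}^{r2} (-1)^{-n} e^{-n zhat}/n].  Ahead of the front the bracket
# is a difference of near-equal terms, so there the exactly equivalent
# alternating tail series r1 sum_{j>=1} (-1)^{j+1} e^{-j zhat}/(r2+j)
# (the first r2 log-series terms cancel the finite sum) is used instead.
s0_closed_form <- function(zhat, r1, r2) {
  stopifnot(r2 == round(r2), r2 >= 1)
  n <- seq_len(r2)
  vapply(zhat, function(zh) {
    if (zh > 0.5) {
      j <- seq_len(max(60, ceiling(40 / zh)))
      return(r1 * sum((-1)^(j + 1) * exp(-j * zh) / (r2 + j)))
    }
    # products formed term-by-term as exp((r2-n) zh) to avoid overflow
    (-1)^r2 * r1 * (exp(r2 * zh) * log1p(exp(-zh)) +
                      sum((-1)^n * exp((r2 - n) * zh) / n))
  }, numeric(1))
}

u1_quadrature <- function(zhat, r1, r2, S0fun) {
  # integrand mu(y) (S0 U0')' with analytic derivatives:
  # (S0 U0')' = S0' U0' + S0 U0'', S0' = r2 S0 - r1 U0,
  # U0' = -U0(1-U0), U0'' = -U0'(1-2U0), mu = (1+e^y)^2/e^y
  g <- function(y) {
    U0 <- 1 / (1 + exp(pmin(y, 700)))
    U0p <- -U0 * (1 - U0)
    U0pp <- -U0p * (1 - 2 * U0)
    S0 <- S0fun(y)
    S0p <- r2 * S0 - r1 * U0
    mu <- (1 + exp(pmin(y, 350)))^2 / exp(pmin(y, 350))
    mu * (S0p * U0p + S0 * U0pp)
  }
  vapply(zhat, function(zh) {
    U0 <- 1 / (1 + exp(min(zh, 700)))
    mu_inv <- exp(min(zh, 350)) / (1 + exp(min(zh, 350)))^2
    val <- integrate(function(y) vapply(y, g, numeric(1)),
                     zh, zh + 80, rel.tol = 1e-10, abs.tol = 1e-15)$value
    mu_inv * val
  }, numeric(1))
}

#' Large-speed perturbation profiles for smooth-fronted waves
#'
#' For fast waves the profile varies on the long scale `zhat = z/c`, and an
#' expansion in the small parameter `1/c^2` gives, at leading order, the
#' logistic front `U0 = 1/(1 + exp(zhat))` (normalised so `U0(0) = 1/2`)
#' and the substrate `S0` obtained by integrating the linear equation
#' driven by `U0`; the first correction `U1` is obtained with an
#' integrating factor.  `S0` uses the closed-form expression when `r2` is a
#' positive integer and adaptive quadrature otherwise; `U1` is always
#' evaluated by quadrature with analytic derivatives, which stays
#' determinate at large `zhat`.  The composite approximation is
#' `U ~ U0 + U1/c^2`, `S ~ S0`.
#'
#' @param c wave speed (the expansion is asymptotic as `c -> Inf`; it is
#'   already accurate at `c = 4`).
#' @param params a [model_params()] object.
#' @param zhat_grid evaluation points of the rescaled coordinate, spanning
#'   both tails.
#' @param use_closed_form evaluate `S0` in closed form when `r2` is a
#'   positive integer (default); non-integer `r2` falls back to quadrature
#'   with a notice.
#' @return An object of class `perturbation_profile`: a data frame with
#'   columns `zhat`, `U0`, `S0`, `U1`, `U` (composite) and attributes `c`,
#'   `r1`, `r2`.
#' @examples
#' pp <- perturbation_solution(4, model_params(1, 1), seq(-6, 6, 0.5))
#' pp$U0[pp$zhat == 0]  # 0.5
#' @export
perturbation_solution <- function(c, params, zhat_grid,
                                  use_closed_form = TRUE) {
  stopifnot(c > 0, inherits(params, "model_params"))
  r1 <- params$r1; r2 <- params$r2
  zh <- sort(zhat_grid)
  U0 <- 1 / (1 + exp(pmin(zh, 700)))
  integer_r2 <- abs(r2 - round(r2)) < 1e-12 && r2 >= 1
  if (use_closed_form && !integer_r2) {
    message("r2 is not a positive integer; evaluating S0 by quadrature")
    use_closed_form <- FALSE
  }
  S0fun <- if (use_closed_form)
    function(y) s0_closed_form(y, r1, round(r2))
  else
    function(y) s0_quadrature(y, r1, r2)
  S0 <- S0fun(zh)
  U1 <- u1_quadrature(zh, r1, r2, S0fun)
  out <- data.frame(zhat = zh, U0 = U0, S0 = S0, U1 = U1,
                    U = U0 + U1 / c^2)
  attr(out, "c") <- c
  attr(out, "params") <- params
  class(out) <- c("perturbation_profile", class(out))
  out
}

#' Far-field consistency of a smooth wave tail
#'
#' Assuming `U ~ C exp(-b z)` ahead of a smooth wave, the substrate and
#' slope tails follow as `S/U -> r1/(b c + r2)` and `W/U -> -b`, and
#' substituting back into the wave equations leaves a leading-order defect
#' proportional to `|b c - 1|`: only `c = 1/b` is consistent, which ties
#' the smooth wave speed to its own tail decay rate.
#'
#' @param b tail decay rate (> 0).
#' @param c wave speed (> 0).
#' @param params a [model_params()] object.
#' @return A list with the asymptotic ratios `S_over_U`, `W_over_U` and
#'   the consistency `defect = |b c - 1|` (zero for admissible waves).
#' @export
farfield_consistency <- function(b, c, params) {
  stopifnot(b > 0, c > 0, inherits(params, "model_params"))
  list(S_over_U = params$r1 / (b * c + params$r2),
       W_over_U = -b,
       defect = abs(b * c - 1))
}

#' Analytic residual of the exact Porous-Fisher wave
#'
#' Evaluates `R (U U')' + c U' + U(1-U)` for the closed-form sharp wave at
#' `c = sqrt(R/2)` using analytic derivatives; the result is zero to
#' round-off behind the front, confirming the profile solves the
#' substituted (fast production/decay) wave equation exactly.
#'
#' @param z evaluation points with `z < z_c`.
#' @param R substrate production/decay ratio.
#' @param z_c front location.
#' @return The pointwise residual.
#' @export
porous_fisher_residual <- function(z, R, z_c = 0) {
  stopifnot(R > 0, all(z < z_c))
  cmin <- sqrt(R / 2)
  E <- exp((z - z_c) / (2 * cmin))
  # R (U U')' = -E/2 + E^2 ; c U' = -E/2 ; U(1-U) = E - E^2
  (-E / 2 + E^2) + (-E / 2) + (E - E^2)
}

#' Residual of a profile in the travelling-wave equations
#'
#' Substitutes sampled `(U, S)` profiles into the wave-frame equations
#' `(S U')' + c U' + U(1-U) = 0` and `c S' + r1 U - r2 S = 0` using centred
#' finite differences, returning the pointwise residuals.  Used to verify
#' the closed-form Porous-Fisher wave and the decay rate of the
#' perturbation error.
#'
#' @param z sample points (uniform spacing).
#' @param U,S profile samples.
#' @param c wave speed.
#' @param params a [model_params()] object.
#' @return A list with vectors `res_u`, `res_s` on the interior points.
#' @export
tw_residual <- function(z, U, S, c, params) {
  dz <- diff(z)
  stopifnot(max(abs(dz - dz[1])) < 1e-8 * dz[1])
  h <- dz[1]
  n <- length(z)
  i <- 2:(n - 1)
  Up <- (U[i + 1] - U[i - 1]) / (2 * h)
  Sp <- (S[i + 1] - S[i - 1]) / (2 * h)
  # (S U')' with face-centred differences
  Sface_r <- (S[i + 1] + S[i]) / 2
  Sface_l <- (S[i] + S[i - 1]) / 2
  flux <- (Sface_r * (U[i + 1] - U[i]) - Sface_l * (U[i] - U[i - 1])) / h^2
  list(res_u = flux + c * Up + U[i] * (1 - U[i]),
       res_s = c * Sp + params$r1 * U[i] - params$r2 * S[i],
       z = z[i])
}
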