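#' Travelling-wave ODE right-hand sides
#'
#' In the wave frame `z = x - c t` the model reduces to the first-order
#' system
#' \deqn{U' = W, \quad S' = -(r_1 U - r_2 S)/c, \quad
#'       W' = W (r_1 U - r_2 S - c^2)/(c S) - U(1-U)/S,}
#' which is singular where `S = 0`.  Rescaling the independent variable by
#' `d(zeta) = dz / S` removes the singularity and yields the desingularised
#' system
#' \deqn{U' = S W, \quad S' = -S (r_1 U - r_2 S)/c, \quad
#'       W' = W (r_1 U - r_2 S - c^2)/c - U(1-U),}
#' which is regular everywhere and valid for both smooth and sharp fronts.
#'
#' @param state numeric vector `c(U, S, W)`.
#' @param c wave speed (> 0).
#' @param params a [model_params()] object.
#' @return The derivative vector `c(dU, dS, dW)` with respect to `z`
#'   (smooth system) or `zeta` (desingularised system).
#' @name tw_rhs
NULL

#' @rdname tw_rhs
#' @export
tw_rhs_smooth <- function(state, c, params) {
  U <- state[1]; S <- state[2]; W <- state[3]
  if (S == 0)
    stop(paste("the smooth-system right-hand side is singular at S = 0;",
               "use the desingularised system (tw_rhs_desing)"),
         call. = FALSE)
  c(W,
    -(params$r1 * U - params$r2 * S) / c,
    W * (params$r1 * U - params$r2 * S - c^2) / (c * S) -
      U * (1 - U) / S)
}

#' @rdname tw_rhs
#' @export
tw_rhs_desing <- function(state, c, params) {
  U <- state[1]; S <- state[2]; W <- state[3]
  c(S * W,
    -S * (params$r1 * U - params$r2 * S) / c,
    W * (params$r1 * U - params$r2 * S - c^2) / c - U * (1 - U))
}

jacobian_smooth <- function(point, c, params) {
  U <- point[1]; S <- point[2]; W <- point[3]
  r1 <- params$r1; r2 <- params$r2
  rbind(c(0, 0, 1),
        c(-r1 / c, r2 / c, 0),
        c((r1 * W - c * (1 - 2 * U)) / (c * S),
          ((-r1 * U + c^2) * W + c * U * (1 - U)) / (c * S^2),
          (-r2 * S + r1 * U - c^2) / (c * S)))
}

jacobian_desing <- function(point, c, params) {
  U <- point[1]; S <- point[2]; W <- point[3]
  r1 <- params$r1; r2 <- params$r2
  rbind(c(0, W, S),
        c(-r1 * S / c, (-r1 * U + 2 * r2 * S) / c, 0),
        c((r1 * W - c * (1 - 2 * U)) / c,
          -r2 * W / c,
          (-r2 * S + r1 * U - c^2) / c))
}

#' Eigenvalues at the travelling-wave equilibria
#'
#' Both phase spaces share the invaded equilibrium `(1, R, 0)` and the
#' uninvaded equilibrium `(0, 0, 0)`.  Closed forms: in the smooth system
#' the invaded point has eigenvalues `r2/c` and
#' `(-c +- sqrt(c^2 + 4R))/(2R)`; in the desingularised system the invaded
#' point has `r1/c` and `(-c +- sqrt(c^2 + 4R))/2`, while the uninvaded
#' point has `-c, 0, 0` and is non-hyperbolic (the zero directions carry
#' the slow-manifold dynamics).  The smooth system's Jacobian is singular
#' at the uninvaded point, so linearisation there is refused.
#'
#' @param system `"smooth"` or `"desing"`.
#' @param point `"invaded"` or `"uninvaded"`.
#' @param c wave speed (> 0).
#' @param params a [model_params()] object.
#' @return A list with `closed_form` and `numeric` eigenvalue triples
#'   (both sorted decreasing) and the `jacobian`; the two triples agree to
#'   near machine precision.
#' @examples
#' equilibrium_eigenvalues("desing", "uninvaded", c = 0.29,
#'                         model_params(1, 1))$closed_form  # -0.29 0 0
#' @export
equilibrium_eigenvalues <- function(system = c("smooth", "desing"),
                                    point = c("invaded", "uninvaded"),
                                    c, params) {
  system <- match.arg(system)
  point <- match.arg(point)
  stopifnot(c > 0, inherits(params, "model_params"))
  R <- params$R
  if (system == "smooth" && point == "uninvaded")
    stop(paste("the smooth-system Jacobian is singular at (0,0,0)",
               "(terms ~ 1/S); linearisation is not useful there --",
               "use the desingularised system"), call. = FALSE)
  pt <- if (point == "invaded") c(1, R, 0) else c(0, 0, 0)
  J <- if (system == "smooth") jacobian_smooth(pt, c, params)
       else jacobian_desing(pt, c, params)
  disc <- sqrt(c^2 + 4 * R)
  closed <- if (system == "smooth") {
    c(params$r2 / c, (-c + disc) / (2 * R), (-c - disc) / (2 * R))
  } else if (point == "invaded") {
    c(params$r1 / c, (-c + disc) / 2, (-c - disc) / 2)
  } else {
    c(-c, 0, 0)
  }
  list(closed_form = sort(closed, decreasing = TRUE),
       numeric = sort(Re(eigen(J, only.values = TRUE)$values),
                      decreasing = TRUE),
       jacobian = J)
}

#' Slow manifold through the uninvaded equilibrium
#'
#' Centre-manifold reduction at the non-hyperbolic origin of the
#' desingularised system gives, to quadratic order and in the original
#' coordinates, the invariant graph
#' \deqn{W(U, S) = [ (c^2 - r_1) U^2 - (1 - r_2) U S - c^2 U ] / c^3.}
#' Smooth-fronted waves enter the origin along this surface; sharp-fronted
#' waves enter directly, off it.
#'
#' @param c wave speed (> 0).
#' @param params a [model_params()] object.
#' @return An object of class `slow_manifold_model` with the quadratic
#'   coefficients (`alpha_UU`, `alpha_US`, `alpha_U`) and the closure
#'   `W(U, S)`.
#' @examples
#' m <- slow_manifold(1, model_params(1, 1))
#' m$W(0.01, 0.005)  # ~ -0.01
#' @export
slow_manifold <- function(c, params) {
  stopifnot(c > 0, inherits(params, "model_params"))
  a_UU <- (c^2 - params$r1) / c^3
  a_US <- -(1 - params$r2) / c^3
  a_U <- -1 / c
  W <- function(U, S) a_UU * U^2 + a_US * U * S + a_U * U
  structure(list(c = c, r1 = params$r1, r2 = params$r2,
                 alpha_UU = a_UU, alpha_US = a_US, alpha_U = a_U, W = W),
            class = "slow_manifold_model")
}

#' Reduced flow on the slow manifold
#'
#' The dynamics restricted to the slow manifold, in the original
#' coordinates:
#' \deqn{dU/d\zeta = S W(U, S), \qquad
#'       dS/d\zeta = (r_2 S^2 - r_1 U S)/c.}
#' Along the heteroclinic branch the orbit leaves the origin with slope
#' `U/S -> (r2 + 1)/r1` in the US-plane, and the profile it encodes decays
#' as `exp(-z/c)` in the wave coordinate.
#'
#' @param U,S coordinates (vectorised).
#' @param c wave speed.
#' @param params a [model_params()] object.
#' @return A list with components `dU` and `dS`.
#' @export
slow_flow_rhs <- function(U, S, c, params) {
  m <- slow_manifold(c, params)
  list(dU = S * m$W(U, S),
       dS = (params$r2 * S^2 - params$r1 * U * S) / c)
}

#' Integrate the reduced slow flow
#'
#' Integrates the slow-manifold dynamics from a starting point, optionally
#' backward in `zeta`, and reconstructs the wave coordinate via
#' `dz = S dzeta`.
#'
#' @param start c(U, S) starting point.
#' @param c wave speed.
#' @param params a [model_params()] object.
#' @param zeta_end integration endpoint (negative integrates backward).
#' @param n number of output points.
#' @param u_stop stop when `U` reaches this value (backward integrations
#'   blow up in finite `zeta` shortly beyond the invaded state, so the
#'   trajectory is terminated at a density just below it).
#' @return A data frame with `zeta`, `U`, `S`, `W` (manifold value), `z`.
#' @export
integrate_slow_flow <- function(start, c, params, zeta_end, n = 2000,
                                u_stop = 0.95) {
  m <- slow_manifold(c, params)
  rhs <- function(zeta, y, p) {
    d <- slow_flow_rhs(y[1], y[2], c, params)
    list(c(d$dU, d$dS, y[2]))
  }
  times <- seq(0, zeta_end, length.out = n)
  out <- suppressWarnings(
    deSolve::ode(c(U = start[1], S = start[2], z = 0), times, rhs,
                 NULL, method = "lsoda", rtol = 1e-10, atol = 1e-12,
                 maxsteps = 5e5,
                 rootfunc = function(zeta, y, p) u_stop - y[1],
                 events = list(root = TRUE, terminalroot = 1)))
  data.frame(zeta = out[, 1], U = out[, "U"], S = out[, "S"],
             W = m$W(out[, "U"], out[, "S"]), z = out[, "z"])
}

#' Extract the phase-space orbit from a PDE solution
#'
#' Rewrites the final stored snapshot of a travelling-wave run in the wave
#' coordinates `(U(z), S(z), W(z))` with `z = x - c t` shifted so the front
#' (level 0.5) sits at `z = 0`; `W = dU/dz` is computed by centred finite
#' differences.  This is the numerical image of the heteroclinic orbit
#' connecting `(1, R, 0)` to `(0, 0, 0)`.
#'
#' @param sol a `substrate_solution1d` that has converged to a travelling
#'   wave (checked via [estimate_wave_speed()] unless `check = FALSE`).
#' @param c the wave speed (used only to centre `z`; the profile shape is
#'   taken from the final snapshot).
#' @param check verify convergence before extracting.
#' @return An object of class `travelling_wave_profile`: a data frame with
#'   columns `z`, `U`, `S`, `W` and attribute `c`.
#' @export
extract_orbit <- function(sol, c, check = TRUE) {
  stopifnot(inherits(sol, "substrate_solution1d"))
  if (check) {
    est <- tryCatch(suppressWarnings(estimate_wave_speed(sol)),
                    error = function(e) NULL)
    if (is.null(est) || !est$converged)
      stop(paste("solution has not converged to a travelling wave;",
                 "run for longer before extracting the orbit"),
           call. = FALSE)
  }
  i <- length(sol$times)
  u <- sol$u[, i]; s <- sol$s[, i]
  xf <- front_position(u, sol$grid$x, 0.5)
  z <- sol$grid$x - xf
  n <- length(u)
  W <- numeric(n)
  dz <- sol$grid$dx
  W[2:(n - 1)] <- (u[3:n] - u[1:(n - 2)]) / (2 * dz)
  W[1] <- (u[2] - u[1]) / dz
  W[n] <- (u[n] - u[n - 1]) / dz
  out <- data.frame(z = z, U = u, S = s, W = W)
  attr(out, "c") <- c
  class(out) <- c("travelling_wave_profile", class(out))
  out
}

#' Classify a travelling wave front as smooth or sharp
#'
#' Smooth-fronted waves enter the uninvaded equilibrium along the slow
#' manifold, so over the orbit tail the measured `W` tracks the manifold
#' graph `W(U, S)`; sharp-fronted waves enter directly, with `|W|` far off
#' the manifold value.  The classifier reads the orbit at fixed
#' log-spaced density levels across the tail window `U` in (1e-3, 1e-2)
#' (by linear interpolation on the monotone leading tail) and computes the
#' relative deviation `|W_orbit - W_manifold| / |W_manifold|` at each
#' level, reporting `smooth` when the median is below 0.1, `sharp` when
#' above 0.5, and `indeterminate` between (the underlying distinction is
#' geometric; the thresholds are reporting conventions).
#'
#' Interpolating at levels rather than using raw samples keeps the check
#' well defined for sharp fronts, whose leading edge steepens toward a
#' density jump as the grid is refined, so no resolution ever places many
#' nodes inside the window itself.  The resolution requirement is instead
#' placed on the front body: at least 20 samples with `U` between the top
#' of the window and 1/2, which guarantees the interpolation is anchored
#' on a resolved profile.
#'
#' @param orbit a `travelling_wave_profile` from [extract_orbit()].
#' @param manifold a `slow_manifold_model` from [slow_manifold()] at the
#'   measured wave speed.
#' @param window tail window on `U` (default `c(1e-3, 1e-2)`).
#' @param n_levels number of interpolation levels across the window.
#' @return A list with `front` (`"smooth"`, `"sharp"` or
#'   `"indeterminate"`), `median_relative_deviation`, `n_tail` (samples
#'   falling inside the window itself), `n_body` (samples across the front
#'   body), and the per-level deviations.
#' @export
classify_front <- function(orbit, manifold, window = c(1e-3, 1e-2),
                           n_levels = 24) {
  stopifnot(inherits(orbit, "travelling_wave_profile"),
            inherits(manifold, "slow_manifold_model"))
  if (min(orbit$U) > window[1])
    stop("orbit does not approach the uninvaded equilibrium", call. = FALSE)
  # leading tail: strictly decreasing part of U from the last U >= 1/2
  i0 <- max(which(orbit$U >= 0.5))
  tail_orb <- orbit[i0:nrow(orbit), ]
  um <- cummin(tail_orb$U)
  tail_orb <- tail_orb[tail_orb$U == um & !duplicated(um), ]
  n_body <- sum(tail_orb$U > window[2] & tail_orb$U < 0.5)
  n_tail <- sum(tail_orb$U > window[1] & tail_orb$U < window[2])
  if (n_body < 20L)
    stop(sprintf(paste("only %d orbit samples resolve the front body;",
                       "re-extract on a finer grid near the front"),
                 n_body), call. = FALSE)
  levels <- 10^seq(log10(window[1]), log10(window[2]),
                   length.out = n_levels)
  # interpolate S and W against U on the monotone tail
  tail_orb <- tail_orb[rev(seq_len(nrow(tail_orb))), ]
  Si <- approx(tail_orb$U, tail_orb$S, xout = levels)$y
  Wi <- approx(tail_orb$U, tail_orb$W, xout = levels)$y
  Wm <- manifold$W(levels, Si)
  dev <- abs(Wi - Wm) / pmax(abs(Wm), .Machine$double.eps)
  mdev <- median(dev)
  front <- if (mdev < 0.1) "smooth" else if (mdev > 0.5) "sharp"
           else "indeterminate"
  list(front = front, median_relative_deviation = mdev,
       n_tail = n_tail, n_body = n_body, deviations = dev)
}

#' Probe the phase space at sub-minimal wave speeds
#'
#' For any `c > 0` there is a unique candidate orbit leaving the invaded
#' saddle `(1, R, 0)` of the desingularised phase space toward the origin:
#' it departs tangent to the weak unstable eigendirection (the strong one
#' is the pure-substrate mode, along which `S` collapses or diverges with
#' the cells left untouched).  The probe traces that orbit by shooting:
#' starting a fixed small distance from the saddle at a mixing angle
#' between the two oriented unstable eigenvectors, it bisects the angle on
#' the dichotomy "substrate collapses" versus "substrate diverges", then
#' follows the best shot and truncates it at its closest approach to the
#' origin (forward shooting along a weak fiber is eventually contaminated
#' by the strong mode, so the tail beyond that point is discarded).
#' The minimum of `U` along the traced orbit distinguishes admissible
#' speeds: for `c >= c_min` the orbit stays in the physical octant
#' `U >= 0, S >= 0, W <= 0`, while for `c < c_min` part of it has
#' `U < 0`, which is why no physically relevant wave travels slower than
#' `c_min`.
#'
#' @param c wave speed to probe (> 0).
#' @param params a [model_params()] object.
#' @param eps displacement of the shooting point from the saddle (fixed
#'   documented constant, default 0.02: small enough for the linearisation
#'   to hold, large enough that the orbit is traversed before the strong
#'   mode contaminates the shot).
#' @param zeta_span maximum integration span per shot.
#' @param bisections number of bisection refinements of the mixing angle.
#' @return A list with the traced `trajectory` (data frame
#'   `zeta, U, S, W`, truncated at closest approach to the origin),
#'   `min_U`, `closest_approach` (distance to the origin), `physical`
#'   (no `U < 0` beyond round-off) and `negative_U_zeta` (the
#'   `zeta`-interval where `U < 0`, `NULL` for physical orbits).
#' @export
probe_subminimal_speed <- function(c, params, eps = 0.02,
                                   zeta_span = 600, bisections = 60) {
  stopifnot(c > 0, inherits(params, "model_params"))
  R <- params$R
  J <- jacobian_desing(c(1, R, 0), c, params)
  ei <- eigen(J)
  lam <- Re(ei$values)
  V <- Re(ei$vectors)
  o <- order(lam, decreasing = TRUE)
  v1 <- V[, o[1]]  # strong unstable: pure substrate mode
  v2 <- V[, o[2]]  # weak unstable: tangent of the connecting orbit
  if (v1[2] > 0) v1 <- -v1  # orient toward decreasing substrate
  if (v2[1] > 0) v2 <- -v2  # orient toward decreasing cell density
  shot <- function(theta, grid_dz = 0.02) {
    y0 <- c(1, R, 0) + eps * (cos(theta) * v1 + sin(theta) * v2)
    rhs <- function(zeta, y, p) list(tw_rhs_desing(y, c, params))
    stopfun <- function(zeta, y, p)
      c(y[2] - 1e-9, 2.5 * R - y[2], 1.3 - y[1])
    tryCatch(
      deSolve::ode(c(U = y0[1], S = y0[2], W = y0[3]),
                   seq(0, zeta_span, grid_dz), rhs, NULL,
                   method = "lsoda", rtol = 1e-12, atol = 1e-16,
                   rootfunc = stopfun,
                   events = list(root = TRUE, terminalroot = c(1, 2, 3)),
                   maxsteps = 5e5),
      error = function(e) NULL)
  }
  lo <- pi / 2 - 0.8
  hi <- pi / 2 + 0.8
  for (k in seq_len(bisections)) {
    mid <- (lo + hi) / 2
    out <- shot(mid)
    if (is.null(out)) {
      return(list(trajectory = NULL, min_U = NA_real_,
                  closest_approach = NA_real_, physical = NA,
                  negative_U_zeta = NULL,
                  diagnostic = "integration blow-up"))
    }
    if (out[nrow(out), "S"] <= 1e-8) lo <- mid else hi <- mid
  }
  out <- shot((lo + hi) / 2, grid_dz = 0.02)
  dist <- sqrt(out[, "U"]^2 + out[, "S"]^2 + out[, "W"]^2)
  imin <- which.min(dist)
  traj <- data.frame(zeta = out[1:imin, 1], U = out[1:imin, "U"],
                     S = out[1:imin, "S"], W = out[1:imin, "W"])
  minU <- min(traj$U)
  neg <- traj$zeta[traj$U < 0]
  list(trajectory = traj, min_U = minU,
       closest_approach = dist[imin],
       physical = minU >= -1e-6 && min(traj$S) >= -1e-12 &&
         min(traj$W) <= 0,
       negative_U_zeta = if (length(neg)) range(neg) else NULL,
       diagnostic = "ok")
}
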