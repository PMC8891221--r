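#' Initial condition families for the 1D model
#'
#' Two families are supported: a compactly supported Heaviside profile
#' (`u = 1` for `x <= beta`, `u = 0` beyond), which selects the sharp-fronted
#' wave moving at the minimum speed, and an exponentially decaying profile
#' (`u = exp(-a (x - beta))` for `x >= beta`), which selects a smooth-fronted
#' wave whose long-time speed is set by the decay rate through the
#' dispersion relation `c = 1/a` (below the critical decay rate).  The
#' substrate starts at zero in both cases.
#'
#' @param kind `"heaviside"` or `"exponential"`.
#' @param beta length of the initially occupied region (default 10).
#' @param a far-field decay rate (exponential kind only, > 0).
#' @return An object of class `initial_condition1d`.
#' @examples
#' initial_condition("exponential", a = 2)
#' @export
initial_condition <- function(kind = c("heaviside", "exponential"),
                              beta = 10, a = NULL) {
  kind <- match.arg(kind)
  stopifnot(beta > 0)
  if (kind == "exponential") {
    if (is.null(a) || !is.numeric(a) || length(a) != 1L || a <= 0)
      stop("exponential initial condition needs a decay rate a > 0",
           call. = FALSE)
  } else {
    a <- NA_real_
  }
  structure(list(kind = kind, beta = beta, a = a),
            class = "initial_condition1d")
}

#' Evaluate an initial condition on a grid
#'
#' The Heaviside profile is closed on the left: `u = 1` for `x <= beta`.
#' This convention is immaterial to the long-time travelling wave but is
#' fixed for reproducibility.
#'
#' @param ic an [initial_condition()] object.
#' @param grid a [grid1d()] object.
#' @return A [field_state()] at `t = 0`.
#' @export
make_ic <- function(ic, grid) {
  stopifnot(inherits(ic, "initial_condition1d"), inherits(grid, "grid1d"))
  if (ic$beta >= grid$X)
    stop("beta must lie inside the truncated domain (beta < X)",
         call. = FALSE)
  x <- grid$x
  u <- if (ic$kind == "heaviside") {
    as.numeric(x <= ic$beta)
  } else {
    ifelse(x < ic$beta, 1, exp(-ic$a * (x - ic$beta)))
  }
  field_state(0, u, numeric(grid$n))
}

#' Solver settings for the implicit time-stepping scheme
#'
#' Time integration is backward Euler with Picard linearisation of the
#' degenerate flux coefficient and of the logistic factor; the linear
#' substrate equation is updated implicitly inside the same iteration.
#' `picard_tol` is the max-norm convergence tolerance on the iterate update
#' per step.
#'
#' @param dt time step.
#' @param t_end final time.
#' @param picard_tol nonlinear iteration tolerance (default 1e-10).
#' @param max_picard iteration cap per step.
#' @param store_every interval (in time units) between stored snapshots.
#' @param scheme spatial discretisation of the degenerate diffusion term:
#'   `"central"` (default) expands `(s u_x)_x = s u_xx + s_x u_x` with
#'   central differences, `"conservative"` uses the finite-volume form with
#'   arithmetic-mean face coefficients.  Both converge to the same solution
#'   under refinement; the central form has the smaller front-speed error on
#'   coarse grids for sharp fronts.
#' @return An object of class `solver_settings`.
#' @export
solver_settings <- function(dt = 1e-3, t_end = 60, picard_tol = 1e-10,
                            max_picard = 200, store_every = 1,
                            scheme = c("central", "conservative")) {
  stopifnot(dt > 0, t_end > 0, picard_tol > 0, max_picard >= 1,
            store_every >= dt)
  scheme <- match.arg(scheme)
  structure(list(dt = dt, t_end = t_end, picard_tol = picard_tol,
                 max_picard = max_picard, store_every = store_every,
                 scheme = scheme),
            class = "solver_settings")
}

solution1d <- function(grid, params, t, u, s, meta) {
  structure(list(grid = grid, params = params, times = t, u = u, s = s,
                 meta = meta),
            class = "substrate_solution1d")
}

#' @export
print.substrate_solution1d <- function(x, ...) {
  cat(sprintf(paste0("substrate invasion solution: %d nodes on [0, %g], ",
                     "%d snapshots to t = %g (r1 = %g, r2 = %g)\n"),
              x$grid$n, x$grid$X, length(x$times), max(x$times),
              x$params$r1, x$params$r2))
  invisible(x)
}

#' Solve the 1D nondimensional model
#'
#' Integrates `u_t = (s u_x)_x + u(1-u)`, `s_t = r1 u - r2 s` on the
#' truncated domain `[0, X]` with a no-flux condition at `x = 0` and `u = 0`
#' imposed at `x = X` (the substrate equation has no spatial derivatives and
#' needs no boundary condition).  Snapshots of both fields are stored every
#' `store_every` time units, including the initial state.
#'
#' @param params a [model_params()] object.
#' @param ic an [initial_condition()] object, or a [field_state()] to
#'   restart from (its `t` is taken as the start time).
#' @param grid a [grid1d()] object.
#' @param settings a [solver_settings()] object.
#' @return A `substrate_solution1d`: the grid, parameters, stored times,
#'   `n x ntimes` matrices `u` and `s`, and scheme metadata with per-step
#'   Picard iteration counts.
#' @examples
#' sol <- solve_1d(model_params(1, 1), initial_condition("heaviside"),
#'                 grid1d(30, 0.05), solver_settings(dt = 0.01, t_end = 5))
#' @export
solve_1d <- function(params, ic, grid, settings = solver_settings()) {
  stopifnot(inherits(params, "model_params"), inherits(grid, "grid1d"),
            inherits(settings, "solver_settings"))
  t0 <- 0
  if (inherits(ic, "initial_condition1d")) {
    state <- make_ic(ic, grid)
  } else if (inherits(ic, "field_state")) {
    state <- ic
    t0 <- state$t
    if (length(state$u) != grid$n)
      stop("restart state does not match the grid", call. = FALSE)
  } else stop("ic must be an initial_condition1d or a field_state",
              call. = FALSE)
  nsteps <- round(settings$t_end / settings$dt)
  store_steps <- max(1L, round(settings$store_every / settings$dt))
  out <- .solve1d_core(state$u, state$s, grid$dx, settings$dt, nsteps,
                       params$r1, params$r2, settings$picard_tol,
                       settings$max_picard, store_steps,
                       if (settings$scheme == "conservative") 0L else 1L)
  if (out$failed) {
    if (is.finite(out$fail_residual) && out$fail_residual < 0)
      stop(sprintf("positivity violation at step %d (min density %.3g)",
                   out$fail_step, out$fail_residual), call. = FALSE)
    stop(sprintf(paste0("Picard iteration failed to converge at step %d ",
                        "(residual %.3g <= tol %.3g not reached in %d ",
                        "iterations)"),
                 out$fail_step, out$fail_residual, settings$picard_tol,
                 settings$max_picard), call. = FALSE)
  }
  solution1d(grid, params, t0 + out$t, out$u, out$s,
             meta = list(settings = settings,
                         picard_iterations = out$iterations))
}

#' Extract one stored snapshot as a field state
#'
#' @param sol a `substrate_solution1d`.
#' @param t a stored time (matched to the nearest snapshot).
#' @return A [field_state()].
#' @export
snapshot <- function(sol, t) {
  stopifnot(inherits(sol, "substrate_solution1d"))
  i <- which.min(abs(sol$times - t))
  field_state(sol$times[i], sol$u[, i], sol$s[, i])
}

#' Solve the 2D dimensional model on the square pore geometry
#'
#' Integrates the dimensional system on `[0, L_hat]^2` with the cell density
#' held at the carrying capacity `Ku_hat` on all boundaries (cells occupy
#' the scaffold perimeter) and `u = s = 0` in the interior at `t = 0`; the
#' initial discontinuity at the boundary is regularised by the scheme.
#' Backward Euler with Picard linearisation; the inner linear solves use
#' damped Jacobi sweeps, which preserve the 8 discrete symmetries of the
#' square.
#'
#' @param p a [dimensional_params()] object.
#' @param settings a [solver_settings()] object; `dt` and times are in days.
#' @param mesh_n nodes per side (the pore-bridging simulations use 101).
#' @param snapshot_times times (days) at which to store the fields.
#' @return An object of class `substrate_solution2d` with the mesh
#'   coordinates and one `mesh_n x mesh_n` matrix per snapshot for each
#'   field.
#' @export
solve_2d <- function(p, settings = solver_settings(dt = 1e-2, t_end = 14),
                     mesh_n = 101, snapshot_times = c(4, 7, 10, 14)) {
  stopifnot(inherits(p, "dimensional_params"), mesh_n >= 5)
  dx <- p$L_hat / (mesh_n - 1)
  nsteps <- round(settings$t_end / settings$dt)
  store_steps <- as.integer(round(snapshot_times / settings$dt))
  stopifnot(all(store_steps >= 1), all(store_steps <= nsteps))
  out <- .solve2d_core(mesh_n, dx, settings$dt, nsteps,
                       p$D_hat, p$lambda_hat, p$Ku_hat, p$Ks_hat,
                       p$r1_hat, p$r2_hat,
                       settings$picard_tol, settings$max_picard,
                       store_steps)
  if (out$failed)
    stop(sprintf("2D Picard iteration failed to converge at step %d",
                 out$fail_step), call. = FALSE)
  u <- lapply(seq_along(snapshot_times),
              function(k) matrix(out$u[, k], mesh_n, mesh_n))
  s <- lapply(seq_along(snapshot_times),
              function(k) matrix(out$s[, k], mesh_n, mesh_n))
  structure(list(params = p, mesh = seq(0, p$L_hat, length.out = mesh_n),
                 times = snapshot_times, u = u, s = s,
                 meta = list(settings = settings)),
            class = "substrate_solution2d")
}

#' Re-solve a travelling wave on a fine grid around the front
#'
#' Classifying the front geometry requires resolving the profile down to
#' densities of order 1e-3, which for sharp fronts lie within a few
#' hundredths of a space unit of the front.  This helper interpolates the
#' final snapshot of a coarse run onto a fine grid covering a window around
#' the front and continues the integration there, giving near-front
#' resolution without paying the fine-grid cost on the whole domain.  The
#' window's left edge sits well behind the front (where `u` is
#' exponentially close to 1, so the no-flux condition is accurate) and its
#' right edge well ahead of it.
#'
#' @param sol a coarse `substrate_solution1d` that has reached a travelling
#'   wave.
#' @param behind,ahead window extent behind/ahead of the front (level 0.5).
#' @param dx_fine fine spacing (default 1e-4).
#' @param t_extra additional integration time on the fine grid.
#' @param settings solver settings for the fine run.
#' @return A `substrate_solution1d` on the window grid (coordinates keep
#'   the original frame).
#' @export
refine_front_window <- function(sol, behind = 10, ahead = 15,
                                dx_fine = 1e-4, t_extra = 2,
                                settings = NULL) {
  stopifnot(inherits(sol, "substrate_solution1d"))
  nlast <- length(sol$times)
  st <- snapshot(sol, sol$times[nlast])
  xf <- front_position(st, sol$grid, level = 0.5)
  # bounds in the solution's own (possibly window-offset) coordinates
  x0 <- max(sol$grid$x[1], xf - behind)
  x1 <- min(sol$grid$x[sol$grid$n], xf + ahead)
  nwin <- floor((x1 - x0) / dx_fine) + 1L
  xw <- x0 + dx_fine * (0:(nwin - 1L))
  u0 <- approx(sol$grid$x, st$u, xw, rule = 2)$y
  s0 <- approx(sol$grid$x, st$s, xw, rule = 2)$y
  if (is.null(settings))
    settings <- solver_settings(dt = 1e-3, t_end = t_extra,
                                store_every = max(1e-3, t_extra / 2))
  wgrid <- structure(list(X = xw[nwin] - x0, dx = dx_fine, n = nwin,
                          x = xw - x0), class = "grid1d")
  fine <- solve_1d(sol$params, field_state(st$t, u0, s0), wgrid, settings)
  fine$grid$x <- fine$grid$x + x0
  fine$meta$window <- c(x0, xw[nwin])
  fine
}
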