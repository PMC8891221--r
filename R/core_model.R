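#' substratewaves: travelling waves in substrate-mediated tissue growth
#'
#' Simulation and travelling-wave analysis for a minimal continuum model of
#' cell invasion in which the diffusive flux of cells is proportional to the
#' density of a substrate that the cells themselves deposit.  The cell
#' density \eqn{u(x,t)} and substrate density \eqn{s(x,t)} obey
#' \deqn{u_t = (s u_x)_x + u(1-u), \qquad s_t = r_1 u - r_2 s,}
#' a degenerate reaction-diffusion system supporting both sharp-fronted
#' travelling waves (from compactly supported initial data, moving at the
#' minimum speed \eqn{c_{min}}) and smooth-fronted waves (from exponentially
#' decaying initial data, moving at \eqn{c = 1/a} where \eqn{a} is the decay
#' rate).  The package provides implicit finite-difference solvers in one
#' and two dimensions, front tracking and wave-speed estimation, the
#' desingularised travelling-wave phase space with its slow-manifold
#' reduction and sharp/smooth front classifier, and closed-form and
#' perturbation reference solutions.
#'
#' @useDynLib substratewaves, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats coef integrate lm median approx
#' @importFrom utils modifyList read.table write.table
#' @keywords internal
"_PACKAGE"

#' Dimensional model parameters
#'
#' Container for the dimensional parameters of the substrate-mediated
#' invasion model in the micrometre/day unit system of the pore-bridging
#' experiments.
#'
#' @param D_hat cell diffusivity (um^2/day).
#' @param lambda_hat cell proliferation rate (1/day).
#' @param Ku_hat cell carrying capacity density (cells/um^2).
#' @param Ks_hat typical maximum substrate density (mol/um^2).
#' @param r1_hat substrate production rate (mol/(cells day)).
#' @param r2_hat substrate decay rate (1/day).
#' @param L_hat side length of the square pore domain (um).
#'
#' @return An object of class `dimensional_params`.
#' @examples
#' dimensional_params(D_hat = 300, lambda_hat = 0.6)
#' @export
dimensional_params <- function(D_hat = 300, lambda_hat = 0.6, Ku_hat = 1,
                               Ks_hat = 1, r1_hat = 1, r2_hat = 1,
                               L_hat = 300) {
  p <- list(D_hat = D_hat, lambda_hat = lambda_hat, Ku_hat = Ku_hat,
            Ks_hat = Ks_hat, r1_hat = r1_hat, r2_hat = r2_hat, L_hat = L_hat)
  for (nm in names(p)) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      stop("dimensional parameter '", nm, "' must be a positive scalar",
           call. = FALSE)
  }
  structure(p, class = "dimensional_params")
}

#' Nondimensional model parameters
#'
#' The dimensionless model has two free parameters: the substrate production
#' rate `r1` and decay rate `r2`.  The ratio `R = r1/r2` is stored alongside
#' them because it sets the substrate level behind the wave (`s -> R`) and
#' indexes the Porous-Fisher limit, where the minimum wave speed approaches
#' `sqrt(R/2)`.
#'
#' @param r1 dimensionless substrate production rate (> 0).
#' @param r2 dimensionless substrate decay rate (> 0).
#'
#' @return An object of class `model_params` with fields `r1`, `r2`, `R`.
#' @examples
#' model_params(1, 2)$R  # 0.5
#' @export
model_params <- function(r1, r2) {
  for (nm in c("r1", "r2")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      stop("'", nm, "' must be a positive scalar", call. = FALSE)
  }
  structure(list(r1 = r1, r2 = r2, R = r1 / r2), class = "model_params")
}

#' @export
print.model_params <- function(x, ...) {
  cat(sprintf("substrate model parameters: r1 = %g, r2 = %g (R = %g)\n",
              x$r1, x$r2, x$R))
  invisible(x)
}

#' Substrate production/decay ratio
#'
#' @param params a [model_params()] object.
#' @return The ratio `R = r1/r2`.
#' @export
substrate_ratio <- function(params) {
  stopifnot(inherits(params, "model_params"))
  params$R
}

#' Nondimensionalise the dimensional model
#'
#' Applies the scalings `u = u_hat/Ku_hat`, `s = s_hat/Ks_hat`,
#' `x = x_hat * sqrt(lambda_hat/D_hat)`, `t = lambda_hat * t_hat`, giving the
#' two-parameter dimensionless model with
#' `r1 = r1_hat * Ku_hat / (lambda_hat * Ks_hat)` and
#' `r2 = r2_hat / lambda_hat`.
#'
#' @param p a [dimensional_params()] object.
#' @return A list with `params` (a [model_params()] object) and `scales`,
#'   the multiplicative factors taking dimensional to dimensionless
#'   variables (`u`, `s`, `x`, `t`) plus the originals needed to invert the
#'   map with [redimensionalise()].
#' @examples
#' nondimensionalise(dimensional_params())$params  # r1 = r2 = 5/3
#' @export
nondimensionalise <- function(p) {
  stopifnot(inherits(p, "dimensional_params"))
  scales <- list(u = 1 / p$Ku_hat,
                 s = 1 / p$Ks_hat,
                 x = sqrt(p$lambda_hat / p$D_hat),
                 t = p$lambda_hat,
                 L_hat = p$L_hat)
  list(params = model_params(p$r1_hat * p$Ku_hat / (p$lambda_hat * p$Ks_hat),
                             p$r2_hat / p$lambda_hat),
       scales = scales)
}

#' Recover dimensional parameters from the nondimensional form
#'
#' Inverse of [nondimensionalise()]; exact up to floating-point round-off.
#'
#' @param nd a list as returned by [nondimensionalise()].
#' @return A [dimensional_params()] object.
#' @export
redimensionalise <- function(nd) {
  sc <- nd$scales
  lambda_hat <- sc$t
  dimensional_params(D_hat = lambda_hat / sc$x^2,
                     lambda_hat = lambda_hat,
                     Ku_hat = 1 / sc$u,
                     Ks_hat = 1 / sc$s,
                     r1_hat = nd$params$r1 * lambda_hat * sc$u / sc$s,
                     r2_hat = nd$params$r2 * lambda_hat,
                     L_hat = sc$L_hat)
}

#' Uniform 1D spatial grid
#'
#' Node-centred uniform grid on `[0, X]` with both endpoints included, so
#' the no-flux condition at `x = 0` and the far-field truncation at `x = X`
#' are applied at nodes.
#'
#' @param X domain length (dimensionless).
#' @param dx requested node spacing; the grid uses `n = round(X/dx) + 1`
#'   nodes, so `X` must be an integer multiple of `dx`.
#' @return An object of class `grid1d` with fields `X`, `dx`, `n`, `x`.
#' @examples
#' grid1d(20, 0.1)$n  # 201
#' @export
grid1d <- function(X, dx) {
  stopifnot(X > 0, dx > 0, dx < X)
  n <- round(X / dx) + 1L
  if (abs((n - 1L) * dx - X) > 1e-9 * X)
    stop("X must be an integer multiple of dx", call. = FALSE)
  structure(list(X = X, dx = dx, n = n, x = seq(0, X, length.out = n)),
            class = "grid1d")
}

#' Field state at a single time
#'
#' @param t time.
#' @param u cell density per node (dimensionless, in `[0, 1]` up to
#'   round-off undershoot).
#' @param s substrate density per node (dimensionless, non-negative).
#' @return An object of class `field_state`.
#' @export
field_state <- function(t, u, s) {
  if (length(u) != length(s))
    stop("u and s must have equal length", call. = FALSE)
  if (any(u < -1e-9) || any(s < -1e-9))
    stop("negative density beyond round-off tolerance", call. = FALSE)
  if (any(u > 1 + 1e-6))
    stop("cell density exceeds carrying capacity beyond tolerance",
         call. = FALSE)
  structure(list(t = t, u = u, s = s), class = "field_state")
}

#' Write model parameters to a key-value config file
#'
#' Parameters are stored one per line as `key: value` (YAML), using the
#' model's own symbol names (`r1`, `r2`, `D_hat`, ...).
#'
#' @param params a [model_params()] or [dimensional_params()] object.
#' @param path file to write.
#' @return `path`, invisibly.
#' @export
write_params <- function(params, path) {
  stopifnot(inherits(params, c("model_params", "dimensional_params")))
  kv <- unclass(params)
  kv$.class <- class(params)[1]
  yaml::write_yaml(kv, path)
  invisible(path)
}

#' Read model parameters from a key-value config file
#'
#' @param path file written by [write_params()].
#' @return A [model_params()] or [dimensional_params()] object.
#' @export
read_params <- function(path) {
  kv <- yaml::read_yaml(path)
  cls <- kv$.class
  kv$.class <- NULL
  if (identical(cls, "model_params")) model_params(kv$r1, kv$r2)
  else do.call(dimensional_params, kv[names(kv) != "R"])
}
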