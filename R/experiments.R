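#' Write a 1D solution as delimited text snapshots
#'
#' One file per stored time with columns `x`, `u`, `s`, plus a YAML
#' manifest recording every parameter and scheme setting needed to
#' regenerate the run.
#'
#' @param sol a `substrate_solution1d`.
#' @param dir output directory (created if needed).
#' @return The manifest path, invisibly.
#' @export
write_solution <- function(sol, dir) {
  stopifnot(inherits(sol, "substrate_solution1d"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(length(sol$times))
  for (i in seq_along(sol$times)) {
    files[i] <- file.path(dir, sprintf("snapshot_t%09.3f.tsv", sol$times[i]))
    df <- data.frame(x = sol$grid$x, u = sol$u[, i], s = sol$s[, i])
    write.table(format(df, digits = 12, scientific = FALSE, trim = TRUE),
                files[i], sep = "\t", quote = FALSE, row.names = FALSE)
  }
  st <- sol$meta$settings
  manifest <- list(r1 = sol$params$r1, r2 = sol$params$r2,
                   X = sol$grid$X, dx = sol$grid$dx, n = sol$grid$n,
                   dt = st$dt, t_end = st$t_end,
                   picard_tol = st$picard_tol, scheme = st$scheme,
                   times = as.numeric(sol$times),
                   mean_picard_iterations =
                     mean(sol$meta$picard_iterations),
                   files = basename(files))
  mpath <- file.path(dir, "manifest.yml")
  yaml::write_yaml(manifest, mpath)
  invisible(mpath)
}

#' Read a 1D solution written by [write_solution()]
#'
#' @param dir directory holding the snapshots and `manifest.yml`.
#' @return A `substrate_solution1d`.
#' @export
read_solution <- function(dir) {
  m <- yaml::read_yaml(file.path(dir, "manifest.yml"))
  g <- grid1d(m$X, m$dx)
  u <- matrix(NA_real_, g$n, length(m$files))
  s <- matrix(NA_real_, g$n, length(m$files))
  for (i in seq_along(m$files)) {
    df <- read.table(file.path(dir, m$files[i]), header = TRUE)
    u[, i] <- df$u; s[, i] <- df$s
  }
  solution1d(g, model_params(m$r1, m$r2), as.numeric(m$times), u, s,
             meta = list(settings = solver_settings(
               dt = m$dt, t_end = m$t_end, picard_tol = m$picard_tol,
               scheme = m$scheme)))
}

experiment_ids <- c("wave-gallery", "cmin-map", "dispersion-sweep",
                    "decay-transition", "front-classify",
                    "porous-fisher-limit", "perturbation-match", "pore-2d")

#' Run a named experiment protocol
#'
#' Orchestrates the simulate/measure/analyse pipelines behind the standard
#' study protocols, writing tables, profiles and a manifest to `out_dir`.
#' Available protocols:
#' \describe{
#'   \item{wave-gallery}{sharp or smooth single run at chosen `(r1, r2)`;
#'     writes snapshot profiles and a wave-speed table.}
#'   \item{cmin-map}{`c_min` table over an `(r1, r2)` grid.}
#'   \item{dispersion-sweep}{wave speed against initial decay rate.}
#'   \item{decay-transition}{single exponential-decay run: solution,
#'     wave-speed table and phase-space orbit.}
#'   \item{front-classify}{orbit extraction plus slow-manifold
#'     classification for a given run.}
#'   \item{porous-fisher-limit}{sharp run compared against the
#'     Porous-Fisher closed form on a shared `z` grid.}
#'   \item{perturbation-match}{smooth run compared against the large-speed
#'     perturbation profiles.}
#'   \item{pore-2d}{two-dimensional pore-bridging simulation; writes one
#'     matrix file per field and snapshot.}
#' }
#' The model is deterministic; `seed` is recorded in the manifest for
#' provenance only.
#'
#' @param id experiment identifier (see above).
#' @param out_dir output directory.
#' @param overrides named list of parameter overrides (`r1`, `r2`, `a`,
#'   `beta`, `X`, `dx`, `dt`, `t_end`, ...).
#' @param seed recorded in the manifest (unused by the computation).
#' @return A manifest (list) of output files, invisibly; also written as
#'   `experiment.yml` in `out_dir`.
#' @export
run_experiment <- function(id, out_dir, overrides = list(), seed = 1L) {
  if (!id %in% experiment_ids)
    stop("unknown experiment id '", id, "'; available: ",
         paste(experiment_ids, collapse = ", "), call. = FALSE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  ov <- function(name, default) {
    if (!is.null(overrides[[name]])) overrides[[name]] else default
  }
  p <- model_params(ov("r1", 1), ov("r2", 1))
  files <- character(0)
  add_table <- function(df, name) {
    path <- file.path(out_dir, name)
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    files <<- c(files, path)
    path
  }
  single_run <- c("wave-gallery", "decay-transition", "front-classify",
                  "porous-fisher-limit", "perturbation-match")
  if (id %in% single_run) {
    a <- ov("a", if (id == "perturbation-match") 0.25
                 else if (id == "wave-gallery") NA else 1)
    sharp <- id == "porous-fisher-limit" ||
      (id %in% c("wave-gallery", "front-classify")) && is.na(a)
    ic <- if (sharp) initial_condition("heaviside", beta = ov("beta", 10))
          else initial_condition("exponential", beta = ov("beta", 10),
                                 a = if (is.na(a)) 1 else a)
    g <- grid1d(ov("X", if (sharp) 50 else 150), ov("dx", 0.01))
    st <- solver_settings(dt = ov("dt", 1e-3), t_end = ov("t_end", 60))
    sol <- solve_1d(p, ic, g, st)
    sdir <- file.path(out_dir, "solution")
    write_solution(sol, sdir)
    files <- c(files, file.path(sdir, "manifest.yml"))
    est <- suppressWarnings(estimate_wave_speed(sol))
    add_table(data.frame(r1 = p$r1, r2 = p$r2, c = est$c,
                         level = est$threshold, converged = est$converged),
              "wavespeed.tsv")
    if (id %in% c("decay-transition", "front-classify")) {
      orbit <- extract_orbit(sol, est$c, check = FALSE)
      add_table(orbit, "orbit.tsv")
    }
    if (id == "front-classify") {
      fine <- refine_front_window(sol)
      orbit <- extract_orbit(fine, est$c, check = FALSE)
      cls <- classify_front(orbit, slow_manifold(est$c, p))
      add_table(data.frame(front = cls$front,
                           median_relative_deviation =
                             cls$median_relative_deviation,
                           n_tail = cls$n_tail),
                "classification.tsv")
    }
    if (id == "porous-fisher-limit") {
      zg <- seq(-15, 5, by = g$dx)
      ref <- porous_fisher_wave(zg, p$R)
      orbit <- extract_orbit(sol, est$c, check = FALSE)
      add_table(data.frame(z = zg,
                           U_ref = ref$U, S_ref = ref$S,
                           U_num = approx(orbit$z, orbit$U, zg, rule = 2)$y,
                           S_num = approx(orbit$z, orbit$S, zg, rule = 2)$y),
                "porous_fisher_comparison.tsv")
    }
    if (id == "perturbation-match") {
      cth <- 1 / ic$a
      zh <- seq(-8, 8, by = 0.01)
      pp <- perturbation_solution(cth, p, zh)
      add_table(pp, "perturbation.tsv")
    }
  } else if (id == "cmin-map") {
    tab <- cmin_heatmap(ov("r1_grid", c(0.25, 0.5, 1, 2, 4, 8)),
                        ov("r2_grid", c(0.25, 0.5, 1, 2, 4, 8)),
                        grid = grid1d(ov("X", 60), ov("dx", 0.01)),
                        settings = solver_settings(dt = ov("dt", 5e-3),
                                                   t_end = ov("t_end", 60)))
    add_table(tab, "cmin_table.tsv")
  } else if (id == "dispersion-sweep") {
    tab <- dispersion_sweep(ov("a_grid", c(0.5, 1, 2, 10 / 3, 5)), p,
                            grid = grid1d(ov("X", 150), ov("dx", 0.01)),
                            settings = solver_settings(dt = ov("dt", 1e-3),
                                                       t_end = ov("t_end",
                                                                  60)))
    add_table(tab, "dispersion.tsv")
  } else if (id == "pore-2d") {
    dp <- dimensional_params()
    snaps <- ov("snapshots", c(4, 7, 10, 14))
    sol2 <- solve_2d(dp, solver_settings(dt = ov("dt", 1e-2),
                                         t_end = max(snaps)),
                     mesh_n = ov("mesh", 101), snapshot_times = snaps)
    for (k in seq_along(snaps)) {
      for (f in c("u", "s")) {
        path <- file.path(out_dir, sprintf("%s_t%05.1f.tsv", f, snaps[k]))
        write.table(sol2[[f]][[k]], path, sep = "\t", quote = FALSE,
                    row.names = FALSE, col.names = FALSE)
        files <- c(files, path)
      }
    }
  }
  manifest <- list(experiment = id, seed = seed,
                   overrides = overrides,
                   r1 = p$r1, r2 = p$r2,
                   package_version =
                     as.character(utils::packageVersion("substratewaves")),
                   files = basename(files))
  yaml::write_yaml(manifest, file.path(out_dir, "experiment.yml"))
  invisible(manifest)
}

#' Generate synthetic fixtures with known ground truth
#'
#' Three kinds of analytically controlled inputs used to validate the
#' measurement and classification machinery independently of the PDE
#' solver:
#' \describe{
#'   \item{translating-profile}{a fixed shape translating rigidly at a
#'     prescribed speed, packaged as a `substrate_solution1d`; the speed
#'     estimator must recover the speed to near machine precision.}
#'   \item{on-manifold-orbit}{a trajectory integrated on the slow-manifold
#'     flow itself, packaged as a `travelling_wave_profile`; the front
#'     classifier must call it smooth.}
#'   \item{uniform-state}{a spatially uniform run whose exact solution is
#'     the logistic ODE for `u` and the driven linear ODE for `s`.}
#' }
#'
#' @param kind fixture kind (see above).
#' @param speed translation speed (translating-profile).
#' @param c,params wave speed and [model_params()] (on-manifold-orbit,
#'   uniform-state closed forms).
#' @param u0 initial uniform density (uniform-state).
#' @param grid,times discretisation of the fixture.
#' @return The fixture object, with the ground truth attached as
#'   attribute `"truth"`.
#' @export
generate_fixture <- function(kind = c("translating-profile",
                                      "on-manifold-orbit",
                                      "uniform-state"),
                             speed = 0.7, c = 1, params = model_params(1, 1),
                             u0 = 0.1, grid = grid1d(100, 0.05),
                             times = 0:40) {
  kind <- match.arg(kind)
  if (kind == "translating-profile") {
    shape <- function(x) 1 / (1 + exp(2 * (x - 20)))
    u <- vapply(times, function(t) shape(grid$x - speed * t),
                numeric(grid$n))
    s <- u * params$R
    sol <- solution1d(grid, params, times, u, s,
                      meta = list(settings = NULL, fixture = kind))
    attr(sol, "truth") <- list(speed = speed)
    sol
  } else if (kind == "on-manifold-orbit") {
    # near the origin the slow flow decays algebraically in zeta
    # (dU/dzeta ~ -k U^2), so reaching order-one densities backward from a
    # 1e-4 start needs a zeta span of order 1e4 * c
    start <- c(1e-4 * (params$r2 + 1) / params$r1, 1e-4)
    tr <- integrate_slow_flow(start, c, params, zeta_end = -1.5e4 * c,
                              n = 8000)
    orbit <- data.frame(z = rev(tr$z), U = rev(tr$U), S = rev(tr$S),
                        W = rev(tr$W))
    orbit <- orbit[orbit$U < 0.999 & is.finite(orbit$W), ]
    attr(orbit, "c") <- c
    class(orbit) <- c("travelling_wave_profile", class(orbit))
    attr(orbit, "truth") <- list(front = "smooth")
    orbit
  } else {
    r1 <- params$r1; r2 <- params$r2
    u_exact <- function(t) u0 / (u0 + (1 - u0) * exp(-t))
    s_exact <- function(t) {
      vapply(t, function(ti) {
        if (ti == 0) return(0)
        integrate(function(y) r1 * u_exact(y) * exp(-r2 * (ti - y)),
                  0, ti, rel.tol = 1e-12)$value
      }, numeric(1))
    }
    u <- t(matrix(u_exact(times), length(times), grid$n))
    s <- t(matrix(s_exact(times), length(times), grid$n))
    sol <- solution1d(grid, params, times, u, s,
                      meta = list(settings = NULL, fixture = kind))
    attr(sol, "truth") <- list(u = u_exact, s = s_exact)
    sol
  }
}
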