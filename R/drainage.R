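#' Autocorrelated fractal noise surface
#'
#' Generates a spatially autocorrelated random field by spectral synthesis:
#' white Gaussian noise is filtered in the Fourier domain with a power-law
#' amplitude spectrum `|k|^-roughness`, then rescaled to mean zero and a
#' sample standard deviation of exactly `sd`. This provides the small
#' random bed irregularities of the drainage plane.
#'
#' @param nx Grid side length in cells (a power of two is recommended but
#'   not required).
#' @param sd Target sample standard deviation (cm); `0` returns a zero grid.
#' @param roughness Spectral amplitude decay exponent; larger values give
#'   smoother, longer-range structure. Default 1.5.
#' @param seed Integer seed; the field is fully reproducible.
#' @return An `nx` x `nx` numeric matrix.
#' @examples
#' z <- fractal_surface(64, sd = 2.5, seed = 42)
#' sd(as.vector(z)) # exactly 2.5
#' @export
fractal_surface <- function(nx, sd, roughness = 1.5, seed = 1) {
  if (sd < 0) abort_tm("`sd` must be non-negative.", "invalid_argument")
  if (nx < 2) abort_tm("`nx` must be at least 2.", "invalid_argument")
  if (sd == 0) return(matrix(0, nx, nx))
  old <- .Random.seed_exists()
  set.seed(seed)
  white <- matrix(rnorm(nx * nx), nx, nx)
  .restore_seed(old)
  k1 <- c(0:(floor(nx / 2)), -((ceiling(nx / 2) - 1):1)) / nx
  kk <- sqrt(outer(k1^2, k1^2, `+`))
  filt <- ifelse(kk > 0, kk^(-roughness), 0)
  f <- stats::fft(white) * filt
  z <- Re(stats::fft(f, inverse = TRUE)) / (nx * nx)
  z <- z - mean(z)
  s <- stats::sd(as.vector(z))
  if (s > 0) z <- z * (sd / s)
  z
}

.Random.seed_exists <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  invisible(NULL)
}

#' Construct an inclined drainage plane
#'
#' The bed surface is a linear ramp declining from the top row to the
#' bottom row (drop per row `100 * cell_size * tan(inclination)` cm) plus a
#' seeded [fractal_surface()] of standard deviation `sigma_s`. The
#' down-slope boundary wraps with an elevation offset equal to the ramp
#' drop over the full domain plus one cell, so a water parcel leaving the
#' bottom re-enters at the top on a continuous gradient.
#'
#' @param nx Side length (cells), at least 16.
#' @param inclination Plane inclination in degrees. Sweeps in this package
#'   stay in `[0, 1.5]` degrees; steeper planes are allowed with a warning.
#' @param sigma_s SD of the autocorrelated bed noise (cm); default 2.5.
#' @param seed Integer seed for the noise field.
#' @param cell_size Cell edge length (m), default 1.
#' @param roughness Passed to [fractal_surface()].
#' @return A `drainage_plane` object.
#' @export
make_plane <- function(nx, inclination, sigma_s = 2.5, seed = 1,
                       cell_size = 1, roughness = 1.5) {
  if (nx < 16) abort_tm("`nx` must be at least 16.", "invalid_argument")
  if (sigma_s < 0) abort_tm("`sigma_s` must be >= 0.", "invalid_argument")
  if (inclination < 0) {
    abort_tm("`inclination` must be >= 0.", "invalid_argument")
  }
  if (inclination > 1.5) {
    warning("Inclination above 1.5 degrees is outside the studied range.")
  }
  drop_per_row <- 100 * cell_size * tan(inclination * pi / 180) # cm
  ramp <- matrix(rep(drop_per_row * (nx - seq_len(nx)), nx), nx, nx)
  noise <- fractal_surface(nx, sigma_s, roughness = roughness, seed = seed)
  structure(list(
    S = ramp + noise,
    ramp = ramp,
    noise = noise,
    S_max = drop_per_row * (nx - 1),
    offset = drop_per_row * nx,
    nx = as.integer(nx),
    cell_size = cell_size,
    inclination = inclination,
    sigma_s = sigma_s,
    roughness = roughness,
    seed = seed
  ), class = "drainage_plane")
}

#' @export
print.drainage_plane <- function(x, ...) {
  cat(sprintf(paste0("<drainage_plane %d x %d> inclination: %g deg,",
                     " noise SD: %g cm, seed: %d\n"),
              x$nx, x$nx, x$inclination, x$sigma_s, x$seed))
  invisible(x)
}

#' Initialise a drainage state
#'
#' @param plane A [make_plane()] plane.
#' @param W_i Initial uniform water depth (cm). Defaults to 10 percent of
#'   the plane's bed-noise standard deviation.
#' @return A `drainage_state` with fields `W`, `t`, `steps`.
#' @export
drainage_state <- function(plane, W_i = NULL) {
  if (is.null(W_i)) W_i <- 0.1 * plane$sigma_s
  if (W_i < 0) abort_tm("`W_i` must be >= 0.", "invalid_argument")
  structure(list(W = matrix(W_i, plane$nx, plane$nx), t = 0, steps = 0L,
                 W_i = W_i),
            class = "drainage_state")
}

admissible_dt <- function(state, K = 1, cfl = 0.2) {
  wmax <- max(state$W)
  if (wmax <= 0) Inf else cfl / (4 * K * wmax)
}

#' Advance the drainage simulation by explicit steps
#'
#' One (or more) conservative explicit update(s) of the nonlinear diffusion
#' `dW/dt = div(K W grad(W + S))` with donor-cell face depths, flux
#' limiting that keeps `W >= 0`, the elevation-offset down-slope wrap and
#' plain periodic lateral boundaries.
#'
#' @param state A [drainage_state()].
#' @param plane The matching [make_plane()] plane.
#' @param dt Time step; must satisfy the stability bound
#'   `dt <= 0.2 * dx^2 / (4 K max(W))`.
#' @param n_steps Number of steps to take (default 1).
#' @param K Hydraulic conductivity multiplier (dimensionless, default 1).
#' @return The updated `drainage_state`.
#' @export
drainage_step <- function(state, plane, dt, n_steps = 1L, K = 1) {
  adm <- admissible_dt(state, K)
  if (dt > adm * (1 + 1e-12)) {
    abort_tm(sprintf("Time step %g violates the stability bound; use dt <= %g.",
                     dt, adm), "stability")
  }
  res <- drainage_core(plane$S, plane$offset, state$W, K, 0.2, 0,
                       as.integer(n_steps), dt, as.integer(n_steps), FALSE)
  structure(list(W = res$W, t = state$t + res$t_total,
                 steps = state$steps + res$steps, W_i = state$W_i),
            class = "drainage_state")
}

#' Simulate drainage to convergence
#'
#' Runs the inclined-plane drainage model from a uniform initial water
#' layer until the mean absolute per-cell water-level change (per unit
#' model time by default, see `tol_mode`) falls to `tol_fraction` of the
#' initial depth (default 0.3 percent), or
#' `max_steps` is reached. The per-cell time-weighted (trapezoidal) average
#' water depth is accumulated over the whole run, including the initial
#' transient, and the flow concentration is the sample SD of that
#' time-averaged field across the grid.
#'
#' @param plane A [make_plane()] plane.
#' @param W_i_fraction Initial depth as a fraction of the bed-noise SD
#'   (default 0.1).
#' @param W_i Explicit initial depth (cm); overrides `W_i_fraction`.
#' @param tol_fraction Convergence tolerance as a fraction of the initial
#'   depth (default 0.003).
#' @param max_steps Step budget (default 200000).
#' @param K Conductivity multiplier (default 1).
#' @param cfl Safety factor of the stability bound (default 0.2).
#' @param tol_mode Whether the stop rule reads the mean absolute change
#'   per unit model time (`"per_time"`, the default: the statistic does not
#'   depend on the adaptive step size, so refining the step cannot trigger
#'   a premature stop) or per explicit step (`"per_step"`).
#' @return A `drainage_result` with the final and time-averaged water
#'   fields (`grid_raster`s), `flow_concentration`, `converged`, `steps`,
#'   `t_total` and the mass-balance residual.
#' @export
simulate_drainage <- function(plane, W_i_fraction = 0.1, W_i = NULL,
                              tol_fraction = 0.003, max_steps = 200000L,
                              K = 1, cfl = 0.2,
                              tol_mode = c("per_time", "per_step")) {
  tol_mode <- match.arg(tol_mode)
  if (is.null(W_i)) W_i <- W_i_fraction * plane$sigma_s
  W0 <- matrix(W_i, plane$nx, plane$nx)
  res <- drainage_core(plane$S, plane$offset, W0, K, cfl,
                       tol_fraction * W_i, as.integer(max_steps), 0, 0L,
                       tol_mode == "per_time")
  w_avg <- grid_raster(res$W_avg, cell_size = plane$cell_size)
  structure(list(
    W_final = grid_raster(res$W, cell_size = plane$cell_size),
    W_avg = w_avg,
    flow_concentration = stats::sd(as.vector(res$W_avg)),
    converged = isTRUE(res$converged),
    steps = res$steps,
    t_total = res$t_total,
    mass_rel_err = res$max_mass_rel_err,
    W_i = W_i,
    plane = plane
  ), class = "drainage_result")
}

#' @export
print.drainage_result <- function(x, ...) {
  cat(sprintf(paste0("<drainage_result> flow concentration: %.5g cm,",
                     " steps: %d, converged: %s\n"),
              x$flow_concentration, x$steps, x$converged))
  cat(sprintf("  mass-balance residual: %.3g (relative)\n", x$mass_rel_err))
  invisible(x)
}

#' @export
glance.drainage_result <- function(x, ...) {
  tibble::tibble(
    flow_concentration = x$flow_concentration,
    converged = x$converged,
    steps = x$steps,
    t_total = x$t_total,
    mass_rel_err = x$mass_rel_err,
    inclination_deg = x$plane$inclination,
    sigma_s = x$plane$sigma_s,
    nx = x$plane$nx
  )
}

#' Flow concentration across a range of plane inclinations
#'
#' Repeats [simulate_drainage()] over a set of inclinations with `n_reps`
#' independently seeded noise surfaces per inclination and summarises the
#' flow concentration per inclination, reproducing the decline from pooled
#' or channelised drainage on near-horizontal beds to uniform sheet flow on
#' steeper ones.
#'
#' @param inclinations Inclinations in degrees.
#' @param n_reps Replicates per inclination (>= 2).
#' @param nx Grid side length (cells).
#' @param sigma_s Bed-noise SD (cm), default 2.5.
#' @param seed Root seed; each replicate derives its own surface seed.
#' @param ... Passed to [simulate_drainage()].
#' @return A tibble with columns `inclination_deg`, `mean_concentration`,
#'   `se`, `n`, `n_converged`; the per-replicate values are in the
#'   `replicates` attribute.
#' @export
slope_sweep <- function(inclinations, n_reps = 10, nx = 128, sigma_s = 2.5,
                        seed = 1, ...) {
  if (n_reps < 2) abort_tm("`n_reps` must be >= 2.", "invalid_argument")
  reps <- purrr::map_dfr(seq_along(inclinations), function(i) {
    purrr::map_dfr(seq_len(n_reps), function(r) {
      s <- derive_seed(seed, sprintf("sweep-%d-%d", i, r))
      pl <- make_plane(nx, inclinations[i], sigma_s = sigma_s, seed = s)
      res <- simulate_drainage(pl, ...)
      tibble::tibble(inclination_deg = inclinations[i], rep = r,
                     concentration = res$flow_concentration,
                     converged = res$converged, steps = res$steps)
    })
  })
  out <- reps |>
    dplyr::group_by(.data$inclination_deg) |>
    dplyr::summarise(
      mean_concentration = mean(.data$concentration),
      se = stats::sd(.data$concentration) / sqrt(dplyr::n()),
      n = dplyr::n(),
      n_converged = sum(.data$converged),
      .groups = "drop"
    )
  attr(out, "replicates") <- reps
  class(out) <- c("slope_sweep", class(out))
  out
}

#' @export
autoplot.slope_sweep <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$inclination_deg,
                               y = .data$mean_concentration)) +
    ggplot2::geom_pointrange(
      ggplot2::aes(ymin = .data$mean_concentration - 2 * .data$se,
                   ymax = .data$mean_concentration + 2 * .data$se)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "plane inclination (degrees)",
                  y = "flow concentration (SD of time-averaged depth, cm)")
}
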