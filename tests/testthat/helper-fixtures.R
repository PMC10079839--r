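# Shared fixtures, built once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, builder) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, builder(), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

small_synth_config <- function(seed = 42, ...) {
  synth_config(rows = 160, cols = 160, cell_size = 1, years = 2004:2008,
               seed = seed, ...)
}

small_scene <- function() {
  cached("small_scene", function() synth_estuary(small_synth_config()))
}

default_scene <- function() {
  cached("default_scene", function() synth_estuary(synth_config(seed = 7)))
}

# Independent brute-force high-tide oracle: repeatedly take the highest
# remaining strict local maximum and discard every other candidate within
# the separation window. O(n^2) but obviously correct.
oracle_high_tides <- function(time_h, level, min_sep = 10) {
  n <- length(level)
  cand <- c()
  for (i in 2:(n - 1)) {
    if (level[i] > level[i - 1] && level[i] > level[i + 1]) {
      cand <- c(cand, i)
    }
  }
  kept <- c()
  remaining <- cand
  while (length(remaining) > 0) {
    best <- remaining[which.max(level[remaining] -
                                  1e-12 * time_h[remaining])]
    kept <- c(kept, best)
    remaining <- remaining[abs(time_h[remaining] - time_h[best]) >= min_sep]
  }
  sort(kept)
}

# Brute-force skipped-percent recount at given elevations.
oracle_skipped <- function(peak_levels, elevations) {
  vapply(elevations, function(e) {
    inundated <- 0
    for (p in peak_levels) if (p > e) inundated <- inundated + 1
    (1 - inundated / length(peak_levels)) * 100
  }, numeric(1))
}

# Central-difference slope oracle (degrees) for smooth surfaces.
oracle_slope_deg <- function(z_cm, cell_m) {
  nr <- nrow(z_cm); nc <- ncol(z_cm)
  z <- z_cm / 100
  out <- matrix(NA_real_, nr, nc)
  for (r in 2:(nr - 1)) {
    for (cc in 2:(nc - 1)) {
      dzdx <- (z[r, cc + 1] - z[r, cc - 1]) / (2 * cell_m)
      dzdy <- (z[r + 1, cc] - z[r - 1, cc]) / (2 * cell_m)
      out[r, cc] <- atan(sqrt(dzdx^2 + dzdy^2)) * 180 / pi
    }
  }
  out
}

make_m2s2_series <- function(days = 15, dt_min = 10, m2 = 150, s2 = 50,
                             noise = 0, seed = 1, position = 0) {
  t_h <- seq(0, days * 24, by = dt_min / 60)
  set.seed(seed)
  lvl <- m2 * cos(2 * pi * t_h / 12.42) + s2 * cos(2 * pi * t_h / 12.00) +
    rnorm(length(t_h), 0, noise)
  water_level_series(t_h, lvl, station = "syn", position_m = position)
}

# plain O(n * w^2) box blur used to build smooth test surfaces
box_blur_for_tests <- function(m, w) {
  nr <- nrow(m); nc <- ncol(m)
  h <- (w - 1) %/% 2
  out <- matrix(0, nr, nc)
  for (r in seq_len(nr)) {
    for (cc in seq_len(nc)) {
      rs <- max(1, r - h):min(nr, r + h)
      cs <- max(1, cc - h):min(nc, cc + h)
      out[r, cc] <- mean(m[rs, cs])
    }
  }
  out
}

# stability bound of the explicit drainage scheme for a given max depth
admissible_dt_for_tests <- function(wmax, K = 1, cfl = 0.2) {
  cfl / (4 * K * wmax)
}

# independent hypsometric oracle: share of values >= v, per unique value
hyps_values_for_tests <- function(values) {
  uv <- sort(unique(values))
  rel <- vapply(uv, function(v) 100 * mean(values >= v), numeric(1))
  data.frame(value = uv, rel_area_pct = rel)
}
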