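#' Define a target cell
#'
#' The sensitive volume is the spherical cell nucleus; coordinates share
#' the flow-domain frame (origin at the capillary bottom-left corner, the
#' third coordinate fixed at 0) so targets may lie outside the lumen
#' (perivascular position).
#'
#' @param x_um,y_um nucleus centre (micrometres).
#' @param cell_radius_um cell radius (reference 5).
#' @param nucleus_radius_um nucleus radius (reference 4).
#' @param density nucleus density, kg/m^3 (water).
#' @return An object of class `target_cell` including the nucleus mass
#'   `m_n` in kg.
#' @examples
#' target_cell(-75, 22)  # upstream perivascular target
#' @export
target_cell <- function(x_um, y_um, cell_radius_um = 5, nucleus_radius_um = 4,
                        density = 1000) {
  if (!(nucleus_radius_um > 0 && nucleus_radius_um <= cell_radius_um))
    stop_config("target_cell: need 0 < nucleus radius <= cell radius")
  structure(list(
    x_um = x_um, y_um = y_um,
    cell_radius_um = cell_radius_um,
    nucleus_radius_um = nucleus_radius_um,
    m_n = 4 / 3 * pi * um(nucleus_radius_um)^3 * density
  ), class = "target_cell")
}

#' Geometric hit probability of an isotropic point source
#'
#' Fraction of isotropic emission directions whose ray intersects the
#' spherical nucleus: `(1 - sqrt(1 - (r_n/d)^2))/2` for a source at
#' distance `d > r_n` from the nucleus centre, 1 for a source inside.
#'
#' @param d source to nucleus-centre distance (micrometres, > 0).
#' @param r_n nucleus radius (micrometres, > 0).
#' @return Hit probability.
#' @export
geometric_hit_probability <- function(d, r_n) {
  if (any(d <= 0) || any(r_n <= 0))
    stop_config("geometric_hit_probability: d and r_n must be > 0")
  # d = r_n gives the hemisphere limit 1/2; strictly interior emitters hit
  # with certainty
  ifelse(d < r_n, 1, (1 - sqrt(pmax(0, 1 - (r_n / d)^2))) / 2)
}

# Chord entry/exit distances along emission directions with polar cosine
# mu measured from the source -> nucleus-centre axis. Returns a list
# (L1, L2) in micrometres; for an interior source the entry distance is 0.
chord_lengths <- function(d, r_n, mu) {
  disc <- sqrt(pmax(0, r_n^2 - d^2 * (1 - mu^2)))
  if (d > r_n) {
    list(L1 = d * mu - disc, L2 = d * mu + disc)
  } else {
    list(L1 = rep(0, length(mu)), L2 = d * mu + disc)
  }
}

single_hit_moments <- function(d, target, E0, mu, model) {
  r_n <- target$nucleus_radius_um
  ch <- chord_lengths(d, r_n, mu)
  E_in <- residual_energy(E0, pmax(ch$L1, 0), model)
  E_out <- residual_energy(E0, pmax(ch$L2, 0), model)
  dE <- pmax(E_in - E_out, 0)
  z <- dE * 1.602e-13 / target$m_n
  list(z = z,
       stoppers = sum(dE > 0 & E_out <= 0),
       crossers = sum(E_out > 0),
       zeros = sum(dE <= 0))
}

#' Monte Carlo single-hit specific-energy spectrum
#'
#' Samples emission directions isotropically within the cone subtended by
#' the nucleus (uniform polar cosine), computes the chord through the
#' nucleus by ray-sphere intersection, deposits the energy difference of
#' the residual-range relation at entry and exit, and converts to specific
#' energy `z = dE x 1.602e-13 J/MeV / m_n`. Emissions inside the cone that
#' stop before reaching the nucleus are retained as zero-deposit samples,
#' so the hit probability stays purely geometric and the moments are
#' unbiased per in-cone emission.
#'
#' @param source source position, `c(x_um, y_um)` in the domain frame.
#' @param target a [target_cell()].
#' @param E0 alpha emission energy (MeV).
#' @param n_samples number of Monte Carlo samples (reference 50000).
#' @param seed integer seed (results are deterministic given the seed).
#' @param model a [range_energy_model()].
#' @return An object of class `single_hit_spectrum`: distance `d_um`,
#'   `p_hit`, first and second moments `z1` (Gy) and `z1sq` (Gy^2),
#'   sample and stopper/crosser counts.
#' @export
single_hit_spectrum_mc <- function(source, target, E0, n_samples = 50000L,
                                   seed = 1L, model = range_energy_model()) {
  stopifnot(inherits(target, "target_cell"), n_samples >= 1)
  d <- sqrt((source[1] - target$x_um)^2 + (source[2] - target$y_um)^2)
  r_n <- target$nucleus_radius_um
  mu_min <- if (d > r_n) sqrt(1 - (r_n / d)^2) else -1
  res <- with_seed(seed, {
    mu <- runif(n_samples, mu_min, 1)
    single_hit_moments(d, target, E0, mu, model)
  })
  structure(list(
    d_um = d, E0_MeV = E0,
    p_hit = if (d > 0) geometric_hit_probability(d, r_n) else 1,
    z1 = mean(res$z), z1sq = mean(res$z^2),
    n_samples = n_samples,
    n_stoppers = res$stoppers, n_crossers = res$crossers,
    n_zero = res$zeros
  ), class = "single_hit_spectrum")
}

#' Deterministic quadrature for the single-hit moments
#'
#' Computes the same in-cone moments as [single_hit_spectrum_mc()] by a
#' midpoint rule over the polar cosine (azimuthal symmetry), serving as
#' the independent deterministic reference for the Monte Carlo spectra.
#'
#' @param source,target,E0,model as in [single_hit_spectrum_mc()].
#' @param n_quadrature number of quadrature nodes.
#' @return A list with the first and second moments `z1` (Gy) and `z1sq`
#'   (Gy^2).
#' @export
single_hit_moments_oracle <- function(source, target, E0,
                                      n_quadrature = 4096L,
                                      model = range_energy_model()) {
  stopifnot(inherits(target, "target_cell"), n_quadrature >= 1)
  d <- sqrt((source[1] - target$x_um)^2 + (source[2] - target$y_um)^2)
  r_n <- target$nucleus_radius_um
  mu_min <- if (d > r_n) sqrt(1 - (r_n / d)^2) else -1
  h <- (1 - mu_min) / n_quadrature
  mu <- mu_min + (seq_len(n_quadrature) - 0.5) * h
  res <- single_hit_moments(d, target, E0, mu, model)
  list(z1 = mean(res$z), z1sq = mean(res$z^2))
}

#' Expected number of alpha hits in a time window
#'
#' Product of the decays in the window (`A_i dt`), the alpha yield per
#' decay, and the geometric hit probability. The default is the
#' deterministic expectation; `mode = "poisson"` draws a Poisson variate
#' with this mean.
#'
#' @param A_i source activity (Bq).
#' @param dt window length (s).
#' @param p_hit geometric hit probability.
#' @param Y_alpha alpha yield per decay.
#' @param mode `"expectation"` or `"poisson"`.
#' @param seed seed for the Poisson mode.
#' @return Expected (or sampled) number of hits.
#' @export
expected_hits <- function(A_i, dt, p_hit, Y_alpha = 1,
                          mode = c("expectation", "poisson"), seed = NULL) {
  mode <- match.arg(mode)
  if (any(c(A_i, dt, p_hit, Y_alpha) < 0))
    stop_config("expected_hits: all inputs must be >= 0")
  mean_hits <- A_i * dt * Y_alpha * p_hit
  if (mode == "expectation") return(mean_hits)
  with_seed(seed, rpois(length(mean_hits), mean_hits))
}

#' Create an empty dose accumulator
#'
#' Running cumulated specific energy `z(t)` and variance `sigma^2(t)`
#' with a per-contribution ledger.
#'
#' @return An object of class `dose_accumulator`.
#' @export
dose_accumulator <- function() {
  structure(list(z = 0, var = 0,
                 ledger = list()), class = "dose_accumulator")
}

#' Accumulate multi-source dose contributions
#'
#' Adds one time window of contributions: `z += sum_i n_i <z1i>` and
#' `sigma^2 += sum_i n_i <z1i^2>`, the discrete form of the multi-source
#' time integrals of the cumulated specific energy and its variance.
#'
#' @param acc a [dose_accumulator()].
#' @param contributions data.frame with columns `n` (hits in the window,
#'   already integrated over `dt`), `z1` and `z1sq` (single-hit moments),
#'   optionally `source`.
#' @param time window timestamp recorded in the ledger (s).
#' @return The updated accumulator.
#' @export
accumulate_dose <- function(acc, contributions, time = NA_real_) {
  stopifnot(inherits(acc, "dose_accumulator"))
  need <- c("n", "z1", "z1sq")
  if (!all(need %in% names(contributions)))
    stop_config("accumulate_dose: contributions need columns n, z1, z1sq")
  if (any(contributions$n < 0) || any(contributions$z1 < 0) ||
      any(contributions$z1sq < 0))
    stop_config("accumulate_dose: negative contribution")
  acc$z <- acc$z + sum(contributions$n * contributions$z1)
  acc$var <- acc$var + sum(contributions$n * contributions$z1sq)
  if (nrow(contributions) > 0L) {
    acc$ledger[[length(acc$ledger) + 1L]] <-
      cbind(time = time, as.data.frame(contributions))
  }
  acc
}
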