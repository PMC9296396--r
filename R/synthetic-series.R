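#' Coupling specification for synthetic dyadic series
#'
#' Parameters of the latent process behind a simulated dyad. Each interactant
#' has a latent burst-driven AR(1) process (intermittent movement episodes
#' with exponentially distributed magnitude, smoothed by autoregression);
#' interactant B's latent signal is a linear mixture of its own process and
#' interactant A's process shifted by `lag_frames`, weighted by
#' `coupling_strength`. Gaussian measurement noise is added and the result is
#' rectified at zero, mimicking the zero-inflated, bursty, autocorrelated
#' shape of real motion-energy traces.
#'
#' @param coupling_strength mixing weight in \[0, 1\]; 0 = independent
#'   interactants, 1 = B is a pure lag-shifted copy of A's latent signal.
#' @param lag_frames signed shift in frames; positive means B follows A.
#' @param ar_coefficient AR(1) coefficient in \[0, 1) (stationarity).
#' @param burst_rate probability per frame of a movement burst onset.
#' @param burst_scale mean magnitude of a burst innovation (motion-energy units).
#' @param noise_sd standard deviation of additive measurement noise.
#' @param seed integer seed; the generator has no global random state.
#' @return An object of class `coupling_spec`.
#' @export
coupling_spec <- function(coupling_strength = 0, lag_frames = 0L,
                          ar_coefficient = 0.95, burst_rate = 0.05,
                          burst_scale = 10, noise_sd = 1, seed = 1L) {
  num <- c(coupling_strength = coupling_strength, lag_frames = lag_frames,
           ar_coefficient = ar_coefficient, burst_rate = burst_rate,
           burst_scale = burst_scale, noise_sd = noise_sd, seed = seed)
  if (any(!is.finite(num))) {
    stop("all coupling_spec fields must be finite: ",
         paste(names(num)[!is.finite(num)], collapse = ", "), call. = FALSE)
  }
  if (coupling_strength < 0 || coupling_strength > 1) {
    stop("'coupling_strength' must lie in [0, 1]", call. = FALSE)
  }
  if (ar_coefficient < 0 || ar_coefficient >= 1) {
    stop("'ar_coefficient' must lie in [0, 1) for stationarity", call. = FALSE)
  }
  if (burst_rate < 0 || burst_rate > 1) stop("'burst_rate' must lie in [0, 1]", call. = FALSE)
  if (burst_scale < 0) stop("'burst_scale' must be nonnegative", call. = FALSE)
  if (noise_sd < 0) stop("'noise_sd' must be nonnegative", call. = FALSE)
  structure(list(coupling_strength = coupling_strength,
                 lag_frames = as.integer(lag_frames),
                 ar_coefficient = ar_coefficient, burst_rate = burst_rate,
                 burst_scale = burst_scale, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "coupling_spec")
}

# latent burst-AR(1): x_t = ar * x_{t-1} + Bern(rate) * Exp(scale).
# A warm-up stretch is discarded so the series starts in its stationary regime.
ar_burst_latent <- function(n, ar, rate, scale, warmup = 200L) {
  m <- n + warmup
  innov <- rbinom(m, 1L, rate) * rexp(m, rate = 1 / max(scale, .Machine$double.eps))
  x <- as.numeric(stats::filter(innov, ar, method = "recursive"))
  x[(warmup + 1L):m]
}

gen_coupled_values <- function(n_frames, spec) {
  lag <- spec$lag_frames
  pad <- abs(lag)
  la <- ar_burst_latent(n_frames + pad, spec$ar_coefficient, spec$burst_rate,
                        spec$burst_scale)
  lb <- ar_burst_latent(n_frames, spec$ar_coefficient, spec$burst_rate,
                        spec$burst_scale)
  idx <- seq_len(n_frames)
  if (lag >= 0) {
    own_a <- la[idx + lag]   # A's observed latent
    shifted <- la[idx]       # equals A's latent at t - lag
  } else {
    own_a <- la[idx]
    shifted <- la[idx + pad]
  }
  c_ <- spec$coupling_strength
  lat_b <- (1 - c_) * lb + c_ * shifted
  a <- pmax(0, own_a + rnorm(n_frames, 0, spec$noise_sd))
  b <- pmax(0, lat_b + rnorm(n_frames, 0, spec$noise_sd))
  list(a = a, b = b)
}

#' Generate a coupled pair of synthetic motion-energy series
#'
#' Simulates the motion-energy traces of two interactants with a known,
#' tunable degree of lagged coupling (see [coupling_spec] for the model).
#' With `coupling_strength = 0` the two series are statistically independent;
#' with `coupling_strength = 1`, `lag_frames = 0` and `noise_sd = 0` the two
#' series are identical frame by frame. Output is deterministic given
#' `spec$seed`.
#'
#' @param n_frames number of frames to generate (>= 2).
#' @param spec a [coupling_spec].
#' @param fps frame rate recorded on the returned series (default 25).
#' @param person_ids,roi_label labels attached to the two series.
#' @return A list with elements `a` and `b`, each a [motion_energy_series].
#' @examples
#' pair <- gen_coupled_series(1500, coupling_spec(coupling_strength = 0.8,
#'                                                lag_frames = 25, seed = 7))
#' @export
gen_coupled_series <- function(n_frames, spec, fps = 25,
                               person_ids = c("A", "B"), roi_label = "head") {
  if (!inherits(spec, "coupling_spec")) stop("'spec' must be a coupling_spec", call. = FALSE)
  n_frames <- as.integer(n_frames)
  if (is.na(n_frames) || n_frames < 2L) stop("'n_frames' must be >= 2", call. = FALSE)
  vals <- with_seed(spec$seed, gen_coupled_values(n_frames, spec))
  list(a = motion_energy_series(vals$a, fps, person_ids[[1L]], roi_label),
       b = motion_energy_series(vals$b, fps, person_ids[[2L]], roi_label))
}
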