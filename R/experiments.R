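#' Synchrony settings for simulation batteries
#'
#' The calibration experiments below keep the analysis shape (60-second
#' windows, 30-second stride, +/- 5 s lags) but run at a reduced frame rate
#' and a coarser lag grid so that hundreds of cohorts can be simulated on a
#' single CPU; correlation-based synchrony is insensitive to the sampling
#' rate of the latent process far above its correlation time.
#'
#' @param fps frame rate of the simulated series.
#' @param lag_step_s lag grid increment in seconds (default 0.5).
#' @return A [sync_config].
#' @export
calibration_sync_config <- function(fps, lag_step_s = 0.5) {
  sync_config(window_s = 60, step_s = 30, max_lag_s = 5,
              lag_step_frames = max(1L, as.integer(round(lag_step_s * fps))))
}

# n independent sessions (coupling as given), head ROI only
gen_sessions <- function(n_dyads, n_frames, fps, cs, seeds) {
  sessions <- vector("list", n_dyads)
  for (i in seq_len(n_dyads)) {
    vals <- with_seed(seeds[[i]], gen_coupled_values(n_frames, cs))
    id <- sprintf("dyad_%03d", i)
    sessions[[i]] <- dyad_session(id, "sim", list(
      personA_head = motion_energy_series(vals$a, fps, paste0(id, "_A"), "head"),
      personB_head = motion_energy_series(vals$b, fps, paste0(id, "_B"), "head")))
  }
  names(sessions) <- vapply(sessions, `[[`, character(1L), "dyad_id")
  sessions
}

sub_seeds <- function(seed, n) with_seed(seed, sample.int(.Machine$integer.max, n))

#' Synchrony response to coupling strength
#'
#' Simulates dyads on a grid of coupling strengths and reports the mean
#' synchrony per grid point. Under a correct pipeline the mean is strictly
#' increasing in the injected coupling.
#'
#' @param grid coupling strengths to probe.
#' @param n_seeds replicate dyads per grid point.
#' @param session_length_s,fps simulated session length and frame rate.
#' @param lag_frames injected lag of the coupled component.
#' @param sc a [sync_config]; defaults to [calibration_sync_config].
#' @param seed master seed.
#' @return Data frame with `coupling`, `mean_ips`, `sd_ips`, `n`.
#' @export
ips_coupling_curve <- function(grid = c(0, 0.25, 0.5, 0.75, 1),
                               n_seeds = 50L, session_length_s = 120, fps = 10,
                               lag_frames = 0L, sc = calibration_sync_config(fps),
                               seed = 1L) {
  n_frames <- as.integer(round(session_length_s * fps))
  seeds <- matrix(sub_seeds(seed, n_seeds * length(grid)), nrow = n_seeds)
  out <- lapply(seq_along(grid), function(gi) {
    cs <- coupling_spec(coupling_strength = grid[[gi]], lag_frames = lag_frames)
    ips <- vapply(seq_len(n_seeds), function(i) {
      vals <- with_seed(seeds[i, gi], gen_coupled_values(n_frames, cs))
      dyad_ips(vals$a, vals$b, sc, fps = fps)
    }, numeric(1L))
    data.frame(coupling = grid[[gi]], mean_ips = mean(ips), sd_ips = sd(ips),
               n = n_seeds)
  })
  do.call(rbind, out)
}

#' Recovery of an injected interaction lag
#'
#' Simulates dyads whose coupled component is shifted by a known number of
#' frames and locates, per replicate, the lag at which the window-averaged
#' absolute cross-correlation peaks. With a working lag axis the mean
#' recovered lag matches the injected one to within a frame.
#'
#' @param lag_frames injected lag (positive: B follows A).
#' @param coupling coupling strength of the simulated dyads.
#' @param n_seeds replicates.
#' @param session_length_s,fps session length and frame rate.
#' @param max_lag_s lag search range in seconds (frame-resolution grid).
#' @param seed master seed.
#' @return List with `mean_lag` (frames), `recovered` (per-replicate lags),
#'   `fps`.
#' @export
ips_lag_recovery <- function(lag_frames = 25L, coupling = 0.8, n_seeds = 50L,
                             session_length_s = 120, fps = 25, max_lag_s = 2,
                             seed = 1L) {
  sc <- sync_config(window_s = 60, step_s = 30, max_lag_s = max_lag_s,
                    lag_step_frames = 1L)
  cs <- coupling_spec(coupling_strength = coupling, lag_frames = lag_frames)
  n_frames <- as.integer(round(session_length_s * fps))
  seeds <- sub_seeds(seed, n_seeds)
  recovered <- vapply(seq_len(n_seeds), function(i) {
    vals <- with_seed(seeds[[i]], gen_coupled_values(n_frames, cs))
    m <- windowed_crosscorr(vals$a, vals$b, sc, fps = fps)
    profile <- colMeans(abs(m$r), na.rm = TRUE)
    m$lags_frames[[which.max(profile)]]
  }, numeric(1L))
  list(mean_lag = mean(recovered), recovered = recovered, fps = fps)
}

#' Null calibration of synchrony against pseudosynchrony
#'
#' Simulates a cohort of entirely uncoupled dyads and compares the real-pair
#' synchrony distribution with the pseudosynchrony distribution from
#' re-paired series. Under zero coupling the two must be indistinguishable
#' (the real pairing carries no information), checked with a two-sample
#' Kolmogorov-Smirnov test.
#'
#' @param n_dyads simulated dyads.
#' @param n_draws surrogate pairings to evaluate.
#' @param session_length_s,fps session length and frame rate.
#' @param sc a [sync_config].
#' @param seed master seed.
#' @return List with `real`, `surrogate` (numeric vectors) and `ks_p`.
#' @export
null_ips_battery <- function(n_dyads = 200L, n_draws = 200L,
                             session_length_s = 120, fps = 10,
                             sc = calibration_sync_config(fps), seed = 1L) {
  n_frames <- as.integer(round(session_length_s * fps))
  cs <- coupling_spec(coupling_strength = 0)
  seeds <- sub_seeds(seed, n_dyads + 1L)
  sessions <- gen_sessions(n_dyads, n_frames, fps, cs, seeds[-1L])
  real <- vapply(sessions, function(s) {
    dyad_ips(session_series(s, "A", "head"), session_series(s, "B", "head"), sc)
  }, numeric(1L))
  surr <- pseudosynchrony(sessions, surrogate_config(n_draws, seed = seeds[[1L]]),
                          sc, roi = "head")
  ks_p <- suppressWarnings(ks.test(real, surr$values)$p.value)
  list(real = unname(real), surrogate = surr$values, ks_p = ks_p)
}

#' Type-I error rate of the synchrony-vs-chance test
#'
#' Repeatedly simulates null cohorts (zero coupling), runs the one-tailed
#' Mann-Whitney comparison of real synchrony against pseudosynchrony, and
#' reports the fraction of cohorts rejected at `alpha`. A calibrated
#' procedure rejects at the nominal rate.
#'
#' @param n_cohorts number of simulated cohorts.
#' @param n_dyads dyads per cohort.
#' @param n_draws surrogate pairings per cohort.
#' @param session_length_s,fps session length and frame rate.
#' @param alpha nominal test level.
#' @param sc a [sync_config].
#' @param seed master seed.
#' @return List with `rate`, `p_values`, `alpha`.
#' @export
type1_battery <- function(n_cohorts = 500L, n_dyads = 16L, n_draws = 50L,
                          session_length_s = 120, fps = 10, alpha = 0.05,
                          sc = calibration_sync_config(fps), seed = 1L) {
  n_frames <- as.integer(round(session_length_s * fps))
  cs <- coupling_spec(coupling_strength = 0)
  master <- sub_seeds(seed, n_cohorts)
  p_values <- vapply(seq_len(n_cohorts), function(k) {
    seeds <- sub_seeds(master[[k]], n_dyads + 1L)
    sessions <- gen_sessions(n_dyads, n_frames, fps, cs, seeds[-1L])
    real <- vapply(sessions, function(s) {
      dyad_ips(session_series(s, "A", "head"), session_series(s, "B", "head"), sc)
    }, numeric(1L))
    surr <- pseudosynchrony(sessions, surrogate_config(n_draws, seed = seeds[[1L]]),
                            sc, roi = "head")
    real_vs_surrogate_test(real, surr)$p
  }, numeric(1L))
  list(rate = mean(p_values < alpha), p_values = p_values, alpha = alpha)
}
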