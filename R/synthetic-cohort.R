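#' Truncated-normal sampling
#'
#' Inverse-CDF sampler for a normal distribution truncated to \[`lower`,
#' `upper`\], used for questionnaire scores that live on a bounded instrument
#' scale. `truncnorm_mean` returns the analytic mean of that distribution and
#' serves as the reference value in generator checks.
#'
#' @param n number of draws.
#' @param mean,sd parameters of the parent normal; `sd = 0` returns `mean`
#'   (clamped to the bounds) for every draw.
#' @param lower,upper truncation bounds.
#' @return `rtruncnorm` a numeric vector of length `n`; `truncnorm_mean` a
#'   single number.
#' @export
rtruncnorm <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  stopifnot(sd >= 0, lower < upper)
  if (sd == 0) return(rep(min(max(mean, lower), upper), n))
  plo <- pnorm(lower, mean, sd)
  phi <- pnorm(upper, mean, sd)
  qnorm(runif(n, plo, phi), mean, sd)
}

#' @rdname rtruncnorm
#' @export
truncnorm_mean <- function(mean, sd, lower = -Inf, upper = Inf) {
  stopifnot(sd >= 0, lower < upper)
  if (sd == 0) return(min(max(mean, lower), upper))
  a <- (lower - mean) / sd
  b <- (upper - mean) / sd
  z <- pnorm(b) - pnorm(a)
  mean + sd * (dnorm(a) - dnorm(b)) / z
}

# Table of published cohort questionnaire summaries (mean, sd) per group with
# instrument score ranges; the cohort generator's default score model.
default_questionnaire_params <- function() {
  list(
    age       = list(ASD_plus = c(34.19, 12.41), ASD_minus = c(39.57, 12.29), range = c(18, 80)),
    verbal_iq = list(ASD_plus = c(103.19, 19.48), ASD_minus = c(105.35, 11.33), range = c(50, 160)),
    aq        = list(ASD_plus = c(36.75, 6.76),  ASD_minus = c(35.70, 8.26),  range = c(0, 50)),
    eq        = list(ASD_plus = c(16.06, 9.98),  ASD_minus = c(19.74, 11.02), range = c(0, 80)),
    adc       = list(ASD_plus = c(54.20, 15.19), ASD_minus = c(42.90, 19.45), range = c(0, 120)),
    tas20     = list(ASD_plus = c(59.44, 13.83), ASD_minus = c(64.13, 10.24), range = c(20, 100)),
    bdi       = list(ASD_plus = c(13.53, 10.18), ASD_minus = c(19.30, 8.63), range = c(0, 63))
  )
}

#' Cohort specification for the synthetic-data generator
#'
#' Describes a two-group cohort of dyads: how many dyads per group, the
#' coupling model of each group's dyadic series, the questionnaire score
#' distributions (truncated normals at the instrument bounds), session length
#' and frame rate. Defaults reproduce the reference study's shape: 16 dyads
#' in the diagnosed group (`ASD_plus`) and 23 in the non-diagnosed group
#' (`ASD_minus`), with the published score means and SDs, 14-minute sessions
#' at 25 fps. The diagnosed group gets a lower default coupling strength,
#' reflecting reduced synchrony.
#'
#' @param group_n named integer vector: dyads per group.
#' @param group_coupling named list of [coupling_spec], one per group (the
#'   spec's own `seed` field is ignored; the cohort `seed` governs all draws).
#' @param questionnaire_params named list: for each score a list with one
#'   `c(mean, sd)` entry per group and a `range = c(lo, hi)` entry.
#' @param session_length_s session length in seconds.
#' @param fps frame rate in frames per second.
#' @param rois ROI labels to simulate per interactant.
#' @param seed integer seed governing every random draw.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(group_n = c(ASD_plus = 16L, ASD_minus = 23L),
                        group_coupling = list(
                          ASD_plus = coupling_spec(coupling_strength = 0.15, lag_frames = 12L),
                          ASD_minus = coupling_spec(coupling_strength = 0.25, lag_frames = 12L)),
                        questionnaire_params = default_questionnaire_params(),
                        session_length_s = 840, fps = 25,
                        rois = c("head", "body"), seed = 1L) {
  if (is.null(names(group_n)) || any(!nzchar(names(group_n)))) {
    stop("'group_n' must be a named vector", call. = FALSE)
  }
  if (any(group_n < 1L)) stop("each group must contain at least one dyad", call. = FALSE)
  if (!setequal(names(group_coupling), names(group_n))) {
    stop("'group_coupling' must name the same groups as 'group_n'", call. = FALSE)
  }
  if (!is.numeric(fps) || fps <= 0) stop("'fps' must be positive", call. = FALSE)
  if (session_length_s * fps < 2) stop("session too short", call. = FALSE)
  for (sc in names(questionnaire_params)) {
    p <- questionnaire_params[[sc]]
    if (is.null(p$range) || p$range[1L] >= p$range[2L]) {
      stop("score '", sc, "' needs a valid range = c(lo, hi)", call. = FALSE)
    }
  }
  structure(list(group_n = group_n, group_coupling = group_coupling,
                 questionnaire_params = questionnaire_params,
                 session_length_s = session_length_s, fps = fps,
                 rois = rois, seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Generate a synthetic two-group cohort of dyads
#'
#' Draws a full cohort under a [cohort_spec]: per dyad, one coupled pair of
#' motion-energy series per ROI (head and body by default) with the group's
#' coupling model, and a participant record with questionnaire scores drawn
#' from truncated normals at the instrument bounds. Reproducible under
#' `spec$seed`.
#'
#' @param spec a [cohort_spec].
#' @return A list with `sessions` (list of [dyad_session]) and `participants`
#'   (data frame: `dyad_id`, `group`, one column per score).
#' @export
gen_cohort <- function(spec) {
  if (!inherits(spec, "cohort_spec")) stop("'spec' must be a cohort_spec", call. = FALSE)
  n_frames <- as.integer(round(spec$session_length_s * spec$fps))
  groups <- names(spec$group_n)
  with_seed(spec$seed, {
    sessions <- list()
    rows <- list()
    for (g in groups) {
      cs <- spec$group_coupling[[g]]
      for (k in seq_len(spec$group_n[[g]])) {
        dyad_id <- sprintf("%s_%02d", g, k)
        ser <- list()
        for (roi in spec$rois) {
          vals <- gen_coupled_values(n_frames, cs)
          ser[[paste0("personA_", roi)]] <-
            motion_energy_series(vals$a, spec$fps, paste0(dyad_id, "_A"), roi)
          ser[[paste0("personB_", roi)]] <-
            motion_energy_series(vals$b, spec$fps, paste0(dyad_id, "_B"), roi)
        }
        sessions[[dyad_id]] <- dyad_session(dyad_id, g, ser)
        scores <- lapply(spec$questionnaire_params, function(p) {
          rtruncnorm(1L, p[[g]][1L], p[[g]][2L], p$range[1L], p$range[2L])
        })
        rows[[dyad_id]] <- data.frame(dyad_id = dyad_id, group = g,
                                      as.data.frame(scores))
      }
    }
    participants <- do.call(rbind, rows)
    rownames(participants) <- NULL
    list(sessions = sessions, participants = participants)
  })
}
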