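#' Surrogate-resampling settings
#'
#' @param n_draws number of surrogate pairings to evaluate (default 1000);
#'   must not exceed the number of eligible pairs (draws are distinct).
#' @param seed integer seed for the draw.
#' @param eligibility pairing rule; currently `"all_non_interacting_pairs"`:
#'   every unordered pair of individual series except the genuinely
#'   interacting pair of each recording. With V recordings (2 series each)
#'   this yields `choose(2V, 2) - V` pairs.
#' @return An object of class `surrogate_config`.
#' @export
surrogate_config <- function(n_draws = 1000L, seed = 1L,
                             eligibility = "all_non_interacting_pairs") {
  eligibility <- match.arg(eligibility, "all_non_interacting_pairs")
  if (n_draws < 1L) stop("'n_draws' must be >= 1", call. = FALSE)
  structure(list(n_draws = as.integer(n_draws), seed = as.integer(seed),
                 eligibility = eligibility),
            class = "surrogate_config")
}

#' Enumerate the non-interacting series pairs of a cohort
#'
#' Pools the two interactants' series of every recording and lists every
#' unordered pair of series whose owners never actually interacted — i.e.
#' all `choose(2V, 2)` pairs minus the V genuine pairs. These pairings carry
#' no true interaction and their synchrony is pseudosynchrony, the chance
#' level against which genuine synchrony is judged.
#'
#' @param sessions list of [dyad_session] (>= 2).
#' @param roi ROI label whose series are pooled (default `"head"`).
#' @return An object of class `surrogate_pairs`: list with `pairs` (2-column
#'   integer matrix of indices into `members`), `members` (list of
#'   [motion_energy_series]), `member_ids` (labels `<dyad>_<A|B>`).
#' @export
enumerate_pairs <- function(sessions, roi = "head") {
  if (length(sessions) < 2L) stop("need at least 2 recordings", call. = FALSE)
  members <- list(); ids <- character(0)
  for (s in sessions) {
    members <- c(members, list(session_series(s, "A", roi), session_series(s, "B", roi)))
    ids <- c(ids, paste0(s$dyad_id, "_A"), paste0(s$dyad_id, "_B"))
  }
  m <- length(members)
  all_pairs <- t(combn(m, 2L))
  true_pair <- (all_pairs[, 2L] == all_pairs[, 1L] + 1L) & (all_pairs[, 1L] %% 2L == 1L)
  structure(list(pairs = all_pairs[!true_pair, , drop = FALSE],
                 members = members, member_ids = ids, roi_label = roi),
            class = "surrogate_pairs")
}

#' @export
print.surrogate_pairs <- function(x, ...) {
  cat(sprintf("<surrogate_pairs> %d eligible pairs from %d series (roi %s)\n",
              nrow(x$pairs), length(x$members), x$roi_label))
  invisible(x)
}

#' Draw surrogate pairings
#'
#' Uniform sampling without replacement of `n_draws` distinct pairs from the
#' eligible set; reproducible under `config$seed`. Requesting every pair
#' returns the full set (in enumeration order).
#'
#' @param pairs an [enumerate_pairs] result.
#' @param config a [surrogate_config].
#' @return The `surrogate_pairs` object restricted to the drawn pairs.
#' @export
sample_surrogates <- function(pairs, config = surrogate_config()) {
  stopifnot(inherits(pairs, "surrogate_pairs"))
  n_avail <- nrow(pairs$pairs)
  if (config$n_draws > n_avail) {
    stop(sprintf("n_draws = %d exceeds the %d eligible pairs",
                 config$n_draws, n_avail), call. = FALSE)
  }
  idx <- if (config$n_draws == n_avail) seq_len(n_avail)
         else with_seed(config$seed, sample.int(n_avail, config$n_draws))
  pairs$pairs <- pairs$pairs[idx, , drop = FALSE]
  pairs
}

#' Pseudosynchrony distribution
#'
#' Runs the identical synchrony pipeline ([windowed_crosscorr] +
#' [aggregate_ips]) on each drawn surrogate pairing. Series of unequal
#' length are truncated to the shorter length. Pairs on which synchrony is
#' undefined (e.g. all-constant series) are skipped with a warning; the
#' run fails only if every pair is degenerate.
#'
#' @param sessions list of [dyad_session].
#' @param config a [surrogate_config].
#' @param sc a [sync_config]; must equal the one used for the real pairs.
#' @param roi ROI label (default `"head"`).
#' @return An object of class `surrogate_distribution`: list with `values`,
#'   `pair_ids`, `roi_label`.
#' @export
pseudosynchrony <- function(sessions, config = surrogate_config(),
                            sc = sync_config(), roi = "head") {
  pairs <- sample_surrogates(enumerate_pairs(sessions, roi), config)
  n <- nrow(pairs$pairs)
  values <- rep(NA_real_, n)
  ids <- character(n)
  for (k in seq_len(n)) {
    i <- pairs$pairs[k, 1L]; j <- pairs$pairs[k, 2L]
    a <- pairs$members[[i]]; b <- pairs$members[[j]]
    len <- min(length(a$values), length(b$values))
    ids[k] <- paste(pairs$member_ids[[i]], pairs$member_ids[[j]], sep = " x ")
    values[k] <- tryCatch(
      dyad_ips(motion_energy_series(a$values[seq_len(len)], a$fps),
               motion_energy_series(b$values[seq_len(len)], b$fps), sc),
      error = function(e) {
        warning("skipping degenerate surrogate pair ", ids[k], ": ",
                conditionMessage(e), call. = FALSE)
        NA_real_
      })
  }
  keep <- !is.na(values)
  if (!any(keep)) stop("no surrogate pair yielded a defined synchrony value", call. = FALSE)
  structure(list(values = values[keep], pair_ids = ids[keep], roi_label = roi),
            class = "surrogate_distribution")
}

#' @export
print.surrogate_distribution <- function(x, ...) {
  cat(sprintf("<surrogate_distribution> roi %s: %d values, mean %.4f, sd %.4f\n",
              x$roi_label, length(x$values), mean(x$values), sd(x$values)))
  invisible(x)
}

#' Test genuine synchrony against pseudosynchrony
#'
#' Mann-Whitney comparison of the real per-dyad synchrony values with the
#' surrogate distribution, one-tailed by default in the direction genuine
#' synchrony must show (real greater than chance), with Cohen's d on the two
#' samples as effect size.
#'
#' @param real numeric vector of real-pair synchrony values.
#' @param surrogate a [pseudosynchrony] result (or numeric vector).
#' @param alternative tail; default `"greater"`.
#' @return A `group_comparison` with the U statistic.
#' @export
real_vs_surrogate_test <- function(real, surrogate,
                                   alternative = c("greater", "two.sided", "less")) {
  alternative <- match.arg(alternative)
  surr <- if (inherits(surrogate, "surrogate_distribution")) surrogate$values
          else as.numeric(surrogate)
  if (length(real) == 0L || length(surr) == 0L) {
    stop("both the real and the surrogate sample must be nonempty", call. = FALSE)
  }
  mann_whitney(real, surr, alternative, variable = "ips_vs_pseudosynchrony")
}
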