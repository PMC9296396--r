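small_sc <- sync_config(window_s = 8, step_s = 4, max_lag_s = 2)

test_that("a series correlated with itself peaks at one on lag zero", {
  a <- fixture_series(200, seed = 1, fps = 5)
  m <- windowed_crosscorr(a, a, small_sc)
  lag0 <- m$r[, m$lags_frames == 0]
  expect_true(all(abs(lag0 - 1) < 1e-12))
})

test_that("a pure shift is recovered at the injected lag", {
  set.seed(2)
  n <- 3000
  base <- pmax(0, cumsum(rnorm(n + 25)))
  a <- motion_energy_series(base[26:(n + 25)], 25)
  b <- motion_energy_series(base[1:n], 25)  # b[t] = a[t - 25]
  sc <- sync_config(window_s = 60, step_s = 30, max_lag_s = 2)
  m <- windowed_crosscorr(a, b, sc)
  peak <- m$lags_frames[which.max(colMeans(m$r, na.rm = TRUE))]
  expect_equal(peak, 25)  # +1 s at 25 fps
})

test_that("windowed cross-correlation matches the first-principles loop", {
  for (seed in 1:8) {
    a <- fixture_series(120, seed, fps = 4)
    b <- fixture_series(120, seed + 500, fps = 4)
    m <- windowed_crosscorr(a, b, sync_config(window_s = 10, step_s = 5, max_lag_s = 2))
    ref <- naive_wcc(a$values, b$values, 4, 10, 5, 2)
    expect_equal(dim(m$r), dim(ref))
    expect_equal(m$r, ref, ignore_attr = TRUE, tolerance = 1e-12)
  }
})

test_that("series mismatches are rejected", {
  a <- fixture_series(100, 1); b <- fixture_series(90, 2)
  expect_error(windowed_crosscorr(a, b, small_sc), "length mismatch")
  b2 <- motion_energy_series(a$values, fps = 10)
  expect_error(windowed_crosscorr(a, b2, small_sc), "frame-rate")
  expect_error(windowed_crosscorr(a$values[1:30], a$values[1:30], small_sc, fps = 5),
               "shorter than one")
})

test_that("zero-variance windows yield missing cells, never zero", {
  a <- motion_energy_series(c(rep(3, 40), pmax(0, rnorm(40, 5))), 5)
  b <- fixture_series(80, 3, fps = 5)
  m <- windowed_crosscorr(a, b, small_sc)
  expect_true(anyNA(m$r[1, ]))        # constant stretch of a
  expect_false(any(m$r[1, ] %in% 0))
})

test_that("Fisher transform follows the closed form with clipping", {
  expect_equal(fisher_z(0), 0)
  expect_equal(fisher_z(0.5), 0.549306, tolerance = 1e-6)
  expect_equal(fisher_z(1), atanh(1 - 1e-7))
  expect_lt(fisher_z(1), 8.5)  # clipped, finite
  expect_true(is.na(fisher_z(NA_real_)))
  expect_error(fisher_z(1.5), "outside")
})

test_that("synchrony aggregates mean absolute Fisher-Z over defined cells", {
  make_mat <- function(r) {
    structure(list(r = r, lags_frames = seq_len(ncol(r)) - 1,
                   window_starts_frames = seq_len(nrow(r)), fps = 5),
              class = "crosscorr_matrix")
  }
  # all-zero correlations aggregate to zero
  expect_equal(aggregate_ips(make_mat(matrix(0, 3, 4)))$ips, 0)
  # cells with z in {1, -1, 0, 0} average to 0.5
  r <- matrix(c(tanh(1), tanh(-1), 0, 0), 2, 2)
  expect_equal(aggregate_ips(make_mat(r))$ips, 0.5, tolerance = 1e-12)
  # oracle: independent scalar loop over cells
  set.seed(4)
  r2 <- matrix(runif(24, -1, 1), 4, 6)
  r2[c(3, 17)] <- NA
  acc <- 0; n_used <- 0
  for (v in as.vector(r2)) {
    if (!is.na(v)) { acc <- acc + abs(atanh(v)); n_used <- n_used + 1 }
  }
  got <- aggregate_ips(make_mat(r2))
  expect_equal(got$ips, acc / n_used, tolerance = 1e-12)
  expect_equal(got$n_cells_used, n_used)
  # all-missing matrix is rejected
  expect_error(aggregate_ips(make_mat(matrix(NA_real_, 2, 2))), "defined correlation cells")
})

test_that("synchrony is symmetric in the interactants", {
  for (seed in 1:6) {
    a <- fixture_series(160, seed, fps = 5)
    b <- fixture_series(160, seed + 50, fps = 5)
    expect_equal(dyad_ips(a, b, small_sc), dyad_ips(b, a, small_sc),
                 tolerance = 1e-12)
  }
})

test_that("the correlation matrix is invariant to positive rescaling", {
  a <- fixture_series(160, 7, fps = 5)
  b <- fixture_series(160, 8, fps = 5)
  m1 <- windowed_crosscorr(a, b, small_sc)
  m2 <- windowed_crosscorr(motion_energy_series(a$values * 37.5, 5),
                           motion_energy_series(b$values * 0.004, 5), small_sc)
  expect_equal(m1$r, m2$r, tolerance = 1e-12)
})

test_that("total-body series is the frame-wise ROI sum", {
  head <- motion_energy_series(c(1, 0), 5, "A", "head", roi_area = 10)
  body <- motion_energy_series(c(0, 2), 5, "A", "body", roi_area = 20)
  total <- total_roi_series(head, body)
  expect_equal(total$values, c(1, 2))
  expect_equal(total$roi_label, "total")
  expect_equal(total$roi_area, 30)
  # zero body leaves the head series unchanged
  zero <- motion_energy_series(c(0, 0), 5, "A", "body")
  expect_equal(total_roi_series(head, zero)$values, head$values)
  # the sum dominates each part frame-wise (nonnegativity)
  h2 <- fixture_series(50, 11, fps = 5); h2$person_id <- "A"
  b2 <- fixture_series(50, 12, fps = 5); b2$person_id <- "A"
  expect_true(all(total_roi_series(h2, b2)$values >= pmax(h2$values, b2$values)))
  other <- motion_energy_series(c(1, 1), 5, "B", "body")
  expect_error(total_roi_series(head, other), "different persons")
})

test_that("split vignettes average with equal weight", {
  v1 <- structure(list(ips = 0.06, n_cells_used = 10L, dyad_id = "d1", roi_label = "head"),
                  class = "synchrony_value")
  v2 <- structure(list(ips = 0.08, n_cells_used = 14L, dyad_id = "d1", roi_label = "head"),
                  class = "synchrony_value")
  comb <- combine_split_vignette(v1, v2)
  expect_equal(comb$ips, 0.07)
  expect_equal(comb$n_cells_used, 24L)
  expect_equal(combine_split_vignette(v1, v1)$ips, v1$ips)
  expect_equal(combine_split_vignette(v2, v1)$ips, comb$ips)  # order-invariant
  v3 <- v2; v3$roi_label <- "body"
  expect_error(combine_split_vignette(v1, v3), "ROI")
  v4 <- v2; v4$dyad_id <- "d2"
  expect_error(combine_split_vignette(v1, v4), "dyads")
})

test_that("smoothing option shortens nothing and stays finite", {
  a <- fixture_series(200, 21, fps = 5)
  b <- fixture_series(200, 22, fps = 5)
  sc <- sync_config(window_s = 8, step_s = 4, max_lag_s = 1, smooth_s = 0.6)
  m <- windowed_crosscorr(a, b, sc)
  expect_true(all(is.na(m$r) | abs(m$r) <= 1))
})
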