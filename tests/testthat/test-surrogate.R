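tiny_session <- function(id, n = 12, seed = 1, fps = 5) {
  set.seed(seed)
  dyad_session(id, "g", list(
    personA_head = motion_energy_series(pmax(0, rnorm(n, 5)), fps, paste0(id, "_A"), "head"),
    personB_head = motion_energy_series(pmax(0, rnorm(n, 5)), fps, paste0(id, "_B"), "head")))
}

test_that("eligible-pair enumeration excludes exactly the true partners", {
  # brute-force oracle: count index pairs not belonging to the same recording
  for (v in 1:10) {
    sessions <- lapply(seq_len(v), function(i) tiny_session(paste0("d", i), seed = i))
    brute <- 0L
    for (i in 1:(2 * v)) for (j in seq_len(2 * v)) {
      if (j > i && !(ceiling(i / 2) == ceiling(j / 2))) brute <- brute + 1L
    }
    if (v < 2) {
      expect_error(enumerate_pairs(sessions), "at least 2")
    } else {
      pairs <- enumerate_pairs(sessions)
      expect_equal(nrow(pairs$pairs), brute)
      expect_equal(nrow(pairs$pairs), choose(2 * v, 2) - v)
      # no genuine pair slipped through
      own <- ceiling(pairs$pairs / 2)
      expect_true(all(own[, 1] != own[, 2]))
    }
  }
  # two recordings leave four cross pairings
  sessions2 <- lapply(1:2, function(i) tiny_session(paste0("d", i), seed = i))
  expect_equal(nrow(enumerate_pairs(sessions2)$pairs), 4)
})

test_that("surrogate draws are distinct, seeded and uniform", {
  sessions <- lapply(1:4, function(i) tiny_session(paste0("d", i), seed = i))
  pairs <- enumerate_pairs(sessions)  # 24 eligible
  # drawing all pairs returns the full set
  full <- sample_surrogates(pairs, surrogate_config(nrow(pairs$pairs)))
  expect_equal(nrow(full$pairs), nrow(pairs$pairs))
  # identical seed, identical draw; distinct rows
  s1 <- sample_surrogates(pairs, surrogate_config(10, seed = 5))
  s2 <- sample_surrogates(pairs, surrogate_config(10, seed = 5))
  expect_identical(s1$pairs, s2$pairs)
  expect_equal(nrow(unique(s1$pairs)), 10)
  # overdrawing reports the eligible count
  expect_error(sample_surrogates(pairs, surrogate_config(25)), "24 eligible")

  # uniformity: each of 10 pairs drawn with frequency 3/10 over many draws
  pairs10 <- pairs; pairs10$pairs <- pairs$pairs[1:10, ]
  counts <- integer(10)
  for (rep in 1:10000) {
    drawn <- sample_surrogates(pairs10, surrogate_config(3, seed = rep))
    hit <- match(paste(drawn$pairs[, 1], drawn$pairs[, 2]),
                 paste(pairs10$pairs[, 1], pairs10$pairs[, 2]))
    counts[hit] <- counts[hit] + 1L
  }
  expect_true(all(abs(counts / 10000 - 0.3) < 0.02))
})

test_that("pseudosynchrony runs the identical pipeline per drawn pair", {
  sessions <- lapply(1:4, function(i) tiny_session(paste0("d", i), n = 60, seed = i))
  sc <- sync_config(window_s = 6, step_s = 3, max_lag_s = 1)
  dist <- pseudosynchrony(sessions, surrogate_config(8, seed = 2), sc)
  expect_length(dist$values, 8)
  expect_true(all(dist$values >= 0))
  # spot-check one pair against a direct recomputation
  pairs <- sample_surrogates(enumerate_pairs(sessions), surrogate_config(8, seed = 2))
  i <- pairs$pairs[1, 1]; j <- pairs$pairs[1, 2]
  expect_equal(dist$values[1],
               dyad_ips(pairs$members[[i]], pairs$members[[j]], sc))
})

test_that("degenerate all-constant cohorts are rejected", {
  flat <- lapply(1:3, function(i) {
    dyad_session(paste0("d", i), "g", list(
      personA_head = motion_energy_series(rep(0, 40), 5),
      personB_head = motion_energy_series(rep(0, 40), 5)))
  })
  sc <- sync_config(window_s = 4, step_s = 2, max_lag_s = 1)
  expect_error(suppressWarnings(
    pseudosynchrony(flat, surrogate_config(3, seed = 1), sc)),
    "no surrogate pair")
})

test_that("unequal-length surrogate pairs are truncated to overlap", {
  s1 <- tiny_session("d1", n = 80, seed = 1)
  s2 <- tiny_session("d2", n = 50, seed = 2)
  sc <- sync_config(window_s = 6, step_s = 3, max_lag_s = 1)
  dist <- pseudosynchrony(list(s1, s2), surrogate_config(4, seed = 1), sc)
  expect_length(dist$values, 4)
  expect_true(all(is.finite(dist$values)))
})

test_that("coupled dyads beat their surrogates, null dyads do not", {
  fps <- 10
  sc <- calibration_sync_config(fps)
  make_cohort <- function(coupling, seed0) {
    lapply(1:8, function(i) {
      p <- gen_coupled_series(900, coupling_spec(coupling_strength = coupling,
                                                 lag_frames = 3, seed = seed0 + i),
                              fps = fps)
      dyad_session(paste0("d", i), "g",
                   list(personA_head = p$a, personB_head = p$b))
    })
  }
  coupled <- make_cohort(0.8, 100)
  real <- vapply(coupled, function(s) {
    dyad_ips(s$series$personA_head, s$series$personB_head, sc)
  }, numeric(1))
  surr <- pseudosynchrony(coupled, surrogate_config(40, seed = 9), sc)
  res <- real_vs_surrogate_test(real, surr)
  expect_lt(res$p, 0.01)
  expect_gt(res$cohens_d, 0)

  nullc <- make_cohort(0, 300)
  real0 <- vapply(nullc, function(s) {
    dyad_ips(s$series$personA_head, s$series$personB_head, sc)
  }, numeric(1))
  surr0 <- pseudosynchrony(nullc, surrogate_config(40, seed = 10), sc)
  expect_lt(abs(mean(real0) - mean(surr0$values)), 3 * sd(surr0$values))
})

test_that("the synchrony-vs-chance test behaves at its extremes", {
  x <- c(0.05, 0.06, 0.07, 0.08)
  same <- real_vs_surrogate_test(x, x)
  expect_equal(same$statistic, length(x)^2 / 2)   # U = n1 n2 / 2 on identical samples
  expect_gt(same$p, 0.3); expect_lt(same$p, 0.7)  # one-tailed p near 0.5

  res <- real_vs_surrogate_test(c(3, 4), c(1, 2))
  expect_equal(res$statistic, 4)  # all real above all surrogate: U at its maximum
  expect_equal(naive_u(c(3, 4), c(1, 2)), 4)
  expect_equal(res$p, naive_u_p_greater(c(3, 4), c(1, 2)))
  expect_error(real_vs_surrogate_test(numeric(0), c(1, 2)), "nonempty")
})
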