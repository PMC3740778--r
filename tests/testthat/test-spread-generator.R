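test_that("empty and degenerate generator cases behave", {
  fib <- generate_spread_fibres(spread_gen_params(n_clusters = 0, seed = 1))
  expect_length(fib, 0)
  expect_equal(nrow(attr(fib, "truth")), 0)

  # sigma = 0 everywhere and exactly 8 tracks/cluster: every span is the
  # closed-form 8*15 + 7*30 = 330 Kb
  p <- spread_gen_params(track_sigma_log = 0, gap_sigma_log = 0,
                         spacer_sigma_log = 0, tus_per_cluster_sd = 0,
                         n_clusters = 10, seed = 3)
  fib <- generate_spread_fibres(p)
  truth <- attr(fib, "truth")
  expect_equal(truth$span_kb, rep(330, 10), tolerance = 1e-9)
  expect_equal(truth$n_tracks, rep(8L, 10))
  expect_true(all(abs(track_lengths(fib) - 15) < 1e-9))
  expect_true(all(abs(intra_cluster_gaps(fib) - 30) < 1e-9))
})

test_that("parameter validation rejects bad inputs", {
  expect_error(spread_gen_params(track_mean_kb = -1), "positive")
  expect_error(spread_gen_params(min_tus_per_cluster = 1), ">= 2")
  expect_error(spread_gen_params(gap_mean_kb = 150), "below max_gap_kb")
  expect_error(generate_spread_fibres(spread_gen_params(n_clusters = 1)),
               "seed")
  expect_error(generate_spread_fibres(list()), "spread_gen_params")
})

test_that("sample moments converge to the configured parameters", {
  p <- spread_gen_params(n_clusters = 1250, seed = 7)
  fib <- generate_spread_fibres(p)
  len <- track_lengths(fib)
  expect_gt(length(len), 9000)

  # mean within 3 standard errors (lognormal sd = mean * sqrt(exp(s^2)-1))
  se_len <- sd(len) / sqrt(length(len))
  expect_lt(abs(mean(len) - 15), 3 * se_len)

  gaps <- intra_cluster_gaps(fib)
  # rejection truncation below 100 Kb shifts the mean to the conditional
  # value ~28.99 Kb (closed form for a lognormal truncated above)
  mu <- log(30) - 0.18; s <- 0.6
  trunc_mean <- 30 * pnorm((log(100) - mu - s^2) / s) /
    pnorm((log(100) - mu) / s)
  expect_lt(abs(mean(gaps) - trunc_mean), 3 * sd(gaps) / sqrt(length(gaps)))

  truth <- attr(fib, "truth")
  expect_lt(abs(mean(truth$n_tracks) - 8),
            3 * sd(truth$n_tracks) / sqrt(nrow(truth)))

  mk <- marks_per_track(fib)
  expect_lt(abs(mk$transcripts$mean - 0.7),
            3 * sqrt(0.7 / mk$n_tracks))
  expect_lt(abs(mk$polii$mean - 0.8), 3 * sqrt(0.8 / mk$n_tracks))
})

test_that("truncation invariants hold on every generated fibre", {
  fib <- generate_spread_fibres(spread_gen_params(n_clusters = 200, seed = 5))
  for (f in fib) {
    validate_spread_fibre(f)
    n <- nrow(f$tracks)
    g <- f$tracks$start_kb[-1] - f$tracks$end_kb[-n]
    same <- f$truth_cluster_ids[-1] == f$truth_cluster_ids[-n]
    expect_true(all(g[same] < 100))   # intra-cluster gaps below the bound
    expect_true(all(g[!same] > 100))  # spacers above it
  }
})

test_that("same seed gives bit-identical output", {
  p <- spread_gen_params(n_clusters = 20, seed = 99)
  expect_identical(generate_spread_fibres(p), generate_spread_fibres(p))
  p2 <- spread_gen_params(n_clusters = 20, seed = 100)
  expect_false(identical(generate_spread_fibres(p),
                         generate_spread_fibres(p2)))
})

test_that("active fraction of the default composition is near 12%", {
  p <- spread_gen_params(n_clusters = 100, clusters_per_fibre = 100, seed = 13)
  fib <- generate_spread_fibres(p)
  expect_lt(abs(active_fraction(fib) - 0.12), 0.015)
})

test_that("negative-binomial mark option is overdispersed", {
  p1 <- spread_gen_params(n_clusters = 600, seed = 8)
  p2 <- spread_gen_params(n_clusters = 600, marks_dispersion = 0.5, seed = 8)
  v1 <- marks_per_track(generate_spread_fibres(p1))$transcripts
  v2 <- marks_per_track(generate_spread_fibres(p2))$transcripts
  expect_gt(v2$sd, v1$sd)
  expect_lt(abs(v2$mean - 0.7), 0.1)
})
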