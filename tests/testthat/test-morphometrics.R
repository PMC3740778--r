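test_that("micron/kilobase conversions follow the calibration", {
  cal <- spread_calibration(3.9)
  expect_equal(microns_to_kb(0, cal), 0)
  expect_equal(microns_to_kb(1, cal), 3.9)
  expect_equal(microns_to_kb(47.26 / 3.9, cal), 47.26)
  # round trip is the identity to floating tolerance
  x <- c(0.3, 1, 12.117, 80)
  expect_equal(kb_to_microns(microns_to_kb(x, cal), cal), x)
  expect_error(microns_to_kb(-1, cal), ">= 0")
  expect_error(microns_to_kb(1, list(kb_per_um = 3.9)), "spread_calibration")
})

test_that("calibration estimation recovers the spreading factor", {
  # single noise-free measurement
  cal <- estimate_calibration(47.26 / 3.9)
  expect_equal(cal$kb_per_um, 3.9, tolerance = 1e-12)
  # identical measurements: zero standard error
  cal <- estimate_calibration(rep(12.117, 7))
  expect_equal(cal$se, 0)
  # multiplicative noise: estimate within 2 se of the truth
  set.seed(31)
  m <- (47.26 / 3.9) * exp(rnorm(100, 0, 0.05))
  cal <- estimate_calibration(m)
  expect_lt(abs(cal$kb_per_um - 3.9), 2 * cal$se + 0.02)
  expect_error(estimate_calibration(numeric(0)), "at least one")
  expect_error(estimate_calibration(c(1, -2)), "positive")
})

test_that("lognormal MLE handles degenerate input and satisfies its identity", {
  f <- fit_lognormal(rep(4.2, 10))
  expect_equal(f$sigma_log, 0)
  expect_equal(f$arith_mean, 4.2)
  f <- fit_lognormal(exp(rnorm(500, 2.53, 0.6)))
  expect_equal(f$arith_mean, exp(f$mu_log + f$sigma_log^2 / 2))
  expect_error(fit_lognormal(c(1, -1, 2)), "positive")
  expect_error(fit_lognormal(3), "at least two")
})

test_that("lognormal MLE agrees with a brute-force likelihood grid search", {
  set.seed(17)
  x <- exp(rnorm(1000, 2.53, 0.6))
  fit <- fit_lognormal(x)
  # independent oracle: dense grid over (meanlog, sdlog)
  mus <- seq(2.3, 2.8, by = 0.004)
  sgs <- seq(0.4, 0.8, by = 0.004)
  ll <- outer(mus, sgs, Vectorize(function(m, s)
    sum(dlnorm(x, m, s, log = TRUE))))
  best <- arrayInd(which.max(ll), dim(ll))
  expect_lt(abs(fit$mu_log - mus[best[1]]), 0.004)
  expect_lt(abs(fit$sigma_log - sgs[best[2]]), 0.004)
})

test_that("cluster detection applies the strict maximum-gap rule", {
  # one track: below min_tracks
  expect_equal(nrow(detect_clusters(make_fibre(0, 10))), 0)
  # gaps 50,50,150,50 over 5 tracks of 10: clusters of 3 and 2
  s <- c(0, 60, 120, 280, 340); e <- s + 10
  cl <- detect_clusters(make_fibre(s, e))
  expect_equal(cl$n_tus, c(3L, 2L))
  expect_equal(cl$span_kb, c(130, 70))
  # gap of exactly 100 does not join tracks (strict inequality)
  cl <- detect_clusters(make_fibre(c(0, 110), c(10, 120)))
  expect_equal(nrow(cl), 0)
  cl <- detect_clusters(make_fibre(c(0, 109.999), c(10, 120)))
  expect_equal(nrow(cl), 1)
  # unsorted or overlapping input is rejected
  bad <- make_fibre(c(50, 0), c(60, 10))
  expect_error(detect_clusters(bad), "unsorted|overlap")
})

test_that("cluster statistics summarise spans, TUs and marks", {
  # single closed-form cluster: 8 tracks of 15 Kb with 30 Kb gaps
  s <- cumsum(c(0, rep(45, 7))); e <- s + 15
  fib <- make_fibre(s, e)
  cl <- detect_clusters(fib)
  st <- cluster_statistics(cl, list(fib))
  expect_equal(st$n_clusters, 1)
  expect_equal(unname(st$span_kb["mean"]), 330)
  expect_equal(unname(st$tus["mean"]), 8)
  # empty input: a valid "no clusters" result, not an error
  st0 <- cluster_statistics(detect_clusters(make_fibre(0, 10)))
  expect_equal(st0$n_clusters, 0)
  expect_true(is.na(st0$span_kb["mean"]))
})

test_that("cluster statistics are invariant to input order", {
  fib <- generate_spread_fibres(spread_gen_params(n_clusters = 30, seed = 21))
  cl <- detect_clusters(fib)
  st1 <- cluster_statistics(cl)
  st2 <- cluster_statistics(cl[rev(seq_len(nrow(cl))), ])
  expect_equal(st1$span_kb, st2$span_kb)
  expect_equal(st1$tus, st2$tus)
})

test_that("marks per track count by containment and report orphans", {
  fib <- make_fibre(c(0, 20, 40), c(10, 30, 50),
                    tmarks = c(25, 42, 45))   # counts 0,1,2
  mk <- marks_per_track(fib)
  expect_equal(mk$transcripts$mean, 1)
  expect_equal(mk$transcripts$sd, 1)
  expect_equal(unname(mk$orphans["transcripts"]), 0L)
  # no marks at all
  mk0 <- marks_per_track(make_fibre(0, 10))
  expect_equal(mk0$transcripts$mean, 0)
  expect_equal(mk0$transcripts$sd, 0)
  # a mark in a gap is counted as an orphan, not dropped
  fib2 <- list(structure(list(
    fibre_id = "f", tracks = data.frame(start_kb = c(0, 20),
                                        end_kb = c(10, 30)),
    transcript_marks = c(5, 15), polii_marks = numeric(0),
    truth_cluster_ids = c(1L, 1L), fibre_length_kb = 100),
    class = "spread_fibre"))
  mk2 <- marks_per_track(fib2)
  expect_equal(unname(mk2$orphans["transcripts"]), 1L)
  expect_equal(mk2$transcripts$mean, 0.5)
})

test_that("detected clusters equal generator truth on truncated-gap fibres", {
  fib <- generate_spread_fibres(spread_gen_params(n_clusters = 150, seed = 33))
  cl <- detect_clusters(fib)
  truth <- attr(fib, "truth")
  expect_equal(nrow(cl), nrow(truth))
  o1 <- order(cl$fibre_id, cl$start_kb)
  o2 <- order(truth$fibre_id, truth$start_kb)
  expect_equal(cl$fibre_id[o1], truth$fibre_id[o2])
  expect_equal(cl$start_kb[o1], truth$start_kb[o2])
  expect_equal(cl$end_kb[o1], truth$end_kb[o2])
  expect_equal(cl$n_tus[o1], truth$n_tracks[o2])
})
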