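#' Spreading calibration (kilobases per micron)
#'
#' Constructs a calibration object converting physical lengths measured on
#' chromatin spreads (microns) into genomic lengths (Kb).
#'
#' @param kb_per_um positive conversion factor, Kb per micron.
#' @param se standard error of the factor (0 when unknown/exact).
#' @param n number of measurements behind the estimate.
#' @return An object of class `spread_calibration`.
#' @export
spread_calibration <- function(kb_per_um, se = 0, n = 0L) {
  if (!is.numeric(kb_per_um) || length(kb_per_um) != 1 || kb_per_um <= 0)
    stop("kb_per_um must be a single positive number", call. = FALSE)
  if (se < 0) stop("se must be >= 0", call. = FALSE)
  structure(list(kb_per_um = kb_per_um, se = se, n = as.integer(n)),
            class = "spread_calibration")
}

#' @export
print.spread_calibration <- function(x, ...) {
  cat(sprintf("Spreading calibration: %.4g +/- %.2g Kb/um (n = %d)\n",
              x$kb_per_um, x$se, x$n))
  invisible(x)
}

#' Estimate the spreading calibration from probe measurements
#'
#' Given repeated micron-length measurements of a hybridised DNA probe of
#' known genomic size, estimates the spreading factor as
#' `probe_kb / mean(measured_um)`. The standard error is propagated from the
#' standard error of the mean measurement (delta method).
#'
#' @param measured_um positive micron lengths of the probe signal.
#' @param probe_kb genomic size of the probe in Kb (default 47.26).
#' @return A [spread_calibration()] object.
#' @examples
#' estimate_calibration(rep(47.26 / 3.9, 5))  # noise-free: 3.9 Kb/um, se 0
#' @export
estimate_calibration <- function(measured_um, probe_kb = 47.26) {
  if (length(measured_um) < 1)
    stop("at least one measurement is required", call. = FALSE)
  if (any(!is.finite(measured_um)) || any(measured_um <= 0))
    stop("all measurements must be positive and finite", call. = FALSE)
  if (probe_kb <= 0) stop("probe_kb must be > 0", call. = FALSE)
  m <- mean(measured_um)
  n <- length(measured_um)
  se_mean <- if (n > 1) stats::sd(measured_um) / sqrt(n) else 0
  # d/dm (probe/m) = -probe/m^2
  spread_calibration(probe_kb / m, se = probe_kb * se_mean / m^2, n = n)
}

#' Convert micron lengths to kilobases
#'
#' @param length_um non-negative lengths in microns.
#' @param cal a [spread_calibration()].
#' @return Lengths in Kb.
#' @export
microns_to_kb <- function(length_um, cal) {
  if (!inherits(cal, "spread_calibration"))
    stop("cal must be a spread_calibration", call. = FALSE)
  if (any(length_um < 0)) stop("lengths must be >= 0", call. = FALSE)
  length_um * cal$kb_per_um
}

#' Convert kilobase lengths to microns
#'
#' Inverse of [microns_to_kb()].
#' @param length_kb non-negative lengths in Kb.
#' @inheritParams microns_to_kb
#' @return Lengths in microns.
#' @export
kb_to_microns <- function(length_kb, cal) {
  if (!inherits(cal, "spread_calibration"))
    stop("cal must be a spread_calibration", call. = FALSE)
  if (any(length_kb < 0)) stop("lengths must be >= 0", call. = FALSE)
  length_kb / cal$kb_per_um
}

#' Maximum-likelihood lognormal fit
#'
#' Fits a lognormal distribution to positive lengths by maximum likelihood:
#' `mu_log` is the mean of the logs and `sigma_log` the population (MLE)
#' standard deviation of the logs. The arithmetic mean of the fitted
#' distribution, `exp(mu_log + sigma_log^2 / 2)`, is reported alongside.
#'
#' @param values_kb positive lengths (at least two).
#' @return An object of class `lognormal_fit` with fields `mu_log`,
#'   `sigma_log`, `arith_mean`, `n`, `log_likelihood`, `sample_mean`.
#' @examples
#' fit_lognormal(rlnorm(1000, log(15) - 0.18, 0.6))
#' @export
fit_lognormal <- function(values_kb) {
  if (length(values_kb) < 2) stop("need at least two values", call. = FALSE)
  if (any(!is.finite(values_kb)) || any(values_kb <= 0))
    stop("all values must be positive and finite", call. = FALSE)
  lg <- log(values_kb)
  mu <- mean(lg)
  sg <- sqrt(mean((lg - mu)^2))
  ll <- if (sg > 0) sum(stats::dlnorm(values_kb, mu, sg, log = TRUE)) else Inf
  structure(list(mu_log = mu, sigma_log = sg,
                 arith_mean = exp(mu + sg^2 / 2),
                 n = length(values_kb), log_likelihood = ll,
                 sample_mean = mean(values_kb)),
            class = "lognormal_fit")
}

#' @export
print.lognormal_fit <- function(x, ...) {
  cat(sprintf(
    "Lognormal MLE: meanlog %.4g, sdlog %.4g; arithmetic mean %.4g (n = %d)\n",
    x$mu_log, x$sigma_log, x$arith_mean, x$n))
  invisible(x)
}

#' Detect clusters of acetylated tracks
#'
#' Applies the maximum-gap cluster rule: a cluster is a maximal run of at
#' least `min_tracks` consecutive tracks whose gaps (next start minus
#' previous end) are all *strictly* below `max_gap_kb`. Tracks separated by
#' exactly `max_gap_kb` or more are split. Clusters never span fibres.
#'
#' @param fibres a `spread_fibre`, a `spread_fibre_set`, or a list of
#'   `spread_fibre` objects; tracks must be sorted and non-overlapping.
#' @param max_gap_kb gap bound in Kb (default 100).
#' @param min_tracks minimum tracks per cluster (default 2).
#' @return A data frame of class `track_clusters` with one row per cluster:
#'   `fibre_id`, `cluster_id`, `first_track`, `last_track`, `n_tus`,
#'   `start_kb`, `end_kb`, `span_kb`, and a list column `members` of track
#'   indices within the fibre.
#' @examples
#' fib <- generate_spread_fibres(spread_gen_params(n_clusters = 3, seed = 2))
#' detect_clusters(fib)
#' @export
detect_clusters <- function(fibres, max_gap_kb = 100, min_tracks = 2L) {
  if (inherits(fibres, "spread_fibre")) fibres <- list(fibres)
  if (max_gap_kb <= 0) stop("max_gap_kb must be > 0", call. = FALSE)
  if (min_tracks < 1) stop("min_tracks must be >= 1", call. = FALSE)
  rows <- list()
  for (f in fibres) {
    validate_spread_fibre(f)
    tr <- f$tracks
    n <- nrow(tr)
    if (n == 0) next
    gap_ok <- if (n > 1) (tr$start_kb[-1] - tr$end_kb[-n]) < max_gap_kb else logical(0)
    run_id <- cumsum(c(1L, as.integer(!gap_ok)))
    cid <- 0L
    for (r in unique(run_id)) {
      idx <- which(run_id == r)
      if (length(idx) < min_tracks) next
      cid <- cid + 1L
      rows[[length(rows) + 1L]] <- data.frame(
        fibre_id = f$fibre_id, cluster_id = cid,
        first_track = idx[1], last_track = idx[length(idx)],
        n_tus = length(idx),
        start_kb = tr$start_kb[idx[1]], end_kb = tr$end_kb[idx[length(idx)]],
        span_kb = tr$end_kb[idx[length(idx)]] - tr$start_kb[idx[1]])
      rows[[length(rows)]]$members <- I(list(idx))
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(fibre_id = character(0), cluster_id = integer(0),
               first_track = integer(0), last_track = integer(0),
               n_tus = integer(0), start_kb = numeric(0), end_kb = numeric(0),
               span_kb = numeric(0), members = I(list()))
  class(out) <- c("track_clusters", "data.frame")
  out
}

summ5 <- function(x) {
  if (!length(x)) return(c(mean = NA_real_, sd = NA_real_,
                           min = NA_real_, max = NA_real_))
  c(mean = mean(x), sd = if (length(x) > 1) stats::sd(x) else 0,
    min = min(x), max = max(x))
}

#' Summary statistics of detected clusters
#'
#' Summarises cluster spans and TU counts (mean, sample SD, min, max) and,
#' when the originating fibres are supplied, mark counts per track within
#' clustered tracks.
#'
#' @param clusters a `track_clusters` data frame from [detect_clusters()].
#' @param fibres optional fibre set for per-track mark summaries.
#' @return An object of class `cluster_stats`. With an empty cluster list a
#'   valid object with `n_clusters = 0` and `NA` summaries is returned
#'   rather than an error.
#' @export
cluster_statistics <- function(clusters, fibres = NULL) {
  out <- list(n_clusters = nrow(clusters),
              tus = summ5(clusters$n_tus),
              span_kb = summ5(clusters$span_kb),
              marks = NULL)
  if (!is.null(fibres) && nrow(clusters)) {
    by_f <- stats::setNames(fibres, vapply(fibres, `[[`, "", "fibre_id"))
    tcounts <- pcounts <- integer(0)
    for (i in seq_len(nrow(clusters))) {
      f <- by_f[[clusters$fibre_id[i]]]
      idx <- clusters$members[[i]]
      cnt <- count_marks_in_tracks(f)
      tcounts <- c(tcounts, cnt$transcripts[idx])
      pcounts <- c(pcounts, cnt$polii[idx])
    }
    out$marks <- list(transcripts = summ5(tcounts), polii = summ5(pcounts))
  }
  class(out) <- "cluster_stats"
  out
}

#' @export
print.cluster_stats <- function(x, ...) {
  cat(sprintf("Cluster statistics over %d clusters\n", x$n_clusters))
  if (x$n_clusters) {
    cat(sprintf("  TUs/cluster: %.3g +/- %.3g (range %g-%g)\n",
                x$tus["mean"], x$tus["sd"], x$tus["min"], x$tus["max"]))
    cat(sprintf("  span: %.4g +/- %.3g Kb (range %.4g-%.4g)\n",
                x$span_kb["mean"], x$span_kb["sd"],
                x$span_kb["min"], x$span_kb["max"]))
    if (!is.null(x$marks))
      cat(sprintf("  marks/track: %.3g transcripts, %.3g pol II\n",
                  x$marks$transcripts["mean"], x$marks$polii["mean"]))
  }
  invisible(x)
}

## per-track containment counts for one fibre (half-open intervals)
count_marks_in_tracks <- function(fibre) {
  tr <- fibre$tracks
  n <- nrow(tr)
  assign_counts <- function(pos) {
    cnt <- integer(n)
    orph <- 0L
    if (length(pos) && n) {
      i <- findInterval(pos, tr$start_kb)
      inside <- i >= 1 & pos < tr$end_kb[pmax(i, 1)]
      tab <- tabulate(i[inside], nbins = n)
      cnt <- tab
      orph <- sum(!inside)
    } else orph <- length(pos)
    list(counts = cnt, orphans = orph)
  }
  tc <- assign_counts(fibre$transcript_marks)
  pc <- assign_counts(fibre$polii_marks)
  list(transcripts = tc$counts, polii = pc$counts,
       orphans = c(transcripts = tc$orphans, polii = pc$orphans))
}

#' Marks per track
#'
#' Counts transcript and polymerase marks per track by half-open interval
#' containment and summarises them (mean, sample SD, count histogram).
#' Marks falling outside every track are reported as orphans, never
#' silently dropped.
#'
#' @param fibres a `spread_fibre`, `spread_fibre_set`, or list of fibres.
#' @return An object of class `marks_per_track`: per mark type `mean`,
#'   `sd`, `histogram` (a table of counts), plus `n_tracks` and `orphans`.
#' @export
marks_per_track <- function(fibres) {
  if (inherits(fibres, "spread_fibre")) fibres <- list(fibres)
  tcounts <- pcounts <- integer(0)
  orph <- c(transcripts = 0L, polii = 0L)
  for (f in fibres) {
    cnt <- count_marks_in_tracks(f)
    tcounts <- c(tcounts, cnt$transcripts)
    pcounts <- c(pcounts, cnt$polii)
    orph <- orph + cnt$orphans
  }
  one <- function(x) list(
    mean = if (length(x)) mean(x) else 0,
    sd = if (length(x) > 1) stats::sd(x) else 0,
    histogram = table(x))
  structure(list(transcripts = one(tcounts), polii = one(pcounts),
                 n_tracks = length(tcounts), orphans = orph),
            class = "marks_per_track")
}

#' @export
print.marks_per_track <- function(x, ...) {
  cat(sprintf("Marks per track over %d tracks\n", x$n_tracks))
  cat(sprintf("  transcripts: %.3g +/- %.3g\n", x$transcripts$mean, x$transcripts$sd))
  cat(sprintf("  P-RNA pol II: %.3g +/- %.3g\n", x$polii$mean, x$polii$sd))
  if (any(x$orphans > 0))
    cat(sprintf("  orphan marks outside tracks: %d transcripts, %d pol II\n",
                x$orphans["transcripts"], x$orphans["polii"]))
  invisible(x)
}
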