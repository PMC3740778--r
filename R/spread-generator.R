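#' Parameters for the chromatin-spread fibre generator
#'
#' Bundles and validates the parameters of the synthetic chromatin-spread
#' model: lognormal H4K16ac track lengths and intra-cluster gaps
#' (parameterised by their *arithmetic* means), a normal-rounded number of
#' transcription units (TUs) per cluster, lognormal inter-cluster spacers,
#' Poisson mark counts per track, and the micron-to-kilobase spreading
#' calibration.
#'
#' Lognormal components are stored as (meanlog, sdlog) pairs derived so that
#' the arithmetic mean equals the requested `*_mean_kb`
#' (`meanlog = log(mean) - sdlog^2 / 2`). Intra-cluster gaps are
#' rejection-truncated below `max_gap_kb` of the cluster rule (100 Kb) so
#' that generated clusters are exactly recoverable by [detect_clusters()];
#' spacers are truncated above it. The default spacer mean (670 Kb) makes
#' the genome-wide active fraction of the default composition
#' `8 * 15 / (8 * 15 + 7 * 30 + 670) = 12%`.
#'
#' @param track_mean_kb arithmetic mean track length, Kb (default 15).
#' @param track_sigma_log lognormal log-scale SD of track lengths (default 0.6).
#' @param gap_mean_kb arithmetic mean intra-cluster gap, Kb (default 30).
#' @param gap_sigma_log lognormal log-scale SD of gaps (default 0.6).
#' @param tus_per_cluster_mean,tus_per_cluster_sd mean and SD of the normal
#'   draw (rounded to integer) for tracks per cluster (defaults 8 and 2).
#' @param min_tus_per_cluster lower truncation for tracks per cluster,
#'   at least 2 (default 2).
#' @param spacer_mean_kb arithmetic mean inter-cluster spacer, Kb (default 670).
#' @param spacer_sigma_log lognormal log-scale SD of spacers (default 0.6).
#' @param transcripts_per_track_rate,polii_per_track_rate Poisson rates of
#'   nascent-transcript and phosphorylated-polymerase marks per track
#'   (defaults 0.7 and 0.8).
#' @param marks_dispersion optional negative-binomial size parameter; when
#'   finite, mark counts are drawn negative-binomial with the given rate as
#'   mean (overdispersed); the default `Inf` is plain Poisson.
#' @param calibration_kb_per_um spreading calibration, Kb per micron
#'   (default 3.9).
#' @param calibration_noise_cv multiplicative measurement noise CV for
#'   simulated calibration measurements (default 0.05).
#' @param max_gap_kb cluster-definition bound, Kb (default 100): gaps are
#'   truncated strictly below it, spacers strictly above it.
#' @param clusters_per_fibre number of clusters laid on each fibre
#'   (default 10); the last fibre may carry fewer.
#' @param n_clusters total number of clusters to generate.
#' @param seed integer seed; required for [generate_spread_fibres()].
#'
#' @return An object of class `spread_gen_params` (a validated list).
#' @seealso [generate_spread_fibres()]
#' @export
spread_gen_params <- function(track_mean_kb = 15, track_sigma_log = 0.6,
                              gap_mean_kb = 30, gap_sigma_log = 0.6,
                              tus_per_cluster_mean = 8, tus_per_cluster_sd = 2,
                              min_tus_per_cluster = 2L,
                              spacer_mean_kb = 670, spacer_sigma_log = 0.6,
                              transcripts_per_track_rate = 0.7,
                              polii_per_track_rate = 0.8,
                              marks_dispersion = Inf,
                              calibration_kb_per_um = 3.9,
                              calibration_noise_cv = 0.05,
                              max_gap_kb = 100,
                              clusters_per_fibre = 10L,
                              n_clusters = 100L,
                              seed = NULL) {
  stop_if <- function(cond, msg) if (cond) stop(msg, call. = FALSE)
  stop_if(!is.numeric(track_mean_kb) || track_mean_kb <= 0,
          "track_mean_kb must be a positive length in Kb")
  stop_if(!is.numeric(gap_mean_kb) || gap_mean_kb <= 0,
          "gap_mean_kb must be a positive length in Kb")
  stop_if(!is.numeric(spacer_mean_kb) || spacer_mean_kb <= 0,
          "spacer_mean_kb must be a positive length in Kb")
  stop_if(track_sigma_log < 0 || gap_sigma_log < 0 || spacer_sigma_log < 0,
          "lognormal sigma_log parameters must be >= 0")
  stop_if(min_tus_per_cluster < 2, "min_tus_per_cluster must be >= 2")
  stop_if(tus_per_cluster_mean <= 0 || tus_per_cluster_sd < 0,
          "tus_per_cluster_mean must be > 0 and sd >= 0")
  stop_if(transcripts_per_track_rate < 0 || polii_per_track_rate < 0,
          "mark rates must be >= 0")
  stop_if(calibration_kb_per_um <= 0, "calibration_kb_per_um must be > 0")
  stop_if(calibration_noise_cv < 0, "calibration_noise_cv must be >= 0")
  stop_if(max_gap_kb <= 0, "max_gap_kb must be > 0")
  stop_if(gap_mean_kb >= max_gap_kb,
          "gap_mean_kb must lie below max_gap_kb (gaps are truncated there)")
  stop_if(spacer_mean_kb <= max_gap_kb,
          "spacer_mean_kb must lie above max_gap_kb (spacers are truncated there)")
  stop_if(clusters_per_fibre < 1, "clusters_per_fibre must be >= 1")
  stop_if(n_clusters < 0, "n_clusters must be >= 0")

  p <- list(track_mean_kb = track_mean_kb, track_sigma_log = track_sigma_log,
            gap_mean_kb = gap_mean_kb, gap_sigma_log = gap_sigma_log,
            tus_per_cluster_mean = tus_per_cluster_mean,
            tus_per_cluster_sd = tus_per_cluster_sd,
            min_tus_per_cluster = as.integer(min_tus_per_cluster),
            spacer_mean_kb = spacer_mean_kb, spacer_sigma_log = spacer_sigma_log,
            transcripts_per_track_rate = transcripts_per_track_rate,
            polii_per_track_rate = polii_per_track_rate,
            marks_dispersion = marks_dispersion,
            calibration_kb_per_um = calibration_kb_per_um,
            calibration_noise_cv = calibration_noise_cv,
            max_gap_kb = max_gap_kb,
            clusters_per_fibre = as.integer(clusters_per_fibre),
            n_clusters = as.integer(n_clusters),
            seed = if (is.null(seed)) NULL else as.integer(seed))
  # (meanlog, sdlog) pairs chosen so the arithmetic mean is the stated one
  p$track_meanlog  <- log(track_mean_kb)  - track_sigma_log^2 / 2
  p$gap_meanlog    <- log(gap_mean_kb)    - gap_sigma_log^2 / 2
  p$spacer_meanlog <- log(spacer_mean_kb) - spacer_sigma_log^2 / 2
  class(p) <- "spread_gen_params"
  p
}

#' @export
print.spread_gen_params <- function(x, ...) {
  cat("Chromatin-spread generator parameters\n")
  cat(sprintf("  tracks : lognormal, arithmetic mean %.3g Kb (sdlog %.3g)\n",
              x$track_mean_kb, x$track_sigma_log))
  cat(sprintf("  gaps   : lognormal, arithmetic mean %.3g Kb (sdlog %.3g), truncated < %g Kb\n",
              x$gap_mean_kb, x$gap_sigma_log, x$max_gap_kb))
  cat(sprintf("  spacers: lognormal, arithmetic mean %.3g Kb, truncated > %g Kb\n",
              x$spacer_mean_kb, x$max_gap_kb))
  cat(sprintf("  TUs/cluster: round(N(%.3g, %.3g)), min %d\n",
              x$tus_per_cluster_mean, x$tus_per_cluster_sd, x$min_tus_per_cluster))
  cat(sprintf("  marks/track: %.3g transcripts, %.3g pol II%s\n",
              x$transcripts_per_track_rate, x$polii_per_track_rate,
              if (is.finite(x$marks_dispersion))
                sprintf(" (negative binomial, size %.3g)", x$marks_dispersion)
              else " (Poisson)"))
  cat(sprintf("  calibration: %.3g Kb/um (noise CV %.3g)\n",
              x$calibration_kb_per_um, x$calibration_noise_cv))
  cat(sprintf("  layout: %d clusters, %d per fibre, seed %s\n",
              x$n_clusters, x$clusters_per_fibre,
              if (is.null(x$seed)) "<unset>" else x$seed))
  invisible(x)
}

## lognormal draws truncated by rejection; the retained distribution is the
## conditional lognormal, so the realised mean shifts slightly from the
## unconditional one (by ~1 Kb at the default gap parameters)
rlnorm_below <- function(n, meanlog, sdlog, upper) {
  out <- numeric(n)
  need <- seq_len(n)
  while (length(need)) {
    draw <- stats::rlnorm(length(need), meanlog, sdlog)
    ok <- draw < upper
    out[need[ok]] <- draw[ok]
    need <- need[!ok]
  }
  out
}

rlnorm_above <- function(n, meanlog, sdlog, lower) {
  out <- numeric(n)
  need <- seq_len(n)
  while (length(need)) {
    draw <- stats::rlnorm(length(need), meanlog, sdlog)
    ok <- draw > lower
    out[need[ok]] <- draw[ok]
    need <- need[!ok]
  }
  out
}

rmarks <- function(n, rate, dispersion) {
  if (rate == 0) return(integer(n))
  if (is.finite(dispersion)) stats::rnbinom(n, size = dispersion, mu = rate)
  else stats::rpois(n, rate)
}

new_spread_fibre <- function(fibre_id, tracks, transcript_marks, polii_marks,
                             truth_cluster_ids, fibre_length_kb) {
  structure(list(fibre_id = fibre_id, tracks = tracks,
                 transcript_marks = transcript_marks,
                 polii_marks = polii_marks,
                 truth_cluster_ids = truth_cluster_ids,
                 fibre_length_kb = fibre_length_kb),
            class = "spread_fibre")
}

#' Validate a spread fibre
#'
#' Checks the fibre invariants: tracks sorted and non-overlapping with
#' positive lengths, and every mark inside exactly one track.
#'
#' @param fibre a `spread_fibre`.
#' @return Invisibly `TRUE`; otherwise an error describing the violation.
#' @export
validate_spread_fibre <- function(fibre) {
  tr <- fibre$tracks
  if (nrow(tr)) {
    if (any(tr$end_kb <= tr$start_kb))
      stop("fibre ", fibre$fibre_id, ": track with non-positive length", call. = FALSE)
    if (nrow(tr) > 1 && any(tr$start_kb[-1] < tr$end_kb[-nrow(tr)]))
      stop("fibre ", fibre$fibre_id, ": tracks unsorted or overlapping", call. = FALSE)
  }
  in_track <- function(pos) {
    i <- findInterval(pos, tr$start_kb)
    i >= 1 & pos < tr$end_kb[pmax(i, 1)]
  }
  for (m in c("transcript_marks", "polii_marks")) {
    pos <- fibre[[m]]
    if (length(pos) && !all(in_track(pos)))
      stop("fibre ", fibre$fibre_id, ": ", m, " outside all tracks", call. = FALSE)
  }
  invisible(TRUE)
}

#' @export
print.spread_fibre <- function(x, ...) {
  cat(sprintf("<spread_fibre %s> %d tracks, %d clusters, %d+%d marks, %.1f Kb\n",
              x$fibre_id, nrow(x$tracks),
              length(unique(x$truth_cluster_ids)),
              length(x$transcript_marks), length(x$polii_marks),
              x$fibre_length_kb))
  invisible(x)
}

#' Generate synthetic chromatin-spread fibres
#'
#' Lays clusters of H4K16ac tracks along fibres according to the calibrated
#' composition in `params`: within a cluster, lognormal track lengths
#' alternate with lognormal gaps truncated strictly below the cluster bound;
#' clusters are separated by lognormal spacers truncated strictly above it,
#' one spacer following every cluster (so a fibre is a whole number of
#' cluster+spacer units and the genome-wide active fraction is well defined).
#' Each track receives Poisson-distributed transcript and polymerase marks
#' placed uniformly within it.
#'
#' @param params a [spread_gen_params()] object with a non-`NULL` seed.
#' @return An object of class `spread_fibre_set`: a list of `spread_fibre`
#'   objects with attributes `params` and `truth` (a per-cluster data frame
#'   with fibre id, cluster id, start, end, span and track count).
#' @examples
#' fib <- generate_spread_fibres(spread_gen_params(n_clusters = 5, seed = 1))
#' summary(track_lengths(fib))
#' @export
generate_spread_fibres <- function(params) {
  if (!inherits(params, "spread_gen_params"))
    stop("params must be built with spread_gen_params()", call. = FALSE)
  if (is.null(params$seed))
    stop("params$seed is required: generation must be reproducible", call. = FALSE)
  set.seed(params$seed)

  n <- params$n_clusters
  fibres <- list()
  truth <- list()
  if (n > 0) {
    fibre_of <- rep(seq_len(ceiling(n / params$clusters_per_fibre)),
                    each = params$clusters_per_fibre)[seq_len(n)]
    for (f in unique(fibre_of)) {
      k <- sum(fibre_of == f)
      fid <- sprintf("fibre_%03d", f)
      cursor <- 0
      starts <- ends <- numeric(0)
      cl_ids <- integer(0)
      tmarks <- pmarks <- numeric(0)
      for (cl in seq_len(k)) {
        ntr <- max(params$min_tus_per_cluster,
                   as.integer(round(stats::rnorm(1, params$tus_per_cluster_mean,
                                                 params$tus_per_cluster_sd))))
        len <- stats::rlnorm(ntr, params$track_meanlog, params$track_sigma_log)
        gap <- if (ntr > 1)
          rlnorm_below(ntr - 1, params$gap_meanlog, params$gap_sigma_log,
                       params$max_gap_kb) else numeric(0)
        s <- cursor + cumsum(c(0, len[-ntr] + gap))
        e <- s + len
        starts <- c(starts, s); ends <- c(ends, e)
        cl_ids <- c(cl_ids, rep.int(cl, ntr))
        nt <- rmarks(ntr, params$transcripts_per_track_rate, params$marks_dispersion)
        np <- rmarks(ntr, params$polii_per_track_rate, params$marks_dispersion)
        tmarks <- c(tmarks, stats::runif(sum(nt), rep(s, nt), rep(e, nt)))
        pmarks <- c(pmarks, stats::runif(sum(np), rep(s, np), rep(e, np)))
        truth[[length(truth) + 1L]] <- data.frame(
          fibre_id = fid, cluster_id = cl, start_kb = s[1], end_kb = e[ntr],
          span_kb = e[ntr] - s[1], n_tracks = ntr)
        cursor <- e[ntr] + rlnorm_above(1, params$spacer_meanlog,
                                        params$spacer_sigma_log, params$max_gap_kb)
      }
      fibres[[length(fibres) + 1L]] <- new_spread_fibre(
        fid, data.frame(start_kb = starts, end_kb = ends),
        sort(tmarks), sort(pmarks), cl_ids, fibre_length_kb = cursor)
    }
  }
  structure(fibres,
            params = params,
            truth = if (length(truth)) do.call(rbind, truth) else
              data.frame(fibre_id = character(0), cluster_id = integer(0),
                         start_kb = numeric(0), end_kb = numeric(0),
                         span_kb = numeric(0), n_tracks = integer(0)),
            class = "spread_fibre_set")
}

#' @export
print.spread_fibre_set <- function(x, ...) {
  tr <- attr(x, "truth")
  cat(sprintf("<spread_fibre_set> %d fibres, %d clusters, %d tracks\n",
              length(x), nrow(tr), sum(tr$n_tracks)))
  invisible(x)
}

#' Track lengths of a fibre set
#'
#' @param fibres a `spread_fibre_set` (or list of `spread_fibre`).
#' @return Numeric vector of track lengths in Kb, in fibre order.
#' @export
track_lengths <- function(fibres) {
  unlist(lapply(fibres, function(f) f$tracks$end_kb - f$tracks$start_kb),
         use.names = FALSE)
}

#' Intra-cluster gap lengths of a fibre set
#'
#' Gaps between consecutive tracks that share a ground-truth cluster;
#' inter-cluster spacers are excluded.
#'
#' @inheritParams track_lengths
#' @return Numeric vector of gap lengths in Kb.
#' @export
intra_cluster_gaps <- function(fibres) {
  unlist(lapply(fibres, function(f) {
    n <- nrow(f$tracks)
    if (n < 2) return(numeric(0))
    g <- f$tracks$start_kb[-1] - f$tracks$end_kb[-n]
    same <- f$truth_cluster_ids[-1] == f$truth_cluster_ids[-n]
    g[same]
  }), use.names = FALSE)
}

#' Genome-wide active fraction of a fibre set
#'
#' Fraction of fibre length covered by H4K16ac tracks, the synthetic
#' analogue of the rod (active chromatin) proportion.
#'
#' @inheritParams track_lengths
#' @return Fraction in `[0, 1]`.
#' @export
active_fraction <- function(fibres) {
  act <- sum(vapply(fibres, function(f) sum(f$tracks$end_kb - f$tracks$start_kb), 0))
  tot <- sum(vapply(fibres, function(f) f$fibre_length_kb, 0))
  if (tot == 0) return(NA_real_)
  act / tot
}
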