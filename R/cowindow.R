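#' Parameters for the sliding-window co-expression test
#'
#' A window of `window_kb` is slid along each chromosome in steps of
#' `step_kb`; the test statistic per window is the number (or fraction) of
#' expressed genes whose midpoints fall in it, compared against a
#' permutation null in which expressed labels are shuffled among gene
#' positions. A window is called significant when the empirical CDF of the
#' observed statistic under the null exceeds `significance_quantile`
#' (the "p > 0.95" reading of significance).
#'
#' @param window_kb window width, Kb (default 500).
#' @param step_kb step, Kb (default 5); must not exceed `window_kb`.
#' @param n_permutations number of label permutations (default 1000).
#' @param significance_quantile call threshold on the empirical CDF
#'   (default 0.95).
#' @param permutation_scope `"per_chromosome"` (labels shuffled within each
#'   chromosome, preserving its expressed count) or `"genome_wide"`.
#' @param statistic `"count"` (default) or `"fraction"` of expressed genes
#'   in the window.
#' @param family_wise if `TRUE`, use the max-statistic null across windows
#'   of a chromosome (family-wise control); off by default.
#' @param seed integer seed for the permutations.
#' @return An object of class `cowindow_params`.
#' @export
cowindow_params <- function(window_kb = 500, step_kb = 5,
                            n_permutations = 1000L,
                            significance_quantile = 0.95,
                            permutation_scope = c("per_chromosome", "genome_wide"),
                            statistic = c("count", "fraction"),
                            family_wise = FALSE, seed = NULL) {
  if (window_kb <= 0 || step_kb <= 0) stop("window and step must be > 0", call. = FALSE)
  if (step_kb > window_kb) stop("step_kb must be <= window_kb", call. = FALSE)
  if (n_permutations < 1) stop("n_permutations must be >= 1", call. = FALSE)
  if (significance_quantile <= 0 || significance_quantile >= 1)
    stop("significance_quantile must be in (0, 1)", call. = FALSE)
  structure(list(window_kb = window_kb, step_kb = step_kb,
                 n_permutations = as.integer(n_permutations),
                 significance_quantile = significance_quantile,
                 permutation_scope = match.arg(permutation_scope),
                 statistic = match.arg(statistic),
                 family_wise = isTRUE(family_wise),
                 seed = if (is.null(seed)) NULL else as.integer(seed)),
            class = "cowindow_params")
}

#' Enumerate sliding windows along a chromosome
#'
#' Windows are `[k * step, k * step + window)` for `k = 0, 1, ...` while the
#' start lies inside the chromosome; windows running past the end are
#' truncated at the chromosome length.
#'
#' @param chrom_length_kb chromosome length, Kb.
#' @param params a [cowindow_params()].
#' @return Data frame with `start_kb`, `end_kb`.
#' @export
enumerate_windows <- function(chrom_length_kb, params = cowindow_params()) {
  if (chrom_length_kb <= 0) stop("chrom_length_kb must be > 0", call. = FALSE)
  starts <- seq(0, by = params$step_kb,
                length.out = ceiling(chrom_length_kb / params$step_kb))
  data.frame(start_kb = starts,
             end_kb = pmin(starts + params$window_kb, chrom_length_kb))
}

## expressed-midpoint counts per window; mids must be sorted
window_counts <- function(mids_sorted, starts, ends) {
  eps <- 1e-9
  findInterval(ends - eps, mids_sorted) - findInterval(starts - eps, mids_sorted)
}

#' Expressed-gene statistic of one window
#'
#' Counts expressed genes whose midpoint lies in the half-open window.
#'
#' @param window a list or one-row data frame with `start_kb`, `end_kb`.
#' @param genes a gene table (see [generate_expression_table()]); only rows
#'   of the relevant chromosome should be passed when several are present.
#' @return Integer count.
#' @export
window_statistic <- function(window, genes) {
  mids <- sort((genes$start_kb + genes$end_kb)[genes$expressed == 1] / 2)
  window_counts(mids, window$start_kb, window$end_kb)
}

#' Sliding-window permutation test for co-expression clustering
#'
#' For every window on every chromosome, computes the expressed-gene
#' statistic and an empirical CDF value against a permutation null in which
#' expressed labels are reassigned uniformly at random among gene positions
#' (within the configured scope). `empirical_p` is the fraction of
#' permutations whose statistic falls strictly below the observed one;
#' windows with `empirical_p > significance_quantile` are flagged
#' significant.
#'
#' @param genes a gene table with columns `chrom`, `start_kb`, `end_kb`,
#'   `expressed`.
#' @param params a [cowindow_params()] with a non-`NULL` seed.
#' @param chrom_length_kb chromosome length; by default the maximum gene
#'   end per chromosome, rounded up to the step.
#' @return A data frame of class `cowindow_result` with one row per window:
#'   `chrom`, `start_kb`, `end_kb`, `n_genes`, `n_expressed`,
#'   `null_quantile_count` (the `significance_quantile` quantile of the
#'   null statistic), `empirical_p`, `significant`.
#' @examples
#' pl <- data.frame(chrom = "chr1", start_kb = 4000, span_kb = 400,
#'                  n_genes_expressed = 8)
#' genes <- generate_expression_table(
#'   expr_gen_params(n_genes = 400, chrom_length_kb = 20000,
#'                   planted_clusters = pl, seed = 3))
#' res <- permutation_test(genes, cowindow_params(n_permutations = 200, seed = 4))
#' merge_significant(res)
#' @export
permutation_test <- function(genes, params = cowindow_params(),
                             chrom_length_kb = NULL) {
  if (!inherits(params, "cowindow_params"))
    stop("params must be built with cowindow_params()", call. = FALSE)
  if (is.null(params$seed))
    stop("params$seed is required: permutations must be reproducible", call. = FALSE)
  set.seed(params$seed)
  chroms <- sort(unique(genes$chrom))
  if (sum(genes$expressed == 1) == 0)
    warning("no expressed genes: every window is non-significant", call. = FALSE)

  mids_all <- (genes$start_kb + genes$end_kb) / 2
  genome_expr_n <- sum(genes$expressed == 1)

  res <- list()
  for (ch in chroms) {
    sel <- genes$chrom == ch
    mids <- mids_all[sel]
    expr <- genes$expressed[sel] == 1
    clen <- if (is.null(chrom_length_kb)) {
      ceiling(max(genes$end_kb[sel]) / params$step_kb) * params$step_kb
    } else chrom_length_kb
    win <- enumerate_windows(clen, params)
    ord <- order(mids)
    mids_sorted <- mids[ord]
    obs_cnt <- window_counts(sort(mids[expr]), win$start_kb, win$end_kb)
    tot_cnt <- window_counts(mids_sorted, win$start_kb, win$end_kb)
    stat_of <- function(cnt) if (params$statistic == "fraction")
      ifelse(tot_cnt > 0, cnt / tot_cnt, 0) else cnt
    obs <- stat_of(obs_cnt)

    n_expr <- if (params$permutation_scope == "per_chromosome") sum(expr)
              else genome_expr_n
    n_expr <- min(n_expr, length(mids))
    nw <- nrow(win)
    below <- numeric(nw)
    null_q <- numeric(nw)
    # accumulate strictly-below counts and the null quantile via a
    # per-window running store of permuted statistics
    perm_store <- matrix(0, nrow = params$n_permutations, ncol = nw)
    if (n_expr > 0 && length(mids) > 0) {
      for (b in seq_len(params$n_permutations)) {
        pm <- sort(sample(mids, n_expr))
        pc <- stat_of(window_counts(pm, win$start_kb, win$end_kb))
        if (params$family_wise) pc <- rep(max(pc), nw)
        perm_store[b, ] <- pc
        below <- below + (pc < obs)
      }
      null_q <- apply(perm_store, 2, stats::quantile,
                      probs = params$significance_quantile, names = FALSE)
    }
    emp_p <- below / params$n_permutations
    res[[ch]] <- data.frame(
      chrom = ch, start_kb = win$start_kb, end_kb = win$end_kb,
      n_genes = tot_cnt, n_expressed = obs_cnt,
      null_quantile_count = null_q, empirical_p = emp_p,
      significant = emp_p > params$significance_quantile,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  attr(out, "params") <- params
  class(out) <- c("cowindow_result", "data.frame")
  out
}

#' Merge significant windows into maximal regions
#'
#' Overlapping or exactly adjacent significant windows on the same
#' chromosome are merged into maximal intervals (the "blue line" regions).
#'
#' @param results a `cowindow_result` data frame.
#' @return Data frame with `chrom`, `start_kb`, `end_kb`, `n_windows`.
#' @export
merge_significant <- function(results) {
  sig <- results[results$significant, , drop = FALSE]
  out <- list()
  for (ch in unique(sig$chrom)) {
    s <- sig[sig$chrom == ch, , drop = FALSE]
    s <- s[order(s$start_kb), , drop = FALSE]
    cur_s <- s$start_kb[1]; cur_e <- s$end_kb[1]; k <- 1L
    for (i in seq_len(nrow(s))[-1]) {
      if (s$start_kb[i] <= cur_e) {           # overlap or adjacency
        cur_e <- max(cur_e, s$end_kb[i]); k <- k + 1L
      } else {
        out[[length(out) + 1L]] <- data.frame(chrom = ch, start_kb = cur_s,
                                              end_kb = cur_e, n_windows = k)
        cur_s <- s$start_kb[i]; cur_e <- s$end_kb[i]; k <- 1L
      }
    }
    out[[length(out) + 1L]] <- data.frame(chrom = ch, start_kb = cur_s,
                                          end_kb = cur_e, n_windows = k)
  }
  if (!length(out))
    return(data.frame(chrom = character(0), start_kb = numeric(0),
                      end_kb = numeric(0), n_windows = integer(0)))
  do.call(rbind, out)
}
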