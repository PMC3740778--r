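#' Parameters for the synthetic expression-table generator
#'
#' Describes a genome of identical chromosomes on which background genes are
#' scattered uniformly and expressed at a background rate, with optional
#' planted co-expression clusters: intervals into which a stated number of
#' additional, expressed genes are placed.
#'
#' @param n_genes number of background genes over the whole genome.
#' @param chrom_length_kb chromosome length in Kb.
#' @param n_chromosomes number of chromosomes (default 1).
#' @param planted_clusters data frame with columns `chrom`, `start_kb`,
#'   `span_kb`, `n_genes_expressed`, or `NULL` for none.
#' @param background_expressed_rate probability a background gene is
#'   expressed.
#' @param gene_length_kb fixed gene length (default 1 Kb); window membership
#'   is by midpoint, so only the midpoint matters downstream.
#' @param seed integer seed, required by [generate_expression_table()].
#' @return An object of class `expr_gen_params`.
#' @export
expr_gen_params <- function(n_genes = 2000L, chrom_length_kb = 100000,
                            n_chromosomes = 1L, planted_clusters = NULL,
                            background_expressed_rate = 0.02,
                            gene_length_kb = 1, seed = NULL) {
  if (n_genes < 0) stop("n_genes must be >= 0", call. = FALSE)
  if (chrom_length_kb <= 0) stop("chrom_length_kb must be > 0", call. = FALSE)
  if (n_chromosomes < 1) stop("n_chromosomes must be >= 1", call. = FALSE)
  if (background_expressed_rate < 0 || background_expressed_rate > 1)
    stop("background_expressed_rate must be in [0, 1]", call. = FALSE)
  if (!is.null(planted_clusters)) {
    need <- c("chrom", "start_kb", "span_kb", "n_genes_expressed")
    if (!all(need %in% names(planted_clusters)))
      stop("planted_clusters needs columns ", paste(need, collapse = ", "),
           call. = FALSE)
    if (any(planted_clusters$start_kb < 0) ||
        any(planted_clusters$start_kb + planted_clusters$span_kb > chrom_length_kb))
      stop("planted cluster extends outside the chromosome", call. = FALSE)
  }
  structure(list(n_genes = as.integer(n_genes),
                 chrom_length_kb = chrom_length_kb,
                 n_chromosomes = as.integer(n_chromosomes),
                 planted_clusters = planted_clusters,
                 background_expressed_rate = background_expressed_rate,
                 gene_length_kb = gene_length_kb,
                 seed = if (is.null(seed)) NULL else as.integer(seed)),
            class = "expr_gen_params")
}

#' Generate a synthetic gene expression table
#'
#' Background genes are placed uniformly along the chromosomes and expressed
#' independently at the background rate; each planted cluster contributes
#' its stated number of additional genes, uniformly within the cluster
#' interval and all marked expressed.
#'
#' @param params an [expr_gen_params()] object with a non-`NULL` seed.
#' @return A data frame (`gene_table`) with columns `chrom`, `start_kb`,
#'   `end_kb`, `gene_id`, `expressed` (0/1) and `planted` (logical),
#'   sorted by chromosome and start.
#' @examples
#' pl <- data.frame(chrom = "chr1", start_kb = 2000, span_kb = 500,
#'                  n_genes_expressed = 8)
#' genes <- generate_expression_table(
#'   expr_gen_params(n_genes = 500, chrom_length_kb = 10000,
#'                   planted_clusters = pl, seed = 7))
#' table(genes$expressed)
#' @export
generate_expression_table <- function(params) {
  if (!inherits(params, "expr_gen_params"))
    stop("params must be built with expr_gen_params()", call. = FALSE)
  if (is.null(params$seed))
    stop("params$seed is required: generation must be reproducible", call. = FALSE)
  set.seed(params$seed)
  chroms <- sprintf("chr%d", seq_len(params$n_chromosomes))
  gl <- params$gene_length_kb
  bg_chrom <- sample(chroms, params$n_genes, replace = TRUE)
  bg_start <- stats::runif(params$n_genes, 0, params$chrom_length_kb - gl)
  bg_expr <- stats::rbinom(params$n_genes, 1, params$background_expressed_rate)
  genes <- data.frame(chrom = bg_chrom, start_kb = bg_start,
                      end_kb = bg_start + gl,
                      expressed = bg_expr, planted = FALSE,
                      stringsAsFactors = FALSE)
  pc <- params$planted_clusters
  if (!is.null(pc) && nrow(pc)) {
    for (i in seq_len(nrow(pc))) {
      k <- pc$n_genes_expressed[i]
      s <- stats::runif(k, pc$start_kb[i], pc$start_kb[i] + pc$span_kb[i] - gl)
      genes <- rbind(genes, data.frame(
        chrom = pc$chrom[i], start_kb = s, end_kb = s + gl,
        expressed = 1L, planted = TRUE, stringsAsFactors = FALSE))
    }
  }
  genes <- genes[order(genes$chrom, genes$start_kb), , drop = FALSE]
  genes$gene_id <- sprintf("gene_%05d", seq_len(nrow(genes)))
  rownames(genes) <- NULL
  genes[, c("chrom", "start_kb", "end_kb", "gene_id", "expressed", "planted")]
}
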