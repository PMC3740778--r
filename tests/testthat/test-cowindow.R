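test_that("window enumeration matches the stepping rule", {
  p <- cowindow_params()
  w <- enumerate_windows(500, p)
  expect_equal(nrow(w), 100)
  expect_equal(w$start_kb, seq(0, 495, by = 5))
  expect_true(all(w$end_kb == 500))       # truncated at the chromosome end
  w <- enumerate_windows(1000, p)
  expect_equal(nrow(w), 200)
  expect_equal(max(w$end_kb), 1000)
  # chromosome shorter than the step: a single window
  w <- enumerate_windows(3, p)
  expect_equal(nrow(w), 1)
  expect_equal(w$end_kb, 3)
})

test_that("window statistic counts expressed midpoints, half-open", {
  genes <- data.frame(chrom = "chr1",
                      start_kb = c(10, 99.5, 100.5, 300),
                      end_kb = c(11, 100.5, 101.5, 301),
                      gene_id = letters[1:4],
                      expressed = c(1, 1, 1, 0))
  win <- list(start_kb = 0, end_kb = 100)
  # midpoints 10.5, 100, 101, 300.5; [0,100) contains only the first
  expect_equal(window_statistic(win, genes), 1)
  expect_equal(window_statistic(list(start_kb = 100, end_kb = 200), genes), 2)
  genes$expressed <- 0
  expect_equal(window_statistic(win, genes), 0)
})

test_that("adding an expressed gene never decreases a window statistic", {
  genes <- generate_expression_table(expr_gen_params(
    n_genes = 300, chrom_length_kb = 5000, background_expressed_rate = 0.2,
    seed = 6))
  win <- list(start_kb = 1000, end_kb = 1500)
  before <- window_statistic(win, genes)
  genes2 <- rbind(genes, data.frame(chrom = "chr1", start_kb = 1200,
                                    end_kb = 1201, gene_id = "extra",
                                    expressed = 1, planted = TRUE))
  expect_gte(window_statistic(win, genes2), before)
  expect_equal(window_statistic(win, genes2), before + 1)
})

test_that("saturated labels are invariant under permutation: nothing is called", {
  genes <- generate_expression_table(expr_gen_params(
    n_genes = 400, chrom_length_kb = 10000, background_expressed_rate = 1,
    seed = 8))
  res <- permutation_test(genes, cowindow_params(n_permutations = 100, seed = 9))
  expect_true(all(!res$significant))
  expect_true(all(res$empirical_p == 0))  # never strictly below itself
})

test_that("zero expressed genes warn and yield no calls", {
  genes <- generate_expression_table(expr_gen_params(
    n_genes = 100, chrom_length_kb = 3000, background_expressed_rate = 0,
    seed = 10))
  expect_warning(res <- permutation_test(
    genes, cowindow_params(n_permutations = 50, seed = 11)),
    "no expressed genes")
  expect_true(all(!res$significant))
})

test_that("the permutation test is deterministic given the seed", {
  genes <- generate_expression_table(expr_gen_params(
    n_genes = 300, chrom_length_kb = 8000, background_expressed_rate = 0.1,
    seed = 12))
  p <- cowindow_params(n_permutations = 100, seed = 13)
  expect_identical(permutation_test(genes, p), permutation_test(genes, p))
})

test_that("a planted co-expression cluster is detected and merged", {
  pl <- data.frame(chrom = "chr1", start_kb = 8000, span_kb = 500,
                   n_genes_expressed = 8)
  genes <- generate_expression_table(expr_gen_params(
    n_genes = 2000, chrom_length_kb = 20000, planted_clusters = pl,
    background_expressed_rate = 0.02, seed = 14))
  res <- permutation_test(genes, cowindow_params(n_permutations = 500,
                                                 seed = 15))
  m <- merge_significant(res)
  covering <- m$start_kb <= 8000 & m$end_kb >= 8500
  expect_true(any(covering))
})

test_that("merging joins overlapping windows and keeps distant ones apart", {
  res <- data.frame(chrom = "chr1",
                    start_kb = c(0, 5, 10000), end_kb = c(500, 505, 10500),
                    n_genes = 1, n_expressed = 1, null_quantile_count = 0,
                    empirical_p = 1, significant = c(TRUE, TRUE, TRUE))
  m <- merge_significant(res)
  expect_equal(nrow(m), 2)
  expect_equal(m$start_kb, c(0, 10000))
  expect_equal(m$end_kb, c(505, 10500))
  # no significant windows: empty result
  res$significant <- FALSE
  expect_equal(nrow(merge_significant(res)), 0)
})
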