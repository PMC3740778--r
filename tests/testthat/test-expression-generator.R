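test_that("null and saturation cases give the expected expressed counts", {
  g0 <- generate_expression_table(expr_gen_params(
    n_genes = 300, chrom_length_kb = 5000, background_expressed_rate = 0,
    seed = 1))
  expect_equal(sum(g0$expressed), 0)

  g1 <- generate_expression_table(expr_gen_params(
    n_genes = 300, chrom_length_kb = 5000, background_expressed_rate = 1,
    seed = 1))
  expect_equal(sum(g1$expressed), nrow(g1))
})

test_that("planted clusters contribute the stated expressed genes in place", {
  pl <- data.frame(chrom = "chr1", start_kb = 2000, span_kb = 500,
                   n_genes_expressed = 8)
  g <- generate_expression_table(expr_gen_params(
    n_genes = 500, chrom_length_kb = 10000, planted_clusters = pl,
    background_expressed_rate = 0, seed = 4))
  expect_equal(nrow(g), 508)
  mids <- (g$start_kb + g$end_kb) / 2
  in_win <- mids >= 2000 & mids < 2500 & g$expressed == 1
  expect_gte(sum(in_win), 8)
  expect_true(all(g$planted == (g$expressed == 1)))
})

test_that("planted clusters outside the chromosome are rejected", {
  pl <- data.frame(chrom = "chr1", start_kb = 9800, span_kb = 500,
                   n_genes_expressed = 3)
  expect_error(expr_gen_params(n_genes = 10, chrom_length_kb = 10000,
                               planted_clusters = pl),
               "outside")
})

test_that("generation is reproducible from the seed", {
  p <- expr_gen_params(n_genes = 200, chrom_length_kb = 8000,
                       n_chromosomes = 2, seed = 11)
  expect_identical(generate_expression_table(p),
                   generate_expression_table(p))
})
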