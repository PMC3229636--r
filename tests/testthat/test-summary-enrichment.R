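toy_calls <- function(lens, chrom = "1", gap = 50000) {
  start <- cumsum(c(10000, head(lens, -1) + gap))
  data.frame(id = sprintf("Chr%s_CNV_%d", chrom, seq_along(lens)),
             chrom = chrom, start = start, end = start + lens,
             stringsAsFactors = FALSE)
}

test_that("toy chromosome summary arithmetic", {
  calls <- toy_calls(c(2000, 3000, 10000))
  s <- summarize_by_chromosome(calls, c("1" = 1e6))
  row <- s[s$chrom == "1", ]
  expect_equal(row$total_cnv_length, 15000)
  expect_equal(row$pct_length_in_cnv, 1.5)
  expect_equal(row$median_len, 3000)
  expect_equal(row$n_cnv, 3)
})

test_that("a single call is its own mean, median, max and min", {
  calls <- toy_calls(4200)
  s <- summarize_by_chromosome(calls, c("1" = 1e6))
  row <- s[s$chrom == "1", ]
  expect_true(all(c(row$mean_len, row$median_len, row$max_len,
                    row$min_len) == 4200))
})

test_that("chromosomes without calls are emitted with zeros", {
  calls <- toy_calls(c(2000, 3000))
  s <- summarize_by_chromosome(calls, c("1" = 1e6, "2" = 5e5, "3" = 4e5))
  expect_equal(nrow(s), 4)   # 3 chromosomes + TOTAL
  z <- s[s$chrom %in% c("2", "3"), ]
  expect_true(all(z$n_cnv == 0 & z$total_cnv_length == 0))
  tot <- s[s$chrom == "TOTAL", ]
  expect_equal(tot$chrom_length, 1.9e6)
  expect_equal(tot$n_cnv, 2)
  expect_error(summarize_by_chromosome(calls, c("2" = 5e5)), "unknown")
})

test_that("genome fraction equals summed lengths over summed chromosomes", {
  set.seed(91)
  calls <- rbind(toy_calls(sample(2000:9000, 5), "1"),
                 toy_calls(sample(2000:9000, 3), "2"))
  lens <- c("1" = 2e6, "2" = 1e6)
  s <- summarize_by_chromosome(calls, lens)
  tot <- s[s$chrom == "TOTAL", ]
  expect_equal(tot$pct_length_in_cnv,
               100 * sum(calls$end - calls$start) / sum(lens))
  expect_equal(tot$mean_len, sum(calls$end - calls$start) / nrow(calls))
})

test_that("gene overlap respects the half-open CNV convention", {
  genes <- data.frame(gene_id = c("gA", "gB"), chrom = "1",
                      start = c(200, 301), end = c(300, 400),
                      stringsAsFactors = FALSE)
  # CNV [100,200) covers 1-based bases 101..200: touches gA at base 200
  cnv1 <- data.frame(id = "c1", chrom = "1", start = 100, end = 200)
  # CNV [100,199) covers bases 101..199: does not reach gA
  cnv2 <- data.frame(id = "c2", chrom = "1", start = 100, end = 199)
  ov1 <- overlap_genes(cnv1, genes)
  ov2 <- overlap_genes(cnv2, genes)
  expect_equal(ov1$genes_hit, "gA")
  expect_equal(length(ov2$genes_hit), 0)
})

test_that("planted gene containment is fully recovered", {
  g <- genome_spec("chr1", 4e5)
  sim <- simulate_gene_models(g, n_genes = 6, seed = 5)
  genes <- sim$models$genes
  # one CNV dead-centre inside each even gene, none elsewhere
  inside <- genes[c(2, 4, 6), ]
  cnvs <- data.frame(id = paste0("c", 1:3), chrom = inside$chrom,
                     start = inside$start + 10, end = inside$start + 500)
  ov <- overlap_genes(cnvs, genes)
  expect_setequal(ov$genes_hit, inside$gene_id)
  expect_equal(nrow(ov$cnv_to_genes), 3)
})

test_that("Fisher enrichment p matches the hypergeometric tail oracle", {
  # 2x2 (study-with 8, study-without 2; rest-with 10, rest-without 80)
  study <- paste0("s", 1:10)
  rest <- paste0("r", 1:90)
  withs <- c(paste0("s", 1:8), paste0("r", 1:10))
  anno <- data.frame(gene = withs, term = "T1", stringsAsFactors = FALSE)
  res <- go_enrichment(study, c(study, rest), anno)
  # oracle: P(X >= 8), X ~ Hypergeom(N=100, K=18, n=10), by direct sum
  oracle <- sum(vapply(8:10, function(k)
    choose(18, k) * choose(82, 10 - k) / choose(100, 10), numeric(1)))
  expect_equal(res$p_fisher, oracle, tolerance = 1e-12)
})

test_that("Fisher p equals the oracle over all small tables", {
  for (N in c(12, 20)) for (K in c(3, 7)) for (n in c(4, 9)) {
    for (k in max(0, K + n - N):min(K, n)) {
      study <- paste0("g", 1:n)
      pop <- paste0("g", 1:N)
      withs <- c(paste0("g", seq_len(k)),
                 paste0("g", n + seq_len(K - k)))
      anno <- data.frame(gene = withs, term = "T",
                         stringsAsFactors = FALSE)
      if (k == 0) next    # term absent from study: not tested
      res <- go_enrichment(study, pop, anno)
      oracle <- sum(stats::dhyper(k:min(K, n), K, N - K, n))
      expect_equal(res$p_fisher, oracle, tolerance = 1e-10)
    }
  }
})

test_that("a universal term is not enriched", {
  study <- paste0("s", 1:5); pop <- paste0("g", 1:20)
  anno <- data.frame(gene = c(study, pop), term = "T1")
  res <- go_enrichment(study, c(study, pop), anno)
  expect_equal(res$p_fisher, 1)
})

test_that("BY dominates BH dominates the raw p-values", {
  set.seed(92)
  pop <- paste0("g", 1:60)
  study <- pop[1:15]
  anno <- do.call(rbind, lapply(1:8, function(i)
    data.frame(gene = sample(pop, 20), term = paste0("T", i))))
  res <- go_enrichment(study, pop, anno)
  bh <- p.adjust(res$p_fisher, method = "BH")
  expect_true(all(res$p_adjusted >= bh - 1e-12))
  expect_true(all(bh >= res$p_fisher - 1e-12))
  expect_error(go_enrichment(c(study, "zzz"), pop, anno), "subset")
  empty <- go_enrichment(character(), pop, anno)
  expect_equal(nrow(empty), 0)
})

test_that("fold coverage is a plain unit-invariant ratio", {
  expect_equal(fold_coverage(100, 50), 2)
  expect_equal(fold_coverage(0, 50), 0)
  expect_equal(fold_coverage(100, 50), fold_coverage(100e6, 50e6))
  expect_error(fold_coverage(10, 0), "positive")
})
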