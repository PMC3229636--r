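test_that("textbook codon substitutions classify correctly", {
  set.seed(51)
  # CDS: ATG GCT CGA TAC ... TAA ; gene on the plus strand
  fix <- make_codon_gene(c("ATG", "GCT", "CGA", "TAC", "AAA", "TAA"))
  cds0 <- fix$cds_start
  # GCT -> GCC (third base T>C of codon 2) is synonymous (both Ala)
  snp1 <- data.frame(chrom = "chr1", pos = cds0 + 5, ref = "T", alt = "C")
  # CGA -> TGA (first base C>T of codon 3) creates a stop
  snp2 <- data.frame(chrom = "chr1", pos = cds0 + 6, ref = "C", alt = "T")
  # TAA -> CAA at the terminal stop removes it
  snp3 <- data.frame(chrom = "chr1", pos = cds0 + 15, ref = "T", alt = "C")
  # TAC -> TAT synonymous (Tyr)
  snp4 <- data.frame(chrom = "chr1", pos = cds0 + 11, ref = "C", alt = "T")
  ann <- classify_snps(rbind(snp1, snp2, snp3, snp4), fix$models,
                       fix$reference)
  expect_equal(ann$class, c("synonymous_coding", "stop_gained",
                            "stop_lost", "synonymous_coding"))
})

test_that("the upstream window boundary is 5000 bp inclusive", {
  set.seed(52)
  fix <- make_codon_gene(c("ATG", "AAA", "TAA"), pad = 6000)
  ref_chars <- strsplit(as.character(fix$reference[[1]]), "")[[1]]
  at <- function(pos) data.frame(chrom = "chr1", pos = pos,
                                 ref = ref_chars[pos], alt = "A")
  p_in <- fix$gstart - 4999
  p_edge <- fix$gstart - 5000
  p_out <- fix$gstart - 5001
  ann <- classify_snps(rbind(at(p_in), at(p_edge), at(p_out)),
                       fix$models, fix$reference)
  expect_equal(ann$class, c("upstream", "upstream", "intergenic"))
})

test_that("classes planted by the generator are recovered", {
  g <- genome_spec("chr1", 4e5)
  sim <- simulate_gene_models(g, n_genes = 8, seed = 3, n_noncoding = 2,
                              n_mirna = 1)
  snps <- plant_classified_snps(sim, 140, seed = 11)
  ann <- classify_snps(snps, sim$models, sim$reference)
  expect_equal(ann$class, ann$true_class)
  expect_false(any(ann$ref_mismatch))
})

test_that("classifier matches an exhaustive independent codon oracle", {
  # all sense codons at an internal CDS position, every single-base
  # substitution, on both strands; expected classes from seqinr's
  # translation, not the table the classifier uses
  sense <- setdiff(as.vector(outer(as.vector(outer(
    c("A", "C", "G", "T"), c("A", "C", "G", "T"), paste0)),
    c("A", "C", "G", "T"), paste0)), c("TAA", "TAG", "TGA"))
  for (strand in c("+", "-")) {
    set.seed(53)
    codons <- c("ATG", sense, "TAA")   # codon k sits at index k+1
    fix <- make_codon_gene(codons, strand = strand, pad = 6000)
    cases <- list()
    for (k in seq_along(sense)) {
      cod <- strsplit(sense[k], "")[[1]]
      for (cp in 1:3) for (nb in setdiff(c("A", "C", "G", "T"), cod[cp])) {
        cds_index <- (k + 1 - 1) * 3 + cp    # 1-based position in CDS
        gpos <- if (strand == "+") fix$cds_start + cds_index - 1
                else fix$cds_end - cds_index + 1
        ref_fwd <- if (strand == "+") cod[cp] else COMP[[cod[cp]]]
        alt_fwd <- if (strand == "+") nb else COMP[[nb]]
        alt_cod <- cod; alt_cod[cp] <- nb
        ref_aa <- oracle_translate(sense[k])
        alt_aa <- oracle_translate(paste(alt_cod, collapse = ""))
        expected <- if (alt_aa == "*") "stop_gained"
                    else if (alt_aa == ref_aa) "synonymous_coding"
                    else "nonsynonymous_coding"
        cases[[length(cases) + 1]] <- data.frame(
          chrom = "chr1", pos = gpos, ref = ref_fwd, alt = alt_fwd,
          expected = expected, stringsAsFactors = FALSE)
      }
    }
    cases <- do.call(rbind, cases)
    ann <- classify_snps(cases, fix$models, fix$reference)
    expect_equal(ann$class, cases$expected,
                 label = paste("strand", strand))
    expect_false(any(ann$ref_mismatch))
  }
})

test_that("mismatched reference alleles are flagged but still classified", {
  set.seed(54)
  fix <- make_codon_gene(c("ATG", "GGG", "TAA"))
  snp <- data.frame(chrom = "chr1", pos = fix$cds_start + 3,
                    ref = "T", alt = "A")   # true base is G
  expect_warning(ann <- classify_snps(snp, fix$models, fix$reference),
                 "disagrees")
  expect_true(ann$ref_mismatch)
  expect_equal(ann$class, "nonsynonymous_coding")  # GGG -> AGG (G>R)
})

test_that("class tabulation obeys inclusion-exclusion", {
  a <- data.frame(chrom = "1", pos = 1:6, alt = "A",
                  class = c(rep("intergenic", 3), rep("intronic", 3)))
  b <- data.frame(chrom = "1", pos = 4:9, alt = "A",
                  class = c(rep("intronic", 3), rep("intergenic", 3)))
  tab <- tabulate_classes(a, b)
  tot <- tab[tab$class == "Total", ]
  expect_equal(tot$count_union,
               tot$count_a + tot$count_b - tot$count_intersection)
  expect_equal(tot$count_intersection, 3)
  expect_equal(tot$count_union, 9)
  # disjoint sets: union is the sum
  b2 <- b; b2$pos <- b2$pos + 100
  tab2 <- tabulate_classes(a, b2)
  expect_equal(tab2$count_intersection, rep(0, nrow(tab2)))
  expect_equal(tab2$count_union, tab2$count_a + tab2$count_b)
  # identical sets: union = intersection = either count
  tab3 <- tabulate_classes(a, a)
  expect_equal(tab3$count_union, tab3$count_a)
  expect_equal(tab3$count_intersection, tab3$count_a)
})
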