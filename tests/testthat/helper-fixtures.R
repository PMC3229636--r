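# Shared fixture builders. Everything is generated in code; no files.

# A window-stat track built directly from counts (bypasses read placement)
make_track <- function(x, y, chrom = "1", window = 200, advance = 100) {
  n <- length(x)
  wc <- data.frame(chrom = chrom, start = (seq_len(n) - 1) * advance,
                   end = (seq_len(n) - 1) * advance + window,
                   x = x, y = y, stringsAsFactors = FALSE)
  attr(wc, "window_length") <- window
  attr(wc, "advance") <- advance
  class(wc) <- c("window_counts", "data.frame")
  wc
}

# A window_stats track with significance set by hand (for run-merging tests)
make_stats <- function(log2_ratio, p_value, significant, chrom = "1",
                       advance = 100, window = 200) {
  n <- length(log2_ratio)
  out <- data.frame(chrom = chrom, start = (seq_len(n) - 1) * advance,
                    end = (seq_len(n) - 1) * advance + window,
                    x = 10, y = 10, log2_ratio = log2_ratio,
                    p_value = p_value, significant = significant,
                    stringsAsFactors = FALSE)
  attr(out, "window_length") <- window
  attr(out, "advance") <- advance
  class(out) <- c("window_stats", "data.frame")
  out
}

# Hand-built single-exon coding gene whose CDS is the given codon string;
# returns list(models, reference) with the gene placed after `pad` bases.
make_codon_gene <- function(codons, strand = "+", pad = 6000,
                            chrom = "chr1") {
  cds <- paste(codons, collapse = "")
  lead <- paste(rep("A", 30), collapse = "")   # 5' UTR, no ATG upstream use
  tail <- paste(rep("C", 30), collapse = "")
  tx_seq <- paste0(lead, cds, tail)
  if (strand == "-")
    tx_seq <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(tx_seq)))
  left_pad <- paste(sample(c("A", "C", "G", "T"), pad, replace = TRUE),
                    collapse = "")
  right_pad <- paste(sample(c("A", "C", "G", "T"), pad, replace = TRUE),
                     collapse = "")
  ref_seq <- paste0(left_pad, tx_seq, right_pad)
  gstart <- pad + 1
  gend <- pad + nchar(tx_seq)
  if (strand == "+") {
    cds_start <- gstart + 30
    cds_end <- gstart + 30 + nchar(cds) - 1
  } else {
    cds_end <- gend - 30
    cds_start <- gend - 30 - nchar(cds) + 1
  }
  models <- structure(list(
    genes = data.frame(gene_id = "g1", chrom = chrom, strand = strand,
                       start = gstart, end = gend,
                       biotype = "protein_coding", stringsAsFactors = FALSE),
    transcripts = data.frame(tx_id = "t1", gene_id = "g1", chrom = chrom,
                             strand = strand, start = gstart, end = gend,
                             cds_start = cds_start, cds_end = cds_end,
                             stringsAsFactors = FALSE),
    exons = data.frame(tx_id = "t1", chrom = chrom, strand = strand,
                       start = gstart, end = gend, rank = 1L,
                       stringsAsFactors = FALSE),
    mature_mirna = data.frame(gene_id = character(), chrom = character(),
                              start = numeric(), end = numeric())),
    class = "gene_models")
  reference <- Biostrings::DNAStringSet(ref_seq)
  names(reference) <- chrom
  list(models = models, reference = reference,
       cds_start = cds_start, cds_end = cds_end,
       gstart = gstart, gend = gend)
}

COMP <- c(A = "T", C = "G", G = "C", T = "A")

# independent translation for the classifier oracle (seqinr, not the
# GENETIC_CODE table the implementation uses)
oracle_translate <- function(codon) {
  seqinr::translate(strsplit(codon, "")[[1]])
}
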