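STOP_CODONS <- c("TAA", "TAG", "TGA")

sense_codons <- function() {
  all <- as.vector(outer(as.vector(outer(DNA_BASES, DNA_BASES, paste0)),
                         DNA_BASES, paste0))
  setdiff(all, STOP_CODONS)
}

random_dna <- function(n) paste(sample(DNA_BASES, n, replace = TRUE),
                                collapse = "")

# split `len` into `k` parts, each >= min_part
random_composition <- function(len, k, min_part = 25) {
  if (k == 1) return(len)
  repeat {
    cuts <- sort(sample.int(len - 1, k - 1))
    parts <- diff(c(0, cuts, len))
    if (all(parts >= min_part)) return(parts)
  }
}

#' Simulate gene models and a matching reference sequence
#'
#' Builds a set of multi-exon protein-coding genes (plus optional noncoding
#' and miRNA genes) packed onto the genome with generous intergenic gaps,
#' and a random reference sequence carrying them. Every coding transcript
#' has a frame-complete CDS (length divisible by 3, ATG start, single
#' terminal stop, no internal stop), 5' and 3' UTRs, and introns of at
#' least 60 bp with canonical GT..AG ends. Genes are placed so that the
#' upstream/downstream windows of neighbouring genes never overlap, which
#' keeps planted-SNP truth labels unambiguous.
#'
#' @param genome A [genome_spec()].
#' @param n_genes Number of protein-coding genes.
#' @param seed Integer seed.
#' @param n_noncoding,n_mirna Numbers of noncoding-RNA and miRNA genes.
#' @param window Upstream/downstream annotation window the packing must
#'   respect (bp, default 5000).
#' @return A `gene_models_sim` list: `models` (a `gene_models` object with
#'   `genes`, `transcripts`, `exons`, `mature_mirna` data frames, 1-based
#'   inclusive coordinates), `reference` (a
#'   [Biostrings::DNAStringSet]) and `genome`.
#' @export
simulate_gene_models <- function(genome, n_genes, seed = 1L,
                                 n_noncoding = 0, n_mirna = 0,
                                 window = 5000) {
  stopifnot(inherits(genome, "genome_spec"))
  with_seed(seed, {
    specs <- c(rep("coding", n_genes), rep("ncRNA", n_noncoding),
               rep("miRNA", n_mirna))
    specs <- sample(specs)   # interleave biotypes along the genome
    genes <- list(); txs <- list(); exs <- list(); mirs <- list()
    chrom_i <- 1
    cursor <- window + 1000
    gid <- 0
    for (bt in specs) {
      gid <- gid + 1
      gene_id <- sprintf("gene%03d", gid)
      tx_id <- sprintf("tx%03d", gid)
      strand <- sample(c("+", "-"), 1)

      if (bt == "coding") {
        n_codons <- sample(40:120, 1)
        codons <- c("ATG", sample(sense_codons(), n_codons - 2, replace = TRUE),
                    sample(STOP_CODONS, 1))
        cds_seq <- paste(codons, collapse = "")
        u5 <- sample(30:100, 1); u3 <- sample(50:200, 1)
        mrna <- paste0(random_dna(u5), cds_seq, random_dna(u3))
        n_exons <- sample(2:4, 1)
      } else if (bt == "ncRNA") {
        mrna <- random_dna(sample(200:800, 1))
        u5 <- NA; u3 <- NA
        n_exons <- sample(1:2, 1)
      } else {                       # miRNA precursor, single exon
        mrna <- random_dna(sample(70:100, 1))
        u5 <- NA; u3 <- NA
        n_exons <- 1
      }
      mrna_len <- nchar(mrna)
      exon_lens <- random_composition(mrna_len, n_exons)
      intron_lens <- if (n_exons > 1) sample(60:300, n_exons - 1,
                                             replace = TRUE) else integer(0)
      intron_seqs <- vapply(intron_lens, function(l)
        paste0("GT", random_dna(l - 4), "AG"), "")

      # local (transcription-order) layout
      exon_tx_end <- cumsum(exon_lens)
      exon_tx_start <- exon_tx_end - exon_lens + 1
      local_seq <- ""
      exon_local_start <- integer(n_exons)
      off <- 0
      for (i in seq_len(n_exons)) {
        exon_local_start[i] <- off + 1
        local_seq <- paste0(local_seq,
                            substr(mrna, exon_tx_start[i], exon_tx_end[i]))
        off <- off + exon_lens[i]
        if (i < n_exons) {
          local_seq <- paste0(local_seq, intron_seqs[i])
          off <- off + intron_lens[i]
        }
      }
      span <- nchar(local_seq)

      # pack onto the genome with >= 2*window + margin between spans
      gap <- 2 * window + sample(200:2000, 1)
      while (cursor + span + window + 1000 > genome$length[chrom_i]) {
        chrom_i <- chrom_i + 1
        if (chrom_i > nrow(genome))
          stop("infeasible packing: genes do not fit in the genome")
        cursor <- window + 1000
      }
      chrom <- genome$chrom[chrom_i]
      gstart <- cursor
      gend <- gstart + span - 1
      cursor <- gend + gap

      loc2gen <- function(l) if (strand == "+") gstart + l - 1 else gend - l + 1
      exon_g1 <- loc2gen(exon_local_start)
      exon_g2 <- loc2gen(exon_local_start + exon_lens - 1)
      ex <- data.frame(tx_id = tx_id, chrom = chrom, strand = strand,
                       start = pmin(exon_g1, exon_g2),
                       end = pmax(exon_g1, exon_g2),
                       rank = seq_len(n_exons), stringsAsFactors = FALSE)

      cds_start <- NA_real_; cds_end <- NA_real_
      if (bt == "coding") {
        # CDS occupies mRNA coords [u5+1, u5+3*n_codons]; map through exons
        cds_tx <- c(u5 + 1, u5 + length(codons) * 3)
        tx2local <- function(t) {
          i <- findInterval(t, exon_tx_start)
          exon_local_start[i] + (t - exon_tx_start[i])
        }
        g <- loc2gen(tx2local(cds_tx))
        cds_start <- min(g); cds_end <- max(g)
      }

      genes[[gid]] <- data.frame(gene_id = gene_id, chrom = chrom,
                                 strand = strand, start = gstart, end = gend,
                                 biotype = if (bt == "coding")
                                   "protein_coding" else bt,
                                 stringsAsFactors = FALSE)
      txs[[gid]] <- data.frame(tx_id = tx_id, gene_id = gene_id,
                               chrom = chrom, strand = strand,
                               start = gstart, end = gend,
                               cds_start = cds_start, cds_end = cds_end,
                               stringsAsFactors = FALSE)
      exs[[gid]] <- ex
      if (bt == "miRNA") {
        m0 <- sample(10:(span - 35), 1)
        mlen <- sample(20:24, 1)
        mg <- sort(loc2gen(c(m0, m0 + mlen - 1)))
        mirs[[length(mirs) + 1]] <- data.frame(gene_id = gene_id,
                                               chrom = chrom,
                                               start = mg[1], end = mg[2],
                                               stringsAsFactors = FALSE)
      }
      attr(exs[[gid]], "local_seq") <- local_seq
    }

    models <- structure(list(
      genes = do.call(rbind, genes),
      transcripts = do.call(rbind, txs),
      exons = do.call(rbind, lapply(exs, function(e) {
        attr(e, "local_seq") <- NULL; e
      })),
      mature_mirna = if (length(mirs)) do.call(rbind, mirs) else
        data.frame(gene_id = character(), chrom = character(),
                   start = numeric(), end = numeric())),
      class = "gene_models")

    # build reference: random background, gene sequences written in place
    ref <- lapply(seq_len(nrow(genome)), function(i)
      random_dna(genome$length[i]))
    names(ref) <- genome$chrom
    for (i in seq_along(exs)) {
      g <- genes[[i]]
      s <- attr(exs[[i]], "local_seq")
      if (g$strand == "-")
        s <- as.character(Biostrings::reverseComplement(
          Biostrings::DNAString(s)))
      substr(ref[[g$chrom]], g$start, g$end) <- s
    }
    reference <- Biostrings::DNAStringSet(unlist(ref))

    structure(list(models = models, reference = reference, genome = genome,
                   window = window), class = "gene_models_sim")
  })
}

#' @export
print.gene_models <- function(x, ...) {
  cat(sprintf("<gene_models> %d gene(s), %d transcript(s), %d exon(s)\n",
              nrow(x$genes), nrow(x$transcripts), nrow(x$exons)))
  print(table(x$genes$biotype))
  invisible(x)
}

# genomic positions of CDS bases in transcription (5'->3') order
cds_map <- function(tx, exons) {
  ex <- exons[exons$tx_id == tx$tx_id, , drop = FALSE]
  ex <- ex[order(ex$rank), , drop = FALSE]
  pos <- unlist(lapply(seq_len(nrow(ex)), function(i) {
    if (tx$strand == "+") seq(ex$start[i], ex$end[i])
    else seq(ex$end[i], ex$start[i])
  }))
  pos[pos >= tx$cds_start & pos <= tx$cds_end]
}

#' Write simulated gene models and reference to disk
#'
#' The models go to GFF3 (1-based, inclusive; gene/mRNA/exon/CDS/UTR
#' features with ID/Parent attributes) and the reference to FASTA.
#'
#' @param sim A `gene_models_sim` from [simulate_gene_models()].
#' @param gff3,fasta Output paths (`NULL` to skip either).
#' @return Invisibly, the paths.
#' @export
write_gene_models <- function(sim, gff3 = NULL, fasta = NULL) {
  if (!is.null(fasta))
    Biostrings::writeXStringSet(sim$reference, fasta)
  if (!is.null(gff3)) {
    m <- sim$models
    lines <- "##gff-version 3"
    fmt <- function(chrom, type, start, end, strand, attrs)
      sprintf("%s\tduovar\t%s\t%d\t%d\t.\t%s\t.\t%s",
              chrom, type, start, end, strand, attrs)
    for (i in seq_len(nrow(m$genes))) {
      g <- m$genes[i, ]
      lines <- c(lines, fmt(g$chrom, "gene", g$start, g$end, g$strand,
                            sprintf("ID=%s;biotype=%s", g$gene_id, g$biotype)))
      tx <- m$transcripts[m$transcripts$gene_id == g$gene_id, ]
      ttype <- switch(g$biotype, protein_coding = "mRNA",
                      miRNA = "miRNA_primary_transcript", "ncRNA")
      lines <- c(lines, fmt(tx$chrom, ttype, tx$start, tx$end, tx$strand,
                            sprintf("ID=%s;Parent=%s", tx$tx_id, g$gene_id)))
      ex <- m$exons[m$exons$tx_id == tx$tx_id, ]
      for (j in seq_len(nrow(ex)))
        lines <- c(lines, fmt(ex$chrom[j], "exon", ex$start[j], ex$end[j],
                              ex$strand[j],
                              sprintf("Parent=%s;rank=%d", tx$tx_id,
                                      ex$rank[j])))
      if (!is.na(tx$cds_start)) {
        cds_pos <- cds_map(tx, m$exons)
        r <- split_runs(sort(cds_pos))
        for (j in seq_len(nrow(r)))
          lines <- c(lines, fmt(tx$chrom, "CDS", r$start[j], r$end[j],
                                tx$strand, sprintf("Parent=%s", tx$tx_id)))
        for (j in seq_len(nrow(ex))) {
          lo <- ex$start[j]; hi <- ex$end[j]
          left <- c(lo, min(hi, tx$cds_start - 1))
          right <- c(max(lo, tx$cds_end + 1), hi)
          for (side in list(left, right)) {
            if (side[1] > side[2]) next
            if (side[2] >= tx$cds_start && side[1] <= tx$cds_end) next
            utr5 <- (tx$strand == "+") == (side[2] < tx$cds_start)
            lines <- c(lines, fmt(tx$chrom,
                                  if (utr5) "five_prime_UTR"
                                  else "three_prime_UTR",
                                  side[1], side[2], tx$strand,
                                  sprintf("Parent=%s", tx$tx_id)))
          }
        }
      }
    }
    mm <- m$mature_mirna
    for (i in seq_len(nrow(mm))) {
      tx <- m$transcripts[m$transcripts$gene_id == mm$gene_id[i], ]
      lines <- c(lines, fmt(mm$chrom[i], "miRNA", mm$start[i], mm$end[i],
                            tx$strand, sprintf("Parent=%s", tx$tx_id)))
    }
    writeLines(lines, gff3)
  }
  invisible(c(gff3 = gff3, fasta = fasta))
}

# contiguous integer runs -> data.frame(start, end)
split_runs <- function(x) {
  if (!length(x)) return(data.frame(start = numeric(), end = numeric()))
  brk <- c(TRUE, diff(x) != 1)
  grp <- cumsum(brk)
  data.frame(start = tapply(x, grp, min), end = tapply(x, grp, max),
             row.names = NULL)
}

#' Extract and translate every CDS in a simulation
#'
#' Mostly a self-check utility: reconstructs each coding sequence from the
#' reference through the exon structure and translates it.
#'
#' @param sim A `gene_models_sim`.
#' @return A named character vector of protein sequences (with terminal
#'   `*`).
#' @export
translate_cds <- function(sim) {
  m <- sim$models
  tx <- m$transcripts[!is.na(m$transcripts$cds_start), , drop = FALSE]
  out <- vapply(seq_len(nrow(tx)), function(i) {
    t1 <- tx[i, ]
    pos <- cds_map(t1, m$exons)
    chrom_seq <- sim$reference[[t1$chrom]]
    bases <- strsplit(as.character(chrom_seq), "")[[1]][pos]
    if (t1$strand == "-") bases <- comp_base(bases)
    as.character(Biostrings::translate(
      Biostrings::DNAString(paste(bases, collapse = ""))))
  }, "")
  names(out) <- tx$tx_id
  out
}

comp_base <- function(b) c(A = "T", C = "G", G = "C", T = "A")[b]
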