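#' Plant SNPs with known functional classes
#'
#' Draws SNPs whose functional class is known by construction from the
#' simulated gene structure: positions are chosen inside the feature that
#' defines each class, and coding alleles are chosen so that substituting
#' them into the codon yields the intended consequence under the standard
#' genetic code. The recorded `true_class` is the label the classifier is
#' expected to reproduce.
#'
#' @param sim A `gene_models_sim` from [simulate_gene_models()].
#' @param n Number of SNPs to plant.
#' @param classes Character vector of classes to cycle through; defaults to
#'   every class realizable in `sim`.
#' @param seed Integer seed.
#' @return Data frame with `chrom`, `pos`, `ref`, `alt` (forward strand)
#'   and `true_class`.
#' @export
plant_classified_snps <- function(sim, n, classes = NULL, seed = 1L) {
  m <- sim$models
  window <- sim$window
  tx_all <- merge(m$transcripts, m$genes[, c("gene_id", "biotype")],
                  by = "gene_id")
  coding <- tx_all[tx_all$biotype == "protein_coding", , drop = FALSE]
  nc <- tx_all[tx_all$biotype == "ncRNA", , drop = FALSE]
  mir <- m$mature_mirna

  if (is.null(classes)) {
    classes <- c("intergenic", "upstream", "downstream", "intronic",
                 "splice_site", "essential_splice_site", "utr5", "utr3",
                 "synonymous_coding", "nonsynonymous_coding",
                 "stop_gained", "stop_lost")
    if (nrow(nc)) classes <- c(classes, "within_noncoding_gene")
    if (nrow(mir)) classes <- c(classes, "within_mature_mirna")
  }

  chars_of <- local({
    cache <- list()
    function(ch) {
      if (is.null(cache[[ch]]))
        cache[[ch]] <<- strsplit(as.character(sim$reference[[ch]]), "")[[1]]
      cache[[ch]]
    }
  })

  introns_of <- function(t1) {
    ex <- m$exons[m$exons$tx_id == t1$tx_id, , drop = FALSE]
    ex <- ex[order(ex$start), , drop = FALSE]
    if (nrow(ex) < 2) return(NULL)
    data.frame(start = ex$end[-nrow(ex)] + 1, end = ex$start[-1] - 1)
  }
  exon_positions <- function(t1) {
    ex <- m$exons[m$exons$tx_id == t1$tx_id, , drop = FALSE]
    unlist(Map(seq, ex$start, ex$end))
  }

  pick_pos <- function(cls) {
    if (cls == "intergenic") {
      for (try in 1:200) {
        i <- sample(nrow(sim$genome), 1)
        ch <- sim$genome$chrom[i]
        pos <- sample.int(sim$genome$length[i], 1)
        g <- m$genes[m$genes$chrom == ch, , drop = FALSE]
        if (!nrow(g) || all(pos < g$start - window | pos > g$end + window))
          return(list(chrom = ch, pos = pos))
      }
      stop("could not find an intergenic position")
    }
    if (cls %in% c("upstream", "downstream")) {
      t1 <- tx_all[sample(nrow(tx_all), 1), ]
      five_prime <- (cls == "upstream") == (t1$strand == "+")
      pos <- if (five_prime) t1$start - sample.int(window, 1)
             else t1$end + sample.int(window, 1)
      return(list(chrom = t1$chrom, pos = pos))
    }
    if (cls %in% c("intronic", "splice_site", "essential_splice_site")) {
      repeat {
        t1 <- tx_all[sample(nrow(tx_all), 1), ]
        intr <- introns_of(t1)
        if (!is.null(intr) && nrow(intr)) break
      }
      iv <- intr[sample(nrow(intr), 1), ]
      d <- switch(cls, essential_splice_site = sample(1:2, 1),
                  splice_site = sample(3:8, 1),
                  intronic = sample(9:(iv$end - iv$start + 1 - 9 + 1), 1))
      pos <- if (stats::runif(1) < 0.5) iv$start + d - 1 else iv$end - d + 1
      return(list(chrom = t1$chrom, pos = pos))
    }
    if (cls %in% c("utr5", "utr3")) {
      t1 <- coding[sample(nrow(coding), 1), ]
      ep <- exon_positions(t1)
      left <- ep[ep < t1$cds_start]; right <- ep[ep > t1$cds_end]
      want_left <- (cls == "utr5") == (t1$strand == "+")
      cand <- if (want_left) left else right
      return(list(chrom = t1$chrom, pos = sample(cand, 1)))
    }
    if (cls == "within_noncoding_gene") {
      t1 <- nc[sample(nrow(nc), 1), ]
      return(list(chrom = t1$chrom, pos = sample(exon_positions(t1), 1)))
    }
    if (cls == "within_mature_mirna") {
      r <- mir[sample(nrow(mir), 1), ]
      return(list(chrom = r$chrom, pos = sample(seq(r$start, r$end), 1)))
    }
    stop("unhandled class ", cls)
  }

  pick_coding <- function(cls) {
    for (try in 1:200) {
      t1 <- coding[sample(nrow(coding), 1), ]
      map <- cds_map(t1, m$exons)
      chars <- chars_of(t1$chrom)
      bases <- chars[map]
      if (t1$strand == "-") bases <- comp_base(bases)
      n_codons <- length(map) / 3
      idx_pool <- if (cls == "stop_lost") n_codons else
        sample(n_codons - 1)        # exclude terminal stop unless stop_lost
      for (ci in idx_pool) {
        cb <- bases[(ci - 1) * 3 + 1:3]
        ref_codon <- paste(cb, collapse = "")
        ref_aa <- translate_codon(ref_codon)
        for (cp in sample(3)) {
          for (ab in sample(setdiff(DNA_BASES, cb[cp]))) {
            nb <- cb; nb[cp] <- ab
            alt_aa <- translate_codon(paste(nb, collapse = ""))
            ok <- switch(cls,
              synonymous_coding = alt_aa == ref_aa,
              nonsynonymous_coding = ref_aa != "*" && alt_aa != "*" &&
                alt_aa != ref_aa,
              stop_gained = ref_aa != "*" && alt_aa == "*",
              stop_lost = ref_aa == "*" && alt_aa != "*",
              FALSE)
            if (ok) {
              gpos <- map[(ci - 1) * 3 + cp]
              ref_fwd <- chars[gpos]
              alt_fwd <- if (t1$strand == "+") ab else comp_base(ab)
              return(list(chrom = t1$chrom, pos = gpos,
                          ref = ref_fwd, alt = unname(alt_fwd)))
            }
          }
        }
      }
    }
    stop("could not plant a ", cls, " SNP")
  }

  with_seed(seed, {
    out <- vector("list", n)
    seen <- character(0)
    for (k in seq_len(n)) {
      cls <- classes[(k - 1) %% length(classes) + 1]
      repeat {
        if (cls %in% c("synonymous_coding", "nonsynonymous_coding",
                       "stop_gained", "stop_lost")) {
          p <- pick_coding(cls)
        } else {
          p <- pick_pos(cls)
          chars <- chars_of(p$chrom)
          p$ref <- chars[p$pos]
          p$alt <- sample(setdiff(DNA_BASES, p$ref), 1)
        }
        key <- paste(p$chrom, p$pos)
        if (!(key %in% seen)) { seen <- c(seen, key); break }
      }
      out[[k]] <- data.frame(chrom = p$chrom, pos = p$pos, ref = p$ref,
                             alt = p$alt, true_class = cls,
                             stringsAsFactors = FALSE)
    }
    do.call(rbind, out)
  })
}
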