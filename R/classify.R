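FUNCTIONAL_CLASSES <- c("essential_splice_site", "stop_gained", "stop_lost",
                        "nonsynonymous_coding", "splice_site",
                        "synonymous_coding", "utr5", "utr3",
                        "within_mature_mirna", "within_noncoding_gene",
                        "intronic", "upstream", "downstream", "intergenic")

# lower index = more severe; reduction across transcripts keeps the minimum
class_rank <- function(cls) match(cls, FUNCTIONAL_CLASSES)

translate_codon <- function(codon) {
  unname(Biostrings::GENETIC_CODE[codon])
}

# classify one SNP against one transcript; snp alleles are forward-strand
classify_against_tx <- function(pos, alt, tx, exons, chrom_chars,
                                mature = NULL, window = 5000) {
  strand <- tx$strand
  if (pos < tx$start || pos > tx$end) {
    if (pos >= tx$start - window && pos < tx$start)
      return(list(class = if (strand == "+") "upstream" else "downstream"))
    if (pos > tx$end && pos <= tx$end + window)
      return(list(class = if (strand == "+") "downstream" else "upstream"))
    return(list(class = "intergenic"))
  }
  ex <- exons[exons$tx_id == tx$tx_id, , drop = FALSE]
  in_exon <- any(pos >= ex$start & pos <= ex$end)
  if (!in_exon) {
    d_prev <- pos - max(ex$end[ex$end < pos])
    d_next <- min(ex$start[ex$start > pos]) - pos
    d <- min(d_prev, d_next)
    cls <- if (d <= 2) "essential_splice_site"
           else if (d <= 8) "splice_site" else "intronic"
    return(list(class = cls))
  }
  if (is.na(tx$cds_start)) {
    if (!is.null(mature) && nrow(mature) &&
        any(pos >= mature$start & pos <= mature$end))
      return(list(class = "within_mature_mirna"))
    return(list(class = "within_noncoding_gene"))
  }
  if (pos < tx$cds_start)
    return(list(class = if (strand == "+") "utr5" else "utr3"))
  if (pos > tx$cds_end)
    return(list(class = if (strand == "+") "utr3" else "utr5"))

  map <- cds_map(tx, exons)
  i <- match(pos, map)
  codon_idx <- (i - 1) %/% 3
  cpos <- (i - 1) %% 3 + 1
  gpos <- map[codon_idx * 3 + 1:3]
  bases <- chrom_chars[gpos]
  if (strand == "-") bases <- comp_base(bases)
  ref_codon <- paste(bases, collapse = "")
  alt_base <- if (strand == "+") alt else comp_base(alt)
  alt_bases <- bases
  alt_bases[cpos] <- alt_base
  alt_codon <- paste(alt_bases, collapse = "")
  ref_aa <- translate_codon(ref_codon)
  alt_aa <- translate_codon(alt_codon)
  cls <- if (ref_aa == "*" && alt_aa == "*") "synonymous_coding"
         else if (ref_aa == "*") "stop_lost"
         else if (alt_aa == "*") "stop_gained"
         else if (ref_aa == alt_aa) "synonymous_coding"
         else "nonsynonymous_coding"
  list(class = cls, ref_codon = ref_codon, alt_codon = alt_codon,
       ref_aa = ref_aa, alt_aa = alt_aa, codon_position = cpos)
}

#' Assign a functional class to each SNP
#'
#' Classifies SNPs against a set of gene models and a reference sequence
#' into exactly one of: essential_splice_site, stop_gained, stop_lost,
#' nonsynonymous_coding, splice_site, synonymous_coding, utr5, utr3,
#' within_mature_mirna, within_noncoding_gene, intronic, upstream,
#' downstream, intergenic (listed most to least severe).
#' Per overlapping transcript the class is determined positionally
#' (upstream/downstream within `window` bp of the transcript, UTRs, splice
#' windows of 1-2 bp (essential) and 3-8 bp into an intron, intronic,
#' noncoding-gene and mature-miRNA containment) or, inside a CDS, by
#' substituting the alternate allele into the reference codon
#' (strand-aware: alleles are reported on the forward strand and
#' complemented for minus-strand CDS) and translating with the standard
#' genetic code. Classes from multiple transcripts are reduced to the most
#' severe.
#'
#' SNPs whose stated reference allele disagrees with the reference base are
#' flagged in `ref_mismatch` and classified from the actual reference base.
#'
#' @param snps Data frame with columns `chrom`, `pos` (1-based), `ref`,
#'   `alt` (forward strand).
#' @param models A `gene_models` object (from [simulate_gene_models()] or
#'   [read_gene_models()]).
#' @param reference A [Biostrings::DNAStringSet] named by chromosome.
#' @param window Upstream/downstream window in bp (default 5000).
#' @return The input with columns `class`, `ref_mismatch`, and for coding
#'   SNPs `ref_aa`, `alt_aa` appended.
#' @export
classify_snps <- function(snps, models, reference, window = 5000) {
  tx <- merge(models$transcripts,
              models$genes[, c("gene_id", "biotype")], by = "gene_id")
  chrom_cache <- new.env(parent = emptyenv())
  get_chars <- function(ch) {
    if (!is.null(chrom_cache[[ch]])) return(chrom_cache[[ch]])
    v <- strsplit(as.character(reference[[ch]]), "")[[1]]
    chrom_cache[[ch]] <- v
    v
  }
  n <- nrow(snps)
  cls <- character(n); mism <- logical(n)
  ref_aa <- rep(NA_character_, n); alt_aa <- rep(NA_character_, n)
  for (k in seq_len(n)) {
    pos <- snps$pos[k]; ch <- snps$chrom[k]
    chars <- get_chars(ch)
    mism[k] <- !is.na(snps$ref[k]) && chars[pos] != snps$ref[k]
    cand <- tx[tx$chrom == ch & pos >= tx$start - window &
                 pos <= tx$end + window, , drop = FALSE]
    if (nrow(cand) == 0) { cls[k] <- "intergenic"; next }
    best <- "intergenic"; best_info <- NULL
    for (j in seq_len(nrow(cand))) {
      t1 <- cand[j, ]
      mat <- models$mature_mirna[models$mature_mirna$gene_id == t1$gene_id, ,
                                 drop = FALSE]
      res <- classify_against_tx(pos, snps$alt[k], t1, models$exons,
                                 chars, mat, window)
      if (class_rank(res$class) < class_rank(best)) {
        best <- res$class; best_info <- res
      }
    }
    cls[k] <- best
    if (!is.null(best_info$ref_aa)) {
      ref_aa[k] <- best_info$ref_aa; alt_aa[k] <- best_info$alt_aa
    }
  }
  if (any(mism))
    warning(sum(mism), " SNP(s) whose ref allele disagrees with the ",
            "reference were classified from the reference base")
  out <- snps
  out$class <- cls
  out$ref_mismatch <- mism
  out$ref_aa <- ref_aa
  out$alt_aa <- alt_aa
  out
}

#' Tabulate functional classes for two animals
#'
#' Produces the classic four-column class membership table: per-animal
#' counts, the intersection (SNPs shared by both animals, keyed on
#' chromosome, position and alternate allele) and the union, with
#' inclusion-exclusion (`union = a + b - intersection`) enforced per class
#' and in the total row. Percentages are of each column's total, to one
#' decimal.
#'
#' @param annotated_a,annotated_b Data frames with `chrom`, `pos`, `alt`
#'   and `class` columns (as from [classify_snps()]).
#' @return A `class_table` data frame with columns `class`, `count_a`,
#'   `count_b`, `count_intersection`, `count_union` and matching `pct_*`
#'   columns, with a `Total` row last.
#' @export
tabulate_classes <- function(annotated_a, annotated_b) {
  key_a <- paste(annotated_a$chrom, annotated_a$pos, annotated_a$alt)
  key_b <- paste(annotated_b$chrom, annotated_b$pos, annotated_b$alt)
  shared <- key_a %in% key_b
  classes <- union(unique(annotated_a$class), unique(annotated_b$class))
  classes <- FUNCTIONAL_CLASSES[FUNCTIONAL_CLASSES %in% classes]
  count_in <- function(x, cls) sum(x == cls)
  rows <- lapply(classes, function(cl) {
    ca <- count_in(annotated_a$class, cl)
    cb <- count_in(annotated_b$class, cl)
    ci <- sum(annotated_a$class == cl & shared)
    data.frame(class = cl, count_a = ca, count_b = cb,
               count_intersection = ci, count_union = ca + cb - ci)
  })
  out <- do.call(rbind, rows)
  class_counts_table(out)
}

#' Build a class membership table from per-class counts
#'
#' The counts-only sibling of [tabulate_classes()], for when the per-animal
#' and intersection counts are already tallied: applies
#' inclusion-exclusion to obtain the union column, adds the total row and
#' the one-decimal percentage columns.
#'
#' @param counts Data frame with columns `class`, `count_a`, `count_b`,
#'   `count_intersection`.
#' @return A `class_table` data frame (see [tabulate_classes()]).
#' @export
class_counts_table <- function(counts) {
  out <- counts
  if (is.null(out$count_union))
    out$count_union <- out$count_a + out$count_b - out$count_intersection
  tot <- data.frame(class = "Total", count_a = sum(out$count_a),
                    count_b = sum(out$count_b),
                    count_intersection = sum(out$count_intersection),
                    count_union = sum(out$count_union))
  out <- rbind(out, tot)
  for (col in c("a", "b", "intersection", "union")) {
    cc <- out[[paste0("count_", col)]]
    out[[paste0("pct_", col)]] <- round(100 * cc / max(cc[out$class == "Total"],
                                                       1), 1)
  }
  class(out) <- c("class_table", "data.frame")
  out
}

#' @export
print.class_table <- function(x, ...) {
  cat("SNP functional class membership\n")
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}
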