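#' Read gene models from a GFF3 file
#'
#' Parses a GFF3 file (1-based, inclusive coordinates) into the
#' `gene_models` structure the classifier consumes. Expects gene features
#' with `ID` (and optionally `biotype`), transcript features (`mRNA`,
#' `ncRNA`, `miRNA_primary_transcript`, ...) with `ID`/`Parent`, `exon` and
#' `CDS` features with `Parent`, and optionally mature `miRNA` features —
#' the layout [write_gene_models()] produces.
#'
#' @param path GFF3 file path.
#' @return A `gene_models` object.
#' @export
read_gene_models <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  df <- as.data.frame(gr)
  df$seqnames <- as.character(df$seqnames)
  df$strand <- as.character(df$strand)
  df$type <- as.character(df$type)
  first_parent <- function(p) vapply(p, function(x)
    if (length(x)) x[[1]] else NA_character_, "")
  df$parent <- if (!is.null(df$Parent)) first_parent(df$Parent)
               else NA_character_

  g <- df[df$type == "gene", , drop = FALSE]
  genes <- data.frame(gene_id = g$ID, chrom = g$seqnames, strand = g$strand,
                      start = g$start, end = g$end,
                      biotype = if (!is.null(g$biotype)) g$biotype
                                else "protein_coding",
                      stringsAsFactors = FALSE)

  tx_types <- c("mRNA", "ncRNA", "miRNA_primary_transcript", "transcript",
                "lnc_RNA", "rRNA", "tRNA")
  t <- df[df$type %in% tx_types, , drop = FALSE]
  cds <- df[df$type == "CDS", , drop = FALSE]
  cds_lo <- tapply(cds$start, cds$parent, min)
  cds_hi <- tapply(cds$end, cds$parent, max)
  transcripts <- data.frame(tx_id = t$ID, gene_id = t$parent,
                            chrom = t$seqnames, strand = t$strand,
                            start = t$start, end = t$end,
                            cds_start = as.numeric(cds_lo[t$ID]),
                            cds_end = as.numeric(cds_hi[t$ID]),
                            stringsAsFactors = FALSE)

  e <- df[df$type == "exon", , drop = FALSE]
  rank <- if (!is.null(e$rank)) as.integer(e$rank) else NA_integer_
  exons <- data.frame(tx_id = e$parent, chrom = e$seqnames,
                      strand = e$strand, start = e$start, end = e$end,
                      rank = rank, stringsAsFactors = FALSE)
  if (anyNA(exons$rank)) {
    # transcription order: ascending start on +, descending on -
    exons <- do.call(rbind, lapply(split(exons, exons$tx_id), function(x) {
      o <- order(x$start, decreasing = x$strand[1] == "-")
      x <- x[o, , drop = FALSE]
      x$rank <- seq_len(nrow(x))
      x
    }))
    rownames(exons) <- NULL
  }

  mm <- df[df$type == "miRNA", , drop = FALSE]
  mature <- if (nrow(mm)) {
    gene_of <- transcripts$gene_id[match(mm$parent, transcripts$tx_id)]
    data.frame(gene_id = gene_of, chrom = mm$seqnames, start = mm$start,
               end = mm$end, stringsAsFactors = FALSE)
  } else data.frame(gene_id = character(), chrom = character(),
                    start = numeric(), end = numeric())

  structure(list(genes = genes, transcripts = transcripts, exons = exons,
                 mature_mirna = mature), class = "gene_models")
}

#' Read a reference FASTA
#'
#' Thin wrapper over [Biostrings::readDNAStringSet()] that trims FASTA
#' descriptions to the sequence name.
#'
#' @param path FASTA file path.
#' @return A [Biostrings::DNAStringSet] named by sequence id.
#' @export
read_reference <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  names(x) <- sub("\\s.*$", "", names(x))
  x
}

#' Read or write a SNP table
#'
#' SNP tables are headered TSV with columns `chrom`, `pos` (1-based),
#' `ref`, `alt`, `zygosity`, and optionally `depth` and annotation columns.
#'
#' @param snps Data frame to write.
#' @param path File path.
#' @return `read_snps()` returns the data frame; `write_snps()` the path,
#'   invisibly.
#' @export
write_snps <- function(snps, path) {
  utils::write.table(snps, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_snps
#' @export
read_snps <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE,
                    colClasses = c(chrom = "character"))
}
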