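#' Per-chromosome CNV summary with genome total
#'
#' For each chromosome: number of CNVs, total CNV length, percentage of
#' chromosome length in CNV, and the mean/median/max/min CNV lengths.
#' Chromosomes with zero calls are emitted with zeros. A `TOTAL` row
#' aggregates across the genome: its mean is total length over total
#' count, and its percentage is total CNV length over total genome length.
#'
#' @param cnvs A `cnv_calls` data frame (columns `chrom`, `start`, `end`;
#'   0-based half-open, so length = end - start).
#' @param chrom_lengths Named numeric vector or [genome_spec()] of
#'   chromosome lengths; every call's chromosome must be present.
#' @return A `cnv_summary` data frame with columns `chrom`, `chrom_length`,
#'   `pct_length_in_cnv`, `total_cnv_length`, `n_cnv`, `mean_len`,
#'   `median_len`, `max_len`, `min_len`.
#' @export
summarize_by_chromosome <- function(cnvs, chrom_lengths) {
  if (inherits(chrom_lengths, "genome_spec"))
    chrom_lengths <- stats::setNames(chrom_lengths$length,
                                     chrom_lengths$chrom)
  unknown <- setdiff(unique(cnvs$chrom), names(chrom_lengths))
  if (length(unknown))
    stop("CNV on unknown chromosome: ", paste(unknown, collapse = ", "))
  len <- cnvs$end - cnvs$start
  rows <- lapply(names(chrom_lengths), function(ch) {
    l <- len[cnvs$chrom == ch]
    data.frame(chrom = ch, chrom_length = unname(chrom_lengths[ch]),
               pct_length_in_cnv = 100 * sum(l) / chrom_lengths[[ch]],
               total_cnv_length = sum(l), n_cnv = length(l),
               mean_len = if (length(l)) mean(l) else 0,
               median_len = if (length(l)) stats::median(l) else 0,
               max_len = if (length(l)) max(l) else 0,
               min_len = if (length(l)) min(l) else 0,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  tot <- summarize_total(out)
  tot$median_len <- if (length(len)) stats::median(len) else 0
  out <- rbind(out, tot)
  rownames(out) <- NULL
  class(out) <- c("cnv_summary", "data.frame")
  out
}

#' Aggregate per-chromosome CNV summaries into a genome total row
#'
#' Works from per-chromosome totals alone: the genome mean CNV length is
#' total CNV length over total CNV count, and the genome percentage is
#' total CNV length over total chromosome length. Median cannot be
#' recovered from per-chromosome summaries and is reported `NA` unless the
#' input carries per-call lengths.
#'
#' @param per_chrom Data frame with columns `chrom_length`,
#'   `total_cnv_length`, `n_cnv`, `max_len`, `min_len` (one row per
#'   chromosome).
#' @return A one-row data frame in the same layout with `chrom = "TOTAL"`.
#' @export
summarize_total <- function(per_chrom) {
  n <- sum(per_chrom$n_cnv)
  tot_len <- sum(per_chrom$total_cnv_length)
  tot_chrom <- sum(per_chrom$chrom_length)
  data.frame(chrom = "TOTAL", chrom_length = tot_chrom,
             pct_length_in_cnv = 100 * tot_len / tot_chrom,
             total_cnv_length = tot_len, n_cnv = n,
             mean_len = if (n) tot_len / n else 0,
             median_len = NA_real_,
             max_len = if (n) max(per_chrom$max_len[per_chrom$n_cnv > 0])
                       else 0,
             min_len = if (n) min(per_chrom$min_len[per_chrom$n_cnv > 0])
                       else 0,
             stringsAsFactors = FALSE)
}

#' @export
print.cnv_summary <- function(x, ...) {
  y <- as.data.frame(x)
  y$pct_length_in_cnv <- sprintf("%.3f", y$pct_length_in_cnv)
  y$mean_len <- round(y$mean_len)
  print.data.frame(y, row.names = FALSE)
  invisible(x)
}

#' Overlap CNV calls with gene intervals
#'
#' A gene overlaps a CNV iff their intervals intersect by at least 1 bp
#' (complete or partial overlap). CNV coordinates are 0-based half-open
#' (BED convention); gene models are 1-based inclusive (GFF3 convention)
#' and converted internally.
#'
#' @param cnvs Data frame with `id` (optional), `chrom`, `start`, `end`
#'   (0-based half-open).
#' @param genes Data frame with `gene_id`, `chrom`, `start`, `end`
#'   (1-based inclusive), e.g. `models$genes`.
#' @return List with `cnv_to_genes` (data frame `cnv_id`, `gene_id`, one
#'   row per overlapping pair), `genes_hit` (unique gene ids) and
#'   `cnvs_hit` (unique CNV ids).
#' @export
overlap_genes <- function(cnvs, genes) {
  cnv_id <- if (!is.null(cnvs$id)) cnvs$id else
    sprintf("cnv%04d", seq_len(nrow(cnvs)))
  gr_cnv <- GenomicRanges::GRanges(
    cnvs$chrom, IRanges::IRanges(start = cnvs$start + 1, end = cnvs$end))
  gr_gene <- GenomicRanges::GRanges(
    genes$chrom, IRanges::IRanges(start = genes$start, end = genes$end))
  hits <- GenomicRanges::findOverlaps(gr_cnv, gr_gene)
  pairs <- data.frame(cnv_id = cnv_id[S4Vectors::queryHits(hits)],
                      gene_id = genes$gene_id[S4Vectors::subjectHits(hits)],
                      stringsAsFactors = FALSE)
  list(cnv_to_genes = pairs,
       genes_hit = unique(pairs$gene_id),
       cnvs_hit = unique(pairs$cnv_id))
}

#' Gene Ontology term enrichment by Fisher's exact test
#'
#' For every term annotated to at least one study gene, tests
#' over-representation of the term in the study set against the population
#' (background) set with a one-sided Fisher's exact test on the 2x2 table
#' (study with/without term vs rest of population with/without term), then
#' adjusts across terms with the Benjamini-Yekutieli procedure, which
#' controls the false discovery rate under arbitrary dependence between
#' terms.
#'
#' @param study_genes Character vector of study gene ids (must be a subset
#'   of `population_genes`).
#' @param population_genes Character vector of background gene ids.
#' @param annotation Data frame `gene`, `term` (one row per
#'   gene-term pair).
#' @return An `enrichment_result` data frame: `term`, `study_count`,
#'   `study_total`, `population_count`, `population_total`, `p_fisher`,
#'   `p_adjusted`, sorted by adjusted then raw p.
#' @export
go_enrichment <- function(study_genes, population_genes, annotation) {
  study_genes <- unique(study_genes)
  population_genes <- unique(population_genes)
  if (!all(study_genes %in% population_genes))
    stop("study genes must be a subset of the population")
  if (length(study_genes) == 0) {
    out <- data.frame(term = character(), study_count = integer(),
                      study_total = integer(), population_count = integer(),
                      population_total = integer(), p_fisher = numeric(),
                      p_adjusted = numeric())
    class(out) <- c("enrichment_result", "data.frame")
    return(out)
  }
  anno <- annotation[annotation$gene %in% population_genes, , drop = FALSE]
  n <- length(study_genes)
  N <- length(population_genes)
  terms <- unique(anno$term[anno$gene %in% study_genes])
  rows <- lapply(terms, function(tm) {
    with_term <- unique(anno$gene[anno$term == tm])
    k <- sum(study_genes %in% with_term)
    K <- length(with_term)
    tab <- matrix(c(k, n - k, K - k, (N - n) - (K - k)), nrow = 2)
    p <- stats::fisher.test(tab, alternative = "greater")$p.value
    data.frame(term = tm, study_count = k, study_total = n,
               population_count = K, population_total = N, p_fisher = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adjusted <- stats::p.adjust(out$p_fisher, method = "BY")
  out <- out[order(out$p_adjusted, out$p_fisher), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("enrichment_result", "data.frame")
  out
}

#' Fold coverage of a genome
#'
#' @param total_mapped_bases Total mapped bases (any unit).
#' @param genome_length Genome length (same unit).
#' @return The ratio (x-fold coverage).
#' @examples
#' fold_coverage(100, 50)  # 2
#' @export
fold_coverage <- function(total_mapped_bases, genome_length) {
  if (genome_length <= 0) stop("genome length must be positive")
  total_mapped_bases / genome_length
}
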