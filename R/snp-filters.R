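#' Remove SNPs with unusually high read depth
#'
#' Computes the nearest-rank empirical percentile of all input depths and
#' removes records whose depth is strictly greater. High-depth SNPs are
#' suspect because excess coverage typically marks collapsed repeats or
#' copy-number-variable sequence where genotype calls are unreliable.
#'
#' @param snps Data frame with a numeric `depth` column.
#' @param percentile Percentile cutoff (default 95). Nearest-rank: the
#'   cutoff depth is the value at rank `ceiling(percentile/100 * n)` of the
#'   sorted depths.
#' @return List with `kept` and `removed` data frames; `removed` gains a
#'   `filter_reason` column. The two partitions the input exactly.
#' @examples
#' s <- data.frame(depth = 1:100)
#' nrow(depth_percentile_filter(s)$removed)  # depths 96..100
#' @export
depth_percentile_filter <- function(snps, percentile = 95) {
  if (percentile <= 0 || percentile > 100)
    stop("percentile must be in (0, 100]")
  if (nrow(snps) == 0)
    return(list(kept = snps, removed = cbind(snps, filter_reason = character(0))))
  d <- sort(snps$depth)
  cutoff <- d[ceiling(percentile / 100 * length(d))]
  drop <- snps$depth > cutoff
  removed <- snps[drop, , drop = FALSE]
  if (nrow(removed)) removed$filter_reason <- "high_depth"
  else removed$filter_reason <- character(0)
  list(kept = snps[!drop, , drop = FALSE], removed = removed,
       cutoff = cutoff)
}

#' Remove SNPs whose flanking sequence is not unique in the reference
#'
#' For each SNP, extracts the reference sequence `flank_length` bp either
#' side of the site (2*flank + 1 bp total) and asks a uniqueness predicate
#' whether that sequence has exactly one placement in the reference. The
#' built-in predicate is an exact substring search over both strands of the
#' supplied reference, which is the desk-scale analogue of remapping flanks
#' to an assembly and discarding ambiguous hits.
#'
#' @param snps Data frame with `chrom`, `pos` (1-based), `ref` columns.
#' @param reference A [Biostrings::DNAStringSet] named by chromosome.
#' @param flank_length Flank on each side in bp (default 100).
#' @param predicate Optional function(sequence_character) -> placement
#'   count; defaults to [count_placements()] against `reference`. A SNP is
#'   kept iff the count is exactly 1.
#' @return List with `kept` and `removed` (with `filter_reason`); SNPs
#'   whose flank runs off a contig edge are searched with the truncated
#'   flank and noted in `attr(, "truncated")`.
#' @export
uniqueness_filter <- function(snps, reference, flank_length = 100,
                              predicate = NULL) {
  stopifnot(methods::is(reference, "DNAStringSet"))
  if (is.null(predicate))
    predicate <- function(seqs) count_placements(seqs, reference)
  n <- nrow(snps)
  if (n == 0) {
    removed <- cbind(snps, filter_reason = character(0))
    return(list(kept = snps, removed = removed))
  }
  lens <- Biostrings::width(reference)[match(snps$chrom, names(reference))]
  if (anyNA(lens)) stop("SNP on chromosome absent from reference")
  from <- pmax(1, snps$pos - flank_length)
  to <- pmin(lens, snps$pos + flank_length)
  truncated <- which(from != snps$pos - flank_length |
                       to != snps$pos + flank_length)
  seqs <- as.character(Biostrings::subseq(
    reference[match(snps$chrom, names(reference))], start = from, end = to))
  counts <- predicate(seqs)
  drop <- counts != 1
  removed <- snps[drop, , drop = FALSE]
  if (nrow(removed)) removed$filter_reason <- "ambiguous_placement"
  else removed$filter_reason <- character(0)
  out <- list(kept = snps[!drop, , drop = FALSE], removed = removed)
  attr(out, "truncated") <- truncated
  out
}

#' Count exact placements of query sequences in a reference
#'
#' Strand-aware: occurrences of the query and of its reverse complement are
#' summed over all chromosomes (a palindromic query counts on both strands).
#'
#' @param seqs Character vector of query sequences.
#' @param reference A [Biostrings::DNAStringSet].
#' @return Integer vector of total placement counts.
#' @export
count_placements <- function(seqs, reference) {
  vapply(seqs, function(s) {
    q <- Biostrings::DNAString(s)
    rc <- Biostrings::reverseComplement(q)
    fwd <- sum(Biostrings::vcountPattern(q, reference))
    rev <- sum(Biostrings::vcountPattern(rc, reference))
    as.integer(fwd + rev - (as.character(rc) == s) * fwd)
  }, integer(1), USE.NAMES = FALSE)
}

#' Apply the SNP quality filters in pipeline order
#'
#' Depth filter first, then placement uniqueness, mirroring a
#' high-depth-removal-then-remapping workflow.
#'
#' @inheritParams depth_percentile_filter
#' @inheritParams uniqueness_filter
#' @return List `kept`, `removed` (all removed records with reasons).
#' @export
filter_snps <- function(snps, reference, percentile = 95,
                        flank_length = 100) {
  s1 <- depth_percentile_filter(snps, percentile)
  s2 <- uniqueness_filter(s1$kept, reference, flank_length)
  list(kept = s2$kept, removed = rbind(s1$removed, s2$removed))
}
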