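#' Build an array-vs-sequencing concordance table
#'
#' Compares array genotype calls to a sequencing SNP list at shared
#' positions. A site is \emph{detectable} when the array call is not
#' homozygous for the reference allele, \emph{called} when a sequencing SNP
#' exists at its position, and \emph{concordant} when the sequencing
#' genotype (unordered allele pair) equals the array genotype. Discordant
#' heterozygous sites are broken down into "single allele" cases — the
#' sequencing call is homozygous for one of the two array alleles — and
#' "other" (alleles incompatible with both array alleles).
#'
#' @param array_calls Data frame with columns `marker`, `chrom`, `pos`,
#'   `allele1`, `allele2`, `call` (genotype string, e.g. `"A/G"`) and
#'   optionally `placeable` (logical; unplaceable markers are dropped).
#' @param seq_calls Data frame with columns `chrom`, `pos`, `ref`, `alt`,
#'   `zygosity` (`"het"` or `"hom_alt"`).
#' @param ref_alleles Data frame `chrom`, `pos`, `ref` giving the reference
#'   allele at the array positions; defaults to the `ref` carried by
#'   overlapping sequencing calls plus `allele1` elsewhere, which suits
#'   arrays whose first allele is the reference.
#' @return A `concordance` object: list with `table` (a
#'   `concordance_counts` object) and `discordance` (counts of het
#'   discordance classes).
#' @export
build_concordance <- function(array_calls, seq_calls, ref_alleles = NULL) {
  a <- array_calls
  if (!is.null(a$placeable)) a <- a[a$placeable, , drop = FALSE]
  key_a <- paste(a$chrom, a$pos)
  if (anyDuplicated(key_a)) stop("duplicate array positions")
  key_s <- paste(seq_calls$chrom, seq_calls$pos)
  if (anyDuplicated(key_s)) stop("duplicate sequencing positions")

  if (is.null(ref_alleles)) {
    ref <- a$allele1
    m <- match(key_a, key_s)
    ref[!is.na(m)] <- seq_calls$ref[m[!is.na(m)]]
  } else {
    m <- match(key_a, paste(ref_alleles$chrom, ref_alleles$pos))
    if (anyNA(m)) stop("ref_alleles missing for some array positions")
    ref <- ref_alleles$ref[m]
  }

  hom_ref <- a$call == paste_sorted(ref, ref)
  det <- !hom_ref
  # zygosity of the array call itself
  alleles <- strsplit(a$call, "/", fixed = TRUE)
  a1 <- vapply(alleles, `[`, "", 1); a2 <- vapply(alleles, `[`, "", 2)
  het <- det & a1 != a2
  hom <- det & !het

  m <- match(key_a, key_s)
  called <- det & !is.na(m)
  seq_geno <- rep(NA_character_, nrow(a))
  ok <- which(!is.na(m))
  seq_geno[ok] <- ifelse(seq_calls$zygosity[m[ok]] == "het",
                         paste_sorted(seq_calls$ref[m[ok]],
                                      seq_calls$alt[m[ok]]),
                         paste_sorted(seq_calls$alt[m[ok]],
                                      seq_calls$alt[m[ok]]))
  concordant <- called & !is.na(seq_geno) & seq_geno == a$call

  tab <- concordance_counts(
    n_hom_detectable = sum(hom), n_hom_called = sum(hom & called),
    n_hom_concordant = sum(hom & concordant),
    n_het_detectable = sum(het), n_het_called = sum(het & called),
    n_het_concordant = sum(het & concordant))

  disc <- het & called & !concordant
  single <- disc & (seq_geno == paste_sorted(a1, a1) |
                      seq_geno == paste_sorted(a2, a2))
  breakdown <- list(n_discordant_het = sum(disc),
                    n_single_allele = sum(single, na.rm = TRUE),
                    n_other = sum(disc) - sum(single, na.rm = TRUE))
  structure(list(table = tab, discordance = breakdown),
            class = "concordance")
}

#' Assemble Table-style concordance counts directly
#'
#' Use this when the six contingency counts are already known (for example,
#' from a published comparison) and only the derived rates are needed.
#'
#' @param n_hom_detectable,n_hom_called,n_hom_concordant Counts for
#'   homozygous-variant array calls.
#' @param n_het_detectable,n_het_called,n_het_concordant Counts for
#'   heterozygous array calls.
#' @return A `concordance_counts` list.
#' @export
concordance_counts <- function(n_hom_detectable, n_hom_called,
                               n_hom_concordant, n_het_detectable,
                               n_het_called, n_het_concordant) {
  x <- list(n_hom_detectable = n_hom_detectable,
            n_hom_called = n_hom_called,
            n_hom_concordant = n_hom_concordant,
            n_het_detectable = n_het_detectable,
            n_het_called = n_het_called,
            n_het_concordant = n_het_concordant)
  if (n_hom_concordant > n_hom_called || n_hom_called > n_hom_detectable ||
      n_het_concordant > n_het_called || n_het_called > n_het_detectable)
    stop("need concordant <= called <= detectable for each zygosity")
  structure(x, class = "concordance_counts")
}

#' Detection, concordance and false-negative rates
#'
#' The false-negative rate for each zygosity class is the percentage of
#' detectable array genotypes not concordantly recovered by sequencing:
#' \eqn{(1 - concordant/detectable) \times 100}. Detection is
#' `called/detectable`, concordance `concordant/detectable`.
#'
#' @param x A `concordance_counts` or `concordance` object.
#' @return A list with full-precision percentages `detection_hom`,
#'   `detection_het`, `concordance_hom`, `concordance_het`, `fn_hom`,
#'   `fn_het`, and integer-rounded `fn_hom_pct`, `fn_het_pct`.
#' @export
false_negative_rates <- function(x) {
  if (inherits(x, "concordance")) x <- x$table
  stopifnot(inherits(x, "concordance_counts"))
  if (x$n_hom_detectable == 0 || x$n_het_detectable == 0)
    stop("false-negative rate undefined with zero detectable genotypes")
  out <- list(
    detection_hom = 100 * x$n_hom_called / x$n_hom_detectable,
    detection_het = 100 * x$n_het_called / x$n_het_detectable,
    concordance_hom = 100 * x$n_hom_concordant / x$n_hom_detectable,
    concordance_het = 100 * x$n_het_concordant / x$n_het_detectable,
    fn_hom = 100 * (1 - x$n_hom_concordant / x$n_hom_detectable),
    fn_het = 100 * (1 - x$n_het_concordant / x$n_het_detectable))
  out$fn_hom_pct <- round(out$fn_hom)
  out$fn_het_pct <- round(out$fn_het)
  out
}

#' Custom-panel false-positive rate
#'
#' A putative SNP genotyped across a population and found monomorphic is
#' counted as a false discovery; the false-positive rate is monomorphic
#' divided by tested, as a percentage.
#'
#' @param n_tested Number of SNPs genotyped on the panel, or a data frame
#'   with a logical `monomorphic` column (as from
#'   [simulate_snp_callsets()]`$panel`), in which case `n_monomorphic` is
#'   taken from it.
#' @param n_monomorphic Number found monomorphic.
#' @return List with `fp` and `validated` (percentages, full precision) and
#'   rounded `fp_pct`, `validated_pct`.
#' @export
false_positive_rate <- function(n_tested, n_monomorphic = NULL) {
  if (is.data.frame(n_tested)) {
    n_monomorphic <- sum(n_tested$monomorphic)
    n_tested <- nrow(n_tested)
  }
  if (n_tested <= 0) stop("false-positive rate undefined with zero tested")
  fp <- 100 * n_monomorphic / n_tested
  list(fp = fp, validated = 100 - fp,
       fp_pct = round(fp), validated_pct = round(100 - fp),
       n_tested = n_tested, n_polymorphic = n_tested - n_monomorphic,
       n_monomorphic = n_monomorphic)
}

#' @export
print.concordance <- function(x, ...) {
  t <- x$table; r <- false_negative_rates(t)
  cat("Array vs sequencing concordance\n")
  cat(sprintf("  Homozygous variant: %d detectable, %d called (%.0f%%), %d concordant (%.0f%%)\n",
              t$n_hom_detectable, t$n_hom_called, r$detection_hom,
              t$n_hom_concordant, r$concordance_hom))
  cat(sprintf("  Heterozygous:       %d detectable, %d called (%.0f%%), %d concordant (%.0f%%)\n",
              t$n_het_detectable, t$n_het_called, r$detection_het,
              t$n_het_concordant, r$concordance_het))
  cat(sprintf("  False-negative rates: hom %.0f%%, het %.0f%%\n",
              r$fn_hom, r$fn_het))
  d <- x$discordance
  if (d$n_discordant_het > 0)
    cat(sprintf("  Discordant het calls: %d (%.0f%% single-allele)\n",
                d$n_discordant_het,
                100 * d$n_single_allele / d$n_discordant_het))
  invisible(x)
}
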