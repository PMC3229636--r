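#' Configuration for the SNP truth-set simulator
#'
#' @param n_sites Number of true variant sites to plant.
#' @param fraction_heterozygous Proportion of planted sites that are
#'   heterozygous (the rest are homozygous for the alternate allele).
#' @param miss_rate_hom Probability a homozygous site is missed entirely by
#'   the simulated sequencing calls.
#' @param miss_rate_het Probability a heterozygous site is not concordantly
#'   called by sequencing.
#' @param allele_drop_fraction Of the heterozygous miss events, the fraction
#'   emitted as a homozygous call for the alternate allele only ("allele
#'   drop"); the remainder are emitted as a call involving an allele not
#'   assayed at the site, so the discordance breakdown can estimate this
#'   fraction.
#' @param monomorphic_fraction Proportion of the reported sequencing SNPs
#'   that are false discoveries (monomorphic in the genotyped population).
#' @param depth_mean Mean simulated read depth attached to sequencing calls.
#' @return A `snp_truth_config` list.
#' @export
snp_truth_config <- function(n_sites = 1e4, fraction_heterozygous = 0.5,
                             miss_rate_hom = 0.10, miss_rate_het = 0.21,
                             allele_drop_fraction = 0.98,
                             monomorphic_fraction = 0.02,
                             depth_mean = 20) {
  probs <- c(fraction_heterozygous, miss_rate_hom, miss_rate_het,
             allele_drop_fraction, monomorphic_fraction)
  if (any(probs < 0 | probs > 1))
    stop("all fractions and probabilities must lie in [0, 1]")
  if (n_sites < 1) stop("n_sites must be >= 1")
  structure(list(n_sites = as.integer(n_sites),
                 fraction_heterozygous = fraction_heterozygous,
                 miss_rate_hom = miss_rate_hom,
                 miss_rate_het = miss_rate_het,
                 allele_drop_fraction = allele_drop_fraction,
                 monomorphic_fraction = monomorphic_fraction,
                 depth_mean = depth_mean),
            class = "snp_truth_config")
}

DNA_BASES <- c("A", "C", "G", "T")

#' Simulate matched truth, sequencing, array and panel SNP tables
#'
#' Plants `n_sites` true variant sites on the genome, then derives the four
#' tables the evaluation module compares:
#' \itemize{
#'   \item `truth`: every planted site with its genotype and the sequencing
#'     outcome (`called`, `omitted`, `single_allele`, `other`).
#'   \item `seq`: the sequencing SNP list. Homozygous sites are omitted with
#'     probability `miss_rate_hom`. Heterozygous sites suffer a miss event
#'     with probability `miss_rate_het`; of these, `allele_drop_fraction`
#'     are emitted as homozygous alternate-allele calls (the classic
#'     "sequencing saw only one allele" failure) and the rest as a call for
#'     a third allele not assayed on the array. False-positive sites (not in
#'     the truth set) are appended so that they make up
#'     `monomorphic_fraction` of the reported list.
#'   \item `array`: all truth sites with their correct genotypes, in
#'     two-allele array format.
#'   \item `panel`: a custom-genotyping result over the reported SNPs, with
#'     false-positive sites flagged monomorphic.
#' }
#'
#' @param config A [snp_truth_config()].
#' @param genome A [genome_spec()]; sites are placed uniformly without
#'   replacement, so `n_sites` must not exceed the genome length.
#' @param seed Integer seed.
#' @return A list with data frames `truth`, `seq`, `array`, `panel`.
#' @export
simulate_snp_callsets <- function(config, genome, seed = 1L) {
  stopifnot(inherits(config, "snp_truth_config"),
            inherits(genome, "genome_spec"))
  if (config$n_sites > sum(genome$length))
    stop("n_sites exceeds total genome length")
  with_seed(seed, {
    n <- config$n_sites
    # sample distinct genomic coordinates (linearized over chromosomes);
    # draw extra to also host false-positive sites
    n_false_target <- round(config$monomorphic_fraction /
                              max(1 - config$monomorphic_fraction, 1e-12) * n)
    total_len <- sum(genome$length)
    lin <- sample.int(total_len, n + n_false_target)
    cum <- cumsum(genome$length)
    ci <- findInterval(lin - 0.5, c(0, cum)) # chromosome index per site
    chrom <- genome$chrom[ci]
    pos <- lin - c(0, cum[-length(cum)])[ci]

    ref <- sample(DNA_BASES, n + n_false_target, replace = TRUE)
    alt <- vapply(ref, function(r) sample(setdiff(DNA_BASES, r), 1), "")
    is_true <- seq_along(lin) <= n

    zyg <- ifelse(stats::runif(n) < config$fraction_heterozygous,
                  "het", "hom_alt")
    truth <- data.frame(chrom = chrom[is_true], pos = pos[is_true],
                        ref = ref[is_true], alt = alt[is_true],
                        zygosity = zyg, stringsAsFactors = FALSE)

    outcome <- rep("called", n)
    is_het <- zyg == "het"
    miss <- ifelse(is_het, stats::runif(n) < config$miss_rate_het,
                   stats::runif(n) < config$miss_rate_hom)
    drop_branch <- stats::runif(n) < config$allele_drop_fraction
    outcome[miss & !is_het] <- "omitted"
    outcome[miss & is_het & drop_branch] <- "single_allele"
    outcome[miss & is_het & !drop_branch] <- "other"
    truth$outcome <- outcome

    # build the sequencing list
    emit <- outcome != "omitted"
    seq_alt <- truth$alt
    seq_zyg <- truth$zygosity
    seq_zyg[outcome %in% c("single_allele", "other")] <- "hom_alt"
    third <- which(outcome == "other")
    if (length(third))
      seq_alt[third] <- vapply(third, function(i)
        sample(setdiff(DNA_BASES, c(truth$ref[i], truth$alt[i])), 1), "")
    seq_tab <- data.frame(chrom = truth$chrom[emit], pos = truth$pos[emit],
                          ref = truth$ref[emit], alt = seq_alt[emit],
                          zygosity = seq_zyg[emit],
                          stringsAsFactors = FALSE)
    false_tab <- data.frame(chrom = chrom[!is_true], pos = pos[!is_true],
                            ref = ref[!is_true], alt = alt[!is_true],
                            zygosity = sample(c("het", "hom_alt"),
                                              sum(!is_true), replace = TRUE),
                            stringsAsFactors = FALSE)
    false_tab$is_false <- if (nrow(false_tab)) TRUE else logical(0)
    seq_tab$is_false <- if (nrow(seq_tab)) FALSE else logical(0)
    seq_all <- rbind(seq_tab, false_tab)
    seq_all <- seq_all[order(match(seq_all$chrom, genome$chrom),
                             seq_all$pos), , drop = FALSE]
    seq_all$depth <- stats::rpois(nrow(seq_all), config$depth_mean) + 1L
    rownames(seq_all) <- NULL

    geno <- function(ref, alt, zyg)
      ifelse(zyg == "het", paste_sorted(ref, alt), paste_sorted(alt, alt))
    array_tab <- data.frame(
      marker = sprintf("mk%07d", seq_len(n)),
      chrom = truth$chrom, pos = truth$pos,
      allele1 = truth$ref, allele2 = truth$alt,
      call = geno(truth$ref, truth$alt, truth$zygosity),
      placeable = TRUE, stringsAsFactors = FALSE)

    panel <- data.frame(snp_id = paste0(seq_all$chrom, ":", seq_all$pos),
                        monomorphic = seq_all$is_false,
                        stringsAsFactors = FALSE)
    seq_out <- seq_all[, c("chrom", "pos", "ref", "alt", "zygosity", "depth")]
    list(truth = truth, seq = seq_out, array = array_tab, panel = panel)
  })
}

# unordered genotype string, e.g. "A/G"
paste_sorted <- function(a, b) {
  ifelse(a <= b, paste(a, b, sep = "/"), paste(b, a, sep = "/"))
}
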