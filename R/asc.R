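AA_ALPHABET <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                 "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

# BLOSUM62 log-odds substitution scores over the 20 standard residues,
# row/column order as AA_ALPHABET.
BLOSUM62_VALUES <- c(
   4, -1, -2, -2,  0, -1, -1,  0, -2, -1, -1, -1, -1, -2, -1,  1,  0, -3, -2,  0,
  -1,  5,  0, -2, -3,  1,  0, -2,  0, -3, -2,  2, -1, -3, -2, -1, -1, -3, -2, -3,
  -2,  0,  6,  1, -3,  0,  0,  0,  1, -3, -3,  0, -2, -3, -2,  1,  0, -4, -2, -3,
  -2, -2,  1,  6, -3,  0,  2, -1, -1, -3, -4, -1, -3, -3, -1,  0, -1, -4, -3, -3,
   0, -3, -3, -3,  9, -3, -4, -3, -3, -1, -1, -3, -1, -2, -3, -1, -1, -2, -2, -1,
  -1,  1,  0,  0, -3,  5,  2, -2,  0, -3, -2,  1,  0, -3, -1,  0, -1, -2, -1, -2,
  -1,  0,  0,  2, -4,  2,  5, -2,  0, -3, -3,  1, -2, -3, -1,  0, -1, -3, -2, -2,
   0, -2,  0, -1, -3, -2, -2,  6, -2, -4, -4, -2, -3, -3, -2,  0, -2, -2, -3, -3,
  -2,  0,  1, -1, -3,  0,  0, -2,  8, -3, -3, -1, -2, -1, -2, -1, -2, -2,  2, -3,
  -1, -3, -3, -3, -1, -3, -3, -4, -3,  4,  2, -3,  1,  0, -3, -2, -1, -3, -1,  3,
  -1, -2, -3, -4, -1, -2, -3, -4, -3,  2,  4, -2,  2,  0, -3, -2, -1, -2, -1,  1,
  -1,  2,  0, -1, -3,  1,  1, -2, -1, -3, -2,  5, -1, -3, -1,  0, -1, -3, -2, -2,
  -1, -1, -2, -3, -1,  0, -2, -3, -2,  1,  2, -1,  5,  0, -2, -1, -1, -1, -1,  1,
  -2, -3, -3, -3, -2, -3, -3, -3, -1,  0,  0, -3,  0,  6, -4, -2, -2,  1,  3, -1,
  -1, -2, -2, -1, -3, -1, -1, -2, -2, -3, -3, -1, -2, -4,  7, -1, -1, -4, -3, -2,
   1, -1,  1,  0, -1,  0,  0,  0, -1, -2, -2,  0, -1, -2, -1,  4,  1, -3, -2, -2,
   0, -1,  0, -1, -1, -1, -1, -2, -2, -1, -1, -1, -1, -2, -1,  1,  5, -2, -2,  0,
  -3, -3, -4, -4, -2, -2, -3, -2, -2, -3, -2, -3, -1,  1, -4, -3, -2, 11,  2, -3,
  -2, -2, -2, -3, -2, -1, -2, -3,  2, -1, -1, -2, -1,  3, -3, -2, -2,  2,  7, -1,
   0, -3, -3, -3, -1, -2, -2, -3, -3,  3,  1, -2,  1, -1, -2, -2,  0, -3, -1,  4)

#' The BLOSUM62 substitution matrix
#'
#' Returns the 20x20 BLOSUM62 log-odds score matrix over the standard amino
#' acids, the matrix used to weigh residue substitutions when scoring
#' variant conservation against orthologues.
#'
#' @return Integer matrix with residue dimnames.
#' @examples
#' blosum62()["D", "D"]  # 6
#' blosum62()["A", "D"]  # -2
#' @export
blosum62 <- function() {
  matrix(as.integer(BLOSUM62_VALUES), nrow = 20, byrow = TRUE,
         dimnames = list(AA_ALPHABET, AA_ALPHABET))
}

check_residues <- function(x) {
  bad <- setdiff(unique(x), AA_ALPHABET)
  if (length(bad))
    stop("nonstandard residue(s): ", paste(bad, collapse = ", "))
  invisible(x)
}

#' Alignment score change of a variant residue against orthologues
#'
#' Quantifies how a coding variant shifts a protein's resemblance to its
#' orthologues: the mean BLOSUM62 score of the variant residue \eqn{v}
#' against each orthologous residue \eqn{o}, minus the mean score of the
#' reference residue \eqn{r} against the same orthologues,
#' \deqn{a = \frac{\sum_o s(v, o)}{n} - \frac{\sum_o s(r, o)}{n}.}
#' Negative values mean the variant breaks conservation; positive values
#' mean it restores it. With no orthologues the score is undefined (not
#' zero).
#'
#' @param ref Reference residue (1-letter code).
#' @param var Variant residue.
#' @param orthologues Character vector of orthologous residues (may be
#'   empty).
#' @param matrix Substitution score matrix; default [blosum62()].
#' @return List with `a` (the score; `NA` when undefined), `n_orthologues`
#'   and `defined`.
#' @examples
#' asc("A", "D", c("D", "D"))$a  # s(D,D) - s(A,D) = 6 - (-2) = 8
#' @export
asc <- function(ref, var, orthologues, matrix = blosum62()) {
  check_residues(c(ref, var, orthologues))
  n <- length(orthologues)
  if (n == 0)
    return(list(a = NA_real_, n_orthologues = 0L, defined = FALSE))
  a <- sum(matrix[var, orthologues]) / n - sum(matrix[ref, orthologues]) / n
  list(a = a, n_orthologues = n, defined = TRUE)
}

#' Score a table of orthologue panels
#'
#' @param panels Data frame with columns `snp_id`, `ref_aa`, `var_aa`,
#'   `orthologue_residues` (comma-separated string, possibly empty), as
#'   written by [simulate_orthologue_panels()].
#' @return The input with `asc`, `n_orthologues` and `defined` columns
#'   appended.
#' @export
asc_panels <- function(panels) {
  res <- lapply(seq_len(nrow(panels)), function(i) {
    o <- panels$orthologue_residues[i]
    o <- if (is.na(o) || o == "") character(0)
         else strsplit(o, ",", fixed = TRUE)[[1]]
    asc(panels$ref_aa[i], panels$var_aa[i], o)
  })
  panels$asc <- vapply(res, `[[`, numeric(1), "a")
  panels$n_orthologues <- vapply(res, `[[`, integer(1), "n_orthologues")
  panels$defined <- vapply(res, `[[`, logical(1), "defined")
  panels
}

#' Bin nonsynonymous SNPs by alignment score change
#'
#' Histograms defined ASC values into bins of fixed width anchored so that
#' zero is a bin edge, and reports per-bin the count, the proportion of
#' heterozygous SNPs, and the proportion shared with the other animal —
#' the binned profile used to show that conservation-breaking variants tend
#' to be heterozygous and private.
#'
#' @param records Data frame with numeric `asc`, logical `heterozygous`
#'   and logical `shared` columns; rows with `NA` asc are dropped.
#' @param bin_width Bin width in score units (default 3).
#' @return An `asc_profile` data frame with columns `bin_lo`, `bin_hi`,
#'   `count`, `proportion_heterozygous`, `proportion_shared`.
#' @export
asc_bin_profile <- function(records, bin_width = 3) {
  records <- records[!is.na(records$asc), , drop = FALSE]
  if (nrow(records) == 0) {
    out <- data.frame(bin_lo = numeric(), bin_hi = numeric(),
                      count = integer(), proportion_heterozygous = numeric(),
                      proportion_shared = numeric())
    class(out) <- c("asc_profile", "data.frame")
    return(out)
  }
  lo <- floor(min(records$asc) / bin_width) * bin_width
  hi <- ceiling(max(records$asc) / bin_width) * bin_width
  if (hi == lo) hi <- lo + bin_width
  edges <- seq(lo, hi, by = bin_width)
  bin <- findInterval(records$asc, edges, rightmost.closed = TRUE)
  out <- do.call(rbind, lapply(seq_len(length(edges) - 1), function(b) {
    in_bin <- bin == b
    data.frame(bin_lo = edges[b], bin_hi = edges[b + 1],
               count = sum(in_bin),
               proportion_heterozygous =
                 if (any(in_bin)) mean(records$heterozygous[in_bin]) else NA_real_,
               proportion_shared =
                 if (any(in_bin)) mean(records$shared[in_bin]) else NA_real_)
  }))
  class(out) <- c("asc_profile", "data.frame")
  out
}

#' Simulate orthologue residue panels
#'
#' For each simulated nonsynonymous SNP, draws a reference residue, a
#' distinct variant residue, and `n_species` orthologous residues each equal
#' to the reference with probability `conservation` (otherwise a uniformly
#' random different residue).
#'
#' @param n_snps Number of panels.
#' @param n_species Orthologues per panel; scalar or vector (may be 0).
#' @param conservation Probability an orthologue residue matches the
#'   reference, in `[0, 1]`.
#' @param seed Integer seed.
#' @return Data frame `snp_id`, `ref_aa`, `var_aa`, `orthologue_residues`
#'   (comma-separated).
#' @export
simulate_orthologue_panels <- function(n_snps, n_species = 6,
                                       conservation = 0.8, seed = 1L) {
  if (conservation < 0 || conservation > 1)
    stop("conservation must lie in [0, 1]")
  if (any(n_species < 0)) stop("n_species must be >= 0")
  n_species <- rep_len(as.integer(n_species), n_snps)
  with_seed(seed, {
    ref <- sample(AA_ALPHABET, n_snps, replace = TRUE)
    var <- vapply(ref, function(r) sample(setdiff(AA_ALPHABET, r), 1), "")
    orth <- vapply(seq_len(n_snps), function(i) {
      k <- n_species[i]
      if (k == 0) return("")
      keep <- stats::runif(k) < conservation
      o <- character(k)
      o[keep] <- ref[i]
      if (any(!keep))
        o[!keep] <- sample(setdiff(AA_ALPHABET, ref[i]), sum(!keep),
                           replace = TRUE)
      paste(o, collapse = ",")
    }, "")
    data.frame(snp_id = sprintf("snp%05d", seq_len(n_snps)),
               ref_aa = ref, var_aa = var, orthologue_residues = orth,
               stringsAsFactors = FALSE)
  })
}
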