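#' Simulate mapped-read placements for two samples
#'
#' Draws single-base read start positions for two samples along a reference,
#' with Poisson counts whose local rate is proportional to each sample's
#' planted copy number. This emulates the "best-hit" placement tables a
#' read-depth CNV caller consumes: one row per mapped read, positions only,
#' no fragment structure.
#'
#' The expected number of sample-\emph{s} reads starting in any interval of
#' length `window_hint` with copy number \eqn{c_s} is
#' \eqn{(c_s / 2) \times} `mean_depth_s`, so a diploid (copy 2) region
#' averages `mean_depth` reads per window-equivalent.
#'
#' @param genome A [genome_spec()].
#' @param plan A [cnv_plan()]; segments must lie inside the genome.
#' @param mean_depth_a,mean_depth_b Expected reads per `window_hint` bp at
#'   copy number 2, per sample (> 0).
#' @param window_hint Reference interval (bp) over which mean depth is
#'   expressed. Default 1000.
#' @param seed Integer seed; identical seeds give identical placements.
#' @return A list with elements `a` and `b` (data frames with columns
#'   `chrom`, `pos`; 1-based read start positions, sorted), and `truth`, the
#'   plan echoed back with the per-sample rates used.
#' @seealso [write_placements()], [count_reads_in_windows()]
#' @export
simulate_read_placements <- function(genome, plan = cnv_plan(),
                                     mean_depth_a, mean_depth_b,
                                     window_hint = 1000, seed = 1L) {
  stopifnot(inherits(genome, "genome_spec"))
  if (mean_depth_a <= 0 || mean_depth_b <= 0)
    stop("mean depths must be positive")
  if (window_hint < 1) stop("window_hint must be >= 1")
  bad <- !(plan$chrom %in% genome$chrom)
  if (any(bad)) stop("cnv_plan segment on unknown chromosome: ",
                     paste(unique(plan$chrom[bad]), collapse = ", "))
  with_seed(seed, {
    draw <- function(depth, col) {
      chroms <- character(0); pos <- numeric(0)
      for (i in seq_len(nrow(genome))) {
        ch <- genome$chrom[i]; len <- genome$length[i]
        steps <- plan_steps(plan, ch, len)
        for (j in seq_len(nrow(steps))) {
          seg_len <- steps$end[j] - steps$start[j] + 1
          rate <- (steps[[col]][j] / 2) * depth / window_hint
          n <- stats::rpois(1, rate * seg_len)
          if (n > 0) {
            p <- steps$start[j] + floor(stats::runif(n) * seg_len)
            chroms <- c(chroms, rep(ch, n)); pos <- c(pos, p)
          }
        }
      }
      out <- data.frame(chrom = chroms, pos = pos, stringsAsFactors = FALSE)
      out[order(match(out$chrom, genome$chrom), out$pos), , drop = FALSE]
    }
    a <- draw(mean_depth_a, "copy_a")
    b <- draw(mean_depth_b, "copy_b")
    truth <- as.data.frame(plan)
    list(a = a, b = b, truth = truth,
         mean_depth = c(a = mean_depth_a, b = mean_depth_b),
         window_hint = window_hint)
  })
}

#' Write or read a read-placement table
#'
#' Placements are stored as headered TSV with columns `chrom` and `pos`
#' (1-based read start), one row per mapped read.
#'
#' @param placements Data frame with columns `chrom`, `pos`.
#' @param path Output (or input) file path.
#' @return `write_placements()` returns `path` invisibly; `read_placements()`
#'   returns the data frame.
#' @export
write_placements <- function(placements, path) {
  utils::write.table(placements[, c("chrom", "pos")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_placements
#' @export
read_placements <- function(path) {
  out <- utils::read.table(path, header = TRUE, sep = "\t",
                           colClasses = c("character", "numeric"))
  names(out) <- c("chrom", "pos")
  out
}
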