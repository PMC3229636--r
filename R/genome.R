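#' Describe a reference genome for simulation
#'
#' A minimal stand-in for a reference assembly: a set of uniquely named
#' chromosomes with positive lengths. All simulators and the CNV caller take
#' one of these to know the coordinate space they operate in.
#'
#' @param names Character vector of chromosome labels (unique).
#' @param lengths Integer-like vector of chromosome lengths in bp (> 0),
#'   same length as `names`.
#' @return An object of class `genome_spec`: a data frame with columns
#'   `chrom` and `length`.
#' @examples
#' genome_spec(c("1", "2"), c(2e5, 1e5))
#' @export
genome_spec <- function(names, lengths) {
  names <- as.character(names)
  lengths <- as.numeric(lengths)
  if (length(names) != length(lengths))
    stop("`names` and `lengths` must have equal length")
  if (anyDuplicated(names))
    stop("chromosome names must be unique")
  if (any(!is.finite(lengths)) || any(lengths <= 0))
    stop("chromosome lengths must be positive")
  out <- data.frame(chrom = names, length = floor(lengths),
                    stringsAsFactors = FALSE)
  class(out) <- c("genome_spec", "data.frame")
  out
}

#' @export
print.genome_spec <- function(x, ...) {
  cat(sprintf("<genome_spec> %d chromosome(s), %.3g bp total\n",
              nrow(x), sum(x$length)))
  print.data.frame(utils::head(as.data.frame(x), 10))
  if (nrow(x) > 10) cat("...\n")
  invisible(x)
}

chrom_length <- function(genome, chrom) {
  i <- match(as.character(chrom), genome$chrom)
  if (anyNA(i)) stop("unknown chromosome: ",
                     paste(unique(chrom[is.na(i)]), collapse = ", "))
  genome$length[i]
}

#' Plan copy-number segments for two samples
#'
#' Defines the "truth" copy states used by [simulate_read_placements()]. Any
#' position not covered by a segment has copy number 2 in both samples.
#'
#' @param chrom,start,end Segment coordinates (1-based, inclusive; vectors
#'   recycled to a common length). Segments must not overlap within a
#'   chromosome.
#' @param copy_a,copy_b Non-negative copy numbers of samples A and B over the
#'   segment. Fractional values are allowed (e.g. mosaic or partial dosage).
#' @return A `cnv_plan` data frame.
#' @export
cnv_plan <- function(chrom = character(), start = numeric(),
                     end = numeric(), copy_a = numeric(),
                     copy_b = numeric()) {
  out <- data.frame(chrom = as.character(chrom), start = as.numeric(start),
                    end = as.numeric(end), copy_a = as.numeric(copy_a),
                    copy_b = as.numeric(copy_b), stringsAsFactors = FALSE)
  if (nrow(out)) {
    if (any(out$end <= out$start)) stop("segment end must exceed start")
    if (any(out$copy_a < 0 | out$copy_b < 0))
      stop("copy numbers must be non-negative")
    for (ch in unique(out$chrom)) {
      seg <- out[out$chrom == ch, , drop = FALSE]
      seg <- seg[order(seg$start), , drop = FALSE]
      if (nrow(seg) > 1 && any(seg$start[-1] <= seg$end[-nrow(seg)]))
        stop("segments overlap on chromosome ", ch)
    }
  }
  class(out) <- c("cnv_plan", "data.frame")
  out
}

# Evaluate sample copy number along one chromosome as a step function.
# Returns breakpoints (starts of constant-copy intervals, 1-based) and the
# per-interval copy numbers for both samples, covering [1, len].
plan_steps <- function(plan, chrom, len) {
  seg <- plan[plan$chrom == chrom, , drop = FALSE]
  seg <- seg[order(seg$start), , drop = FALSE]
  if (nrow(seg) && any(seg$start < 1 | seg$end > len))
    stop("cnv_plan segment outside chromosome bounds on ", chrom)
  starts <- 1; ca <- 2; cb <- 2
  pos <- 1
  if (nrow(seg)) {
    starts <- numeric(0); ca <- numeric(0); cb <- numeric(0)
    for (i in seq_len(nrow(seg))) {
      if (seg$start[i] > pos) {
        starts <- c(starts, pos); ca <- c(ca, 2); cb <- c(cb, 2)
      }
      starts <- c(starts, seg$start[i])
      ca <- c(ca, seg$copy_a[i]); cb <- c(cb, seg$copy_b[i])
      pos <- seg$end[i] + 1
    }
    if (pos <= len) { starts <- c(starts, pos); ca <- c(ca, 2); cb <- c(cb, 2) }
  }
  ends <- c(starts[-1] - 1, len)
  data.frame(start = starts, end = ends, copy_a = ca, copy_b = cb)
}

# Run `expr` under a private RNG stream seeded with `seed`, restoring the
# caller's stream afterwards so simulators are deterministic without
# clobbering the session RNG.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    set.seed(as.integer(seed))
    on.exit({
      if (is.null(old)) rm(".Random.seed", envir = globalenv())
      else assign(".Random.seed", old, envir = globalenv())
    })
  }
  expr
}
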