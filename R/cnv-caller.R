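#' Merge runs of significant windows into CNV calls
#'
#' Scans the window statistics in positional order and reports every maximal
#' run of at least `min_windows` consecutive significant windows sharing the
#' sign of their log2 ratio as one CNV. "Consecutive" means adjacent in the
#' sliding-window order within a chromosome; a single non-significant window
#' (or a sign change) breaks a run, which is how a real dosage change can be
#' split into several reported CNVs when depth dips mid-segment.
#'
#' @param stats A `window_stats` track from [window_ratio_test()], ordered
#'   by chromosome then start (the order the window functions emit).
#' @param config A [caller_config()]; only `min_windows` is used here.
#' @return A `cnv_calls` data frame with columns `id` (Chr{chrom}_CNV_{k},
#'   numbered per chromosome in positional order), `chrom`, `start`, `end`
#'   (0-based half-open, spanning first window start to last window end),
#'   `mean_log2_ratio`, `combined_p` (minimum member p-value), `n_windows`
#'   and `direction` (`"gain_in_A"` when the mean log2 ratio is positive,
#'   else `"gain_in_B"`).
#' @export
call_cnvs <- function(stats, config = caller_config()) {
  grouped <- length(rle(stats$chrom)$values) == length(unique(stats$chrom))
  within_sorted <- all(vapply(unique(stats$chrom), function(ch)
    !is.unsorted(stats$start[stats$chrom == ch]), logical(1)))
  if (!grouped || !within_sorted)
    stop("window stats must be ordered by chromosome then start")
  sig <- stats$significant
  sgn <- sign(stats$log2_ratio)
  sgn[!sig | is.na(sgn)] <- 0
  # run key: chromosome + sign; zero-sign windows never extend a run
  key <- paste(stats$chrom, sgn)
  run_id <- cumsum(c(TRUE, key[-1] != key[-length(key)]))
  keep <- sgn != 0
  calls <- list()
  for (r in unique(run_id[keep])) {
    idx <- which(run_id == r)
    if (length(idx) < config$min_windows) next
    w <- stats[idx, , drop = FALSE]
    m <- mean(w$log2_ratio)
    calls[[length(calls) + 1]] <- data.frame(
      chrom = w$chrom[1], start = min(w$start), end = max(w$end),
      mean_log2_ratio = m, combined_p = min(w$p_value),
      n_windows = length(idx),
      direction = if (m > 0) "gain_in_A" else "gain_in_B",
      stringsAsFactors = FALSE)
  }
  out <- if (length(calls)) do.call(rbind, calls) else
    data.frame(chrom = character(), start = numeric(), end = numeric(),
               mean_log2_ratio = numeric(), combined_p = numeric(),
               n_windows = integer(), direction = character())
  # per-chromosome positional ids, Chr{N}_CNV_{k}
  out <- out[order(match(out$chrom, unique(stats$chrom)), out$start), ,
             drop = FALSE]
  id <- character(0)
  if (nrow(out)) {
    k <- stats::ave(seq_len(nrow(out)), out$chrom, FUN = seq_along)
    label <- ifelse(grepl("^chr", out$chrom, ignore.case = TRUE),
                    out$chrom, paste0("Chr", out$chrom))
    id <- sprintf("%s_CNV_%d", label, k)
  }
  out <- cbind(id = id, out, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "config") <- config
  for (a in c("window_length", "advance"))
    attr(out, a) <- attr(stats, a)
  class(out) <- c("cnv_calls", "data.frame")
  out
}

#' Run the full two-sample read-depth CNV pipeline
#'
#' Convenience wrapper: counts reads in sliding windows (auto-sizing the
#' window from the library totals unless `config$window_length` is set),
#' tests every window with the Poisson ratio test, and merges significant
#' runs into calls.
#'
#' @inheritParams count_reads_in_windows
#' @param config A [caller_config()].
#' @return A `cnv_calls` object; the tested `window_stats` track is attached
#'   as `attr(, "window_stats")` for plotting.
#' @export
detect_cnvs <- function(placements_a, placements_b, genome,
                        config = caller_config()) {
  wl <- config$window_length
  if (is.null(wl))
    wl <- auto_window_length(sum(genome$length), nrow(placements_a),
                             nrow(placements_b), config)
  counts <- count_reads_in_windows(placements_a, placements_b, genome,
                                   window_length = wl)
  stats <- window_ratio_test(counts, config = config)
  calls <- call_cnvs(stats, config)
  attr(calls, "window_stats") <- stats
  calls
}

#' @export
print.cnv_calls <- function(x, ...) {
  cat(sprintf("<cnv_calls> %d CNV(s)", nrow(x)))
  wl <- attr(x, "window_length")
  if (!is.null(wl))
    cat(sprintf(" (window %d bp, advance %d bp)", wl, attr(x, "advance")))
  cat("\n")
  if (nrow(x)) print.data.frame(utils::head(as.data.frame(x), 10), digits = 4)
  if (nrow(x) > 10) cat("...\n")
  invisible(x)
}

#' @export
summary.cnv_calls <- function(object, ...) {
  n <- nrow(object)
  len <- object$end - object$start
  cat(sprintf("CNV calls: %d (%d gain_in_A, %d gain_in_B)\n", n,
              sum(object$direction == "gain_in_A"),
              sum(object$direction == "gain_in_B")))
  if (n) {
    cat(sprintf("Lengths (bp): mean %.0f, median %.0f, range %d-%d\n",
                mean(len), stats::median(len), min(len), max(len)))
    cat(sprintf("Total length in CNV: %d bp\n", sum(len)))
  }
  invisible(object)
}

#' Plot window log2 ratios with calls highlighted
#'
#' Draws the per-window normalized log2 read-count ratio along one
#' chromosome and shades the called CNV intervals, in the style of a
#' read-depth ratio track.
#'
#' @param x A `cnv_calls` object carrying its `window_stats` attribute
#'   (as returned by [detect_cnvs()]).
#' @param chrom Chromosome to draw (default: first with data).
#' @param ... Passed to [plot()].
#' @export
plot.cnv_calls <- function(x, chrom = NULL, ...) {
  stats <- attr(x, "window_stats")
  if (is.null(stats)) stop("no window_stats attached; use detect_cnvs()")
  if (is.null(chrom)) chrom <- stats$chrom[1]
  s <- stats[stats$chrom == chrom, , drop = FALSE]
  mid <- (s$start + s$end) / 2
  lr <- s$log2_ratio
  lr[!is.finite(lr)] <- NA
  plot(mid, lr, pch = 20, cex = 0.4,
       col = ifelse(s$significant, "firebrick", "grey40"),
       xlab = sprintf("position on %s (bp)", chrom),
       ylab = "log2 read-count ratio (A/B)", ...)
  graphics::abline(h = 0, col = "grey70")
  calls <- x[x$chrom == chrom, , drop = FALSE]
  if (nrow(calls)) {
    usr <- graphics::par("usr")
    graphics::rect(calls$start, usr[3], calls$end, usr[4],
                   col = grDevices::adjustcolor("steelblue", 0.2), border = NA)
  }
  invisible(x)
}

#' Write CNV calls as BED and TSV
#'
#' @param calls A `cnv_calls` object.
#' @param bed,tsv Output paths (either may be `NULL` to skip).
#' @return Invisibly, the paths written.
#' @export
write_cnv_calls <- function(calls, bed = NULL, tsv = NULL) {
  if (!is.null(bed)) {
    bed_df <- data.frame(calls$chrom, format(calls$start, scientific = FALSE,
                                             trim = TRUE),
                         format(calls$end, scientific = FALSE, trim = TRUE),
                         calls$id)
    utils::write.table(bed_df, bed, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  if (!is.null(tsv))
    utils::write.table(as.data.frame(calls), tsv, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  invisible(c(bed = bed, tsv = tsv))
}
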