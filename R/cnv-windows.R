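#' Count read starts in sliding windows
#'
#' Tiles every chromosome with half-open windows
#' \code{[k*advance, k*advance + window_length)} (0-based) and counts, for
#' each of two samples, the read starts falling in each window. A trailing
#' window that would extend past the chromosome end is dropped. Read
#' positions are 1-based on input (a read at position p occupies 0-based
#' coordinate p - 1).
#'
#' @param placements_a,placements_b Data frames with columns `chrom`, `pos`
#'   (as from [simulate_read_placements()] or [read_placements()]).
#' @param genome A [genome_spec()] giving chromosome lengths.
#' @param window_length Window length in bp.
#' @param advance Step between successive window starts, in bp;
#'   `window_length >= advance >= 1`. Defaults to `window_length / 2`
#'   (half-overlapping sliding windows).
#' @return A `window_counts` data frame with columns `chrom`, `start`, `end`
#'   (0-based half-open), `x` (sample A count), `y` (sample B count).
#'   Reads beyond the chromosome end are skipped with a warning; the number
#'   skipped is kept in `attr(, "n_skipped")`.
#' @examples
#' g <- genome_spec("1", 20)
#' a <- data.frame(chrom = "1", pos = 1:10)
#' count_reads_in_windows(a, a[0, ], g, window_length = 10, advance = 5)
#' @export
count_reads_in_windows <- function(placements_a, placements_b, genome,
                                   window_length,
                                   advance = window_length / 2) {
  stopifnot(inherits(genome, "genome_spec"))
  window_length <- as.integer(window_length)
  advance <- as.integer(advance)
  if (advance < 1 || window_length < advance)
    stop("need window_length >= advance >= 1")

  n_skipped <- 0L
  rows <- vector("list", nrow(genome))
  for (i in seq_len(nrow(genome))) {
    ch <- genome$chrom[i]; len <- genome$length[i]
    n_win <- (len - window_length) %/% advance + 1
    if (n_win < 1) { rows[[i]] <- NULL; next }
    starts <- (seq_len(n_win) - 1) * advance
    count_one <- function(pl) {
      p <- pl$pos[pl$chrom == ch] - 1        # to 0-based
      out_of_range <- p < 0 | p >= len
      n_skipped <<- n_skipped + sum(out_of_range)
      p <- sort(p[!out_of_range])
      # count in [s, s+L) = #{p <= s+L-1} - #{p <= s-1}
      findInterval(starts + window_length - 1, p) - findInterval(starts - 1, p)
    }
    rows[[i]] <- data.frame(chrom = ch, start = starts,
                            end = starts + window_length,
                            x = count_one(placements_a),
                            y = count_one(placements_b),
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(chrom = character(), start = numeric(),
                      end = numeric(), x = integer(), y = integer())
  if (n_skipped > 0)
    warning(n_skipped, " read placement(s) beyond chromosome bounds skipped")
  attr(out, "n_skipped") <- n_skipped
  attr(out, "window_length") <- window_length
  attr(out, "advance") <- advance
  class(out) <- c("window_counts", "data.frame")
  out
}

# Geary-Hinkley tail probability for an observed Poisson count ratio z = x/y
# against null means mu_x, mu_y: t = (mu_y*z - mu_x)/sqrt(mu_y*z^2 + mu_x)
# is treated as standard normal. Handles z = Inf (y = 0, x > 0) by its
# analytic limit t -> sqrt(mu_y).
gh_statistic <- function(x, y, mu_x, mu_y) {
  z <- x / y
  t <- ifelse(is.infinite(z), sqrt(mu_y),
              (mu_y * z - mu_x) / sqrt(mu_y * z^2 + mu_x))
  t
}

#' Two-sample Poisson ratio test on window counts
#'
#' For each window, computes the normalized log2 read-count ratio
#' \deqn{\log_2\{(x / N_A) / (y / N_B)\}} and a two-sided p-value for a
#' departure from equal copy number. Significance of the count ratio
#' \eqn{z = x/y} is assessed with the Geary-Hinkley transformation of a
#' ratio of Poisson variables: with null per-window means
#' \eqn{\mu_x = N_A/W} and \eqn{\mu_y = N_B/W} (W = number of windows),
#' \eqn{t = (\mu_y z - \mu_x)/\sqrt{\mu_y z^2 + \mu_x}} is treated as
#' standard normal and \eqn{p = 2\Phi(-|t|)}.
#'
#' Windows with `x = 0` and `y = 0` get `NA` log2 ratio and p-value and are
#' never significant. `y = 0` with `x > 0` yields a `+Inf` log2 sentinel
#' (`-Inf` for the mirror case) with the p-value from the transform's limit.
#'
#' @param counts A `window_counts` track from [count_reads_in_windows()].
#' @param total_a,total_b Library sizes used for normalization; default to
#'   the track sums.
#' @param config A [caller_config()] supplying the significance thresholds.
#' @return A `window_stats` data frame: the track columns plus `log2_ratio`,
#'   `p_value` and `significant` (p <= p_threshold AND |log2| >=
#'   log2_threshold).
#' @export
window_ratio_test <- function(counts, total_a = sum(counts$x),
                              total_b = sum(counts$y),
                              config = caller_config()) {
  if (total_a <= 0 || total_b <= 0) stop("library totals must be positive")
  n_win <- nrow(counts)
  mu_x <- total_a / n_win
  mu_y <- total_b / n_win
  x <- counts$x; y <- counts$y
  log2_ratio <- log2((x / total_a) / (y / total_b))
  log2_ratio[x == 0 & y == 0] <- NA_real_
  t <- gh_statistic(x, y, mu_x, mu_y)
  p <- 2 * stats::pnorm(-abs(t))
  empty <- x == 0 & y == 0
  p[empty] <- NA_real_
  sig <- !empty & p <= config$p_threshold &
    abs(log2_ratio) >= config$log2_threshold
  sig[is.na(sig)] <- FALSE
  out <- as.data.frame(counts)
  out$log2_ratio <- log2_ratio
  out$p_value <- p
  out$significant <- sig
  for (a in c("window_length", "advance"))
    attr(out, a) <- attr(counts, a)
  attr(out, "totals") <- c(a = total_a, b = total_b)
  class(out) <- c("window_stats", "data.frame")
  out
}

#' Detection-threshold configuration for the CNV caller
#'
#' @param p_threshold Per-window two-sided p-value threshold (default 0.001).
#' @param log2_threshold Minimum |log2 ratio| for a window to count as
#'   significant (default 0.6).
#' @param min_windows Minimum number of consecutive significant sliding
#'   windows required to report a CNV (default 10).
#' @param window_multiplier Multiplier applied to the minimal detectable
#'   window length by [auto_window_length()] (default 2).
#' @param window_length Optional explicit window length in bp; when `NULL`
#'   the automatic sizing is used.
#' @return A `caller_config` list.
#' @export
caller_config <- function(p_threshold = 0.001, log2_threshold = 0.6,
                          min_windows = 10, window_multiplier = 2,
                          window_length = NULL) {
  if (p_threshold <= 0 || p_threshold >= 1) stop("p_threshold in (0,1)")
  if (log2_threshold <= 0) stop("log2_threshold must be positive")
  if (min_windows < 1) stop("min_windows must be >= 1")
  structure(list(p_threshold = p_threshold,
                 log2_threshold = log2_threshold,
                 min_windows = as.integer(min_windows),
                 window_multiplier = window_multiplier,
                 window_length = window_length),
            class = "caller_config")
}

#' Automatic window sizing from library totals
#'
#' Finds, by integer search, the smallest window length for which a window
#' whose true |log2 ratio| equals `log2_threshold` reaches the critical
#' value of the Geary-Hinkley ratio test at `p_threshold`, given per-window
#' null means scaled from the two library totals; the returned length is
#' that minimum times `window_multiplier`. Larger libraries give shorter
#' windows (more power per bp).
#'
#' @param genome_length Total reference length (bp) being tiled.
#' @param total_a,total_b Total mapped reads in samples A and B.
#' @param config A [caller_config()].
#' @return Window length in bp (integer).
#' @export
auto_window_length <- function(genome_length, total_a, total_b,
                               config = caller_config()) {
  if (total_a <= 0 || total_b <= 0) stop("library totals must be positive")
  crit <- stats::qnorm(1 - config$p_threshold / 2)
  detectable <- function(w) {
    mu_x <- total_a * w / genome_length
    mu_y <- total_b * w / genome_length
    # count ratio corresponding to +/- log2_threshold after normalization
    z_hi <- 2^config$log2_threshold * (total_a / total_b)
    z_lo <- 2^(-config$log2_threshold) * (total_a / total_b)
    t_hi <- (mu_y * z_hi - mu_x) / sqrt(mu_y * z_hi^2 + mu_x)
    t_lo <- (mu_y * z_lo - mu_x) / sqrt(mu_y * z_lo^2 + mu_x)
    abs(t_hi) >= crit && abs(t_lo) >= crit
  }
  lo <- 1
  if (detectable(lo)) return(as.integer(ceiling(config$window_multiplier)))
  hi <- 2
  while (!detectable(hi)) {
    hi <- hi * 2
    if (hi > genome_length)
      stop("no feasible window length <= genome length at these totals")
  }
  lo <- hi %/% 2
  while (hi - lo > 1) {               # detectable() is monotone in w
    mid <- (lo + hi) %/% 2
    if (detectable(mid)) hi <- mid else lo <- mid
  }
  as.integer(ceiling(config$window_multiplier * hi))
}
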