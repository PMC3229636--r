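#' Plan a qPCR copy-number experiment
#'
#' @param true_copy_numbers Named numeric vector, sample -> true copy
#'   number (0 means the segment is absent and its target reactions never
#'   amplify).
#' @param calibrator_copy_number Copy number assumed for the calibrator
#'   sample (default 2).
#' @param replicates Technical replicates per reaction (default 4).
#' @param ct_noise_sd Gaussian noise added to each replicate Ct, in cycles.
#' @param reference_gene_ct Baseline Ct of the single-copy reference gene.
#' @return A `qpcr_plan` list.
#' @export
qpcr_plan <- function(true_copy_numbers, calibrator_copy_number = 2,
                      replicates = 4, ct_noise_sd = 0.1,
                      reference_gene_ct = 20) {
  if (is.null(names(true_copy_numbers)))
    stop("true_copy_numbers must be a named vector (sample -> copies)")
  if (any(true_copy_numbers < 0)) stop("copy numbers must be non-negative")
  if (replicates < 1) stop("need at least one replicate")
  if (ct_noise_sd < 0) stop("noise sd must be non-negative")
  structure(list(true_copy_numbers = true_copy_numbers,
                 calibrator_copy_number = calibrator_copy_number,
                 replicates = as.integer(replicates),
                 ct_noise_sd = ct_noise_sd,
                 reference_gene_ct = reference_gene_ct),
            class = "qpcr_plan")
}

#' Simulate a Ct replicate table
#'
#' Each sample gets `replicates` target and reference Ct values. The
#' expected target Ct follows the exponential amplification model
#' \deqn{Ct_{target} = Ct_{ref} - \log_2(c/2)/\log_2(1+E)} for copy number
#' c and per-cycle efficiency E (E = 1 is perfect doubling), plus Gaussian
#' replicate noise. A copy number of zero yields censored (`NA`) target
#' Ct values: the sequence is absent, so the reaction never crosses
#' threshold.
#'
#' @param plan A [qpcr_plan()].
#' @param efficiency Amplification efficiency per cycle, in (0.9, 1.1].
#' @param assay Assay label.
#' @param seed Integer seed.
#' @return Data frame `sample`, `assay`, `target_ct_rep1..r`,
#'   `reference_ct_rep1..r`.
#' @export
simulate_qpcr <- function(plan, efficiency = 1, assay = "assay1",
                          seed = 1L) {
  stopifnot(inherits(plan, "qpcr_plan"))
  if (efficiency <= 0.9 || efficiency > 1.1)
    stop("efficiency must lie in (0.9, 1.1]")
  r <- plan$replicates
  with_seed(seed, {
    rows <- lapply(names(plan$true_copy_numbers), function(s) {
      cn <- plan$true_copy_numbers[[s]]
      ref_ct <- plan$reference_gene_ct +
        stats::rnorm(r, sd = plan$ct_noise_sd)
      if (cn == 0) {
        tgt_ct <- rep(NA_real_, r)
      } else {
        tgt_ct <- plan$reference_gene_ct - log2(cn / 2) / log2(1 + efficiency) +
          stats::rnorm(r, sd = plan$ct_noise_sd)
      }
      row <- data.frame(sample = s, assay = assay, stringsAsFactors = FALSE)
      for (i in seq_len(r)) row[[paste0("target_ct_rep", i)]] <- tgt_ct[i]
      for (i in seq_len(r)) row[[paste0("reference_ct_rep", i)]] <- ref_ct[i]
      row
    })
    do.call(rbind, rows)
  })
}

#' Average delta-Ct of one sample
#'
#' \eqn{\Delta Ct = mean(Ct_{target}) - mean(Ct_{ref})} over replicates.
#' Censored (`NA`) target replicates among valid ones are dropped with a
#' warning; if every target replicate is censored the sample's segment is
#' taken as absent and \eqn{\Delta Ct = +\infty}. Per-replicate
#' \eqn{\Delta Ct} values (each target replicate against the mean reference
#' Ct) are retained for min/max error bars.
#'
#' @param target_ct,reference_ct Numeric replicate vectors.
#' @return List with `dct`, `per_replicate`, `n_used`.
#' @export
delta_ct <- function(target_ct, reference_ct) {
  ok <- !is.na(target_ct)
  if (!any(ok))
    return(list(dct = Inf, per_replicate = numeric(0), n_used = 0L))
  if (any(!ok))
    warning(sum(!ok), " censored target replicate(s) dropped")
  ref_mean <- mean(reference_ct, na.rm = TRUE)
  per <- target_ct[ok] - ref_mean
  list(dct = mean(target_ct[ok]) - ref_mean, per_replicate = per,
       n_used = sum(ok))
}

#' Relative copy number from delta-delta-Ct
#'
#' \eqn{\Delta\Delta Ct = \Delta Ct_{sample} - \Delta Ct_{calibrator}};
#' copy number \eqn{= c_{cal} \times 2^{-\Delta\Delta Ct}} under the
#' assumption that the calibrator carries `calibrator_cn` copies (2 by
#' default) and amplification doubles per cycle. A censored sample
#' (\eqn{\Delta Ct = \infty}) is called copy number 0.
#'
#' @param sample_dct,calibrator_dct Delta-Ct values in cycles.
#' @param calibrator_cn Copies assumed in the calibrator.
#' @return List with `ddct`, `copy_number`, `rounded_cn`.
#' @export
copy_number <- function(sample_dct, calibrator_dct, calibrator_cn = 2) {
  if (is.infinite(calibrator_dct))
    stop("calibrator is censored; calibration impossible")
  ddct <- sample_dct - calibrator_dct
  cn <- calibrator_cn * 2^(-ddct)
  list(ddct = ddct, copy_number = cn, rounded_cn = as.integer(round(cn)))
}

#' Call copy numbers for every sample in a Ct table
#'
#' Runs [delta_ct()] per sample, anchors on the named calibrator sample
#' and converts to copy numbers with [copy_number()]. Per-sample min/max
#' copy-number ranges are derived from the replicate-level delta-Ct spread.
#'
#' @param ct_table Wide Ct table as from [simulate_qpcr()].
#' @param calibrator Sample name of the calibrator.
#' @param calibrator_cn Copies assumed in the calibrator (default 2).
#' @return A `copy_number_calls` data frame: `sample`, `delta_ct`, `ddct`,
#'   `copy_number`, `rounded_cn`, `cn_min`, `cn_max` (calibrator row
#'   included, flagged by `is_calibrator`).
#' @export
call_copy_numbers <- function(ct_table, calibrator, calibrator_cn = 2) {
  if (!calibrator %in% ct_table$sample)
    stop("calibrator sample not in table: ", calibrator)
  tgt_cols <- grep("^target_ct_rep", names(ct_table), value = TRUE)
  ref_cols <- grep("^reference_ct_rep", names(ct_table), value = TRUE)
  dcts <- lapply(seq_len(nrow(ct_table)), function(i)
    delta_ct(as.numeric(ct_table[i, tgt_cols]),
             as.numeric(ct_table[i, ref_cols])))
  cal <- dcts[[match(calibrator, ct_table$sample)]]
  rows <- lapply(seq_along(dcts), function(i) {
    d <- dcts[[i]]
    if (is.infinite(d$dct)) {
      return(data.frame(sample = ct_table$sample[i], delta_ct = Inf,
                        ddct = Inf, copy_number = 0, rounded_cn = 0L,
                        cn_min = 0, cn_max = 0, stringsAsFactors = FALSE))
    }
    cc <- copy_number(d$dct, cal$dct, calibrator_cn)
    rng <- calibrator_cn * 2^(-(d$per_replicate - cal$dct))
    data.frame(sample = ct_table$sample[i], delta_ct = d$dct,
               ddct = cc$ddct, copy_number = cc$copy_number,
               rounded_cn = cc$rounded_cn,
               cn_min = min(rng), cn_max = max(rng),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$is_calibrator <- out$sample == calibrator
  class(out) <- c("copy_number_calls", "data.frame")
  out
}

#' Re-anchor copy-number calls on the modal level
#'
#' When the intended calibrator cannot be used (for example the segment is
#' absent from it), the most frequently observed rounded copy-number level
#' among the remaining samples is assumed to represent two copies and all
#' calls are rescaled accordingly. A tie between modal levels is an error
#' (there is no principled way to pick one).
#'
#' @param calls A `copy_number_calls` table (calibrator rows are ignored).
#' @return The rescaled `copy_number_calls`.
#' @export
mode_calibrate <- function(calls) {
  s <- calls[!isTRUE_col(calls$is_calibrator), , drop = FALSE]
  if (nrow(s) < 3) stop("mode calibration needs at least 3 samples")
  tab <- table(s$rounded_cn)
  modes <- as.numeric(names(tab)[tab == max(tab)])
  if (length(modes) > 1)
    stop("modal copy-number tie between ", paste(modes, collapse = " and "),
         "; cannot mode-calibrate")
  f <- 2 / modes
  out <- calls
  out$copy_number <- out$copy_number * f
  out$rounded_cn <- as.integer(round(out$copy_number))
  out$cn_min <- out$cn_min * f
  out$cn_max <- out$cn_max * f
  out
}

isTRUE_col <- function(x) if (is.null(x)) FALSE else x %in% TRUE

#' @export
print.copy_number_calls <- function(x, ...) {
  cat(sprintf("<copy_number_calls> %d sample(s)\n", nrow(x)))
  print.data.frame(as.data.frame(x), digits = 3, row.names = FALSE)
  invisible(x)
}

#' Plot copy-number calls with replicate min/max bars
#'
#' One bar per sample, error bars spanning the minimum and maximum
#' replicate-level copy number.
#'
#' @param x A `copy_number_calls` object.
#' @param ... Passed to [graphics::barplot()].
#' @export
plot.copy_number_calls <- function(x, ...) {
  mid <- graphics::barplot(x$copy_number, names.arg = x$sample, las = 2,
                           ylab = "relative copy number",
                           ylim = c(0, max(x$cn_max, 2) * 1.1), ...)
  graphics::arrows(mid, x$cn_min, mid, x$cn_max, angle = 90, code = 3,
                   length = 0.03)
  graphics::abline(h = 2, lty = 2, col = "grey50")
  invisible(x)
}

#' Write or read a Ct replicate table
#'
#' @param ct_table Data frame as from [simulate_qpcr()].
#' @param path TSV path.
#' @export
write_ct_table <- function(ct_table, path) {
  utils::write.table(ct_table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_ct_table
#' @export
read_ct_table <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
}
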