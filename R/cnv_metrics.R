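#' Scale-normalize amplicon counts against a reference sample
#'
#' Within one PCR of one sample run, per-amplicon counts are divided by the
#' sample's total filtered count (library-size scaling) and then by the same
#' quantity for the reference sample, giving
#' \code{ratio_i = (A_test,i / T_test) / (A_ref,i / T_ref)}. Amplicons with a
#' zero reference count get an undefined (NA) ratio and are excluded
#' downstream.
#'
#' @param test_counts data.frame \code{amplicon, count} for the test sample
#'   (one PCR).
#' @param ref_counts data.frame \code{amplicon, count} for the reference
#'   sample (same PCR).
#' @return data.frame \code{amplicon, ratio} of class \code{clpp_ratio}.
#' @export
scale_normalize <- function(test_counts, ref_counts) {
  common <- intersect(test_counts$amplicon, ref_counts$amplicon)
  if (!length(common)) stop("disjoint amplicon sets", call. = FALSE)
  tt <- test_counts$count[match(common, test_counts$amplicon)]
  rr <- ref_counts$count[match(common, ref_counts$amplicon)]
  t_tot <- sum(test_counts$count)
  r_tot <- sum(ref_counts$count)
  if (t_tot == 0 || r_tot == 0) stop("zero total count", call. = FALSE)
  ratio <- ifelse(rr > 0, (tt / t_tot) / (rr / r_tot), NA_real_)
  structure(data.frame(amplicon = common, ratio = ratio,
                       stringsAsFactors = FALSE),
            class = c("clpp_ratio", "data.frame"))
}

#' Median-combine normalized ratios across PCRs and repeats
#'
#' Per amplicon, the median over the available (non-NA) normalized ratios.
#' Amplicons missing (or NA) in every table stay flagged as NA.
#'
#' @param ratio_tables list of data.frames from \code{\link{scale_normalize}}.
#' @return data.frame \code{amplicon, ratio}.
#' @export
median_combine <- function(ratio_tables) {
  if (!length(ratio_tables)) stop("need at least one ratio table",
                                  call. = FALSE)
  amps <- unique(unlist(lapply(ratio_tables, `[[`, "amplicon")))
  ratio <- vapply(amps, function(a) {
    v <- unlist(lapply(ratio_tables, function(tb)
      tb$ratio[match(a, tb$amplicon)]))
    v <- v[!is.na(v)]
    if (length(v)) median(v) else NA_real_
  }, numeric(1L))
  structure(data.frame(amplicon = amps, ratio = unname(ratio),
                       stringsAsFactors = FALSE),
            class = c("clpp_ratio", "data.frame"))
}

#' Lowess-smoothed copy-number ratio curve
#'
#' Locally weighted scatterplot smoothing of per-amplicon ratios along
#' genomic order, for visualizing segments of copy-number change. Calls are
#' made on unsmoothed ratios; smoothing is presentation only.
#'
#' @param ratios numeric ratios.
#' @param positions genomic positions (amplicon midpoints).
#' @param frac smoother span.
#' @return numeric vector of smoothed values in input order.
#' @export
lowess_smooth <- function(ratios, positions, frac = 0.3) {
  ok <- !is.na(ratios) & !is.na(positions)
  if (sum(ok) < 3L) {
    warning("fewer than 3 points; returning input unchanged", call. = FALSE)
    return(ratios)
  }
  out <- rep(NA_real_, length(ratios))
  sm <- lowess(positions[ok], ratios[ok], f = frac)
  # lowess returns values sorted by x; map back to input order
  ord <- order(positions[ok])
  vals <- numeric(sum(ok))
  vals[ord] <- sm$y
  out[ok] <- vals
  out
}

#' Standard deviation of log2 coverage ratios in coverage-matched bins
#'
#' Amplicons are sorted by reference coverage and grouped into bins of
#' \code{bin_size}; each bin reports the SD of the log2 ratios and its median
#' reference coverage, quantifying how count noise shrinks with coverage.
#'
#' @param ratios per-amplicon ratios (positive; NAs dropped).
#' @param coverages matching reference coverages.
#' @param bin_size amplicons per bin.
#' @return data.frame \code{bin, n, median_coverage, sd_log2}.
#' @export
binned_logratio_sd <- function(ratios, coverages, bin_size = 200L) {
  if (bin_size < 2L) stop("bin_size must be at least 2", call. = FALSE)
  ok <- !is.na(ratios) & ratios > 0 & !is.na(coverages)
  ratios <- ratios[ok]; coverages <- coverages[ok]
  ord <- order(coverages)
  ratios <- ratios[ord]; coverages <- coverages[ord]
  n <- length(ratios)
  bin <- (seq_len(n) - 1L) %/% bin_size + 1L
  out <- lapply(unique(bin), function(b) {
    sel <- bin == b
    data.frame(bin = b, n = sum(sel),
               median_coverage = median(coverages[sel]),
               sd_log2 = sd(log2(ratios[sel])))
  })
  do.call(rbind, out)
}

#' Threshold copy-number calls from combined ratios
#'
#' Per-amplicon states (loss when the combined ratio is at most
#' \code{loss_max}, gain when at least \code{gain_min}, neutral otherwise,
#' after dividing out the expected per-contig ploidy baseline when supplied)
#' are merged into calls over runs of at least \code{min_consecutive}
#' amplicons in genomic order; a whole-contig summary row is always emitted.
#'
#' @param combined data.frame \code{amplicon, ratio} from
#'   \code{\link{median_combine}}.
#' @param refs a \code{clpp_panel_refs} (for genomic order and positions).
#' @param loss_max,gain_min ratio thresholds (diploid baseline: midway
#'   between integer copy states).
#' @param min_consecutive minimum run length for a focal call.
#' @param ploidy optional named vector of expected test-sample copy number
#'   per contig relative to the reference's diploid baseline (e.g. X = 1 for
#'   a male test vs female reference); ratios are divided by
#'   \code{ploidy/2} before thresholding.
#' @return list with \code{per_amplicon} (amplicon, contig, position, ratio,
#'   state), \code{calls} (focal run calls) and \code{contig_summary}.
#' @export
call_cnv <- function(combined, refs, loss_max = 0.7, gain_min = 1.35,
                     min_consecutive = 2L, ploidy = NULL) {
  if (loss_max >= gain_min)
    stop("loss_max must be below gain_min", call. = FALSE)
  tg <- refs$targets
  m <- match(tg$name, combined$amplicon)
  df <- data.frame(amplicon = tg$name, contig = tg$contig,
                   position = (tg$start + tg$end) %/% 2L,
                   ratio = combined$ratio[m], stringsAsFactors = FALSE)
  df <- df[order(df$contig, df$position), , drop = FALSE]
  adj <- df$ratio
  if (!is.null(ploidy)) {
    base <- ploidy[df$contig] / 2
    adj <- ifelse(is.na(base), adj, adj / base)
  }
  df$state <- ifelse(is.na(adj), NA_character_,
                     ifelse(adj <= loss_max, "loss",
                            ifelse(adj >= gain_min, "gain", "neutral")))
  calls <- list()
  for (ctg in unique(df$contig)) {
    sub <- df[df$contig == ctg & !is.na(df$state), , drop = FALSE]
    if (!nrow(sub)) next
    r <- rle(sub$state)
    endi <- cumsum(r$lengths)
    starti <- endi - r$lengths + 1L
    for (j in seq_along(r$values)) {
      if (r$values[j] == "neutral" || r$lengths[j] < min_consecutive) next
      sel <- starti[j]:endi[j]
      calls[[length(calls) + 1L]] <- data.frame(
        contig = ctg, start_position = min(sub$position[sel]),
        end_position = max(sub$position[sel]), state = r$values[j],
        n_amplicons = length(sel), mean_ratio = mean(sub$ratio[sel]),
        amplicons = paste(sub$amplicon[sel], collapse = ","),
        stringsAsFactors = FALSE)
    }
  }
  contig_summary <- do.call(rbind, lapply(unique(df$contig), function(ctg) {
    sel <- df$contig == ctg & !is.na(df$ratio)
    mr <- mean(df$ratio[sel])
    ma <- if (!is.null(ploidy) && !is.na(ploidy[ctg]))
      mr / (ploidy[[ctg]] / 2) else mr
    data.frame(contig = ctg, n_amplicons = sum(sel), mean_ratio = mr,
               state = if (ma <= loss_max) "loss" else
                 if (ma >= gain_min) "gain" else "neutral",
               stringsAsFactors = FALSE)
  }))
  list(per_amplicon = df, calls = do.call(rbind, calls),
       contig_summary = contig_summary)
}

#' Per-PCR ratio tables for a test sample against a reference sample
#'
#' Convenience wrapper running \code{\link{scale_normalize}} per PCR group
#' and \code{\link{median_combine}} across them.
#'
#' @param test_counts,ref_counts count tables (\code{amplicon, group,
#'   count}) from \code{\link{compute_coverage}}.
#' @return data.frame \code{amplicon, ratio} (combined).
#' @export
normalize_sample <- function(test_counts, ref_counts) {
  groups <- intersect(unique(test_counts$group), unique(ref_counts$group))
  tabs <- lapply(groups, function(g)
    scale_normalize(test_counts[test_counts$group == g, , drop = FALSE],
                    ref_counts[ref_counts$group == g, , drop = FALSE]))
  median_combine(tabs)
}
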