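# Stratification of methylated fractions by central-C 3-mer context and the
# GCU vs non-GCU comparison: median fold change, two-tailed Welch z test,
# Cohen's d, and paired native/IVT summaries.

#' Histogram of methylated fractions on [0,1]
#'
#' Bins are half-open `[low, low + width)` with the final bin closed so a
#' fraction of exactly 1.0 is counted. When `bin_width` does not divide 1
#' evenly the last bin is partial.
#'
#' @param fractions Numeric vector in [0,1].
#' @param bin_width Bin width in (0,1]; default 0.025 (40 bins).
#' @return Data.frame with `bin_low`, `bin_high`, `count`;
#'   `sum(count) == length(fractions)`.
#' @export
summarize_density <- function(fractions, bin_width = 0.025) {
  stopifnot(bin_width > 0, bin_width <= 1)
  n_bins <- ceiling(1 / bin_width - 1e-9)
  lows <- (seq_len(n_bins) - 1L) * bin_width
  highs <- pmin(lows + bin_width, 1)
  # findInterval against the actual edge values keeps [low, high) semantics
  # exact even when bin_width is not representable in binary
  idx <- pmin(findInterval(fractions, lows), n_bins)
  data.frame(bin_low = lows, bin_high = highs,
             count = tabulate(idx, nbins = n_bins))
}

#' Stratify site fractions by central k-mer context
#'
#' Applies the strict filters `depth > min_depth` and
#' `fraction > min_fraction` (both exclusive, matching the printed
#' conventions "depth >10" / "fraction >0"), annotates each surviving site
#' with its central k-mer (RNA alphabet), and summarizes each stratum.
#' Sites too close to a transcript end for a full k-mer are dropped.
#'
#' @param sites Site data.frame.
#' @param ref Reference (DNAStringSet or named character vector).
#' @param k Odd k-mer length (default 3).
#' @param min_depth,min_fraction Strict filter cutoffs (defaults 10 and 0).
#' @param bin_width Histogram bin width (default 0.025).
#' @return Named list (by k-mer) of `stratum_summary` objects: `kmer`, `n`,
#'   `median`, `mean`, `sd`, `histogram`, and the raw `fractions`.
#' @export
stratify <- function(sites, ref, k = 3L, min_depth = 10L, min_fraction = 0,
                     bin_width = 0.025) {
  stopifnot(k %% 2L == 1L)
  kept <- sites[sites$depth > min_depth & sites$fraction > min_fraction, ,
                drop = FALSE]
  if (nrow(kept) == 0L) return(stats::setNames(list(), character(0)))
  kmer <- central_kmers(ref, kept, k = k)
  kept <- kept[!is.na(kmer), , drop = FALSE]
  kmer <- kmer[!is.na(kmer)]
  out <- lapply(split(kept$fraction, kmer), function(fr) {
    structure(list(
      kmer = NULL,  # filled below
      n = length(fr),
      median = median(fr),
      mean = mean(fr),
      sd = if (length(fr) > 1L) sd(fr) else NA_real_,
      histogram = summarize_density(fr, bin_width),
      fractions = fr
    ), class = "stratum_summary")
  })
  for (km in names(out)) out[[km]]$kmer <- km
  out
}

#' @export
print.stratum_summary <- function(x, ...) {
  cat(sprintf("%s: n %d, median %.3f, mean %.3f, sd %.3f\n",
              x$kmer, x$n, x$median, x$mean, x$sd))
  invisible(x)
}

#' Flatten strata to a summary table
#'
#' @param strata Result of [stratify()].
#' @return Data.frame with one row per k-mer stratum.
#' @export
strata_table <- function(strata) {
  do.call(rbind, lapply(strata, function(s) {
    data.frame(kmer = s$kmer, n = s$n, median = s$median, mean = s$mean,
               sd = s$sd, stringsAsFactors = FALSE)
  })) -> df
  if (is.null(df)) {
    df <- data.frame(kmer = character(), n = integer(), median = numeric(),
                     mean = numeric(), sd = numeric())
  }
  rownames(df) <- NULL
  df
}

# Welch two-sample z on fractions; shared by compare_gcu and its tests.
welch_z <- function(a, b) {
  (mean(a) - mean(b)) / sqrt(stats::var(a) / length(a) +
                             stats::var(b) / length(b))
}

cohens_d_pooled <- function(a, b) {
  na <- length(a); nb <- length(b)
  sp <- sqrt(((na - 1) * stats::var(a) + (nb - 1) * stats::var(b)) /
             (na + nb - 2))
  (mean(a) - mean(b)) / sp
}

#' Compare GCU-context against all other central-C cytosines
#'
#' Sites passing the strict depth filter are split into the GCU central
#' 3-mer group and all other central-C 3-mers, and their methylated
#' fractions compared: group medians and median fold change
#' (GCU / non-GCU), a two-tailed Welch z test
#' `z = (mean_A - mean_B) / sqrt(s2_A/n_A + s2_B/n_B)` referred to the
#' normal distribution, and Cohen's d with the classical pooled standard
#' deviation. A positive `z` / `d` means GCU fractions are elevated — the
#' signature of the context artifact when it also appears in IVT RNA.
#'
#' @param sites Site data.frame.
#' @param ref Reference (DNAStringSet or named character vector).
#' @param min_depth Strict depth cutoff (default 100; use 10 for shallow
#'   samples).
#' @param min_fraction Optional strict fraction cutoff (default none).
#' @param kmer Context defining group A (default "GCU").
#' @return Object of class `gcu_comparison`: `n_gcu`, `n_other`,
#'   `median_gcu`, `median_other`, `median_fold`, `z`, `p_two_tailed`,
#'   `cohens_d`.
#' @export
compare_gcu <- function(sites, ref, min_depth = 100L, min_fraction = NULL,
                        kmer = "GCU") {
  kept <- filter_depth(sites, min_depth)
  if (!is.null(min_fraction)) {
    kept <- kept[kept$fraction > min_fraction, , drop = FALSE]
  }
  ctx <- central_kmers(ref, kept, k = nchar(kmer))
  kept <- kept[!is.na(ctx), , drop = FALSE]
  ctx <- ctx[!is.na(ctx)]
  a <- kept$fraction[ctx == kmer]
  b <- kept$fraction[ctx != kmer]
  if (length(a) == 0L || length(b) == 0L) {
    stop_gcu("gcuaudit_comparison_error",
             "empty group after filtering (n_%s = %d, n_other = %d)",
             kmer, length(a), length(b))
  }
  na <- length(a); nb <- length(b)
  sp <- sqrt(((na - 1) * stats::var(a) + (nb - 1) * stats::var(b)) /
             (na + nb - 2))
  if (!is.finite(sp) || sp == 0) {
    stop_gcu("gcuaudit_degenerate_variance_error",
             "pooled standard deviation is zero")
  }
  z <- welch_z(a, b)
  med_a <- median(a); med_b <- median(b)
  structure(list(
    kmer = kmer,
    n_gcu = na, n_other = nb,
    median_gcu = med_a, median_other = med_b,
    median_fold = if (med_b > 0) med_a / med_b else NA_real_,
    z = z,
    p_two_tailed = 2 * (1 - pnorm(abs(z))),
    cohens_d = (mean(a) - mean(b)) / sp
  ), class = "gcu_comparison")
}

#' @export
print.gcu_comparison <- function(x, ...) {
  cat(sprintf(
    "%s (n=%d) vs non-%s (n=%d): medians %.3f vs %.3f (fold %.2f)\n",
    x$kmer, x$n_gcu, x$kmer, x$n_other, x$median_gcu, x$median_other,
    x$median_fold))
  cat(sprintf("  Welch z = %.3f, two-tailed p = %.3g, Cohen's d = %.3f\n",
              x$z, x$p_two_tailed, x$cohens_d))
  invisible(x)
}

#' Paired comparison of native and IVT samples per k-mer context
#'
#' Both samples are filtered with the same strict cutoffs; in
#' position-matched mode (the default) only cytosines passing the filters in
#' both samples are kept, so the two distributions cover identical
#' positions. Per shared k-mer the summary holds both strata, the
#' Kolmogorov–Smirnov statistic between the two fraction samples (a
#' descriptive distance; native and IVT being indistinguishable at GCU is
#' the artifact's hallmark), and the native − IVT median difference.
#'
#' @param native_sites,ivt_sites Site data.frames for the native and the
#'   in-vitro-transcribed sample.
#' @param ref Shared reference.
#' @param k Odd k-mer length (default 3).
#' @param min_depth,min_fraction Strict cutoffs applied to both samples.
#' @param bin_width Histogram bin width.
#' @param position_matched Keep only positions passing filters in both
#'   samples (default TRUE).
#' @return Object of class `paired_comparison`: per-k-mer list with
#'   `native`, `ivt` (stratum summaries), `ks_statistic`,
#'   `median_difference`; plus the per-sample [compare_gcu()] inputs.
#' @export
paired_sample_compare <- function(native_sites, ivt_sites, ref, k = 3L,
                                  min_depth = 10L, min_fraction = 0,
                                  bin_width = 0.025, position_matched = TRUE) {
  pass <- function(s) s[s$depth > min_depth & s$fraction > min_fraction, ,
                        drop = FALSE]
  nat <- pass(native_sites)
  ivt <- pass(ivt_sites)
  if (position_matched) {
    kn <- paste(nat$transcript_id, nat$pos)
    ki <- paste(ivt$transcript_id, ivt$pos)
    shared <- intersect(kn, ki)
    nat <- nat[kn %in% shared, , drop = FALSE]
    ivt <- ivt[ki %in% shared, , drop = FALSE]
  }
  sn <- stratify(nat, ref, k = k, min_depth = -1L, min_fraction = -1,
                 bin_width = bin_width)
  si <- stratify(ivt, ref, k = k, min_depth = -1L, min_fraction = -1,
                 bin_width = bin_width)
  shared_kmers <- intersect(names(sn), names(si))
  if (length(shared_kmers) == 0L) {
    stop_gcu("gcuaudit_comparison_error",
             "no k-mer context shared by both samples after filtering")
  }
  per_kmer <- lapply(shared_kmers, function(km) {
    fn <- sn[[km]]$fractions
    fi <- si[[km]]$fractions
    ks <- suppressWarnings(stats::ks.test(fn, fi))$statistic
    list(kmer = km, native = sn[[km]], ivt = si[[km]],
         ks_statistic = unname(ks),
         median_difference = sn[[km]]$median - si[[km]]$median)
  })
  names(per_kmer) <- shared_kmers
  structure(list(per_kmer = per_kmer,
                 native_filtered = nat, ivt_filtered = ivt,
                 min_depth = min_depth, min_fraction = min_fraction,
                 position_matched = position_matched),
            class = "paired_comparison")
}

#' @export
print.paired_comparison <- function(x, ...) {
  cat(sprintf("paired comparison over %d shared k-mers (%s)\n",
              length(x$per_kmer),
              if (x$position_matched) "position-matched" else "unmatched"))
  for (pk in x$per_kmer) {
    cat(sprintf("  %s: native median %.3f, IVT median %.3f, KS %.3f\n",
                pk$kmer, pk$native$median, pk$ivt$median, pk$ks_statistic))
  }
  invisible(x)
}

#' Paired comparison as a flat table
#'
#' @param paired Result of [paired_sample_compare()].
#' @return Data.frame with one row per shared k-mer.
#' @export
paired_table <- function(paired) {
  df <- do.call(rbind, lapply(paired$per_kmer, function(pk) {
    data.frame(kmer = pk$kmer, n_native = pk$native$n, n_ivt = pk$ivt$n,
               median_native = pk$native$median, median_ivt = pk$ivt$median,
               ks_statistic = pk$ks_statistic,
               median_difference = pk$median_difference,
               stringsAsFactors = FALSE)
  }))
  rownames(df) <- NULL
  df
}
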