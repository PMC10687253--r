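# Site-level statistics: aggregation of per-read calls into per-cytosine
# methylated fractions, depth filtering, ranking, top-N selection, and
# extraction of sequence-context windows around candidate sites.

#' Aggregate per-read modification calls into per-site methylated fractions
#'
#' For every (transcript, position) present in `calls`, depth is the number
#' of covering reads and `mod_count` the number whose per-read modification
#' probability is at or above `call_threshold`; the methylated fraction is
#' their quotient. Binary callers emit `p_mod` of exactly 0/1, for which any
#' threshold in (0,1] gives the same answer.
#'
#' @param calls Data.frame with columns `read_id`, `transcript_id`, `pos`,
#'   `p_mod` (see [read_per_read_table()]).
#' @param call_threshold Per-read probability at or above which a read counts
#'   as modified. Default 0.5.
#' @return Site data.frame (`transcript_id`, `pos`, `depth`, `mod_count`,
#'   `fraction`), ordered by transcript then position.
#' @export
aggregate_fractions <- function(calls, call_threshold = 0.5) {
  stopifnot(call_threshold >= 0, call_threshold <= 1)
  if (nrow(calls) == 0L) return(empty_sites())
  dt <- data.table::data.table(transcript_id = calls$transcript_id,
                               pos = as.integer(calls$pos),
                               mod = calls$p_mod >= call_threshold)
  agg <- dt[, list(depth = .N, mod_count = sum(mod)),
            by = c("transcript_id", "pos")]
  data.table::setorderv(agg, c("transcript_id", "pos"))
  out <- as.data.frame(agg)
  out$mod_count <- as.integer(out$mod_count)
  out$fraction <- out$mod_count / out$depth
  out
}

#' Keep sites strictly deeper than a depth cutoff
#'
#' The cutoff is strict (`depth > min_depth`), matching the printed filter
#' conventions "depth >100" and "depth >10"; a site with depth exactly
#' `min_depth` is excluded. Input order is preserved.
#'
#' @param sites Site data.frame.
#' @param min_depth Non-negative integer cutoff.
#' @return Filtered site data.frame.
#' @export
filter_depth <- function(sites, min_depth) {
  stopifnot(min_depth >= 0)
  out <- sites[sites$depth > min_depth, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Rank sites by methylated fraction and keep the top N
#'
#' Sites pass the strict depth filter, are sorted by fraction descending with
#' deterministic tie-breaks (depth descending, then transcript id and
#' position ascending), and the first `min(n, available)` are kept. The
#' lowest selected fraction is recorded: for whole transcriptomes this is the
#' "floor" of the top-N set (0.85 in well-powered samples), and a low value
#' signals that a top-N analysis is uninformative for the reference at hand.
#'
#' @param sites Site data.frame.
#' @param n Number of sites requested (>= 1).
#' @param min_depth Strict depth cutoff applied before ranking (default 0).
#' @return An object of class `ranked_sites`: list with `sites` (ordered
#'   data.frame), `n_requested`, `min_depth`, `min_fraction_rank`.
#' @export
rank_top_n <- function(sites, n = 1000L, min_depth = 0L) {
  stopifnot(n >= 1)
  kept <- filter_depth(sites, min_depth)
  ord <- order(-kept$fraction, -kept$depth, kept$transcript_id, kept$pos)
  kept <- kept[ord, , drop = FALSE]
  kept <- head(kept, n)
  rownames(kept) <- NULL
  structure(list(
    sites = kept,
    n_requested = as.integer(n),
    min_depth = as.integer(min_depth),
    min_fraction_rank = if (nrow(kept)) min(kept$fraction) else NA_real_
  ), class = "ranked_sites")
}

#' @export
print.ranked_sites <- function(x, ...) {
  cat(sprintf("ranked_sites: %d of %d requested (depth > %d), min fraction %.3f\n",
              nrow(x$sites), x$n_requested, x$min_depth, x$min_fraction_rank))
  invisible(x)
}

#' Extract the sequence-context window around one cytosine
#'
#' Returns the reference substring of length `2*flank + 1` centered on the
#' 0-based position `pos`. Sites closer than `flank` to either transcript end
#' are rejected with reason `"edge"`; sites whose reference base is not C are
#' rejected with reason `"not-C"`.
#'
#' @param ref Reference (DNAStringSet or named character vector).
#' @param transcript_id Transcript name.
#' @param pos 0-based position of the central cytosine.
#' @param flank Bases of context on each side (>= 1).
#' @return A list with `transcript_id`, `pos`, `window`, `flank`; or, on
#'   rejection, a list with `rejected = TRUE` and `reason`.
#' @export
extract_window <- function(ref, transcript_id, pos, flank = 5L) {
  stopifnot(flank >= 1)
  chars <- as_ref_chars(ref)
  if (!transcript_id %in% names(chars)) {
    stop_gcu("gcuaudit_lookup_error", "unknown transcript '%s'", transcript_id)
  }
  seq <- chars[[transcript_id]]
  len <- nchar(seq)
  if (pos < 0 || pos > len - 1L) {
    stop_gcu("gcuaudit_lookup_error", "position %d outside transcript '%s'",
             pos, transcript_id)
  }
  if (pos < flank || pos > len - 1L - flank) {
    return(list(rejected = TRUE, reason = "edge",
                transcript_id = transcript_id, pos = pos))
  }
  if (substring(seq, pos + 1L, pos + 1L) != "C") {
    return(list(rejected = TRUE, reason = "not-C",
                transcript_id = transcript_id, pos = pos))
  }
  list(transcript_id = transcript_id, pos = as.integer(pos),
       window = substring(seq, pos + 1L - flank, pos + 1L + flank),
       flank = as.integer(flank))
}

#' Extract context windows for a set of sites
#'
#' Vectorized companion to [extract_window()]: windows for all accepted
#' sites, plus a table of rejections with reasons.
#'
#' @param ref Reference (DNAStringSet or named character vector).
#' @param sites Site data.frame (only `transcript_id` and `pos` are used).
#' @param flank Bases of context on each side.
#' @return List with `windows` (data.frame: `transcript_id`, `pos`,
#'   `window`, `flank`) and `rejected` (data.frame with `reason`).
#' @export
extract_windows <- function(ref, sites, flank = 5L) {
  stopifnot(flank >= 1)
  chars <- as_ref_chars(ref)
  unknown <- setdiff(unique(sites$transcript_id), names(chars))
  if (length(unknown)) {
    stop_gcu("gcuaudit_lookup_error", "unknown transcript '%s'", unknown[1])
  }
  seqs <- chars[sites$transcript_id]
  lens <- nchar(seqs)
  pos <- as.integer(sites$pos)
  edge <- pos < flank | pos > lens - 1L - flank
  base <- substring(seqs, pos + 1L, pos + 1L)
  notc <- !edge & base != "C"
  ok <- !edge & !notc
  windows <- data.frame(
    transcript_id = sites$transcript_id[ok],
    pos = pos[ok],
    window = substring(seqs[ok], pos[ok] + 1L - flank, pos[ok] + 1L + flank),
    flank = as.integer(flank),
    stringsAsFactors = FALSE
  )
  rejected <- data.frame(
    transcript_id = sites$transcript_id[!ok],
    pos = pos[!ok],
    reason = ifelse(edge[!ok], "edge", "not-C"),
    stringsAsFactors = FALSE
  )
  list(windows = windows, rejected = rejected)
}

#' Central k-mer at a cytosine, reported in the RNA alphabet
#'
#' The k-mer centered on `pos` (k odd) with T mapped to U, so the artifact
#' context of interest reads "GCU". Rejection rules are those of
#' [extract_window()] with flank `(k-1)/2`.
#'
#' @inheritParams extract_window
#' @param k Odd k-mer length (default 3).
#' @return The RNA-alphabet k-mer string, or a rejection list.
#' @export
central_kmer <- function(ref, transcript_id, pos, k = 3L) {
  stopifnot(k %% 2L == 1L)
  w <- extract_window(ref, transcript_id, pos, flank = (k - 1L) %/% 2L)
  if (isTRUE(w$rejected)) return(w)
  dna_to_rna(w$window)
}

#' Central k-mers for a set of sites
#'
#' Vectorized [central_kmer()]: returns `NA` for edge or non-C sites instead
#' of a rejection object.
#'
#' @param ref Reference (DNAStringSet or named character vector).
#' @param sites Site data.frame.
#' @param k Odd k-mer length.
#' @return Character vector (RNA alphabet) aligned with rows of `sites`.
#' @export
central_kmers <- function(ref, sites, k = 3L) {
  stopifnot(k %% 2L == 1L)
  flank <- (k - 1L) %/% 2L
  chars <- as_ref_chars(ref)
  unknown <- setdiff(unique(sites$transcript_id), names(chars))
  if (length(unknown)) {
    stop_gcu("gcuaudit_lookup_error", "unknown transcript '%s'", unknown[1])
  }
  seqs <- chars[sites$transcript_id]
  lens <- nchar(seqs)
  pos <- as.integer(sites$pos)
  out <- rep(NA_character_, nrow(sites))
  ok <- pos >= flank & pos <= lens - 1L - flank
  okc <- ok & substring(seqs, pos + 1L, pos + 1L) == "C"
  out[okc] <- dna_to_rna(substring(seqs[okc], pos[okc] + 1L - flank,
                                   pos[okc] + 1L + flank))
  out
}

#' Write context windows as FASTA
#'
#' One record per window, id `transcript:pos` — the shape handed to motif
#' discovery.
#'
#' @param windows Window data.frame from [extract_windows()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_windows_fasta <- function(windows, path) {
  seqs <- windows$window
  names(seqs) <- sprintf("%s:%d", windows$transcript_id, windows$pos)
  write_fasta(seqs, path)
}
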