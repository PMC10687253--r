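# Seeded generator of synthetic transcriptomes and per-read m5C calls with a
# planted sequence-context false-positive bias, used to validate the whole
# audit pipeline by parameter recovery. The generative model mirrors the
# statistical structure of the audited artifact: every read covering a
# cytosine is called "modified" with a probability that depends only on the
# site's central 3-mer (elevated at GCU), independent of any true
# modification, so the planted bias persists in a fully unmodified IVT
# sample.

#' Build a simulation configuration
#'
#' Defaults describe the study conditions used throughout the package's
#' validation: a 3-mer-specific false-call probability of 0.25 at GCU
#' against a 0.1 baseline (a planted median fold of 2.5), mean per-site
#' depth 100, and a transcriptome large enough to carry several hundred GCU
#' sites.
#'
#' @param n_transcripts Number of transcripts (default 25).
#' @param length_mean Mean transcript length in nt (default 1500); lengths
#'   are drawn uniformly within +/-20%.
#' @param gc GC content in (0,1); P(G) = P(C) = gc/2 (default 0.5).
#' @param depth_mean Expected per-site read depth (default 100).
#' @param depth_model `"poisson"` (default) or `"negative_binomial"`
#'   (overdispersed, with `nb_size` as the size parameter).
#' @param nb_size Negative-binomial size (dispersion) parameter (default 10).
#' @param p_base Per-read false-call probability at unbiased C sites
#'   (default 0.1).
#' @param p_context Named numeric vector mapping central 3-mers (RNA
#'   alphabet) to per-read call probabilities; default `c(GCU = 0.25)`.
#' @param n_true_sites Number of truly modified C sites (default 0).
#' @param true_fraction Per-read call probability at true sites
#'   (default 0.9).
#' @param seed Integer seed; everything downstream is reproducible from it.
#' @return A `sim_config` list.
#' @export
simulation_config <- function(n_transcripts = 25L, length_mean = 1500L,
                              gc = 0.5, depth_mean = 100,
                              depth_model = c("poisson", "negative_binomial"),
                              nb_size = 10, p_base = 0.1,
                              p_context = c(GCU = 0.25), n_true_sites = 0L,
                              true_fraction = 0.9, seed = 1L) {
  depth_model <- match.arg(depth_model)
  probs <- c(p_base, p_context, true_fraction)
  if (any(probs < 0 | probs > 1)) {
    stop_gcu("gcuaudit_config_error", "probabilities must lie in [0,1]")
  }
  if (depth_mean <= 0 || gc <= 0 || gc >= 1) {
    stop_gcu("gcuaudit_config_error",
             "need depth_mean > 0 and gc in (0,1)")
  }
  if (length(p_context) && is.null(names(p_context))) {
    stop_gcu("gcuaudit_config_error", "p_context must be named by 3-mer")
  }
  structure(list(n_transcripts = as.integer(n_transcripts),
                 length_mean = as.integer(length_mean), gc = gc,
                 depth_mean = depth_mean, depth_model = depth_model,
                 nb_size = nb_size, p_base = p_base, p_context = p_context,
                 n_true_sites = as.integer(n_true_sites),
                 true_fraction = true_fraction, seed = as.integer(seed)),
            class = "sim_config")
}

#' Generate a random reference transcriptome
#'
#' Sequences are i.i.d. letters with `P(G) = P(C) = gc/2` and
#' `P(A) = P(T) = (1-gc)/2`; lengths are uniform on
#' `[0.8, 1.2] * length_mean`. Deterministic given `config$seed`.
#'
#' @param config A `sim_config` from [simulation_config()].
#' @return A [Biostrings::DNAStringSet] named `tx0001`, `tx0002`, ...
#' @export
generate_transcriptome <- function(config) {
  with_seed(derive_seed(config$seed, 1L), {
    lens <- as.integer(round(runif(config$n_transcripts,
                                   0.8 * config$length_mean,
                                   1.2 * config$length_mean)))
    lens[lens < 50L] <- 50L
    p <- c(A = (1 - config$gc) / 2, C = config$gc / 2,
           G = config$gc / 2, T = (1 - config$gc) / 2)
    seqs <- vapply(lens, function(n) {
      paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
    }, character(1))
    out <- Biostrings::DNAStringSet(seqs)
    names(out) <- sprintf("tx%04d", seq_along(out))
    out
  })
}

# Enumerate every C site of the reference with its central 3-mer (RNA
# alphabet; NA where the transcript end truncates the context).
enumerate_c_sites <- function(ref) {
  chars <- as_ref_chars(ref)
  out <- lapply(names(chars), function(id) {
    s <- chars[[id]]
    pos <- as.integer(gregexpr("C", s, fixed = TRUE)[[1]])
    if (length(pos) == 1L && pos[1] == -1L) return(NULL)
    pos0 <- pos - 1L
    km <- rep(NA_character_, length(pos0))
    ok <- pos0 >= 1L & pos0 <= nchar(s) - 2L
    km[ok] <- dna_to_rna(substring(s, pos0[ok], pos0[ok] + 2L))
    data.frame(transcript_id = id, pos = pos0, kmer = km,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) {
    out <- data.frame(transcript_id = character(), pos = integer(),
                      kmer = character(), stringsAsFactors = FALSE)
  }
  out
}

#' Simulate per-read modification calls over a reference
#'
#' For every cytosine: depth is drawn from the configured depth model; each
#' covering read is called modified (binary `p_mod` 1) with probability
#' `p_context[central 3-mer]` when that 3-mer is configured, else `p_base`.
#' `n_true_sites` cytosines drawn at random instead use `true_fraction` as
#' their per-read call probability and are flagged in the truth table.
#' Edge cytosines without a full 3-mer context use `p_base`.
#'
#' @param ref Reference (DNAStringSet or named character vector).
#' @param config A `sim_config`.
#' @return List with `calls` (per-read data.frame: `read_id`,
#'   `transcript_id`, `pos`, `p_mod`) and `truth` (per-C-site data.frame:
#'   `transcript_id`, `pos`, `kmer`, `p_call`, `is_true_modified`, `depth`).
#' @export
simulate_calls <- function(ref, config) {
  sites <- enumerate_c_sites(ref)
  n <- nrow(sites)
  p_call <- rep(config$p_base, n)
  if (length(config$p_context)) {
    hit <- match(sites$kmer, names(config$p_context))
    p_call[!is.na(hit)] <- config$p_context[hit[!is.na(hit)]]
  }
  is_true <- rep(FALSE, n)
  with_seed(derive_seed(config$seed, 2L), {
    if (config$n_true_sites > 0L) {
      if (config$n_true_sites > n) {
        stop_gcu("gcuaudit_config_error",
                 "n_true_sites (%d) exceeds available C sites (%d)",
                 config$n_true_sites, n)
      }
      chosen <- sample.int(n, config$n_true_sites)
      is_true[chosen] <- TRUE
      p_call[chosen] <- config$true_fraction
    }
    depth <- switch(config$depth_model,
      poisson = rpois(n, config$depth_mean),
      negative_binomial = rnbinom(n, size = config$nb_size,
                                  mu = config$depth_mean))
    mod <- rbinom(n, depth, p_call)
    # expand per-site (depth, mod) into binary per-read calls
    covered <- depth > 0L
    tx <- rep(sites$transcript_id[covered], depth[covered])
    pos <- rep(sites$pos[covered], depth[covered])
    ridx <- sequence(depth[covered])
    p_mod <- as.numeric(ridx <= rep(mod[covered], depth[covered]))
    calls <- data.frame(
      read_id = sprintf("%s:%d:r%d", tx, pos, ridx),
      transcript_id = tx, pos = pos, p_mod = p_mod,
      stringsAsFactors = FALSE
    )
    truth <- data.frame(sites, p_call = p_call, is_true_modified = is_true,
                        depth = depth, stringsAsFactors = FALSE)
    list(calls = calls, truth = truth)
  })
}

#' Simulate a native / IVT sample pair over one reference
#'
#' The IVT member conventionally has no true modification sites (it is
#' fully unmodified RNA) but inherits the same context-specific call
#' probabilities — the defining behavior of a caller artifact: the planted
#' GCU elevation appears in both samples. The two members use independent
#' RNG streams derived from their own seeds.
#'
#' @param ref Shared reference.
#' @param config_native,config_ivt `sim_config` objects (give them
#'   different seeds for independent noise).
#' @return List with elements `native` and `ivt`, each as returned by
#'   [simulate_calls()].
#' @export
simulate_pair <- function(ref, config_native, config_ivt) {
  list(native = simulate_calls(ref, config_native),
       ivt = simulate_calls(ref, config_ivt))
}

#' Write a truth table TSV
#'
#' @param truth Truth data.frame from [simulate_calls()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_truth_table <- function(truth, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines("transcript_id\tpos\tkmer\tp_call\tis_true_modified\tdepth", con)
  if (nrow(truth)) {
    writeLines(paste(truth$transcript_id, truth$pos, truth$kmer,
                     format_fraction(truth$p_call),
                     as.integer(truth$is_true_modified), truth$depth,
                     sep = "\t"), con)
  }
  invisible(path)
}
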