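# Motif discovery in top-site context windows: exhaustive central-k-mer
# enrichment counting, and a ZOOPS EM position-weight-matrix learner with
# 0-order background, probabilistic erasure between successive motifs, and
# mononucleotide-shuffle permutation significance.

# ---- encoding helpers -------------------------------------------------------

# Windows may arrive as a character vector or as the data.frame produced by
# extract_windows(). Returns an integer matrix of 0-based letter codes.
encode_windows <- function(windows) {
  if (is.data.frame(windows)) windows <- windows$window
  windows <- toupper(rna_to_dna(windows))
  n <- length(windows)
  if (n == 0L) return(matrix(integer(0), 0L, 0L))
  lens <- nchar(windows)
  if (length(unique(lens)) != 1L) {
    stop_gcu("gcuaudit_input_error", "windows must all have equal length")
  }
  chars <- strsplit(windows, "", fixed = TRUE)
  codes <- match(unlist(chars), DNA_LETTERS) - 1L
  if (anyNA(codes)) {
    stop_gcu("gcuaudit_input_error",
             "windows may only contain A/C/G/T (U accepted, mapped to T)")
  }
  matrix(codes, nrow = n, ncol = lens[1], byrow = TRUE)
}

decode_windows <- function(X) {
  apply(X, 1L, function(r) paste(DNA_LETTERS[r + 1L], collapse = ""))
}

# Laplace-smoothed 0-order background from the window letters themselves.
letter_background <- function(X) {
  counts <- tabulate(as.vector(X) + 1L, nbins = 4L)
  (counts + 1) / (sum(counts) + 4)
}

# Initial PWM: majority mass on the letters of the most frequent width-w
# word among the windows (lexicographically first on ties), 0.1 pseudocount
# elsewhere. Deterministic, in the spirit of substring seeding.
seed_pwm <- function(X, width, pseudo = 0.1) {
  n <- nrow(X); L <- ncol(X); m <- L - width + 1L
  pw <- 4^((width - 1L):0)  # big-endian: code order == lexicographic order
  codes <- integer(n * m)
  for (j in seq_len(m)) {
    codes[seq.int((j - 1L) * n + 1L, j * n)] <-
      as.integer(X[, j:(j + width - 1L), drop = FALSE] %*% pw)
  }
  tab <- tabulate(codes + 1L, nbins = 4L^width)
  best <- which.max(tab) - 1L
  word <- (best %/% pw) %% 4L
  pwm <- matrix(pseudo, nrow = 4L, ncol = width)
  pwm[cbind(word + 1L, seq_len(width))] <- 1 + pseudo
  sweep(pwm, 2L, colSums(pwm), "/")
}

# ---- central k-mer enrichment ----------------------------------------------

#' Count the central k-mers of context windows
#'
#' Tallies the k-mer centered on each window's middle base (the candidate
#' cytosine) and reports the ratio of the most frequent k-mer to the
#' runner-up — the headline enrichment statistic of the audit ("how many
#' more GCU-centred top sites are there than anything else").
#'
#' @param windows Window data.frame from [extract_windows()] or character
#'   vector of equal-length odd windows.
#' @param k Odd k-mer length not exceeding the window length.
#' @return Object of class `kmer_enrichment`: list with `counts` (named
#'   integer vector, decreasing), `k`, `total`, `top_kmer`, `top_ratio`
#'   (top count / runner-up count; `Inf` with a single k-mer, `NA` when
#'   empty). K-mers are reported in the RNA alphabet.
#' @export
count_central_kmers <- function(windows, k = 3L) {
  stopifnot(k %% 2L == 1L)
  if (is.data.frame(windows)) windows <- windows$window
  total <- length(windows)
  if (total == 0L) {
    return(structure(list(counts = integer(0), k = as.integer(k), total = 0L,
                          top_kmer = NA_character_, top_ratio = NA_real_),
                     class = "kmer_enrichment"))
  }
  L <- unique(nchar(windows))
  if (length(L) != 1L) {
    stop_gcu("gcuaudit_input_error", "windows must all have equal length")
  }
  if (k > L) stop_gcu("gcuaudit_input_error", "k exceeds window length")
  mid <- (L + 1L) %/% 2L
  half <- (k - 1L) %/% 2L
  kmers <- dna_to_rna(toupper(substring(windows, mid - half, mid + half)))
  counts <- sort(table(kmers), decreasing = TRUE)
  counts <- stats::setNames(as.integer(counts), names(counts))
  ratio <- if (length(counts) >= 2L) counts[[1]] / counts[[2]] else Inf
  structure(list(counts = counts, k = as.integer(k), total = total,
                 top_kmer = names(counts)[1], top_ratio = unname(ratio)),
            class = "kmer_enrichment")
}

#' @export
print.kmer_enrichment <- function(x, ...) {
  cat(sprintf("central %d-mer counts over %d windows\n", x$k, x$total))
  if (x$total) {
    cat(sprintf("  top: %s (%d), ratio to runner-up %.2f\n",
                x$top_kmer, x$counts[[1]], x$top_ratio))
    print(head(x$counts, 10L))
  }
  invisible(x)
}

# ---- ZOOPS EM ---------------------------------------------------------------

#' Fit a single-width ZOOPS motif model by EM
#'
#' Zero-or-one-occurrence-per-sequence model: a sequence contains a motif
#' site with prior probability `lambda` (uniform over offsets), otherwise it
#' is pure 0-order background. The E-step computes each sequence's posterior
#' over \{no site, site at offset j\}; the M-step re-estimates the PWM (with
#' 0.1 pseudocount per cell) and `lambda`. The maximized objective — data
#' log-likelihood plus the Dirichlet term implied by the pseudocounts — is
#' non-decreasing each iteration and the fit stops when its relative change
#' falls below `tol`.
#'
#' @param windows Equal-length windows (character vector or window
#'   data.frame).
#' @param width Motif width (<= window length).
#' @param background Length-4 probability vector (A,C,G,T order); default:
#'   Laplace-smoothed letter frequencies of the windows.
#' @param max_iter,tol EM stopping controls.
#' @param lambda0 Initial occupancy (default 0.5).
#' @param init_pwm Optional 4 x width initial PWM; default substring seeding.
#' @param avail Optional availability matrix (internal, motif erasure).
#' @param pseudocount Per-cell M-step pseudocount (default 0.1).
#' @return Object of class `motif_model` (see [discover_motifs()]);
#'   `p_empirical` is `NA` here, and `objective_trace` holds the penalized
#'   EM objective per iteration.
#' @export
em_zoops <- function(windows, width, background = NULL, max_iter = 200L,
                     tol = 1e-6, lambda0 = 0.5, init_pwm = NULL,
                     avail = NULL, pseudocount = 0.1) {
  X <- if (is.matrix(windows)) windows else encode_windows(windows)
  if (width > ncol(X)) {
    stop_gcu("gcuaudit_input_error", "width %d exceeds window length %d",
             width, ncol(X))
  }
  if (is.null(background)) background <- letter_background(X)
  stopifnot(length(background) == 4L, all(background > 0))
  background <- background / sum(background)
  if (is.null(init_pwm)) init_pwm <- seed_pwm(X, width, pseudocount)
  if (is.null(avail)) avail <- matrix(1, nrow(X), ncol(X))
  fit <- .em_zoops_core(X, avail, init_pwm, background, lambda0,
                        as.integer(max_iter), tol, pseudocount)
  new_motif_model(fit, width = width, background = background)
}

new_motif_model <- function(fit, width, background, p_empirical = NA_real_) {
  pwm <- fit$pwm
  rownames(pwm) <- DNA_LETTERS
  site_prob <- 1 - fit$z0
  structure(list(
    width = as.integer(width),
    pwm = pwm,
    occupancy = fit$lambda,
    loglik = fit$loglik,
    score = fit$loglik - fit$logp0_sum,  # log-likelihood ratio vs background
    consensus = dna_to_rna(paste(DNA_LETTERS[apply(pwm, 2L, which.max)],
                                 collapse = "")),
    p_empirical = p_empirical,
    n_sites = sum(site_prob > 0.5),
    background = background,
    objective_trace = fit$objective_trace,
    z = fit$z, z0 = fit$z0,
    n_iter = fit$n_iter
  ), class = "motif_model")
}

#' @export
print.motif_model <- function(x, ...) {
  cat(sprintf("motif %s (width %d): occupancy %.2f, n_sites %d, LLR %.1f",
              x$consensus, x$width, x$occupancy, x$n_sites, x$score))
  if (!is.na(x$p_empirical)) cat(sprintf(", p_empirical %.4g", x$p_empirical))
  cat("\n")
  invisible(x)
}

# Mononucleotide shuffle: permute the letters inside each window
# independently; per-window letter composition is exactly preserved.
shuffle_window_matrix <- function(X) {
  t(apply(X, 1L, sample))
}

#' Permutation p-value for a motif score
#'
#' Scores the observed windows and `n_shuffles` mononucleotide-shuffled
#' replicates (each window permuted independently, composition preserved)
#' with `motif_score_fn`, and returns
#' `p = (1 + #\{null >= observed\}) / (1 + n_shuffles)`.
#'
#' @param windows Equal-length windows.
#' @param motif_score_fn Function taking a character vector of windows and
#'   returning a scalar score (larger = stronger motif).
#' @param n_shuffles Number of shuffled replicates (>= 19).
#' @param seed Integer seed; shuffles are reproducible given it.
#' @return List with `p_empirical`, `observed`, `null_scores`.
#' @export
shuffle_null <- function(windows, motif_score_fn, n_shuffles = 100L, seed = 1L) {
  if (n_shuffles < 19L) {
    stop_gcu("gcuaudit_input_error", "n_shuffles must be >= 19")
  }
  X <- encode_windows(windows)
  observed <- motif_score_fn(decode_windows(X))
  null_scores <- vapply(seq_len(n_shuffles), function(r) {
    Xs <- with_seed(derive_seed(seed, r), shuffle_window_matrix(X))
    motif_score_fn(decode_windows(Xs))
  }, numeric(1))
  list(p_empirical = (1 + sum(null_scores >= observed)) / (1 + n_shuffles),
       observed = observed, null_scores = null_scores)
}

# Internal fast path: LLR scores of EM fits at several widths for one window
# matrix. Returns a named numeric vector indexed by width.
.em_scores_by_width <- function(X, widths, background, max_iter, tol,
                                avail = NULL) {
  if (is.null(avail)) avail <- matrix(1, nrow(X), ncol(X))
  vapply(widths, function(w) {
    fit <- .em_zoops_core(X, avail, seed_pwm(X, w), background, 0.5,
                          as.integer(max_iter), tol, 0.1)
    fit$loglik - fit$logp0_sum
  }, numeric(1))
}

#' Discover enriched motifs in context windows
#'
#' Re-runs a MEME-style search as ZOOPS EM over candidate widths with a
#' 0-order background estimated from the input letters, given strand only.
#' For each motif in turn: EM is fit at every width in `[minw, maxw]`; each
#' width's score (log-likelihood ratio against background) is compared with
#' the same score on mononucleotide-shuffled windows; the width with the
#' smallest per-width permutation p is chosen (ties: larger
#' null-standardized score, then smaller width). The motif's reported
#' `p_empirical` is selection-adjusted across widths (Westfall–Young min-p
#' over the shared shuffle ensemble), so searching several widths does not
#' inflate significance. Subsequent motifs are found after probabilistic
#' erasure: each position's availability is reduced by its posterior
#' probability of being covered by earlier motifs' sites.
#'
#' @param windows >= 10 equal-length windows.
#' @param nmotifs Maximum number of motifs (default 5).
#' @param minw,maxw Width range searched (defaults 3 and 6).
#' @param n_shuffles Shuffled replicates for the permutation null
#'   (default 100; minimum 19).
#' @param seed Integer seed; results are bit-reproducible given it.
#' @param max_iter,tol EM stopping controls.
#' @return List of `motif_model` objects ordered by `p_empirical` then
#'   descending log-likelihood.
#' @export
discover_motifs <- function(windows, nmotifs = 5L, minw = 3L, maxw = 6L,
                            n_shuffles = 100L, seed = 1L, max_iter = 200L,
                            tol = 1e-6) {
  X <- encode_windows(windows)
  if (nrow(X) < 10L) {
    stop_gcu("gcuaudit_insufficient_data_error",
             "motif discovery needs at least 10 windows, got %d", nrow(X))
  }
  if (n_shuffles < 19L) {
    stop_gcu("gcuaudit_input_error", "n_shuffles must be >= 19")
  }
  if (!(minw <= maxw && maxw <= ncol(X))) {
    stop_gcu("gcuaudit_input_error",
             "need minw <= maxw <= window length (%d)", ncol(X))
  }
  widths <- seq.int(minw, maxw)
  background <- letter_background(X)

  # Null LLR scores, one shuffle ensemble shared by all motifs: the null does
  # not depend on which motifs were already erased, and reusing it keeps the
  # search at (n_shuffles + nmotifs) EM fits per width.
  null_scores <- matrix(NA_real_, n_shuffles, length(widths),
                        dimnames = list(NULL, widths))
  for (r in seq_len(n_shuffles)) {
    Xs <- with_seed(derive_seed(seed, r), shuffle_window_matrix(X))
    null_scores[r, ] <- .em_scores_by_width(Xs, widths, background,
                                            max_iter, tol)
  }
  null_mean <- colMeans(null_scores)
  null_sd <- apply(null_scores, 2L, sd)
  null_sd[null_sd == 0] <- 1e-12
  # per-replicate per-width ranks within the ensemble (for min-p adjustment)
  null_q <- apply(null_scores, 2L, function(col) {
    vapply(col, function(s) mean(col >= s), numeric(1))
  })
  null_minq <- apply(null_q, 1L, min)

  avail <- matrix(1, nrow(X), ncol(X))
  motifs <- vector("list", nmotifs)
  for (mi in seq_len(nmotifs)) {
    fits <- lapply(widths, function(w) {
      .em_zoops_core(X, avail, seed_pwm(X, w), background, 0.5,
                     as.integer(max_iter), tol, 0.1)
    })
    obs <- vapply(fits, function(f) f$loglik - f$logp0_sum, numeric(1))
    p_w <- vapply(seq_along(widths), function(wi) {
      (1 + sum(null_scores[, wi] >= obs[wi])) / (1 + n_shuffles)
    }, numeric(1))
    zscore <- (obs - null_mean) / null_sd
    best <- which(p_w == min(p_w))
    if (length(best) > 1L) best <- best[which.max(zscore[best])]
    p_adj <- (1 + sum(null_minq <= min(p_w))) / (1 + n_shuffles)
    motifs[[mi]] <- new_motif_model(fits[[best]], width = widths[best],
                                    background = background,
                                    p_empirical = p_adj)
    # probabilistic erasure of this motif's posterior site coverage
    z <- fits[[best]]$z
    w <- widths[best]
    cover <- matrix(0, nrow(X), ncol(X))
    for (j in seq_len(ncol(z))) {
      cols <- j:(j + w - 1L)
      cover[, cols] <- cover[, cols] + z[, j]
    }
    avail <- avail * pmax(1 - cover, 0)
  }
  ord <- order(vapply(motifs, `[[`, numeric(1), "p_empirical"),
               -vapply(motifs, `[[`, numeric(1), "loglik"))
  motifs[ord]
}

#' Write a motif report
#'
#' Tab-separated summary (consensus, width, occupancy, n_sites, LLR score,
#' p_empirical) followed by one text PWM block per motif.
#'
#' @param motifs List of `motif_model` objects from [discover_motifs()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_motif_report <- function(motifs, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines("consensus\twidth\toccupancy\tn_sites\tscore\tp_empirical", con)
  for (mo in motifs) {
    writeLines(sprintf("%s\t%d\t%.6g\t%d\t%.6g\t%.6g", mo$consensus, mo$width,
                       mo$occupancy, mo$n_sites, mo$score, mo$p_empirical),
               con)
  }
  writeLines("", con)
  for (mo in motifs) {
    writeLines(sprintf("# PWM %s (width %d), rows A C G U", mo$consensus,
                       mo$width), con)
    for (a in seq_len(4L)) {
      writeLines(paste(sprintf("%.6f", mo$pwm[a, ]), collapse = "\t"), con)
    }
    writeLines("", con)
  }
  invisible(path)
}
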