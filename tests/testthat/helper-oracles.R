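# Brute-force oracles, written deliberately as plain loops so they share no
# code path with the package implementations they check.

oracle_aggregate <- function(calls, threshold = 0.5) {
  keys <- unique(paste(calls$transcript_id, calls$pos, sep = "\r"))
  rows <- list()
  for (key in keys) {
    parts <- strsplit(key, "\r", fixed = TRUE)[[1]]
    sel <- calls$transcript_id == parts[1] & calls$pos == as.integer(parts[2])
    depth <- 0L; mod <- 0L
    for (p in calls$p_mod[sel]) {
      depth <- depth + 1L
      if (p >= threshold) mod <- mod + 1L
    }
    rows[[key]] <- data.frame(transcript_id = parts[1],
                              pos = as.integer(parts[2]), depth = depth,
                              mod_count = mod, fraction = mod / depth,
                              stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$transcript_id, out$pos), , drop = FALSE]
  rownames(out) <- NULL
  out
}

oracle_central_kmer_counts <- function(windows, k = 3) {
  counts <- list()
  for (w in windows) {
    L <- nchar(w)
    mid <- (L + 1) %/% 2
    km <- chartr("T", "U", substr(w, mid - (k - 1) %/% 2, mid + (k - 1) %/% 2))
    counts[[km]] <- (if (is.null(counts[[km]])) 0L else counts[[km]]) + 1L
  }
  unlist(counts)
}

oracle_histogram <- function(x, width = 0.025) {
  n_bins <- ceiling(1 / width - 1e-9)
  counts <- integer(n_bins)
  for (v in x) {
    b <- 1L
    while (b < n_bins && v >= b * width) b <- b + 1L
    counts[b] <- counts[b] + 1L
  }
  counts
}

oracle_welch_z <- function(a, b) {
  ma <- sum(a) / length(a); mb <- sum(b) / length(b)
  va <- sum((a - ma)^2) / (length(a) - 1)
  vb <- sum((b - mb)^2) / (length(b) - 1)
  (ma - mb) / sqrt(va / length(a) + vb / length(b))
}

oracle_cohens_d <- function(a, b) {
  na <- length(a); nb <- length(b)
  ma <- sum(a) / na; mb <- sum(b) / nb
  va <- sum((a - ma)^2) / (na - 1)
  vb <- sum((b - mb)^2) / (nb - 1)
  (ma - mb) / sqrt(((na - 1) * va + (nb - 1) * vb) / (na + nb - 2))
}

# ZOOPS log-likelihood computed directly from the model definition, used to
# cross-check the EM engine's reported likelihood at its fitted parameters.
oracle_zoops_loglik <- function(windows, pwm, lambda, bg) {
  letters_ <- c("A", "C", "G", "T")
  total <- 0
  for (w in windows) {
    x <- match(strsplit(w, "")[[1]], letters_)
    L <- length(x); width <- ncol(pwm); m <- L - width + 1
    p0 <- prod(bg[x])
    psites <- 0
    for (j in seq_len(m)) {
      pj <- p0
      for (kk in seq_len(width)) {
        a <- x[j + kk - 1]
        pj <- pj * pwm[a, kk] / bg[a]
      }
      psites <- psites + pj
    }
    total <- total + log((1 - lambda) * p0 + (lambda / m) * psites)
  }
  unname(total)
}

# ---- fixtures ---------------------------------------------------------------

# Tiny two-transcript reference exercising edges, non-C bases, and both GCU
# and non-GCU central contexts.
tiny_ref <- function() {
  c(tx1 = "AAGCTAAACGCTATGCTC",
    tx2 = "CCGCTTAGCATCCCGCTA")
}

random_calls <- function(n_sites = 8, max_depth = 12) {
  tx <- sample(c("tx1", "tx2"), n_sites, replace = TRUE)
  pos <- sample(0:50, n_sites, replace = FALSE)
  rows <- lapply(seq_len(n_sites), function(i) {
    d <- sample.int(max_depth, 1)
    data.frame(read_id = sprintf("r%d_%d", i, seq_len(d)),
               transcript_id = tx[i], pos = pos[i],
               p_mod = round(runif(d), 3), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

random_sites <- function(n = 20, transcripts = c("tx1", "tx2"),
                         max_pos = 17, max_depth = 200) {
  pick <- expand.grid(transcript_id = transcripts, pos = 0:max_pos,
                      stringsAsFactors = FALSE)
  pick <- pick[sample.int(nrow(pick), min(n, nrow(pick))), ]
  depth <- sample.int(max_depth, nrow(pick), replace = TRUE)
  mod <- vapply(depth, function(d) sample.int(d + 1L, 1L) - 1L, integer(1))
  data.frame(transcript_id = pick$transcript_id, pos = pick$pos,
             depth = depth, mod_count = mod, fraction = mod / depth,
             stringsAsFactors = FALSE)
}

random_windows <- function(n = 30, len = 11) {
  vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
  }, character(1))
}

# Windows with one exact copy of `word` embedded at a random offset each.
planted_windows <- function(n = 50, len = 15, word = "GCTTAG") {
  w <- strsplit(word, "")[[1]]
  vapply(seq_len(n), function(i) {
    s <- sample(c("A", "C", "G", "T"), len, replace = TRUE)
    off <- sample.int(len - length(w) + 1L, 1)
    s[off:(off + length(w) - 1L)] <- w
    paste(s, collapse = "")
  }, character(1))
}
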