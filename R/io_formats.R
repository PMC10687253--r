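# File formats: reference FASTA, site tables, per-read call tables, and
# interop with per-site fraction/coverage tracks (wiggle / bedGraph).
#
# Conventions fixed here and used everywhere else in the package:
#   * internal alphabet is DNA {A,C,G,T,N}; RNA 'U' is mapped to 'T' on read
#   * coordinates are 0-based transcript positions, strand always '+'
#   * tables are tab-separated, '.' decimal, LF line endings

SITE_TABLE_HEADER <- c("transcript_id", "pos", "depth", "mod_count", "fraction")
PER_READ_HEADER <- c("read_id", "transcript_id", "pos", "p_mod")

#' Read a reference transcriptome FASTA
#'
#' Sequences are uppercased and RNA 'U' is mapped to 'T' so that all
#' downstream coordinates and k-mers live in the DNA alphabet. Only
#' \{A,C,G,T,N\} are accepted after normalization.
#'
#' @param path Path to a FASTA file.
#' @return A [Biostrings::DNAStringSet] named by the FASTA header token up to
#'   the first whitespace, in file order.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) {
    stop_gcu("gcuaudit_format_error", "FASTA file not found: %s", path)
  }
  set <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) {
      stop_gcu("gcuaudit_format_error", "malformed FASTA '%s': %s",
               path, conditionMessage(e))
    }
  )
  ids <- sub("\\s.*$", "", names(set))
  if (length(ids) && any(!nzchar(ids))) {
    stop_gcu("gcuaudit_format_error", "empty FASTA header id in %s", path)
  }
  if (anyDuplicated(ids)) {
    stop_gcu("gcuaudit_duplicate_id_error", "duplicate FASTA id '%s' in %s",
             ids[duplicated(ids)][1], path)
  }
  seqs <- toupper(chartr("uU", "tT", as.character(set)))
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad)) {
    stop_gcu("gcuaudit_format_error",
             "illegal character in sequence at line %d of %s",
             .find_bad_fasta_line(path), path)
  }
  out <- Biostrings::DNAStringSet(seqs)
  names(out) <- ids
  out
}

.find_bad_fasta_line <- function(path) {
  lines <- readLines(path, warn = FALSE)
  for (i in seq_along(lines)) {
    ln <- lines[i]
    if (startsWith(ln, ">")) next
    if (grepl("[^ACGTUNacgtun[:space:]]", ln)) return(i)
  }
  NA_integer_
}

#' Write transcripts to FASTA
#'
#' @param ref A DNAStringSet or named character vector.
#' @param path Output path.
#' @param width Line wrap width.
#' @return Invisibly, `path`.
#' @export
write_fasta <- function(ref, path, width = 70L) {
  chars <- as_ref_chars(ref)
  con <- file(path, open = "wb")
  on.exit(close(con))
  for (i in seq_along(chars)) {
    writeLines(sprintf(">%s", names(chars)[i]), con, sep = "\n")
    s <- chars[[i]]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))),
               con, sep = "\n")
  }
  invisible(path)
}

#' Read a per-site table of methylated fractions
#'
#' Expects the tab-separated dialect with header
#' `transcript_id  pos  depth  mod_count  fraction` and 0-based positions.
#' Rows with depth 0 carry an undefined fraction and are dropped with a
#' counted warning. The stored fraction must agree with `mod_count/depth`
#' within 1e-6; on success the returned fraction is the exact quotient, so
#' write-then-read round-trips are exact.
#'
#' @param path Path to the TSV file.
#' @return A data.frame with the five dialect columns.
#' @export
read_site_table <- function(path) {
  if (!file.exists(path)) {
    stop_gcu("gcuaudit_format_error", "site table not found: %s", path)
  }
  df <- read.delim(path, header = TRUE, sep = "\t", colClasses = "character",
                   check.names = FALSE, stringsAsFactors = FALSE)
  if (!identical(names(df), SITE_TABLE_HEADER)) {
    stop_gcu("gcuaudit_format_error",
             "site table header must be '%s', got '%s'",
             paste(SITE_TABLE_HEADER, collapse = "\t"),
             paste(names(df), collapse = "\t"))
  }
  if (nrow(df) == 0L) return(empty_sites())
  for (col in c("pos", "depth", "mod_count")) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    if (anyNA(v) || any(v != floor(v))) {
      stop_gcu("gcuaudit_format_error", "non-integer %s at row %d",
               col, which(is.na(v) | v != floor(v))[1])
    }
    df[[col]] <- as.integer(v)
  }
  df$fraction <- suppressWarnings(as.numeric(df$fraction))
  if (anyNA(df$fraction)) {
    stop_gcu("gcuaudit_format_error", "non-numeric fraction at row %d",
             which(is.na(df$fraction))[1])
  }
  zero <- df$depth == 0L
  if (any(zero)) {
    warning(sprintf("dropped %d depth-0 row(s) with undefined fraction",
                    sum(zero)), call. = FALSE)
    df <- df[!zero, , drop = FALSE]
    rownames(df) <- NULL
  }
  bad <- df$mod_count > df$depth
  if (any(bad)) {
    stop_gcu("gcuaudit_consistency_error",
             "mod_count > depth at row %d", which(bad)[1])
  }
  exact <- df$mod_count / df$depth
  off <- abs(df$fraction - exact) > 1e-6
  if (any(off)) {
    stop_gcu("gcuaudit_consistency_error",
             "fraction disagrees with mod_count/depth at row %d", which(off)[1])
  }
  df$fraction <- exact
  df
}

# Serialize a fraction with a guaranteed decimal point ("1.0", never "1").
format_fraction <- function(x) {
  s <- sprintf("%.9g", x)
  needs_dot <- !grepl("[.eE]", s)
  s[needs_dot] <- paste0(s[needs_dot], ".0")
  s
}

#' Write a per-site table
#'
#' Inverse of [read_site_table()]; writing then reading is the identity on
#' valid tables.
#'
#' @param sites Site data.frame (see [read_site_table()]).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_site_table <- function(sites, path) {
  if (nrow(sites)) validate_sites(sites)
  con <- tryCatch(file(path, open = "wb"),
                  error = function(e) stop_gcu("gcuaudit_io_error",
                                               "cannot write %s", path))
  on.exit(close(con))
  writeLines(paste(SITE_TABLE_HEADER, collapse = "\t"), con, sep = "\n")
  if (nrow(sites)) {
    writeLines(paste(sites$transcript_id, sites$pos, sites$depth,
                     sites$mod_count, format_fraction(sites$fraction),
                     sep = "\t"), con, sep = "\n")
  }
  invisible(path)
}

#' Read / write per-read modification call tables
#'
#' Dialect: header `read_id  transcript_id  pos  p_mod`, tab-separated,
#' 0-based positions, `p_mod` in [0,1] (binary callers emit exactly 0/1).
#'
#' @param path Path to the TSV file.
#' @return A data.frame with the four dialect columns.
#' @export
read_per_read_table <- function(path) {
  if (!file.exists(path)) {
    stop_gcu("gcuaudit_format_error", "per-read table not found: %s", path)
  }
  df <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                   colClasses = c("character", "character", "integer", "numeric"),
                   stringsAsFactors = FALSE)
  if (!identical(names(df), PER_READ_HEADER)) {
    stop_gcu("gcuaudit_format_error",
             "per-read table header must be '%s'",
             paste(PER_READ_HEADER, collapse = "\t"))
  }
  if (nrow(df) && (anyNA(df$p_mod) || any(df$p_mod < 0 | df$p_mod > 1))) {
    stop_gcu("gcuaudit_format_error", "p_mod outside [0,1] at row %d",
             which(is.na(df$p_mod) | df$p_mod < 0 | df$p_mod > 1)[1])
  }
  df
}

#' @rdname read_per_read_table
#' @param calls Per-read call data.frame.
#' @export
write_per_read_table <- function(calls, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste(PER_READ_HEADER, collapse = "\t"), con, sep = "\n")
  if (nrow(calls)) {
    writeLines(paste(calls$read_id, calls$transcript_id, calls$pos,
                     format_fraction(calls$p_mod), sep = "\t"),
               con, sep = "\n")
  }
  invisible(path)
}

#' Assemble site records from per-site fraction and coverage tracks
#'
#' Interop reader for callers that emit per-site methylated-fraction and
#' per-site coverage tracks (fixed-step or variable-step wiggle, or 1-bp
#' bedGraph). The two tracks are joined on (transcript, 0-based position);
#' `mod_count` is reconstructed as `round(fraction * depth)` (half away from
#' zero). Whichever fraction track the upstream caller exported (raw or
#' dampened) is taken at face value; the source filename is recorded in the
#' `source` attribute of the result.
#'
#' @param value_path Track of per-site fractions in [0,1].
#' @param coverage_path Track of per-site read depth.
#' @return Site data.frame as in [read_site_table()].
#' @export
read_fraction_track <- function(value_path, coverage_path) {
  frac <- .read_track(value_path)
  cov <- .read_track(coverage_path)
  if (nrow(frac) && (any(frac$value < 0) || any(frac$value > 1))) {
    stop_gcu("gcuaudit_format_error",
             "fraction outside [0,1] in %s", value_path)
  }
  key_f <- paste(frac$transcript_id, frac$pos)
  key_c <- paste(cov$transcript_id, cov$pos)
  only_f <- setdiff(key_f, key_c)
  only_c <- setdiff(key_c, key_f)
  if (length(only_f) || length(only_c)) {
    stop_gcu("gcuaudit_join_error",
             "position(s) present in one track only: %s",
             paste(head(c(only_f, only_c), 5L), collapse = ", "))
  }
  depth <- cov$value[match(key_f, key_c)]
  if (any(depth != floor(depth)) || any(depth < 0)) {
    stop_gcu("gcuaudit_format_error",
             "coverage track has non-integer or negative depth")
  }
  out <- data.frame(transcript_id = frac$transcript_id, pos = frac$pos,
                    depth = as.integer(depth),
                    mod_count = as.integer(floor(frac$value * depth + 0.5)),
                    stringsAsFactors = FALSE)
  zero <- out$depth == 0L
  if (any(zero)) {
    warning(sprintf("dropped %d depth-0 track position(s)", sum(zero)),
            call. = FALSE)
    out <- out[!zero, , drop = FALSE]
  }
  out$fraction <- out$mod_count / out$depth
  out <- out[order(out$transcript_id, out$pos), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "source") <- c(fraction = value_path, coverage = coverage_path)
  out
}

# Minimal wiggle/bedGraph track parser -> data.frame(transcript_id, pos, value)
# with 0-based positions. Wiggle declarations are 1-based per the format spec;
# bedGraph starts are already 0-based. Spans/intervals must cover single bases.
.read_track <- function(path) {
  if (!file.exists(path)) {
    stop_gcu("gcuaudit_format_error", "track file not found: %s", path)
  }
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  lines <- lines[!startsWith(lines, "track")]
  tx <- character(0); pos <- integer(0); val <- numeric(0)
  mode <- "bedGraph"; cur_tx <- NA_character_
  step <- 1L; at <- NA_integer_
  for (i in seq_along(lines)) {
    ln <- lines[i]
    if (startsWith(ln, "fixedStep") || startsWith(ln, "variableStep")) {
      fields <- strsplit(ln, "[ \t]+")[[1]]
      kv <- strsplit(fields[-1], "=")
      opts <- stats::setNames(vapply(kv, `[`, "", 2L), vapply(kv, `[`, "", 1L))
      if (!is.na(opts["span"]) && as.integer(opts["span"]) != 1L) {
        stop_gcu("gcuaudit_format_error", "wiggle span must be 1 (%s)", path)
      }
      cur_tx <- unname(opts["chrom"])
      if (startsWith(ln, "fixedStep")) {
        mode <- "fixed"
        at <- as.integer(opts["start"]) - 1L  # wiggle is 1-based
        step <- if (is.na(opts["step"])) 1L else as.integer(opts["step"])
      } else {
        mode <- "variable"
      }
      next
    }
    parts <- strsplit(ln, "[ \t]+")[[1]]
    if (mode == "fixed") {
      tx <- c(tx, cur_tx); pos <- c(pos, at); val <- c(val, as.numeric(parts[1]))
      at <- at + step
    } else if (mode == "variable") {
      tx <- c(tx, cur_tx); pos <- c(pos, as.integer(parts[1]) - 1L)
      val <- c(val, as.numeric(parts[2]))
    } else {
      if (length(parts) != 4L) {
        stop_gcu("gcuaudit_format_error",
                 "bedGraph line %d of %s does not have 4 columns", i, path)
      }
      start <- as.integer(parts[2]); end <- as.integer(parts[3])
      if (end != start + 1L) {
        stop_gcu("gcuaudit_format_error",
                 "bedGraph interval must be single-base (line %d of %s)",
                 i, path)
      }
      tx <- c(tx, parts[1]); pos <- c(pos, start); val <- c(val, as.numeric(parts[4]))
    }
  }
  if (anyNA(val)) {
    stop_gcu("gcuaudit_format_error", "non-numeric track value in %s", path)
  }
  data.frame(transcript_id = tx, pos = pos, value = val,
             stringsAsFactors = FALSE)
}
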