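#' @useDynLib gcuaudit, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom data.table data.table setorderv
#' @importFrom stats median pnorm rbinom rnbinom rpois runif sd
#' @importFrom utils head read.delim
NULL

.datatable.aware <- TRUE

DNA_LETTERS <- c("A", "C", "G", "T")

# Classed conditions so callers (and the CLI) can map failures to exit codes.
stop_gcu <- function(class, msg, ...) {
  stop(structure(
    class = c(class, "gcuaudit_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

#' Convert between DNA- and RNA-alphabet strings
#'
#' The package works internally in the DNA alphabet (reference FASTA
#' convention) but reports motifs and k-mers in the RNA alphabet, so that a
#' central 3-mer reads "GCU" rather than "GCT".
#'
#' @param x Character vector of sequences.
#' @return Character vector with T and U interchanged.
#' @export
dna_to_rna <- function(x) chartr("T", "U", x)

#' @rdname dna_to_rna
#' @export
rna_to_dna <- function(x) chartr("U", "T", x)

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG afterwards so seeded helpers do not perturb user code.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# Derive a reproducible child seed from a parent seed and an index, staying
# inside the 32-bit signed integer range.
derive_seed <- function(seed, index) {
  as.integer((as.double(seed) * 48271 + index * 16807) %% 2147483647)
}

# Accept a reference as either a Biostrings::DNAStringSet or a named
# character vector; return a named character vector of uppercase sequences.
as_ref_chars <- function(ref) {
  if (methods::is(ref, "XStringSet")) {
    out <- as.character(ref)
  } else if (is.character(ref)) {
    out <- toupper(chartr("U", "T", ref))
  } else {
    stop_gcu("gcuaudit_lookup_error",
             "reference must be a DNAStringSet or named character vector")
  }
  if (is.null(names(out)) || any(!nzchar(names(out)))) {
    stop_gcu("gcuaudit_lookup_error", "reference sequences must be named")
  }
  out
}

# Validate a site table data.frame (SiteRecord columns and invariants).
validate_sites <- function(sites, where = "site table") {
  req <- c("transcript_id", "pos", "depth", "mod_count", "fraction")
  missing_cols <- setdiff(req, names(sites))
  if (length(missing_cols)) {
    stop_gcu("gcuaudit_format_error", "%s lacks column(s): %s",
             where, paste(missing_cols, collapse = ", "))
  }
  if (any(sites$depth <= 0)) {
    stop_gcu("gcuaudit_consistency_error", "%s contains depth <= 0 rows", where)
  }
  if (any(sites$mod_count > sites$depth)) {
    stop_gcu("gcuaudit_consistency_error",
             "%s has mod_count > depth (row %d)",
             where, which(sites$mod_count > sites$depth)[1])
  }
  bad <- abs(sites$fraction - sites$mod_count / sites$depth) > 1e-6
  if (any(bad)) {
    stop_gcu("gcuaudit_consistency_error",
             "%s fraction inconsistent with mod_count/depth (row %d)",
             where, which(bad)[1])
  }
  invisible(sites)
}

empty_sites <- function() {
  data.frame(transcript_id = character(), pos = integer(), depth = integer(),
             mod_count = integer(), fraction = numeric(),
             stringsAsFactors = FALSE)
}
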