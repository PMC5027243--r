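# Internal helpers shared across modules. All genomic coordinates inside the
# package are 1-based closed; BED/BEDPE conventions are converted at the I/O
# boundary only.

# midpoint of a closed interval [start, end]; may be half-integer
interval_midpoint <- function(start, end) (start + end) / 2

# run code under a fixed RNG seed without disturbing the caller's RNG state
with_seed <- function(seed, code) {
  withr::with_seed(seed, code)
}

# derive a reproducible child seed from a master seed; kept well below 2^31
child_seed <- function(seed, index) {
  (as.integer(seed) %% 1000003L) * 1009L + 7L * as.integer(index) %% 97L +
    as.integer(index)
}

# coerce a reference to a named character vector of chromosome sequences
as_reference <- function(reference) {
  if (inherits(reference, "DNAStringSet")) {
    out <- as.character(reference)
    names(out) <- names(reference)
    return(out)
  }
  if (is.character(reference)) {
    if (is.null(names(reference))) {
      abort("reference sequences must be named by chromosome")
    }
    return(reference)
  }
  abort("reference must be a named character vector or a DNAStringSet")
}

ref_chrom <- function(reference, chrom) {
  seqs <- as_reference(reference)
  if (!chrom %in% names(seqs)) {
    abort(paste0("chromosome '", chrom, "' not present in the reference"))
  }
  seqs[[chrom]]
}

# validate that a vector of p-values is in [0, 1]
check_probabilities <- function(p, what = "p-values") {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1)) {
    abort(paste0(what, " must all lie in [0, 1]"))
  }
  invisible(p)
}

# Shannon entropy (natural log) of a count vector, 0 for degenerate input
shannon_entropy <- function(counts) {
  counts <- counts[counts > 0]
  if (length(counts) <= 1L) {
    return(0)
  }
  p <- counts / sum(counts)
  -sum(p * log(p))
}

`%g0%` <- function(x, default) if (length(x) == 0L || is.na(x[1L])) default else x
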