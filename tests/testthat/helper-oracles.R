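# Independent oracles and small fixture builders used across the suite.

# exhaustive character-by-character junction-microhomology oracle:
# deletion of length `len` anchored at `pos` (deleted span pos+1 .. pos+len)
mh_oracle <- function(chromseq, pos, len) {
  clen <- nchar(chromseq)
  r <- 0L
  while (r < len && pos + len + r + 1L <= clen &&
         substr(chromseq, pos + r + 1L, pos + r + 1L) ==
         substr(chromseq, pos + len + r + 1L, pos + len + r + 1L)) {
    r <- r + 1L
  }
  l <- 0L
  while (l < len && pos - l >= 1L &&
         substr(chromseq, pos + len - l, pos + len - l) ==
         substr(chromseq, pos - l, pos - l)) {
    l <- l + 1L
  }
  max(l, r)
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# candidate-pair predicate written directly from the screen definition,
# independent of the package's pairing code
candidate_edges_oracle <- function(calls, slop_bp = 500L) {
  pad <- function(s, e) {
    deg <- s == e
    list(s = ifelse(deg, s - slop_bp, s), e = ifelse(deg, e + slop_bp, e))
  }
  low <- pad(calls$low_start, calls$low_end)
  high <- pad(calls$high_start, calls$high_end)
  heads <- which(calls$orient == "head_head")
  tails <- which(calls$orient == "tail_tail")
  out <- NULL
  for (h in heads) {
    for (t in tails) {
      if (calls$chrom_low[h] == calls$chrom_low[t] &&
          low$s[h] <= low$e[t] && low$s[t] <= low$e[h] &&
          high$s[h] <= high$e[t] && high$s[t] <= high$e[h]) {
        out <- rbind(out, data.frame(h = h, t = t))
      }
    }
  }
  if (is.null(out)) data.frame(h = integer(), t = integer()) else out
}

# exhaustive maximum matching over a small candidate edge set
max_matching_oracle <- function(edges) {
  if (nrow(edges) == 0L) return(0L)
  e <- edges[1L, ]
  rest <- edges[-1L, , drop = FALSE]
  skip <- max_matching_oracle(rest)
  compat <- rest[rest$h != e$h & rest$t != e$t, , drop = FALSE]
  take <- 1L + max_matching_oracle(compat)
  max(skip, take)
}

# random inverted-call catalogue for pairing stress tests: some reciprocal
# pairs with jittered breakpoints, some lone calls
random_inversion_catalogue <- function(n_calls_max = 30L) {
  n_pairs <- sample(0:5, 1L)
  n_lone <- sample(0:max(0L, n_calls_max - 2L * n_pairs), 1L)
  calls <- list()
  id <- 0L
  mk <- function(orient, p1, p2, w) {
    id <<- id + 1L
    tibble::tibble(
      call_id = sprintf("c%03d", id), chrom_low = "chr1",
      low_start = as.integer(p1), low_end = as.integer(p1 + w),
      chrom_high = "chr1",
      high_start = as.integer(p2), high_end = as.integer(p2 + w),
      orient = orient, read_support = sample(6:20, 1L), sample_id = "s1"
    )
  }
  for (i in seq_len(n_pairs)) {
    p1 <- sample.int(9e5, 1L)
    p2 <- p1 + sample(3000:50000, 1L)
    w <- sample(c(0L, 100L, 400L), 1L)
    jit <- sample(-300:300, 2L)
    calls <- c(calls, list(mk("head_head", p1, p2, w),
                           mk("tail_tail", p1 + jit[1L], p2 + jit[2L], w)))
  }
  for (i in seq_len(n_lone)) {
    p1 <- sample.int(9e5, 1L)
    calls <- c(calls, list(mk(sample(c("head_head", "tail_tail"), 1L),
                              p1, p1 + sample(3000:50000, 1L),
                              sample(c(0L, 200L), 1L))))
  }
  if (length(calls) == 0L) {
    return(radsig:::empty_rearrangements())
  }
  dplyr::bind_rows(calls)
}

# write a minimal VCF body with the standard header
write_test_vcf <- function(rows, path = tempfile(fileext = ".vcf")) {
  writeLines(c("##fileformat=VCFv4.2",
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
               rows), path)
  path
}

# small catalogue with given record counts (content is immaterial)
stub_catalogue <- function(sample_id, group, n_subs = 0L, n_del = 0L,
                           n_ins = 0L, n_rearr = 0L) {
  subs <- if (n_subs > 0L) {
    tibble::tibble(chrom = "chr1", pos = seq_len(n_subs), ref_base = "A",
                   alt_base = "C", vaf = 0.4, sample_id = sample_id)
  }
  mk_ind <- function(n, class, ref, alt) {
    if (n == 0L) return(NULL)
    tibble::tibble(chrom = "chr1", pos = seq_len(n) * 10L, ref_allele = ref,
                   alt_allele = alt, indel_class = class,
                   length = 1L,
                   deleted_seq = if (class == "deletion") "T" else
                     NA_character_,
                   vaf = 0.4, mh_len = NA_integer_, clonality = "unknown",
                   sample_id = sample_id)
  }
  indels <- dplyr::bind_rows(mk_ind(n_del, "deletion", "AT", "A"),
                             mk_ind(n_ins, "insertion", "A", "AT"))
  rearr <- if (n_rearr > 0L) {
    tibble::tibble(call_id = sprintf("%s_r%d", sample_id, seq_len(n_rearr)),
                   chrom_low = "chr1", low_start = 1000L, low_end = 1000L,
                   chrom_high = "chr1", high_start = 900000L,
                   high_end = 900000L, orient = "other",
                   read_support = 20L, sample_id = sample_id)
  }
  tumour_catalogue(sample_id, group, substitutions = subs,
                   indels = if (is.null(indels) || nrow(indels) == 0L)
                     NULL else indels,
                   rearrangements = rearr)
}
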