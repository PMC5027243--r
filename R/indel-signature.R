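# Deletion/insertion burden metrics, deletion size spectra, junction
# microhomology measured from the reference, and distribution comparisons.

#' Junction microhomology of deletions
#'
#' For a deletion of sequence `D` (length `L`), the right-side microhomology
#' is the longest `k <= L` for which the first `k` deleted bases equal the
#' `k` reference bases immediately 3' of the deleted span; the left-side
#' microhomology is the longest `k` for which the last `k` deleted bases
#' equal the `k` bases immediately 5' of the span. The reported value is the
#' maximum of the two, so it always lies in `[0, L]`. Microhomology at the
#' junction is the hallmark of microhomology-mediated / non-homologous
#' end-joining repair.
#'
#' @param deletions Indel tibble (rows with `indel_class != "deletion"` get
#'   `NA`). Needs `chrom`, `pos` (anchor base), `length`.
#' @param reference Reference genome (named character vector or
#'   `DNAStringSet`).
#' @return `deletions` with the `mh_len` column filled.
#' @export
compute_microhomology <- function(deletions, reference) {
  reference <- as_reference(reference)
  deletions <- tibble::as_tibble(deletions)
  if (!"mh_len" %in% names(deletions)) deletions$mh_len <- NA_integer_
  idx <- which(deletions$indel_class == "deletion")
  if (length(idx) == 0L) return(deletions)
  for (ch in unique(deletions$chrom[idx])) {
    chromseq <- ref_chrom(reference, ch)
    clen <- nchar(chromseq)
    sel <- idx[deletions$chrom[idx] == ch]
    pos <- deletions$pos[sel]
    len <- deletions$length[sel]
    if (any(pos + len > clen | pos < 0L)) {
      abort(paste0("deletion span outside reference on ", ch))
    }
    del_seq <- substring(chromseq, pos + 1L, pos + len)
    deletions$mh_len[sel] <- mh_len_vec(chromseq, pos, len, del_seq, clen)
  }
  deletions
}

# vectorized max(left, right) junction identity, capped at deletion length
# and at the available flank
mh_len_vec <- function(chromseq, pos, len, del_seq, clen) {
  n <- length(pos)
  mh_right <- integer(n)
  active <- seq_len(n)
  k <- 1L
  while (length(active) > 0L) {
    ok <- k <= len[active] & (pos[active] + len[active] + k) <= clen
    cand <- active[ok]
    if (length(cand) == 0L) break
    match <- substr(del_seq[cand], k, k) ==
      substring(chromseq, pos[cand] + len[cand] + k, pos[cand] + len[cand] + k)
    mh_right[cand[match]] <- k
    active <- cand[match]
    k <- k + 1L
  }
  mh_left <- integer(n)
  active <- seq_len(n)
  k <- 1L
  while (length(active) > 0L) {
    ok <- k <= len[active] & (pos[active] - k + 1L) >= 1L
    cand <- active[ok]
    if (length(cand) == 0L) break
    match <- substr(del_seq[cand], len[cand] - k + 1L, len[cand] - k + 1L) ==
      substring(chromseq, pos[cand] - k + 1L, pos[cand] - k + 1L)
    mh_left[cand[match]] <- k
    active <- cand[match]
    k <- k + 1L
  }
  pmax(mh_left, mh_right)
}

#' Per-sample mutation burden summary
#'
#' Counts substitutions, deletions, insertions and complex indels and forms
#' the indel/substitution and deletion/insertion ratios. Complex indels are
#' excluded from the deletion/insertion ratio (which contrasts deletions
#' against insertions specifically) but are counted. Ratios with a zero
#' denominator are reported as `NA` with counts intact.
#'
#' @param catalogue A [tumour_catalogue()], or a list of them.
#' @return Tibble with one row per sample: `sample_id`, `group`, `n_subs`,
#'   `n_del`, `n_ins`, `n_complex`, `indel_sub_ratio`, `del_ins_ratio`.
#' @export
burden_summary <- function(catalogue) {
  if (inherits(catalogue, "tumour_catalogue")) catalogue <- list(catalogue)
  purrr::map_dfr(catalogue, function(cat) {
    cls <- cat$indels$indel_class
    n_subs <- nrow(cat$substitutions)
    n_del <- sum(cls == "deletion")
    n_ins <- sum(cls == "insertion")
    n_complex <- sum(cls == "complex")
    tibble::tibble(
      sample_id = cat$sample_id, group = cat$group,
      n_subs = n_subs, n_del = n_del, n_ins = n_ins, n_complex = n_complex,
      indel_sub_ratio = if (n_subs > 0) (n_del + n_ins + n_complex) / n_subs
                        else NA_real_,
      del_ins_ratio = if (n_ins > 0) n_del / n_ins else NA_real_
    )
  })
}

#' Deletion size spectrum
#'
#' Histogram of deletion lengths over 1-100 bp plus a `">100"` bin.
#'
#' @param indels Indel tibble.
#' @param normalize Return fractions summing to 1 (default) or raw counts.
#' @return Tibble with `length_bin` (factor, `1`..`100`, `">100"`) and
#'   `count` / `fraction`; class `radsig_spectrum`.
#' @export
deletion_size_spectrum <- function(indels, normalize = TRUE) {
  lens <- indels$length[indels$indel_class == "deletion"]
  bins <- c(as.character(1:100), ">100")
  binned <- ifelse(lens > 100L, ">100", as.character(lens))
  counts <- table(factor(binned, levels = bins))
  out <- tibble::tibble(
    length_bin = factor(bins, levels = bins),
    count = as.integer(counts)
  )
  if (normalize) {
    total <- sum(out$count)
    out$fraction <- if (total > 0) out$count / total else rep(0, nrow(out))
  }
  class(out) <- c("radsig_spectrum", class(out))
  out
}

#' Kolmogorov-Smirnov distance between two samples
#'
#' `D = sup |ECDF_a - ECDF_b|`, computed directly from the pooled jump
#' points. Used to compare deletion size or microhomology-length
#' distributions between groups.
#'
#' @param a,b Non-empty numeric vectors.
#' @return The statistic `D` in `[0, 1]`.
#' @export
ks_statistic <- function(a, b) {
  if (length(a) == 0L || length(b) == 0L) {
    abort("both samples must be non-empty")
  }
  pts <- sort(unique(c(a, b)))
  fa <- ecdf(a)(pts)
  fb <- ecdf(b)(pts)
  max(abs(fa - fb))
}

#' Excess indel burden of an exposed group over a naive baseline
#'
#' The baseline indel/substitution ratio `r0` is the median of the naive
#' samples' ratios; each exposed sample's excess is
#' `n_indels - r0 * n_subs`. This is the transparent median-baseline
#' estimator; the cohort-level mixed model ([mixed_interaction_model()]) is
#' the model-based route to the same contrast.
#'
#' @param exposed,naive Burden tibbles from [burden_summary()] (or catalogue
#'   lists, which are summarised first).
#' @return List with `per_sample` (tibble: `sample_id`, `excess`),
#'   `median_excess`, `sd_excess`, `baseline_ratio`.
#' @export
excess_indel_estimate <- function(exposed, naive) {
  as_burden <- function(x) {
    if (is.data.frame(x)) tibble::as_tibble(x) else burden_summary(x)
  }
  exposed <- as_burden(exposed)
  naive <- as_burden(naive)
  if (nrow(naive) == 0L) abort("naive group is empty")
  if (nrow(exposed) == 0L) abort("exposed group is empty")
  r0 <- median(naive$indel_sub_ratio, na.rm = TRUE)
  n_indels <- exposed$n_del + exposed$n_ins + exposed$n_complex
  excess <- n_indels - r0 * exposed$n_subs
  list(
    per_sample = tibble::tibble(sample_id = exposed$sample_id,
                                excess = excess),
    median_excess = median(excess),
    sd_excess = if (length(excess) > 1L) sd(excess) else NA_real_,
    baseline_ratio = r0
  )
}
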