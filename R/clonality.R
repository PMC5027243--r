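# Mutation copy number, clonal/subclonal classification, and the clonal
# versus subclonal deletion contrast.

#' Mutation copy number
#'
#' Standard plug-in estimate of the number of tumour chromosome copies
#' carrying a mutation:
#' `mcn = f * (rho * CN_t + CN_n * (1 - rho)) / rho`
#' with variant allele fraction `f`, tumour purity `rho`, local tumour total
#' copy number `CN_t`, and normal copy number `CN_n` (2 for autosomes).
#' Clonal heterozygous mutations in a diploid region sit at `mcn ~ 1`.
#'
#' @param vaf Variant allele fraction in `[0, 1]` (vectorized).
#' @param purity Tumour purity in `(0, 1]`.
#' @param tumour_cn Local total tumour copy number (>= 0).
#' @param normal_cn Normal copy number (default 2).
#' @return Numeric vector of mutation copy numbers (`NA` where any input is
#'   missing).
#' @export
mutation_copy_number <- function(vaf, purity, tumour_cn, normal_cn = 2) {
  if (any(purity <= 0, na.rm = TRUE)) {
    abort("purity must be > 0")
  }
  if (any(vaf < 0 | vaf > 1, na.rm = TRUE)) {
    abort("vaf must lie in [0, 1]")
  }
  vaf * (purity * tumour_cn + normal_cn * (1 - purity)) / purity
}

#' Classify mutations as clonal or subclonal
#'
#' Threshold classification on mutation copy number: clonal mutations sit at
#' `mcn ~ 1`, subclonal below. The boundary is inclusive: `mcn` equal to the
#' threshold is clonal.
#'
#' @param mcn Mutation copy number (vectorized; `NA` maps to `"unknown"`).
#' @param clonal_threshold Default 0.75.
#' @return Character vector in `{"clonal", "subclonal", "unknown"}`.
#' @export
classify_clonality <- function(mcn, clonal_threshold = 0.75) {
  dplyr::case_when(
    is.na(mcn) ~ "unknown",
    mcn >= clonal_threshold ~ "clonal",
    TRUE ~ "subclonal"
  )
}

# local tumour copy number at positions, from a segment table
# (chrom, start, end, cn); NA outside segments or without a table
lookup_copy_number <- function(copy_number, chrom, pos) {
  if (is.null(copy_number)) return(rep(NA_real_, length(pos)))
  out <- rep(NA_real_, length(pos))
  for (ch in unique(chrom)) {
    seg <- copy_number[copy_number$chrom == ch, ]
    sel <- which(chrom == ch)
    if (nrow(seg) == 0L) next
    idx <- findInterval(pos[sel], seg$start)
    hit <- idx >= 1L & pos[sel] <= seg$end[pmax(idx, 1L)]
    out[sel[hit]] <- seg$cn[idx[hit]]
  }
  out
}

#' Assign clonality classes to a catalogue's indels
#'
#' Computes per-record mutation copy number from VAF, sample purity and
#' local copy number, then classifies. Records missing any ingredient are
#' reported `"unknown"` rather than guessed.
#'
#' @param catalogue A [tumour_catalogue()] (uses its `purity` and
#'   `copy_number`).
#' @param clonal_threshold Passed to [classify_clonality()].
#' @return The catalogue with `indels$clonality` (and `indels$mcn`) filled.
#' @export
assign_clonality <- function(catalogue, clonal_threshold = 0.75) {
  ind <- catalogue$indels
  cn <- lookup_copy_number(catalogue$copy_number, ind$chrom, ind$pos)
  mcn <- rep(NA_real_, nrow(ind))
  ok <- !is.na(ind$vaf) & !is.na(catalogue$purity) & !is.na(cn)
  if (any(ok)) {
    mcn[ok] <- mutation_copy_number(ind$vaf[ok], catalogue$purity, cn[ok])
  }
  ind$mcn <- mcn
  ind$clonality <- classify_clonality(mcn, clonal_threshold)
  catalogue$indels <- ind
  catalogue
}

#' Two-sided Fisher's exact test for a 2x2 table
#'
#' Direct hypergeometric enumeration: with margins fixed, the two-sided
#' p-value sums the probabilities of all tables no more probable than the
#' observed one (the same convention as the classical test; a relative
#' tolerance of 1e-7 guards ties against floating-point noise).
#'
#' @param tab 2x2 matrix of non-negative counts.
#' @return List with `p_value` and `odds_ratio` (sample odds ratio,
#'   `Inf`/`NaN`-safe).
#' @export
fisher_test_2x2 <- function(tab) {
  stopifnot(is.matrix(tab), all(dim(tab) == 2L), all(tab >= 0))
  m <- sum(tab[1L, ])
  n <- sum(tab[2L, ])
  k <- sum(tab[, 1L])
  x <- tab[1L, 1L]
  support <- max(0L, k - n):min(k, m)
  probs <- dhyper(support, m, n, k)
  p_obs <- dhyper(x, m, n, k)
  p <- sum(probs[probs <= p_obs * (1 + 1e-7)])
  or <- (tab[1L, 1L] * tab[2L, 2L]) / (tab[1L, 2L] * tab[2L, 1L])
  list(p_value = min(1, p), odds_ratio = or)
}

#' Clonal versus subclonal deletion contrast
#'
#' Tests whether deletions are enriched among clonal relative to subclonal
#' indels: rows of the 2x2 table are deletion / other indel, columns clonal /
#' subclonal, compared by the two-sided Fisher's exact test. A radiation
#' exposure predating tumour expansion leaves its deletion excess among the
#' early, clonal mutations only.
#'
#' @param indels Indel tibble with `indel_class` and `clonality` filled (for
#'   example via [assign_clonality()]); `"unknown"` records are dropped.
#' @return List with `table`, `p_value`, `odds_ratio` and `computable`
#'   (`FALSE`, with `p_value = NA`, when either clonality class is absent).
#' @export
clonal_deletion_contrast <- function(indels) {
  if (inherits(indels, "tumour_catalogue")) indels <- indels$indels
  known <- indels[indels$clonality %in% c("clonal", "subclonal"), ]
  tab <- matrix(c(
    sum(known$clonality == "clonal" & known$indel_class == "deletion"),
    sum(known$clonality == "subclonal" & known$indel_class == "deletion"),
    sum(known$clonality == "clonal" & known$indel_class != "deletion"),
    sum(known$clonality == "subclonal" & known$indel_class != "deletion")
  ), nrow = 2L, byrow = TRUE,
  dimnames = list(c("deletion", "other_indel"), c("clonal", "subclonal")))
  if (any(colSums(tab) == 0L)) {
    return(list(table = tab, p_value = NA_real_, odds_ratio = NA_real_,
                computable = FALSE))
  }
  ft <- fisher_test_2x2(tab)
  list(table = tab, p_value = ft$p_value, odds_ratio = ft$odds_ratio,
       computable = TRUE)
}
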