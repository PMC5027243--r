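# Catalogue I/O: VCF, BEDPE, BED/bedGraph, FASTA and manifest readers/writers.
# All in-memory coordinates are 1-based closed (VCF convention); BED and BEDPE
# 0-based half-open coordinates are converted at this boundary only.

#' Read a reference genome from FASTA
#'
#' @param path FASTA file.
#' @return Named character vector of chromosome sequences (names truncated at
#'   the first whitespace, as aligners do).
#' @export
read_genome_fasta <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  as_reference(seqs)
}

#' @rdname read_genome_fasta
#' @param genome Named character vector of sequences.
#' @export
write_genome_fasta <- function(genome, path) {
  genome <- as_reference(genome)
  dss <- Biostrings::DNAStringSet(unname(genome))
  names(dss) <- names(genome)
  Biostrings::writeXStringSet(dss, path, width = 80L)
  invisible(path)
}

# ---------------------------------------------------------------------------
# VCF

# light pre-scan so malformed rows are reported with their line number,
# which vcfR does not do
validate_vcf_lines <- function(path) {
  lines <- readLines(path)
  body <- which(!startsWith(lines, "#"))
  nfield <- vapply(strsplit(lines[body], "\t", fixed = TRUE), length, 1L)
  bad <- body[nfield < 8L & nzchar(lines[body])]
  if (length(bad) > 0L) {
    abort(paste0("malformed VCF line ", bad[1L], " in ", path,
                 ": fewer than 8 tab-separated fields"))
  }
  invisible(lines)
}

vcf_fix_tibble <- function(path) {
  validate_vcf_lines(path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- tibble::as_tibble(as.data.frame(vcfR::getFIX(v, getINFO = TRUE),
                                         stringsAsFactors = FALSE))
  if (nrow(fix) == 0L) {
    return(tibble::tibble(CHROM = character(), POS = integer(),
                          REF = character(), ALT = character(),
                          INFO = character()))
  }
  fix$POS <- as.integer(fix$POS)
  fix
}

info_field <- function(info, key) {
  m <- stringr::str_match(info, paste0("(?:^|;)", key, "=([^;]+)"))[, 2L]
  suppressWarnings(as.numeric(m))
}

#' Read somatic substitutions from VCF
#'
#' Only biallelic single-nucleotide rows are returned. A `VAF=` INFO key, if
#' present, populates `vaf`.
#'
#' @param path VCF file.
#' @param sample_id Sample identifier attached to every record.
#' @return Tibble with columns `chrom`, `pos`, `ref_base`, `alt_base`, `vaf`,
#'   `sample_id`.
#' @export
read_substitution_vcf <- function(path, sample_id = NA_character_) {
  fix <- vcf_fix_tibble(path)
  keep <- nchar(fix$REF) == 1L & nchar(fix$ALT) == 1L
  fix <- fix[keep, , drop = FALSE]
  out <- tibble::tibble(
    chrom = fix$CHROM, pos = fix$POS,
    ref_base = fix$REF, alt_base = fix$ALT,
    vaf = info_field(fix$INFO, "VAF"),
    sample_id = sample_id
  )
  bad <- out$ref_base == out$alt_base |
    !out$ref_base %in% c("A", "C", "G", "T") |
    !out$alt_base %in% c("A", "C", "G", "T")
  if (any(bad)) {
    abort(paste0("invalid substitution record(s) in ", path, " at row(s) ",
                 paste(head(which(bad), 3L), collapse = ", ")))
  }
  out
}

classify_indel <- function(ref, alt) {
  nr <- nchar(ref)
  na <- nchar(alt)
  dplyr::case_when(
    nr > na & na == 1L & substr(ref, 1L, 1L) == alt ~ "deletion",
    na > nr & nr == 1L & substr(alt, 1L, 1L) == ref ~ "insertion",
    TRUE ~ "complex"
  )
}

# left-align a deletion against the reference: while the base preceding the
# anchor equals the last deleted base, the same event can be written one base
# to the left. Canonical placement makes microhomology and size spectra
# independent of caller-specific placement.
left_align_deletion <- function(chromseq, pos, deleted_seq) {
  len <- nchar(deleted_seq)
  repeat {
    if (pos < 1L) break
    last_del <- substr(chromseq, pos + len, pos + len)
    anchor <- substr(chromseq, pos, pos)
    if (pos - 1L >= 1L && anchor == last_del) {
      pos <- pos - 1L
      deleted_seq <- substr(chromseq, pos + 1L, pos + len)
    } else {
      break
    }
  }
  list(pos = pos, deleted_seq = deleted_seq)
}

#' Read somatic indels from VCF
#'
#' Rows are normalized to anchor-base VCF semantics: a deletion's ALT is a
#' one-base prefix of REF (and symmetrically for insertions); anything else is
#' flagged `complex` and retained. With a reference, deletions are left-aligned
#' and their deleted sequence is checked against (and extracted from) the
#' reference.
#'
#' @param path VCF file.
#' @param reference Optional reference genome (named character vector or
#'   `DNAStringSet`) used for validation and left alignment.
#' @param sample_id Sample identifier attached to every record.
#' @return Tibble with columns `chrom`, `pos` (anchor base), `ref_allele`,
#'   `alt_allele`, `indel_class`, `length`, `deleted_seq`, `vaf`, `mh_len`,
#'   `clonality`, `sample_id`.
#' @export
read_indel_vcf <- function(path, reference = NULL, sample_id = NA_character_) {
  fix <- vcf_fix_tibble(path)
  keep <- nchar(fix$REF) > 1L | nchar(fix$ALT) > 1L
  fix <- fix[keep, , drop = FALSE]
  cls <- classify_indel(fix$REF, fix$ALT)
  len <- dplyr::case_when(
    cls == "deletion" ~ nchar(fix$REF) - nchar(fix$ALT),
    cls == "insertion" ~ nchar(fix$ALT) - nchar(fix$REF),
    TRUE ~ pmax(nchar(fix$REF), nchar(fix$ALT)) -
      as.integer(substr(fix$REF, 1L, 1L) == substr(fix$ALT, 1L, 1L))
  )
  out <- tibble::tibble(
    chrom = fix$CHROM, pos = fix$POS,
    ref_allele = fix$REF, alt_allele = fix$ALT,
    indel_class = cls, length = as.integer(len),
    deleted_seq = ifelse(cls == "deletion", substr(fix$REF, 2L, nchar(fix$REF)),
                         NA_character_),
    vaf = info_field(fix$INFO, "VAF"),
    mh_len = NA_integer_,
    clonality = "unknown",
    sample_id = sample_id
  )
  if (!is.null(reference)) {
    reference <- as_reference(reference)
    for (i in which(out$indel_class == "deletion")) {
      chromseq <- ref_chrom(reference, out$chrom[i])
      span <- substr(chromseq, out$pos[i] + 1L, out$pos[i] + out$length[i])
      if (!identical(span, out$deleted_seq[i])) {
        abort(paste0("REF allele at ", out$chrom[i], ":", out$pos[i],
                     " does not match the reference (", out$deleted_seq[i],
                     " vs ", span, ")"))
      }
      la <- left_align_deletion(chromseq, out$pos[i], out$deleted_seq[i])
      out$pos[i] <- la$pos
      out$deleted_seq[i] <- la$deleted_seq
      out$ref_allele[i] <- substr(chromseq, la$pos, la$pos + out$length[i])
      out$alt_allele[i] <- substr(chromseq, la$pos, la$pos)
    }
  }
  out
}

#' Write indel or substitution records as VCF
#'
#' Minimal VCF 4.2 writer used for round-tripping catalogues and for the
#' synthetic-cohort generator. VAFs are carried in the INFO column.
#'
#' @param records Tibble from [read_indel_vcf()] / [read_substitution_vcf()]
#'   (or the generator).
#' @param path Output path.
#' @param reference Optional reference; contig headers are emitted from it.
#' @export
write_variant_vcf <- function(records, path, reference = NULL) {
  header <- c("##fileformat=VCFv4.2",
              "##INFO=<ID=VAF,Number=1,Type=Float,Description=\"Variant allele fraction\">")
  if (!is.null(reference)) {
    reference <- as_reference(reference)
    header <- c(header, paste0("##contig=<ID=", names(reference),
                               ",length=", nchar(reference), ">"))
  }
  header <- c(header,
              "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  if (all(c("ref_base", "alt_base") %in% names(records))) {
    ref <- records$ref_base
    alt <- records$alt_base
  } else {
    ref <- records$ref_allele
    alt <- records$alt_allele
  }
  info <- ifelse(is.na(records$vaf %||% rep(NA_real_, nrow(records))), ".",
                 sprintf("VAF=%.6g", records$vaf))
  body <- paste(records$chrom, records$pos, ".", ref, alt, ".", "PASS", info,
                sep = "\t")
  ord <- order(records$chrom, records$pos)
  writeLines(c(header, body[ord]), path)
  invisible(path)
}

# ---------------------------------------------------------------------------
# BEDPE

orient_from_strands <- function(s1, s2) {
  dplyr::case_when(
    s1 == "+" & s2 == "+" ~ "head_head",
    s1 == "-" & s2 == "-" ~ "tail_tail",
    TRUE ~ "other"
  )
}

#' Read rearrangement junctions from BEDPE
#'
#' Expects 10+ columns: the two breakpoint intervals, a junction name, read
#' support in column 8 and the two strands in columns 9-10. BEDPE 0-based
#' half-open intervals are converted to 1-based closed; the strand pair maps
#' `(+,+)` to `head_head`, `(-,-)` to `tail_tail` and anything else to
#' `other`. Intrachromosomal calls are stored with the lower-midpoint
#' breakpoint first.
#'
#' @param path BEDPE file.
#' @param sample_id Sample identifier attached to every call.
#' @return Tibble with columns `call_id`, `chrom_low`, `low_start`, `low_end`,
#'   `chrom_high`, `high_start`, `high_end`, `orient`, `read_support`,
#'   `sample_id`.
#' @export
read_rearrangement_bedpe <- function(path, sample_id = NA_character_) {
  cols <- c("chrom1", "start1", "end1", "chrom2", "start2", "end2",
            "name", "score", "strand1", "strand2")
  empty <- tibble::tibble(
    call_id = character(), chrom_low = character(),
    low_start = integer(), low_end = integer(),
    chrom_high = character(), high_start = integer(), high_end = integer(),
    orient = character(), read_support = integer(), sample_id = character()
  )
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0L) return(empty)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- vapply(fields, length, 1L)
  if (any(nf < 10L)) {
    abort(paste0("BEDPE line ", which(nf < 10L)[1L], " in ", path,
                 " has fewer than 10 columns"))
  }
  df <- tibble::as_tibble(setNames(
    as.data.frame(do.call(rbind, lapply(fields, `[`, 1:10)),
                  stringsAsFactors = FALSE), cols))
  for (nm in c("start1", "end1", "start2", "end2")) {
    df[[nm]] <- as.integer(df[[nm]])
  }
  if (any(df$start1 < 0L | df$start2 < 0L)) {
    abort(paste0("negative coordinates in BEDPE file ", path))
  }
  out <- tibble::tibble(
    call_id = df$name,
    chrom_low = df$chrom1, low_start = df$start1 + 1L, low_end = df$end1,
    chrom_high = df$chrom2, high_start = df$start2 + 1L, high_end = df$end2,
    orient = orient_from_strands(df$strand1, df$strand2),
    read_support = as.integer(df$score),
    sample_id = sample_id
  )
  # canonical breakpoint order on the same chromosome: lower midpoint first
  flip <- out$chrom_low == out$chrom_high &
    interval_midpoint(out$low_start, out$low_end) >
      interval_midpoint(out$high_start, out$high_end)
  if (any(flip)) {
    tmp <- out[flip, c("low_start", "low_end")]
    out[flip, c("low_start", "low_end")] <-
      out[flip, c("high_start", "high_end")]
    out[flip, c("high_start", "high_end")] <- tmp
  }
  if (any(out$read_support < 0L, na.rm = TRUE)) {
    abort(paste0("negative read support in BEDPE file ", path))
  }
  out
}

#' @rdname read_rearrangement_bedpe
#' @param calls Tibble of rearrangement calls.
#' @export
write_rearrangement_bedpe <- function(calls, path) {
  s1 <- dplyr::case_when(calls$orient == "head_head" ~ "+",
                         calls$orient == "tail_tail" ~ "-",
                         TRUE ~ "+")
  s2 <- dplyr::case_when(calls$orient == "head_head" ~ "+",
                         calls$orient == "tail_tail" ~ "-",
                         TRUE ~ "-")
  body <- paste(calls$chrom_low, calls$low_start - 1L, calls$low_end,
                calls$chrom_high, calls$high_start - 1L, calls$high_end,
                calls$call_id, calls$read_support, s1, s2, sep = "\t")
  writeLines(body, path)
  invisible(path)
}

# ---------------------------------------------------------------------------
# Callable regions

#' Read callable regions from BED
#'
#' Intervals are converted to 1-based closed, sorted, and adjacent or
#' overlapping intervals merged, so `callable_total_bases()` is invariant
#' under re-ordering of the input.
#'
#' @param path BED file (0-based half-open).
#' @return Tibble with columns `chrom`, `start`, `end`, of class
#'   `callable_regions`.
#' @export
read_callable_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "bed")
  callable_regions(tibble::tibble(
    chrom = as.character(GenomeInfoDb::seqnames(gr)),
    start = BiocGenerics::start(gr),
    end = BiocGenerics::end(gr)
  ))
}

#' @rdname read_callable_bed
#' @param intervals Data frame of 1-based closed intervals
#'   (`chrom`, `start`, `end`).
#' @export
callable_regions <- function(intervals) {
  intervals <- tibble::as_tibble(intervals)[, c("chrom", "start", "end")]
  merged <- intervals |>
    dplyr::group_by(.data$chrom) |>
    dplyr::group_modify(function(tb, key) {
      ir <- IRanges::reduce(IRanges::IRanges(tb$start, tb$end),
                            min.gapwidth = 1L)
      tibble::tibble(start = BiocGenerics::start(ir),
                     end = BiocGenerics::end(ir))
    }) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$chrom, .data$start)
  class(merged) <- c("callable_regions", class(merged))
  merged
}

#' @rdname read_callable_bed
#' @param callable A `callable_regions` tibble.
#' @export
callable_total_bases <- function(callable) {
  sum(callable$end - callable$start + 1)
}

#' @rdname read_callable_bed
#' @export
write_callable_bed <- function(callable, path) {
  writeLines(paste(callable$chrom, callable$start - 1L, callable$end,
                   sep = "\t"), path)
  invisible(path)
}

#' Read callable regions and declared feature tracks together
#'
#' @param callable_bed BED file of callable regions.
#' @param track_config YAML sidecar declaring the tracks (see
#'   [read_feature_tracks()]).
#' @return List with elements `callable` and `tracks`.
#' @export
read_tracks_and_regions <- function(callable_bed, track_config) {
  list(callable = read_callable_bed(callable_bed),
       tracks = read_feature_tracks(track_config))
}

# ---------------------------------------------------------------------------
# Manifest and catalogues

#' Read a cohort manifest
#'
#' Tab-separated table with at least `sample_id` and `group`; optional
#' `purity` and per-sample file-path columns (`substitution_vcf`, `indel_vcf`,
#' `rearrangement_bedpe`).
#'
#' @param path Manifest TSV.
#' @param groups Allowed group labels; defaults to the labels present.
#' @return Tibble, one row per sample.
#' @export
read_manifest <- function(path, groups = NULL) {
  mf <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (!all(c("sample_id", "group") %in% names(mf))) {
    abort("manifest must contain sample_id and group columns")
  }
  if (!is.null(groups) && !all(mf$group %in% groups)) {
    bad <- setdiff(unique(mf$group), groups)
    abort(paste0("unknown group label(s) in manifest: ",
                 paste(bad, collapse = ", ")))
  }
  mf
}

#' Assemble a per-tumour variant catalogue
#'
#' @param sample_id Sample identifier.
#' @param group Cohort group label.
#' @param substitutions,indels,rearrangements Record tibbles (may be empty).
#' @param purity Optional tumour purity in `[0, 1]`.
#' @param copy_number Optional per-interval total tumour copy number
#'   (`chrom`, `start`, `end`, `cn`).
#' @return Object of class `tumour_catalogue`.
#' @export
tumour_catalogue <- function(sample_id, group,
                             substitutions = NULL, indels = NULL,
                             rearrangements = NULL, purity = NA_real_,
                             copy_number = NULL) {
  structure(
    list(sample_id = sample_id, group = group, purity = purity,
         substitutions = substitutions %||% empty_substitutions(),
         indels = indels %||% empty_indels(),
         rearrangements = rearrangements %||% empty_rearrangements(),
         copy_number = copy_number),
    class = "tumour_catalogue"
  )
}

empty_substitutions <- function() {
  tibble::tibble(chrom = character(), pos = integer(),
                 ref_base = character(), alt_base = character(),
                 vaf = numeric(), sample_id = character())
}

empty_indels <- function() {
  tibble::tibble(chrom = character(), pos = integer(),
                 ref_allele = character(), alt_allele = character(),
                 indel_class = character(), length = integer(),
                 deleted_seq = character(), vaf = numeric(),
                 mh_len = integer(), clonality = character(),
                 sample_id = character())
}

empty_rearrangements <- function() {
  tibble::tibble(call_id = character(), chrom_low = character(),
                 low_start = integer(), low_end = integer(),
                 chrom_high = character(), high_start = integer(),
                 high_end = integer(), orient = character(),
                 read_support = integer(), sample_id = character())
}

#' @export
print.tumour_catalogue <- function(x, ...) {
  cat("<tumour_catalogue>", x$sample_id, "group:", x$group, "\n",
      " substitutions:", nrow(x$substitutions),
      " indels:", nrow(x$indels),
      " rearrangements:", nrow(x$rearrangements), "\n")
  invisible(x)
}

#' Read every catalogue referenced by a manifest
#'
#' @param manifest Tibble from [read_manifest()] (paths resolved against
#'   `base_dir`).
#' @param reference Optional reference genome for indel normalization.
#' @param base_dir Directory that relative paths in the manifest refer to.
#' @return Named list of [tumour_catalogue()] objects.
#' @export
read_cohort <- function(manifest, reference = NULL, base_dir = ".") {
  resolve <- function(p) {
    ifelse(file.exists(p), p, file.path(base_dir, p))
  }
  purrr::pmap(manifest, function(...) {
    row <- list(...)
    need <- function(col) {
      if (is.null(row[[col]]) || is.na(row[[col]])) return(NULL)
      p <- resolve(row[[col]])
      if (!file.exists(p)) {
        abort(paste0("sample ", row$sample_id, ": missing input file ",
                     row[[col]]))
      }
      p
    }
    subs <- need("substitution_vcf")
    ind <- need("indel_vcf")
    rearr <- need("rearrangement_bedpe")
    tumour_catalogue(
      sample_id = row$sample_id, group = row$group,
      purity = row$purity %||% NA_real_,
      substitutions = if (!is.null(subs))
        read_substitution_vcf(subs, row$sample_id),
      indels = if (!is.null(ind))
        read_indel_vcf(ind, reference, row$sample_id),
      rearrangements = if (!is.null(rearr))
        read_rearrangement_bedpe(rearr, row$sample_id)
    )
  }) |> setNames(manifest$sample_id)
}
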