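# Balanced-inversion screen: post-processing filters on inverted-orientation
# rearrangement calls, reciprocal pairing of head-to-head and tail-to-tail
# junctions whose breakpoint ranges overlap at both ends, and cohort-level
# summaries.

#' Screen configuration for the balanced-inversion search
#'
#' A call passes the filter when it is an intrachromosomal inverted junction
#' with read support strictly greater than `min_reads` and size strictly
#' greater than `min_size_bp`, *or* read support strictly greater than
#' `high_conf_reads` (in which case no size threshold applies). Degenerate
#' point breakpoints are padded by `slop_bp` before overlap testing.
#'
#' @param min_reads Read-support threshold (strict `>`). Default 5.
#' @param min_size_bp Size threshold in bp (strict `>`). Default 2500.
#' @param high_conf_reads Read support above which size is ignored
#'   (strict `>`). Default 10.
#' @param slop_bp Padding applied to zero-width breakpoint intervals before
#'   overlap testing. Default 500.
#' @return A `screen_config` list.
#' @export
screen_config <- function(min_reads = 5L, min_size_bp = 2500L,
                          high_conf_reads = 10L, slop_bp = 500L) {
  stopifnot(min_reads >= 0, min_size_bp >= 0, slop_bp >= 0,
            high_conf_reads >= min_reads)
  structure(list(min_reads = min_reads, min_size_bp = min_size_bp,
                 high_conf_reads = high_conf_reads, slop_bp = slop_bp),
            class = "screen_config")
}

# size of a single call: distance between its breakpoint-interval midpoints
call_size <- function(calls) {
  interval_midpoint(calls$high_start, calls$high_end) -
    interval_midpoint(calls$low_start, calls$low_end)
}

#' Filter inverted rearrangement calls
#'
#' Keeps intrachromosomal `head_head` / `tail_tail` calls passing the
#' read-support and size rules of [screen_config()]; input order is
#' preserved. Calls with `orient == "other"` never pass (the screen is
#' defined only on inverted-orientation junctions).
#'
#' @param calls Rearrangement-call tibble
#'   (see [read_rearrangement_bedpe()]).
#' @param config A [screen_config()].
#' @return The kept subset of `calls`, with a `size` column added.
#' @export
filter_inversion_calls <- function(calls, config = screen_config()) {
  calls <- tibble::as_tibble(calls)
  if (nrow(calls) == 0L) {
    return(dplyr::mutate(calls, size = numeric(0)))
  }
  calls$size <- call_size(calls)
  keep <- calls$chrom_low == calls$chrom_high &
    calls$orient %in% c("head_head", "tail_tail") &
    ((calls$read_support > config$min_reads &
        calls$size > config$min_size_bp) |
       calls$read_support > config$high_conf_reads)
  calls[keep, , drop = FALSE]
}

# pad zero-width breakpoint intervals by slop_bp
pad_degenerate <- function(calls, slop_bp) {
  deg_low <- calls$low_start == calls$low_end
  deg_high <- calls$high_start == calls$high_end
  calls$low_start[deg_low] <- calls$low_start[deg_low] - slop_bp
  calls$low_end[deg_low] <- calls$low_end[deg_low] + slop_bp
  calls$high_start[deg_high] <- calls$high_start[deg_high] - slop_bp
  calls$high_end[deg_high] <- calls$high_end[deg_high] + slop_bp
  calls
}

overlaps <- function(s1, e1, s2, e2) s1 <= e2 & s2 <= e1

#' Pair reciprocal junctions into balanced inversions
#'
#' A balanced inversion is one `head_head` plus one `tail_tail` call on the
#' same chromosome whose low breakpoint intervals overlap and whose high
#' breakpoint intervals overlap (after padding degenerate point intervals by
#' `slop_bp`). Candidate pairs are resolved greedily by repeatedly taking the
#' mate pair with the smallest summed midpoint distance (ties broken by
#' lexicographic call-id pair), each call joining at most one inversion. The
#' result is independent of input order.
#'
#' @param calls Filtered calls from [filter_inversion_calls()].
#' @param config A [screen_config()].
#' @return List with `inversions` (one row per balanced inversion: ids,
#'   chromosome, size, the four breakpoint midpoints) and `unpaired` (calls
#'   not consumed by any pair).
#' @export
pair_balanced_inversions <- function(calls, config = screen_config()) {
  calls <- tibble::as_tibble(calls)
  empty_inv <- tibble::tibble(
    head_call_id = character(), tail_call_id = character(),
    chrom = character(), size = numeric(),
    head_low_mid = numeric(), head_high_mid = numeric(),
    tail_low_mid = numeric(), tail_high_mid = numeric(),
    sample_id = character()
  )
  if (nrow(calls) == 0L) {
    return(list(inversions = empty_inv, unpaired = calls))
  }
  padded <- pad_degenerate(calls, config$slop_bp)
  heads <- which(calls$orient == "head_head")
  tails <- which(calls$orient == "tail_tail")
  # candidate edges
  edges <- tidyr::expand_grid(h = heads, t = tails)
  if (nrow(edges) > 0L) {
    ok <- calls$chrom_low[edges$h] == calls$chrom_low[edges$t] &
      overlaps(padded$low_start[edges$h], padded$low_end[edges$h],
               padded$low_start[edges$t], padded$low_end[edges$t]) &
      overlaps(padded$high_start[edges$h], padded$high_end[edges$h],
               padded$high_start[edges$t], padded$high_end[edges$t])
    edges <- edges[ok, , drop = FALSE]
  }
  if (nrow(edges) == 0L) {
    return(list(inversions = empty_inv, unpaired = calls))
  }
  low_mid <- interval_midpoint(calls$low_start, calls$low_end)
  high_mid <- interval_midpoint(calls$high_start, calls$high_end)
  edges$dist <- abs(low_mid[edges$h] - low_mid[edges$t]) +
    abs(high_mid[edges$h] - high_mid[edges$t])
  edges <- edges[order(edges$dist, calls$call_id[edges$h],
                       calls$call_id[edges$t]), , drop = FALSE]
  used <- logical(nrow(calls))
  picked <- integer(0)
  for (i in seq_len(nrow(edges))) {
    h <- edges$h[i]
    t <- edges$t[i]
    if (!used[h] && !used[t]) {
      used[h] <- used[t] <- TRUE
      picked <- c(picked, i)
    }
  }
  sel <- edges[picked, , drop = FALSE]
  inversions <- tibble::tibble(
    head_call_id = calls$call_id[sel$h],
    tail_call_id = calls$call_id[sel$t],
    chrom = calls$chrom_low[sel$h],
    size = pmax(high_mid[sel$h] - low_mid[sel$h],
                high_mid[sel$t] - low_mid[sel$t]),
    head_low_mid = low_mid[sel$h], head_high_mid = high_mid[sel$h],
    tail_low_mid = low_mid[sel$t], tail_high_mid = high_mid[sel$t],
    sample_id = calls$sample_id[sel$h]
  )
  inversions <- dplyr::arrange(inversions, .data$chrom, .data$head_low_mid)
  list(inversions = inversions, unpaired = calls[!used, , drop = FALSE])
}

#' Run the full balanced-inversion screen on one catalogue
#'
#' Convenience wrapper: filter then pair.
#'
#' @param calls Raw rearrangement-call tibble.
#' @param config A [screen_config()].
#' @return As [pair_balanced_inversions()].
#' @export
screen_balanced_inversions <- function(calls, config = screen_config()) {
  pair_balanced_inversions(filter_inversion_calls(calls, config), config)
}

#' Flag inversion breakpoints that fall in genes
#'
#' Each balanced inversion contributes four breakpoints (head/tail x
#' low/high); a breakpoint hits a gene when its midpoint lies inside at least
#' one gene interval.
#'
#' @param inversions Inversion tibble from [pair_balanced_inversions()].
#' @param genes Tibble of 1-based closed gene intervals (`chrom`, `start`,
#'   `end`, optional `gene`).
#' @return List with `breakpoints` (long tibble, one row per breakpoint, with
#'   `in_gene`) and `fraction_in_genes`.
#' @export
annotate_breakpoint_genes <- function(inversions, genes) {
  genes <- tibble::as_tibble(genes)
  bp <- tidyr::pivot_longer(
    inversions[, c("head_call_id", "tail_call_id", "chrom", "head_low_mid",
                   "head_high_mid", "tail_low_mid", "tail_high_mid")],
    cols = dplyr::ends_with("_mid"),
    names_to = "breakpoint", values_to = "position"
  )
  hit <- purrr::map_lgl(seq_len(nrow(bp)), function(i) {
    any(genes$chrom == bp$chrom[i] & genes$start <= bp$position[i] &
          genes$end >= bp$position[i])
  })
  bp$in_gene <- hit
  list(breakpoints = bp,
       fraction_in_genes = if (nrow(bp)) mean(hit) else NA_real_)
}

#' Cohort summary of the balanced-inversion screen
#'
#' Screens every catalogue with one shared configuration and tabulates, per
#' group: tumours screened, tumours with at least one balanced inversion, and
#' the total number of balanced inversions.
#'
#' @param catalogues List of [tumour_catalogue()] objects.
#' @param config A [screen_config()].
#' @param groups Declared group labels; a catalogue outside this set is an
#'   error. Default: labels present.
#' @return Tibble with columns `group`, `n_screened`, `n_with_inversion`,
#'   `n_inversions`.
#' @export
inversion_cohort_summary <- function(catalogues, config = screen_config(),
                                     groups = NULL) {
  labels <- purrr::map_chr(catalogues, "group")
  if (is.null(groups)) groups <- unique(labels)
  if (!all(labels %in% groups)) {
    abort(paste0("unknown group label(s): ",
                 paste(setdiff(labels, groups), collapse = ", ")))
  }
  per_sample <- purrr::map2_dfr(catalogues, labels, function(cat, gr) {
    n_inv <- nrow(screen_balanced_inversions(cat$rearrangements,
                                             config)$inversions)
    tibble::tibble(sample_id = cat$sample_id, group = gr, n_inversions = n_inv)
  })
  out <- tibble::tibble(group = groups) |>
    dplyr::left_join(
      per_sample |>
        dplyr::group_by(.data$group) |>
        dplyr::summarise(n_screened = dplyr::n(),
                         n_with_inversion = sum(.data$n_inversions > 0L),
                         n_inversions = sum(.data$n_inversions)),
      by = "group"
    ) |>
    tidyr::replace_na(list(n_screened = 0L, n_with_inversion = 0L,
                           n_inversions = 0L))
  attr(out, "per_sample") <- per_sample
  out
}

#' Pool rows of an inversion cohort summary
#'
#' Aggregates selected group rows (for example all radiation-naive primary
#' cohorts) into a single pooled row.
#'
#' @param summary Tibble with `group`, `n_screened`, `n_with_inversion`,
#'   `n_inversions` (as from [inversion_cohort_summary()] or a published
#'   survey table).
#' @param groups Character vector of group labels to pool.
#' @param label Name of the pooled row.
#' @return One-row tibble in the same shape.
#' @export
pool_inversion_summary <- function(summary, groups, label = "pooled") {
  sel <- summary[summary$group %in% groups, , drop = FALSE]
  if (nrow(sel) < length(groups)) {
    abort(paste0("unknown group label(s): ",
                 paste(setdiff(groups, summary$group), collapse = ", ")))
  }
  tibble::tibble(group = label,
                 n_screened = sum(sel$n_screened),
                 n_with_inversion = sum(sel$n_with_inversion),
                 n_inversions = sum(sel$n_inversions))
}
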