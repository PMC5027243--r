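#' Construct a genomic feature track
#'
#' A feature track is a genomic property queryable at any position:
#' quantitative (for example replication timing), binary (peak membership) or
#' categorical (chromatin state). Positions not covered by any interval take
#' `default`.
#'
#' @param intervals Data frame with columns `chrom`, `start`, `end` (1-based
#'   closed) and `value`.
#' @param name Track name.
#' @param kind One of `"quantitative"`, `"binary"`, `"categorical"`.
#' @param default Value returned for uncovered positions.
#' @return An object of class `feature_track`.
#' @export
feature_track <- function(intervals, name, kind = c("quantitative", "binary",
                                                    "categorical"),
                          default = NA) {
  kind <- match.arg(kind)
  intervals <- tibble::as_tibble(intervals)
  stopifnot(all(c("chrom", "start", "end", "value") %in% names(intervals)))
  if (any(intervals$start > intervals$end)) {
    abort("track intervals must satisfy start <= end")
  }
  intervals <- dplyr::arrange(intervals, .data$chrom, .data$start)
  if (kind == "categorical") {
    check_categorical_overlaps(intervals)
    if (is.na(default)) default <- "none"
  } else if (is.na(default)) {
    default <- 0
  }
  structure(
    list(name = name, kind = kind, intervals = intervals, default = default,
         levels = if (kind == "categorical") {
           sort(unique(c(as.character(intervals$value), as.character(default))))
         } else NULL),
    class = "feature_track"
  )
}

# overlapping categorical intervals are only legal when they agree on the label
check_categorical_overlaps <- function(intervals) {
  by_chrom <- split(intervals, intervals$chrom)
  for (tb in by_chrom) {
    if (nrow(tb) < 2L) next
    tb <- tb[order(tb$start), ]
    overlaps <- tb$start[-1L] <= tb$end[-nrow(tb)]
    conflict <- overlaps & (tb$value[-1L] != tb$value[-nrow(tb)])
    if (any(conflict)) {
      abort(paste0("overlapping categorical intervals with conflicting ",
                   "labels on ", tb$chrom[1L]))
    }
  }
  invisible(intervals)
}

#' @export
print.feature_track <- function(x, ...) {
  cat("<feature_track>", x$name, "(", x$kind, "),",
      nrow(x$intervals), "intervals, default =", format(x$default), "\n")
  invisible(x)
}

#' Query a feature track at genomic positions
#'
#' @param track A [feature_track()].
#' @param chrom,pos Parallel vectors of chromosome names and 1-based positions.
#' @return A tibble with columns `value` and `covered` (`FALSE` where the
#'   default was used).
#' @export
track_query <- function(track, chrom, pos) {
  stopifnot(inherits(track, "feature_track"), length(chrom) == length(pos))
  n <- length(pos)
  value <- rep(track$default, n)
  covered <- rep(FALSE, n)
  for (ch in unique(chrom)) {
    iv <- track$intervals[track$intervals$chrom == ch, ]
    sel <- which(chrom == ch)
    if (nrow(iv) == 0L) next
    idx <- findInterval(pos[sel], iv$start)
    hit <- idx >= 1L & pos[sel] <= iv$end[pmax(idx, 1L)]
    value[sel[hit]] <- iv$value[idx[hit]]
    covered[sel[hit]] <- TRUE
  }
  tibble::tibble(value = value, covered = covered)
}

#' @rdname track_query
#' @export
track_value <- function(track, chrom, pos) {
  track_query(track, chrom, pos)$value
}

#' Read feature tracks declared in a sidecar configuration
#'
#' Track kind is never guessed from the data: each track's kind (and optional
#' default) is declared in a YAML sidecar listing `name`, `path`, `kind` and
#' optionally `default` per track. Quantitative tracks are bedGraph; binary
#' and categorical tracks are BED (binary: covered intervals are 1; the BED
#' name column carries categorical labels).
#'
#' @param config Path to the YAML sidecar, or an equivalent list.
#' @param base_dir Directory against which relative track paths are resolved.
#' @return A named list of [feature_track()] objects.
#' @export
read_feature_tracks <- function(config, base_dir = ".") {
  if (is.character(config)) {
    base_dir <- dirname(config)
    config <- yaml::read_yaml(config)
  }
  specs <- config$tracks %||% config
  tracks <- purrr::map(specs, function(sp) {
    path <- sp$path
    if (!file.exists(path)) path <- file.path(base_dir, sp$path)
    if (!file.exists(path)) {
      abort(paste0("track file not found: ", sp$path))
    }
    kind <- match.arg(sp$kind, c("quantitative", "binary", "categorical"))
    if (kind == "quantitative") {
      gr <- rtracklayer::import(path, format = "bedGraph")
      iv <- tibble::tibble(
        chrom = as.character(GenomeInfoDb::seqnames(gr)),
        start = BiocGenerics::start(gr), end = BiocGenerics::end(gr),
        value = gr$score
      )
    } else {
      gr <- rtracklayer::import(path, format = "bed")
      value <- if (kind == "binary") rep(1, length(gr)) else gr$name
      iv <- tibble::tibble(
        chrom = as.character(GenomeInfoDb::seqnames(gr)),
        start = BiocGenerics::start(gr), end = BiocGenerics::end(gr),
        value = value
      )
    }
    feature_track(iv, name = sp$name, kind = kind,
                  default = sp$default %||% NA)
  })
  setNames(tracks, purrr::map_chr(specs, "name"))
}
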