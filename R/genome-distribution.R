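# Association of mutation density with genomic features: background
# sampling, per-position annotation (GC, 3-mer sequence complexity, declared
# tracks), a kind-dispatched test battery, Benjamini-Yekutieli adjustment,
# the dual significance rule, per-bin density ratios and the indel
# probability profile.

#' Sample background positions uniformly from callable regions
#'
#' Positions are drawn with replacement, uniformly over callable bases (each
#' base equally likely, so chromosomes are weighted by callable length).
#'
#' @param callable `callable_regions` tibble.
#' @param n Number of positions.
#' @param seed RNG seed; the draw is deterministic for a fixed seed.
#' @return Tibble with `chrom`, `pos`.
#' @export
sample_background <- function(callable, n, seed = 1L) {
  if (n <= 0L) abort("n must be positive")
  if (nrow(callable) == 0L) abort("callable regions are empty")
  widths <- callable$end - callable$start + 1
  with_seed(seed, {
    iv <- sample.int(nrow(callable), n, replace = TRUE, prob = widths)
    offset <- floor(runif(n) * widths[iv])
    tibble::tibble(chrom = callable$chrom[iv],
                   pos = as.integer(callable$start[iv] + offset))
  })
}

#' Annotate genomic positions with sequence and track features
#'
#' At each position a window of `window_bp` centred on it provides the GC
#' fraction and the sequence complexity (Shannon entropy of overlapping
#' 3-mers, normalized by `log(64)` to `[0, 1]`; a homopolymer scores 0).
#' Every supplied feature track is queried directly at the position. Windows
#' extending past a chromosome end are truncated and flagged.
#'
#' @param positions Tibble with `chrom`, `pos`.
#' @param reference Reference genome.
#' @param tracks Named list of [feature_track()] objects (may be empty).
#' @param window_bp Window width for GC/complexity (default 100).
#' @return Tibble: `chrom`, `pos`, `gc`, `complexity`, `window_truncated`,
#'   then one column per track (plus `<name>_covered` flags for tracks with
#'   uncovered queries).
#' @export
annotate_positions <- function(positions, reference, tracks = list(),
                               window_bp = 100L) {
  reference <- as_reference(reference)
  positions <- tibble::as_tibble(positions)
  half <- floor(window_bp / 2)
  n <- nrow(positions)
  gc <- numeric(n)
  complexity <- numeric(n)
  truncated <- logical(n)
  for (ch in unique(positions$chrom)) {
    sel <- which(positions$chrom == ch)
    chromseq <- Biostrings::DNAString(ref_chrom(reference, ch))
    clen <- length(chromseq)
    s <- pmax(1L, positions$pos[sel] - half)
    e <- pmin(clen, positions$pos[sel] + half)
    truncated[sel] <- s != positions$pos[sel] - half |
      e != positions$pos[sel] + half
    v <- Biostrings::Views(chromseq, start = s, end = e)
    gc[sel] <- Biostrings::letterFrequency(v, "GC", as.prob = TRUE)[, 1L]
    tnf <- Biostrings::trinucleotideFrequency(Biostrings::DNAStringSet(v))
    complexity[sel] <- apply(tnf, 1L, shannon_entropy) / log(64)
  }
  out <- dplyr::mutate(positions, gc = gc, complexity = complexity,
                       window_truncated = truncated)
  for (nm in names(tracks)) {
    q <- track_query(tracks[[nm]], positions$chrom, positions$pos)
    val <- q$value
    if (tracks[[nm]]$kind != "categorical") val <- as.numeric(val)
    out[[nm]] <- val
    if (any(!q$covered)) out[[paste0(nm, "_covered")]] <- q$covered
  }
  out
}

#' Two-sample feature comparison
#'
#' Dispatches on the feature kind: a pooled two-proportion z-test for binary
#' features, Welch's t-test for other quantitative features (large-sample
#' normal theory), and a chi-squared test on the label contingency for
#' categorical features. P-values are two-sided.
#'
#' @param variant_values,background_values Non-empty vectors of feature
#'   values at variant and comparison positions.
#' @param kind `"quantitative"`, `"binary"` or `"categorical"`.
#' @return One-row tibble: `kind`, `statistic`, `raw_p`, `mean_1`, `mean_2`
#'   (group means; for categorical features `NA` with the label tables in
#'   the `tables` list-column), `magnitude_diff`, `degenerate`.
#' @export
compare_feature <- function(variant_values, background_values,
                            kind = c("quantitative", "binary",
                                     "categorical")) {
  kind <- match.arg(kind)
  x <- variant_values[!is.na(variant_values)]
  y <- background_values[!is.na(background_values)]
  if (length(x) == 0L || length(y) == 0L) {
    abort("both samples must be non-empty")
  }
  degenerate <- FALSE
  tables <- list(NULL)
  if (kind == "binary") {
    p1 <- mean(x)
    p2 <- mean(y)
    pp <- (sum(x) + sum(y)) / (length(x) + length(y))
    se <- sqrt(pp * (1 - pp) * (1 / length(x) + 1 / length(y)))
    if (se == 0) {
      stat <- 0
      p <- 1
      degenerate <- TRUE
    } else {
      stat <- (p1 - p2) / se
      p <- 2 * pnorm(-abs(stat))
    }
    m1 <- p1
    m2 <- p2
  } else if (kind == "quantitative") {
    m1 <- mean(x)
    m2 <- mean(y)
    if (var(x) == 0 && var(y) == 0) {
      stat <- 0
      p <- 1
      degenerate <- TRUE
    } else {
      tt <- t.test(x, y)
      stat <- unname(tt$statistic)
      p <- tt$p.value
    }
  } else {
    labs <- sort(unique(c(as.character(x), as.character(y))))
    tab <- rbind(table(factor(x, levels = labs)),
                 table(factor(y, levels = labs)))
    tables <- list(tab)
    if (length(labs) < 2L) {
      stat <- 0
      p <- 1
      degenerate <- TRUE
    } else {
      ct <- suppressWarnings(chisq.test(tab, correct = FALSE))
      stat <- unname(ct$statistic)
      p <- ct$p.value
    }
    m1 <- NA_real_
    m2 <- NA_real_
  }
  mag <- feature_magnitude(kind, m1, m2, tables[[1L]])
  tibble::tibble(kind = kind, statistic = stat, raw_p = p,
                 mean_1 = m1, mean_2 = m2, magnitude_diff = mag,
                 degenerate = degenerate, tables = tables)
}

# magnitude of difference: relative difference of means for quantitative
# features, proportion-scale for binary (still relative), total-variation
# distance between label distributions for categorical
feature_magnitude <- function(kind, m1, m2, tab = NULL,
                              mode = c("relative", "absolute")) {
  mode <- match.arg(mode)
  if (kind == "categorical") {
    if (is.null(tab)) return(NA_real_)
    p1 <- tab[1L, ] / sum(tab[1L, ])
    p2 <- tab[2L, ] / sum(tab[2L, ])
    return(sum(abs(p1 - p2)) / 2)
  }
  if (m1 == 0 && m2 == 0) return(0)
  if (mode == "absolute") return(abs(m1 - m2))
  abs(m1 - m2) / max(abs(m1), abs(m2))
}

#' Benjamini-Yekutieli adjusted q-values
#'
#' FDR control valid under arbitrary dependence among tests (the feature set
#' is strongly correlated, hence BY rather than BH).
#'
#' @param raw_ps Vector of p-values in `[0, 1]`.
#' @return q-values in the input order.
#' @export
adjust_benjamini_yekutieli <- function(raw_ps) {
  check_probabilities(raw_ps)
  p.adjust(raw_ps, method = "BY")
}

#' Apply the dual significance rule
#'
#' A feature is significant when its BY q-value is below `q_threshold` *and*
#' the magnitude of the between-group difference is at least
#' `magnitude_threshold` (relative difference of the group means for
#' quantitative/binary features -- configurable to absolute -- and
#' total-variation distance for categorical features). The dual rule guards
#' against large-sample significance of negligible differences.
#'
#' @param results Tibble of per-feature rows as from [compare_feature()]
#'   (bound together, with a `feature` column).
#' @param q_threshold q-value cut-off (default 0.01).
#' @param magnitude_threshold Minimum magnitude (default 0.05, i.e. 5%).
#' @param magnitude_mode `"relative"` (default) or `"absolute"`.
#' @return `results` with `q_value`, recomputed `magnitude_diff` (if mode is
#'   absolute) and `significant` columns; class `radsig_feature_tests`.
#' @export
flag_significant <- function(results, q_threshold = 0.01,
                             magnitude_threshold = 0.05,
                             magnitude_mode = c("relative", "absolute")) {
  magnitude_mode <- match.arg(magnitude_mode)
  results$q_value <- adjust_benjamini_yekutieli(results$raw_p)
  if (magnitude_mode == "absolute") {
    results$magnitude_diff <- purrr::pmap_dbl(
      list(results$kind, results$mean_1, results$mean_2, results$tables),
      function(kind, m1, m2, tab) {
        feature_magnitude(kind, m1, m2, tab, mode = "absolute")
      })
  }
  results$significant <- results$q_value < q_threshold &
    results$magnitude_diff >= magnitude_threshold
  class(results) <- unique(c("radsig_feature_tests", class(results)))
  results
}

#' Full feature-association battery
#'
#' Runs [compare_feature()] for every declared feature over two annotation
#' tables, then adjusts and flags.
#'
#' @param variant_annot,background_annot Annotation tibbles from
#'   [annotate_positions()].
#' @param kinds Named character vector mapping feature column names to kinds;
#'   defaults to `gc`/`complexity` quantitative plus every track column,
#'   with kinds taken from `tracks` when supplied.
#' @param tracks Optional named list of [feature_track()]s used to infer
#'   kinds.
#' @param ... Passed to [flag_significant()].
#' @return A `radsig_feature_tests` tibble, one row per feature.
#' @export
test_feature_associations <- function(variant_annot, background_annot,
                                      kinds = NULL, tracks = NULL, ...) {
  if (is.null(kinds)) {
    kinds <- c(gc = "quantitative", complexity = "quantitative")
    for (nm in names(tracks)) kinds[nm] <- tracks[[nm]]$kind
  }
  kinds <- kinds[names(kinds) %in% names(variant_annot)]
  results <- purrr::imap_dfr(kinds, function(kind, nm) {
    dplyr::mutate(
      compare_feature(variant_annot[[nm]], background_annot[[nm]], kind),
      feature = nm, .before = 1L
    )
  })
  flag_significant(results, ...)
}

#' Per-bin mutation density ratio over a quantitative feature
#'
#' Bins a quantitative feature and reports, per bin, the fraction of
#' variants over the fraction of background positions. Bins with zero
#' background are flagged undefined.
#'
#' @param variant_annot,background_annot Annotation tibbles.
#' @param feature Feature column name.
#' @param bins Bin edges (passed to [cut()], right-closed).
#' @return Tibble: `bin`, `variant_fraction`, `background_fraction`,
#'   `ratio`, `undefined`.
#' @export
density_ratio <- function(variant_annot, background_annot, feature, bins) {
  v <- variant_annot[[feature]]
  b <- background_annot[[feature]]
  if (length(v) == 0L) abort("variant set is empty")
  vb <- cut(v, bins, include.lowest = TRUE)
  bb <- cut(b, bins, include.lowest = TRUE)
  vf <- as.numeric(table(vb)) / length(v)
  bf <- as.numeric(table(bb)) / length(b)
  ratio <- ifelse(bf > 0, vf / bf, NA_real_)
  tibble::tibble(bin = levels(vb), variant_fraction = vf,
                 background_fraction = bf, ratio = ratio,
                 undefined = bf == 0)
}

#' Mean feature values over fixed-width genome bins
#'
#' Divides each chromosome into `bin_bp` windows and computes the mean GC,
#' sequence complexity and quantitative/binary track values per bin
#' (quantitative tracks are averaged on a 1 kb query grid). Used as the
#' evaluation grid for [indel_probability_profile()].
#'
#' @param reference Reference genome.
#' @param tracks Named list of tracks; categorical tracks are skipped.
#' @param bin_bp Bin width (default 100 kb).
#' @return Tibble: `chrom`, `start`, `end`, `gc`, `complexity`, one column
#'   per non-categorical track.
#' @export
genome_feature_bins <- function(reference, tracks = list(),
                                bin_bp = 100000L) {
  reference <- as_reference(reference)
  bins <- purrr::imap_dfr(reference, function(seq, ch) {
    clen <- nchar(seq)
    starts <- seq.int(1L, clen, by = bin_bp)
    tibble::tibble(chrom = ch, start = starts,
                   end = pmin(starts + bin_bp - 1L, clen))
  })
  gc <- numeric(nrow(bins))
  complexity <- numeric(nrow(bins))
  for (ch in unique(bins$chrom)) {
    sel <- which(bins$chrom == ch)
    chromseq <- Biostrings::DNAString(reference[[ch]])
    v <- Biostrings::Views(chromseq, start = bins$start[sel],
                           end = bins$end[sel])
    gc[sel] <- Biostrings::letterFrequency(v, "GC", as.prob = TRUE)[, 1L]
    tnf <- Biostrings::trinucleotideFrequency(Biostrings::DNAStringSet(v))
    complexity[sel] <- apply(tnf, 1L, shannon_entropy) / log(64)
  }
  bins$gc <- gc
  bins$complexity <- complexity
  grid_step <- 1000L
  for (nm in names(tracks)) {
    tr <- tracks[[nm]]
    if (tr$kind == "categorical") next
    bins[[nm]] <- purrr::map_dbl(seq_len(nrow(bins)), function(i) {
      grid <- seq.int(bins$start[i], bins$end[i], by = grid_step)
      mean(as.numeric(track_value(tr, rep(bins$chrom[i], length(grid)),
                                  grid)))
    })
  }
  bins
}

#' Relative indel probability profile across the genome
#'
#' Fits a logistic variant-vs-background contrast on standardized
#' quantitative/binary features, evaluates the fitted score on each genome
#' bin's mean features, and normalizes to a relative probability profile
#' summing to 1 across bins. Uniformly placed mutations (the
#' radiation-like signature) yield a near-flat profile; feature-correlated
#' placement yields visible genome-scale structure. On perfect separation
#' the fit is flagged and a ridge-penalized fit is used instead.
#'
#' @param variant_annot,background_annot Annotation tibbles.
#' @param genome_bins Tibble from [genome_feature_bins()].
#' @param features Feature columns to use; default: numeric columns common
#'   to the annotations and the bins.
#' @return List with `profile` (genome_bins plus `score` and `probability`),
#'   `coefficients` (tibble), `separation_flag`; class `radsig_profile`.
#' @export
indel_probability_profile <- function(variant_annot, background_annot,
                                      genome_bins, features = NULL) {
  if (is.null(features)) {
    num <- function(df) names(df)[vapply(df, is.numeric, TRUE)]
    features <- intersect(setdiff(num(variant_annot),
                                  c("pos", "start", "end")),
                          num(genome_bins))
  }
  x <- rbind(as.data.frame(variant_annot[, features, drop = FALSE]),
             as.data.frame(background_annot[, features, drop = FALSE]))
  y <- c(rep(1L, nrow(variant_annot)), rep(0L, nrow(background_annot)))
  centers <- vapply(x, mean, 0)
  scales <- vapply(x, sd, 0)
  scales[scales == 0] <- 1
  xs <- sweep(sweep(as.matrix(x), 2L, centers), 2L, scales, "/")
  separation <- FALSE
  fit <- withCallingHandlers(
    glm(y ~ xs, family = binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities|did not converge", conditionMessage(w))) {
        separation <<- TRUE
        invokeRestart("muffleWarning")
      }
    }
  )
  if (separation || any(abs(coef(fit)[-1L]) > 15, na.rm = TRUE)) {
    separation <- TRUE
    pen <- glmnet::glmnet(xs, y, family = "binomial", alpha = 0,
                          lambda = 0.01)
    beta <- as.numeric(pen$beta)
    intercept <- pen$a0
  } else {
    beta <- unname(coef(fit)[-1L])
    beta[is.na(beta)] <- 0
    intercept <- unname(coef(fit)[1L])
  }
  bx <- sweep(sweep(as.matrix(as.data.frame(
    genome_bins[, features, drop = FALSE])), 2L, centers), 2L, scales, "/")
  score <- drop(intercept + bx %*% beta)
  prob <- stats::plogis(score)
  prob <- prob / sum(prob)
  out <- list(
    profile = dplyr::mutate(genome_bins, score = score, probability = prob),
    coefficients = tibble::tibble(feature = features, estimate = beta),
    separation_flag = separation
  )
  class(out) <- "radsig_profile"
  out
}
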