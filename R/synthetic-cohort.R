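# Synthetic-cohort generator: seeded mini-genome references, feature
# tracks, per-tumour variant catalogues and rearrangement catalogues with
# the statistical structure the analysis modules assume, plus
# machine-readable ground truth so recovery is testable end to end.

#' Simulation parameters
#'
#' Defaults describe the study conditions the package is validated under: a
#' 3 x 5 Mb mini-genome and a two-group cohort of 6 radiation-like tumours
#' (elevated indel/substitution ratio, 3:1 deletion:insertion odds, heavier
#' 2-100 bp deletion tail, frequent junction microhomology, uniform genomic
#' placement, deletions predominantly clonal, ~4 balanced inversions per
#' genome) versus 20 naive-like tumours (1:1 odds, short deletions,
#' replication-timing-correlated placement, balanced inversions rare).
#'
#' @param n_chroms,chrom_length_bp,gc Mini-genome shape.
#' @param masked_bp Masked (non-callable) prefix of each chromosome.
#' @param track_period_bp Period of the synthetic replication-timing
#'   sinusoid; also drives the binary peak track.
#' @param chromatin_block_bp Width of the categorical chromatin-state
#'   blocks.
#' @param track_bin_bp Resolution at which quantitative tracks are emitted.
#' @param groups Named list of per-group parameter lists; see
#'   [sim_group_params()].
#' @return A `sim_params` list.
#' @export
sim_params <- function(n_chroms = 3L, chrom_length_bp = 5e6L, gc = 0.41,
                       masked_bp = 50000L, track_period_bp = 1e6L,
                       chromatin_block_bp = 250000L, track_bin_bp = 2000L,
                       groups = list(
                         radiation = sim_group_params(
                           n_samples = 6L, indel_sub_ratio = 0.2,
                           del_ins_odds = 3, del_size_model = "radiation",
                           mh_implant_prob = 0.5, mh_len_max = 3L,
                           placement = "uniform", clonal_del_prob = 0.9,
                           inversion_mean = 4
                         ),
                         naive = sim_group_params(
                           n_samples = 20L, indel_sub_ratio = 0.1,
                           del_ins_odds = 1, del_size_model = "short",
                           mh_implant_prob = 0.1, mh_len_max = 1L,
                           placement = "feature_weighted",
                           clonal_del_prob = 0.5, inversion_mean = 0.25
                         )
                       )) {
  if (chrom_length_bp < 10000L) {
    abort("chrom_length_bp must be >= 10 kb (annotation windows undefined)")
  }
  structure(list(
    n_chroms = n_chroms, chrom_length_bp = as.integer(chrom_length_bp),
    gc = gc, masked_bp = as.integer(masked_bp),
    track_period_bp = track_period_bp,
    chromatin_block_bp = as.integer(chromatin_block_bp),
    track_bin_bp = as.integer(track_bin_bp),
    groups = groups
  ), class = "sim_params")
}

#' @rdname sim_params
#' @param n_samples Samples in the group.
#' @param sub_meanlog,sub_sdlog Log-normal substitution burden.
#' @param indel_sub_ratio Expected indels per substitution.
#' @param del_ins_odds Odds that an indel is a deletion.
#' @param del_size_model `"short"` (geometric, mostly 1-2 bp) or
#'   `"radiation"` (mixture with a heavier 2-100 bp tail).
#' @param mh_implant_prob Fraction of deletions placed so that the junction
#'   carries at least `k` bases of microhomology (`k` uniform on
#'   `1..mh_len_max`).
#' @param mh_len_max Maximum implanted microhomology length.
#' @param placement `"uniform"` over callable bases or `"feature_weighted"`
#'   (acceptance probability proportional to `exp(beta * timing)`).
#' @param placement_beta Strength of feature-weighted placement.
#' @param clonal_del_prob,clonal_other_prob Probability that a deletion
#'   (resp. insertion/substitution) is clonal.
#' @param purity Simulated tumour purity.
#' @param inversion_mean Poisson mean of balanced inversions per genome.
#' @param unbalanced_mean,artefact_mean,noise_mean Poisson means of
#'   unbalanced inverted calls, small low-support artefacts, and
#'   non-inverted/interchromosomal noise calls.
#' @param jitter_bp Maximum breakpoint jitter between the two junctions of
#'   an implanted balanced inversion.
#' @export
sim_group_params <- function(n_samples = 10L,
                             sub_meanlog = log(1000), sub_sdlog = 0.25,
                             indel_sub_ratio = 0.1, del_ins_odds = 1,
                             del_size_model = c("short", "radiation"),
                             mh_implant_prob = 0.1, mh_len_max = 1L,
                             placement = c("uniform", "feature_weighted"),
                             placement_beta = 1.5,
                             clonal_del_prob = 0.5, clonal_other_prob = 0.5,
                             purity = 0.7,
                             inversion_mean = 1, unbalanced_mean = 2,
                             artefact_mean = 3, noise_mean = 2,
                             jitter_bp = 100L) {
  list(n_samples = n_samples, sub_meanlog = sub_meanlog,
       sub_sdlog = sub_sdlog, indel_sub_ratio = indel_sub_ratio,
       del_ins_odds = del_ins_odds,
       del_size_model = match.arg(del_size_model),
       mh_implant_prob = mh_implant_prob, mh_len_max = as.integer(mh_len_max),
       placement = match.arg(placement), placement_beta = placement_beta,
       clonal_del_prob = clonal_del_prob,
       clonal_other_prob = clonal_other_prob, purity = purity,
       inversion_mean = inversion_mean, unbalanced_mean = unbalanced_mean,
       artefact_mean = artefact_mean, noise_mean = noise_mean,
       jitter_bp = as.integer(jitter_bp))
}

# synthetic replication timing: smooth deterministic sinusoid of coordinate
timing_at <- function(pos, period) sin(2 * pi * pos / period)

#' Generate a seeded mini-genome reference and its callable regions
#'
#' Chromosome sequences are i.i.d. nucleotides at the configured GC
#' fraction; callable regions are the whole chromosomes minus the masked
#' prefix blocks. Byte-identical for a fixed `(params, seed)`.
#'
#' @param params [sim_params()].
#' @param seed RNG seed.
#' @return List with `genome` (named character vector) and `callable`.
#' @export
generate_reference <- function(params = sim_params(), seed = 1L) {
  base_bytes <- as.raw(c(65L, 67L, 71L, 84L))  # A C G T
  prob <- c((1 - params$gc) / 2, params$gc / 2, params$gc / 2,
            (1 - params$gc) / 2)
  genome <- with_seed(seed, {
    vapply(seq_len(params$n_chroms), function(i) {
      idx <- sample.int(4L, params$chrom_length_bp, replace = TRUE,
                        prob = prob)
      rawToChar(base_bytes[idx])
    }, character(1L))
  })
  names(genome) <- paste0("chr", seq_len(params$n_chroms))
  callable <- callable_regions(tibble::tibble(
    chrom = names(genome),
    start = params$masked_bp + 1L,
    end = params$chrom_length_bp
  ))
  list(genome = genome, callable = callable)
}

#' Generate deterministic synthetic feature tracks
#'
#' Quantitative `timing` (sinusoid of the coordinate, emitted at
#' `track_bin_bp` resolution), categorical `chromatin` (alternating labelled
#' blocks) and binary `in_peak` (timing above zero). All are deterministic
#' functions of the coordinate, independent of the genome sequence.
#'
#' @param params [sim_params()].
#' @return Named list of [feature_track()]s.
#' @export
generate_tracks <- function(params = sim_params()) {
  chroms <- paste0("chr", seq_len(params$n_chroms))
  clen <- params$chrom_length_bp
  bins <- tidyr::expand_grid(
    chrom = chroms,
    start = seq.int(1L, clen, by = params$track_bin_bp)
  ) |>
    dplyr::mutate(end = pmin(.data$start + params$track_bin_bp - 1L, clen),
                  mid = (.data$start + .data$end) / 2)
  timing <- feature_track(
    dplyr::transmute(bins, .data$chrom, .data$start, .data$end,
                     value = timing_at(.data$mid, params$track_period_bp)),
    name = "timing", kind = "quantitative", default = 0
  )
  peak_iv <- dplyr::filter(
    dplyr::transmute(bins, .data$chrom, .data$start, .data$end,
                     up = timing_at(.data$mid, params$track_period_bp) > 0),
    .data$up
  )
  in_peak <- feature_track(
    dplyr::transmute(peak_iv, .data$chrom, .data$start, .data$end, value = 1),
    name = "in_peak", kind = "binary", default = 0
  )
  labels <- c("stateA", "stateB", "stateC", "stateD")
  blocks <- tidyr::expand_grid(
    chrom = chroms,
    start = seq.int(1L, clen, by = params$chromatin_block_bp)
  ) |>
    dplyr::mutate(
      end = pmin(.data$start + params$chromatin_block_bp - 1L, clen),
      value = labels[(as.integer(
        (.data$start - 1L) / params$chromatin_block_bp) %% 4L) + 1L]
    )
  chromatin <- feature_track(
    blocks[, c("chrom", "start", "end", "value")],
    name = "chromatin", kind = "categorical", default = "stateA"
  )
  list(timing = timing, in_peak = in_peak, chromatin = chromatin)
}

# draw n genomic positions from the callable regions, uniform or weighted by
# exp(beta * timing); margin_bp keeps a safety band inside each interval
draw_positions <- function(callable, n, placement = "uniform", beta = 0,
                           period = 1e6, margin_bp = 200L) {
  if (n == 0L) {
    return(tibble::tibble(chrom = character(), pos = integer()))
  }
  shrink <- dplyr::mutate(callable, start = .data$start + margin_bp,
                          end = .data$end - margin_bp)
  shrink <- shrink[shrink$end > shrink$start, , drop = FALSE]
  pool_n <- max(2000L, 10L * n)
  widths <- shrink$end - shrink$start + 1
  iv <- sample.int(nrow(shrink), pool_n, replace = TRUE, prob = widths)
  pos <- as.integer(shrink$start[iv] + floor(runif(pool_n) * widths[iv]))
  chrom <- shrink$chrom[iv]
  if (placement == "feature_weighted") {
    w <- exp(beta * timing_at(pos, period))
    pick <- sample.int(pool_n, n, replace = TRUE, prob = w)
  } else {
    pick <- sample.int(pool_n, n, replace = TRUE)
  }
  tibble::tibble(chrom = chrom[pick], pos = pos[pick])
}

# place deletions so that the first k deleted bases equal the k bases
# immediately 3' of the deleted span (junction microhomology >= k measured
# from the reference alone); rejection sampling over candidate anchors
draw_mh_sites <- function(genome, callable, lens, ks, placement, beta,
                          period, max_rounds = 120L) {
  n <- length(lens)
  chrom <- character(n)
  anchor <- integer(n)
  pending <- seq_len(n)
  rounds <- 0L
  while (length(pending) > 0L && rounds < max_rounds) {
    rounds <- rounds + 1L
    m <- length(pending)
    cand <- draw_positions(callable, 5L * m, placement, beta, period)
    idx <- rep(pending, 5L)[seq_len(nrow(cand))]
    k <- ks[idx]
    l <- lens[idx]
    seqs <- genome[cand$chrom]
    left <- substring(seqs, cand$pos + 1L, cand$pos + k)
    right <- substring(seqs, cand$pos + l + 1L, cand$pos + l + k)
    hit <- which(left == right & k <= l)
    for (h in hit) {
      i <- idx[h]
      if (anchor[i] == 0L) {
        anchor[i] <- cand$pos[h]
        chrom[i] <- cand$chrom[h]
      }
    }
    pending <- which(anchor == 0L)
  }
  if (length(pending) > 0L) {
    warn("microhomology implant fell back to unconstrained placement")
    fallback <- draw_positions(callable, length(pending), placement, beta,
                               period)
    anchor[pending] <- fallback$pos
    chrom[pending] <- fallback$chrom
    ks[pending] <- 0L
  }
  tibble::tibble(chrom = chrom, pos = anchor, implanted_mh = ks)
}

# deletion length models: short = geometric around 1-2 bp; radiation = the
# same plus a dominant heavier 2-100 bp component
draw_del_lengths <- function(n, model) {
  if (n == 0L) return(integer(0))
  if (model == "short") {
    lens <- 1L + rgeom(n, 0.5)
  } else {
    heavy <- runif(n) < 0.65
    lens <- ifelse(heavy, 2L + rgeom(n, 0.08), 1L + rgeom(n, 0.5))
  }
  pmin(as.integer(lens), 100L)
}

draw_vaf <- function(era, purity) {
  mu <- ifelse(era == "clonal", purity / 2, purity / 6)
  conc <- 60
  rbeta(length(era), mu * conc, (1 - mu) * conc)
}

#' Simulate one tumour's variant catalogue
#'
#' Substitution burden is log-normal; the indel count is Poisson around
#' `indel_sub_ratio` times the substitution count; each indel is a deletion
#' with probability `odds / (1 + odds)`; deletion lengths follow the group's
#' size model truncated to 1-100 bp; placement is uniform over callable
#' bases or weighted by the synthetic replication-timing sinusoid; a
#' configured fraction of deletions is placed at sites whose junction
#' carries at least `k` bases of microhomology (measured blind from the
#' reference by the analysis code); VAFs follow the clonal/subclonal era
#' model. Ground truth is emitted record for record.
#'
#' @param reference Output of [generate_reference()] (list with `genome`,
#'   `callable`).
#' @param group_params [sim_group_params()].
#' @param sample_id Sample name.
#' @param group Group label stored in the catalogue.
#' @param seed RNG seed.
#' @param params [sim_params()] (for track geometry).
#' @return List with `catalogue` ([tumour_catalogue()]) and `truth`.
#' @export
simulate_tumour <- function(reference, group_params, sample_id, group,
                            seed = 1L, params = sim_params()) {
  genome <- reference$genome
  callable <- reference$callable
  gp <- group_params
  with_seed(seed, {
    period <- params$track_period_bp
    # effective placement: feature-weighted on a flat track degrades to
    # uniform with a warning
    placement <- gp$placement
    if (placement == "feature_weighted" && gp$placement_beta == 0) {
      warn("feature_weighted placement with flat weighting; using uniform")
      placement <- "uniform"
    }
    n_sub <- max(1L, round(rlnorm(1L, gp$sub_meanlog, gp$sub_sdlog)))
    sub_pos <- draw_positions(callable, n_sub, "uniform", 0, period)
    ref_base <- substring(genome[sub_pos$chrom], sub_pos$pos, sub_pos$pos)
    alt_base <- vapply(ref_base, function(b) {
      sample(setdiff(c("A", "C", "G", "T"), b), 1L)
    }, character(1L), USE.NAMES = FALSE)
    sub_era <- ifelse(runif(n_sub) < gp$clonal_other_prob, "clonal",
                      "subclonal")
    substitutions <- tibble::tibble(
      chrom = sub_pos$chrom, pos = sub_pos$pos,
      ref_base = ref_base, alt_base = alt_base,
      vaf = draw_vaf(sub_era, gp$purity), sample_id = sample_id
    )

    n_ind <- rpois(1L, gp$indel_sub_ratio * n_sub)
    is_del <- runif(n_ind) < gp$del_ins_odds / (1 + gp$del_ins_odds)
    n_del <- sum(is_del)
    n_ins <- n_ind - n_del

    del_len <- draw_del_lengths(n_del, gp$del_size_model)
    implant <- runif(n_del) < gp$mh_implant_prob
    ks <- integer(n_del)
    ks[implant] <- sample.int(gp$mh_len_max, sum(implant), replace = TRUE)
    ks <- pmin(ks, del_len)
    del_sites <- tibble::tibble(chrom = character(n_del),
                                pos = integer(n_del),
                                implanted_mh = ks)
    if (any(implant)) {
      del_sites[implant, ] <- draw_mh_sites(
        genome, callable, del_len[implant], ks[implant], placement,
        gp$placement_beta, period)
    }
    if (any(!implant)) {
      free <- draw_positions(callable, sum(!implant), placement,
                             gp$placement_beta, period)
      del_sites$chrom[!implant] <- free$chrom
      del_sites$pos[!implant] <- free$pos
    }
    del_era <- ifelse(runif(n_del) < gp$clonal_del_prob, "clonal",
                      "subclonal")
    del_ref <- substring(genome[del_sites$chrom], del_sites$pos,
                         del_sites$pos + del_len)
    deletions <- tibble::tibble(
      chrom = del_sites$chrom, pos = del_sites$pos,
      ref_allele = del_ref, alt_allele = substr(del_ref, 1L, 1L),
      indel_class = "deletion", length = del_len,
      deleted_seq = substr(del_ref, 2L, nchar(del_ref)),
      vaf = draw_vaf(del_era, gp$purity),
      mh_len = NA_integer_, clonality = "unknown", sample_id = sample_id
    )

    ins_len <- pmin(1L + rgeom(n_ins, 0.5), 100L)
    ins_sites <- draw_positions(callable, n_ins, placement,
                                gp$placement_beta, period)
    ins_era <- ifelse(runif(n_ins) < gp$clonal_other_prob, "clonal",
                      "subclonal")
    ins_anchor <- substring(genome[ins_sites$chrom], ins_sites$pos,
                            ins_sites$pos)
    ins_seq <- vapply(ins_len, function(L) {
      paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = "")
    }, character(1L))
    insertions <- tibble::tibble(
      chrom = ins_sites$chrom, pos = ins_sites$pos,
      ref_allele = ins_anchor, alt_allele = paste0(ins_anchor, ins_seq),
      indel_class = "insertion", length = ins_len,
      deleted_seq = NA_character_,
      vaf = draw_vaf(ins_era, gp$purity),
      mh_len = NA_integer_, clonality = "unknown", sample_id = sample_id
    )

    indels <- dplyr::bind_rows(deletions, insertions)
    rearr <- simulate_rearrangements(gp, genome, sample_id)
    copy_number <- tibble::tibble(chrom = names(genome), start = 1L,
                                  end = nchar(genome), cn = 2)
    catalogue <- tumour_catalogue(
      sample_id = sample_id, group = group,
      substitutions = substitutions, indels = indels,
      rearrangements = rearr$calls, purity = gp$purity,
      copy_number = copy_number
    )
    truth <- list(
      sample_id = sample_id, group = group, placement = placement,
      n_substitutions = n_sub, n_deletions = n_del, n_insertions = n_ins,
      deletion_truth = tibble::tibble(
        chrom = deletions$chrom, pos = deletions$pos,
        length = deletions$length,
        implanted_mh = del_sites$implanted_mh, era = del_era
      ),
      insertion_era = ins_era, substitution_era = sub_era,
      inversion_pairs = rearr$truth_pairs
    )
    list(catalogue = catalogue, truth = truth)
  })
}

#' Simulate a rearrangement catalogue
#'
#' Implants balanced inversions (a reciprocal `head_head` + `tail_tail`
#' junction pair with breakpoints jittered by at most `jitter_bp` and
#' point intervals), unbalanced single inverted junctions, small
#' low-read-support inverted artefacts, and non-inverted /
#' inter-chromosomal noise calls.
#'
#' @param gp [sim_group_params()].
#' @param genome Named character vector of chromosome sequences (only the
#'   lengths are used).
#' @param sample_id Sample name.
#' @param seed Optional seed; when `NULL` the caller's RNG stream is used
#'   (as [simulate_tumour()] does).
#' @return List with `calls` (rearrangement tibble) and `truth_pairs`
#'   (tibble of implanted head/tail id pairs).
#' @export
simulate_rearrangements <- function(gp, genome, sample_id, seed = NULL) {
  run <- function() {
    chroms <- names(genome)
    clen <- nchar(genome)
    names(clen) <- chroms
    margin <- max(100L, min(10000L, as.integer(min(clen) %/% 20L)))
    cap_size <- function(size, ch) {
      min(size, clen[[ch]] - 2L * margin - 10L)
    }
    place <- function(ch, size) {
      sample.int(max(1L, clen[[ch]] - as.integer(size) - 2L * margin), 1L) +
        margin
    }
    calls <- list()
    pairs <- list()
    point_call <- function(id, chrom, p1, p2, orient, support) {
      if (p1 > p2) {
        tmp <- p1
        p1 <- p2
        p2 <- tmp
      }
      tibble::tibble(call_id = id, chrom_low = chrom,
                     low_start = as.integer(p1), low_end = as.integer(p1),
                     chrom_high = chrom,
                     high_start = as.integer(p2), high_end = as.integer(p2),
                     orient = orient, read_support = as.integer(support),
                     sample_id = sample_id)
    }
    n_bal <- rpois(1L, gp$inversion_mean)
    for (i in seq_len(n_bal)) {
      ch <- sample(chroms, 1L)
      size <- cap_size(round(10^runif(1L, 3.7, 6)), ch)
      p1 <- place(ch, size)
      p2 <- p1 + size
      j <- gp$jitter_bp
      e <- as.integer(round(runif(4L, -j / 2, j / 2)))
      hid <- sprintf("%s_bal%02d_h", sample_id, i)
      tid <- sprintf("%s_bal%02d_t", sample_id, i)
      support <- 10L + rpois(2L, 6)
      calls <- c(calls, list(
        point_call(hid, ch, p1 + e[1L], p2 + e[2L], "head_head",
                   support[1L]),
        point_call(tid, ch, p1 + 1L + e[3L], p2 + 1L + e[4L], "tail_tail",
                   support[2L])
      ))
      pairs <- c(pairs, list(tibble::tibble(
        head_call_id = hid, tail_call_id = tid, chrom = ch, size = size
      )))
    }
    n_unb <- rpois(1L, gp$unbalanced_mean)
    for (i in seq_len(n_unb)) {
      ch <- sample(chroms, 1L)
      size <- cap_size(round(10^runif(1L, 4, 6)), ch)
      p1 <- place(ch, size)
      calls <- c(calls, list(point_call(
        sprintf("%s_unb%02d", sample_id, i), ch, p1, p1 + size,
        sample(c("head_head", "tail_tail"), 1L), 8L + rpois(1L, 6))))
    }
    n_art <- rpois(1L, gp$artefact_mean)
    for (i in seq_len(n_art)) {
      ch <- sample(chroms, 1L)
      size <- cap_size(sample(200:2000, 1L), ch)
      p1 <- place(ch, size)
      calls <- c(calls, list(point_call(
        sprintf("%s_art%02d", sample_id, i), ch, p1, p1 + size,
        sample(c("head_head", "tail_tail"), 1L), sample.int(5L, 1L))))
    }
    n_noise <- rpois(1L, gp$noise_mean)
    for (i in seq_len(n_noise)) {
      ch2 <- sample(chroms, 2L, replace = length(chroms) < 2L)
      p1 <- place(ch2[1L], 0L)
      p2 <- place(ch2[2L], 0L)
      cl <- point_call(sprintf("%s_noise%02d", sample_id, i), ch2[1L],
                       p1, p2, "other", 5L + rpois(1L, 10))
      cl$chrom_high <- ch2[2L]
      calls <- c(calls, list(cl))
    }
    calls_tb <- if (length(calls)) dplyr::bind_rows(calls) else
      empty_rearrangements()
    pairs_tb <- if (length(pairs)) dplyr::bind_rows(pairs) else
      tibble::tibble(head_call_id = character(),
                     tail_call_id = character(), chrom = character(),
                     size = numeric())
    list(calls = calls_tb, truth_pairs = pairs_tb)
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}

#' Simulate a full cohort
#'
#' Generates the reference, tracks and every group's catalogues under one
#' master seed (per-sample child seeds derive from it).
#'
#' @param params [sim_params()].
#' @param seed Master seed.
#' @return List with `reference`, `callable`, `tracks`, `catalogues`
#'   (named list), `truth` (named list), `params`, `seed`.
#' @export
simulate_cohort <- function(params = sim_params(), seed = 1L) {
  reference <- generate_reference(params, seed = child_seed(seed, 0L))
  tracks <- generate_tracks(params)
  catalogues <- list()
  truth <- list()
  i <- 0L
  for (gname in names(params$groups)) {
    gp <- params$groups[[gname]]
    for (s in seq_len(gp$n_samples)) {
      i <- i + 1L
      sid <- sprintf("%s_%02d", gname, s)
      sim <- simulate_tumour(reference, gp, sid, gname,
                             seed = child_seed(seed, i), params = params)
      catalogues[[sid]] <- sim$catalogue
      truth[[sid]] <- sim$truth
    }
  }
  list(reference = reference$genome, callable = reference$callable,
       tracks = tracks, catalogues = catalogues, truth = truth,
       params = params, seed = seed)
}

#' Lightweight count-level cohort simulation
#'
#' Draws only per-sample substitution/deletion/insertion counts (no genome,
#' no placement); used for model-calibration studies where thousands of
#' replicates are needed.
#'
#' @param groups Named list of [sim_group_params()].
#' @param seed RNG seed.
#' @return Long count table as from [long_count_table()].
#' @export
simulate_count_table <- function(groups, seed = 1L) {
  with_seed(seed, {
    purrr::imap_dfr(groups, function(gp, gname) {
      n_sub <- pmax(1L, round(rlnorm(gp$n_samples, gp$sub_meanlog,
                                     gp$sub_sdlog)))
      n_ind <- rpois(gp$n_samples, gp$indel_sub_ratio * n_sub)
      p_del <- gp$del_ins_odds / (1 + gp$del_ins_odds)
      n_del <- rbinom(gp$n_samples, n_ind, p_del)
      tibble::tibble(
        sample_id = sprintf("%s_%02d", gname, seq_len(gp$n_samples)),
        group = gname,
        substitution = n_sub, deletion = n_del, insertion = n_ind - n_del
      )
    }) |>
      tidyr::pivot_longer(c("substitution", "deletion", "insertion"),
                          names_to = "mutation_type", values_to = "count")
  })
}

#' Write a simulated cohort to standard file formats
#'
#' Emits the reference FASTA, callable BED, track files (bedGraph + BED)
#' with their YAML sidecar, per-sample substitution/indel VCFs and
#' rearrangement BEDPEs, a manifest TSV, and the ground truth as JSON.
#'
#' @param sim Output of [simulate_cohort()].
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_genome_fasta(sim$reference, file.path(dir, "reference.fa"))
  write_callable_bed(sim$callable, file.path(dir, "callable.bed"))
  tr <- sim$tracks
  readr::write_tsv(
    dplyr::transmute(tr$timing$intervals, .data$chrom,
                     start = .data$start - 1L, .data$end, .data$value),
    file.path(dir, "timing.bedgraph"), col_names = FALSE
  )
  readr::write_tsv(
    dplyr::transmute(tr$in_peak$intervals, .data$chrom,
                     start = .data$start - 1L, .data$end),
    file.path(dir, "in_peak.bed"), col_names = FALSE
  )
  readr::write_tsv(
    dplyr::transmute(tr$chromatin$intervals, .data$chrom,
                     start = .data$start - 1L, .data$end, .data$value),
    file.path(dir, "chromatin.bed"), col_names = FALSE
  )
  yaml::write_yaml(list(tracks = list(
    list(name = "timing", path = "timing.bedgraph", kind = "quantitative",
         default = 0),
    list(name = "in_peak", path = "in_peak.bed", kind = "binary",
         default = 0),
    list(name = "chromatin", path = "chromatin.bed", kind = "categorical",
         default = "stateA")
  )), file.path(dir, "tracks.yaml"))
  manifest <- purrr::map_dfr(sim$catalogues, function(cat) {
    sid <- cat$sample_id
    write_variant_vcf(cat$substitutions,
                      file.path(dir, paste0(sid, ".subs.vcf")),
                      sim$reference)
    write_variant_vcf(cat$indels, file.path(dir, paste0(sid, ".indels.vcf")),
                      sim$reference)
    write_rearrangement_bedpe(cat$rearrangements,
                              file.path(dir, paste0(sid, ".bedpe")))
    tibble::tibble(sample_id = sid, group = cat$group, purity = cat$purity,
                   substitution_vcf = paste0(sid, ".subs.vcf"),
                   indel_vcf = paste0(sid, ".indels.vcf"),
                   rearrangement_bedpe = paste0(sid, ".bedpe"))
  })
  readr::write_tsv(manifest, file.path(dir, "manifest.tsv"))
  truth_json <- purrr::map(sim$truth, function(tt) {
    tt$deletion_truth <- as.data.frame(tt$deletion_truth)
    tt$inversion_pairs <- as.data.frame(tt$inversion_pairs)
    tt
  })
  jsonlite::write_json(list(seed = sim$seed, truth = truth_json),
                       file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
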