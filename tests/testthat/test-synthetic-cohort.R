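# Generator determinism, marginal calibration, and ground-truth
# consistency with the analysis modules.

small_params <- function(...) {
  sim_params(n_chroms = 2L, chrom_length_bp = 400000L, masked_bp = 5000L,
             track_period_bp = 100000L, chromatin_block_bp = 25000L, ...)
}

test_that("the generator is fully deterministic per seed", {
  p <- small_params(groups = list(g = sim_group_params(
    n_samples = 2L, sub_meanlog = log(100))))
  a <- simulate_cohort(p, seed = 42)
  b <- simulate_cohort(p, seed = 42)
  expect_identical(a$reference, b$reference)
  expect_identical(a$catalogues[[1]]$indels, b$catalogues[[1]]$indels)
  expect_identical(a$catalogues[[2]]$rearrangements,
                   b$catalogues[[2]]$rearrangements)
  d1 <- file.path(tempfile(), "x")
  d2 <- file.path(tempfile(), "y")
  write_cohort(a, d1)
  write_cohort(b, d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), info = f)
  }
  c_other <- simulate_cohort(p, seed = 43)
  expect_false(identical(a$catalogues[[1]]$indels,
                         c_other$catalogues[[1]]$indels))
})

test_that("reference GC tracks the requested fraction", {
  p <- sim_params(n_chroms = 1L, chrom_length_bp = 1000000L, gc = 0.6)
  ref <- generate_reference(p, seed = 7)
  gc <- Biostrings::letterFrequency(
    Biostrings::DNAStringSet(ref$genome), "GC", as.prob = TRUE)[1]
  expect_lt(abs(gc - 0.6), 3 * sqrt(0.6 * 0.4 / 1e6))
  expect_equal(ref$callable$start, 50001L)
  expect_error(sim_params(chrom_length_bp = 5000), "10 kb")
})

test_that("tracks are periodic, blocky, and mutually consistent", {
  p <- small_params()
  tr <- generate_tracks(p)
  pos <- c(30000L, 130000L, 230000L)   # one period apart
  v <- as.numeric(track_value(tr$timing, rep("chr1", 3), pos))
  expect_equal(v[1], v[2], tolerance = 1e-9)
  expect_equal(v[2], v[3], tolerance = 1e-9)
  # binary peak track is the thresholded sinusoid
  grid <- seq.int(5000L, 390000L, by = 7000L)
  tv <- as.numeric(track_value(tr$timing, rep("chr1", length(grid)), grid))
  pv <- as.numeric(track_value(tr$in_peak, rep("chr1", length(grid)), grid))
  expect_equal(pv, as.numeric(tv > 0))
  # chromatin labels change exactly at block boundaries
  lab <- track_value(tr$chromatin, rep("chr1", 4),
                     c(24999L, 25001L, 50001L, 75001L))
  expect_equal(lab, c("stateA", "stateB", "stateC", "stateD"))
})

test_that("simulated burdens match their requested distributions", {
  groups <- list(g = sim_group_params(n_samples = 20L,
                                      sub_meanlog = log(4000),
                                      sub_sdlog = 1e-9,
                                      indel_sub_ratio = 0.1,
                                      del_ins_odds = 3))
  tb <- simulate_count_table(groups, seed = 55) |>
    tidyr::pivot_wider(names_from = "mutation_type", values_from = "count")
  # indel counts are Poisson(400): the pooled mean sits within 3 sd
  n_ind <- tb$deletion + tb$insertion
  expect_lt(abs(mean(n_ind) - 400), 3 * sqrt(400 / 20))
  # deletion fraction is 3:1 odds = 0.75 within 3 binomial sd
  frac <- sum(tb$deletion) / sum(n_ind)
  expect_lt(abs(frac - 0.75), 3 * sqrt(0.25 * 0.75 / sum(n_ind)))
})

test_that("every emitted variant lies in callable space and matches the
           reference", {
  p <- small_params(groups = list(g = sim_group_params(
    n_samples = 2L, sub_meanlog = log(300), indel_sub_ratio = 0.3,
    mh_implant_prob = 0.4, mh_len_max = 3L)))
  sim <- simulate_cohort(p, seed = 12)
  in_callable <- function(chrom, pos) {
    purrr::map2_lgl(chrom, pos, function(ch, x) {
      any(sim$callable$chrom == ch & sim$callable$start <= x &
            sim$callable$end >= x)
    })
  }
  for (cat in sim$catalogues) {
    expect_true(all(in_callable(cat$substitutions$chrom,
                                cat$substitutions$pos)))
    expect_true(all(in_callable(cat$indels$chrom, cat$indels$pos)))
    dels <- cat$indels[cat$indels$indel_class == "deletion", ]
    expect_identical(dels$deleted_seq,
                     substring(sim$reference[dels$chrom], dels$pos + 1L,
                               dels$pos + dels$length))
    subs <- cat$substitutions
    expect_identical(subs$ref_base,
                     substring(sim$reference[subs$chrom], subs$pos,
                               subs$pos))
    expect_true(all(subs$ref_base != subs$alt_base))
  }
})

test_that("implanted microhomology is measurable blind from the reference", {
  p <- small_params(groups = list(g = sim_group_params(
    n_samples = 3L, sub_meanlog = log(400), indel_sub_ratio = 0.3,
    del_ins_odds = 3, mh_implant_prob = 0.6, mh_len_max = 3L)))
  sim <- simulate_cohort(p, seed = 9)
  for (sid in names(sim$catalogues)) {
    ind <- compute_microhomology(sim$catalogues[[sid]]$indels,
                                 sim$reference)
    dels <- ind[ind$indel_class == "deletion", ]
    truth <- sim$truth[[sid]]$deletion_truth
    expect_equal(nrow(dels), nrow(truth))
    expect_true(all(dels$mh_len >= truth$implanted_mh))
  }
})

test_that("implanted balanced inversions are recovered exactly by the
           screen", {
  gp <- sim_group_params(inversion_mean = 5, unbalanced_mean = 0,
                         artefact_mean = 0, noise_mean = 0,
                         jitter_bp = 100L)
  genome <- setNames(rep(strrep("A", 3e6), 2), c("chr1", "chr2"))
  withr::with_seed(4, {
    found_all <- TRUE
    for (r in 1:5) {
      out <- simulate_rearrangements(gp, genome, "s1", seed = 100 + r)
      res <- screen_balanced_inversions(out$calls)
      truth_keys <- sort(paste(out$truth_pairs$head_call_id,
                               out$truth_pairs$tail_call_id))
      got_keys <- sort(paste(res$inversions$head_call_id,
                             res$inversions$tail_call_id))
      found_all <- found_all && identical(truth_keys, got_keys)
    }
    expect_true(found_all)
  })

  artefacts <- simulate_rearrangements(
    sim_group_params(inversion_mean = 0, unbalanced_mean = 0,
                     artefact_mean = 6, noise_mean = 0),
    genome, "s2", seed = 3)
  expect_equal(nrow(screen_balanced_inversions(
    artefacts$calls)$inversions), 0L)

  unbalanced <- simulate_rearrangements(
    sim_group_params(inversion_mean = 0, unbalanced_mean = 5,
                     artefact_mean = 0, noise_mean = 0),
    genome, "s3", seed = 3)
  res_u <- screen_balanced_inversions(unbalanced$calls)
  expect_equal(nrow(res_u$inversions), 0L)
  expect_equal(nrow(res_u$unpaired), nrow(
    filter_inversion_calls(unbalanced$calls)))
})

test_that("feature-weighted placement with a flat weight warns and falls
           back to uniform", {
  p <- small_params(groups = list(g = sim_group_params(
    n_samples = 1L, sub_meanlog = log(50), placement = "feature_weighted",
    placement_beta = 0)))
  ref <- generate_reference(p, seed = 2)
  expect_warning(
    simulate_tumour(ref, p$groups$g, "s1", "g", seed = 3, params = p),
    "flat")
})
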