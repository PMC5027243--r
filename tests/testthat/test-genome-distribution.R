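# Background sampling, position annotation, the feature test battery,
# Benjamini-Yekutieli adjustment, significance flagging, density ratios
# and the indel probability profile.

test_that("background positions stay in callable space, deterministically", {
  callable <- callable_regions(tibble::tibble(chrom = "chr1", start = 1L,
                                              end = 1000L))
  pos <- sample_background(callable, 10, seed = 3)
  expect_true(all(pos$pos >= 1 & pos$pos <= 1000))
  expect_identical(pos, sample_background(callable, 10, seed = 3))
  expect_error(sample_background(callable, 0), "positive")
  expect_error(sample_background(callable[0, ], 5), "empty")
})

test_that("two equal chromosomes each receive about half the draws", {
  callable <- callable_regions(tibble::tibble(chrom = c("chr1", "chr2"),
                                              start = 1L, end = 500000L))
  n <- 100000L
  pos <- sample_background(callable, n, seed = 9)
  n1 <- sum(pos$chrom == "chr1")
  expect_lt(abs(n1 - n / 2), 3 * sqrt(n * 0.25))
})

test_that("window annotation computes GC and 3-mer entropy as defined", {
  ref <- c(chr1 = paste0(strrep("G", 200), strrep("A", 200),
                         strrep("ACGT", 100)))
  ann <- annotate_positions(
    tibble::tibble(chrom = "chr1", pos = c(100L, 300L, 600L)), ref,
    window_bp = 100L)
  expect_equal(ann$gc[1], 1)
  expect_equal(ann$complexity[2], 0)           # homopolymer
  # period-4 sequence: exactly 4 distinct 3-mers, equally frequent
  expect_equal(ann$complexity[3], log(4) / log(64), tolerance = 1e-2)
  expect_false(any(ann$window_truncated))
  edge <- annotate_positions(tibble::tibble(chrom = "chr1", pos = 3L), ref)
  expect_true(edge$window_truncated)
})

test_that("track gaps fall back to the declared default with a flag", {
  tr <- feature_track(tibble::tibble(chrom = "chr1", start = 1L, end = 50L,
                                     value = 2.5),
                      "timing", "quantitative", default = -1)
  ref <- c(chr1 = strrep("ACGT", 50))
  ann <- annotate_positions(tibble::tibble(chrom = "chr1",
                                           pos = c(20L, 120L)),
                            ref, tracks = list(timing = tr))
  expect_equal(ann$timing, c(2.5, -1))
  expect_equal(ann$timing_covered, c(TRUE, FALSE))
})

test_that("the two-proportion z-test matches the pooled closed form", {
  res <- compare_feature(c(rep(1, 10), rep(0, 90)),
                         c(rep(1, 20), rep(0, 80)), "binary")
  expect_equal(res$statistic, -0.1 / sqrt(0.15 * 0.85 * 2 / 100),
               tolerance = 1e-10)
  expect_equal(res$statistic, -1.980, tolerance = 1e-3)

  same <- compare_feature(c(1, 2, 3), c(1, 2, 3), "quantitative")
  expect_equal(same$statistic, 0)
  expect_equal(same$raw_p, 1)

  cat_same <- compare_feature(rep(c("a", "b"), each = 10),
                              rep(c("a", "b"), each = 10), "categorical")
  expect_equal(cat_same$statistic, 0)
  expect_equal(cat_same$raw_p, 1)
  one_label <- compare_feature(rep("a", 5), rep("a", 7), "categorical")
  expect_true(one_label$degenerate)
  expect_equal(one_label$raw_p, 1)
})

test_that("z squared equals the 2x2 chi-squared without correction", {
  withr::with_seed(23, {
    for (i in 1:100) {
      n1 <- sample(20:200, 1)
      n2 <- sample(20:200, 1)
      x <- c(rep(1, sample(1:(n1 - 1), 1)))
      a <- c(x, rep(0, n1 - length(x)))
      y <- c(rep(1, sample(1:(n2 - 1), 1)))
      b <- c(y, rep(0, n2 - length(y)))
      z <- compare_feature(a, b, "binary")$statistic
      tab <- rbind(c(sum(a), n1 - sum(a)), c(sum(b), n2 - sum(b)))
      chi <- suppressWarnings(chisq.test(tab, correct = FALSE)$statistic)
      expect_equal(z^2, unname(chi), tolerance = 1e-10)
    }
  })
})

test_that("Benjamini-Yekutieli matches hand computation and bounds BH", {
  # m = 3, c(3) = 11/6: every adjusted value collapses to 0.055
  expect_equal(adjust_benjamini_yekutieli(c(0.01, 0.02, 0.03)),
               rep(0.055, 3), tolerance = 1e-12)
  expect_equal(adjust_benjamini_yekutieli(0.2), 0.2)
  expect_error(adjust_benjamini_yekutieli(c(0.5, 1.2)), "\\[0, 1\\]")
  withr::with_seed(11, {
    for (i in 1:20) {
      p <- runif(sample(2:40, 1))
      q <- adjust_benjamini_yekutieli(p)
      expect_true(all(q <= 1 + 1e-12))
      expect_true(all(q >= p.adjust(p, "BH") - 1e-12))
      expect_true(all(diff(q[order(p)]) >= -1e-12))
    }
  })
})

test_that("significance needs both a small q and a real magnitude", {
  mk <- function(p, m1, m2) {
    tibble::tibble(feature = "f", kind = "quantitative", statistic = 1,
                   raw_p = p, mean_1 = m1, mean_2 = m2,
                   magnitude_diff = ifelse(max(abs(c(m1, m2))) == 0, 0,
                                           abs(m1 - m2) /
                                             max(abs(c(m1, m2)))),
                   degenerate = FALSE, tables = list(NULL))
  }
  expect_true(flag_significant(mk(0.005, 0.10, 0.20))$significant)
  expect_false(flag_significant(mk(0.005, 0.100, 0.101))$significant)
  expect_false(flag_significant(mk(0.02, 0, 1))$significant)
})

test_that("density ratios compare bin occupancy against the background", {
  withr::with_seed(2, {
    v <- runif(5000)
    b <- runif(20000)
  })
  same <- density_ratio(tibble::tibble(f = v), tibble::tibble(f = b), "f",
                        seq(0, 1, by = 0.25))
  expect_true(all(abs(same$ratio - 1) < 0.15))

  top <- density_ratio(tibble::tibble(f = rep(0.9, 100)),
                       tibble::tibble(f = b), "f", seq(0, 1, by = 0.25))
  expect_equal(top$ratio[4], 4, tolerance = 0.1)
  expect_equal(top$ratio[1:3], rep(0, 3))
  expect_error(density_ratio(tibble::tibble(f = numeric(0)),
                             tibble::tibble(f = b), "f", 0:1), "empty")
})

test_that("the probability profile is flat under the null and bends with an
           implanted feature effect", {
  params <- sim_params(n_chroms = 1L, chrom_length_bp = 2e6L,
                       masked_bp = 10000L, track_period_bp = 5e5L)
  reference <- generate_reference(params, seed = 21)
  tracks <- generate_tracks(params)
  bins <- genome_feature_bins(reference$genome, tracks, bin_bp = 100000L)
  bg <- annotate_positions(sample_background(reference$callable, 5000, 77),
                           reference$genome, tracks)
  null_var <- annotate_positions(
    sample_background(reference$callable, 5000, 78),
    reference$genome, tracks)
  null_prof <- indel_probability_profile(null_var, bg, bins)
  p <- null_prof$profile$probability
  expect_lt(max(p) / min(p), 1.2)

  # variants drawn where timing is high: positive timing coefficient and a
  # structured profile
  cand <- sample_background(reference$callable, 30000, 79)
  w <- exp(2 * sin(2 * pi * cand$pos / params$track_period_bp))
  withr::with_seed(80, {
    pick <- sample.int(nrow(cand), 4000, prob = w)
  })
  eff_var <- annotate_positions(cand[pick, ], reference$genome, tracks)
  eff_prof <- indel_probability_profile(eff_var, bg, bins)
  co <- eff_prof$coefficients
  expect_gt(co$estimate[co$feature == "timing"], 0)
  cv <- function(x) sd(x) / mean(x)
  expect_gt(cv(eff_prof$profile$probability),
            cv(null_prof$profile$probability))
})
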