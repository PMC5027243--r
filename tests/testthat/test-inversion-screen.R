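# Filters, reciprocal pairing, and cohort summaries of the
# balanced-inversion screen.

mk_call <- function(id, orient, p1, p2, support, w = 0L, chrom = "chr1",
                    sample_id = "s1") {
  tibble::tibble(call_id = id, chrom_low = chrom,
                 low_start = as.integer(p1), low_end = as.integer(p1 + w),
                 chrom_high = chrom, high_start = as.integer(p2),
                 high_end = as.integer(p2 + w), orient = orient,
                 read_support = as.integer(support), sample_id = sample_id)
}

test_that("the read-support and size filter applies strict inequalities", {
  calls <- dplyr::bind_rows(
    mk_call("a", "head_head", 1000, 4000, 6),    # 6 reads, 3000 bp: kept
    mk_call("b", "head_head", 1000, 3000, 6),    # 6 reads, 2000 bp: dropped
    mk_call("c", "tail_tail", 1000, 1800, 11),   # 11 reads, 800 bp: kept
    mk_call("d", "tail_tail", 1000, 1800, 10),   # 10 reads, 800 bp: dropped
    mk_call("e", "other", 1000, 9000, 20),       # not inverted: dropped
    mk_call("f", "head_head", 5, 5000, 5)        # 5 reads: dropped
  )
  kept <- filter_inversion_calls(calls, screen_config())
  expect_equal(kept$call_id, c("a", "c"))
  inter <- mk_call("g", "head_head", 1000, 9000, 20)
  inter$chrom_high <- "chr2"
  expect_equal(nrow(filter_inversion_calls(inter)), 0L)
  expect_equal(nrow(filter_inversion_calls(calls[0, ])), 0L)
})

test_that("raising any filter threshold never increases the kept count", {
  withr::with_seed(41, {
    for (rep in 1:20) {
      calls <- random_inversion_catalogue()
      if (nrow(calls) == 0) next
      base <- nrow(filter_inversion_calls(calls, screen_config()))
      for (cfg in list(screen_config(min_reads = 8),
                       screen_config(min_size_bp = 5000),
                       screen_config(high_conf_reads = 15),
                       screen_config(min_reads = 8, min_size_bp = 5000,
                                     high_conf_reads = 15))) {
        expect_lte(nrow(filter_inversion_calls(calls, cfg)), base)
      }
    }
  })
})

test_that("reciprocal junctions with doubly overlapping ranges pair up", {
  head <- mk_call("h1", "head_head", 1000, 50000, 12, w = 10L)
  tail <- mk_call("t1", "tail_tail", 1004, 50003, 12, w = 10L)
  res <- pair_balanced_inversions(dplyr::bind_rows(head, tail))
  expect_equal(nrow(res$inversions), 1L)
  expect_equal(res$inversions$size, 49000)
  expect_equal(nrow(res$unpaired), 0L)

  # overlap must hold at BOTH ends
  tail_far <- mk_call("t2", "tail_tail", 2000, 50003, 12, w = 10L)
  res2 <- pair_balanced_inversions(dplyr::bind_rows(head, tail_far))
  expect_equal(nrow(res2$inversions), 0L)
  expect_equal(nrow(res2$unpaired), 2L)
})

test_that("degenerate point breakpoints are rescued by slop padding", {
  head <- mk_call("h1", "head_head", 1000, 50000, 12)
  tail <- mk_call("t1", "tail_tail", 1300, 50200, 12)
  expect_equal(nrow(pair_balanced_inversions(
    dplyr::bind_rows(head, tail), screen_config(slop_bp = 500))$inversions),
    1L)
  expect_equal(nrow(pair_balanced_inversions(
    dplyr::bind_rows(head, tail), screen_config(slop_bp = 100))$inversions),
    0L)
})

test_that("among several candidates the nearest mate wins", {
  tail <- mk_call("t1", "tail_tail", 1000, 50000, 12, w = 400L)
  heads <- dplyr::bind_rows(
    mk_call("h_far", "head_head", 1300, 50300, 12, w = 400L),
    mk_call("h_near", "head_head", 1010, 50010, 12, w = 400L),
    mk_call("h_mid", "head_head", 1100, 50100, 12, w = 400L)
  )
  res <- pair_balanced_inversions(dplyr::bind_rows(heads, tail))
  expect_equal(nrow(res$inversions), 1L)
  expect_equal(res$inversions$head_call_id, "h_near")
  expect_equal(sort(res$unpaired$call_id), c("h_far", "h_mid"))
})

test_that("greedy pairing is order-invariant and never beats the optimum", {
  withr::with_seed(99, {
    n_conflict_free <- 0L
    for (rep in 1:60) {
      calls <- random_inversion_catalogue()
      if (nrow(calls) == 0) next
      res <- pair_balanced_inversions(calls)
      edges <- candidate_edges_oracle(calls)
      opt <- max_matching_oracle(edges)
      expect_lte(nrow(res$inversions), opt)
      degrees <- c(table(edges$h), table(edges$t))
      if (length(degrees) == 0L || all(degrees <= 1L)) {
        n_conflict_free <- n_conflict_free + 1L
        expect_equal(nrow(res$inversions), opt)
      }
      shuffled <- calls[sample.int(nrow(calls)), ]
      res2 <- pair_balanced_inversions(shuffled)
      key <- function(r) sort(paste(r$inversions$head_call_id,
                                    r$inversions$tail_call_id))
      expect_equal(key(res2), key(res))
    }
    expect_gt(n_conflict_free, 5L)  # the equality branch was exercised
  })
})

test_that("breakpoint midpoints are flagged against gene intervals", {
  head <- mk_call("h1", "head_head", 100, 50000, 12, w = 100L)
  tail <- mk_call("t1", "tail_tail", 140, 50040, 12, w = 100L)
  inv <- pair_balanced_inversions(dplyr::bind_rows(head, tail))$inversions
  genes <- tibble::tibble(chrom = "chr1", start = c(100, 49000),
                          end = c(300, 49500), gene = c("G1", "G2"))
  ann <- annotate_breakpoint_genes(inv, genes)
  # low midpoints (150, 190) fall in G1; high midpoints (50050, 50090) miss
  expect_equal(sum(ann$breakpoints$in_gene), 2L)
  expect_equal(ann$fraction_in_genes, 0.5)
})

test_that("cohort summaries count tumours and inversions per group", {
  has3 <- stub_catalogue("s1", "g1")
  has3$rearrangements <- dplyr::bind_rows(
    mk_call("h1", "head_head", 1000, 50000, 12, sample_id = "s1"),
    mk_call("t1", "tail_tail", 1050, 50050, 12, sample_id = "s1"),
    mk_call("h2", "head_head", 200000, 400000, 12, sample_id = "s1"),
    mk_call("t2", "tail_tail", 200050, 400050, 12, sample_id = "s1"),
    mk_call("h3", "head_head", 600000, 700000, 12, sample_id = "s1"),
    mk_call("t3", "tail_tail", 600050, 700050, 12, sample_id = "s1")
  )
  none <- stub_catalogue("s2", "g2")
  out <- inversion_cohort_summary(list(has3, none))
  expect_equal(out$n_screened, c(1L, 1L))
  expect_equal(out$n_with_inversion, c(1L, 0L))
  expect_equal(out$n_inversions, c(3L, 0L))
  expect_error(inversion_cohort_summary(list(has3), groups = "other"),
               "unknown group")
})

test_that("pooling published survey rows reproduces the naive totals", {
  survey <- readr::read_tsv(
    system.file("extdata", "inversion_survey.tsv", package = "radsig"),
    show_col_types = FALSE)
  pooled <- pool_inversion_summary(
    survey, c("primary_breast", "primary_osteosarcoma"), "radiation_naive")
  expect_equal(pooled$n_screened, 286)
  expect_equal(pooled$n_with_inversion, 43)
  expect_equal(pooled$n_inversions, 66)
})
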