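# Burden metrics, size spectra, microhomology and distribution distances.

del_record <- function(chrom, pos, len, ref) {
  chromseq <- ref[[chrom]]
  tibble::tibble(
    chrom = chrom, pos = as.integer(pos),
    ref_allele = substring(chromseq, pos, pos + len),
    alt_allele = substring(chromseq, pos, pos),
    indel_class = "deletion", length = as.integer(len),
    deleted_seq = substring(chromseq, pos + 1L, pos + len),
    vaf = NA_real_, mh_len = NA_integer_, clonality = "unknown",
    sample_id = "s1"
  )
}

test_that("microhomology is the longer of the two junction identities", {
  # delete TAG (positions 4-6): right flank TCC shares T; left flank AAG
  # shares AG -> 2
  ref <- c(chr1 = "AAGTAGTCC")
  d <- compute_microhomology(del_record("chr1", 3, 3, ref), ref)
  expect_equal(d$mh_len, 2L)

  # delete CA (positions 2-3) of GCACAT: right flank CAT matches both
  # deleted bases -> capped at L = 2
  ref2 <- c(chr1 = "GCACAT")
  d2 <- compute_microhomology(del_record("chr1", 1, 2, ref2), ref2)
  expect_equal(d2$mh_len, 2L)

  # flanks sharing no terminal bases -> 0
  ref3 <- c(chr1 = "CCCTAGCCC")
  d3 <- compute_microhomology(del_record("chr1", 3, 3, ref3), ref3)
  expect_equal(d3$mh_len, 0L)

  expect_error(compute_microhomology(del_record("chr1", 7, 3, ref3), ref3),
               "outside")
})

test_that("microhomology equals the exhaustive oracle on random deletions", {
  withr::with_seed(31, {
    chromseq <- paste0(random_dna(4000),
                       strrep("TA", 300),     # dinucleotide repeat tract
                       random_dna(2000),
                       strrep("AGC", 200),    # trinucleotide repeat tract
                       random_dna(2000))
    ref <- c(chr1 = chromseq)
    n <- 400
    pos <- sample(50:(nchar(chromseq) - 160), n)
    len <- sample(1:100, n, replace = TRUE)
    recs <- purrr::map_dfr(seq_len(n),
                           function(i) del_record("chr1", pos[i], len[i],
                                                  ref))
    got <- compute_microhomology(recs, ref)$mh_len
    want <- vapply(seq_len(n),
                   function(i) mh_oracle(chromseq, pos[i], len[i]),
                   integer(1))
    expect_identical(got, want)
    # repeat-tract deletions reach the length cap
    expect_true(any(got == len))
  })
})

test_that("microhomology is invariant under deletion left-alignment", {
  withr::with_seed(17, {
    chromseq <- paste0(random_dna(500), strrep("CAG", 50), random_dna(500))
    ref <- c(chr1 = chromseq)
    # a CAG-unit deletion written at several anchors inside the repeat
    anchors <- c(520L, 523L, 526L)
    mh <- vapply(anchors, function(p) {
      row <- sprintf("chr1\t%d\t.\t%s\t%s\t.\tPASS\t.", p,
                     substring(chromseq, p, p + 3L),
                     substring(chromseq, p, p))
      rec <- read_indel_vcf(write_test_vcf(row), ref)
      compute_microhomology(rec, ref)$mh_len
    }, integer(1))
    expect_equal(length(unique(mh)), 1L)
    expect_equal(mh[1], 3L)  # unit deletion in a tandem repeat: mh = L
  })
})

test_that("burden ratios follow the counts and stay NA-safe", {
  b <- burden_summary(stub_catalogue("s1", "g", n_subs = 1000, n_del = 90,
                                     n_ins = 30))
  expect_equal(b$indel_sub_ratio, 0.12)
  expect_equal(b$del_ins_ratio, 3)

  no_ins <- burden_summary(stub_catalogue("s2", "g", n_subs = 10,
                                          n_del = 5))
  expect_true(is.na(no_ins$del_ins_ratio))
  expect_equal(no_ins$n_del, 5L)

  empty <- burden_summary(stub_catalogue("s3", "g"))
  expect_equal(empty$n_subs + empty$n_del + empty$n_ins, 0L)
  expect_true(is.na(empty$indel_sub_ratio))
})

test_that("the KS distance matches hand-enumerated ECDFs", {
  expect_equal(ks_statistic(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(ks_statistic(c(1, 1, 1), c(2, 2, 2)), 1)
  expect_equal(ks_statistic(c(1, 2, 3, 4), c(3, 4, 5, 6)), 0.5)
  expect_error(ks_statistic(numeric(0), 1), "non-empty")
  withr::with_seed(5, {
    for (i in 1:10) {
      a <- rpois(40, 4) + 1
      b <- rpois(30, 6) + 1
      expect_equal(ks_statistic(a, b), ks_statistic(b, a))
      expect_equal(ks_statistic(a, b),
                   unname(suppressWarnings(ks.test(a, b)$statistic)))
    }
  })
})

test_that("excess indel burden is measured against the naive median ratio", {
  naive <- tibble::tibble(sample_id = paste0("n", 1:3), group = "naive",
                          n_subs = 1000L, n_del = 60L, n_ins = 40L,
                          n_complex = 0L, indel_sub_ratio = 0.1,
                          del_ins_ratio = 1.5)
  exposed <- tibble::tibble(sample_id = "r1", group = "radiation",
                            n_subs = 1000L, n_del = 200L, n_ins = 100L,
                            n_complex = 0L, indel_sub_ratio = 0.3,
                            del_ins_ratio = 2)
  est <- excess_indel_estimate(exposed, naive)
  expect_equal(est$per_sample$excess, 200)
  expect_equal(est$baseline_ratio, 0.1)

  at_baseline <- dplyr::mutate(exposed, n_del = 60L, n_ins = 40L)
  expect_equal(excess_indel_estimate(at_baseline, naive)$per_sample$excess, 0)

  three <- dplyr::bind_rows(
    dplyr::mutate(exposed, sample_id = "a", n_del = 50L, n_ins = 40L),
    dplyr::mutate(exposed, sample_id = "b", n_del = 201L, n_ins = 100L),
    dplyr::mutate(exposed, sample_id = "c", n_del = 400L, n_ins = 200L))
  est3 <- excess_indel_estimate(three, naive)
  expect_equal(est3$median_excess, 201)
  expect_error(excess_indel_estimate(exposed, naive[0, ]), "empty")
})

test_that("the deletion size spectrum normalizes over its support", {
  ind <- dplyr::bind_rows(
    tibble::tibble(indel_class = "deletion", length = c(1L, 1L, 5L, 120L)),
    tibble::tibble(indel_class = "insertion", length = 2L))
  sp <- deletion_size_spectrum(ind)
  expect_equal(sum(sp$fraction), 1)
  expect_equal(sp$fraction[sp$length_bin == "1"], 0.5)
  expect_equal(sp$count[sp$length_bin == ">100"], 1L)
  expect_equal(sum(sp$count), 4L)
})

test_that("3:1 deletion odds produce higher deletion/insertion ratios than
           1:1 in nearly every seeded replicate", {
  groups <- list(
    radiation = sim_group_params(n_samples = 6, indel_sub_ratio = 0.2,
                                 del_ins_odds = 3),
    naive = sim_group_params(n_samples = 20, indel_sub_ratio = 0.1,
                             del_ins_odds = 1)
  )
  wins <- 0L
  for (r in 1:20) {
    tb <- simulate_count_table(groups, seed = 700 + r) |>
      tidyr::pivot_wider(names_from = "mutation_type",
                         values_from = "count") |>
      dplyr::group_by(group) |>
      dplyr::summarise(ratio = median(deletion / pmax(insertion, 1)))
    wins <- wins + (tb$ratio[tb$group == "radiation"] >
                      tb$ratio[tb$group == "naive"])
  }
  expect_gte(wins, 19L)
})
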