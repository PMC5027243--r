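# radsig

Genomic signatures of ionizing radiation in tumour genomes.

Tumours arising inside a prior radiotherapy field carry two mutational
imprints of the radiation that caused them, irrespective of tumour type:

1. **An excess of small deletions** (1–100 bp), frequently with
   microhomology at the breakpoint junction — the footprint of
   microhomology-mediated / non-homologous end-joining repair of
   radiation-induced double-strand breaks — and, unlike deletions in
   radiation-naive tumours, distributed *uniformly* across the genome,
   uncorrelated with replication timing, GC content, sequence complexity
   or chromatin state.
2. **An excess of balanced inversions**: reciprocal head-to-head plus
   tail-to-tail rearrangement junction pairs whose breakpoint ranges
   overlap at both ends, with no copy-number change.

`radsig` is an R toolkit for whole-genome somatic variant catalogues that
implements the complete analysis: catalogue I/O (VCF, BEDPE, BED,
bedGraph, FASTA), the balanced-inversion screen, deletion burden /
size-spectrum / microhomology metrics, mutation-density association tests
against genomic features with Benjamini–Yekutieli FDR control and a dual
significance rule (q < 0.01 **and** ≥ 5% magnitude difference),
clonal/subclonal classification from mutation copy number
(`mcn = f(ρ·CNt + 2(1−ρ))/ρ`), cohort models
(`log(count+1) ~ type × group + (1 | sample)` mixed model; Poisson count
regression with overdispersion diagnostics), and a fully seeded
synthetic-cohort generator with record-level ground truth. It is written
for cancer-genomics analysts who have per-tumour somatic variant calls
and want to quantify radiation-associated signatures or validate a
detection pipeline end to end.

## Worked example

Simulate the default two-group cohort (6 radiation-like vs 20 naive-like
tumours on a 3 × 5 Mb mini-genome), then screen, model, and test:

```r
library(radsig)
library(dplyr)

sim  <- simulate_cohort(sim_params(), seed = 11)
cats <- sim$catalogues

# deletion/insertion burdens per group
burden_summary(cats) |>
  group_by(group) |>
  summarise(median_del_ins = median(n_del / n_ins))
#> # A tibble: 2 × 2
#>   group     median_del_ins
#>   <chr>              <dbl>
#> 1 naive              0.933
#> 2 radiation          2.99

# balanced-inversion screen across the cohort
inversion_cohort_summary(cats)
#> # A tibble: 2 × 4
#>   group     n_screened n_with_inversion n_inversions
#>   <chr>          <int>            <int>        <int>
#> 1 radiation          6                6           21
#> 2 naive             20                2            2

# deletion-specific enrichment: type x group interaction
mm <- mixed_interaction_model(long_count_table(cats), group_ref = "naive")
tidy(mm)
#> # A tibble: 2 × 5
#>   term                                  estimate std_error    df  p_value
#>   <chr>                                    <dbl>     <dbl> <dbl>    <dbl>
#> 1 mutation_typedeletion:groupradiation    1.10      0.0809  48.0 4.81e-18
#> 2 mutation_typeinsertion:groupradiation  -0.0327    0.0809  48.0 6.88e- 1
```

The deletion × group estimate of 1.10 ≈ log 3 recovers the implanted 3:1
deletion:insertion odds (insertions show no enrichment), and the screen
finds balanced inversions in every radiation-like genome but almost no
naive one. Feature-association tests
(`test_feature_associations()`) flag the replication-timing covariates
for the naive group's feature-correlated deletions and nothing for the
uniformly placed radiation-like deletions; `autoplot()` methods display
size spectra, feature batteries and genome-wide probability profiles.

Real catalogues enter through `read_manifest()` + `read_cohort()` (VCF /
BEDPE / BED paths per sample), and `run_pipeline()` orchestrates
simulate/load → screen → metrics → genome distribution → clonality →
cohort report with a provenance block, writing `report.json` and
per-stage TSVs.

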