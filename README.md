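# imprecover

Can the content of an exome genotyping array be recovered by statistical
imputation from an ordinary GWAS array — and how much does a small
population-specific reference panel add on top of a cosmopolitan one?

`imprecover` is an R package that builds a fully synthetic, seeded
version of this evaluation for populations that were *not* part of an
exome chip's design. It is aimed at statistical geneticists who want a
self-contained, reproducible sandbox for studying ascertainment bias,
reference-panel composition and imputation quality metrics, with every
stage — simulation, array QC, LD-surrogate array rebuilding, haplotype-
copying imputation, and MAF-binned evaluation — implemented and tested
in one place.

## What is inside

* **Synthetic cohorts.** A founder-mosaic simulator with post-split
  drift and single-origin (infinite-sites) population-private
  mutations; exonic sites carry a purifying-selection-shifted frequency
  spectrum. Ascertainment-biased exome-style chips, evenly spaced dense
  GWAS arrays, and genotyping with error and missingness.
* **Array QC.** The three-step protocol: joint SNP filters
  (coordinates, allele conflicts, cross-array concordance < 99.5%,
  missingness > 5%, exact Hardy–Weinberg test at p < 1e-8), sample
  filters (missingness > 2%, excessive identity-by-state with the
  higher-call-rate sample retained, PCA outliers), and per-population
  SNP filters (missingness, HWE p < 0.001).
* **Legacy array rebuilding.** The hierarchical LD surrogate search:
  perfect r² in both panels, in one panel, or the best pooled r² ≥ 0.80
  within 1 Mb, with deterministic positional tie-breaks.
* **Imputation.** A Li–Stephens haplotype-copying HMM
  (forward–backward over the reference haplotypes; switch probability
  `1 − exp(−4·Ne·d_cM / (100·K))` between typed sites, mismatch
  probability θ, Ne = 15000), reference-panel merging by reciprocal
  cross-imputation, 5 Mb core / 5 Mb buffer chunking, and genotype
  calls thresholded at posterior 0.90.
* **Evaluation.** The info score
  `1 − Σ(f_i − e_i²) / (2N·θ̂(1−θ̂))`, thresholded call rate,
  well-imputed classification (info ≥ 0.3 and call rate ≥ 0.95), MAF
  bins (rare ≤ 0.01 < low-frequency < 0.05 ≤ common), overall and
  minor-allele concordance, and coverage/recoverable-content
  accounting of exonic sites.

File formats: VCF 4.x (GT and GP fields), IMPUTE-style
hap/legend/sample panels and genetic maps, TSV report tables, and a
flat key/value scenario configuration.

## A worked example

```r
library(imprecover)
report <- run_scenario(scenario_config(
  simulation = simulation_config(seed = 1)))
print(report)
```

```
evaluation report
  chip: 200 sites, 52.5% monomorphic in target
  legacy rebuild: 200/450 manifest entries recovered
  well-imputed % by array x panel x MAF bin:
  array          panel_config           bin n_sites n_covered n_well pct_well
  dense          cosmopolitan          rare      19        19     10 52.63158
  dense          cosmopolitan low_frequency      42        40     24 57.14286
  dense          cosmopolitan        common       6         5      3 50.00000
  dense cosmopolitan_specific          rare      19        19     12 63.15789
  dense cosmopolitan_specific low_frequency      42        42     24 57.14286
  dense cosmopolitan_specific        common       6         6      2 33.33333
 legacy          cosmopolitan          rare      23        23      4 17.39130
 legacy          cosmopolitan low_frequency      56        54     22 39.28571
 legacy          cosmopolitan        common       8         7      1 12.50000
 legacy cosmopolitan_specific          rare      23        23      7 30.43478
 legacy cosmopolitan_specific low_frequency      56        56     25 44.64286
 legacy cosmopolitan_specific        common       8         8      1 12.50000
```

Reading this: just over half of the 200-site exome-style chip is
monomorphic in the target population (it was ascertained in the two
other populations), and of the polymorphic off-array chip sites,
roughly half are well imputed from the dense GWAS array against the
cosmopolitan panel. The legacy rebuild recovered 200 of the 450
manifest SNPs through direct hits and LD surrogates, and imputation
from that sparser array is clearly worse.

The panel comparison quantifies what the 40-haplotype
population-specific panel adds (positive delta = improvement):

```r
compare_panel_configs(report)
```

```
                     metric               bin  config1  config2     delta
1          well_imputed_pct              rare 52.63158 63.15789  1.05e+01
8  minor_allele_discordance              rare  0.14286  0.12500  1.79e-02
9  minor_allele_discordance     low_frequency  0.41818  0.33929  7.89e-02
10 minor_allele_discordance rare_low_combined  0.38710  0.31250  7.46e-02
```

Merging the specific panel lifts rare-bin well-imputed percentage by
about 10 points and removes about 7 points of combined rare/low
minor-allele discordance — the imputation errors that matter most for
rare-variant association work.

Individual stages are exported and usable on their own:
`simulate_founders()` / `simulate_population()`,
`design_exome_chip()`, `run_qc()`, `find_surrogate()` /
`rebuild_array()`, `merge_panels()`, `impute_genotypes()` /
`threshold_calls()`, `info_score()`, `minor_allele_concordance()`, and
the readers/writers in `read_vcf()` / `write_vcf_with_gp()` /
`read_genetic_map()` / `write_report()`. A thin command-line wrapper
lives at `inst/cli/imprecover.R`. See the vignette
(`vignettes/imputing-exome-content.Rmd`) for the models, parameter
choices and known limitations.

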