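# qtlfine

Fine-mapping a quantitative trait locus (QTL) usually ends with three
questions: *which side of a recombination breakpoint carries the causal
region*, *which sequence variants in the narrowed interval track the QTL
perfectly*, and *do the candidate gene's downstream targets actually shift
in expression*. qtlfine is an R package for answering all three on tabular
data — phenotype tables from F2/recombinant crosses, called variant panels
(VCF) with a sample manifest, and normalized expression matrices with gene
sets (GMT) — plus seeded simulators that generate all three input kinds
with known planted truth, so the whole pipeline is testable end to end
without any external download. It was built around a stickleback
tooth-number QTL workflow (marine × benthic crosses narrowing a candidate
interval around a developmental signalling gene), but every stage is
generic.

The statistical core:

* **Recombinant direction test.** With diploid classes from two flanking
  markers (M = marine, B = benthic, R = recombinant haplotype), fit
  Gaussian class-mean models by maximum likelihood: FULL (each class its
  own mean), R≡M and R≡B (R-bearing classes merged with their relabelled
  counterparts). Each merge is tested against FULL with
  `2ΔlogL = n·log(RSS_merged/RSS_full) ~ χ²(Δk)`; the supported direction
  is the merge *not* rejected, reported with the p-value rejecting the
  opposite merge. Companion tools: marginal covariate screening with
  back-transformed residuals (`size_correct`), one-way genotype ANOVA with
  class means ± SE, per-benthic-chromosome effect LRTs for four-allele
  markers, and a Mendelian segregation chi-square.
* **QTL concordance screen.** After a fixed filter chain (site QUAL > 400;
  no missing/low-GQ call in a high-coverage genome; ≤ 2 bad genomes
  overall; flank matching > 6 genome locations removed), each variant is
  scored `|p_pos − p_neg|`, the absolute difference in alternate-allele
  frequency between QTL-positive and QTL-negative called chromosomes;
  score 1 = perfect concordance. A cluster report summarises the perfect
  set (count, SNP/indel split, genomic span).
* **Gene-set enrichment.** Per-gene pooled t-tests on log2(FPKM + 1) are
  mapped to signed z-scores via the probit transform `z = qnorm(pt(t, df))`
  (standard normal under the null even at n = 3 per group); each set's
  z-scores get a one-sample t-test against 0, Bonferroni correction over
  the N sets, and an empirical band from 10,000 same-size random gene
  subsets with cutoffs at the `2.5/N` and `100 − 2.5/N` percentiles. A set
  is called significant only when both criteria agree.

Results are tibbles or small S3 objects with `tidy()`/`glance()` methods
and `autoplot()` views, so everything chains with the pipe.

## Worked example

Simulate a recombinant cross whose R haplotype carries the benthic causal
allele (additive effect 2 teeth per benthic chromosome, residual SD 1.5,
length slope 1.2 teeth/mm), correct for length, assign classes, and call
the direction:

```r
library(qtlfine)

p <- cross_sim_params(200, c(RM = 52, RB = 54, MM = 50, MB = 52),
                      residual_sd = 1.5, length_slope = 1.2, seed = 42)
fish      <- simulate_cross(p)
corrected <- size_correct(fish)                      # screens length/sex/family
classes   <- assign_genotype_class(fish)
d   <- dplyr::left_join(tibble::as_tibble(corrected), classes, by = "fish_id")
lrt <- recombinant_direction_lrt(d, alpha = 0.01)
lrt
#> Recombinant direction LRT (n = 200): benthic-like
#>   R==M merge: 2*dLL = 97.915, df = 2, p = 5.47e-22
#>   R==B merge: 2*dLL = 4.931, df = 1, p = 0.0264
```

Merging R into the marine classes is overwhelmingly rejected while the
benthic merge is not, so the recombinant chromosome behaves like a benthic
one — its benthic segment contains the causal region — with p = 5.5e-22.

Screen a simulated 100 kb panel (10 perfect SNPs planted within 4.4 kb
among 120 differentiated variants, plus missingness, quality and repeat
noise) and recover the planted cluster:

```r
pp  <- variant_panel_params(interval_bp = 100000, n_differentiated = 120,
                            n_perfect = 10, cluster_span_bp = 4400,
                            missing_rate = 0.02, repeat_fraction = 0.1, seed = 42)
sim <- simulate_variant_panel(pp)
scr <- screen_variants(sim$variants, sim$calls, sim$panel, sim$genome,
                       interval = sim$truth$interval)
scr$report
#> Cluster report (score >= 1): 10 variant(s) [10 SNP, 0 indel]
#>   positions 89155..93548, span 4394 bp
setequal(scr$report$variants$variant_id, sim$truth$perfect_ids)
#> [1] TRUE
```

The screen returns exactly the ten planted SNPs, all within the requested
4.4 kb span; `scr$tally` itemises what each filter rule removed
(12 by site quality, 16 by the high-coverage rule, 3 by flank uniqueness
here). Finally, a 3-vs-3 expression matrix with one gene set shifted down
1 log2 unit:

```r
es  <- simulate_expression(expr_sim_params(
  n_genes = 1000, noise_sd = 0.5,
  baseline_law = list(dist = "normal", mean = 6, sd = 1),
  sets = list(list(name = "bmp_targets", size = 50, shift = -1),
              list(name = "control_set", size = 50, shift = 0)), seed = 42))
res <- evaluate_gene_sets(es$expr, es$groups, es$sets, n_perm = 10000, seed = 42)
tibble::as_tibble(res)[, c("set", "mean_z", "t_statistic", "bonferroni_p", "significant", "direction")]
#>   set         mean_z  t_statistic bonferroni_p significant direction
#> 1 bmp_targets -1.97        -21.1      6.35e-26 TRUE        down
#> 2 control_set -0.0724      -0.542     1                FALSE down
```

The shifted set is flagged significant and down (its t statistic far
outside the permutation band, Bonferroni p = 6e-26); the null set is not.

File-based workflows (`read_vcf`, `read_phenotypes`, `read_gmt`,
`write_vcf`, ...) and a one-shot orchestrator (`run_pipeline`) with a
reproducibility manifest are documented in the function reference; the
methods vignette (`vignettes/fine-mapping-methods.Rmd`) records the models,
parameter defaults and design decisions.

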