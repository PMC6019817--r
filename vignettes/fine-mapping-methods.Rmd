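---
title: "Methods: recombinant fine-mapping, variant concordance, and gene-set enrichment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: recombinant fine-mapping, variant concordance, and gene-set enrichment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

qtlfine implements three linked analyses used to narrow a quantitative
trait locus (QTL) to a candidate haplotype: (1) covariate-corrected
phenotyping of F2 and recombinant crosses with likelihood-ratio tests on
merged genotype-class linear models, (2) a filtered variant concordance
screen over the fine-mapped interval, and (3) gene-set enrichment on a
two-group expression matrix with a permutation-calibrated null. A fourth
module simulates all three input kinds with known planted truth, so every
stage can be validated end to end without external data. This vignette
records the statistical models, the tunable parameters, and the design
choices made where the methods were genuinely open.

## Cross phenotyping and the direction test

**Size correction.** Tooth number in sticklebacks scales with body size, and
sex and family can contribute too. `size_correct()` screens each candidate
covariate (standard length in mm, sex, family) marginally at level `alpha`
(default 0.05, per-covariate F-test); the significant ones enter one joint
linear model. Corrected phenotypes are the residuals back-transformed to the
cross mean standard length: residuals plus the population-averaged model
prediction at the reference length. Averaging factor effects over the
observed sample (rather than fixing a baseline level) makes the identity
`mean(corrected) == mean(raw)` exact, so corrected values stay on the
original tooth-count scale; the convention and the reference length are
recorded in the result's metadata. Covariates that cannot be tested (one
sex, one family, constant length) are skipped with a note; a constant
response returns uncorrected values with a warning. Sex and family are
fixed effects throughout — with family counts this small a random-effect
fit would be poorly identified, and fixed effects match the per-cross
correction style of the study design.

**Genotype classes.** Two flanking markers define phased two-locus
haplotypes. A haplotype is scored M (marine allele at both markers), B
(benthic at both), or R when it matches the cross-specific recombinant
haplotype (by default marine-left / benthic-right). Diploid classes are
canonical ordered pairs (R before M before B): MM, MB, BB, RM, RB, RR.
Combinations inconsistent with the cross design are returned flagged with a
reason, never silently dropped.

**ANOVA.** `genotype_anova()` is a fixed-effects one-way ANOVA of the
corrected phenotype on class, reporting F, degrees of freedom, p, and the
per-class means with standard errors (pooled residual SD over sqrt(n)) —
the quantities a cross summary figure plots.

**Direction test.** Whether a recombinant chromosome behaves like a marine
or a benthic chromosome is decided by likelihood ratio. Three Gaussian
class-mean models are fit by maximum likelihood (MLE variance, so
`2*dLL = n log(RSS_reduced/RSS_full)`): FULL, with every class its own
mean; R==M, with each R-bearing class merged with its R-relabelled-as-M
counterpart; and R==B likewise. The two merged models are not nested in one
another, so each is tested against FULL (which nests both), with df equal
to the class levels lost in the merge. The supported direction is the merge
that is *not* rejected; the reported p-value is the rejection of the
opposite merge, and if both or neither merge is rejected the call is
`indeterminate` with both p-values reported. The same FULL-model anchoring
is used for the per-benthic-chromosome test below; it is what makes the
statistics non-negative and chi-square calibrated.

**Per-benthic-chromosome test.** In crosses where a four-allele marker
distinguishes the two wild benthic chromosomes, the encompassing model
gives each benthic chromosome its own additive per-copy effect
(`y = mu + d1*n1 + d2*n2`). The test for chromosome i compares FULL against
the nested restriction `d_i = 0` with the other effect free (df = 1). The
alternative phrasing — equal-effect additive model versus
chromosome-i-has-no-effect — compares two non-nested models of equal
dimension, whose log-likelihood difference is not chi-square and can be
negative; anchoring on FULL restores a calibrated test while the
equal-effect model's log-likelihood is kept in the output for audit. When
the benthic chromosomes cannot be distinguished molecularly the result is
NA with a reason.

**Mendelian ratios.** `mendelian_ratio_test()` is the Pearson
goodness-of-fit chi-square of observed genotype-class counts against an
expected segregation ratio (1:2:1 intercross, 1:1 backcross), df =
classes − 1; deviations flag differential mortality.

## The variant concordance screen

The screen consumes a called VCF (sites + per-sample GT/GQ), a sample
manifest assigning each sample a QTL status (`QTL_pos`/`QTL_neg`) and a
coverage class (`high`/`low`), and optionally a genome for the
flank-uniqueness rule. Upstream alignment and calling are out of scope.

**Filter chain**, applied in fixed order with a per-rule removal tally:

1. site quality strictly greater than 400 (`min_site_quality`; QUAL exactly
   400 fails);
2. no high-coverage sample missing or with genotype quality below 10
   (`min_genotype_quality`);
3. at most 2 samples in total missing or below the GQ threshold
   (`max_bad_genomes`) — the "no more than two genomes" rule read as a cap
   on bad genomes;
4. flank uniqueness: a variant is removed when its flanking sequence
   (100 bp each side) matches strictly more than 6 places in the genome
   (`max_genome_matches`; 6 matches retained, 7 removed).

Calls without a GQ pass rule 2 and 3 (the rules target calls positively
known to be low-confidence); this is logged. The built-in flank matcher
counts exact occurrences of the concatenated 200 bp flank — the identity-1
special case of the ≥99%-identity criterion, and exact ground truth for the
simulator's literal copy-paste repeats. A similarity-search matcher
honouring an e-value ceiling can be plugged in via the `matcher` argument.
Flanks truncated at a sequence end are logged and matched over the
available length. Coordinates are 1-based inclusive everywhere; only the
BED writer converts to 0-based half-open, at write time.

**Concordance score.** For each variant,
`score = |p_pos − p_neg|` where `p` is the proportion of called
chromosomes carrying the alternate allele in each group (hom-alt = 2/2,
het = 1/2; missing calls excluded from denominators). Counting per
chromosome rather than per fish is the better-defined reading when
heterozygotes occur; the two coincide for homozygous panels, and
`per_fish = TRUE` switches to carrier counting. A variant with no called
samples in one group is flagged NA, never scored 0. A score of 1 is
perfect concordance; `perfect_cluster_report()` summarises the qualifying
variants' count, SNP/indel split, and positional span
(`max_pos − min_pos + 1`).

## Gene-set enrichment

**Per-gene z-scores.** Each gene gets a two-sample t-test (mutant vs
wild-type) on `log2(FPKM + 1)`; the pseudocount is configurable and the
pooled-variance (Student) test is the default at n = 3 per group, with
Welch switchable. The signed z is the probit transform of the t cumulative
probability, `z = qnorm(pt(t, df))` — exactly standard normal under the
null even at tiny n, monotone in t, sign = direction (positive = higher in
mutant); the raw t is retained. Genes with mean FPKM below 1 across all
samples (`expression_floor`) or zero variance in both groups are excluded
with reasons. The transform, pseudocount and floor are choices this package
fixes and exposes; none is dictated by the method's source material.

**Set statistic and null.** Each set's z-scores are tested against mean 0
with a one-sample t-test (two-sided). Two significance criteria are
combined: a Bonferroni-corrected p (N = number of sets) below `alpha`, and
the observed t falling outside an empirical band from 10,000 (default)
random same-size gene subsets drawn without replacement from all scored
genes — the permutation pool is the post-floor background, so observed and
null statistics see the same gene universe. Band cutoffs sit at the
`2.5/N` and `100 − 2.5/N` percentiles (linear interpolation between order
statistics, R quantile type 7). A set is significant only if both criteria
agree; both are always reported, with direction from the sign of the mean
z. Degenerate sets (fewer than two scored members, zero-variance z) return
NA rows with reasons, and a zero-variance set is given p = 1 by convention.

## The simulators and what they do (and do not) emulate

All generators are pure functions of (params, seed); each internal
component draws from its own deterministically derived sub-stream, so
adding a component later does not perturb earlier draws.

**Crosses** (`simulate_cross`): diploid classes drawn uniformly from the
design's Punnett classes; tooth number = class mean + length slope ×
(length − mean length) + sex/family offsets + Gaussian noise. Tooth counts
are rounded to integers by default (fish have whole teeth);
`integer_counts = FALSE` keeps the continuous latent trait, which is what
the calibration simulations use so that p-value uniformity is exact.

**Variant panels** (`simulate_variant_panel`): the planted perfect variants
are the clean signal — alt-homozygous in every QTL-positive sample,
ref-homozygous in every QTL-negative one, clustered within
`cluster_span_bp`, generated with high site/genotype qualities, no missing
calls and unique flanks. All noise lands on the background variants: each
gets `1 + Binomial(n_samples − 1, flip_rate)` discordant calls (at least
one, so no background variant is accidentally perfect — a plain
independent-flip scheme would leave about `0.85^10 ≈ 20%` of them
untouched), then missingness, genotype-quality draws, site-quality draws,
and, for a `repeat_fraction` of them, literal copy-pastes of their 200 bp
flank into the genome margin beyond the interval (7 copies, one more than
the filter's ceiling). Discordant calls are exempt from the missingness
mask; otherwise a variant whose only discordant call went missing would
drift back to perfect concordance and exact planted recovery would be
ill-posed. The toy genome is uniform-random nucleotides, so flank identity
is exact-match by construction.

**Expression** (`simulate_expression`): per-gene baseline log2 abundances
(default Normal(4, 2)), i.i.d. Gaussian measurement noise in log2 space,
exponentiated to a non-negative FPKM-like scale; designated sets get a
constant log2 shift in the mutant group; n = 3 per group by default,
matching the emulated design. Count-level machinery (library size,
dispersion, length bias) is deliberately not simulated: the pipeline
consumes normalized values, so log-normal noise is the right level of
abstraction. Consequently, passing tests demonstrate correctness of the
statistics on normalized data, not robustness to quantification artefacts.

The cross simulator likewise does not model linkage, genotyping error, or
selection; the panel simulator does not model reads, local haplotype
structure, or indel realignment noise. Tests passing on these simulations
validate the computations, not the upstream data generation of a real
study.

## Numerical choices and simulation sizes

* LRT statistics are clamped at 0 against floating-point drift; Gaussian
  log-likelihoods use the MLE variance.
* Probit z-scores are capped at |z| = 38 where `qnorm` saturates.
* Permutation cutoffs use linear interpolation (quantile type 7).
* Ties in class canonicalisation are broken by the fixed allele order R, M,
  B.
* Calibration checks run 500 replicates (n = 120–150 fish) and compare
  p-values to Uniform(0,1) and statistics to their chi-square reference by
  Kolmogorov–Smirnov test at 0.01; set-statistic calibration uses 1,000
  random sets over 2,000 scored genes. Power checks run 100 replicates at
  the stated effect sizes (benthic effect 2 teeth per chromosome, residual
  SD 1, n = 150; expression shift −1 log2 unit, set size 50, noise 0.5
  log2). The all-null family-wise-error simulation uses 400 replicates of
  400 genes, three 25-gene sets and 400 permutations per set. In the power
  protocol the direction call uses alpha = 0.01, the same rejection level
  that defines a successful call. These sizes are the package's own
  simulation-design choices, balancing Monte Carlo error against runtime.
* The interval-scale recovery check plants 10 perfect SNPs within 4.4 kb
  among 372 differentiated variants over an 884 kb interval screened by 7
  QTL-positive (2 high-coverage) and 3 QTL-negative samples, with 2%
  missingness and 10% repeat flanks — the screen must return exactly the
  planted ten.

## Known limitations

* Tooth counts are modelled as continuous Gaussian; no count-likelihood
  (Poisson/negative-binomial) option in this version.
* The direction test reports `indeterminate` whenever zero or two merges
  are rejected; it does not attempt a non-nested model comparison (e.g.
  Vuong) between the two merges.
* The flank filter's built-in matcher is exact-match only; diverged repeats
  below 100% identity require plugging in a similarity-search matcher.
* Family effects are fixed, not random; crosses with many small families
  may prefer a mixed model.
* The enrichment stage assumes sets are evaluated against the same
  expression matrix; cross-platform set transfer is out of scope.
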