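#' Parameters for a simulated variant panel
#'
#' Describes a resequencing panel over a fine-mapped interval: a planted
#' cluster of perfectly QTL-concordant SNPs, a background of imperfectly
#' differentiated variants, per-call missingness and genotype-quality noise,
#' site-quality noise, and a configurable fraction of variants whose flanking
#' sequence recurs in the toy genome (repeat-like loci).
#'
#' The planted perfect variants are the clean signal: they are generated with
#' high site and genotype qualities, no missing calls, and unique flanks, so
#' the screen's exact-recovery behaviour is well defined. All noise
#' (missingness, sub-threshold qualities, repeat flanks, discordant calls) is
#' applied to the non-planted variants.
#'
#' @param interval_bp Length of the fine-mapped interval in bp; variants are
#'   placed inside `[flank_bp + 1, interval_bp - flank_bp]`.
#' @param n_differentiated Total number of group-differentiated variants.
#' @param n_perfect Number of planted perfectly concordant SNPs
#'   (`<= n_differentiated`).
#' @param cluster_span_bp Maximum span (bp, inclusive of both endpoints) of
#'   the planted cluster; must be `<= interval_bp`.
#' @param n_qtl_pos,n_qtl_neg Numbers of QTL-positive / QTL-negative samples.
#' @param n_high_coverage How many QTL-positive samples are labelled
#'   high-coverage (`<= n_qtl_pos + n_qtl_neg`).
#' @param missing_rate Per-call probability a non-planted call is missing.
#' @param site_quality_law Distribution spec (see details in
#'   [simulate_variant_panel()]) for site QUAL values.
#' @param gq_law Distribution spec for per-call genotype qualities.
#' @param repeat_fraction Probability a non-planted variant's flank is
#'   copy-pasted into the genome more than `repeat_copies` - 1 extra times.
#' @param repeat_copies Number of pasted copies for a repeat variant (default
#'   7, one more than the screen's default uniqueness ceiling).
#' @param flip_rate Per-sample discordance intensity for non-planted
#'   variants; each such variant receives `1 + Binomial(n_samples - 1,
#'   flip_rate)` discordant calls so that no background variant is
#'   accidentally perfect.
#' @param indel_fraction Fraction of non-planted variants simulated as 1 bp
#'   insertions rather than SNPs.
#' @param flank_bp Flank length used when planting repeats (default 100).
#' @param genome_bp Toy genome length; `NULL` (default) sizes it to the
#'   interval plus the margin needed to host the pasted repeat copies.
#' @param seed Integer seed.
#' @return A validated `variant_panel_params` list.
#' @export
variant_panel_params <- function(interval_bp = 884000,
                                 n_differentiated = 372,
                                 n_perfect = 10,
                                 cluster_span_bp = 4400,
                                 n_qtl_pos = 7,
                                 n_qtl_neg = 3,
                                 n_high_coverage = 2,
                                 missing_rate = 0.02,
                                 site_quality_law = list(dist = "uniform", min = 100, max = 3000),
                                 gq_law = list(dist = "uniform", min = 5, max = 99),
                                 repeat_fraction = 0.1,
                                 repeat_copies = 7,
                                 flip_rate = 0.15,
                                 indel_fraction = 49 / 372,
                                 flank_bp = 100,
                                 genome_bp = NULL,
                                 seed = 1L) {
  p <- list(
    interval_bp = check_count(interval_bp, "interval_bp", min = 1L),
    n_differentiated = check_count(n_differentiated, "n_differentiated", min = 1L),
    n_perfect = check_count(n_perfect, "n_perfect", min = 0L),
    cluster_span_bp = check_count(cluster_span_bp, "cluster_span_bp", min = 1L),
    n_qtl_pos = check_count(n_qtl_pos, "n_qtl_pos", min = 1L),
    n_qtl_neg = check_count(n_qtl_neg, "n_qtl_neg", min = 1L),
    n_high_coverage = check_count(n_high_coverage, "n_high_coverage", min = 0L),
    missing_rate = check_prob(missing_rate, "missing_rate"),
    site_quality_law = site_quality_law,
    gq_law = gq_law,
    repeat_fraction = check_prob(repeat_fraction, "repeat_fraction"),
    repeat_copies = check_count(repeat_copies, "repeat_copies", min = 1L),
    flip_rate = check_prob(flip_rate, "flip_rate"),
    indel_fraction = check_prob(indel_fraction, "indel_fraction"),
    flank_bp = check_count(flank_bp, "flank_bp", min = 1L),
    genome_bp = if (!is.null(genome_bp)) check_count(genome_bp, "genome_bp", min = 1L),
    seed = check_count(seed, "seed")
  )
  if (p$n_perfect > p$n_differentiated) {
    abort("`n_perfect` must not exceed `n_differentiated` (configuration error).")
  }
  if (p$cluster_span_bp > p$interval_bp) {
    abort("`cluster_span_bp` exceeds `interval_bp` (configuration error).")
  }
  if (p$n_high_coverage > p$n_qtl_pos + p$n_qtl_neg) {
    abort("`n_high_coverage` exceeds the number of samples (configuration error).")
  }
  if (p$interval_bp < 2 * p$flank_bp + p$n_differentiated) {
    abort("Interval too short to place the requested variants with full flanks.")
  }
  structure(p, class = "variant_panel_params")
}

#' Simulate a variant panel over a toy genome with planted truth
#'
#' Builds a uniform-random nucleotide toy genome, places
#' `n_differentiated` biallelic variants in the interval, plants `n_perfect`
#' of them as perfectly concordant SNPs clustered within `cluster_span_bp`,
#' gives every other variant at least one discordant call, and layers on
#' missingness, genotype-quality noise, site-quality noise and repeat flanks
#' according to the parameters. Repeat flanks are literal copy-pastes of a
#' variant's concatenated 2 x `flank_bp` flanking sequence into the genome
#' margin beyond the interval, so exact-substring matching is ground truth
#' at generation time.
#'
#' Distribution specs (`site_quality_law`, `gq_law`) are either a
#' `function(n)` or a list such as `list(dist = "uniform", min = , max = )`
#' (`"normal"`, `"exponential"` and `"lognormal"` are also understood).
#'
#' @param params A [variant_panel_params()] object.
#' @return A list with
#'   * `variants`: tibble of sites (`variant_id`, `chrom`, `pos`, `ref`,
#'     `alt`, `site_quality`, `variant_class`),
#'   * `calls`: long tibble of per-sample calls (`variant_id`, `sample_id`,
#'     `gt` in `hom_ref`/`het`/`hom_alt`/`missing`, `gq`),
#'   * `panel`: sample manifest tibble (`sample_id`, `qtl_status`,
#'     `coverage`),
#'   * `genome`: a [Biostrings::DNAStringSet] with one toy chromosome,
#'   * `truth`: list with `perfect_ids`, `repeat_ids`, `cluster_span_bp`.
#' @examples
#' pp <- variant_panel_params(interval_bp = 20000, n_differentiated = 30,
#'                            n_perfect = 4, cluster_span_bp = 1000, seed = 7)
#' sim <- simulate_variant_panel(pp)
#' sim$variants
#' @export
simulate_variant_panel <- function(params) {
  stopifnot(inherits(params, "variant_panel_params"))
  p <- params
  chrom <- "chr_toy"
  n <- p$n_differentiated
  n_samples <- p$n_qtl_pos + p$n_qtl_neg

  # Sample manifest: high-coverage labels go to QTL-positive samples first
  # (the deeply sequenced genomes in the design are QTL carriers).
  panel <- tibble::tibble(
    sample_id = c(sprintf("pos_%02d", seq_len(p$n_qtl_pos)),
                  sprintf("neg_%02d", seq_len(p$n_qtl_neg))),
    qtl_status = rep(c("QTL_pos", "QTL_neg"), c(p$n_qtl_pos, p$n_qtl_neg))
  )
  panel$coverage <- ifelse(seq_len(n_samples) <= p$n_high_coverage, "high", "low")

  # Repeat assignment first so the genome can be sized to fit the pastes.
  repeat_flag_bg <- with_stream(p$seed, 10L,
                                runif(n - p$n_perfect) < p$repeat_fraction)
  n_repeat <- sum(repeat_flag_bg)
  slot <- 2L * p$flank_bp
  margin_needed <- n_repeat * p$repeat_copies * slot + slot
  genome_bp <- p$genome_bp %||% (p$interval_bp + max(10000L, margin_needed))
  if (genome_bp < p$interval_bp + margin_needed) {
    abort(sprintf("`genome_bp` = %d too small to host %d repeat copies beyond the interval.",
                  genome_bp, n_repeat * p$repeat_copies))
  }
  genome_chars <- with_stream(p$seed, 11L,
                              sample(c("A", "C", "G", "T"), genome_bp, replace = TRUE))

  # Positions: planted cluster inside a window of cluster_span_bp, background
  # anywhere in the interval with full flanks; all positions distinct.
  lo <- p$flank_bp + 1L
  hi <- p$interval_bp - p$flank_bp
  pos_all <- with_stream(p$seed, 12L, {
    win_max <- min(p$cluster_span_bp, hi - lo + 1L)
    start <- sample(lo:(hi - win_max + 1L), 1L)
    perfect_pos <- sort(sample(start:(start + win_max - 1L), p$n_perfect))
    bg_pool <- setdiff(lo:hi, perfect_pos)
    bg_pos <- sort(sample(bg_pool, n - p$n_perfect))
    list(perfect = perfect_pos, background = bg_pos)
  })
  pos <- c(pos_all$perfect, pos_all$background)
  is_perfect <- rep(c(TRUE, FALSE), c(p$n_perfect, n - p$n_perfect))
  is_repeat <- c(rep(FALSE, p$n_perfect), repeat_flag_bg)

  # Alleles: ref is the genome base; planted variants are SNPs, background
  # variants are SNPs or 1 bp insertions.
  alleles <- with_stream(p$seed, 13L, {
    ref_base <- genome_chars[pos]
    alt <- vapply(ref_base, function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1L),
                  "", USE.NAMES = FALSE)
    ins <- !is_perfect & (runif(n) < p$indel_fraction)
    alt[ins] <- paste0(ref_base[ins],
                       sample(c("A", "C", "G", "T"), sum(ins), replace = TRUE))
    list(ref = ref_base, alt = alt)
  })

  site_quality <- with_stream(p$seed, 14L, draw_law(p$site_quality_law, n))
  site_quality[is_perfect] <- pmax(site_quality[is_perfect], 1000)

  # Genotype matrix (variants x samples), starting from the perfectly
  # differentiated pattern: alt-homozygous in QTL_pos, ref-homozygous in
  # QTL_neg.
  gt <- matrix(rep(ifelse(panel$qtl_status == "QTL_pos", "hom_alt", "hom_ref"),
                   each = n),
               nrow = n, dimnames = list(NULL, panel$sample_id))
  flip_mask <- matrix(FALSE, n, n_samples)
  gt <- with_stream(p$seed, 15L, {
    for (i in which(!is_perfect)) {
      k <- 1L + rbinom(1L, n_samples - 1L, p$flip_rate)
      idx <- sample(n_samples, k)
      flip_mask[i, idx] <- TRUE
      gt[i, idx] <- vapply(gt[i, idx], function(g) {
        sample(setdiff(c("hom_ref", "het", "hom_alt"), g), 1L)
      }, "")
    }
    gt
  })
  gt <- with_stream(p$seed, 16L, {
    miss <- matrix(runif(n * n_samples) < p$missing_rate, nrow = n)
    miss[is_perfect, ] <- FALSE
    # discordant calls stay observed, so no background variant can drift to
    # perfect concordance through missingness alone
    miss[flip_mask] <- FALSE
    gt[miss] <- "missing"
    gt
  })
  gq <- with_stream(p$seed, 17L, {
    q <- matrix(draw_law(p$gq_law, n * n_samples), nrow = n)
    q[is_perfect, ] <- 99
    round(q, 1)
  })

  # Paste repeat flanks into the margin beyond the interval.
  if (n_repeat > 0) {
    rep_idx <- which(is_repeat)
    slots <- with_stream(p$seed, 18L, {
      starts <- p$interval_bp + slot +
        (seq_len(n_repeat * p$repeat_copies) - 1L) * slot
      sample(starts)
    })
    s <- 1L
    for (i in rep_idx) {
      fl <- c(genome_chars[(pos[i] - p$flank_bp):(pos[i] - 1L)],
              genome_chars[(pos[i] + 1L):(pos[i] + p$flank_bp)])
      for (k in seq_len(p$repeat_copies)) {
        genome_chars[slots[s]:(slots[s] + slot - 1L)] <- fl
        s <- s + 1L
      }
    }
  }

  variant_id <- sprintf("%s:%d_%s/%s", chrom, pos, alleles$ref, alleles$alt)
  variants <- tibble::tibble(
    variant_id = variant_id,
    chrom = chrom,
    pos = as.integer(pos),
    ref = alleles$ref,
    alt = alleles$alt,
    site_quality = round(site_quality, 2),
    variant_class = ifelse(nchar(alleles$ref) == 1 & nchar(alleles$alt) == 1,
                           "SNP", "indel")
  ) |> dplyr::arrange(pos)

  calls <- tibble::tibble(
    variant_id = rep(variant_id, times = n_samples),
    sample_id = rep(panel$sample_id, each = n),
    gt = as.vector(gt),
    gq = as.vector(gq)
  ) |> dplyr::arrange(match(variant_id, variants$variant_id), sample_id)

  genome <- Biostrings::DNAStringSet(paste(genome_chars, collapse = ""))
  names(genome) <- chrom

  list(
    variants = variants,
    calls = calls,
    panel = panel,
    genome = genome,
    truth = list(
      perfect_ids = variant_id[is_perfect],
      repeat_ids = variant_id[is_repeat],
      cluster_span_bp = if (p$n_perfect >= 2) {
        as.integer(diff(range(pos[is_perfect])) + 1L)
      } else {
        NA_integer_
      },
      interval = c(start = 1L, end = p$interval_bp)
    )
  )
}
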