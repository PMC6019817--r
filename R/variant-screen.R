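#' Default thresholds for the variant quality filter chain
#'
#' @param min_site_quality Site QUAL must be strictly greater than this
#'   (default 400).
#' @param min_genotype_quality Per-call GQ below this counts the call as bad
#'   (default 10).
#' @param max_bad_genomes Maximum number of samples allowed to be missing or
#'   below `min_genotype_quality` (default 2).
#' @param flank_bp Flank length per side for the uniqueness rule (default
#'   100).
#' @param max_genome_matches A variant is removed when its flank matches
#'   strictly more than this many genome locations (default 6).
#' @param flank_identity Fraction of the flank that must match for a hit to
#'   count (default 0.99; the built-in exact matcher operates at identity 1).
#' @param evalue_ceiling E-value ceiling honoured by an external
#'   similarity-search matcher, if one is plugged in (default 1e-30).
#' @return A `filter_thresholds` list.
#' @export
filter_thresholds <- function(min_site_quality = 400,
                              min_genotype_quality = 10,
                              max_bad_genomes = 2,
                              flank_bp = 100,
                              max_genome_matches = 6,
                              flank_identity = 0.99,
                              evalue_ceiling = 1e-30) {
  structure(
    list(
      min_site_quality = check_number(min_site_quality, "min_site_quality"),
      min_genotype_quality = check_number(min_genotype_quality, "min_genotype_quality"),
      max_bad_genomes = check_count(max_bad_genomes, "max_bad_genomes"),
      flank_bp = check_count(flank_bp, "flank_bp", min = 1L),
      max_genome_matches = check_count(max_genome_matches, "max_genome_matches"),
      flank_identity = check_prob(flank_identity, "flank_identity"),
      evalue_ceiling = check_number(evalue_ceiling, "evalue_ceiling", min = 0)
    ),
    class = "filter_thresholds"
  )
}

# Per-variant count of bad calls (missing or GQ below threshold), split by
# coverage class. Absent GQ passes (the rule targets calls positively known
# to be low-confidence); this is noted once per run.
bad_call_summary <- function(calls, panel, min_gq) {
  missing_panel <- setdiff(unique(calls$sample_id), panel$sample_id)
  if (length(missing_panel) > 0) {
    abort(sprintf("Sample(s) in the variant calls absent from the panel manifest: %s",
                  paste(missing_panel, collapse = ", ")))
  }
  if (anyNA(calls$gq)) {
    inform("Calls without a genotype quality are treated as passing the GQ rule.")
  }
  calls |>
    dplyr::left_join(panel, by = "sample_id") |>
    dplyr::mutate(bad = gt == "missing" | (!is.na(gq) & gq < min_gq)) |>
    dplyr::group_by(variant_id) |>
    dplyr::summarise(
      n_bad = sum(bad),
      n_bad_high = sum(bad & coverage == "high"),
      .groups = "drop"
    )
}

#' Quality-filter a variant panel
#'
#' Applies the screen's quality rules in fixed order and tallies removals per
#' rule: (1) site quality strictly greater than `min_site_quality`; (2) no
#' high-coverage sample may be missing or have genotype quality below
#' `min_genotype_quality`; (3) at most `max_bad_genomes` samples in total may
#' be missing or below the genotype-quality threshold. Each rule only ever
#' removes variants, so the tally sums to input minus output.
#'
#' @param variants Site tibble (`variant_id`, `site_quality`, ...).
#' @param calls Long per-sample call tibble (`variant_id`, `sample_id`, `gt`,
#'   `gq`).
#' @param panel Sample manifest tibble (`sample_id`, `qtl_status`,
#'   `coverage`).
#' @param thresholds A [filter_thresholds()] object.
#' @return List with `variants` (retained sites) and `tally` (tibble `rule`,
#'   `n_removed`, in application order).
#' @export
filter_variants <- function(variants, calls, panel,
                            thresholds = filter_thresholds()) {
  stopifnot(is.data.frame(variants), is.data.frame(calls), is.data.frame(panel))
  th <- thresholds
  bad <- bad_call_summary(calls, panel, th$min_genotype_quality)
  v <- dplyr::left_join(variants, bad, by = "variant_id") |>
    dplyr::mutate(
      n_bad = dplyr::coalesce(n_bad, 0L),
      n_bad_high = dplyr::coalesce(n_bad_high, 0L)
    )

  tally <- tibble::tibble(rule = character(0), n_removed = integer(0))
  apply_rule <- function(v, keep, rule) {
    tally <<- dplyr::bind_rows(tally,
                               tibble::tibble(rule = rule,
                                              n_removed = sum(!keep)))
    v[keep, , drop = FALSE]
  }

  v <- apply_rule(v, v$site_quality > th$min_site_quality, "site_quality")
  v <- apply_rule(v, v$n_bad_high == 0, "high_coverage_calls")
  v <- apply_rule(v, v$n_bad <= th$max_bad_genomes, "missingness_count")

  list(
    variants = dplyr::select(v, -n_bad, -n_bad_high),
    tally = tally
  )
}

# Extract a variant's concatenated flanking sequence (left then right,
# excluding the variant base), truncating at sequence ends.
variant_flank <- function(genome, chrom, pos, flank_bp) {
  seq <- genome[[chrom]]
  len <- length(seq)
  left <- Biostrings::subseq(seq, max(1L, pos - flank_bp), max(1L, pos - 1L))
  if (pos == 1L) left <- Biostrings::subseq(seq, 1L, 0L)
  right_end <- min(len, pos + flank_bp)
  right <- if (pos < len) Biostrings::subseq(seq, pos + 1L, right_end) else Biostrings::subseq(seq, 1L, 0L)
  truncated <- (pos - flank_bp < 1L) || (pos + flank_bp > len)
  list(seq = Biostrings::xscat(left, right), truncated = truncated)
}

#' Remove variants whose flanking sequence recurs in the genome
#'
#' A variant is removed when its flanking sequence (100 bp each side by
#' default) matches strictly more than `max_genome_matches` locations in the
#' genome — a repeat-like locus whose calls are untrustworthy. The matcher is
#' pluggable: the built-in one counts exact occurrences of the concatenated
#' 2 x `flank_bp` flank (the identity-1 special case of the >= 99%-identity
#' rule); a custom `matcher(flank_seq, genome, thresholds)` returning a match
#' count can implement similarity search with an e-value ceiling instead.
#'
#' Flanks running off a sequence end are truncated (and logged); identity is
#' then computed over the available length.
#'
#' @param variants Site tibble with `chrom` and `pos` (1-based).
#' @param genome A [Biostrings::DNAStringSet] covering the variants' chroms.
#' @param thresholds A [filter_thresholds()] object.
#' @param matcher Optional `function(flank_seq, genome, thresholds)`
#'   returning the number of genome locations matched.
#' @return List with `variants` (retained), `n_removed`, and `match_counts`
#'   (integer vector aligned with the input variants).
#' @export
flank_uniqueness_filter <- function(variants, genome,
                                    thresholds = filter_thresholds(),
                                    matcher = NULL) {
  stopifnot(is.data.frame(variants), inherits(genome, "DNAStringSet"))
  th <- thresholds
  missing_chrom <- setdiff(unique(variants$chrom), names(genome))
  if (length(missing_chrom) > 0) {
    abort(sprintf("Genome lacks sequence(s): %s", paste(missing_chrom, collapse = ", ")))
  }
  matcher <- matcher %||% exact_flank_matcher
  n <- nrow(variants)
  counts <- integer(n)
  n_truncated <- 0L
  for (i in seq_len(n)) {
    fl <- variant_flank(genome, variants$chrom[i], variants$pos[i], th$flank_bp)
    if (fl$truncated) n_truncated <- n_truncated + 1L
    counts[i] <- matcher(fl$seq, genome, th)
  }
  if (n_truncated > 0) {
    inform(sprintf("%d variant flank(s) truncated at a sequence end.", n_truncated))
  }
  keep <- counts <= th$max_genome_matches
  list(
    variants = variants[keep, , drop = FALSE],
    n_removed = sum(!keep),
    match_counts = counts
  )
}

# Built-in matcher: exact occurrences of the concatenated flank across all
# genome sequences (forward strand).
exact_flank_matcher <- function(flank_seq, genome, thresholds) {
  if (length(flank_seq) == 0) return(0L)
  sum(vapply(seq_along(genome), function(i) {
    Biostrings::countPattern(flank_seq, genome[[i]])
  }, 0L))
}

#' QTL concordance scores for a variant panel
#'
#' For each variant, computes the proportion of called chromosomes carrying
#' the alternate allele in the QTL-positive and QTL-negative sample groups
#' (a homozygous-alt fish contributes 2/2 chromosomes, a het 1/2; missing
#' calls are excluded from the denominators) and scores the variant by the
#' absolute difference: `score = |p_pos - p_neg|`, 1 meaning perfect
#' concordance between genotype and QTL status. With `per_fish = TRUE` the
#' proportion is instead the fraction of called fish carrying at least one
#' alternate allele; the two readings coincide when samples are homozygous.
#'
#' A variant with no called samples in one group gets `score = NA` and
#' `undefined = TRUE` — flagged, never silently 0.
#'
#' @param variants Site tibble (`variant_id` plus site columns, carried
#'   through).
#' @param calls Long call tibble (`variant_id`, `sample_id`, `gt`).
#' @param panel Sample manifest (`sample_id`, `qtl_status`).
#' @param per_fish Count allele presence per fish instead of per chromosome
#'   (default `FALSE`).
#' @return Tibble: the site columns plus `p_pos`, `p_neg`, `n_called_pos`,
#'   `n_called_neg`, `score`, `undefined`.
#' @export
concordance_scores <- function(variants, calls, panel, per_fish = FALSE) {
  stopifnot(is.data.frame(variants), is.data.frame(calls), is.data.frame(panel))
  missing_panel <- setdiff(unique(calls$sample_id), panel$sample_id)
  if (length(missing_panel) > 0) {
    abort(sprintf("Sample(s) absent from the panel manifest: %s",
                  paste(missing_panel, collapse = ", ")))
  }
  allele_weight <- c(hom_ref = 0, het = 0.5, hom_alt = 1)
  carrier <- c(hom_ref = 0, het = 1, hom_alt = 1)

  props <- calls |>
    dplyr::filter(variant_id %in% variants$variant_id) |>
    dplyr::left_join(dplyr::select(panel, sample_id, qtl_status), by = "sample_id") |>
    dplyr::filter(gt != "missing") |>
    dplyr::group_by(variant_id, qtl_status) |>
    dplyr::summarise(
      p = if (per_fish) mean(carrier[gt]) else mean(allele_weight[gt]),
      n_called = dplyr::n(),
      .groups = "drop"
    ) |>
    tidyr::pivot_wider(names_from = qtl_status,
                       values_from = c(p, n_called),
                       values_fill = list(n_called = 0L))

  for (col in c("p_QTL_pos", "p_QTL_neg", "n_called_QTL_pos", "n_called_QTL_neg")) {
    if (!col %in% names(props)) props[[col]] <- if (grepl("^p_", col)) NA_real_ else 0L
  }

  out <- variants |>
    dplyr::left_join(props, by = "variant_id") |>
    dplyr::mutate(
      p_pos = p_QTL_pos,
      p_neg = p_QTL_neg,
      n_called_pos = dplyr::coalesce(n_called_QTL_pos, 0L),
      n_called_neg = dplyr::coalesce(n_called_QTL_neg, 0L),
      undefined = n_called_pos == 0 | n_called_neg == 0,
      score = ifelse(undefined, NA_real_, abs(p_pos - p_neg))
    ) |>
    dplyr::select(-dplyr::any_of(c("p_QTL_pos", "p_QTL_neg",
                                   "n_called_QTL_pos", "n_called_QTL_neg")))
  if (any(out$undefined)) {
    inform(sprintf("%d variant(s) have no called samples in one group; score flagged NA.",
                   sum(out$undefined)))
  }
  out
}

#' Report the perfectly concordant variant cluster
#'
#' Restricts concordance records to an interval, keeps those with
#' `score >= score_threshold`, and summarises their genomic clustering:
#' count, SNP/indel breakdown, positional extremes and span
#' (`max_pos - min_pos + 1`, defined when at least two variants qualify).
#' The full score track is retained for plotting.
#'
#' @param records Output of [concordance_scores()].
#' @param interval Optional `c(start, end)` (1-based inclusive) restricting
#'   the records; `NULL` keeps all.
#' @param score_threshold Minimum score to qualify (default 1.0, i.e. perfect
#'   concordance).
#' @return A `cluster_report` object: `variants` (qualifying records),
#'   `count`, `snp_count`, `indel_count`, `min_pos`, `max_pos`, `span_bp`,
#'   `score_track` (all in-interval records), `score_threshold`.
#' @export
perfect_cluster_report <- function(records, interval = NULL,
                                   score_threshold = 1.0) {
  stopifnot(is.data.frame(records))
  track <- records
  if (!is.null(interval)) {
    track <- dplyr::filter(track, pos >= interval[1], pos <= interval[2])
  }
  hits <- dplyr::filter(track, !is.na(score), score >= score_threshold)
  count <- nrow(hits)
  structure(
    list(
      variants = hits,
      count = count,
      snp_count = sum(hits$variant_class == "SNP"),
      indel_count = sum(hits$variant_class == "indel"),
      min_pos = if (count > 0) min(hits$pos) else NA_integer_,
      max_pos = if (count > 0) max(hits$pos) else NA_integer_,
      span_bp = if (count >= 2) as.integer(diff(range(hits$pos)) + 1L) else NA_integer_,
      score_track = track,
      score_threshold = score_threshold
    ),
    class = "cluster_report"
  )
}

#' @export
print.cluster_report <- function(x, ...) {
  cat(sprintf("Cluster report (score >= %g): %d variant(s) [%d SNP, %d indel]\n",
              x$score_threshold, x$count, x$snp_count, x$indel_count))
  if (x$count >= 2) {
    cat(sprintf("  positions %d..%d, span %d bp\n", x$min_pos, x$max_pos, x$span_bp))
  }
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.cluster_report <- function(x, ...) x$variants

#' @exportS3Method generics::glance
glance.cluster_report <- function(x, ...) {
  tibble::tibble(count = x$count, snp_count = x$snp_count,
                 indel_count = x$indel_count, min_pos = x$min_pos,
                 max_pos = x$max_pos, span_bp = x$span_bp,
                 score_threshold = x$score_threshold)
}

#' Full variant screen: filter, flank uniqueness, score, cluster
#'
#' Convenience wrapper running the screen end to end in the fixed rule
#' order (site quality, high-coverage calls, missingness count, flank
#' uniqueness) followed by concordance scoring and the perfect-cluster
#' report.
#'
#' @inheritParams filter_variants
#' @inheritParams flank_uniqueness_filter
#' @inheritParams perfect_cluster_report
#' @param genome Optional genome; `NULL` skips the flank-uniqueness rule.
#' @param per_fish Passed to [concordance_scores()].
#' @return List: `report` (a `cluster_report`), `scores`, `tally`
#'   (per-rule removals including `flank_uniqueness`), `retained`.
#' @export
screen_variants <- function(variants, calls, panel, genome = NULL,
                            thresholds = filter_thresholds(),
                            interval = NULL, score_threshold = 1.0,
                            per_fish = FALSE, matcher = NULL) {
  flt <- filter_variants(variants, calls, panel, thresholds)
  tally <- flt$tally
  v <- flt$variants
  if (!is.null(genome)) {
    fu <- flank_uniqueness_filter(v, genome, thresholds, matcher)
    tally <- dplyr::bind_rows(tally,
                              tibble::tibble(rule = "flank_uniqueness",
                                             n_removed = fu$n_removed))
    v <- fu$variants
  }
  scores <- concordance_scores(v, calls, panel, per_fish = per_fish)
  report <- perfect_cluster_report(scores, interval = interval,
                                   score_threshold = score_threshold)
  list(report = report, scores = scores, tally = tally, retained = v)
}
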