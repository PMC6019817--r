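samples6 <- c("hc1", "hc2", "lo1", "lo2", "lo3", "lo4")
panel6 <- make_manifest(samples6,
                        qtl_status = c(rep("QTL_pos", 3), rep("QTL_neg", 3)),
                        coverage = c("high", "high", rep("low", 4)))

test_that("site-quality rule is strictly greater-than", {
  gt <- matrix("hom_alt", 3, 6, dimnames = list(NULL, samples6))
  fx <- make_panel_fixture(gt, site_quality = c(400, 400.001, 399))
  res <- filter_variants(fx$variants, fx$calls, panel6)
  expect_identical(res$variants$site_quality, 400.001)
  expect_identical(res$tally$n_removed[res$tally$rule == "site_quality"], 2L)
})

test_that("any bad call in a high-coverage genome removes the variant", {
  gt <- matrix("hom_alt", 3, 6, dimnames = list(NULL, samples6))
  gt[1, "hc1"] <- "missing"          # missing in a high-coverage genome
  gq <- matrix(99, 3, 6)
  gq[2, 2] <- 9.5                    # low GQ in a high-coverage genome
  fx <- make_panel_fixture(gt, site_quality = rep(1000, 3), gq = gq)
  res <- filter_variants(fx$variants, fx$calls, panel6)
  expect_identical(nrow(res$variants), 1L)
  expect_identical(res$tally$n_removed,
                   c(0L, 2L, 0L))
})

test_that("missingness rule tolerates at most two bad genomes", {
  gt <- matrix("hom_alt", 2, 6, dimnames = list(NULL, samples6))
  gt[1, c("lo1", "lo2")] <- "missing"          # exactly two: retained
  gt[2, c("lo1", "lo2", "lo3")] <- "missing"   # three: removed
  fx <- make_panel_fixture(gt)
  res <- filter_variants(fx$variants, fx$calls, panel6)
  expect_identical(nrow(res$variants), 1L)
  expect_identical(res$tally$n_removed[res$tally$rule == "missingness_count"], 1L)
})

test_that("filter chain is monotone and its tally sums to input minus output", {
  withr::with_seed(2, {
    pp <- variant_panel_params(interval_bp = 60000, n_differentiated = 80,
                               n_perfect = 5, cluster_span_bp = 2000,
                               missing_rate = 0.05, seed = 14)
    sim <- simulate_variant_panel(pp)
    res <- filter_variants(sim$variants, sim$calls, sim$panel)
    expect_identical(sum(res$tally$n_removed),
                     nrow(sim$variants) - nrow(res$variants))
    expect_true(all(res$variants$variant_id %in% sim$variants$variant_id))
  })
})

test_that("a sample missing from the manifest is a named error", {
  gt <- matrix("hom_alt", 1, 6, dimnames = list(NULL, samples6))
  fx <- make_panel_fixture(gt)
  expect_error(filter_variants(fx$variants, fx$calls, panel6[-3, ]), "lo1")
})

test_that("flank matched in more than six places is removed, six retained", {
  withr::with_seed(8, {
    bases <- sample(c("A", "C", "G", "T"), 30000, replace = TRUE)
    flank_bp <- 100
    pos <- c(5000, 9000, 13000)
    fx <- make_panel_fixture(
      matrix("hom_alt", 3, 2, dimnames = list(NULL, c("s1", "s2"))),
      pos = pos)
    paste_copies <- function(bases, pos, n_copies, at) {
      fl <- c(bases[(pos - flank_bp):(pos - 1)], bases[(pos + 1):(pos + flank_bp)])
      for (k in seq_len(n_copies)) {
        start <- at + (k - 1) * 220
        bases[start:(start + 2 * flank_bp - 1)] <- fl
      }
      bases
    }
    bases <- paste_copies(bases, 5000, 7, at = 16000)  # > six: removed
    bases <- paste_copies(bases, 9000, 6, at = 18000)  # exactly six: retained
    genome <- make_genome(bases)
    res <- flank_uniqueness_filter(fx$variants, genome)
    expect_identical(res$match_counts, c(7L, 6L, 0L))
    expect_setequal(res$variants$pos, c(9000, 13000))
  })
})

test_that("flanks at a sequence end are truncated and logged, not fatal", {
  withr::with_seed(3, {
    bases <- sample(c("A", "C", "G", "T"), 500, replace = TRUE)
    fx <- make_panel_fixture(
      matrix("hom_alt", 1, 2, dimnames = list(NULL, c("s1", "s2"))), pos = 30)
    expect_message(res <- flank_uniqueness_filter(fx$variants, make_genome(bases)),
                   "truncated")
    expect_identical(nrow(res$variants), 1L)
  })
})

test_that("concordance scores follow the allele-frequency formula", {
  # perfect segregation: alt-hom in 7/7 positives, ref-hom in 3/3 negatives
  gt <- matrix(rep(c("hom_alt", "hom_ref"), c(7, 3)), 1)
  colnames(gt) <- sprintf("s%02d", 1:10)
  pan <- make_manifest(colnames(gt), rep(c("QTL_pos", "QTL_neg"), c(7, 3)))
  fx <- make_panel_fixture(gt)
  sc <- concordance_scores(fx$variants, fx$calls, pan)
  expect_equal(sc$score, 1.0)

  # identical proportions in both groups
  gt[] <- "hom_alt"
  fx2 <- make_panel_fixture(gt)
  expect_equal(concordance_scores(fx2$variants, fx2$calls, pan)$score, 0.0)

  # 10/14 positive chromosomes vs 2/6 negative chromosomes -> 8/21
  gt3 <- matrix(c(rep("hom_alt", 3), rep("het", 4),       # 3*2 + 4*1 = 10/14
                  rep("het", 2), "hom_ref"), 1)           # 2/6
  colnames(gt3) <- colnames(gt)
  fx3 <- make_panel_fixture(gt3)
  sc3 <- concordance_scores(fx3$variants, fx3$calls, pan)
  expect_equal(sc3$score, 8 / 21, tolerance = 1e-12)
  expect_equal(sc3$p_pos, 10 / 14)
  expect_equal(sc3$n_called_pos, 7L)
})

test_that("scores match a brute-force recount on random small panels", {
  withr::with_seed(19, {
    for (rep in 1:5) {
      nv <- sample(3:10, 1); ns <- sample(4:10, 1)
      gt <- matrix(sample(c("hom_ref", "het", "hom_alt", "missing"),
                          nv * ns, replace = TRUE),
                   nv, ns, dimnames = list(NULL, sprintf("s%02d", 1:ns)))
      pan <- make_manifest(colnames(gt),
                           sample(rep(c("QTL_pos", "QTL_neg"), c(ceiling(ns / 2),
                                                                 floor(ns / 2)))))
      fx <- make_panel_fixture(gt)
      sc <- suppressMessages(concordance_scores(fx$variants, fx$calls, pan))
      oracle <- brute_force_scores(fx$variants, fx$calls, pan)
      expect_identical(sc$variant_id, fx$variants$variant_id)
      expect_equal(sc$score, oracle)
    }
  })
})

test_that("scores are invariant to allele relabelling and sample order", {
  withr::with_seed(23, {
    gt <- matrix(sample(c("hom_ref", "het", "hom_alt"), 40, replace = TRUE),
                 5, 8, dimnames = list(NULL, sprintf("s%d", 1:8)))
    pan <- make_manifest(colnames(gt), rep(c("QTL_pos", "QTL_neg"), each = 4))
    fx <- make_panel_fixture(gt)
    sc <- concordance_scores(fx$variants, fx$calls, pan)
    # swap ref/alt labels
    swap <- c(hom_ref = "hom_alt", het = "het", hom_alt = "hom_ref")
    fx_swap <- fx
    fx_swap$calls$gt <- unname(swap[fx$calls$gt])
    expect_equal(concordance_scores(fx_swap$variants, fx_swap$calls, pan)$score,
                 sc$score)
    # shuffle call rows and the manifest
    fx_shuf <- fx
    fx_shuf$calls <- fx$calls[sample(nrow(fx$calls)), ]
    expect_equal(concordance_scores(fx_shuf$variants, fx_shuf$calls,
                                    pan[sample(nrow(pan)), ])$score,
                 sc$score)
  })
})

test_that("a group with no called samples yields a flagged NA, not zero", {
  gt <- matrix(c("hom_alt", "hom_alt", "missing", "missing"), 1)
  colnames(gt) <- sprintf("s%d", 1:4)
  pan <- make_manifest(colnames(gt), rep(c("QTL_pos", "QTL_neg"), each = 2))
  fx <- make_panel_fixture(gt)
  expect_message(sc <- concordance_scores(fx$variants, fx$calls, pan), "flagged")
  expect_true(sc$undefined)
  expect_true(is.na(sc$score))
})

test_that("cluster report summarises the perfect set and is threshold-monotone", {
  recs <- tibble::tibble(
    variant_id = sprintf("v%d", 1:6), chrom = "chrT",
    pos = c(100L, 500L, 900L, 1500L, 3000L, 9000L),
    variant_class = c("SNP", "SNP", "indel", "SNP", "SNP", "SNP"),
    score = c(1, 1, 1, 0.95, 0.5, NA), undefined = c(rep(FALSE, 5), TRUE)
  )
  rep1 <- perfect_cluster_report(recs, interval = c(1, 5000))
  expect_identical(rep1$count, 3L)
  expect_identical(rep1$snp_count, 2L)
  expect_identical(rep1$indel_count, 1L)
  expect_identical(rep1$span_bp, 801L)
  counts <- vapply(c(1.0, 0.9, 0.5),
                   function(th) perfect_cluster_report(recs, c(1, 5000), th)$count,
                   1L)
  expect_true(all(diff(counts) >= 0))
  empty <- perfect_cluster_report(recs[0, ])
  expect_identical(empty$count, 0L)
  expect_true(is.na(empty$span_bp))
})

test_that("end-to-end screen on a noisy planted panel recovers the truth", {
  pp <- variant_panel_params(interval_bp = 100000, n_differentiated = 120,
                             n_perfect = 8, cluster_span_bp = 4000,
                             missing_rate = 0.03, repeat_fraction = 0.08,
                             seed = 99)
  sim <- simulate_variant_panel(pp)
  scr <- screen_variants(sim$variants, sim$calls, sim$panel, sim$genome,
                         interval = sim$truth$interval)
  expect_setequal(scr$report$variants$variant_id, sim$truth$perfect_ids)
  expect_identical(scr$report$indel_count, 0L)
  expect_lte(scr$report$span_bp, 4000)
  expect_identical(sum(scr$tally$n_removed),
                   nrow(sim$variants) - nrow(scr$retained))
})
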