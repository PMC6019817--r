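# Small fixture builders shared across test files. Everything is generated
# in code; no stored data.

`%||%` <- function(x, y) if (is.null(x)) y else x

# A tiny variant table + long calls from a genotype matrix (variants x
# samples, entries hom_ref/het/hom_alt/missing).
make_panel_fixture <- function(gt_matrix, site_quality = NULL, gq = NULL,
                               pos = NULL, ref = "A", alt = "T") {
  n <- nrow(gt_matrix)
  samples <- colnames(gt_matrix)
  pos <- pos %||% seq(1000, by = 500, length.out = n)
  variants <- tibble::tibble(
    variant_id = sprintf("chrT:%d_%s/%s", pos, ref, alt),
    chrom = "chrT",
    pos = as.integer(pos),
    ref = ref,
    alt = alt,
    site_quality = site_quality %||% rep(1000, n),
    variant_class = ifelse(nchar(ref) == 1 & nchar(alt) == 1, "SNP", "indel")
  )
  gq <- gq %||% matrix(99, n, length(samples))
  calls <- tibble::tibble(
    variant_id = rep(variants$variant_id, times = length(samples)),
    sample_id = rep(samples, each = n),
    gt = as.vector(gt_matrix),
    gq = as.vector(gq)
  )
  list(variants = variants, calls = calls)
}

make_manifest <- function(samples, qtl_status, coverage = NULL) {
  tibble::tibble(
    sample_id = samples,
    qtl_status = qtl_status,
    coverage = coverage %||% rep("low", length(samples))
  )
}

# Independent brute-force recount of allele-presence proportions: loops over
# fish and chromosomes, no shared code with concordance_scores().
brute_force_scores <- function(variants, calls, panel) {
  vapply(variants$variant_id, function(vid) {
    props <- sapply(c("QTL_pos", "QTL_neg"), function(status) {
      ids <- panel$sample_id[panel$qtl_status == status]
      n_chrom <- 0; n_alt <- 0
      for (s in ids) {
        g <- calls$gt[calls$variant_id == vid & calls$sample_id == s]
        if (g == "missing") next
        n_chrom <- n_chrom + 2
        n_alt <- n_alt + switch(g, hom_ref = 0, het = 1, hom_alt = 2)
      }
      if (n_chrom == 0) NA_real_ else n_alt / n_chrom
    })
    abs(props[[1]] - props[[2]])
  }, 1.0, USE.NAMES = FALSE)
}

# Marker genotypes for an F2 segregating two distinguishable benthic
# chromosomes: each allele drawn iid from {B1, B2, M} with probs
# (1/4, 1/4, 1/2), phenotype additive per benthic copy.
make_benthic_cross <- function(n, d1, d2, sd = 1) {
  a1 <- sample(c("B1", "B2", "M"), n, replace = TRUE, prob = c(.25, .25, .5))
  a2 <- sample(c("B1", "B2", "M"), n, replace = TRUE, prob = c(.25, .25, .5))
  nb1 <- (a1 == "B1") + (a2 == "B1")
  nb2 <- (a1 == "B2") + (a2 == "B2")
  tibble::tibble(
    marker = paste(a1, a2, sep = "/"),
    corrected = 50 + d1 * nb1 + d2 * nb2 + rnorm(n, 0, sd)
  )
}

# A toy genome as a DNAStringSet with given character content.
make_genome <- function(chars, name = "chrT") {
  g <- Biostrings::DNAStringSet(paste(chars, collapse = ""))
  names(g) <- name
  g
}
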