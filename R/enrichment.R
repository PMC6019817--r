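#' Per-gene signed z-scores from a two-group expression matrix
#'
#' Each gene is tested for differential expression between the mutant and
#' wild-type groups with a two-sample t-test on `log2(abundance +
#' pseudocount)` (pooled-variance Student test by default; Welch available).
#' The signed z-score is the probit transform of the t-test's cumulative
#' probability, `z = qnorm(pt(t, df))`: standard normal under the null even
#' at n = 3 per group, with the sign of the mean difference (positive =
#' higher in mutant). The raw t statistic is kept for audit.
#'
#' Genes are excluded, with a reason, when their mean abundance across all
#' samples is below `expression_floor` (not expressed) or when both groups
#' have zero within-group variance (no information for a t-test).
#'
#' @param expr Tibble: `gene_id` column plus one numeric column per sample.
#' @param groups Tibble `sample_id`, `group` with groups `wildtype` and
#'   `mutant`, >= 2 samples each.
#' @param pseudocount Added before the log2 transform (default 1).
#' @param expression_floor Minimum mean abundance (original scale) for a gene
#'   to be scored (default 1).
#' @param var_equal Pooled-variance t-test if `TRUE` (default), Welch
#'   otherwise.
#' @return A `gene_z` object: tibble `gene_id`, `t`, `df`, `z` for scored
#'   genes, with attribute `excluded` (tibble `gene_id`, `reason`).
#' @examples
#' sim <- simulate_expression(expr_sim_params(n_genes = 50, seed = 2))
#' per_gene_z(sim$expr, sim$groups)
#' @export
per_gene_z <- function(expr, groups, pseudocount = 1, expression_floor = 1,
                       var_equal = TRUE) {
  stopifnot(is.data.frame(expr), is.data.frame(groups))
  if (!"gene_id" %in% names(expr)) abort("`expr` needs a `gene_id` column.")
  if (anyDuplicated(expr$gene_id)) abort("Duplicate gene ids in `expr`.")
  samples <- setdiff(names(expr), "gene_id")
  missing_groups <- setdiff(samples, groups$sample_id)
  if (length(missing_groups) > 0) {
    abort(sprintf("Sample(s) without a group label: %s",
                  paste(missing_groups, collapse = ", ")))
  }
  grp <- groups$group[match(samples, groups$sample_id)]
  wt <- samples[grp == "wildtype"]
  mut <- samples[grp == "mutant"]
  if (length(wt) < 2 || length(mut) < 2) {
    abort("At least 2 samples per group are required.")
  }

  mat <- as.matrix(expr[, samples])
  floor_fail <- rowMeans(mat) < expression_floor
  lmat <- log2(mat + pseudocount)
  x <- lmat[, mut, drop = FALSE]  # mutant first: positive = higher in mutant
  y <- lmat[, wt, drop = FALSE]
  nx <- ncol(x); ny <- ncol(y)
  mx <- rowMeans(x); my <- rowMeans(y)
  vx <- rowSums((x - mx)^2) / (nx - 1)
  vy <- rowSums((y - my)^2) / (ny - 1)
  zero_var <- vx == 0 & vy == 0

  if (var_equal) {
    sp2 <- ((nx - 1) * vx + (ny - 1) * vy) / (nx + ny - 2)
    se <- sqrt(sp2 * (1 / nx + 1 / ny))
    df <- rep(nx + ny - 2, length(se))
  } else {
    se <- sqrt(vx / nx + vy / ny)
    df <- (vx / nx + vy / ny)^2 /
      ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  }
  tstat <- (mx - my) / se
  z <- qnorm(pt(tstat, df))
  # Guard the probit against saturation at extreme |t|.
  z[is.infinite(z)] <- sign(tstat[is.infinite(z)]) * 38

  keep <- !floor_fail & !zero_var
  excluded <- tibble::tibble(
    gene_id = expr$gene_id[!keep],
    reason = dplyr::case_when(
      floor_fail[!keep] ~ "below expression floor",
      TRUE ~ "zero variance in both groups"
    )
  )
  scores <- tibble::tibble(
    gene_id = expr$gene_id[keep],
    t = tstat[keep],
    df = df[keep],
    z = z[keep]
  )
  structure(scores,
            excluded = excluded,
            pseudocount = pseudocount,
            expression_floor = expression_floor,
            var_equal = var_equal,
            class = c("gene_z", class(scores)))
}

# One-sample t statistics of z-score subsets against mean 0; `idx` is a
# set-size x n_draws index matrix into `z`. Vectorised for the permutation
# null.
set_t_stats <- function(z, idx) {
  m <- matrix(z[idx], nrow = nrow(idx))
  k <- nrow(idx)
  means <- colMeans(m)
  sds <- sqrt(colSums((m - rep(means, each = k))^2) / (k - 1))
  means / (sds / sqrt(k))
}

#' One-sample t-test of a gene set's z-scores
#'
#' Tests the null that a set's per-gene z-scores are draws from a standard
#' normal centred at 0 — no concerted differential expression — with a
#' one-sample t-test against mean 0 (two-sided).
#'
#' @param z A [per_gene_z()] result (or any tibble with `gene_id` and `z`).
#' @param set Character vector of member gene ids.
#' @return One-row tibble: `n_genes` (effective size after intersection),
#'   `mean_z`, `t_statistic`, `p_value`, `reason` (NA unless degenerate).
#' @examples
#' z <- tibble::tibble(gene_id = c("a", "b", "c"), z = c(-1, -2, -3))
#' set_statistic(z, c("a", "b", "c"))
#' @export
set_statistic <- function(z, set) {
  stopifnot(is.data.frame(z))
  zz <- z$z[z$gene_id %in% set]
  k <- length(zz)
  if (k < 2) {
    return(tibble::tibble(n_genes = k, mean_z = if (k) mean(zz) else NA_real_,
                          t_statistic = NA_real_, p_value = NA_real_,
                          reason = "fewer than 2 scored members"))
  }
  if (sd(zz) == 0) {
    return(tibble::tibble(n_genes = k, mean_z = mean(zz),
                          t_statistic = NA_real_, p_value = 1,
                          reason = "zero variance among member z-scores"))
  }
  tt <- t.test(zz, mu = 0)
  tibble::tibble(n_genes = k, mean_z = mean(zz),
                 t_statistic = unname(tt$statistic),
                 p_value = tt$p.value, reason = NA_character_)
}

#' Empirical permutation null for a set size
#'
#' Draws `n_perm` random gene subsets of the given size, without replacement,
#' from all scored genes; computes the one-sample t statistic of each; and
#' takes the significance cutoffs at the `2.5/N` and `100 - 2.5/N`
#' percentiles (linear interpolation between order statistics), where `N` is
#' the number of hypotheses tested. Deterministic under a fixed seed.
#'
#' @param z A [per_gene_z()] result.
#' @param set_size Size of the subsets to draw (<= number of scored genes).
#' @param n_perm Number of permutations (default 10000).
#' @param n_hypotheses `N`, the number of gene sets tested (default 1).
#' @param seed Integer seed.
#' @return A `permutation_null` object: `set_size`, `n_perm`,
#'   `n_hypotheses`, `percentiles` (`c(low, high)` in percent), `cutoff_low`,
#'   `cutoff_high`, `statistics`, `seed`.
#' @export
permutation_null <- function(z, set_size, n_perm = 10000, n_hypotheses = 1,
                             seed = 1L) {
  stopifnot(is.data.frame(z))
  set_size <- check_count(set_size, "set_size", min = 2L)
  n_perm <- check_count(n_perm, "n_perm", min = 1L)
  n_hypotheses <- check_count(n_hypotheses, "n_hypotheses", min = 1L)
  n_scored <- nrow(z)
  if (set_size > n_scored) {
    abort(sprintf("`set_size` (%d) exceeds the number of scored genes (%d).",
                  set_size, n_scored))
  }
  pct <- permutation_percentiles(n_hypotheses)
  stats <- with_stream(seed, 31L, {
    idx <- replicate(n_perm, sample.int(n_scored, set_size))
    set_t_stats(z$z, matrix(idx, nrow = set_size))
  })
  cuts <- quantile(stats, probs = pct / 100, names = FALSE, type = 7)
  structure(
    list(set_size = set_size, n_perm = n_perm, n_hypotheses = n_hypotheses,
         percentiles = pct, cutoff_low = cuts[1], cutoff_high = cuts[2],
         statistics = stats, seed = seed),
    class = "permutation_null"
  )
}

#' Percentile pair for the permutation cutoffs
#'
#' For `N` hypotheses the two-sided empirical band uses the `2.5/N` and
#' `100 - 2.5/N` percentiles of the permutation distribution; at `N = 1`
#' this is the unadjusted two-sided 5% band (2.5, 97.5).
#'
#' @param n_hypotheses `N` >= 1.
#' @return Numeric `c(low, high)` in percent.
#' @examples
#' permutation_percentiles(12)
#' @export
permutation_percentiles <- function(n_hypotheses) {
  n_hypotheses <- check_count(n_hypotheses, "n_hypotheses", min = 1L)
  c(2.5 / n_hypotheses, 100 - 2.5 / n_hypotheses)
}

#' @export
print.permutation_null <- function(x, ...) {
  cat(sprintf(
    "Permutation null: %d draws of size %d; cutoffs [%.3f, %.3f] at percentiles (%.4g, %.4g)\n",
    x$n_perm, x$set_size, x$cutoff_low, x$cutoff_high,
    x$percentiles[1], x$percentiles[2]))
  invisible(x)
}

#' Evaluate gene sets for concerted differential expression
#'
#' Runs [per_gene_z()] once, then for every gene set computes the one-sample
#' t-test of its member z-scores, a Bonferroni-corrected p-value with `N` =
#' number of sets, and a matched-size permutation null band. A set is called
#' significant when its corrected p-value is below `alpha` *and* its observed
#' t statistic falls outside the permutation band; direction follows the
#' sign of the mean z (up = higher in mutant).
#'
#' @param expr,groups As in [per_gene_z()].
#' @param sets Named list of member gene-id vectors (e.g. from
#'   [read_gmt()]).
#' @param n_perm Permutations per set (default 10000).
#' @param seed Integer seed (one sub-stream per set).
#' @param alpha Family-wise significance level (default 0.05).
#' @param ... Passed to [per_gene_z()].
#' @return An `enrichment_result`: tibble with one row per set (`set`,
#'   `n_genes`, `mean_z`, `t_statistic`, `p_value`, `bonferroni_p`,
#'   `cutoff_low`, `cutoff_high`, `significant`, `direction`, `reason`),
#'   with the `gene_z` scores in attribute `gene_z`.
#' @examples
#' sim <- simulate_expression(expr_sim_params(
#'   n_genes = 300, sets = list(list(name = "hit", size = 20, shift = -1),
#'                              list(name = "null", size = 20, shift = 0)),
#'   seed = 9))
#' evaluate_gene_sets(sim$expr, sim$groups, sim$sets, n_perm = 500, seed = 1)
#' @export
evaluate_gene_sets <- function(expr, groups, sets, n_perm = 10000, seed = 1L,
                               alpha = 0.05, ...) {
  if (length(sets) == 0) abort("`sets` must be a non-empty named list.")
  if (is.null(names(sets)) || any(!nzchar(names(sets)))) {
    abort("Every gene set needs a name.")
  }
  z <- per_gene_z(expr, groups, ...)
  n_sets <- length(sets)

  rows <- purrr::imap(sets, function(members, nm) {
    st <- set_statistic(z, members)
    row <- dplyr::mutate(st, set = nm, .before = 1)
    if (!is.na(st$reason)) {
      return(dplyr::mutate(row,
                           bonferroni_p = NA_real_, cutoff_low = NA_real_,
                           cutoff_high = NA_real_, significant = NA,
                           direction = NA_character_))
    }
    pn <- permutation_null(z, st$n_genes, n_perm = n_perm,
                           n_hypotheses = n_sets,
                           seed = derive_seed(seed, 100L + match(nm, names(sets))))
    bonf <- min(1, st$p_value * n_sets)
    outside <- st$t_statistic < pn$cutoff_low | st$t_statistic > pn$cutoff_high
    dplyr::mutate(row,
                  bonferroni_p = bonf,
                  cutoff_low = pn$cutoff_low,
                  cutoff_high = pn$cutoff_high,
                  significant = bonf < alpha & outside,
                  direction = ifelse(mean_z >= 0, "up", "down"))
  })
  res <- dplyr::bind_rows(rows) |>
    dplyr::relocate(reason, .after = dplyr::last_col())
  structure(res,
            gene_z = z, n_perm = n_perm, seed = seed, alpha = alpha,
            class = c("enrichment_result", class(res)))
}

#' @exportS3Method generics::glance
glance.enrichment_result <- function(x, ...) {
  tibble::tibble(
    n_sets = nrow(x),
    n_significant = sum(x$significant, na.rm = TRUE),
    n_perm = attr(x, "n_perm"),
    alpha = attr(x, "alpha")
  )
}
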