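# Gaussian maximum-likelihood machinery shared by the LRTs. For a linear
# model with MLE variance, loglik = -n/2 (log(2 pi RSS/n) + 1), so the LRT
# statistic between nested fits is n log(RSS_reduced / RSS_full).

gauss_loglik <- function(rss, n) {
  -n / 2 * (log(2 * pi * rss / n) + 1)
}

fit_class_model <- function(y, cls) {
  if (length(unique(cls)) == 1) {
    rss <- sum((y - mean(y))^2)
    k <- 1L
  } else {
    fit <- lm(y ~ factor(cls))
    rss <- sum(resid(fit)^2)
    k <- length(unique(cls))
  }
  list(rss = rss, k = k, loglik = gauss_loglik(rss, length(y)))
}

#' Which side does a recombinant chromosome fall on?
#'
#' Likelihood-ratio test of whether a recombinant chromosome behaves like a
#' marine or a benthic chromosome. Three Gaussian class-mean models are fit
#' by maximum likelihood: FULL (every diploid class its own mean), R==M
#' (each R-bearing class merged with the class obtained by relabelling R as
#' M), and R==B (R relabelled as B). Each merged model is nested in FULL, so
#' `2 * (loglik_FULL - loglik_merged)` is chi-square with df equal to the
#' number of class levels lost in the merge. The supported direction is the
#' merge that is *not* rejected at `alpha`, and the reported p-value is that
#' of rejecting the opposite merge; if both or neither merge is rejected the
#' direction is indeterminate and both p-values are still reported.
#'
#' @param data Tibble with one row per fish.
#' @param response Response column (default `"corrected"`).
#' @param class Diploid class column (default `"class"`); classes are
#'   two-letter codes over the alleles M, B, R (e.g. `RM`, `RB`, `MM`, `MB`).
#' @param alpha Rejection level for the direction call (default 0.05).
#' @return A `qtlfine_lrt` object: full/merged logliks, per-merge statistics
#'   and p-values (`p_marine_merge`, `p_benthic_merge`), `df`,
#'   `supported_direction` in `marine-like`/`benthic-like`/`indeterminate`,
#'   and the headline `p_value`.
#' @examples
#' p <- cross_sim_params(200, c(RM = 55, RB = 60, MM = 50, MB = 55),
#'                       residual_sd = 1, seed = 11)
#' fish <- simulate_cross(p)
#' recombinant_direction_lrt(fish, response = "tooth_total",
#'                           class = "true_class")
#' @export
recombinant_direction_lrt <- function(data,
                                      response = "corrected",
                                      class = "class",
                                      alpha = 0.05) {
  stopifnot(is.data.frame(data))
  y <- data[[response]]
  cls <- data[[class]]
  keep <- !is.na(y) & !is.na(cls)
  y <- y[keep]; cls <- cls[keep]
  if (!any(grepl("R", cls))) {
    abort("No recombinant-bearing class present; nothing to test.")
  }
  n <- length(y)

  merge_classes <- function(cls, to) {
    out <- gsub("R", to, cls)
    rank <- c(R = 1L, M = 2L, B = 3L)
    a <- substr(out, 1, 1); b <- substr(out, 2, 2)
    ifelse(rank[a] <= rank[b], paste0(a, b), paste0(b, a))
  }

  full <- fit_class_model(y, cls)
  as_m <- fit_class_model(y, merge_classes(cls, "M"))
  as_b <- fit_class_model(y, merge_classes(cls, "B"))

  one_merge <- function(m) {
    df <- full$k - m$k
    stat <- max(0, n * log(m$rss / full$rss))
    p <- if (df > 0) pchisq(stat, df, lower.tail = FALSE) else NA_real_
    list(stat = stat, df = df, p = p)
  }
  tm <- one_merge(as_m)  # rejecting this says "R is not marine-like"
  tb <- one_merge(as_b)

  rej_m <- !is.na(tm$p) && tm$p < alpha
  rej_b <- !is.na(tb$p) && tb$p < alpha
  if (rej_m && !rej_b) {
    direction <- "benthic-like"; p_value <- tm$p
    statistic <- tm$stat; df <- tm$df
  } else if (rej_b && !rej_m) {
    direction <- "marine-like"; p_value <- tb$p
    statistic <- tb$stat; df <- tb$df
  } else {
    direction <- "indeterminate"; p_value <- NA_real_
    statistic <- NA_real_; df <- NA_integer_
  }

  structure(
    list(
      full_loglik = full$loglik,
      marine_merge_loglik = as_m$loglik,
      benthic_merge_loglik = as_b$loglik,
      stat_marine_merge = tm$stat, df_marine_merge = tm$df, p_marine_merge = tm$p,
      stat_benthic_merge = tb$stat, df_benthic_merge = tb$df, p_benthic_merge = tb$p,
      statistic = statistic, df = df, p_value = p_value,
      supported_direction = direction,
      alpha = alpha, n = n
    ),
    class = "qtlfine_lrt"
  )
}

#' @export
print.qtlfine_lrt <- function(x, ...) {
  cat(sprintf("Recombinant direction LRT (n = %d): %s\n", x$n, x$supported_direction))
  cat(sprintf("  R==M merge: 2*dLL = %.3f, df = %d, p = %.3g\n",
              x$stat_marine_merge, x$df_marine_merge, x$p_marine_merge))
  cat(sprintf("  R==B merge: 2*dLL = %.3f, df = %d, p = %.3g\n",
              x$stat_benthic_merge, x$df_benthic_merge, x$p_benthic_merge))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.qtlfine_lrt <- function(x, ...) {
  tibble::tibble(
    merge = c("R==M", "R==B"),
    statistic = c(x$stat_marine_merge, x$stat_benthic_merge),
    df = c(x$df_marine_merge, x$df_benthic_merge),
    p_value = c(x$p_marine_merge, x$p_benthic_merge)
  )
}

#' @exportS3Method generics::glance
glance.qtlfine_lrt <- function(x, ...) {
  tibble::tibble(supported_direction = x$supported_direction,
                 statistic = x$statistic, df = x$df, p_value = x$p_value,
                 n = x$n)
}

#' Per-chromosome effect tests in a two-benthic-chromosome cross
#'
#' In a cross whose four-allele marker distinguishes the two wild benthic
#' chromosomes, tests each benthic chromosome for an effect on the
#' (corrected) phenotype. The encompassing model gives each benthic
#' chromosome its own additive per-copy effect (`y ~ mu + d1 n1 + d2 n2`
#' with `n_i` the number of copies of benthic chromosome i); the test for
#' chromosome i compares the FULL fit against the nested restriction
#' `d_i = 0` (the other chromosome's effect stays free), df = 1, chi-square
#' p. The equal-effect additive model's log-likelihood is reported for
#' audit. When the marker cannot distinguish the two benthic chromosomes the
#' result is `NA` with a reason, rather than a number.
#'
#' @param data Tibble with one row per fish.
#' @param response Response column (default `"corrected"`).
#' @param marker Column holding the four-allele marker genotype as `"a/b"`
#'   strings (default `"marker"`).
#' @param benthic_alleles Length-2 character vector naming the two benthic
#'   alleles (default `c("B1", "B2")`).
#' @return A `qtlfine_benthic_lrt` object with a `results` tibble
#'   (`chromosome`, `statistic`, `df`, `p_value`), logliks, and
#'   `applicable`/`reason` fields.
#' @export
benthic_chromosome_lrt <- function(data,
                                   response = "corrected",
                                   marker = "marker",
                                   benthic_alleles = c("B1", "B2")) {
  stopifnot(is.data.frame(data))
  not_applicable <- function(reason) {
    structure(
      list(applicable = FALSE, reason = reason,
           results = tibble::tibble(chromosome = benthic_alleles,
                                    statistic = NA_real_, df = NA_integer_,
                                    p_value = NA_real_)),
      class = "qtlfine_benthic_lrt"
    )
  }
  if (length(benthic_alleles) != 2 || anyNA(benthic_alleles) ||
      benthic_alleles[1] == benthic_alleles[2]) {
    return(not_applicable("benthic chromosomes cannot be molecularly distinguished"))
  }
  y <- data[[response]]
  gt <- strsplit(data[[marker]], "/", fixed = TRUE)
  if (any(lengths(gt) != 2)) abort("Malformed marker genotype (want \"a/b\").")
  n1 <- vapply(gt, function(g) sum(g == benthic_alleles[1]), 0L)
  n2 <- vapply(gt, function(g) sum(g == benthic_alleles[2]), 0L)
  keep <- !is.na(y)
  y <- y[keep]; n1 <- n1[keep]; n2 <- n2[keep]
  if (var(n1) == 0 || var(n2) == 0) {
    return(not_applicable("a benthic chromosome shows no copy-number variation in the cross"))
  }
  n <- length(y)

  rss_of <- function(fml, dat) sum(resid(lm(fml, data = dat))^2)
  dat <- data.frame(y = y, n1 = n1, n2 = n2)
  rss_full <- rss_of(y ~ n1 + n2, dat)
  rss_no1 <- rss_of(y ~ n2, dat)
  rss_no2 <- rss_of(y ~ n1, dat)
  rss_equal <- rss_of(y ~ I(n1 + n2), dat)

  stat <- pmax(0, n * log(c(rss_no1, rss_no2) / rss_full))
  structure(
    list(
      applicable = TRUE, reason = NA_character_,
      full_loglik = gauss_loglik(rss_full, n),
      equal_effect_loglik = gauss_loglik(rss_equal, n),
      results = tibble::tibble(
        chromosome = benthic_alleles,
        statistic = stat,
        df = 1L,
        p_value = pchisq(stat, 1, lower.tail = FALSE)
      ),
      n = n
    ),
    class = "qtlfine_benthic_lrt"
  )
}

#' @export
print.qtlfine_benthic_lrt <- function(x, ...) {
  if (!x$applicable) {
    cat(sprintf("Benthic chromosome LRT: NA (%s)\n", x$reason))
  } else {
    cat(sprintf("Benthic chromosome LRTs (n = %d):\n", x$n))
    print(x$results)
  }
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.qtlfine_benthic_lrt <- function(x, ...) x$results
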