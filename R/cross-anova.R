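#' One-way ANOVA of corrected phenotype on genotype class
#'
#' Fixed-effects one-way ANOVA of a (size-corrected) phenotype on diploid
#' genotype class, reporting the F statistic, degrees of freedom, p-value,
#' and the per-class back-transformed means with standard errors — the
#' quantities a cross summary figure plots.
#'
#' @param data Tibble holding one row per fish with the class and response
#'   columns (typically `size_correct()` output joined to
#'   `assign_genotype_class()` output).
#' @param response Response column name (default `"corrected"`).
#' @param class Class column name (default `"class"`).
#' @param keep_classes Optional character vector restricting which classes
#'   enter the test (e.g. `c("MM", "MB", "BB")` for a plain F2 comparison);
#'   `NULL` keeps all observed classes.
#' @return A `qtlfine_anova` object: list with `F`, `df_between`,
#'   `df_within`, `p_value`, and `class_means` (tibble `class`, `n`, `mean`,
#'   `se`; `se` is the pooled residual SD divided by `sqrt(n)`).
#' @examples
#' d <- tibble::tibble(class = rep(c("MM", "BB"), each = 2),
#'                     corrected = c(10, 12, 20, 22))
#' genotype_anova(d)
#' @export
genotype_anova <- function(data,
                           response = "corrected",
                           class = "class",
                           keep_classes = NULL) {
  stopifnot(is.data.frame(data))
  if (!all(c(response, class) %in% names(data))) {
    abort(sprintf("Columns `%s` and `%s` are required.", response, class))
  }
  d <- tibble::tibble(y = data[[response]], cls = data[[class]])
  d <- d[!is.na(d$cls) & !is.na(d$y), ]
  if (!is.null(keep_classes)) d <- d[d$cls %in% keep_classes, ]

  tab <- table(d$cls)
  small <- names(tab)[tab < 2]
  if (length(small) > 0) {
    warn(sprintf("Class(es) with < 2 fish excluded from the ANOVA: %s",
                 paste(small, collapse = ", ")))
    d <- d[!d$cls %in% small, ]
  }
  if (length(unique(d$cls)) < 2) {
    abort("At least two classes with >= 2 fish each are required.")
  }

  fit <- aov(y ~ cls, data = transform(d, cls = factor(cls)))
  a <- summary(fit)[[1]]
  sigma <- sqrt(a["Residuals", "Mean Sq"])

  class_means <- d |>
    dplyr::group_by(class = cls) |>
    dplyr::summarise(n = dplyr::n(), mean = mean(y), .groups = "drop") |>
    dplyr::mutate(se = sigma / sqrt(n))

  structure(
    list(
      F = unname(a["cls", "F value"]),
      df_between = unname(a["cls", "Df"]),
      df_within = unname(a["Residuals", "Df"]),
      p_value = unname(a["cls", "Pr(>F)"]),
      class_means = class_means,
      n = nrow(d)
    ),
    class = "qtlfine_anova"
  )
}

#' @export
print.qtlfine_anova <- function(x, ...) {
  cat(sprintf("One-way genotype ANOVA: F(%d, %d) = %.4g, p = %.4g\n",
              x$df_between, x$df_within, x$F, x$p_value))
  print(x$class_means)
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @exportS3Method generics::tidy
tidy.qtlfine_anova <- function(x, ...) x$class_means

#' @exportS3Method generics::glance
glance.qtlfine_anova <- function(x, ...) {
  tibble::tibble(statistic = x$F, df_between = x$df_between,
                 df_within = x$df_within, p_value = x$p_value, n = x$n)
}
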