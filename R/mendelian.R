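#' Chi-square test of Mendelian segregation ratios
#'
#' Pearson goodness-of-fit test of observed genotype-class counts against an
#' expected segregation ratio (1:2:1 for an intercross, 1:1 for a backcross),
#' with `df = classes - 1`. Deviation from the expected ratio in a viability
#' cross flags differential mortality among genotype classes.
#'
#' @param observed Non-negative integer counts, one per genotype class.
#' @param expected_ratio Positive ratio terms of the same length (e.g.
#'   `c(1, 2, 1)`).
#' @return A one-row tibble: `statistic`, `df`, `p_value`, `n`.
#' @examples
#' mendelian_ratio_test(c(25, 50, 25), c(1, 2, 1)) # exact fit: p = 1
#' mendelian_ratio_test(c(60, 40), c(1, 1))
#' @export
mendelian_ratio_test <- function(observed, expected_ratio) {
  if (length(observed) != length(expected_ratio)) {
    abort("`observed` and `expected_ratio` must have the same number of classes.")
  }
  if (length(observed) < 2) abort("At least two classes are required.")
  if (any(!is.finite(observed)) || any(observed < 0) ||
      any(observed != round(observed))) {
    abort("`observed` must be non-negative integer counts.")
  }
  if (any(!is.finite(expected_ratio)) || any(expected_ratio <= 0)) {
    abort("`expected_ratio` terms must be positive.")
  }
  total <- sum(observed)
  if (total == 0) abort("Total observed count is zero.")

  expected <- total * expected_ratio / sum(expected_ratio)
  statistic <- sum((observed - expected)^2 / expected)
  df <- length(observed) - 1L
  tibble::tibble(
    statistic = statistic,
    df = df,
    p_value = pchisq(statistic, df, lower.tail = FALSE),
    n = as.integer(total)
  )
}
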