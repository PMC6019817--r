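#' Percentage reduction between two printed sizes
#'
#' Convenience arithmetic for reporting how much a fine-mapping step shrank an
#' interval or a gene list: `100 * (1 - after / before)`.
#'
#' @param before,after Positive scalars on the same scale (bp, kb, gene
#'   counts); `after <= before` is not required but a negative reduction
#'   signals growth.
#' @return The percentage reduction as a bare numeric.
#' @examples
#' percent_reduction(2560, 884) # interval shrink, kb
#' percent_reduction(59, 21)    # candidate genes
#' @export
percent_reduction <- function(before, after) {
  stopifnot(is.numeric(before), is.numeric(after), before > 0, after >= 0)
  100 * (1 - after / before)
}

# Deterministic sub-seed derivation: one user-facing seed per generator call,
# independent sub-streams per component so adding a component later does not
# perturb earlier draws. Kept below 2^31 - 1.
derive_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  (abs(as.double(seed)) * 48271 + stream * 69621) %% 2147483587 + 1
}

# Run `expr` under a derived seed without disturbing the caller's RNG state.
with_stream <- function(seed, stream, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(derive_seed(seed, stream))
  expr
}

# Shared argument checks -------------------------------------------------

check_count <- function(x, name, min = 0L) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x) || x != round(x) || x < min) {
    abort(sprintf("`%s` must be a single integer >= %d.", name, min))
  }
  as.integer(x)
}

check_number <- function(x, name, min = -Inf, strict = FALSE) {
  ok <- is.numeric(x) && length(x) == 1 && is.finite(x) &&
    (if (strict) x > min else x >= min)
  if (!ok) {
    abort(sprintf("`%s` must be a single finite number %s %s.",
                  name, if (strict) ">" else ">=", format(min)))
  }
  as.double(x)
}

check_prob <- function(x, name) {
  x <- check_number(x, name, min = 0)
  if (x > 1) abort(sprintf("`%s` must lie in [0, 1].", name))
  x
}

# Draw `n` values from a distribution spec: either a function(n) or a list
# like list(dist = "uniform", min = , max = ) / "normal" / "exponential" /
# "lognormal".
draw_law <- function(law, n) {
  if (is.function(law)) {
    return(as.double(law(n)))
  }
  if (!is.list(law) || is.null(law$dist)) {
    abort("A distribution spec must be a function(n) or a list with a `dist` field.")
  }
  switch(law$dist,
    uniform     = runif(n, law$min %||% 0, law$max %||% 1),
    normal      = rnorm(n, law$mean %||% 0, law$sd %||% 1),
    exponential = rexp(n, law$rate %||% 1),
    lognormal   = exp(rnorm(n, law$meanlog %||% 0, law$sdlog %||% 1)),
    abort(sprintf("Unknown distribution spec `%s`.", law$dist))
  )
}
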