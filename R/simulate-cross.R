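#' Parameters for a simulated cross
#'
#' Bundles the generative model for an F2 or recombinant cross: diploid
#' genotype classes with class-specific mean tooth numbers, a standard-length
#' covariate with a linear effect on tooth number, optional sex and family
#' offsets, and Gaussian residual noise.
#'
#' @param n_offspring Number of fish to simulate (>= 4).
#' @param class_means Named numeric vector or list mapping each diploid class
#'   of the cross design (e.g. `c(MM = 50, MB = 55, BB = 60)` for an F2, or
#'   `c(RM = ..., RB = ..., MM = ..., MB = ...)` for a recombinant cross) to
#'   its mean tooth number. Offspring classes are drawn from these with equal
#'   probability, mirroring a balanced Punnett square.
#' @param residual_sd Residual standard deviation in teeth (> 0).
#' @param length_mean,length_sd Standard length distribution in mm
#'   (`length_sd >= 0`).
#' @param length_slope Teeth per mm of standard length.
#' @param sex_effect Additive offset (teeth) for males relative to females.
#' @param family_effects Numeric vector of per-family offsets (teeth); fish
#'   are assigned to families uniformly. A single 0 means one family.
#' @param integer_counts If `TRUE`, tooth counts are rounded to the nearest
#'   non-negative integer (real fish have whole teeth); `FALSE` keeps the
#'   continuous latent trait, which is what the calibration simulations use.
#' @param seed Integer seed; the generator is a pure function of
#'   (parameters, seed).
#' @return A `cross_sim_params` list, validated.
#' @seealso [simulate_cross()]
#' @export
cross_sim_params <- function(n_offspring,
                             class_means,
                             residual_sd = 2,
                             length_mean = 30,
                             length_sd = 2,
                             length_slope = 0,
                             sex_effect = 0,
                             family_effects = 0,
                             integer_counts = TRUE,
                             seed = 1L) {
  n_offspring <- check_count(n_offspring, "n_offspring", min = 4L)
  class_means <- unlist(class_means)
  if (is.null(names(class_means)) || any(!nzchar(names(class_means)))) {
    abort("`class_means` must be named by diploid class (configuration error).")
  }
  if (anyDuplicated(names(class_means))) {
    abort("Duplicate diploid class in `class_means` (configuration error).")
  }
  params <- list(
    n_offspring = n_offspring,
    class_means = class_means,
    residual_sd = check_number(residual_sd, "residual_sd", min = 0, strict = TRUE),
    length_mean = check_number(length_mean, "length_mean", min = 0, strict = TRUE),
    length_sd = check_number(length_sd, "length_sd", min = 0),
    length_slope = check_number(length_slope, "length_slope"),
    sex_effect = check_number(sex_effect, "sex_effect"),
    family_effects = as.double(family_effects),
    integer_counts = isTRUE(integer_counts),
    seed = check_count(seed, "seed")
  )
  structure(params, class = "cross_sim_params")
}

#' Simulate a phenotyped cross with known class truth
#'
#' Draws each offspring's diploid class uniformly from the cross design's
#' Punnett classes, then builds its tooth number as
#' `class mean + length_slope * (length - length_mean) + sex/family offsets +
#' Normal(0, residual_sd)`. The emitted table carries the true class so
#' downstream genotype-class assignment and model fits can be checked against
#' planted truth.
#'
#' @param params A [cross_sim_params()] object.
#' @return A tibble with one row per fish: `fish_id`, `family`, `sex`,
#'   `std_length_mm`, `tooth_total`, `true_class`, plus two marker columns
#'   (`marker_L`, `marker_R`) whose ordered `"x/y"` allele pairs encode the
#'   two haplotypes consistently with `true_class` (`R` haplotypes carry the
#'   marine allele at the left marker and the benthic allele at the right).
#' @examples
#' p <- cross_sim_params(20, c(MM = 50, MB = 55, BB = 60), seed = 42)
#' simulate_cross(p)
#' @export
simulate_cross <- function(params) {
  stopifnot(inherits(params, "cross_sim_params"))
  classes <- names(params$class_means)
  bad <- setdiff(unique(unlist(strsplit(classes, ""))), c("M", "B", "R"))
  if (length(bad) > 0) {
    abort(sprintf("Class map uses alleles outside the cross design: %s",
                  paste(bad, collapse = ", ")))
  }
  n <- params$n_offspring

  class_draw <- with_stream(params$seed, 1L, sample(classes, n, replace = TRUE))
  sex_draw <- with_stream(params$seed, 2L, sample(c("F", "M"), n, replace = TRUE))
  fam_draw <- with_stream(params$seed, 3L,
                          sample(seq_along(params$family_effects), n, replace = TRUE))
  lengths <- with_stream(params$seed, 4L,
                         rnorm(n, params$length_mean, params$length_sd))
  noise <- with_stream(params$seed, 5L, rnorm(n, 0, params$residual_sd))

  tooth <- unname(params$class_means[class_draw]) +
    params$length_slope * (lengths - params$length_mean) +
    ifelse(sex_draw == "M", params$sex_effect, 0) +
    params$family_effects[fam_draw] +
    noise
  if (params$integer_counts) tooth <- pmax(0, round(tooth))

  hap <- strsplit(class_draw, "")
  tibble::tibble(
    fish_id = sprintf("fish_%04d", seq_len(n)),
    family = sprintf("fam%d", fam_draw),
    sex = sex_draw,
    std_length_mm = lengths,
    tooth_total = tooth,
    true_class = class_draw,
    marker_L = vapply(hap, function(h) paste(marker_allele(h, "L"), collapse = "/"), ""),
    marker_R = vapply(hap, function(h) paste(marker_allele(h, "R"), collapse = "/"), "")
  )
}

# Haplotype -> marker allele: a recombinant haplotype is marine at the left
# flanking marker and benthic at the right; M and B haplotypes are uniform.
marker_allele <- function(haps, side) {
  vapply(haps, function(a) {
    switch(a, M = "M", B = "B", R = if (side == "L") "M" else "B")
  }, "")
}
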