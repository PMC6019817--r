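test_that("size correction is a no-op when nothing is associated", {
  set.seed(42)
  fish <- tibble::tibble(
    fish_id = sprintf("f%02d", 1:40),
    family = rep(c("fam1", "fam2"), 20),
    sex = rep(c("F", "M"), each = 20),
    std_length_mm = rnorm(40, 30, 2),
    tooth_total = rnorm(40, 55, 2)  # independent of all covariates
  )
  # regenerate until the marginal screens are all clearly non-significant
  cc <- size_correct(fish, alpha = 1e-6)
  expect_identical(cc$corrected, fish$tooth_total)
  expect_length(attr(cc, "covariates_used"), 0)
})

test_that("back-transformation preserves the phenotype mean exactly", {
  set.seed(1)
  for (slope in c(0.5, 2)) {
    fish <- tibble::tibble(
      fish_id = sprintf("f%02d", 1:60),
      family = sample(c("fam1", "fam2", "fam3"), 60, replace = TRUE),
      sex = sample(c("F", "M"), 60, replace = TRUE),
      std_length_mm = rnorm(60, 30, 3)
    )
    fish$tooth_total <- 40 + slope * fish$std_length_mm +
      2 * (fish$sex == "M") + rnorm(60, 0, 1)
    cc <- size_correct(fish)
    expect_lt(abs(mean(cc$corrected) - mean(fish$tooth_total)), 1e-9)
    expect_true("length" %in% attr(cc, "covariates_used"))
  }
})

test_that("length correction equals the closed-form regression residuals", {
  # 4 fish, exact linear length effect (slope 2) plus class offsets
  fish <- tibble::tibble(
    fish_id = c("a", "b", "c", "d"),
    family = "fam1", sex = c("F", "F", "M", "M"),
    std_length_mm = c(20, 25, 30, 35),
    tooth_total = c(0, 0, 10, 10) + 2 * c(20, 25, 30, 35) + 40
  )
  cc <- suppressMessages(size_correct(fish))
  # closed-form simple-regression oracle (normal equations)
  x <- fish$std_length_mm; y <- fish$tooth_total
  b1 <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  b0 <- mean(y) - b1 * mean(x)
  resid_hand <- y - (b0 + b1 * x)
  expect_equal(cc$corrected, resid_hand + (b0 + b1 * mean(x)), tolerance = 1e-9)
})

test_that("degenerate size-correction inputs are handled, not hidden", {
  fish <- tibble::tibble(fish_id = letters[1:6], family = "fam1", sex = "F",
                         std_length_mm = rnorm(6, 30), tooth_total = rep(5, 6))
  expect_warning(cc <- size_correct(fish), "constant")
  expect_identical(cc$corrected, fish$tooth_total)
  # single sex / single family are skipped with a note, never an error
  fish$tooth_total <- rnorm(6, 50)
  cc2 <- size_correct(fish)
  expect_true(any(grepl("sex skipped", attr(cc2, "notes"))))
  expect_true(any(grepl("family skipped", attr(cc2, "notes"))))
  expect_error(size_correct(fish[1:3, ]), "4 fish")
})

test_that("two-locus haplotypes map to diploid classes per the cross design", {
  # marine-left / benthic-right haplotype is recombinant
  fish <- tibble::tibble(
    fish_id = c("r_hap", "mm", "unassignable"),
    marker_L = c("M/M", "M/M", "B/M"),
    marker_R = c("B/M", "M/M", "M/M")
  )
  res <- suppressMessages(assign_genotype_class(fish))
  expect_identical(res$class, c("RM", "MM", NA))
  expect_false(res$assignable[3])
  expect_match(res$note[3], "inconsistent")
})

test_that("the full Punnett enumeration yields exactly the design classes", {
  # cross: parent 1 haplotypes {R, M}, parent 2 haplotypes {M, B}
  haps1 <- list(R = c("M", "B"), M = c("M", "M"))
  haps2 <- list(M = c("M", "M"), B = c("B", "B"))
  combos <- expand.grid(h1 = names(haps1), h2 = names(haps2),
                        stringsAsFactors = FALSE)
  fish <- tibble::tibble(
    fish_id = paste(combos$h1, combos$h2, sep = "x"),
    marker_L = mapply(function(a, b) paste(haps1[[a]][1], haps2[[b]][1], sep = "/"),
                      combos$h1, combos$h2),
    marker_R = mapply(function(a, b) paste(haps1[[a]][2], haps2[[b]][2], sep = "/"),
                      combos$h1, combos$h2)
  )
  res <- assign_genotype_class(fish)
  expect_setequal(res$class, c("RM", "RB", "MM", "MB"))
  expect_true(all(res$assignable))
})

test_that("genotype ANOVA matches the textbook sums-of-squares oracle", {
  d <- tibble::tibble(class = rep(c("MM", "BB"), each = 2),
                      corrected = c(10, 12, 20, 22))
  av <- genotype_anova(d)
  # independent oracle: explicit between/within sums of squares
  grand <- mean(d$corrected)
  ssb <- sum(tapply(d$corrected, d$class, function(g) length(g) * (mean(g) - grand)^2))
  ssw <- sum(tapply(d$corrected, d$class, function(g) sum((g - mean(g))^2)))
  f_hand <- (ssb / 1) / (ssw / 2)
  expect_equal(av$F, f_hand, tolerance = 1e-9)
  expect_equal(av$F, 50, tolerance = 1e-9)
  expect_equal(av$p_value, pf(50, 1, 2, lower.tail = FALSE), tolerance = 1e-9)
  expect_identical(av$df_between, 1)
  cm <- tidy(av)
  expect_equal(cm$mean[cm$class == "BB"], 21)
})

test_that("ANOVA degenerate classes are excluded or rejected", {
  d <- tibble::tibble(class = c("MM", "MM", "MB", "MB", "BB"),
                      corrected = c(1, 2, 3, 4, 5))
  expect_warning(av <- genotype_anova(d), "BB")
  expect_identical(sort(av$class_means$class), c("MB", "MM"))
  expect_error(
    suppressWarnings(genotype_anova(tibble::tibble(class = "MM", corrected = 1:4 * 1.0))),
    "two classes")
})

test_that("recombinant LRT calls the planted direction with nested statistics", {
  # additive benthic effect d = 2 teeth per benthic chromosome; the R
  # haplotype carries the benthic (or, mirrored, the marine) causal allele
  run_one <- function(means, seed) {
    p <- cross_sim_params(150, means, residual_sd = 1, seed = seed,
                          integer_counts = FALSE)
    recombinant_direction_lrt(simulate_cross(p), response = "tooth_total",
                              class = "true_class")
  }
  withr::with_seed(21, {
    benthic_means <- c(RM = 52, RB = 54, MM = 50, MB = 52)
    marine_means <- c(RM = 50, RB = 52, MM = 50, MB = 52)
    res_b <- lapply(1:30, function(i) run_one(benthic_means, sample.int(1e6, 1)))
    res_m <- lapply(1:30, function(i) run_one(marine_means, sample.int(1e6, 1)))
    ok_b <- vapply(res_b, function(x) {
      x$supported_direction == "benthic-like" && x$p_value < 0.01
    }, TRUE)
    ok_m <- vapply(res_m, function(x) {
      x$supported_direction == "marine-like" && x$p_value < 0.01
    }, TRUE)
    expect_gte(mean(ok_b), 0.8)
    expect_gte(mean(ok_m), 0.8)
    # nesting invariants hold in every fit
    for (x in c(res_b, res_m)) {
      expect_gte(x$full_loglik, x$marine_merge_loglik)
      expect_gte(x$full_loglik, x$benthic_merge_loglik)
      expect_gte(x$stat_marine_merge, 0)
      expect_gte(x$stat_benthic_merge, 0)
    }
  })
})

test_that("benthic chromosome test is NA when chromosomes are indistinguishable", {
  d <- tibble::tibble(marker = c("B1/M", "B1/B1"), corrected = c(1, 2))
  res <- benthic_chromosome_lrt(d, benthic_alleles = c("B1", "B1"))
  expect_false(res$applicable)
  expect_true(all(is.na(res$results$p_value)))
  expect_match(res$reason, "distinguish")
  # marker present but one chromosome absent from the cross
  withr::with_seed(4, {
    d2 <- make_benthic_cross(50, 2, 0)
    d2$marker <- gsub("B2", "B1", d2$marker)
    expect_false(benthic_chromosome_lrt(d2)$applicable)
  })
})

test_that("benthic chromosome test detects real effects and only those", {
  withr::with_seed(31, {
    hits <- replicate(30, {
      d <- make_benthic_cross(200, 2, 2)
      all(benthic_chromosome_lrt(d)$results$p_value < 0.05)
    })
    expect_gte(mean(hits), 0.95)
  })
})

test_that("Mendelian ratio chi-square matches the hand oracle", {
  exact <- mendelian_ratio_test(c(25, 50, 25), c(1, 2, 1))
  expect_equal(exact$statistic, 0)
  expect_equal(exact$p_value, 1)

  # hand oracle: expected (8, 16, 8) -> 0.5 + 1 + 4.5 = 6
  r <- mendelian_ratio_test(c(10, 20, 2), c(1, 2, 1))
  expect_equal(r$statistic, 6, tolerance = 1e-9)
  expect_identical(r$df, 2L)
  expect_equal(r$p_value, exp(-3), tolerance = 1e-9)
  oracle <- suppressWarnings(chisq.test(c(10, 20, 2), p = c(1, 2, 1) / 4))
  expect_equal(r$statistic, unname(oracle$statistic), tolerance = 1e-12)

  bc <- mendelian_ratio_test(c(60, 40), c(1, 1))
  expect_equal(bc$statistic, 4, tolerance = 1e-9)
  expect_equal(bc$p_value, 0.0455, tolerance = 1e-3)

  expect_error(mendelian_ratio_test(c(0, 0), c(1, 1)), "zero")
  expect_error(mendelian_ratio_test(c(1, 2, 3), c(1, 1)), "same number")
  expect_error(mendelian_ratio_test(c(1, 2), c(1, 0)), "positive")
})

test_that("correction followed by ANOVA is invariant to shifting all lengths", {
  withr::with_seed(9, {
    p <- cross_sim_params(100, c(MM = 50, MB = 55, BB = 60), residual_sd = 1,
                          length_slope = 1.5, seed = 77, integer_counts = FALSE)
    fish <- simulate_cross(p)
    run <- function(f) {
      cc <- size_correct(f)
      glance(genotype_anova(dplyr::mutate(tibble::as_tibble(cc),
                                          class = f$true_class)))
    }
    shifted <- dplyr::mutate(fish, std_length_mm = std_length_mm + 100)
    expect_equal(run(fish), run(shifted), tolerance = 1e-9)
  })
})

test_that("back-transformed class means recover the simulation truth", {
  withr::with_seed(12, {
    truth <- c(MM = 50, MB = 55, BB = 60)
    p <- cross_sim_params(300, truth, residual_sd = 2, length_slope = 2,
                          seed = 5, integer_counts = FALSE)
    fish <- simulate_cross(p)
    cc <- size_correct(fish)
    av <- genotype_anova(dplyr::mutate(tibble::as_tibble(cc),
                                       class = fish$true_class))
    cm <- av$class_means
    # truth means shift with the covariate back-transformation reference;
    # compare class mean *differences*, which are reference-free
    expect_lt(abs((cm$mean[cm$class == "BB"] - cm$mean[cm$class == "MM"]) - 10),
              3 * sqrt(sum((cm$se[cm$class %in% c("BB", "MM")])^2)))
    expect_lt(abs((cm$mean[cm$class == "MB"] - cm$mean[cm$class == "MM"]) - 5),
              3 * sqrt(sum((cm$se[cm$class %in% c("MB", "MM")])^2)))
  })
})
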