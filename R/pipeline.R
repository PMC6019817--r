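#' Validate a pipeline configuration and read its inputs
#'
#' A run configuration is a named list with a `seed`, an `out_dir`, and one
#' entry per requested stage (`simulate`, `crossqtl`, `concord`, `enrich`);
#' each stage entry names its input files and parameters. Every referenced
#' path must exist at validation time.
#'
#' @param config Named list (see [run_pipeline()]).
#' @return A list of parsed in-memory tables, one entry per stage.
#' @export
read_inputs <- function(config) {
  stopifnot(is.list(config))
  paths <- unlist(lapply(config[c("crossqtl", "concord", "enrich")], function(st) {
    if (is.null(st)) NULL else st[intersect(names(st),
                                            c("phenotypes", "vcf", "panel",
                                              "genome", "expr", "groups", "sets"))]
  }))
  paths <- as.character(paths %||% character(0))
  missing <- paths[!file.exists(paths)]
  if (length(missing) > 0) {
    abort(sprintf("Input file(s) not found: %s", paste(missing, collapse = ", ")))
  }
  out <- list()
  if (!is.null(config$crossqtl)) {
    out$crossqtl <- list(phenotypes = read_phenotypes(config$crossqtl$phenotypes))
  }
  if (!is.null(config$concord)) {
    st <- config$concord
    out$concord <- c(read_vcf(st$vcf),
                     list(panel = read_sample_panel(st$panel),
                          genome = if (!is.null(st$genome)) read_genome(st$genome)))
  }
  if (!is.null(config$enrich)) {
    st <- config$enrich
    out$enrich <- list(expr = read_expression(st$expr),
                       groups = read_groups(st$groups),
                       sets = read_gmt(st$sets))
  }
  out
}

stage_warning <- function(manifest, msg) {
  manifest$warnings <- c(manifest$warnings, msg)
  manifest
}

#' Run the fine-mapping pipeline
#'
#' Executes the selected stages in dependency order and writes their outputs
#' plus a machine-readable run manifest under `config$out_dir`. With
#' identical config, inputs and seed the outputs are byte-identical.
#'
#' Config layout (all stages optional):
#' * `seed`, `out_dir`
#' * `simulate`: any of `cross` (a [cross_sim_params()]), `panel`
#'   (a [variant_panel_params()]), `expression` (an [expr_sim_params()])
#' * `crossqtl`: `phenotypes` (TSV path), optional `response`, `alpha`,
#'   `markers`, `recombinant_haplotype`
#' * `concord`: `vcf`, `panel`, optional `genome` (paths), optional
#'   `interval` (`c(start, end)`), `thresholds` (a [filter_thresholds()]),
#'   `score_threshold`
#' * `enrich`: `expr`, `groups`, `sets` (paths), optional `n_perm`, `alpha`
#'
#' @param config Named configuration list.
#' @return The run manifest (list), invisibly written as
#'   `manifest.json`; stage results are attached in `$results`.
#' @export
run_pipeline <- function(config) {
  stopifnot(is.list(config), !is.null(config$out_dir))
  out_dir <- config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- config$seed %||% 1L
  manifest <- list(
    tool = "qtlfine",
    version = as.character(utils::packageVersion("qtlfine")),
    seed = seed,
    config = config_echo(config),
    input_checksums = list(),
    row_counts = list(),
    warnings = character(0)
  )
  results <- list()

  if (!is.null(config$simulate)) {
    sim <- config$simulate
    if (!is.null(sim$cross)) {
      fish <- simulate_cross(sim$cross)
      write_phenotypes(dplyr::select(fish, -dplyr::any_of("true_class")),
                       file.path(out_dir, "phenotypes.tsv"))
      jsonlite::write_json(list(true_class = fish$true_class),
                           file.path(out_dir, "cross_truth.json"))
      manifest$row_counts$simulate_cross <- nrow(fish)
      results$cross <- fish
    }
    if (!is.null(sim$panel)) {
      pan <- simulate_variant_panel(sim$panel)
      write_vcf(pan$variants, pan$calls, file.path(out_dir, "panel.vcf"),
                contig_lengths = setNames(Biostrings::width(pan$genome),
                                          names(pan$genome)))
      write_sample_panel(pan$panel, file.path(out_dir, "panel_manifest.tsv"))
      write_genome(pan$genome, file.path(out_dir, "genome.fa"))
      jsonlite::write_json(pan$truth, file.path(out_dir, "panel_truth.json"),
                           auto_unbox = TRUE)
      manifest$row_counts$simulate_panel <- nrow(pan$variants)
      results$panel <- pan
    }
    if (!is.null(sim$expression)) {
      ex <- simulate_expression(sim$expression)
      write_expression(ex$expr, file.path(out_dir, "expression.tsv"))
      readr::write_tsv(ex$groups, file.path(out_dir, "groups.tsv"), progress = FALSE)
      write_gmt(ex$sets, file.path(out_dir, "sets.gmt"))
      jsonlite::write_json(ex$truth, file.path(out_dir, "expression_truth.json"))
      manifest$row_counts$simulate_expression <- nrow(ex$expr)
      results$expression <- ex
    }
  }

  inputs <- read_inputs(config)
  for (p in unlist(lapply(config[c("crossqtl", "concord", "enrich")], function(st) {
    st[intersect(names(st), c("phenotypes", "vcf", "panel", "genome",
                              "expr", "groups", "sets"))]
  }))) {
    manifest$input_checksums[[basename(p)]] <- unname(tools::md5sum(p))
  }

  if (!is.null(config$crossqtl)) {
    st <- config$crossqtl
    fish <- inputs$crossqtl$phenotypes
    corrected <- size_correct(fish, response = st$response %||% "tooth_total",
                              alpha = st$alpha %||% 0.05)
    classes <- assign_genotype_class(
      fish,
      markers = st$markers %||% c("marker_L", "marker_R"),
      recombinant_haplotype = st$recombinant_haplotype %||% c(L = "M", R = "B"))
    d <- dplyr::left_join(tibble::as_tibble(corrected), classes, by = "fish_id")
    readr::write_tsv(dplyr::select(d, fish_id, class, corrected),
                     file.path(out_dir, "corrected_phenotypes.tsv"),
                     na = "NA", progress = FALSE)
    av <- genotype_anova(d, keep_classes = c("MM", "MB", "BB"))
    lrt <- if (any(grepl("R", d$class[!is.na(d$class)]))) {
      recombinant_direction_lrt(d)
    }
    jsonlite::write_json(
      list(anova = c(glance(av), list(class_means = av$class_means)),
           direction_lrt = if (!is.null(lrt)) unclass(lrt)),
      file.path(out_dir, "cross_models.json"),
      auto_unbox = TRUE, digits = NA, null = "null")
    manifest$row_counts$crossqtl <- nrow(d)
    results$crossqtl <- list(corrected = corrected, classes = classes,
                             anova = av, direction_lrt = lrt)
  }

  if (!is.null(config$concord)) {
    st <- config$concord
    scr <- screen_variants(
      inputs$concord$variants, inputs$concord$calls, inputs$concord$panel,
      genome = inputs$concord$genome,
      thresholds = st$thresholds %||% filter_thresholds(),
      interval = st$interval,
      score_threshold = st$score_threshold %||% 1.0,
      per_fish = isTRUE(st$per_fish))
    readr::write_tsv(
      dplyr::select(scr$scores, chrom, pos, ref, alt, class = variant_class,
                    score, p_pos, p_neg),
      file.path(out_dir, "concordance.tsv"), na = "NA", progress = FALSE)
    jsonlite::write_json(c(glance(scr$report), list(tally = scr$tally)),
                         file.path(out_dir, "cluster_report.json"),
                         auto_unbox = TRUE, digits = NA)
    if (scr$report$count >= 1) {
      write_bed_span(scr$scores$chrom[1], scr$report$min_pos,
                     scr$report$max_pos %||% scr$report$min_pos,
                     file.path(out_dir, "perfect_span.bed"))
    }
    manifest$row_counts$concord <- nrow(scr$scores)
    results$concord <- scr
  }

  if (!is.null(config$enrich)) {
    st <- config$enrich
    res <- evaluate_gene_sets(inputs$enrich$expr, inputs$enrich$groups,
                              inputs$enrich$sets,
                              n_perm = st$n_perm %||% 10000,
                              seed = seed, alpha = st$alpha %||% 0.05)
    readr::write_tsv(tibble::as_tibble(res),
                     file.path(out_dir, "enrichment.tsv"), na = "NA",
                     progress = FALSE)
    z <- attr(res, "gene_z")
    readr::write_tsv(tibble::as_tibble(z), file.path(out_dir, "gene_z.tsv"),
                     na = "NA", progress = FALSE)
    manifest$row_counts$enrich <- nrow(res)
    results$enrich <- res
  }

  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       force = TRUE)
  manifest$results <- results
  invisible(manifest)
}

# Echo the config with parameter objects flattened to plain lists so the
# manifest is JSON-serialisable.
config_echo <- function(x) {
  if (is.list(x)) {
    lapply(unclass(x), config_echo)
  } else if (is.function(x)) {
    "<function>"
  } else {
    x
  }
}
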