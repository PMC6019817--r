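#' Parameters for a simulated two-group expression matrix
#'
#' Generative model for a wild-type vs mutant expression comparison:
#' per-gene baseline log2 abundances drawn from `baseline_law`, i.i.d.
#' Gaussian noise of `noise_sd` log2 units per measurement, and concerted
#' shifts of `shift` log2 units injected into the mutant group for every gene
#' of a designated set. Values are exponentiated to an FPKM-like non-negative
#' scale.
#'
#' @param n_genes Number of genes (rows).
#' @param n_per_group Samples per group (>= 2); the study design this
#'   emulates has 3 per group.
#' @param baseline_law Distribution spec for baseline log2 abundance
#'   (function or list; see [simulate_variant_panel()] for the spec format).
#' @param noise_sd Measurement noise standard deviation, log2 units.
#' @param sets A list of gene sets, each `list(name = , size = , shift = )`
#'   with `shift` in log2 units (0 = null set). Member genes are drawn
#'   without replacement and sets are disjoint.
#' @param seed Integer seed.
#' @return A validated `expr_sim_params` list.
#' @export
expr_sim_params <- function(n_genes = 2000,
                            n_per_group = 3,
                            baseline_law = list(dist = "normal", mean = 4, sd = 2),
                            noise_sd = 0.5,
                            sets = list(),
                            seed = 1L) {
  p <- list(
    n_genes = check_count(n_genes, "n_genes", min = 2L),
    n_per_group = check_count(n_per_group, "n_per_group", min = 2L),
    baseline_law = baseline_law,
    noise_sd = check_number(noise_sd, "noise_sd", min = 0, strict = TRUE),
    sets = sets,
    seed = check_count(seed, "seed")
  )
  if (length(sets) > 0) {
    sizes <- vapply(sets, function(s) check_count(s$size, "set size", 1L), 1L)
    nms <- vapply(sets, function(s) s$name %||% "", "")
    if (any(!nzchar(nms)) || anyDuplicated(nms)) {
      abort("Each set needs a unique non-empty `name`.")
    }
    if (sum(sizes) > p$n_genes) {
      abort("Total set size exceeds `n_genes`; sets are drawn disjoint.")
    }
  }
  structure(p, class = "expr_sim_params")
}

#' Simulate an expression matrix with injected gene-set shifts
#'
#' @param params An [expr_sim_params()] object.
#' @return A list with
#'   * `expr`: tibble, `gene_id` column plus one numeric column per sample
#'     (FPKM-like, non-negative),
#'   * `groups`: tibble (`sample_id`, `group` in `wildtype`/`mutant`),
#'   * `sets`: named list of member gene-id character vectors (GMT-ready),
#'   * `truth`: tibble (`set`, `size`, `shift`, `nonnull`).
#' @examples
#' p <- expr_sim_params(n_genes = 100, sets = list(list(name = "s1", size = 10, shift = -1)),
#'                      seed = 3)
#' sim <- simulate_expression(p)
#' head(sim$expr)
#' @export
simulate_expression <- function(params) {
  stopifnot(inherits(params, "expr_sim_params"))
  p <- params
  gene_id <- sprintf("gene_%05d", seq_len(p$n_genes))
  if (anyDuplicated(gene_id)) abort("Duplicate gene ids (generation error).")
  n_samples <- 2L * p$n_per_group
  sample_id <- c(sprintf("wt_%d", seq_len(p$n_per_group)),
                 sprintf("mut_%d", seq_len(p$n_per_group)))
  group <- rep(c("wildtype", "mutant"), each = p$n_per_group)

  baseline <- with_stream(p$seed, 21L, draw_law(p$baseline_law, p$n_genes))
  noise <- with_stream(p$seed, 22L,
                       matrix(rnorm(p$n_genes * n_samples, 0, p$noise_sd),
                              nrow = p$n_genes))

  log2expr <- baseline + noise
  members <- list()
  if (length(p$sets) > 0) {
    pool <- with_stream(p$seed, 23L, sample(gene_id))
    offset <- 0L
    for (s in p$sets) {
      ids <- pool[(offset + 1L):(offset + s$size)]
      offset <- offset + s$size
      members[[s$name]] <- sort(ids)
      shift <- check_number(s$shift %||% 0, "shift")
      if (shift != 0) {
        rows <- match(ids, gene_id)
        log2expr[rows, group == "mutant"] <-
          log2expr[rows, group == "mutant"] + shift
      }
    }
  }

  expr <- tibble::as_tibble(as.data.frame(2^log2expr))
  names(expr) <- sample_id
  expr <- dplyr::bind_cols(tibble::tibble(gene_id = gene_id), expr)

  truth <- tibble::tibble(
    set = names(members) %||% character(0),
    size = vapply(p$sets, function(s) as.integer(s$size), 1L),
    shift = vapply(p$sets, function(s) as.double(s$shift %||% 0), 1.0),
    nonnull = vapply(p$sets, function(s) (s$shift %||% 0) != 0, TRUE)
  )

  list(
    expr = expr,
    groups = tibble::tibble(sample_id = sample_id, group = group),
    sets = members,
    truth = truth
  )
}
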