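# Interchange formats. TSV dialect: tab-separated, UTF-8, mandatory header,
# "NA" for missing scalars. All coordinates are 1-based inclusive except the
# BED writer, which converts to 0-based half-open at write time only.

#' Read a phenotype table
#'
#' Expects the columns `fish_id`, `family`, `sex`, `std_length_mm`,
#' `tooth_total` plus any marker columns; errors name the first missing
#' column.
#'
#' @param path Path to a tab-separated phenotype file.
#' @return A tibble.
#' @export
read_phenotypes <- function(path) {
  tbl <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  required <- c("fish_id", "family", "sex", "std_length_mm", "tooth_total")
  missing <- setdiff(required, names(tbl))
  if (length(missing) > 0) {
    abort(sprintf("%s: schema error, missing column(s): %s",
                  basename(path), paste(missing, collapse = ", ")))
  }
  if (any(!is.na(tbl$std_length_mm) & tbl$std_length_mm <= 0)) {
    abort(sprintf("%s: `std_length_mm` must be positive.", basename(path)))
  }
  if (any(!is.na(tbl$tooth_total) & tbl$tooth_total < 0)) {
    abort(sprintf("%s: `tooth_total` must be non-negative.", basename(path)))
  }
  tbl
}

#' Write a phenotype table
#' @param fish Tibble of fish records.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_phenotypes <- function(fish, path) {
  readr::write_tsv(fish, path, na = "NA", progress = FALSE)
  invisible(path)
}

#' Read a sample manifest
#'
#' Columns `sample_id`, `qtl_status` (`QTL_pos`/`QTL_neg`) and `coverage`
#' (`high`/`low`) are required.
#'
#' @param path Path to a tab-separated manifest.
#' @return A tibble.
#' @export
read_sample_panel <- function(path) {
  tbl <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  missing <- setdiff(c("sample_id", "qtl_status", "coverage"), names(tbl))
  if (length(missing) > 0) {
    abort(sprintf("%s: schema error, missing column(s): %s",
                  basename(path), paste(missing, collapse = ", ")))
  }
  bad <- setdiff(unique(tbl$qtl_status), c("QTL_pos", "QTL_neg"))
  if (length(bad) > 0) {
    abort(sprintf("%s: invalid qtl_status value(s): %s",
                  basename(path), paste(bad, collapse = ", ")))
  }
  bad_cov <- setdiff(unique(tbl$coverage), c("high", "low"))
  if (length(bad_cov) > 0) {
    abort(sprintf("%s: invalid coverage value(s): %s",
                  basename(path), paste(bad_cov, collapse = ", ")))
  }
  tbl
}

#' @rdname read_sample_panel
#' @param panel Manifest tibble.
#' @export
write_sample_panel <- function(panel, path) {
  readr::write_tsv(panel, path, na = "NA", progress = FALSE)
  invisible(path)
}

gt_to_vcf <- c(hom_ref = "0/0", het = "0/1", hom_alt = "1/1", missing = "./.")

#' Write a variant panel as VCFv4.2
#'
#' Site QUAL from `site_quality`; per-sample `GT` and `GQ` FORMAT fields;
#' missing genotypes written `./.` with GQ `.`.
#'
#' @param variants Site tibble (`variant_id`, `chrom`, `pos`, `ref`, `alt`,
#'   `site_quality`).
#' @param calls Long call tibble (`variant_id`, `sample_id`, `gt`, `gq`).
#' @param path Output path (plain text).
#' @param contig_lengths Optional named integer vector for `##contig` lines.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(variants, calls, path, contig_lengths = NULL) {
  samples <- unique(calls$sample_id)
  gt_wide <- calls |>
    dplyr::mutate(
      field = ifelse(gt == "missing", "./.:.",
                     paste0(gt_to_vcf[gt], ":", format(gq, trim = TRUE)))
    ) |>
    dplyr::select(variant_id, sample_id, field) |>
    tidyr::pivot_wider(names_from = sample_id, values_from = field)

  body <- variants |>
    dplyr::left_join(gt_wide, by = "variant_id") |>
    dplyr::arrange(chrom, pos)
  header <- c(
    "##fileformat=VCFv4.2",
    sprintf("##source=qtlfine_%s", as.character(utils::packageVersion("qtlfine"))),
    if (!is.null(contig_lengths)) {
      sprintf("##contig=<ID=%s,length=%d>", names(contig_lengths),
              as.integer(contig_lengths))
    },
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=GQ,Number=1,Type=Float,Description=\"Genotype quality\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t")
  )
  cols <- c(list(body$chrom, format(body$pos, trim = TRUE, scientific = FALSE),
                 ".", body$ref, body$alt,
                 format(body$site_quality, trim = TRUE, scientific = FALSE),
                 "PASS", ".", "GT:GQ"),
            lapply(samples, function(s) body[[s]]))
  lines <- do.call(paste, c(cols, sep = "\t"))
  writeLines(c(header, lines), path)
  invisible(path)
}

#' Read a VCF into site and call tables
#'
#' Parses a VCFv4.2 file (via \pkg{vcfR}) into the screen's site/call
#' tables. Multiallelic records are split into one biallelic record per
#' alternate allele; symbolic alternate alleles are rejected. `./.` (or any
#' genotype containing `.`) becomes a `missing` call; an absent GQ is `NA`.
#'
#' @param path Path to a VCF file.
#' @return List with `variants` (tibble `variant_id`, `chrom`, `pos`, `ref`,
#'   `alt`, `site_quality`, `variant_class`) and `calls` (tibble
#'   `variant_id`, `sample_id`, `gt`, `gq`).
#' @export
read_vcf <- function(path) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- t(fix)  # single-record VCFs drop to a vector
  fix <- as.data.frame(fix, stringsAsFactors = FALSE)
  if (nrow(fix) == 0) abort(sprintf("%s: no variant records.", basename(path)))
  gt_raw <- vcfR::extract.gt(vcf, element = "GT")
  gq_raw <- suppressWarnings(vcfR::extract.gt(vcf, element = "GQ", as.numeric = TRUE))
  if (is.null(gq_raw)) gq_raw <- matrix(NA_real_, nrow(gt_raw), ncol(gt_raw),
                                        dimnames = dimnames(gt_raw))
  samples <- colnames(gt_raw)

  out_v <- list(); out_c <- list()
  for (i in seq_len(nrow(fix))) {
    alts <- strsplit(fix$ALT[i], ",", fixed = TRUE)[[1]]
    if (any(grepl("^<", alts))) {
      abort(sprintf("%s: record %d has a symbolic alternate allele (%s); not supported.",
                    basename(path), i, fix$ALT[i]))
    }
    for (k in seq_along(alts)) {
      vid <- sprintf("%s:%s_%s/%s", fix$CHROM[i], fix$POS[i], fix$REF[i], alts[k])
      out_v[[length(out_v) + 1L]] <- tibble::tibble(
        variant_id = vid, chrom = fix$CHROM[i], pos = as.integer(fix$POS[i]),
        ref = fix$REF[i], alt = alts[k],
        site_quality = as.numeric(fix$QUAL[i])
      )
      g <- gt_raw[i, ]
      n_alt <- vapply(strsplit(ifelse(is.na(g), ".", g), "[/|]"), function(a) {
        if (any(a == ".")) return(NA_integer_)
        sum(a == as.character(k))
      }, 1L)
      out_c[[length(out_c) + 1L]] <- tibble::tibble(
        variant_id = vid, sample_id = samples,
        gt = dplyr::case_when(is.na(n_alt) ~ "missing",
                              n_alt == 0 ~ "hom_ref",
                              n_alt == 1 ~ "het",
                              TRUE ~ "hom_alt"),
        gq = unname(gq_raw[i, ])
      )
    }
  }
  variants <- dplyr::bind_rows(out_v) |>
    dplyr::mutate(variant_class = ifelse(nchar(ref) == 1 & nchar(alt) == 1,
                                         "SNP", "indel"))
  list(variants = variants, calls = dplyr::bind_rows(out_c))
}

#' Read / write gene sets in GMT format
#'
#' One set per line: name, description, then tab-separated member gene ids.
#' Malformed lines are reported with their line number.
#'
#' @param path Path to a `.gmt` file.
#' @return Named list of character vectors of member gene ids.
#' @export
read_gmt <- function(path) {
  lines <- readr::read_lines(path, progress = FALSE)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 3)
  if (length(bad) > 0) {
    abort(sprintf("%s: line %d has %d field(s); GMT requires name, description and >= 1 gene.",
                  basename(path), bad[1], lengths(fields)[bad[1]]))
  }
  sets <- lapply(fields, function(f) f[-(1:2)])
  names(sets) <- vapply(fields, `[[`, "", 1L)
  if (anyDuplicated(names(sets))) {
    abort(sprintf("%s: duplicate set name(s): %s", basename(path),
                  paste(unique(names(sets)[duplicated(names(sets))]), collapse = ", ")))
  }
  sets
}

#' @rdname read_gmt
#' @param sets Named list of member gene-id vectors.
#' @param descriptions Optional character vector of set descriptions.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  descriptions <- descriptions %||% rep("na", length(sets))
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], descriptions[i], sets[[i]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Read / write an expression matrix
#'
#' Gene rows by sample columns, tab-separated, first column `gene_id`.
#'
#' @param path Path to a tab-separated expression file.
#' @return A tibble.
#' @export
read_expression <- function(path) {
  tbl <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (names(tbl)[1] != "gene_id") {
    abort(sprintf("%s: first column must be `gene_id`.", basename(path)))
  }
  if (anyDuplicated(tbl$gene_id)) {
    abort(sprintf("%s: duplicate gene id(s).", basename(path)))
  }
  tbl
}

#' @rdname read_expression
#' @param expr Expression tibble (`gene_id` + sample columns).
#' @export
write_expression <- function(expr, path) {
  readr::write_tsv(expr, path, na = "NA", progress = FALSE)
  invisible(path)
}

#' Read a sample-group table
#'
#' Columns `sample_id` and `group` (`wildtype`/`mutant`).
#'
#' @param path Path to a tab-separated file.
#' @return A tibble.
#' @export
read_groups <- function(path) {
  tbl <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  missing <- setdiff(c("sample_id", "group"), names(tbl))
  if (length(missing) > 0) {
    abort(sprintf("%s: schema error, missing column(s): %s",
                  basename(path), paste(missing, collapse = ", ")))
  }
  bad <- setdiff(unique(tbl$group), c("wildtype", "mutant"))
  if (length(bad) > 0) {
    abort(sprintf("%s: invalid group value(s): %s", basename(path),
                  paste(bad, collapse = ", ")))
  }
  tbl
}

#' Write a genomic span as BED
#'
#' Converts from the package's 1-based inclusive coordinates to BED's
#' 0-based half-open convention at write time.
#'
#' @param chrom Chromosome name.
#' @param start,end 1-based inclusive span.
#' @param path Output path.
#' @param name Feature name (default `"perfect_cluster"`).
#' @return `path`, invisibly.
#' @export
write_bed_span <- function(chrom, start, end, path, name = "perfect_cluster") {
  stopifnot(start >= 1, end >= start)
  writeLines(sprintf("%s\t%d\t%d\t%s", chrom, as.integer(start) - 1L,
                     as.integer(end), name), path)
  invisible(path)
}

#' Read / write a FASTA genome
#' @param path FASTA path.
#' @return A [Biostrings::DNAStringSet].
#' @export
read_genome <- function(path) {
  Biostrings::readDNAStringSet(path)
}

#' @rdname read_genome
#' @param genome A [Biostrings::DNAStringSet].
#' @export
write_genome <- function(genome, path) {
  Biostrings::writeXStringSet(genome, path)
  invisible(path)
}
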