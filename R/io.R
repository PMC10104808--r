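#' @importFrom rlang .data
#' @importFrom ggplot2 autoplot
#' @keywords internal
"_PACKAGE"

# MAF variant-classification vocabulary (MC3 dialect subset).
maf_classifications <- c(
  "Missense_Mutation", "Nonsense_Mutation", "Splice_Site",
  "Frame_Shift_Del", "Frame_Shift_Ins", "In_Frame_Del", "In_Frame_Ins",
  "Translation_Start_Site", "Nonstop_Mutation", "Silent",
  "3'UTR", "5'UTR", "Intron", "3'Flank", "5'Flank", "Splice_Region", "IGR"
)

# Classifications that make a tumor TP53mut (non-synonymous coding or splice).
qualifying_classifications <- c(
  "Missense_Mutation", "Nonsense_Mutation", "Splice_Site",
  "Translation_Start_Site", "Nonstop_Mutation",
  "Frame_Shift_Del", "Frame_Shift_Ins", "In_Frame_Del", "In_Frame_Ins"
)

# Classifications taken as evidence of protein truncation (fallback LOF rule).
truncating_classifications <- c(
  "Nonsense_Mutation", "Frame_Shift_Del", "Frame_Shift_Ins",
  "Splice_Site", "Translation_Start_Site", "Nonstop_Mutation"
)

pipeline_log <- function(..., verbose = getOption("tp53pancan.verbose", FALSE)) {
  if (isTRUE(verbose)) message("[tp53pancan] ", ...)
  invisible(NULL)
}

#' Run configuration
#'
#' Bundles the tunable parameters of the pipeline with validation. Defaults
#' reflect the reference analysis: raw significance 0.05 for consensus
#' counting, FDR 10% everywhere, fixed subsample size 15, consensus threshold
#' 16 cancer types, cohort inclusion at 7 TP53-mutant tumors per type, and the
#' hotspot recurrence screen at 2 carriers / 1% prevalence.
#'
#' @param alpha_raw Raw p-value threshold used when counting cancer types for
#'   consensus membership.
#' @param fdr_q Benjamini-Hochberg false-discovery-rate level.
#' @param n_sub Fixed per-group sample size for subsampled contrasts
#'   (one of 10, 15, 20).
#' @param consensus_threshold Minimum number of cancer types with raw p below
#'   `alpha_raw` for consensus membership.
#' @param min_mut_per_type Minimum number of TP53-mutant tumors a cancer type
#'   must have to enter the cohort.
#' @param hotspot_min_count Minimum carrier count for the recurrence screen.
#' @param hotspot_min_prev Minimum prevalence for the recurrence screen.
#' @param hotspot_denominator Denominator of hotspot prevalences: `"mut"`
#'   (TP53-mutant tumors of the type) or `"all"` (all tumors of the type).
#' @param log2_offset Offset used in the `log2(x + offset)` expression
#'   transform.
#' @param seed Integer seed for all randomized steps.
#' @return A list of class `tp53_config`.
#' @export
tp53_config <- function(alpha_raw = 0.05, fdr_q = 0.10, n_sub = 15,
                        consensus_threshold = 16, min_mut_per_type = 7,
                        hotspot_min_count = 2, hotspot_min_prev = 0.01,
                        hotspot_denominator = c("mut", "all"),
                        log2_offset = 1, seed = 1L) {
  stopifnot(alpha_raw > 0, alpha_raw < 1, fdr_q > 0, fdr_q < 1,
            n_sub >= 2, consensus_threshold >= 1, min_mut_per_type >= 0,
            hotspot_min_count >= 1, hotspot_min_prev >= 0, log2_offset > 0)
  structure(list(
    alpha_raw = alpha_raw, fdr_q = fdr_q, n_sub = as.integer(n_sub),
    consensus_threshold = as.integer(consensus_threshold),
    min_mut_per_type = as.integer(min_mut_per_type),
    hotspot_min_count = as.integer(hotspot_min_count),
    hotspot_min_prev = hotspot_min_prev,
    hotspot_denominator = match.arg(hotspot_denominator),
    log2_offset = log2_offset, seed = as.integer(seed)
  ), class = "tp53_config")
}

parse_codon <- function(protein_change) {
  codon <- suppressWarnings(as.integer(
    stringr::str_match(protein_change, "^p\\.[A-Za-z*](\\d+)")[, 2]
  ))
  codon
}

#' Read a MAF-dialect mutation table
#'
#' Reads tab-separated somatic mutation calls in the MC3-compatible dialect:
#' a header containing at least `Hugo_Symbol`, `Variant_Classification`,
#' `Tumor_Sample_Barcode` and `HGVSp_Short` (order free, extra columns
#' ignored, lines starting with `#` skipped). The protein-level codon is
#' parsed from `HGVSp_Short` where it matches `p.<AA><digits>`.
#'
#' @param path Path to the MAF file.
#' @param gene_filter Optional HGNC symbol; only records for this gene are
#'   returned.
#' @return A tibble with columns `sample_id`, `gene`,
#'   `variant_classification`, `protein_change` and `codon` (integer, `NA`
#'   when not parseable).
#' @export
read_maf <- function(path, gene_filter = NULL) {
  raw <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                         col_types = readr::cols(.default = readr::col_character()))
  required <- c("Hugo_Symbol", "Variant_Classification",
                "Tumor_Sample_Barcode", "HGVSp_Short")
  missing <- setdiff(required, names(raw))
  if (length(missing) > 0) {
    stop("MAF file is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  out <- tibble::tibble(
    sample_id = stringr::str_trim(raw$Tumor_Sample_Barcode),
    gene = stringr::str_trim(raw$Hugo_Symbol),
    variant_classification = raw$Variant_Classification,
    protein_change = dplyr::coalesce(raw$HGVSp_Short, "")
  )
  bad <- setdiff(unique(out$variant_classification), maf_classifications)
  if (length(bad) > 0) {
    stop("Unknown Variant_Classification term(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  if (!is.null(gene_filter)) out <- dplyr::filter(out, .data$gene == gene_filter)
  out$codon <- parse_codon(out$protein_change)
  n_unparsed <- sum(out$protein_change != "" & is.na(out$codon))
  if (n_unparsed > 0) {
    pipeline_log(n_unparsed, " protein changes without a parseable codon")
  }
  out
}

#' Write variant records as a MAF-dialect file
#'
#' @param variants Tibble as returned by [read_maf()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_maf <- function(variants, path) {
  out <- tibble::tibble(
    Hugo_Symbol = variants$gene,
    Variant_Classification = variants$variant_classification,
    Tumor_Sample_Barcode = variants$sample_id,
    HGVSp_Short = variants$protein_change
  )
  readr::write_tsv(out, path)
  invisible(path)
}

#' Read an expression matrix and transform to the log2 scale
#'
#' Reads a tab-separated gene-by-sample table of non-negative, linear-scale
#' normalized expression values (first column gene identifiers) and applies
#' `log2(x + offset)` elementwise. Duplicate gene rows are collapsed by
#' keeping the row with the largest total signal; genes with any missing
#' value are dropped.
#'
#' @param path Path to the TSV file.
#' @param log2_offset Offset in the log transform (default 1, so 0 maps to 0).
#' @return A tibble with column `gene` followed by one numeric column per
#'   sample, values on the log2 scale.
#' @export
read_expression <- function(path, log2_offset = 1) {
  raw <- readr::read_tsv(path, show_col_types = FALSE,
                         col_types = readr::cols(.default = readr::col_character()))
  if (ncol(raw) < 2) stop("Expression table needs a gene column plus samples",
                          call. = FALSE)
  gene <- stringr::str_trim(raw[[1]])
  vals <- as.data.frame(raw[-1])
  for (j in seq_along(vals)) {
    v <- suppressWarnings(as.numeric(vals[[j]]))
    bad <- which(!is.na(vals[[j]]) & is.na(v))
    if (length(bad) > 0) {
      stop(sprintf("Non-numeric expression value at row %d, column '%s'",
                   bad[1], names(vals)[j]), call. = FALSE)
    }
    vals[[j]] <- v
  }
  mat <- as.matrix(vals)
  colnames(mat) <- stringr::str_trim(colnames(raw)[-1])

  keep <- stats::complete.cases(mat)
  if (any(!keep)) {
    pipeline_log("dropping ", sum(!keep), " genes with missing values")
    mat <- mat[keep, , drop = FALSE]
    gene <- gene[keep]
  }
  if (anyDuplicated(gene)) {
    totals <- rowSums(mat)
    ord <- order(gene, -totals)
    first <- !duplicated(gene[ord])
    pipeline_log("collapsing ", sum(!first), " duplicate gene rows")
    sel <- sort(ord[first])
    mat <- mat[sel, , drop = FALSE]
    gene <- gene[sel]
  }
  if (any(mat < 0)) stop("Expression values must be non-negative on the linear scale",
                         call. = FALSE)
  mat <- log2(mat + log2_offset)
  dplyr::bind_cols(tibble::tibble(gene = gene), tibble::as_tibble(mat))
}

#' Write a log2-scale expression tibble back to the linear-scale TSV dialect
#'
#' Inverse of [read_expression()]: values are written as
#' `2^x - offset` so a subsequent read recovers the log2 values exactly.
#'
#' @param expr Expression tibble (`gene` column + sample columns, log2 scale).
#' @param path Output path.
#' @param log2_offset Offset used by the matching [read_expression()] call.
#' @return `path`, invisibly.
#' @export
write_expression <- function(expr, path, log2_offset = 1) {
  out <- expr
  for (j in setdiff(names(out), "gene")) out[[j]] <- 2^out[[j]] - log2_offset
  readr::write_tsv(out, path)
  invisible(path)
}

expr_matrix <- function(expr) {
  m <- as.matrix(expr[setdiff(names(expr), "gene")])
  rownames(m) <- expr$gene
  m
}

#' Read a GMT gene-set catalog
#'
#' Standard GMT: one set per line, tab-separated fields
#' `name, description, members...`. Member lists are deduplicated; the
#' catalog universe is the union of all member genes.
#'
#' @param path Path to the GMT file.
#' @param catalog_name Name recorded for the catalog (default: file base name).
#' @return A `gs_catalog` object: list with `name`, `sets` (named list of
#'   character vectors), `universe` and `n_universe`.
#' @export
read_gmt <- function(path, catalog_name = NULL) {
  lines <- readr::read_lines(path)
  lines <- lines[nzchar(lines)]
  sets <- list()
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    fields <- fields[nzchar(stringr::str_trim(fields))]
    if (length(fields) < 3) {
      stop(sprintf("GMT line %d has fewer than 3 non-empty fields", i),
           call. = FALSE)
    }
    sets[[fields[1]]] <- unique(fields[-(1:2)])
  }
  if (anyDuplicated(names(sets))) {
    stop("Duplicate set names within one GMT catalog", call. = FALSE)
  }
  gs_catalog(sets, name = catalog_name %||% basename(path))
}

#' Construct a gene-set catalog
#'
#' @param sets Named list of character vectors (gene symbols).
#' @param name Catalog name.
#' @return A `gs_catalog` object.
#' @export
gs_catalog <- function(sets, name = "catalog") {
  stopifnot(is.list(sets), length(sets) > 0, !is.null(names(sets)))
  sets <- lapply(sets, unique)
  universe <- unique(unlist(sets, use.names = FALSE))
  structure(list(name = name, sets = sets, universe = universe,
                 n_universe = length(universe)),
            class = "gs_catalog")
}

#' @export
print.gs_catalog <- function(x, ...) {
  cat(sprintf("<gs_catalog '%s': %d sets, universe %d genes>\n",
              x$name, length(x$sets), x$n_universe))
  invisible(x)
}

#' Write a gene-set catalog as GMT
#'
#' @param catalog A `gs_catalog`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(catalog, path) {
  lines <- vapply(names(catalog$sets), function(nm) {
    paste(c(nm, nm, catalog$sets[[nm]]), collapse = "\t")
  }, character(1))
  readr::write_lines(lines, path)
  invisible(path)
}

#' Read a sample-annotation table
#'
#' Tab-separated with columns `sample_id`, `cancer_type` and optional subtype
#' stratifiers `hpv_status` (`pos`/`neg`/`unknown`), `msi_status`
#' (`MSI-H`/`MSI-L/MSS`/`unknown`) and `brca_subtype`
#' (`HR+/HER2-`/`HER2+`/`TNBC`/`unknown`).
#'
#' @param path Path to the TSV file.
#' @return A tibble; missing optional columns are filled with `"unknown"`.
#' @export
read_sample_annotations <- function(path) {
  ann <- readr::read_tsv(path, show_col_types = FALSE,
                         col_types = readr::cols(.default = readr::col_character()))
  required <- c("sample_id", "cancer_type")
  missing <- setdiff(required, names(ann))
  if (length(missing) > 0) {
    stop("Annotation file is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  ann$sample_id <- stringr::str_trim(ann$sample_id)
  if (anyDuplicated(ann$sample_id)) {
    stop("Duplicate sample_id in annotation table", call. = FALSE)
  }
  for (col in c("hpv_status", "msi_status", "brca_subtype")) {
    if (!col %in% names(ann)) ann[[col]] <- "unknown"
    ann[[col]] <- dplyr::coalesce(ann[[col]], "unknown")
  }
  ann
}

#' Read a variant functional-annotation table
#'
#' Emulates a functional mutation database lookup: tab-separated with columns
#' `protein_change`, `gof`, `lof`, `dn` (logical or 0/1).
#'
#' @param path Path to the TSV file.
#' @return A tibble with unique `protein_change` keys and logical flags.
#' @export
read_variant_annotations <- function(path) {
  db <- readr::read_tsv(path, show_col_types = FALSE)
  required <- c("protein_change", "gof", "lof", "dn")
  missing <- setdiff(required, names(db))
  if (length(missing) > 0) {
    stop("Variant-annotation file is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(db$protein_change)) {
    stop("Duplicate protein_change keys in variant-annotation table",
         call. = FALSE)
  }
  dplyr::mutate(db, dplyr::across(c("gof", "lof", "dn"), as.logical))
}

#' Read an immune cell-abundance matrix
#'
#' Tab-separated, one row per sample: `sample_id` plus one numeric column per
#' immune cell population.
#'
#' @param path Path to the TSV file.
#' @return A tibble with `sample_id` and numeric abundance columns.
#' @export
read_immune <- function(path) {
  imm <- readr::read_tsv(path, show_col_types = FALSE)
  if (!"sample_id" %in% names(imm)) {
    stop("Immune abundance file is missing required column: sample_id",
         call. = FALSE)
  }
  imm$sample_id <- stringr::str_trim(as.character(imm$sample_id))
  imm
}

#' Apply the cohort-inclusion filter
#'
#' Removes cancer types with fewer than `min_mut` TP53-mutant tumors.
#'
#' @param cohort Sample-annotation tibble (`sample_id`, `cancer_type`, ...).
#' @param statuses Tibble with `sample_id` and `status`
#'   (`"TP53mut"`/`"TP53wt"`) covering every cohort sample.
#' @param min_mut Minimum number of TP53-mutant tumors per cancer type.
#' @return The filtered cohort tibble.
#' @export
apply_cohort_filter <- function(cohort, statuses, min_mut = 7) {
  stopifnot(all(cohort$sample_id %in% statuses$sample_id))
  counts <- cohort |>
    dplyr::left_join(statuses, by = "sample_id") |>
    dplyr::group_by(.data$cancer_type) |>
    dplyr::summarise(n_mut = sum(.data$status == "TP53mut"), .groups = "drop")
  keep <- counts$cancer_type[counts$n_mut >= min_mut]
  dropped <- dplyr::filter(counts, !.data$cancer_type %in% keep)
  if (nrow(dropped) > 0) {
    pipeline_log("dropping ", nrow(dropped), " cancer type(s) below ",
                 min_mut, " TP53mut tumors: ",
                 paste(sprintf("%s (%d)", dropped$cancer_type, dropped$n_mut),
                       collapse = ", "))
  }
  out <- dplyr::filter(cohort, .data$cancer_type %in% keep)
  if (nrow(out) == 0) {
    stop("No cancer type satisfies the minimum TP53mut count (",
         min_mut, ")", call. = FALSE)
  }
  out
}

#' Write a JSON run manifest
#'
#' Records configuration, seed, input file checksums and basic counts for a
#' pipeline run.
#'
#' @param path Output JSON path.
#' @param config A [tp53_config()] object.
#' @param files Named character vector of input files (checksummed when they
#'   exist).
#' @param counts Named list of counts to record.
#' @return `path`, invisibly.
#' @export
write_run_manifest <- function(path, config, files = character(), counts = list()) {
  checksums <- lapply(files, function(f) {
    if (file.exists(f)) unname(tools::md5sum(f)) else NA_character_
  })
  manifest <- list(
    config = unclass(config),
    seed = config$seed,
    inputs = checksums,
    counts = counts
  )
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
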