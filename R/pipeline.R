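# End-to-end orchestration of the pipeline stages on harmonized inputs.

#' Run the full TP53 pan-cancer pipeline
#'
#' Harmonizes the inputs (samples are matched by exact id between the cohort
#' table and the expression matrix), applies the cohort-inclusion filter,
#' classifies tumors, screens mutation hotspots, runs the per-cancer-type
#' TP53-mutant vs wildtype differential expression with the fixed-n
#' subsampling design, builds the pan-cancer consensus with Fisher's method
#' and direction voting, bi-clusters the consensus fold-change matrix, tests
#' type clusters against mutation prevalence, and (when an immune matrix is
#' given) associates immune abundances and TMB with TP53 status across
#' subtypes.
#'
#' @param maf Genome-wide variant tibble ([read_maf()]).
#' @param expression Log2-scale expression tibble ([read_expression()]).
#' @param cohort Sample-annotation tibble ([read_sample_annotations()]).
#' @param variant_db Variant-annotation tibble
#'   ([read_variant_annotations()]).
#' @param immune Optional immune abundance tibble ([read_immune()]).
#' @param config A [tp53_config()].
#' @param k_genes,k_types Cluster counts for the consensus bi-clustering.
#' @return A list of class `tp53_pipeline` with elements `cohort` (filtered),
#'   `statuses`, `tumors`, `class_overlap`, `hotspots`, `de_by_type`,
#'   `consensus`, `biclust`, `prevalence_test`, `immune_assoc`, `tmb`,
#'   `config`.
#' @export
tp53_pipeline <- function(maf, expression, cohort, variant_db, immune = NULL,
                          config = tp53_config(), k_genes = 6, k_types = 3) {
  expr_samples <- setdiff(names(expression), "gene")
  common <- intersect(cohort$sample_id, expr_samples)
  if (length(common) == 0) {
    stop("No samples shared between cohort table and expression matrix",
         call. = FALSE)
  }
  dropped <- length(union(cohort$sample_id, expr_samples)) - length(common)
  if (dropped > 0) {
    pipeline_log(dropped, " samples present in only one of cohort/expression ",
                 "dropped during harmonization")
  }
  cohort <- dplyr::filter(cohort, .data$sample_id %in% common)
  expression <- expression[c("gene", cohort$sample_id)]

  tp53 <- dplyr::filter(maf, .data$gene == "TP53",
                        .data$sample_id %in% common)
  statuses <- call_tp53_status(tp53, cohort$sample_id)
  cohort <- apply_cohort_filter(cohort, statuses, config$min_mut_per_type)
  statuses <- dplyr::filter(statuses, .data$sample_id %in% cohort$sample_id)
  tp53 <- dplyr::filter(tp53, .data$sample_id %in% cohort$sample_id)
  expression <- expression[c("gene", cohort$sample_id)]

  classified <- classify_variants(tp53, variant_db)
  agg <- aggregate_tumor_classes(classified, statuses)
  tumors <- dplyr::left_join(agg$tumors,
                             dplyr::select(cohort, "sample_id", "cancer_type"),
                             by = "sample_id")

  hotspots <- hotspot_report(tp53, statuses, cohort, config)

  types <- sort(unique(cohort$cancer_type))
  de_by_type <- purrr::map(types, function(ct) {
    subsampled_contrast(expression, tumors, ct, "TP53mut", "TP53wt",
                        n_sub = config$n_sub, seed = config$seed,
                        fdr_q = config$fdr_q)
  })
  names(de_by_type) <- types

  consensus <- build_consensus(de_by_type, alpha_raw = config$alpha_raw,
                               t = config$consensus_threshold)
  n_members <- sum(consensus$stats$member)
  biclust <- NULL
  prevalence_test <- NULL
  if (n_members >= k_genes && length(types) >= k_types) {
    biclust <- cluster_heatmap(consensus, k_genes = k_genes, k_types = k_types)
    prev <- tumors |>
      dplyr::group_by(.data$cancer_type) |>
      dplyr::summarise(prevalence = mean(.data$status == "TP53mut"),
                       .groups = "drop")
    prevalence <- stats::setNames(prev$prevalence, prev$cancer_type)
    prevalence_test <- cluster_prevalence_test(biclust$type_clusters,
                                               prevalence)
  } else {
    pipeline_log("consensus too small to bi-cluster (", n_members, " members)")
  }

  immune_assoc <- NULL
  tmb <- compute_tmb(maf, samples = cohort$sample_id)
  if (!is.null(immune)) {
    subtypes <- build_subtypes(cohort)
    immune_assoc <- immune_association(immune, statuses, subtypes, tmb = tmb,
                                       fdr_q = config$fdr_q)
  }

  structure(list(
    cohort = cohort, statuses = statuses, tumors = tumors,
    class_overlap = agg$overlap, hotspots = hotspots,
    de_by_type = de_by_type, consensus = consensus, biclust = biclust,
    prevalence_test = prevalence_test, immune_assoc = immune_assoc,
    tmb = tmb, config = config
  ), class = "tp53_pipeline")
}

#' @export
print.tp53_pipeline <- function(x, ...) {
  cat("<tp53_pipeline>\n")
  cat(sprintf("  cohort: %d samples, %d cancer types\n", nrow(x$cohort),
              length(unique(x$cohort$cancer_type))))
  cat(sprintf("  TP53mut: %d / TP53wt: %d\n",
              sum(x$statuses$status == "TP53mut"),
              sum(x$statuses$status == "TP53wt")))
  print(x$consensus)
  if (!is.null(x$immune_assoc)) {
    cat(sprintf("  immune: %d significant (subtype, endpoint) pairs\n",
                sum(x$immune_assoc$direction != "none")))
  }
  invisible(x)
}
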