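# Tumor mutational burden and immune-microenvironment association with
# TP53 status across cancer subtypes.

#' Compute tumor mutational burden
#'
#' TMB is defined as the per-sample count of missense mutations across the
#' genome-wide MAF. Duplicate identical records are removed before counting
#' (logged); samples in `samples` absent from the MAF get 0.
#'
#' @param maf Genome-wide variant tibble ([read_maf()] without a gene filter).
#' @param samples Optional character vector of sample ids to report (default:
#'   samples present in the MAF).
#' @return A tibble with `sample_id` and integer `tmb`.
#' @export
compute_tmb <- function(maf, samples = NULL) {
  n0 <- nrow(maf)
  maf <- dplyr::distinct(maf, .data$sample_id, .data$gene,
                         .data$variant_classification, .data$protein_change)
  if (nrow(maf) < n0) {
    pipeline_log(n0 - nrow(maf), " duplicate MAF records removed before TMB")
  }
  counts <- maf |>
    dplyr::filter(.data$variant_classification == "Missense_Mutation") |>
    dplyr::count(.data$sample_id, name = "tmb")
  samples <- samples %||% sort(unique(maf$sample_id))
  tibble::tibble(sample_id = samples) |>
    dplyr::left_join(counts, by = "sample_id") |>
    dplyr::mutate(tmb = as.integer(ifelse(is.na(.data$tmb), 0L, .data$tmb)))
}

#' Build cancer-subtype labels from stratifiers
#'
#' HNSC and CESC are split by HPV status, STAD/UCEC/COAD/READ by MSI status
#' (MSI-H vs MSI-L/MSS), BRCA by receptor subtype; all other cancer types map
#' to themselves. Samples with an unknown stratifier in a stratified type get
#' `NA` and are excluded from subtype analyses (logged).
#'
#' @param cohort Sample-annotation tibble with `sample_id`, `cancer_type` and
#'   optional `hpv_status`, `msi_status`, `brca_subtype` columns.
#' @return A tibble with `sample_id` and `subtype` (`NA` for unknown
#'   stratifier).
#' @export
build_subtypes <- function(cohort) {
  hpv_types <- c("HNSC", "CESC")
  msi_types <- c("STAD", "UCEC", "COAD", "READ")
  for (col in c("hpv_status", "msi_status", "brca_subtype")) {
    if (!col %in% names(cohort)) cohort[[col]] <- "unknown"
  }
  out <- cohort |>
    dplyr::mutate(subtype = dplyr::case_when(
      .data$cancer_type %in% hpv_types & .data$hpv_status == "pos" ~
        paste0("HPV+ ", .data$cancer_type),
      .data$cancer_type %in% hpv_types & .data$hpv_status == "neg" ~
        paste0("HPV- ", .data$cancer_type),
      .data$cancer_type %in% hpv_types ~ NA_character_,
      .data$cancer_type %in% msi_types & .data$msi_status == "MSI-H" ~
        paste0("MSI-H ", .data$cancer_type),
      .data$cancer_type %in% msi_types & .data$msi_status == "MSI-L/MSS" ~
        paste0("MSI-L/MSS ", .data$cancer_type),
      .data$cancer_type %in% msi_types ~ NA_character_,
      .data$cancer_type == "BRCA" &
        .data$brca_subtype %in% c("HR+/HER2-", "HER2+", "TNBC") ~
        paste0(.data$brca_subtype, " BRCA"),
      .data$cancer_type == "BRCA" ~ NA_character_,
      TRUE ~ .data$cancer_type
    ))
  n_na <- sum(is.na(out$subtype))
  if (n_na > 0) {
    pipeline_log(n_na, " samples with unknown stratifier excluded from ",
                 "subtype analyses")
  }
  dplyr::select(out, "sample_id", "subtype")
}

#' Associate immune-cell abundances and TMB with TP53 status per subtype
#'
#' For every (subtype, endpoint) pair — each immune cell population plus TMB —
#' a two-sided Wilcoxon rank-sum test compares TP53-mutant against wildtype
#' tumors; BH correction is applied jointly across all tested pairs and the
#' direction (`"up"`/`"down"` in TP53mut, or `"none"`) is the sign of the
#' median difference for pairs significant at `fdr_q`. Subtypes with fewer
#' than `min_group` mutant or wildtype profiled samples are skipped (logged).
#'
#' @param immune Immune abundance tibble (`sample_id` + population columns).
#' @param statuses Tumor status tibble.
#' @param subtypes Output of [build_subtypes()].
#' @param tmb Optional TMB tibble ([compute_tmb()]); when given, `TMB` is
#'   tested as an additional endpoint.
#' @param fdr_q FDR level (default 0.10).
#' @param min_group Minimum per-group sample count (default 2).
#' @return A tibble with `subtype`, `endpoint`, `n_mut`, `n_wt`,
#'   `median_diff` (mut - wt), `p`, `q`, `direction`.
#' @export
immune_association <- function(immune, statuses, subtypes, tmb = NULL,
                               fdr_q = 0.10, min_group = 2) {
  data <- immune |>
    dplyr::inner_join(statuses, by = "sample_id") |>
    dplyr::inner_join(subtypes, by = "sample_id") |>
    dplyr::filter(!is.na(.data$subtype))
  if (!is.null(tmb)) data <- dplyr::left_join(data, tmb, by = "sample_id")
  endpoints <- setdiff(names(data), c("sample_id", "status", "subtype"))
  if ("tmb" %in% endpoints) {
    endpoints <- c(setdiff(endpoints, "tmb"), "TMB")
    data$TMB <- data$tmb
    data$tmb <- NULL
  }
  rows <- purrr::map_dfr(split(data, data$subtype), function(d) {
    n_mut <- sum(d$status == "TP53mut")
    n_wt <- sum(d$status == "TP53wt")
    if (n_mut < min_group || n_wt < min_group) {
      pipeline_log("subtype ", d$subtype[1], " skipped: ", n_mut, " mut / ",
                   n_wt, " wt profiled samples")
      return(NULL)
    }
    purrr::map_dfr(endpoints, function(ep) {
      x <- d[[ep]][d$status == "TP53mut"]
      y <- d[[ep]][d$status == "TP53wt"]
      p <- if (length(unique(c(x, y))) == 1) 1 else
        suppressWarnings(stats::wilcox.test(x, y, exact = FALSE,
                                            correct = TRUE)$p.value)
      tibble::tibble(subtype = d$subtype[1], endpoint = ep,
                     n_mut = n_mut, n_wt = n_wt,
                     median_diff = stats::median(x) - stats::median(y),
                     p = p)
    })
  })
  if (nrow(rows) == 0) stop("No subtype satisfies the group-size requirement",
                            call. = FALSE)
  rows |>
    dplyr::mutate(
      q = stats::p.adjust(.data$p, method = "BH"),
      direction = dplyr::case_when(
        .data$q > fdr_q ~ "none",
        .data$median_diff > 0 ~ "up",
        .data$median_diff < 0 ~ "down",
        TRUE ~ "none"
      )
    )
}

#' Tile plot of subtype x endpoint immune associations
#'
#' @param assoc Output of [immune_association()].
#' @return A ggplot object: red = higher in TP53-mutant tumors, green = lower.
#' @export
plot_immune_associations <- function(assoc) {
  ggplot2::ggplot(assoc, ggplot2::aes(x = .data$endpoint, y = .data$subtype,
                                      fill = .data$direction)) +
    ggplot2::geom_tile(colour = "white") +
    ggplot2::scale_fill_manual(values = c(up = "firebrick", down = "darkgreen",
                                          none = "grey92"),
                               name = "In TP53mut") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5))
}
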