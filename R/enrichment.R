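# Over-representation analysis: Fisher exact test against a gene-set
# catalog, the enrichment fold-change statistic, and the jointly
# BH-corrected (cancer type x category) hallmark grid.

#' Enrichment fold change
#'
#' `FC = (k/K) / (n/N)`: the share of the query list annotated to a category
#' over the share of the catalog universe annotated to it. Values above 1
#' indicate enrichment, below 1 depletion.
#'
#' @param k Query genes in the category.
#' @param K Query list size.
#' @param n Category size within the catalog.
#' @param N Catalog universe size.
#' @return The fold change (vectorized).
#' @export
enrichment_fc <- function(k, K, n, N) {
  stopifnot(all(K > 0), all(n > 0), all(N > 0), all(k >= 0), all(k <= K),
            all(n <= N))
  (k / K) / (n / N)
}

#' Fisher exact test of query-category overlap
#'
#' Two-sided Fisher exact test on the 2x2 table
#' `[[k, K - k], [n - k, N - n - K + k]]` (query membership x category
#' membership over the catalog universe). Query genes outside the universe
#' are dropped before counting (logged).
#'
#' @param query Character vector of query genes.
#' @param category Character vector: the gene set.
#' @param universe Character vector: the catalog universe.
#' @return A list with `k` (overlap after filtering), `K` (filtered query
#'   size) and `p` (two-sided Fisher exact p; `NA` if the query is empty
#'   after filtering).
#' @export
fisher_enrichment <- function(query, category, universe) {
  query <- unique(query)
  category <- unique(intersect(category, universe))
  dropped <- setdiff(query, universe)
  if (length(dropped) > 0) {
    pipeline_log(length(dropped), " query genes outside the catalog universe dropped")
    query <- intersect(query, universe)
  }
  K <- length(query)
  if (K == 0) return(list(k = NA_integer_, K = 0L, p = NA_real_))
  k <- length(intersect(query, category))
  n <- length(category)
  N <- length(unique(universe))
  tab <- matrix(c(k, K - k, n - k, N - n - K + k), nrow = 2, byrow = TRUE)
  list(k = k, K = K, p = stats::fisher.test(tab)$p.value)
}

#' Over-representation of a gene list across a catalog
#'
#' Runs [fisher_enrichment()] for every set in the catalog, computes the
#' enrichment fold change and the percentage of the query annotated to each
#' category, and applies BH correction across the catalog's categories.
#'
#' @param query Character vector of query genes.
#' @param catalog A [gs_catalog()].
#' @param fdr_q FDR level for the significance flag (default 0.10).
#' @return A tibble with columns `catalog`, `category`, `k`, `K`, `n`, `N`,
#'   `pct` (`100 k/K`), `fc`, `p`, `q`, `direction`
#'   (`"enriched"`/`"depleted"`), `significant`.
#' @export
enrich_catalog <- function(query, catalog, fdr_q = 0.10) {
  stopifnot(inherits(catalog, "gs_catalog"))
  universe <- catalog$universe
  rows <- purrr::imap_dfr(catalog$sets, function(set, nm) {
    fe <- fisher_enrichment(query, set, universe)
    n <- length(intersect(set, universe))
    if (is.na(fe$p)) {
      return(tibble::tibble(category = nm, k = NA_integer_, K = fe$K,
                            n = n, N = catalog$n_universe,
                            pct = NA_real_, fc = NA_real_, p = NA_real_))
    }
    tibble::tibble(
      category = nm, k = fe$k, K = fe$K, n = n, N = catalog$n_universe,
      pct = 100 * fe$k / fe$K,
      fc = enrichment_fc(fe$k, fe$K, n, catalog$n_universe),
      p = fe$p
    )
  })
  rows |>
    dplyr::mutate(
      catalog = catalog$name,
      q = stats::p.adjust(.data$p, method = "BH"),
      direction = dplyr::case_when(is.na(.data$fc) ~ NA_character_,
                                   .data$fc > 1 ~ "enriched",
                                   .data$fc < 1 ~ "depleted",
                                   TRUE ~ "none"),
      significant = !is.na(.data$q) & .data$q <= fdr_q
    ) |>
    dplyr::select("catalog", "category", "k", "K", "n", "N", "pct", "fc",
                  "p", "q", "direction", "significant") |>
    dplyr::arrange(.data$p)
}

#' Cancer-type x category enrichment grid with joint BH correction
#'
#' Runs the catalog over-representation for every cancer type's gene list and
#' applies one BH correction jointly across all (cancer type, category) pairs
#' of the grid, as done separately for over- and underexpressed lists. Types
#' with an empty gene list contribute all-`NA` rows.
#'
#' @param gene_lists Named list (by cancer type) of character vectors.
#' @param catalog A [gs_catalog()] (e.g. the 50 hallmark sets).
#' @param fdr_q FDR level (default 0.10).
#' @return A tibble like [enrich_catalog()] with an extra leading
#'   `cancer_type` column; `q` is the joint BH adjustment.
#' @export
hallmark_grid <- function(gene_lists, catalog, fdr_q = 0.10) {
  stopifnot(length(gene_lists) > 0, !is.null(names(gene_lists)))
  grid <- purrr::imap_dfr(gene_lists, function(gl, ty) {
    res <- enrich_catalog(gl, catalog, fdr_q = fdr_q)
    res$cancer_type <- ty
    res
  })
  grid |>
    dplyr::mutate(q = stats::p.adjust(.data$p, method = "BH"),
                  significant = !is.na(.data$q) & .data$q <= fdr_q) |>
    dplyr::select("cancer_type", dplyr::everything())
}

#' Tile plot of an enrichment grid
#'
#' @param grid Output of [hallmark_grid()].
#' @return A ggplot object: significant cells colored by direction.
#' @export
plot_enrichment_grid <- function(grid) {
  df <- dplyr::mutate(grid,
                      status = dplyr::case_when(
                        !.data$significant | is.na(.data$direction) ~ "n.s.",
                        .data$direction == "enriched" ~ "enriched",
                        TRUE ~ "depleted"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$cancer_type, y = .data$category,
                                   fill = .data$status)) +
    ggplot2::geom_tile(colour = "white") +
    ggplot2::scale_fill_manual(values = c(enriched = "firebrick",
                                          depleted = "darkgreen",
                                          n.s. = "grey92"), name = NULL) +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5))
}
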