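# Pan-cancer aggregation: Fisher's method, the consensus gene list with
# direction voting, Manhattan/average-linkage bi-clustering and the
# cluster-vs-prevalence test.

#' Combine p-values with Fisher's method
#'
#' `X2 = -2 * sum(log(p))`, compared against a chi-square distribution with
#' `2k` degrees of freedom, `k` the number of available (non-`NA`) p-values.
#' Zero p-values are clamped to the smallest positive double with a warning.
#'
#' @param p_values Numeric vector of p-values in (0, 1]; `NA`s are dropped.
#' @return A list with `x2`, `df` and `p` (all `NA` for an empty vector).
#' @export
fisher_combine <- function(p_values) {
  p <- p_values[!is.na(p_values)]
  if (length(p) == 0) return(list(x2 = NA_real_, df = NA_integer_, p = NA_real_))
  if (any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]", call. = FALSE)
  if (any(p == 0)) {
    warning("zero p-values clamped to the smallest positive double")
    p[p == 0] <- .Machine$double.xmin
  }
  x2 <- -2 * sum(log(p))
  df <- 2L * length(p)
  list(x2 = x2, df = df, p = stats::pchisq(x2, df = df, lower.tail = FALSE))
}

#' Build the pan-cancer consensus gene list
#'
#' Aggregates per-cancer-type TP53mut-vs-wildtype differential expression
#' results: counts, per gene, the cancer types with raw p below `alpha_raw`
#' (direction-agnostic); a gene is a consensus member when that count reaches
#' `t` cancer types, where `t` is fixed regardless of how many types the gene
#' could be tested in. Per-type p-values are combined with Fisher's method
#' and the expression direction is assigned by strict majority of the
#' log2-fold-change signs (ties resolved by the sign of the summed
#' fold change).
#'
#' @param de_list Named list (by cancer type) of DE tibbles from
#'   [wilcoxon_de()] (or `tp53_contrast` objects; not-analyzable entries are
#'   skipped).
#' @param alpha_raw Raw significance threshold (default 0.05).
#' @param t Consensus threshold: minimum number of cancer types (default 16).
#' @return A `tp53_consensus` object. Its `stats` tibble has one row per gene
#'   with `n_sig`, `n_tested`, `fisher_x2`, `fisher_df`, `fisher_p`,
#'   `direction` and `member`; `fc_matrix` and `p_matrix` are gene-by-type
#'   matrices.
#' @export
build_consensus <- function(de_list, alpha_raw = 0.05, t = 16) {
  stopifnot(length(de_list) > 0, !is.null(names(de_list)))
  de_list <- purrr::map(de_list, function(x) {
    if (inherits(x, "tp53_contrast")) {
      if (x$na) return(NULL)
      return(x$de)
    }
    x
  })
  de_list <- purrr::compact(de_list)
  if (length(de_list) < t) {
    stop("Fewer analyzed cancer types (", length(de_list),
         ") than the consensus threshold (", t, ")", call. = FALSE)
  }
  types <- names(de_list)
  genes <- sort(unique(unlist(purrr::map(de_list, "gene"))))
  pm <- fm <- matrix(NA_real_, length(genes), length(types),
                     dimnames = list(genes, types))
  for (ty in types) {
    de <- de_list[[ty]]
    pm[de$gene, ty] <- de$p_raw
    fm[de$gene, ty] <- de$log2fc
  }
  n_sig <- unname(rowSums(pm < alpha_raw, na.rm = TRUE))
  n_tested <- unname(rowSums(!is.na(pm)))
  comb <- apply(pm, 1, fisher_combine)
  pos <- unname(rowSums(fm > 0, na.rm = TRUE))
  neg <- unname(rowSums(fm < 0, na.rm = TRUE))
  sum_fc <- unname(rowSums(fm, na.rm = TRUE))
  direction <- dplyr::case_when(
    n_tested == 0 ~ NA_character_,
    pos > neg ~ "over",
    neg > pos ~ "under",
    TRUE ~ ifelse(sum_fc > 0, "over", "under")
  )
  n_tie <- sum(pos == neg & n_tested > 0)
  if (n_tie > 0) pipeline_log(n_tie, " genes with tied direction votes")
  stats_tbl <- tibble::tibble(
    gene = genes,
    n_sig = as.integer(n_sig),
    n_tested = as.integer(n_tested),
    fisher_x2 = unname(purrr::map_dbl(comb, "x2")),
    fisher_df = unname(purrr::map_int(comb, ~ as.integer(.x$df))),
    fisher_p = unname(purrr::map_dbl(comb, "p")),
    direction = direction,
    member = n_sig >= t
  )
  structure(list(stats = stats_tbl, fc_matrix = fm, p_matrix = pm,
                 alpha_raw = alpha_raw, t = as.integer(t),
                 types = types),
            class = "tp53_consensus")
}

#' @export
print.tp53_consensus <- function(x, ...) {
  n_over <- sum(x$stats$member & x$stats$direction == "over", na.rm = TRUE)
  n_under <- sum(x$stats$member & x$stats$direction == "under", na.rm = TRUE)
  cat(sprintf(paste0("<tp53_consensus: %d genes x %d cancer types; %d members ",
                     "(raw p < %g in >= %d types): %d over / %d under>\n"),
              nrow(x$stats), length(x$types), sum(x$stats$member),
              x$alpha_raw, x$t, n_over, n_under))
  invisible(x)
}

#' Tidy a consensus object into its per-gene table
#'
#' @param x A `tp53_consensus`.
#' @param ... Unused.
#' @return The per-gene stats tibble.
#' @export
tidy.tp53_consensus <- function(x, ...) x$stats

#' One-row summary of a consensus object
#'
#' @param x A `tp53_consensus`.
#' @param ... Unused.
#' @return A one-row tibble with member counts, direction split and the
#'   smallest combined p among members.
#' @export
glance.tp53_consensus <- function(x, ...) {
  members <- dplyr::filter(x$stats, .data$member)
  tibble::tibble(
    n_genes = nrow(x$stats),
    n_types = length(x$types),
    n_members = nrow(members),
    n_over = sum(members$direction == "over", na.rm = TRUE),
    n_under = sum(members$direction == "under", na.rm = TRUE),
    pct_over = ifelse(nrow(members) > 0,
                      round(100 * mean(members$direction == "over")), NA_real_),
    min_fisher_p = ifelse(nrow(members) > 0, min(members$fisher_p), NA_real_),
    alpha_raw = x$alpha_raw,
    t = x$t
  )
}

#' Generic tidiers
#'
#' `tidy()` returns the per-element table of a fitted object; `glance()` a
#' one-row summary.
#' @param x Object to tidy.
#' @param ... Passed to methods.
#' @return A tibble.
#' @export
tidy <- function(x, ...) UseMethod("tidy")

#' @rdname tidy
#' @export
glance <- function(x, ...) UseMethod("glance")

#' Heatmap of consensus-member fold changes
#'
#' @param object A `tp53_consensus`.
#' @param ... Unused.
#' @return A ggplot tile plot of the member-gene log2 fold-change matrix.
#' @method autoplot tp53_consensus
#' @export
autoplot.tp53_consensus <- function(object, ...) {
  members <- object$stats$gene[object$stats$member]
  fm <- object$fc_matrix[members, , drop = FALSE]
  df <- tibble::as_tibble(fm, rownames = "gene") |>
    tidyr::pivot_longer(-"gene", names_to = "cancer_type",
                        values_to = "log2fc")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$cancer_type, y = .data$gene,
                                   fill = .data$log2fc)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "darkgreen", mid = "white",
                                  high = "firebrick", midpoint = 0) +
    ggplot2::labs(x = NULL, y = NULL, fill = "log2 FC") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank(),
                   axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5))
}

#' Bi-cluster the consensus fold-change matrix
#'
#' Independent agglomerative clustering of genes (rows) and cancer types
#' (columns) of a log2 fold-change matrix with the Manhattan (L1) metric and
#' average linkage (UPGMA); partitions are obtained by cutting each tree.
#' `NA` entries are imputed as 0 (logged).
#'
#' @param fc_matrix Numeric gene-by-type matrix, or a `tp53_consensus` (its
#'   member genes are used).
#' @param k_genes Number of gene clusters (default 6).
#' @param k_types Number of cancer-type clusters (default 3).
#' @return A `tp53_biclust` object with `hclust_genes`, `hclust_types`,
#'   `gene_clusters` and `type_clusters` (named integer vectors).
#' @export
cluster_heatmap <- function(fc_matrix, k_genes = 6, k_types = 3) {
  if (inherits(fc_matrix, "tp53_consensus")) {
    members <- fc_matrix$stats$gene[fc_matrix$stats$member]
    fc_matrix <- fc_matrix$fc_matrix[members, , drop = FALSE]
  }
  stopifnot(is.matrix(fc_matrix))
  if (k_genes > nrow(fc_matrix)) stop("k_genes exceeds the gene count",
                                      call. = FALSE)
  if (k_types > ncol(fc_matrix)) stop("k_types exceeds the type count",
                                      call. = FALSE)
  if (anyNA(fc_matrix)) {
    pipeline_log(sum(is.na(fc_matrix)), " NA fold changes imputed as 0")
    fc_matrix[is.na(fc_matrix)] <- 0
  }
  hg <- stats::hclust(stats::dist(fc_matrix, method = "manhattan"),
                      method = "average")
  ht <- stats::hclust(stats::dist(t(fc_matrix), method = "manhattan"),
                      method = "average")
  structure(list(
    hclust_genes = hg, hclust_types = ht,
    gene_clusters = stats::cutree(hg, k = k_genes),
    type_clusters = stats::cutree(ht, k = k_types),
    fc_matrix = fc_matrix
  ), class = "tp53_biclust")
}

#' @export
print.tp53_biclust <- function(x, ...) {
  cat(sprintf("<tp53_biclust: %d genes in %d clusters, %d types in %d clusters>\n",
              nrow(x$fc_matrix), max(x$gene_clusters),
              ncol(x$fc_matrix), max(x$type_clusters)))
  invisible(x)
}

#' @rdname tidy
#' @export
tidy.tp53_biclust <- function(x, ...) {
  dplyr::bind_rows(
    tibble::tibble(item = names(x$gene_clusters), axis = "gene",
                   cluster = unname(x$gene_clusters)),
    tibble::tibble(item = names(x$type_clusters), axis = "cancer_type",
                   cluster = unname(x$type_clusters))
  )
}

#' @rdname tidy
#' @export
glance.tp53_biclust <- function(x, ...) {
  tibble::tibble(
    n_genes = nrow(x$fc_matrix), k_genes = max(x$gene_clusters),
    n_types = ncol(x$fc_matrix), k_types = max(x$type_clusters)
  )
}

#' Heatmap ordered by the bi-clustering dendrograms
#'
#' @param object A `tp53_biclust`.
#' @param ... Unused.
#' @return A ggplot tile plot with rows/columns in dendrogram order.
#' @method autoplot tp53_biclust
#' @export
autoplot.tp53_biclust <- function(object, ...) {
  fm <- object$fc_matrix[object$hclust_genes$order,
                         object$hclust_types$order, drop = FALSE]
  df <- tibble::as_tibble(fm, rownames = "gene") |>
    tidyr::pivot_longer(-"gene", names_to = "cancer_type",
                        values_to = "log2fc") |>
    dplyr::mutate(gene = factor(.data$gene, levels = rownames(fm)),
                  cancer_type = factor(.data$cancer_type, levels = colnames(fm)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$cancer_type, y = .data$gene,
                                   fill = .data$log2fc)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "darkgreen", mid = "white",
                                  high = "firebrick", midpoint = 0) +
    ggplot2::labs(x = NULL, y = NULL, fill = "log2 FC") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank(),
                   axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5))
}

#' Export bi-clustering dendrograms as Newick trees
#'
#' @param biclust A `tp53_biclust`.
#' @param gene_path,type_path Output Newick file paths.
#' @return Invisibly, the two paths.
#' @export
export_newick <- function(biclust, gene_path, type_path) {
  ape::write.tree(ape::as.phylo(biclust$hclust_genes), file = gene_path)
  ape::write.tree(ape::as.phylo(biclust$hclust_types), file = type_path)
  invisible(c(gene_path, type_path))
}

#' Test cancer-type clusters against TP53 mutation prevalence
#'
#' Kruskal-Wallis rank-sum test of per-cancer-type TP53-mutant prevalence
#' across type clusters. With a single observation per cluster the chi-square
#' approximation is used and the result is flagged small-sample.
#'
#' @param type_clusters Named integer vector (cancer type -> cluster), as in
#'   `tp53_biclust$type_clusters`.
#' @param prevalence Named numeric vector of per-type TP53-mutant prevalence.
#' @return A one-row tibble with `statistic`, `df`, `p_value`, `method`,
#'   `small_sample`.
#' @export
cluster_prevalence_test <- function(type_clusters, prevalence) {
  stopifnot(length(type_clusters) >= 2)
  common <- intersect(names(type_clusters), names(prevalence))
  if (length(common) < length(type_clusters)) {
    stop("Prevalence missing for some clustered cancer types", call. = FALSE)
  }
  g <- factor(type_clusters[common])
  if (any(table(g) == 0) || nlevels(g) < 2) {
    stop("Need at least two non-empty clusters", call. = FALSE)
  }
  x <- prevalence[common]
  if (length(unique(x)) == 1) {
    return(tibble::tibble(statistic = 0, df = nlevels(g) - 1L, p_value = 1,
                          method = "Kruskal-Wallis rank sum test",
                          small_sample = all(table(g) == 1)))
  }
  kt <- stats::kruskal.test(x, g)
  tibble::tibble(
    statistic = unname(kt$statistic),
    df = as.integer(unname(kt$parameter)),
    p_value = kt$p.value,
    method = "Kruskal-Wallis rank sum test",
    small_sample = all(table(g) == 1)
  )
}
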