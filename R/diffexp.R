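# Wilcoxon rank-sum differential expression with BH control and the
# fixed-sample-size subsampled contrast design between mutation classes.

#' Wilcoxon rank-sum differential expression
#'
#' Per-gene two-sided Wilcoxon rank-sum test between two disjoint sample
#' groups on log2-scale expression. The exact null distribution is used when
#' the combined group size is at most 25 and the gene has no ties; otherwise
#' the normal approximation with tie correction and continuity correction.
#' Genes with zero variance across both groups get p = 1. P-values are
#' BH-adjusted across genes; the log2 fold change is `mean(A) - mean(B)`.
#'
#' @param expr Expression tibble (`gene` column + log2-scale sample columns).
#' @param a_samples,b_samples Character vectors of sample ids (disjoint, each
#'   of size >= 2, all present in `expr`).
#' @param fdr_q FDR level for the `significant` flag (default 0.10).
#' @return A tibble with `gene`, `p_raw`, `p_adj`, `log2fc`, `significant`,
#'   `n_a`, `n_b`.
#' @export
wilcoxon_de <- function(expr, a_samples, b_samples, fdr_q = 0.10) {
  if (length(intersect(a_samples, b_samples)) > 0) {
    stop("Sample groups overlap", call. = FALSE)
  }
  stopifnot(length(a_samples) >= 2, length(b_samples) >= 2)
  missing <- setdiff(c(a_samples, b_samples), names(expr))
  if (length(missing) > 0) {
    stop("Samples absent from the expression matrix: ",
         paste(utils::head(missing, 5), collapse = ", "), call. = FALSE)
  }
  ma <- expr_matrix(expr)[, a_samples, drop = FALSE]
  mb <- expr_matrix(expr)[, b_samples, drop = FALSE]
  n_a <- length(a_samples)
  n_b <- length(b_samples)
  small <- (n_a + n_b) <= 25

  p_raw <- vapply(seq_len(nrow(ma)), function(i) {
    a <- ma[i, ]; b <- mb[i, ]
    comb <- c(a, b)
    if (max(comb) == min(comb)) return(1)
    use_exact <- small && !anyDuplicated(comb)
    suppressWarnings(
      stats::wilcox.test(a, b, exact = use_exact, correct = TRUE)$p.value
    )
  }, numeric(1))

  tibble::tibble(
    gene = expr$gene,
    p_raw = p_raw,
    p_adj = stats::p.adjust(p_raw, method = "BH"),
    log2fc = unname(rowMeans(ma) - rowMeans(mb)),
    n_a = n_a, n_b = n_b
  ) |>
    dplyr::mutate(significant = .data$p_adj <= fdr_q)
}

#' Select tumors matching a mutation-class selector
#'
#' Selectors: `TP53mut`, `TP53wt`, the functional classes `LOF`, `GOF`, `DN`,
#' `nonDN`, the codon groups `R175`, `R248`, `R273` (any qualifying variant in
#' that codon), and `Hotspots` (the fixed pool of the ten most frequent
#' missense mutations).
#'
#' @param tumors Tumor-class tibble ([aggregate_tumor_classes()]`$tumors`,
#'   optionally joined with cohort annotations).
#' @param selector One of the selector names.
#' @return Character vector of sample ids.
#' @export
select_class_samples <- function(tumors, selector) {
  switch(selector,
    TP53mut = tumors$sample_id[tumors$status == "TP53mut"],
    TP53wt = tumors$sample_id[tumors$status == "TP53wt"],
    LOF = tumors$sample_id[tumors$lof],
    GOF = tumors$sample_id[tumors$gof],
    DN = tumors$sample_id[tumors$dn],
    nonDN = tumors$sample_id[tumors$nondn],
    Hotspots = tumors$sample_id[tumors$hotspot_pool],
    R175 = tumors$sample_id[purrr::map_lgl(tumors$codons, ~ 175L %in% .x)],
    R248 = tumors$sample_id[purrr::map_lgl(tumors$codons, ~ 248L %in% .x)],
    R273 = tumors$sample_id[purrr::map_lgl(tumors$codons, ~ 273L %in% .x)],
    stop("Unknown class selector: ", selector, call. = FALSE)
  )
}

# Deterministic 31-bit string hash (polynomial rolling hash), used to derive
# per-contrast seeds so that adding contrasts never perturbs existing ones.
stable_hash <- function(key) {
  h <- 0
  for (v in utf8ToInt(key)) h <- (h * 31 + v) %% 2147483647
  as.integer(h)
}

contrast_seed <- function(seed, cancer_type, group_a, group_b) {
  key <- paste(cancer_type, group_a, group_b, sep = "|")
  bitwXor(as.integer(seed) %% 2147483647L, stable_hash(key))
}

#' Fixed-sample-size subsampled contrast
#'
#' Implements the fixed-n contrast design: within one cancer type, draw
#' exactly `n_sub` tumors per group uniformly without replacement (seeded by
#' the run seed combined with a stable hash of the contrast key) and run the
#' Wilcoxon differential expression. Tumors selected by both group selectors
#' (e.g. a tumor with one DN and one non-DN variant in a DN vs non-DN
#' contrast) are excluded from both groups to keep them disjoint. If either
#' group has fewer than `n_sub` eligible tumors, the contrast is marked
#' not-analyzable (`na = TRUE`) rather than an error.
#'
#' @param expr Expression tibble.
#' @param tumors Tumor-class tibble including a `cancer_type` column.
#' @param cancer_type Cancer type to analyze.
#' @param group_a,group_b Class selectors (see [select_class_samples()]).
#' @param n_sub Per-group sample size.
#' @param seed Run seed.
#' @param fdr_q FDR level.
#' @return A `tp53_contrast` object: list with `cancer_type`, `group_a`,
#'   `group_b`, `n_sub`, `na`, `n_eligible_a`, `n_eligible_b`, `samples_a`,
#'   `samples_b`, `de` (DE tibble or `NULL`), `n_significant` (`NA` when not
#'   analyzable).
#' @export
subsampled_contrast <- function(expr, tumors, cancer_type, group_a, group_b,
                                n_sub = 15, seed = 1L, fdr_q = 0.10) {
  in_type <- dplyr::filter(tumors, .data$cancer_type == !!cancer_type)
  a <- select_class_samples(in_type, group_a)
  b <- select_class_samples(in_type, group_b)
  both <- intersect(a, b)
  if (length(both) > 0) {
    pipeline_log(length(both), " tumors in both groups of ", cancer_type, " ",
                 group_a, " vs ", group_b, " excluded from the contrast")
    a <- setdiff(a, both)
    b <- setdiff(b, both)
  }
  a <- intersect(a, names(expr))
  b <- intersect(b, names(expr))
  res <- list(cancer_type = cancer_type, group_a = group_a, group_b = group_b,
              n_sub = as.integer(n_sub), n_eligible_a = length(a),
              n_eligible_b = length(b))
  if (length(a) < n_sub || length(b) < n_sub) {
    res$na <- TRUE
    res$samples_a <- character()
    res$samples_b <- character()
    res$de <- NULL
    res$n_significant <- NA_integer_
    return(structure(res, class = "tp53_contrast"))
  }
  cs <- contrast_seed(seed, cancer_type, group_a, group_b)
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old), add = TRUE)
  set.seed(cs)
  sel_a <- sort(sample(sort(a), n_sub))
  sel_b <- sort(sample(sort(b), n_sub))
  de <- wilcoxon_de(expr, sel_a, sel_b, fdr_q = fdr_q)
  res$na <- FALSE
  res$samples_a <- sel_a
  res$samples_b <- sel_b
  res$de <- de
  res$n_significant <- sum(de$significant)
  structure(res, class = "tp53_contrast")
}

.Random.seed_get <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_set <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' @export
print.tp53_contrast <- function(x, ...) {
  cat(sprintf("<tp53_contrast %s: %s vs %s, n_sub = %d> %s\n",
              x$cancer_type, x$group_a, x$group_b, x$n_sub,
              if (x$na) "N.A. (insufficient samples)"
              else sprintf("%d significant genes", x$n_significant)))
  invisible(x)
}

#' Count significant genes in a differential-expression result
#'
#' @param de A DE tibble from [wilcoxon_de()] or a `tp53_contrast`; the
#'   not-analyzable marker propagates as `NA`.
#' @return Integer count (or `NA`).
#' @export
count_significant <- function(de) {
  if (inherits(de, "tp53_contrast")) {
    return(if (de$na) NA_integer_ else de$n_significant)
  }
  sum(de$significant)
}

#' Default contrast plan between mutation classes and against wildtype
#'
#' The class-vs-class comparisons (codon groups against each other and
#' against LOF, hotspot pool vs LOF, LOF vs GOF, DN vs non-DN) and every
#' class against wildtype.
#'
#' @return A tibble with `group_a`, `group_b` and `kind`
#'   (`"class_vs_class"` / `"class_vs_wt"`).
#' @export
default_contrasts <- function() {
  cls <- tibble::tribble(
    ~group_a, ~group_b,
    "R175", "R248",
    "R175", "R273",
    "R248", "R273",
    "R175", "LOF",
    "R248", "LOF",
    "R273", "LOF",
    "Hotspots", "LOF",
    "LOF", "GOF",
    "DN", "nonDN"
  )
  cls$kind <- "class_vs_class"
  wt <- tibble::tibble(
    group_a = c("R175", "R248", "R273", "Hotspots", "LOF", "GOF", "DN",
                "nonDN", "TP53mut"),
    group_b = "TP53wt",
    kind = "class_vs_wt"
  )
  dplyr::bind_rows(cls, wt)
}

#' Contrast-by-cancer-type matrix of significant gene counts
#'
#' Runs every contrast in every cancer type with the fixed-n subsampling
#' design and tabulates the number of FDR-significant genes (`NA` where a
#' contrast is not analyzable). Optionally adds a pan-cancer column: per gene
#' the available per-type p-values are combined with Fisher's method, BH
#' applied across genes, and significant genes counted.
#'
#' @param expr Expression tibble.
#' @param tumors Tumor-class tibble with `cancer_type`.
#' @param contrasts Tibble with `group_a`, `group_b` ([default_contrasts()]).
#' @param cancer_types Cancer types to analyze (default: all in `tumors`).
#' @param config A [tp53_config()].
#' @param pan_cancer Add the Fisher-combined pan-cancer column?
#' @return A tibble with `group_a`, `group_b`, `cancer_type`
#'   (`"pan-cancer"` for the combined column) and `n_significant`.
#' @export
contrast_matrix <- function(expr, tumors, contrasts = default_contrasts(),
                            cancer_types = NULL, config = tp53_config(),
                            pan_cancer = TRUE) {
  cancer_types <- cancer_types %||% sort(unique(tumors$cancer_type))
  purrr::pmap_dfr(
    contrasts[c("group_a", "group_b")],
    function(group_a, group_b) {
      runs <- purrr::map(cancer_types, function(ct) {
        subsampled_contrast(expr, tumors, ct, group_a, group_b,
                            n_sub = config$n_sub, seed = config$seed,
                            fdr_q = config$fdr_q)
      })
      out <- tibble::tibble(
        group_a = group_a, group_b = group_b, cancer_type = cancer_types,
        n_significant = purrr::map_int(runs, count_significant)
      )
      if (pan_cancer) {
        avail <- purrr::keep(runs, ~ !.x$na)
        n_pan <- NA_integer_
        if (length(avail) > 0) {
          pmat <- do.call(cbind, purrr::map(avail, ~ .x$de$p_raw))
          comb <- apply(pmat, 1, function(p) fisher_combine(p)$p)
          n_pan <- sum(stats::p.adjust(comb, method = "BH") <= config$fdr_q)
        }
        out <- dplyr::bind_rows(out, tibble::tibble(
          group_a = group_a, group_b = group_b, cancer_type = "pan-cancer",
          n_significant = n_pan
        ))
      }
      out
    }
  )
}

#' Tile plot of the contrast-by-cancer-type matrix
#'
#' @param cm Output of [contrast_matrix()].
#' @return A ggplot object; cells show significant-gene counts, `N.A.` where
#'   a contrast was not analyzable.
#' @export
plot_contrast_matrix <- function(cm) {
  cm <- dplyr::mutate(cm,
                      contrast = paste(.data$group_a, "vs", .data$group_b),
                      label = ifelse(is.na(.data$n_significant), "N.A.",
                                     as.character(.data$n_significant)))
  ggplot2::ggplot(cm, ggplot2::aes(x = .data$cancer_type, y = .data$contrast,
                                   fill = log10(.data$n_significant + 1))) +
    ggplot2::geom_tile(colour = "white") +
    ggplot2::geom_text(ggplot2::aes(label = .data$label), size = 2.5) +
    ggplot2::scale_fill_gradient(low = "white", high = "firebrick",
                                 na.value = "grey85",
                                 name = "log10(genes + 1)") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5))
}
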