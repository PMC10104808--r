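# Hotspot recurrence screening, exact prevalence intervals and
# cross-cancer-type homogeneity testing.

#' Tally variant carriers per cancer type
#'
#' Counts, for every protein change, the number of distinct carrier tumors in
#' each cancer type (a tumor carrying the same variant twice counts once).
#' Variants with an empty protein-change string cannot be keyed and are
#' excluded (logged). Denominators are either the TP53-mutant tumors of the
#' type (default, `denominator = "mut"`) or all tumors (`"all"`).
#'
#' @param variants TP53 variant records (qualifying variants are tallied).
#' @param statuses Tumor status tibble ([call_tp53_status()]).
#' @param cohort Sample-annotation tibble with `sample_id`, `cancer_type`.
#' @param denominator `"mut"` or `"all"`.
#' @return A tibble with `protein_change`, `cancer_type`, `x` (carriers),
#'   `m` (denominator), `prevalence`.
#' @export
tally_variants <- function(variants, statuses, cohort,
                           denominator = c("mut", "all")) {
  denominator <- match.arg(denominator)
  v <- dplyr::filter(variants,
                     .data$variant_classification %in% qualifying_classifications)
  n_unkeyed <- sum(v$protein_change == "")
  if (n_unkeyed > 0) {
    pipeline_log(n_unkeyed, " variants without a protein-change key excluded ",
                 "from hotspot tallies")
    v <- dplyr::filter(v, .data$protein_change != "")
  }
  denom <- cohort |>
    dplyr::left_join(statuses, by = "sample_id") |>
    dplyr::group_by(.data$cancer_type) |>
    dplyr::summarise(
      m = if (denominator == "mut") sum(.data$status == "TP53mut") else dplyr::n(),
      .groups = "drop"
    )
  counts <- v |>
    dplyr::left_join(dplyr::select(cohort, "sample_id", "cancer_type"),
                     by = "sample_id") |>
    dplyr::filter(!is.na(.data$cancer_type)) |>
    dplyr::distinct(.data$protein_change, .data$sample_id, .data$cancer_type) |>
    dplyr::count(.data$protein_change, .data$cancer_type, name = "x")
  tidyr::expand_grid(protein_change = unique(counts$protein_change),
                     cancer_type = denom$cancer_type) |>
    dplyr::left_join(counts, by = c("protein_change", "cancer_type")) |>
    dplyr::mutate(x = ifelse(is.na(.data$x), 0L, .data$x)) |>
    dplyr::left_join(denom, by = "cancer_type") |>
    dplyr::mutate(prevalence = ifelse(.data$m > 0, .data$x / .data$m, NA_real_))
}

#' Select recurrent hotspot variants
#'
#' A variant is recurrent iff there is at least one cancer type where it is
#' carried by at least `min_count` tumors and its prevalence is at least
#' `min_prev`.
#'
#' @param tallies Output of [tally_variants()].
#' @param min_count Minimum carrier count (default 2).
#' @param min_prev Minimum prevalence (default 0.01).
#' @return Character vector of recurrent protein changes.
#' @export
select_recurrent <- function(tallies, min_count = 2, min_prev = 0.01) {
  tallies |>
    dplyr::filter(.data$m > 0,
                  .data$x >= min_count,
                  .data$x / .data$m >= min_prev) |>
    dplyr::distinct(.data$protein_change) |>
    dplyr::pull("protein_change")
}

#' Clopper-Pearson exact binomial confidence interval
#'
#' Exact interval from Beta-distribution quantiles:
#' `lower = qbeta(alpha/2; x, m - x + 1)` (0 when `x = 0`) and
#' `upper = qbeta(1 - alpha/2; x + 1, m - x)` (1 when `x = m`). Vectorized
#' over `x` and `m`.
#'
#' @param x Number of successes.
#' @param m Number of trials (must be >= 1).
#' @param conf Confidence level (default 0.95).
#' @return A tibble with columns `lower` and `upper`.
#' @export
clopper_pearson <- function(x, m, conf = 0.95) {
  if (any(m < 1)) stop("Clopper-Pearson interval undefined for m = 0",
                       call. = FALSE)
  stopifnot(all(x >= 0), all(x <= m), conf > 0, conf < 1)
  alpha <- 1 - conf
  lower <- ifelse(x == 0, 0, stats::qbeta(alpha / 2, x, m - x + 1))
  upper <- ifelse(x == m, 1, stats::qbeta(1 - alpha / 2, x + 1, m - x))
  tibble::tibble(lower = lower, upper = upper)
}

#' Chi-square homogeneity test of prevalences across cancer types
#'
#' Tests equality of carrier proportions across cancer types with the
#' multi-group chi-square test of `prop.test` (no continuity correction),
#' df = groups - 1. Degenerate tables (all x = 0 or all x = m) return p = 1.
#'
#' @param x Per-type carrier counts.
#' @param m Per-type denominators (types with `m = 0` are dropped).
#' @return The p-value.
#' @export
homogeneity_test <- function(x, m) {
  keep <- m > 0
  x <- x[keep]; m <- m[keep]
  if (length(x) < 2) stop("Homogeneity test needs at least two cancer types",
                          call. = FALSE)
  if (sum(x) == 0 || sum(m - x) == 0) return(1)
  suppressWarnings(stats::prop.test(x, m, correct = FALSE)$p.value)
}

#' Hotspot report with exact intervals and FDR-flagged homogeneity tests
#'
#' For each recurrent variant: per-cancer-type prevalence with 95%
#' Clopper-Pearson intervals, one cross-type homogeneity p-value, and a
#' Benjamini-Hochberg significance flag at level `fdr_q` across all recurrent
#' variants. A codon-level tally (lollipop-style) is returned alongside.
#'
#' @param variants TP53 variant records.
#' @param statuses Tumor status tibble.
#' @param cohort Sample-annotation tibble.
#' @param config A [tp53_config()]; drives the recurrence screen, prevalence
#'   denominator and FDR level.
#' @return A list with `hotspots` (tibble: one row per variant x cancer type,
#'   with `homogeneity_p`, `q` and `fdr_significant` constant within variant)
#'   and `codon_tally` (tibble: `codon`, `n`).
#' @export
hotspot_report <- function(variants, statuses, cohort, config = tp53_config()) {
  tallies <- tally_variants(variants, statuses, cohort,
                            denominator = config$hotspot_denominator)
  recurrent <- select_recurrent(tallies, config$hotspot_min_count,
                                config$hotspot_min_prev)
  tab <- dplyr::filter(tallies, .data$protein_change %in% recurrent,
                       .data$m > 0)
  ci <- clopper_pearson(tab$x, tab$m)
  tab$ci_lower <- ci$lower
  tab$ci_upper <- ci$upper
  tests <- tab |>
    dplyr::group_by(.data$protein_change) |>
    dplyr::summarise(homogeneity_p = homogeneity_test(.data$x, .data$m),
                     .groups = "drop") |>
    dplyr::mutate(q = stats::p.adjust(.data$homogeneity_p, method = "BH"),
                  fdr_significant = .data$q <= config$fdr_q)
  hotspots <- dplyr::left_join(tab, tests, by = "protein_change") |>
    dplyr::arrange(.data$protein_change, .data$cancer_type)

  codon_tally <- variants |>
    dplyr::filter(.data$variant_classification %in% qualifying_classifications,
                  !is.na(.data$codon)) |>
    dplyr::distinct(.data$sample_id, .data$protein_change, .data$codon) |>
    dplyr::count(.data$codon, name = "n") |>
    dplyr::arrange(.data$codon)

  list(hotspots = hotspots, codon_tally = codon_tally)
}

#' Lollipop-style plot of the codon-level mutation tally
#'
#' @param codon_tally Tibble with `codon` and `n` ([hotspot_report()]).
#' @return A ggplot object.
#' @export
plot_codon_lollipop <- function(codon_tally) {
  ggplot2::ggplot(codon_tally, ggplot2::aes(x = .data$codon, y = .data$n)) +
    ggplot2::geom_segment(ggplot2::aes(xend = .data$codon, yend = 0),
                          linewidth = 0.4, colour = "grey50") +
    ggplot2::geom_point(colour = "firebrick", size = 1.6) +
    ggplot2::labs(x = "TP53 codon", y = "Mutation count") +
    ggplot2::theme_minimal()
}
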