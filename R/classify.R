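# Two-step TP53 classification: tumor-level mut/wt calling, then
# variant-level GOF/LOF/DN/nonDN/VUS classes lifted to non-exclusive
# tumor-level flags.

#' Call tumor-level TP53 status
#'
#' A tumor is TP53-mutant iff it carries at least one variant whose
#' classification is non-synonymous coding or splice-site (missense, nonsense,
#' splice site, translation start site, non-stop, frameshift or in-frame
#' indel). Tumors with only silent/UTR/intron/flank/splice-region/intergenic
#' variants, or with no TP53 variant at all, are wildtype.
#'
#' @param variants Tibble of TP53 variant records ([read_maf()] restricted to
#'   TP53).
#' @param samples Character vector of all sample ids in the cohort.
#' @return A tibble with `sample_id` and `status` (`"TP53mut"`/`"TP53wt"`).
#' @export
call_tp53_status <- function(variants, samples) {
  mut <- unique(variants$sample_id[
    variants$variant_classification %in% qualifying_classifications
  ])
  tibble::tibble(
    sample_id = samples,
    status = ifelse(samples %in% mut, "TP53mut", "TP53wt")
  )
}

#' Classify TP53 variants into functional classes
#'
#' Applies the two-stage rule to every TP53mut-qualifying variant:
#' \enumerate{
#'   \item If the protein change has a database entry: GOF when the entry is
#'     GOF-annotated (GOF takes precedence over a co-annotated LOF); LOF when
#'     LOF-annotated and not GOF; DN when DN-annotated, otherwise non-DN.
#'   \item If absent from the database: LOF (and non-DN) when the
#'     classification is evidence of truncation (nonsense, frameshift, splice
#'     site, translation start site, non-stop); otherwise a variant of
#'     unknown significance (VUS).
#' }
#' Non-qualifying variants (silent etc.) receive all-`FALSE` flags.
#'
#' @param variants Tibble of TP53 variant records.
#' @param db Variant-annotation tibble ([read_variant_annotations()]).
#' @return The input with added logical columns `qualifying`, `gof`, `lof`,
#'   `dn`, `nondn`, `vus`.
#' @export
classify_variants <- function(variants, db) {
  stopifnot(!anyDuplicated(db$protein_change))
  idx <- match(variants$protein_change, db$protein_change)
  in_db <- !is.na(idx) & variants$protein_change != ""
  db_gof <- ifelse(in_db, db$gof[idx], FALSE)
  db_lof <- ifelse(in_db, db$lof[idx], FALSE)
  db_dn <- ifelse(in_db, db$dn[idx], FALSE)
  truncating <- variants$variant_classification %in% truncating_classifications
  qualifying <- variants$variant_classification %in% qualifying_classifications

  gof <- in_db & db_gof
  lof <- (in_db & db_lof & !db_gof) | (!in_db & truncating)
  dn <- in_db & db_dn
  nondn <- (in_db & !db_dn) | (!in_db & truncating)
  vus <- !in_db & !truncating

  out <- variants
  out$qualifying <- qualifying
  out$gof <- gof & qualifying
  out$lof <- lof & qualifying
  out$dn <- dn & qualifying
  out$nondn <- nondn & qualifying
  out$vus <- vus & qualifying
  out
}

#' Aggregate variant classes to tumor-level flags
#'
#' A tumor carries a class flag iff any of its qualifying variants carries it
#' ("any variant" semantics); flags are non-exclusive, so a tumor can be both
#' GOF and DN, or carry DN and non-DN flags via different variants. Also
#' reports the pairwise overlap summary: for every ordered class pair (A, B),
#' `100 * |A intersect B| / |A|` rounded to the nearest integer.
#'
#' @param classified Output of [classify_variants()].
#' @param statuses Output of [call_tp53_status()] for all cohort samples.
#' @return A list with `tumors` (tibble: `sample_id`, `status`, logical class
#'   flag columns, `codons` list-column, `hotspot_pool` flag) and `overlap`
#'   (tibble: `class_a`, `class_b`, `n_a`, `n_ab`, `overlap_pct`).
#' @export
aggregate_tumor_classes <- function(classified, statuses) {
  flags <- classified |>
    dplyr::filter(.data$qualifying) |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::summarise(
      lof = any(.data$lof), gof = any(.data$gof), dn = any(.data$dn),
      nondn = any(.data$nondn), vus = any(.data$vus),
      codons = list(sort(unique(.data$codon[!is.na(.data$codon)]))),
      hotspot_pool = any(.data$protein_change %in% hotspot_pool_variants),
      .groups = "drop"
    )
  tumors <- statuses |>
    dplyr::left_join(flags, by = "sample_id") |>
    dplyr::mutate(
      dplyr::across(c("lof", "gof", "dn", "nondn", "vus", "hotspot_pool"),
                    ~ ifelse(is.na(.x), FALSE, .x)),
      codons = purrr::map(.data$codons, ~ if (is.null(.x)) integer(0) else .x)
    )
  # wildtype tumors must not carry class flags
  stopifnot(!any(tumors$status == "TP53wt" &
                   (tumors$lof | tumors$gof | tumors$dn | tumors$nondn | tumors$vus)))

  classes <- c("lof", "gof", "dn", "nondn")
  overlap <- tidyr::expand_grid(class_a = classes, class_b = classes) |>
    dplyr::filter(.data$class_a != .data$class_b) |>
    dplyr::mutate(
      n_a = purrr::map_int(.data$class_a, ~ sum(tumors[[.x]])),
      n_ab = purrr::map2_int(.data$class_a, .data$class_b,
                             ~ sum(tumors[[.x]] & tumors[[.y]])),
      overlap_pct = ifelse(.data$n_a > 0, round(100 * .data$n_ab / .data$n_a),
                           NA_real_)
    )
  list(tumors = tumors, overlap = overlap)
}

#' Overlap percentage between two tumor classes
#'
#' `100 * n_ab / n_a` rounded to the nearest integer — the share of class A
#' tumors that are also in class B.
#'
#' @param n_a Size of class A.
#' @param n_ab Size of the intersection of A and B.
#' @return Rounded percentage.
#' @export
class_overlap_pct <- function(n_a, n_ab) {
  stopifnot(n_a > 0, n_ab >= 0, n_ab <= n_a)
  round(100 * n_ab / n_a)
}

# The fixed pool of the ten most frequent TP53 missense hotspot mutations
# used by the "Hotspots" contrast selector.
hotspot_pool_variants <- c(
  "p.R175H", "p.R273C", "p.R273H", "p.R248Q", "p.R248W",
  "p.R282W", "p.Y220C", "p.G45S", "p.H179R", "p.V157F"
)
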