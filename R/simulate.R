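# Synthetic cohort generator: emits a full input bundle (MAF, expression,
# annotations, variant-annotation table, immune matrix) with known planted
# structure so every downstream stage has a recoverable truth.

# The 24 TCGA cancer-type codes of the reference cohort.
tcga_cancer_types <- c(
  "ACC", "BLCA", "BRCA", "CESC", "COAD", "ESCA", "GBM", "HNSC", "KICH",
  "KIRC", "KIRP", "LGG", "LIHC", "LUAD", "LUSC", "MESO", "OV", "PAAD",
  "PRAD", "READ", "SARC", "SKCM", "STAD", "UCEC"
)

#' Default cancer-type design
#'
#' The 24 cancer types with 30 samples each and TP53 mutation fraction 0.5
#' (15 mutant + 15 wildtype tumors per type).
#'
#' @return A tibble with `name`, `n_samples`, `mut_fraction`.
#' @export
default_cancer_types <- function() {
  tibble::tibble(name = tcga_cancer_types, n_samples = 30L, mut_fraction = 0.5)
}

#' Default TP53 variant catalog
#'
#' A weighted catalog emulating the observed TP53 mutation spectrum: the ten
#' most frequent missense hotspots with database annotations (GOF taking
#' precedence where co-annotated with LOF, DN flags on most DNA-binding-domain
#' hotspots), further database-annotated missense variants, truncating and
#' splice variants absent from the database (classified LOF by the truncation
#' fallback), and missense variants absent from the database (VUS). Within
#' codon 175 the weights put an 89% share on p.R175H. The overall mix is
#' roughly 65% missense, 26% truncating and 7% splice, and the implied class
#' mix roughly matches the reference cohort (GOF about a third, DN and
#' non-DN each about half).
#'
#' @return A tibble with `protein_change`, `variant_classification`,
#'   `weight`, `in_db`, `gof`, `lof`, `dn`.
#' @export
default_variant_catalog <- function() {
  tibble::tribble(
    ~protein_change, ~variant_classification, ~weight, ~in_db, ~gof, ~lof, ~dn,
    # codon 175: 89% / 7% / 4% within-codon shares
    "p.R175H", "Missense_Mutation", 0.0979, TRUE, TRUE, TRUE, TRUE,
    "p.R175G", "Missense_Mutation", 0.0077, TRUE, FALSE, TRUE, FALSE,
    "p.R175L", "Missense_Mutation", 0.0044, TRUE, FALSE, TRUE, FALSE,
    # remaining top-ten hotspot pool
    "p.R273C", "Missense_Mutation", 0.0700, TRUE, TRUE, TRUE, TRUE,
    "p.R273H", "Missense_Mutation", 0.0560, TRUE, TRUE, TRUE, TRUE,
    "p.R248Q", "Missense_Mutation", 0.0600, TRUE, TRUE, TRUE, TRUE,
    "p.R248W", "Missense_Mutation", 0.0430, TRUE, TRUE, TRUE, TRUE,
    "p.R282W", "Missense_Mutation", 0.0250, TRUE, FALSE, TRUE, TRUE,
    "p.Y220C", "Missense_Mutation", 0.0200, TRUE, FALSE, TRUE, FALSE,
    "p.G45S",  "Missense_Mutation", 0.0100, TRUE, TRUE, FALSE, FALSE,
    "p.H179R", "Missense_Mutation", 0.0100, TRUE, FALSE, TRUE, TRUE,
    "p.V157F", "Missense_Mutation", 0.0120, TRUE, FALSE, TRUE, TRUE,
    # other annotated missense
    "p.R249S", "Missense_Mutation", 0.0100, TRUE, FALSE, TRUE, FALSE,
    "p.G245S", "Missense_Mutation", 0.0150, TRUE, FALSE, TRUE, TRUE,
    "p.R158L", "Missense_Mutation", 0.0080, TRUE, FALSE, TRUE, FALSE,
    "p.C176F", "Missense_Mutation", 0.0090, TRUE, FALSE, TRUE, TRUE,
    "p.R280K", "Missense_Mutation", 0.0080, TRUE, FALSE, TRUE, FALSE,
    "p.E285K", "Missense_Mutation", 0.0150, TRUE, TRUE, TRUE, TRUE,
    # missense absent from the database (VUS)
    "p.A159V", "Missense_Mutation", 0.0200, FALSE, NA, NA, NA,
    "p.P72R",  "Missense_Mutation", 0.0100, FALSE, NA, NA, NA,
    "p.D393Y", "Missense_Mutation", 0.0080, FALSE, NA, NA, NA,
    # truncating, absent from the database (fallback LOF)
    "p.R213*", "Nonsense_Mutation", 0.0500, FALSE, NA, NA, NA,
    "p.R196*", "Nonsense_Mutation", 0.0300, FALSE, NA, NA, NA,
    "p.R342*", "Nonsense_Mutation", 0.0200, FALSE, NA, NA, NA,
    "p.P152fs", "Frame_Shift_Del", 0.0400, FALSE, NA, NA, NA,
    "p.T256fs", "Frame_Shift_Ins", 0.0200, FALSE, NA, NA, NA,
    "p.X125_splice", "Splice_Site", 0.0300, FALSE, NA, NA, NA,
    "p.X331_splice", "Splice_Site", 0.0250, FALSE, NA, NA, NA,
    "p.I255del", "In_Frame_Del", 0.0100, FALSE, NA, NA, NA,
    "p.*394L", "Nonstop_Mutation", 0.0050, FALSE, NA, NA, NA,
    "p.M1?", "Translation_Start_Site", 0.0050, FALSE, NA, NA, NA
  )
}

# 14 generic immune cell population labels.
default_immune_populations <- c(
  "B_cells", "Plasma_cells", "CD4_T_cells", "CD8_T_cells", "Tregs",
  "Gamma_delta_T_cells", "NK_cells", "Monocytes", "Macrophages_M1",
  "Macrophages_M2", "Dendritic_cells", "Mast_cells", "Neutrophils",
  "Eosinophils"
)

#' Default planted immune shifts
#'
#' Abundance shifts (in units of the immune noise SD) added to TP53-mutant
#' tumors, emulating the reference pattern: exclusively decreased populations
#' in six subtypes, a mixed pattern in four (including Treg increases in the
#' hormone-receptor and HER2 breast subtypes), exclusive increases in two,
#' and no shift in the remaining twenty subtypes. The magnitude (3 noise SDs)
#' is chosen so that a planted shift is recoverable with high power even in
#' the smallest stratified subtypes of the default design (about 5 mutant vs
#' 9 wildtype tumors after HPV/MSI/receptor splits) under joint FDR control.
#'
#' @return A tibble with `subtype`, `population`, `shift`.
#' @export
default_immune_shifts <- function() {
  tibble::tribble(
    ~subtype, ~population, ~shift,
    # exclusively decreased (6 subtypes)
    "HPV- HNSC", "CD8_T_cells", -3,
    "HPV+ HNSC", "CD8_T_cells", -3,
    "HPV+ HNSC", "Tregs", -3,
    "MSI-L/MSS STAD", "CD8_T_cells", -3,
    "MSI-L/MSS STAD", "Tregs", -3,
    "MSI-L/MSS UCEC", "CD8_T_cells", -3,
    "SKCM", "NK_cells", -3,
    "PAAD", "Macrophages_M2", -3,
    # mixed (4 subtypes)
    "LGG", "CD8_T_cells", -3,
    "LGG", "Tregs", -3,
    "LGG", "B_cells", 3,
    "HR+/HER2- BRCA", "Tregs", 3,
    "HR+/HER2- BRCA", "CD4_T_cells", -3,
    "HER2+ BRCA", "Tregs", 3,
    "HER2+ BRCA", "NK_cells", -3,
    "LUAD", "Dendritic_cells", 3,
    "LUAD", "B_cells", -3,
    # exclusively increased (2 subtypes)
    "BLCA", "Neutrophils", 3,
    "PRAD", "Mast_cells", 3
  )
}

#' Default TMB multipliers for TP53-mutant tumors
#'
#' Multiplies the mean missense count of mutant tumors per subtype: elevated
#' (x2) in 15 subtypes, decreased (x0.5) in 5, unchanged elsewhere.
#'
#' @return A tibble with `subtype`, `multiplier`.
#' @export
default_tmb_multipliers <- function() {
  dplyr::bind_rows(
    tibble::tibble(subtype = c("ACC", "BLCA", "ESCA", "GBM", "HPV- HNSC",
                               "KIRC", "LGG", "LIHC", "LUAD", "LUSC", "OV",
                               "PAAD", "PRAD", "SARC", "SKCM"),
                   multiplier = 2),
    tibble::tibble(subtype = c("MSI-H STAD", "MSI-H UCEC", "MSI-H COAD",
                               "MSI-H READ", "HPV+ CESC"),
                   multiplier = 0.5)
  )
}

#' Simulation parameters
#'
#' Defaults encode the study conditions of the reference design: 24 cancer
#' types with 15 TP53-mutant and 15 wildtype tumors each, 500 genes, 100
#' planted overexpressed genes with effect size 2 log2 units active in 20 of
#' the 24 types, expression noise SD 1 log2 unit, the default variant
#' catalog, 14 immune populations with the default planted shifts, and a
#' mean missense burden of 40 mutations per tumor.
#'
#' @param cancer_types Tibble (`name`, `n_samples`, `mut_fraction`).
#' @param variant_catalog Tibble as in [default_variant_catalog()].
#' @param variant_weights Optional variant-by-type weight matrix overriding
#'   the catalog's global `weight` column (rownames = protein changes,
#'   colnames = cancer types).
#' @param n_genes Number of expression genes.
#' @param n_planted_up,n_planted_down Numbers of planted over-/underexpressed
#'   genes (disjoint sets).
#' @param delta_up,delta_down Planted effect sizes in log2 units.
#' @param n_active_types Number of cancer types in which each planted gene's
#'   effect is active.
#' @param noise_sd Expression noise SD (log2 units).
#' @param baseline_type_sd SD of per-type baseline shifts (log2 units).
#' @param immune_populations Population names (`NULL` disables the immune
#'   matrix).
#' @param immune_shifts Tibble (`subtype`, `population`, `shift`).
#' @param immune_noise_sd Immune abundance noise SD.
#' @param tmb_mean Mean missense count per tumor (Poisson).
#' @param tmb_multipliers Tibble (`subtype`, `multiplier`) applied to mutant
#'   tumors.
#' @param silent_wt_fraction Fraction of wildtype tumors receiving a silent
#'   TP53 variant (exercises wildtype calling).
#' @param multi_variant_prob Probability that a mutant tumor carries a second
#'   qualifying variant (exercises tumor-level class aggregation).
#' @param seed Integer seed; identical seeds give bit-identical bundles.
#' @return A list of class `sim_params`.
#' @export
sim_params <- function(cancer_types = default_cancer_types(),
                       variant_catalog = default_variant_catalog(),
                       variant_weights = NULL,
                       n_genes = 500, n_planted_up = 100, n_planted_down = 0,
                       delta_up = 2, delta_down = -2, n_active_types = 20,
                       noise_sd = 1, baseline_type_sd = 0.5,
                       immune_populations = default_immune_populations,
                       immune_shifts = default_immune_shifts(),
                       immune_noise_sd = 1,
                       tmb_mean = 40,
                       tmb_multipliers = default_tmb_multipliers(),
                       silent_wt_fraction = 0.1,
                       multi_variant_prob = 0,
                       seed = 1L) {
  stopifnot(nrow(cancer_types) >= 1,
            all(cancer_types$mut_fraction > 0 & cancer_types$mut_fraction < 1),
            all(variant_catalog$weight >= 0), any(variant_catalog$weight > 0),
            n_planted_up + n_planted_down <= n_genes,
            n_active_types <= nrow(cancer_types),
            noise_sd >= 0, tmb_mean > 0)
  if (!is.null(variant_weights)) {
    stopifnot(is.matrix(variant_weights),
              nrow(variant_weights) == nrow(variant_catalog),
              all(cancer_types$name %in% colnames(variant_weights)),
              all(variant_weights >= 0))
  }
  n_mut <- floor(cancer_types$n_samples * cancer_types$mut_fraction + 0.5)
  if (all(n_mut < 1)) {
    warning("mut_fraction * n_samples < 1 for every cancer type; ",
            "the cohort filter will reject such a cohort")
  }
  structure(as.list(environment()), class = "sim_params")
}

sim_stratifiers <- function(type, n) {
  hpv <- c("HNSC", "CESC"); msi <- c("STAD", "UCEC", "COAD", "READ")
  out <- tibble::tibble(hpv_status = rep("unknown", n),
                        msi_status = "unknown", brca_subtype = "unknown")
  if (type %in% hpv) {
    out$hpv_status <- sample(c("pos", "neg"), n, replace = TRUE,
                             prob = c(0.5, 0.5))
  } else if (type %in% msi) {
    out$msi_status <- sample(c("MSI-H", "MSI-L/MSS"), n, replace = TRUE,
                             prob = c(0.35, 0.65))
  } else if (type == "BRCA") {
    out$brca_subtype <- sample(c("HR+/HER2-", "HER2+", "TNBC"), n,
                               replace = TRUE, prob = c(0.45, 0.3, 0.25))
  }
  out
}

# Truth-side variant class flags, computed directly from catalog annotations
# (independent of the classifier's code path).
catalog_truth_flags <- function(catalog) {
  truncating <- catalog$variant_classification %in% truncating_classifications
  in_db <- catalog$in_db
  tibble::tibble(
    protein_change = catalog$protein_change,
    t_gof = in_db & !is.na(catalog$gof) & catalog$gof,
    t_lof = (in_db & !is.na(catalog$lof) & catalog$lof &
               !(!is.na(catalog$gof) & catalog$gof)) | (!in_db & truncating),
    t_dn = in_db & !is.na(catalog$dn) & catalog$dn,
    t_nondn = (in_db & !(!is.na(catalog$dn) & catalog$dn)) |
      (!in_db & truncating),
    t_vus = !in_db & !truncating
  )
}

#' Generate a synthetic cohort with planted structure
#'
#' Per cancer type, `round(n * mut_fraction)` tumors (round half up) receive
#' one qualifying TP53 variant drawn from the weighted catalog (optionally a
#' second with `multi_variant_prob`); a fraction of wildtype tumors receive a
#' silent TP53 variant. Log2-scale expression for gene g in sample s is
#' `baseline(type, g) + delta(g, type) * [s mutant] + Normal(0, noise_sd^2)`,
#' with planted effects active in a per-gene random subset of
#' `n_active_types` cancer types. Genome-wide missense background mutations
#' are drawn per sample as `Poisson(tmb_mean * multiplier)` to define TMB,
#' and immune abundances as `base + shift * [mutant] + noise`. Identical
#' seeds give identical output.
#'
#' @param params A [sim_params()] object.
#' @return A list of class `sim_bundle` with `maf`, `expression` (log2-scale
#'   tibble), `annotations`, `variant_annotations`, `immune` (or `NULL`) and
#'   `truth` (per-sample status/class flags, planted gene lists with active
#'   types, immune shifts, TMB multipliers, per-type mutant counts).
#' @export
generate_cohort <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old), add = TRUE)
  set.seed(params$seed)

  types <- params$cancer_types
  catalog <- params$variant_catalog
  tflags <- catalog_truth_flags(catalog)

  # --- samples, stratifiers, mutation assignment ---
  ann <- purrr::pmap_dfr(types, function(name, n_samples, mut_fraction) {
    dplyr::bind_cols(
      tibble::tibble(
        sample_id = sprintf("%s_S%03d", name, seq_len(n_samples)),
        cancer_type = name
      ),
      sim_stratifiers(name, n_samples)
    )
  })
  subtypes <- build_subtypes(ann)
  ann_sub <- dplyr::left_join(ann, subtypes, by = "sample_id")

  mut_samples <- character(0)
  maf_rows <- list()
  for (i in seq_len(nrow(types))) {
    ty <- types$name[i]
    ids <- ann$sample_id[ann$cancer_type == ty]
    n_mut <- floor(length(ids) * types$mut_fraction[i] + 0.5)
    sel <- sort(sample(ids, n_mut))
    mut_samples <- c(mut_samples, sel)
    w <- if (is.null(params$variant_weights)) catalog$weight
         else params$variant_weights[, ty]
    if (n_mut > 0) {
      idx <- sample.int(nrow(catalog), n_mut, replace = TRUE, prob = w)
      rows <- tibble::tibble(
        sample_id = sel, gene = "TP53",
        variant_classification = catalog$variant_classification[idx],
        protein_change = catalog$protein_change[idx]
      )
      if (params$multi_variant_prob > 0) {
        second <- stats::runif(n_mut) < params$multi_variant_prob
        if (any(second)) {
          idx2 <- sample.int(nrow(catalog), sum(second), replace = TRUE,
                             prob = w)
          rows <- dplyr::bind_rows(rows, tibble::tibble(
            sample_id = sel[second], gene = "TP53",
            variant_classification = catalog$variant_classification[idx2],
            protein_change = catalog$protein_change[idx2]
          ))
        }
      }
      maf_rows[[ty]] <- rows
    }
    # silent TP53 variants on some wildtype tumors
    wt <- setdiff(ids, sel)
    n_silent <- floor(length(wt) * params$silent_wt_fraction + 0.5)
    if (n_silent > 0) {
      maf_rows[[paste0(ty, "_silent")]] <- tibble::tibble(
        sample_id = sort(sample(wt, n_silent)), gene = "TP53",
        variant_classification = "Silent", protein_change = "p.P36P"
      )
    }
  }
  tp53_maf <- dplyr::bind_rows(maf_rows)
  is_mut <- ann$sample_id %in% mut_samples

  # --- genome-wide missense background (defines TMB) ---
  mult <- rep(1, nrow(ann))
  mm <- match(ann_sub$subtype, params$tmb_multipliers$subtype)
  mult[!is.na(mm)] <- params$tmb_multipliers$multiplier[mm[!is.na(mm)]]
  lambda <- params$tmb_mean * ifelse(is_mut, mult, 1)
  bg_pool <- sprintf("BG%05d", seq_len(max(5000, ceiling(20 * max(lambda)))))
  n_bg <- stats::rpois(nrow(ann), lambda)
  bg_maf <- tibble::tibble(
    sample_id = rep(ann$sample_id, n_bg),
    gene = unlist(purrr::map(n_bg, ~ sample(bg_pool, .x))),
    variant_classification = "Missense_Mutation",
    protein_change = ""
  )
  maf <- dplyr::bind_rows(tp53_maf, bg_maf)
  maf$codon <- parse_codon(maf$protein_change)
  maf <- dplyr::arrange(maf, .data$sample_id, .data$gene, .data$protein_change)

  # --- expression with planted differential effects ---
  genes <- sprintf("G%04d", seq_len(params$n_genes))
  planted <- sample(genes, params$n_planted_up + params$n_planted_down)
  up_genes <- planted[seq_len(params$n_planted_up)]
  down_genes <- setdiff(planted, up_genes)
  active_up <- purrr::map(up_genes,
                          ~ sort(sample(types$name, params$n_active_types)))
  names(active_up) <- up_genes
  active_down <- purrr::map(down_genes,
                            ~ sort(sample(types$name, params$n_active_types)))
  names(active_down) <- down_genes

  gene_mean <- stats::runif(params$n_genes, 3, 9)
  base_shift <- matrix(stats::rnorm(params$n_genes * nrow(types),
                                    sd = params$baseline_type_sd),
                       params$n_genes, nrow(types),
                       dimnames = list(genes, types$name))
  delta <- matrix(0, params$n_genes, nrow(types),
                  dimnames = list(genes, types$name))
  for (g in up_genes) delta[g, active_up[[g]]] <- params$delta_up
  for (g in down_genes) delta[g, active_down[[g]]] <- params$delta_down

  ti <- match(ann$cancer_type, types$name)
  expr <- gene_mean + base_shift[, ti, drop = FALSE]
  expr <- expr + sweep(delta[, ti, drop = FALSE], 2, as.numeric(is_mut), `*`)
  expr <- expr + matrix(stats::rnorm(length(expr), sd = params$noise_sd),
                        nrow(expr), ncol(expr))
  expr <- pmax(expr, 0)
  colnames(expr) <- ann$sample_id
  expression <- dplyr::bind_cols(tibble::tibble(gene = genes),
                                 tibble::as_tibble(expr))

  # --- immune abundances ---
  immune <- NULL
  if (!is.null(params$immune_populations) &&
      length(params$immune_populations) > 0) {
    pops <- params$immune_populations
    base <- stats::runif(length(pops), 4, 6)
    imat <- matrix(stats::rnorm(nrow(ann) * length(pops),
                                sd = params$immune_noise_sd),
                   nrow(ann), length(pops), dimnames = list(NULL, pops))
    imat <- sweep(imat, 2, base, `+`)
    if (nrow(params$immune_shifts) > 0) {
      for (j in seq_len(nrow(params$immune_shifts))) {
        s <- params$immune_shifts[j, ]
        hit <- ann_sub$subtype %in% s$subtype & is_mut
        if (s$population %in% pops && any(hit)) {
          imat[hit, s$population] <- imat[hit, s$population] + s$shift
        }
      }
    }
    immune <- dplyr::bind_cols(tibble::tibble(sample_id = ann$sample_id),
                               tibble::as_tibble(imat))
  }

  # --- variant-annotation table (database rows only) ---
  variant_annotations <- catalog |>
    dplyr::filter(.data$in_db) |>
    dplyr::select("protein_change", "gof", "lof", "dn")

  # --- truth record ---
  truth_flags <- tp53_maf |>
    dplyr::filter(.data$variant_classification %in% qualifying_classifications) |>
    dplyr::left_join(tflags, by = "protein_change") |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::summarise(lof = any(.data$t_lof), gof = any(.data$t_gof),
                     dn = any(.data$t_dn), nondn = any(.data$t_nondn),
                     vus = any(.data$t_vus), .groups = "drop")
  truth_status <- ann |>
    dplyr::select("sample_id", "cancer_type") |>
    dplyr::left_join(subtypes, by = "sample_id") |>
    dplyr::mutate(status = ifelse(.data$sample_id %in% mut_samples,
                                  "TP53mut", "TP53wt")) |>
    dplyr::left_join(truth_flags, by = "sample_id") |>
    dplyr::mutate(dplyr::across(c("lof", "gof", "dn", "nondn", "vus"),
                                ~ ifelse(is.na(.x), FALSE, .x)))
  truth <- list(
    status = truth_status,
    planted_up = up_genes, planted_down = down_genes,
    active_up = active_up, active_down = active_down,
    delta_up = params$delta_up, delta_down = params$delta_down,
    immune_shifts = params$immune_shifts,
    tmb_multipliers = params$tmb_multipliers,
    n_mut_per_type = table(ann$cancer_type[is_mut])
  )

  structure(list(maf = maf, expression = expression, annotations = ann,
                 variant_annotations = variant_annotations, immune = immune,
                 truth = truth, params = params),
            class = "sim_bundle")
}

#' @export
print.sim_bundle <- function(x, ...) {
  cat(sprintf(paste0("<sim_bundle: %d samples, %d cancer types, %d genes, ",
                     "%d TP53mut tumors>\n"),
              nrow(x$annotations), length(unique(x$annotations$cancer_type)),
              nrow(x$expression),
              sum(x$truth$status$status == "TP53mut")))
  invisible(x)
}

#' Write a synthetic bundle to disk
#'
#' Emits the bundle in the exact dialects the readers consume: `maf.tsv`,
#' `expression.tsv` (linear scale; reading it back recovers the log2 values),
#' `annotations.tsv`, `variant_annotations.tsv`, `immune.tsv` (omitted when
#' the bundle has no immune matrix, noted in the manifest), `truth.json` and
#' `manifest.json`.
#'
#' @param bundle A `sim_bundle` from [generate_cohort()].
#' @param dir Output directory (created if missing).
#' @return Named character vector of the written file paths, invisibly.
#' @export
emit_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "sim_bundle"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    maf = file.path(dir, "maf.tsv"),
    expression = file.path(dir, "expression.tsv"),
    annotations = file.path(dir, "annotations.tsv"),
    variant_annotations = file.path(dir, "variant_annotations.tsv")
  )
  write_maf(bundle$maf, paths["maf"])
  write_expression(bundle$expression, paths["expression"])
  readr::write_tsv(bundle$annotations, paths["annotations"])
  readr::write_tsv(bundle$variant_annotations, paths["variant_annotations"])
  if (!is.null(bundle$immune)) {
    paths["immune"] <- file.path(dir, "immune.tsv")
    readr::write_tsv(bundle$immune, paths["immune"])
  }
  truth_path <- file.path(dir, "truth.json")
  truth <- bundle$truth
  truth$n_mut_per_type <- as.list(truth$n_mut_per_type)
  jsonlite::write_json(truth, truth_path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  config <- tp53_config(seed = bundle$params$seed)
  manifest_path <- file.path(dir, "manifest.json")
  write_run_manifest(
    manifest_path, config, files = paths,
    counts = list(
      n_samples = nrow(bundle$annotations),
      n_cancer_types = length(unique(bundle$annotations$cancer_type)),
      n_genes = nrow(bundle$expression),
      n_tp53_variants = sum(bundle$maf$gene == "TP53"),
      immune_matrix_emitted = !is.null(bundle$immune),
      mut_count_rounding = "round half up of n * mut_fraction"
    )
  )
  invisible(c(paths, truth = truth_path, manifest = manifest_path))
}
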