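make_expr <- function(mat, genes = NULL, samples = NULL) {
  genes <- genes %||% sprintf("G%02d", seq_len(nrow(mat)))
  samples <- samples %||% sprintf("S%02d", seq_len(ncol(mat)))
  colnames(mat) <- samples
  dplyr::bind_cols(tibble::tibble(gene = genes), tibble::as_tibble(mat))
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("exact Wilcoxon p matches hand-derived and enumerated values", {
  expr <- make_expr(matrix(c(1, 2, 3, 4, 5, 6), nrow = 1))
  de <- wilcoxon_de(expr, c("S01", "S02", "S03"), c("S04", "S05", "S06"))
  expect_equal(de$p_raw, 0.1)  # 2 extreme orderings / C(6,3)
  expect_equal(de$log2fc, -3)
})

test_that("zero-variance genes get p = 1", {
  expr <- make_expr(matrix(5, nrow = 2, ncol = 8))
  de <- wilcoxon_de(expr, paste0("S0", 1:4), paste0("S0", 5:8))
  expect_equal(de$p_raw, c(1, 1))
  expect_equal(de$log2fc, c(0, 0))
})

test_that("overlapping groups are rejected", {
  expr <- make_expr(matrix(rnorm(8), nrow = 1))
  expect_error(wilcoxon_de(expr, paste0("S0", 1:4), paste0("S0", 4:8)),
               "overlap")
})

test_that("exact path equals the permutation-enumeration oracle", {
  withr::local_seed(4)
  for (n in c(3, 4)) {
    for (rep in 1:15) {
      vals <- sample(1:100, 2 * n)  # tie-free integers
      a <- vals[seq_len(n)]; b <- vals[-seq_len(n)]
      expr <- make_expr(matrix(vals, nrow = 1))
      de <- wilcoxon_de(expr, sprintf("S%02d", seq_len(n)),
                        sprintf("S%02d", n + seq_len(n)))
      expect_equal(de$p_raw, wilcoxon_enum_p(a, b), info = paste(n, rep))
    }
  }
})

test_that("log2fc is antisymmetric and p invariant under group swap", {
  withr::local_seed(8)
  expr <- make_expr(matrix(rnorm(10 * 12), nrow = 10))
  a <- sprintf("S%02d", 1:6); b <- sprintf("S%02d", 7:12)
  d1 <- wilcoxon_de(expr, a, b)
  d2 <- wilcoxon_de(expr, b, a)
  expect_equal(d1$log2fc, -d2$log2fc)
  expect_equal(d1$p_raw, d2$p_raw)
  expect_true(all(d1$p_adj >= d1$p_raw))
  expect_true(all(d1$p_adj[d1$significant] <= 0.10))
})

sim_tumors <- function() {
  b <- generate_cohort(small_sim_params(seed = 19L))
  tp53 <- dplyr::filter(b$maf, gene == "TP53")
  st <- call_tp53_status(tp53, b$annotations$sample_id)
  agg <- aggregate_tumor_classes(classify_variants(tp53, b$variant_annotations),
                                 st)
  tumors <- dplyr::left_join(
    agg$tumors, dplyr::select(b$annotations, sample_id, cancer_type),
    by = "sample_id")
  list(bundle = b, tumors = tumors)
}

test_that("subsampled contrasts return the NA marker when underpowered", {
  s <- sim_tumors()
  res <- subsampled_contrast(s$bundle$expression, s$tumors, "LUAD",
                             "R175", "R248", n_sub = 15)
  expect_true(res$na)
  expect_equal(count_significant(res), NA_integer_)
})

test_that("subsampling is deterministic and respects group labels", {
  s <- sim_tumors()
  r1 <- subsampled_contrast(s$bundle$expression, s$tumors, "LUAD",
                            "TP53mut", "TP53wt", n_sub = 10, seed = 2)
  r2 <- subsampled_contrast(s$bundle$expression, s$tumors, "LUAD",
                            "TP53mut", "TP53wt", n_sub = 10, seed = 2)
  expect_identical(r1$samples_a, r2$samples_a)
  expect_identical(r1$de, r2$de)
  # every selected sample verifiably belongs to its selector class
  in_type <- dplyr::filter(s$tumors, cancer_type == "LUAD")
  expect_true(all(r1$samples_a %in%
                    in_type$sample_id[in_type$status == "TP53mut"]))
  expect_true(all(r1$samples_b %in%
                    in_type$sample_id[in_type$status == "TP53wt"]))
  # a different seed draws a different subsample
  r3 <- subsampled_contrast(s$bundle$expression, s$tumors, "LUAD",
                            "TP53mut", "TP53wt", n_sub = 10, seed = 3)
  expect_false(identical(r1$samples_a, r3$samples_a))
})

test_that("planted effects produce the mut-vs-wt / class-vs-class dichotomy", {
  s <- sim_tumors()
  mutwt <- subsampled_contrast(s$bundle$expression, s$tumors, "LUAD",
                               "TP53mut", "TP53wt", n_sub = 15, seed = 1)
  expect_false(mutwt$na)
  expect_gt(mutwt$n_significant, 3)  # 5 planted genes at delta = 2
  lofgof <- subsampled_contrast(s$bundle$expression, s$tumors, "LUAD",
                                "LOF", "GOF", n_sub = 5, seed = 1)
  if (!lofgof$na) expect_lte(lofgof$n_significant, 1)
})

test_that("count_significant counts flags and propagates NA", {
  de <- tibble::tibble(gene = letters[1:4],
                       significant = c(TRUE, FALSE, TRUE, FALSE))
  expect_equal(count_significant(de), 2)
})

test_that("contrast matrix tabulates types plus a pan-cancer column", {
  s <- sim_tumors()
  cm <- contrast_matrix(
    s$bundle$expression, s$tumors,
    contrasts = tibble::tibble(group_a = "TP53mut", group_b = "TP53wt"),
    config = tp53_config(n_sub = 15, seed = 1)
  )
  expect_setequal(cm$cancer_type, c("LUAD", "BRCA", "pan-cancer"))
  expect_true(all(cm$n_significant > 0))
  p <- plot_contrast_matrix(cm)
  expect_s3_class(p, "ggplot")
})

test_that("per-contrast seeds are independent of other contrasts", {
  expect_equal(tp53pancan:::contrast_seed(1, "LUAD", "A", "B"),
               tp53pancan:::contrast_seed(1, "LUAD", "A", "B"))
  expect_false(tp53pancan:::contrast_seed(1, "LUAD", "A", "B") ==
                 tp53pancan:::contrast_seed(1, "LUAD", "A", "C"))
  expect_false(tp53pancan:::contrast_seed(1, "LUAD", "A", "B") ==
                 tp53pancan:::contrast_seed(2, "LUAD", "A", "B"))
})
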