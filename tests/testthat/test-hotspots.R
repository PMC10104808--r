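test_that("recurrence screen applies count and prevalence jointly", {
  tallies <- tibble::tibble(
    protein_change = c("v1", "v1", "v2", "v3", "v3"),
    cancer_type = c("A", "B", "A", "A", "B"),
    x = c(2L, 0L, 1L, 3L, 3L),
    m = c(100L, 50L, 100L, 400L, 400L)
  )
  rec <- select_recurrent(tallies, min_count = 2, min_prev = 0.01)
  expect_true("v1" %in% rec)    # 2 carriers at 2% in type A
  expect_false("v2" %in% rec)   # single carrier anywhere
  expect_false("v3" %in% rec)   # 3 carriers but 0.75% everywhere
  # brute-force oracle over the predicate
  for (v in unique(tallies$protein_change)) {
    rows <- tallies[tallies$protein_change == v, ]
    oracle <- any(rows$x >= 2 & rows$x / rows$m >= 0.01)
    expect_equal(v %in% rec, oracle, info = v)
  }
})

test_that("recurrence is monotone in carrier counts", {
  withr::local_seed(42)
  for (i in 1:20) {
    tallies <- tibble::tibble(
      protein_change = "v",
      cancer_type = paste0("T", 1:4),
      x = as.integer(sample(0:5, 4, replace = TRUE)),
      m = 200L
    )
    before <- "v" %in% select_recurrent(tallies)
    j <- sample(4, 1)
    tallies$x[j] <- tallies$x[j] + 1L
    after <- "v" %in% select_recurrent(tallies)
    expect_false(before & !after)
  }
})

test_that("Clopper-Pearson bounds match closed forms and binom.test", {
  ci <- clopper_pearson(0, 10)
  expect_equal(ci$lower, 0)
  expect_equal(ci$upper, 1 - 0.025^(1 / 10))  # closed form at x = 0
  ci <- clopper_pearson(10, 10)
  expect_equal(ci$upper, 1)
  expect_equal(ci$lower, 0.025^(1 / 10))
  ci <- clopper_pearson(5, 10)
  expect_equal(ci$lower, 1 - ci$upper)        # symmetry at x = m/2
  # cross-check the Beta-quantile construction against binom.test
  withr::local_seed(7)
  for (i in 1:25) {
    m <- sample(1:200, 1); x <- sample(0:m, 1)
    expect_equal(unlist(clopper_pearson(x, m)),
                 stats::setNames(binom.test(x, m)$conf.int[1:2],
                                 c("lower", "upper")),
                 tolerance = 1e-12)
  }
  expect_error(clopper_pearson(0, 0), "m = 0")
})

test_that("interval coverage is at least nominal (conservative)", {
  withr::local_seed(13)
  for (p in c(0.05, 0.5)) {
    m <- 40
    x <- stats::rbinom(2000, m, p)
    ci <- clopper_pearson(x, m)
    cover <- mean(ci$lower <= p & p <= ci$upper)
    mc_sd <- sqrt(0.95 * 0.05 / 2000)
    expect_gte(cover, 0.95 - 3 * mc_sd)
  }
})

test_that("homogeneity test handles equal, degenerate and 2x2 cases", {
  expect_equal(homogeneity_test(c(10, 10), c(100, 100)), 1)
  expect_equal(homogeneity_test(c(0, 0), c(50, 80)), 1)
  expect_equal(homogeneity_test(c(50, 80), c(50, 80)), 1)
  expect_error(homogeneity_test(5, 10), "at least two")
  # hand-computed Pearson chi-square on the 2x2 table (20/100 vs 5/100)
  o <- matrix(c(20, 80, 5, 95), nrow = 2, byrow = TRUE)
  e <- outer(rowSums(o), colSums(o)) / sum(o)
  x2 <- sum((o - e)^2 / e)
  expect_equal(homogeneity_test(c(20, 5), c(100, 100)),
               stats::pchisq(x2, df = 1, lower.tail = FALSE))
})

test_that("BH never discovers fewer than Bonferroni", {
  withr::local_seed(99)
  for (i in 1:30) {
    p <- stats::runif(sample(3:40, 1))^sample(1:3, 1)
    bh <- sum(stats::p.adjust(p, "BH") <= 0.10)
    bonf <- sum(stats::p.adjust(p, "bonferroni") <= 0.10)
    expect_gte(bh, bonf)
  }
})

test_that("hotspot report flags a planted cancer-type-specific hotspot", {
  catalog <- tibble::tibble(
    protein_change = c("p.R175H", "p.R248Q", "p.R213*"),
    variant_classification = c("Missense_Mutation", "Missense_Mutation",
                               "Nonsense_Mutation"),
    weight = c(0.3, 0.3, 0.4),
    in_db = c(TRUE, TRUE, FALSE),
    gof = c(TRUE, TRUE, NA), lof = c(TRUE, TRUE, NA), dn = c(TRUE, TRUE, NA)
  )
  types <- paste0("T", 1:6)
  w <- matrix(c(0.30, 0.30, 0.40), 3, 6, dimnames = list(NULL, types))
  w[, "T1"] <- c(0.70, 0.15, 0.15)  # p.R175H planted high in T1 only
  p <- sim_params(
    cancer_types = tibble::tibble(name = types, n_samples = 120L,
                                  mut_fraction = 0.5),
    variant_catalog = catalog, variant_weights = w,
    n_genes = 5, n_planted_up = 1, n_planted_down = 0, n_active_types = 1,
    immune_populations = NULL,
    tmb_multipliers = tibble::tibble(subtype = character(),
                                     multiplier = numeric()),
    seed = 17L
  )
  b <- generate_cohort(p)
  tp53 <- dplyr::filter(b$maf, gene == "TP53")
  st <- call_tp53_status(tp53, b$annotations$sample_id)
  rep <- hotspot_report(tp53, st, b$annotations)
  r175 <- dplyr::filter(rep$hotspots, protein_change == "p.R175H")
  expect_true(all(r175$fdr_significant))
  expect_true(all(r175$ci_lower <= r175$prevalence &
                    r175$prevalence <= r175$ci_upper))
  # codon tally covers the catalog codons
  expect_setequal(rep$codon_tally$codon, c(175L, 248L, 213L))
  # degenerate: identical prevalences everywhere are never flagged
  expect_false(any(is.na(rep$hotspots$homogeneity_p)))
})

test_that("all-equal homogeneity p-values yield no FDR flags", {
  variants <- tibble::tibble(
    sample_id = c("A1", "A2", "B1", "B2"), gene = "TP53",
    variant_classification = "Missense_Mutation",
    protein_change = "p.R175H", codon = 175L
  )
  cohort <- tibble::tibble(sample_id = c("A1", "A2", "B1", "B2"),
                           cancer_type = c("A", "A", "B", "B"))
  st <- call_tp53_status(variants, cohort$sample_id)
  rep <- hotspot_report(variants, st, cohort)
  expect_true(all(rep$hotspots$homogeneity_p == 1))
  expect_false(any(rep$hotspots$fdr_significant))
})
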