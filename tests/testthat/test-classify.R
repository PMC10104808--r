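make_variant <- function(sample_id, classification, pc) {
  tibble::tibble(sample_id = sample_id, gene = "TP53",
                 variant_classification = classification,
                 protein_change = pc,
                 codon = tp53pancan:::parse_codon(pc))
}

toy_db <- tibble::tibble(
  protein_change = c("p.R175H", "p.Y220C", "p.R282W", "p.G45S"),
  gof = c(TRUE, FALSE, FALSE, TRUE),
  lof = c(TRUE, TRUE, TRUE, FALSE),
  dn = c(TRUE, FALSE, TRUE, FALSE)
)

test_that("tumor status calling follows the qualifying-variant rule", {
  variants <- dplyr::bind_rows(
    make_variant("S1", "Missense_Mutation", "p.R175H"),
    make_variant("S2", "Silent", "p.P36P"),
    make_variant("S2", "Intron", ""),
    make_variant("S4", "Splice_Site", "p.X125_splice"),
    make_variant("S5", "5'UTR", "")
  )
  st <- call_tp53_status(variants, paste0("S", 1:5))
  expect_equal(st$status, c("TP53mut", "TP53wt", "TP53wt", "TP53mut", "TP53wt"))
})

test_that("variant classification covers every rule branch", {
  v <- dplyr::bind_rows(
    make_variant("S1", "Missense_Mutation", "p.R175H"),  # db GOF+LOF -> GOF
    make_variant("S2", "Missense_Mutation", "p.Y220C"),  # db LOF only, nonDN
    make_variant("S3", "Missense_Mutation", "p.R282W"),  # db LOF, DN
    make_variant("S4", "Missense_Mutation", "p.G45S"),   # db GOF only, nonDN
    make_variant("S5", "Nonsense_Mutation", "p.R213*"),  # fallback LOF
    make_variant("S6", "Missense_Mutation", "p.A159V"),  # absent missense VUS
    make_variant("S7", "Silent", "p.P36P")               # non-qualifying
  )
  cl <- classify_variants(v, toy_db)
  expect_true(cl$gof[1] && !cl$lof[1] && cl$dn[1])   # GOF precedence
  expect_true(cl$lof[2] && !cl$gof[2] && cl$nondn[2] && !cl$dn[2])
  expect_true(cl$lof[3] && cl$dn[3] && !cl$nondn[3])
  expect_true(cl$gof[4] && !cl$lof[4] && cl$nondn[4])
  expect_true(cl$lof[5] && cl$nondn[5] && !cl$vus[5]) # truncation fallback
  expect_true(cl$vus[6] && !cl$lof[6] && !cl$gof[6])
  expect_false(any(unlist(cl[7, c("gof", "lof", "dn", "nondn", "vus")])))
})

test_that("qualifying variants partition on both class axes", {
  # GOF / LOF-only / VUS is a partition; DN xor nonDN for annotated variants
  b <- generate_cohort(small_sim_params(seed = 21L))
  tp53 <- dplyr::filter(b$maf, gene == "TP53")
  cl <- classify_variants(tp53, b$variant_annotations)
  q <- dplyr::filter(cl, qualifying)
  expect_true(all(q$gof + q$lof + q$vus == 1))
  annotated <- q$protein_change %in% b$variant_annotations$protein_change
  expect_true(all(xor(q$dn[annotated], q$nondn[annotated])))
  expect_false(any(q$dn & q$nondn))
  # purity: identical inputs give identical flags
  expect_identical(cl, classify_variants(tp53, b$variant_annotations))
})

test_that("tumor-level flags are the union over qualifying variants", {
  v <- dplyr::bind_rows(
    make_variant("T1", "Missense_Mutation", "p.R175H"),  # GOF + DN
    make_variant("T2", "Missense_Mutation", "p.Y220C"),  # LOF + nonDN
    make_variant("T2", "Missense_Mutation", "p.G45S"),   # GOF + nonDN
    make_variant("T3", "Silent", "p.P36P")
  )
  cl <- classify_variants(v, toy_db)
  st <- call_tp53_status(v, c("T1", "T2", "T3"))
  agg <- aggregate_tumor_classes(cl, st)
  t1 <- agg$tumors[agg$tumors$sample_id == "T1", ]
  expect_true(t1$gof && t1$dn && !t1$lof)
  t2 <- agg$tumors[agg$tumors$sample_id == "T2", ]   # non-exclusive LOF+GOF
  expect_true(t2$gof && t2$lof && t2$nondn)
  t3 <- agg$tumors[agg$tumors$sample_id == "T3", ]
  expect_equal(t3$status, "TP53wt")
  expect_false(any(unlist(t3[c("gof", "lof", "dn", "nondn", "vus")])))
})

test_that("flag unions on a three-variant tumor match brute-force enumeration", {
  # enumerate all subsets of three annotated variants on one tumor and check
  # the aggregated flags equal the union of the per-variant flags
  pcs <- c("p.R175H", "p.Y220C", "p.R282W")
  single <- classify_variants(
    make_variant(paste0("V", 1:3), "Missense_Mutation", pcs), toy_db)
  for (take in 1:7) {
    idx <- which(bitwAnd(take, c(1L, 2L, 4L)) > 0)
    v <- make_variant(rep("T", length(idx)), "Missense_Mutation", pcs[idx])
    agg <- aggregate_tumor_classes(classify_variants(v, toy_db),
                                   call_tp53_status(v, "T"))
    for (fl in c("gof", "lof", "dn", "nondn", "vus")) {
      expect_equal(agg$tumors[[fl]], any(single[[fl]][idx]),
                   info = paste("subset", take, "flag", fl))
    }
  }
})

test_that("class overlap summary reports rounded intersection percentages", {
  expect_equal(class_overlap_pct(1208, 1086), 90)
  expect_equal(class_overlap_pct(2050, 1666), 81)
  v <- dplyr::bind_rows(
    make_variant(paste0("G", 1:10), "Missense_Mutation", "p.R175H"), # GOF+DN
    make_variant(paste0("L", 1:3), "Missense_Mutation", "p.Y220C")   # LOF+nonDN
  )
  cl <- classify_variants(v, toy_db)
  st <- call_tp53_status(v, v$sample_id)
  ov <- aggregate_tumor_classes(cl, st)$overlap
  row <- ov[ov$class_a == "gof" & ov$class_b == "dn", ]
  expect_equal(row$overlap_pct, 100)
  row2 <- ov[ov$class_a == "lof" & ov$class_b == "dn", ]
  expect_equal(row2$overlap_pct, 0)
})

test_that("recovered class sizes equal the generator truth exactly", {
  b <- generate_cohort(small_sim_params(seed = 33L, noise_sd = 5))
  tp53 <- dplyr::filter(b$maf, gene == "TP53")
  st <- call_tp53_status(tp53, b$annotations$sample_id)
  agg <- aggregate_tumor_classes(classify_variants(tp53, b$variant_annotations),
                                 st)
  truth <- b$truth$status
  expect_equal(sum(agg$tumors$status == "TP53mut"),
               sum(truth$status == "TP53mut"))
  for (fl in c("lof", "gof", "dn", "nondn", "vus")) {
    expect_equal(sum(agg$tumors[[fl]]), sum(truth[[fl]]), info = fl)
  }
})
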