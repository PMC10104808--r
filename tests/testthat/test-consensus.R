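# de_list builder: per-type DE tibbles with prescribed p and fold change.
fake_de_list <- function(p_mat, fc_mat) {
  types <- colnames(p_mat)
  out <- lapply(types, function(ty) {
    tibble::tibble(gene = rownames(p_mat), p_raw = p_mat[, ty],
                   p_adj = p_mat[, ty], log2fc = fc_mat[, ty],
                   n_a = 15L, n_b = 15L, significant = p_mat[, ty] <= 0.1)
  })
  names(out) <- types
  out
}

test_that("Fisher combination matches hand values and closed forms", {
  fc <- fisher_combine(c(0.1, 0.1))
  expect_equal(fc$x2, -2 * log(0.01))
  expect_equal(fc$df, 4L)
  # chi-square survival at df = 4: exp(-x/2) * (1 + x/2)
  expect_equal(fc$p, exp(-fc$x2 / 2) * (1 + fc$x2 / 2), tolerance = 1e-12)
  expect_equal(fisher_combine(c(1, 1, 1))$x2, 0)
  expect_equal(fisher_combine(c(1, 1, 1))$p, 1)
  expect_equal(fisher_combine(0.03)$p, 0.03)  # k = 1 identity
  expect_true(is.na(fisher_combine(numeric(0))$p))
  expect_warning(out <- fisher_combine(c(0, 0.5)), "clamped")
  expect_true(out$p > 0)
})

test_that("Fisher combination is permutation-invariant and monotone", {
  withr::local_seed(2)
  for (i in 1:20) {
    p <- stats::runif(sample(2:10, 1))
    expect_equal(fisher_combine(p)$p, fisher_combine(rev(p))$p)
    j <- sample(length(p), 1)
    p2 <- p; p2[j] <- p2[j] * stats::runif(1)
    expect_lte(fisher_combine(p2)$p, fisher_combine(p)$p)
  }
})

test_that("consensus membership applies the fixed type threshold", {
  withr::local_seed(5)
  types <- paste0("T", 1:24)
  genes <- c("g16", "g15", "gnull")
  p_mat <- matrix(0.5, 3, 24, dimnames = list(genes, types))
  p_mat["g16", 1:16] <- 0.01   # exactly 16 types -> member
  p_mat["g15", 1:15] <- 0.01   # 15 types -> not a member
  fc_mat <- matrix(1, 3, 24, dimnames = list(genes, types))
  cons <- build_consensus(fake_de_list(p_mat, fc_mat), alpha_raw = 0.05, t = 16)
  st <- tidy(cons)
  expect_true(st$member[st$gene == "g16"])
  expect_false(st$member[st$gene == "g15"])
  expect_equal(st$n_sig[st$gene == "g16"], 16L)
  expect_equal(st$fisher_df, rep(48L, 3))
  g <- glance(cons)
  expect_equal(g$n_members, 1L)
  expect_equal(g$pct_over, 100)
})

test_that("direction is a majority vote with sum-of-FC tie break", {
  types <- paste0("T", 1:4)
  genes <- c("up", "down", "tie_pos")
  p_mat <- matrix(0.01, 3, 4, dimnames = list(genes, types))
  fc_mat <- rbind(c(1, 1, 1, -1), c(-1, -1, -1, 1), c(2, 2, -1, -1))
  dimnames(fc_mat) <- list(genes, types)
  cons <- build_consensus(fake_de_list(p_mat, fc_mat), t = 4)
  st <- tidy(cons)
  expect_equal(st$direction[match(c("up", "down", "tie_pos"), st$gene)],
               c("over", "under", "over"))
})

test_that("membership is monotone in alpha and anti-monotone in t", {
  withr::local_seed(31)
  types <- paste0("T", 1:8)
  genes <- paste0("g", 1:30)
  p_mat <- matrix(stats::runif(240), 30, 8, dimnames = list(genes, types))
  fc_mat <- matrix(stats::rnorm(240), 30, 8, dimnames = list(genes, types))
  dl <- fake_de_list(p_mat, fc_mat)
  m1 <- tidy(build_consensus(dl, alpha_raw = 0.05, t = 4))$member
  m2 <- tidy(build_consensus(dl, alpha_raw = 0.20, t = 4))$member
  expect_true(all(m2 | !m1))  # larger alpha never loses members
  m3 <- tidy(build_consensus(dl, alpha_raw = 0.05, t = 6))$member
  expect_true(all(m1 | !m3))  # larger t never gains members
})

test_that("UPGMA clustering matches a hand-computed trace", {
  # rows A, B, C with L1 distances d(A,B) = 1, d(A,C) = 4, d(B,C) = 5:
  # first merge A,B at height 1, then (AB),C at (4 + 5) / 2 = 4.5
  m <- rbind(A = c(0, 0), B = c(0, 1), C = c(4, 0))
  expect_equal(as.numeric(stats::dist(m, method = "manhattan")), c(1, 4, 5))
  cl <- cluster_heatmap(m, k_genes = 2, k_types = 1)
  expect_equal(cl$hclust_genes$height, c(1, 4.5))
  expect_equal(cl$gene_clusters, c(A = 1L, B = 1L, C = 2L))
  # identical rows merge first at distance 0
  m2 <- rbind(A = c(1, 2), B = c(1, 2), C = c(9, 9))
  cl2 <- cluster_heatmap(m2, k_genes = 2, k_types = 1)
  expect_equal(cl2$hclust_genes$height[1], 0)
})

test_that("gene partitions are invariant to row order", {
  withr::local_seed(6)
  m <- matrix(rnorm(60), 12, 5,
              dimnames = list(paste0("g", 1:12), paste0("t", 1:5)))
  c1 <- cluster_heatmap(m, k_genes = 3, k_types = 2)$gene_clusters
  perm <- sample(12)
  c2 <- cluster_heatmap(m[perm, ], k_genes = 3, k_types = 2)$gene_clusters
  # same partition: co-membership must agree for every pair
  co <- function(cl) outer(cl[paste0("g", 1:12)], cl[paste0("g", 1:12)], "==")
  expect_equal(co(c1), co(c2))
})

test_that("k larger than the item count raises", {
  m <- matrix(rnorm(6), 3, 2, dimnames = list(letters[1:3], c("x", "y")))
  expect_error(cluster_heatmap(m, k_genes = 4, k_types = 1), "k_genes")
  expect_error(cluster_heatmap(m, k_genes = 2, k_types = 3), "k_types")
})

test_that("dendrograms export as parseable Newick trees", {
  withr::local_seed(10)
  m <- matrix(rnorm(40), 8, 5,
              dimnames = list(paste0("g", 1:8), paste0("t", 1:5)))
  cl <- cluster_heatmap(m, k_genes = 2, k_types = 2)
  dir <- withr::local_tempdir()
  export_newick(cl, file.path(dir, "genes.nwk"), file.path(dir, "types.nwk"))
  tg <- ape::read.tree(file.path(dir, "genes.nwk"))
  expect_setequal(tg$tip.label, paste0("g", 1:8))
  tt <- ape::read.tree(file.path(dir, "types.nwk"))
  expect_setequal(tt$tip.label, paste0("t", 1:5))
})

test_that("cluster-prevalence test matches the closed-form chi-square", {
  clusters <- c(A = 1L, B = 1L, C = 1L, D = 2L, E = 2L, F = 2L)
  prev <- c(A = 0.1, B = 0.2, C = 0.3, D = 0.4, E = 0.5, F = 0.6)
  out <- cluster_prevalence_test(clusters, prev)
  # ranks 1:6 split into {1,2,3} and {4,5,6}: H = 12/(6*7) * sum n_i (rbar - 3.5)^2
  h <- 12 / 42 * (3 * (2 - 3.5)^2 + 3 * (5 - 3.5)^2)
  expect_equal(out$statistic, h)
  expect_equal(out$p_value, stats::pchisq(h, 1, lower.tail = FALSE))
  # identical prevalences: degenerate ranks, p = 1
  same <- cluster_prevalence_test(clusters, stats::setNames(rep(0.3, 6),
                                                            names(prev)))
  expect_equal(same$p_value, 1)
  # single observation per cluster: flagged small-sample
  out3 <- cluster_prevalence_test(c(A = 1L, B = 2L, C = 3L),
                                  c(A = 0.1, B = 0.2, C = 0.3))
  expect_true(out3$small_sample)
  expect_equal(out3$df, 2L)
})

test_that("consensus and biclust expose plots and tidiers", {
  withr::local_seed(12)
  types <- paste0("T", 1:16)
  genes <- paste0("g", 1:20)
  p_mat <- matrix(0.01, 20, 16, dimnames = list(genes, types))
  fc_mat <- matrix(rnorm(320, 2), 20, 16, dimnames = list(genes, types))
  cons <- build_consensus(fake_de_list(p_mat, fc_mat), t = 16)
  expect_s3_class(ggplot2::autoplot(cons), "ggplot")
  cl <- cluster_heatmap(cons, k_genes = 3, k_types = 2)
  expect_s3_class(ggplot2::autoplot(cl), "ggplot")
  td <- tidy(cl)
  expect_setequal(td$item[td$axis == "gene"], genes)
  expect_equal(glance(cl)$k_types, 2L)
})
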