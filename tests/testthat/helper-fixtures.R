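# Shared fixture builders; everything is generated in code.

write_fixture_maf <- function(path, rows) {
  header <- "Hugo_Symbol\tVariant_Classification\tTumor_Sample_Barcode\tHGVSp_Short"
  writeLines(c("# MC3-style comment", header, rows), path)
  path
}

# A small two-type simulation, cheap enough for unit tests.
small_sim_params <- function(seed = 11L, ...) {
  sim_params(
    cancer_types = tibble::tibble(name = c("LUAD", "BRCA"), n_samples = 30L,
                                  mut_fraction = 0.5),
    n_genes = 50, n_planted_up = 5, n_planted_down = 0,
    n_active_types = 2,
    immune_populations = NULL,
    immune_shifts = tibble::tibble(subtype = character(),
                                   population = character(),
                                   shift = numeric()),
    tmb_multipliers = tibble::tibble(subtype = character(),
                                     multiplier = numeric()),
    seed = seed,
    ...
  )
}

# Independent two-sided exact Wilcoxon oracle: full enumeration of all
# group assignments; p = min(1, 2 * min(P(W <= w), P(W >= w))).
wilcoxon_enum_p <- function(a, b) {
  comb <- c(a, b)
  stopifnot(!anyDuplicated(comb))
  r <- rank(comb)
  n_a <- length(a)
  w_obs <- sum(r[seq_len(n_a)])
  sets <- utils::combn(length(comb), n_a)
  w_all <- apply(sets, 2, function(idx) sum(r[idx]))
  p_lo <- mean(w_all <= w_obs)
  p_hi <- mean(w_all >= w_obs)
  min(1, 2 * min(p_lo, p_hi))
}

# Independent two-sided Fisher exact oracle by minimum-likelihood tail
# summation over the hypergeometric support.
fisher_enum_p <- function(k, K, n, N) {
  support <- max(0, K + n - N):min(K, n)
  d <- stats::dhyper(support, n, N - n, K)
  d_obs <- stats::dhyper(k, n, N - n, K)
  sum(d[d <= d_obs * (1 + 1e-7)])
}
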