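# Selection-coefficient mapping: parsimony ancestor, counts, PRF kernels,
# MCMC behaviour.

test_that("parsimony ancestor follows the outgroup and flags 2-vs-2 splits", {
  taxa <- c("human", "chimp", "orang", "macaque")
  mk <- function(h, c, o, m) {
    codon_alignment(stats::setNames(c(h, c, o, m), taxa))
  }
  # all identical
  a1 <- parsimony_ancestor(mk("ATG", "ATG", "ATG", "ATG"), taxa)
  expect_equal(a1$codon_state, "ATG")
  expect_false(a1$ambiguous)
  # human differs, other three agree
  a2 <- parsimony_ancestor(mk("ATA", "ATG", "ATG", "ATG"), taxa)
  expect_equal(a2$codon_state, "ATG")
  # ingroup/outgroup 2-vs-2 crossing split is ambiguous
  a3 <- parsimony_ancestor(mk("ATA", "ATG", "ATA", "ATG"), taxa)
  expect_true(a3$ambiguous)
  expect_true(is.na(a3$codon_state))
  # ingroup pair vs outgroup pair resolves to the ingroup state
  a4 <- parsimony_ancestor(mk("ATA", "ATA", "ATG", "ATG"), taxa)
  expect_equal(a4$codon_state, "ATA")
  expect_error(parsimony_ancestor(mk("ATA", "ATA", "ATG", "ATG"),
                                  c("human", "chimp", "orang", "gibbon")),
               "gibbon")
})

test_that("site counts classify fixed and segregating changes", {
  taxa <- c("human", "chimp", "orang", "macaque")
  # ancestor AAA (Lys); human carries fixed nonsynonymous AAA->GAA (Glu)
  aln <- codon_alignment(stats::setNames(
    c("GAAATG", "AAAATG", "AAAATG", "AAAATG"), taxa))
  anc <- parsimony_ancestor(aln, taxa)
  smp <- population_sample("human", n = 10, snps = tibble::tibble(
    codon = integer(), pos = integer(), ancestral = character(),
    derived = character(), derived_count = integer()))
  cnt <- derive_site_counts(aln, smp, anc)
  expect_equal(cnt$D_n, c(1L, 0L))
  expect_equal(cnt$D_s, c(0L, 0L))
  expect_true(all(cnt$P_n == 0) && all(cnt$P_s == 0))
  expect_true(all(cnt$Z_n > 0))

  # a synonymous SNP at codon 2 (ATG? no - use CTG->TTG, both Leu)
  aln2 <- codon_alignment(stats::setNames(
    c("AAACTG", "AAACTG", "AAACTG", "AAACTG"), taxa))
  anc2 <- parsimony_ancestor(aln2, taxa)
  smp2 <- population_sample("human", n = 10, snps = tibble::tibble(
    codon = 2L, pos = 1L, ancestral = "C", derived = "T",
    derived_count = 3L))
  cnt2 <- derive_site_counts(aln2, smp2, anc2)
  expect_equal(cnt2$P_s, c(0L, 1L))
  expect_equal(cnt2$P_n, c(0L, 0L))
  expect_true(all(cnt2$D_s == 0) && all(cnt2$D_n == 0))

  expect_error(population_sample("x", 10, tibble::tibble(
    codon = 1L, pos = 1L, ancestral = "A", derived = "G",
    derived_count = 10L)), "\\[1, n-1\\]")
  smp3 <- population_sample("human", n = 10, snps = tibble::tibble(
    codon = 99L, pos = 1L, ancestral = "A", derived = "G",
    derived_count = 2L))
  expect_error(derive_site_counts(aln2, smp3, anc2), "outside")
})

test_that("PRF kernels satisfy their identities", {
  expect_equal(prf_fixation_factor(0), 1)
  expect_equal(prf_polymorphism_factor(0, 20), 1, tolerance = 1e-10)
  for (g in c(1, 5, 50, 500)) {
    expect_equal(prf_fixation_factor(g) / prf_fixation_factor(-g),
                 exp(g), tolerance = 1e-12)
  }
  grid <- sort(gamma_grid())
  expect_true(all(diff(vapply(grid, prf_fixation_factor, numeric(1))) > 0))
  expect_true(all(diff(vapply(grid, prf_polymorphism_factor, numeric(1),
                              n = 20)) > 0))
})

test_that("PRF log-likelihood is order-invariant and prefers the truth", {
  sim <- simulate_prf_site_counts(50, gamma = rep(10, 50), theta = 0.05,
                                  T_div = 2, n_chrom = 20, seed = 3)
  ll10 <- gamma_site_loglik(sim$counts, 10, 0.05, 2)
  llm10 <- gamma_site_loglik(sim$counts, -10, 0.05, 2)
  expect_gt(ll10, llm10)
  perm <- sample(50)
  expect_equal(gamma_site_loglik(sim$counts[perm, ], 10, 0.05, 2), ll10,
               tolerance = 1e-10)
  expect_error(gamma_site_loglik(sim$counts, 10, -1, 2), "positive")
})

test_that("the sampler is deterministic and returns normalised masses", {
  sim <- simulate_prf_site_counts(30, gamma = rep(0, 30), theta = 0.05,
                                  T_div = 2, n_chrom = 20, seed = 6)
  pri <- prior_spec(log(0.05), 1, log(2), 1)
  p1 <- run_gammamap_mcmc(sim$counts, pri, iterations = 2000, thin = 5,
                          chains = 2, seed = 44)
  p2 <- run_gammamap_mcmc(sim$counts, pri, iterations = 2000, thin = 5,
                          chains = 2, seed = 44)
  expect_identical(p1$posterior, p2$posterior)
  expect_equal(rowSums(as.matrix(p1$posterior[, -1])), rep(1, 30),
               tolerance = 1e-9)
  expect_tbl_cols(p1$diagnostics, c("parameter", "rhat", "ess"))
})

test_that("persistence couples adjacent codons", {
  set.seed(8)
  g <- rep(c(0, 50), each = 20)[sample(40)]  # scattered signal
  sim <- simulate_prf_site_counts(40, gamma = g, theta = 0.05, T_div = 2,
                                  n_chrom = 20, seed = 8)
  pri <- prior_spec(log(0.05), 1, log(2), 1)
  cors <- vapply(c(0, 0.5, 0.9), function(p) {
    prof <- suppressWarnings(
      run_gammamap_mcmc(sim$counts, pri, iterations = 4000, thin = 5,
                        chains = 1, fix_p = p, seed = 19))
    x <- prof$P_ge1
    suppressWarnings(cor(x[-1], x[-length(x)], method = "spearman"))
  }, numeric(1))
  expect_true(all(diff(cors) > 0))
})

test_that("classification thresholds behave at the extremes", {
  sim <- simulate_prf_site_counts(10, gamma = rep(0, 10), theta = 0,
                                  T_div = 1, n_chrom = 10, seed = 2)
  expect_true(all(sim$counts$D_s == 0))
  prof <- structure(list(
    posterior = tibble::as_tibble(cbind(tibble::tibble(codon = 1:3),
      tibble::as_tibble(matrix(c(rep(0, 15), rep(1, 3), rep(0, 18)), 3, 12,
        dimnames = list(NULL, paste0("g", gamma_grid())))))),
    P_ge1 = rep(0, 3), P_gt0 = rep(0, 3), codon = 1:3,
    grid = gamma_grid()), class = "selection_profile")
  expect_equal(nrow(classify_and_summarize(prof)$selected), 0L)
  expect_equal(nrow(classify_and_summarize(prof,
                                           threshold = 1.01)$selected), 0L)
})

test_that("posterior reduces to the prior in the no-data limit", {
  # all-zero counts with theta pinned tiny: every class explains the data
  # equally, so the class posterior is the (uniform) prior
  cnt <- tibble::tibble(codon = 1:5, D_s = 0L, D_n = 0L, P_s = 0L,
                        P_n = 0L, Z_n = 2.5, n = 20)
  pri <- prior_spec(log(1e-8), 0.1, log(1e-4), 0.1)
  prof <- run_gammamap_mcmc(cnt, pri, iterations = 4000, thin = 5,
                            chains = 1, seed = 3)
  post <- as.matrix(prof$posterior[, -1])
  expect_true(max(abs(post - 1 / 12)) < 0.05)
})
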