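# LRTs, Bayesian site detection, consensus, episodic test, fingerprinting.

make_sel_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      tree <- fixture_tree(8, 1.2)
      sim <- simulate_codon_alignment(
        tree, mixture_spec(c(0.85, 0.15), c(0.2, 5)), 150, kappa = 2,
        seed = 21)
      m0 <- maximize_likelihood(sim$aln, tree, "M0",
                                options = fit_opts_fast())
      cache <<- list(tree = tree, sim = sim, m0 = m0,
                     planted = sim$truth$codon[sim$truth$class == 2])
    }
    cache
  }
})

test_that("likelihood-ratio test clamps and rejects non-nested pairs", {
  f1 <- structure(list(model = "M1a", lnL = -100), class = "codon_fit")
  f2 <- structure(list(model = "M2a", lnL = -101), class = "codon_fit")
  r <- likelihood_ratio_test(f1, f2)
  expect_equal(r$two_delta_lnl, 0)
  expect_equal(r$p_value, 1)
  expect_equal(r$df, 2L)

  f2$lnL <- -92.85
  r2 <- likelihood_ratio_test(f1, f2)
  expect_equal(r2$two_delta_lnl, 14.3)
  expect_equal(r2$p_value, pchisq(14.3, 2, lower.tail = FALSE))

  f3 <- structure(list(model = "M7", lnL = -100), class = "codon_fit")
  expect_error(likelihood_ratio_test(f3, f2), "nested")
})

test_that("BEB flags planted selection and stays quiet on purifying data", {
  cx <- make_sel_sim()
  m8 <- maximize_likelihood(cx$sim$aln, cx$m0$tree, "M8",
                            options = fit_opts_fast(branch_mode = "fixed",
                                                    n_starts = 2))
  beb <- beb_posteriors(m8, cx$sim$aln)
  expect_true(all(beb$posterior >= 0 & beb$posterior <= 1))
  expect_identical(beb$flag, beb$posterior >= 0.90)
  expect_gt(mean(beb$flag[beb$codon %in% cx$planted]), 0.5)
  expect_lt(mean(beb$flag[!beb$codon %in% cx$planted]), 0.05)
  expect_error(beb_posteriors(cx$m0, cx$sim$aln), "M8 or M2a")

  pur <- simulate_codon_alignment(cx$tree, mixture_spec(1, 0.2), 120,
                                  kappa = 2, seed = 31)
  m0p <- maximize_likelihood(pur$aln, cx$tree, "M0",
                             options = fit_opts_fast())
  m8p <- maximize_likelihood(pur$aln, m0p$tree, "M8",
                             options = fit_opts_fast(branch_mode = "fixed"))
  bebp <- beb_posteriors(m8p, pur$aln)
  expect_lte(mean(bebp$flag), 0.01)
})

test_that("REL posteriors and Bayes factors behave", {
  cx <- make_sel_sim()
  rel <- rel_posteriors(cx$sim$aln, cx$tree, m0_fit = cx$m0)
  expect_true(all(rel$posterior >= 0 & rel$posterior <= 1))
  expect_gt(mean(rel$flag[rel$codon %in% cx$planted]), 0.5)
  expect_lt(mean(rel$flag[!rel$codon %in% cx$planted]), 0.05)

  # monomorphic alignment: no evidence, no flags
  mono <- codon_alignment(stats::setNames(
    rep(paste(rep("ATGGCTAAA", 4), collapse = ""), 4),
    paste0("t", 1:4)))
  tr <- fixture_tree(4, 0.5)
  suppressWarnings({
    relm <- rel_posteriors(mono, tr,
                           options = list(n_starts = 1, factr = 1e9))
  })
  expect_true(all(!relm$flag))
})

test_that("FUBAR posterior matches exact enumeration on a toy grid", {
  tree3 <- ape::read.tree(text = "(A:0.3,B:0.3,C:0.3);")
  sim5 <- simulate_codon_alignment(tree3, mixture_spec(1, 1), 5,
                                   kappa = 2, seed = 2)
  m0 <- maximize_likelihood(sim5$aln, tree3, "M0",
                            options = fit_opts_fast())
  fub <- fubar_posteriors(sim5$aln, tree3, grid_size = 2, rate_max = 2,
                          iterations = 8000, burnin = 1000, thin = 5,
                          chains = 2, seed = 13, m0_fit = m0)
  # exact posterior by product-rule quadrature over the Dirichlet(0.5)
  # prior (gamma-quantile representation handles the boundary singularity)
  vals <- (seq(0, 1, length.out = 2))^2 * 2
  lat <- expand.grid(alpha = vals, beta = vals)
  L <- codonsel:::ab_site_logliks(sim5$aln, m0$tree, lat$alpha, lat$beta,
                                  m0$freqs$pi, m0$kappa)
  Lm <- exp(L - apply(L, 1, max))
  qs <- qgamma((seq_len(14) - 0.5) / 14, 0.5, 1)
  gw <- as.matrix(expand.grid(qs, qs, qs, qs))
  W <- gw / rowSums(gw)
  lik <- exp(rowSums(log(W %*% t(Lm))))
  pw <- lik / sum(lik)
  pos <- lat$beta > lat$alpha
  exact <- vapply(1:5, function(s) {
    sum(pw * (W[, pos, drop = FALSE] %*% Lm[s, pos]) / (W %*% Lm[s, ]))
  }, numeric(1))
  expect_equal(fub$posterior, exact, tolerance = 0.03)
})

test_that("consensus set logic respects thresholds and coordinates", {
  mk <- function(method, flags) {
    codonsel:::new_site_posterior_table(1:5, method,
                                        posterior = as.numeric(flags),
                                        flag = flags, cutoff = 0.9)
  }
  t1 <- mk("BEB", c(TRUE, TRUE, FALSE, FALSE, TRUE))
  t2 <- mk("REL", c(TRUE, FALSE, TRUE, FALSE, TRUE))
  t3 <- mk("FUBAR", c(FALSE, FALSE, FALSE, FALSE, TRUE))
  rep3 <- consensus_sites(list(t1, t2, t3))
  expect_equal(rep3$consensus, c(1L, 5L))   # site 2 has one method only
  expect_equal(rep3$strict, 5L)
  expect_true(all(rep3$strict %in% rep3$consensus))

  # fewer tables than min_methods: consensus is empty
  expect_length(consensus_sites(list(t1), min_methods = 2)$consensus, 0)

  t4 <- mk("X", c(TRUE, FALSE, TRUE, FALSE, TRUE))
  t4$codon <- 2:6
  expect_error(consensus_sites(list(t1, t4)), "coordinates")
})

test_that("episodic-selection test keeps its nesting and null behaviour", {
  tree <- fixture_tree(6, 1.0)
  null_sim <- simulate_codon_alignment(
    tree, mixture_spec(c(0.7, 0.3), c(0.2, 1)), 100, kappa = 2, seed = 17)
  m0 <- maximize_likelihood(null_sim$aln, tree, "M0",
                            options = fit_opts_fast(branch_mode = "scale"))
  bt <- busted_test(null_sim$aln, tree, m0_fit = m0,
                    options = list(n_starts = 1, factr = 1e9))
  expect_lte(bt$lnl_constrained, bt$lnl_unconstrained + 1e-6)
  expect_gte(bt$p_value, 0)
  expect_lte(bt$p_value, 1)
  expect_true(all(diff(bt$classes$omega) >= -1e-8))
  # conservative option never gives a smaller p
  bt2 <- busted_test(null_sim$aln, tree, null_dist = "chisq2", m0_fit = m0,
                     options = list(n_starts = 1, factr = 1e9))
  expect_gte(bt2$p_value, bt$p_value - 1e-12)
})

test_that("fingerprinting recovers a 2-class structure and normalises", {
  tree <- fixture_tree(8, 1.2)
  hits <- 0
  for (r in 1:4) {
    sim <- simulate_codon_alignment(
      tree, mixture_spec(c(0.7, 0.3), c(0.05, 2.5)), 200, kappa = 2,
      seed = 40 + r)
    m0 <- maximize_likelihood(sim$aln, tree, "M0",
                              options = fit_opts_fast(branch_mode = "scale"))
    fp <- evolutionary_fingerprint(sim$aln, tree, k_max = 3, m0_fit = m0,
                                   options = list(n_starts = 1))
    expect_equal(sum(fp$classes$weight), 1, tolerance = 1e-6)
    expect_equal(fp$classes$dnds, fp$classes$beta / fp$classes$alpha)
    if (fp$k == 2) hits <- hits + 1
  }
  expect_gte(hits, 3)
})
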