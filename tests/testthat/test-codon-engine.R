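# Rate matrices, beta discretisation, pruning likelihoods, ML fitting.

test_that("rate matrix follows the GY94 construction", {
  pi <- rep(1 / 61, 61)
  rm <- build_codon_rate_matrix(kappa = 3, omega = 0.5, pi)
  code <- genetic_code()
  i <- match("TTT", code$sense)
  # TTT -> TTC synonymous transition; TTT -> TTA nonsynonymous transversion
  expect_equal(rm$Q[i, match("TTC", code$sense)] /
                 rm$Q[i, match("TTA", code$sense)], 3 / 0.5)
  # multi-nucleotide changes are forbidden
  expect_equal(rm$Q[i, match("AAA", code$sense)], 0)
  expect_equal(max(abs(rowSums(rm$Q))), 0, tolerance = 1e-12)
  # detailed balance and unit stationary rate
  expect_equal(max(abs(pi * rm$Q - t(pi * rm$Q))), 0, tolerance = 1e-14)
  expect_equal(-sum(pi * diag(rm$Q)), 1, tolerance = 1e-12)

  # with omega = kappa = 1 and equal pi, all allowed rates are equal
  rm1 <- build_codon_rate_matrix(1, 1, pi, normalize = FALSE)
  off <- rm1$Q[codonsel:::codon_pairs()$single]
  expect_equal(length(unique(round(off, 14))), 1L)
  expect_error(build_codon_rate_matrix(-1, 0.5, pi))
})

test_that("transition probabilities are stochastic and exp(Q*0) = I", {
  pi <- estimate_codon_frequencies(random_codon_aln(3, 50, seed = 5),
                                   "F61")$pi
  rm <- build_codon_rate_matrix(2, 0.3, pi)
  expect_equal(transition_probabilities(rm, 0), diag(61), tolerance = 1e-10)
  set.seed(6)
  for (t in runif(4, 0, 5)) {
    P <- transition_probabilities(rm, t)
    expect_true(all(P >= 0))
    expect_equal(rowSums(P), rep(1, 61), tolerance = 1e-10)
  }
})

test_that("beta discretisation matches closed forms and quadrature", {
  m <- discretize_beta(1, 1, 10)
  expect_equal(m$omega, seq(0.05, 0.95, by = 0.1), tolerance = 1e-12)
  expect_equal(m$weights, rep(0.1, 10))

  m2 <- discretize_beta(2, 5, 10)
  edges <- qbeta((0:10) / 10, 2, 5)
  oracle <- vapply(1:10, function(i) {
    stats::integrate(function(x) x * dbeta(x, 2, 5), edges[i],
                     edges[i + 1], rel.tol = 1e-10)$value * 10
  }, numeric(1))
  expect_equal(m2$omega, oracle, tolerance = 1e-6)
  expect_equal(sum(m2$weights * m2$omega), 2 / 7, tolerance = 1e-8)
  expect_error(discretize_beta(-1, 2))
})

test_that("pruning equals exhaustive enumeration on 3-taxon toys", {
  tree <- toy_tree3()
  aln <- codon_alignment(c(A = "ATGGCT", B = "ATAGCC", C = "ATGGAT"))
  pi <- rep(1 / 61, 61)
  mix <- mixture_spec(c(0.6, 0.4), c(0.2, 2))
  got <- mixture_site_likelihoods(aln, tree, mix, pi, kappa = 2)
  want <- brute_force_mixture_lik(aln, tree, mix, pi, kappa = 2)
  expect_equal(exp(got$site_loglik), want, tolerance = 1e-12)
})

test_that("degenerate and convexity identities hold", {
  tree <- toy_tree3()
  tree$edge.length[] <- 0
  aln <- codon_alignment(c(A = "ATG", B = "ATG", C = "ATG"))
  pi <- rep(1 / 61, 61)
  out <- mixture_site_likelihoods(aln, tree, mixture_spec(1, 0.5), pi, 2)
  expect_equal(exp(out$site_loglik), 1 / 61, tolerance = 1e-12)

  # mixture of two identical classes equals the single class
  tree <- toy_tree3()
  aln2 <- random_codon_aln(3, 20, seed = 7)
  names(aln2$taxa) <- NULL
  aln2$taxa <- c("A", "B", "C")
  rownames(aln2$states) <- aln2$taxa
  one <- mixture_site_likelihoods(aln2, tree, mixture_spec(1, 0.7), pi, 2)
  two <- mixture_site_likelihoods(aln2, tree,
                                  mixture_spec(c(0.3, 0.7), c(0.7, 0.7)),
                                  pi, 2)
  expect_equal(one$site_loglik, two$site_loglik, tolerance = 1e-10)
})

test_that("likelihood is invariant to taxon order and root placement", {
  unrooted <- ape::read.tree(text = "(A:0.1,B:0.2,(C:0.15,D:0.25):0.1);")
  rooted <- ape::read.tree(
    text = "((A:0.1,B:0.2):0.05,(C:0.15,D:0.25):0.05);")
  aln <- random_codon_aln(4, 30, seed = 8)
  aln$taxa <- c("A", "B", "C", "D")
  rownames(aln$states) <- aln$taxa
  pi <- estimate_codon_frequencies(aln, "F3X4")$pi
  mix <- mixture_spec(c(0.5, 0.5), c(0.1, 1.5))
  l1 <- sum(mixture_site_likelihoods(aln, unrooted, mix, pi, 2)$site_loglik)
  l2 <- sum(mixture_site_likelihoods(aln, rooted, mix, pi, 2)$site_loglik)
  expect_equal(l1, l2, tolerance = 1e-8)

  perm <- aln
  ord <- c(3, 1, 4, 2)
  perm$taxa <- aln$taxa[ord]
  perm$states <- aln$states[ord, ]
  l3 <- sum(mixture_site_likelihoods(perm, unrooted, mix, pi, 2)$site_loglik)
  expect_equal(l1, l3, tolerance = 1e-10)
})

test_that("M0 fitting recovers simulation truth and is a fixed point", {
  tree <- fixture_tree(8, 1.0)
  sim <- simulate_codon_alignment(tree, mixture_spec(1, 0.4), 150,
                                  kappa = 2, seed = 42)
  fit <- maximize_likelihood(sim$aln, tree, "M0", options = fit_opts_fast())
  expect_gt(fit$est$omega, 0.25)
  expect_lt(fit$est$omega, 0.6)
  expect_gt(fit$kappa, 1.2)
  expect_lt(fit$kappa, 3.5)

  # refitting from the returned optimum does not move the likelihood
  refit <- maximize_likelihood(sim$aln, fit$tree, "M0",
                               options = fit_opts_fast(branch_mode = "fixed"))
  expect_gte(refit$lnL + 1e-6, fit$lnL - 2e-4)
})

test_that("nested site models satisfy the likelihood inequalities", {
  tree <- fixture_tree(6, 1.0)
  sim <- simulate_codon_alignment(tree, mixture_spec(c(0.8, 0.2), c(0.2, 1)),
                                  100, kappa = 2, seed = 9)
  m0 <- maximize_likelihood(sim$aln, tree, "M0",
                            options = fit_opts_fast(branch_mode = "scale"))
  opts <- fit_opts_fast(branch_mode = "fixed", n_starts = 2)
  f1 <- maximize_likelihood(sim$aln, m0$tree, "M1a", options = opts)
  f2 <- maximize_likelihood(sim$aln, m0$tree, "M2a",
                            options = c(opts, list(warm_start = f1)))
  f7 <- maximize_likelihood(sim$aln, m0$tree, "M7", options = opts)
  f8 <- maximize_likelihood(sim$aln, m0$tree, "M8",
                            options = c(opts, list(warm_start = f7)))
  expect_gte(f2$lnL, f1$lnL - 1e-6)
  expect_gte(f8$lnL, f7$lnL - 1e-6)
  # weights stay on the simplex
  for (f in list(f1, f2, f7, f8)) {
    expect_equal(sum(f$mix$weights), 1, tolerance = 1e-8)
  }
})
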