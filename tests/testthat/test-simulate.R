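# Generators: determinism, degenerate limits, and distributional checks
# against their own model.

test_that("fixture trees have the declared shape and depth", {
  t2 <- fixture_tree(2, 1)
  expect_equal(ape::Ntip(t2), 2L)
  t8 <- fixture_tree(8, 0.9)
  depths <- ape::node.depth.edgelength(t8)[1:8]
  expect_equal(depths, rep(0.9, 8), tolerance = 1e-12)
  tl <- fixture_tree(5, 1, shape = "ladder")
  expect_equal(ape::Ntip(tl), 5L)
  expect_error(fixture_tree(1, 1))

  f <- withr::local_tempfile(fileext = ".nwk")
  write_newick(t8, f)
  expect_equal(sum(read_newick(f)$edge.length), sum(t8$edge.length),
               tolerance = 1e-8)
})

test_that("alignment simulation honours seeds and degenerate limits", {
  tree <- fixture_tree(4, 1)
  s1 <- simulate_codon_alignment(tree, mixture_spec(1, 0.5), 30, seed = 3)
  s2 <- simulate_codon_alignment(tree, mixture_spec(1, 0.5), 30, seed = 3)
  expect_identical(s1$aln$states, s2$aln$states)
  expect_tbl_cols(s1$truth, c("codon", "class", "omega"))

  tree0 <- tree
  tree0$edge.length[] <- 0
  s0 <- simulate_codon_alignment(tree0, mixture_spec(1, 0.5), 40, seed = 4)
  expect_true(all(apply(s0$aln$states, 2, function(col)
    length(unique(col)) == 1)))
  expect_error(simulate_codon_alignment(tree, mixture_spec(1, 0.5), 10),
               "seed")
})

test_that("tip states reach the stationary distribution on long branches", {
  tree <- ape::read.tree(text = "(A:40,B:40);")
  sim <- simulate_codon_alignment(tree, mixture_spec(1, 1), 5000,
                                  kappa = 2, seed = 11)
  obs <- tabulate(sim$aln$states, nbins = 61)
  p <- suppressWarnings(chisq.test(obs, p = rep(1 / 61, 61))$p.value)
  expect_gt(p, 0.01)
})

test_that("counting-based dN/dS on an M0 simulation tracks the input omega", {
  tree <- fixture_tree(8, 1.0)
  sim <- simulate_codon_alignment(tree, mixture_spec(1, 0.4), 300,
                                  kappa = 2, seed = 42)
  res <- slac_analysis(sim$aln, tree, bootstrap_reps = 100, seed = 1,
                       options = fit_opts_fast())
  expect_lt(abs(res$dnds - 0.4) / 0.4, 0.25)
})

test_that("PRF count generator matches its own mean structure", {
  expect_true(all(unlist(
    simulate_prf_site_counts(20, gamma = rep(0, 20), theta = 0, T_div = 1,
                             n_chrom = 10, seed = 1)$counts[, 2:5]) == 0))

  big <- simulate_prf_site_counts(10000, gamma = rep(0, 10000),
                                  theta = 0.04, T_div = 2, n_chrom = 20,
                                  seed = 2)
  m <- mean(big$counts$D_s)
  mu <- 0.04 / 2 * 2
  expect_lt(abs(m - mu), 3 * sqrt(mu / 10000))

  # gamma = 50 inflates fixed nonsynonymous differences by ~h(50)
  sel <- simulate_prf_site_counts(10000, gamma = rep(50, 10000),
                                  theta = 0.04, T_div = 2, n_chrom = 20,
                                  seed = 3)
  ratio <- mean(sel$counts$D_n) / mean(big$counts$D_n)
  expect_lt(abs(ratio - prf_fixation_factor(50)) /
              prf_fixation_factor(50), 0.1)

  expect_error(simulate_prf_site_counts(5, gamma = rep(7, 5), seed = 1),
               "off the 12-class grid")
})

test_that("expression generator respects trend, noise and seed", {
  s0 <- simulate_expression(n = c(h = 20), trend = "late_rise",
                            amplitude = 2, noise_sd = 0, seed = 5)
  x <- log2(s0$age_years + 0.75)
  expect_equal(s0$expression, 2 * pmax(x - median(x), 0), tolerance = 1e-12)

  s1 <- simulate_expression(seed = 6)
  s2 <- simulate_expression(seed = 6)
  expect_identical(s1, s2)

  sn <- simulate_expression(n = c(h = 1000), trend = "flat",
                            noise_sd = 0.4, seed = 7)
  expect_lt(abs(sd(sn$expression) - 0.4), 0.03)
  expect_error(simulate_expression(noise_sd = -1, seed = 1))
})

test_that("PRF generator and likelihood agree at the truth", {
  # average log-likelihood at the generating parameters beats perturbed ones
  sim <- simulate_prf_site_counts(400, gamma = rep(5, 400), theta = 0.05,
                                  T_div = 2, n_chrom = 20, seed = 9)
  ll_true <- gamma_site_loglik(sim$counts, 5, 0.05, 2)
  expect_gt(ll_true, gamma_site_loglik(sim$counts, -5, 0.05, 2))
  expect_gt(ll_true, gamma_site_loglik(sim$counts, 5, 0.15, 2))
  expect_gt(ll_true, gamma_site_loglik(sim$counts, 5, 0.05, 6))
})
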