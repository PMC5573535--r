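# Counting-based dN/dS: opportunity enumeration, ancestral reconstruction,
# substitution tallies, bootstrap interval.

test_that("mutational opportunity splits 3 sites per codon with stops excluded", {
  opp <- codon_opportunity()
  expect_equal(opp$ES + opp$EN, rep(3, 61), tolerance = 1e-12)
  # TTT: one synonymous (TTC) of nine sense neighbors
  ttt <- opp[opp$codon == "TTT", ]
  expect_equal(ttt$ES, 1 / 3)
  expect_equal(ttt$EN, 8 / 3)
  expect_equal(ttt$n_sense_neighbors, 9)
  # ATG has no synonymous neighbor
  expect_equal(opp$ES[opp$codon == "ATG"], 0)
})

test_that("joint reconstruction matches exhaustive argmax on a 3-taxon toy", {
  tree <- toy_tree3()
  aln <- codon_alignment(c(A = "ATGAAA", B = "ATGAAG", C = "ATAAAA"))
  m0 <- maximize_likelihood(aln, tree, "M0",
                            options = fit_opts_fast(branch_mode = "fixed"))
  anc <- reconstruct_ancestors(aln, tree, m0)
  # brute force over the single internal node
  rates <- build_codon_rate_matrix(m0$kappa, m0$est$omega, m0$freqs$pi)
  po <- anc$tree
  root <- po$edge[nrow(po$edge), 1]
  for (s in 1:2) {
    score <- vapply(1:61, function(r) {
      pr <- log(m0$freqs$pi[r])
      for (e in seq_len(nrow(po$edge))) {
        ch <- po$edge[e, 2]
        P <- transition_probabilities(rates, po$edge.length[e])
        st <- aln$states[match(po$tip.label[ch], aln$taxa), s]
        pr <- pr + log(P[r, st])
      }
      pr
    }, numeric(1))
    expect_equal(anc$states[root, s], which.max(score))
  }
  # identical leaves force the shared codon everywhere
  same <- codon_alignment(c(A = "ATG", B = "ATG", C = "ATG"))
  anc2 <- reconstruct_ancestors(same, tree, m0)
  expect_true(all(anc2$states == match("ATG", genetic_code()$sense)))
})

test_that("substitution counts follow single paths and identity cases", {
  tree <- toy_tree3()
  m0 <- maximize_likelihood(
    codon_alignment(c(A = "TTT", B = "TTC", C = "TTT")), tree, "M0",
    options = fit_opts_fast(branch_mode = "fixed"))
  # no substitutions anywhere
  same <- codon_alignment(c(A = "ATGGCT", B = "ATGGCT", C = "ATGGCT"))
  cnt0 <- slac_counts(same, anc = reconstruct_ancestors(same, tree, m0))
  expect_true(all(cnt0$OS == 0) && all(cnt0$ON == 0))

  # a single synonymous change TTT -> TTC on one branch
  one <- codon_alignment(c(A = "TTT", B = "TTC", C = "TTT"))
  cnt1 <- slac_counts(one, anc = reconstruct_ancestors(one, tree, m0))
  expect_equal(cnt1$OS, 1)
  expect_equal(cnt1$ON, 0)

  # multi-step change averages over minimal stop-free paths
  pc <- codonsel:::path_counts(match("TTT", genetic_code()$sense),
                               match("TTA", genetic_code()$sense))
  expect_equal(sum(pc), 1)
})

test_that("global ratio is invariant to codon order and taxon relabeling", {
  tree <- fixture_tree(6, 1.0)
  sim <- simulate_codon_alignment(tree, mixture_spec(1, 0.5), 120,
                                  kappa = 2, seed = 12)
  m0 <- maximize_likelihood(sim$aln, tree, "M0",
                            options = fit_opts_fast(branch_mode = "scale"))
  anc <- reconstruct_ancestors(sim$aln, m0$tree, m0)
  cnt <- slac_counts(sim$aln, anc = anc)
  res <- slac_dnds(cnt, bootstrap_reps = 200, seed = 5)

  perm <- sample(nrow(cnt))
  res2 <- slac_dnds(cnt[perm, ], bootstrap_reps = 200, seed = 5)
  expect_equal(res$dnds, res2$dnds, tolerance = 1e-12)

  expect_true(res$ci[1] <= res$dnds && res$dnds <= res$ci[2])
  expect_true(all(!is.na(res$sites$p_value[cnt$OS + cnt$ON > 0])))
})

test_that("undefined ratios raise explicit errors", {
  cnt <- tibble::tibble(codon = 1:3, ES = 1, EN = 2, OS = 0, ON = c(1, 0, 2))
  expect_error(slac_dnds(cnt, seed = 1), "undefined")
})

test_that("counting estimate tracks the simulated omega", {
  tree <- fixture_tree(8, 1.0)
  sim <- simulate_codon_alignment(tree, mixture_spec(1, 0.4), 250,
                                  kappa = 2, seed = 77)
  res <- slac_analysis(sim$aln, tree, bootstrap_reps = 200, seed = 3,
                       options = fit_opts_fast())
  expect_gt(res$dnds, 0.3)
  expect_lt(res$dnds, 0.5)
})
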