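# Shared fixture builders and independent oracles. Everything is generated
# in code; no stored data.

toy_tree3 <- function() ape::read.tree(text = "(A:0.2,B:0.35,C:0.5);")

random_codon_aln <- function(n_taxa, n_codons, seed) {
  set.seed(seed)
  code <- genetic_code()
  seqs <- vapply(seq_len(n_taxa), function(i) {
    paste(sample(code$sense, n_codons, replace = TRUE), collapse = "")
  }, character(1))
  names(seqs) <- paste0("t", seq_len(n_taxa))
  codon_alignment(seqs)
}

# Independent pruning oracle for a 3-taxon star tree: exhaustive summation
# over the internal (root) state. The transition matrices come either from
# Matrix::expm (fully independent matrix exponential, itself accurate to
# ~1e-12) or from a plain R reversible-eigen formula (so the summation
# structure can be compared at machine precision).
brute_force_mixture_lik <- function(aln, tree, mix, pi, kappa,
                                    p_method = c("expm", "eigen")) {
  p_method <- match.arg(p_method)
  P_of <- function(Q, t) {
    if (p_method == "expm") return(as.matrix(Matrix::expm(Q * t)))
    sp <- sqrt(pi)
    B <- Q * (sp %o% (1 / sp))
    B <- (B + t(B)) / 2
    e <- eigen(B, symmetric = TRUE)
    (e$vectors / sp) %*% (exp(e$values * t) * t(e$vectors * sp))
  }
  parts <- codonsel:::codon_q_parts(kappa, pi)
  S <- sum(mix$weights * (parts$rA + mix$omega * parts$rB))
  tips <- tree$tip.label
  lens <- tree$edge.length[match(match(tips, tree$tip.label),
                                 tree$edge[, 2])]
  vapply(seq_len(aln$n_codons), function(s) {
    tot <- 0
    for (k in seq_along(mix$omega)) {
      Q <- (parts$A + mix$omega[k] * parts$B) / S
      diag(Q) <- -rowSums(Q)
      Ps <- lapply(lens, function(t) P_of(Q, t))
      st <- aln$states[match(tips, aln$taxa), s]
      contrib <- sum(vapply(1:61, function(r) {
        pr <- pi[r]
        for (j in seq_along(st)) {
          pr <- pr * if (is.na(st[j])) 1 else Ps[[j]][r, st[j]]
        }
        pr
      }, numeric(1)))
      tot <- tot + mix$weights[k] * contrib
    }
    tot
  }, numeric(1))
}

fit_opts_fast <- function(...) {
  utils::modifyList(list(n_starts = 1, factr = 1e9), list(...))
}

expect_tbl_cols <- function(tb, cols) {
  expect_true(all(cols %in% names(tb)),
              info = paste("missing:", paste(setdiff(cols, names(tb)),
                                             collapse = ", ")))
}
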