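# Alignment/tree I/O, masking, and codon frequency schemes.

test_that("codon FASTA parsing validates frame, stops and names", {
  f <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">A", "ATGGCT", ">B", "ATAGCC"), f)
  aln <- read_codon_fasta(f)
  expect_equal(length(aln$taxa), 2L)
  expect_equal(aln$n_codons, 2L)

  writeLines(c(">A", "ATGGCTA", ">B", "ATAGCCA"), f)
  expect_error(read_codon_fasta(f), "divisible by 3.*A")

  writeLines(c(">A", "ATGTAAGGG", ">B", "ATGAAAGGG"), f)
  expect_error(read_codon_fasta(f), "stop codon in taxon A at codon 2")

  expect_error(codon_alignment(c(A = "ATG", A = "ATG")), "duplicate")
  # gaps and ambiguity become missing data, not errors
  aln2 <- codon_alignment(c(A = "ATG---", B = "ATGNNN"))
  expect_true(all(is.na(aln2$states[, 2])))
})

test_that("newick reading accepts rooted and unrooted trees and checks pairing", {
  f <- withr::local_tempfile(fileext = ".nwk")
  writeLines("(A:0.1,B:0.2);", f)
  tr <- read_newick(f)
  expect_equal(sort(tr$tip.label), c("A", "B"))
  expect_equal(sort(tr$edge.length), c(0.1, 0.2))

  writeLines("(A:1,B:1,C:1);", f)
  expect_equal(ape::Ntip(read_newick(f)), 3L)

  writeLines("(A:0.1,B:-0.2);", f)
  expect_error(read_newick(f), "negative")

  aln <- codon_alignment(c(A = "ATG", B = "ATG", C = "ATG"))
  tr2 <- ape::read.tree(text = "(A:1,B:1,D:1);")
  expect_error(codonsel:::check_taxa(aln, tr2), "D")
})

test_that("masking removes codons but preserves unmasked-gene coordinates", {
  aln <- random_codon_aln(4, 1000, seed = 1)
  masked <- mask_codon_range(aln, list(c(101, 180)))  # 80 codons = 240 bp
  expect_equal(masked$n_codons, 920L)
  expect_false(any(masked$site_index %in% 101:180))
  expect_equal(masked$site_index[100:101], c(100L, 181L))

  expect_identical(mask_codon_range(aln, list()), aln)
  expect_error(mask_codon_range(aln, list(c(1, 1000))), "every codon")
  expect_error(mask_codon_range(aln, list(c(0, 5))), "out of bounds")
  expect_error(mask_codon_range(aln, list(c(990, 1100))), "out of bounds")
})

test_that("masking equals building the alignment without those columns", {
  aln <- random_codon_aln(5, 60, seed = 2)
  masked <- mask_codon_range(aln, list(c(11, 20), c(41, 45)))
  keep <- setdiff(1:60, c(11:20, 41:45))
  code <- genetic_code()
  seqs <- vapply(seq_along(aln$taxa), function(i) {
    paste(code$sense[aln$states[i, keep]], collapse = "")
  }, character(1))
  names(seqs) <- aln$taxa
  direct <- codon_alignment(seqs)
  expect_identical(masked$states, direct$states)
  for (scheme in c("equal", "F3X4", "F61")) {
    expect_identical(estimate_codon_frequencies(masked, scheme)$pi,
                     estimate_codon_frequencies(direct, scheme)$pi)
  }
})

test_that("codon frequency schemes are normalised and match hand counts", {
  aln <- random_codon_aln(3, 40, seed = 3)
  for (scheme in c("equal", "F3X4", "F61")) {
    pi <- estimate_codon_frequencies(aln, scheme)$pi
    expect_equal(sum(pi), 1, tolerance = 1e-12)
    expect_true(all(pi > 0))
  }
  expect_equal(unname(estimate_codon_frequencies(aln, "equal")$pi),
               rep(1 / 61, 61))

  # F61 oracle: manual codon tally with the 0.5 pseudocount
  small <- codon_alignment(c(A = "ATGATGGCTAAAGCTATGGCTAAAGCTGCT"))
  counts <- table(factor(
    c("ATG", "ATG", "GCT", "AAA", "GCT", "ATG", "GCT", "AAA", "GCT", "GCT"),
    levels = genetic_code()$sense))
  manual <- (as.numeric(counts) + 0.5) / sum(as.numeric(counts) + 0.5)
  expect_equal(unname(estimate_codon_frequencies(small, "F61")$pi), manual)

  expect_error(estimate_codon_frequencies(
    codon_alignment(c(A = "---")), "F61"), "empty")
})

test_that("F3X4 with uniform nucleotide composition gives 1/61 after stop renormalisation", {
  # each codon position sees each base equally often
  aln <- codon_alignment(c(A = "AAACCCGGGTTT"))
  pi <- estimate_codon_frequencies(aln, "F3X4")$pi
  expect_equal(unname(pi), rep(1 / 61, 61), tolerance = 1e-12)
})

test_that("FASTA and newick round-trips preserve content", {
  aln <- random_codon_aln(4, 25, seed = 4)
  aln$states[2, 5] <- NA  # a missing codon survives as ---
  f <- withr::local_tempfile(fileext = ".fa")
  write_codon_fasta(aln, f)
  back <- read_codon_fasta(f)
  expect_identical(back$taxa, aln$taxa)
  expect_identical(back$states, aln$states)

  tr <- fixture_tree(6, 0.8)
  nf <- withr::local_tempfile(fileext = ".nwk")
  write_newick(tr, nf)
  tr2 <- read_newick(nf)
  expect_equal(sort(tr2$tip.label), sort(tr$tip.label))
  expect_equal(sum(tr2$edge.length), sum(tr$edge.length), tolerance = 1e-8)
})
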