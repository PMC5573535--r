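#' Construct a codon alignment from character sequences
#'
#' Validates frame (length divisible by 3), equal lengths, unique taxon
#' names, and the absence of internal stop codons, then stores each codon
#' column as an index into the 61 sense codons. Codons containing a gap or
#' ambiguity character in a taxon are kept as missing data for that taxon
#' (the likelihood sums over all 61 states there) rather than dropping the
#' column.
#'
#' @param seqs Named character vector of aligned in-frame nucleotide
#'   sequences (or a list of per-taxon character vectors of single bases).
#' @param code A [genetic_code()].
#' @return An object of class `codon_aln` with fields `taxa`, `states`
#'   (taxa x codons integer matrix, `NA` = missing), `site_index` (1-based
#'   codon numbering in the original, unmasked gene), `n_codons`, `code_id`.
#' @export
codon_alignment <- function(seqs, code = genetic_code()) {
  if (is.list(seqs)) {
    seqs <- vapply(seqs, function(x) paste(x, collapse = ""), character(1))
  }
  taxa <- names(seqs)
  if (is.null(taxa) || any(!nzchar(taxa))) {
    stop("sequences must be named by taxon", call. = FALSE)
  }
  if (anyDuplicated(taxa)) {
    stop("duplicate taxon names: ",
         paste(unique(taxa[duplicated(taxa)]), collapse = ", "), call. = FALSE)
  }
  seqs <- toupper(gsub("U", "T", toupper(seqs)))
  len <- nchar(seqs)
  if (length(unique(len)) != 1L) {
    stop("sequences are not aligned (unequal lengths)", call. = FALSE)
  }
  if (len[1] %% 3L != 0L) {
    bad <- taxa[which(len %% 3L != 0L)[1]]
    stop("sequence length not divisible by 3 for taxon ", bad, call. = FALSE)
  }
  n_codons <- unname(len[1]) %/% 3L
  states <- matrix(NA_integer_, length(taxa), n_codons,
                   dimnames = list(taxa, NULL))
  for (i in seq_along(taxa)) {
    cds <- substring(seqs[i], 3L * seq_len(n_codons) - 2L,
                     3L * seq_len(n_codons))
    clean <- grepl("^[ACGT]{3}$", cds)
    idx <- rep(NA_integer_, n_codons)
    idx[clean] <- match(cds[clean], code$sense)
    is_stop <- clean & cds %in% code$stop
    if (any(is_stop)) {
      stop("internal stop codon in taxon ", taxa[i], " at codon ",
           which(is_stop)[1], call. = FALSE)
    }
    states[i, ] <- idx
  }
  structure(
    list(taxa = taxa, states = states, site_index = seq_len(n_codons),
         n_codons = n_codons, code_id = code$code_id),
    class = "codon_aln"
  )
}

#' @export
print.codon_aln <- function(x, ...) {
  cat("<codon_aln> ", length(x$taxa), " taxa x ", x$n_codons, " codons (",
      sum(is.na(x$states)), " missing cells)\n", sep = "")
  invisible(x)
}

#' Read an aligned, in-frame codon FASTA file
#'
#' @param path Path to an aligned FASTA file.
#' @inheritParams codon_alignment
#' @return A `codon_aln`; see [codon_alignment()] for the validation rules.
#' @export
read_codon_fasta <- function(path, code = genetic_code()) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  dna <- ape::read.FASTA(path)
  seqs <- vapply(as.character(dna), function(x) paste(x, collapse = ""),
                 character(1))
  codon_alignment(seqs, code = code)
}

#' Write a codon alignment to FASTA
#'
#' Missing codons are written as `---`.
#' @param aln A `codon_aln`.
#' @param path Output path.
#' @export
write_codon_fasta <- function(aln, path) {
  code <- genetic_code()
  lines <- character(0)
  for (i in seq_along(aln$taxa)) {
    cds <- ifelse(is.na(aln$states[i, ]), "---", code$sense[aln$states[i, ]])
    lines <- c(lines, paste0(">", aln$taxa[i]), paste(cds, collapse = ""))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a phylogeny in newick format
#'
#' Branch lengths are in expected substitutions per codon. Rooted and
#' unrooted trees are both accepted.
#'
#' @param path Path to a newick file.
#' @return An [ape::read.tree()] `phylo` object, validated to carry
#'   non-negative branch lengths.
#' @export
read_newick <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tree <- tryCatch(ape::read.tree(path),
                   error = function(e) stop("malformed newick: ",
                                            conditionMessage(e), call. = FALSE))
  if (is.null(tree)) stop("malformed newick in ", path, call. = FALSE)
  validate_tree(tree)
}

validate_tree <- function(tree) {
  if (!inherits(tree, "phylo")) stop("not a phylo object", call. = FALSE)
  if (is.null(tree$edge.length)) {
    stop("tree has no branch lengths", call. = FALSE)
  }
  if (any(tree$edge.length < 0)) {
    stop("negative branch length in tree", call. = FALSE)
  }
  tree
}

#' @rdname read_newick
#' @param tree A `phylo` object.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

# Leaf set must equal alignment taxa when a tree and alignment are paired.
check_taxa <- function(aln, tree) {
  extra <- setdiff(tree$tip.label, aln$taxa)
  missing <- setdiff(aln$taxa, tree$tip.label)
  if (length(extra) || length(missing)) {
    stop("tree/alignment taxa mismatch: ",
         if (length(extra)) paste0("tree-only: ",
                                   paste(extra, collapse = ", ")) else "",
         if (length(extra) && length(missing)) "; " else "",
         if (length(missing)) paste0("alignment-only: ",
                                     paste(missing, collapse = ", ")) else "",
         call. = FALSE)
  }
  invisible(TRUE)
}

#' Mask codon intervals out of an alignment
#'
#' Masked columns are removed from all downstream computation, but reported
#' codon coordinates keep the original (unmasked-gene, 1-based, closed
#' interval) numbering through the `site_index` map.
#'
#' @param aln A `codon_aln`.
#' @param intervals A list of `c(start, end)` pairs (or a two-column matrix),
#'   1-based closed codon intervals in unmasked-gene coordinates.
#' @return The masked `codon_aln`.
#' @export
mask_codon_range <- function(aln, intervals) {
  if (is.matrix(intervals)) {
    intervals <- split(intervals, row(intervals)[, 1])
  }
  if (length(intervals) == 0L) return(aln)
  n_orig <- max(aln$site_index)
  drop <- logical(aln$n_codons)
  for (iv in intervals) {
    if (length(iv) != 2L || iv[1] > iv[2] || iv[1] < 1 || iv[2] > n_orig) {
      stop("mask interval out of bounds: [", iv[1], ", ", iv[2], "]",
           call. = FALSE)
    }
    drop <- drop | (aln$site_index >= iv[1] & aln$site_index <= iv[2])
  }
  if (all(drop)) stop("mask removes every codon", call. = FALSE)
  aln$states <- aln$states[, !drop, drop = FALSE]
  aln$site_index <- aln$site_index[!drop]
  aln$n_codons <- sum(!drop)
  aln
}

#' Estimate equilibrium codon frequencies
#'
#' @param aln A `codon_aln`.
#' @param scheme `"equal"` (1/61 for every sense codon), `"F3X4"` (product of
#'   position-specific nucleotide frequencies, renormalised over the 61 sense
#'   codons), or `"F61"` (empirical sense-codon counts with a 0.5 pseudocount
#'   per codon, renormalised).
#' @return A `codon_freqs` object: `scheme` plus `pi`, 61 weights summing
#'   to 1.
#' @export
estimate_codon_frequencies <- function(aln,
                                       scheme = c("F3X4", "F61", "equal")) {
  scheme <- match.arg(scheme)
  code <- genetic_code()
  n_sense <- length(code$sense)
  if (aln$n_codons == 0L || all(is.na(aln$states))) {
    stop("empty alignment", call. = FALSE)
  }
  pi <- switch(scheme,
    equal = rep(1 / n_sense, n_sense),
    F61 = {
      counts <- tabulate(aln$states[!is.na(aln$states)], nbins = n_sense)
      w <- counts + 0.5
      w / sum(w)
    },
    F3X4 = {
      obs <- code$sense[aln$states[!is.na(aln$states)]]
      ntmat <- do.call(rbind, strsplit(obs, ""))
      nts <- c("A", "C", "G", "T")
      posfreq <- vapply(1:3, function(p) {
        # 0.5 pseudocount per base keeps every sense codon at positive
        # weight (a zero frequency breaks reversibility scaling)
        tab <- table(factor(ntmat[, p], levels = nts)) + 0.5
        as.numeric(tab) / sum(tab)
      }, numeric(4))  # 4 x 3
      sense_nt <- do.call(rbind, strsplit(code$sense, ""))
      w <- posfreq[match(sense_nt[, 1], nts), 1] *
        posfreq[match(sense_nt[, 2], nts), 2] *
        posfreq[match(sense_nt[, 3], nts), 3]
      w / sum(w)
    }
  )
  names(pi) <- code$sense
  structure(list(scheme = scheme, pi = pi), class = "codon_freqs")
}

#' @export
print.codon_freqs <- function(x, ...) {
  cat("<codon_freqs>", x$scheme, "| 61 weights, sum =",
      format(sum(x$pi), digits = 15), "\n")
  invisible(x)
}

#' Dump codon frequencies as a tibble
#' @param freqs A `codon_freqs`.
#' @return A tibble with columns `codon`, `weight`.
#' @export
codon_frequency_table <- function(freqs) {
  tibble::tibble(codon = names(freqs$pi), weight = unname(freqs$pi))
}
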