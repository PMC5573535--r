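#' The standard genetic code over the 61 sense codons
#'
#' Builds the codon-to-amino-acid map used throughout the package. Codons are
#' indexed 1..61 in alphabetical (A < C < G < T) order of the sense codons;
#' this ordering also defines the deterministic tie-break used by the joint
#' ancestral reconstruction ("lowest codon index").
#'
#' @param code_id Identifier of the code table. Only `"standard"` is
#'   supported; the standard code has exactly 61 sense codons, and all rate
#'   and opportunity computations exclude the three stop codons.
#' @return An object of class `genetic_code`: a list with `code_id`, `codons`
#'   (the 64 triplets), `aa` (named amino-acid vector, `*` = stop),
#'   `sense` (the 61 sense triplets), `stop` (the 3 stop triplets).
#' @export
genetic_code <- function(code_id = "standard") {
  if (!identical(code_id, "standard")) {
    stop("only the standard genetic code is supported", call. = FALSE)
  }
  .codonsel_cache$code
}

# Built once at load from seqinr's translation table rather than typed in.
.build_standard_code <- function() {
  nts <- c("A", "C", "G", "T")
  codons <- as.vector(t(outer(
    as.vector(t(outer(nts, nts, paste0))), nts, paste0
  )))
  codons <- sort(codons)
  aa <- vapply(
    codons,
    function(cd) seqinr::translate(strsplit(cd, "")[[1]]),
    character(1)
  )
  names(aa) <- codons
  sense <- codons[aa != "*"]
  stopifnot(length(sense) == 61L)
  structure(
    list(
      code_id = "standard",
      codons = codons,
      aa = aa,
      sense = sense,
      stop = codons[aa == "*"]
    ),
    class = "genetic_code"
  )
}

#' @export
print.genetic_code <- function(x, ...) {
  cat("<genetic_code>", x$code_id, ":", length(x$sense), "sense codons,",
      length(x$stop), "stop codons\n")
  invisible(x)
}

# Pairwise structure of single-nucleotide changes among sense codons:
# 61 x 61 logical matrices `single` (exactly one position differs, both
# sense), `transition` (that difference is a transition), `synonymous`.
.build_codon_pairs <- function(code) {
  n <- length(code$sense)
  mat <- do.call(rbind, strsplit(code$sense, ""))
  aa <- code$aa[code$sense]
  ndiff <- matrix(0L, n, n)
  trans_pos <- matrix(FALSE, n, n)
  purine <- c(A = TRUE, G = TRUE, C = FALSE, T = FALSE)
  for (p in 1:3) {
    d <- outer(mat[, p], mat[, p], "!=")
    ndiff <- ndiff + d
    ts <- outer(purine[mat[, p]], purine[mat[, p]], "==") & d
    trans_pos <- trans_pos | ts
  }
  single <- ndiff == 1L
  list(
    single = single,
    transition = single & trans_pos,
    synonymous = single & outer(aa, aa, "=="),
    ndiff = ndiff
  )
}

# Per-codon mutational opportunity from single-nucleotide neighbor
# enumeration, stop codons excluded: ES + EN = 3 for every sense codon.
.build_opportunity <- function(code, pairs) {
  n_syn <- rowSums(pairs$synonymous)
  n_sense <- rowSums(pairs$single)
  es <- unname(3 * n_syn / n_sense)
  tibble::tibble(codon = code$sense, ES = es, EN = 3 - es,
                 n_sense_neighbors = unname(n_sense))
}

.codonsel_cache <- new.env(parent = emptyenv())

.onLoad <- function(libname, pkgname) {
  code <- .build_standard_code()
  .codonsel_cache$code <- code
  .codonsel_cache$pairs <- .build_codon_pairs(code)
  .codonsel_cache$opportunity <- .build_opportunity(code, .codonsel_cache$pairs)
}

codon_pairs <- function() .codonsel_cache$pairs

#' Synonymous and nonsynonymous mutational opportunity per sense codon
#'
#' Enumerates the single-nucleotide neighbors of each sense codon (stop
#' codons excluded) and splits the codon's 3 mutable sites into an expected
#' synonymous (`ES`) and nonsynonymous (`EN`) part, so `ES + EN = 3` exactly.
#' For example `TTT` has 9 sense neighbors of which one (`TTC`) is
#' synonymous, giving `ES = 1/3`.
#'
#' @return A tibble with columns `codon`, `ES`, `EN`, `n_sense_neighbors`.
#' @export
codon_opportunity <- function() .codonsel_cache$opportunity

# index <-> codon helpers -----------------------------------------------

codon_index <- function(codons, code = genetic_code()) {
  idx <- match(codons, code$sense)
  if (anyNA(idx) && !anyNA(codons)) {
    bad <- codons[!is.na(codons) & is.na(idx)]
    if (any(bad %in% code$stop)) {
      stop("stop codon encountered: ", bad[bad %in% code$stop][1],
           call. = FALSE)
    }
  }
  idx
}

codon_aa <- function(idx, code = genetic_code()) {
  unname(code$aa[code$sense[idx]])
}
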