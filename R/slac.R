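# Counting-based dN/dS: one joint maximum-likelihood ancestral
# reconstruction under the M0 matrix, per-site synonymous/nonsynonymous
# opportunity from neighbor enumeration, substitutions tallied along every
# branch, and a bootstrap confidence interval on the global ratio.

#' Joint maximum-likelihood ancestral reconstruction
#'
#' Assigns one codon state to every internal node at every site by
#' max-product dynamic programming over the tree under the M0 rate matrix
#' and the fitted branch lengths. Ties are broken deterministically toward
#' the lowest codon index; leaves retain their observed states (missing
#' leaf codons are back-filled from the optimum).
#'
#' @param aln A `codon_aln`.
#' @param tree A `phylo` (defaults to the fitted tree in `m0_fit`).
#' @param m0_fit An M0 `codon_fit` supplying the rate matrix and branch
#'   lengths.
#' @return An `ancestral_assignment`: `states` (node x site codon indices,
#'   ape node numbering of the postorder tree), `tree` (postorder), and
#'   the site index map.
#' @export
reconstruct_ancestors <- function(aln, tree = m0_fit$tree, m0_fit) {
  if (missing(m0_fit) || !inherits(m0_fit, "codon_fit")) {
    stop("an M0 codon_fit is required", call. = FALSE)
  }
  check_taxa(aln, tree)
  pi <- m0_fit$freqs$pi
  rates <- build_codon_rate_matrix(m0_fit$kappa, m0_fit$est$omega %||%
                                     m0_fit$mix$omega[1], pi)
  eg <- codon_eigen(rates$Q, pi)
  po <- stats::reorder(tree, "postorder")
  ts <- aln$states[match(po$tip.label, aln$taxa), , drop = FALSE]
  ts[is.na(ts)] <- 0L
  storage.mode(ts) <- "integer"
  edge <- po$edge
  storage.mode(edge) <- "integer"
  logP <- lapply(po$edge.length, function(t) {
    P <- eg$U %*% (exp(eg$d * t) * eg$Ui)
    log(pmax(P, 1e-300))
  })
  states <- cpp_joint_reconstruct(edge, logP, length(po$tip.label),
                                  length(po$tip.label) + po$Nnode, ts,
                                  log(pi))
  structure(
    list(states = states, tree = po, method = "joint_ML",
         site_index = aln$site_index),
    class = "ancestral_assignment"
  )
}

#' @export
print.ancestral_assignment <- function(x, ...) {
  cat("<ancestral_assignment> joint ML |", nrow(x$states), "nodes x",
      ncol(x$states), "sites\n")
  invisible(x)
}

# Average syn/nonsyn substitution counts between two codons over all
# minimal mutational paths, excluding paths that pass through a stop codon.
# Memoised on first use.
path_counts <- function(i, j, code = genetic_code()) {
  key <- paste0(i, "_", j)
  memo <- .codonsel_cache$paths
  if (is.null(memo)) {
    memo <- new.env(parent = emptyenv())
    .codonsel_cache$paths <- memo
  }
  if (!is.null(memo[[key]])) return(memo[[key]])
  a <- strsplit(code$sense[i], "")[[1]]
  b <- strsplit(code$sense[j], "")[[1]]
  pos <- which(a != b)
  count_path <- function(order) {
    cur <- a
    syn <- nonsyn <- 0
    for (p in order) {
      nxt <- cur
      nxt[p] <- b[p]
      cd_cur <- paste(cur, collapse = "")
      cd_nxt <- paste(nxt, collapse = "")
      if (code$aa[cd_nxt] == "*") return(NULL)
      if (code$aa[cd_cur] == code$aa[cd_nxt]) syn <- syn + 1
      else nonsyn <- nonsyn + 1
      cur <- nxt
    }
    c(syn, nonsyn)
  }
  orders <- if (length(pos) == 1) list(pos) else {
    perms <- function(v) {
      if (length(v) == 1) return(list(v))
      unlist(lapply(seq_along(v), function(i) {
        lapply(perms(v[-i]), function(r) c(v[i], r))
      }), recursive = FALSE)
    }
    perms(pos)
  }
  counts <- Filter(Negate(is.null), lapply(orders, count_path))
  if (!length(counts)) {
    # every minimal path passes a stop: fall back to all minimal paths
    counts <- lapply(orders, function(o) {
      cur <- a; syn <- nonsyn <- 0
      for (p in o) {
        nxt <- cur; nxt[p] <- b[p]
        same <- code$aa[paste(cur, collapse = "")] ==
          code$aa[paste(nxt, collapse = "")]
        if (isTRUE(same)) syn <- syn + 1 else nonsyn <- nonsyn + 1
        cur <- nxt
      }
      c(syn, nonsyn)
    })
  }
  out <- colMeans(do.call(rbind, counts))
  memo[[key]] <- out
  out
}

#' Per-site SLAC opportunity and substitution counts
#'
#' `ES`/`EN` split each codon's 3 mutable sites into synonymous and
#' nonsynonymous opportunity by single-nucleotide neighbor enumeration
#' (stops excluded; `ES + EN = 3` per codon state), averaged over the
#' states assigned to every node of the tree at that site. `OS`/`ON` tally
#' substitutions along every branch between assigned states; branches
#' changing at several codon positions are resolved by averaging over all
#' minimal mutational paths that avoid stop codons.
#'
#' @param aln A `codon_aln`.
#' @param tree The tree used for the reconstruction (defaults to the one
#'   stored in `anc`).
#' @param anc An [reconstruct_ancestors()] result.
#' @return A `slac_site_counts` tibble: `codon`, `ES`, `EN`, `OS`, `ON`.
#' @export
slac_counts <- function(aln, tree = anc$tree, anc) {
  opp <- codon_opportunity()
  states <- anc$states
  po <- anc$tree
  n_sites <- ncol(states)
  es <- en <- os <- on <- numeric(n_sites)
  for (s in seq_len(n_sites)) {
    st <- states[, s]
    ok <- st > 0
    es[s] <- mean(opp$ES[st[ok]])
    en[s] <- mean(opp$EN[st[ok]])
  }
  for (e in seq_len(nrow(po$edge))) {
    pa <- states[po$edge[e, 1], ]
    ch <- states[po$edge[e, 2], ]
    diff <- which(pa != ch & pa > 0 & ch > 0)
    for (s in diff) {
      cnt <- path_counts(pa[s], ch[s])
      os[s] <- os[s] + cnt[1]
      on[s] <- on[s] + cnt[2]
    }
  }
  out <- tibble::tibble(codon = anc$site_index, ES = es, EN = en,
                        OS = os, ON = on)
  class(out) <- c("slac_site_counts", class(out))
  out
}

#' Global counting-based dN/dS with bootstrap confidence interval
#'
#' `dN = sum(ON)/sum(EN)`, `dS = sum(OS)/sum(ES)`; the ratio's 95%
#' confidence interval comes from a nonparametric percentile bootstrap
#' over codon sites. Each site also gets a two-sided binomial test of its
#' nonsynonymous substitution fraction against the neutral expectation
#' `EN/(EN+ES)`.
#'
#' @param counts A `slac_site_counts` tibble.
#' @param bootstrap_reps Bootstrap replicates.
#' @param seed Mandatory integer seed.
#' @param conf_level Confidence level of the percentile interval.
#' @return A `slac_result`: `dn`, `ds`, `dnds`, `ci`, `sites` (per-codon
#'   tibble with `dn_minus_ds` and `p_value`), `bootstrap_reps`, `seed`.
#' @export
slac_dnds <- function(counts, bootstrap_reps = 1000, seed,
                      conf_level = 0.95) {
  stopifnot(!missing(seed))
  if (sum(counts$OS) == 0) {
    stop("no synonymous substitutions: dN/dS is undefined", call. = FALSE)
  }
  ratio_of <- function(idx) {
    dn <- sum(counts$ON[idx]) / sum(counts$EN[idx])
    ds <- sum(counts$OS[idx]) / sum(counts$ES[idx])
    if (ds == 0) NA_real_ else dn / ds
  }
  n <- nrow(counts)
  dn <- sum(counts$ON) / sum(counts$EN)
  ds <- sum(counts$OS) / sum(counts$ES)
  set.seed(seed)
  boot <- vapply(seq_len(bootstrap_reps), function(b) {
    ratio_of(sample.int(n, n, replace = TRUE))
  }, numeric(1))
  a <- (1 - conf_level) / 2
  ci <- stats::quantile(boot, c(a, 1 - a), na.rm = TRUE, names = FALSE)
  p_neutral <- counts$EN / (counts$EN + counts$ES)
  site_p <- vapply(seq_len(n), function(s) {
    tot <- round(counts$ON[s] + counts$OS[s])
    if (tot == 0) return(NA_real_)
    stats::binom.test(round(counts$ON[s]), tot, p_neutral[s])$p.value
  }, numeric(1))
  sites <- tibble::tibble(
    codon = counts$codon, ES = counts$ES, EN = counts$EN,
    OS = counts$OS, ON = counts$ON,
    dn_minus_ds = counts$ON / counts$EN - counts$OS / counts$ES,
    p_value = site_p)
  structure(
    list(dn = dn, ds = ds, dnds = dn / ds, ci = ci,
         conf_level = conf_level, sites = sites,
         bootstrap_reps = bootstrap_reps, seed = seed,
         n_dropped_reps = sum(is.na(boot))),
    class = "slac_result"
  )
}

#' @export
print.slac_result <- function(x, ...) {
  cat("<slac_result> dN/dS = ", round(x$dnds, 3), " (",
      100 * x$conf_level, "% CI: ", round(x$ci[1], 3), "-",
      round(x$ci[2], 3), "), ", x$bootstrap_reps, " bootstrap reps\n",
      sep = "")
  invisible(x)
}

#' One-call SLAC analysis
#'
#' Fits M0 (if not supplied), reconstructs ancestors, counts, and returns
#' the global ratio with its bootstrap interval.
#'
#' @inheritParams slac_dnds
#' @param aln A `codon_aln`.
#' @param tree A `phylo`.
#' @param m0_fit Optional precomputed M0 fit.
#' @param options Options for the inner M0 fit.
#' @export
slac_analysis <- function(aln, tree, bootstrap_reps = 1000, seed,
                          m0_fit = NULL, options = list()) {
  stopifnot(!missing(seed))
  m0_fit <- m0_fit %||% maximize_likelihood(
    aln, tree, "M0",
    options = utils::modifyList(list(n_starts = 2), options))
  anc <- reconstruct_ancestors(aln, m0_fit$tree, m0_fit)
  counts <- slac_counts(aln, anc = anc)
  slac_dnds(counts, bootstrap_reps = bootstrap_reps, seed = seed)
}
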