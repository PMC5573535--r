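# Seed-deterministic generators emulating every input the analysis assumes:
# codon alignments evolved under site-class omega mixtures on a tree,
# per-codon polymorphism/divergence counts under the PRF model, and
# age-expression trajectories. Each generator emits a truth table with the
# same coordinate conventions as the analysis outputs.

#' Deterministic fixture phylogeny
#'
#' Near-balanced (default) or ladder topology with deterministic tip labels
#' `t1..tn`, made ultrametric with root-to-tip path length `total_depth`
#' (expected substitutions per codon).
#'
#' @param n_taxa Number of tips (>= 2).
#' @param total_depth Root-to-tip path length.
#' @param shape `"balanced"` or `"ladder"`.
#' @return A `phylo`.
#' @export
fixture_tree <- function(n_taxa, total_depth = 1, shape = c("balanced", "ladder")) {
  shape <- match.arg(shape)
  stopifnot(n_taxa >= 2)
  build <- function(labels) {
    n <- length(labels)
    if (n == 1) return(labels)
    k <- if (shape == "balanced") ceiling(n / 2) else n - 1
    paste0("(", build(labels[seq_len(k)]), ",",
           build(labels[-seq_len(k)]), ")")
  }
  txt <- paste0(build(paste0("t", seq_len(n_taxa))), ";")
  tree <- ape::read.tree(text = txt)
  depth <- ape::node.depth(tree, method = 2)  # levels below each node
  tree$edge.length <- vapply(seq_len(nrow(tree$edge)), function(e) {
    hp <- depth[tree$edge[e, 1]]
    hc <- depth[tree$edge[e, 2]]
    total_depth * (hp - hc) / (depth[ape::Ntip(tree) + 1] - 1)
  }, numeric(1))
  tree
}

#' Simulate a codon alignment under a site-class omega mixture
#'
#' Root codons are drawn from `pi`; each site is assigned a mixture class
#' and evolved along the tree by exact transition probabilities
#' `exp(Q_c t)` (matrix-exponential sampling per branch). Rate matrices are
#' normalised so the mixture-averaged substitution rate is 1, matching the
#' fitting convention.
#'
#' @param tree A `phylo` with branch lengths in substitutions per codon.
#' @param mix A [mixture_spec()] of (weight, omega) site classes.
#' @param n_codons Number of codon sites.
#' @param kappa Transition/transversion ratio.
#' @param pi A `codon_freqs`, 61 weights, or `NULL` for equal frequencies.
#' @param seed Mandatory integer seed.
#' @return A list: `aln` (a `codon_aln`) and `truth`, a tibble with
#'   `codon`, `class`, `omega` for every site.
#' @export
simulate_codon_alignment <- function(tree, mix, n_codons, kappa = 2,
                                     pi = NULL, seed) {
  stopifnot(inherits(mix, "mixture_spec"), n_codons >= 1, !missing(seed))
  validate_tree(tree)
  if (is.null(pi)) pi <- rep(1 / 61, 61)
  if (inherits(pi, "codon_freqs")) pi <- pi$pi
  set.seed(seed)

  parts <- codon_q_parts(kappa, pi)
  S <- sum(mix$weights * (parts$rA + mix$omega * parts$rB))
  P_for <- function(w, t) {
    Q <- (parts$A + w * parts$B) / S
    diag(Q) <- -rowSums(Q)
    eg <- codon_eigen(Q, pi)
    P <- eg$U %*% (exp(eg$d * t) * eg$Ui)
    P[P < 0] <- 0
    P / rowSums(P)
  }

  classes <- sample.int(length(mix$weights), n_codons, replace = TRUE,
                        prob = mix$weights)
  po <- stats::reorder(tree, "postorder")
  n_tip <- length(po$tip.label)
  n_node <- n_tip + po$Nnode
  states <- matrix(NA_integer_, n_node, n_codons)
  root <- po$edge[nrow(po$edge), 1]
  states[root, ] <- sample.int(61, n_codons, replace = TRUE, prob = pi)
  for (e in rev(seq_len(nrow(po$edge)))) {  # preorder: parent always set
    par <- po$edge[e, 1]; ch <- po$edge[e, 2]; t <- po$edge.length[e]
    for (k in seq_along(mix$omega)) {
      idx <- which(classes == k)
      if (!length(idx)) next
      P <- P_for(mix$omega[k], t)
      ps <- states[par, idx]
      for (s in sort(unique(ps))) {
        sel <- idx[ps == s]
        states[ch, sel] <- sample.int(61, length(sel), replace = TRUE,
                                      prob = P[s, ])
      }
    }
  }
  code <- genetic_code()
  seqs <- vapply(seq_len(n_tip), function(i) {
    paste(code$sense[states[i, ]], collapse = "")
  }, character(1))
  names(seqs) <- po$tip.label
  list(
    aln = codon_alignment(seqs),
    truth = tibble::tibble(codon = seq_len(n_codons), class = classes,
                           omega = mix$omega[classes])
  )
}

#' Simulate per-codon polymorphism/divergence counts under the PRF model
#'
#' Draws `D_s, D_n, P_s, P_n` as independent Poissons with the
#' selection-dependent means used by [gamma_site_loglik()], given a truth
#' profile of population-scaled selection coefficients. Optionally the
#' profile is persistence-structured: adjacent codons copy their gamma with
#' probability `persistence`, else redraw from `gamma_weights`.
#'
#' @param n_codons Number of codons.
#' @param gamma Either a length-`n_codons` vector of truth gamma values (on
#'   the 12-class grid), or `NULL` to draw from `gamma_weights`.
#' @param theta Neutral mutation rate per site.
#' @param T_div Divergence branch length.
#' @param n_chrom Sampled chromosomes (>= 2).
#' @param Z_n Nonsynonymous/synonymous opportunity ratio per codon
#'   (recycled).
#' @param gamma_weights Simplex weights over [gamma_grid()] for random
#'   profiles.
#' @param persistence Probability adjacent codons share gamma.
#' @param seed Mandatory integer seed.
#' @return A list: `counts` (tibble `codon, D_s, D_n, P_s, P_n, Z_n, n`)
#'   and `truth` (tibble `codon, gamma`).
#' @export
simulate_prf_site_counts <- function(n_codons, gamma = NULL, theta = 1e-3,
                                     T_div = 1, n_chrom = 20, Z_n = 2.5,
                                     gamma_weights = NULL, persistence = 0,
                                     seed) {
  stopifnot(!missing(seed), n_codons >= 1, theta >= 0, T_div >= 0,
            n_chrom >= 2)
  set.seed(seed)
  grid <- gamma_grid()
  if (is.null(gamma)) {
    w <- gamma_weights %||% rep(1 / 12, 12)
    g <- numeric(n_codons)
    g[1] <- sample(grid, 1, prob = w)
    for (i in seq_len(n_codons - 1)) {
      g[i + 1] <- if (stats::runif(1) < persistence) g[i] else
        sample(grid, 1, prob = w)
    }
    gamma <- g
  }
  stopifnot(length(gamma) == n_codons)
  off <- setdiff(unique(gamma), grid)
  if (length(off)) {
    stop("gamma values off the 12-class grid: ",
         paste(off, collapse = ", "), call. = FALSE)
  }
  Z_n <- rep_len(Z_n, n_codons)
  a_n <- sum(1 / seq_len(n_chrom - 1))
  h <- vapply(gamma, prf_fixation_factor, numeric(1))
  Gr <- vapply(gamma, prf_polymorphism_factor, numeric(1), n = n_chrom)
  lam_Ds <- rep((theta / 2) * T_div, n_codons)
  lam_Dn <- (theta / 2) * T_div * Z_n * h
  lam_Ps <- rep((theta / 2) * a_n, n_codons)
  lam_Pn <- (theta / 2) * a_n * Z_n * Gr
  counts <- tibble::tibble(
    codon = seq_len(n_codons),
    D_s = stats::rpois(n_codons, lam_Ds),
    D_n = stats::rpois(n_codons, lam_Dn),
    P_s = stats::rpois(n_codons, lam_Ps),
    P_n = stats::rpois(n_codons, lam_Pn),
    Z_n = Z_n, n = n_chrom
  )
  list(counts = counts,
       truth = tibble::tibble(codon = seq_len(n_codons), gamma = gamma))
}

#' Simulate age-expression trajectories
#'
#' Ages are drawn over the species lifespan; expression is a trend in
#' transformed age (`x = log2(age + offset)`) plus Gaussian noise, one
#' record per individual.
#'
#' @param n Individuals per species (named vector; names become species).
#' @param trend A function of transformed age (or a named list of functions
#'   per species). `"flat"` and `"late_rise"` are accepted shorthands.
#' @param amplitude Trend amplitude multiplier.
#' @param noise_sd Gaussian noise standard deviation (>= 0).
#' @param max_age Maximum age in years per species (recycled).
#' @param age_offset Offset inside the log2 age transform.
#' @param region Brain-region label stored in the records.
#' @param seed Mandatory integer seed.
#' @return An `expression_series` tibble: `individual`, `species`, `region`,
#'   `age_years`, `expression`.
#' @export
simulate_expression <- function(n = c(human = 25, macaque = 31, chimp = 12),
                                trend = "flat", amplitude = 1,
                                noise_sd = 0.3, max_age = 90,
                                age_offset = 0.75, region = "PFC", seed) {
  stopifnot(!missing(seed), noise_sd >= 0)
  set.seed(seed)
  species <- names(n)
  if (is.null(species)) species <- paste0("sp", seq_along(n))
  max_age <- rep_len(max_age, length(n))
  as_fun <- function(tr) {
    if (is.function(tr)) return(tr)
    switch(tr,
      flat = function(x) 0 * x,
      late_rise = function(x) pmax(x - stats::median(x), 0),
      stop("unknown trend: ", tr, call. = FALSE))
  }
  rows <- purrr::map(seq_along(species), function(i) {
    tr <- if (is.list(trend)) as_fun(trend[[species[i]]]) else as_fun(trend)
    age <- sort(stats::runif(n[i], 0, max_age[i]))
    x <- log2(age + age_offset)
    expr <- amplitude * tr(x) + stats::rnorm(n[i], 0, noise_sd)
    tibble::tibble(
      individual = paste0(species[i], "_", seq_len(n[i])),
      species = species[i], region = region,
      age_years = age, expression = expr)
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("expression_series", class(out))
  out
}
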