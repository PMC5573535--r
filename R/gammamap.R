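# Population-genetics-phylogenetics mapping of selection coefficients along
# a gene. Per-codon polymorphism/divergence counts are modelled as
# independent Poissons with Poisson-random-field means over a fixed 12-value
# grid of population-scaled selection coefficients; a persistence-coupled
# MCMC gives per-codon posteriors.

#' The 12-value grid of population-scaled selection coefficients
#'
#' From strongly beneficial (100, 50) through moderately (10, 5) and weakly
#' (1) beneficial, neutral (0), weakly (-1) / moderately (-5, -10) /
#' strongly (-50, -100) deleterious, to inviable (-500).
#' @return Numeric vector of length 12.
#' @export
gamma_grid <- function() {
  c(100, 50, 10, 5, 1, 0, -1, -5, -10, -50, -100, -500)
}

#' Poisson-random-field selection kernels
#'
#' `prf_fixation_factor()` returns the relative fixation rate
#' `h(gamma) = gamma / (1 - exp(-gamma))` with `h(0) = 1` by continuity.
#' `prf_polymorphism_factor()` returns the relative expected polymorphism
#' `G(gamma, n) / G(0, n)` with
#' `G(gamma, n) = Int_0^1 g(q; gamma) (1 - q^n - (1-q)^n) dq` and
#' `g(q; gamma) = [(1 - e^{-gamma(1-q)})/(1 - e^{-gamma})] * 2/(q(1-q))`,
#' evaluated by adaptive quadrature in an overflow-safe parameterisation.
#'
#' @param gamma Population-scaled selection coefficient (finite).
#' @param n Number of sampled chromosomes (>= 2).
#' @param relative Return `G/G(0, n)` (default) or the raw integral.
#' @return A scalar factor.
#' @export
prf_fixation_factor <- function(gamma) {
  stopifnot(is.finite(gamma))
  if (abs(gamma) < 1e-8) return(1)
  if (gamma > 0) gamma / (-expm1(-gamma)) else gamma * exp(gamma) / expm1(gamma)
}

# sojourn-density ratio (1 - e^{-gamma(1-q)}) / (1 - e^{-gamma}), stable for
# |gamma| up to the grid extremes.
.prf_ratio <- function(q, gamma) {
  if (abs(gamma) < 1e-8) return(1 - q)
  if (gamma > 0) expm1(-gamma * (1 - q)) / expm1(-gamma)
  else (exp(gamma * q) - exp(gamma)) / (1 - exp(gamma))
}

#' @rdname prf_fixation_factor
#' @export
prf_polymorphism_factor <- function(gamma, n, relative = TRUE) {
  stopifnot(is.finite(gamma), n >= 2)
  quad <- function(g) {
    f <- function(q) {
      vapply(q, function(qi) {
        .prf_ratio(qi, g) * 2 / (qi * (1 - qi)) * (1 - qi^n - (1 - qi)^n)
      }, numeric(1))
    }
    breaks <- c(0, 1e-4, 1e-2, 0.1, 0.5, 0.9, 0.99, 1)
    val <- 0
    for (i in seq_len(length(breaks) - 1)) {
      piece <- tryCatch(
        stats::integrate(f, breaks[i], breaks[i + 1],
                         rel.tol = 1e-10, subdivisions = 400L)$value,
        error = function(e) stop("PRF integration failed at gamma = ", g,
                                 ", n = ", n, ": ", conditionMessage(e),
                                 call. = FALSE))
      val <- val + piece
    }
    val
  }
  G <- quad(gamma)
  if (!relative) return(G)
  G / quad(0)
}

harmonic_number <- function(n) sum(1 / seq_len(n - 1))

#' Poisson-random-field log-likelihood of per-codon counts
#'
#' Independent Poisson likelihoods with means
#' `lambda_Ds = (theta/2) T`, `lambda_Dn = (theta/2) T Z_n h(gamma)`,
#' `lambda_Ps = (theta/2) a_n`, `lambda_Pn = (theta/2) a_n Z_n G_rel(gamma, n)`,
#' where `a_n = sum_{i=1}^{n-1} 1/i`.
#'
#' @param counts A site-counts tibble with columns `D_s, D_n, P_s, P_n,
#'   Z_n, n` (see [derive_site_counts()] / [simulate_prf_site_counts()]).
#' @param gamma A single selection coefficient applied to every codon.
#' @param theta Neutral mutation rate per site (> 0).
#' @param T_div Divergence branch length (> 0).
#' @return Total log-likelihood over the codons.
#' @export
gamma_site_loglik <- function(counts, gamma, theta, T_div) {
  if (theta <= 0 || T_div <= 0) stop("theta and T_div must be positive",
                                     call. = FALSE)
  h <- prf_fixation_factor(gamma)
  n <- counts$n[1]
  Gr <- prf_polymorphism_factor(gamma, n)
  a_n <- harmonic_number(n)
  sum(stats::dpois(counts$D_s, (theta / 2) * T_div, log = TRUE) +
      stats::dpois(counts$D_n, (theta / 2) * T_div * counts$Z_n * h, log = TRUE) +
      stats::dpois(counts$P_s, (theta / 2) * a_n, log = TRUE) +
      stats::dpois(counts$P_n, (theta / 2) * a_n * counts$Z_n * Gr, log = TRUE))
}

# Per-codon x per-class log-likelihood matrix given theta, T. h_k and the
# G_rel matrix are precomputed once per data set.
prf_loglik_matrix <- function(counts, theta, T_div, h_k, G_mat) {
  a_n <- harmonic_number(counts$n[1])
  base <- stats::dpois(counts$D_s, (theta / 2) * T_div, log = TRUE) +
    stats::dpois(counts$P_s, (theta / 2) * a_n, log = TRUE)
  lam_dn <- (theta / 2) * T_div * outer(counts$Z_n, h_k)
  lam_pn <- (theta / 2) * a_n * counts$Z_n * G_mat
  stats::dpois(counts$D_n, lam_dn, log = TRUE) +
    stats::dpois(counts$P_n, lam_pn, log = TRUE) + base
}

#' Prior specification for the selection-coefficient MCMC
#'
#' Lognormal hyperpriors on the neutral mutation rate `theta` and branch
#' length `T`, a uniform prior on the persistence probability `p`, and a
#' uniform Dirichlet prior over the 12 selection classes.
#'
#' @param theta_meanlog,theta_sdlog Lognormal hyperparameters for theta.
#' @param T_meanlog,T_sdlog Lognormal hyperparameters for T.
#' @return A `prior_spec`.
#' @export
prior_spec <- function(theta_meanlog = log(1e-3), theta_sdlog = 1,
                       T_meanlog = log(1), T_sdlog = 1) {
  stopifnot(is.finite(theta_meanlog), is.finite(theta_sdlog),
            is.finite(T_meanlog), is.finite(T_sdlog),
            theta_sdlog > 0, T_sdlog > 0)
  structure(list(theta_meanlog = theta_meanlog, theta_sdlog = theta_sdlog,
                 T_meanlog = T_meanlog, T_sdlog = T_sdlog),
            class = "prior_spec")
}

#' Parsimony ancestor from four reference species
#'
#' Per-codon parsimony state on the fixed unrooted topology
#' `((ingroup1, ingroup2), outgroup1, outgroup2)` - in the intended use,
#' ((human, chimpanzee), orangutan, macaque) - evaluated at the internal
#' node adjacent to the ingroup pair. Sites where several states are
#' equally parsimonious (e.g. a 2-vs-2 split across the pairs) are flagged
#' ambiguous and excluded downstream.
#'
#' @param aln A `codon_aln` containing the four taxa.
#' @param taxa Character vector of 4 taxon names in the order ingroup1,
#'   ingroup2, outgroup1, outgroup2.
#' @return A tibble: `codon` (unmasked-gene numbering), `state` (codon
#'   index or `NA`), `codon_state` (triplet or `NA`), `ambiguous`.
#' @export
parsimony_ancestor <- function(aln, taxa) {
  stopifnot(length(taxa) == 4)
  missing_taxa <- setdiff(taxa, aln$taxa)
  if (length(missing_taxa)) {
    stop("taxa absent from alignment: ",
         paste(missing_taxa, collapse = ", "), call. = FALSE)
  }
  S <- aln$states[match(taxa, aln$taxa), , drop = FALSE]
  code <- genetic_code()
  res <- vapply(seq_len(aln$n_codons), function(s) {
    obs <- S[, s]
    cand <- unique(obs[!is.na(obs)])
    if (!length(cand)) return(c(NA_integer_, 1L))
    cost1 <- vapply(cand, function(x) {
      inner <- sum(obs[1] != x, na.rm = TRUE) + sum(obs[2] != x, na.rm = TRUE)
      outer_cost <- min(vapply(cand, function(y) {
        (x != y) + sum(obs[3] != y, na.rm = TRUE) +
          sum(obs[4] != y, na.rm = TRUE)
      }, numeric(1)))
      inner + outer_cost
    }, numeric(1))
    best <- cand[cost1 == min(cost1)]
    if (length(best) > 1) c(NA_integer_, 1L) else c(best, 0L)
  }, integer(2))
  tibble::tibble(
    codon = aln$site_index,
    state = res[1, ],
    codon_state = ifelse(is.na(res[1, ]), NA_character_,
                         code$sense[res[1, ]]),
    ambiguous = res[2, ] == 1L
  )
}

#' A population SNP sample for one lineage
#'
#' @param lineage Lineage name (must match an alignment taxon for
#'   [derive_site_counts()]).
#' @param n Number of sampled chromosomes.
#' @param snps A tibble with columns `codon` (1-based codon index in
#'   unmasked-gene coordinates), `pos` (position in codon, 1-3), `ancestral`
#'   and `derived` alleles (single bases), `derived_count` in `[1, n-1]`.
#' @return A `population_sample`.
#' @export
population_sample <- function(lineage, n, snps) {
  snps <- tibble::as_tibble(snps)
  need <- c("codon", "pos", "ancestral", "derived", "derived_count")
  if (!all(need %in% names(snps))) {
    stop("snps must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(snps) && (any(snps$derived_count < 1) ||
                     any(snps$derived_count > n - 1))) {
    stop("derived counts must lie in [1, n-1] for polymorphic records",
         call. = FALSE)
  }
  structure(list(lineage = lineage, n = n, snps = snps),
            class = "population_sample")
}

#' Read a minimal VCF-like SNP table
#'
#' Expects a tab-separated file with columns `CHROM, POS, REF, ALT, AC, AN`
#' (a `#`-prefixed header line is accepted). `POS` is interpreted as the
#' 1-based nucleotide position within the coding sequence; the ancestral
#' allele is taken from `ancestor` when supplied, else `REF`.
#'
#' @param path File path.
#' @param lineage Lineage name for the resulting sample.
#' @param ancestor Optional ancestor table from [parsimony_ancestor()] used
#'   to orient alleles.
#' @return A [population_sample()].
#' @export
read_snp_table <- function(path, lineage, ancestor = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  header <- readLines(path, n = 1)
  if (startsWith(header, "#")) {
    tab <- utils::read.table(path, header = FALSE, skip = 1,
                             comment.char = "", sep = "\t",
                             stringsAsFactors = FALSE)
    names(tab) <- strsplit(sub("^#", "", header), "\t")[[1]]
  } else {
    tab <- utils::read.table(path, header = TRUE, comment.char = "",
                             sep = "\t", stringsAsFactors = FALSE)
  }
  need <- c("CHROM", "POS", "REF", "ALT", "AC", "AN")
  if (!all(need %in% names(tab))) {
    stop("SNP table must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  codon <- (tab$POS - 1L) %/% 3L + 1L
  pos <- (tab$POS - 1L) %% 3L + 1L
  anc <- tab$REF
  der <- tab$ALT
  cnt <- tab$AC
  if (!is.null(ancestor)) {
    anc_codon <- ancestor$codon_state[match(codon, ancestor$codon)]
    anc_nt <- substr(anc_codon, pos, pos)
    flip <- !is.na(anc_nt) & anc_nt == tab$ALT
    anc[flip] <- tab$ALT[flip]
    der[flip] <- tab$REF[flip]
    cnt[flip] <- tab$AN[flip] - tab$AC[flip]
  }
  keep <- cnt >= 1 & cnt <= tab$AN - 1
  population_sample(lineage, n = max(tab$AN),
                    snps = tibble::tibble(codon = codon[keep],
                                          pos = pos[keep],
                                          ancestral = anc[keep],
                                          derived = der[keep],
                                          derived_count = cnt[keep]))
}

# classify an ancestral->derived single-base change within a codon
.classify_change <- function(anc_codon, pos, derived_nt, code) {
  der_codon <- anc_codon
  substr(der_codon, pos, pos) <- derived_nt
  if (der_codon %in% code$stop || anc_codon %in% code$stop) return(NA)
  code$aa[anc_codon] == code$aa[der_codon]
}

#' Per-codon polymorphism/divergence counts for one lineage
#'
#' Fixed differences are positions where the lineage sequence differs from
#' the parsimony ancestor and no SNP segregates; segregating sites come
#' from the population sample. Both are classified synonymous vs
#' nonsynonymous in the ancestral codon context. `Z_n` is the
#' nonsynonymous/synonymous mutational-opportunity ratio of the ancestral
#' codon from single-nucleotide neighbor enumeration (the synonymous part
#' floored at 1/3 site so the ratio stays finite). Codons with an ambiguous
#' or missing ancestor are flagged `excluded` and dropped from the
#' likelihood.
#'
#' @param aln A `codon_aln` containing the lineage taxon.
#' @param sample A [population_sample()].
#' @param ancestor A tibble from [parsimony_ancestor()].
#' @param lineage Taxon name of the lineage in the alignment (defaults to
#'   the sample's lineage).
#' @return A tibble: `codon`, `D_s`, `D_n`, `P_s`, `P_n`, `Z_n`, `n`,
#'   `anc_codon`, `lineage_codon`, `excluded`.
#' @export
derive_site_counts <- function(aln, sample, ancestor,
                               lineage = sample$lineage) {
  if (!lineage %in% aln$taxa) {
    stop("lineage taxon not in alignment: ", lineage, call. = FALSE)
  }
  code <- genetic_code()
  opp <- codon_opportunity()
  lin <- aln$states[match(lineage, aln$taxa), ]
  anc_state <- ancestor$state[match(aln$site_index, ancestor$codon)]
  bad_codon <- setdiff(sample$snps$codon, aln$site_index)
  if (length(bad_codon)) {
    stop("SNP outside the coding alignment at codon ",
         paste(bad_codon, collapse = ", "), call. = FALSE)
  }
  out <- purrr::map(seq_len(aln$n_codons), function(i) {
    site <- aln$site_index[i]
    anc <- anc_state[i]
    if (is.na(anc)) {
      return(tibble::tibble(codon = site, D_s = 0L, D_n = 0L, P_s = 0L,
                            P_n = 0L, Z_n = NA_real_, n = sample$n,
                            anc_codon = NA_character_,
                            lineage_codon = NA_character_, excluded = TRUE))
    }
    anc_cd <- code$sense[anc]
    lin_cd <- if (is.na(lin[i])) NA_character_ else code$sense[lin[i]]
    snps <- sample$snps[sample$snps$codon == site, , drop = FALSE]
    ps <- pn <- ds <- dn <- 0L
    if (nrow(snps)) {
      for (r in seq_len(nrow(snps))) {
        anc_nt <- substr(anc_cd, snps$pos[r], snps$pos[r])
        if (!is.na(snps$ancestral[r]) && snps$ancestral[r] != anc_nt) next
        syn <- .classify_change(anc_cd, snps$pos[r], snps$derived[r], code)
        if (is.na(syn)) next
        if (syn) ps <- ps + 1L else pn <- pn + 1L
      }
    }
    if (!is.na(lin_cd) && lin_cd != anc_cd) {
      for (p in 1:3) {
        if (substr(lin_cd, p, p) == substr(anc_cd, p, p)) next
        if (nrow(snps) && p %in% snps$pos) next  # segregating, not fixed
        syn <- .classify_change(anc_cd, p, substr(lin_cd, p, p), code)
        if (is.na(syn)) next
        if (syn) ds <- ds + 1L else dn <- dn + 1L
      }
    }
    row <- opp[opp$codon == anc_cd, ]
    tibble::tibble(codon = site, D_s = ds, D_n = dn, P_s = ps, P_n = pn,
                   Z_n = row$EN / max(row$ES, 1 / 3), n = sample$n,
                   anc_codon = anc_cd, lineage_codon = lin_cd,
                   excluded = FALSE)
  })
  dplyr::bind_rows(out)
}

# ---------------------------------------------------------------------------
# MCMC

#' Persistence-coupled MCMC over the selection-coefficient grid
#'
#' Metropolis-within-Gibbs sampler over (theta, T, p, class weights,
#' per-codon gamma assignments). Adjacent codons share their gamma class
#' with probability `p` (first-order persistence chain), else redraw from
#' the Dirichlet weights; the assignment vector is sampled exactly by
#' forward-filtering backward-sampling, and `p` and the weights get
#' conjugate updates through copy/fresh auxiliary indicators. theta and T
#' use lognormal random-walk Metropolis steps. The first `burn_frac` of
#' each chain is discarded; chains are compared (split R-hat on theta, T,
#' p) and merged.
#'
#' @param counts A site-counts tibble (rows flagged `excluded` are
#'   dropped).
#' @param priors A [prior_spec()].
#' @param iterations Iterations per chain.
#' @param thin Thinning interval.
#' @param chains Number of chains (>= 1).
#' @param burn_frac Fraction of each chain discarded as burn-in.
#' @param fix_p Optional fixed persistence probability; when supplied, `p`
#'   is held at this value instead of being sampled.
#' @param seed Mandatory integer seed.
#' @return A `selection_profile`: `posterior` (tibble codon x 12 class
#'   masses), `P_ge1`, `P_gt0` per codon, hyperparameter draws,
#'   `diagnostics` (R-hat and effective sizes), and a `warning` status when
#'   any R-hat exceeds 1.1.
#' @export
run_gammamap_mcmc <- function(counts, priors = prior_spec(),
                              iterations = 100000, thin = 10, chains = 2,
                              burn_frac = 0.1, fix_p = NULL, seed) {
  stopifnot(!missing(seed), iterations >= 100, chains >= 1)
  if ("excluded" %in% names(counts)) counts <- counts[!counts$excluded, ]
  if (nrow(counts) == 0L) stop("no usable codons in counts", call. = FALSE)
  grid <- gamma_grid()
  K <- length(grid)
  L <- nrow(counts)
  n_chrom <- counts$n[1]
  h_k <- vapply(grid, prf_fixation_factor, numeric(1))
  G_k <- vapply(grid, prf_polymorphism_factor, numeric(1), n = n_chrom)
  G_mat <- matrix(G_k, L, K, byrow = TRUE)

  run_chain <- function(chain_seed) {
    set.seed(chain_seed)
    theta <- exp(priors$theta_meanlog)
    T_div <- exp(priors$T_meanlog)
    p <- fix_p %||% 0.5
    w <- rep(1 / K, K)
    E <- prf_loglik_matrix(counts, theta, T_div, h_k, G_mat)
    z <- max.col(E)
    n_keep <- floor((iterations * (1 - burn_frac)) / thin)
    occ <- matrix(0, L, K)
    hyper <- matrix(NA_real_, n_keep, 3,
                    dimnames = list(NULL, c("theta", "T", "p")))
    kept <- 0L
    burn <- floor(iterations * burn_frac)
    loglik_z <- function(theta, T_div, z) {
      a_n <- harmonic_number(n_chrom)
      sum(stats::dpois(counts$D_s, (theta / 2) * T_div, log = TRUE) +
          stats::dpois(counts$D_n,
                       (theta / 2) * T_div * counts$Z_n * h_k[z], log = TRUE) +
          stats::dpois(counts$P_s, (theta / 2) * a_n, log = TRUE) +
          stats::dpois(counts$P_n,
                       (theta / 2) * a_n * counts$Z_n * G_k[z], log = TRUE))
    }
    ll_cur <- loglik_z(theta, T_div, z)
    for (it in seq_len(iterations)) {
      # -- z | theta, T, p, w : exact FFBS over the persistence chain
      Em <- exp(E - apply(E, 1, max))
      f <- matrix(0, L, K)
      f[1, ] <- w * Em[1, ]
      f[1, ] <- f[1, ] / sum(f[1, ])
      if (L > 1) {
        for (i in 2:L) {
          v <- Em[i, ] * (p * f[i - 1, ] + (1 - p) * w)
          f[i, ] <- v / sum(v)
        }
      }
      z[L] <- sample.int(K, 1, prob = f[L, ])
      if (L > 1) {
        for (i in (L - 1):1) {
          l <- z[i + 1]
          v <- f[i, ] * ((1 - p) * w[l])
          v[l] <- v[l] + p * f[i, l]
          z[i] <- sample.int(K, 1, prob = v)
        }
      }
      # -- copy/fresh auxiliaries -> conjugate p and w updates
      fresh <- rep(TRUE, L)
      if (L > 1) {
        same <- z[-1] == z[-L]
        pr_copy <- ifelse(same, p / (p + (1 - p) * w[z[-1]]), 0)
        copy <- stats::runif(L - 1) < pr_copy
        fresh[-1] <- !copy
        if (is.null(fix_p)) {
          p <- stats::rbeta(1, 1 + sum(copy), 1 + sum(!copy))
        }
      }
      cnt <- tabulate(z[fresh], nbins = K)
      gdraw <- stats::rgamma(K, shape = 1 + cnt, rate = 1)
      w <- gdraw / sum(gdraw)
      # -- theta, T | z : lognormal random-walk Metropolis
      ll_cur <- loglik_z(theta, T_div, z)
      for (par in c("theta", "T")) {
        cur <- if (par == "theta") theta else T_div
        prop <- cur * exp(stats::rnorm(1, 0, 0.3))
        ll_prop <- if (par == "theta") loglik_z(prop, T_div, z) else
          loglik_z(theta, prop, z)
        pri_cur <- stats::dlnorm(cur,
          if (par == "theta") priors$theta_meanlog else priors$T_meanlog,
          if (par == "theta") priors$theta_sdlog else priors$T_sdlog,
          log = TRUE)
        pri_prop <- stats::dlnorm(prop,
          if (par == "theta") priors$theta_meanlog else priors$T_meanlog,
          if (par == "theta") priors$theta_sdlog else priors$T_sdlog,
          log = TRUE)
        # lognormal random walk: Hastings correction log(prop/cur)
        if (log(stats::runif(1)) <
            ll_prop + pri_prop - ll_cur - pri_cur + log(prop) - log(cur)) {
          if (par == "theta") theta <- prop else T_div <- prop
          ll_cur <- ll_prop
        }
      }
      E <- prf_loglik_matrix(counts, theta, T_div, h_k, G_mat)
      if (it > burn && (it - burn) %% thin == 0L && kept < n_keep) {
        kept <- kept + 1L
        occ[cbind(seq_len(L), z)] <- occ[cbind(seq_len(L), z)] + 1
        hyper[kept, ] <- c(theta, T_div, p)
      }
    }
    list(occ = occ, hyper = hyper[seq_len(kept), , drop = FALSE])
  }

  chain_seeds <- seed + 1000L * (seq_len(chains) - 1L)
  runs <- lapply(chain_seeds, run_chain)
  occ <- Reduce(`+`, lapply(runs, `[[`, "occ"))
  post <- occ / rowSums(occ)
  colnames(post) <- paste0("g", grid)

  diag_tbl <- purrr::map_dfr(c("theta", "T", "p"), function(par) {
    draws <- lapply(runs, function(r) r$hyper[, par])
    tibble::tibble(parameter = par,
                   rhat = split_rhat(draws),
                   ess = sum(vapply(draws, ess_acf, numeric(1))))
  })
  status <- if (any(diag_tbl$rhat > 1.1, na.rm = TRUE)) "warning" else "ok"
  if (status == "warning") {
    warning("R-hat > 1.1 on a hyperparameter; chains may not have converged",
            call. = FALSE)
  }
  pos_ge1 <- grid >= 1
  pos_gt0 <- grid > 0
  structure(
    list(posterior = tibble::as_tibble(cbind(
           tibble::tibble(codon = counts$codon), tibble::as_tibble(post))),
         P_ge1 = rowSums(post[, pos_ge1, drop = FALSE]),
         P_gt0 = rowSums(post[, pos_gt0, drop = FALSE]),
         codon = counts$codon,
         hyper = dplyr::bind_rows(lapply(seq_along(runs), function(i) {
           tibble::as_tibble(runs[[i]]$hyper) |>
             dplyr::mutate(chain = i)
         })),
         diagnostics = diag_tbl, status = status,
         grid = grid, seed = seed, chains = chains,
         iterations = iterations, thin = thin),
    class = "selection_profile"
  )
}

#' @export
print.selection_profile <- function(x, ...) {
  cat("<selection_profile> ", length(x$codon), " codons | ", x$chains,
      " chains x ", x$iterations, " it | status: ", x$status, "\n", sep = "")
  invisible(x)
}

split_rhat <- function(draws) {
  halves <- unlist(lapply(draws, function(d) {
    n <- length(d) %/% 2
    list(d[seq_len(n)], d[n + seq_len(n)])
  }), recursive = FALSE)
  m <- length(halves); n <- length(halves[[1]])
  if (n < 4) return(NA_real_)
  means <- vapply(halves, mean, numeric(1))
  vars <- vapply(halves, stats::var, numeric(1))
  B <- n * stats::var(means)
  W <- mean(vars)
  if (W <= 0) return(1)
  sqrt(((n - 1) / n * W + B / n) / W)
}

ess_acf <- function(d, max_lag = 50) {
  n <- length(d)
  if (n < 10 || stats::var(d) == 0) return(n)
  ac <- stats::acf(d, lag.max = min(max_lag, n - 2), plot = FALSE)$acf[-1]
  pos <- which(ac < 0.05)[1]
  if (!is.na(pos)) ac <- ac[seq_len(pos)]
  max(1, n / (1 + 2 * sum(ac)))
}

#' Classify codons from a selection profile
#'
#' Declares a codon a positive-selection target when its cumulative
#' posterior mass on beneficial classes exceeds `threshold`. The default
#' criterion is `P(gamma >= 1) > threshold` (classes 1, 5, 10, 50, 100);
#' `criterion = "gt0"` uses `P(gamma > 0)` instead.
#'
#' @param profile A `selection_profile`.
#' @param counts Optional site-counts tibble carrying `anc_codon` /
#'   `lineage_codon`, used to annotate ancestral and derived amino acids.
#' @param threshold Posterior-probability threshold (default 0.80).
#' @param criterion `"ge1"` or `"gt0"`.
#' @return A list: `selected` (tibble `codon`, `ancestral_aa`,
#'   `derived_aa`, `Pr`) and `class_summary` (tibble `gamma`, `mean_mass`),
#'   the per-class posterior mass averaged over codons (violin-plot ready
#'   per-codon masses are in `profile$posterior`).
#' @export
classify_and_summarize <- function(profile, counts = NULL, threshold = 0.80,
                                   criterion = c("ge1", "gt0")) {
  criterion <- match.arg(criterion)
  pr <- if (criterion == "ge1") profile$P_ge1 else profile$P_gt0
  sel <- which(pr > threshold)
  code <- genetic_code()
  anc_aa <- der_aa <- rep(NA_character_, length(sel))
  if (!is.null(counts) && length(sel)) {
    idx <- match(profile$codon[sel], counts$codon)
    anc_aa <- ifelse(is.na(counts$anc_codon[idx]), NA_character_,
                     unname(code$aa[counts$anc_codon[idx]]))
    der_aa <- ifelse(is.na(counts$lineage_codon[idx]), NA_character_,
                     unname(code$aa[counts$lineage_codon[idx]]))
  }
  post <- as.matrix(profile$posterior[, -1])
  list(
    selected = tibble::tibble(codon = profile$codon[sel],
                              ancestral_aa = anc_aa, derived_aa = der_aa,
                              Pr = pr[sel]),
    class_summary = tibble::tibble(gamma = profile$grid,
                                   mean_mass = colMeans(post))
  )
}

# Exact single-codon posterior over the gamma grid by quadrature over the
# (theta, T) hyperpriors; the oracle the MCMC is checked against.
gammamap_enumerate_single <- function(counts_row, priors = prior_spec(),
                                      n_grid = 200, width = 8) {
  grid <- gamma_grid()
  # trapezoid rule on the log scale, wide enough to cover likelihood mass
  # far from the prior mode
  s <- seq(-width, width, length.out = n_grid)
  ds <- s[2] - s[1]
  thetas <- exp(priors$theta_meanlog + priors$theta_sdlog * s)
  Ts <- exp(priors$T_meanlog + priors$T_sdlog * s)
  w_theta <- stats::dlnorm(thetas, priors$theta_meanlog,
                           priors$theta_sdlog) * thetas *
    priors$theta_sdlog * ds
  w_T <- stats::dlnorm(Ts, priors$T_meanlog, priors$T_sdlog) * Ts *
    priors$T_sdlog * ds
  lw_grid <- log(outer(w_theta, w_T))
  h_k <- vapply(grid, prf_fixation_factor, numeric(1))
  G_k <- vapply(grid, prf_polymorphism_factor, numeric(1),
                n = counts_row$n[1])
  a_n <- harmonic_number(counts_row$n[1])
  post <- numeric(length(grid))
  for (k in seq_along(grid)) {
    ll <- outer(thetas, Ts, function(th, Td) {
      stats::dpois(counts_row$D_s, (th / 2) * Td, log = TRUE) +
        stats::dpois(counts_row$D_n, (th / 2) * Td * counts_row$Z_n * h_k[k],
                     log = TRUE) +
        stats::dpois(counts_row$P_s, (th / 2) * a_n, log = TRUE) +
        stats::dpois(counts_row$P_n,
                     (th / 2) * a_n * counts_row$Z_n * G_k[k], log = TRUE)
    })
    ll <- ll + lw_grid
    m <- max(ll)
    post[k] <- exp(m) * sum(exp(ll - m))
  }
  post / sum(post)
}
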