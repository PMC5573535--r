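# The site-model battery: M-series fits and LRTs, Bayesian site detection
# (BEB / REL / FUBAR), multi-method consensus, the episodic-selection test,
# and evolutionary fingerprinting.

#' Fit a codon site model
#'
#' Thin wrapper over [maximize_likelihood()] for the M-series models.
#' M1a fits (p0, omega0 < 1) plus a neutral class; M2a adds (p2,
#' omega2 >= 1); M7 uses a 10-class discretised beta; M8 adds an extra
#' class with omega_s >= 1 on top of the beta classes.
#'
#' @inheritParams maximize_likelihood
#' @export
fit_site_model <- function(aln, tree, model = c("M0", "M1a", "M2a", "M7", "M8"),
                           freq_scheme = c("F3X4", "F61", "equal"),
                           options = list()) {
  model <- match.arg(model)
  freq_scheme <- match.arg(freq_scheme)
  maximize_likelihood(aln, tree, model, freq_scheme, options)
}

#' Likelihood-ratio test between nested site models
#'
#' `2dlnL = 2 (lnL_alt - lnL_null)`, clamped at zero, referred to a
#' chi-square distribution with 2 degrees of freedom (the standard choice
#' for both the M1a/M2a and M7/M8 comparisons).
#'
#' @param fit_null,fit_alt `codon_fit` objects of a nested pair
#'   (M1a in M2a, or M7 in M8; M0 in M2a is also accepted).
#' @return An `lrt_result` tibble: `null_model`, `alt_model`,
#'   `two_delta_lnl`, `df`, `p_value`.
#' @export
likelihood_ratio_test <- function(fit_null, fit_alt) {
  pairs <- list(c("M1a", "M2a"), c("M7", "M8"), c("M0", "M1a"),
                c("M0", "M2a"))
  ok <- any(vapply(pairs, function(p) {
    identical(p, c(fit_null$model, fit_alt$model))
  }, logical(1)))
  if (!ok) {
    stop("models are not a supported nested pair: ", fit_null$model,
         " vs ", fit_alt$model, call. = FALSE)
  }
  df <- if (identical(c(fit_null$model, fit_alt$model), c("M0", "M1a"))) 1L else 2L
  stat <- max(0, 2 * (fit_alt$lnL - fit_null$lnL))
  out <- tibble::tibble(
    null_model = fit_null$model, alt_model = fit_alt$model,
    two_delta_lnl = stat, df = df,
    p_value = stats::pchisq(stat, df, lower.tail = FALSE))
  class(out) <- c("lrt_result", class(out))
  out
}

# ---------------------------------------------------------------------------
# Bayes empirical Bayes

#' Bayes empirical Bayes site posteriors under M8 or M2a
#'
#' Integrates over parameter uncertainty on a uniform grid of 10 values per
#' free distribution parameter (M8: p0, p, q, omega_s; M2a: the class
#' proportions, omega0, omega2), with kappa, codon frequencies and branch
#' lengths fixed at their maximum-likelihood estimates. Reports the
#' posterior probability that each codon belongs to the positive-selection
#' class, flagged at the stated cutoff.
#'
#' @param fit A `codon_fit` for M8 or M2a.
#' @param aln,tree The data the fit was produced from (tree defaults to the
#'   fitted tree).
#' @param cutoff Posterior-probability cutoff for the detection flag.
#' @return A `site_posterior_table` tibble: `codon` (unmasked-gene
#'   numbering), `method`, `posterior`, `omega_mean`, `flag`.
#' @export
beb_posteriors <- function(fit, aln, tree = fit$tree, cutoff = 0.90) {
  if (!fit$model %in% c("M8", "M2a")) {
    stop("BEB requires an M8 or M2a fit, got ", fit$model, call. = FALSE)
  }
  pi <- fit$freqs$pi
  kappa <- fit$kappa
  mids <- (2 * (1:10) - 1) / 20          # midpoints of (0,1)
  w_pos_grid <- 1 + 10 * mids            # midpoints of (1,11)

  if (fit$model == "M8") {
    shape_grid <- 2 * mids               # midpoints of (0,2)
    combos <- expand.grid(p0 = mids, p = shape_grid, q = shape_grid,
                          ws = w_pos_grid)
    class_omegas <- function(row) {
      bm <- discretize_beta(row$p, row$q, 10)
      list(omega = c(bm$omega, row$ws),
           weights = c(row$p0 * bm$weights, 1 - row$p0))
    }
  } else {
    combos <- expand.grid(p0 = mids, p1f = mids, w0 = mids, w2 = w_pos_grid)
    class_omegas <- function(row) {
      p1 <- (1 - row$p0) * row$p1f
      list(omega = c(row$w0, 1, row$w2),
           weights = c(row$p0, p1, 1 - row$p0 - p1))
    }
  }
  specs <- lapply(seq_len(nrow(combos)), function(i) class_omegas(combos[i, ]))
  all_omega <- sort(unique(round(unlist(lapply(specs, `[[`, "omega")), 12)))
  # one pruning pass per distinct omega, shared across the whole grid; the
  # rate normalisation stays at the fitted mixture's scale
  M <- omega_site_logliks(aln, tree, all_omega, pi, kappa,
                          scale = fit_mixture_scale(fit))
  n_sites <- nrow(M)
  log_post <- numeric(length(specs))
  pos_num <- matrix(0, n_sites, length(specs))
  omega_num <- matrix(0, n_sites, length(specs))
  for (g in seq_along(specs)) {
    sp <- specs[[g]]
    idx <- match(round(sp$omega, 12), all_omega)
    Lg <- M[, idx, drop = FALSE]
    mixlog <- log_weighted_sum_exp(Lg, sp$weights)
    log_post[g] <- sum(mixlog)
    n_cl <- length(sp$omega)
    post_c <- exp(Lg - mixlog) * rep(sp$weights, each = n_sites)
    pos_num[, g] <- post_c[, n_cl]
    omega_num[, g] <- post_c %*% sp$omega
  }
  pg <- exp(log_post - max(log_post))
  pg <- pg / sum(pg)
  posterior <- as.numeric(pos_num %*% pg)
  omega_mean <- as.numeric(omega_num %*% pg)
  new_site_posterior_table(fit$site_index, "BEB", posterior,
                           omega_mean = omega_mean,
                           flag = posterior >= cutoff, cutoff = cutoff)
}

# Site log-likelihoods under single-class matrices for a vector of omegas,
# all divided by ONE common scale so relative substitution rates between
# classes are preserved (the branch lengths stay in the units fixed by the
# fitted mixture; fast sites really are fast).
omega_site_logliks <- function(aln, tree, omegas, pi, kappa, scale) {
  parts <- codon_q_parts(kappa, pi)
  Q_list <- lapply(omegas, function(w) {
    Q <- (parts$A + w * parts$B) / scale
    diag(Q) <- -rowSums(Q)
    Q
  })
  class_site_logliks(aln, tree, Q_list, pi)
}

# the stationary-rate normaliser of a fitted mixture, in the same units
# the fit used
fit_mixture_scale <- function(fit) {
  parts <- codon_q_parts(fit$kappa, fit$freqs$pi)
  sum(fit$mix$weights * (parts$rA + fit$mix$omega * parts$rB))
}

new_site_posterior_table <- function(codon, method, posterior,
                                     omega_mean = NA_real_,
                                     bayes_factor = NA_real_, flag,
                                     cutoff) {
  out <- tibble::tibble(codon = codon, method = method,
                        posterior = posterior, omega_mean = omega_mean,
                        bayes_factor = bayes_factor, flag = flag)
  attr(out, "cutoff") <- cutoff
  class(out) <- c("site_posterior_table", class(out))
  out
}

# ---------------------------------------------------------------------------
# general discrete (alpha, beta) mixtures: shared by REL and fingerprinting

gdd_def <- function(k) {
  par <- c(stats::setNames(rep(0, k), paste0("la", 1:k)),
           stats::setNames(log(seq(0.2, 2, length.out = k)), paste0("lb", 1:k)),
           if (k > 1) stats::setNames(rep(0, k - 1), paste0("a", 1:(k - 1))))
  lower <- c(rep(log(1e-3), 2 * k), rep(-10, k - 1))
  upper <- c(rep(log(50), 2 * k), rep(10, k - 1))
  unpack <- function(p) {
    alpha <- exp(p[1:k])
    beta <- exp(p[(k + 1):(2 * k)])
    w <- rep(1, k)
    if (k > 1) {
      stick <- .sig(p[(2 * k + 1):(3 * k - 1)])
      rem <- 1
      for (i in 1:(k - 1)) {
        w[i] <- rem * stick[i]
        rem <- rem - w[i]
      }
      w[k] <- rem
    }
    list(alpha = alpha, beta = beta, w = w)
  }
  list(par = par, lower = lower, upper = upper, unpack = unpack,
       n_free = 3 * k - 2)
}

# ML fit of a k-class general discrete distribution over per-site
# synonymous (alpha) and nonsynonymous (beta) rates, mean rate normalised
# to 1; kappa and branch lengths held fixed.
fit_gdd <- function(aln, tree, k, kappa, pi, n_starts = 2, maxit = 200) {
  parts <- codon_q_parts(kappa, pi)
  def <- gdd_def(k)
  loglik_parts <- function(up) {
    rho <- sum(up$w * (up$alpha * parts$rA + up$beta * parts$rB))
    a <- up$alpha / rho
    b <- up$beta / rho
    Q_list <- Map(function(ai, bi) {
      Q <- ai * parts$A + bi * parts$B
      diag(Q) <- -rowSums(Q)
      Q
    }, a, b)
    M <- class_site_logliks(aln, tree, Q_list, pi)
    list(M = M, alpha = a, beta = b)
  }
  obj <- function(p) {
    up <- def$unpack(stats::setNames(p, names(def$par)))
    ll <- tryCatch(
      sum(log_weighted_sum_exp(loglik_parts(up)$M, up$w)),
      error = function(e) NA_real_)
    if (!is.finite(ll)) 1e10 else -ll
  }
  starts <- list(def$par)
  if (n_starts > 1) {
    starts <- c(starts, lapply(seq_len(n_starts - 1), function(j) {
      s <- def$par
      s[1:k] <- log(seq(0.5, 1.5, length.out = k)) + 0.2 * j
      s[(k + 1):(2 * k)] <- log(seq(0.05, 3 + j, length.out = k))
      s
    }))
  }
  best <- NULL
  for (s in starts) {
    fit <- tryCatch(
      stats::optim(s, obj, method = "L-BFGS-B", lower = def$lower,
                   upper = def$upper,
                   control = list(maxit = maxit, factr = 4.5e7,
                                  ndeps = rep(1e-5, length(s)))),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$value < best$value)) best <- fit
  }
  if (is.null(best)) stop("GDD optimisation failed (k = ", k, ")",
                          call. = FALSE)
  up <- def$unpack(stats::setNames(best$par, names(def$par)))
  lp <- loglik_parts(up)
  list(lnL = -best$value, alpha = lp$alpha, beta = lp$beta, w = up$w,
       class_loglik = lp$M, n_free = def$n_free, k = k)
}

#' Random-effects-likelihood site posteriors
#'
#' Fits a 3-class general discrete distribution over per-site synonymous
#' (alpha) and nonsynonymous (beta) rates by maximum likelihood (mean rate
#' normalised to 1; kappa and branch lengths fixed at the M0 estimates),
#' then assigns each site an empirical-Bayes posterior probability of
#' beta > alpha. The Bayes factor is the posterior odds over the prior
#' odds; sites are flagged at `bf_cutoff` (default 50).
#'
#' @param aln A `codon_aln`.
#' @param tree A `phylo`.
#' @param n_classes Number of (alpha, beta) classes.
#' @param bf_cutoff Bayes-factor detection cutoff.
#' @param m0_fit Optional precomputed M0 `codon_fit` to reuse.
#' @param options Options forwarded to the inner M0 fit.
#' @return A `site_posterior_table` with `posterior` and `bayes_factor`.
#' @export
rel_posteriors <- function(aln, tree, n_classes = 3, bf_cutoff = 50,
                           m0_fit = NULL, options = list()) {
  m0_fit <- m0_fit %||% maximize_likelihood(
    aln, tree, "M0", options = utils::modifyList(list(n_starts = 2), options))
  g <- fit_gdd(aln, m0_fit$tree, n_classes, m0_fit$kappa, m0_fit$freqs$pi,
               n_starts = options$n_starts %||% 2)
  if (length(unique(round(g$beta / g$alpha, 6))) < n_classes) {
    warning("REL classes collapsed to fewer than ", n_classes,
            " distinct dN/dS ratios", call. = FALSE)
  }
  pos <- g$beta > g$alpha
  prior <- sum(g$w[pos])
  n_sites <- nrow(g$class_loglik)
  mixlog <- log_weighted_sum_exp(g$class_loglik, g$w)
  post_c <- exp(g$class_loglik - mixlog) * rep(g$w, each = n_sites)
  posterior <- rowSums(post_c[, pos, drop = FALSE])
  bf <- if (prior <= 0 || prior >= 1) {
    rep(NA_real_, n_sites)
  } else {
    (posterior / pmax(1 - posterior, 1e-12)) / (prior / (1 - prior))
  }
  flag <- !is.na(bf) & bf >= bf_cutoff
  out <- new_site_posterior_table(m0_fit$site_index, "REL", posterior,
                                  omega_mean = as.numeric(
                                    post_c %*% (g$beta / pmax(g$alpha, 1e-8))),
                                  bayes_factor = bf, flag = flag,
                                  cutoff = bf_cutoff)
  attr(out, "classes") <- tibble::tibble(weight = g$w, alpha = g$alpha,
                                         beta = g$beta)
  out
}

# ---------------------------------------------------------------------------
# FUBAR

#' FUBAR-style grid posteriors of diversifying selection
#'
#' Site likelihoods are precomputed on a `grid_size` x `grid_size` lattice
#' of (alpha, beta) synonymous/nonsynonymous rates (quadratically spaced on
#' `[0, rate_max]`), a symmetric Dirichlet(0.5) prior is placed on the
#' lattice weights, and the weights are Gibbs-sampled (site allocations by
#' Gumbel-max categorical draws, weights by conjugate Dirichlet updates).
#' The reported per-site posterior `P(beta > alpha)` averages the
#' allocation posterior over the retained weight draws; sites are flagged
#' at `cutoff`.
#'
#' @param aln A `codon_aln`.
#' @param tree A `phylo`.
#' @param grid_size Lattice points per axis.
#' @param rate_max Upper end of the rate lattice.
#' @param iterations,burnin,thin,chains MCMC settings per chain.
#' @param cutoff Posterior cutoff for the detection flag.
#' @param seed Mandatory integer seed.
#' @param m0_fit Optional precomputed M0 fit (kappa, branch lengths,
#'   frequencies are taken from it).
#' @param options Options forwarded to the inner M0 fit.
#' @return A `site_posterior_table`; attribute `"diagnostics"` carries the
#'   split R-hat of the mean positive-selection posterior.
#' @export
fubar_posteriors <- function(aln, tree, grid_size = 20, rate_max = 50,
                             iterations = 2500, burnin = 500, thin = 5,
                             chains = 2, cutoff = 0.90, seed,
                             m0_fit = NULL, options = list()) {
  stopifnot(!missing(seed))
  m0_fit <- m0_fit %||% maximize_likelihood(
    aln, tree, "M0", options = utils::modifyList(list(n_starts = 2), options))
  vals <- (seq(0, 1, length.out = grid_size))^2 * rate_max
  lattice <- expand.grid(alpha = vals, beta = vals)
  L <- ab_site_logliks(aln, m0_fit$tree, lattice$alpha, lattice$beta,
                       m0_fit$freqs$pi, m0_fit$kappa)
  n_sites <- nrow(L)
  G <- nrow(lattice)
  pos <- lattice$beta > lattice$alpha
  Lmax <- apply(L, 1, max)
  Lexp <- exp(L - Lmax)

  run_chain <- function(chain_seed) {
    set.seed(chain_seed)
    w <- rep(1 / G, G)
    acc <- matrix(0, n_sites, 2)  # cumulative (positive mass, draws)
    trace <- numeric(0)
    for (it in seq_len(iterations)) {
      # Gumbel-max categorical draw; ties.method = "first" because
      # max.col's "random" method treats values within a relative
      # tolerance of the row range as tied, which corrupts the draw when
      # some cells have ~zero likelihood (Gumbel ties have measure zero)
      noise <- -log(-log(matrix(stats::runif(n_sites * G), n_sites, G)))
      z <- max.col(sweep(L, 2, log(w), "+") + noise, ties.method = "first")
      cnt <- tabulate(z, nbins = G)
      gd <- stats::rgamma(G, shape = 0.5 + cnt, rate = 1)
      w <- gd / sum(gd)
      if (it > burnin && (it - burnin) %% thin == 0L) {
        num <- Lexp[, pos, drop = FALSE] %*% w[pos]
        den <- Lexp %*% w
        ps <- as.numeric(num / den)
        acc[, 1] <- acc[, 1] + ps
        acc[, 2] <- acc[, 2] + 1
        trace <- c(trace, mean(ps))
      }
    }
    list(post = acc[, 1] / acc[, 2], trace = trace)
  }
  runs <- lapply(seed + 1000L * (seq_len(chains) - 1L), run_chain)
  posterior <- rowMeans(do.call(cbind, lapply(runs, `[[`, "post")))
  rhat <- split_rhat(lapply(runs, `[[`, "trace"))
  if (is.finite(rhat) && rhat > 1.1) {
    warning("FUBAR weight chains may not have converged (R-hat = ",
            round(rhat, 3), ")", call. = FALSE)
  }
  out <- new_site_posterior_table(m0_fit$site_index, "FUBAR", posterior,
                                  flag = posterior >= cutoff,
                                  cutoff = cutoff)
  attr(out, "diagnostics") <- tibble::tibble(parameter = "mean_pos_posterior",
                                             rhat = rhat)
  attr(out, "lattice") <- tibble::as_tibble(lattice)
  out
}

# ---------------------------------------------------------------------------
# consensus

#' Consensus of site-detection methods
#'
#' A codon is a consensus positive-selection target when it is flagged by
#' at least `min_methods` of the supplied method tables; the strict set
#' requires every supplied method.
#'
#' @param tables List of `site_posterior_table` objects on the same codon
#'   coordinates.
#' @param min_methods Minimum number of agreeing methods.
#' @return A `consensus_report`: `table` (per-codon method flags and
#'   tally), `consensus` and `strict` codon vectors, and the cutoffs used.
#' @export
consensus_sites <- function(tables, min_methods = 2) {
  stopifnot(length(tables) >= 1)
  codons <- tables[[1]]$codon
  for (tb in tables[-1]) {
    if (!identical(tb$codon, codons)) {
      stop("site tables are on different codon coordinates", call. = FALSE)
    }
  }
  methods <- vapply(tables, function(tb) tb$method[1], character(1))
  flags <- do.call(cbind, lapply(tables, `[[`, "flag"))
  colnames(flags) <- methods
  tally <- rowSums(flags)
  consensus <- if (length(tables) >= min_methods) {
    codons[tally >= min_methods]
  } else {
    integer(0)
  }
  strict <- codons[tally == length(tables)]
  structure(
    list(table = tibble::as_tibble(cbind(tibble::tibble(codon = codons),
                                         tibble::as_tibble(flags),
                                         tibble::tibble(n_methods = tally))),
         consensus = consensus, strict = strict,
         min_methods = min_methods,
         cutoffs = stats::setNames(
           vapply(tables, function(tb) attr(tb, "cutoff"), numeric(1)),
           methods)),
    class = "consensus_report"
  )
}

#' @export
print.consensus_report <- function(x, ...) {
  cat("<consensus_report> ", length(x$consensus), " consensus sites (>= ",
      x$min_methods, " methods), ", length(x$strict),
      " by all methods\n", sep = "")
  invisible(x)
}

# ---------------------------------------------------------------------------
# BUSTED-style episodic test

busted_def <- function(constrained) {
  par <- c(lk = log(2), a0 = .logit(0.7), a1 = .logit(0.7),
           b2 = .logit(0.8), bv = .logit(0.3))
  lower <- c(log(0.1), -15, -15, -15, -15)
  upper <- c(log(20), 15, 15, 15, 15)
  if (!constrained) {
    par <- c(par, t3 = log(1))
    lower <- c(lower, log(1e-6))
    upper <- c(upper, log(49))
  }
  unpack <- function(p) {
    w2 <- .sig(p[["b2"]])
    w1 <- w2 * .sig(p[["bv"]])
    p1 <- .sig(p[["a0"]])
    p2 <- (1 - p1) * .sig(p[["a1"]])
    p3 <- 1 - p1 - p2
    w3 <- if (constrained) 1 else 1 + exp(p[["t3"]])
    list(kappa = exp(p[["lk"]]),
         mix = mixture_spec(c(p1, p2, p3), c(w1, w2, w3)))
  }
  list(par = par, lower = lower, upper = upper, unpack = unpack)
}

#' Episodic diversifying-selection test
#'
#' Gene-level test for a fraction of sites evolving with omega > 1
#' (foreground = all branches): an unconstrained 3-class omega
#' distribution (omega1 <= omega2 <= 1 <= omega3) is compared against the
#' null with omega3 = 1 by a likelihood-ratio test. The p-value uses an
#' equal-weights mixture of chi-square(0), chi-square(1) and chi-square(2)
#' for the boundary problem; `null_dist = "chisq2"` gives the conservative
#' plain chi-square(2) alternative.
#'
#' @param aln A `codon_aln`.
#' @param tree A `phylo`.
#' @param null_dist Reference distribution for the LRT.
#' @param m0_fit Optional precomputed M0 fit providing branch lengths and
#'   frequencies.
#' @param options List: `n_starts` (default 2) and inner M0 options.
#' @return A `busted_result`: `lnl_unconstrained`, `lnl_constrained`,
#'   `classes` (tibble weight/omega of the unconstrained fit), `statistic`,
#'   `p_value`.
#' @export
busted_test <- function(aln, tree, null_dist = c("mixture", "chisq2"),
                        m0_fit = NULL, options = list()) {
  null_dist <- match.arg(null_dist)
  n_starts <- options$n_starts %||% 2
  m0_fit <- m0_fit %||% maximize_likelihood(
    aln, tree, "M0",
    options = utils::modifyList(list(n_starts = 2), options))
  pi <- m0_fit$freqs$pi
  tr <- m0_fit$tree

  fit_one <- function(constrained) {
    def <- busted_def(constrained)
    obj <- function(p) {
      up <- def$unpack(stats::setNames(p, names(def$par)))
      ll <- tryCatch(
        sum(mixture_site_likelihoods(aln, tr, up$mix, pi, up$kappa)$site_loglik),
        error = function(e) NA_real_)
      if (!is.finite(ll)) 1e10 else -ll
    }
    starts <- list(def$par)
    if (n_starts > 1) {
      starts <- c(starts, lapply(seq_len(n_starts - 1), function(j) {
        s <- def$par
        s[["b2"]] <- .logit(min(0.95, 0.3 + 0.2 * j))
        s[["a0"]] <- .logit(max(0.05, 0.9 - 0.2 * j))
        if (!constrained) s[["t3"]] <- log(1 + 2 * j)
        s
      }))
    }
    best <- NULL
    for (s in starts) {
      fit <- tryCatch(
        stats::optim(s, obj, method = "L-BFGS-B", lower = def$lower,
                     upper = def$upper,
                     control = list(maxit = 300, factr = 4.5e7,
                                    ndeps = rep(1e-5, length(s)))),
        error = function(e) NULL)
      if (!is.null(fit) && (is.null(best) || fit$value < best$value)) {
        best <- fit
      }
    }
    if (is.null(best)) stop("episodic-test optimisation failed", call. = FALSE)
    up <- def$unpack(stats::setNames(best$par, names(def$par)))
    list(lnL = -best$value, mix = up$mix, kappa = up$kappa)
  }

  alt <- fit_one(constrained = FALSE)
  null <- fit_one(constrained = TRUE)
  # enforce nesting numerically: the alt space contains the null optimum
  lnl_alt <- max(alt$lnL, null$lnL)
  stat <- max(0, 2 * (lnl_alt - null$lnL))
  p <- if (stat <= 0) {
    1
  } else if (null_dist == "mixture") {
    (stats::pchisq(stat, 1, lower.tail = FALSE) +
       stats::pchisq(stat, 2, lower.tail = FALSE)) / 3
  } else {
    stats::pchisq(stat, 2, lower.tail = FALSE)
  }
  ord <- order(alt$mix$omega)
  structure(
    list(lnl_unconstrained = lnl_alt, lnl_constrained = null$lnL,
         classes = tibble::tibble(weight = alt$mix$weights[ord],
                                  omega = alt$mix$omega[ord]),
         statistic = stat, p_value = p, null_dist = null_dist,
         kappa = alt$kappa),
    class = "busted_result"
  )
}

#' @export
print.busted_result <- function(x, ...) {
  cat("<busted_result> LRT = ", round(x$statistic, 3), ", p = ",
      format(x$p_value, digits = 4), " (", x$null_dist, ")\n", sep = "")
  print(x$classes)
  invisible(x)
}

# ---------------------------------------------------------------------------
# evolutionary fingerprinting

#' Evolutionary fingerprint of site rate classes
#'
#' Partitions sites into k classes of (synonymous alpha, nonsynonymous
#' beta) rates by fitting general discrete bivariate mixtures for
#' k = 1..k_max (mean rate normalised to 1, kappa and branch lengths fixed
#' at M0 estimates) and selecting k by small-sample AIC (AICc with n = the
#' number of codons). Classes with negligible weight are pruned from the
#' report.
#'
#' @param aln A `codon_aln`.
#' @param tree A `phylo`.
#' @param k_max Largest class count scanned.
#' @param m0_fit Optional precomputed M0 fit.
#' @param options List: `n_starts` for the mixture fits.
#' @return A `fingerprint_result`: `k`, `classes` (tibble `weight`,
#'   `alpha`, `beta`, `dnds`), `criterion` (AICc trace over k), `lnL`.
#' @export
evolutionary_fingerprint <- function(aln, tree, k_max = 5, m0_fit = NULL,
                                     options = list()) {
  m0_fit <- m0_fit %||% maximize_likelihood(
    aln, tree, "M0",
    options = utils::modifyList(list(n_starts = 2), options))
  n <- aln$n_codons
  fits <- vector("list", k_max)
  aicc <- rep(NA_real_, k_max)
  for (k in seq_len(k_max)) {
    fits[[k]] <- fit_gdd(aln, m0_fit$tree, k, m0_fit$kappa, m0_fit$freqs$pi,
                         n_starts = options$n_starts %||% 2)
    m <- fits[[k]]$n_free
    if (n - m - 1 > 0) {
      aicc[k] <- -2 * fits[[k]]$lnL + 2 * m + 2 * m * (m + 1) / (n - m - 1)
    }
  }
  k_best <- which.min(aicc)
  f <- fits[[k_best]]
  keep <- f$w > 1e-3
  classes <- tibble::tibble(weight = f$w[keep], alpha = f$alpha[keep],
                            beta = f$beta[keep],
                            dnds = f$beta[keep] / f$alpha[keep]) |>
    dplyr::arrange(.data$dnds)
  structure(
    list(k = sum(keep), classes = classes,
         criterion = tibble::tibble(k = seq_len(k_max), aicc = aicc),
         lnL = f$lnL),
    class = "fingerprint_result"
  )
}

#' @export
print.fingerprint_result <- function(x, ...) {
  cat("<fingerprint_result>", x$k, "rate classes | lnL =",
      format(x$lnL, digits = 10), "\n")
  print(x$classes)
  invisible(x)
}
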