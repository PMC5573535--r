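# Shared numerical core: GY94-style codon rate matrices, per-site class
# likelihoods via the pruning algorithm (C++ backend), and bounded
# quasi-Newton maximum-likelihood fitting with deterministic multi-start.

# Synonymous (A) and nonsynonymous (B) parts of the unnormalised rate
# matrix: q_ij = pi_j * kappa^[transition] for single-nucleotide changes,
# zero otherwise. r1 is the stationary rate of A + B (the omega = 1 matrix).
codon_q_parts <- function(kappa, pi) {
  pr <- codon_pairs()
  base <- matrix(0, 61, 61)
  base[pr$single] <- 1
  base[pr$transition] <- kappa
  base <- sweep(base, 2, pi, "*")
  A <- base
  A[!pr$synonymous] <- 0
  B <- base - A
  list(A = A, B = B,
       rA = sum(pi * rowSums(A)), rB = sum(pi * rowSums(B)))
}

#' Build a GY94-style codon substitution rate matrix
#'
#' Off-diagonal rates are `pi_j`, times `kappa` for transitions, times
#' `omega` for nonsynonymous changes; codons differing at more than one
#' position get rate zero. The matrix satisfies detailed balance
#' `pi_i q_ij = pi_j q_ji` and is normalised (by default) so the expected
#' substitution rate at stationarity is 1, putting branch lengths in
#' expected substitutions per codon.
#'
#' @param kappa Transition/transversion rate ratio (> 0).
#' @param omega Nonsynonymous/synonymous rate ratio dN/dS (>= 0).
#' @param pi A `codon_freqs` object or a vector of 61 sense-codon weights.
#' @param normalize Divide by the stationary rate so it equals 1.
#' @return A `codon_rates` object: `Q` (61 x 61), `kappa`, `omega`, `pi`,
#'   and `scale`, the stationary rate of the unnormalised matrix.
#' @export
build_codon_rate_matrix <- function(kappa, omega, pi, normalize = TRUE) {
  if (inherits(pi, "codon_freqs")) pi <- pi$pi
  stopifnot(is.finite(kappa), kappa > 0, is.finite(omega), omega >= 0,
            length(pi) == 61, all(is.finite(pi)), all(pi > 0))
  pi <- pi / sum(pi)
  parts <- codon_q_parts(kappa, pi)
  Q <- parts$A + omega * parts$B
  diag(Q) <- -rowSums(Q)
  scale <- -sum(pi * diag(Q))
  if (normalize) Q <- Q / scale
  structure(list(Q = Q, kappa = kappa, omega = omega, pi = pi,
                 scale = scale),
            class = "codon_rates")
}

# Eigen-factorisation of a reversible Q through its symmetrised form,
# so transition probabilities are exp(Qt) = U diag(exp(dt)) Ui.
codon_eigen <- function(Q, pi) {
  sp <- sqrt(pi)
  B <- Q * (sp %o% (1 / sp))
  B <- (B + t(B)) / 2
  e <- eigen(B, symmetric = TRUE)
  list(U = e$vectors / sp, Ui = t(e$vectors * sp), d = e$values)
}

#' Transition probability matrix exp(Qt)
#' @param rates A `codon_rates` object.
#' @param t Branch length (>= 0).
#' @return A 61 x 61 stochastic matrix.
#' @export
transition_probabilities <- function(rates, t) {
  eg <- codon_eigen(rates$Q, rates$pi)
  P <- eg$U %*% (exp(eg$d * t) * eg$Ui)
  P[P < 0] <- 0
  P
}

# Per-site log-likelihood under each rate matrix in Q_list (shared pi).
class_site_logliks <- function(aln, tree, Q_list, pi) {
  check_taxa(aln, tree)
  po <- stats::reorder(tree, "postorder")
  ts <- aln$states[match(po$tip.label, aln$taxa), , drop = FALSE]
  ts[is.na(ts)] <- 0L
  storage.mode(ts) <- "integer"
  edge <- po$edge
  storage.mode(edge) <- "integer"
  eigs <- lapply(Q_list, codon_eigen, pi = pi)
  M <- cpp_pruning_logliks(edge, po$edge.length, length(po$tip.label),
                           length(po$tip.label) + po$Nnode, ts,
                           lapply(eigs, `[[`, "U"),
                           lapply(eigs, `[[`, "Ui"),
                           lapply(eigs, `[[`, "d"), pi)
  if (any(is.nan(M))) stop("non-finite site likelihood", call. = FALSE)
  # a class can assign probability zero to a site (e.g. a zero-rate class
  # with a variable column); keep it finite so mixture weights handle it
  M[M == -Inf] <- -1e8
  M
}

#' A site-class mixture specification
#'
#' @param weights Class weights on the simplex (sum to 1 within 1e-10).
#' @param omega Per-class dN/dS values (>= 0), same length as `weights`.
#' @return A `mixture_spec`.
#' @export
mixture_spec <- function(weights, omega) {
  stopifnot(length(weights) == length(omega),
            all(weights >= 0), all(weights <= 1),
            abs(sum(weights) - 1) < 1e-10, all(omega >= 0))
  structure(list(weights = weights, omega = omega), class = "mixture_spec")
}

#' @export
print.mixture_spec <- function(x, ...) {
  cat("<mixture_spec>", length(x$weights), "classes\n")
  print(tibble::tibble(weight = x$weights, omega = x$omega))
  invisible(x)
}

#' Discretise a beta distribution into equal-weight classes
#'
#' Used by the M7/M8 site models: `K` classes of weight `1/K`, each
#' represented by the conditional mean of the beta distribution within its
#' equal-probability bin (closed form through the regularised incomplete
#' beta function). A `"median"` representative (the bin midpoint quantile)
#' is available as a documented switch.
#'
#' @param p,q Beta shape parameters (> 0).
#' @param K Number of classes (>= 2).
#' @param representative `"mean"` (default) or `"median"`.
#' @return A [mixture_spec()] with `K` equal weights.
#' @export
discretize_beta <- function(p, q, K = 10, representative = c("mean", "median")) {
  representative <- match.arg(representative)
  stopifnot(p > 0, q > 0, K >= 2)
  # qbeta warns about its own tolerance at extreme shapes; bin edges only
  # need ~1e-6 accuracy here
  edges <- suppressWarnings(stats::qbeta((0:K) / K, p, q))
  omega <- if (representative == "mean") {
    (p / (p + q)) * K *
      (stats::pbeta(edges[-1], p + 1, q) - stats::pbeta(edges[-(K + 1)], p + 1, q))
  } else {
    stats::qbeta(((1:K) - 0.5) / K, p, q)
  }
  mixture_spec(rep(1 / K, K), pmin(pmax(omega, 0), 1))
}

#' Per-site likelihoods under a site-class mixture
#'
#' Computes, by the pruning algorithm, the per-site likelihood
#' `sum_c w_c P(site | omega_c)` in log space. Rate matrices share `kappa`
#' and are normalised so the mixture-averaged substitution rate is 1,
#' keeping branch lengths comparable across models.
#'
#' @param aln A `codon_aln`.
#' @param tree A `phylo` with branch lengths in substitutions per codon.
#' @param mix A [mixture_spec()].
#' @param pi A `codon_freqs` (or 61 weights).
#' @param kappa Transition/transversion ratio.
#' @return A list: `site_loglik` (length n_codons), `class_loglik`
#'   (n_codons x n_classes matrix of per-class log-likelihoods), `mix`,
#'   `scale` (the common normaliser).
#' @export
mixture_site_likelihoods <- function(aln, tree, mix, pi, kappa) {
  if (inherits(pi, "codon_freqs")) pi <- pi$pi
  parts <- codon_q_parts(kappa, pi)
  rates_c <- parts$rA + mix$omega * parts$rB
  S <- sum(mix$weights * rates_c)
  Q_list <- lapply(mix$omega, function(w) {
    Q <- (parts$A + w * parts$B) / S
    diag(Q) <- -rowSums(Q)
    Q
  })
  M <- class_site_logliks(aln, tree, Q_list, pi)
  list(site_loglik = log_weighted_sum_exp(M, mix$weights),
       class_loglik = M, mix = mix, scale = S)
}

# Per-site likelihoods for (alpha, beta) synonymous/nonsynonymous rate
# classes (REL / FUBAR / fingerprinting). Matrices are scaled relative to
# the alpha = beta = 1 matrix having rate 1; set normalize_mean to rescale
# so the mixture-average rate is 1.
ab_site_logliks <- function(aln, tree, alpha, beta, pi, kappa,
                            weights = NULL, normalize_mean = FALSE) {
  if (inherits(pi, "codon_freqs")) pi <- pi$pi
  parts <- codon_q_parts(kappa, pi)
  r1 <- parts$rA + parts$rB
  sc <- r1
  if (normalize_mean) {
    stopifnot(!is.null(weights))
    sc <- sum(weights * (alpha * parts$rA + beta * parts$rB))
  }
  Q_list <- Map(function(a, b) {
    Q <- (a * parts$A + b * parts$B) / sc
    diag(Q) <- -rowSums(Q)
    Q
  }, alpha, beta)
  class_site_logliks(aln, tree, Q_list, pi)
}

log_weighted_sum_exp <- function(M, w) {
  lw <- log(w)
  X <- sweep(M, 2, lw, "+")
  m <- apply(X, 1, max)
  m + log(rowSums(exp(X - m)))
}

# ---------------------------------------------------------------------------
# Model parameterisations. Free parameters live on unconstrained scales
# (logs, logits, stick-breaking) inside a box; bounds follow the documented
# conventions omega in [1e-4, 50], kappa in [0.1, 20].

.sig <- function(x) 1 / (1 + exp(-x))
.logit <- function(p) log(p / (1 - p))

model_def <- function(model, K = 10) {
  switch(model,
    M0 = list(
      par = c(lk = log(2), lw = log(0.3)),
      lower = c(log(0.1), log(1e-4)), upper = c(log(20), log(50)),
      starts = list(c(log(2), log(0.3)), c(log(1), log(1)),
                    c(log(4), log(0.1)), c(log(2), log(2)),
                    c(log(8), log(0.05))),
      unpack = function(par) {
        list(kappa = exp(par[["lk"]]),
             mix = mixture_spec(1, exp(par[["lw"]])),
             est = list(omega = exp(par[["lw"]])))
      },
      n_free = 2
    ),
    M1a = list(
      par = c(lk = log(2), a0 = .logit(0.7), b0 = .logit(0.1)),
      lower = c(log(0.1), -15, -15), upper = c(log(20), 15, 15),
      starts = list(c(log(2), .logit(0.7), .logit(0.1)),
                    c(log(2), .logit(0.5), .logit(0.3)),
                    c(log(4), .logit(0.9), .logit(0.05)),
                    c(log(1), .logit(0.3), .logit(0.5)),
                    c(log(8), .logit(0.8), .logit(0.02))),
      unpack = function(par) {
        p0 <- .sig(par[["a0"]]); w0 <- .sig(par[["b0"]])
        list(kappa = exp(par[["lk"]]),
             mix = mixture_spec(c(p0, 1 - p0), c(w0, 1)),
             est = list(p0 = p0, p1 = 1 - p0, omega0 = w0))
      },
      n_free = 3
    ),
    M2a = list(
      par = c(lk = log(2), a0 = .logit(0.7), a1 = .logit(0.7),
              b0 = .logit(0.1), t2 = log(1)),
      lower = c(log(0.1), -15, -15, -15, log(1e-6)),
      upper = c(log(20), 15, 15, 15, log(49)),
      starts = list(
        c(log(2), .logit(0.7), .logit(0.7), .logit(0.1), log(1)),
        c(log(2), .logit(0.5), .logit(0.9), .logit(0.3), log(4)),
        c(log(4), .logit(0.85), .logit(0.5), .logit(0.05), log(0.5)),
        c(log(1), .logit(0.6), .logit(0.95), .logit(0.2), log(9)),
        c(log(8), .logit(0.8), .logit(0.3), .logit(0.02), log(2))),
      unpack = function(par) {
        p0 <- .sig(par[["a0"]]); p1 <- (1 - p0) * .sig(par[["a1"]])
        p2 <- 1 - p0 - p1
        w0 <- .sig(par[["b0"]]); w2 <- 1 + exp(par[["t2"]])
        list(kappa = exp(par[["lk"]]),
             mix = mixture_spec(c(p0, p1, p2), c(w0, 1, w2)),
             est = list(p0 = p0, p1 = p1, p2 = p2, omega0 = w0, omega2 = w2))
      },
      n_free = 5
    ),
    M7 = list(
      par = c(lk = log(2), lp = log(0.5), lq = log(1)),
      lower = c(log(0.1), log(0.02), log(0.02)),
      upper = c(log(20), log(50), log(50)),
      starts = list(c(log(2), log(0.5), log(1)), c(log(2), log(1), log(1)),
                    c(log(4), log(0.2), log(2)), c(log(1), log(2), log(0.5)),
                    c(log(8), log(5), log(5))),
      unpack = function(par, K. = K) {
        p <- exp(par[["lp"]]); q <- exp(par[["lq"]])
        list(kappa = exp(par[["lk"]]),
             mix = discretize_beta(p, q, K = K.),
             est = list(p = p, q = q))
      },
      n_free = 3
    ),
    M8 = list(
      par = c(lk = log(2), a0 = .logit(0.9), lp = log(0.5), lq = log(1),
              ts = log(1)),
      lower = c(log(0.1), -15, log(0.02), log(0.02), log(1e-6)),
      upper = c(log(20), 15, log(50), log(50), log(49)),
      starts = list(
        c(log(2), .logit(0.9), log(0.5), log(1), log(1)),
        c(log(2), .logit(0.7), log(1), log(1), log(4)),
        c(log(4), .logit(0.95), log(0.2), log(2), log(0.5)),
        c(log(1), .logit(0.8), log(2), log(0.5), log(9)),
        c(log(8), .logit(0.99), log(5), log(5), log(2))),
      unpack = function(par, K. = K) {
        p0 <- .sig(par[["a0"]])
        p <- exp(par[["lp"]]); q <- exp(par[["lq"]])
        ws <- 1 + exp(par[["ts"]])
        bmix <- discretize_beta(p, q, K = K.)
        list(kappa = exp(par[["lk"]]),
             mix = mixture_spec(c(p0 * bmix$weights, 1 - p0),
                                c(bmix$omega, ws)),
             est = list(p0 = p0, p = p, q = q, omega_s = ws))
      },
      n_free = 5
    ),
    stop("unknown model: ", model, call. = FALSE)
  )
}

# Initial branch lengths: keep supplied positive lengths; otherwise
# least-squares lengths from pairwise ML nucleotide distances.
init_branch_lengths <- function(aln, tree) {
  if (!is.null(tree$edge.length) && all(tree$edge.length > 0)) return(tree)
  code <- genetic_code()
  chars <- lapply(seq_along(aln$taxa), function(i) {
    cds <- ifelse(is.na(aln$states[i, ]), "---",
                  code$sense[aln$states[i, ]])
    tolower(strsplit(paste(cds, collapse = ""), "")[[1]])
  })
  names(chars) <- aln$taxa
  dna <- ape::as.DNAbin(chars)
  dm <- suppressWarnings(ape::dist.dna(dna, model = "F84",
                                       pairwise.deletion = TRUE)) * 3
  dm[!is.finite(dm)] <- max(dm[is.finite(dm)], 1)
  tr <- phangorn::nnls.tree(dm, tree, method = "unrooted")
  tr$edge.length <- pmax(tr$edge.length, 1e-4)
  tr
}

#' Maximum-likelihood fit of a codon site model
#'
#' Fits M0, M1a, M2a, M7 or M8 by bounded quasi-Newton (L-BFGS-B)
#' optimisation with deterministic multi-start. By default, branch lengths
#' are estimated jointly under M0 and held fixed for the site models
#' (`branch_mode = "m0"`); alternatives are `"full"` (joint optimisation of
#' every branch), `"scale"` (one common scale factor on the initial
#' lengths), and `"fixed"` (use the tree as given).
#'
#' @param aln A `codon_aln` (masked if applicable).
#' @param tree A `phylo`; taxa must match the alignment.
#' @param model One of `"M0"`, `"M1a"`, `"M2a"`, `"M7"`, `"M8"`.
#' @param freq_scheme `"F3X4"`, `"F61"` or `"equal"`.
#' @param options List of optional settings: `n_starts` (default 5),
#'   `branch_mode` (default `"full"` for M0, `"m0"` otherwise),
#'   `m0_branch_mode` (branch mode of the inner M0 fit, default `"full"`),
#'   `K` (beta classes, default 10), `maxit`, `freqs` (a precomputed
#'   `codon_freqs`).
#' @return A `codon_fit`: `model`, `lnL`, `kappa`, `mix` (fitted
#'   [mixture_spec()]), `est` (named estimates), `tree` (with the branch
#'   lengths used), `freqs`, `convergence` (per-start log-likelihoods and
#'   optimiser status), `site_index`, `n_codons`.
#' @export
maximize_likelihood <- function(aln, tree, model, freq_scheme = "F3X4",
                                options = list()) {
  opt <- utils::modifyList(
    list(n_starts = 5,
         branch_mode = if (model == "M0") "full" else "m0",
         m0_branch_mode = "full", K = 10, maxit = 300, freqs = NULL,
         warm_start = NULL, factr = 4.5e7),
    options)
  check_taxa(aln, tree)
  freqs <- opt$freqs %||% estimate_codon_frequencies(aln, freq_scheme)
  pi <- freqs$pi

  m0_fit <- NULL
  if (model != "M0" && opt$branch_mode == "m0") {
    m0_fit <- maximize_likelihood(
      aln, tree, "M0", freq_scheme,
      options = list(n_starts = min(opt$n_starts, 3),
                     branch_mode = opt$m0_branch_mode,
                     maxit = opt$maxit, freqs = freqs))
    tree <- m0_fit$tree
    bl_mode <- "fixed"
  } else {
    bl_mode <- opt$branch_mode
  }

  tree <- init_branch_lengths(aln, tree)
  def <- model_def(model, K = opt$K)
  n_model <- length(def$par)
  n_edge <- nrow(tree$edge)
  init_len <- tree$edge.length

  bl_par <- switch(bl_mode,
    fixed = numeric(0),
    scale = c(lbs = 0),
    full = stats::setNames(log(pmax(init_len, 1e-5)),
                           paste0("lbl", seq_len(n_edge))))
  bl_lower <- switch(bl_mode, fixed = numeric(0), scale = -5,
                     full = rep(log(1e-6), n_edge))
  bl_upper <- switch(bl_mode, fixed = numeric(0), scale = 5,
                     full = rep(log(10), n_edge))

  edge_lengths <- function(par) {
    switch(bl_mode,
      fixed = init_len,
      scale = init_len * exp(par[n_model + 1]),
      full = exp(par[(n_model + 1):(n_model + n_edge)]))
  }
  obj <- function(par) {
    up <- def$unpack(stats::setNames(par[seq_len(n_model)], names(def$par)))
    tr <- tree
    tr$edge.length <- edge_lengths(par)
    ll <- tryCatch(
      sum(mixture_site_likelihoods(aln, tr, up$mix, pi, up$kappa)$site_loglik),
      error = function(e) NA_real_)
    if (!is.finite(ll)) 1e10 else -ll
  }

  starts <- def$starts[seq_len(min(opt$n_starts, length(def$starts)))]
  if (!is.null(opt$warm_start)) {
    ws <- warm_start_par(model, opt$warm_start)
    if (!is.null(ws)) starts <- c(list(ws), starts[-length(starts)])
  }
  lower <- c(def$lower, bl_lower)
  upper <- c(def$upper, bl_upper)
  best <- NULL
  lnl_starts <- numeric(0)
  for (s in starts) {
    par0 <- pmin(pmax(c(s, bl_par), lower), upper)
    fit <- tryCatch(
      stats::optim(par0, obj, method = "L-BFGS-B", lower = lower,
                   upper = upper,
                   control = list(maxit = opt$maxit, factr = opt$factr,
                                  ndeps = rep(1e-5, length(par0)))),
      error = function(e) NULL)
    if (is.null(fit)) next
    lnl_starts <- c(lnl_starts, -fit$value)
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best)) {
    stop("optimisation failed for every start of model ", model,
         call. = FALSE)
  }

  up <- def$unpack(stats::setNames(best$par[seq_len(n_model)],
                                   names(def$par)))
  out_tree <- tree
  out_tree$edge.length <- edge_lengths(best$par)
  structure(
    list(model = model, lnL = -best$value, kappa = up$kappa, mix = up$mix,
         est = up$est, tree = out_tree, freqs = freqs,
         convergence = list(n_starts = length(lnl_starts),
                            lnl_starts = lnl_starts,
                            status = best$convergence,
                            message = best$message,
                            branch_mode = bl_mode),
         m0_fit = m0_fit, n_codons = aln$n_codons,
         site_index = aln$site_index, n_free = def$n_free),
    class = "codon_fit"
  )
}

#' @export
print.codon_fit <- function(x, ...) {
  cat("<codon_fit> ", x$model, " | lnL = ", format(x$lnL, digits = 10),
      " | kappa = ", round(x$kappa, 3), "\n", sep = "")
  print(tibble::tibble(weight = x$mix$weights, omega = x$mix$omega))
  invisible(x)
}

#' @export
logLik.codon_fit <- function(object, ...) {
  structure(object$lnL, df = object$n_free, class = "logLik")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Start vector for an alternative model at its nested null's optimum
# (selection-class weight ~ 0): makes lnL(alt) >= lnL(null) hold
# numerically and speeds up fits when the null is true.
warm_start_par <- function(model, fit) {
  eps <- 1e-4
  clamp01 <- function(p) pmin(pmax(p, 1e-6), 1 - 1e-6)
  if (model == "M2a" && fit$model == "M1a") {
    p0 <- clamp01(fit$est$p0 * (1 - eps))
    p1 <- clamp01(fit$est$p1 * (1 - eps))
    c(lk = log(fit$kappa), a0 = .logit(p0),
      a1 = .logit(clamp01(p1 / (1 - p0))),
      b0 = .logit(clamp01(fit$est$omega0)), t2 = log(eps))
  } else if (model == "M8" && fit$model == "M7") {
    c(lk = log(fit$kappa), a0 = .logit(1 - eps),
      lp = log(fit$est$p), lq = log(fit$est$q), ts = log(eps))
  } else {
    NULL
  }
}
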