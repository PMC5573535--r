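# broom-style tidiers and ggplot2 autoplot methods for the result objects.

#' @importFrom rlang .data
NULL

#' Tidy a fitted codon site model
#'
#' One row per site class with its weight and dN/dS.
#' @param x A `codon_fit`.
#' @param ... Unused.
#' @export
tidy.codon_fit <- function(x, ...) {
  tibble::tibble(model = x$model, class = seq_along(x$mix$weights),
                 weight = x$mix$weights, omega = x$mix$omega)
}

#' @rdname tidy.codon_fit
#' @export
glance.codon_fit <- function(x, ...) {
  tibble::tibble(model = x$model, logLik = x$lnL, kappa = x$kappa,
                 n_free = x$n_free, n_codons = x$n_codons,
                 freq_scheme = x$freqs$scheme,
                 prop_positive = sum(x$mix$weights[x$mix$omega > 1]),
                 convergence = x$convergence$status)
}

#' @export
tidy.lrt_result <- function(x, ...) tibble::as_tibble(x)

#' @export
tidy.site_posterior_table <- function(x, ...) tibble::as_tibble(x)

#' @export
glance.site_posterior_table <- function(x, ...) {
  tibble::tibble(method = x$method[1], cutoff = attr(x, "cutoff"),
                 n_sites = nrow(x), n_flagged = sum(x$flag))
}

#' @export
tidy.consensus_report <- function(x, ...) x$table

#' @export
glance.consensus_report <- function(x, ...) {
  tibble::tibble(min_methods = x$min_methods,
                 n_consensus = length(x$consensus),
                 n_strict = length(x$strict))
}

#' @export
tidy.slac_result <- function(x, ...) x$sites

#' @export
glance.slac_result <- function(x, ...) {
  tibble::tibble(dn = x$dn, ds = x$ds, dnds = x$dnds,
                 ci_lower = x$ci[1], ci_upper = x$ci[2],
                 conf_level = x$conf_level,
                 bootstrap_reps = x$bootstrap_reps)
}

#' @export
tidy.busted_result <- function(x, ...) x$classes

#' @export
glance.busted_result <- function(x, ...) {
  tibble::tibble(lnl_unconstrained = x$lnl_unconstrained,
                 lnl_constrained = x$lnl_constrained,
                 statistic = x$statistic, p_value = x$p_value,
                 null_dist = x$null_dist)
}

#' @export
tidy.fingerprint_result <- function(x, ...) x$classes

#' @export
glance.fingerprint_result <- function(x, ...) {
  tibble::tibble(k = x$k, logLik = x$lnL,
                 aicc_best = min(x$criterion$aicc, na.rm = TRUE))
}

#' @export
tidy.selection_profile <- function(x, ...) {
  x$posterior |>
    tidyr::pivot_longer(-"codon", names_to = "gamma", values_to = "mass") |>
    dplyr::mutate(gamma = as.numeric(sub("^g", "", .data$gamma)))
}

#' @export
glance.selection_profile <- function(x, ...) {
  tibble::tibble(n_codons = length(x$codon), chains = x$chains,
                 iterations = x$iterations, thin = x$thin,
                 status = x$status,
                 max_rhat = max(x$diagnostics$rhat, na.rm = TRUE))
}

#' @export
tidy.expr_envelope <- function(x, ...) x$grid

#' @export
glance.expr_envelope <- function(x, ...) {
  tibble::tibble(species = x$species, region = x$region, B = x$B,
                 frac_exceed = mean(x$grid$exceed != 0),
                 span = x$span)
}

# ---------------------------------------------------------------------------
# plots

#' Plot an expression envelope
#'
#' Individuals as points, the observed lowess curve, and the permutation
#' null band on the log2 age axis.
#' @param object An `expr_envelope`.
#' @param ... Unused.
#' @export
autoplot.expr_envelope <- function(object, ...) {
  g <- object$grid
  pts <- object$series
  pts$age_x <- log2(pts$age_years + object$age_offset)
  ggplot2::ggplot(g, ggplot2::aes(x = .data$age_x)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lower, ymax = .data$upper),
                         fill = "grey80", alpha = 0.7) +
    ggplot2::geom_point(data = pts,
                        ggplot2::aes(y = .data$expression), size = 1.5) +
    ggplot2::geom_line(ggplot2::aes(y = .data$fitted), linewidth = 0.8,
                       colour = "firebrick") +
    ggplot2::labs(x = "log2(age + offset) [years]", y = "expression",
                  title = paste(object$species, object$region, sep = " / "),
                  subtitle = paste0("null band from ", object$B,
                                    " permutations")) +
    ggplot2::theme_minimal()
}

#' Plot per-codon selection-class posteriors as violins
#'
#' @param object A `selection_profile`.
#' @param ... Unused.
#' @export
autoplot.selection_profile <- function(object, ...) {
  long <- tidy.selection_profile(object)
  long$gamma <- factor(long$gamma, levels = sort(unique(long$gamma)))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$gamma, y = .data$mass)) +
    ggplot2::geom_violin(scale = "width", fill = "steelblue",
                         alpha = 0.6) +
    ggplot2::labs(x = "population-scaled selection coefficient",
                  y = "per-codon posterior mass") +
    ggplot2::theme_minimal()
}

#' Plot an evolutionary fingerprint
#'
#' Rate classes on the (alpha, beta) plane (log-log), sized by weight,
#' with the neutral beta = alpha diagonal.
#' @param object A `fingerprint_result`.
#' @param ... Unused.
#' @export
autoplot.fingerprint_result <- function(object, ...) {
  cl <- object$classes
  ggplot2::ggplot(cl, ggplot2::aes(x = .data$alpha, y = .data$beta,
                                   size = .data$weight)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2) +
    ggplot2::geom_point(alpha = 0.8, colour = "darkorange") +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::labs(x = "synonymous rate (alpha)",
                  y = "nonsynonymous rate (beta)") +
    ggplot2::theme_minimal()
}

#' Plot site posteriors along the gene
#'
#' @param object A `site_posterior_table`.
#' @param cutoff Cutoff line to draw (defaults to the table's own).
#' @param ... Unused.
#' @export
autoplot.site_posterior_table <- function(object,
                                          cutoff = attr(object, "cutoff"),
                                          ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$codon,
                                            y = .data$posterior)) +
    ggplot2::geom_segment(ggplot2::aes(xend = .data$codon, yend = 0),
                          colour = "grey50") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$flag), size = 1) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey40",
                                            `TRUE` = "firebrick")) +
    ggplot2::labs(x = "codon (unmasked-gene numbering)",
                  y = paste0(object$method[1], " posterior")) +
    ggplot2::theme_minimal()
  if (is.finite(cutoff) && cutoff <= 1) {
    p <- p + ggplot2::geom_hline(yintercept = cutoff, linetype = 3)
  }
  p
}
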