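# Orchestration: a validated config, staged execution with per-stage
# seeds and timing, and TSV/JSON/markdown report rendering.

config_template <- function() {
  list(
    inputs = list(fasta = NULL, tree = NULL, snps = NULL, expression = NULL),
    mask = NULL,
    seed = 1L,
    site_models = list(freq_schemes = c("F3X4", "F61"), n_starts = 5,
                       branch_mode = "m0", m0_branch_mode = "full",
                       n_starts_m0 = 3),
    detect = list(beb_cutoff = 0.90, fubar_cutoff = 0.90,
                  rel_bf_cutoff = 50, min_methods = 2,
                  fubar_grid_size = 20, fubar_rate_max = 50,
                  fubar_iterations = 2500, fubar_burnin = 500,
                  fubar_thin = 5, fubar_chains = 2),
    slac = list(bootstrap_reps = 1000),
    busted = list(null_dist = "mixture", n_starts = 2),
    fingerprint = list(k_max = 5, n_starts = 2),
    gammamap = list(ancestor_taxa = NULL, iterations = 20000, thin = 10,
                    chains = 2, threshold = 0.80, criterion = "ge1",
                    theta_meanlog = log(1e-3), theta_sdlog = 1,
                    T_meanlog = 0, T_sdlog = 1),
    expression = list(B = 1000, span = 0.5, robust_iters = 3,
                      grid_points = 100, age_offset = 0.75,
                      percentiles = c(2.5, 97.5))
  )
}

#' Validate a pipeline run configuration
#'
#' Unknown keys at any level are rejected by name (a silent typo in a
#' cutoff would corrupt the consensus logic); known keys are merged over
#' the documented defaults.
#'
#' @param config A nested list; see `codonsel:::config_template()` for the
#'   full key set. `inputs` holds file paths (`fasta`, `tree`,
#'   `expression`, and `snps`, a named list of per-lineage SNP tables);
#'   `mask` is a list of `c(start, end)` codon intervals; `seed` is the
#'   global seed fanned out to per-stage seeds by stable hashing of stage
#'   names.
#' @return The validated, default-completed config.
#' @export
validate_run_config <- function(config) {
  tmpl <- config_template()
  check_keys <- function(x, ref, path) {
    bad <- setdiff(names(x), names(ref))
    if (length(bad)) {
      stop("unknown config key", if (length(bad) > 1) "s", ": ",
           paste0(path, bad, collapse = ", "), call. = FALSE)
    }
    for (k in names(x)) {
      if (is.list(ref[[k]]) && !is.null(names(ref[[k]])) && is.list(x[[k]]) &&
          k != "snps" && k != "mask") {
        check_keys(x[[k]], ref[[k]], paste0(path, k, "$"))
      }
    }
  }
  check_keys(config, tmpl, "")
  out <- utils::modifyList(tmpl, config)
  for (f in c("fasta", "tree", "expression")) {
    p <- out$inputs[[f]]
    if (!is.null(p) && !file.exists(p)) {
      stop("input file does not exist: ", f, " = ", p, call. = FALSE)
    }
  }
  for (p in out$inputs$snps) {
    if (!file.exists(p)) stop("SNP table does not exist: ", p, call. = FALSE)
  }
  out
}

stage_seed <- function(seed, stage) {
  (as.integer(seed) + 131L * sum(utf8ToInt(stage))) %% 2147483587L
}

#' Run the full selection-analysis pipeline
#'
#' Executes the requested stages in dependency order: `sitemodels` (M-series
#' fits, LRTs, BEB/REL/FUBAR site detection and the multi-method
#' consensus), `slac`, `busted`, `fingerprint`, `gammamap` (one run per
#' SNP-table lineage) and `expression` (one envelope per species/region).
#' Stage timings and seeds are logged via `message()`; a failing stage
#' stops the run naming the stage.
#'
#' @param config A config list (validated by [validate_run_config()]).
#' @param stages Character subset of
#'   `c("sitemodels", "slac", "busted", "fingerprint", "gammamap",
#'   "expression")`.
#' @return A `report_bundle` with one element per executed stage plus
#'   `provenance` (package version, seed, config hash).
#' @export
run_pipeline <- function(config,
                         stages = c("sitemodels", "slac", "busted",
                                    "fingerprint", "gammamap",
                                    "expression")) {
  stages <- match.arg(stages, several.ok = TRUE)
  cfg <- validate_run_config(config)
  bundle <- list(provenance = list(
    package = "codonsel",
    version = as.character(utils::packageVersion("codonsel")),
    seed = cfg$seed, config_hash = rlang::hash(cfg)))

  needs_seq <- intersect(stages, c("sitemodels", "slac", "busted",
                                   "fingerprint", "gammamap"))
  aln <- tree <- NULL
  if (length(needs_seq)) {
    if (is.null(cfg$inputs$fasta) || is.null(cfg$inputs$tree)) {
      stop("stages ", paste(needs_seq, collapse = ", "),
           " require inputs$fasta and inputs$tree", call. = FALSE)
    }
    aln <- read_codon_fasta(cfg$inputs$fasta)
    if (!is.null(cfg$mask)) aln <- mask_codon_range(aln, cfg$mask)
    tree <- read_newick(cfg$inputs$tree)
    check_taxa(aln, tree)
  }

  run_stage <- function(stage, fn) {
    t0 <- Sys.time()
    message(sprintf("[%s] stage %s (seed %d) ...",
                    format(t0, "%H:%M:%S"), stage,
                    stage_seed(cfg$seed, stage)))
    out <- tryCatch(fn(), error = function(e) {
      stop("stage '", stage, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    message(sprintf("[%s] stage %s done (%.1f s)",
                    format(Sys.time(), "%H:%M:%S"), stage,
                    as.numeric(Sys.time() - t0, units = "secs")))
    out
  }

  m0_cache <- new.env(parent = emptyenv())
  get_m0 <- function(scheme) {
    if (is.null(m0_cache[[scheme]])) {
      m0_cache[[scheme]] <- maximize_likelihood(
        aln, tree, "M0", scheme,
        options = list(n_starts = cfg$site_models$n_starts_m0,
                       branch_mode = cfg$site_models$m0_branch_mode))
    }
    m0_cache[[scheme]]
  }

  if ("sitemodels" %in% stages) {
    bundle$sitemodels <- run_stage("sitemodels", function() {
      sm <- cfg$site_models
      fits <- list()
      lrt <- list()
      for (scheme in sm$freq_schemes) {
        m0 <- get_m0(scheme)
        opts <- list(n_starts = sm$n_starts, branch_mode = "fixed")
        for (mod in c("M1a", "M2a", "M7", "M8")) {
          fits[[paste(mod, scheme, sep = "_")]] <-
            maximize_likelihood(aln, m0$tree, mod, scheme, options = opts)
        }
        for (pair in list(c("M1a", "M2a"), c("M7", "M8"))) {
          r <- likelihood_ratio_test(
            fits[[paste(pair[1], scheme, sep = "_")]],
            fits[[paste(pair[2], scheme, sep = "_")]])
          m8 <- fits[[paste("M8", scheme, sep = "_")]]
          r$freq_scheme <- scheme
          r$pct_sites <- if (pair[2] == "M8") {
            100 * (1 - m8$est$p0)
          } else {
            100 * fits[[paste("M2a", scheme, sep = "_")]]$est$p2
          }
          r$avg_dnds <- if (pair[2] == "M8") m8$est$omega_s else
            fits[[paste("M2a", scheme, sep = "_")]]$est$omega2
          lrt[[paste(pair[2], scheme)]] <- r
        }
      }
      det <- cfg$detect
      scheme1 <- sm$freq_schemes[1]
      m0 <- get_m0(scheme1)
      beb <- beb_posteriors(fits[[paste("M8", scheme1, sep = "_")]], aln,
                            cutoff = det$beb_cutoff)
      rel <- rel_posteriors(aln, tree, bf_cutoff = det$rel_bf_cutoff,
                            m0_fit = m0)
      fub <- fubar_posteriors(aln, tree, grid_size = det$fubar_grid_size,
                              rate_max = det$fubar_rate_max,
                              iterations = det$fubar_iterations,
                              burnin = det$fubar_burnin,
                              thin = det$fubar_thin,
                              chains = det$fubar_chains,
                              cutoff = det$fubar_cutoff,
                              seed = stage_seed(cfg$seed, "fubar"),
                              m0_fit = m0)
      list(fits = fits, lrt_table = dplyr::bind_rows(lrt),
           site_tables = list(BEB = beb, REL = rel, FUBAR = fub),
           consensus = consensus_sites(list(beb, rel, fub),
                                       min_methods = det$min_methods))
    })
  }

  if ("slac" %in% stages) {
    bundle$slac <- run_stage("slac", function() {
      slac_analysis(aln, tree,
                    bootstrap_reps = cfg$slac$bootstrap_reps,
                    seed = stage_seed(cfg$seed, "slac"),
                    m0_fit = get_m0(cfg$site_models$freq_schemes[1]))
    })
  }

  if ("busted" %in% stages) {
    bundle$busted <- run_stage("busted", function() {
      busted_test(aln, tree, null_dist = cfg$busted$null_dist,
                  m0_fit = get_m0(cfg$site_models$freq_schemes[1]),
                  options = list(n_starts = cfg$busted$n_starts))
    })
  }

  if ("fingerprint" %in% stages) {
    bundle$fingerprint <- run_stage("fingerprint", function() {
      evolutionary_fingerprint(
        aln, tree, k_max = cfg$fingerprint$k_max,
        m0_fit = get_m0(cfg$site_models$freq_schemes[1]),
        options = list(n_starts = cfg$fingerprint$n_starts))
    })
  }

  if ("gammamap" %in% stages) {
    bundle$gammamap <- run_stage("gammamap", function() {
      gm <- cfg$gammamap
      if (is.null(gm$ancestor_taxa) || is.null(cfg$inputs$snps)) {
        stop("gammamap needs gammamap$ancestor_taxa and inputs$snps",
             call. = FALSE)
      }
      anc <- parsimony_ancestor(aln, gm$ancestor_taxa)
      priors <- prior_spec(gm$theta_meanlog, gm$theta_sdlog,
                           gm$T_meanlog, gm$T_sdlog)
      purrr::imap(cfg$inputs$snps, function(path, lineage) {
        smp <- read_snp_table(path, lineage, ancestor = anc)
        counts <- derive_site_counts(aln, smp, anc)
        prof <- run_gammamap_mcmc(
          counts, priors, iterations = gm$iterations, thin = gm$thin,
          chains = gm$chains,
          seed = stage_seed(cfg$seed, paste0("gammamap_", lineage)))
        list(profile = prof, counts = counts,
             classified = classify_and_summarize(
               prof, counts, threshold = gm$threshold,
               criterion = gm$criterion))
      })
    })
  }

  if ("expression" %in% stages) {
    bundle$expression <- run_stage("expression", function() {
      ex <- cfg$expression
      if (is.null(cfg$inputs$expression)) {
        stop("expression stage needs inputs$expression", call. = FALSE)
      }
      series <- read_expression_table(cfg$inputs$expression)
      groups <- split(series,
                      paste(series$species, series$region, sep = "."))
      envs <- purrr::imap(groups, function(g, nm) {
        null_envelope(g, B = ex$B, percentiles = ex$percentiles,
                      span = ex$span, robust_iters = ex$robust_iters,
                      grid_points = ex$grid_points,
                      age_offset = ex$age_offset,
                      seed = stage_seed(cfg$seed, paste0("expr_", nm)))
      })
      list(envelopes = envs, report = deviation_report(envs))
    })
  }

  class(bundle) <- "report_bundle"
  bundle
}

#' @export
print.report_bundle <- function(x, ...) {
  cat("<report_bundle> stages:",
      paste(setdiff(names(x), "provenance"), collapse = ", "), "\n")
  invisible(x)
}

#' Render a report bundle to files
#'
#' Writes the likelihood-ratio table (columns Model / 2dLnL / p-value /
#' percent of sites (average dN/dS)), the per-site detection tables in
#' unmasked 1-based codon coordinates, and the per-stage summaries.
#' Sections requested through a bundle that lacks them produce an explicit
#' omission notice in the manifest rather than a silent absence. `tsv` and
#' `json` renders carry identical numbers.
#'
#' @param bundle A `report_bundle`.
#' @param dir Output directory (created if missing).
#' @param fmt One or more of `"tsv"`, `"json"`, `"markdown"`.
#' @return Invisibly, the paths written.
#' @export
write_report <- function(bundle, dir, fmt = c("tsv", "json", "markdown")) {
  fmt <- match.arg(fmt, several.ok = TRUE)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  sections <- list()
  omitted <- character(0)

  if (!is.null(bundle$sitemodels)) {
    lrt <- bundle$sitemodels$lrt_table |>
      dplyr::transmute(
        Model = paste(.data$null_model, "vs", .data$alt_model),
        freq_scheme = .data$freq_scheme,
        `2dLnL` = .data$two_delta_lnl, `p value` = .data$p_value,
        `% of sites` = .data$pct_sites,
        `average dN/dS` = .data$avg_dnds)
    sections$lrt_table <- lrt
    sections$consensus <- bundle$sitemodels$consensus$table
    for (nm in names(bundle$sitemodels$site_tables)) {
      sections[[paste0("sites_", nm)]] <-
        tibble::as_tibble(bundle$sitemodels$site_tables[[nm]])
    }
  } else {
    omitted <- c(omitted, "sitemodels")
  }
  if (!is.null(bundle$slac)) {
    sections$slac_sites <- bundle$slac$sites
    sections$slac_global <- glance.slac_result(bundle$slac)
  } else {
    omitted <- c(omitted, "slac")
  }
  if (!is.null(bundle$busted)) {
    sections$busted <- glance.busted_result(bundle$busted)
  } else {
    omitted <- c(omitted, "busted")
  }
  if (!is.null(bundle$fingerprint)) {
    sections$fingerprint <- bundle$fingerprint$classes
  } else {
    omitted <- c(omitted, "fingerprint")
  }
  if (!is.null(bundle$gammamap)) {
    sections$gammamap_selected <- purrr::imap_dfr(
      bundle$gammamap, function(x, lineage) {
        dplyr::mutate(x$classified$selected, lineage = lineage,
                      .before = 1)
      })
  } else {
    omitted <- c(omitted, "gammamap")
  }
  if (!is.null(bundle$expression)) {
    sections$expression <- bundle$expression$report
  } else {
    omitted <- c(omitted, "expression")
  }

  if ("tsv" %in% fmt) {
    for (nm in names(sections)) {
      p <- file.path(dir, paste0(nm, ".tsv"))
      utils::write.table(sections[[nm]], p, sep = "\t", row.names = FALSE,
                         quote = FALSE)
      paths <- c(paths, p)
    }
  }
  if ("json" %in% fmt) {
    p <- file.path(dir, "report.json")
    jsonlite::write_json(
      c(list(provenance = bundle$provenance,
             omitted_sections = omitted), sections),
      p, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    paths <- c(paths, p)
  }
  if ("markdown" %in% fmt) {
    p <- file.path(dir, "report.md")
    lines <- c("# Selection analysis report", "",
               paste0("- package: codonsel ", bundle$provenance$version),
               paste0("- seed: ", bundle$provenance$seed),
               paste0("- config hash: ", bundle$provenance$config_hash), "")
    if (length(omitted)) {
      lines <- c(lines, paste0("Omitted sections (not in bundle): ",
                               paste(omitted, collapse = ", ")), "")
    }
    for (nm in names(sections)) {
      tb <- sections[[nm]]
      lines <- c(lines, paste0("## ", nm), "",
                 paste(names(tb), collapse = " | "),
                 paste(rep("---", ncol(tb)), collapse = " | "),
                 apply(tb, 1, function(r) paste(r, collapse = " | ")), "")
    }
    writeLines(lines, p)
    paths <- c(paths, p)
  }
  manifest <- file.path(dir, "MANIFEST.txt")
  writeLines(c(paste0("written: ", paths),
               if (length(omitted)) paste0("omitted: ", omitted)),
             manifest)
  invisible(c(paths, manifest))
}
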