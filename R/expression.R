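# Age-trend analysis of expression: lowess fits on a log2 age axis and a
# permutation envelope under the null of constant expression over the
# lifespan.

#' Lowess age-trend curve for one expression series
#'
#' Locally weighted regression of expression on transformed age
#' (`x = log2(age_years + age_offset)`), evaluated on an even grid spanning
#' the observed age range. The fit is robust (lowess with
#' `robust_iters` robustness iterations) and invariant to input row order.
#'
#' @param series A tibble with columns `age_years` and `expression`,
#'   holding a single species/region series.
#' @param span Lowess smoother span (fraction of points in each window).
#' @param robust_iters Robustness iterations.
#' @param grid_points Evaluation grid size.
#' @param age_offset Offset in the log2 age transform (default 0.75 years,
#'   roughly a human gestation, so age 0 maps to a finite value).
#' @return A tibble: `age_x` (transformed age grid), `age_years`, `fitted`.
#' @export
lowess_curve <- function(series, span = 0.5, robust_iters = 3,
                         grid_points = 100, age_offset = 0.75) {
  if (nrow(series) < 4) stop("need at least 4 points", call. = FALSE)
  if (any(series$age_years < 0)) stop("negative ages", call. = FALSE)
  x <- log2(series$age_years + age_offset)
  if (length(unique(x)) < 3) {
    stop("too few distinct ages for a lowess window", call. = FALSE)
  }
  grid <- seq(min(x), max(x), length.out = grid_points)
  fit <- stats::lowess(x, series$expression, f = span, iter = robust_iters)
  tibble::tibble(
    age_x = grid,
    age_years = 2^grid - age_offset,
    fitted = stats::approx(fit$x, fit$y, xout = grid, ties = mean,
                           rule = 2)$y)
}

#' Permutation null envelope for an age-expression trend
#'
#' Reshuffles expression values across individuals `B` times - the null
#' hypothesis of constant expression during the lifespan - refits the
#' lowess curve on the same age grid for each permutation, and takes
#' pointwise percentiles (default 2.5% and 97.5%) as the envelope. Grid
#' points where the observed curve leaves the envelope are flagged with
#' their direction.
#'
#' @inheritParams lowess_curve
#' @param B Number of permutations (>= 100).
#' @param percentiles Lower/upper percentile pair.
#' @param seed Mandatory integer seed.
#' @return An `expr_envelope`: `grid` (tibble `age_x`, `age_years`,
#'   `fitted`, `lower`, `upper`, `exceed` in {-1, 0, 1}), `B`, `seed`,
#'   `species`, `region`, and the smoothing settings.
#' @export
null_envelope <- function(series, B = 1000, percentiles = c(2.5, 97.5),
                          span = 0.5, robust_iters = 3, grid_points = 100,
                          age_offset = 0.75, seed) {
  stopifnot(!missing(seed))
  if (B < 100) stop("B < 100 gives unstable percentiles", call. = FALSE)
  if (nrow(series) < 8) {
    stop("need at least 8 individuals for an envelope", call. = FALSE)
  }
  obs <- lowess_curve(series, span, robust_iters, grid_points, age_offset)
  x <- log2(series$age_years + age_offset)
  grid <- obs$age_x
  set.seed(seed)
  perm <- matrix(NA_real_, B, grid_points)
  for (b in seq_len(B)) {
    y <- sample(series$expression)
    fit <- stats::lowess(x, y, f = span, iter = robust_iters)
    perm[b, ] <- stats::approx(fit$x, fit$y, xout = grid, ties = mean,
                               rule = 2)$y
  }
  # type 6 ((n+1)p order-statistic convention): the standard finite-sample
  # percentile for permutation distributions; less tail-biased than the
  # default interpolation at B ~ 1000
  qs <- apply(perm, 2, stats::quantile, probs = percentiles / 100,
              names = FALSE, type = 6)
  exceed <- integer(grid_points)
  exceed[obs$fitted > qs[2, ]] <- 1L
  exceed[obs$fitted < qs[1, ]] <- -1L
  structure(
    list(grid = tibble::tibble(age_x = grid, age_years = obs$age_years,
                               fitted = obs$fitted, lower = qs[1, ],
                               upper = qs[2, ], exceed = exceed),
         B = B, percentiles = percentiles, seed = seed,
         species = if ("species" %in% names(series))
           series$species[1] else NA_character_,
         region = if ("region" %in% names(series))
           series$region[1] else NA_character_,
         span = span, robust_iters = robust_iters,
         age_offset = age_offset,
         series = tibble::as_tibble(series)),
    class = "expr_envelope"
  )
}

#' @export
print.expr_envelope <- function(x, ...) {
  cat("<expr_envelope> ", x$species, "/", x$region, " | B = ", x$B,
      " | ", round(100 * mean(x$grid$exceed != 0), 1),
      "% of grid outside the null band\n", sep = "")
  invisible(x)
}

#' Compare permutation envelopes across species/regions
#'
#' @param envelopes A list of `expr_envelope` objects.
#' @return A tibble with one row per envelope: `species`, `region`,
#'   `frac_exceed`, `frac_up`, `frac_down`, `direction` (a compact
#'   up/down/none call), and `age_intervals`, the age ranges (years) of
#'   contiguous exceedance runs.
#' @export
deviation_report <- function(envelopes) {
  if (!length(envelopes)) {
    return(tibble::tibble(species = character(), region = character(),
                          frac_exceed = numeric(), frac_up = numeric(),
                          frac_down = numeric(), direction = character(),
                          age_intervals = character()))
  }
  purrr::map_dfr(envelopes, function(e) {
    g <- e$grid
    runs <- rle(g$exceed != 0)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1
    ivs <- purrr::map2_chr(starts[runs$values], ends[runs$values],
                           function(a, b) {
                             sprintf("[%.1f, %.1f]", g$age_years[a],
                                     g$age_years[b])
                           })
    up <- mean(g$exceed == 1)
    down <- mean(g$exceed == -1)
    tibble::tibble(
      species = e$species, region = e$region,
      frac_exceed = mean(g$exceed != 0), frac_up = up, frac_down = down,
      direction = if (up == 0 && down == 0) "none"
                  else if (up >= down) "up" else "down",
      age_intervals = paste(ivs, collapse = "; "))
  })
}

#' Read an expression table
#'
#' Tab-separated with columns `individual`, `species`, `region`,
#' `age_years`, `expression`.
#' @param path File path.
#' @return An `expression_series` tibble.
#' @export
read_expression_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  need <- c("individual", "species", "region", "age_years", "expression")
  if (!all(need %in% names(tab))) {
    stop("expression table must have columns ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  out <- tibble::as_tibble(tab)
  class(out) <- c("expression_series", class(out))
  out
}
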