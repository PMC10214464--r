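#' Box-Cox transform selection for a positive variable
#'
#' Profiles the Box-Cox likelihood of an intercept-only model over a
#' lambda grid on `[-2, 2]` (via `MASS::boxcox`) and records whether
#' `lambda = 0` -- the natural log -- lies inside the 95% profile
#' interval.  The chosen transform is the natural log unless overridden:
#' the log is preferred for interpretability whenever it is supported, and
#' the profile is attached so the choice can be audited.
#'
#' @param values Positive numeric vector.
#' @param variable Name used in reporting.
#' @param override Optional transform label to force (e.g. `"identity"`).
#' @return A `TransformChoice` (S3 list): `variable`, `lambda_grid`,
#'   `profile`, `lambda_hat`, `ci` (lambda interval), `log_supported`,
#'   `chosen`.
#' @export
selectTransform <- function(values, variable = "value", override = NULL) {
  if (any(!is.finite(values)) || any(values <= 0))
    stop("all values must be positive and finite")
  if (stats::sd(values) == 0)
    stop("constant vector: Box-Cox profile is degenerate")
  bc <- MASS::boxcox(values ~ 1, lambda = seq(-2, 2, 0.01),
                     plotit = FALSE)
  lhat <- bc$x[which.max(bc$y)]
  cut <- max(bc$y) - stats::qchisq(0.95, 1) / 2
  inside <- bc$x[bc$y >= cut]
  ci <- range(inside)
  logOK <- ci[1] <= 0 && 0 <= ci[2]
  chosen <- if (is.null(override)) "log" else override
  structure(list(variable = variable, lambda_grid = bc$x,
                 profile = bc$y, lambda_hat = lhat, ci = ci,
                 log_supported = logOK, chosen = chosen),
            class = "TransformChoice")
}

#' @export
print.TransformChoice <- function(x, ...) {
  cat(sprintf(
    "TransformChoice for '%s': lambda_hat = %.2f (95%% CI %.2f to %.2f)\n",
    x$variable, x$lambda_hat, x$ci[1], x$ci[2]))
  cat(sprintf("  natural log (lambda = 0) %s the interval; chosen: %s\n",
              if (x$log_supported) "inside" else "outside", x$chosen))
  invisible(x)
}

#' Fit the energy-diversity regression per biome and pooled
#'
#' Ordinary least squares of `ln(theta)` on `ln(energy)` for each biome
#' with at least `min_n` usable guilds, plus the pooled fit over all
#' biomes.  `predictor = "yield"` uses the maximum energetic yield;
#' `predictor = "catabolic"` uses the magnitude of the catabolic free
#' energy, `ln|dGcat|` (the catabolic energy is stored negative, so its
#' absolute value is logged).  Rows with non-finite or boundary theta are
#' dropped; biomes left with fewer than `min_n` points are skipped with a
#' message.
#'
#' @param tab `data.frame` with columns `biome`, `guild`, `theta` and the
#'   energy column (`yield` or `dG_cat`).
#' @param predictor `"yield"` or `"catabolic"`.
#' @param min_n Minimum guilds per fitted biome (default 3).
#' @return `data.frame` with one row per fit (`biome`, with `"overall"`
#'   for the pooled fit) and columns `slope`, `intercept`, `p_slope`,
#'   `p_intercept`, `r2_adjusted`, `n`; the underlying `lm` objects are
#'   attached as attribute `"fits"` (a named list), and residuals are
#'   recoverable from them.
#' @examples
#' tab <- data.frame(biome = "A", guild = letters[1:5],
#'                   theta = exp(3 + 0.9 * log(1:5)), yield = 1:5)
#' fitEnergyDiversity(tab)  # recovers slope 0.9 exactly
#' @export
fitEnergyDiversity <- function(tab, predictor = c("yield", "catabolic"),
                               min_n = 3) {
  predictor <- match.arg(predictor)
  x <- if (predictor == "yield") tab$yield else abs(tab$dG_cat)
  if (is.null(x)) stop("missing predictor column for '", predictor, "'")
  ok <- is.finite(tab$theta) & tab$theta > 0 & is.finite(x) & x > 0
  if ("boundary" %in% names(tab)) ok <- ok & tab$boundary == "none"
  d <- data.frame(biome = tab$biome[ok], lnTheta = log(tab$theta[ok]),
                  lnE = log(x[ok]), stringsAsFactors = FALSE)
  fits <- list()
  rows <- list()
  oneFit <- function(dd, label) {
    fit <- stats::lm(lnTheta ~ lnE, data = dd)
    cf <- summary(fit)$coefficients
    rows[[length(rows) + 1]] <<- data.frame(
      biome = label, slope = cf["lnE", "Estimate"],
      intercept = cf["(Intercept)", "Estimate"],
      p_slope = cf["lnE", "Pr(>|t|)"],
      p_intercept = cf["(Intercept)", "Pr(>|t|)"],
      r2_adjusted = summary(fit)$adj.r.squared, n = nrow(dd),
      stringsAsFactors = FALSE)
    fits[[label]] <<- fit
  }
  for (b in unique(d$biome)) {
    db <- d[d$biome == b, ]
    if (nrow(db) < min_n || stats::sd(db$lnE) == 0) {
      message("skipping biome '", b, "': fewer than ", min_n,
              " usable guilds (or no energy spread)")
      next
    }
    oneFit(db, b)
  }
  if (nrow(d) >= min_n && stats::sd(d$lnE) > 0) oneFit(d, "overall")
  if (length(rows) == 0) stop("no biome had enough usable guilds to fit")
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  attr(res, "fits") <- fits
  res
}

#' Summarize regression slopes across biomes
#'
#' The median of the slopes whose `p_slope` is below `alpha` (the pooled
#' `"overall"` row is not a biome and is excluded from the median), counts
#' of significant and total biome fits, and a Shapiro-Wilk residual
#' normality p-value per fit when the `lm` objects are attached.
#'
#' @param fits Result of [fitEnergyDiversity()].
#' @param alpha Significance level (default 0.05).
#' @return List with `median_significant_slope` (`NA` when no slope is
#'   significant), `n_significant`, `n_total`, `significant` (logical per
#'   biome row), `shapiro_p` (named vector or `NULL`).
#' @export
summarizeSlopes <- function(fits, alpha = 0.05) {
  stopifnot(nrow(fits) >= 1)
  bi <- fits[fits$biome != "overall", , drop = FALSE]
  sig <- bi$p_slope < alpha
  med <- if (any(sig)) stats::median(bi$slope[sig]) else NA_real_
  lmfits <- attr(fits, "fits")
  shp <- NULL
  if (!is.null(lmfits))
    shp <- vapply(lmfits, function(f) {
      r <- stats::residuals(f)
      if (length(r) >= 3 && stats::sd(r) > 0)
        stats::shapiro.test(r)$p.value else NA_real_
    }, numeric(1))
  list(median_significant_slope = med, n_significant = sum(sig),
       n_total = nrow(bi),
       significant = stats::setNames(sig, bi$biome), shapiro_p = shp)
}

#' Restrict an analysis table to simple-substrate guilds
#'
#' The guilds living on a broad range of complex organics (aerobic
#' heterotrophs, fermenting organisms, sulphate reducers and iron
#' reducers) can owe extra diversity to substrate versatility rather than
#' energy; this filter keeps only the simple-substrate guilds for the
#' sensitivity analysis.  Methylotrophs are retained by default; set
#' `drop_methylotrophs = TRUE` for the sensitivity variant.
#'
#' @param tab `data.frame` with a `guild` column.
#' @param catalogue Metabolism catalogue supplying `substrateComplexity`.
#' @param drop_methylotrophs Also drop "Methylotroph (methanol)"?
#' @return The filtered `data.frame`.
#' @export
simpleSubstrateSubset <- function(tab, catalogue = defaultCatalogue(),
                                  drop_methylotrophs = FALSE) {
  cx <- vapply(catalogue, function(m) m@substrateComplexity,
               character(1))
  simple <- names(cx)[cx == "simple"]
  if (drop_methylotrophs)
    simple <- setdiff(simple, "Methylotroph (methanol)")
  tab[tab$guild %in% simple, , drop = FALSE]
}
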