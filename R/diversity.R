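#' Inverse Simpson diversity
#'
#' `1 / sum((n_i/J)^2)` for a species-abundance vector; equals the species
#' count for perfectly even communities and 1 for a monoculture.  Computed
#' through `vegan::diversity(..., index = "invsimpson")`.
#'
#' @param counts Positive integer vector of species abundances (zeros are
#'   dropped).
#' @return Diversity value in `[1, S]`.
#' @examples
#' inverseSimpson(c(3, 1))  # 1.6
#' @export
inverseSimpson <- function(counts) {
  counts <- counts[counts > 0]
  if (length(counts) == 0) stop("empty abundance vector")
  unname(vegan::diversity(counts, index = "invsimpson"))
}

#' Ewens log-likelihood in theta (up to a data-only constant)
#'
#' Under the Ewens sampling formula the probability of a sample
#' configuration depends on theta through `theta^S / (theta)_J` (rising
#' factorial), so the theta-dependent log-likelihood for a pool with `S`
#' species among `J` individuals is
#' `S log(theta) + lgamma(theta) - lgamma(theta + J)`.
#'
#' @param theta Positive numeric (vectorized).
#' @param S,J Species count and pool size.
#' @return Log-likelihood values (data-independent constant dropped).
#' @export
ewensLogLik <- function(theta, S, J) {
  S * log(theta) + lgamma(theta) - lgamma(theta + J)
}

# Expected species count under the ESF: E[S] = theta * (psi(theta+J) - psi(theta))
# (identical to sum_{i=0}^{J-1} theta/(theta+i), but O(1))
ewensExpectedS <- function(theta, J) {
  theta * (digamma(theta + J) - digamma(theta))
}

#' Maximum-likelihood fundamental biodiversity number
#'
#' Solves the Ewens sampling formula maximum-likelihood equation
#' `S = sum_{i=0}^{J-1} theta / (theta + i)` for theta -- the estimator
#' depends on the data only through the species count `S` and pool size
#' `J`.  The root is found by monotone bracketed root-finding (the
#' expected species count is strictly increasing in theta) to a relative
#' tolerance of `1e-8`, deterministic, no randomness.  A 95%
#' profile-likelihood interval is attached, from the drop of the Ewens
#' log-likelihood below its maximum by `qchisq(0.95, 1)/2`.
#'
#' Boundary cases are flagged rather than estimated: all-singleton pools
#' (`S == J`) return `theta = Inf` (`boundary = "upper"`), monocultures
#' (`S == 1`) return `theta = 0` (`boundary = "lower"`); both are excluded
#' from downstream regression.
#'
#' @param counts Species-abundance vector, or `NULL` when `S` and `J` are
#'   given directly.
#' @param S,J Species count and pool size (derived from `counts` when
#'   supplied).
#' @param conf Confidence level of the profile interval.
#' @return A [ThetaEstimate-class].
#' @examples
#' est <- ewensThetaMLE(S = 20, J = 100)
#' thetaValue(est)  # about 7.5
#' @export
ewensThetaMLE <- function(counts = NULL, S = NULL, J = NULL,
                          conf = 0.95) {
  if (!is.null(counts)) {
    counts <- counts[counts > 0]
    if (length(counts) == 0) stop("empty abundance vector")
    S <- length(counts)
    J <- sum(counts)
  }
  if (is.null(S) || is.null(J))
    stop("supply either counts or both S and J")
  if (S < 1) stop("S must be at least 1")
  if (S > J) stop("S cannot exceed J (", S, " > ", J, ")")
  if (S == J)
    return(new("ThetaEstimate", theta = Inf, J = as.numeric(J),
               S = as.numeric(S), loglik = NA_real_, ciLo = NA_real_,
               ciHi = NA_real_, boundary = "upper"))
  if (S == 1)
    return(new("ThetaEstimate", theta = 0, J = as.numeric(J),
               S = as.numeric(S), loglik = NA_real_, ciLo = NA_real_,
               ciHi = NA_real_, boundary = "lower"))
  lo <- 1e-9
  hi <- 10 * J
  f <- function(th) ewensExpectedS(th, J) - S
  while (f(hi) < 0) hi <- hi * 10   # safety; E[S] -> J as theta -> Inf
  root <- stats::uniroot(f, c(lo, hi), tol = .Machine$double.eps^0.5)
  theta <- root$root
  # polish to relative tolerance 1e-8 by Newton steps on the score
  for (it in 1:50) {
    g <- ewensExpectedS(theta, J) - S
    dg <- digamma(theta + J) - digamma(theta) +
      theta * (trigamma(theta + J) - trigamma(theta))
    step <- g / dg
    if (!is.finite(step) || theta - step <= 0) break
    theta <- theta - step
    if (abs(step) <= 1e-8 * theta) break
  }
  lhat <- ewensLogLik(theta, S, J)
  drop <- stats::qchisq(conf, df = 1) / 2
  pf <- function(th) ewensLogLik(th, S, J) - (lhat - drop)
  ciLo <- if (pf(lo) > 0) lo else
    stats::uniroot(pf, c(lo, theta), tol = 1e-10)$root
  hi2 <- theta * 2
  while (pf(hi2) > 0 && hi2 < 1e12) hi2 <- hi2 * 2
  ciHi <- if (pf(hi2) > 0) Inf else
    stats::uniroot(pf, c(theta, hi2), tol = 1e-8)$root
  new("ThetaEstimate", theta = theta, J = as.numeric(J),
      S = as.numeric(S), loglik = lhat, ciLo = ciLo, ciHi = ciHi,
      boundary = "none")
}

#' Accessors for ThetaEstimate
#'
#' @param x A [ThetaEstimate-class].
#' @return `thetaValue`: the point estimate; `thetaCI`: `c(lo, hi)`.
#' @export
thetaValue <- function(x) x@theta

#' @rdname thetaValue
#' @export
thetaCI <- function(x) c(x@ciLo, x@ciHi)

setMethod("show", "ThetaEstimate", function(object) {
  if (object@boundary != "none") {
    cat(sprintf(
      "ThetaEstimate: boundary (%s), theta -> %s  [J = %d, S = %d]\n",
      object@boundary, format(object@theta), as.integer(object@J),
      as.integer(object@S)))
  } else {
    cat(sprintf(
      "ThetaEstimate: %.4g (95%% PL interval %.4g-%.4g)  [J = %d, S = %d]\n",
      object@theta, object@ciLo, object@ciHi, as.integer(object@J),
      as.integer(object@S)))
  }
  invisible(NULL)
})

#' Pool samples and estimate theta per (biome, guild)
#'
#' Sums the per-sample abundance vectors of every guild over all samples
#' within each biome (one metacommunity pool per biome and guild), then
#' applies [ewensThetaMLE()].  The per-sample inverse Simpson median is
#' attached for the alpha-diversity view of the same table.  Pools at an
#' estimator boundary are kept in the table with their flag; pools with no
#' assigned reads are omitted with a message.
#'
#' @param gc A [GuildedCounts-class].
#' @param scope Biome label(s) to include; `NULL` (default) uses all.
#' @return `data.frame` with columns `biome`, `guild`, `J`, `S`, `theta`,
#'   `ci_lo`, `ci_hi`, `boundary`, `inv_simpson_median`.
#' @export
poolAndEstimate <- function(gc, scope = NULL) {
  cnt <- gc@counts
  if (!is.null(scope)) {
    cnt <- cnt[cnt$biome %in% scope, , drop = FALSE]
    if (nrow(cnt) == 0) stop("no samples in scope: ",
                             paste(scope, collapse = ", "))
  }
  if (nrow(cnt) == 0) stop("no assigned counts to pool")
  out <- list()
  for (b in unique(cnt$biome)) {
    cb <- cnt[cnt$biome == b, ]
    for (g in unique(cb$guild)) {
      cg <- cb[cb$guild == g, ]
      pooled <- tapply(cg$count, cg$taxon, sum)
      pooled <- pooled[pooled > 0]
      if (length(pooled) == 0) {
        message("omitting empty pool: ", b, " / ", g)
        next
      }
      est <- ewensThetaMLE(as.numeric(pooled))
      invs <- tapply(seq_len(nrow(cg)), cg$sample, function(i)
        inverseSimpson(cg$count[i]))
      out[[length(out) + 1]] <- data.frame(
        biome = b, guild = g, J = est@J, S = est@S,
        theta = est@theta, ci_lo = est@ciLo, ci_hi = est@ciHi,
        boundary = est@boundary,
        inv_simpson_median = stats::median(unlist(invs)),
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Friedman rank-consistency test across biomes
#'
#' Tests whether the ranking of guild diversity is consistent across
#' biomes: biomes are blocks, guilds are treatments, and the Friedman
#' chi-square is computed on within-biome ranks (ties mid-ranked) of the
#' chosen diversity column, via `stats::friedman.test`.  Only guilds
#' present in every biome form the complete block; if fewer than 3 remain
#' (or fewer than 2 biomes are present) an error names the missing cells.
#'
#' @param div `data.frame` with columns `biome`, `guild` and the diversity
#'   measure.
#' @param value Name of the diversity column (default `"theta"`).
#' @return `htest` object (statistic, df, p-value).
#' @export
friedmanRankConsistency <- function(div, value = "theta") {
  biomes <- unique(div$biome)
  if (length(biomes) < 2)
    stop("need at least 2 biomes, got ", length(biomes))
  keep <- is.finite(div[[value]]) & div[[value]] > 0
  div <- div[keep, , drop = FALSE]
  common <- Reduce(intersect,
                   lapply(split(div$guild, div$biome), unique))
  if (length(common) < 3) {
    missing <- setdiff(unique(div$guild), common)
    stop("incomplete block: only ", length(common),
         " guild(s) present in all biomes; missing cells for guild(s): ",
         paste(utils::head(missing, 10), collapse = ", "))
  }
  div <- div[div$guild %in% common, ]
  ag <- tapply(div[[value]], list(div$biome, div$guild), mean)
  stats::friedman.test(as.matrix(ag))
}
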