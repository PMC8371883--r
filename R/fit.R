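#' @include AllClasses.R traitTable.R
NULL

#' Fit a power law by least squares on ln-transformed data
#'
#' Fits \eqn{y = a x^b} by ordinary least squares on the ln-transformed
#' pairs, i.e. the linear regression \eqn{\ln y = \ln a + b \ln x}. This
#' is the standard treatment for traits spanning orders of magnitude on
#' double-logarithmic axes. The back-transformed constant is
#' `a = exp(intercept)` with delta-method standard error
#' `se(a) = a * se(intercept)`; `R^2` refers to the ln-space regression.
#' The residual sum of squares and centered sum of squares of `ln x` are
#' kept on the returned object so that exponents of two independent fits
#' can be compared with [compareSlopes()].
#'
#' @param x,y strictly positive numeric vectors of equal length >= 3.
#'   `x` may also be a two-column data.frame/matrix of `(x, y)` pairs.
#' @return a [PowerLawFit-class].
#' @examples
#' x <- c(0.01, 1, 100, 1e4)
#' fit <- fitPowerLaw(x, 2 * sqrt(x))  # recovers a = 2, b = 0.5 exactly
#' exponent(fit)
#' normConst(fit)
#' @seealso [compareSlopes()], [asModel()], [filterTraits()]
#' @export
fitPowerLaw <- function(x, y = NULL) {
  if (is.null(y)) {
    if (NCOL(x) < 2L) stop("need both 'x' and 'y'")
    y <- x[[2L]]
    x <- x[[1L]]
  }
  x <- as.numeric(x)
  y <- as.numeric(y)
  if (length(x) != length(y)) stop("'x' and 'y' must have equal length")
  if (any(!is.finite(x)) || any(!is.finite(y)) || any(x <= 0) || any(y <= 0))
    stop("power-law fitting needs strictly positive, finite data")
  n <- length(x)
  if (n < 3L) stop("need at least 3 data pairs")
  lx <- log(x)
  ly <- log(y)
  ssx <- sum((lx - mean(lx))^2)
  if (ssx < .Machine$double.eps * n * max(1, mean(lx)^2))
    stop("degenerate design: 'x' has zero variance on the log scale")
  fit <- stats::lm(ly ~ lx)
  cf <- stats::coef(fit)
  rss <- sum(stats::residuals(fit)^2)
  ssTot <- sum((ly - mean(ly))^2)
  r2 <- if (ssTot > 0) 1 - rss / ssTot else 1
  s2 <- rss / (n - 2L)
  seB <- sqrt(s2 / ssx)
  seInt <- sqrt(s2 * (1 / n + mean(lx)^2 / ssx))
  a <- exp(cf[[1L]])
  new("PowerLawFit", n = n, exponent = cf[[2L]], exponentSE = seB,
      lnIntercept = cf[[1L]], lnInterceptSE = seInt, normConst = a,
      normConstSE = a * seInt, rSquared = max(0, min(1, r2)),
      residualSS = rss, xCenteredSS = ssx, df = n - 2L)
}

#' Fit the trait-table scaling law
#'
#' Convenience wrapper: selects the complete, positive cases of two
#' trait columns and fits the power law. The default columns give the
#' ribosomal-gene-content allometry (`rrn_per_cell` against
#' `volume_um3`); other trait scalings (ploidy, genome size, DNA content
#' per cell against volume) use the same call with a different `y`.
#'
#' @param traits a canonical trait data.frame (see [loadTraitTable()]).
#' @param x,y trait column names.
#' @return a [PowerLawFit-class].
#' @examples
#' tab <- simulateTraitTable(n = 50, lnNoiseSd = 0, seed = 1)
#' fitTraits(tab)
#' @export
fitTraits <- function(traits, x = "volume_um3", y = "rrn_per_cell") {
  cc <- completeCases(traits, x, y)
  fitPowerLaw(cc[[x]], cc[[y]])
}

#' Compare the exponents of two power-law fits
#'
#' Classical t test for the equality of two regression slopes fitted on
#' independent datasets: the residual variances are pooled,
#' \eqn{s^2 = (RSS_1 + RSS_2) / (n_1 + n_2 - 4)}, and
#' \deqn{t = (b_1 - b_2) / \sqrt{s^2 (1/SSX_1 + 1/SSX_2)}}
#' with \eqn{SSX} the centered sum of squares of `ln x` in each dataset.
#' The two-sided p value comes from the t distribution on
#' \eqn{n_1 + n_2 - 4} degrees of freedom.
#'
#' @param fit1,fit2 two [PowerLawFit-class] objects from independent
#'   datasets.
#' @return a [SlopeComparison-class].
#' @examples
#' x <- exp(seq(0, 10, length.out = 20))
#' f1 <- fitPowerLaw(x, 2 * x^0.5 * exp(rnorm(20, sd = 0.1)))
#' f2 <- fitPowerLaw(x, 2 * x^1.0 * exp(rnorm(20, sd = 0.1)))
#' compareSlopes(f1, f2)
#' @export
compareSlopes <- function(fit1, fit2) {
  stopifnot(is(fit1, "PowerLawFit"), is(fit2, "PowerLawFit"))
  df <- fit1@n + fit2@n - 4L
  if (df <= 0L) stop("insufficient data: pooled df must be positive")
  s2 <- (fit1@residualSS + fit2@residualSS) / df
  se <- sqrt(s2 * (1 / fit1@xCenteredSS + 1 / fit2@xCenteredSS))
  t <- if (se == 0) {
    if (fit1@exponent == fit2@exponent) 0 else sign(fit1@exponent - fit2@exponent) * Inf
  } else (fit1@exponent - fit2@exponent) / se
  p <- if (is.infinite(t)) 0 else 2 * stats::pt(-abs(t), df)
  new("SlopeComparison", statistic = t, df = df, pValue = p)
}

#' Subset a trait table by the standard exclusion rules
#'
#' Reproduces the dataset restrictions used in scaling re-analyses:
#'
#' * `"exclude_rc_leq"` drops records with `rrn_per_cell <= threshold`
#'   (guards against floor effects at the low end, where copies per cell
#'   cannot physiologically fall below 1; the conventional threshold is
#'   2, removal boundary inclusive);
#' * `"exclude_euk_below_v"` drops *eukaryote* records with
#'   `volume_um3 < threshold` (e.g. 20 um^3, to set aside
#'   pico-eukaryotes whose organellar rDNA may bias cellular counts);
#'   prokaryotes are untouched;
#' * `"domain_only"` keeps records whose `domain` equals `label`
#'   (`"prokaryote"` keeps bacteria plus archaea).
#'
#' Records missing the field a rule tests are kept (the rule cannot
#' exclude them); the input is never modified.
#'
#' @param traits a canonical trait data.frame.
#' @param rule one of `"exclude_rc_leq"`, `"exclude_euk_below_v"`,
#'   `"domain_only"`.
#' @param threshold numeric cutoff for the first two rules (defaults 2
#'   and 20 um^3 respectively).
#' @param label domain label for `"domain_only"`: `"bacteria"`,
#'   `"archaea"`, `"eukaryote"` or `"prokaryote"`.
#' @return the surviving subset (a new data.frame).
#' @examples
#' tab <- data.frame(taxon_id = c("a", "b", "c"),
#'                   domain = c("bacteria", "eukaryote", "eukaryote"),
#'                   volume_um3 = c(1, 19, 3000),
#'                   rrn_per_cell = c(1, 3, 800))
#' filterTraits(tab, "exclude_rc_leq")        # drops 'a'
#' filterTraits(tab, "exclude_euk_below_v")   # drops 'b'
#' filterTraits(tab, "domain_only", label = "eukaryote")
#' @export
filterTraits <- function(traits,
                         rule = c("exclude_rc_leq", "exclude_euk_below_v",
                                  "domain_only"),
                         threshold = NULL, label = NULL) {
  rule <- match.arg(rule)
  keep <- switch(rule,
    exclude_rc_leq = {
      if (is.null(threshold)) threshold <- 2
      is.na(traits$rrn_per_cell) | traits$rrn_per_cell > threshold
    },
    exclude_euk_below_v = {
      if (is.null(threshold)) threshold <- 20
      !(!is.na(traits$domain) & traits$domain == "eukaryote" &
          !is.na(traits$volume_um3) & traits$volume_um3 < threshold)
    },
    domain_only = {
      if (is.null(label))
        stop("rule 'domain_only' needs a 'label'")
      wanted <- if (identical(label, "prokaryote"))
        c("bacteria", "archaea")
      else match.arg(label, .traitDomains)
      !is.na(traits$domain) & traits$domain %in% wanted
    })
  traits[keep, , drop = FALSE]
}
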