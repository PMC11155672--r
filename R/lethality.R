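#' Per-plate embryonic lethality
#'
#' The fraction of embryos that failed to hatch:
#' \code{1 - n_hatched/n_embryos}.
#'
#' @param plates a \code{data.frame} with columns \code{n_embryos} and
#'   \code{n_hatched} (one row per plate).
#' @return numeric vector of lethality fractions.
#' @examples
#' plateLethality(data.frame(n_embryos = 100, n_hatched = 80))
#' @export
plateLethality <- function(plates) {
  if (any(plates$n_embryos <= 0))
    stop("invalid record: n_embryos must be > 0")
  if (any(plates$n_hatched < 0 | plates$n_hatched > plates$n_embryos))
    stop("invalid record: n_hatched must lie in [0, n_embryos]")
  1 - plates$n_hatched / plates$n_embryos
}

.groupStats <- function(values, groups) {
  groups <- as.character(groups)
  n <- tapply(values, groups, length)
  m <- tapply(values, groups, mean)
  v <- tapply(values, groups, stats::var)
  list(labels = names(n), n = as.vector(n), mean = as.vector(m),
       var = as.vector(v))
}

#' Heteroscedasticity-robust one-way ANOVA
#'
#' Computes Welch's F (heteroscedastic ANOVA with Satterthwaite-type
#' denominator degrees of freedom) and the Brown-Forsythe F* variant
#' alongside, matching the "Brown-Forsythe and Welch ANOVA" convention of
#' common graphing software.  If any group has zero variance the robust
#' statistics are undefined and the function falls back to the ordinary
#' (equal-variance) one-way ANOVA with a warning; if all observations are
#' identical it errors.
#'
#' @param values numeric observations (e.g. per-plate lethality fractions).
#' @param groups group labels, same length as \code{values}; at least two
#'   groups with at least two observations each.
#' @return a list with elements \code{welch} (\code{F}, \code{df1},
#'   \code{df2}, \code{p}), \code{brown_forsythe} (same fields), the
#'   per-group summary \code{groups}, and \code{method}
#'   (\code{"welch+brown-forsythe"} or \code{"classic_fallback"}).
#' @examples
#' set.seed(1)
#' welchAnova(c(rnorm(9), rnorm(9, 0, 3)), rep(c("a", "b"), each = 9))
#' @export
welchAnova <- function(values, groups) {
  gs <- .groupStats(values, groups)
  k <- length(gs$labels)
  if (k < 2L) stop("need at least 2 groups")
  if (any(gs$n < 2L)) stop("every group needs at least 2 observations")
  if (stats::var(values) == 0)
    stop("degenerate input: all observations identical")
  groupDf <- data.frame(group = gs$labels, n = gs$n, mean = gs$mean,
                        var = gs$var, stringsAsFactors = FALSE)
  if (any(gs$var == 0)) {
    warning("group with zero variance: falling back to ordinary ANOVA")
    fit <- stats::oneway.test(values ~ factor(groups), var.equal = TRUE)
    res <- list(F = unname(fit$statistic), df1 = unname(fit$parameter[1]),
                df2 = unname(fit$parameter[2]), p = fit$p.value)
    return(list(welch = res, brown_forsythe = res, groups = groupDf,
                method = "classic_fallback"))
  }
  # Welch (1951) heteroscedastic F
  w <- gs$n / gs$var
  sw <- sum(w)
  mw <- sum(w * gs$mean) / sw
  h <- sum((1 - w / sw)^2 / (gs$n - 1))
  Fw <- sum(w * (gs$mean - mw)^2) / (k - 1) /
    (1 + 2 * (k - 2) / (k^2 - 1) * h)
  df2w <- (k^2 - 1) / (3 * h)
  pw <- stats::pf(Fw, k - 1, df2w, lower.tail = FALSE)
  # Brown & Forsythe (1974) F*
  N <- sum(gs$n)
  gm <- sum(gs$n * gs$mean) / N
  denomTerms <- (1 - gs$n / N) * gs$var
  Fb <- sum(gs$n * (gs$mean - gm)^2) / sum(denomTerms)
  c_i <- denomTerms / sum(denomTerms)
  df2b <- 1 / sum(c_i^2 / (gs$n - 1))
  pb <- stats::pf(Fb, k - 1, df2b, lower.tail = FALSE)
  list(welch = list(F = Fw, df1 = k - 1, df2 = df2w, p = pw),
       brown_forsythe = list(F = Fb, df1 = k - 1, df2 = df2b, p = pb),
       groups = groupDf,
       method = "welch+brown-forsythe")
}

.welchT <- function(m1, v1, n1, m2, v2, n2) {
  se2 <- v1 / n1 + v2 / n2
  t <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p <- 2 * stats::pt(-abs(t), df)
  list(t = t, df = df, p = p)
}

#' Control-wise multiple comparisons after Welch ANOVA
#'
#' For each non-control group, a Welch-type two-sample t statistic against
#' the control group, with a multiplicity adjustment over the k
#' comparisons.  Adjustment methods: \code{"sidak"} (default;
#' \code{1 - (1 - p)^k}), \code{"bonferroni"}, or \code{"mc"}, a seeded
#' Monte Carlo estimate of the Dunnett-type max-|t| null distribution that
#' accounts for the shared control sample (the refinement used in place of
#' exact studentized-maximum-modulus quantiles).  With a single comparison
#' every method returns the unadjusted p.
#'
#' @param values numeric observations.
#' @param groups group labels, same length as \code{values}.
#' @param control label of the control group (must be present).
#' @param method adjustment method.
#' @param alpha two-tailed significance threshold for the
#'   \code{significant} flag (default 0.05).
#' @param nsim Monte Carlo draws for \code{method = "mc"}.
#' @param seed optional integer seed for \code{method = "mc"}.
#' @return a \code{data.frame} with one row per comparison: group, group
#'   and control means, \code{estimate} (difference), \code{t}, \code{df},
#'   \code{p}, \code{p_adj}, \code{significant}.
#' @export
dunnettVsControl <- function(values, groups, control,
                             method = c("sidak", "bonferroni", "mc"),
                             alpha = 0.05, nsim = 10000L, seed = NULL) {
  method <- match.arg(method)
  groups <- as.character(groups)
  if (!control %in% groups)
    stop("control group '", control, "' not present")
  gs <- .groupStats(values, groups)
  if (any(gs$n < 2L)) stop("every group needs at least 2 observations")
  ci <- which(gs$labels == control)
  oi <- setdiff(seq_along(gs$labels), ci)
  k <- length(oi)
  tt <- .welchT(gs$mean[oi], gs$var[oi], gs$n[oi],
                gs$mean[ci], gs$var[ci], gs$n[ci])
  padj <- switch(method,
    # -expm1(k*log1p(-p)) is the cancellation-safe 1-(1-p)^k; the pmax
    # guards the adjusted >= raw invariant against rounding
    sidak = pmax(tt$p, -expm1(k * log1p(-tt$p))),
    bonferroni = pmin(1, tt$p * k),
    mc = {
      if (!is.null(seed)) set.seed(seed)
      maxT <- replicate(nsim, {
        cvals <- stats::rnorm(gs$n[ci], 0, sqrt(gs$var[ci]))
        tmax <- 0
        for (j in oi) {
          gv <- stats::rnorm(gs$n[j], 0, sqrt(gs$var[j]))
          tj <- .welchT(mean(gv), stats::var(gv), gs$n[j],
                        mean(cvals), stats::var(cvals), gs$n[ci])
          tmax <- max(tmax, abs(tj$t))
        }
        tmax
      })
      vapply(abs(tt$t), function(t0) mean(maxT >= t0), numeric(1))
    })
  data.frame(group = gs$labels[oi],
             mean = gs$mean[oi],
             control_mean = gs$mean[ci],
             estimate = gs$mean[oi] - gs$mean[ci],
             t = tt$t, df = tt$df, p = tt$p, p_adj = padj,
             significant = padj < alpha,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Embryonic-lethality analysis against the vehicle control
#'
#' The lethality stage of the pipeline: per-plate lethality fractions,
#' per-group means, the heteroscedasticity-robust ANOVA across all groups
#' ([welchAnova()]), and control-wise multiple comparisons
#' ([dunnettVsControl()]) with a two-tailed significance threshold.
#'
#' @param plates lethality plate table (\code{chemical_id},
#'   \code{n_embryos}, \code{n_hatched}; one row per plate).
#' @param control control label (default \code{"DMSO"}).
#' @inheritParams dunnettVsControl
#' @return a list with elements \code{group_means}, \code{anova} (the
#'   [welchAnova()] result) and \code{comparisons} (the
#'   [dunnettVsControl()] table).
#' @examples
#' cfg <- simConfig(nChemicals = 4, seed = 3)
#' res <- lethalityAnalysis(simulateLethality(cfg))
#' res$comparisons[, c("group", "mean", "p_adj", "significant")]
#' @export
lethalityAnalysis <- function(plates, control = "DMSO",
                              method = c("sidak", "bonferroni", "mc"),
                              alpha = 0.05, nsim = 10000L, seed = NULL) {
  frac <- plateLethality(plates)
  groups <- as.character(plates$chemical_id)
  means <- stats::aggregate(frac, list(chemical_id = groups), mean)
  names(means)[2] <- "mean_lethality"
  list(group_means = means,
       anova = welchAnova(frac, groups),
       comparisons = dunnettVsControl(frac, groups, control,
                                      method = method, alpha = alpha,
                                      nsim = nsim, seed = seed))
}
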