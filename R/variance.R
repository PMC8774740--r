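# Heterozygote variance-inflation screen for parent-of-origin effects in
# unrelated individuals.
#
# Mechanism: opposite (or merely unequal) maternal and paternal allele effects
# leave heterozygote means near the homozygote means but add a two-point
# mixture component of width |beta_pat - beta_mat| to the heterozygote
# residual distribution, inflating its variance by delta^2 where
# delta = |beta_pat - beta_mat| / 2.

#' Map genotype dosages to per-group membership weights
#'
#' Fractional dosages in `[0, 2]` (e.g. imputed mean genotypes) are mapped to
#' weights over the hard-call groups (0, 1, 2) by linear interpolation:
#' dosage `d <= 1` gives weights `(1 - d, d, 0)`, dosage `d > 1` gives
#' `(0, 2 - d, d - 1)`. Integer dosages reduce to exact group membership.
#'
#' @param dosage numeric vector in `[0, 2]`.
#' @return numeric matrix with columns `g0`, `g1`, `g2`; rows sum to 1.
#' @export
mean_genotype_support <- function(dosage) {
  if (any(is.na(dosage)) || any(dosage < 0 | dosage > 2)) {
    stop("dosages must be non-missing and within [0, 2]")
  }
  w <- cbind(
    g0 = pmax(1 - dosage, 0),
    g1 = 1 - abs(dosage - 1),
    g2 = pmax(dosage - 1, 0)
  )
  w
}

.weighted_median <- function(x, w) {
  o <- order(x)
  cw <- cumsum(w[o]) / sum(w)
  x[o][which(cw >= 0.5)[1]]
}

# symmetric two-component normal mixture fit for the heterozygote residuals:
# H1: 0.5 N(mu - delta, s^2) + 0.5 N(mu + delta, s^2); H0: delta = 0
.mixture_loglik <- function(x, mu, delta, s) {
  sum(log(0.5 * stats::dnorm(x, mu - delta, s) +
    0.5 * stats::dnorm(x, mu + delta, s)))
}

.fit_sym_mixture_one <- function(x, delta0, maxit = 500L, tol = 1e-9) {
  mu <- mean(x)
  s <- sqrt(max(stats::var(x) - delta0^2, stats::var(x) / 4))
  delta <- delta0
  ll <- .mixture_loglik(x, mu, delta, s)
  for (it in seq_len(maxit)) {
    ll_old <- ll
    d1 <- stats::dnorm(x, mu - delta, s)
    d2 <- stats::dnorm(x, mu + delta, s)
    g <- d2 / pmax(d1 + d2, 1e-300) # responsibility of the +delta component
    # constrained M step: minimise sum w1 (x - mu + delta)^2 +
    # sum w2 (x - mu - delta)^2 exactly in (mu, delta)
    s1 <- sum(1 - g); s2w <- sum(g)
    a <- sum((1 - g) * x); b <- sum(g * x)
    n <- s1 + s2w; d <- s2w - s1
    det <- n^2 - d^2
    if (abs(det) < 1e-12) break
    mu <- (n * (a + b) - d * (b - a)) / det
    delta <- max((n * (b - a) - d * (a + b)) / det, 0)
    s2 <- mean((1 - g) * (x - (mu - delta))^2 + g * (x - (mu + delta))^2)
    s <- sqrt(max(s2, 1e-12))
    ll <- .mixture_loglik(x, mu, delta, s)
    if (ll - ll_old < tol) break
  }
  list(mu = mu, delta = delta, s = s, loglik = ll)
}

.fit_sym_mixture <- function(x) {
  sdx <- stats::sd(x)
  fits <- lapply(c(0.25, 0.5, 1, 1.5) * sdx, function(d0) {
    .fit_sym_mixture_one(x, d0)
  })
  fits[[which.max(vapply(fits, `[[`, numeric(1), "loglik"))]]
}

#' Heterozygote variance-inflation test for parent-of-origin effects
#'
#' Tests whether the residual variance among heterozygotes exceeds that of the
#' pooled homozygotes, the signature of hidden opposite-direction parental
#' allele effects. Trait values are first residualised on the covariates by
#' least squares; two methods are provided:
#'
#' * `levene` (default): Brown-Forsythe-style comparison of median-centred
#'   absolute deviations, heterozygotes vs pooled homozygotes, one-sided in
#'   the inflation direction. With fractional dosages the group medians and
#'   the two-sample comparison use the interpolation weights from
#'   [mean_genotype_support()].
#' * `mixture`: likelihood-ratio test of the heterozygote residuals as an
#'   equal-weight two-component normal mixture with means `mu +/- delta`
#'   against `delta = 0`, referred to a 50:50 mixture of a point mass at zero
#'   and chi-squared(1) (boundary correction). Requires hard-call genotypes.
#'
#' @param y trait values.
#' @param g genotypes: integers in `{0, 1, 2}` or dosages in `[0, 2]`.
#' @param covariates optional data.frame of covariates.
#' @param method `"levene"` or `"mixture"`.
#' @param min_group minimum per-group effective size (default 10); smaller
#'   groups yield a flagged, untested result.
#' @return data.frame row: group sizes `n0`, `n1`, `n2`, residual variances
#'   `var0`, `var1`, `var2`, `statistic`, `p`, `method`, `tested`.
#' @export
het_variance_test <- function(y, g, covariates = NULL,
                              method = c("levene", "mixture"),
                              min_group = 10L) {
  method <- match.arg(method)
  cc <- !is.na(y) & !is.na(g)
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    cc <- cc & stats::complete.cases(covariates)
  }
  y <- y[cc]
  g <- g[cc]
  if (!is.null(covariates)) {
    Z <- stats::model.matrix(~., data = covariates[cc, , drop = FALSE])
    r <- stats::lm.fit(Z, y)$residuals
  } else {
    r <- y - mean(y)
  }
  w <- mean_genotype_support(g)
  n_eff <- colSums(w)
  wvar <- function(j) {
    wj <- w[, j]
    if (sum(wj) < 2) return(NA_real_)
    mu <- sum(wj * r) / sum(wj)
    sum(wj * (r - mu)^2) / (sum(wj) - 1)
  }
  vars <- vapply(1:3, wvar, numeric(1))
  out <- data.frame(
    n0 = n_eff[1], n1 = n_eff[2], n2 = n_eff[3],
    var0 = vars[1], var1 = vars[2], var2 = vars[3],
    statistic = NA_real_, p = NA_real_, method = paste0(method, "_het"),
    tested = FALSE, stringsAsFactors = FALSE, row.names = NULL
  )
  if (any(n_eff[c(1, 2)] < min_group) ||
      (n_eff[1] + n_eff[3]) < min_group) {
    warning("genotype group below min_group; test not run")
    return(out)
  }
  if (method == "levene") {
    w_het <- w[, 2]
    w_hom <- w[, 1] + w[, 3]
    med_het <- .weighted_median(r[w_het > 0], w_het[w_het > 0])
    med_hom <- .weighted_median(r[w_hom > 0], w_hom[w_hom > 0])
    d_het <- abs(r - med_het)
    d_hom <- abs(r - med_hom)
    m1 <- sum(w_het * d_het) / sum(w_het)
    m0 <- sum(w_hom * d_hom) / sum(w_hom)
    v1 <- sum(w_het * (d_het - m1)^2) / (sum(w_het) - 1)
    v0 <- sum(w_hom * (d_hom - m0)^2) / (sum(w_hom) - 1)
    if ((v1 + v0) == 0) {
      out$statistic <- 0
      out$p <- 1
      out$tested <- TRUE
      return(out)
    }
    se <- sqrt(v1 / sum(w_het) + v0 / sum(w_hom))
    tstat <- (m1 - m0) / se
    df <- sum(w_het) + sum(w_hom) - 2
    out$statistic <- tstat
    out$p <- stats::pt(tstat, df, lower.tail = FALSE) # one-sided: inflation
    out$tested <- TRUE
  } else {
    if (any(abs(g - round(g)) > 1e-8)) {
      stop("mixture method requires hard-call genotypes")
    }
    x <- r[round(g) == 1L]
    if (stats::sd(x) == 0) {
      out$statistic <- 0
      out$p <- 1
      out$tested <- TRUE
      return(out)
    }
    ll0 <- sum(stats::dnorm(x, mean(x),
      stats::sd(x) * sqrt((length(x) - 1) / length(x)), log = TRUE))
    alt <- .fit_sym_mixture(x)
    lrt <- max(2 * (alt$loglik - ll0), 0)
    out$statistic <- lrt
    out$p <- if (lrt == 0) 1 else
      0.5 * stats::pchisq(lrt, df = 1, lower.tail = FALSE)
    out$tested <- TRUE
  }
  out
}
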