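# Parent-offspring trait resemblance: correlations, mixed-model slopes and
# their maternal-vs-paternal comparisons.

#' Build parent-offspring trait pairs
#'
#' @param pedigree validated pedigree.
#' @param phenotypes data.frame keyed by `individual_id` containing the trait
#'   column and (when `oldest_only = TRUE`) an `age` column.
#' @param trait trait column name.
#' @param parent `"father"` or `"mother"`.
#' @param offspring_sex optional filter: `"male"` (sons) or `"female"`
#'   (daughters).
#' @param oldest_only keep only the oldest offspring per family (families with
#'   all offspring ages missing are skipped with a warning).
#' @return data.frame with columns `family_id`, `parent_id`, `offspring_id`,
#'   `parent_value`, `offspring_value`.
#' @export
parent_offspring_pairs <- function(pedigree, phenotypes, trait,
                                   parent = c("father", "mother"),
                                   offspring_sex = NULL,
                                   oldest_only = TRUE) {
  parent <- match.arg(parent)
  off <- pedigree[pedigree$role == "offspring", , drop = FALSE]
  if (!is.null(offspring_sex)) {
    off <- off[off$sex == offspring_sex, , drop = FALSE]
  }
  val <- function(ids, col) {
    out <- rep(NA_real_, length(ids))
    hit <- !is.na(ids) & ids %in% phenotypes$individual_id
    out[hit] <- phenotypes[[col]][match(ids[hit], phenotypes$individual_id)]
    out
  }
  if (oldest_only && nrow(off)) {
    if (!"age" %in% names(phenotypes)) {
      stop("oldest_only = TRUE requires an 'age' column in phenotypes")
    }
    age <- val(off$individual_id, "age")
    keep <- unlist(lapply(split(seq_len(nrow(off)), off$family_id),
      function(i) {
        a <- age[i]
        if (all(is.na(a))) {
          warning("family ", off$family_id[i[1]],
            " skipped: offspring ages all missing")
          return(integer(0))
        }
        i[which.max(a)]
      }), use.names = FALSE)
    off <- off[sort(keep), , drop = FALSE]
  }
  pid <- if (parent == "father") off$father_id else off$mother_id
  pv <- val(pid, trait)
  ov <- val(off$individual_id, trait)
  keep <- !is.na(pid) & !is.na(pv) & !is.na(ov)
  data.frame(
    family_id = off$family_id[keep],
    parent_id = pid[keep],
    offspring_id = off$individual_id[keep],
    parent_value = pv[keep],
    offspring_value = ov[keep],
    stringsAsFactors = FALSE
  )
}

#' Spearman (optionally partial) rank correlation
#'
#' Plain Spearman correlation of `x` and `y`, or, given covariates, the
#' partial rank correlation: both variables are ranked, the ranks are
#' residualised on the covariates by least squares, and the Pearson
#' correlation of the residuals is returned. The p-value uses the
#' t-approximation with `n - 2 - k` degrees of freedom (`k` covariates).
#'
#' @param x,y numeric vectors.
#' @param covariates optional data.frame/matrix of covariates (rows aligned
#'   with `x`/`y`).
#' @return list with `r`, `n`, `p`.
#' @export
spearman_partial <- function(x, y, covariates = NULL) {
  cc <- !is.na(x) & !is.na(y)
  k <- 0L
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    cc <- cc & stats::complete.cases(covariates)
    k <- ncol(covariates)
  }
  n <- sum(cc)
  if (n < 4L) {
    return(list(r = NA_real_, n = n, p = NA_real_))
  }
  rx <- rank(x[cc])
  ry <- rank(y[cc])
  if (k > 0L) {
    cv <- covariates[cc, , drop = FALSE]
    cv[] <- lapply(cv, function(col) {
      if (is.numeric(col)) rank(col) else col # rank-based throughout
    })
    Z <- stats::model.matrix(~., data = cv)
    rx <- stats::lm.fit(Z, rx)$residuals
    ry <- stats::lm.fit(Z, ry)$residuals
  }
  r <- stats::cor(rx, ry)
  df <- n - 2L - k
  p <- if (df > 0 && abs(r) < 1) {
    tval <- r * sqrt(df / (1 - r^2))
    2 * stats::pt(-abs(tval), df)
  } else if (abs(r) >= 1) 0 else NA_real_
  list(r = r, n = n, p = p)
}

#' Family random-intercept regression of offspring trait on parent trait
#'
#' Fits `offspring_value ~ parent_value + covariates + (1 | family_id)` with
#' `lme4::lmer` (ML) and returns the parent-trait slope with its standard
#' error and a Wald normal p-value. With no between-family variance the
#' slope coincides with the ordinary least-squares slope.
#'
#' @param pairs output of [parent_offspring_pairs()] (with
#'   `oldest_only = FALSE` for the all-offspring models).
#' @param covariates optional data.frame of offspring covariates, rows
#'   aligned with `pairs`.
#' @param model_tag label stored in the result (`"model2"` by default;
#'   use `"model3"` when covariates include sex, age, age squared and BMI).
#' @return data.frame row: `slope`, `se`, `z`, `p`, `n`, `n_families`,
#'   `converged`, `model`.
#' @export
mixed_slope <- function(pairs, covariates = NULL, model_tag = "model2") {
  dat <- data.frame(
    y = pairs$offspring_value, x = pairs$parent_value,
    family_id = pairs$family_id, stringsAsFactors = FALSE
  )
  form <- y ~ x + (1 | family_id)
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    dat <- cbind(dat, covariates)
    form <- stats::reformulate(
      c("x", colnames(covariates), "(1 | family_id)"),
      response = "y"
    )
  }
  dat <- dat[stats::complete.cases(dat), , drop = FALSE]
  if (length(unique(dat$family_id)) < 2L) {
    stop("mixed_slope needs >= 2 families")
  }
  converged <- TRUE
  if (max(table(dat$family_id)) == 1L) {
    # one observation per family: the random intercept is not identifiable
    # and the model collapses to ordinary least squares
    fit <- stats::lm(lme4::nobars(form), data = dat)
    co <- summary(fit)$coefficients
  } else {
    fit <- withCallingHandlers(
      lme4::lmer(form, data = dat, REML = FALSE,
        control = lme4::lmerControl(check.conv.singular = "ignore")),
      warning = function(w) {
        converged <<- FALSE
        invokeRestart("muffleWarning")
      }
    )
    co <- summary(fit)$coefficients
  }
  b <- co["x", "Estimate"]
  se <- co["x", "Std. Error"]
  z <- b / se
  data.frame(
    slope = b, se = se, z = z, p = 2 * stats::pnorm(-abs(z)),
    n = nrow(dat), n_families = length(unique(dat$family_id)),
    converged = converged, model = model_tag,
    stringsAsFactors = FALSE
  )
}

#' Fisher r-to-z comparison of two independent correlations
#'
#' `z = (atanh(r1) - atanh(r2)) / sqrt(1/(n1-3) + 1/(n2-3))` with a two-sided
#' normal p-value.
#'
#' @param r1,r2 correlations with `|r| < 1`.
#' @param n1,n2 pair counts (each at least 4).
#' @return list with `z` and `p`.
#' @export
fisher_r_to_z_compare <- function(r1, n1, r2, n2) {
  if (any(abs(c(r1, r2)) >= 1)) {
    stop("|r| must be < 1 for the Fisher transform")
  }
  if (any(c(n1, n2) < 4L)) stop("each sample needs n >= 4")
  z <- (atanh(r1) - atanh(r2)) / sqrt(1 / (n1 - 3) + 1 / (n2 - 3))
  list(z = z, p = 2 * stats::pnorm(-abs(z)))
}

#' Wald comparison of two regression slopes
#'
#' `z = (b1 - b2) / sqrt(se1^2 + se2^2)` with a two-sided normal p-value.
#'
#' @param b1,b2 slope estimates.
#' @param se1,se2 their standard errors (positive).
#' @return list with `z` and `p`.
#' @export
wald_slope_compare <- function(b1, se1, b2, se2) {
  if (any(c(se1, se2) <= 0)) stop("standard errors must be positive")
  z <- (b1 - b2) / sqrt(se1^2 + se2^2)
  list(z = z, p = 2 * stats::pnorm(-abs(z)))
}

#' Compare father-offspring and mother-offspring trait correlations
#'
#' Computes the Spearman (optionally partial) correlation for father-offspring
#' and mother-offspring pairs and tests their difference with the Fisher
#' r-to-z comparison. The two correlations share offspring, so the
#' independent-samples test is anti-conservative in principle; a
#' dependent-correlation variant (Steiger's test on the subset of offspring
#' with both parents measured, accounting for the father-mother correlation)
#' is available via `dependent = TRUE`.
#'
#' @inheritParams parent_offspring_pairs
#' @param covariates character vector of covariate column names in
#'   `phenotypes` to partial out (offspring covariates).
#' @param dependent use the dependent-correlation comparison.
#' @return one-row data.frame (trait, stratum, r/n per parent, z, p).
#' @export
compare_parent_offspring <- function(pedigree, phenotypes, trait,
                                     offspring_sex = NULL,
                                     covariates = NULL,
                                     oldest_only = TRUE,
                                     dependent = FALSE) {
  get_pairs <- function(parent) {
    parent_offspring_pairs(pedigree, phenotypes, trait,
      parent = parent, offspring_sex = offspring_sex,
      oldest_only = oldest_only)
  }
  pf <- get_pairs("father")
  pm <- get_pairs("mother")
  cov_for <- function(pairs) {
    if (is.null(covariates)) return(NULL)
    phenotypes[match(pairs$offspring_id, phenotypes$individual_id),
      covariates, drop = FALSE]
  }
  rf <- spearman_partial(pf$parent_value, pf$offspring_value, cov_for(pf))
  rm_ <- spearman_partial(pm$parent_value, pm$offspring_value, cov_for(pm))
  stratum <- if (is.null(offspring_sex)) "all" else
    if (offspring_sex == "male") "sons" else "daughters"
  if (is.na(rf$r) || is.na(rm_$r)) {
    z <- NA_real_; p <- NA_real_
  } else if (dependent) {
    both <- intersect(pf$offspring_id, pm$offspring_id)
    i_f <- match(both, pf$offspring_id)
    i_m <- match(both, pm$offspring_id)
    r12 <- stats::cor(rank(pf$parent_value[i_f]),
      rank(pf$offspring_value[i_f]))
    r13 <- stats::cor(rank(pm$parent_value[i_m]),
      rank(pm$offspring_value[i_m]))
    r23 <- stats::cor(rank(pf$parent_value[i_f]),
      rank(pm$parent_value[i_m]))
    n <- length(both)
    # Steiger (1980) comparison of two correlations sharing a variable
    rbar <- (r12 + r13) / 2
    cov_z <- (r23 * (1 - 2 * rbar^2) - 0.5 * rbar^2 *
      (1 - 2 * rbar^2 - r23^2)) / (1 - rbar^2)^2
    z <- (atanh(r12) - atanh(r13)) * sqrt((n - 3) / (2 - 2 * cov_z))
    p <- 2 * stats::pnorm(-abs(z))
    rf$r <- r12; rf$n <- n; rm_$r <- r13; rm_$n <- n
  } else {
    cmp <- fisher_r_to_z_compare(rf$r, rf$n, rm_$r, rm_$n)
    z <- cmp$z; p <- cmp$p
  }
  data.frame(
    trait = trait, stratum = stratum,
    r_father = rf$r, n_father = rf$n,
    r_mother = rm_$r, n_mother = rm_$n,
    z_diff = z, p_diff = p,
    stringsAsFactors = FALSE
  )
}
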