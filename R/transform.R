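# Trait derivations and normalising transformations.

#' Friedewald estimate of LDL cholesterol
#'
#' `LDL = TC - HDL - TG/5` in mg/dL, valid only when `TG < 400` mg/dL
#' (otherwise `NA`). In mmol/L the same relation reads
#' `LDL = TC - HDL - TG/2.2` with the validity threshold at 4.52 mmol/L.
#' The threshold is exclusive: a TG value exactly at the limit yields `NA`.
#'
#' @param tc,hdl,tg total, HDL cholesterol and triglycerides (non-negative).
#' @param unit `"mg/dL"` or `"mmol/L"`; must be declared explicitly.
#' @return numeric vector of LDL estimates (`NA` where TG is at/over the
#'   threshold or any input is missing).
#' @export
friedewald_ldl <- function(tc, hdl, tg, unit = c("mg/dL", "mmol/L")) {
  unit <- match.arg(unit)
  if (any(tc < 0 | hdl < 0 | tg < 0, na.rm = TRUE)) {
    stop("negative lipid value passed to friedewald_ldl")
  }
  div <- if (unit == "mg/dL") 5 else 2.2
  thr <- if (unit == "mg/dL") 400 else 4.52
  ldl <- tc - hdl - tg / div
  ldl[!is.na(tg) & tg >= thr] <- NA_real_
  ldl
}

#' Blom rank-based inverse normal transformation
#'
#' Replaces each non-missing value by
#' `qnorm((rank - 3/8) / (n + 1/4))`, with average ranks for ties and `n` the
#' number of non-missing values. Missing entries are preserved.
#'
#' @param values numeric vector (possibly with `NA`).
#' @return transformed vector of the same length.
#' @export
blom_transform <- function(values) {
  obs <- !is.na(values)
  n <- sum(obs)
  if (n < 2L) stop("blom_transform needs >= 2 non-missing values")
  x <- values[obs]
  if (max(x) == min(x)) stop("blom_transform undefined for constant input")
  r <- rank(x, ties.method = "average")
  out <- values
  out[obs] <- stats::qnorm((r - 3 / 8) / (n + 1 / 4))
  out
}

#' Natural-log transformation with non-positive values set missing
#'
#' @param values numeric vector.
#' @return `log(values)`, with non-positive entries recorded as `NA`
#'   (with a warning).
#' @export
ln_transform <- function(values) {
  bad <- !is.na(values) & values <= 0
  if (any(bad)) {
    warning(sum(bad), " non-positive value(s) set to NA before log transform")
    values[bad] <- NA_real_
  }
  log(values)
}

#' Single-pass k-SD outlier filter
#'
#' Computes the mean and SD of the non-missing values once and sets to `NA`
#' every value farther than `k` SD from the mean. Intended to run on the
#' transformed scale; a single pass suffices in practice (remaining data lie
#' well inside the band), making the filter idempotent on its own output.
#'
#' @param values numeric vector.
#' @param k SD multiplier (default 5).
#' @return list with `values` (filtered vector) and `removed` (integer indices
#'   of removed entries).
#' @export
sd_outlier_filter <- function(values, k = 5) {
  obs <- which(!is.na(values))
  if (length(obs) < 3L) stop("sd_outlier_filter needs >= 3 non-missing values")
  mu <- mean(values[obs])
  s <- stats::sd(values[obs])
  if (is.na(s) || s == 0) {
    return(list(values = values, removed = integer(0)))
  }
  removed <- obs[abs(values[obs] - mu) > k * s]
  values[removed] <- NA_real_
  list(values = values, removed = removed)
}

# traits -> transformation scheme: Blom for TG, ApoB, LDL and all obesity
# measures; natural log for the remaining lipid measures.
.blom_traits <- c("tg", "apob", "ldl", "bmi", "whr", "whtr")
.ln_traits <- c("tc", "hdl", "apoa1", "apoa2", "apob_apoa1")

#' Derive and transform the standard lipid/obesity trait set
#'
#' Fills in derived traits where their inputs are present and not already
#' supplied: `bmi = weight / height^2`, `whr = waist / hip`,
#' `whtr = waist / height`, `apob_apoa1 = apob / apoa1`, and Friedewald LDL
#' from TC/HDL/TG. Each trait is then normalised per the standard scheme
#' (Blom inverse-normal for TG, ApoB, LDL and all obesity measures; natural
#' log for the other lipid measures) and passed through the single-pass k-SD
#' outlier filter on the transformed scale. An `age2 = age^2` covariate
#' column is added when `age` is present.
#'
#' Expected column names (any subset): `height` (m), `weight` (kg), `waist`
#' (cm), `hip` (cm), `tc`, `tg`, `hdl`, `ldl`, `apoa1`, `apoa2`, `apob`,
#' plus identifiers/covariates which are carried through untouched.
#'
#' @param pheno phenotype data.frame.
#' @param lipid_unit unit of TC/TG/HDL: `"mmol/L"` or `"mg/dL"`. Must be
#'   declared explicitly whenever lipid columns are present.
#' @param k_sd SD multiplier for the outlier filter (default 5).
#' @param filter_scale apply the outlier filter on the `"transformed"`
#'   (default) or `"raw"` scale.
#' @return the phenotype table with derived/transformed trait columns; the
#'   applied transformation per trait is recorded in `attr(x, "transforms")`
#'   and the removed outlier count per trait in `attr(x, "outliers_removed")`.
#' @export
derive_traits <- function(pheno, lipid_unit,
                          k_sd = 5,
                          filter_scale = c("transformed", "raw")) {
  filter_scale <- match.arg(filter_scale)
  has <- function(v) v %in% names(pheno)
  lipid_cols <- intersect(c("tc", "tg", "hdl", "ldl", "apoa1", "apoa2", "apob"),
    names(pheno))
  if (length(lipid_cols) && missing(lipid_unit)) {
    stop("lipid_unit must be declared ('mmol/L' or 'mg/dL')")
  }
  if (missing(lipid_unit)) lipid_unit <- "mmol/L"
  lipid_unit <- match.arg(lipid_unit, c("mmol/L", "mg/dL"))

  anthro <- intersect(c("height", "weight", "waist", "hip"), names(pheno))
  for (v in anthro) {
    if (any(!is.na(pheno[[v]]) & pheno[[v]] <= 0)) {
      stop("anthropometric column '", v, "' must be strictly positive")
    }
  }
  if (!has("bmi") && has("weight") && has("height")) {
    pheno$bmi <- pheno$weight / pheno$height^2
  }
  if (!has("whr") && has("waist") && has("hip")) {
    pheno$whr <- pheno$waist / pheno$hip
  }
  if (!has("whtr") && has("waist") && has("height")) {
    # waist in cm, height in m
    pheno$whtr <- pheno$waist / (pheno$height * 100)
  }
  if (!has("ldl") && has("tc") && has("hdl") && has("tg")) {
    pheno$ldl <- friedewald_ldl(pheno$tc, pheno$hdl, pheno$tg,
      unit = lipid_unit)
  }
  if (!has("apob_apoa1") && has("apob") && has("apoa1")) {
    pheno$apob_apoa1 <- pheno$apob / pheno$apoa1
  }
  if (has("age") && !has("age2")) pheno$age2 <- pheno$age^2

  transforms <- character(0)
  outliers <- integer(0)
  for (v in c(.blom_traits, .ln_traits)) {
    if (!has(v)) next
    x <- pheno[[v]]
    if (sum(!is.na(x)) < 3L) next
    if (filter_scale == "raw") x <- sd_outlier_filter(x, k = k_sd)$values
    tx <- if (v %in% .blom_traits) blom_transform(x) else ln_transform(x)
    if (filter_scale == "transformed") {
      flt <- sd_outlier_filter(tx, k = k_sd)
      tx <- flt$values
      outliers[v] <- length(flt$removed)
    } else {
      outliers[v] <- sum(is.na(x)) - sum(is.na(pheno[[v]]))
    }
    pheno[[v]] <- tx
    transforms[v] <- if (v %in% .blom_traits) "blom" else "ln"
  }
  attr(pheno, "transforms") <- transforms
  attr(pheno, "outliers_removed") <- outliers
  attr(pheno, "lipid_unit") <- lipid_unit
  pheno
}
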