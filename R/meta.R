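# Fixed-effects meta-analysis of per-cohort POE estimates.

#' Inverse-variance fixed-effects meta-analysis
#'
#' Weights `w_i = 1 / se_i^2`; meta beta `sum(w b) / sum(w)`, meta SE
#' `1 / sqrt(sum(w))`, z = beta / se, two-sided normal p. A single estimate
#' is passed through with a warning.
#'
#' @param beta per-cohort effect estimates.
#' @param se their standard errors (positive).
#' @return list with `beta`, `se`, `z`, `p`, `k`, `direction` (one `+`/`-`
#'   per cohort), `method = "inverse_variance"`.
#' @export
inverse_variance_meta <- function(beta, se) {
  stopifnot(length(beta) == length(se))
  if (any(is.na(beta) | is.na(se))) stop("missing estimates not allowed")
  if (any(se <= 0)) stop("standard errors must be positive")
  if (length(beta) < 2L) {
    warning("single estimate: meta-analysis is a passthrough")
  }
  w <- 1 / se^2
  b <- sum(w * beta) / sum(w)
  s <- 1 / sqrt(sum(w))
  z <- b / s
  list(
    beta = b, se = s, z = z, p = 2 * stats::pnorm(-abs(z)),
    k = length(beta),
    direction = paste(ifelse(beta >= 0, "+", "-"), collapse = ""),
    method = "inverse_variance"
  )
}

#' Sample-size-weighted z-score meta-analysis
#'
#' `z_meta = sum(z_i * sqrt(n_i)) / sqrt(sum(n_i))` with signed per-cohort z
#' scores and a two-sided normal p-value.
#'
#' @param z signed per-cohort z statistics.
#' @param n per-cohort sample sizes (positive).
#' @return list with `z`, `p`, `k`, `direction`,
#'   `method = "sample_size_z"`.
#' @export
sample_size_meta <- function(z, n) {
  stopifnot(length(z) == length(n))
  if (any(is.na(z) | is.na(n))) stop("missing estimates not allowed")
  if (any(n <= 0)) stop("sample sizes must be positive")
  if (length(z) < 2L) {
    warning("single estimate: meta-analysis is a passthrough")
  }
  zm <- sum(z * sqrt(n)) / sqrt(sum(n))
  list(
    z = zm, p = 2 * stats::pnorm(-abs(zm)), k = length(z),
    direction = paste(ifelse(z >= 0, "+", "-"), collapse = ""),
    method = "sample_size_z"
  )
}

#' Do all per-cohort effect estimates share a sign?
#'
#' @param beta per-cohort estimates (`NA` entries ignored).
#' @return logical flag.
#' @export
direction_consistency <- function(beta) {
  beta <- beta[!is.na(beta)]
  if (!length(beta)) stop("no non-missing estimates")
  if (length(beta) < 2L) {
    warning("single estimate: direction is trivially consistent")
    return(TRUE)
  }
  all(beta > 0) || all(beta < 0)
}

#' Meta-analyse POE contrasts across cohorts
#'
#' Combines the parent-of-origin contrast (`b_poe`, `se_poe`) of matching
#' SNP x trait x stratum rows across two or more association-result tables
#' (one per cohort) by inverse-variance (default) or sample-size-weighted
#' fixed-effects meta-analysis.
#'
#' @param results_list list of [run_analysis()] outputs, one per cohort.
#' @param method `"inverse_variance"` or `"sample_size_z"`.
#' @return data.frame with per-row meta beta/SE/z/p, cohort count, direction
#'   string and direction-consistency flag.
#' @export
meta_poe <- function(results_list,
                     method = c("inverse_variance", "sample_size_z")) {
  method <- match.arg(method)
  if (length(results_list) < 2L) stop("need >= 2 cohorts")
  all_res <- do.call(rbind, lapply(seq_along(results_list), function(i) {
    r <- results_list[[i]]
    r$.cohort_idx <- i
    r[, c("snp_id", "trait", "stratum", "b_poe", "se_poe", "p_poe",
      "n_het", ".cohort_idx")]
  }))
  all_res <- all_res[!is.na(all_res$b_poe) & !is.na(all_res$se_poe), ,
    drop = FALSE]
  keys <- unique(all_res[, c("snp_id", "trait", "stratum")])
  rows <- lapply(seq_len(nrow(keys)), function(i) {
    sub <- all_res[
      all_res$snp_id == keys$snp_id[i] &
        all_res$trait == keys$trait[i] &
        all_res$stratum == keys$stratum[i], , drop = FALSE
    ]
    if (nrow(sub) < 2L) return(NULL)
    m <- if (method == "inverse_variance") {
      inverse_variance_meta(sub$b_poe, sub$se_poe)
    } else {
      z <- sub$b_poe / sub$se_poe
      c(sample_size_meta(z, sub$n_het), list(beta = NA_real_, se = NA_real_))
    }
    data.frame(
      snp_id = keys$snp_id[i], trait = keys$trait[i],
      stratum = keys$stratum[i], k = m$k,
      meta_beta = m$beta, meta_se = m$se, meta_z = m$z, meta_p = m$p,
      direction = m$direction,
      direction_consistent = suppressWarnings(
        direction_consistency(sub$b_poe)),
      method = m$method,
      stringsAsFactors = FALSE
    )
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) {
    stop("no SNP x trait x stratum combination present in >= 2 cohorts")
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
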