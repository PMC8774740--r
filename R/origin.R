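# Inference of the parental origin of minor alleles from trio/duo genotypes.

#' Infer parental origin of minor alleles for one offspring genotype
#'
#' Given an offspring minor-allele count and the (possibly missing) parental
#' counts, determines how many minor alleles were transmitted maternally and
#' paternally. A call is `assigned` when exactly one ordered transmission
#' configuration (maternal allele, paternal allele) is compatible with the
#' observed genotypes, `mendelian_error` when none is, `ambiguous` when more
#' than one is compatible and at least one parent is observed, and
#' `untestable` when more than one is compatible and both parents are missing
#' (i.e. a heterozygous offspring with no parental information). Homozygous
#' offspring have a logically certain origin split (0/0 or 1/1) and are
#' `assigned` whenever no Mendelian inconsistency arises.
#'
#' All arguments are vectorised and recycled to a common length.
#'
#' @param offspring_gt offspring minor-allele count in `{0, 1, 2}`
#'   (non-missing).
#' @param mother_gt,father_gt parental minor-allele counts in `{0, 1, 2}` or
#'   `NA`.
#' @return data.frame with columns `status`, `maternal_minor`,
#'   `paternal_minor`; the two counts are `NA` unless `status == "assigned"`,
#'   in which case they sum to `offspring_gt`.
#' @export
infer_trio_origin <- function(offspring_gt, mother_gt = NA, father_gt = NA) {
  n <- max(length(offspring_gt), length(mother_gt), length(father_gt))
  o <- rep_len(as.integer(offspring_gt), n)
  m <- rep_len(as.integer(mother_gt), n)
  f <- rep_len(as.integer(father_gt), n)
  if (anyNA(o)) stop("offspring genotype must be non-missing")
  chk <- function(g, who) {
    if (any(!is.na(g) & !(g %in% 0:2))) {
      stop("invalid ", who, " genotype code (expected 0/1/2/NA)")
    }
  }
  chk(o, "offspring"); chk(m, "mother"); chk(f, "father")

  can0 <- function(g) is.na(g) | g <= 1L # can transmit the major allele
  can1 <- function(g) is.na(g) | g >= 1L # can transmit the minor allele

  status <- rep("mendelian_error", n)
  mat <- rep(NA_integer_, n)
  pat <- rep(NA_integer_, n)

  i0 <- o == 0L
  ok <- i0 & can0(m) & can0(f)
  status[ok] <- "assigned"; mat[ok] <- 0L; pat[ok] <- 0L

  i2 <- o == 2L
  ok <- i2 & can1(m) & can1(f)
  status[ok] <- "assigned"; mat[ok] <- 1L; pat[ok] <- 1L

  i1 <- o == 1L
  cfg_mp <- i1 & can1(m) & can0(f) # maternal minor, paternal major
  cfg_pm <- i1 & can0(m) & can1(f) # maternal major, paternal minor
  ncfg <- cfg_mp + cfg_pm
  ok <- i1 & ncfg == 1L
  status[ok] <- "assigned"
  mat[ok] <- as.integer(cfg_mp[ok])
  pat[ok] <- as.integer(cfg_pm[ok])
  amb <- i1 & ncfg == 2L
  status[amb] <- ifelse(is.na(m[amb]) & is.na(f[amb]),
    "untestable", "ambiguous")

  data.frame(
    status = status, maternal_minor = mat, paternal_minor = pat,
    stringsAsFactors = FALSE
  )
}

#' Infer parental allele origins for every offspring in a cohort
#'
#' One origin call per offspring x SNP with a non-missing offspring genotype;
#' parental genotypes are looked up through the pedigree links (missing when
#' the parent is absent or ungenotyped).
#'
#' @param pedigree validated pedigree (see [read_pedigree()]).
#' @param genotypes genotype matrix of minor-allele counts.
#' @return data.frame with columns `family_id`, `individual_id`, `snp_id`,
#'   `status`, `maternal_minor`, `paternal_minor`. The per-SNP status counts
#'   are available via [origin_summary()].
#' @export
infer_cohort_origins <- function(pedigree, genotypes) {
  off <- pedigree[pedigree$role == "offspring", , drop = FALSE]
  lk <- function(ids, snp) {
    out <- rep(NA_integer_, length(ids))
    hit <- !is.na(ids) & ids %in% rownames(genotypes)
    out[hit] <- genotypes[ids[hit], snp]
    out
  }
  snps <- colnames(genotypes)
  res <- vector("list", length(snps))
  for (k in seq_along(snps)) {
    snp <- snps[k]
    o <- lk(off$individual_id, snp)
    keep <- !is.na(o)
    if (!any(keep)) next
    calls <- infer_trio_origin(
      o[keep], lk(off$mother_id, snp)[keep], lk(off$father_id, snp)[keep]
    )
    res[[k]] <- data.frame(
      family_id = off$family_id[keep],
      individual_id = off$individual_id[keep],
      snp_id = snp,
      calls,
      stringsAsFactors = FALSE
    )
  }
  res <- res[!vapply(res, is.null, logical(1))]
  if (!length(res)) {
    return(data.frame(
      family_id = character(), individual_id = character(),
      snp_id = character(), status = character(),
      maternal_minor = integer(), paternal_minor = integer(),
      stringsAsFactors = FALSE
    ))
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Per-SNP summary of origin-call statuses
#'
#' @param origins output of [infer_cohort_origins()].
#' @return data.frame with one row per SNP and columns `assigned`,
#'   `ambiguous`, `mendelian_error`, `untestable`.
#' @export
origin_summary <- function(origins) {
  lv <- c("assigned", "ambiguous", "mendelian_error", "untestable")
  tab <- table(
    factor(origins$snp_id), factor(origins$status, levels = lv)
  )
  out <- as.data.frame.matrix(tab)
  out <- cbind(snp_id = rownames(out), out)
  rownames(out) <- NULL
  out
}
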