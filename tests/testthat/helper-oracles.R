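# Independent brute-force oracles used across the suite.

# Origin-call oracle: enumerate all ordered parental transmissions
# (maternal allele, paternal allele) compatible with the observed genotypes
# and classify by the number of surviving configurations.
oracle_trio_origin <- function(o, m, f) {
  # transmissible alleles: each parent passes one of its two alleles
  alleles <- function(g) {
    if (is.na(g)) c(0L, 1L) else unique(c(
      if (g <= 1L) 0L, if (g >= 1L) 1L
    ))
  }
  cfgs <- list()
  for (am in alleles(m)) {
    for (ap in alleles(f)) {
      if (am + ap == o) cfgs[[length(cfgs) + 1L]] <- c(am, ap)
    }
  }
  cfgs <- unique(cfgs)
  if (length(cfgs) == 0L) {
    return(list(status = "mendelian_error",
      maternal = NA_integer_, paternal = NA_integer_))
  }
  if (length(cfgs) == 1L) {
    return(list(status = "assigned",
      maternal = cfgs[[1]][1], paternal = cfgs[[1]][2]))
  }
  status <- if (is.na(m) && is.na(f)) "untestable" else "ambiguous"
  list(status = status, maternal = NA_integer_, paternal = NA_integer_)
}

# Exact HWE oracle: place the minor alleles on the 2n allele slots in every
# possible way (all allocations equally likely given the allele counts),
# pair consecutive slots into genotypes, and tally heterozygote counts.
oracle_hwe_pvalue <- function(n_major, n_het, n_minor) {
  n <- n_major + n_het + n_minor
  na <- 2L * n_minor + n_het
  slots <- 2L * n
  if (na == 0L || na == slots) return(1)
  combos <- utils::combn(slots, na)
  hets <- apply(combos, 2, function(pos) {
    minor <- rep(0L, slots)
    minor[pos] <- 1L
    g <- minor[seq(1, slots, 2)] + minor[seq(2, slots, 2)]
    sum(g == 1L)
  })
  tab <- table(hets) / ncol(combos)
  p_obs <- tab[[as.character(n_het)]]
  sum(tab[tab <= p_obs * (1 + 1e-12)])
}

# weighted-least-squares oracle for the inverse-variance meta estimate
oracle_ivw <- function(beta, se) {
  fit <- stats::lm(beta ~ 1, weights = 1 / se^2)
  c(coef(fit), sqrt(1 / sum(1 / se^2)))
}

# small canonical trio pedigree writer used by the IO tests
write_tiny_pedigree <- function(path,
                                father_sex = "1",
                                child_father = "P1") {
  lines <- c(
    "family_id\tindividual_id\tfather_id\tmother_id\tsex",
    paste("F1", "P1", "0", "0", father_sex, sep = "\t"),
    "F1\tP2\t0\t0\t2",
    paste("F1", "C1", child_father, "P2", "1", sep = "\t")
  )
  writeLines(lines, path)
  path
}

# quick null family cohort for calibration-style tests
null_cohort_config <- function(seed, n_families = 300, maf = 0.3,
                               beta_mat = 0, beta_pat = 0, ...) {
  sim_config(
    seed = seed, n_families = n_families,
    snps = data.frame(snp_id = "s1", maf = maf,
      beta_mat = beta_mat, beta_pat = beta_pat,
      stringsAsFactors = FALSE),
    traits = list(bmi = c(26.69, 4.61)),
    focal_trait = "bmi", ...
  )
}

# fit the three POE contrasts for the focal trait of a simulated cohort and
# return the association row
fit_focal_assoc <- function(cohort, splits = "combined", strata = "all",
                            contrast_mode = "subset") {
  ph <- cohort$phenotypes
  ph$bmi <- blom_transform(ph$bmi)
  plan <- poe_plan(
    traits = data.frame(trait = "bmi", family = "obesity",
      stringsAsFactors = FALSE),
    splits = splits, strata = strata, contrast_mode = contrast_mode
  )
  run_analysis(plan, list(
    pedigree = cohort$pedigree, genotypes = cohort$genotypes,
    phenotypes = ph
  ))
}

# lean single-SNP fit of the three contrasts using the package machinery;
# returns the estimates needed by calibration/recovery loops
focal_contrast_fit <- function(seed, n_families = 300, maf = 0.3,
                               bm = 0, bp = 0) {
  co <- simulate_families(null_cohort_config(seed, n_families = n_families,
    maf = maf, beta_mat = bm, beta_pat = bp))
  ph <- co$phenotypes
  ph$bmi <- blom_transform(ph$bmi)
  origins <- infer_cohort_origins(co$pedigree, co$genotypes)
  one <- function(contrast) {
    s <- suppressWarnings(build_contrast_sample(origins, co$genotypes,
      "s1", contrast))
    i <- match(s$individual_id, ph$individual_id)
    d <- ph[i, , drop = FALSE]
    d$exposure <- s$exposure
    d$fam <- s$family_id
    gee_fit(bmi ~ exposure + sex + age + age2 + diabetes, d, id = "fam")
  }
  fm <- one("maternal"); fp <- one("paternal"); fo <- one("poe")
  c(
    b_mat = unname(fm$coefficients["exposure"]),
    se_mat = unname(fm$se["exposure"]),
    b_pat = unname(fp$coefficients["exposure"]),
    se_pat = unname(fp$se["exposure"]),
    b_poe = unname(fo$coefficients["exposure"]),
    se_poe = unname(fo$se["exposure"]),
    p_poe = unname(fo$p["exposure"])
  )
}

# heterozygote / pooled-homozygote residual-variance ratio for one simulated
# unrelated cohort, plus the variance-test p-value
het_ratio_fit <- function(seed, n = 3000, maf = 0.5, bm = 0, bp = 0) {
  cfg <- sim_config(seed = seed,
    snps = data.frame(snp_id = "s1", maf = maf, beta_mat = bm,
      beta_pat = bp, stringsAsFactors = FALSE),
    traits = list(bmi = c(26.69, 4.61)), focal_trait = "bmi")
  u <- simulate_unrelateds(cfg, n)
  out <- het_variance_test(u$phenotypes$bmi, u$genotypes[, 1],
    covariates = u$phenotypes[, c("sex", "age", "age2", "diabetes")])
  ratio <- out$var1 / ((out$n0 * out$var0 + out$n2 * out$var2) /
    (out$n0 + out$n2))
  c(ratio = unname(ratio), p = out$p)
}
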