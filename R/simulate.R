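# Synthetic nuclear-family and unrelated cohorts with tracked allele origins.
#
# The generator emulates the structure of large Scandinavian/Hungarian family
# cohorts: ~2257 nuclear families with 1-2 genotyped parents and 1+ offspring
# (offspring make up ~44% of individuals), biallelic candidate SNPs in HWE
# with Mendelian transmission, trait distributions matching published cohort
# means/SDs, parental-origin-specific and sex-specific allele effects, a
# family-level random intercept, and genotype/phenotype missingness.

#' Trait mean/SD presets for the two emulated family cohorts
#'
#' Published cohort characteristics (all-individuals column): BMI, WHR, WHtR
#' and — for the Botnia-like preset — the lipid panel (TC, TG, LDL, HDL in
#' mmol/L; ApoA1, ApoA2, ApoB in mg/L; ApoB/ApoA1 ratio). The HTB-like preset
#' has no lipid panel.
#'
#' @param cohort `"botnia"` or `"htb"`.
#' @return named list, each element `c(mean, sd)`.
#' @export
table1_defaults <- function(cohort = c("botnia", "htb")) {
  cohort <- match.arg(cohort)
  if (cohort == "botnia") {
    list(
      bmi = c(26.69, 4.61), whr = c(0.90, 0.10), whtr = c(0.54, 0.08),
      tc = c(5.44, 1.11), tg = c(1.47, 0.94), ldl = c(3.47, 0.99),
      hdl = c(1.31, 0.35), apoa1 = c(135.88, 22.98),
      apoa2 = c(36.06, 12.63), apob = c(93.39, 23.84),
      apob_apoa1 = c(0.71, 0.22)
    )
  } else {
    list(
      bmi = c(27.89, 5.45), whr = c(0.86, 0.13), whtr = c(0.52, 0.09)
    )
  }
}

#' Simulation configuration for synthetic cohorts
#'
#' Defines the complete generative truth: family structure, SNP panel with
#' parental-origin-specific effects (in trait-SD units, applied to
#' `focal_trait` on the latent analysis scale), sex-specific effect
#' multipliers, covariate coefficients, variance components, trait mean/SD
#' targets and missingness rates.
#'
#' @param seed integer seed; all randomness in the generator flows from it.
#' @param n_families number of nuclear families.
#' @param offspring_lambda offspring per family is `1 + Poisson(lambda)`,
#'   truncated at `max_offspring`.
#' @param max_offspring truncation for the offspring count.
#' @param snps data.frame with columns `snp_id`, `maf` (in (0, 0.5]),
#'   `beta_mat`, `beta_pat` (latent-SD units per maternally/paternally
#'   inherited minor allele).
#' @param daughter_mult,son_mult multiplicative scaling of
#'   (`beta_mat`, `beta_pat`) by offspring sex.
#' @param covar_coef latent-scale coefficients for standardised age,
#'   age squared, sex, diabetes status and (lipid traits only) BMI.
#' @param family_sd SD of the shared family random intercept.
#' @param resid_sd residual SD; the default makes the latent trait have unit
#'   variance under the null together with `family_sd = 0.3`.
#' @param traits named list of `c(mean, sd)` targets
#'   (default [table1_defaults()] for the Botnia-like preset).
#' @param focal_trait the trait carrying the genetic effects.
#' @param geno_missing element-wise genotype missingness rate.
#' @param parent_untyped probability that a parent is entirely ungenotyped
#'   (at least one genotyped parent per family is enforced).
#' @param pheno_missing element-wise phenotype missingness rate.
#' @param diabetes_prev_offspring,diabetes_prev_parent prevalence of the
#'   binary diabetes-affection covariate.
#' @return list of class `sim_config` (validated; invalid values are a hard
#'   error before any sampling).
#' @export
sim_config <- function(seed = 1L,
                       n_families = 2257L,
                       offspring_lambda = 0.5,
                       max_offspring = 5L,
                       snps = data.frame(
                         snp_id = "snp1", maf = 0.3,
                         beta_mat = 0, beta_pat = 0,
                         stringsAsFactors = FALSE
                       ),
                       daughter_mult = 1,
                       son_mult = 1,
                       covar_coef = c(age = 0.2, age2 = 0.05, sex = 0.2,
                         diabetes = 0.3, bmi = 0.3),
                       family_sd = 0.3,
                       resid_sd = sqrt(1 - 0.09),
                       traits = table1_defaults("botnia"),
                       focal_trait = "bmi",
                       geno_missing = 0.05,
                       parent_untyped = 0.15,
                       pheno_missing = 0.05,
                       diabetes_prev_offspring = 0.27,
                       diabetes_prev_parent = 0.41) {
  cfg <- list(
    seed = as.integer(seed), n_families = as.integer(n_families),
    offspring_lambda = offspring_lambda,
    max_offspring = as.integer(max_offspring),
    snps = as.data.frame(snps), daughter_mult = daughter_mult,
    son_mult = son_mult, covar_coef = covar_coef,
    family_sd = family_sd, resid_sd = resid_sd, traits = traits,
    focal_trait = focal_trait, geno_missing = geno_missing,
    parent_untyped = parent_untyped, pheno_missing = pheno_missing,
    diabetes_prev_offspring = diabetes_prev_offspring,
    diabetes_prev_parent = diabetes_prev_parent
  )
  need <- c("snp_id", "maf", "beta_mat", "beta_pat")
  if (!all(need %in% names(cfg$snps))) {
    stop("snps needs columns: ", paste(need, collapse = ", "))
  }
  if (any(cfg$snps$maf <= 0 | cfg$snps$maf > 0.5)) {
    stop("maf must lie in (0, 0.5]")
  }
  if (cfg$n_families < 1L) stop("n_families must be >= 1")
  if (cfg$family_sd < 0 || cfg$resid_sd < 0) stop("SDs must be >= 0")
  rates <- c(cfg$geno_missing, cfg$parent_untyped, cfg$pheno_missing)
  if (any(rates < 0 | rates >= 1)) stop("missingness rates must be in [0, 1)")
  if (!cfg$focal_trait %in% names(cfg$traits)) {
    stop("focal_trait must be one of the configured traits")
  }
  class(cfg) <- "sim_config"
  cfg
}

# latent z for one trait given genetic and covariate inputs
.latent_trait <- function(gen_effect, age, sex, diabetes, bmi_z, coef,
                          use_bmi, fam_eff, resid) {
  age_z <- (age - 50) / 16
  z <- gen_effect +
    coef[["age"]] * age_z + coef[["age2"]] * age_z^2 +
    coef[["sex"]] * ifelse(sex == "male", 0.5, -0.5) +
    coef[["diabetes"]] * diabetes +
    fam_eff + resid
  if (use_bmi) z <- z + coef[["bmi"]] * bmi_z
  z
}

#' Simulate a nuclear-family cohort with tracked allele origins
#'
#' Parents are drawn under HWE at the configured minor-allele frequencies;
#' offspring alleles follow Mendelian transmission with the transmitted
#' origin recorded. The latent (analysis-scale) focal trait is
#' `beta_mat * (maternal minor count) + beta_pat * (paternal minor count)`
#' (scaled by the offspring-sex multiplier) plus covariate terms, a shared
#' family intercept and residual noise; every trait is then mapped to its
#' configured mean/SD by a location-scale transform. Parents receive the same
#' genetic effect through hidden random origins of their own alleles.
#' Missingness is applied last. Mendelian consistency holds exactly and runs
#' with identical seeds are identical.
#'
#' @param config a [sim_config()].
#' @return list of class `poe_cohort` with elements `pedigree`, `genotypes`,
#'   `origins_true` (long data.frame of true maternal/paternal minor counts
#'   for offspring), `phenotypes`, `config`.
#' @export
simulate_families <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  .with_seed(config$seed, {
    n_fam <- config$n_families
    k <- pmin(1L + stats::rpois(n_fam, config$offspring_lambda),
      config$max_offspring)
    fam <- sprintf("F%05d", seq_len(n_fam))
    fam_of_off <- rep(fam, k)
    n_off <- sum(k)
    off_id <- paste0(fam_of_off, "_C",
      unlist(lapply(k, seq_len), use.names = FALSE))
    father <- paste0(fam, "_F")
    mother <- paste0(fam, "_M")
    ped <- data.frame(
      family_id = c(fam, fam, fam_of_off),
      individual_id = c(father, mother, off_id),
      father_id = c(rep(NA_character_, 2L * n_fam), paste0(fam_of_off, "_F")),
      mother_id = c(rep(NA_character_, 2L * n_fam), paste0(fam_of_off, "_M")),
      sex = c(rep("male", n_fam), rep("female", n_fam),
        sample(c("male", "female"), n_off, replace = TRUE)),
      stringsAsFactors = FALSE
    )
    ped <- validate_pedigree(ped)
    n_all <- nrow(ped)
    snps <- config$snps
    S <- nrow(snps)
    gt <- matrix(NA_integer_, n_all, S,
      dimnames = list(ped$individual_id, snps$snp_id))
    mat_cnt <- matrix(NA_integer_, n_all, S,
      dimnames = list(ped$individual_id, snps$snp_id))
    pat_cnt <- matrix(NA_integer_, n_all, S,
      dimnames = list(ped$individual_id, snps$snp_id))
    off_rows <- match(off_id, ped$individual_id)
    f_rows <- match(father, ped$individual_id)
    m_rows <- match(mother, ped$individual_id)
    fo_rows <- match(paste0(fam_of_off, "_F"), ped$individual_id)
    mo_rows <- match(paste0(fam_of_off, "_M"), ped$individual_id)
    for (s in seq_len(S)) {
      q <- snps$maf[s]
      g_f <- stats::rbinom(n_fam, 2L, q)
      g_m <- stats::rbinom(n_fam, 2L, q)
      gt[f_rows, s] <- g_f
      gt[m_rows, s] <- g_m
      # hidden origins of the parents' own alleles (grandparental, 50/50)
      for (rows in list(f_rows, m_rows)) {
        gp <- gt[rows, s]
        m1 <- integer(length(gp))
        het <- gp == 1L
        m1[het] <- stats::rbinom(sum(het), 1L, 0.5)
        m1[gp == 2L] <- 1L
        mat_cnt[rows, s] <- m1
        pat_cnt[rows, s] <- gp - m1
      }
      a_m <- stats::rbinom(n_off, 1L, gt[mo_rows, s] / 2)
      a_f <- stats::rbinom(n_off, 1L, gt[fo_rows, s] / 2)
      gt[off_rows, s] <- a_m + a_f
      mat_cnt[off_rows, s] <- a_m
      pat_cnt[off_rows, s] <- a_f
    }
    is_parent <- ped$role == "parent"
    age <- numeric(n_all)
    age[is_parent] <- pmin(pmax(stats::rnorm(sum(is_parent), 59.9, 12.5),
      35), 95)
    age[!is_parent] <- pmin(pmax(stats::rnorm(sum(!is_parent), 44.4, 16.1),
      18), 85)
    diabetes <- stats::rbinom(n_all, 1L, ifelse(is_parent,
      config$diabetes_prev_parent, config$diabetes_prev_offspring))
    sex_mult <- ifelse(ped$sex == "male", config$son_mult,
      config$daughter_mult)
    gen <- drop(mat_cnt %*% snps$beta_mat + pat_cnt %*% snps$beta_pat) *
      sex_mult
    fam_eff <- stats::rnorm(n_fam, 0, config$family_sd)
    fam_eff <- fam_eff[match(ped$family_id, fam)]
    pheno <- data.frame(
      individual_id = ped$individual_id, family_id = ped$family_id,
      sex = ped$sex, age = age, age2 = age^2, diabetes = diabetes,
      stringsAsFactors = FALSE
    )
    bmi_z <- NULL
    for (tr in names(config$traits)) {
      ms <- config$traits[[tr]]
      g_tr <- if (tr == config$focal_trait) gen else 0
      z <- .latent_trait(
        g_tr, age, ped$sex, diabetes,
        bmi_z = if (is.null(bmi_z)) 0 else bmi_z,
        coef = config$covar_coef,
        use_bmi = !is.null(bmi_z) &&
          tr %in% c("tc", "tg", "ldl", "hdl", "apoa1", "apoa2", "apob",
            "apob_apoa1"),
        fam_eff = fam_eff,
        resid = stats::rnorm(n_all, 0, config$resid_sd)
      )
      if (tr == "bmi") bmi_z <- z
      pheno[[tr]] <- ms[1] + ms[2] * z
    }
    origins_true <- data.frame(
      family_id = rep(fam_of_off, S),
      individual_id = rep(off_id, S),
      snp_id = rep(snps$snp_id, each = n_off),
      maternal_minor = as.integer(mat_cnt[off_rows, ]),
      paternal_minor = as.integer(pat_cnt[off_rows, ]),
      stringsAsFactors = FALSE
    )
    # missingness last: whole-parent non-genotyping (>= 1 typed parent per
    # family), then element-wise genotype and phenotype dropout
    if (config$parent_untyped > 0) {
      drop_f <- stats::runif(n_fam) < config$parent_untyped
      drop_m <- stats::runif(n_fam) < config$parent_untyped
      both <- drop_f & drop_m
      keep_f <- stats::runif(sum(both)) < 0.5
      drop_f[both][keep_f] <- FALSE
      drop_m[both][!keep_f] <- FALSE
      gt[f_rows[drop_f], ] <- NA_integer_
      gt[m_rows[drop_m], ] <- NA_integer_
    }
    if (config$geno_missing > 0) {
      gt[stats::runif(length(gt)) < config$geno_missing] <- NA_integer_
    }
    if (config$pheno_missing > 0) {
      for (tr in names(config$traits)) {
        pheno[[tr]][stats::runif(n_all) < config$pheno_missing] <- NA_real_
      }
    }
    structure(list(
      pedigree = ped, genotypes = gt, origins_true = origins_true,
      phenotypes = pheno, config = config
    ), class = "poe_cohort")
  })
}

#' Simulate unrelated individuals with hidden allele origins
#'
#' Each individual is the offspring of a pair of unobserved parents drawn
#' under HWE; the phenotype uses the true (hidden) allele origins, so
#' opposite parental effects inflate the heterozygote variance, but the
#' returned data expose the genotype only. The truth is returned separately
#' for validation.
#'
#' @param config a [sim_config()] (family parameters are ignored).
#' @param n number of individuals.
#' @return list with `genotypes` (matrix), `phenotypes` (data.frame) and
#'   `truth` (hidden origin counts).
#' @export
simulate_unrelateds <- function(config, n) {
  stopifnot(inherits(config, "sim_config"))
  .with_seed(config$seed, {
    snps <- config$snps
    S <- nrow(snps)
    ids <- sprintf("U%06d", seq_len(n))
    gt <- matrix(NA_integer_, n, S, dimnames = list(ids, snps$snp_id))
    mat_cnt <- matrix(0L, n, S)
    pat_cnt <- matrix(0L, n, S)
    for (s in seq_len(S)) {
      q <- snps$maf[s]
      g_m <- stats::rbinom(n, 2L, q)
      g_f <- stats::rbinom(n, 2L, q)
      a_m <- stats::rbinom(n, 1L, g_m / 2)
      a_f <- stats::rbinom(n, 1L, g_f / 2)
      gt[, s] <- a_m + a_f
      mat_cnt[, s] <- a_m
      pat_cnt[, s] <- a_f
    }
    sex <- sample(c("male", "female"), n, replace = TRUE)
    age <- pmin(pmax(stats::rnorm(n, 50.7, 16.6), 18), 95)
    diabetes <- stats::rbinom(n, 1L, config$diabetes_prev_offspring)
    sex_mult <- ifelse(sex == "male", config$son_mult, config$daughter_mult)
    gen <- drop(mat_cnt %*% snps$beta_mat + pat_cnt %*% snps$beta_pat) *
      sex_mult
    pheno <- data.frame(
      individual_id = ids, sex = sex, age = age, age2 = age^2,
      diabetes = diabetes, stringsAsFactors = FALSE
    )
    for (tr in names(config$traits)) {
      ms <- config$traits[[tr]]
      g_tr <- if (tr == config$focal_trait) gen else 0
      # an unrelated individual's (unobserved) family effect does not vanish;
      # it folds into the residual so the latent variance matches the
      # family cohorts
      z <- .latent_trait(g_tr, age, sex, diabetes, 0, config$covar_coef,
        use_bmi = FALSE, fam_eff = 0,
        resid = stats::rnorm(n, 0,
          sqrt(config$resid_sd^2 + config$family_sd^2)))
      pheno[[tr]] <- ms[1] + ms[2] * z
    }
    list(
      genotypes = gt, phenotypes = pheno,
      truth = data.frame(
        individual_id = rep(ids, S),
        snp_id = rep(snps$snp_id, each = n),
        maternal_minor = as.integer(mat_cnt),
        paternal_minor = as.integer(pat_cnt),
        stringsAsFactors = FALSE
      )
    )
  })
}

#' Write a simulated cohort as the TSV files the pipeline reads
#'
#' Emits `pedigree.tsv` (canonical dialect), `genotypes.tsv`,
#' `phenotypes.tsv` and `origins_true.tsv` (truth manifest) under `dir`.
#'
#' @param cohort a [simulate_families()] result.
#' @param dir output directory (created if needed).
#' @return invisibly, the named vector of file paths.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "poe_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    pedigree = file.path(dir, "pedigree.tsv"),
    genotypes = file.path(dir, "genotypes.tsv"),
    phenotypes = file.path(dir, "phenotypes.tsv"),
    origins_true = file.path(dir, "origins_true.tsv")
  )
  write_pedigree(cohort$pedigree, paths["pedigree"])
  gt <- data.frame(individual_id = rownames(cohort$genotypes),
    cohort$genotypes, check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(gt, paths["genotypes"], sep = "\t", quote = FALSE,
    row.names = FALSE)
  utils::write.table(cohort$phenotypes, paths["phenotypes"], sep = "\t",
    quote = FALSE, row.names = FALSE)
  utils::write.table(cohort$origins_true, paths["origins_true"], sep = "\t",
    quote = FALSE, row.names = FALSE)
  invisible(paths)
}
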