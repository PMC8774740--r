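test_that("invalid configurations fail before any sampling", {
  expect_error(null_cohort_config(1, maf = 0.7), "maf")
  expect_error(null_cohort_config(1, geno_missing = 1), "missingness")
  expect_error(sim_config(traits = list(bmi = c(25, 4)),
    focal_trait = "whr"), "focal_trait")
  expect_error(sim_config(family_sd = -1), "SDs")
})

test_that("identical seeds reproduce identical cohorts", {
  a <- simulate_families(null_cohort_config(51, n_families = 60))
  b <- simulate_families(null_cohort_config(51, n_families = 60))
  expect_identical(a$genotypes, b$genotypes)
  expect_identical(a$phenotypes, b$phenotypes)
  expect_identical(a$origins_true, b$origins_true)
  c_ <- simulate_families(null_cohort_config(52, n_families = 60))
  expect_false(identical(a$genotypes, c_$genotypes))
})

test_that("the generator leaves the caller's RNG stream untouched", {
  set.seed(99)
  before <- .Random.seed
  invisible(simulate_families(null_cohort_config(53, n_families = 20)))
  expect_identical(before, .Random.seed)
})

test_that("founder allele frequency converges to the configured maf", {
  for (maf in c(0.1, 0.3, 0.5)) {
    co <- simulate_families(null_cohort_config(60 + maf * 10,
      n_families = 500, maf = maf, geno_missing = 0, parent_untyped = 0))
    founders <- co$pedigree$individual_id[co$pedigree$role == "parent"]
    g <- co$genotypes[founders, 1]
    n_alleles <- 2 * length(g)
    se <- sqrt(maf * (1 - maf) / n_alleles)
    expect_lt(abs(mean(g) / 2 - maf), 3 * se)
  }
})

test_that("cohort structure matches the emulated study design", {
  co <- simulate_families(null_cohort_config(54, n_families = 800,
    geno_missing = 0))
  ped <- co$pedigree
  off_frac <- mean(ped$role == "offspring")
  expect_equal(off_frac, 0.44, tolerance = 0.03) # 1.5 kids / 3.5 members
  # whole-parent non-genotyping keeps at least one typed parent per family
  typed <- rownames(co$genotypes)[rowSums(!is.na(co$genotypes)) > 0]
  par_fams <- unique(ped$family_id[ped$role == "parent" &
    ped$individual_id %in% typed])
  expect_setequal(par_fams, unique(ped$family_id))
  # true origin counts always sum to the offspring genotype
  tr <- co$origins_true
  expect_true(all(tr$maternal_minor + tr$paternal_minor ==
    co$genotypes[cbind(match(tr$individual_id, rownames(co$genotypes)),
      match(tr$snp_id, colnames(co$genotypes)))] |
    is.na(co$genotypes[cbind(match(tr$individual_id, rownames(co$genotypes)),
      match(tr$snp_id, colnames(co$genotypes)))])))
})

test_that("phenotype targets and default prevalences are honoured", {
  cfg <- sim_config(seed = 55, n_families = 1200,
    snps = data.frame(snp_id = "s1", maf = 0.3, beta_mat = 0, beta_pat = 0),
    pheno_missing = 0)
  co <- simulate_families(cfg)
  ph <- co$phenotypes
  expect_equal(mean(ph$bmi), 26.69, tolerance = 0.6)
  expect_equal(sd(ph$whr[ph$sex == "male"]) > 0, TRUE)
  off <- ph$individual_id %in%
    co$pedigree$individual_id[co$pedigree$role == "offspring"]
  expect_equal(mean(ph$diabetes[off]), 0.27, tolerance = 0.05)
  d <- table1_defaults("botnia")
  expect_equal(d$bmi, c(26.69, 4.61))
  expect_equal(d$whr[1], 0.90)
  expect_equal(table1_defaults("htb")$bmi[1], 27.89)
})

test_that("unrelated cohorts expose genotypes but hide origins", {
  cfg <- null_cohort_config(56, maf = 0.4, beta_mat = 0.2, beta_pat = -0.2)
  u <- simulate_unrelateds(cfg, 500)
  expect_equal(nrow(u$genotypes), 500)
  expect_false("maternal_minor" %in% names(u$phenotypes))
  expect_true(all(u$truth$maternal_minor + u$truth$paternal_minor ==
    as.vector(u$genotypes)))
  u2 <- simulate_unrelateds(cfg, 500)
  expect_identical(u$genotypes, u2$genotypes)
})

test_that("cohort files round-trip through the readers", {
  dir <- withr::local_tempdir()
  co <- simulate_families(null_cohort_config(57, n_families = 40))
  paths <- write_cohort(co, dir)
  back <- read_pedigree(paths["pedigree"], paths["genotypes"])
  expect_equal(back$pedigree$individual_id, co$pedigree$individual_id)
  expect_equal(back$pedigree$role, co$pedigree$role)
  expect_identical(back$genotypes, co$genotypes)
})
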