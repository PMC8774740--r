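make_corr_cohort <- function(seed = 1, n_fam = 120, slope = 0.4,
                             fam_sd = 0, kids = 2) {
  set.seed(seed)
  fam <- sprintf("F%03d", seq_len(n_fam))
  ped <- do.call(rbind, lapply(fam, function(f) {
    data.frame(
      family_id = f,
      individual_id = c(paste0(f, "_F"), paste0(f, "_M"),
        paste0(f, "_C", seq_len(kids))),
      father_id = c(NA, NA, rep(paste0(f, "_F"), kids)),
      mother_id = c(NA, NA, rep(paste0(f, "_M"), kids)),
      sex = c("male", "female",
        sample(c("male", "female"), kids, replace = TRUE)),
      stringsAsFactors = FALSE
    )
  }))
  ped <- validate_pedigree(ped)
  u <- rnorm(n_fam, 0, fam_sd)
  val <- rnorm(nrow(ped))
  is_off <- ped$role == "offspring"
  pv <- val[match(ped$father_id, ped$individual_id)]
  val[is_off] <- slope * pv[is_off] + u[match(ped$family_id, fam)][is_off] +
    rnorm(sum(is_off), 0, sqrt(1 - slope^2))
  pheno <- data.frame(
    individual_id = ped$individual_id, trait = val,
    age = ifelse(is_off, runif(nrow(ped), 20, 40), runif(nrow(ped), 50, 70)),
    stringsAsFactors = FALSE
  )
  list(pedigree = ped, phenotypes = pheno)
}

test_that("pair construction honours the oldest-only and sex filters", {
  co <- make_corr_cohort(kids = 3)
  all_pairs <- parent_offspring_pairs(co$pedigree, co$phenotypes, "trait",
    parent = "father", oldest_only = FALSE)
  oldest <- parent_offspring_pairs(co$pedigree, co$phenotypes, "trait",
    parent = "father", oldest_only = TRUE)
  expect_equal(nrow(all_pairs), 3 * 120)
  expect_equal(nrow(oldest), 120)
  expect_equal(anyDuplicated(oldest$family_id), 0L)
  sons <- parent_offspring_pairs(co$pedigree, co$phenotypes, "trait",
    parent = "mother", offspring_sex = "male", oldest_only = FALSE)
  sex_of <- co$pedigree$sex[match(sons$offspring_id,
    co$pedigree$individual_id)]
  expect_true(all(sex_of == "male"))
})

test_that("spearman correlation is exact on monotone pairs and null-centred", {
  expect_equal(spearman_partial(1:20, (1:20)^3)$r, 1)
  set.seed(2)
  r <- spearman_partial(rnorm(1000), rnorm(1000))$r
  expect_lt(abs(r), 0.08) # null sampling SD ~ 1/sqrt(n)
  # partialling out a shared driver removes the correlation
  c0 <- rnorm(800)
  x <- c0 + rnorm(800, 0, 0.3)
  y <- c0 + rnorm(800, 0, 0.3)
  raw <- spearman_partial(x, y)$r
  part <- spearman_partial(x, y, covariates = data.frame(c0 = c0))$r
  expect_gt(raw, 0.8)
  expect_lt(abs(part), 0.15)
  expect_true(is.na(spearman_partial(1:3, 3:1)$r))
})

test_that("mixed-model slope reduces to OLS without family variance", {
  co <- make_corr_cohort(seed = 3, fam_sd = 0, kids = 1)
  pairs <- parent_offspring_pairs(co$pedigree, co$phenotypes, "trait",
    parent = "father", oldest_only = FALSE)
  ms <- mixed_slope(pairs)
  ols <- coef(lm(offspring_value ~ parent_value, data = pairs))[2]
  expect_equal(ms$slope, unname(ols), tolerance = 1e-6)
  # identical traits give slope 1 with overwhelming evidence
  pairs$offspring_value <- pairs$parent_value
  ms1 <- suppressWarnings(mixed_slope(pairs)) # perfect fit warns in lm

  expect_equal(ms1$slope, 1, tolerance = 1e-8)
  expect_lt(ms1$p, 1e-10)
})

test_that("mixed-model slope recovers the simulated value", {
  co <- make_corr_cohort(seed = 4, n_fam = 500, slope = 0.4, fam_sd = 0.3)
  pairs <- parent_offspring_pairs(co$pedigree, co$phenotypes, "trait",
    parent = "father", oldest_only = FALSE)
  ms <- mixed_slope(pairs)
  expect_lt(abs(ms$slope - 0.4), 3 * ms$se)
})

test_that("Fisher r-to-z and Wald comparisons follow their closed forms", {
  eq <- fisher_r_to_z_compare(0.3, 50, 0.3, 80)
  expect_equal(eq$z, 0)
  expect_equal(eq$p, 1)
  cmp <- fisher_r_to_z_compare(0.5, 103, 0.0, 103)
  expect_equal(cmp$z, atanh(0.5) / sqrt(2 / 100), tolerance = 1e-12)
  expect_equal(cmp$z, 3.884, tolerance = 1e-3)
  swap <- fisher_r_to_z_compare(0.0, 103, 0.5, 103)
  expect_equal(swap$z, -cmp$z)
  expect_equal(swap$p, cmp$p)
  expect_error(fisher_r_to_z_compare(1, 10, 0, 10), "< 1")

  expect_equal(wald_slope_compare(0.2, 0.05, 0.2, 0.07)$z, 0)
  expect_equal(wald_slope_compare(1, 0.1, 0, 0.1)$z, 1 / sqrt(0.02))
  expect_equal(wald_slope_compare(1, 0.1, 0, 0.1)$z, 7.0711, tolerance = 1e-4)
  expect_equal(wald_slope_compare(0, 0.1, 1, 0.1)$z,
    -wald_slope_compare(1, 0.1, 0, 0.1)$z)
  expect_error(wald_slope_compare(1, 0, 0, 0.1), "positive")
})

test_that("null difference p-values from the Fisher comparison are calibrated", {
  set.seed(5)
  n1 <- 100; n2 <- 100
  reps <- 2000
  p <- replicate(reps, {
    r1 <- cor(rnorm(n1), rnorm(n1))
    r2 <- cor(rnorm(n2), rnorm(n2))
    fisher_r_to_z_compare(r1, n1, r2, n2)$p
  })
  rate <- mean(p < 0.05)
  expect_gte(rate, 0.03)
  expect_lte(rate, 0.07)
})

test_that("the parent comparison wrapper assembles both correlations", {
  co <- make_corr_cohort(seed = 6, n_fam = 200, kids = 1)
  row <- compare_parent_offspring(co$pedigree, co$phenotypes, "trait",
    oldest_only = FALSE)
  expect_equal(row$stratum, "all")
  expect_gt(row$r_father, 0.2) # offspring built from the father's value
  expect_lt(abs(row$r_mother), 0.2)
  expect_lt(row$p_diff, 0.05)
  dep <- compare_parent_offspring(co$pedigree, co$phenotypes, "trait",
    oldest_only = FALSE, dependent = TRUE)
  expect_true(is.finite(dep$z_diff))
})
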