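make_clustered_data <- function(seed = 1, n_clus = 80, size = 3,
                                beta = 0.5, icc_sd = 0.5) {
  set.seed(seed)
  id <- rep(seq_len(n_clus), each = size)
  x <- rnorm(n_clus * size)
  u <- rnorm(n_clus, 0, icc_sd)[id]
  data.frame(y = 1 + beta * x + u + rnorm(n_clus * size), x = x, id = id)
}

test_that("independence GEE equals OLS with the cluster sandwich oracle", {
  skip_if_not_installed("sandwich")
  d <- make_clustered_data()
  fit <- gee_fit(y ~ x, d, id = "id")
  ols <- lm(y ~ x, data = d)
  expect_equal(unname(fit$coefficients), unname(coef(ols)),
    tolerance = 1e-10)
  V <- sandwich::vcovCL(ols, cluster = d$id, type = "HC0", cadjust = FALSE)
  expect_equal(unname(fit$se), unname(sqrt(diag(V))), tolerance = 1e-8)
})

test_that("size-one clusters with independence reduce exactly to OLS", {
  d <- make_clustered_data(n_clus = 200, size = 1, icc_sd = 0)
  fit <- gee_fit(y ~ x, d, id = "id")
  ols <- lm(y ~ x, data = d)
  expect_equal(unname(fit$coefficients), unname(coef(ols)),
    tolerance = 1e-8)
})

test_that("exchangeable working correlation estimates the cluster correlation", {
  d <- make_clustered_data(seed = 2, n_clus = 400, size = 4, icc_sd = 1)
  fit <- gee_fit(y ~ x, d, id = "id", corstr = "exchangeable")
  expect_gt(fit$alpha, 0.3) # true ICC = 1 / (1 + 1) = 0.5
  expect_lt(fit$alpha, 0.7)
  expect_lt(abs(fit$coefficients["x"] - 0.5), 3 * fit$se["x"])
})

test_that("degenerate designs and clustering are hard errors", {
  d <- make_clustered_data()
  d$x2 <- d$x
  expect_error(gee_fit(y ~ x + x2, d, id = "id"), "aliased")
  expect_error(gee_fit(y ~ x, d, id = rep(1, nrow(d))), ">= 2 clusters")
})

test_that("family splits are deterministic, exhaustive and near-equal", {
  fams <- sprintf("F%04d", 1:2257)
  s1 <- split_families(fams, seed = 9)
  s2 <- split_families(fams, seed = 9)
  expect_identical(s1, s2)
  expect_setequal(s1$family_id, fams)
  expect_equal(sort(table(s1$subset), decreasing = TRUE),
    sort(c(discovery = 1129, replication = 1128), decreasing = TRUE),
    ignore_attr = TRUE)
  s3 <- split_families(fams, seed = 10)
  expect_false(identical(s1$subset, s3$subset))
})

test_that("contrast samples follow the exposure-coding rules", {
  status <- c(rep("assigned", 10 + 4 + 3 + 1), rep("ambiguous", 2))
  ids <- sprintf("i%02d", seq_along(status))
  gt <- matrix(c(rep(0L, 10), rep(1L, 4 + 3), rep(2L, 1), rep(1L, 2)),
    ncol = 1, dimnames = list(ids, "s1"))
  origins <- data.frame(
    family_id = ids, individual_id = ids, snp_id = "s1", status = status,
    maternal_minor = c(rep(0L, 10), rep(1L, 4), rep(0L, 3), 1L, NA, NA),
    paternal_minor = c(rep(0L, 10), rep(0L, 4), rep(1L, 3), 1L, NA, NA),
    stringsAsFactors = FALSE
  )
  expect_equal(nrow(build_contrast_sample(origins, gt, "s1", "maternal")), 14)
  expect_equal(nrow(build_contrast_sample(origins, gt, "s1", "paternal")), 13)
  poe <- build_contrast_sample(origins, gt, "s1", "poe")
  expect_equal(nrow(poe), 7)
  expect_equal(sum(poe$exposure), 3) # paternal-origin hets are the exposed
  origins$status[11:18] <- "ambiguous"
  expect_warning(out <- build_contrast_sample(origins, gt, "s1", "poe"),
    "skipped")
  expect_equal(nrow(out), 0L)
})

test_that("swapping origin labels flips the POE sign and keeps its p-value", {
  co <- simulate_families(null_cohort_config(21, n_families = 250,
    beta_pat = 0.4))
  res <- fit_focal_assoc(co)
  swapped <- co
  orig <- infer_cohort_origins(co$pedigree, co$genotypes)
  flipped <- orig
  flipped$maternal_minor <- orig$paternal_minor
  flipped$paternal_minor <- orig$maternal_minor
  ph <- co$phenotypes
  ph$bmi <- blom_transform(ph$bmi)
  plan <- poe_plan(traits = data.frame(trait = "bmi", family = "obesity"))
  res_fl <- run_analysis(plan, list(pedigree = co$pedigree,
    genotypes = co$genotypes, phenotypes = ph, origins = flipped))
  expect_equal(res_fl$b_poe, -res$b_poe, tolerance = 1e-8)
  expect_equal(res_fl$p_poe, res$p_poe, tolerance = 1e-8)
  expect_equal(res_fl$b_mat, res$b_pat, tolerance = 1e-8)
})

test_that("marginal and POE contrasts recover simulated parental effects", {
  co <- simulate_families(null_cohort_config(22, n_families = 400,
    beta_mat = 0.0, beta_pat = 0.35))
  res <- fit_focal_assoc(co)
  expect_lt(abs(res$b_pat - 0.35), 3 * res$se_pat)
  expect_lt(abs(res$b_mat - 0), 3 * res$se_mat)
  expect_lt(abs(res$b_poe - 0.35), 3 * res$se_poe)
  expect_equal(sign(res$b_poe), sign(res$b_pat - res$b_mat))
})

test_that("the joint-dosage mode estimates both parental effects at once", {
  co <- simulate_families(null_cohort_config(23, n_families = 400,
    beta_mat = -0.2, beta_pat = 0.3))
  res <- fit_focal_assoc(co, contrast_mode = "joint")
  expect_lt(abs(res$b_mat - (-0.2)), 3 * res$se_mat)
  expect_lt(abs(res$b_pat - 0.3), 3 * res$se_pat)
  expect_lt(abs(res$b_poe - 0.5), 3 * res$se_poe)
})

test_that("replication calls require nominal significance and matching sign", {
  co <- simulate_families(null_cohort_config(24, n_families = 500,
    beta_pat = 0.6))
  res <- fit_focal_assoc(co, splits = c("discovery", "replication"))
  repl <- res[res$split == "replication", ]
  disc <- res[res$split == "discovery", ]
  expected <- disc$p_poe < 0.05 & repl$p_poe < 0.05 &
    sign(repl$b_poe) == sign(disc$b_poe)
  expect_equal(repl$replicated, expected)
  expect_true(all(is.na(disc$replicated)))
})

test_that("sex-stratified runs drop sex from the covariates and subset rows", {
  co <- simulate_families(null_cohort_config(25, n_families = 300,
    beta_pat = 0.4, daughter_mult = 1, son_mult = 0))
  res <- fit_focal_assoc(co, strata = c("sons", "daughters"))
  expect_setequal(res$stratum, c("sons", "daughters"))
  expect_true(all(res$n_het < sum(co$pedigree$role == "offspring")))
  # the simulated effect is daughter-only
  expect_gt(res$b_pat[res$stratum == "daughters"],
    res$b_pat[res$stratum == "sons"])
})
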