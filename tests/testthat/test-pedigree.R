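test_that("a minimal trio pedigree parses with correct roles", {
  path <- withr::local_tempfile(fileext = ".tsv")
  write_tiny_pedigree(path)
  ped <- read_pedigree(path)$pedigree
  expect_equal(nrow(ped), 3L)
  expect_equal(ped$role[ped$individual_id == "C1"], "offspring")
  expect_setequal(ped$role[ped$individual_id %in% c("P1", "P2")], "parent")
})

test_that("PLINK-style headerless FAM files are auto-detected", {
  path <- withr::local_tempfile(fileext = ".fam")
  writeLines(c("F1 P1 0 0 1 -9", "F1 P2 0 0 2 -9", "F1 C1 P1 P2 2 -9"), path)
  ped <- read_pedigree(path)$pedigree
  expect_equal(ped$father_id[3], "P1")
  expect_equal(ped$sex, c("male", "female", "female"))
})

test_that("invalid pedigrees are rejected with informative errors", {
  path <- withr::local_tempfile(fileext = ".tsv")
  write_tiny_pedigree(path, child_father = "P2") # P2 is female
  expect_error(read_pedigree(path), "F1/C1")

  writeLines(c(
    "family_id\tindividual_id\tfather_id\tmother_id\tsex",
    "F1\tP1\t0\t0\t1", "F1\tP1\t0\t0\t1"
  ), path)
  expect_error(read_pedigree(path), "duplicated individual_id")

  write_tiny_pedigree(path, child_father = "P9")
  expect_warning(read_pedigree(path), "absent from pedigree")
})

test_that("genotype files are validated cell-wise with line numbers", {
  ped_path <- withr::local_tempfile(fileext = ".tsv")
  write_tiny_pedigree(ped_path)
  gt_path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    "individual_id\tsnpA", "P1\t2", "P2\t3", "C1\t1"
  ), gt_path)
  expect_error(read_pedigree(ped_path, gt_path), "line 3")
  writeLines(c(
    "individual_id\tsnpA", "P1\t2", "P2\tNA", "C1\t1"
  ), gt_path)
  gt <- read_pedigree(ped_path, gt_path)$genotypes
  expect_identical(gt["P1", "snpA"], 2L)
  expect_true(is.na(gt["P2", "snpA"]))
})

test_that("canonical pedigree files round-trip byte-identically", {
  p1 <- withr::local_tempfile(fileext = ".tsv")
  p2 <- withr::local_tempfile(fileext = ".tsv")
  ped <- suppressWarnings(
    simulate_families(null_cohort_config(11, n_families = 20)))$pedigree
  write_pedigree(ped, p1)
  write_pedigree(read_pedigree(p1)$pedigree, p2)
  expect_identical(readLines(p1), readLines(p2))
})

test_that("the shipped candidate-SNP panel loads and validates", {
  panel <- read_snp_panel(system.file("extdata", "snp_panel.tsv",
    package = "poefam"))
  expect_equal(nrow(panel), 8L)
  expect_true(all(panel$effect_allele != panel$other_allele))
  expect_true("rs10503669" %in% panel$snp_id)
})

test_that("exact HWE p-values match brute-force allele-pairing enumeration", {
  cases <- list(
    c(2, 2, 1), c(1, 3, 1), c(3, 0, 2), c(4, 1, 0), c(2, 4, 0), c(1, 1, 3)
  )
  for (cs in cases) {
    expect_equal(
      hwe_exact_pvalue(cs[1], cs[2], cs[3]),
      oracle_hwe_pvalue(cs[1], cs[2], cs[3]),
      tolerance = 1e-10,
      info = paste(cs, collapse = "/")
    )
  }
})

test_that("exact HWE test behaves at the reference configurations", {
  expect_equal(hwe_exact_pvalue(25, 50, 25), 1, tolerance = 1e-12)
  expect_lt(hwe_exact_pvalue(100, 0, 100), 1e-6)
  expect_warning(p <- hwe_exact_pvalue(10, 0, 0), "monomorphic")
  expect_equal(p, 1)
})

test_that("founders-only HWE restricts to parents", {
  co <- simulate_families(null_cohort_config(3, n_families = 150,
    geno_missing = 0, parent_untyped = 0))
  p_founders <- hwe_exact_test(co$genotypes, co$pedigree)
  founders <- co$pedigree$individual_id[co$pedigree$role == "parent"]
  direct <- hwe_exact_test(co$genotypes[founders, 1])
  expect_equal(unname(p_founders[1]), direct)
})

test_that("mendelian_check flags impossible trios and only those", {
  ped <- data.frame(
    family_id = "F1", individual_id = c("M", "F", "C1", "C2", "C3"),
    father_id = c(NA, NA, "F", "F", "F"),
    mother_id = c(NA, NA, "M", "M", "M"),
    sex = c("female", "male", "male", "male", "female"),
    stringsAsFactors = FALSE
  )
  ped <- validate_pedigree(ped)
  gt <- matrix(
    c(0L, 0L, 1L, 0L, NA,  # s1: C1 impossible (both parents 0)
      2L, 2L, 1L, 2L, 2L), # s2: C1 impossible (both parents 2)
    ncol = 2, dimnames = list(c("M", "F", "C1", "C2", "C3"), c("s1", "s2"))
  )
  flags <- mendelian_check(ped, gt)
  expect_equal(nrow(flags), 2L)
  expect_setequal(flags$individual_id, "C1")
  # mother 1, father missing, offspring 2 is compatible
  gt2 <- matrix(c(1L, NA, 2L), ncol = 1,
    dimnames = list(c("M", "F", "C1"), "s1"))
  expect_equal(nrow(mendelian_check(ped[1:3, ], gt2)), 0L)
})

test_that("simulated cohorts without genotyping error are Mendelian-clean", {
  for (seed in c(1, 2, 3)) {
    co <- simulate_families(null_cohort_config(seed, n_families = 80,
      geno_missing = 0, parent_untyped = 0))
    expect_equal(nrow(mendelian_check(co$pedigree, co$genotypes)), 0L)
  }
})
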