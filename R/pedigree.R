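# Pedigree + genotype ingestion and per-SNP quality control.

.sex_decode <- function(x) {
  x <- tolower(trimws(as.character(x)))
  out <- rep("unknown", length(x))
  out[x %in% c("1", "m", "male")] <- "male"
  out[x %in% c("2", "f", "female")] <- "female"
  out
}

.sex_encode <- function(x) {
  c(male = "1", female = "2", unknown = "0")[x]
}

.id_missing <- function(x) {
  is.na(x) | x == "" | x == "0" | toupper(x) == "NA"
}

#' Read a nuclear-family pedigree (and optionally its genotype matrix)
#'
#' Accepts either a headered TSV dialect (columns `family_id`, `individual_id`,
#' `father_id`, `mother_id`, `sex`; common synonyms such as `FID`/`IID` are
#' recognised) or a headerless 5/6-column PLINK-style PED/FAM file
#' (`FID IID PAT MAT SEX [PHENO]`, `0` = missing parent, `1` = male,
#' `2` = female). The dialect is auto-detected from the first line.
#'
#' Individuals with at least one parent link are classified as offspring;
#' all others as parents (founders). Validation enforces globally unique
#' individual ids, sex-consistent parent links (a `father_id` must name a male
#' family member, a `mother_id` a female one) and same-family parent links.
#' References to parents absent from the pedigree are reported with a warning
#' and retained (such parents simply contribute no genotype).
#'
#' @param pedigree_path path to the pedigree file.
#' @param genotype_path optional path to a genotype TSV (see
#'   [read_genotypes()]).
#' @return a list with elements `pedigree` (data.frame with columns
#'   `family_id`, `individual_id`, `father_id`, `mother_id`, `sex`, `role`)
#'   and `genotypes` (integer matrix or `NULL`).
#' @export
read_pedigree <- function(pedigree_path, genotype_path = NULL) {
  if (!file.exists(pedigree_path)) {
    stop("pedigree file not found: ", pedigree_path)
  }
  first <- readLines(pedigree_path, n = 1L)
  toks <- tolower(strsplit(trimws(first), "[\t ]+")[[1]])
  headered <- any(toks %in% c(
    "family", "family_id", "fid", "individual", "individual_id", "iid"
  ))
  if (headered) {
    raw <- utils::read.table(pedigree_path,
      header = TRUE, sep = "\t", colClasses = "character",
      check.names = FALSE, quote = "", comment.char = ""
    )
    names(raw) <- tolower(names(raw))
    pick <- function(opts) {
      hit <- intersect(opts, names(raw))
      if (!length(hit)) {
        stop("pedigree file lacks a required column (one of: ",
          paste(opts, collapse = ", "), ")")
      }
      raw[[hit[1]]]
    }
    ped <- data.frame(
      family_id = pick(c("family_id", "family", "fid")),
      individual_id = pick(c("individual_id", "individual", "iid")),
      father_id = pick(c("father_id", "father", "pat")),
      mother_id = pick(c("mother_id", "mother", "mat")),
      sex = pick(c("sex")),
      stringsAsFactors = FALSE
    )
  } else {
    raw <- utils::read.table(pedigree_path,
      header = FALSE, colClasses = "character", quote = "",
      comment.char = ""
    )
    if (ncol(raw) < 5L) {
      stop("headerless pedigree must have >= 5 columns (FID IID PAT MAT SEX)")
    }
    ped <- data.frame(
      family_id = raw[[1]], individual_id = raw[[2]],
      father_id = raw[[3]], mother_id = raw[[4]], sex = raw[[5]],
      stringsAsFactors = FALSE
    )
  }
  ped$father_id[.id_missing(ped$father_id)] <- NA_character_
  ped$mother_id[.id_missing(ped$mother_id)] <- NA_character_
  ped$sex <- .sex_decode(ped$sex)
  ped <- validate_pedigree(ped)
  genotypes <- NULL
  if (!is.null(genotype_path)) {
    genotypes <- read_genotypes(genotype_path, ped$individual_id)
  }
  list(pedigree = ped, genotypes = genotypes)
}

#' Validate a pedigree data.frame and assign parent/offspring roles
#'
#' @param ped data.frame with columns `family_id`, `individual_id`,
#'   `father_id`, `mother_id`, `sex`.
#' @return the validated pedigree with a `role` column added.
#' @export
validate_pedigree <- function(ped) {
  need <- c("family_id", "individual_id", "father_id", "mother_id", "sex")
  miss <- setdiff(need, names(ped))
  if (length(miss)) stop("pedigree lacks columns: ", paste(miss, collapse = ", "))
  dup <- ped$individual_id[duplicated(ped$individual_id)]
  if (length(dup)) {
    stop("duplicated individual_id: ", paste(unique(dup), collapse = ", "))
  }
  idx <- match(ped$father_id, ped$individual_id)
  bad <- which(!is.na(idx) & ped$sex[idx] != "male")
  if (length(bad)) {
    stop(
      "father link names a non-male member: ",
      paste(sprintf("%s/%s", ped$family_id[bad], ped$individual_id[bad]),
        collapse = ", ")
    )
  }
  bad <- which(!is.na(idx) & ped$family_id[idx] != ped$family_id)
  if (length(bad)) {
    stop("father link crosses families: ",
      paste(ped$individual_id[bad], collapse = ", "))
  }
  unknown_f <- unique(ped$father_id[!is.na(ped$father_id) & is.na(idx)])
  idx <- match(ped$mother_id, ped$individual_id)
  bad <- which(!is.na(idx) & ped$sex[idx] != "female")
  if (length(bad)) {
    stop(
      "mother link names a non-female member: ",
      paste(sprintf("%s/%s", ped$family_id[bad], ped$individual_id[bad]),
        collapse = ", ")
    )
  }
  bad <- which(!is.na(idx) & ped$family_id[idx] != ped$family_id)
  if (length(bad)) {
    stop("mother link crosses families: ",
      paste(ped$individual_id[bad], collapse = ", "))
  }
  unknown_m <- unique(ped$mother_id[!is.na(ped$mother_id) & is.na(idx)])
  unknown <- c(unknown_f, unknown_m)
  if (length(unknown)) {
    warning("parent id(s) referenced but absent from pedigree: ",
      paste(unknown, collapse = ", "))
  }
  ped$role <- ifelse(is.na(ped$father_id) & is.na(ped$mother_id),
    "parent", "offspring")
  has_off <- ped$family_id %in% ped$family_id[ped$role == "offspring"]
  if (!all(has_off)) {
    # childless families are legal inputs but play no role in POE analysis
    ped$role[!has_off] <- "parent"
  }
  rownames(ped) <- NULL
  ped
}

#' Write a pedigree in the canonical headered TSV dialect
#'
#' Columns `family_id`, `individual_id`, `father_id`, `mother_id`, `sex` with
#' `0` for missing parents and `1`/`2`/`0` sex codes. Reading a file written
#' by this function and writing it again reproduces it byte-identically.
#'
#' @param ped validated pedigree data.frame.
#' @param path output path.
#' @export
write_pedigree <- function(ped, path) {
  out <- data.frame(
    family_id = ped$family_id,
    individual_id = ped$individual_id,
    father_id = ifelse(is.na(ped$father_id), "0", ped$father_id),
    mother_id = ifelse(is.na(ped$mother_id), "0", ped$mother_id),
    sex = unname(.sex_encode(ped$sex)),
    stringsAsFactors = FALSE
  )
  utils::write.table(out, path,
    sep = "\t", quote = FALSE, row.names = FALSE, col.names = TRUE
  )
  invisible(path)
}

#' Read a genotype matrix (minor-allele counts)
#'
#' TSV with a header; the first column holds individual ids, remaining columns
#' one SNP each with cells in `{0, 1, 2, NA}` (minor-allele counts). Any other
#' value is a parse error reported with its line number.
#'
#' @param path genotype TSV path.
#' @param pedigree_ids optional character vector; individuals in the pedigree
#'   but absent from the file get all-`NA` rows, and genotyped ids missing
#'   from the pedigree trigger a warning.
#' @return integer matrix, rows = individuals, columns = SNPs.
#' @export
read_genotypes <- function(path, pedigree_ids = NULL) {
  if (!file.exists(path)) stop("genotype file not found: ", path)
  raw <- utils::read.table(path,
    header = TRUE, sep = "\t", colClasses = "character",
    check.names = FALSE, quote = "", comment.char = ""
  )
  if (ncol(raw) < 2L) stop("genotype file needs an id column plus >=1 SNP")
  ids <- raw[[1]]
  if (anyDuplicated(ids)) {
    stop("duplicated individual_id in genotype file: ",
      paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  gt <- as.matrix(raw[, -1, drop = FALSE])
  ok <- is.na(gt) | gt %in% c("0", "1", "2", "NA", "")
  if (!all(ok)) {
    bad <- which(!ok, arr.ind = TRUE)[1, ]
    stop(sprintf(
      "invalid genotype value '%s' at line %d, column '%s' (expected 0/1/2/NA)",
      gt[bad[1], bad[2]], bad[1] + 1L, colnames(gt)[bad[2]]
    ))
  }
  gt[gt %in% c("NA", "")] <- NA_character_
  storage.mode(gt) <- "integer"
  rownames(gt) <- ids
  if (!is.null(pedigree_ids)) {
    extra <- setdiff(ids, pedigree_ids)
    if (length(extra)) {
      warning("genotyped individuals absent from pedigree: ",
        paste(extra, collapse = ", "))
    }
    full <- matrix(NA_integer_,
      nrow = length(pedigree_ids), ncol = ncol(gt),
      dimnames = list(pedigree_ids, colnames(gt))
    )
    keep <- intersect(ids, pedigree_ids)
    full[keep, ] <- gt[keep, , drop = FALSE]
    gt <- full
  }
  gt
}

#' Read a SNP panel table
#'
#' TSV with columns `snp_id`, `chr`, `gene`, `location` (optional),
#' `effect_allele`, `other_allele` and optionally `maf`.
#'
#' @param path SNP panel TSV.
#' @return data.frame.
#' @export
read_snp_panel <- function(path) {
  panel <- utils::read.table(path,
    header = TRUE, sep = "\t", stringsAsFactors = FALSE,
    quote = "", comment.char = ""
  )
  need <- c("snp_id", "chr", "gene", "effect_allele", "other_allele")
  miss <- setdiff(need, names(panel))
  if (length(miss)) stop("SNP panel lacks columns: ", paste(miss, collapse = ", "))
  if (any(panel$effect_allele == panel$other_allele)) {
    stop("effect_allele must differ from other_allele")
  }
  if (!is.null(panel$maf) &&
      any(!is.na(panel$maf) & (panel$maf <= 0 | panel$maf > 0.5))) {
    stop("maf must lie in (0, 0.5]")
  }
  if (is.null(panel$location)) panel$location <- NA_character_
  panel
}

#' Exact Hardy-Weinberg test p-value from genotype counts
#'
#' Two-sided exact test: the p-value sums the exact conditional probabilities
#' (given the allele counts) of every heterozygote count whose probability does
#' not exceed that of the observed count.
#'
#' @param n_major count of major-allele homozygotes.
#' @param n_het count of heterozygotes.
#' @param n_minor count of minor-allele homozygotes.
#' @return p-value in `[0, 1]`.
#' @export
hwe_exact_pvalue <- function(n_major, n_het, n_minor) {
  stopifnot(n_major >= 0, n_het >= 0, n_minor >= 0)
  n <- n_major + n_het + n_minor
  if (n == 0L) stop("no genotyped individuals")
  n_a <- 2L * n_minor + n_het # minor-allele count
  if (n_a > n) { # ensure n_a is the rarer allele's count
    n_a <- 2L * n - n_a
  }
  if (n_a == 0L) {
    warning("monomorphic SNP: HWE p-value set to 1")
    return(1)
  }
  hets <- seq.int(n_a %% 2L, n_a, by = 2L)
  # log P(het = h | n, n_a) up to a constant:
  #   log n! - log nAA! - log h! - log naa! + h log 2
  haa <- (n_a - hets) / 2
  hAA <- n - hets - haa
  logp <- -lgamma(hAA + 1) - lgamma(hets + 1) - lgamma(haa + 1) + hets * log(2)
  logp <- logp - max(logp)
  pr <- exp(logp)
  pr <- pr / sum(pr)
  obs <- which(hets == n_het)
  if (!length(obs)) {
    # observed het count has the wrong parity for the allele count: impossible
    stop("inconsistent genotype counts for HWE test")
  }
  min(1, sum(pr[pr <= pr[obs] * (1 + 1e-12)]))
}

#' Exact Hardy-Weinberg test for one or more SNPs
#'
#' @param genotypes integer vector (one SNP) or matrix (individuals x SNPs)
#'   of minor-allele counts.
#' @param pedigree optional validated pedigree; required when
#'   `founders_only = TRUE` so that the test can be restricted to parents
#'   (offspring genotypes are correlated with their parents').
#' @param founders_only restrict to founders (default `TRUE`).
#' @return named numeric vector of p-values (or a single p-value).
#' @export
hwe_exact_test <- function(genotypes, pedigree = NULL, founders_only = TRUE) {
  if (is.matrix(genotypes)) {
    sub <- genotypes
    if (founders_only) {
      if (is.null(pedigree)) stop("founders_only = TRUE requires a pedigree")
      keep <- pedigree$individual_id[pedigree$role == "parent"]
      sub <- genotypes[intersect(rownames(genotypes), keep), , drop = FALSE]
    }
    return(vapply(seq_len(ncol(sub)), function(j) {
      g <- sub[, j]
      g <- g[!is.na(g)]
      if (!length(g)) return(NA_real_)
      hwe_exact_pvalue(sum(g == 0L), sum(g == 1L), sum(g == 2L))
    }, numeric(1), USE.NAMES = FALSE) |> stats::setNames(colnames(sub)))
  }
  g <- genotypes[!is.na(genotypes)]
  if (!length(g)) stop("no non-missing genotypes")
  hwe_exact_pvalue(sum(g == 0L), sum(g == 1L), sum(g == 2L))
}

# transmissible minor-allele counts per parental genotype; NA parent -> 0:1
.transmissible <- function(g) {
  if (is.na(g)) 0:1 else if (g == 0L) 0L else if (g == 2L) 1L else 0:1
}

#' Mendelian consistency check for offspring genotypes
#'
#' Flags every offspring whose minor-allele count at a SNP is impossible given
#' the non-missing genotypes of its pedigree parents.
#'
#' @param pedigree validated pedigree.
#' @param genotypes genotype matrix (see [read_genotypes()]).
#' @param snp_ids SNPs to check (default: all columns).
#' @return data.frame with columns `family_id`, `individual_id`, `snp_id`,
#'   `offspring_gt`, `mother_gt`, `father_gt` (zero rows when consistent).
#' @export
mendelian_check <- function(pedigree, genotypes, snp_ids = colnames(genotypes)) {
  off <- pedigree[pedigree$role == "offspring", , drop = FALSE]
  res <- vector("list", length(snp_ids))
  lk <- function(ids, snp) {
    out <- rep(NA_integer_, length(ids))
    hit <- !is.na(ids) & ids %in% rownames(genotypes)
    out[hit] <- genotypes[ids[hit], snp]
    out
  }
  for (k in seq_along(snp_ids)) {
    snp <- snp_ids[k]
    o <- lk(off$individual_id, snp)
    m <- lk(off$mother_id, snp)
    f <- lk(off$father_id, snp)
    # offspring gt possible iff it splits into a transmissible pair
    can0 <- function(g) is.na(g) | g <= 1L # parent can transmit major allele
    can1 <- function(g) is.na(g) | g >= 1L # parent can transmit minor allele
    possible <- rep(TRUE, length(o))
    idx0 <- !is.na(o) & o == 0L
    idx1 <- !is.na(o) & o == 1L
    idx2 <- !is.na(o) & o == 2L
    possible[idx0] <- can0(m[idx0]) & can0(f[idx0])
    possible[idx1] <- (can0(m[idx1]) & can1(f[idx1])) |
      (can1(m[idx1]) & can0(f[idx1]))
    possible[idx2] <- can1(m[idx2]) & can1(f[idx2])
    bad <- which(!is.na(o) & !possible)
    if (length(bad)) {
      res[[k]] <- data.frame(
        family_id = off$family_id[bad],
        individual_id = off$individual_id[bad],
        snp_id = snp,
        offspring_gt = o[bad], mother_gt = m[bad], father_gt = f[bad],
        stringsAsFactors = FALSE
      )
    }
  }
  res <- res[!vapply(res, is.null, logical(1))]
  if (!length(res)) {
    return(data.frame(
      family_id = character(), individual_id = character(),
      snp_id = character(), offspring_gt = integer(),
      mother_gt = integer(), father_gt = integer(),
      stringsAsFactors = FALSE
    ))
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Per-SNP quality-control summary
#'
#' Call rate, estimated minor-allele frequency, exact HWE p-value (founders by
#' default) and Mendelian-error count per SNP.
#'
#' @inheritParams mendelian_check
#' @param founders_only compute HWE and MAF on founders only.
#' @return data.frame, one row per SNP.
#' @export
snp_qc <- function(pedigree, genotypes, founders_only = TRUE) {
  merr <- mendelian_check(pedigree, genotypes)
  hwe <- suppressWarnings(
    hwe_exact_test(genotypes, pedigree, founders_only = founders_only)
  )
  sub <- genotypes
  if (founders_only) {
    keep <- pedigree$individual_id[pedigree$role == "parent"]
    sub <- genotypes[intersect(rownames(genotypes), keep), , drop = FALSE]
  }
  data.frame(
    snp_id = colnames(genotypes),
    n_typed = colSums(!is.na(genotypes)),
    call_rate = colMeans(!is.na(genotypes)),
    maf = vapply(seq_len(ncol(sub)), function(j) {
      g <- sub[, j][!is.na(sub[, j])]
      if (!length(g)) return(NA_real_)
      min(mean(g) / 2, 1 - mean(g) / 2)
    }, numeric(1)),
    hwe_p = unname(hwe[colnames(genotypes)]),
    n_mendel_errors = vapply(
      colnames(genotypes),
      function(s) sum(merr$snp_id == s), integer(1)
    ),
    row.names = NULL, stringsAsFactors = FALSE
  )
}
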