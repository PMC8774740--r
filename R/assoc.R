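# Family-clustered GEE association: maternal, paternal and parent-of-origin
# contrasts per SNP x trait x stratum.

# run code with a temporary RNG state seeded by `seed`, restoring the caller's
# stream afterwards
.with_seed <- function(seed, code) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  code
}

#' Randomly split families into discovery and replication subsets
#'
#' Every family is assigned wholly to one subset; the two subsets differ in
#' size by at most one family. Deterministic given `seed`.
#'
#' @param family_ids character vector of family ids (duplicates allowed).
#' @param seed integer seed.
#' @return data.frame with columns `family_id` and `subset`
#'   (`"discovery"`/`"replication"`).
#' @export
split_families <- function(family_ids, seed) {
  fams <- unique(as.character(family_ids))
  if (length(fams) < 2L) stop("need >= 2 families to split")
  perm <- .with_seed(seed, sample(fams))
  n_disc <- ceiling(length(fams) / 2)
  out <- data.frame(
    family_id = perm,
    subset = rep(c("discovery", "replication"),
      c(n_disc, length(fams) - n_disc)),
    stringsAsFactors = FALSE
  )
  out <- out[order(out$family_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Build the analysis sample for one association contrast
#'
#' Exposure coding per contrast:
#' * `maternal`: major-allele homozygotes (exposure 0) vs origin-assigned
#'   heterozygotes whose minor allele is maternal (exposure 1);
#' * `paternal`: the symmetric comparison for paternally inherited minor
#'   alleles;
#' * `poe`: origin-assigned heterozygotes only, exposure 1 for a paternal and
#'   0 for a maternal minor allele.
#'
#' Ambiguous, Mendelian-error and untestable calls, and minor-allele
#' homozygotes, are excluded throughout.
#'
#' @param origins output of [infer_cohort_origins()].
#' @param genotypes genotype matrix.
#' @param snp_id SNP to analyse.
#' @param contrast `"maternal"`, `"paternal"` or `"poe"`.
#' @return data.frame with columns `individual_id`, `family_id`, `exposure`.
#' @export
build_contrast_sample <- function(origins, genotypes, snp_id,
                                  contrast = c("maternal", "paternal", "poe")) {
  contrast <- match.arg(contrast)
  oc <- origins[origins$snp_id == snp_id, , drop = FALSE]
  gt <- genotypes[match(oc$individual_id, rownames(genotypes)), snp_id]
  assigned <- oc$status == "assigned"
  het <- assigned & gt == 1L
  if (contrast == "poe") {
    keep <- het
    exposure <- oc$paternal_minor[keep]
  } else {
    ctrl <- assigned & gt == 0L
    exposed <- if (contrast == "maternal") {
      het & oc$maternal_minor == 1L
    } else {
      het & oc$paternal_minor == 1L
    }
    keep <- ctrl | exposed
    exposure <- as.integer(exposed[keep])
  }
  if (!any(keep) || sum(exposure, na.rm = TRUE) == 0L) {
    warning("contrast '", contrast, "' for ", snp_id,
      " has no exposed individuals; skipped")
    return(data.frame(individual_id = character(), family_id = character(),
      exposure = integer(), stringsAsFactors = FALSE))
  }
  data.frame(
    individual_id = oc$individual_id[keep],
    family_id = oc$family_id[keep],
    exposure = exposure,
    stringsAsFactors = FALSE
  )
}

#' Gaussian identity-link GEE with cluster-robust standard errors
#'
#' Fits the linear mean model by generalized estimating equations with the
#' chosen working correlation, grouping observations by cluster id, and
#' reports robust (sandwich) standard errors with two-sided Wald p-values.
#' Under the independence working correlation the point estimates coincide
#' with ordinary least squares; the exchangeable structure estimates a common
#' within-cluster correlation by moments and iterates the weighted estimating
#' equations to convergence.
#'
#' @param formula model formula (first non-intercept term is typically the
#'   exposure of interest).
#' @param data data.frame.
#' @param id cluster identifier: a column name in `data` or a vector.
#' @param corstr working correlation: `"independence"` or `"exchangeable"`.
#' @param p_ref reference distribution for the Wald p-values. The default
#'   `"t_cluster"` scales the z statistic by `sqrt(G / (G - 1))` (`G`
#'   clusters) and refers it to a t distribution with `G - p` degrees of
#'   freedom, a standard small-sample correction that keeps the type-I error
#'   near nominal at the modest cluster counts typical of per-SNP origin
#'   contrasts; `"normal"` is the uncorrected large-sample convention.
#'   The reported `se` is the unadjusted sandwich estimate either way.
#' @param tol,maxit convergence control for the exchangeable iteration.
#' @return object of class `gee_fit`: list with `coefficients`, `se`, `z`,
#'   `p`, `vcov`, `alpha` (estimated working correlation), `n`,
#'   `n_clusters`, `corstr`, `p_ref`.
#' @export
gee_fit <- function(formula, data, id,
                    corstr = c("independence", "exchangeable"),
                    p_ref = c("t_cluster", "normal"),
                    tol = 1e-8, maxit = 25L) {
  corstr <- match.arg(corstr)
  p_ref <- match.arg(p_ref)
  if (is.character(id) && length(id) == 1L && id %in% names(data)) {
    id <- data[[id]]
  }
  if (length(id) != nrow(data)) stop("cluster id length must match data rows")
  mf <- stats::model.frame(formula, data, na.action = stats::na.pass)
  cc <- stats::complete.cases(mf) & !is.na(id)
  mf <- mf[cc, , drop = FALSE]
  id <- as.character(id[cc])
  y <- stats::model.response(mf)
  X <- stats::model.matrix(attr(mf, "terms"), mf)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    aliased <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("design matrix is rank deficient; aliased column(s): ",
      paste(aliased, collapse = ", "))
  }
  clus <- split(seq_along(id), id)
  if (length(clus) < 2L) stop("GEE needs >= 2 clusters")

  beta <- qr.coef(qrX, y)
  alpha <- 0
  if (corstr == "exchangeable") {
    p <- ncol(X)
    for (it in seq_len(maxit)) {
      r <- y - drop(X %*% beta)
      phi <- sum(r^2) / (length(y) - p)
      num <- 0; den <- 0
      for (ix in clus) {
        ni <- length(ix)
        if (ni < 2L) next
        s <- sum(r[ix])
        num <- num + (s^2 - sum(r[ix]^2)) / 2
        den <- den + ni * (ni - 1) / 2
      }
      alpha <- if (den > 0) num / (phi * den) else 0
      alpha <- max(min(alpha, 0.99), -0.99)
      # solve sum_c X_c' R^{-1} X_c beta = sum_c X_c' R^{-1} y_c with
      # R = (1-a) I + a J  =>  R^{-1} = [I - a/(1 - a + a n) J] / (1 - a)
      A <- matrix(0, p, p)
      b <- numeric(p)
      for (ix in clus) {
        ni <- length(ix)
        Xc <- X[ix, , drop = FALSE]
        yc <- y[ix]
        f <- alpha / (1 - alpha + alpha * ni)
        cs_x <- colSums(Xc)
        A <- A + (crossprod(Xc) - f * tcrossprod(cs_x)) / (1 - alpha)
        b <- b + (crossprod(Xc, yc) - f * cs_x * sum(yc)) / (1 - alpha)
      }
      beta_new <- drop(solve(A, b))
      if (max(abs(beta_new - beta)) < tol) {
        beta <- beta_new
        break
      }
      beta <- beta_new
    }
  }
  r <- y - drop(X %*% beta)
  p <- ncol(X)
  if (corstr == "independence") {
    bread <- chol2inv(qr.R(qrX))
    meat <- matrix(0, p, p)
    for (ix in clus) {
      g <- crossprod(X[ix, , drop = FALSE], r[ix])
      meat <- meat + tcrossprod(g)
    }
  } else {
    A <- matrix(0, p, p)
    meat <- matrix(0, p, p)
    for (ix in clus) {
      ni <- length(ix)
      Xc <- X[ix, , drop = FALSE]
      f <- alpha / (1 - alpha + alpha * ni)
      cs_x <- colSums(Xc)
      A <- A + (crossprod(Xc) - f * tcrossprod(cs_x)) / (1 - alpha)
      g <- (crossprod(Xc, r[ix]) - f * cs_x * sum(r[ix])) / (1 - alpha)
      meat <- meat + tcrossprod(g)
    }
    bread <- solve(A)
  }
  V <- bread %*% meat %*% bread
  dimnames(V) <- list(colnames(X), colnames(X))
  se <- sqrt(diag(V))
  z <- beta / se
  G <- length(clus)
  pval <- if (p_ref == "normal") {
    2 * stats::pnorm(-abs(z))
  } else {
    2 * stats::pt(-abs(z) / sqrt(G / (G - 1)), df = max(G - p, 1L))
  }
  structure(list(
    coefficients = beta, se = se, z = z, p = pval,
    vcov = V, alpha = alpha, n = length(y),
    n_clusters = G, corstr = corstr, p_ref = p_ref
  ), class = "gee_fit")
}

#' @export
print.gee_fit <- function(x, ...) {
  cat("Gaussian GEE (", x$corstr, " working correlation), ",
    x$n, " obs in ", x$n_clusters, " clusters\n", sep = "")
  print(data.frame(
    estimate = x$coefficients, robust_se = x$se, z = x$z, p = x$p
  ))
  invisible(x)
}

#' Construct an analysis plan for the POE association sweep
#'
#' Covariate sets follow the trait family: lipid traits are adjusted for BMI,
#' sex, age, age squared and diabetes affection status; obesity traits for
#' sex, age, age squared and diabetes status; the BMI-adjusted WHR analysis
#' (`family = "obesity_adjbmi"`) appends BMI to the obesity covariates.
#' Sex-stratified runs drop sex from the covariates.
#'
#' @param traits data.frame with columns `trait` (phenotype column name),
#'   `family` (`"lipid"`, `"obesity"`, `"obesity_adjbmi"`) and optionally
#'   `label` (reporting name, defaults to `trait`).
#' @param snps character vector of SNP ids (`NULL` = all genotyped SNPs).
#' @param strata subset of `c("all", "sons", "daughters")`.
#' @param splits subset of `c("combined", "discovery", "replication")`.
#' @param alpha nominal significance level (default 0.05).
#' @param bonferroni_m number of tests for the Bonferroni flag; defaults to
#'   the number of SNP x trait tests executed in the sweep.
#' @param corstr GEE working correlation.
#' @param p_ref p-value reference distribution (see [gee_fit()]).
#' @param split_seed seed for the discovery/replication family split.
#' @param contrast_mode `"subset"` (marginal contrasts exclude minor-allele
#'   homozygotes, per the reporting convention) or `"joint"` (maternal and
#'   paternal minor-allele counts as two regressors over all origin-assigned
#'   offspring).
#' @return list of class `poe_plan`.
#' @export
poe_plan <- function(traits, snps = NULL,
                     strata = "all",
                     splits = "combined",
                     alpha = 0.05, bonferroni_m = NULL,
                     corstr = "independence", p_ref = "t_cluster",
                     split_seed = 1L,
                     contrast_mode = c("subset", "joint")) {
  contrast_mode <- match.arg(contrast_mode)
  traits <- as.data.frame(traits)
  stopifnot(all(c("trait", "family") %in% names(traits)))
  if (is.null(traits$label)) traits$label <- traits$trait
  bad <- setdiff(traits$family, c("lipid", "obesity", "obesity_adjbmi"))
  if (length(bad)) stop("unknown trait family: ", paste(bad, collapse = ", "))
  strata <- match.arg(strata, c("all", "sons", "daughters"),
    several.ok = TRUE)
  splits <- match.arg(splits, c("combined", "discovery", "replication"),
    several.ok = TRUE)
  structure(list(
    traits = traits, snps = snps, strata = strata, splits = splits,
    alpha = alpha, bonferroni_m = bonferroni_m, corstr = corstr,
    p_ref = p_ref, split_seed = split_seed, contrast_mode = contrast_mode
  ), class = "poe_plan")
}

.plan_covariates <- function(family, stratum) {
  covs <- switch(family,
    lipid = c("bmi", "sex", "age", "age2", "diabetes"),
    obesity = c("sex", "age", "age2", "diabetes"),
    obesity_adjbmi = c("sex", "age", "age2", "diabetes", "bmi")
  )
  if (stratum != "all") covs <- setdiff(covs, "sex")
  covs
}

#' Run the POE association sweep
#'
#' For every SNP x trait x stratum x split, fits the maternal, paternal and
#' parent-of-origin contrasts with family-clustered GEE and the plan's
#' covariates. Fit failures are propagated as flagged rows (NA estimates with
#' a note), never aborting the sweep. When both discovery and replication
#' splits are requested, replication calls follow the rule: replication
#' p-value below `alpha` with the same direction of effect as discovery.
#'
#' @param plan a [poe_plan()].
#' @param cohort list with elements `pedigree`, `genotypes`, `phenotypes`
#'   (transformed; must contain `individual_id`, `sex`, `age`, `age2`,
#'   `diabetes` and the trait columns), optionally `origins` (computed if
#'   absent), `snp_panel` and `cohort_label`.
#' @return data.frame of association results, one row per SNP x trait x
#'   stratum x split, with maternal/paternal/POE estimates, robust SEs,
#'   p-values, `n_het`, Bonferroni and replication flags.
#' @export
run_analysis <- function(plan, cohort) {
  stopifnot(inherits(plan, "poe_plan"))
  ped <- cohort$pedigree
  gt <- cohort$genotypes
  ph <- cohort$phenotypes
  origins <- cohort$origins
  if (is.null(origins)) origins <- infer_cohort_origins(ped, gt)
  label <- if (is.null(cohort$cohort_label)) "cohort" else cohort$cohort_label
  panel <- cohort$snp_panel
  snps <- if (is.null(plan$snps)) colnames(gt) else plan$snps
  if (!"age2" %in% names(ph) && "age" %in% names(ph)) ph$age2 <- ph$age^2

  split_tab <- NULL
  if (any(plan$splits %in% c("discovery", "replication"))) {
    split_tab <- split_families(ped$family_id, plan$split_seed)
  }
  off_sex <- ped$sex[match(ph$individual_id, ped$individual_id)]

  rows <- list()
  for (split in plan$splits) {
    fams <- if (split == "combined") unique(ped$family_id) else
      split_tab$family_id[split_tab$subset == split]
    for (stratum in plan$strata) {
      sex_keep <- switch(stratum,
        all = rep(TRUE, nrow(ph)),
        sons = off_sex == "male",
        daughters = off_sex == "female"
      )
      for (ti in seq_len(nrow(plan$traits))) {
        trait <- plan$traits$trait[ti]
        covs <- .plan_covariates(plan$traits$family[ti], stratum)
        covs <- intersect(covs, names(ph))
        for (snp in snps) {
          rows[[length(rows) + 1L]] <- .fit_snp_trait(
            origins, gt, ph, sex_keep, fams, snp, trait,
            label = plan$traits$label[ti], covs = covs,
            corstr = plan$corstr, p_ref = plan$p_ref,
            contrast_mode = plan$contrast_mode,
            cohort_label = label, split = split, stratum = stratum
          )
        }
      }
    }
  }
  res <- do.call(rbind, rows)
  rownames(res) <- NULL

  m <- plan$bonferroni_m
  if (is.null(m)) m <- length(snps) * nrow(plan$traits)
  res$bonferroni <- !is.na(res$p_poe) & res$p_poe < plan$alpha / m

  res$replicated <- NA
  if (all(c("discovery", "replication") %in% plan$splits)) {
    key <- function(d) paste(d$snp_id, d$trait, d$stratum)
    disc <- res[res$split == "discovery", , drop = FALSE]
    repl <- res[res$split == "replication", , drop = FALSE]
    i <- match(key(repl), key(disc))
    hit <- !is.na(i) &
      !is.na(disc$p_poe[i]) & disc$p_poe[i] < plan$alpha &
      !is.na(repl$p_poe) & repl$p_poe < plan$alpha &
      sign(repl$b_poe) == sign(disc$b_poe[i])
    res$replicated[res$split == "replication"] <- hit
  }
  if (!is.null(panel)) {
    i <- match(res$snp_id, panel$snp_id)
    res$chr <- panel$chr[i]
    res$gene <- panel$gene[i]
    res$location <- panel$location[i]
    res$effect_allele <- panel$effect_allele[i]
    res$other_allele <- panel$other_allele[i]
  }
  res
}

.fit_snp_trait <- function(origins, gt, ph, sex_keep, fams, snp, trait,
                           label, covs, corstr, p_ref, contrast_mode,
                           cohort_label, split, stratum) {
  out <- data.frame(
    snp_id = snp, trait = label, cohort = cohort_label,
    split = split, stratum = stratum, n_het = NA_integer_,
    b_mat = NA_real_, se_mat = NA_real_, p_mat = NA_real_,
    b_pat = NA_real_, se_pat = NA_real_, p_pat = NA_real_,
    b_poe = NA_real_, se_poe = NA_real_, p_poe = NA_real_,
    note = "", stringsAsFactors = FALSE
  )
  fit_one <- function(sample) {
    i <- match(sample$individual_id, ph$individual_id)
    keep <- !is.na(i) & !is.na(sex_keep[pmax(i, 1L)]) &
      sex_keep[pmax(i, 1L)] & sample$family_id %in% fams
    dat <- ph[i[keep], , drop = FALSE]
    dat$exposure <- sample$exposure[keep]
    dat$.fam <- sample$family_id[keep]
    form <- stats::reformulate(c("exposure", covs), response = trait)
    fit <- gee_fit(form, dat, id = ".fam", corstr = corstr, p_ref = p_ref)
    list(
      b = unname(fit$coefficients["exposure"]),
      se = unname(fit$se["exposure"]),
      p = unname(fit$p["exposure"]),
      n = fit$n
    )
  }
  res <- tryCatch({
    if (contrast_mode == "joint") {
      oc <- origins[origins$snp_id == snp & origins$status == "assigned", ,
        drop = FALSE]
      i <- match(oc$individual_id, ph$individual_id)
      keep <- !is.na(i) & !is.na(sex_keep[pmax(i, 1L)]) &
        sex_keep[pmax(i, 1L)] & oc$family_id %in% fams
      dat <- ph[i[keep], , drop = FALSE]
      dat$mat_count <- oc$maternal_minor[keep]
      dat$pat_count <- oc$paternal_minor[keep]
      dat$.fam <- oc$family_id[keep]
      form <- stats::reformulate(c("mat_count", "pat_count", covs),
        response = trait)
      fit <- gee_fit(form, dat, id = ".fam", corstr = corstr, p_ref = p_ref)
      cvec <- rep(0, length(fit$coefficients))
      names(cvec) <- names(fit$coefficients)
      cvec["pat_count"] <- 1
      cvec["mat_count"] <- -1
      b_poe <- sum(cvec * fit$coefficients)
      se_poe <- sqrt(drop(t(cvec) %*% fit$vcov %*% cvec))
      gtv <- gt[match(dat$individual_id, rownames(gt)), snp]
      list(
        mat = list(b = unname(fit$coefficients["mat_count"]),
          se = unname(fit$se["mat_count"]), p = unname(fit$p["mat_count"])),
        pat = list(b = unname(fit$coefficients["pat_count"]),
          se = unname(fit$se["pat_count"]), p = unname(fit$p["pat_count"])),
        poe = list(b = b_poe, se = se_poe,
          p = if (p_ref == "normal") {
            2 * stats::pnorm(-abs(b_poe / se_poe))
          } else {
            G <- fit$n_clusters
            2 * stats::pt(-abs(b_poe / se_poe) / sqrt(G / (G - 1)),
              df = max(G - length(fit$coefficients), 1L))
          }),
        n_het = sum(gtv == 1L, na.rm = TRUE)
      )
    } else {
      sm <- suppressWarnings(
        build_contrast_sample(origins, gt, snp, "maternal"))
      sp <- suppressWarnings(
        build_contrast_sample(origins, gt, snp, "paternal"))
      so <- suppressWarnings(build_contrast_sample(origins, gt, snp, "poe"))
      poe <- fit_one(so)
      list(mat = fit_one(sm), pat = fit_one(sp), poe = poe,
        n_het = poe$n)
    }
  }, error = function(e) e)
  if (inherits(res, "error")) {
    out$note <- conditionMessage(res)
    return(out)
  }
  out$n_het <- res$n_het
  out$b_mat <- res$mat$b; out$se_mat <- res$mat$se; out$p_mat <- res$mat$p
  out$b_pat <- res$pat$b; out$se_pat <- res$pat$se; out$p_pat <- res$pat$p
  out$b_poe <- res$poe$b; out$se_poe <- res$poe$se; out$p_poe <- res$poe$p
  out
}

#' Format association results with the standard reporting column layout
#'
#' @param results output of [run_analysis()].
#' @return data.frame with columns `Trait`, `SNP`, `Cohort`, `CHR`, `GENE`,
#'   `Location`, `E/O`, `N`, `B_MAT`, `P_MAT`, `B_PAT`, `P_PAT`, `P_POE`.
#' @export
format_results_table <- function(results) {
  g <- function(col, default = NA) {
    if (col %in% names(results)) results[[col]] else
      rep(default, nrow(results))
  }
  eo <- ifelse(
    is.na(g("effect_allele")) | is.na(g("other_allele")), NA_character_,
    paste0(g("effect_allele"), "/", g("other_allele"))
  )
  out <- data.frame(
    Trait = results$trait, SNP = results$snp_id,
    Cohort = paste(results$cohort, results$split, results$stratum, sep = ":"),
    CHR = g("chr"), GENE = g("gene"), Location = g("location"),
    check.names = FALSE, stringsAsFactors = FALSE
  )
  out[["E/O"]] <- eo
  out$N <- results$n_het
  out$B_MAT <- results$b_mat
  out$P_MAT <- results$p_mat
  out$B_PAT <- results$b_pat
  out$P_PAT <- results$p_pat
  out$P_POE <- results$p_poe
  out
}
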