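## Covariate-adjusted additive association with max-T permutation adjustment
## and per-SNP variance explained.

#' Additive linear association of one SNP with a phenotype
#'
#' Ordinary least squares of `y` on an intercept, the 0/1/2 genotype dosage
#' and the covariates; the reported test is on the dosage coefficient.
#'
#' @param y phenotype vector.
#' @param g genotype dosage vector (0/1/2).
#' @param covariates data.frame/matrix of covariates (e.g. age, sex 0/1,
#'   altitude in metres), or `NULL`.
#' @return list: `beta`, `se`, `t`, `p`, `df`, `n`.
#' @export
fit_additive <- function(y, g, covariates = NULL) {
  X <- cbind(`(Intercept)` = 1, g = g)
  if (!is.null(covariates)) X <- cbind(X, as.matrix(covariates))
  ok <- complete.cases(X) & !is.na(y)
  X <- X[ok, , drop = FALSE]; y <- y[ok]
  n <- nrow(X)
  if (n <= ncol(X)) stop("too few observations for the design")
  if (var(X[, "g"]) == 0) stop("monomorphic genotype vector")
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("collinear design columns: ", paste(bad, collapse = ", "))
  }
  beta <- qr.coef(qrX, y)
  res <- y - X %*% beta
  df <- n - ncol(X)
  sigma2 <- sum(res^2) / df
  XtXinv <- chol2inv(qr.R(qrX))[order(qrX$pivot), order(qrX$pivot), drop = FALSE]
  se <- sqrt(sigma2 * diag(XtXinv))
  names(se) <- colnames(X)
  tstat <- beta[["g"]] / se[["g"]]
  list(beta = unname(beta[["g"]]), se = unname(se[["g"]]), t = tstat,
       p = 2 * pt(-abs(tstat), df), df = df, n = n)
}

# t statistics of every SNP column of G against y given covariates, via
# residualization (Frisch-Waugh): equivalent to per-SNP OLS with covariates.
snp_tstats <- function(y, G, C) {
  qc <- qr(C)
  ry <- qr.resid(qc, y)
  RG <- qr.resid(qc, G)
  df <- length(y) - ncol(C) - 1L
  gss <- colSums(RG^2)
  beta <- colSums(RG * ry) / gss
  rss <- sum(ry^2) - beta^2 * gss
  se <- sqrt(pmax(rss, 0) / df / gss)
  t <- beta / se
  list(beta = beta, se = se, t = t, df = df)
}

#' Max-T permutation adjustment of SNP association p-values
#'
#' Freedman-Lane residual permutation: the phenotype is regressed on the
#' covariates, the residuals are permuted `B` times and added back to the
#' covariate fit, and all SNPs are refit per permutation. The family-wise
#' adjusted p for SNP j is `(1 + #{b : max_j' |t*_bj'| >= |t_j|}) / (B+1)`;
#' a per-SNP (non-family) permutation p is reported alongside.
#'
#' @param y phenotype vector.
#' @param G matrix of genotype dosages (samples x SNPs).
#' @param covariates covariate data.frame/matrix or `NULL`.
#' @param B number of permutations (default 1000; the production-scale
#'   convention is 100000).
#' @return `data.table`: `snp, beta, se, t, p_nominal, p_perm, p_adjusted`.
#' @export
permutation_adjust <- function(y, G, covariates = NULL, B = 1000) {
  G <- as.matrix(G)
  if (is.null(colnames(G))) colnames(G) <- paste0("snp", seq_len(ncol(G)))
  C <- cbind(rep(1, length(y)),
             if (!is.null(covariates)) as.matrix(covariates))
  ok <- complete.cases(C) & !is.na(y) & complete.cases(G)
  y <- y[ok]; G <- G[ok, , drop = FALSE]; C <- C[ok, , drop = FALSE]
  stopifnot(B >= 100)
  obs <- snp_tstats(y, G, C)
  qc <- qr(C)
  fitted <- qr.fitted(qc, y)
  resid <- qr.resid(qc, y)
  n <- length(y)
  exceed_max <- rep(0L, ncol(G))
  exceed_snp <- rep(0L, ncol(G))
  at <- abs(obs$t)
  for (b in seq_len(B)) {
    ystar <- fitted + resid[sample.int(n)]
    tstar <- abs(snp_tstats(ystar, G, C)$t)
    mx <- max(tstar)
    exceed_max <- exceed_max + (mx >= at)
    exceed_snp <- exceed_snp + (tstar >= at)
  }
  data.table(
    snp = colnames(G), beta = obs$beta, se = obs$se, t = obs$t,
    p_nominal = 2 * pt(-at, obs$df),
    p_perm = (1 + exceed_snp) / (B + 1),
    p_adjusted = (1 + exceed_max) / (B + 1))
}

#' Fraction of phenotypic variance explained by one SNP
#'
#' `ve = beta^2 Var(g) / Var(y)`, clipped to `[0, 1]`.
#'
#' @param beta fitted additive effect.
#' @param g genotype dosages.
#' @param y phenotype vector.
#' @return variance explained in `[0, 1]`, `NA` if `Var(y) = 0`.
#' @export
variance_explained <- function(beta, g, y) {
  vy <- var(y)
  if (is.na(vy) || vy == 0) return(NA_real_)
  min(1, max(0, beta^2 * var(g) / vy))
}

#' Candidate-SNP association scan with permutation adjustment
#'
#' Runs [fit_additive] per SNP and phenotype, with [permutation_adjust]
#' family-wise adjustment over the SNP set, and per-SNP variance explained.
#'
#' @param gm a [genotype_matrix] of candidate SNPs.
#' @param pheno phenotype table including covariate columns, rows matched to
#'   `gm$samples` by a `sample` column.
#' @param phenotypes phenotype column names to test.
#' @param covars covariate column names (default `c("age","sex","altitude")`).
#' @param B permutations (default 1000).
#' @return `data.table`: snp, phenotype, beta, se, t, p_nominal, p_perm,
#'   p_adjusted, ve.
#' @export
association_scan <- function(gm, pheno, phenotypes,
                             covars = c("age", "sex", "altitude"), B = 1000) {
  pheno <- as.data.table(pheno)
  stopifnot("sample" %in% names(pheno))
  idx <- match(gm$samples, pheno$sample)
  if (anyNA(idx)) stop("phenotype table is missing samples present in genotypes")
  ph <- pheno[idx]
  sex_num <- ph$sex
  if (is.character(sex_num) || is.factor(sex_num)) {
    sex_num <- as.integer(factor(sex_num)) - 1L
  }
  covm <- as.matrix(data.table(age = ph$age, sex = sex_num,
                               altitude = ph$altitude)[, covars, with = FALSE])
  res <- list()
  for (p in phenotypes) {
    y <- ph[[p]]
    poly <- apply(gm$calls, 2, function(g) var(g, na.rm = TRUE) > 0)
    G <- gm$calls[, poly, drop = FALSE]
    # mean-impute the rare missing dosage so the permutation matrix is complete
    G <- apply(G, 2, function(g) { g[is.na(g)] <- mean(g, na.rm = TRUE); g })
    tab <- permutation_adjust(y, G, covm, B = B)
    tab[, phenotype := p]
    ok <- !is.na(y)
    tab[, ve := vapply(seq_len(ncol(G)), function(j)
      variance_explained(beta[j], G[ok, j], y[ok]), numeric(1))]
    res[[p]] <- tab
  }
  rbindlist(res)[]
}
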