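## Blood-phenotype QC and analysis: +/- 3 SD outlier removal, group
## difference t-tests with FDR, phenotype correlations, altitude-response
## blunting, reference ranges.

#' Single-pass mean +/- k SD outlier filter
#'
#' Mean and SD are computed once from all points; values outside
#' `mean +/- k SD` are removed. With constant input (SD = 0) nothing is
#' removed. Applied once by design; pass `iterate = TRUE` for repeated
#' trimming until stable.
#'
#' @param values numeric vector (length >= 3), names used as ids.
#' @param k SD multiplier (default 3).
#' @param iterate repeat until no point is removed (default `FALSE`).
#' @return list: `values` (retained), `removed` (ids or indices removed).
#' @export
outlier_filter <- function(values, k = 3, iterate = FALSE) {
  if (length(values) < 3L) stop("outlier_filter needs at least 3 values")
  ids <- names(values)
  if (is.null(ids)) ids <- as.character(seq_along(values))
  keep <- rep(TRUE, length(values))
  repeat {
    x <- values[keep]
    s <- sd(x)
    if (!is.finite(s) || s == 0) break
    out <- keep & (values < mean(x) - k * s | values > mean(x) + k * s)
    if (!any(out)) break
    keep <- keep & !out
    if (!iterate) break
  }
  list(values = values[keep], removed = ids[!keep])
}

#' Welch t-tests between two populations across phenotypes
#'
#' One Welch two-sample t-test per phenotype, Benjamini-Hochberg adjusted
#' across the phenotype set.
#'
#' @param pheno `data.table`/data.frame with a `population` column and the
#'   phenotype columns.
#' @param groups two population labels to compare.
#' @param phenotypes phenotype column names (default: all numeric columns
#'   except covariates `altitude, age, sex`).
#' @param fdr significance threshold on q (default 0.05).
#' @return `data.table`: per phenotype the group means/SDs/ns, `t`, `p`,
#'   `q`, `significant`.
#' @export
group_diff <- function(pheno, groups, phenotypes = NULL, fdr = 0.05) {
  pheno <- as.data.table(pheno)
  stopifnot(length(groups) == 2, all(groups %in% pheno$population))
  if (is.null(phenotypes)) {
    num <- names(pheno)[vapply(pheno, is.numeric, logical(1))]
    phenotypes <- setdiff(num, c("altitude", "age", "sex"))
  }
  rows <- lapply(phenotypes, function(ph) {
    x <- pheno[population == groups[1]][[ph]]
    y <- pheno[population == groups[2]][[ph]]
    x <- x[!is.na(x)]; y <- y[!is.na(y)]
    if (length(x) < 2 || length(y) < 2 || (sd(x) == 0 && sd(y) == 0)) {
      return(data.table(phenotype = ph, mean1 = mean(x), sd1 = sd(x),
                        n1 = length(x), mean2 = mean(y), sd2 = sd(y),
                        n2 = length(y), t = NA_real_, p = NA_real_))
    }
    tt <- stats::t.test(x, y, var.equal = FALSE)
    data.table(phenotype = ph, mean1 = mean(x), sd1 = sd(x), n1 = length(x),
               mean2 = mean(y), sd2 = sd(y), n2 = length(y),
               t = unname(tt$statistic), p = tt$p.value)
  })
  res <- rbindlist(rows)
  res[, q := p.adjust(p, method = "BH")]
  res[, significant := !is.na(q) & q < fdr]
  res[]
}

#' Pairwise phenotype correlations with FDR
#'
#' Pearson correlation per phenotype pair (pairwise-complete observations),
#' Benjamini-Hochberg adjusted across pairs.
#'
#' @param pheno phenotype table.
#' @param phenotypes phenotype column names.
#' @param fdr significance threshold on q (default 0.05).
#' @return `data.table`: `pheno1, pheno2, r, n, p, q, significant`.
#' @export
pheno_correlations <- function(pheno, phenotypes, fdr = 0.05) {
  pheno <- as.data.table(pheno)
  pairs <- utils::combn(phenotypes, 2)
  rows <- lapply(seq_len(ncol(pairs)), function(i) {
    a <- pheno[[pairs[1, i]]]; b <- pheno[[pairs[2, i]]]
    ok <- !is.na(a) & !is.na(b)
    n <- sum(ok)
    if (n < 3 || sd(a[ok]) == 0 || sd(b[ok]) == 0) {
      return(data.table(pheno1 = pairs[1, i], pheno2 = pairs[2, i],
                        r = NA_real_, n = n, p = NA_real_))
    }
    ct <- stats::cor.test(a[ok], b[ok])
    data.table(pheno1 = pairs[1, i], pheno2 = pairs[2, i],
               r = unname(ct$estimate), n = n, p = ct$p.value)
  })
  res <- rbindlist(rows)
  res[, q := p.adjust(p, method = "BH")]
  res[, significant := !is.na(q) & q < fdr]
  res[]
}

#' Altitude-response slopes and blunting interaction
#'
#' Fits per-population least-squares slopes of a phenotype on altitude, and
#' a joint model `phenotype ~ altitude * population` whose interaction
#' coefficient tests whether the target population's altitude response is
#' blunted relative to the reference.
#'
#' @param pheno phenotype table with `population` and `altitude` columns.
#' @param phenotype phenotype column name (default `"HGB"`).
#' @param target,ref population labels; the interaction contrasts `target`
#'   against `ref`.
#' @return list: `slopes` (`data.table` population, slope, se, n),
#'   `interaction` (estimate, se, t, p) for the target x altitude term.
#' @export
altitude_blunting <- function(pheno, phenotype = "HGB", target, ref) {
  pheno <- as.data.table(pheno)
  d <- pheno[population %in% c(target, ref) & !is.na(get(phenotype)) &
               !is.na(altitude)]
  slopes <- d[, {
    if (length(unique(altitude)) < 2L) {
      list(slope = NA_real_, se = NA_real_, n = .N)
    } else {
      fit <- lm(get(phenotype) ~ altitude, data = .SD)
      cf <- summary(fit)$coefficients
      list(slope = cf["altitude", 1], se = cf["altitude", 2], n = .N)
    }
  }, by = population]
  d[, popf := factor(population, levels = c(ref, target))]
  fit <- lm(get(phenotype) ~ altitude * popf, data = d)
  cf <- summary(fit)$coefficients
  term <- grep("^altitude:popf", rownames(cf), value = TRUE)
  inter <- if (length(term) == 1L) {
    list(estimate = cf[term, 1], se = cf[term, 2], t = cf[term, 3],
         p = cf[term, 4])
  } else {
    list(estimate = NA_real_, se = NA_real_, t = NA_real_, p = NA_real_)
  }
  list(slopes = slopes[], interaction = inter)
}

#' Reference range as mean +/- k SD
#'
#' @param values numeric vector (length >= 3).
#' @param k SD multiplier (default 1, the `mean +/- SD` convention).
#' @return list: `mean`, `sd`, `lower`, `upper`, `k`.
#' @export
reference_range <- function(values, k = 1) {
  if (length(values) < 3L) stop("reference_range needs at least 3 values")
  m <- mean(values); s <- sd(values)
  list(mean = m, sd = s, lower = m - k * s, upper = m + k * s, k = k)
}
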