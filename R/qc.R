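## Variant- and sample-level QC: GATK-style hard filter, Hardy-Weinberg exact
## test, missingness / heterozygosity / MAF filters, PCA outlier flagging.

#' GATK-style hard filter for a variant site
#'
#' Applies the standard short-variant hard-filter expression
#' `QD < 2.0 || MQ < 40 || FS > 60.0 || SOR > 3.0 || MQRankSum < -12.5 ||
#' ReadPosRankSum < -8.0`. All inequalities are strict; an absent or `NA`
#' INFO key never fires its clause.
#'
#' @param info named list or single-row data.frame of numeric INFO values
#'   (any subset of `QD, MQ, FS, SOR, MQRankSum, ReadPosRankSum`).
#' @return list with `pass` (logical) and `reasons` (character vector of
#'   violated clause names, empty when passing).
#' @export
gatk_hard_filter <- function(info) {
  info <- as.list(info)
  val <- function(k) {
    v <- info[[k]]
    if (is.null(v) || length(v) == 0L || is.na(v)) NA_real_ else as.numeric(v)
  }
  fired <- c(
    QD = isTRUE(val("QD") < 2.0),
    MQ = isTRUE(val("MQ") < 40),
    FS = isTRUE(val("FS") > 60.0),
    SOR = isTRUE(val("SOR") > 3.0),
    MQRankSum = isTRUE(val("MQRankSum") < -12.5),
    ReadPosRankSum = isTRUE(val("ReadPosRankSum") < -8.0)
  )
  list(pass = !any(fired), reasons = names(fired)[fired])
}

#' Hardy-Weinberg exact test
#'
#' Two-sided exact test conditional on the observed allele counts: the
#' p-value sums the probabilities of all heterozygote counts (with the same
#' allele counts) whose probability does not exceed that of the observed
#' count.
#'
#' @param n_AA,n_Aa,n_aa genotype counts (non-negative, at least one > 0).
#' @return p-value in (0, 1].
#' @export
hwe_exact_test <- function(n_AA, n_Aa, n_aa) {
  stopifnot(n_AA >= 0, n_Aa >= 0, n_aa >= 0)
  n <- n_AA + n_Aa + n_aa
  if (n < 1) stop("all genotype counts are zero")
  nA <- 2L * n_AA + n_Aa
  na <- 2L * n_aa + n_Aa
  rare <- min(nA, na)
  if (rare == 0L) return(1.0)
  # heterozygote count shares parity with the rare-allele count
  hets <- seq.int(rare %% 2L, rare, by = 2L)
  # log P(n_het | nA, na) up to a common constant:
  # P ~ 2^het * n! / (nAA! nAa! naa!) with nAA=(nA-het)/2, naa=(na-het)/2
  logp <- hets * log(2) - lfactorial((nA - hets) / 2) - lfactorial(hets) -
    lfactorial((na - hets) / 2)
  p <- exp(logp - max(logp))
  p <- p / sum(p)
  obs <- which(hets == n_Aa)
  if (!length(obs)) stop("observed heterozygote count inconsistent with allele counts")
  min(1, sum(p[p <= p[obs] * (1 + 1e-12)]))
}

site_missing_rate <- function(gm) colMeans(is.na(gm$calls))
sample_missing_rate <- function(gm) rowMeans(is.na(gm$calls))

site_maf <- function(gm) {
  p <- colMeans(gm$calls, na.rm = TRUE) / 2
  p[is.nan(p)] <- NA_real_
  pmin(p, 1 - p)
}

site_hwe_p <- function(gm) {
  vapply(seq_len(ncol(gm$calls)), function(j) {
    g <- gm$calls[, j]
    g <- g[!is.na(g)]
    if (!length(g)) return(NA_real_)
    hwe_exact_test(sum(g == 0L), sum(g == 1L), sum(g == 2L))
  }, numeric(1))
}

#' Variant-level QC
#'
#' Removes sites failing the Hardy-Weinberg exact test (`p < hwe_p`), with
#' missing genotype rate above `mgr`, or with minor allele frequency below
#' `maf` (frequency computed from non-missing calls). Site order is
#' preserved.
#'
#' @param gm a [genotype_matrix].
#' @param hwe_p HWE p-value threshold (default `1e-6`).
#' @param mgr maximum missing genotype rate (default `0.05`).
#' @param maf minimum minor allele frequency (default `0.05`).
#' @return list with the filtered `genotype_matrix` and a `report`
#'   data.table (`id`, `reason`) of removed sites.
#' @export
variant_qc <- function(gm, hwe_p = 1e-6, mgr = 0.05, maf = 0.05) {
  stopifnot(length(gm$samples) >= 1L)
  mr <- site_missing_rate(gm)
  mafs <- site_maf(gm)
  hwe <- site_hwe_p(gm)
  reason <- rep(NA_character_, ncol(gm$calls))
  reason[!is.na(hwe) & hwe < hwe_p] <- "hwe"
  reason[is.na(reason) & mr > mgr] <- "mgr"
  reason[is.na(reason) & (is.na(mafs) | mafs < maf)] <- "maf"
  keep <- is.na(reason)
  out <- genotype_matrix(gm$calls[, keep, drop = FALSE],
                         gm$sites[keep], gm$samples)
  list(matrix = out,
       report = data.table(id = gm$sites$id[!keep], reason = reason[!keep]))
}

observed_heterozygosity <- function(gm) {
  rowMeans(gm$calls == 1L, na.rm = TRUE)
}

#' Sample-level QC
#'
#' Removes samples with missing rate above `miss`; then, among the remaining
#' samples, removes those whose observed heterozygosity lies outside
#' `mean +/- het_sd * SD` (single pass). When the heterozygosity SD is zero
#' the rule is vacuous and no sample is removed by it.
#'
#' @param gm a [genotype_matrix] with at least 3 samples.
#' @param miss maximum per-sample missing rate (default `0.05`).
#' @param het_sd SD multiplier for the heterozygosity rule (default `3`).
#' @return list with the filtered `genotype_matrix` and a `report`
#'   data.table (`sample`, `reason`).
#' @export
sample_qc <- function(gm, miss = 0.05, het_sd = 3) {
  if (length(gm$samples) < 3L) stop("sample_qc needs at least 3 samples")
  mr <- sample_missing_rate(gm)
  drop_miss <- mr > miss
  kept <- !drop_miss
  het <- observed_heterozygosity(gm)
  hk <- het[kept]
  s <- sd(hk)
  drop_het <- rep(FALSE, length(gm$samples))
  if (is.finite(s) && s > 0) {
    lo <- mean(hk) - het_sd * s
    hi <- mean(hk) + het_sd * s
    drop_het <- kept & (het < lo | het > hi)
  }
  keep <- !(drop_miss | drop_het)
  out <- genotype_matrix(gm$calls[keep, , drop = FALSE], gm$sites,
                         gm$samples[keep])
  list(matrix = out,
       report = data.table(
         sample = gm$samples[!keep],
         reason = ifelse(drop_miss[!keep], "missingness", "heterozygosity")))
}

#' PCA with iterative outlier flagging
#'
#' Computes principal components of the centered, `sqrt(p(1-p))`-scaled
#' genotype matrix (Patterson convention; missing calls mean-imputed for the
#' decomposition only). A sample is flagged when its PC1 or PC2 coordinate
#' lies outside `mean +/- sd_mult * SD` within its declared population;
#' flagged samples are removed and the PCA re-run until no sample is
#' flagged.
#'
#' @param gm a [genotype_matrix].
#' @param populations population label per sample (same order as
#'   `gm$samples`).
#' @param k number of components (default 2; flagging always uses PC1/PC2).
#' @param sd_mult SD multiplier for flagging (default 6).
#' @param max_iter safety cap on outlier-removal rounds.
#' @return list with `scores` (final-round PC coordinates, samples x k),
#'   `flagged` (character vector of all removed sample ids) and `kept`.
#' @export
pca_outliers <- function(gm, populations, k = 2, sd_mult = 6, max_iter = 20) {
  stopifnot(length(populations) == length(gm$samples),
            length(gm$samples) >= k + 1)
  flagged <- character(0)
  keep <- rep(TRUE, length(gm$samples))
  scores <- NULL
  for (iter in seq_len(max_iter)) {
    X <- gm$calls[keep, , drop = FALSE]
    p <- colMeans(X, na.rm = TRUE) / 2
    v <- p * (1 - p)
    use <- !is.na(v) & v > 0
    if (!any(use)) stop("degenerate genotype matrix: no polymorphic sites")
    Z <- sweep(X[, use, drop = FALSE], 2, 2 * p[use], "-")
    Z <- sweep(Z, 2, sqrt(v[use]), "/")
    Z[is.na(Z)] <- 0
    if (sum(apply(Z, 2, var)) == 0) stop("degenerate (zero-variance) matrix")
    kk <- min(k, nrow(Z) - 1L, ncol(Z))
    sv <- svd(Z, nu = kk, nv = 0)
    scores <- sv$u %*% diag(sv$d[seq_len(kk)], kk)
    rownames(scores) <- gm$samples[keep]
    pops <- populations[keep]
    out <- rep(FALSE, nrow(scores))
    for (pp in unique(pops)) {
      rows <- which(pops == pp)
      if (length(rows) < 3L) next
      for (j in seq_len(min(2L, kk))) {
        x <- scores[rows, j]
        s <- sd(x)
        if (is.finite(s) && s > 0) {
          out[rows] <- out[rows] | abs(x - mean(x)) > sd_mult * s
        }
      }
    }
    if (!any(out)) break
    flagged <- c(flagged, rownames(scores)[out])
    keep[match(rownames(scores)[out], gm$samples)] <- FALSE
  }
  list(scores = scores, flagged = flagged, kept = gm$samples[keep])
}

#' Full QC pipeline in the canonical order
#'
#' Applies, in order: GATK-style hard filtering on site INFO annotations;
#' sample missingness; sample heterozygosity; PCA admixture-outlier
#' flagging (when `populations` given); variant-level HWE / missing-rate /
#' MAF filters.
#'
#' @param gm a [genotype_matrix] whose site table may carry INFO columns.
#' @param populations optional population label per sample, enables the PCA
#'   step.
#' @param hwe_p,mgr,maf variant-level thresholds (see [variant_qc]).
#' @param miss,het_sd sample-level thresholds (see [sample_qc]).
#' @param pca_sd PCA outlier SD multiplier (see [pca_outliers]).
#' @return list: `matrix` (clean [genotype_matrix]) and `report` with
#'   `removed_samples` (`sample`, `reason` in
#'   `missingness|heterozygosity|pca_outlier`), `removed_sites` (`id`,
#'   `reason` in `hard_filter|hwe|mgr|maf`) and before/after `counts`.
#' @export
qc_pipeline <- function(gm, populations = NULL, hwe_p = 1e-6, mgr = 0.05,
                        maf = 0.05, miss = 0.05, het_sd = 3, pca_sd = 6) {
  n0 <- length(gm$samples); m0 <- ncol(gm$calls)
  # 1. hard filter on INFO
  info_cols <- intersect(INFO_KEYS, names(gm$sites))
  hard_fail <- rep(FALSE, m0)
  if (length(info_cols)) {
    for (j in seq_len(m0)) {
      hard_fail[j] <- !gatk_hard_filter(as.list(gm$sites[j, info_cols,
                                                         with = FALSE]))$pass
    }
  }
  site_report <- data.table(id = gm$sites$id[hard_fail],
                            reason = rep("hard_filter", sum(hard_fail)))
  gm <- genotype_matrix(gm$calls[, !hard_fail, drop = FALSE],
                        gm$sites[!hard_fail], gm$samples)
  # 2-3. sample missingness + heterozygosity
  sq <- sample_qc(gm, miss = miss, het_sd = het_sd)
  gm <- sq$matrix
  sample_report <- sq$report
  # 4. PCA outliers within declared populations
  if (!is.null(populations)) {
    pops <- populations[match(gm$samples, names(populations))]
    if (anyNA(pops)) stop("populations must be named by sample id and cover all samples")
    pc <- pca_outliers(gm, pops, sd_mult = pca_sd)
    if (length(pc$flagged)) {
      sample_report <- rbind(sample_report,
                             data.table(sample = pc$flagged,
                                        reason = "pca_outlier"))
      keep <- gm$samples %in% pc$kept
      gm <- genotype_matrix(gm$calls[keep, , drop = FALSE], gm$sites,
                            gm$samples[keep])
    }
  }
  # 5. variant-level filters
  vq <- variant_qc(gm, hwe_p = hwe_p, mgr = mgr, maf = maf)
  site_report <- rbind(site_report, vq$report)
  list(matrix = vq$matrix,
       report = list(removed_samples = sample_report,
                     removed_sites = site_report,
                     counts = list(samples_before = n0,
                                   samples_after = length(vq$matrix$samples),
                                   sites_before = m0,
                                   sites_after = ncol(vq$matrix$calls))))
}
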