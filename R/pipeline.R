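## End-to-end selection-scan pipeline on a study bundle.

#' Run the selection scan on a study
#'
#' Computes the five per-SNP statistics for the target against the primary
#' reference, scores the composite, thresholds genome-wide, clumps into
#' candidate regions, and calls peak-SNP candidate genes.
#'
#' @param study a [simulate_study] object, or any list with `panels`
#'   (named: target first), `annotation`.
#' @param dists calibrated `score_distributions`; `NULL` uses
#'   [calibrate_empirical] on the observed scores.
#' @param target,ref,ref2 population names in `study$panels`.
#' @param index_q,sp2_q,r2_min,radius_kb,min_sp2 clumping parameters (see
#'   [clump], [call_candidate_regions]).
#' @param q genome-wide CMS top quantile (default 0.001).
#' @param min_components minimum defined CMS components (default 3).
#' @param scan_maf dataset-level minor-allele-frequency floor applied across
#'   the pooled target + reference samples before any statistic is computed
#'   (default 0.05, mirroring locus-level QC); 0 disables.
#' @param null_cms optional vector of composite scores from neutral
#'   reference simulations. When given, the significance threshold and the
#'   clump index/SP2 thresholds are quantiles of this neutral distribution
#'   instead of the scan's own values — appropriate when the scanned
#'   chromosome is short enough that a sweep distorts its quantiles.
#' @param ... passed to [compute_site_scores].
#' @return list: `scores`, `cms`, `threshold`, `regions`,
#'   `candidate_regions`, `genes` (peak-SNP gene calls with the
#'   target-enriched `tbpe_*` allele columns).
#' @export
run_scan <- function(study, dists = NULL, target = "TBP", ref = "DUROC",
                     ref2 = "YKX", q = 0.001, min_components = 3,
                     index_q = 0.001, sp2_q = 0.01, r2_min = 0.2,
                     radius_kb = 500, min_sp2 = 5, scan_maf = 0.05,
                     null_cms = NULL, ...) {
  panels <- pooled_maf_filter(study$panels, scan_maf)
  sc <- compute_site_scores(panels[[target]], panels[[ref]],
                            ref2 = if (!is.null(ref2) && ref2 %in% names(panels))
                              panels[[ref2]] else NULL, ...)
  if (is.null(dists)) dists <- calibrate_empirical(sc)
  cm <- cms_score(sc, dists, min_components = min_components)
  if (is.null(null_cms)) {
    thr <- genome_threshold(cm$cms, q = q)
    thr_i <- thr_s <- NULL
  } else {
    # thresholds from the neutral reference distribution: on a short
    # simulated chromosome the sweep itself distorts the within-scan
    # quantiles, whereas a real genome-wide quantile is essentially neutral
    v <- null_cms[!is.na(null_cms)]
    thr <- list(threshold = quantile(v, 1 - q, type = 7, names = FALSE))
    thr$flags <- !is.na(cm$cms) & cm$cms >= thr$threshold
    thr_i <- quantile(v, 1 - index_q, type = 7, names = FALSE)
    thr_s <- quantile(v, 1 - sp2_q, type = 7, names = FALSE)
  }
  regions <- clump(cm, panels[[target]], index_q = index_q, sp2_q = sp2_q,
                   r2_min = r2_min, radius_kb = radius_kb,
                   thr_index = thr_i, thr_sp2 = thr_s)
  cand <- call_candidate_regions(regions, min_sp2 = min_sp2)
  genes <- if (nrow(cand) && !is.null(study$annotation)) {
    peak_gene(cand, study$annotation)
  } else {
    data.table(gene = character(0))
  }
  if (nrow(genes) && "peak_id" %in% names(genes)) {
    # target-enriched allele at each peak SNP, against every reference
    refs <- Filter(Negate(is.null),
                   list(panels[[ref]],
                        if (!is.null(ref2) && ref2 %in% names(panels))
                          panels[[ref2]]))
    tg <- panels[[target]]
    info <- lapply(genes$peak_id, function(id) {
      j <- match(id, tg$sites$id)
      ea <- enriched_allele(allele_freq(tg, j),
                            lapply(refs, allele_freq, site_index = j))
      list(allele = ea$allele, freq = ea$freq_target, margin = ea$margin,
           ambiguous = ea$ambiguous)
    })
    genes[, `:=`(
      tbpe_allele = vapply(info, `[[`, integer(1), "allele"),
      tbpe_freq_target = vapply(info, `[[`, numeric(1), "freq"),
      tbpe_margin = vapply(info, `[[`, numeric(1), "margin"),
      tbpe_ambiguous = vapply(info, `[[`, logical(1), "ambiguous"))]
  }
  list(scores = sc, cms = cm, threshold = thr$threshold, regions = regions,
       candidate_regions = cand, genes = genes)
}

#' Dataset-level MAF filter across pooled panels
#'
#' Keeps sites whose minor-allele frequency in the pooled haplotypes of all
#' supplied panels is at least `maf` — the locus-level QC conventionally
#' applied before selection statistics are computed.
#'
#' @param panels named list of [haplotype_panel]s sharing one site list.
#' @param maf MAF floor (0 disables).
#' @return the filtered panel list.
#' @export
pooled_maf_filter <- function(panels, maf = 0.05) {
  if (maf <= 0) return(panels)
  pooled <- do.call(rbind, lapply(panels, `[[`, "haps"))
  pfreq <- colMeans(pooled)
  keep <- pmin(pfreq, 1 - pfreq) >= maf
  lapply(panels, subset_panel, keep = keep)
}
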