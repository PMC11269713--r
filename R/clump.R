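## LD computation, greedy LD clumping of CMS-significant SNPs, peak-SNP gene
## calling, interval-class annotation, and target-enriched allele calls.

#' Squared haplotype correlation between two sites
#'
#' `r^2 = D^2 / (pA(1-pA) pB(1-pB))` with `D = pAB - pA pB`, computed from
#' phased haplotype counts.
#'
#' @param panel a [haplotype_panel].
#' @param i,j 1-based site indices; both must be polymorphic in the panel.
#' @return r-squared in `[0, 1]`, or `NA` when a site is monomorphic.
#' @export
ld_r2 <- function(panel, i, j) {
  a <- panel$haps[, i]; b <- panel$haps[, j]
  pa <- mean(a); pb <- mean(b)
  if (pa %in% c(0, 1) || pb %in% c(0, 1)) return(NA_real_)
  pab <- mean(a == 1L & b == 1L)
  D <- pab - pa * pb
  D^2 / (pa * (1 - pa) * pb * (1 - pb))
}

#' Greedy LD clumping of CMS-significant SNPs
#'
#' PLINK-style clumping on composite scores: SNPs at or above the top
#' `index_q` genome-wide quantile are sorted by descending cms (ties broken
#' by smaller position); each still-unclaimed index SNP claims as members
#' all unclaimed SNPs within `radius_kb` whose cms reaches the top `sp2_q`
#' quantile and whose r-squared with the index is at least `r2_min`.
#' Claimed SNPs can neither seed nor join later clumps.
#'
#' @param cms_result a [cms_score] table.
#' @param panel [haplotype_panel] covering the same sites (LD is computed in
#'   this panel, conventionally the target population).
#' @param index_q index-SNP top quantile (default 0.001).
#' @param sp2_q member (SP2) top quantile (default 0.01).
#' @param r2_min LD threshold (default 0.2).
#' @param radius_kb clump radius in kb (default 500).
#' @param thr_index,thr_sp2 explicit score thresholds overriding the
#'   quantile-derived ones (e.g. a threshold from a reference scan).
#' @return `data.table` of regions: `region_id, chrom, index_id, index_pos,
#'   index_cms, start, end, n_members, member_ids`; zero rows when nothing
#'   is significant.
#' @export
clump <- function(cms_result, panel, index_q = 0.001, sp2_q = 0.01,
                  r2_min = 0.2, radius_kb = 500, thr_index = NULL,
                  thr_sp2 = NULL) {
  stopifnot(nrow(cms_result) == ncol(panel$haps))
  radius <- radius_kb * 1000
  v <- cms_result$cms
  if (is.null(thr_index)) thr_index <- genome_threshold(v, index_q)$threshold
  if (is.null(thr_sp2)) thr_sp2 <- genome_threshold(v, sp2_q)$threshold
  idx_cand <- which(!is.na(v) & v >= thr_index)
  if (!length(idx_cand)) {
    return(data.table(region_id = integer(0), chrom = character(0),
                      index_id = character(0), index_pos = integer(0),
                      index_cms = numeric(0), start = integer(0),
                      end = integer(0), n_members = integer(0),
                      member_ids = character(0)))
  }
  ord <- idx_cand[order(-v[idx_cand], cms_result$pos[idx_cand])]
  claimed <- rep(FALSE, nrow(cms_result))
  regions <- list()
  rid <- 0L
  for (s in ord) {
    if (claimed[s]) next
    claimed[s] <- TRUE
    rid <- rid + 1L
    near <- which(!claimed &
                    cms_result$chrom == cms_result$chrom[s] &
                    abs(cms_result$pos - cms_result$pos[s]) <= radius &
                    !is.na(v) & v >= thr_sp2)
    members <- near[vapply(near, function(j) {
      r2 <- ld_r2(panel, s, j)
      !is.na(r2) && r2 >= r2_min
    }, logical(1))]
    claimed[members] <- TRUE
    pos_all <- c(cms_result$pos[s], cms_result$pos[members])
    regions[[rid]] <- data.table(
      region_id = rid, chrom = cms_result$chrom[s],
      index_id = cms_result$id[s], index_pos = cms_result$pos[s],
      index_cms = v[s], start = min(pos_all), end = max(pos_all),
      n_members = length(members),
      member_ids = paste(cms_result$id[members], collapse = ","))
  }
  rbindlist(regions)
}

#' Filter clump regions on SP2 membership
#'
#' Keeps regions with strictly more than `min_sp2` member SNPs.
#'
#' @param regions a [clump] table.
#' @param min_sp2 membership floor (default 5; a region needs >= 6 members).
#' @return the retained rows.
#' @export
call_candidate_regions <- function(regions, min_sp2 = 5) {
  regions[regions$n_members > min_sp2]
}

#' Read a BED6+ gene/feature annotation
#'
#' Columns `chrom start end gene class strand` (0-based half-open,
#' BED convention); `class` must be one of `CDS, UTR5, UTR3, intron,
#' regulatory, intergenic`.
#'
#' @param path path to the BED file.
#' @return `data.table` with those columns.
#' @export
read_annotation <- function(path) {
  a <- fread(path, header = FALSE, sep = "\t")
  setnames(a, c("chrom", "start", "end", "gene", "class",
                "strand")[seq_len(min(6L, ncol(a)))])
  if ("gene" %in% names(a)) a[gene == ".", gene := NA_character_]
  validate_annotation(a)
  a
}

validate_annotation <- function(a) {
  stopifnot(all(c("chrom", "start", "end", "gene", "class") %in% names(a)),
            all(a$start < a$end),
            all(a$class %in% c("CDS", "UTR5", "UTR3", "intron", "regulatory",
                               "intergenic")))
  invisible(a)
}

#' Write a BED-like annotation table
#' @param a annotation `data.table`.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_annotation <- function(a, path) {
  a <- copy(as.data.table(a))
  if ("gene" %in% names(a)) a[is.na(gene), gene := "."]
  fwrite(a, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

# intervals are 0-based half-open; SNP positions 1-based -> bp index pos-1
snp_in_interval <- function(pos, start, end) {
  (pos - 1L) >= start & (pos - 1L) < end
}

#' Peak-SNP gene calls for candidate regions
#'
#' For each region, every gene whose body (union of its non-intergenic
#' feature intervals) contains the index (peak) SNP becomes a candidate
#' gene; a peak overlapping several genes yields one row per gene flagged
#' `ambiguous`. Regions whose peak lies in no gene are retained with
#' `gene = NA`. Duplicate genes across regions are deduplicated keeping the
#' occurrence with maximal cms.
#'
#' @param regions a [call_candidate_regions] table.
#' @param annotation a gene/feature annotation ([read_annotation] dialect).
#' @return `data.table`: `gene, chrom, peak_id, peak_pos, peak_cms,
#'   region_id, start, end, ambiguous`.
#' @export
peak_gene <- function(regions, annotation) {
  gene_bodies <- annotation[class != "intergenic" & !is.na(gene),
                            .(start = min(start), end = max(end)),
                            by = .(chrom, gene)]
  out <- list()
  for (r in seq_len(nrow(regions))) {
    reg <- regions[r]
    hit <- gene_bodies[chrom == reg$chrom &
                         snp_in_interval(reg$index_pos, start, end)]
    if (nrow(hit) == 0L) {
      out[[length(out) + 1L]] <- data.table(
        gene = NA_character_, chrom = reg$chrom, peak_id = reg$index_id,
        peak_pos = reg$index_pos, peak_cms = reg$index_cms,
        region_id = reg$region_id, start = reg$start, end = reg$end,
        ambiguous = FALSE)
    } else {
      out[[length(out) + 1L]] <- data.table(
        gene = hit$gene, chrom = reg$chrom, peak_id = reg$index_id,
        peak_pos = reg$index_pos, peak_cms = reg$index_cms,
        region_id = reg$region_id, start = reg$start, end = reg$end,
        ambiguous = nrow(hit) > 1L)
    }
  }
  res <- rbindlist(out)
  if (nrow(res)) {
    setorder(res, -peak_cms)
    res <- res[is.na(gene) | !duplicated(gene)]
    setorder(res, region_id)
  }
  res[]
}

#' Interval-class annotation of SNPs
#'
#' Assigns each SNP the highest-priority overlapping feature class
#' (`CDS > UTR5 = UTR3 > regulatory > intron > intergenic`); positions not
#' covered by the annotation are `intergenic`. The summary counts `coding`
#' as CDS and everything else as `noncoding`.
#'
#' @param snps `data.table` with `chrom` and `pos` (1-based).
#' @param annotation feature annotation ([read_annotation] dialect).
#' @return list: `per_snp` (input plus `class`), `summary` (`class, count,
#'   percent`), `coding_percent`, `noncoding_percent`.
#' @export
annotate_snps <- function(snps, annotation) {
  priority <- c(CDS = 1, UTR5 = 2, UTR3 = 2, regulatory = 3, intron = 4,
                intergenic = 5)
  cls <- rep("intergenic", nrow(snps))
  for (i in seq_len(nrow(snps))) {
    hits <- annotation[chrom == snps$chrom[i] &
                         snp_in_interval(snps$pos[i], start, end), class]
    if (length(hits)) cls[i] <- hits[which.min(priority[hits])]
  }
  per_snp <- copy(as.data.table(snps))[, class := cls]
  tab <- per_snp[, .(count = .N), by = class]
  tab[, percent := 100 * count / nrow(per_snp)]
  coding <- sum(cls == "CDS")
  list(per_snp = per_snp, summary = tab[],
       coding_percent = 100 * coding / nrow(per_snp),
       noncoding_percent = 100 * (nrow(per_snp) - coding) / nrow(per_snp))
}

#' Target-enriched allele at a site
#'
#' Returns the allele (derived-coded `1`, or `0`) whose frequency in the
#' target population exceeds its frequency in every reference population;
#' when neither allele qualifies, the allele maximizing
#' `target - max(ref)` is returned with `ambiguous = TRUE`.
#'
#' @param freq_target target [allele_freq] (list with `p`).
#' @param freq_refs list of reference allele frequencies for the same
#'   allele.
#' @return list: `allele` (1 = panel-coded allele, 0 = the other),
#'   `freq_target`, `freq_refs`, `margin`, `ambiguous`.
#' @export
enriched_allele <- function(freq_target, freq_refs) {
  pt <- freq_target$p
  prs <- vapply(freq_refs, function(f) f$p, numeric(1))
  margin1 <- pt - max(prs)            # allele coded 1
  margin0 <- (1 - pt) - max(1 - prs)  # allele coded 0
  if (margin1 > 0) {
    list(allele = 1L, freq_target = pt, freq_refs = prs, margin = margin1,
         ambiguous = FALSE)
  } else if (margin0 > 0) {
    list(allele = 0L, freq_target = 1 - pt, freq_refs = 1 - prs,
         margin = margin0, ambiguous = FALSE)
  } else if (margin1 >= margin0) {
    list(allele = 1L, freq_target = pt, freq_refs = prs, margin = margin1,
         ambiguous = TRUE)
  } else {
    list(allele = 0L, freq_target = 1 - pt, freq_refs = 1 - prs,
         margin = margin0, ambiguous = TRUE)
  }
}
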