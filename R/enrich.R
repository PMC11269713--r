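## Organ/system enrichment of candidate genes via eQTL-interval overlap and
## one-sided Fisher's exact test.

#' Read an organ eQTL map (BED4)
#'
#' Columns `chrom start end organ`, 0-based half-open intervals.
#'
#' @param path path to the BED file.
#' @return `data.table` with those columns.
#' @export
read_eqtl_map <- function(path) {
  a <- fread(path, header = FALSE, sep = "\t")
  setnames(a, c("chrom", "start", "end", "organ")[seq_len(min(4L, ncol(a)))])
  stopifnot(all(c("chrom", "start", "end", "organ") %in% names(a)),
            all(a$start < a$end))
  a
}

#' Map genes to organs by interval overlap
#'
#' A gene belongs to an organ iff its interval overlaps at least one of the
#' organ's eQTL intervals by >= 1 bp (half-open arithmetic). Genes without
#' an interval in `gene_intervals` are excluded with a warning.
#'
#' @param genes character vector of gene names (candidates or background).
#' @param gene_intervals `data.table` `chrom, start, end, gene` (0-based
#'   half-open gene bodies).
#' @param eqtl an [read_eqtl_map] table.
#' @return named list: per organ, the character vector of member genes.
#' @export
map_genes_to_organs <- function(genes, gene_intervals, eqtl) {
  gi <- as.data.table(gene_intervals)[gene %in% genes]
  missing <- setdiff(genes, gi$gene)
  if (length(missing)) {
    warning("genes without intervals excluded: ",
            paste(missing, collapse = ", "))
  }
  out <- list()
  for (org in unique(eqtl$organ)) {
    iv <- eqtl[organ == org]
    member <- gi[, {
      hit <- FALSE
      for (r in seq_len(nrow(iv))) {
        if (chrom == iv$chrom[r] && start < iv$end[r] && end > iv$start[r]) {
          hit <- TRUE
          break
        }
      }
      list(hit = hit)
    }, by = .(gene, chrom, start, end)]
    out[[org]] <- unique(member[hit == TRUE]$gene)
  }
  out
}

#' One-sided Fisher exact enrichment of candidate genes per organ
#'
#' For each organ, tests whether candidate genes overlap the organ's gene
#' set more often than expected from the background, using the
#' hypergeometric upper tail (one-sided "greater"); Benjamini-Hochberg
#' across organs.
#'
#' @param candidates character vector of candidate genes (must be a subset
#'   of `background`).
#' @param background character vector of background genes.
#' @param organ_sets named list of per-organ gene sets
#'   ([map_genes_to_organs]).
#' @return `data.table`: `organ, a, b, c, d` (candidate-in/out,
#'   background-rest-in/out), `odds_ratio, p, q`.
#' @export
fisher_enrichment <- function(candidates, background, organ_sets) {
  if (!length(background)) stop("empty background gene set")
  if (!all(candidates %in% background)) {
    stop("candidates must be a subset of the background")
  }
  rows <- lapply(names(organ_sets), function(org) {
    set <- intersect(organ_sets[[org]], background)
    a <- length(intersect(candidates, set))
    b <- length(candidates) - a
    cc <- length(setdiff(set, candidates))
    d <- length(background) - length(candidates) - cc
    p <- fisher_greater(a, b, cc, d)
    or <- if (b * cc > 0) (a * d) / (b * cc) else Inf
    data.table(organ = org, a = a, b = b, c = cc, d = d, odds_ratio = or,
               p = p)
  })
  res <- rbindlist(rows)
  res[, q := p.adjust(p, method = "BH")]
  res[]
}

# one-sided (greater) Fisher exact p from the hypergeometric tail:
# P(X >= a) with X ~ Hypergeom(white = a+c, black = b+d, drawn = a+b)
fisher_greater <- function(a, b, c, d) {
  phyper(a - 1, a + c, b + d, a + b, lower.tail = FALSE)
}
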