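## Core containers: variant site tables, genotype matrices, haplotype panels.

#' Build a variant site table
#'
#' A site table is a `data.table` with one row per biallelic SNV and columns
#' `chrom`, `pos` (1-based), `id`, `ref`, `alt`, `ancestral`
#' (`"ref"`, `"alt"` or `"unknown"`), plus optional numeric INFO columns
#' (`QD`, `MQ`, `FS`, `SOR`, `MQRankSum`, `ReadPosRankSum`).
#'
#' @param chrom chromosome labels.
#' @param pos 1-based positions, strictly increasing within a chromosome.
#' @param id variant identifiers; `NA` entries are replaced by
#'   `chrom_pos` synthetic ids.
#' @param ref,alt single-nucleotide alleles, `ref != alt` per site.
#' @param ancestral which allele is ancestral: `"ref"`, `"alt"` or
#'   `"unknown"`.
#' @param info optional `data.frame` of numeric INFO annotations.
#' @return a `data.table` of class `variant_sites`.
#' @export
variant_sites <- function(chrom, pos, id = NA_character_, ref = "A", alt = "G",
                          ancestral = "unknown", info = NULL) {
  n <- length(pos)
  dt <- data.table(
    chrom = as.character(rep_len(chrom, n)),
    pos = as.integer(pos),
    id = as.character(rep_len(id, n)),
    ref = as.character(rep_len(ref, n)),
    alt = as.character(rep_len(alt, n)),
    ancestral = as.character(rep_len(ancestral, n))
  )
  dt[is.na(id), id := paste0(chrom, "_", pos)]
  if (!is.null(info)) {
    info <- as.data.table(info)
    stopifnot(nrow(info) == n)
    dt <- cbind(dt, info)
  }
  validate_sites(dt)
  setattr(dt, "class", c("variant_sites", class(dt)))
  dt[]
}

validate_sites <- function(sites) {
  stopifnot(all(sites$pos >= 1L), all(sites$ref != sites$alt),
            all(sites$ancestral %in% c("ref", "alt", "unknown")))
  bad <- sites[, any(diff(pos) <= 0), by = chrom]$V1
  if (any(bad)) stop("site positions must be strictly increasing within a chromosome")
  invisible(sites)
}

INFO_KEYS <- c("QD", "MQ", "FS", "SOR", "MQRankSum", "ReadPosRankSum")

#' Construct a genotype matrix
#'
#' Diploid genotypes coded as alt-allele dosage 0/1/2 with `NA` for missing
#' calls; rows are samples, columns are sites.
#'
#' @param calls integer matrix samples x sites with values in
#'   `{0, 1, 2, NA}`.
#' @param sites a [variant_sites] table with `ncol(calls)` rows.
#' @param samples sample identifiers, unique, length `nrow(calls)`.
#' @return an object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(calls, sites, samples) {
  calls <- as.matrix(calls)
  storage.mode(calls) <- "integer"
  stopifnot(nrow(sites) == ncol(calls), length(samples) == nrow(calls),
            !anyDuplicated(samples))
  ok <- calls %in% c(0L, 1L, 2L) | is.na(calls)
  if (!all(ok)) stop("genotype calls must be 0, 1, 2 or NA")
  dimnames(calls) <- list(samples, sites$id)
  structure(list(calls = calls, sites = sites, samples = as.character(samples)),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("<genotype_matrix> %d samples x %d sites, %.2f%% missing\n",
              nrow(x$calls), ncol(x$calls), 100 * mean(is.na(x$calls))))
  invisible(x)
}

#' Construct a phased haplotype panel
#'
#' Haplotypes are stored derived-coded: a 1 means the derived allele where the
#' ancestral allele is known, and the alt allele where it is unknown. Input
#' may be alt-coded (VCF convention); set `coding = "alt"` to flip columns
#' with `ancestral == "alt"` at construction.
#'
#' @param haps binary matrix, 2n haplotype rows x m site columns, no missing
#'   entries.
#' @param sites a [variant_sites] table.
#' @param samples diploid sample ids; haplotype rows `2i-1, 2i` belong to
#'   sample `i`.
#' @param population population label for the panel.
#' @param coding `"derived"` (already derived-coded) or `"alt"` (VCF alt
#'   dosage; flipped where ancestral is the alt allele).
#' @return an object of class `haplotype_panel`.
#' @export
haplotype_panel <- function(haps, sites, samples, population = "POP",
                            coding = c("derived", "alt")) {
  coding <- match.arg(coding)
  haps <- as.matrix(haps)
  storage.mode(haps) <- "integer"
  stopifnot(!anyNA(haps), all(haps %in% c(0L, 1L)),
            ncol(haps) == nrow(sites), nrow(haps) == 2L * length(samples))
  if (coding == "alt") {
    flip <- which(sites$ancestral == "alt")
    if (length(flip)) haps[, flip] <- 1L - haps[, flip]
  }
  structure(list(
    haps = haps, sites = sites,
    sample_of_haplotype = rep(as.character(samples), each = 2L),
    samples = as.character(samples), population = population
  ), class = "haplotype_panel")
}

#' @export
print.haplotype_panel <- function(x, ...) {
  cat(sprintf("<haplotype_panel> %s: %d haplotypes x %d sites\n",
              x$population, nrow(x$haps), ncol(x$haps)))
  invisible(x)
}

#' Alt-coded haplotype matrix of a panel
#'
#' Returns the haplotypes recoded so 1 always means the alt allele
#' (VCF dosage convention), undoing the derived-coding flip.
#'
#' @param panel a [haplotype_panel].
#' @return integer matrix 2n x m.
#' @export
alt_coded <- function(panel) {
  haps <- panel$haps
  flip <- which(panel$sites$ancestral == "alt")
  if (length(flip)) haps[, flip] <- 1L - haps[, flip]
  haps
}

#' Collapse a phased panel to genotype dosages
#'
#' @param panel a [haplotype_panel].
#' @return a [genotype_matrix] with alt-allele dosages.
#' @export
panel_to_genotypes <- function(panel) {
  a <- alt_coded(panel)
  n <- length(panel$samples)
  calls <- a[seq(1L, 2L * n, by = 2L), , drop = FALSE] +
    a[seq(2L, 2L * n, by = 2L), , drop = FALSE]
  genotype_matrix(calls, panel$sites, panel$samples)
}

#' Read a sample manifest
#'
#' Tab-separated file with header `sample  population  altitude  sex  age`.
#'
#' @param path path to the TSV file.
#' @return a `data.table` with those columns.
#' @export
read_manifest <- function(path) {
  m <- fread(path, sep = "\t", header = TRUE, colClasses = list(character = "sample"))
  need <- c("sample", "population", "altitude", "sex", "age")
  if (!all(need %in% names(m))) {
    stop("manifest must have columns: ", paste(need, collapse = ", "))
  }
  if (anyDuplicated(m$sample)) stop("duplicate sample ids in manifest")
  if (any(m$altitude < 0)) stop("altitude must be >= 0")
  m
}

#' Write a sample manifest
#' @param manifest a manifest `data.table`.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_manifest <- function(manifest, path) {
  fwrite(manifest, path, sep = "\t")
  invisible(path)
}

#' Subset a haplotype panel to selected sites
#'
#' @param panel a [haplotype_panel].
#' @param keep logical mask or integer site indices.
#' @return a [haplotype_panel] restricted to those sites, order preserved.
#' @export
subset_panel <- function(panel, keep) {
  haplotype_panel(panel$haps[, keep, drop = FALSE], panel$sites[keep],
                  panel$samples, panel$population)
}
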