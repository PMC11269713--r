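## Restricted-dialect VCF 4.2 reader/writer: biallelic SNVs, GT calls, AA and
## GATK hard-filter INFO keys. Round-trip identity on calls and site metadata
## is part of the contract and is tested.

#' Read a VCF of biallelic SNVs
#'
#' Parses a VCF 4.x file restricted to biallelic single-nucleotide variants.
#' Records that are multi-allelic or not SNVs are skipped and counted. The
#' ancestral allele is taken from the `AA` INFO key when present and equal to
#' REF or ALT, otherwise `"unknown"`. Numeric INFO keys `QD, MQ, FS, SOR,
#' MQRankSum, ReadPosRankSum` are carried into the site table when present.
#'
#' @param path path to an uncompressed VCF file.
#' @param require_phased if `TRUE`, all genotypes must be phased (`|`
#'   separator, no missing alleles) and a [haplotype_panel] is returned;
#'   otherwise a [genotype_matrix] (missing call `./.` becomes `NA`).
#' @param population population label attached to a returned panel.
#' @param samples optional character vector restricting (and ordering) the
#'   samples read.
#' @return a [haplotype_panel] or [genotype_matrix]; the number of skipped
#'   records is attached as attribute `skipped`.
#' @export
read_vcf <- function(path, require_phased = FALSE, population = "POP",
                     samples = NULL) {
  lines <- readLines(path)
  meta <- startsWith(lines, "##")
  hdr_i <- which(startsWith(lines, "#CHROM"))
  if (length(hdr_i) != 1L) stop("malformed VCF header: no #CHROM line in ", path)
  hdr <- strsplit(lines[hdr_i], "\t", fixed = TRUE)[[1]]
  if (length(hdr) < 10L) stop("VCF has no sample columns: ", path)
  all_samples <- hdr[-(1:9)]
  body <- lines[-seq_len(hdr_i)]
  body <- body[!startsWith(body, "#")]

  empty_sites <- variant_sites(character(0), integer(0))
  if (!length(body)) {
    out <- if (require_phased) {
      haplotype_panel(matrix(integer(0), 2L * length(all_samples), 0),
                      empty_sites, all_samples, population)
    } else {
      genotype_matrix(matrix(integer(0), length(all_samples), 0),
                      empty_sites, all_samples)
    }
    attr(out, "skipped") <- 0L
    return(out)
  }
  f <- strsplit(body, "\t", fixed = TRUE)
  nf <- lengths(f)
  if (any(nf != length(hdr))) stop("malformed VCF record (field count) in ", path)
  rec <- do.call(rbind, f)

  ref <- rec[, 4]; alt <- rec[, 5]
  keep <- nchar(ref) == 1L & nchar(alt) == 1L & !grepl(",", alt, fixed = TRUE) &
    ref %in% c("A", "C", "G", "T") & alt %in% c("A", "C", "G", "T")
  skipped <- sum(!keep)
  rec <- rec[keep, , drop = FALSE]
  if (!nrow(rec)) stop("no biallelic SNV records in ", path)

  info <- parse_info(rec[, 8])
  anc <- rep("unknown", nrow(rec))
  if (!is.null(info$AA)) {
    anc[!is.na(info$AA) & info$AA == rec[, 4]] <- "ref"
    anc[!is.na(info$AA) & info$AA == rec[, 5]] <- "alt"
  }
  keep_cols <- intersect(INFO_KEYS, names(info$num))
  num_info <- if (length(keep_cols)) info$num[, keep_cols, with = FALSE] else NULL
  sites <- variant_sites(chrom = rec[, 1], pos = as.integer(rec[, 2]),
                         id = ifelse(rec[, 3] == ".", NA_character_, rec[, 3]),
                         ref = rec[, 4], alt = rec[, 5], ancestral = anc,
                         info = num_info)

  gt <- rec[, -(1:9), drop = FALSE]
  colnames(gt) <- all_samples
  if (!is.null(samples)) {
    missing <- setdiff(samples, all_samples)
    if (length(missing)) stop("samples not in VCF: ", paste(missing, collapse = ", "))
    gt <- gt[, samples, drop = FALSE]
  } else {
    samples <- all_samples
  }
  # first colon-separated subfield is GT
  gt <- sub(":.*$", "", gt)

  if (require_phased) {
    ok_gt <- grepl("^[01]\\|[01]$", gt)
    dim(ok_gt) <- dim(gt)
    bad <- which(!ok_gt, arr.ind = TRUE)
    if (nrow(bad)) {
      stop(sprintf("unphased or missing genotype '%s' at %s:%s (sample %s)",
                   gt[bad[1, , drop = FALSE]], sites$chrom[bad[1, 1]],
                   sites$pos[bad[1, 1]], samples[bad[1, 2]]))
    }
    a1 <- matrix(as.integer(substr(gt, 1, 1)), nrow(gt), ncol(gt))
    a2 <- matrix(as.integer(substr(gt, 3, 3)), nrow(gt), ncol(gt))
    haps <- matrix(0L, 2L * length(samples), nrow(sites))
    haps[seq(1L, nrow(haps), 2L), ] <- t(a1)
    haps[seq(2L, nrow(haps), 2L), ] <- t(a2)
    out <- haplotype_panel(haps, sites, samples, population, coding = "alt")
  } else {
    miss <- gt %in% c("./.", ".|.", ".")
    dos <- suppressWarnings(
      as.integer(substr(gt, 1, 1)) + as.integer(substr(gt, 3, 3)))
    dos[miss] <- NA_integer_
    if (anyNA(dos[!miss])) stop("unparseable genotype in ", path)
    out <- genotype_matrix(t(matrix(dos, nrow(gt), ncol(gt))), sites, samples)
  }
  attr(out, "skipped") <- skipped
  out
}

parse_info <- function(info_str) {
  kvs <- strsplit(info_str, ";", fixed = TRUE)
  aa <- rep(NA_character_, length(info_str))
  num <- matrix(NA_real_, length(info_str), length(INFO_KEYS),
                dimnames = list(NULL, INFO_KEYS))
  for (i in seq_along(kvs)) {
    for (kv in kvs[[i]]) {
      eq <- regexpr("=", kv, fixed = TRUE)
      if (eq < 0) next
      key <- substr(kv, 1, eq - 1)
      val <- substr(kv, eq + 1, nchar(kv))
      if (key == "AA") aa[i] <- val
      else if (key %in% INFO_KEYS) num[i, key] <- as.numeric(val)
    }
  }
  keep <- colnames(num)[colSums(!is.na(num)) > 0]
  list(AA = if (any(!is.na(aa))) aa else NULL,
       num = as.data.table(num[, keep, drop = FALSE]))
}

#' Write a panel or genotype matrix as VCF
#'
#' Emits VCF 4.2. Panels are written with phased `a|b` genotypes in alt
#' coding; genotype matrices with unphased `0/0, 0/1, 1/1, ./.`. The `AA`
#' INFO key is written whenever the ancestral allele is known, and any of the
#' numeric hard-filter INFO keys present in the site table are emitted.
#'
#' @param x a [haplotype_panel] or [genotype_matrix].
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_vcf <- function(x, path) {
  sites <- x$sites
  info_cols <- intersect(INFO_KEYS, names(sites))
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=cmsscan",
    "##INFO=<ID=AA,Number=1,Type=Character,Description=\"Ancestral allele\">",
    sprintf("##INFO=<ID=%s,Number=1,Type=Float,Description=\"%s\">",
            info_cols, info_cols),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", x$samples), collapse = "\t"))
  m <- nrow(sites)
  if (m == 0L) {
    writeLines(hdr, path)
    return(invisible(path))
  }
  info <- rep("", m)
  known <- sites$ancestral != "unknown"
  aa <- ifelse(sites$ancestral == "ref", sites$ref, sites$alt)
  info[known] <- paste0("AA=", aa[known])
  for (k in info_cols) {
    v <- sites[[k]]
    has <- !is.na(v)
    piece <- paste0(k, "=", formatC(v[has], format = "g", digits = 8))
    info[has] <- ifelse(nzchar(info[has]), paste0(info[has], ";", piece), piece)
  }
  info[!nzchar(info)] <- "."

  if (inherits(x, "haplotype_panel")) {
    a <- alt_coded(x)
    o <- seq(1L, nrow(a), 2L)
    gtm <- matrix(paste0(a[o, , drop = FALSE], "|", a[o + 1L, , drop = FALSE]),
                  nrow = length(o))
  } else {
    d <- x$calls
    gtm <- matrix("./.", nrow(d), ncol(d))
    gtm[!is.na(d) & d == 0L] <- "0/0"
    gtm[!is.na(d) & d == 1L] <- "0/1"
    gtm[!is.na(d) & d == 2L] <- "1/1"
  }
  body <- paste(sites$chrom, sites$pos, sites$id, sites$ref, sites$alt,
                ".", "PASS", info, "GT",
                apply(gtm, 2, paste, collapse = "\t"), sep = "\t")
  writeLines(c(hdr, body), path)
  invisible(path)
}
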