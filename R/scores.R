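## Per-SNP selection statistics: allele frequencies, FST, EHH/iHH, iHS,
## XPEHH, delta-iHH, nSL, and frequency-bin standardization.

#' Derived allele frequency at a site
#'
#' @param panel a [haplotype_panel].
#' @param site_index 1-based site index.
#' @return list with `p` (derived, or alt where ancestral unknown, allele
#'   frequency) and `n` (number of sampled alleles).
#' @export
allele_freq <- function(panel, site_index) {
  stopifnot(site_index >= 1, site_index <= ncol(panel$haps))
  col <- panel$haps[, site_index]
  list(p = mean(col), n = length(col))
}

#' Per-site FST between two populations
#'
#' Hudson estimator (with sample-size correction) or the haploid-sample
#' Weir-Cockerham two-population theta-hat. Negative estimates are reported
#' as computed unless `clip = TRUE`.
#'
#' @param p1,p2 allele frequencies of the same allele in the two populations.
#' @param n1,n2 numbers of sampled alleles (>= 2).
#' @param estimator `"hudson"` (default) or `"weir_cockerham"`.
#' @param clip clip negative estimates at zero (default `FALSE`).
#' @return FST estimate; `NA` (flagged undefined) when both populations are
#'   fixed for the same allele.
#' @export
fst_pair <- function(p1, n1, p2, n2, estimator = c("hudson", "weir_cockerham"),
                     clip = FALSE) {
  estimator <- match.arg(estimator)
  stopifnot(n1 >= 2, n2 >= 2)
  if (estimator == "hudson") {
    den <- p1 * (1 - p2) + p2 * (1 - p1)
    if (den == 0) return(NA_real_)
    num <- (p1 - p2)^2 - p1 * (1 - p1) / (n1 - 1) - p2 * (1 - p2) / (n2 - 1)
    f <- num / den
  } else {
    r <- 2
    nbar <- (n1 + n2) / 2
    pbar <- (n1 * p1 + n2 * p2) / (n1 + n2)
    if (pbar == 0 || pbar == 1) return(NA_real_)
    s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
    nc <- (n1 + n2 - (n1^2 + n2^2) / (n1 + n2)) / (r - 1)
    a <- (nbar / nc) *
      (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2) / (nbar - 1))
    b <- (nbar / (nbar - 1)) * (pbar * (1 - pbar) - (r - 1) / r * s2)
    if (a + b == 0) return(NA_real_)
    f <- a / (a + b)
  }
  if (clip) f <- max(0, f)
  f
}

#' Extended haplotype homozygosity curve
#'
#' EHH at offset x is the probability that two random haplotypes carrying the
#' core allele are identical at every site from the core through x, computed
#' site-by-site outward.
#'
#' @param panel a [haplotype_panel].
#' @param core_index 1-based core site index.
#' @param core_allele 0 or 1 in derived coding; `-1` pools all haplotypes
#'   (identity then includes the core site itself).
#' @param direction `"left"` or `"right"`.
#' @param min_ehh stop once EHH falls below this (crossing value included).
#' @param max_steps cap on flanking sites examined (`Inf` = none).
#' @return list of class `ehh_curve`: `distances` (bp offsets, starting at
#'   0), `ehh` values, `side`, `core_index`, `n_carriers`; `NULL` when fewer
#'   than 2 haplotypes carry the core allele.
#' @export
ehh <- function(panel, core_index, core_allele, direction = c("right", "left"),
                min_ehh = 0, max_steps = Inf) {
  direction <- match.arg(direction)
  dir <- if (direction == "right") 1L else -1L
  ms <- if (is.finite(max_steps)) as.integer(max_steps) else -1L
  e <- ehh_steps_cpp(panel$haps, core_index - 1L, as.integer(core_allele),
                     dir, min_ehh, ms)
  if (!length(e)) return(NULL)
  steps <- length(e) - 1L
  sites <- core_index + dir * seq_len(steps)
  d <- c(0, abs(panel$sites$pos[sites] - panel$sites$pos[core_index]))
  structure(list(core_index = core_index, side = direction,
                 distances = d, ehh = as.numeric(e),
                 n_carriers = attr(e, "n_carriers")),
            class = "ehh_curve")
}

# Integrate one side of an EHH curve from the core outward.
# Stops at the interpolated cutoff crossing, at the first inter-site gap
# larger than max_gap, or at the chromosome end (flagged).
ihh_side <- function(distances, ehh_vals, cutoff = 0.05, max_gap = 200000) {
  stopifnot(length(distances) == length(ehh_vals))
  total <- 0
  status <- "truncated_end"
  if (length(distances) < 2L) {
    return(list(ihh = 0, status = if (ehh_vals[1] < cutoff) "complete" else status))
  }
  for (i in 2:length(distances)) {
    d0 <- distances[i - 1]; d1 <- distances[i]
    e0 <- ehh_vals[i - 1]; e1 <- ehh_vals[i]
    if (d1 - d0 > max_gap) { status <- "truncated_gap"; break }
    if (e1 < cutoff) {
      # interpolate crossing point
      dstar <- d0 + (d1 - d0) * (e0 - cutoff) / (e0 - e1)
      total <- total + (e0 + cutoff) / 2 * (dstar - d0)
      status <- "complete"
      break
    }
    total <- total + (e0 + e1) / 2 * (d1 - d0)
  }
  list(ihh = total, status = status)
}

#' Integrated EHH from a pair of one-sided curves
#'
#' Trapezoidal integral of EHH over physical distance, each side integrated
#' from the core outward until EHH drops below `cutoff` (the crossing point
#' is interpolated), the inter-site gap exceeds `max_gap`, or the chromosome
#' ends; sides are summed.
#'
#' @param curve_left,curve_right [ehh] curves for the two sides.
#' @param cutoff EHH integration cutoff (default 0.05).
#' @param max_gap maximum inter-site gap in bp (default 200 kb).
#' @return list: `ihh`, `truncated` flag, per-side statuses.
#' @export
ihh <- function(curve_left, curve_right, cutoff = 0.05, max_gap = 200000) {
  if (is.null(curve_left) || is.null(curve_right)) return(NULL)
  l <- ihh_side(curve_left$distances, curve_left$ehh, cutoff, max_gap)
  r <- ihh_side(curve_right$distances, curve_right$ehh, cutoff, max_gap)
  list(ihh = l$ihh + r$ihh, truncated = (l$status != "complete") ||
         (r$status != "complete"), left = l$status, right = r$status)
}

site_ihh <- function(panel, core_index, core_allele, cutoff = 0.05,
                     max_gap = 200000) {
  cl <- ehh(panel, core_index, core_allele, "left", min_ehh = cutoff * 0.999)
  cr <- ehh(panel, core_index, core_allele, "right", min_ehh = cutoff * 0.999)
  ihh(cl, cr, cutoff, max_gap)
}

#' Frequency-bin standardization bins
#'
#' Equal-width bins on derived allele frequency, with adjacent bins merged
#' left-to-right until every bin holds at least `min_count` defined values;
#' per-bin mean and SD are stored.
#'
#' @param values unstandardized statistic values (NA allowed).
#' @param dafs derived allele frequencies, same length.
#' @param bin_width bin width on (0,1) (default 0.02).
#' @param min_count minimum values per bin after merging (default 20).
#' @return object of class `std_bins`: `edges`, `mean`, `sd`, `n`.
#' @export
build_bins <- function(values, dafs, bin_width = 0.02, min_count = 20) {
  ok <- !is.na(values) & !is.na(dafs)
  if (!any(ok)) stop("no defined values to build standardization bins")
  v <- values[ok]; d <- dafs[ok]
  edges <- seq(0, 1, by = bin_width)
  if (edges[length(edges)] < 1) edges <- c(edges, 1)
  idx <- findInterval(d, edges, rightmost.closed = TRUE, all.inside = TRUE)
  cnt <- tabulate(idx, nbins = length(edges) - 1L)
  # merge adjacent bins left-to-right until each holds >= min_count
  merged_edges <- edges[1]
  acc <- 0
  for (b in seq_along(cnt)) {
    acc <- acc + cnt[b]
    if (acc >= min_count) {
      merged_edges <- c(merged_edges, edges[b + 1])
      acc <- 0
    }
  }
  if (length(merged_edges) == 1L) {
    merged_edges <- c(0, 1)
  } else {
    merged_edges[length(merged_edges)] <- 1
    if (acc > 0 && length(merged_edges) > 2L) {
      # fold a trailing underfull bin into its neighbour
      merged_edges <- merged_edges[-(length(merged_edges) - 1L)]
    }
  }
  bi <- findInterval(d, merged_edges, rightmost.closed = TRUE,
                     all.inside = TRUE)
  nb <- length(merged_edges) - 1L
  mu <- vapply(seq_len(nb), function(b) mean(v[bi == b]), numeric(1))
  sg <- vapply(seq_len(nb), function(b) sd(v[bi == b]), numeric(1))
  n <- tabulate(bi, nbins = nb)
  structure(list(edges = merged_edges, mean = mu, sd = sg, n = n),
            class = "std_bins")
}

#' Standardize values within frequency bins
#'
#' @param values unstandardized values.
#' @param dafs derived allele frequencies.
#' @param bins a [build_bins] object.
#' @return standardized values (`NA` preserved; `NA` where the bin SD is 0
#'   or undefined).
#' @export
standardize_by_bins <- function(values, dafs, bins) {
  out <- rep(NA_real_, length(values))
  ok <- !is.na(values) & !is.na(dafs)
  bi <- findInterval(dafs[ok], bins$edges, rightmost.closed = TRUE,
                     all.inside = TRUE)
  mu <- bins$mean[bi]; sg <- bins$sd[bi]
  res <- (values[ok] - mu) / sg
  res[!is.finite(res)] <- NA_real_
  out[ok] <- res
  out
}

# SL of an allele class: mean over carrier pairs of the number of consecutive
# sites (counting the core) over which the pair is identical, both directions.
site_sl <- function(panel, core_index, core_allele) {
  l <- ehh_steps_cpp(panel$haps, core_index - 1L, as.integer(core_allele),
                     -1L, 0, -1L)
  r <- ehh_steps_cpp(panel$haps, core_index - 1L, as.integer(core_allele),
                     1L, 0, -1L)
  if (!length(l) || !length(r)) return(NA_real_)
  1 + sum(l[-1]) + sum(r[-1])
}

#' Unstandardized iHS, delta-iHH and nSL at one site
#'
#' iHS is `ln(iHH_A / iHH_D)`, delta-iHH is `iHH_D - iHH_A`, nSL is
#' `ln(SL_A / SL_D)`; all require a known ancestral allele. A hard sweep on
#' the derived allele drives iHS and nSL negative and delta-iHH positive.
#'
#' @param panel a [haplotype_panel] (derived-coded).
#' @param site_index 1-based site index.
#' @param cutoff,max_gap iHH integration parameters.
#' @return list `ihh_a`, `ihh_d`, `ihs_u`, `dihh_u`, `nsl_u` (NA where
#'   undefined).
#' @keywords internal
site_haplo_stats <- function(panel, site_index, cutoff = 0.05,
                             max_gap = 200000) {
  out <- list(ihh_a = NA_real_, ihh_d = NA_real_, ihs_u = NA_real_,
              dihh_u = NA_real_, nsl_u = NA_real_)
  if (panel$sites$ancestral[site_index] == "unknown") return(out)
  ia <- site_ihh(panel, site_index, 0L, cutoff, max_gap)
  id <- site_ihh(panel, site_index, 1L, cutoff, max_gap)
  if (!is.null(ia)) out$ihh_a <- ia$ihh
  if (!is.null(id)) out$ihh_d <- id$ihh
  if (!is.null(ia) && !is.null(id)) {
    out$dihh_u <- id$ihh - ia$ihh
    if (ia$ihh > 0 && id$ihh > 0) out$ihs_u <- log(ia$ihh / id$ihh)
  }
  sa <- site_sl(panel, site_index, 0L)
  sd_ <- site_sl(panel, site_index, 1L)
  if (!is.na(sa) && !is.na(sd_) && sa > 0 && sd_ > 0) {
    out$nsl_u <- log(sa / sd_)
  }
  out
}

#' Unstandardized cross-population EHH statistic at one site
#'
#' `ln(iHH_target / iHH_ref)` with each population's iHH computed from all
#' of its haplotypes (core site included in the identity span) and a common
#' stopping point on each side chosen where the pooled two-population EHH
#' drops below `cutoff` (Sabeti-style symmetric truncation).
#'
#' @param panel_target,panel_ref panels sharing the same site list.
#' @param site_index 1-based site index.
#' @param cutoff pooled-EHH stopping cutoff.
#' @param max_gap maximum inter-site gap in bp.
#' @return unstandardized XPEHH value, or NA when undefined.
#' @export
xpehh_u <- function(panel_target, panel_ref, site_index, cutoff = 0.05,
                    max_gap = 200000) {
  ht <- alt_coded(panel_target)
  hr <- alt_coded(panel_ref)
  xpehh_u_mat(ht, hr, rbind(ht, hr), panel_target$sites$pos, site_index,
              cutoff, max_gap)
}

xpehh_u_mat <- function(ht, hr, pooled, pos, site_index, cutoff = 0.05,
                        max_gap = 200000) {
  it <- 0; ir <- 0
  for (dir in c(-1L, 1L)) {
    ep <- ehh_steps_cpp(pooled, site_index - 1L, -1L, dir, cutoff * 0.999, -1L)
    if (!length(ep)) return(NA_real_)
    steps <- length(ep) - 1L
    sites <- site_index + dir * seq_len(steps)
    d <- c(0, abs(pos[sites] - pos[site_index]))
    dstop <- side_stop_distance(d, ep, cutoff, max_gap)
    et <- ehh_steps_cpp(ht, site_index - 1L, -1L, dir, 0, steps)
    er <- ehh_steps_cpp(hr, site_index - 1L, -1L, dir, 0, steps)
    if (!length(et) || !length(er)) return(NA_real_)
    it <- it + integrate_to(d[seq_along(et)], et, dstop)
    ir <- ir + integrate_to(d[seq_along(er)], er, dstop)
  }
  if (it <= 0 || ir <= 0) return(NA_real_)
  log(it / ir)
}

# distance at which integration stops for a curve: cutoff crossing
# (interpolated), gap, or end of data
side_stop_distance <- function(distances, ehh_vals, cutoff, max_gap) {
  if (length(distances) < 2L) return(distances[1])
  for (i in 2:length(distances)) {
    if (distances[i] - distances[i - 1] > max_gap) return(distances[i - 1])
    if (ehh_vals[i] < cutoff) {
      e0 <- ehh_vals[i - 1]; e1 <- ehh_vals[i]
      return(distances[i - 1] +
               (distances[i] - distances[i - 1]) * (e0 - cutoff) / (e0 - e1))
    }
  }
  distances[length(distances)]
}

# trapezoid integral of a piecewise-linear curve from 0 to dstop
integrate_to <- function(distances, ehh_vals, dstop) {
  total <- 0
  if (length(distances) < 2L || dstop <= 0) return(0)
  for (i in 2:length(distances)) {
    d0 <- distances[i - 1]; d1 <- distances[i]
    e0 <- ehh_vals[i - 1]; e1 <- ehh_vals[i]
    if (d1 >= dstop) {
      estar <- if (d1 > d0) e0 + (e1 - e0) * (dstop - d0) / (d1 - d0) else e1
      total <- total + (e0 + estar) / 2 * (dstop - d0)
      return(total)
    }
    total <- total + (e0 + e1) / 2 * (d1 - d0)
  }
  total
}

#' Compute the five per-SNP selection statistics for a target panel
#'
#' Produces a per-SNP table of derived allele frequency, Hudson (or
#' Weir-Cockerham) FST against the reference population(s), and standardized
#' iHS, XPEHH, delta-iHH and nSL. iHS and nSL are computed only at sites
#' with known ancestral allele and minor allele frequency at or above
#' `min_maf`; delta-iHH wherever the ancestral allele is known; XPEHH at all
#' sites segregating in either population. iHS, delta-iHH and nSL are
#' standardized within derived-allele-frequency bins, XPEHH genome-wide.
#'
#' @param target target-population [haplotype_panel].
#' @param ref reference-population panel sharing the target's site list.
#' @param ref2 optional second reference panel (extra FST column).
#' @param cutoff EHH integration cutoff (default 0.05).
#' @param max_gap maximum inter-site gap in bp (default 200 kb).
#' @param min_maf MAF floor for iHS/nSL (default 0.05).
#' @param estimator FST estimator, `"hudson"` or `"weir_cockerham"`.
#' @param bin_width,min_count standardization-bin parameters.
#' @return `data.table` with columns `chrom, pos, id, daf, fst` (vs `ref`),
#'   optionally `fst_ref2`, unstandardized `ihs_u, xpehh_u, dihh_u, nsl_u`,
#'   `ihh_a, ihh_d`, and standardized `ihs, xpehh, dihh, nsl`.
#' @export
compute_site_scores <- function(target, ref, ref2 = NULL, cutoff = 0.05,
                                max_gap = 200000, min_maf = 0.05,
                                estimator = "hudson", bin_width = 0.02,
                                min_count = 20) {
  m <- ncol(target$haps)
  stopifnot(ncol(ref$haps) == m)
  nt <- nrow(target$haps); nr <- nrow(ref$haps)
  pt <- colMeans(target$haps)
  pr <- colMeans(ref$haps)
  maf_t <- pmin(pt, 1 - pt)

  fst <- vapply(seq_len(m), function(j)
    fst_pair(pt[j], nt, pr[j], nr, estimator), numeric(1))
  fst2 <- NULL
  if (!is.null(ref2)) {
    p2 <- colMeans(ref2$haps)
    fst2 <- vapply(seq_len(m), function(j)
      fst_pair(pt[j], nt, p2[j], nrow(ref2$haps), estimator), numeric(1))
  }

  ihs_u <- dihh_u <- nsl_u <- xp_u <- rep(NA_real_, m)
  ihh_a <- ihh_d <- rep(NA_real_, m)
  anc_known <- target$sites$ancestral != "unknown"
  ht <- alt_coded(target)
  hr <- alt_coded(ref)
  pooled <- rbind(ht, hr)
  pos <- target$sites$pos
  for (j in seq_len(m)) {
    if (anc_known[j] && maf_t[j] > 0) {
      hs <- site_haplo_stats(target, j, cutoff, max_gap)
      ihh_a[j] <- hs$ihh_a; ihh_d[j] <- hs$ihh_d
      dihh_u[j] <- hs$dihh_u
      if (maf_t[j] >= min_maf) {
        ihs_u[j] <- hs$ihs_u
        nsl_u[j] <- hs$nsl_u
      }
    }
    if ((pt[j] > 0 && pt[j] < 1) || (pr[j] > 0 && pr[j] < 1)) {
      xp_u[j] <- xpehh_u_mat(ht, hr, pooled, pos, j, cutoff, max_gap)
    }
  }

  daf <- pt
  std_or_na <- function(u) {
    ok <- !is.na(u) & !is.na(daf)
    if (sum(ok) >= min_count) {
      bins <- build_bins(u, daf, bin_width, min_count)
      standardize_by_bins(u, daf, bins)
    } else rep(NA_real_, m)
  }
  res <- data.table(
    chrom = target$sites$chrom, pos = target$sites$pos, id = target$sites$id,
    daf = daf, fst = fst,
    ihh_a = ihh_a, ihh_d = ihh_d,
    ihs_u = ihs_u, xpehh_u = xp_u, dihh_u = dihh_u, nsl_u = nsl_u,
    ihs = std_or_na(ihs_u),
    xpehh = {
      ok <- !is.na(xp_u)
      z <- rep(NA_real_, m)
      if (sum(ok) >= 2 && sd(xp_u[ok]) > 0)
        z[ok] <- (xp_u[ok] - mean(xp_u[ok])) / sd(xp_u[ok])
      z
    },
    dihh = std_or_na(dihh_u),
    nsl = std_or_na(nsl_u)
  )
  if (!is.null(fst2)) res[, fst_ref2 := fst2]
  res[]
}
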