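## Composite of multiple signals: calibrated score densities under selection
## and neutrality, per-SNP log-likelihood-ratio composite, genome-wide
## quantile threshold.

CMS_STATS <- c("fst", "ihs", "xpehh", "dihh", "nsl")

# histogram density with an epsilon floor on empty bins; integrates to 1
fit_density <- function(values, breaks) {
  v <- values[!is.na(values)]
  n <- length(v)
  v <- pmin(pmax(v, breaks[1]), breaks[length(breaks)])
  cnt <- tabulate(findInterval(v, breaks, rightmost.closed = TRUE,
                               all.inside = TRUE),
                  nbins = length(breaks) - 1L)
  eps <- 1 / (10 * n)
  mass <- pmax(cnt / n, eps)
  mass <- mass / sum(mass)
  list(breaks = breaks, mass = mass,
       density = mass / diff(breaks), n = n, eps = eps)
}

density_at <- function(dens, x) {
  b <- findInterval(pmin(pmax(x, dens$breaks[1]),
                         dens$breaks[length(dens$breaks)]),
                    dens$breaks, rightmost.closed = TRUE, all.inside = TRUE)
  dens$density[b]
}

#' Calibrate CMS score distributions from labelled panels
#'
#' Computes the five selection statistics on simulator output labelled
#' neutral versus swept and fits, for each statistic, binned histogram
#' densities under selection (`f_sel`, scores at the sweep site and its
#' flank) and neutrality (`f_neu`, all neutral-replicate scores). Densities
#' use `n_bins` bins spanning the pooled range with a `1/(10 n)` floor on
#' empty bins.
#'
#' @param neutral_panels list of `list(target=, ref=)` panel pairs from
#'   neutral simulations.
#' @param sweep_panels list of `list(target=, ref=, sweep_pos=)` panel pairs
#'   from sweep simulations.
#' @param flank bp window around the sweep position contributing to the
#'   selected class (default 50 kb).
#' @param n_bins histogram bins (default 64).
#' @param min_values minimum defined values required per statistic per class
#'   (default 500).
#' @param ... passed to [compute_site_scores].
#' @return object of class `score_distributions`: per statistic a list with
#'   `f_sel`, `f_neu`; plus calibration metadata.
#' @export
calibrate_cms <- function(neutral_panels, sweep_panels, flank = 50000,
                          n_bins = 64, min_values = 500, ...) {
  pull <- function(pp, sel_window) {
    sc <- compute_site_scores(pp$target, pp$ref, ...)
    if (!is.null(sel_window)) {
      sc <- sc[abs(pos - sel_window) <= flank]
    }
    sc
  }
  neu <- rbindlist(lapply(neutral_panels, pull, sel_window = NULL),
                   fill = TRUE)
  sel <- rbindlist(lapply(sweep_panels, function(pp)
    pull(pp, sel_window = pp$sweep_pos)), fill = TRUE)
  dists <- list()
  for (st in CMS_STATS) {
    vn <- neu[[st]]; vs <- sel[[st]]
    vn <- vn[!is.na(vn)]; vs <- vs[!is.na(vs)]
    if (length(vn) < min_values || length(vs) < min_values) {
      stop(sprintf("insufficient calibration values for %s (neutral %d, selected %d, need %d)",
                   st, length(vn), length(vs), min_values))
    }
    rng <- range(c(vn, vs))
    if (diff(rng) == 0) rng <- rng + c(-0.5, 0.5)
    breaks <- seq(rng[1], rng[2], length.out = n_bins + 1L)
    dists[[st]] <- list(f_sel = fit_density(vs, breaks),
                        f_neu = fit_density(vn, breaks))
  }
  structure(list(stats = dists,
                 meta = list(source = "simulation", flank = flank,
                             n_bins = n_bins,
                             n_neutral = length(neutral_panels),
                             n_sweep = length(sweep_panels))),
            class = "score_distributions")
}

#' Calibrate CMS densities from the empirical tail of observed scores
#'
#' Fallback when no simulations are available: `f_neu` is fitted from all
#' observed values of each statistic and `f_sel` from its selected-direction
#' tail (lower tail for iHS/nSL, upper tail for FST/XPEHH/delta-iHH). This
#' is an approximation — the tail is contaminated by neutral SNPs — and is
#' labelled as such in the metadata.
#'
#' @param scores a [compute_site_scores] table.
#' @param tail_q tail fraction treated as selected (default 0.01).
#' @param n_bins histogram bins (default 64).
#' @return a `score_distributions` object with `source = "empirical-tail"`.
#' @export
calibrate_empirical <- function(scores, tail_q = 0.01, n_bins = 64) {
  lower_tail <- c(ihs = TRUE, nsl = TRUE, fst = FALSE, xpehh = FALSE,
                  dihh = FALSE)
  dists <- list()
  for (st in CMS_STATS) {
    v <- scores[[st]]
    v <- v[!is.na(v)]
    if (length(v) < 50) stop("insufficient values for empirical calibration of ", st)
    thr <- quantile(v, if (lower_tail[[st]]) tail_q else 1 - tail_q,
                    type = 7, names = FALSE)
    vs <- if (lower_tail[[st]]) v[v <= thr] else v[v >= thr]
    rng <- range(v)
    if (diff(rng) == 0) rng <- rng + c(-0.5, 0.5)
    breaks <- seq(rng[1], rng[2], length.out = n_bins + 1L)
    dists[[st]] <- list(f_sel = fit_density(vs, breaks),
                        f_neu = fit_density(v, breaks))
  }
  structure(list(stats = dists,
                 meta = list(source = "empirical-tail", tail_q = tail_q,
                             n_bins = n_bins)),
            class = "score_distributions")
}

#' Per-SNP composite-of-multiple-signals score
#'
#' For each SNP and each defined component statistic `s_i`,
#' `LLR_i = ln(f_sel(s_i) / f_neu(s_i))`; the composite is
#' `cms = (5/k) * sum(LLR_i)` over the `k` defined components when
#' `k >= min_components`, otherwise undefined. The `5/k` scaling keeps
#' scores comparable across SNPs with missing components.
#'
#' @param site_scores a [compute_site_scores] table.
#' @param dists a calibrated `score_distributions` object.
#' @param min_components minimum defined components (default 3).
#' @return `data.table`: `chrom, pos, id, daf`, per-component `llr_*`, `k`,
#'   `cms`.
#' @export
cms_score <- function(site_scores, dists, min_components = 3) {
  stopifnot(inherits(dists, "score_distributions"))
  m <- nrow(site_scores)
  llr <- matrix(NA_real_, m, length(CMS_STATS),
                dimnames = list(NULL, CMS_STATS))
  for (st in CMS_STATS) {
    v <- site_scores[[st]]
    ok <- !is.na(v)
    if (!any(ok)) next
    d <- dists$stats[[st]]
    llr[ok, st] <- log(density_at(d$f_sel, v[ok]) /
                         density_at(d$f_neu, v[ok]))
  }
  k <- rowSums(!is.na(llr))
  cms <- ifelse(k >= min_components,
                (5 / k) * rowSums(llr, na.rm = TRUE), NA_real_)
  out <- data.table(chrom = site_scores$chrom, pos = site_scores$pos,
                    id = site_scores$id, daf = site_scores$daf)
  for (st in CMS_STATS) out[[paste0("llr_", st)]] <- llr[, st]
  out$k <- as.integer(k)
  out$cms <- cms
  out[]
}

#' Genome-wide CMS significance threshold
#'
#' The threshold is the empirical `(1 - q)` quantile (type-7 interpolation)
#' of the defined composite scores; SNPs with `cms >= threshold` are
#' flagged.
#'
#' @param cms_values numeric vector of composite scores (NA allowed).
#' @param q top quantile (default 0.001, the top 1 per mille).
#' @return list: `threshold`, logical `flags` (aligned with input, `FALSE`
#'   where cms is NA), `n_defined`.
#' @export
genome_threshold <- function(cms_values, q = 0.001) {
  v <- cms_values[!is.na(cms_values)]
  if (!length(v)) stop("no defined CMS values")
  if (length(v) < 1 / q) {
    warning(sprintf("only %d defined CMS values for q = %g; threshold is noisy",
                    length(v), q))
  }
  thr <- quantile(v, 1 - q, type = 7, names = FALSE)
  list(threshold = thr,
       flags = !is.na(cms_values) & cms_values >= thr,
       n_defined = length(v))
}

#' Write a calibration to JSON
#'
#' Stores bin edges and masses per statistic per class plus metadata, so a
#' calibration can be reused across scans.
#'
#' @param dists a `score_distributions` object.
#' @param path output path (.json).
#' @return invisibly, `path`.
#' @export
write_calibration <- function(dists, path) {
  stopifnot(inherits(dists, "score_distributions"))
  if (!requireNamespace("jsonlite", quietly = TRUE)) {
    stop("jsonlite is required to write calibration JSON")
  }
  payload <- list(
    meta = dists$meta,
    stats = lapply(dists$stats, function(st) lapply(st, function(d)
      list(breaks = d$breaks, mass = d$mass, n = d$n, eps = d$eps))))
  writeLines(jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA),
             path)
  invisible(path)
}

#' Read a calibration from JSON
#'
#' @param path path written by [write_calibration].
#' @return a `score_distributions` object.
#' @export
read_calibration <- function(path) {
  if (!requireNamespace("jsonlite", quietly = TRUE)) {
    stop("jsonlite is required to read calibration JSON")
  }
  payload <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  stats <- lapply(payload$stats, function(st) lapply(st, function(d) {
    breaks <- as.numeric(d$breaks)
    mass <- as.numeric(d$mass)
    list(breaks = breaks, mass = mass, density = mass / diff(breaks),
         n = as.numeric(d$n), eps = as.numeric(d$eps))
  }))
  structure(list(stats = stats, meta = payload$meta),
            class = "score_distributions")
}
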