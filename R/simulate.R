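## Synthetic studies: forward Wright-Fisher simulation of three populations
## with an optional hard sweep, a sample manifest with altitudes, blood
## phenotypes with a blunted altitude response, fixture annotations and an
## organ eQTL map -- all with recorded ground truth.

#' Simulation configuration
#'
#' Defaults describe the package's reference synthetic world: three
#' populations of `N = 500` diploids on a 2 Mb chromosome, a target
#' population (`TBP`-like) split 300 generations ago, two lowland reference
#' populations (`DUROC`, `YKX`) split from each other 150 generations ago,
#' and a hard sweep (`s = 0.05` per copy) acting for the last 100
#' generations on a haplotype-coherent standing variant in the central half
#' of the chromosome. Mutation and recombination rates are per bp per
#' generation; after N-rescaling the defaults give `theta = 4*N*mu =
#' 4e-4`/bp, deliberately below real pig diversity but dense enough that
#' top-quantile clumping rules are non-degenerate (see the methods
#' vignette).
#'
#' @param N diploid population size per population.
#' @param L chromosome length in bp.
#' @param mu per-site per-generation mutation rate.
#' @param rho per-bp per-generation recombination rate.
#' @param burn_in ancestral burn-in generations (default `2 N`).
#' @param split_target generations ago the target split from the reference
#'   lineage.
#' @param split_refs generations ago the two reference populations split.
#' @param s selection coefficient per derived-allele copy (0 = neutral).
#' @param sweep_pos target bp position of the sweep.
#' @param sweep_pop population carrying the sweep.
#' @param sweep_start_gen generations ago selection started
#'   (must be `<= split_refs` so all three populations exist).
#' @param sweep_freq_range derived-frequency window from which the standing
#'   sweep variant is picked.
#' @param sweep_min_freq final target-population frequency the swept allele
#'   must reach for the run to count as an established sweep; lower
#'   outcomes (loss or stalling) retry the sweep phase. Matches the
#'   frequency range of target-enriched alleles at reported selected loci.
#' @param n_sample named vector of sampled diploids per population.
#' @param chrom chromosome label for output.
#' @param max_retries resimulation attempts when the sweep allele is lost.
#' @param chunk generations between joint site-pruning passes.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(N = 500, L = 2e6, mu = 2e-7, rho = 2.5e-8,
                       burn_in = 2 * N, split_target = 300, split_refs = 150,
                       s = 0.05, sweep_pos = 1e6, sweep_pop = "TBP",
                       sweep_start_gen = 100,
                       sweep_freq_range = c(0.04, 0.10),
                       sweep_min_freq = 0.8,
                       n_sample = c(TBP = 60, DUROC = 25, YKX = 16),
                       chrom = "1", max_retries = 20, chunk = 50) {
  stopifnot(mu >= 0, rho >= 0, s >= 0, sweep_pos < L,
            split_refs <= split_target, sweep_start_gen <= split_refs)
  structure(as.list(environment()), class = "sim_config")
}

#' One Wright-Fisher evolution bout for a single population
#'
#' Thin wrapper over the compiled core: evolves a 2N x m haplotype matrix
#' `gens` generations with recombination, mutation (new sites appended) and
#' optional selection on one site. Uses R's RNG stream.
#'
#' @param haps 2N x m 0/1 integer matrix.
#' @param pos site positions (double bp on `[0, L)`), length m.
#' @param gens generations.
#' @param mu,rho,L rates and chromosome length.
#' @param s selection coefficient; `sweep_site` 1-based site index (or
#'   `NA`).
#' @param prune_every drop sites lost or fixed in this population every so
#'   many generations (0 = never; only valid while no other population
#'   shares the site list, and incompatible with `sweep_site`).
#' @return list `haps`, `pos`.
#' @export
wf_evolve <- function(haps, pos, gens, mu, rho, L, s = 0,
                      sweep_site = NA_integer_, prune_every = 0) {
  ss <- if (is.na(sweep_site)) -1L else as.integer(sweep_site) - 1L
  wf_evolve_cpp(haps, as.numeric(pos), as.integer(gens), mu, rho, L, s, ss,
                as.integer(prune_every))
}

# drop sites lost in all pops or fixed in all pops; keep_pos are positions
# that must survive regardless
prune_sites <- function(pops, keep_pos = numeric(0)) {
  pos <- pops[[1]]$pos
  if (!length(pos)) return(pops)
  tot <- Reduce(`+`, lapply(pops, function(p) colSums(p$haps)))
  n_all <- sum(vapply(pops, function(p) nrow(p$haps), integer(1)))
  keep <- (tot > 0L & tot < n_all) | pos %in% keep_pos
  lapply(pops, function(p)
    list(haps = p$haps[, keep, drop = FALSE], pos = p$pos[keep]))
}

evolve_pops <- function(pops, gens, cfg, s = 0, sweep_pop = NULL,
                        sweep_pos_val = NA_real_) {
  if (gens == 0) return(pops)
  if (length(pops) == 1L && is.null(sweep_pop)) {
    # single population, no sweep: the compiled core prunes lost/fixed
    # sites itself, so one call covers the whole bout
    p <- pops[[1]]
    pops[[1]] <- wf_evolve(p$haps, p$pos, gens, cfg$mu, cfg$rho, cfg$L,
                           s = 0, prune_every = 5L)
    return(prune_sites(pops))
  }
  # multi-population phase: shared site list, joint pruning in the core
  svec <- rep(0, length(pops))
  ss <- -1L
  if (!is.null(sweep_pop) && !is.na(sweep_pos_val)) {
    svec[match(sweep_pop, names(pops))] <- s
    ss <- match(sweep_pos_val, pops[[1]]$pos) - 1L
    if (is.na(ss)) ss <- -1L
  }
  res <- wf_multi_cpp(lapply(pops, `[[`, "haps"), pops[[1]]$pos,
                      as.integer(gens), cfg$mu, cfg$rho, cfg$L, svec, ss,
                      prune_every = 5L)
  out <- lapply(seq_along(pops), function(i)
    list(haps = res$haps[[i]], pos = res$pos))
  names(out) <- names(pops)
  out
}

# fraction of carrier pairs of the derived allele at site j that are
# identical over all sites within +/- window bp -- high for young variants
# residing on a single haplotype background
carrier_coherence <- function(haps, pos, j, window = 5e4) {
  carriers <- which(haps[, j] == 1L)
  if (length(carriers) < 2L) return(0)
  span <- which(abs(pos - pos[j]) <= window)
  sub <- haps[carriers, span, drop = FALSE]
  key <- do.call(paste0, as.data.frame(sub))
  cnt <- table(key)
  sum(choose(cnt, 2)) / choose(length(carriers), 2)
}

# give every population the same (union) site list, absent sites as 0 columns
align_sites <- function(pops) {
  if (length(pops) == 1L) return(pops)
  all_pos <- sort(unique(unlist(lapply(pops, `[[`, "pos"))))
  lapply(pops, function(p) {
    m <- matrix(0L, nrow(p$haps), length(all_pos))
    m[, match(p$pos, all_pos)] <- p$haps
    list(haps = m, pos = all_pos)
  })
}

#' Simulate three populations with an optional hard sweep
#'
#' Discrete-generation forward Wright-Fisher simulation: an ancestral
#' population is burnt in, the target lineage splits `split_target`
#' generations before present, the two reference populations split
#' `split_refs` generations before present, and from `sweep_start_gen`
#' generations before present the derived allele at the segregating site
#' nearest `sweep_pos` (with frequency inside `sweep_freq_range`) gains
#' multiplicative fitness `1 + s` per copy in `sweep_pop`. If the swept
#' allele is lost the sweep phase is retried from its starting state
#' (bounded by `max_retries`, recorded in the truth). Deterministic given
#' `seed`.
#'
#' @param config a [sim_config].
#' @param seed integer seed (mandatory).
#' @return list: `panels` (named list of [haplotype_panel]s, derived-coded,
#'   ancestral allele known for every site), `truth` (sweep position/id,
#'   per-population sweep-allele frequencies, retries).
#' @export
simulate_populations <- function(config, seed) {
  stopifnot(inherits(config, "sim_config"), !missing(seed))
  set.seed(seed)
  cfg <- config

  anc <- list(haps = matrix(0L, 2L * cfg$N, 0), pos = numeric(0))
  anc <- evolve_pops(list(ANC = anc), cfg$burn_in, cfg)$ANC

  pops <- list(TBP = anc, REFL = anc)
  pops <- evolve_pops(pops, cfg$split_target - cfg$split_refs, cfg)
  pops <- list(TBP = pops$TBP, DUROC = pops$REFL, YKX = pops$REFL)

  neutral_gens <- cfg$split_refs - cfg$sweep_start_gen
  do_sweep <- cfg$s > 0 && cfg$sweep_start_gen > 0
  pops <- evolve_pops(pops, if (do_sweep) neutral_gens else cfg$split_refs, cfg)

  sweep_actual <- NA_real_
  retries <- 0L
  lost <- FALSE
  if (do_sweep) {
    freqs <- colMeans(pops[[cfg$sweep_pop]]$haps)
    pos <- pops[[cfg$sweep_pop]]$pos
    # central half of the chromosome, so both EHH flanks have room
    central <- pos >= 0.25 * cfg$L & pos <= 0.75 * cfg$L
    cand <- which(freqs >= cfg$sweep_freq_range[1] &
                    freqs <= cfg$sweep_freq_range[2] & central)
    if (!length(cand)) {
      cand <- which(freqs >= cfg$sweep_freq_range[1] &
                      freqs <= cfg$sweep_freq_range[2])
    }
    if (!length(cand)) cand <- which(freqs > 0 & freqs < 1)
    if (!length(cand)) stop("no segregating site available for the sweep")
    # hard-sweep regime: among frequency-eligible standing variants, seed
    # the sweep on the most haplotype-coherent one (carriers sharing one
    # young haplotype), so selection amplifies a single long haplotype
    site <- cand[which.max(vapply(cand, function(j)
      carrier_coherence(pops[[cfg$sweep_pop]]$haps, pos, j, window = 1e5),
      numeric(1)))]
    sweep_actual <- pos[site]
    snapshot <- pops
    repeat {
      pops <- evolve_pops(snapshot, cfg$sweep_start_gen, cfg, s = cfg$s,
                          sweep_pop = cfg$sweep_pop,
                          sweep_pos_val = sweep_actual)
      j <- match(sweep_actual, pops[[cfg$sweep_pop]]$pos)
      f <- if (is.na(j)) 0 else mean(pops[[cfg$sweep_pop]]$haps[, j])
      if (f >= cfg$sweep_min_freq) break
      retries <- retries + 1L
      if (retries >= cfg$max_retries) { lost <- TRUE; break }
    }
  }

  # sample diploids and build panels
  panels <- list()
  samp_rows <- list()
  for (nm in names(cfg$n_sample)) {
    n <- cfg$n_sample[[nm]]
    ind <- sample.int(cfg$N, n)
    rows <- as.vector(rbind(2L * ind - 1L, 2L * ind))
    samp_rows[[nm]] <- pops[[nm]]$haps[rows, , drop = FALSE]
  }
  pos <- pops[[1]]$pos
  seg <- Reduce(`+`, lapply(samp_rows, colSums))
  tot <- sum(vapply(samp_rows, nrow, integer(1)))
  keep <- (seg > 0L & seg < tot) | pos %in% sweep_actual
  pos <- pos[keep]
  ord <- order(pos)
  pos <- pos[ord]
  ipos <- as.integer(floor(pos)) + 1L
  while (any(dup <- duplicated(ipos))) ipos[dup] <- ipos[dup] + 1L
  o <- order(ipos)
  ipos <- ipos[o]

  nts <- c("A", "C", "G", "T")
  refa <- sample(nts, length(ipos), replace = TRUE)
  alta <- vapply(refa, function(r) sample(setdiff(nts, r), 1), character(1))
  sites <- variant_sites(chrom = config$chrom, pos = ipos,
                         id = sprintf("snp%06d", seq_along(ipos)),
                         ref = refa, alt = alta, ancestral = "ref")
  for (nm in names(cfg$n_sample)) {
    h <- samp_rows[[nm]][, keep, drop = FALSE][, ord, drop = FALSE][, o, drop = FALSE]
    panels[[nm]] <- haplotype_panel(
      h, sites, sprintf("%s_%03d", nm, seq_len(cfg$n_sample[[nm]])), nm)
  }

  sweep_ipos <- if (!is.na(sweep_actual)) {
    ipos[which(pos[o] == sweep_actual)[1]]
  } else NA_integer_
  truth <- list(
    sweep_pos_target = cfg$sweep_pos, sweep_pos = sweep_ipos,
    sweep_id = if (!is.na(sweep_ipos)) sites$id[sites$pos == sweep_ipos] else NA_character_,
    sweep_pop = cfg$sweep_pop, s = cfg$s, lost = lost, retries = retries,
    sweep_freq = if (!is.na(sweep_ipos)) {
      vapply(panels, function(p)
        mean(p$haps[, which(p$sites$pos == sweep_ipos)]), numeric(1))
    } else NULL,
    seed = seed)
  list(panels = panels, truth = truth)
}

#' Simulate a sample manifest with the study's altitude design
#'
#' Target-population samples are assigned high altitudes (3000-4300 m);
#' reference samples span 1000-4000 m. Sex is balanced at random, age is
#' uniform on 1-6 years.
#'
#' @param panels named list of panels (sample ids and populations taken
#'   from them).
#' @param target target population label (default `"TBP"`).
#' @return manifest `data.table`: `sample, population, altitude, sex, age`.
#' @export
simulate_manifest <- function(panels, target = "TBP") {
  rows <- lapply(names(panels), function(nm) {
    n <- length(panels[[nm]]$samples)
    data.table(
      sample = panels[[nm]]$samples, population = nm,
      altitude = if (nm == target) runif(n, 3000, 4300) else runif(n, 1000, 4000),
      sex = sample(c("F", "M"), n, replace = TRUE),
      age = round(runif(n, 1, 6), 1))
  })
  rbindlist(rows)
}

#' Simulate blood phenotypes with a causal SNP and blunted altitude response
#'
#' Hemoglobin is generated as
#' `HGB = intercept + slope_pop * altitude + beta * dosage + load * latent +
#' noise`, with the altitude slope positive in the reference populations and
#' zero (blunted) in the target. RBC and HCT share the latent factor with
#' HGB, inducing the observed correlation structure; the remaining indices
#' are independent noise around typical values. When `ve` is given, `beta`
#' is derived so the causal SNP explains that fraction of target-population
#' phenotypic variance.
#'
#' @param panels named list of panels (used for the causal dosage).
#' @param manifest a [simulate_manifest] table.
#' @param causal_id id of the causal SNP (default: the site nearest the
#'   middle of the chromosome among segregating sites of the target panel).
#' @param target target population (blunted slope).
#' @param beta causal effect on HGB in g/L per derived copy (ignored when
#'   `ve` given).
#' @param ve target fraction of (target-population) HGB variance explained
#'   by the causal SNP, or `NULL` to use `beta`.
#' @param slope_ref altitude slope in the references (g/L per m).
#' @param slope_target altitude slope in the target (default 0, blunted).
#' @param intercept baseline HGB (g/L).
#' @param sigma residual SD of HGB (g/L).
#' @param latent_load loading of the shared latent factor on HGB.
#' @return list: `pheno` (`data.table` of sample, population, covariates and
#'   the nine indices), `truth` (causal id, beta, slopes, sigma, ve).
#' @export
simulate_phenotypes <- function(panels, manifest, causal_id = NULL,
                                target = "TBP", beta = -8, ve = NULL,
                                slope_ref = 0.02, slope_target = 0,
                                intercept = 120, sigma = 15,
                                latent_load = 10) {
  tp <- panels[[target]]
  if (is.null(causal_id)) {
    p <- colMeans(tp$haps)
    segg <- which(p > 0 & p < 1)
    if (!length(segg)) stop("monomorphic target panel: no causal SNP available")
    causal_id <- tp$sites$id[segg[which.min(abs(tp$sites$pos[segg] -
                                                  median(tp$sites$pos)))]]
  }
  dosage <- unlist(lapply(panels, function(p) {
    j <- match(causal_id, p$sites$id)
    if (is.na(j)) stop("causal SNP absent from a panel")
    colSums(matrix(p$haps[, j], nrow = 2))
  }))
  names(dosage) <- unlist(lapply(panels, `[[`, "samples"))
  tsel <- manifest$sample[manifest$population == target]
  if (!length(tsel)) tsel <- manifest$sample
  if (var(dosage[tsel]) == 0) {
    stop("causal SNP is monomorphic in the target samples")
  }
  d <- dosage[manifest$sample]
  n <- nrow(manifest)
  is_t <- manifest$population == target
  slope <- ifelse(is_t, slope_target, slope_ref)
  latent <- rnorm(n)
  base <- intercept + slope * manifest$altitude + latent_load * latent +
    rnorm(n, 0, sigma)
  if (!is.null(ve)) {
    stopifnot(ve > 0, ve < 1)
    sel <- if (any(is_t)) is_t else rep(TRUE, n)
    vb <- var(base[sel])
    beta <- -sqrt(ve / (1 - ve) * vb / var(d[sel]))
  }
  hgb <- base + beta * d

  pheno <- data.table(
    sample = manifest$sample, population = manifest$population,
    altitude = manifest$altitude,
    sex = ifelse(manifest$sex == "M", 1L, 0L), age = manifest$age,
    HGB = hgb,
    RBC = 6.5 + 0.4 * latent + 0.02 * beta * d + rnorm(n, 0, 0.6),
    HCT = 0.40 + 0.04 * latent + 0.002 * beta * d + rnorm(n, 0, 0.04),
    RDW = rnorm(n, 15, 1.5), WBC = rnorm(n, 12, 2.5),
    PLT = rnorm(n, 300, 60), MCV = rnorm(n, 55, 4),
    MCH = rnorm(n, 17, 1.5), MCHC = rnorm(n, 320, 15))
  list(pheno = pheno,
       truth = list(causal_id = causal_id, beta = beta,
                    slope_ref = slope_ref, slope_target = slope_target,
                    sigma = sigma, latent_load = latent_load, ve = ve))
}

#' Fixture gene annotation and organ eQTL map
#'
#' Tiles non-overlapping genes over `[0, L)`: each 120 kb period holds a
#' 100 kb gene body (UTR5, alternating CDS/intron blocks summing to about
#' 9 percent CDS, UTR3) and a 20 kb intergenic gap containing a 2 kb
#' regulatory interval. The tiling phase is chosen so one gene spans
#' `sweep_pos`. Organs are assigned to genes at random, with `blood`
#' strongly enriched within `blood_window` of `causal_pos`.
#'
#' @param L chromosome length bp.
#' @param sweep_pos bp position that must fall inside a gene body.
#' @param causal_pos bp position near which blood-organ intervals are
#'   enriched (default `sweep_pos`).
#' @param chrom chromosome label.
#' @param organs organ labels.
#' @param blood_window bp window of blood-organ enrichment.
#' @param p_blood_near,p_blood_far blood-assignment probabilities inside /
#'   outside the window.
#' @return list: `annotation` (BED6+ table), `eqtl` (BED4 table),
#'   `sweep_gene` (name of the gene spanning `sweep_pos`).
#' @export
make_fixture_annotations <- function(L, sweep_pos, causal_pos = sweep_pos,
                                     chrom = "1",
                                     organs = c("blood", "heart", "brain",
                                                "muscle", "digestion", "liver"),
                                     blood_window = 2e5,
                                     p_blood_near = 0.9, p_blood_far = 0.2) {
  period <- 480000; body <- 400000
  phase <- (sweep_pos - body / 2) %% period
  starts <- seq(phase - period, L, by = period)
  starts <- starts[starts + body > 0 & starts < L]
  rows <- list()
  sweep_gene <- NA_character_
  for (i in seq_along(starts)) {
    g0 <- max(0, starts[i]); g1 <- min(L, starts[i] + body)
    gene <- sprintf("GENE%03d", i)
    if (sweep_pos >= g0 && sweep_pos < g1) sweep_gene <- gene
    # body layout (relative): UTR5 | 9 x (CDS + intron) | UTR3, ~6% CDS
    feats <- list(c(0, 2000, "UTR5"))
    at <- 2000
    cds_block <- 2000; intron_block <- floor((body - 4000 - 9 * cds_block) / 9)
    for (b in 1:9) {
      feats <- c(feats, list(c(at, at + cds_block, "CDS")))
      at <- at + cds_block
      feats <- c(feats, list(c(at, at + intron_block, "intron")))
      at <- at + intron_block
    }
    feats <- c(feats, list(c(at, body, "UTR3")))
    for (f in feats) {
      s <- starts[i] + as.numeric(f[1]); e <- starts[i] + as.numeric(f[2])
      if (e <= 0 || s >= L) next
      rows[[length(rows) + 1L]] <- data.table(
        chrom = chrom, start = max(0, s), end = min(L, e), gene = gene,
        class = f[3], strand = "+")
    }
    reg0 <- starts[i] + body + 9000
    if (reg0 >= 0 && reg0 + 2000 <= L) {
      rows[[length(rows) + 1L]] <- data.table(
        chrom = chrom, start = reg0, end = reg0 + 2000,
        gene = NA_character_, class = "regulatory", strand = ".")
    }
  }
  ann <- rbindlist(rows)
  ann[, `:=`(start = as.integer(start), end = as.integer(end))]

  bodies <- ann[class != "intergenic" & !is.na(gene),
                .(start = min(start), end = max(end)), by = .(chrom, gene)]
  eq <- list()
  for (r in seq_len(nrow(bodies))) {
    mid <- (bodies$start[r] + bodies$end[r]) / 2
    near <- abs(mid - causal_pos) <= blood_window
    p_blood <- if (near) p_blood_near else p_blood_far
    assigned <- c(if (runif(1) < p_blood) "blood",
                  sample(setdiff(organs, "blood"),
                         sample(0:2, 1)))
    for (org in assigned) {
      eq[[length(eq) + 1L]] <- data.table(
        chrom = bodies$chrom[r], start = bodies$start[r],
        end = bodies$end[r], organ = org)
    }
  }
  eqtl <- rbindlist(eq)
  list(annotation = ann[], eqtl = eqtl[], sweep_gene = sweep_gene)
}

#' Simulate a complete study with ground truth
#'
#' Bundles [simulate_populations], [simulate_manifest],
#' [simulate_phenotypes] and [make_fixture_annotations] into one
#' reproducible object.
#'
#' @param config a [sim_config].
#' @param seed integer seed (mandatory; drives every random choice).
#' @param pheno_args extra arguments passed to [simulate_phenotypes].
#' @return list of class `simulated_study`: `panels`, `manifest`, `pheno`,
#'   `annotation`, `eqtl`, `truth` (sweep, causal SNP, effect sizes,
#'   slopes, sweep gene).
#' @export
simulate_study <- function(config = sim_config(), seed,
                           pheno_args = list()) {
  sim <- simulate_populations(config, seed)
  manifest <- simulate_manifest(sim$panels, target = config$sweep_pop)
  causal <- if (!is.null(pheno_args$causal_id)) {
    pheno_args$causal_id
  } else {
    # causal phenotype SNP: the swept site, unless it fixed in the sampled
    # target panel, then the nearest segregating site
    tp <- sim$panels[[config$sweep_pop]]
    p <- colMeans(tp$haps)
    j <- match(sim$truth$sweep_id, tp$sites$id)
    if (!is.na(j) && p[j] > 0 && p[j] < 1) {
      sim$truth$sweep_id
    } else {
      segg <- which(p > 0 & p < 1)
      anchor <- if (!is.na(sim$truth$sweep_pos)) sim$truth$sweep_pos else
        config$sweep_pos
      tp$sites$id[segg[which.min(abs(tp$sites$pos[segg] - anchor))]]
    }
  }
  ph <- do.call(simulate_phenotypes,
                c(list(panels = sim$panels, manifest = manifest,
                       causal_id = causal, target = config$sweep_pop),
                  pheno_args[setdiff(names(pheno_args), "causal_id")]))
  causal_pos <- sim$panels[[1]]$sites$pos[
    match(ph$truth$causal_id, sim$panels[[1]]$sites$id)]
  fx <- make_fixture_annotations(config$L,
                                 sweep_pos = if (!is.na(sim$truth$sweep_pos))
                                   sim$truth$sweep_pos else config$sweep_pos,
                                 causal_pos = causal_pos,
                                 chrom = config$chrom)
  structure(list(
    panels = sim$panels, manifest = manifest, pheno = ph$pheno,
    annotation = fx$annotation, eqtl = fx$eqtl,
    truth = c(sim$truth, ph$truth, list(sweep_gene = fx$sweep_gene,
                                        causal_pos = causal_pos))),
    class = "simulated_study")
}

#' Write a simulated study to a directory
#'
#' Emits `panel_<POP>.vcf` per population, a combined `genotypes.vcf` with
#' all samples, `manifest.tsv`, `pheno.tsv`, `genes.bed`, `organs.bed` and
#' `truth.json` (if jsonlite is available).
#'
#' @param study a [simulate_study] object.
#' @param dir output directory (created if needed).
#' @return invisibly, `dir`.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in names(study$panels)) {
    write_vcf(study$panels[[nm]], file.path(dir, paste0("panel_", nm, ".vcf")))
  }
  # combined VCF across populations (sample -> population via the manifest)
  combined <- haplotype_panel(
    do.call(rbind, lapply(study$panels, `[[`, "haps")),
    study$panels[[1]]$sites,
    unlist(lapply(study$panels, `[[`, "samples")), "ALL")
  write_vcf(combined, file.path(dir, "genotypes.vcf"))
  write_manifest(study$manifest, file.path(dir, "manifest.tsv"))
  fwrite(study$pheno, file.path(dir, "pheno.tsv"), sep = "\t")
  write_annotation(study$annotation, file.path(dir, "genes.bed"))
  fwrite(study$eqtl, file.path(dir, "organs.bed"), sep = "\t",
         col.names = FALSE)
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    writeLines(jsonlite::toJSON(study$truth, auto_unbox = TRUE, digits = NA,
                                null = "null"),
               file.path(dir, "truth.json"))
  }
  invisible(dir)
}
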