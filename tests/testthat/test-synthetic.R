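# Wright-Fisher simulator properties, phenotype model, fixture annotations,
# determinism.

test_that("neutral single-generation resampling preserves expected frequency", {
  # s = 0, mu = 0: frequency changes only by binomial resampling
  set.seed(91)
  n <- 40  # haplotypes
  haps <- matrix(rbinom(n * 5, 1, 0.35), n, 5)
  p0 <- colMeans(haps)
  drift <- replicate(500, {
    out <- wf_evolve(haps, seq(0.1, 0.9, length.out = 5) * 1e5, gens = 1,
                     mu = 0, rho = 1e-8, L = 1e5, s = 0)
    mean(colMeans(out$haps) - p0)
  })
  expect_lt(abs(mean(drift)), 0.01)
  expect_gt(sd(drift), 0)         # it does drift
})

test_that("a strong sweep follows logistic growth to high frequency", {
  # s = 0.1, N = 200, 300 generations from ~5%: frequency > 0.8 in most runs
  set.seed(92)
  n <- 400
  freqs <- replicate(6, {
    haps <- matrix(0L, n, 11)
    haps[seq_len(0.05 * n), 6] <- 1L
    haps[, -6] <- rbinom(n * 10, 1, 0.3)
    out <- wf_evolve(haps, seq(1e4, 1.1e5, by = 1e4), gens = 300, mu = 0,
                     rho = 1e-8, L = 1.2e5, s = 0.1, sweep_site = 6)
    mean(out$haps[, 6])
  })
  retained <- freqs[freqs > 0]
  expect_gte(length(retained), 3)
  expect_gte(mean(retained > 0.8), 0.8)
})

test_that("identical seeds give bit-identical simulator output", {
  cfg <- scaled_config(s = 0.125, sweep_start_gen = 40, L = 5e5,
                       n_sample = c(TBP = 20, DUROC = 10, YKX = 10))
  a <- simulate_populations(cfg, seed = 7)
  b <- simulate_populations(cfg, seed = 7)
  expect_identical(a$panels$TBP$haps, b$panels$TBP$haps)
  expect_identical(a$panels$DUROC$haps, b$panels$DUROC$haps)
  expect_identical(a$truth$sweep_pos, b$truth$sweep_pos)
  c <- simulate_populations(cfg, seed = 8)
  expect_false(identical(a$panels$TBP$haps, c$panels$TBP$haps))
})

test_that("neutral FST grows with split time", {
  base <- function(split) {
    sim_config(N = 50, L = 3e5, mu = 2e-7, rho = 2.5e-8, burn_in = 150,
               split_target = split, split_refs = max(2, split %/% 2),
               s = 0, sweep_pos = 1.5e5, sweep_start_gen = 0,
               n_sample = c(TBP = 15, DUROC = 15, YKX = 5))
  }
  mean_fst <- function(split, seeds) {
    vapply(seeds, function(sd) {
      s <- simulate_populations(base(split), seed = sd)
      pt <- colMeans(s$panels$TBP$haps)
      pr <- colMeans(s$panels$DUROC$haps)
      keep <- (pt + pr) > 0 & (pt + pr) < 2
      mean(vapply(which(keep), function(j)
        fst_pair(pt[j], 30, pr[j], 30), numeric(1)), na.rm = TRUE)
    }, numeric(1))
  }
  f <- lapply(c(10, 40, 120), mean_fst, seeds = 1:20)
  expect_lt(mean(f[[1]]), mean(f[[2]]))
  expect_lt(mean(f[[2]]), mean(f[[3]]))
})

test_that("simulated panels carry known ancestral alleles and clean sites", {
  s <- get_small_study()
  pan <- s$panels$TBP
  expect_true(all(pan$sites$ancestral == "ref"))
  expect_false(anyNA(pan$haps))
  expect_true(all(diff(pan$sites$pos) > 0))
  # panels share one site list and cross-reference the manifest
  expect_identical(pan$sites$pos, s$panels$DUROC$sites$pos)
  expect_setequal(s$manifest$sample,
                  unlist(lapply(s$panels, `[[`, "samples")))
  expect_true(all(s$manifest$altitude[s$manifest$population == "TBP"] >= 3000))
})

test_that("phenotype model plants effects that are recoverable", {
  set.seed(93)
  # noiseless model is exactly linear in dosage and altitude
  h <- matrix(rbinom(200 * 5, 1, 0.5), 200, 5)
  pan <- make_panel(h, pop = "YKX")
  panels <- list(YKX = pan)
  manifest <- simulate_manifest(panels, target = "TBP")
  ph0 <- simulate_phenotypes(panels, manifest, causal_id = pan$sites$id[3],
                             target = "TBP", beta = -8, sigma = 0,
                             latent_load = 0)
  d <- colSums(matrix(h[, 3], nrow = 2))
  expect_equal(ph0$pheno$HGB,
               120 + 0.02 * manifest$altitude - 8 * d, tolerance = 1e-9)

  # planted beta recovered within 2 SE in >= 95% of 100 phenotype draws;
  # n = 1000 per draw keeps the nominal +/- 2 SE coverage (95.4%) above
  # the 95% bar, which a small-n t distribution would undercut
  hb <- cbind(rbinom(2000, 1, 0.4), rbinom(2000, 1, 0.5))
  bpan <- make_panel(hb, pop = "TBP")
  bman <- simulate_manifest(list(TBP = bpan), target = "TBP")
  gb <- colSums(matrix(hb[, 1], nrow = 2))
  hits <- 0
  for (i in 1:100) {
    set.seed(9300 + i)
    ph <- simulate_phenotypes(list(TBP = bpan), bman,
                              causal_id = bpan$sites$id[1],
                              target = "TBP", beta = -8)
    fit <- fit_additive(ph$pheno$HGB, gb,
                        data.frame(age = ph$pheno$age, sex = ph$pheno$sex,
                                   altitude = ph$pheno$altitude))
    hits <- hits + (abs(fit$beta - (-8)) <= 2 * fit$se)
  }
  expect_gte(hits, 95)

  # planted VE recovered at n = 2000
  set.seed(94)
  n <- 2000
  h2 <- matrix(rbinom(2 * n, 1, 0.3), 2 * n, 1)
  h2 <- cbind(h2, rbinom(2 * n, 1, 0.5))
  pan2 <- make_panel(h2, pop = "TBP")
  panels2 <- list(TBP = pan2)
  man2 <- simulate_manifest(panels2, target = "TBP")
  ph2 <- simulate_phenotypes(panels2, man2, causal_id = pan2$sites$id[1],
                             target = "TBP", ve = 0.05)
  g2 <- colSums(matrix(h2[, 1], nrow = 2))
  fit2 <- fit_additive(ph2$pheno$HGB, g2)
  expect_lt(abs(variance_explained(fit2$beta, g2, ph2$pheno$HGB) - 0.05),
            0.01)
})

test_that("fixture annotations tile cleanly around the sweep", {
  set.seed(95)
  fx <- make_fixture_annotations(L = 2e6, sweep_pos = 1.1e6)
  validate_ann <- fx$annotation
  # sweep position inside exactly one gene body
  bodies <- validate_ann[!is.na(gene),
                         .(start = min(start), end = max(end)),
                         by = gene]
  inside <- bodies[1.1e6 >= start & 1.1e6 < end]
  expect_equal(nrow(inside), 1)
  expect_equal(inside$gene, fx$sweep_gene)
  # gene bodies never overlap
  data.table::setkey(bodies, start)
  expect_true(all(bodies$start[-1] >= bodies$end[-nrow(bodies)]))
  # BED round trip
  f <- withr::local_tempfile(fileext = ".bed")
  write_annotation(fx$annotation, f)
  back <- read_annotation(f)
  expect_equal(back$start, fx$annotation$start)
  expect_equal(back$gene, fx$annotation$gene)
  expect_equal(back$class, fx$annotation$class)
  # eQTL map dialect round trip
  f2 <- withr::local_tempfile(fileext = ".bed")
  data.table::fwrite(fx$eqtl, f2, sep = "\t", col.names = FALSE)
  eq <- read_eqtl_map(f2)
  expect_equal(eq$organ, fx$eqtl$organ)
})

test_that("a full study bundle is deterministic and internally consistent", {
  cfg <- scaled_config(s = 0.125, sweep_start_gen = 60, L = 5e5,
                       n_sample = c(TBP = 20, DUROC = 10, YKX = 10))
  a <- simulate_study(cfg, seed = 5)
  b <- simulate_study(cfg, seed = 5)
  expect_identical(a$panels$TBP$haps, b$panels$TBP$haps)
  expect_equal(a$pheno, b$pheno)
  expect_equal(a$manifest, b$manifest)
  expect_equal(a$annotation, b$annotation)
  expect_equal(a$truth$causal_id, b$truth$causal_id)
  # study writes to plain-text files and reads back
  dir <- withr::local_tempdir()
  write_study(a, dir)
  pan <- read_vcf(file.path(dir, "panel_TBP.vcf"), require_phased = TRUE,
                  population = "TBP")
  expect_identical(pan$haps, a$panels$TBP$haps)
  man <- read_manifest(file.path(dir, "manifest.tsv"))
  expect_equal(man$sample, a$manifest$sample)
})
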