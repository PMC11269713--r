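# LD r2, greedy clumping, candidate-region filtering, peak genes,
# interval-class annotation and enriched-allele calls.

test_that("ld_r2 matches haplotype-count arithmetic", {
  # perfectly co-inherited pair
  h <- cbind(rep(c(0L, 1L), 6), rep(c(0L, 1L), 6))
  expect_equal(ld_r2(make_panel(h), 1, 2), 1)
  # monomorphic site undefined
  hm <- cbind(rep(1L, 8), rbinom(8, 1, 0.5))
  expect_true(is.na(ld_r2(make_panel(hm), 1, 2)))
  # 8-haplotype fixture against the 2x2 count oracle, many draws
  set.seed(51)
  for (i in 1:50) {
    a <- rbinom(8, 1, 0.5); b <- rbinom(8, 1, 0.5)
    if (var(a) == 0 || var(b) == 0) next
    expect_equal(ld_r2(make_panel(cbind(a, b)), 1, 2), oracle_r2(a, b),
                 tolerance = 1e-12)
  }
  # independently shuffled columns at 500 haplotypes are near zero
  a <- rbinom(500, 1, 0.5); b <- sample(a)
  expect_lt(ld_r2(make_panel(cbind(a, b)), 1, 2), 0.05)
  # r2 is invariant to derived/alt coding flips
  sites_flip <- variant_sites("1", c(1000, 2000),
                              ancestral = c("alt", "ref"))
  p1 <- haplotype_panel(cbind(a, b), sites_flip, paste0("s", 1:250),
                        coding = "alt")
  p2 <- make_panel(cbind(a, b))
  expect_equal(ld_r2(p1, 1, 2), ld_r2(p2, 1, 2), tolerance = 1e-12)
})

test_that("clump reproduces a constructed two-block fixture", {
  # 12 SNPs: block A (1-5) in tight LD, block B (7-11) in tight LD,
  # SNPs 6 and 12 unlinked
  set.seed(52)
  n <- 200
  base_a <- rbinom(n, 1, 0.5)
  base_b <- rbinom(n, 1, 0.5)
  flip <- function(x, rate) ifelse(runif(n) < rate, 1L - x, x)
  haps <- cbind(
    base_a, flip(base_a, 0.02), flip(base_a, 0.02), flip(base_a, 0.05),
    flip(base_a, 0.05), rbinom(n, 1, 0.5),
    base_b, flip(base_b, 0.02), flip(base_b, 0.02), flip(base_b, 0.05),
    flip(base_b, 0.05), rbinom(n, 1, 0.5))
  pos <- c(1:6 * 10000, 1e6 + 1:6 * 10000)
  pan <- make_panel(haps, pos = pos)
  cms <- c(10, 6, 6, 6, 6, 1, 9, 6, 6, 6, 6, 1)
  cmr <- data.table::data.table(chrom = "1", pos = pos,
                                id = paste0("v", 1:12), daf = 0.5,
                                k = 5L, cms = cms)
  regions <- clump(cmr, pan, index_q = 2 / 12, sp2_q = 6 / 12,
                   r2_min = 0.2, radius_kb = 500)
  expect_equal(nrow(regions), 2)
  expect_equal(regions$index_id, c("v1", "v7"))
  expect_equal(regions$n_members, c(4L, 4L))
  expect_false(any(grepl("v6|v12", regions$member_ids)))

  # no SNP at or above an explicit index threshold -> empty result
  expect_equal(nrow(clump(cmr, pan, thr_index = 99, thr_sp2 = 99)), 0)
  # one isolated significant SNP with no LD partners
  iso <- data.table::copy(cmr)[, cms := c(10, rep(0, 11))]
  r <- clump(iso, pan, index_q = 1 / 12, sp2_q = 1 / 12)
  expect_equal(nrow(r), 1)
  expect_equal(r$n_members, 0L)
})

test_that("greedy clumping equals an independent re-implementation", {
  set.seed(53)
  for (rep in 1:40) {
    m <- sample(10:50, 1)
    n <- 100
    haps <- matrix(rbinom(n * m, 1, runif(1, 0.3, 0.7)), n, m)
    # induce some LD by copying neighbours
    for (j in 2:m) {
      if (runif(1) < 0.5) {
        haps[, j] <- ifelse(runif(n) < 0.05, 1L - haps[, j - 1], haps[, j - 1])
      }
    }
    poly <- apply(haps, 2, var) > 0
    haps <- haps[, poly, drop = FALSE]
    m <- ncol(haps)
    if (m < 5) next
    pos <- sort(sample(1:2e6, m))
    pan <- make_panel(haps, pos = pos)
    cms <- round(rnorm(m, 5, 3), 2)
    cmr <- data.table::data.table(chrom = "1", pos = pos,
                                  id = paste0("v", 1:m), daf = 0.5, k = 5L,
                                  cms = cms)
    index_q <- 0.2; sp2_q <- 0.5
    regions <- clump(cmr, pan, index_q = index_q, sp2_q = sp2_q,
                     r2_min = 0.2, radius_kb = 300)
    r2mat <- outer(1:m, 1:m, Vectorize(function(i, j) ld_r2(pan, i, j)))
    want <- oracle_clump(pos, cms,
                         r2mat,
                         quantile(cms, 1 - index_q, type = 7),
                         quantile(cms, 1 - sp2_q, type = 7),
                         0.2, 3e5)
    expect_equal(nrow(regions), length(want))
    for (k in seq_along(want)) {
      expect_equal(regions$index_pos[k], pos[want[[k]]$index])
      expect_equal(regions$n_members[k], length(want[[k]]$members))
    }
    # post-hoc audit: members within radius and in LD with their index
    for (k in seq_len(nrow(regions))) {
      mem <- strsplit(regions$member_ids[k], ",")[[1]]
      mem <- mem[nzchar(mem)]
      mi <- match(mem, cmr$id)
      si <- match(regions$index_id[k], cmr$id)
      if (length(mi)) {
        expect_true(all(abs(pos[mi] - pos[si]) <= 3e5))
        expect_true(all(r2mat[si, mi] >= 0.2))
      }
    }
    # membership disjoint across regions
    all_mem <- unlist(strsplit(regions$member_ids, ","))
    all_mem <- all_mem[nzchar(all_mem)]
    expect_false(any(duplicated(c(regions$index_id, all_mem))))
  }
})

test_that("call_candidate_regions keeps regions with more than min_sp2 members", {
  reg <- data.table::data.table(region_id = 1:4, chrom = "1",
                                index_id = paste0("v", 1:4),
                                index_pos = 1:4 * 1000,
                                index_cms = 9:6, start = 1, end = 2,
                                n_members = c(5L, 6L, 0L, 12L),
                                member_ids = "")
  kept <- call_candidate_regions(reg, min_sp2 = 5)
  expect_equal(kept$region_id, c(2L, 4L))      # 5 dropped, 6 kept
  expect_equal(call_candidate_regions(reg, min_sp2 = 5)$n_members,
               reg$n_members[reg$n_members > 5])
})

test_that("peak_gene assigns genes by peak SNP containment", {
  ann <- data.table::data.table(
    chrom = "1",
    start = c(1000L, 5000L, 8000L, 20000L),
    end = c(4000L, 9000L, 12000L, 25000L),
    gene = c("G1", "G2", "G3", "G4"),
    class = "CDS", strand = "+")
  reg <- data.table::data.table(
    region_id = 1:3, chrom = "1",
    index_id = c("a", "b", "c"),
    index_pos = c(2001L, 8501L, 15000L),   # G1; G2+G3 overlap; none
    index_cms = c(10, 9, 8), start = 1L, end = 30000L,
    n_members = 6L, member_ids = "")
  res <- peak_gene(reg, ann)
  expect_equal(res[region_id == 1, gene], "G1")
  expect_setequal(res[region_id == 2, gene], c("G2", "G3"))
  expect_true(all(res[region_id == 2, ambiguous]))
  expect_true(is.na(res[region_id == 3, gene]))      # retained, not dropped
  # duplicate genes deduplicated keeping max cms
  reg2 <- rbind(reg, data.table::data.table(
    region_id = 4L, chrom = "1", index_id = "d", index_pos = 2500L,
    index_cms = 3, start = 1L, end = 30000L, n_members = 6L,
    member_ids = ""))
  res2 <- peak_gene(reg2, ann)
  expect_equal(nrow(res2[gene == "G1"]), 1)
  expect_equal(res2[gene == "G1", peak_cms], 10)
})

test_that("annotate_snps applies class priority and sums to totals", {
  ann <- data.table::data.table(
    chrom = "1",
    start = c(0L, 0L, 100L, 200L),
    end = c(50L, 80L, 150L, 300L),
    gene = c("G1", "G1", "G1", NA),
    class = c("CDS", "regulatory", "intron", "regulatory"),
    strand = "+")
  snps <- data.table::data.table(chrom = "1",
                                 pos = c(10L, 60L, 120L, 250L, 999L))
  res <- annotate_snps(snps, ann)
  expect_equal(res$per_snp$class,
               c("CDS", "regulatory", "intron", "regulatory", "intergenic"))
  expect_equal(sum(res$summary$count), nrow(snps))
  expect_equal(res$coding_percent + res$noncoding_percent, 100)
  # empty annotation -> all intergenic
  empty <- annotate_snps(snps, ann[0])
  expect_true(all(empty$per_snp$class == "intergenic"))
})

test_that("enriched_allele follows the margin rule", {
  f <- function(p) list(p = p, n = 100)
  # Table-1-style: target 0.83 vs refs 0.35 / 0.43 -> panel allele enriched
  r <- enriched_allele(f(0.83), list(f(0.35), f(0.43)))
  expect_equal(r$allele, 1L)
  expect_false(r$ambiguous)
  # low but enriched: 0.18 vs 0.01, 0.01
  r2 <- enriched_allele(f(0.18), list(f(0.01), f(0.01)))
  expect_equal(r2$allele, 1L)
  expect_false(r2$ambiguous)
  # tie: ambiguous with margin 0
  r3 <- enriched_allele(f(0.5), list(f(0.5), f(0.5)))
  expect_true(r3$ambiguous)
  expect_equal(r3$margin, 0)
  # the other allele can be the enriched one
  r4 <- enriched_allele(f(0.1), list(f(0.6), f(0.7)))
  expect_equal(r4$allele, 0L)
})

test_that("run_scan attaches target-enriched allele calls to gene rows", {
  st <- get_small_study()
  scan <- suppressWarnings(
    run_scan(st, index_q = 0.02, sp2_q = 0.2, min_sp2 = 1))
  if (nrow(scan$genes)) {
    expect_true(all(c("tbpe_allele", "tbpe_freq_target", "tbpe_margin",
                      "tbpe_ambiguous") %in% names(scan$genes)))
    expect_true(all(scan$genes$tbpe_allele %in% c(0L, 1L)))
    expect_true(all(scan$genes$tbpe_freq_target >= 0 &
                      scan$genes$tbpe_freq_target <= 1))
    # unambiguous calls really are enriched over every reference
    expect_true(all(scan$genes$tbpe_margin[!scan$genes$tbpe_ambiguous] > 0))
  } else {
    succeed("no candidate regions in this fixture")
  }
})
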