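# Allele frequencies, FST, EHH/iHH, iHS/XPEHH/delta-iHH/nSL and
# standardization bins against brute-force oracles.

test_that("allele_freq counts derived alleles", {
  pan <- make_panel(matrix(1L, 10, 3))
  expect_equal(allele_freq(pan, 1), list(p = 1.0, n = 10))
  pan2 <- make_panel(matrix(c(1, 0, 1, 0), 4, 1))
  expect_equal(allele_freq(pan2, 1)$p, 0.5)
  # 60 diploids at frequency 0.83 (Table-1-style check)
  col <- c(rep(1L, round(0.83 * 120)), rep(0L, 120 - round(0.83 * 120)))
  pan3 <- make_panel(matrix(col, 120, 1))
  expect_equal(allele_freq(pan3, 1)$p, 0.83, tolerance = 0.005)
})

test_that("fst_pair matches the direct-formula oracles", {
  # fixed difference -> 1 in the large-sample limit
  expect_equal(fst_pair(1, 1e6, 0, 1e6), 1, tolerance = 1e-5)
  # same frequency: 0 up to the sampling correction, exactly 0 as n -> Inf
  expect_equal(fst_pair(0.5, 1e9, 0.5, 1e9), 0, tolerance = 1e-6)
  expect_lte(fst_pair(0.5, 20, 0.5, 20), 0)
  # spec-style numeric case against the independent arithmetic oracle
  expect_equal(fst_pair(0.97, 120, 0.27, 50),
               oracle_hudson(0.97, 120, 0.27, 50), tolerance = 1e-12)
  set.seed(31)
  for (i in 1:20) {
    p1 <- runif(1); p2 <- runif(1); n1 <- sample(10:200, 1)
    n2 <- sample(10:200, 1)
    expect_equal(fst_pair(p1, n1, p2, n2), oracle_hudson(p1, n1, p2, n2),
                 tolerance = 1e-12)
  }
  # both fixed for the same allele is undefined
  expect_true(is.na(fst_pair(1, 50, 1, 50)))
  # Weir-Cockerham behaves sensibly at the extremes
  expect_equal(fst_pair(1, 1e6, 0, 1e6, estimator = "weir_cockerham"), 1,
               tolerance = 1e-4)
  expect_lt(abs(fst_pair(0.5, 1e9, 0.5, 1e9, estimator = "weir_cockerham")),
            1e-6)
  expect_equal(fst_pair(-0.1 + 0.2, 30, 0.9, 40, clip = TRUE) >= 0, TRUE)
})

test_that("ehh equals the pair-enumeration oracle and is non-increasing", {
  # all carriers identical -> EHH stays 1
  pan <- make_panel(rbind(matrix(1L, 4, 7), matrix(0L, 4, 7)))
  cv <- ehh(pan, 4, 1, "right")
  expect_true(all(cv$ehh == 1))
  # two carriers that differ at the first flanking site -> EHH 0 beyond it
  h2 <- rbind(c(0L, 1L, 0L), c(1L, 1L, 1L), c(0L, 0L, 0L), c(1L, 0L, 1L))
  cv2 <- ehh(make_panel(h2), 2, 1, "right")
  expect_equal(cv2$ehh, c(1, 0))
  # four carriers become pairwise distinct after two flanking sites
  h4 <- cbind(c(0L, 0L, 1L, 1L), rep(1L, 4), c(0L, 1L, 0L, 1L),
              c(0L, 0L, 1L, 1L))
  cv4 <- ehh(make_panel(h4), 2, 1, "right")
  expect_equal(cv4$ehh, c(1, 2 / 6, 0))
  # randomized suite against the oracle, <= 12 haplotypes x <= 10 sites
  set.seed(32)
  for (i in 1:100) {
    n <- sample(c(4, 6, 8, 12), 1); m <- sample(3:10, 1)
    hh <- matrix(rbinom(n * m, 1, runif(1, 0.2, 0.8)), n, m)
    core <- sample(m, 1); al <- sample(0:1, 1)
    dir <- sample(c("left", "right"), 1)
    if (sum(hh[, core] == al) < 2) next
    pan <- make_panel(hh)
    got <- ehh(pan, core, al, dir)
    want <- oracle_ehh(hh, core, al, if (dir == "right") 1 else -1)
    expect_equal(got$ehh, want[seq_along(got$ehh)], tolerance = 1e-12)
    if (length(got$ehh) < length(want)) {
      expect_equal(got$ehh[length(got$ehh)], 0)   # only stops early at zero
    }
    expect_true(all(diff(got$ehh) <= 1e-12))
  }
})

test_that("ihh integrates EHH with interpolated cutoff crossing", {
  # rectangle: EHH = 1 over [0, L] both sides, cutoff 0 -> 2L
  L <- 5e4
  curve <- structure(list(distances = c(0, L), ehh = c(1, 1)),
                     class = "ehh_curve")
  expect_equal(ihh(curve, curve, cutoff = 0)$ihh, 2 * L)
  # triangle: EHH drops 1 -> 0 at the first site both sides
  tri <- structure(list(distances = c(0, 1000), ehh = c(1, 0)),
                   class = "ehh_curve")
  expect_equal(ihh(tri, tri, cutoff = 0)$ihh, 1000)
  # piecewise-linear fixture against a hand-integrated value, cutoff 0.05:
  # segments (0,1)->(100,0.8)->(300,0.5)->(600,0.2)->(700,0.0)
  pl <- structure(list(distances = c(0, 100, 300, 600, 700),
                       ehh = c(1, 0.8, 0.5, 0.2, 0)),
                  class = "ehh_curve")
  # crossing of 0.05 on the last segment: d* = 600 + 100*(0.2-0.05)/0.2 = 675
  hand <- (1 + .8) / 2 * 100 + (.8 + .5) / 2 * 200 + (.5 + .2) / 2 * 300 +
    (.2 + .05) / 2 * 75
  flat <- structure(list(distances = 0, ehh = 1), class = "ehh_curve")
  expect_equal(ihh(pl, flat, cutoff = 0.05)$ihh, hand, tolerance = 1e-12)
  # a gap larger than max_gap truncates and flags
  gap <- structure(list(distances = c(0, 1000, 300000), ehh = c(1, 0.9, 0.3)),
                   class = "ehh_curve")
  res <- ihh(gap, tri, cutoff = 0.0)
  expect_true(res$truncated)
  expect_equal(res$left, "truncated_gap")
})

test_that("iHS / delta-iHH / nSL are zero under ancestral-derived symmetry", {
  # ancestral and derived carrier sets with mirrored haplotype structure
  block <- matrix(rbinom(4 * 9, 1, 0.5), 4, 9)
  h <- rbind(cbind(block[, 1:4], 0L, block[, 5:9]),
             cbind(block[, 1:4], 1L, block[, 5:9]))
  pan <- make_panel(h)
  st <- cmsscan:::site_haplo_stats(pan, 5)
  expect_equal(st$ihs_u, 0, tolerance = 1e-12)
  expect_equal(st$dihh_u, 0, tolerance = 1e-9)
  expect_equal(st$nsl_u, 0, tolerance = 1e-12)
})

test_that("nSL segment lengths equal pair enumeration", {
  # two identical haplotypes over m sites -> SL = m for their pair
  m <- 9
  h <- rbind(rep(1L, m), rep(1L, m), matrix(0L, 2, m))
  pan <- make_panel(h)
  expect_equal(cmsscan:::site_sl(pan, 5, 1L), m)
  set.seed(33)
  for (i in 1:40) {
    n <- sample(c(4, 6, 8), 1); mm <- sample(4:10, 1)
    hh <- matrix(rbinom(n * mm, 1, 0.5), n, mm)
    core <- sample(mm, 1); al <- sample(0:1, 1)
    if (sum(hh[, core] == al) < 2) next
    expect_equal(cmsscan:::site_sl(make_panel(hh), core, al),
                 oracle_sl(hh, core, al), tolerance = 1e-12)
  }
})

test_that("xpehh is zero for identical panels and standardizes genome-wide", {
  set.seed(34)
  h <- matrix(rbinom(20 * 30, 1, 0.5), 20, 30)
  pan <- make_panel(h)
  for (j in c(5, 15, 25)) {
    expect_equal(xpehh_u(pan, pan, j), 0, tolerance = 1e-12)
  }
})

test_that("build_bins merges to occupancy and standardization recenters", {
  set.seed(35)
  daf <- runif(5000)
  val <- rnorm(5000, mean = daf)        # frequency-dependent mean
  bins <- build_bins(val, daf, bin_width = 0.02, min_count = 20)
  expect_equal(length(bins$edges) - 1, 50)  # uniform dafs: nothing merged
  # merged-bin means/SDs equal recomputation from raw values
  bi <- findInterval(daf, bins$edges, rightmost.closed = TRUE,
                     all.inside = TRUE)
  for (b in c(1, 25, 50)) {
    expect_equal(bins$mean[b], mean(val[bi == b]), tolerance = 1e-12)
    expect_equal(bins$sd[b], sd(val[bi == b]), tolerance = 1e-12)
  }
  z <- standardize_by_bins(val, daf, bins)
  for (b in c(1, 25, 50)) {
    expect_equal(mean(z[bi == b]), 0, tolerance = 1e-10)
    expect_equal(sd(z[bi == b]), 1, tolerance = 1e-10)
  }
  # all dafs inside one narrow bin -> everything merges into one bin
  one <- build_bins(rnorm(100), rep(0.5, 100))
  expect_true(length(one$edges) - 1 <= 2)
  expect_equal(sum(one$n), 100)
})

test_that("compute_site_scores standardizes per bin and flags undefined", {
  st <- get_small_study()
  sc <- cached("small_scores", function()
    compute_site_scores(st$panels$TBP, st$panels$DUROC,
                        ref2 = st$panels$YKX))
  # standardized columns are centered and scaled where defined
  for (col in c("ihs", "nsl", "dihh", "xpehh")) {
    v <- sc[[col]]
    expect_equal(mean(v, na.rm = TRUE), 0, tolerance = 0.05)
    expect_equal(sd(v, na.rm = TRUE), 1, tolerance = 0.05)
  }
  # iHS/nSL undefined below the MAF floor
  low <- sc$daf < 0.05 | sc$daf > 0.95
  expect_true(all(is.na(sc$ihs[low])))
  expect_true(all(is.na(sc$nsl[low])))
  # two FST columns present with a second reference
  expect_true("fst_ref2" %in% names(sc))
})
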