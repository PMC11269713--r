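# Independent brute-force oracles used across the suite. These deliberately
# re-derive each quantity from first principles (pair enumeration, direct
# formulas, full tail sums) and must stay independent of the package's
# computation paths.

# EHH by pair enumeration: fraction of carrier pairs identical over the span
# core..core+dir*k, for k = 0, 1, 2, ...
oracle_ehh <- function(haps, core, allele, dir) {
  carriers <- which(haps[, core] == allele)
  prs <- utils::combn(carriers, 2)
  m <- ncol(haps)
  out <- 1
  k <- 1
  while (core + dir * k >= 1 && core + dir * k <= m) {
    span <- if (dir > 0) core:(core + k) else (core - k):core
    out <- c(out, mean(apply(prs, 2, function(pr)
      all(haps[pr[1], span] == haps[pr[2], span]))))
    k <- k + 1
  }
  out
}

# SL by pair enumeration: mean over carrier pairs of the number of
# consecutive sites (counting the core) over which the pair is identical
oracle_sl <- function(haps, core, allele) {
  carriers <- which(haps[, core] == allele)
  if (length(carriers) < 2) return(NA_real_)
  prs <- utils::combn(carriers, 2)
  m <- ncol(haps)
  mean(apply(prs, 2, function(pr) {
    len <- 1
    k <- 1
    while (core - k >= 1 && haps[pr[1], core - k] == haps[pr[2], core - k]) {
      len <- len + 1; k <- k + 1
    }
    k <- 1
    while (core + k <= m && haps[pr[1], core + k] == haps[pr[2], core + k]) {
      len <- len + 1; k <- k + 1
    }
    len
  }))
}

# Hudson FST by direct arithmetic
oracle_hudson <- function(p1, n1, p2, n2) {
  ((p1 - p2)^2 - p1 * (1 - p1) / (n1 - 1) - p2 * (1 - p2) / (n2 - 1)) /
    (p1 * (1 - p2) + p2 * (1 - p1))
}

# HWE exact p by full enumeration over heterozygote counts with explicit
# factorials (small totals only)
oracle_hwe <- function(nAA, nAa, naa) {
  n <- nAA + nAa + naa
  nA <- 2 * nAA + nAa
  na <- 2 * naa + nAa
  hets <- seq(min(nA, na) %% 2, min(nA, na), by = 2)
  prob <- vapply(hets, function(h) {
    aa <- (nA - h) / 2
    bb <- (na - h) / 2
    factorial(n) / (factorial(aa) * factorial(h) * factorial(bb)) *
      2^h * factorial(nA) * factorial(na) / factorial(2 * n)
  }, numeric(1))
  prob <- prob / sum(prob)
  sum(prob[prob <= prob[hets == nAa] * (1 + 1e-12)])
}

# one-sided (greater) Fisher exact p by explicit hypergeometric tail sum
oracle_fisher_greater <- function(a, b, c, d) {
  white <- a + c; black <- b + d; drawn <- a + b
  ks <- a:min(drawn, white)
  sum(vapply(ks, function(k)
    choose(white, k) * choose(black, drawn - k) / choose(white + black, drawn),
    numeric(1)))
}

# OLS via explicit normal equations
oracle_ols <- function(y, X) {
  XtX <- t(X) %*% X
  beta <- solve(XtX, t(X) %*% y)
  res <- y - X %*% beta
  df <- length(y) - ncol(X)
  sigma2 <- sum(res^2) / df
  se <- sqrt(sigma2 * diag(solve(XtX)))
  list(beta = as.numeric(beta), se = as.numeric(se), df = df)
}

# Benjamini-Hochberg step-up by direct arithmetic
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  q <- p[o] * n / seq_len(n)
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  out <- numeric(n)
  out[o] <- q
  out
}

# 2x2 haplotype-count r^2
oracle_r2 <- function(a, b) {
  n <- length(a)
  pAB <- sum(a == 1 & b == 1) / n
  pA <- mean(a); pB <- mean(b)
  (pAB - pA * pB)^2 / (pA * (1 - pA) * pB * (1 - pB))
}

# independent greedy clumping re-implementation (quadratic, explicit)
oracle_clump <- function(pos, cms, r2mat, thr_index, thr_sp2, r2_min,
                         radius) {
  claimed <- rep(FALSE, length(pos))
  idx <- which(!is.na(cms) & cms >= thr_index)
  idx <- idx[order(-cms[idx], pos[idx])]
  regions <- list()
  for (s in idx) {
    if (claimed[s]) next
    claimed[s] <- TRUE
    members <- integer(0)
    for (j in seq_along(pos)) {
      if (claimed[j] || is.na(cms[j])) next
      if (abs(pos[j] - pos[s]) <= radius && cms[j] >= thr_sp2 &&
          !is.na(r2mat[s, j]) && r2mat[s, j] >= r2_min) {
        members <- c(members, j)
      }
    }
    claimed[members] <- TRUE
    regions[[length(regions) + 1]] <- list(index = s, members = members)
  }
  regions
}

# quick binary panel builder around a site table on one chromosome
make_panel <- function(haps, pos = NULL, ancestral = "ref", pop = "TBP") {
  haps <- as.matrix(haps)
  storage.mode(haps) <- "integer"
  if (is.null(pos)) pos <- seq_len(ncol(haps)) * 1000L
  sites <- variant_sites("1", pos, ancestral = ancestral)
  haplotype_panel(haps, sites, sprintf("%s_%d", pop, seq_len(nrow(haps) / 2)),
                  pop)
}
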