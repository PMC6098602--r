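# Shared test helpers. Oracles here stay independent of the code paths
# they check: they work from raw frequency arithmetic, not package internals.

# random valid haplotype-frequency tensor (Dirichlet(1) on the 8-simplex)
random_hap <- function() {
  g <- rgamma(8, 1)
  hap_freq(g / sum(g))
}

# random valid decomposition via the simplex (rejection-free)
random_decomp <- function() {
  haplotypes_to_params(random_hap())
}

# brute-force oracle for the admissible range of d_TMK: scan a grid and
# keep values where all eight frequencies (affine in d) are non-negative
grid_bounds_oracle <- function(p, step = 1e-4) {
  # recompute the constant parts from first principles
  a <- c(p[["f_T"]], 1 - p[["f_T"]])
  b <- c(p[["f_M"]], 1 - p[["f_M"]])
  cc <- c(p[["f_K"]], 1 - p[["f_K"]])
  sg <- c(1, -1)
  konst <- numeric(8)
  sgn <- numeric(8)
  n <- 0
  for (k in 1:2) for (j in 1:2) for (i in 1:2) {
    n <- n + 1
    konst[n] <- a[i] * b[j] * cc[k] +
      a[i] * sg[j] * sg[k] * p[["d_MK"]] +
      b[j] * sg[i] * sg[k] * p[["d_TK"]] +
      cc[k] * sg[i] * sg[j] * p[["d_TM"]]
    sgn[n] <- sg[i] * sg[j] * sg[k]
  }
  d <- seq(-0.13, 0.13, by = step)
  ok <- rep(TRUE, length(d))
  for (n in 1:8) ok <- ok & (konst[n] + sgn[n] * d >= -1e-12)
  list(lower = min(d[ok]), upper = max(d[ok]))
}

# direct unphased-genotype sampler used as an oracle for seeded generators
expected_counts <- function(h, N) {
  genotype_counts(unclass(genotype_probabilities(h)) * N)
}

# tiny independent two-locus EM for the reduction oracle (counts: 3x3,
# codes 1/2/3); returns the maximized log-likelihood
two_locus_em_oracle <- function(cnt, tol = 1e-10, max_iter = 5000) {
  # haplotypes 11, 12, 21, 22 (locus1 allele, locus2 allele)
  f <- rep(0.25, 4)
  hapA <- c(1, 1, 2, 2)
  hapB <- c(1, 2, 1, 2)
  N <- sum(cnt)
  for (it in seq_len(max_iter)) {
    e <- numeric(4)
    for (a in 1:4) for (b in 1:4) {
      g1 <- if (hapA[a] == hapA[b]) hapA[a] else 3
      g2 <- if (hapB[a] == hapB[b]) hapB[a] else 3
      n <- cnt[g1, g2]
      if (n == 0) next
      # probability of the cell under current f
      phi <- 0
      for (x in 1:4) for (y in 1:4) {
        if ((if (hapA[x] == hapA[y]) hapA[x] else 3) == g1 &&
            (if (hapB[x] == hapB[y]) hapB[x] else 3) == g2) {
          phi <- phi + f[x] * f[y]
        }
      }
      e[a] <- e[a] + n * f[a] * f[b] / phi
      e[b] <- e[b] + n * f[a] * f[b] / phi
    }
    f_new <- e / (2 * N)
    if (max(abs(f_new - f)) < tol) {
      f <- f_new
      break
    }
    f <- f_new
  }
  ll <- 0
  for (g1 in 1:3) for (g2 in 1:3) {
    if (cnt[g1, g2] == 0) next
    phi <- 0
    for (x in 1:4) for (y in 1:4) {
      if ((if (hapA[x] == hapA[y]) hapA[x] else 3) == g1 &&
          (if (hapB[x] == hapB[y]) hapB[x] else 3) == g2) {
        phi <- phi + f[x] * f[y]
      }
    }
    ll <- ll + cnt[g1, g2] * log(phi)
  }
  ll
}

# small .ped/.map fixture written to a temp prefix: 3 SNPs, 4 samples
write_pedmap_fixture <- function(prefix) {
  writeLines(c(
    "1\trs1\t0\t1000",
    "1\trs2\t0\t2000",
    "2\trs3\t0\t500"
  ), paste0(prefix, ".map"))
  writeLines(c(
    "f1 s1 0 0 0 -9 A A C C G T",
    "f1 s2 0 0 0 -9 A G C T T T",
    "f2 s3 0 0 0 -9 G G C C 0 0",
    "f2 s4 0 0 0 -9 A A T T G G"
  ), paste0(prefix, ".ped"))
  prefix
}

# minimal VCF fixture with one triallelic site
write_vcf_fixture <- function(path) {
  writeLines(c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    "##contig=<ID=1>",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "s1", "s2", "s3", sep = "\t"),
    paste("1", "100", "v1", "A", "G", ".", "PASS", ".", "GT",
          "0/0", "0/1", "1/1", sep = "\t"),
    paste("1", "200", "v2", "C", "T,G", ".", "PASS", ".", "GT",
          "0/0", "0/1", "0/2", sep = "\t"),
    paste("1", "300", "v3", "G", "A", ".", "PASS", ".", "GT",
          "0/1", "0/1", "0/0", sep = "\t")
  ), path)
  path
}
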