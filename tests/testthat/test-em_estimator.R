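# Genotype probabilities, EM fitting, likelihood and the LRT.

test_that("genotype probabilities match direct pair enumeration", {
  # uniform haplotypes: triple heterozygote has probability
  # 2 * 4 * (1/8)^2 = 1/8
  phi <- genotype_probabilities(hap_freq(rep(1 / 8, 8)))
  expect_equal(phi[3, 3, 3], 1 / 8)
  expect_equal(sum(phi), 1, tolerance = 1e-12)

  # two complementary haplotypes at 1/2: only three genotypes possible
  h <- hap_freq(c(0.5, 0, 0, 0, 0, 0, 0, 0.5))
  phi2 <- genotype_probabilities(h)
  expect_equal(phi2[1, 1, 1], 0.25)
  expect_equal(phi2[2, 2, 2], 0.25)
  expect_equal(phi2[3, 3, 3], 0.5)
  expect_equal(sum(phi2 > 0), 3)

  set.seed(1)
  for (i in 1:20) expect_equal(sum(genotype_probabilities(random_hap())), 1,
                               tolerance = 1e-12)
})

test_that("hap_loglik evaluates the multinomial log-likelihood", {
  cnt <- array(0, c(3, 3, 3))
  cnt[3, 3, 3] <- 1
  expect_equal(hap_loglik(hap_freq(rep(1 / 8, 8)), genotype_counts(cnt)),
               log(1 / 8))
  # impossible observation
  h <- hap_freq(c(0.5, 0, 0, 0, 0, 0, 0, 0.5))
  cnt2 <- array(0, c(3, 3, 3))
  cnt2[1, 2, 1] <- 1
  expect_identical(hap_loglik(h, genotype_counts(cnt2)), -Inf)
  # linearity in counts
  set.seed(2)
  h2 <- random_hap()
  cnt3 <- expected_counts(h2, 100)
  expect_equal(hap_loglik(h2, genotype_counts(unclass(cnt3) * 2)),
               2 * hap_loglik(h2, cnt3), tolerance = 1e-10)
})

test_that("EM recovers the truth from expected-count data", {
  h_star <- params_to_haplotypes(ld_decomp(0.5, 0.5, 0.5, d_TMK = 0.125))
  cnt <- genotype_counts(round(unclass(genotype_probabilities(h_star)) * 10000))
  fit <- em_fit(cnt)
  expect_true(fit$converged)
  expect_lt(max(abs(unclass(fit$haplotypes) - unclass(h_star))), 1e-3)
  expect_lt(abs(fit$decomposition[["d_TMK"]] - 0.125), 1e-3)
  expect_true(all(diff(fit$loglik_trace) > -1e-8))
})

test_that("EM equals direct gamete counting when phase is unambiguous", {
  # no individual heterozygous at two or more loci: every genotype
  # resolves to a unique gamete pair
  tab <- data.frame(
    g1 = c(1, 3, 1, 2, 2), g2 = c(1, 1, 2, 2, 2),
    g3 = c(1, 1, 1, 3, 2), count = c(10, 5, 4, 6, 3)
  )
  cnt <- genotype_counts(tab)
  fit <- em_fit(cnt)
  # hand gamete count: each row contributes 2*count gametes; heterozygous
  # locus splits one allele each way
  gam <- c("111" = 20 + 5, "211" = 5, "121" = 8,
           "221" = 6, "222" = 6 + 6)
  oracle <- gam / (2 * sum(tab$count))
  v <- hap_vector(fit$haplotypes)
  expect_equal(unname(v[names(gam)]), unname(oracle), tolerance = 1e-7)
  expect_equal(sum(v), 1, tolerance = 1e-12)
})

test_that("a single homozygous genotype class fixes one haplotype", {
  cnt <- array(0, c(3, 3, 3))
  cnt[1, 1, 1] <- 50
  fit <- em_fit(genotype_counts(cnt))
  expect_equal(unname(hap_vector(fit$haplotypes)[["111"]]), 1)
  p <- unclass(fit$decomposition)
  expect_equal(unname(p[1:3]), c(1, 1, 1))
  expect_equal(unname(p[4:7]), rep(0, 4), tolerance = 1e-12)
})

test_that("the E-step ambiguity weights reproduce the W formulas", {
  set.seed(3)
  cnt <- sample_triplet_genotypes(random_hap(), 500, seed = 9)
  fit <- em_fit(cnt)
  f <- hap_vector(fit$haplotypes)
  W <- fit$ambiguity_weights
  # double heterozygote at the first two loci, homozygote 1 at the third
  w331 <- W[["331"]]
  coup <- w331$weight[w331$hap1 == "111" & w331$hap2 == "221"]
  expect_equal(coup,
               f[["111"]] * f[["221"]] /
                 (f[["111"]] * f[["221"]] + f[["121"]] * f[["211"]]))
  # triple heterozygote: four complementary resolutions
  w333 <- W[["333"]]
  expect_equal(nrow(w333), 4)
  coup3 <- w333$weight[w333$hap1 == "111" & w333$hap2 == "222"]
  expect_equal(coup3,
               f[["111"]] * f[["222"]] /
                 (f[["111"]] * f[["222"]] + f[["221"]] * f[["112"]] +
                    f[["211"]] * f[["122"]] + f[["212"]] * f[["121"]]))
})

test_that("log-likelihood is monotone and haplotype error shrinks with N", {
  set.seed(4)
  err_by_n <- sapply(c(300, 3000, 30000), function(N) {
    errs <- sapply(1:20, function(r) {
      h <- random_hap()
      cnt <- sample_triplet_genotypes(h, N, seed = 1000 * N + r)
      fit <- em_fit(cnt)
      expect_true(all(diff(fit$loglik_trace) > -1e-8))
      mean(abs(unclass(fit$haplotypes) - unclass(h)))
    })
    mean(errs)
  })
  expect_true(all(diff(err_by_n) < 0))
})

test_that("EM attains the coarse-grid likelihood optimum for tiny samples", {
  # exhaustive search over all 8-part compositions of 4 (step 1/4 simplex)
  grid <- as.matrix(expand.grid(rep(list(0:4), 7)))
  grid <- cbind(grid, 4 - rowSums(grid))
  grid <- grid[grid[, 8] >= 0, ] / 4
  set.seed(5)
  for (rep in 1:5) {
    cnt <- sample_triplet_genotypes(random_hap(), 25, seed = 600 + rep)
    best <- max(apply(grid, 1, function(f) {
      hap_loglik(hap_freq(array(f, c(2, 2, 2))), cnt)
    }))
    fit <- em_fit(cnt)
    expect_gte(fit$loglik, best - 1e-6)
  }
})

test_that("the estimated decomposition respects the core invariants", {
  set.seed(6)
  for (i in 1:20) {
    cnt <- sample_triplet_genotypes(random_hap(), 200, seed = 700 + i)
    fit <- em_fit(cnt)
    p <- unclass(fit$decomposition)
    b <- delta3_bounds(p[["f_T"]], p[["f_M"]], p[["f_K"]],
                       p[["d_TM"]], p[["d_TK"]], p[["d_MK"]])
    expect_gte(p[["d_TMK"]], b$lower - 1e-9)
    expect_lte(p[["d_TMK"]], b$upper + 1e-9)
    expect_lte(abs(p[["d_TMK"]]), 0.125 + 1e-9)
  }
})

test_that("the LRT is powered against strong third-order LD", {
  h_star <- params_to_haplotypes(ld_decomp(0.5, 0.5, 0.5, d_TMK = 0.125))
  hits <- sapply(1:50, function(r) {
    cnt <- sample_triplet_genotypes(h_star, 300, seed = 800 + r)
    lrt_independence(cnt)$statistic > 9.49
  })
  expect_gte(mean(hits), 0.99)
})

test_that("a monomorphic third locus reduces the LRT to the two-locus case", {
  set.seed(7)
  # two-locus pool embedded at a fixed third allele
  f4 <- c(0.4, 0.1, 0.2, 0.3)
  h <- hap_freq(c(f4[1], 0, f4[2], 0, f4[3], 0, f4[4], 0))
  cnt <- sample_triplet_genotypes(h, 400, seed = 900)
  expect_true(all(unclass(cnt)[, , 2:3] == 0))
  res <- lrt_independence(cnt)
  # independent two-locus oracle on the collapsed table
  cnt2 <- apply(unclass(cnt), c(1, 2), sum)
  ll_full_2 <- two_locus_em_oracle(cnt2)
  n1 <- apply(cnt2, 1, sum)
  n2 <- apply(cnt2, 2, sum)
  fA <- (2 * n1[1] + n1[3]) / (2 * sum(cnt2))
  fB <- (2 * n2[1] + n2[3]) / (2 * sum(cnt2))
  f0 <- c(fA * fB, fA * (1 - fB), (1 - fA) * fB, (1 - fA) * (1 - fB))
  ll0_2 <- 0
  hapA <- c(1, 1, 2, 2); hapB <- c(1, 2, 1, 2)
  for (g1 in 1:3) for (g2 in 1:3) {
    if (cnt2[g1, g2] == 0) next
    phi <- 0
    for (x in 1:4) for (y in 1:4) {
      if ((if (hapA[x] == hapA[y]) hapA[x] else 3) == g1 &&
          (if (hapB[x] == hapB[y]) hapB[x] else 3) == g2) {
        phi <- phi + f0[x] * f0[y]
      }
    }
    ll0_2 <- ll0_2 + cnt2[g1, g2] * log(phi)
  }
  expect_equal(res$statistic, as.numeric(2 * (ll_full_2 - ll0_2)),
               tolerance = 1e-4)
})

test_that("degenerate inputs are rejected", {
  expect_error(genotype_counts(array(0, c(3, 3, 3))), "zero")
  expect_error(genotype_counts(array(-1, c(3, 3, 3))), "non-negative")
  expect_error(em_fit(array(1, c(2, 2, 2))))
})
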