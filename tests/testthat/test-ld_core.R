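# Decomposition <-> haplotype conversions, bounds and normalization.

test_that("params_to_haplotypes handles the canonical configurations", {
  # maximal third-order LD at intermediate frequencies: 4 haplotypes at 1/4
  h <- hap_vector(params_to_haplotypes(ld_decomp(0.5, 0.5, 0.5,
                                                 d_TMK = 0.125)))
  expect_equal(unname(h[c("111", "221", "122", "212")]), rep(0.25, 4))
  expect_equal(unname(h[c("112", "121", "211", "222")]), rep(0, 4))

  # maximal pairwise LD forces d_TMK = 0 and two haplotypes at 1/2
  h2 <- hap_vector(params_to_haplotypes(ld_decomp(0.5, 0.5, 0.5,
                                                  0.25, 0.25, 0.25)))
  expect_equal(unname(h2[c("111", "222")]), c(0.5, 0.5))
  expect_equal(sum(h2), 1)

  # independence: tensor is the outer product of allele frequencies
  d <- ld_decomp(0.3, 0.6, 0.9)
  h3 <- unclass(params_to_haplotypes(d))
  expect_equal(h3, outer(outer(c(0.3, 0.7), c(0.6, 0.4)), c(0.9, 0.1)),
               tolerance = 1e-12, ignore_attr = TRUE)

  expect_error(params_to_haplotypes(c(0.5, 0.5, 0.5, 0.25, 0.25, 0, 0)),
               "invalid decomposition")
})

test_that("haplotypes_to_params inverts the expansion", {
  expect_equal(unclass(haplotypes_to_params(hap_freq(rep(1 / 8, 8)))),
               c(f_T = 0.5, f_M = 0.5, f_K = 0.5, d_TM = 0, d_TK = 0,
                 d_MK = 0, d_TMK = 0))
  h <- hap_freq(c(0.25, 0, 0, 0.25, 0, 0.25, 0.25, 0))
  p <- haplotypes_to_params(h)
  expect_equal(p[["d_TMK"]], 0.125)
  expect_equal(unname(p[c("d_TM", "d_TK", "d_MK")]), c(0, 0, 0))
  expect_error(haplotypes_to_params(c(0.5, 0.5, 0.5, 0, 0, 0, 0, 0)),
               "sum")
})

test_that("round-trip identity holds on random valid decompositions", {
  set.seed(101)
  for (i in 1:1000) {
    d <- random_decomp()
    d2 <- haplotypes_to_params(params_to_haplotypes(d))
    expect_equal(unclass(d2), unclass(d), tolerance = 1e-12)
  }
})

test_that("allele relabeling flips d_TMK iff an odd number of loci flip", {
  set.seed(202)
  for (i in 1:50) {
    h <- unclass(random_hap())
    p <- haplotypes_to_params(hap_freq(h))
    for (axes in list(1L, 2L, c(1L, 2L), 1:3)) {
      hf <- h
      for (ax in axes) {
        idx <- rep(list(1:2), 3)
        idx[[ax]] <- 2:1
        hf <- do.call(`[`, c(list(hf), idx))
      }
      pf <- haplotypes_to_params(hap_freq(hf))
      sgn <- if (length(axes) %% 2 == 1) -1 else 1
      expect_equal(pf[["d_TMK"]], sgn * p[["d_TMK"]], tolerance = 1e-12)
      # a single flip at locus T negates d_TM and d_TK, leaves d_MK alone
      if (identical(axes, 1L)) {
        expect_equal(pf[["d_TM"]], -p[["d_TM"]], tolerance = 1e-12)
        expect_equal(pf[["d_TK"]], -p[["d_TK"]], tolerance = 1e-12)
        expect_equal(pf[["d_MK"]], p[["d_MK"]], tolerance = 1e-12)
      }
    }
  }
})

test_that("delta3_bounds matches its closed-form cases and the grid oracle", {
  b <- delta3_bounds(0.5, 0.5, 0.5, 0, 0, 0)
  expect_equal(b$lower, -0.125)
  expect_equal(b$upper, 0.125)

  b2 <- delta3_bounds(0.5, 0.5, 0.5, 0.25, 0.25, 0.25)
  expect_equal(b2$lower, 0)
  expect_equal(b2$upper, 0)

  expect_error(delta3_bounds(0.5, 0.5, 0.5, 0.25, 0.25, 0),
               "infeasible pairwise system")

  set.seed(303)
  for (i in 1:100) {
    p <- random_decomp()
    b <- delta3_bounds(p[["f_T"]], p[["f_M"]], p[["f_K"]],
                       p[["d_TM"]], p[["d_TK"]], p[["d_MK"]])
    g <- grid_bounds_oracle(p, step = 1e-4)
    expect_lt(abs(b$lower - g$lower), 1e-4 + 1e-12)
    expect_lt(abs(b$upper - g$upper), 1e-4 + 1e-12)
    # at either bound at least one haplotype frequency hits exactly zero
    for (x in c(b$lower, b$upper)) {
      h <- params_to_haplotypes(
        ld_decomp(p[["f_T"]], p[["f_M"]], p[["f_K"]], p[["d_TM"]],
                  p[["d_TK"]], p[["d_MK"]], x, validate = FALSE))
      expect_lt(min(unclass(h)), 1e-12)
    }
  }
})

test_that("normalize_robinson classifies and scales correctly", {
  # interior: halfway into the positive admissible range
  r <- normalize_robinson(ld_decomp(0.5, 0.5, 0.5, d_TMK = 0.0625))
  expect_equal(r$category, "interior")
  expect_equal(r$value, 0.5)

  # definitional extremes
  r1 <- normalize_robinson(ld_decomp(0.5, 0.5, 0.5, d_TMK = 0.125))
  expect_equal(r1$category, "plus_one")
  expect_equal(r1$value, 1)
  rm1 <- normalize_robinson(ld_decomp(0.5, 0.5, 0.5, d_TMK = -0.125))
  expect_equal(rm1$category, "minus_one")
  expect_equal(rm1$value, -1)

  # range collapsed to a single admissible value
  ru <- normalize_robinson(ld_decomp(0.5, 0.5, 0.5, 0.25, 0.25, 0.25))
  expect_equal(ru$category, "undefined_single_value")
  expect_true(is.na(ru$value))

  r0 <- normalize_robinson(ld_decomp(0.4, 0.3, 0.6))
  expect_equal(r0$category, "zero")

  # negative interior values are signed
  rn <- normalize_robinson(ld_decomp(0.5, 0.5, 0.5, d_TMK = -0.0625))
  expect_equal(rn$value, -0.5)
})

test_that("beta_proportion behaves at its extremes and in between", {
  expect_equal(beta_proportion(ld_decomp(0.5, 0.5, 0.5, d_TMK = 0.05)), 1)
  expect_equal(beta_proportion(ld_decomp(0.5, 0.5, 0.5, 0.1, 0.05, 0.02)), 0)
  expect_equal(
    beta_proportion(ld_decomp(0.5, 0.5, 0.5, 0.02, 0.02, 0.02, 0.02)), 0.25)
  expect_true(is.na(beta_proportion(ld_decomp(0.3, 0.4, 0.5))))
})

test_that("count_segregating_haplotypes counts entries above tolerance", {
  expect_equal(count_segregating_haplotypes(hap_freq(rep(1 / 8, 8))), 8)
  expect_equal(count_segregating_haplotypes(
    params_to_haplotypes(ld_decomp(0.5, 0.5, 0.5, d_TMK = 0.125))), 4)
  expect_equal(count_segregating_haplotypes(
    params_to_haplotypes(ld_decomp(0.5, 0.5, 0.5, 0.25, 0.25, 0.25))), 2)
})

test_that("parameter and haplotype files round-trip", {
  tmp <- tempfile()
  ds <- list(ld_decomp(0.5, 0.5, 0.5, d_TMK = 0.125),
             ld_decomp(0.3, 0.6, 0.9))
  write_ld_decomp(ds, tmp)
  ds2 <- read_ld_decomp(tmp)
  expect_equal(unclass(ds2[[1]]), unclass(ds[[1]]), tolerance = 1e-15)
  expect_equal(unclass(ds2[[2]]), unclass(ds[[2]]), tolerance = 1e-15)

  tmp2 <- tempfile()
  h <- params_to_haplotypes(ds[[1]])
  write_hap_freq(h, tmp2)
  expect_equal(unclass(read_hap_freq(tmp2)), unclass(h), tolerance = 1e-15)
})
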