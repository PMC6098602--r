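# Maximum-likelihood estimation of the eight three-locus haplotype
# frequencies from unphased diploid genotypes, via EM under HWE.
#
# Genotypes are coded per locus as 1 (homozygote for allele 1),
# 2 (homozygote for allele 2) and 3 (heterozygote); a joint triplet
# genotype is one of 27 cells of a 3x3x3 count table. Individuals
# heterozygous at two or more of the loci are phase-ambiguous: the E-step
# apportions them among the compatible haplotype pairs (coupling vs
# repulsion) in proportion to the current haplotype-frequency products,
# which reproduces the classical W weights; the M-step is gamete counting
# of the resolved expectations. The generic E-step enumerates the <= 4
# compatible unordered pairs per genotype cell rather than hard-coding the
# 27 cases, so the scheme extends beyond three loci.

# Static lookup tables shared by all fits ----------------------------------
# For ordered haplotype pairs (a, b), a,b in 1..8 (linear index of the
# 2x2x2 tensor, first locus fastest): the joint genotype cell in 1..27
# (linear index of the 3x3x3 table, first locus fastest).
.em_tables <- local({
  hap_allele <- as.matrix(expand.grid(1:2, 1:2, 1:2)) # row = hap, col = locus
  pairs <- expand.grid(a = 1:8, b = 1:8)
  geno <- matrix(0L, nrow = 64, ncol = 3)
  for (l in 1:3) {
    aa <- hap_allele[pairs$a, l]
    bb <- hap_allele[pairs$b, l]
    geno[, l] <- ifelse(aa == bb, aa, 3L)
  }
  gcell <- geno[, 1] + 3L * (geno[, 2] - 1L) + 9L * (geno[, 3] - 1L)
  list(
    a = pairs$a,
    b = pairs$b,
    gfac = factor(gcell, levels = 1:27),
    gcell = gcell,
    afac = factor(pairs$a, levels = 1:8),
    bfac = factor(pairs$b, levels = 1:8),
    hap_allele = hap_allele
  )
})

# genotype-cell probabilities as a length-27 vector from a length-8 f
.phi27 <- function(f8) {
  P <- as.vector(outer(f8, f8))
  as.vector(rowsum(P, .em_tables$gfac))
}

#' Triplet genotype counts
#'
#' Validates (and optionally builds) the 3x3x3 table of individual counts
#' by joint genotype at three biallelic loci, coded 1/2 for the two
#' homozygotes and 3 for the heterozygote.
#'
#' @param x A 3x3x3 non-negative numeric array (expected counts may be
#'   non-integer), or a data frame with columns `g1`, `g2`, `g3`, `count`.
#' @return A 3x3x3 array of class `geno_counts`.
#' @export
genotype_counts <- function(x) {
  if (is.data.frame(x)) {
    stopifnot(all(c("g1", "g2", "g3", "count") %in% names(x)))
    a <- array(0, c(3, 3, 3))
    for (r in seq_len(nrow(x))) {
      a[x$g1[r], x$g2[r], x$g3[r]] <- a[x$g1[r], x$g2[r], x$g3[r]] + x$count[r]
    }
    x <- a
  }
  stopifnot(is.array(x), all(dim(x) == c(3, 3, 3)))
  storage.mode(x) <- "double"
  if (any(x < 0)) stop("genotype counts must be non-negative")
  if (sum(x) <= 0) stop("all genotype counts are zero")
  dimnames(x) <- list(g1 = 1:3, g2 = 1:3, g3 = 1:3)
  class(x) <- c("geno_counts", "array")
  x
}

#' Tabulate genotype codes into a triplet count table
#'
#' Complete-case tabulation: individuals missing any of the three codes
#' are dropped.
#'
#' @param g1,g2,g3 Integer vectors of per-locus genotype codes in
#'   \{1, 2, 3, NA\}, one element per individual.
#' @return A `geno_counts` array.
#' @export
counts_from_codes <- function(g1, g2, g3) {
  stopifnot(length(g1) == length(g2), length(g2) == length(g3))
  keep <- !(is.na(g1) | is.na(g2) | is.na(g3))
  g1 <- g1[keep]; g2 <- g2[keep]; g3 <- g3[keep]
  stopifnot(all(g1 %in% 1:3), all(g2 %in% 1:3), all(g3 %in% 1:3))
  a <- array(0, c(3, 3, 3))
  cell <- g1 + 3L * (g2 - 1L) + 9L * (g3 - 1L)
  tab <- tabulate(cell, nbins = 27L)
  a[] <- tab
  genotype_counts(a)
}

#' Joint genotype probabilities under HWE
#'
#' Probability of each of the 27 triplet genotypes given haplotype
#' frequencies: the sum over ordered pairs of compatible gametes of the
#' product of their frequencies (`2 f_a f_b` per unordered heterozygous
#' resolution, `f_a^2` for homozygous pairs).
#'
#' @param h A `hap_freq` tensor.
#' @return A 3x3x3 array of class `geno_prob`, summing to 1.
#' @export
genotype_probabilities <- function(h) {
  f8 <- as.vector(.as_hap(h))
  a <- array(.phi27(f8), c(3, 3, 3))
  dimnames(a) <- list(g1 = 1:3, g2 = 1:3, g3 = 1:3)
  class(a) <- c("geno_prob", "array")
  a
}

#' Multinomial log-likelihood of triplet genotype counts
#'
#' `sum_i n_i log phi_i` over the 27 genotype cells; the multinomial
#' combinatorial constant is omitted, so values are comparable across
#' haplotype frequencies for fixed counts.
#'
#' @param h A `hap_freq` tensor.
#' @param counts A `geno_counts` array.
#' @return Log-likelihood (up to an additive constant); `-Inf` when an
#'   observed genotype cell has probability zero.
#' @export
hap_loglik <- function(h, counts) {
  counts <- genotype_counts(unclass(counts))
  phi <- .phi27(as.vector(.as_hap(h)))
  n <- as.vector(unclass(counts))
  obs <- n > 0
  if (any(phi[obs] <= 0)) return(-Inf)
  sum(n[obs] * log(phi[obs]))
}

#' EM estimation of haplotype frequencies from unphased genotypes
#'
#' Iterates expectation (phase resolution of multiply-heterozygous
#' genotypes) and maximization (gamete counting) until the largest change
#' in any haplotype frequency falls below `tol`.
#'
#' @param counts A `geno_counts` array (or coercible input).
#' @param init `"uniform"` (all 1/8, the default), `"random"` (Dirichlet(1)
#'   draw), or a `hap_freq` start.
#' @param tol Convergence tolerance on the max absolute haplotype-frequency
#'   change per iteration. Default 1e-8.
#' @param max_iter Iteration cap; non-convergence is reported, not an
#'   error. Default 10000.
#' @param n_restarts Extra random restarts; the fit with the best
#'   log-likelihood wins. Requires `seed` when > 0. Default 0.
#' @param seed RNG seed for random initialization.
#' @return A list of class `em_fit`: `haplotypes`, `decomposition`,
#'   `loglik`, `loglik_trace`, `iterations`, `converged`, `n` (total
#'   individuals) and `ambiguity_weights` (the final-phase posterior
#'   weights of each ambiguous genotype cell's unordered pair resolutions,
#'   the W weights).
#' @examples
#' h <- params_to_haplotypes(ld_decomp(0.5, 0.5, 0.5, d_TMK = 0.125))
#' n <- genotype_counts(unclass(genotype_probabilities(h)) * 1000)
#' em_fit(n)$decomposition
#' @export
em_fit <- function(counts, init = "uniform", tol = 1e-8, max_iter = 10000,
                   n_restarts = 0, seed = NULL) {
  counts <- genotype_counts(unclass(counts))
  inits <- list(.em_init(init, seed))
  if (n_restarts > 0) {
    if (is.null(seed)) stop("random restarts require a seed")
    inits <- c(inits, lapply(seq_len(n_restarts), function(i) {
      .em_init("random", seed + i)
    }))
  }
  fits <- lapply(inits, function(f0) .em_run(counts, f0, tol, max_iter))
  best <- fits[[which.max(vapply(fits, `[[`, 0, "loglik"))]]
  best
}

.em_init <- function(init, seed = NULL) {
  if (is.character(init) && init == "uniform") return(rep(1 / 8, 8))
  if (is.character(init) && init == "random") {
    if (is.null(seed)) stop("random initialization requires a seed")
    withr::with_seed(seed, {
      g <- stats::rgamma(8, 1)
      g / sum(g)
    })
  } else {
    as.vector(.as_hap(init))
  }
}

.em_run <- function(counts, f8, tol, max_iter) {
  tb <- .em_tables
  n27 <- as.vector(unclass(counts))
  N <- sum(n27)
  trace <- numeric(0)
  converged <- FALSE
  iter <- 0L
  repeat {
    iter <- iter + 1L
    P <- as.vector(outer(f8, f8))
    phi <- as.vector(rowsum(P, tb$gfac))
    # posterior mass of each ordered pair within its genotype cell
    w <- n27 / phi
    w[n27 == 0] <- 0
    dead <- which(n27 > 0 & phi <= 0)
    m <- P * w[tb$gcell]
    for (g in dead) {
      # observed cell with zero probability under the current frequencies:
      # split its count equally across the compatible ordered pairs
      idx <- which(tb$gcell == g)
      m[idx] <- n27[g] / length(idx)
    }
    ll <- if (length(dead) > 0) -Inf else
      sum(n27[n27 > 0] * log(phi[n27 > 0]))
    trace <- c(trace, ll)
    copies <- as.vector(rowsum(m, tb$afac)) + as.vector(rowsum(m, tb$bfac))
    f_new <- copies / (2 * N)
    delta <- max(abs(f_new - f8))
    f8 <- f_new
    if (delta < tol) {
      converged <- TRUE
      break
    }
    if (iter >= max_iter) break
  }
  h <- hap_freq(array(f8, c(2, 2, 2)))
  structure(list(
    haplotypes = h,
    decomposition = haplotypes_to_params(h),
    loglik = hap_loglik(h, counts),
    loglik_trace = trace,
    iterations = iter,
    converged = converged,
    n = N,
    ambiguity_weights = .ambiguity_weights(f8)
  ), class = "em_fit")
}

# Posterior resolution weights for the phase-ambiguous genotype cells:
# for each cell with >1 compatible unordered haplotype pair, the
# probability of each pair under haplotype frequencies f8.
.ambiguity_weights <- function(f8) {
  tb <- .em_tables
  lab27 <- as.matrix(expand.grid(g1 = 1:3, g2 = 1:3, g3 = 1:3))
  hap_lab <- apply(as.matrix(expand.grid(1:2, 1:2, 1:2)), 1,
                   paste, collapse = "")
  out <- list()
  for (g in 1:27) {
    idx <- which(tb$gcell == g & tb$a <= tb$b)
    if (length(idx) < 2) next
    pr <- ifelse(tb$a[idx] == tb$b[idx],
                 f8[tb$a[idx]]^2, 2 * f8[tb$a[idx]] * f8[tb$b[idx]])
    tot <- sum(pr)
    out[[paste(lab27[g, ], collapse = "")]] <- data.frame(
      hap1 = hap_lab[tb$a[idx]],
      hap2 = hap_lab[tb$b[idx]],
      weight = if (tot > 0) pr / tot else rep(1 / length(idx), length(idx))
    )
  }
  out
}

#' @export
print.em_fit <- function(x, ...) {
  cat(sprintf("EM fit on %g individuals: %s after %d iterations, logL = %.6f\n",
              x$n, if (x$converged) "converged" else "NOT converged",
              x$iterations, x$loglik))
  print(x$decomposition)
  invisible(x)
}

#' Likelihood-ratio test: full model versus allele frequencies only
#'
#' Compares the EM optimum (7 free parameters: three allele frequencies,
#' three pairwise and one third-order LD coefficient) against the
#' independence model in which haplotype frequencies are products of the
#' observed allele frequencies (3 free parameters). The chi-square(4)
#' reference follows from the 7 - 3 parameter-count difference and is
#' nominal: the bounded parameter space can make it conservative or
#' anticonservative near the boundary.
#'
#' @param counts A `geno_counts` array (or coercible input).
#' @param ... Passed to [em_fit()].
#' @return A list: `statistic` (2 * log-likelihood difference), `df` (4),
#'   `p_nominal`, plus the underlying `fit` and the null log-likelihood.
#' @export
lrt_independence <- function(counts, ...) {
  counts <- genotype_counts(unclass(counts))
  fit <- em_fit(counts, ...)
  fr <- .allele_freqs_from_counts(counts)
  h0 <- hap_freq(outer(outer(c(fr[1], 1 - fr[1]), c(fr[2], 1 - fr[2])),
                       c(fr[3], 1 - fr[3])))
  ll0 <- hap_loglik(h0, counts)
  stat <- 2 * (fit$loglik - ll0)
  if (stat < -1e-8) {
    stop(sprintf("EM log-likelihood below independence null by %.3g", -stat))
  }
  stat <- max(stat, 0)
  list(statistic = stat, df = 4L,
       p_nominal = stats::pchisq(stat, df = 4L, lower.tail = FALSE),
       loglik_null = ll0, fit = fit)
}

# observed allele-1 frequency at each locus from a genotype count table
.allele_freqs_from_counts <- function(counts) {
  a <- unclass(counts)
  N <- sum(a)
  vapply(1:3, function(l) {
    marg <- apply(a, l, sum)
    (2 * marg[1] + marg[3]) / (2 * N)
  }, 0)
}
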