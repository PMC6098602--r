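# Seeded simulation of unphased diploid SNP genotypes.
#
# All generators sample gametes from a haplotype pool under random mating
# (Hardy-Weinberg at the genotype level) and share one gamete-formation
# rule with the deterministic recombination module: no interference,
# independent recombination per marker interval. Every stochastic entry
# point takes an explicit seed; nothing touches the caller's RNG state.

#' Sample unphased triplet genotypes under HWE
#'
#' Each individual is the union of two independent haplotype draws from
#' `h`; the resulting joint genotypes (codes 1/2/3 per locus) are
#' tabulated.
#'
#' @param h A `hap_freq` tensor to draw gametes from.
#' @param N Number of diploid individuals (>= 1).
#' @param seed RNG seed (required).
#' @return A `geno_counts` array with `sum == N`.
#' @export
sample_triplet_genotypes <- function(h, N, seed) {
  codes <- sample_triplet_codes(h, N, seed)
  counts_from_codes(codes[, 1], codes[, 2], codes[, 3])
}

#' @rdname sample_triplet_genotypes
#' @return `sample_triplet_codes`: an `N` x 3 integer matrix of per-locus
#'   genotype codes.
#' @export
sample_triplet_codes <- function(h, N, seed) {
  stopifnot(N >= 1)
  f8 <- as.vector(.as_hap(h))
  alle <- .em_tables$hap_allele
  withr::with_seed(seed, {
    g1 <- sample.int(8, N, replace = TRUE, prob = f8)
    g2 <- sample.int(8, N, replace = TRUE, prob = f8)
    codes <- matrix(0L, N, 3)
    for (l in 1:3) {
      a <- alle[g1, l]
      b <- alle[g2, l]
      codes[, l] <- ifelse(a == b, a, 3L)
    }
    codes
  })
}

#' Wright-Fisher drift of three-locus haplotype frequencies
#'
#' Finite-population counterpart of [ld_trajectory()]: each generation,
#' `2 * n_pop` gametes are formed by drawing two parental haplotypes from
#' the current pool and recombining them per interval (no interference,
#' the same gamete rule as [next_generation()]), then the pool is replaced
#' by the sample. Drift both erodes and creates disequilibrium.
#'
#' @param h0 Starting `hap_freq` tensor.
#' @param r A `recomb_rates` object.
#' @param n_pop Diploid population size (>= 2).
#' @param generations Number of generations (>= 1).
#' @param seed RNG seed (required).
#' @return A data frame like [ld_trajectory()]'s: per generation, realized
#'   haplotype frequencies and the derived decomposition.
#' @export
simulate_drift <- function(h0, r, n_pop, generations, seed) {
  stopifnot(inherits(r, "recomb_rates"), n_pop >= 2, generations >= 1)
  f8 <- as.vector(.as_hap(h0))
  alle <- .em_tables$hap_allele
  n_gam <- 2L * n_pop
  withr::with_seed(seed, {
    pool <- alle[sample.int(8, n_gam, replace = TRUE, prob = f8), ,
                 drop = FALSE]
    rows <- vector("list", generations + 1L)
    rows[[1]] <- .drift_row(0L, pool)
    for (t in seq_len(generations)) {
      p1 <- pool[sample.int(n_gam, n_gam, replace = TRUE), , drop = FALSE]
      p2 <- pool[sample.int(n_gam, n_gam, replace = TRUE), , drop = FALSE]
      pool <- .recombine_gametes(p1, p2, c(r$c_TM, r$c_MK))
      rows[[t + 1L]] <- .drift_row(t, pool)
    }
  })
  do.call(rbind, rows)
}

# form gametes from paired parental haplotype matrices (rows = gametes,
# cols = loci); switch the source chromosome at each interval with the
# interval's recombination fraction
.recombine_gametes <- function(p1, p2, c_int) {
  n <- nrow(p1)
  L <- ncol(p1)
  src <- matrix(0L, n, L)
  src[, 1] <- sample.int(2, n, replace = TRUE) - 1L
  for (l in 2:L) {
    flip <- stats::rbinom(n, 1, c_int[l - 1L])
    src[, l] <- (src[, l - 1L] + flip) %% 2L
  }
  out <- p1
  out[src == 1L] <- p2[src == 1L]
  out
}

.drift_row <- function(t, pool) {
  cell <- pool[, 1] + 2L * (pool[, 2] - 1L) + 4L * (pool[, 3] - 1L)
  f8 <- tabulate(cell, nbins = 8L) / nrow(pool)
  h <- hap_freq(array(f8, c(2, 2, 2)))
  v <- hap_vector(h)
  names(v) <- paste0("f", names(v))
  data.frame(t = t, as.list(v), as.list(unclass(haplotypes_to_params(h))))
}

#' Sample genotypes from an admixed gene pool
#'
#' Draws gametes from the tau-mixture of the two parental haplotype pools
#' (the admixed population one generation after crossing, mating at
#' random), so an EM fit on the output recovers [admix_closed_form()]'s
#' decomposition up to sampling error.
#'
#' @param s An `admix_scenario`.
#' @param N Number of diploid individuals.
#' @param seed RNG seed (required).
#' @return A `geno_counts` array.
#' @export
simulate_admixed_cohort <- function(s, N, seed) {
  stopifnot(inherits(s, "admix_scenario"))
  hx <- .as_hap(params_to_haplotypes(s$popX))
  hy <- .as_hap(params_to_haplotypes(s$popY))
  hz <- hap_freq(s$tau * hx + (1 - s$tau) * hy)
  sample_triplet_genotypes(hz, N, seed)
}

#' Generate a multi-chromosome SNP genotype panel
#'
#' Per chromosome, a pool of `pool_depth` founder haplotypes is drawn
#' (alleles i.i.d. with frequency `founder_maf`..0.5 of allele 2 per SNP);
#' each of the `2 * n_samples` sample gametes is a founder mosaic that
#' switches to a random founder with probability `switch_prob` at each
#' marker interval. Small pools give strong multi-locus LD; the mosaic
#' switching makes LD decay with distance; chromosomes are independent, so
#' inter-chromosomal LD is zero in expectation.
#'
#' @param n_chr Number of chromosomes.
#' @param snps_per_chr Integer vector (recycled) of SNPs per chromosome.
#' @param n_samples Number of diploid samples.
#' @param pool_depth Founder haplotypes per chromosome. Default 8.
#' @param switch_prob Per-interval mosaic switch probability (controls how
#'   fast LD decays with distance). Default 0.05.
#' @param spacing_bp Mean spacing between consecutive SNPs in bp (spacings
#'   are drawn uniformly in 0.5..1.5 times this). Default 92600, a typical
#'   medium-density pig array spacing.
#' @param founder_maf Lower bound of the per-SNP allele-2 frequency used
#'   to draw founder alleles. Default 0.2.
#' @param seed RNG seed (required).
#' @return A list: `panel` (a `geno_panel`, see [genotype_panel()]) and
#'   `pools` (per-chromosome founder haplotype matrices, the truth for
#'   oracle checks).
#' @export
generate_panel <- function(n_chr, snps_per_chr, n_samples, pool_depth = 8,
                           switch_prob = 0.05, spacing_bp = 92600,
                           founder_maf = 0.2, seed) {
  stopifnot(n_chr >= 1, n_samples >= 1, pool_depth >= 1)
  snps_per_chr <- rep_len(snps_per_chr, n_chr)
  withr::with_seed(seed, {
    maps <- list()
    genos <- list()
    pools <- list()
    for (ch in seq_len(n_chr)) {
      S <- snps_per_chr[ch]
      p2 <- stats::runif(S, founder_maf, 0.5)
      pool <- matrix(1L + (stats::runif(pool_depth * S) < rep(p2,
        each = pool_depth)), pool_depth, S)
      gam <- .founder_mosaic(pool, 2L * n_samples, switch_prob)
      g1 <- gam[seq_len(n_samples), , drop = FALSE]
      g2 <- gam[n_samples + seq_len(n_samples), , drop = FALSE]
      codes <- matrix(3L, n_samples, S)
      codes[g1 == g2] <- g1[g1 == g2]
      pos <- cumsum(round(stats::runif(S, 0.5, 1.5) * spacing_bp))
      maps[[ch]] <- data.frame(
        chr = as.character(ch),
        snp = sprintf("chr%d_snp%d", ch, seq_len(S)),
        pos = pos,
        a1 = "A", a2 = "B",
        stringsAsFactors = FALSE
      )
      genos[[ch]] <- codes
      pools[[ch]] <- pool
    }
    map <- do.call(rbind, maps)
    geno <- do.call(cbind, genos)
  })
  colnames(geno) <- map$snp
  panel <- genotype_panel(map, geno,
                          samples = sprintf("ind%04d", seq_len(n_samples)))
  list(panel = panel, pools = pools)
}

# sample gametes as founder mosaics: start from a random founder row and
# switch to a (uniformly) random founder with prob switch_prob per interval
.founder_mosaic <- function(pool, n_gametes, switch_prob) {
  S <- ncol(pool)
  depth <- nrow(pool)
  id <- matrix(0L, n_gametes, S)
  id[, 1] <- sample.int(depth, n_gametes, replace = TRUE)
  if (S > 1) {
    for (l in 2:S) {
      sw <- stats::runif(n_gametes) < switch_prob
      id[, l] <- ifelse(sw, sample.int(depth, n_gametes, replace = TRUE),
                        id[, l - 1L])
    }
  }
  out <- matrix(0L, n_gametes, S)
  for (l in seq_len(S)) out[, l] <- pool[id[, l], l]
  out
}
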