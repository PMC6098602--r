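# Deterministic break-up of three-locus LD by recombination.
#
# Infinite population, random mating, no interference: the two marker
# intervals recombine independently with fractions c_TM and c_MK. Each
# generation a gamete keeps its parental three-locus haplotype with
# probability (1-c_TM)(1-c_MK); otherwise it recombines one or both
# intervals, splicing in two-locus or single-locus marginal frequencies.
# Allele frequencies are conserved exactly; all disequilibria decay.

#' Recombination fractions for a marker triplet
#'
#' @param c_TM Recombination fraction between the first and second locus.
#' @param c_MK Recombination fraction between the second and third locus.
#' @return A list of class `recomb_rates`.
#' @export
recomb_rates <- function(c_TM, c_MK) {
  stopifnot(is.numeric(c_TM), is.numeric(c_MK),
            c_TM >= 0, c_TM <= 0.5, c_MK >= 0, c_MK <= 0.5)
  structure(list(c_TM = c_TM, c_MK = c_MK), class = "recomb_rates")
}

#' One generation of random mating with recombination
#'
#' Applies the no-interference recursion
#' `f'[ijk] = (1-cTM)(1-cMK) f[ijk] + cTM (1-cMK) f[i..] f[.jk]
#'  + cMK (1-cTM) f[ij.] f[..k] + cTM cMK f[i..] f[.j.] f[..k]`.
#'
#' @param h A `hap_freq` tensor.
#' @param r A `recomb_rates` object.
#' @return The next generation's `hap_freq` tensor. Marginal allele
#'   frequencies are preserved exactly.
#' @export
next_generation <- function(h, r) {
  stopifnot(inherits(r, "recomb_rates"))
  f <- .as_hap(h)
  cTM <- r$c_TM
  cMK <- r$c_MK
  fT <- apply(f, 1, sum)        # f[i..]
  fM <- apply(f, 2, sum)        # f[.j.]
  fK <- apply(f, 3, sum)        # f[..k]
  fTM <- apply(f, c(1, 2), sum) # f[ij.]
  fMK <- apply(f, c(2, 3), sum) # f[.jk]
  out <- array(0, c(2, 2, 2))
  for (i in 1:2) for (j in 1:2) for (k in 1:2) {
    out[i, j, k] <-
      (1 - cTM) * (1 - cMK) * f[i, j, k] +
      cTM * (1 - cMK) * fT[i] * fMK[j, k] +
      cMK * (1 - cTM) * fTM[i, j] * fK[k] +
      cTM * cMK * fT[i] * fM[j] * fK[k]
  }
  # guard against float drift of the simplex sum over long trajectories
  hap_freq(out / sum(out))
}

#' Multi-generation LD trajectory under recombination
#'
#' Iterates [next_generation()] and records the haplotype frequencies and
#' the full LD decomposition each generation.
#'
#' @param h0 Starting `hap_freq` tensor (generation 0).
#' @param r A `recomb_rates` object.
#' @param generations Number of generations to iterate (>= 0).
#' @return A data frame with one row per generation `t = 0..generations`:
#'   the eight haplotype frequencies (lexicographic columns `f111..f222`)
#'   and the seven decomposition parameters.
#' @examples
#' h0 <- params_to_haplotypes(ld_decomp(0.5, 0.5, 0.5, d_TMK = 0.125))
#' tr <- ld_trajectory(h0, recomb_rates(0.1, 0.1), 10)
#' tr$d_TMK / tr$d_TMK[1] # (0.9 * 0.9)^t
#' @export
ld_trajectory <- function(h0, r, generations) {
  stopifnot(generations >= 0)
  h <- hap_freq(.as_hap(h0))
  rows <- vector("list", generations + 1L)
  for (t in 0:generations) {
    v <- hap_vector(h)
    names(v) <- paste0("f", names(v))
    p <- haplotypes_to_params(h)
    rows[[t + 1L]] <- data.frame(t = t, as.list(v), as.list(unclass(p)))
    if (t < generations) h <- next_generation(h, r)
  }
  do.call(rbind, rows)
}
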