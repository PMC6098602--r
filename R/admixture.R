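# Generation of third-order LD by crossing two populations.
#
# When a fraction tau of the admixed gene pool comes from population X and
# 1 - tau from population Y, every haplotype frequency in the cross Z is
# the tau-weighted average of the parental frequencies. Differences in
# allele frequency (gamma_L = f_L^X - f_L^Y) create pairwise LD in Z, and
# differences in allele frequency together with differences in pairwise LD
# create third-order LD even when neither parent has any.

#' Define a two-population admixture scenario
#'
#' @param popX,popY Parental populations as `ld_decomp` objects.
#' @param tau Mixing proportion contributed by `popX`, in \[0, 1\].
#' @param validate Require both parents to imply non-negative haplotype
#'   frequencies (default). With `FALSE` the admixture algebra is evaluated
#'   formally on the decomposition parameters, which is how published
#'   illustration grids sometimes use it.
#' @return A list of class `admix_scenario`.
#' @export
admix_scenario <- function(popX, popY, tau, validate = TRUE) {
  stopifnot(is.numeric(tau), length(tau) == 1L, tau >= 0, tau <= 1)
  if (validate) {
    # both parents must be valid decompositions
    params_to_haplotypes(popX)
    params_to_haplotypes(popY)
  }
  structure(list(popX = .as_decomp(popX), popY = .as_decomp(popY), tau = tau,
                 validate = validate),
            class = "admix_scenario")
}

#' Admixture LD by the closed-form expressions
#'
#' Computes the full decomposition of the cross: allele frequencies are
#' tau-weighted averages; pairwise LD follows the classical admixture
#' formula `d^Z = tau d^X + (1-tau) d^Y + tau (1-tau) gamma gamma`; the
#' third-order coefficient is the mixed three-locus haplotype frequency
#' minus the allele-frequency product and the pairwise terms of the cross.
#'
#' @param s An `admix_scenario`.
#' @return The cross's `ld_decomp`.
#' @examples
#' X <- ld_decomp(0.5, 0.5, 0.5, 0.25, 0.25, 0.25)
#' Y <- ld_decomp(0.2, 0.2, 0.2)
#' admix_closed_form(admix_scenario(X, Y, 0.5))["d_TMK"] # 0.05625
#' @export
admix_closed_form <- function(s) {
  stopifnot(inherits(s, "admix_scenario"))
  x <- s$popX
  y <- s$popY
  tau <- s$tau
  g_T <- x[["f_T"]] - y[["f_T"]]
  g_M <- x[["f_M"]] - y[["f_M"]]
  g_K <- x[["f_K"]] - y[["f_K"]]
  f_T <- tau * x[["f_T"]] + (1 - tau) * y[["f_T"]]
  f_M <- tau * x[["f_M"]] + (1 - tau) * y[["f_M"]]
  f_K <- tau * x[["f_K"]] + (1 - tau) * y[["f_K"]]
  d_MK <- tau * x[["d_MK"]] + (1 - tau) * y[["d_MK"]] +
    tau * (1 - tau) * g_M * g_K
  d_TK <- tau * x[["d_TK"]] + (1 - tau) * y[["d_TK"]] +
    tau * (1 - tau) * g_T * g_K
  d_TM <- tau * x[["d_TM"]] + (1 - tau) * y[["d_TM"]] +
    tau * (1 - tau) * g_T * g_M
  d_TMK <-
    tau * (x[["f_T"]] * x[["f_M"]] * x[["f_K"]] +
             x[["f_T"]] * x[["d_MK"]] + x[["f_M"]] * x[["d_TK"]] +
             x[["f_K"]] * x[["d_TM"]] + x[["d_TMK"]]) +
    (1 - tau) * (y[["f_T"]] * y[["f_M"]] * y[["f_K"]] +
                   y[["f_T"]] * y[["d_MK"]] + y[["f_M"]] * y[["d_TK"]] +
                   y[["f_K"]] * y[["d_TM"]] + y[["d_TMK"]]) -
    f_T * f_M * f_K - f_T * d_MK - f_M * d_TK - f_K * d_TM
  ld_decomp(f_T, f_M, f_K, d_TM, d_TK, d_MK, d_TMK,
            validate = isTRUE(s$validate))
}

#' Admixture LD by haplotype mixing
#'
#' Mixes all eight parental haplotype frequencies
#' (`f^Z = tau f^X + (1-tau) f^Y`) and re-derives the decomposition. This
#' is an independent route to the same quantity as [admix_closed_form()]
#' and is used as its oracle in the test suite: the two must agree to
#' numerical precision.
#'
#' @param s An `admix_scenario`.
#' @return The cross's `ld_decomp`.
#' @export
admix_via_haplotypes <- function(s) {
  stopifnot(inherits(s, "admix_scenario"))
  if (isTRUE(s$validate)) {
    hx <- .as_hap(params_to_haplotypes(s$popX))
    hy <- .as_hap(params_to_haplotypes(s$popY))
    haplotypes_to_params(hap_freq(s$tau * hx + (1 - s$tau) * hy))
  } else {
    # formal evaluation: mix the affine expansions without simplex checks
    hz <- s$tau * .hap_raw(s$popX) + (1 - s$tau) * .hap_raw(s$popY)
    .params_from_raw(hz)
  }
}

#' Reference grid of admixture scenarios
#'
#' Nine canonical scenarios (equal mixing, no third-order LD in either
#' parent) illustrating when admixture does and does not generate
#' third-order LD: parents must differ both in allele frequencies and in
#' pairwise LD. Returns inputs and the generated third-order coefficient.
#'
#' @param digits Decimal places for the printed `d_TMK_Z_rounded` column
#'   (full precision is kept in `d_TMK_Z`). Default 3.
#' @return A data frame with one row per scenario: parental allele
#'   frequencies, parental pairwise LD, and the cross's `d_TMK`.
#' @export
admix_reference_table <- function(digits = 3) {
  rows <- list(
    # fX (T,M,K), fY, dX (MK,TK,TM), dY
    list(c(0.8, 0.8, 0.8), c(0.2, 0.2, 0.2), c(0, 0, 0), c(0, 0, 0)),
    list(c(0.8, 0.2, 0.8), c(0.2, 0.8, 0.2), c(0, 0, 0), c(0, 0, 0)),
    list(c(0.5, 0.5, 0.5), c(0.5, 0.5, 0.5), c(0.25, 0.25, 0.25), c(0, 0, 0)),
    list(c(0.5, 0.5, 0.5), c(0.5, 0.5, 0.5), c(0.25, 0.25, 0), c(0, 0, 0)),
    list(c(0.5, 0.5, 0.5), c(0.5, 0.5, 0.5), c(0.25, 0, 0), c(0, 0, 0)),
    list(c(0.5, 0.5, 0.5), c(0.2, 0.2, 0.2), c(0.25, 0.25, 0.25), c(0, 0, 0)),
    list(c(0.5, 0.5, 0.5), c(0.2, 0.2, 0.2), c(0.25, 0.25, 0), c(0, 0, 0)),
    list(c(0.5, 0.5, 0.5), c(0.1, 0.1, 0.1), c(0.25, 0.25, 0.25), c(0, 0, 0)),
    list(c(0.5, 0.5, 0.5), c(0.01, 0.01, 0.01), c(0.25, 0.25, 0.25), c(0, 0, 0))
  )
  out <- do.call(rbind, lapply(rows, function(r) {
    # validate = FALSE: two of the canonical scenarios pair pairwise LD
    # values that admit no non-negative haplotype distribution; the
    # admixture algebra is evaluated formally there (see vignette)
    X <- ld_decomp(r[[1]][1], r[[1]][2], r[[1]][3],
                   d_MK = r[[3]][1], d_TK = r[[3]][2], d_TM = r[[3]][3],
                   validate = FALSE)
    Y <- ld_decomp(r[[2]][1], r[[2]][2], r[[2]][3],
                   d_MK = r[[4]][1], d_TK = r[[4]][2], d_TM = r[[4]][3],
                   validate = FALSE)
    z <- admix_closed_form(admix_scenario(X, Y, 0.5, validate = FALSE))
    data.frame(
      fT_X = r[[1]][1], fM_X = r[[1]][2], fK_X = r[[1]][3],
      fT_Y = r[[2]][1], fM_Y = r[[2]][2], fK_Y = r[[2]][3],
      dMK_X = r[[3]][1], dTK_X = r[[3]][2], dTM_X = r[[3]][3],
      dMK_Y = r[[4]][1], dTK_Y = r[[4]][2], dTM_Y = r[[4]][3],
      d_TMK_Z = z[["d_TMK"]]
    )
  }))
  out$d_TMK_Z_rounded <- round(out$d_TMK_Z, digits)
  out
}
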