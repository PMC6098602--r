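# Canonical parameterization of a three-biallelic-locus system.
#
# A haplotype over loci T/t, M/m, K/k is indexed (i, j, k) with allele index
# 1 = first-listed allele (A1 in .ped/.map, REF in VCF) and 2 = the other.
# Writing s(1) = +1, s(2) = -1, the eight haplotype frequencies decompose as
#
#   f[ijk] = a_i b_j c_k + a_i s_j s_k dMK + b_j s_i s_k dTK
#            + c_k s_i s_j dTM + s_i s_j s_k dTMK
#
# where a, b, c are the marginal allele frequencies at the three loci. All
# delta signs are orientation-dependent: relabeling alleles at one locus
# negates dTMK and the two pairwise deltas involving that locus.

.HAP_SIGN <- c(1, -1)

# 2x2x2 array of s_i*s_j*s_k, the coefficient of dTMK for each haplotype
.sign3 <- function() {
  outer(outer(.HAP_SIGN, .HAP_SIGN), .HAP_SIGN)
}

.hap_dimnames <- list(T = c("1", "2"), M = c("1", "2"), K = c("1", "2"))

# raw affine expansion of the decomposition; no validation
.hap_raw <- function(p) {
  a <- c(p[["f_T"]], 1 - p[["f_T"]])
  b <- c(p[["f_M"]], 1 - p[["f_M"]])
  cc <- c(p[["f_K"]], 1 - p[["f_K"]])
  s <- .HAP_SIGN
  f <- array(0, c(2, 2, 2))
  for (i in 1:2) for (j in 1:2) for (k in 1:2) {
    f[i, j, k] <- a[i] * b[j] * cc[k] +
      a[i] * s[j] * s[k] * p[["d_MK"]] +
      b[j] * s[i] * s[k] * p[["d_TK"]] +
      cc[k] * s[i] * s[j] * p[["d_TM"]] +
      s[i] * s[j] * s[k] * p[["d_TMK"]]
  }
  f
}

#' Construct an LD decomposition of a three-locus system
#'
#' Bundles the seven parameters that determine the eight haplotype
#' frequencies of three biallelic loci: three allele frequencies (of the
#' first-listed allele), three pairwise linkage-disequilibrium coefficients
#' and one third-order coefficient.
#'
#' @param f_T,f_M,f_K Allele frequency of allele 1 at each locus, in \[0,1\].
#' @param d_TM,d_TK,d_MK Pairwise LD coefficients (two-locus haplotype
#'   frequency minus the product of allele frequencies), each in
#'   \[-0.25, 0.25\].
#' @param d_TMK Third-order LD coefficient, in \[-0.125, 0.125\].
#' @param validate If `TRUE` (default), check that the implied haplotype
#'   frequencies are a valid probability distribution.
#' @return A named numeric vector of class `ld_decomp` with elements
#'   `f_T, f_M, f_K, d_TM, d_TK, d_MK, d_TMK`.
#' @examples
#' d <- ld_decomp(0.5, 0.5, 0.5, d_TMK = 0.125)
#' params_to_haplotypes(d)
#' @export
ld_decomp <- function(f_T, f_M, f_K, d_TM = 0, d_TK = 0, d_MK = 0,
                      d_TMK = 0, validate = TRUE) {
  x <- c(f_T = f_T, f_M = f_M, f_K = f_K,
         d_TM = d_TM, d_TK = d_TK, d_MK = d_MK, d_TMK = d_TMK)
  stopifnot(length(x) == 7L, all(is.finite(x)))
  class(x) <- "ld_decomp"
  if (validate) {
    params_to_haplotypes(x) # errors if any implied frequency is out of range
  }
  x
}

#' @export
print.ld_decomp <- function(x, digits = 6, ...) {
  cat("Three-locus LD decomposition:\n")
  print(round(unclass(x), digits))
  invisible(x)
}

.as_decomp <- function(d) {
  if (inherits(d, "ld_decomp")) return(unclass(d))
  d <- unclass(d)
  stopifnot(is.numeric(d), length(d) == 7L)
  names(d) <- c("f_T", "f_M", "f_K", "d_TM", "d_TK", "d_MK", "d_TMK")
  d
}

#' Construct/validate a haplotype-frequency tensor
#'
#' @param x A 2x2x2 numeric array, or a numeric vector of length 8 in
#'   lexicographic allele order (111, 112, 121, 122, 211, 212, 221, 222,
#'   axes ordered T, M, K).
#' @param tol Tolerance for the simplex check (entries >= -tol, sum within
#'   `tol` of 1). Default 1e-9.
#' @return A 2x2x2 array of class `hap_freq`, dimnames `T`, `M`, `K`.
#' @examples
#' hap_freq(rep(1 / 8, 8))
#' @export
hap_freq <- function(x, tol = 1e-9) {
  if (is.numeric(x) && is.null(dim(x)) && length(x) == 8L) {
    # lexicographic order has the K index fastest; fill and transpose
    a <- aperm(array(x, c(2, 2, 2)), c(3, 2, 1))
  } else if (is.array(x) && all(dim(x) == c(2, 2, 2))) {
    a <- x
  } else {
    stop("haplotype frequencies must be a 2x2x2 array or a length-8 vector")
  }
  storage.mode(a) <- "double"
  if (any(a < -tol) || any(a > 1 + tol)) {
    stop("haplotype frequencies outside [0, 1]")
  }
  if (abs(sum(a) - 1) > tol) {
    stop(sprintf("haplotype frequencies sum to %.12g, not 1", sum(a)))
  }
  a[a < 0] <- 0
  dimnames(a) <- .hap_dimnames
  class(a) <- c("hap_freq", "array")
  a
}

.as_hap <- function(h, tol = 1e-9) {
  if (!inherits(h, "hap_freq")) h <- hap_freq(h, tol = tol)
  unclass(h)
}

#' Flatten a haplotype tensor to lexicographic order
#'
#' @param h A `hap_freq` tensor (or coercible input).
#' @return Named numeric vector, order 111, 112, ..., 222 (axes T, M, K).
#' @export
hap_vector <- function(h) {
  a <- .as_hap(h)
  v <- as.vector(aperm(a, c(3, 2, 1)))
  g <- expand.grid(k = 1:2, m = 1:2, t = 1:2)
  names(v) <- paste0(g$t, g$m, g$k)
  v
}

#' Haplotype frequencies from the LD decomposition
#'
#' Expands the seven-parameter decomposition into the eight haplotype
#' frequencies. Each frequency is the triple product of marginal allele
#' frequencies plus signed pairwise terms plus the signed third-order term.
#'
#' @param d An `ld_decomp` (or numeric vector of its 7 elements).
#' @param tol Tolerance below 0 / above 1 at which an implied frequency is
#'   an error rather than rounded. Default 1e-12.
#' @return A `hap_freq` tensor.
#' @export
params_to_haplotypes <- function(d, tol = 1e-12) {
  p <- .as_decomp(d)
  if (any(p[1:3] < -tol) || any(p[1:3] > 1 + tol)) {
    stop("allele frequencies outside [0, 1]")
  }
  f <- .hap_raw(p)
  bad <- which(f < -tol | f > 1 + tol, arr.ind = TRUE)
  if (nrow(bad) > 0) {
    lab <- paste(bad[1, ], collapse = "")
    stop(sprintf(
      "invalid decomposition: implied frequency of haplotype %s is %.6g",
      lab, f[bad[1, , drop = FALSE]]))
  }
  hap_freq(f, tol = 1e-9)
}

#' LD decomposition from haplotype frequencies
#'
#' Inverts [params_to_haplotypes()]: allele frequencies are marginal sums,
#' each pairwise coefficient is a two-locus haplotype frequency minus the
#' product of its allele frequencies, and the third-order coefficient is
#' the residual of the three-locus frequency after removing the allele
#' frequency product and the pairwise terms.
#'
#' @param h A `hap_freq` tensor (or coercible input).
#' @param tol Simplex validation tolerance (default 1e-9).
#' @return An `ld_decomp`.
#' @export
haplotypes_to_params <- function(h, tol = 1e-9) {
  .params_from_raw(.as_hap(h, tol = tol))
}

# decomposition arithmetic on a raw 2x2x2 array; no simplex validation
.params_from_raw <- function(f) {
  f_T <- sum(f[1, , ])
  f_M <- sum(f[, 1, ])
  f_K <- sum(f[, , 1])
  d_TM <- sum(f[1, 1, ]) - f_T * f_M
  d_TK <- sum(f[1, , 1]) - f_T * f_K
  d_MK <- sum(f[, 1, 1]) - f_M * f_K
  d_TMK <- f[1, 1, 1] - f_T * f_M * f_K -
    f_T * d_MK - f_M * d_TK - f_K * d_TM
  out <- c(f_T = f_T, f_M = f_M, f_K = f_K,
           d_TM = d_TM, d_TK = d_TK, d_MK = d_MK, d_TMK = d_TMK)
  class(out) <- "ld_decomp"
  out
}

#' Admissible range of the third-order LD coefficient
#'
#' Given allele frequencies and the three pairwise coefficients, each
#' haplotype frequency is affine in the third-order coefficient with slope
#' +1 or -1, so requiring all eight frequencies to be non-negative yields a
#' closed-form interval.
#'
#' @param f_T,f_M,f_K Allele frequencies.
#' @param d_TM,d_TK,d_MK Pairwise LD coefficients.
#' @return A list with elements `lower` and `upper`.
#' @examples
#' delta3_bounds(0.5, 0.5, 0.5, 0, 0, 0) # [-0.125, 0.125]
#' @export
delta3_bounds <- function(f_T, f_M, f_K, d_TM = 0, d_TK = 0, d_MK = 0) {
  p <- c(f_T = f_T, f_M = f_M, f_K = f_K,
         d_TM = d_TM, d_TK = d_TK, d_MK = d_MK, d_TMK = 0)
  # constant (dTMK-free) part of each haplotype frequency
  konst <- .hap_raw(p)
  s3 <- .sign3()
  lower <- max(-konst[s3 > 0])
  upper <- min(konst[s3 < 0])
  if (lower > upper + 1e-12) {
    stop("infeasible pairwise system: no admissible third-order coefficient")
  }
  list(lower = lower, upper = upper)
}

#' Normalized third-order LD (range-based)
#'
#' Rescales the observed third-order coefficient by the admissible range of
#' its sign, given the allele frequencies and pairwise coefficients: the
#' amount by which the observed value exceeds the minimum possible of its
#' sign, divided by the length of the admissible range with that sign.
#' When the whole admissible interval collapses to a single point the
#' normalization is undefined (`undefined_single_value`): the coefficient
#' can take only one value, so no relative position exists.
#'
#' @param d An `ld_decomp`.
#' @param tol Width below which the admissible range counts as a single
#'   value, and distance from an endpoint at which the result is classified
#'   `plus_one`/`minus_one`/`zero`. Default 1e-9.
#' @return A list with `category` (one of `undefined_single_value`, `zero`,
#'   `plus_one`, `minus_one`, `interior`), `value` (the signed normalized
#'   coefficient, `NA` when undefined), `beta` (see [beta_proportion()]),
#'   and the `lower`/`upper` bounds used.
#' @export
normalize_robinson <- function(d, tol = 1e-9) {
  p <- .as_decomp(d)
  b <- delta3_bounds(p[["f_T"]], p[["f_M"]], p[["f_K"]],
                     p[["d_TM"]], p[["d_TK"]], p[["d_MK"]])
  bt <- beta_proportion(d)
  res <- function(category, value) {
    list(category = category, value = value, beta = bt,
         lower = b$lower, upper = b$upper)
  }
  if (b$upper - b$lower < tol) {
    return(res("undefined_single_value", NA_real_))
  }
  x <- p[["d_TMK"]]
  if (abs(x) < tol) return(res("zero", 0))
  if (x > 0) {
    lo <- max(0, b$lower)
    hi <- b$upper
    if (hi - lo < tol) return(res("undefined_single_value", NA_real_))
    v <- (x - lo) / (hi - lo)
    if (abs(v - 1) < tol) return(res("plus_one", 1))
  } else {
    hi <- min(0, b$upper)
    lo <- b$lower
    if (hi - lo < tol) return(res("undefined_single_value", NA_real_))
    v <- (x - hi) / (hi - lo) # signed: -1 at the lower extreme
    if (abs(v + 1) < tol) return(res("minus_one", -1))
  }
  res("interior", v)
}

#' Proportion of third-order versus total disequilibrium
#'
#' `|dTMK| / (|dTMK| + |dTM| + |dMK| + |dTK|)`: 1 means all disequilibrium
#' is third order, 0 means all is second order. Undefined (returns `NA`)
#' when all four coefficients are zero.
#'
#' @param d An `ld_decomp`.
#' @param tol All-zero tolerance, default 1e-12.
#' @return A number in \[0, 1\], or `NA_real_` when undefined.
#' @export
beta_proportion <- function(d, tol = 1e-12) {
  p <- .as_decomp(d)
  denom <- abs(p[["d_TMK"]]) + abs(p[["d_TM"]]) +
    abs(p[["d_MK"]]) + abs(p[["d_TK"]])
  if (denom < tol) return(NA_real_)
  abs(p[["d_TMK"]]) / denom
}

#' Number of segregating haplotypes
#'
#' @param h A `hap_freq` tensor.
#' @param tol Frequencies at or below `tol` count as absent. Default 1e-9.
#' @return Integer in 1..8.
#' @export
count_segregating_haplotypes <- function(h, tol = 1e-9) {
  sum(.as_hap(h) > tol)
}

# ---- plain-text parameter files ------------------------------------------

#' Read/write decomposition parameter files
#'
#' One decomposition per line, whitespace-separated:
#' `fT fM fK dTM dTK dMK dTMK`. Lines starting with `#` are skipped.
#'
#' @param path File path.
#' @return `read_ld_decomp`: a list of `ld_decomp` objects.
#' @export
read_ld_decomp <- function(path) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  lapply(seq_along(lines), function(i) {
    x <- suppressWarnings(as.numeric(strsplit(lines[i], "[[:space:]]+")[[1]]))
    if (length(x) != 7L || anyNA(x)) {
      stop(sprintf("malformed decomposition on line %d of %s", i, path))
    }
    ld_decomp(x[1], x[2], x[3], x[4], x[5], x[6], x[7])
  })
}

#' @rdname read_ld_decomp
#' @param decomps A list of `ld_decomp` objects (or a single one).
#' @export
write_ld_decomp <- function(decomps, path) {
  if (inherits(decomps, "ld_decomp")) decomps <- list(decomps)
  lines <- vapply(decomps, function(d) {
    paste(format(unclass(.as_decomp(d)), digits = 17, trim = TRUE),
          collapse = " ")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read/write haplotype-frequency files
#'
#' Eight labeled values, one `label value` pair per line, labels in
#' lexicographic allele order (111, 112, 121, 122, 211, 212, 221, 222).
#'
#' @param path File path.
#' @return `read_hap_freq`: a `hap_freq` tensor.
#' @export
read_hap_freq <- function(path) {
  tab <- utils::read.table(path, header = FALSE,
                           col.names = c("hap", "freq"),
                           colClasses = c("character", "numeric"))
  want <- names(hap_vector(hap_freq(rep(1 / 8, 8))))
  if (!setequal(tab$hap, want)) {
    stop("haplotype file must label exactly the 8 haplotypes 111..222")
  }
  hap_freq(tab$freq[match(want, tab$hap)])
}

#' @rdname read_hap_freq
#' @param h A `hap_freq` tensor.
#' @export
write_hap_freq <- function(h, path) {
  v <- hap_vector(h)
  writeLines(paste(names(v), format(v, digits = 17, trim = TRUE)), path)
  invisible(path)
}
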