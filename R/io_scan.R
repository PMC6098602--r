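# SNP panel container, PLINK .ped/.map and VCF input, QC filtering, and
# the three triplet scan designs (consecutive, inter-chromosomal, rolling
# window) with per-triplet EM estimation.

#' SNP genotype panel
#'
#' Container for a biallelic SNP panel: a map (chromosome, SNP id,
#' position, the two allele labels) and a samples x SNPs matrix of
#' per-locus genotype codes (1 = homozygote for allele 1, 2 = homozygote
#' for allele 2, 3 = heterozygote, `NA` = missing). Allele 1 is the
#' first-listed allele of the input (A1 column order in .ped, REF in VCF),
#' so all delta signs are orientation-dependent.
#'
#' @param map Data frame with columns `chr`, `snp`, `pos`, `a1`, `a2`.
#' @param geno Integer matrix, rows = samples, columns = SNPs (same order
#'   as `map`), entries in \{1, 2, 3, NA\}.
#' @param samples Character vector of sample identifiers.
#' @return A list of class `geno_panel`. SNPs are sorted by chromosome and
#'   position; duplicate positions within a chromosome are an error.
#' @export
genotype_panel <- function(map, geno, samples = NULL) {
  stopifnot(is.data.frame(map),
            all(c("chr", "snp", "pos", "a1", "a2") %in% names(map)),
            is.matrix(geno), ncol(geno) == nrow(map))
  if (is.null(samples)) samples <- sprintf("sample%d", seq_len(nrow(geno)))
  stopifnot(length(samples) == nrow(geno))
  ok <- geno %in% c(1L, 2L, 3L) | is.na(geno)
  if (!all(ok)) stop("genotype codes must be 1, 2, 3 or NA")
  ord <- order(map$chr, map$pos)
  map <- map[ord, , drop = FALSE]
  geno <- geno[, ord, drop = FALSE]
  dup <- stats::ave(map$pos, map$chr, FUN = function(p) duplicated(p)) > 0
  if (any(dup)) {
    stop(sprintf("duplicate position within a chromosome (SNP %s)",
                 map$snp[which(dup)[1]]))
  }
  rownames(map) <- NULL
  colnames(geno) <- map$snp
  rownames(geno) <- samples
  structure(list(map = map, geno = geno, samples = samples),
            class = "geno_panel")
}

#' @export
print.geno_panel <- function(x, ...) {
  cat(sprintf("SNP panel: %d samples x %d SNPs on %d chromosome(s)\n",
              length(x$samples), nrow(x$map), length(unique(x$map$chr))))
  invisible(x)
}

#' Read a SNP panel from PLINK .ped/.map or VCF
#'
#' For `format = "pedmap"`, `path` is the file prefix (reads `path.ped`
#' and `path.map`); allele 1 of each SNP is the first non-missing allele
#' label encountered in the .ped file. For `format = "vcf"` (requires the
#' VariantAnnotation package), REF maps to allele 1; non-biallelic sites
#' are dropped with a warning.
#'
#' @param path File prefix (pedmap) or file path (vcf).
#' @param format `"pedmap"` or `"vcf"`.
#' @return A `geno_panel`.
#' @export
read_panel <- function(path, format = c("pedmap", "vcf")) {
  format <- match.arg(format)
  if (format == "pedmap") .read_pedmap(path) else .read_vcf(path)
}

.read_pedmap <- function(prefix) {
  map_path <- paste0(prefix, ".map")
  ped_path <- paste0(prefix, ".ped")
  if (!file.exists(map_path) || !file.exists(ped_path)) {
    stop(sprintf("missing %s.map or %s.ped", prefix, prefix))
  }
  map_raw <- utils::read.table(map_path, header = FALSE,
                               colClasses = c("character", "character",
                                              "numeric", "numeric"))
  names(map_raw) <- c("chr", "snp", "cm", "pos")
  S <- nrow(map_raw)
  lines <- readLines(ped_path)
  lines <- lines[nzchar(trimws(lines))]
  toks <- strsplit(trimws(lines), "[[:space:]]+")
  nfield <- 6L + 2L * S
  samples <- character(length(toks))
  allele <- matrix(NA_character_, length(toks), 2L * S)
  for (i in seq_along(toks)) {
    if (length(toks[[i]]) != nfield) {
      stop(sprintf("malformed .ped line %d: %d fields, expected %d",
                   i, length(toks[[i]]), nfield))
    }
    samples[i] <- toks[[i]][2]
    allele[i, ] <- toks[[i]][-(1:6)]
  }
  allele[allele %in% c("0", "-9", ".", "N")] <- NA_character_
  geno <- matrix(NA_integer_, length(toks), S)
  a1 <- character(S)
  a2 <- character(S)
  for (s in seq_len(S)) {
    al <- allele[, c(2 * s - 1, 2 * s), drop = FALSE]
    labs <- unique(stats::na.omit(as.vector(t(al)))) # first-listed order
    if (length(labs) > 2) {
      stop(sprintf("SNP %s has %d allele labels; biallelic input required",
                   map_raw$snp[s], length(labs)))
    }
    a1[s] <- if (length(labs) >= 1) labs[1] else NA_character_
    a2[s] <- if (length(labs) == 2) labs[2] else NA_character_
    miss <- is.na(al[, 1]) | is.na(al[, 2])
    code <- ifelse(al[, 1] == al[, 2],
                   ifelse(al[, 1] == a1[s], 1L, 2L), 3L)
    code[miss] <- NA_integer_
    geno[, s] <- code
  }
  map <- data.frame(chr = map_raw$chr, snp = map_raw$snp, pos = map_raw$pos,
                    a1 = a1, a2 = a2, stringsAsFactors = FALSE)
  genotype_panel(map, geno, samples)
}

.read_vcf <- function(path) {
  if (!requireNamespace("VariantAnnotation", quietly = TRUE)) {
    stop("reading VCF requires the VariantAnnotation package")
  }
  vcf <- VariantAnnotation::readVcf(path)
  alt <- VariantAnnotation::alt(vcf)
  biallelic <- lengths(alt) == 1L
  n_drop <- sum(!biallelic)
  if (n_drop > 0) {
    warning(sprintf("dropped %d non-biallelic site(s)", n_drop))
    vcf <- vcf[biallelic]
  }
  gt <- VariantAnnotation::geno(vcf)$GT
  rr <- SummarizedExperiment::rowRanges(vcf)
  code1 <- c("0/0" = 1L, "0|0" = 1L, "1/1" = 2L, "1|1" = 2L,
             "0/1" = 3L, "0|1" = 3L, "1/0" = 3L, "1|0" = 3L)
  geno <- matrix(code1[as.vector(gt)], nrow = nrow(gt), ncol = ncol(gt))
  map <- data.frame(
    chr = as.character(GenomicRanges::seqnames(rr)),
    snp = rownames(gt),
    pos = GenomicRanges::start(rr),
    a1 = as.character(VariantAnnotation::ref(vcf)),
    a2 = vapply(as(VariantAnnotation::alt(vcf), "CharacterList"),
                `[`, character(1), 1),
    stringsAsFactors = FALSE
  )
  genotype_panel(map, t(geno), samples = colnames(gt))
}

#' Write a panel as PLINK .ped/.map
#'
#' @param panel A `geno_panel`.
#' @param prefix Output file prefix (writes `prefix.ped`, `prefix.map`).
#' @export
write_panel <- function(panel, prefix) {
  stopifnot(inherits(panel, "geno_panel"))
  map <- panel$map
  utils::write.table(
    data.frame(map$chr, map$snp, 0, map$pos),
    paste0(prefix, ".map"),
    quote = FALSE, row.names = FALSE, col.names = FALSE, sep = "\t")
  g <- panel$geno
  S <- nrow(map)
  al <- matrix("0", nrow(g), 2L * S)
  for (s in seq_len(S)) {
    a <- c(map$a1[s], map$a2[s])
    code <- g[, s]
    al[, 2 * s - 1] <- ifelse(is.na(code), "0",
                              ifelse(code == 2L, a[2], a[1]))
    al[, 2 * s] <- ifelse(is.na(code), "0",
                          ifelse(code == 1L, a[1], a[2]))
  }
  ped <- cbind(panel$samples, panel$samples, "0", "0", "0", "-9", al)
  utils::write.table(ped, paste0(prefix, ".ped"), quote = FALSE,
                     row.names = FALSE, col.names = FALSE, sep = " ")
  invisible(prefix)
}

#' QC-filter a panel on MAF and call rate
#'
#' Removes SNPs with minor allele frequency at or below `maf_min` or call
#' rate at or below `call_rate_min`; counts of removals are reported via
#' `message()`.
#'
#' @param panel A `geno_panel`.
#' @param maf_min MAF threshold (SNP kept iff MAF > `maf_min`).
#'   Default 0.05.
#' @param call_rate_min Call-rate threshold (kept iff call rate >
#'   `call_rate_min`). Default 0.99.
#' @return The filtered `geno_panel`.
#' @export
qc_filter <- function(panel, maf_min = 0.05, call_rate_min = 0.99) {
  stopifnot(inherits(panel, "geno_panel"),
            maf_min >= 0, maf_min <= 1, call_rate_min >= 0, call_rate_min <= 1)
  g <- panel$geno
  call_rate <- colMeans(!is.na(g))
  n1 <- colSums(g == 1L, na.rm = TRUE)
  n2 <- colSums(g == 2L, na.rm = TRUE)
  n3 <- colSums(g == 3L, na.rm = TRUE)
  f1 <- (2 * n1 + n3) / (2 * (n1 + n2 + n3))
  maf <- pmin(f1, 1 - f1)
  maf[is.nan(maf)] <- 0
  keep <- maf > maf_min & call_rate > call_rate_min
  message(sprintf("qc_filter: removed %d/%d SNPs (%d MAF <= %g, %d call rate <= %g)",
                  sum(!keep), length(keep), sum(maf <= maf_min),
                  maf_min, sum(call_rate <= call_rate_min), call_rate_min))
  genotype_panel(panel$map[keep, , drop = FALSE],
                 panel$geno[, keep, drop = FALSE], panel$samples)
}

# ---- triplet fitting ------------------------------------------------------

# Fit one SNP triplet (panel column indices) and return a one-row record.
# Monomorphic columns make the EM degenerate but still well-defined; the
# caller decides whether to skip them.
.fit_triplet <- function(panel, idx, lrt = TRUE) {
  g <- panel$geno[, idx, drop = FALSE]
  keep <- stats::complete.cases(g)
  n <- sum(keep)
  map <- panel$map[idx, , drop = FALSE]
  span <- max(map$pos) - min(map$pos)
  base <- data.frame(
    snp1 = map$snp[1], snp2 = map$snp[2], snp3 = map$snp[3],
    chr1 = map$chr[1], chr2 = map$chr[2], chr3 = map$chr[3],
    pos1 = map$pos[1], pos2 = map$pos[2], pos3 = map$pos[3],
    span_bp = if (length(unique(map$chr)) == 1L) span else NA_real_,
    n = n, stringsAsFactors = FALSE
  )
  counts <- counts_from_codes(g[keep, 1], g[keep, 2], g[keep, 3])
  res <- lrt_independence(counts)
  fit <- res$fit
  p <- unclass(fit$decomposition)
  nr <- normalize_robinson(fit$decomposition)
  cbind(base, data.frame(
    f_T = p[["f_T"]], f_M = p[["f_M"]], f_K = p[["f_K"]],
    d_TM = p[["d_TM"]], d_TK = p[["d_TK"]], d_MK = p[["d_MK"]],
    d_TMK = p[["d_TMK"]],
    beta = nr$beta, norm_category = nr$category,
    norm_value = nr$value,
    n_haplotypes = count_segregating_haplotypes(fit$haplotypes, tol = 1e-6),
    loglik = fit$loglik, lrt = res$statistic,
    iterations = fit$iterations, converged = fit$converged,
    stringsAsFactors = FALSE
  ))
}

.scan_records <- function(panel, idx_list, fit = TRUE) {
  if (length(idx_list) == 0) return(.empty_scan(fit))
  if (!fit) {
    # vectorized bookkeeping-only path (fast for genome-scale counts)
    idx <- do.call(rbind, idx_list)
    map <- panel$map
    cc <- !is.na(panel$geno)
    intra <- map$chr[idx[, 1]] == map$chr[idx[, 2]] &
      map$chr[idx[, 2]] == map$chr[idx[, 3]]
    pos <- cbind(map$pos[idx[, 1]], map$pos[idx[, 2]], map$pos[idx[, 3]])
    span <- apply(pos, 1, max) - apply(pos, 1, min)
    return(data.frame(
      snp1 = map$snp[idx[, 1]], snp2 = map$snp[idx[, 2]],
      snp3 = map$snp[idx[, 3]],
      chr1 = map$chr[idx[, 1]], chr2 = map$chr[idx[, 2]],
      chr3 = map$chr[idx[, 3]],
      pos1 = pos[, 1], pos2 = pos[, 2], pos3 = pos[, 3],
      span_bp = ifelse(intra, span, NA_real_),
      n = colSums(cc[, idx[, 1], drop = FALSE] &
                    cc[, idx[, 2], drop = FALSE] &
                    cc[, idx[, 3], drop = FALSE]),
      stringsAsFactors = FALSE
    ))
  }
  do.call(rbind, lapply(idx_list, function(idx) .fit_triplet(panel, idx)))
}

.empty_scan <- function(fit = TRUE) {
  out <- data.frame(snp1 = character(0), snp2 = character(0),
                    snp3 = character(0), chr1 = character(0),
                    chr2 = character(0), chr3 = character(0),
                    pos1 = numeric(0), pos2 = numeric(0), pos3 = numeric(0),
                    span_bp = numeric(0), n = integer(0))
  out
}

#' Scan all consecutive SNP triplets
#'
#' One record per sliding window of three adjacent SNPs per chromosome
#' (short-range intra-chromosomal design): a chromosome with `n` SNPs
#' contributes `max(0, n - 2)` triplets.
#'
#' @param panel A `geno_panel`.
#' @param fit Estimate LD for every triplet (default). With `fit = FALSE`
#'   only the triplet bookkeeping columns are returned (fast; useful for
#'   design counts).
#' @param drop_monomorphic Skip triplets containing a SNP monomorphic
#'   among the triplet's complete cases (EM degenerate); skipped triplets
#'   are reported via `message()`. Default `TRUE`.
#' @return A data frame of scan records ordered by chromosome and
#'   position; when `fit = TRUE`, columns include the seven decomposition
#'   parameters, `beta`, the normalization category/value, the number of
#'   segregating haplotypes, log-likelihood, LRT and EM diagnostics.
#' @export
scan_consecutive <- function(panel, fit = TRUE, drop_monomorphic = TRUE) {
  stopifnot(inherits(panel, "geno_panel"))
  idx_mat <- do.call(rbind, lapply(unique(panel$map$chr), function(ch) {
    w <- which(panel$map$chr == ch)
    n <- length(w)
    if (n < 3) return(NULL)
    cbind(w[1:(n - 2L)], w[2:(n - 1L)], w[3:n])
  }))
  idx_list <- if (is.null(idx_mat)) list() else
    lapply(seq_len(nrow(idx_mat)), function(i) idx_mat[i, ])
  .run_scan(panel, idx_list, fit, drop_monomorphic)
}

#' Scan random inter-chromosomal SNP triplets
#'
#' Each draw picks three distinct chromosomes at random and one random SNP
#' within each; physically unlinked loci, so disequilibrium is expected to
#' be negligible. Reproducible under `seed`.
#'
#' @param panel A `geno_panel` with SNPs on at least three chromosomes.
#' @param n_draws Number of triplets to draw.
#' @param seed RNG seed (required).
#' @inheritParams scan_consecutive
#' @return A data frame of scan records (see [scan_consecutive()]);
#'   `span_bp` is `NA` for inter-chromosomal triplets.
#' @export
scan_inter_chromosomal <- function(panel, n_draws, seed, fit = TRUE,
                                   drop_monomorphic = TRUE) {
  stopifnot(inherits(panel, "geno_panel"), n_draws >= 0)
  chrs <- unique(panel$map$chr)
  if (length(chrs) < 3) stop("inter-chromosomal scan needs >= 3 chromosomes")
  if (n_draws == 0) return(.empty_scan(fit))
  idx_list <- withr::with_seed(seed, {
    lapply(seq_len(n_draws), function(i) {
      ch3 <- sample(chrs, 3)
      vapply(ch3, function(ch) {
        w <- which(panel$map$chr == ch)
        w[sample.int(length(w), 1)]
      }, 0L)
    })
  })
  .run_scan(panel, idx_list, fit, drop_monomorphic)
}

#' Scan all SNP triplets inside a rolling window
#'
#' Every unordered triplet on `chromosome` whose outermost SNPs fall
#' within `window_snps` consecutive SNPs (index span < `window_snps`),
#' deduplicated across overlapping windows. Spans are recorded for
#' distance-versus-LD analyses.
#'
#' @param panel A `geno_panel`.
#' @param chromosome Chromosome label to scan.
#' @param window_snps Window width in SNPs (>= 3).
#' @inheritParams scan_consecutive
#' @return A data frame of scan records (see [scan_consecutive()]).
#' @export
scan_window_all_triplets <- function(panel, chromosome, window_snps,
                                     fit = TRUE, drop_monomorphic = TRUE) {
  stopifnot(inherits(panel, "geno_panel"), window_snps >= 3)
  w <- which(panel$map$chr == as.character(chromosome))
  if (length(w) < 3) return(.empty_scan(fit))
  idx_list <- list()
  for (i in seq_len(length(w) - 2L)) {
    k_max <- min(length(w), i + window_snps - 1L)
    if (k_max < i + 2L) next
    for (k in (i + 2L):k_max) {
      for (j in (i + 1L):(k - 1L)) {
        idx_list[[length(idx_list) + 1L]] <- w[c(i, j, k)]
      }
    }
  }
  .run_scan(panel, idx_list, fit, drop_monomorphic)
}

.run_scan <- function(panel, idx_list, fit, drop_monomorphic) {
  if (fit && drop_monomorphic && length(idx_list) > 0) {
    poly <- vapply(idx_list, function(idx) {
      g <- panel$geno[, idx, drop = FALSE]
      g <- g[stats::complete.cases(g), , drop = FALSE]
      nrow(g) > 0 && all(apply(g, 2, function(x) length(unique(x)) > 1))
    }, TRUE)
    if (any(!poly)) {
      message(sprintf("skipped %d triplet(s) with a monomorphic SNP",
                      sum(!poly)))
    }
    idx_list <- idx_list[poly]
  }
  .scan_records(panel, idx_list, fit = fit)
}

#' Distance versus third-order LD summary
#'
#' Pearson correlation between `|d_TMK|` and the triplet span, with its
#' large-sample standard error, plus binned 25/50/75th percentile curves
#' of `d_TMK` against span.
#'
#' @param records A scan-record data frame with columns `span_bp` and
#'   `d_TMK` (intra-chromosomal records; rows with `NA` span are dropped).
#' @param n_bins Number of equal-count distance bins for the percentile
#'   curves. Default 10.
#' @return A list: `correlation`, `se`, `n`, and `percentiles` (a data
#'   frame of bin mid-distance and the 25/50/75th percentiles of `d_TMK`).
#'   `correlation` is `NA` (flagged undefined) when `|d_TMK|` or span is
#'   constant.
#' @export
distance_ld_summary <- function(records, n_bins = 10) {
  stopifnot(is.data.frame(records),
            all(c("span_bp", "d_TMK") %in% names(records)))
  rec <- records[!is.na(records$span_bp), , drop = FALSE]
  if (nrow(rec) < 2) stop("need at least 2 intra-chromosomal records")
  x <- rec$span_bp
  y <- abs(rec$d_TMK)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    corr <- NA_real_
    se <- NA_real_
  } else {
    corr <- stats::cor(x, y)
    se <- sqrt((1 - corr^2) / (nrow(rec) - 2))
  }
  n_bins <- max(1L, min(n_bins, nrow(rec)))
  br <- unique(stats::quantile(x, probs = seq(0, 1, length.out = n_bins + 1)))
  bin <- cut(x, breaks = br, include.lowest = TRUE)
  perc <- do.call(rbind, lapply(split(seq_along(x), bin), function(i) {
    q <- stats::quantile(rec$d_TMK[i], c(0.25, 0.5, 0.75))
    data.frame(span_mid = stats::median(x[i]), n = length(i),
               p25 = q[[1]], p50 = q[[2]], p75 = q[[3]])
  }))
  rownames(perc) <- NULL
  list(correlation = corr, se = se, n = nrow(rec), percentiles = perc)
}
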