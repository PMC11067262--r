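#' Pre-analysis QC thresholds
#'
#' Default values are the standard array-QC settings used throughout the
#' package: variant call rate >= 0.98, MAF >= 0.05, HWE exact p >= 1e-6,
#' sample call rate >= 0.98, heterozygosity within mean +/- 3 SD, and
#' pairwise relatedness (method-of-moments PI-hat) <= 0.1875.
#'
#' @param variant_call_rate_min,maf_min,hwe_p_min,sample_call_rate_min,het_sd,ibd_max
#'   individual thresholds; see description.
#' @return list of class `qc_thresholds`.
#' @export
qc_thresholds <- function(variant_call_rate_min = 0.98, maf_min = 0.05,
                          hwe_p_min = 1e-6, sample_call_rate_min = 0.98,
                          het_sd = 3, ibd_max = 0.1875) {
  stopifnot(variant_call_rate_min >= 0, variant_call_rate_min <= 1,
            maf_min >= 0, maf_min <= 1, hwe_p_min >= 0, hwe_p_min <= 1,
            sample_call_rate_min >= 0, sample_call_rate_min <= 1,
            het_sd > 0, ibd_max >= 0, ibd_max <= 1)
  structure(list(variant_call_rate_min = variant_call_rate_min,
                 maf_min = maf_min, hwe_p_min = hwe_p_min,
                 sample_call_rate_min = sample_call_rate_min,
                 het_sd = het_sd, ibd_max = ibd_max),
            class = "qc_thresholds")
}

#' Exact test for Hardy-Weinberg equilibrium
#'
#' Two-sided exact test on one biallelic variant's genotype counts: the
#' conditional distribution of the heterozygote count given the allele counts
#' is enumerated, and the p-value is the sum of probabilities of all
#' heterozygote counts at most as probable as the observed one (no mid-p
#' adjustment). Monomorphic variants return 1.
#'
#' @param n_hom_ref,n_het,n_hom_alt genotype counts.
#' @return exact p-value in (0, 1].
#' @examples
#' hwe_exact_test(10, 0, 0)  # monomorphic: 1
#' hwe_exact_test(5, 0, 5)   # extreme heterozygote deficit
#' @export
hwe_exact_test <- function(n_hom_ref, n_het, n_hom_alt) {
  stopifnot(n_hom_ref >= 0, n_het >= 0, n_hom_alt >= 0)
  n <- n_hom_ref + n_het + n_hom_alt
  if (n == 0) stop("all genotype counts are zero")
  rare <- 2L * min(n_hom_ref, n_hom_alt) + n_het  # minor allele count
  if (rare == 0L) return(1)
  # heterozygote counts share the parity of the rare allele count
  hs <- seq.int(rare %% 2L, min(rare, 2L * n - rare), by = 2L)
  # log P(het = h | allele counts): multinomial / hypergeometric form
  lp <- lchoose(n, (rare - hs) / 2) +
    lgamma(n - (rare - hs) / 2 + 1) - lgamma(hs + 1) -
    lgamma(n - (rare + hs) / 2 + 1) + hs * log(2)
  pr <- exp(lp - max(lp))
  pr <- pr / sum(pr)
  obs <- pr[hs == n_het]
  min(1, sum(pr[pr <= obs + 1e-12 * obs]))
}

# per-variant metrics on a dosage matrix (missing excluded from MAF and HWE)
.variant_metrics <- function(dosage) {
  n <- nrow(dosage)
  nm <- colSums(!is.na(dosage))
  call_rate <- nm / n
  af <- colSums(dosage, na.rm = TRUE) / (2 * pmax(nm, 1L))
  maf <- pmin(af, 1 - af)
  hwe_p <- vapply(seq_len(ncol(dosage)), function(j) {
    d <- dosage[, j]
    d <- d[!is.na(d)]
    if (!length(d)) return(NA_real_)
    hwe_exact_test(sum(d == 0L), sum(d == 1L), sum(d == 2L))
  }, 1.0)
  data.frame(variant_id = colnames(dosage), call_rate = call_rate,
             maf = maf, hwe_p = hwe_p, stringsAsFactors = FALSE,
             row.names = NULL)
}

#' Variant quality control
#'
#' Drops variants failing any of: call rate below threshold, minor allele
#' frequency below threshold, HWE exact p below threshold. Missing dosages
#' are excluded from the MAF and HWE computations.
#'
#' @param gm a [genotype_matrix()].
#' @param thr a [qc_thresholds()].
#' @return list with `genotypes` (filtered matrix) and `report` (per-variant
#'   data.frame: variant_id, call_rate, maf, hwe_p, status, reason).
#' @export
variant_qc <- function(gm, thr = qc_thresholds()) {
  stopifnot(inherits(gm, "genotype_matrix"), nrow(gm$variants) > 0L)
  met <- .variant_metrics(gm$dosage)
  fail_cr  <- met$call_rate < thr$variant_call_rate_min
  fail_maf <- met$maf < thr$maf_min
  fail_hwe <- !is.na(met$hwe_p) & met$hwe_p < thr$hwe_p_min
  reason <- mapply(function(a, b, c) {
    paste(c("call_rate", "maf", "hwe")[c(a, b, c)], collapse = ",")
  }, fail_cr, fail_maf, fail_hwe, USE.NAMES = FALSE)
  drop <- fail_cr | fail_maf | fail_hwe
  met$status <- ifelse(drop, "fail", "pass")
  met$reason <- reason
  list(genotypes = subset_gm(gm, variants = which(!drop)), report = met)
}

#' Method-of-moments pairwise relatedness
#'
#' Estimates relatedness for every subject pair as the average product of
#' allele-frequency-standardized dosages over non-missing variants (the
#' genomic-relationship estimator). Its expectation is the proportion of the
#' genome shared identical-by-descent (PI-hat) under no inbreeding; a
#' duplicate pair scores about 1.
#'
#' @param gm a [genotype_matrix()].
#' @return symmetric subjects x subjects matrix.
#' @export
ibd_estimate <- function(gm) {
  X <- gm$dosage
  p <- colSums(X, na.rm = TRUE) / (2 * pmax(colSums(!is.na(X)), 1L))
  keep <- p > 0 & p < 1
  X <- X[, keep, drop = FALSE]; p <- p[keep]
  if (!ncol(X)) stop("no polymorphic variants for relatedness estimation")
  Z <- sweep(X, 2L, 2 * p, "-")
  Z <- sweep(Z, 2L, sqrt(2 * p * (1 - p)), "/")
  miss <- is.na(Z)
  Z[miss] <- 0
  cnt <- tcrossprod((!miss) * 1)
  K <- tcrossprod(Z) / pmax(cnt, 1L)
  dimnames(K) <- list(gm$samples, gm$samples)
  K
}

#' Sample quality control
#'
#' Drops subjects failing any of: sample call rate below threshold;
#' heterozygosity rate outside mean +/- `het_sd` SD (skipped with a warning
#' when fewer than 3 samples); pairwise relatedness above `ibd_max` (both
#' members flagged, the one with the lower call rate dropped; ties drop the
#' lexicographically larger ID); sex mismatch when both reported and inferred
#' sex are supplied. The sex check is skipped silently when either input is
#' absent.
#'
#' @param gm a [genotype_matrix()].
#' @param thr a [qc_thresholds()].
#' @param reported_sex,inferred_sex optional vectors (same length/order as
#'   samples); compared element-wise when both are given.
#' @return list with `genotypes` and per-sample `report` (sample, call_rate,
#'   het_rate, max_ibd, status, reason).
#' @export
sample_qc <- function(gm, thr = qc_thresholds(), reported_sex = NULL,
                      inferred_sex = NULL) {
  stopifnot(inherits(gm, "genotype_matrix"), length(gm$samples) > 0L)
  X <- gm$dosage
  n <- nrow(X)
  nm <- rowSums(!is.na(X))
  call_rate <- nm / ncol(X)
  het_rate <- rowSums(X == 1L, na.rm = TRUE) / pmax(nm, 1L)

  fail_cr <- call_rate < thr$sample_call_rate_min
  if (n >= 3L) {
    mu <- mean(het_rate); s <- stats::sd(het_rate)
    fail_het <- if (s > 0) abs(het_rate - mu) > thr$het_sd * s else rep(FALSE, n)
  } else {
    warning("fewer than 3 samples; heterozygosity filter skipped")
    fail_het <- rep(FALSE, n)
  }

  K <- ibd_estimate(gm)
  diag(K) <- 0
  max_ibd <- apply(K, 1L, max)
  fail_ibd <- rep(FALSE, n)
  pairs <- which(upper.tri(K) & K > thr$ibd_max, arr.ind = TRUE)
  if (nrow(pairs)) {
    for (r in seq_len(nrow(pairs))) {
      i <- pairs[r, 1L]; j <- pairs[r, 2L]
      drop <- if (call_rate[i] < call_rate[j]) i
              else if (call_rate[j] < call_rate[i]) j
              else if (gm$samples[i] > gm$samples[j]) i else j
      fail_ibd[drop] <- TRUE
    }
  }

  fail_sex <- rep(FALSE, n)
  if (!is.null(reported_sex) && !is.null(inferred_sex)) {
    stopifnot(length(reported_sex) == n, length(inferred_sex) == n)
    fail_sex <- !is.na(reported_sex) & !is.na(inferred_sex) &
      reported_sex != inferred_sex
  }

  reason <- mapply(function(a, b, c, d) {
    paste(c("call_rate", "het", "ibd", "sex")[c(a, b, c, d)], collapse = ",")
  }, fail_cr, fail_het, fail_ibd, fail_sex, USE.NAMES = FALSE)
  drop <- fail_cr | fail_het | fail_ibd | fail_sex
  report <- data.frame(sample = gm$samples, call_rate = call_rate,
                       het_rate = het_rate, max_ibd = max_ibd,
                       status = ifelse(drop, "fail", "pass"),
                       reason = reason, stringsAsFactors = FALSE)
  list(genotypes = subset_gm(gm, samples = which(!drop)), report = report)
}

#' Write a QC report as TSV
#'
#' @param report data.frame from [variant_qc()] or [sample_qc()].
#' @param path output path.
#' @export
write_qc_report <- function(report, path) {
  utils::write.table(report, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
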