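#' Carrier percentage from integer counts
#'
#' Reproduces report arithmetic exactly from integer counts: carrier percent
#' = 100 * carriers / cohort size, rounded to 2 decimals.
#'
#' @param carriers carrier count(s).
#' @param n cohort size.
#' @return percentage(s), 2 decimals.
#' @export
carrier_percent <- function(carriers, n) {
  stopifnot(all(carriers >= 0), n > 0)
  round(100 * carriers / n, 2)
}

#' Expected carrier fraction under Hardy-Weinberg equilibrium
#'
#' For allele frequency p the expected fraction of subjects carrying at
#' least one copy is 1 - (1 - p)^2.
#'
#' @param p allele frequency in [0, 1].
#' @return expected carrier fraction.
#' @export
hwe_expected_carriers <- function(p) {
  stopifnot(all(p >= 0), all(p <= 1))
  1 - (1 - p)^2
}

#' Load the bundled ADR-associated allele list
#'
#' A curated list of HLA alleles with reported adverse-drug-reaction
#' associations (allele, drug, reaction, population, citation key),
#' transcribed from published pharmacogenomic reports. The drugs/reactions
#' are annotations only; no risk modelling is done.
#'
#' @param path optional path to a custom TSV with at least an `allele`
#'   column; defaults to the bundled list.
#' @return data.frame; every allele is validated with [parse_allele()].
#' @export
load_adr_alleles <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "adr_alleles.tsv", package = "hlapheno")
  }
  adr <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!"allele" %in% names(adr)) stop("ADR list needs an 'allele' column")
  parse_allele(adr$allele)  # errors on unparseable entries, naming them
  adr
}

#' Carrier report for ADR-associated HLA alleles
#'
#' For each listed allele: carriers (subjects with at least one copy among
#' subjects called at the allele's gene), carrier percent (2 decimals),
#' allele frequency (copies / (2 x called subjects), 4 decimals), and the
#' HWE-expected carrier fraction for comparison. Alleles absent from the
#' cohort are reported with count 0. A homozygote counts once as a carrier
#' but contributes two copies to the allele frequency.
#'
#' @param calls imputed call or typing table (`sample`, `gene`, `allele1`,
#'   `allele2`, optional `called`).
#' @param adr_alleles data.frame with an `allele` column (see
#'   [load_adr_alleles()]), or a character vector of alleles.
#' @return data.frame of class `carrier_report`: `allele`, `carriers`,
#'   `carrier_pct`, `allele_freq`, `n_called`, `hwe_expected_pct`.
#' @export
carrier_report <- function(calls, adr_alleles = load_adr_alleles()) {
  if (is.character(adr_alleles)) {
    adr_alleles <- data.frame(allele = adr_alleles, stringsAsFactors = FALSE)
  }
  alleles <- unique(adr_alleles$allele)
  pa <- parse_allele(alleles)
  if (!"called" %in% names(calls)) calls$called <- TRUE
  rows <- lapply(seq_along(alleles), function(i) {
    a <- pa$allele[i]
    cg <- calls[calls$gene == pa$gene[i] & calls$called, , drop = FALSE]
    n_called <- length(unique(cg$sample))
    copies <- (cg$allele1 == a) + (cg$allele2 == a)
    carriers <- sum(copies >= 1L)
    freq <- if (n_called > 0) sum(copies) / (2 * n_called) else NA_real_
    data.frame(allele = a, carriers = carriers,
               carrier_pct = if (n_called > 0)
                 carrier_percent(carriers, n_called) else NA_real_,
               allele_freq = round(freq, 4),
               n_called = n_called,
               hwe_expected_pct = round(100 * hwe_expected_carriers(freq), 2),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("carrier_report", "data.frame")
  out
}
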