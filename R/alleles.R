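#' Parse HLA allele names
#'
#' Parses colon-delimited HLA nomenclature (`"B*58:01"`, `"HLA-B*58:01:01"`)
#' into gene and numeric fields. A trailing expression-status letter suffix
#' (N, L, S, Q, ...) is stripped before parsing. Resolution is two digits per
#' field: `"B*58"` is 2-digit, `"B*58:01"` 4-digit, `"B*58:01:01"` 6-digit.
#'
#' @param x character vector of allele names.
#' @return data.frame with columns `allele` (normalised `GENE*FF:FF` form
#'   without the `HLA-` prefix), `gene` (`"HLA-B"` form), `field1`..`field3`
#'   (integer, NA when absent) and `resolution` (2, 4 or 6).
#' @examples
#' parse_allele("B*58:01")
#' parse_allele("HLA-DQA1*06:01")
#' @export
parse_allele <- function(x) {
  stopifnot(is.character(x), length(x) >= 1L)
  stripped <- sub("^HLA-", "", x)
  stripped <- sub("([0-9])[A-Za-z]$", "\\1", stripped)  # expression suffix
  m <- regmatches(stripped, regexec("^([A-Z][A-Z0-9]*)\\*([0-9]+)(?::([0-9]+))?(?::([0-9]+))?$",
                                    stripped))
  bad <- vapply(m, length, 1L) == 0L
  if (any(bad)) {
    stop("malformed HLA allele name(s): ", paste(sQuote(x[bad]), collapse = ", "))
  }
  gene  <- vapply(m, `[`, "", 2L)
  f1 <- vapply(m, `[`, "", 3L)
  f2 <- vapply(m, `[`, "", 4L)
  f3 <- vapply(m, `[`, "", 5L)
  nf <- 1L + (nchar(f2) > 0L) + (nchar(f3) > 0L)
  norm <- paste0(gene, "*", f1, ifelse(nchar(f2) > 0L, paste0(":", f2), ""),
                 ifelse(nchar(f3) > 0L, paste0(":", f3), ""))
  data.frame(allele = norm,
             gene = paste0("HLA-", gene),
             field1 = as.integer(f1),
             field2 = ifelse(nchar(f2) > 0L, as.integer(f2), NA_integer_),
             field3 = ifelse(nchar(f3) > 0L, as.integer(f3), NA_integer_),
             resolution = 2L * nf,
             stringsAsFactors = FALSE)
}

#' Truncate HLA alleles to a lower field resolution
#'
#' @param x character vector of allele names.
#' @param resolution target resolution: 2, 4 or 6 (digits).
#' @return character vector of truncated allele names.
#' @examples
#' truncate_allele("B*58:01:01", 4)  # "B*58:01"
#' truncate_allele("B*58:01", 2)     # "B*58"
#' @export
truncate_allele <- function(x, resolution) {
  stopifnot(resolution %in% c(2L, 4L, 6L))
  p <- parse_allele(x)
  if (any(p$resolution < resolution)) {
    bad <- x[p$resolution < resolution]
    stop("cannot truncate to ", resolution, "-digit resolution; allele(s) typed lower: ",
         paste(sQuote(bad), collapse = ", "))
  }
  nf <- resolution / 2L
  gene <- sub("^HLA-", "", p$gene)
  out <- paste0(gene, "*", sprintf("%02d", p$field1))
  if (nf >= 2L) out <- paste0(out, ":", sprintf("%02d", p$field2))
  if (nf >= 3L) out <- paste0(out, ":", sprintf("%02d", p$field3))
  out
}

#' Validate an HLA typing table
#'
#' A typing table records, per subject and gene, an unordered pair of HLA
#' alleles. Used both for sequencing-based truth typings and imputed calls.
#'
#' @param typing data.frame with columns `sample`, `gene`, `allele1`, `allele2`.
#' @return the validated data.frame (invisibly classed `hla_typing`).
#' @export
as_hla_typing <- function(typing) {
  need <- c("sample", "gene", "allele1", "allele2")
  if (!all(need %in% names(typing))) {
    stop("typing table needs columns: ", paste(need, collapse = ", "))
  }
  p1 <- parse_allele(typing$allele1)
  p2 <- parse_allele(typing$allele2)
  if (any(p1$gene != typing$gene | p2$gene != typing$gene)) {
    stop("allele gene does not match the 'gene' column for some rows")
  }
  if (any(p1$resolution != p2$resolution)) {
    stop("allele pairs must share one resolution")
  }
  class(typing) <- c("hla_typing", "data.frame")
  typing
}

#' Truncate a typing table to a target resolution
#'
#' @param typing typing table (`sample`, `gene`, `allele1`, `allele2`).
#' @param resolution 2, 4 or 6.
#' @return typing table with both alleles truncated.
#' @export
truncate_typing <- function(typing, resolution) {
  typing$allele1 <- truncate_allele(typing$allele1, resolution)
  typing$allele2 <- truncate_allele(typing$allele2, resolution)
  typing
}

# genomic anchors of the eight classical HLA genes (GRCh38, chromosome 6)
.hla_gene_coords <- data.frame(
  gene  = c("HLA-A", "HLA-C", "HLA-B", "HLA-DRB1",
            "HLA-DQA1", "HLA-DQB1", "HLA-DPA1", "HLA-DPB1"),
  start = c(29942470L, 31268749L, 31353872L, 32578775L,
            32628179L, 32659467L, 33064569L, 33075990L),
  end   = c(29945884L, 31272130L, 31357188L, 32589848L,
            32647062L, 32668383L, 33080775L, 33089696L),
  stringsAsFactors = FALSE
)

#' Coordinates of the eight classical HLA genes
#'
#' GRCh38 chromosome 6 start/end anchors used to define imputation flanks.
#' @return data.frame with columns `gene`, `start`, `end`.
#' @export
hla_gene_coords <- function() .hla_gene_coords

#' The MHC region
#'
#' The class I - class II interval on chromosome 6 (GRCh38), 1-based and
#' inclusive at both ends.
#' @return a region list (`chrom`, `start`, `end`).
#' @export
mhc_region <- function() region("6", 28510120L, 33480577L)

#' Construct a genomic region
#'
#' @param chrom chromosome name.
#' @param start,end 1-based positions, inclusive at both ends.
#' @return list of class `region`.
#' @export
region <- function(chrom, start, end) {
  stopifnot(length(chrom) == 1L, length(start) == 1L, length(end) == 1L,
            start <= end, start >= 1)
  structure(list(chrom = as.character(chrom),
                 start = as.integer(start), end = as.integer(end)),
            class = "region")
}
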