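#' Construct a genotype matrix
#'
#' The package's genotype container: an additive dosage matrix (count of the
#' alternate allele, 0/1/2, NA for missing) with per-variant metadata. Rows
#' are subjects, columns variants. Positions are 1-based.
#'
#' @param dosage numeric/integer matrix, subjects x variants, values in
#'   \{0, 1, 2, NA\}.
#' @param variants data.frame with columns `chrom`, `pos`, `id`, `ref`, `alt`,
#'   one row per dosage column, positions non-decreasing within a chromosome.
#' @param samples character vector of subject IDs, one per dosage row.
#' @return object of class `genotype_matrix`: list with elements `samples`,
#'   `variants`, `dosage`.
#' @export
genotype_matrix <- function(dosage, variants, samples) {
  dosage <- as.matrix(dosage)
  storage.mode(dosage) <- "integer"
  stopifnot(nrow(dosage) == length(samples),
            ncol(dosage) == nrow(variants))
  need <- c("chrom", "pos", "id", "ref", "alt")
  if (!all(need %in% names(variants))) {
    stop("variants needs columns: ", paste(need, collapse = ", "))
  }
  bad <- dosage[!is.na(dosage)]
  if (length(bad) && (min(bad) < 0L || max(bad) > 2L)) {
    stop("dosage values must be 0, 1, 2 or NA")
  }
  if (any(variants$ref == variants$alt)) stop("ref allele equals alt allele")
  for (ch in unique(variants$chrom)) {
    p <- variants$pos[variants$chrom == ch]
    if (is.unsorted(p)) stop("positions must be non-decreasing within chromosome ", ch)
  }
  variants <- as.data.frame(variants, stringsAsFactors = FALSE)
  rownames(variants) <- NULL
  dimnames(dosage) <- list(samples, variants$id)
  structure(list(samples = as.character(samples),
                 variants = variants[, need],
                 dosage = dosage),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix:", length(x$samples), "subjects x",
      nrow(x$variants), "variants\n")
  if (nrow(x$variants)) {
    cat("  chrom", unique(x$variants$chrom), " pos",
        min(x$variants$pos), "-", max(x$variants$pos), "\n")
  }
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$dosage)

# subset by sample / variant index vectors
subset_gm <- function(gm, samples = NULL, variants = NULL) {
  si <- if (is.null(samples)) seq_along(gm$samples) else samples
  vi <- if (is.null(variants)) seq_len(nrow(gm$variants)) else variants
  genotype_matrix(gm$dosage[si, vi, drop = FALSE],
                  gm$variants[vi, , drop = FALSE],
                  gm$samples[si])
}

#' Extract variants inside a genomic region
#'
#' Keeps variants with `region$start <= pos <= region$end` on the region's
#' chromosome; both boundaries inclusive. Output variants keep input order.
#'
#' @param gm a [genotype_matrix()].
#' @param region a [region()], e.g. [mhc_region()].
#' @return a `genotype_matrix` (possibly with zero variants).
#' @export
extract_region <- function(gm, region) {
  stopifnot(inherits(gm, "genotype_matrix"), inherits(region, "region"))
  keep <- which(gm$variants$chrom == region$chrom &
                gm$variants$pos >= region$start &
                gm$variants$pos <= region$end)
  subset_gm(gm, variants = keep)
}

#' Read genotypes from VCF or PLINK files
#'
#' VCF rows must be biallelic (split multiallelic records upstream, e.g. with
#' `bcftools norm -m-`). Genotypes are converted to additive dosages of the
#' alternate allele; missing genotypes stay missing. For PLINK input, `path`
#' is the prefix of the bed/bim/fam trio; the bim A1 allele is treated as the
#' counted (alt) allele.
#'
#' @param path file path (VCF) or bed/bim/fam prefix (PLINK).
#' @param format "vcf", "plink", or "auto" (by file extension).
#' @return a [genotype_matrix()].
#' @export
read_genotypes <- function(path, format = c("auto", "vcf", "plink")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.vcf(\\.gz)?$", path)) "vcf" else "plink"
  }
  if (format == "vcf") .read_vcf(path) else .read_plink(path)
}

.read_vcf <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  if (nrow(fix) == 0L) stop("VCF contains no variant records: ", path)
  multi <- grepl(",", fix$ALT)
  if (any(multi)) {
    stop("multiallelic VCF record(s) at line(s) ",
         paste(which(multi), collapse = ", "),
         "; split them first (bcftools norm -m-)")
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  if (is.null(gt)) stop("VCF has no GT field: ", path)
  dos <- .gt_to_dosage(gt)
  ids <- fix$ID
  ids[is.na(ids) | ids == "."] <- paste0(fix$CHROM, ":", fix$POS,
                                         "_", fix$REF, "_", fix$ALT)[is.na(ids) | ids == "."]
  variants <- data.frame(chrom = fix$CHROM, pos = as.integer(fix$POS),
                         id = ids, ref = fix$REF, alt = fix$ALT,
                         stringsAsFactors = FALSE)
  genotype_matrix(t(dos), variants, colnames(gt))
}

# GT string matrix (variants x samples) -> integer dosage matrix
.gt_to_dosage <- function(gt) {
  u <- unique(as.vector(gt))
  u <- u[!is.na(u)]
  map <- vapply(u, function(g) {
    al <- strsplit(g, "[/|]")[[1]]
    if (any(al == ".")) return(NA_integer_)
    al <- suppressWarnings(as.integer(al))
    if (anyNA(al) || any(al > 1L)) {
      stop("unparseable or multiallelic genotype string: ", sQuote(g))
    }
    sum(al)
  }, 1L)
  out <- matrix(map[match(as.vector(gt), u)], nrow = nrow(gt))
  dimnames(out) <- dimnames(gt)
  out
}

#' Write genotypes to VCF or PLINK files
#'
#' @param gm a [genotype_matrix()].
#' @param path output VCF path or PLINK prefix.
#' @param format "vcf" or "plink".
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(gm, path, format = c("vcf", "plink")) {
  format <- match.arg(format)
  if (format == "vcf") .write_vcf(gm, path) else .write_plink(gm, path)
  invisible(path)
}

.write_vcf <- function(gm, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", gm$samples), collapse = "\t")), con)
  gtc <- c("0/0", "0/1", "1/1")
  for (j in seq_len(nrow(gm$variants))) {
    d <- gm$dosage[, j]
    g <- ifelse(is.na(d), "./.", gtc[d + 1L])
    v <- gm$variants[j, ]
    writeLines(paste(c(v$chrom, v$pos, v$id, v$ref, v$alt, ".", "PASS", ".",
                       "GT", g), collapse = "\t"), con)
  }
}

# ---- PLINK 1 bed/bim/fam (SNP-major). A1 = counted/alt allele. ----

.read_plink <- function(prefix) {
  bed <- paste0(prefix, ".bed"); bim <- paste0(prefix, ".bim"); fam <- paste0(prefix, ".fam")
  for (f in c(bed, bim, fam)) if (!file.exists(f)) stop("file not found: ", f)
  bimd <- utils::read.table(bim, header = FALSE, stringsAsFactors = FALSE,
                            col.names = c("chrom", "id", "cm", "pos", "a1", "a2"))
  famd <- utils::read.table(fam, header = FALSE, stringsAsFactors = FALSE)
  n <- nrow(famd); m <- nrow(bimd)
  raw <- readBin(bed, "raw", n = file.info(bed)$size)
  if (length(raw) < 3L || raw[1] != as.raw(0x6c) || raw[2] != as.raw(0x1b)) {
    stop("not a PLINK bed file: ", bed)
  }
  if (raw[3] != as.raw(0x01)) stop("only SNP-major bed files are supported")
  bpv <- ceiling(n / 4)
  if (length(raw) != 3L + bpv * m) stop("bed file size inconsistent with bim/fam")
  body <- raw[-(1:3)]
  # 2-bit codes per subject: 00 hom A1 (dosage 2), 01 missing, 10 het, 11 hom A2
  codes <- matrix(0L, nrow = 4L, ncol = length(body))
  ints <- as.integer(body)
  for (k in 0:3) codes[k + 1L, ] <- bitwAnd(bitwShiftR(ints, 2L * k), 3L)
  lut <- c(2L, NA_integer_, 1L, 0L)
  dos <- matrix(lut[codes + 1L], nrow = 4L * bpv)[seq_len(n), , drop = FALSE]
  dim(dos) <- c(n, m)
  genotype_matrix(dos,
                  data.frame(chrom = as.character(bimd$chrom), pos = bimd$pos,
                             id = bimd$id, ref = bimd$a2, alt = bimd$a1,
                             stringsAsFactors = FALSE),
                  as.character(famd[[2]]))
}

.write_plink <- function(gm, prefix) {
  n <- length(gm$samples); m <- nrow(gm$variants)
  utils::write.table(data.frame(gm$variants$chrom, gm$variants$id, 0L,
                                gm$variants$pos, gm$variants$alt, gm$variants$ref),
                     paste0(prefix, ".bim"), sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  utils::write.table(data.frame(gm$samples, gm$samples, 0L, 0L, 0L, -9L),
                     paste0(prefix, ".fam"), sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  bpv <- ceiling(n / 4)
  code <- c(3L, 2L, 0L)  # dosage 0,1,2 -> 2-bit code; NA -> 1
  out <- raw(3 + bpv * m)
  out[1:3] <- as.raw(c(0x6c, 0x1b, 0x01))
  for (j in seq_len(m)) {
    d <- gm$dosage[, j]
    cc <- ifelse(is.na(d), 1L, code[d + 1L])
    cc <- c(cc, integer(4L * bpv - n))
    cm <- matrix(cc, nrow = 4L)
    bytes <- cm[1, ] + bitwShiftL(cm[2, ], 2L) + bitwShiftL(cm[3, ], 4L) +
      bitwShiftL(cm[4, ], 6L)
    out[3L + (j - 1L) * bpv + seq_len(bpv)] <- as.raw(bytes)
  }
  writeBin(out, paste0(prefix, ".bed"))
}
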