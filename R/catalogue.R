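#' HLA allele dosages from typing calls
#'
#' One biallelic variant per distinct allele; a subject's dosage is the
#' number of copies carried (0/1/2). Subjects without a call at a gene
#' (posterior below the call threshold, or absent) are missing for all of
#' that gene's alleles.
#'
#' @param calls typing or imputed-call table (`sample`, `gene`, `allele1`,
#'   `allele2`, optional logical `called`).
#' @param samples subject universe (default: samples present in `calls`).
#' @return list: `dosage` (subjects x alleles matrix), `meta` (id, source,
#'   gene).
#' @export
allele_dosages <- function(calls, samples = unique(calls$sample)) {
  if (!"called" %in% names(calls)) calls$called <- TRUE
  alleles <- sort(unique(c(calls$allele1[calls$called],
                           calls$allele2[calls$called])))
  D <- matrix(NA_integer_, length(samples), length(alleles),
              dimnames = list(samples, alleles))
  for (g in unique(calls$gene)) {
    cg <- calls[calls$gene == g, , drop = FALSE]
    cg <- cg[match(samples, cg$sample), , drop = FALSE]
    ok <- !is.na(cg$sample) & cg$called
    ga <- sort(unique(c(cg$allele1[ok], cg$allele2[ok])))
    for (a in ga) {
      D[ok, a] <- (cg$allele1[ok] == a) + (cg$allele2[ok] == a)
    }
  }
  meta <- data.frame(id = alleles, source = "hla_allele",
                     gene = parse_allele(alleles)$gene,
                     stringsAsFactors = FALSE)
  list(dosage = D, meta = meta)
}

#' Translate HLA calls to amino-acid variants
#'
#' Maps each called 4-digit allele to its residue string (6-digit calls are
#' truncated first; synonymous third-field differences do not change the
#' protein). Positions with at least two observed residues are polymorphic:
#' each residue there becomes a biallelic presence variant named
#' `GENE-<residue><position>` (e.g. `HLA-B-Q94`), and the position itself is
#' recorded for the omnibus test with its per-residue dosage matrix.
#' Monomorphic positions are dropped. Alleles absent from the table give a
#' warning and missing dosages for that gene's positions.
#'
#' @param calls call table (`sample`, `gene`, `allele1`, `allele2`, optional
#'   `called`).
#' @param aa_table an allele-to-sequence table (`allele`, `gene`, `offset`,
#'   `sequence`), e.g. from [make_aa_table()].
#' @param samples subject universe.
#' @return list: `residue_dosage` (subjects x residue-variants), `meta`
#'   (id, source, gene, position, residue), `positions` (list per
#'   polymorphic position: gene, position, residues, dosage matrix
#'   subjects x residues).
#' @export
translate_amino_acids <- function(calls, aa_table,
                                  samples = unique(calls$sample)) {
  if (!"called" %in% names(calls)) calls$called <- TRUE
  res_cols <- list(); res_meta <- list(); positions <- list()
  for (g in unique(calls$gene)) {
    tab <- aa_table[aa_table$gene == g, , drop = FALSE]
    if (!nrow(tab)) next
    L <- unique(nchar(tab$sequence))
    stopifnot(length(L) == 1L)
    offset <- tab$offset[1L]
    cg <- calls[calls$gene == g, , drop = FALSE]
    cg <- cg[match(samples, cg$sample), , drop = FALSE]
    ok <- !is.na(cg$sample) & cg$called
    k1 <- truncate_allele(ifelse(ok, cg$allele1, tab$allele[1L]), 4L)
    k2 <- truncate_allele(ifelse(ok, cg$allele2, tab$allele[1L]), 4L)
    i1 <- match(k1, tab$allele); i2 <- match(k2, tab$allele)
    unknown <- unique(c(k1[ok & is.na(i1)], k2[ok & is.na(i2)]))
    if (length(unknown)) {
      warning("allele(s) missing from the amino-acid table for ", g, ": ",
              paste(unknown, collapse = ", "))
    }
    ok1 <- ok & !is.na(i1); ok2 <- ok & !is.na(i2)
    seq_m <- do.call(rbind, strsplit(tab$sequence, ""))
    for (pos in seq_len(L)) {
      r1 <- ifelse(ok1, seq_m[i1, pos], NA_character_)
      r2 <- ifelse(ok2, seq_m[i2, pos], NA_character_)
      residues <- sort(unique(c(r1, r2)))
      residues <- residues[!is.na(residues)]
      if (length(residues) < 2L) next
      prot_pos <- offset + pos - 1L
      dm <- matrix(NA_integer_, length(samples), length(residues),
                   dimnames = list(samples, residues))
      full <- ok1 & ok2
      for (r in residues) {
        dm[full, r] <- (r1[full] == r) + (r2[full] == r)
      }
      positions[[paste0(g, " pos ", prot_pos)]] <-
        list(gene = g, position = prot_pos, residues = residues, dosage = dm)
      for (r in residues) {
        id <- paste0(g, "-", r, prot_pos)
        res_cols[[id]] <- dm[, r]
        res_meta[[id]] <- data.frame(id = id, source = "aa_residue",
                                     gene = g, position = prot_pos,
                                     residue = r, stringsAsFactors = FALSE)
      }
    }
  }
  residue_dosage <- if (length(res_cols)) {
    do.call(cbind, res_cols)
  } else matrix(integer(0), length(samples), 0L,
                dimnames = list(samples, NULL))
  meta <- if (length(res_meta)) do.call(rbind, res_meta) else
    data.frame(id = character(0), source = character(0), gene = character(0),
               position = integer(0), residue = character(0))
  rownames(meta) <- NULL
  list(residue_dosage = residue_dosage, meta = meta, positions = positions)
}

#' Assemble the unified PheWAS variant catalogue
#'
#' Joins region SNVs/indels, HLA-allele dosages and amino-acid variants into
#' one biallelic dosage matrix plus the list of multiallelic amino-acid
#' positions. Sources are labelled `snv`, `indel` (ref/alt length > 1),
#' `hla_allele` and `aa_residue`.
#'
#' @param gm region [genotype_matrix()] of SNVs/indels (may be NULL).
#' @param hla [allele_dosages()] output (may be NULL).
#' @param aa [translate_amino_acids()] output (may be NULL).
#' @return object of class `variant_catalogue`: `dosage` (subjects x
#'   biallelic variants), `meta` (id, source, gene), `positions`, `samples`.
#' @export
build_catalogue <- function(gm = NULL, hla = NULL, aa = NULL) {
  mats <- list(); metas <- list(); samples <- NULL
  if (!is.null(gm)) {
    src <- ifelse(nchar(gm$variants$ref) > 1L | nchar(gm$variants$alt) > 1L,
                  "indel", "snv")
    mats$gm <- gm$dosage
    metas$gm <- data.frame(id = gm$variants$id, source = src,
                           gene = "-", stringsAsFactors = FALSE)
    samples <- gm$samples
  }
  if (!is.null(hla)) {
    mats$hla <- hla$dosage
    metas$hla <- data.frame(id = hla$meta$id, source = hla$meta$source,
                            gene = hla$meta$gene, stringsAsFactors = FALSE)
    samples <- samples %||% rownames(hla$dosage)
  }
  positions <- list()
  if (!is.null(aa)) {
    if (ncol(aa$residue_dosage)) {
      mats$aa <- aa$residue_dosage
      metas$aa <- data.frame(id = aa$meta$id, source = aa$meta$source,
                             gene = aa$meta$gene, stringsAsFactors = FALSE)
    }
    positions <- aa$positions
    samples <- samples %||% rownames(aa$residue_dosage)
  }
  stopifnot(length(mats) > 0L)
  ns <- unique(vapply(mats, nrow, 1L))
  stopifnot(length(ns) == 1L)
  dosage <- do.call(cbind, unname(mats))
  meta <- do.call(rbind, unname(metas))
  rownames(meta) <- NULL
  colnames(dosage) <- meta$id
  structure(list(dosage = dosage, meta = meta, positions = positions,
                 samples = samples),
            class = "variant_catalogue")
}

#' @export
print.variant_catalogue <- function(x, ...) {
  tl <- catalogue_tally(x)
  cat("variant_catalogue:", length(x$samples), "subjects\n")
  cat("  biallelic:", tl[["total_biallelic"]],
      sprintf("(snv %d, indel %d, hla_allele %d, aa_residue %d)",
              tl[["snv"]], tl[["indel"]], tl[["hla_allele"]],
              tl[["aa_residue"]]), "\n")
  cat("  multiallelic amino-acid positions:", tl[["aa_position"]], "\n")
  cat("  total:", tl[["total"]], "\n")
  invisible(x)
}

#' Catalogue class tallies
#'
#' Counts variants per class and their total; the biallelic classes plus the
#' multiallelic positions always reconcile to the total. Can also be applied
#' to a named vector of printed class counts.
#'
#' @param x a `variant_catalogue`, or a named numeric vector with entries
#'   `snv`, `indel`, `hla_allele`, `aa_residue`, `aa_position`.
#' @return named vector: per-class counts, `total_biallelic`, `total`.
#' @export
catalogue_tally <- function(x) {
  if (inherits(x, "variant_catalogue")) {
    counts <- c(snv = sum(x$meta$source == "snv"),
                indel = sum(x$meta$source == "indel"),
                hla_allele = sum(x$meta$source == "hla_allele"),
                aa_residue = sum(x$meta$source == "aa_residue"),
                aa_position = length(x$positions))
  } else {
    need <- c("snv", "indel", "hla_allele", "aa_residue", "aa_position")
    stopifnot(all(need %in% names(x)))
    counts <- x[need]
  }
  tb <- sum(counts[c("snv", "indel", "hla_allele", "aa_residue")])
  c(counts, total_biallelic = unname(tb),
    total = unname(tb + counts[["aa_position"]]))
}

#' Post-imputation variant QC
#'
#' HLA alleles and biallelic amino-acid residues are dropped when missing
#' rate exceeds `missing_max` or MAF falls below `maf_min`; multiallelic
#' amino-acid positions are dropped on missing rate only (no MAF filter).
#' SNVs and indels pass through untouched (they were QCed upstream).
#'
#' @param cat a `variant_catalogue`.
#' @param missing_max maximum missing rate (default 0.05).
#' @param maf_min minimum MAF for biallelic HLA variants (default 0.01).
#' @return filtered `variant_catalogue` with a `qc_report` attribute.
#' @export
post_imputation_qc <- function(cat, missing_max = 0.05, maf_min = 0.01) {
  stopifnot(inherits(cat, "variant_catalogue"))
  D <- cat$dosage
  n <- nrow(D)
  miss <- colSums(is.na(D)) / n
  nm <- colSums(!is.na(D))
  af <- colSums(D, na.rm = TRUE) / (2 * pmax(nm, 1L))
  maf <- pmin(af, 1 - af)
  hla_like <- cat$meta$source %in% c("hla_allele", "aa_residue")
  drop <- hla_like & (miss > missing_max | maf < maf_min)
  pos_miss <- vapply(cat$positions, function(p) {
    mean(apply(is.na(p$dosage), 1L, any))
  }, 1.0)
  pos_drop <- pos_miss > missing_max
  report <- data.frame(id = c(cat$meta$id, names(cat$positions)),
                       class = c(cat$meta$source,
                                 rep("aa_position", length(cat$positions))),
                       missing_rate = c(miss, pos_miss),
                       maf = c(maf, rep(NA_real_, length(cat$positions))),
                       status = ifelse(c(drop, pos_drop), "fail", "pass"),
                       stringsAsFactors = FALSE)
  out <- structure(list(dosage = D[, !drop, drop = FALSE],
                        meta = cat$meta[!drop, , drop = FALSE],
                        positions = cat$positions[!pos_drop],
                        samples = cat$samples),
                   class = "variant_catalogue")
  rownames(out$meta) <- NULL
  attr(out, "qc_report") <- report
  out
}

#' Squared-correlation LD between two dosage vectors
#'
#' Squared Pearson correlation over pairwise-complete subjects; undefined
#' (NA) when either vector has zero variance.
#'
#' @param a,b numeric dosage vectors of equal length.
#' @return r-squared in [0, 1], or NA.
#' @export
ld_r2 <- function(a, b) {
  ok <- !is.na(a) & !is.na(b)
  if (sum(ok) < 2L) stop("need at least 2 pairwise-complete subjects")
  a <- a[ok]; b <- b[ok]
  if (stats::var(a) == 0 || stats::var(b) == 0) return(NA_real_)
  stats::cor(a, b)^2
}

#' Assign SNVs/indels to HLA genes by LD
#'
#' Tags each SNV/indel with every classical HLA gene that has an HLA allele
#' or amino-acid polymorphism in high LD (r-squared at or above the
#' threshold, boundary inclusive) with it. Multiple genes give a
#' comma-joined tag; no gene gives `"-"`.
#'
#' @param cat a `variant_catalogue`.
#' @param r2_threshold LD threshold (default 0.7).
#' @return the catalogue with the `gene` column of SNV/indel rows updated.
#' @export
assign_to_gene <- function(cat, r2_threshold = 0.7) {
  stopifnot(inherits(cat, "variant_catalogue"))
  snv_idx <- which(cat$meta$source %in% c("snv", "indel"))
  hla_idx <- which(cat$meta$source %in% c("hla_allele", "aa_residue"))
  if (!length(snv_idx) || !length(hla_idx)) return(cat)
  for (j in snv_idx) {
    r2 <- vapply(hla_idx, function(k) {
      r <- tryCatch(ld_r2(cat$dosage[, j], cat$dosage[, k]),
                    error = function(e) NA_real_)
      if (is.na(r)) -1 else r
    }, 1.0)
    genes <- sort(unique(cat$meta$gene[hla_idx[r2 >= r2_threshold]]))
    cat$meta$gene[j] <- if (length(genes)) paste(genes, collapse = ",") else "-"
  }
  cat
}

#' Variants in complete LD with a given variant
#'
#' @param id variant id in the catalogue.
#' @param cat a `variant_catalogue`.
#' @param tol tolerance on 1 - r2 (default 1e-12).
#' @return character vector of companion variant ids (possibly empty).
#' @export
complete_ld_companions <- function(id, cat, tol = 1e-12) {
  stopifnot(inherits(cat, "variant_catalogue"))
  j <- match(id, cat$meta$id)
  if (is.na(j)) stop("variant not in catalogue: ", id)
  others <- setdiff(seq_len(ncol(cat$dosage)), j)
  hit <- vapply(others, function(k) {
    r <- tryCatch(ld_r2(cat$dosage[, j], cat$dosage[, k]),
                  error = function(e) NA_real_)
    !is.na(r) && r >= 1 - tol
  }, TRUE)
  cat$meta$id[others[hit]]
}
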