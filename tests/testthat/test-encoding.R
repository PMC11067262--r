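# small imputed-call table used across encoding tests
enc_calls <- data.frame(
  sample = rep(sprintf("s%d", 1:4), each = 1),
  gene = "HLA-B",
  allele1 = c("B*58:01", "B*58:01", "B*15:02", "B*58:01"),
  allele2 = c("B*58:01", "B*15:02", "B*15:02", "B*40:01"),
  called = c(TRUE, TRUE, TRUE, FALSE),
  stringsAsFactors = FALSE)

test_that("allele dosages count copies and propagate uncalled as missing", {
  ad <- allele_dosages(enc_calls)
  D <- ad$dosage
  expect_equal(D["s1", "B*58:01"], 2L)
  expect_equal(D["s2", "B*58:01"], 1L)
  expect_equal(D["s2", "B*15:02"], 1L)
  expect_true(all(is.na(D["s4", ])))
  # conservation: per-gene dosage sum is 2 for every called subject
  expect_true(all(rowSums(D[1:3, ]) == 2L))
  expect_equal(ad$meta$source, rep("hla_allele", ncol(D)))
})

test_that("allele frequencies from dosages match direct counting", {
  ad <- allele_dosages(enc_calls)
  D <- ad$dosage
  called <- enc_calls$called
  for (a in colnames(D)) {
    direct <- sum(enc_calls$allele1[called] == a) +
      sum(enc_calls$allele2[called] == a)
    expect_equal(sum(D[, a], na.rm = TRUE), direct)
  }
})

test_that("amino-acid translation finds polymorphic positions and residues", {
  aa <- data.frame(allele = c("B*58:01", "B*15:02", "B*40:01"),
                   gene = "HLA-B", offset = 94L,
                   sequence = c("QAKH", "QAKQ", "QAKQ"),
                   stringsAsFactors = FALSE)
  tr <- translate_amino_acids(enc_calls, aa)
  # only position 97 (offset 94 + 3) varies: H vs Q
  expect_length(tr$positions, 1L)
  pos <- tr$positions[[1]]
  expect_equal(pos$position, 97L)
  expect_equal(sort(pos$residues), c("H", "Q"))
  expect_equal(sort(colnames(tr$residue_dosage)),
               c("HLA-B-H97", "HLA-B-Q97"))
  # dosage conservation at the position for fully-called subjects
  sums <- rowSums(pos$dosage)
  expect_true(all(sums[1:3] == 2L))
  expect_true(all(is.na(pos$dosage["s4", ])))
})

test_that("a three-residue position yields 3 biallelic variants and df 2", {
  calls3 <- data.frame(sample = sprintf("s%d", 1:3), gene = "HLA-B",
                       allele1 = c("B*58:01", "B*15:02", "B*40:01"),
                       allele2 = c("B*58:01", "B*15:02", "B*40:01"),
                       called = TRUE, stringsAsFactors = FALSE)
  aa <- data.frame(allele = c("B*58:01", "B*15:02", "B*40:01"),
                   gene = "HLA-B", offset = 1L,
                   sequence = c("HA", "QA", "YA"), stringsAsFactors = FALSE)
  tr <- translate_amino_acids(calls3, aa)
  expect_length(tr$positions, 1L)
  expect_equal(length(tr$positions[[1]]$residues), 3L)
  expect_equal(ncol(tr$residue_dosage), 3L)
})

test_that("six-digit calls are truncated to protein level before lookup", {
  calls6 <- data.frame(sample = "s1", gene = "HLA-B",
                       allele1 = "B*58:01:01", allele2 = "B*15:02:01",
                       called = TRUE, stringsAsFactors = FALSE)
  aa <- data.frame(allele = c("B*58:01", "B*15:02"), gene = "HLA-B",
                   offset = 1L, sequence = c("H", "Q"),
                   stringsAsFactors = FALSE)
  tr <- translate_amino_acids(calls6, aa)
  expect_equal(unname(tr$positions[[1]]$dosage["s1", c("H", "Q")]),
               c(1L, 1L))
})

test_that("alleles missing from the table warn and give missing dosages", {
  aa <- data.frame(allele = "B*58:01", gene = "HLA-B", offset = 1L,
                   sequence = "H", stringsAsFactors = FALSE)
  expect_warning(tr <- translate_amino_acids(enc_calls, aa), "B\\*15:02")
})

test_that("catalogue tallies reconcile and reproduce printed accounting", {
  counts <- c(snv = 27055, indel = 2224, hla_allele = 269,
              aa_residue = 437, aa_position = 203)
  tl <- catalogue_tally(counts)
  expect_equal(tl[["total_biallelic"]], 29985)
  expect_equal(tl[["total"]], 30188)
})

test_that("post-imputation QC applies the two class-specific rules", {
  n <- 200
  set.seed(21)
  snv <- matrix(rbinom(n, 2, 0.001), n, 1)  # rare SNV: must pass untouched
  rare_hla <- matrix(rbinom(n, 2, 0.005), n, 1)       # MAF < 0.01
  missing_hla <- matrix(rbinom(n, 2, 0.3), n, 1)
  missing_hla[seq_len(0.06 * n), 1] <- NA             # missing rate 0.06
  good_hla <- matrix(rbinom(n, 2, 0.2), n, 1)
  D <- cbind(snv, rare_hla, missing_hla, good_hla)
  samples <- sprintf("s%03d", 1:n)
  rownames(D) <- samples
  meta <- data.frame(id = c("rs1", "B*99:01", "B*98:01", "B*58:01"),
                     source = c("snv", "hla_allele", "hla_allele",
                                "hla_allele"),
                     gene = c("-", "HLA-B", "HLA-B", "HLA-B"),
                     stringsAsFactors = FALSE)
  colnames(D) <- meta$id
  # multiallelic positions: one clean (retained even with a rare residue,
  # no MAF rule), one with missing rate 0.06 (dropped)
  mk_pos <- function(p_na) {
    dm <- cbind(A = rbinom(n, 2, 0.001), B = 0L)
    dm[, "B"] <- 2L - dm[, "A"]
    if (p_na > 0) dm[seq_len(p_na * n), ] <- NA
    rownames(dm) <- samples
    list(gene = "HLA-B", position = 9L, residues = c("A", "B"), dosage = dm)
  }
  cat0 <- structure(list(dosage = D, meta = meta,
                         positions = list(`HLA-B pos 9` = mk_pos(0.04),
                                          `HLA-B pos 10` = mk_pos(0.06)),
                         samples = samples), class = "variant_catalogue")
  out <- post_imputation_qc(cat0)
  expect_equal(out$meta$id, c("rs1", "B*58:01"))
  expect_equal(names(out$positions), "HLA-B pos 9")
  rep <- attr(out, "qc_report")
  expect_equal(rep$status[rep$id == "B*99:01"], "fail")
  tl <- catalogue_tally(out)
  expect_equal(unname(tl[["total"]]),
               unname(tl[["total_biallelic"]] + tl[["aa_position"]]))
})

test_that("LD r2 is symmetric, bounded and NA on constant input", {
  set.seed(22)
  a <- rbinom(500, 2, 0.3); b <- rbinom(500, 2, 0.3)
  expect_equal(ld_r2(a, a), 1.0)
  expect_equal(ld_r2(a, b), ld_r2(b, a))
  expect_lt(ld_r2(rbinom(2000, 2, 0.3), rbinom(2000, 2, 0.3)), 0.01)
  expect_true(is.na(ld_r2(rep(1, 10), rbinom(10, 2, 0.5))))
  expect_error(ld_r2(c(1, NA), c(NA, 1)), "complete")
})

test_that("gene assignment is r2-threshold inclusive and multi-gene aware", {
  set.seed(23)
  n <- 1000
  hla_b <- rbinom(n, 2, 0.3)
  hla_a <- rbinom(n, 2, 0.3)
  snv_dup <- hla_b                       # r2 = 1 with the HLA-B allele
  snv_multi <- hla_a                     # tags alleles at two genes below
  snv_indep <- rbinom(n, 2, 0.3)
  D <- cbind(snv_dup, snv_multi, snv_indep, hla_b, hla_a, hla_a)
  meta <- data.frame(id = c("rs_dup", "rs_multi", "rs_indep",
                            "B*58:01", "A*02:01", "DQA1*06:01"),
                     source = c("snv", "snv", "snv", "hla_allele",
                                "hla_allele", "hla_allele"),
                     gene = c("-", "-", "-", "HLA-B", "HLA-A", "HLA-DQA1"),
                     stringsAsFactors = FALSE)
  colnames(D) <- meta$id
  samples <- sprintf("s%04d", 1:n)
  rownames(D) <- samples
  cat0 <- structure(list(dosage = D, meta = meta, positions = list(),
                         samples = samples), class = "variant_catalogue")
  out <- assign_to_gene(cat0, r2_threshold = 0.7)
  expect_equal(out$meta$gene[out$meta$id == "rs_dup"], "HLA-B")
  expect_equal(out$meta$gene[out$meta$id == "rs_multi"], "HLA-A,HLA-DQA1")
  expect_equal(out$meta$gene[out$meta$id == "rs_indep"], "-")
})

test_that("complete-LD companions are found and symmetric", {
  set.seed(24)
  n <- 300
  a <- rbinom(n, 2, 0.3)
  D <- cbind(v1 = a, v2 = a, v3 = rbinom(n, 2, 0.3))
  samples <- sprintf("s%03d", 1:n)
  rownames(D) <- samples
  meta <- data.frame(id = colnames(D), source = "snv", gene = "-",
                     stringsAsFactors = FALSE)
  cat0 <- structure(list(dosage = D, meta = meta, positions = list(),
                         samples = samples), class = "variant_catalogue")
  expect_equal(complete_ld_companions("v1", cat0), "v2")
  expect_equal(complete_ld_companions("v2", cat0), "v1")
  expect_length(complete_ld_companions("v3", cat0), 0L)
})

test_that("translation is deterministic given typing and table", {
  pool <- simulate_reference_pool(300, 20, c(4, 3), 0.9, seed = 25)
  coh <- simulate_cohort(pool, 150, seed = 26)
  aa <- make_aa_table(pool, seed = 27)
  t1 <- translate_amino_acids(coh$typing, aa)
  t2 <- translate_amino_acids(coh$typing, aa)
  expect_identical(t1, t2)
})
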