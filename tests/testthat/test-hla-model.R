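# deterministic-tagging training cohort shared by several tests
dt_cohort <- local({
  pool <- simulate_reference_pool(400, 20, c(4), 1, seed = 31)
  coh <- simulate_cohort(pool, 250, seed = 32)
  list(pool = pool, gm = coh$genotypes, typing = coh$typing)
})

test_that("the requested number of classifiers is trained", {
  m <- hla_ab_train(dt_cohort$gm, dt_cohort$typing, "HLA-A", 4,
                    n_classifiers = 7, seed = 1)
  expect_length(m$classifiers, 7L)
  expect_s3_class(m, "hla_ab_model")
})

test_that("perfect tagging gives concentrated tables and OOB accuracy 1", {
  m <- hla_ab_train(dt_cohort$gm, dt_cohort$typing, "HLA-A", 4,
                    n_classifiers = 5, seed = 2)
  oob <- vapply(m$classifiers, `[[`, 1.0, "oob_accuracy")
  expect_true(all(oob == 1))
  for (cl in m$classifiers) {
    expect_equal(sum(cl$freq), 1, tolerance = 1e-9)
    # each allele's mass sits on a dominant pattern
    for (a in unique(cl$allele)) {
      fa <- cl$freq[cl$allele == a]
      expect_gt(max(fa) / sum(fa), 0.99)
    }
  }
})

test_that("deterministic tagging recovers the truth for every subject", {
  m <- hla_ab_train(dt_cohort$gm, dt_cohort$typing, "HLA-A", 4,
                    n_classifiers = 5, seed = 3)
  calls <- predict(m, dt_cohort$gm)
  expect_true(all(calls$called))
  expect_equal(call_accuracy(calls, dt_cohort$typing, "HLA-A"), 1.0)
})

test_that("classifier EM matches the direct likelihood maximization oracle", {
  # one SNP in partial LD with a two-allele gene; joint haplotypes
  # (bit, allele) span a 4-simplex we can optimize directly
  set.seed(41)
  n <- 80
  truth <- c(0.35, 0.15, 0.10, 0.40)  # (0,A1) (1,A1) (0,A2) (1,A2)
  bits <- c(0L, 1L, 0L, 1L)
  alls <- c("A*01:01", "A*01:01", "A*02:01", "A*02:01")
  h1 <- sample(4, n, TRUE, truth); h2 <- sample(4, n, TRUE, truth)
  G <- matrix(bits[h1] + bits[h2], ncol = 1)
  a1 <- pmin(alls[h1], alls[h2]); a2 <- pmax(alls[h1], alls[h2])
  fit <- hlapheno:::.fit_freq_table(G, a1, a2, tol = 1e-12, max_iter = 5000)
  key_fit <- paste(fit$allele, fit$pattern)
  loglik <- function(f) {
    ll <- 0
    for (i in seq_len(n)) {
      pr <- 0
      for (x in 1:4) for (y in 1:4) {
        if (bits[x] + bits[y] == G[i, 1] &&
            min(alls[x], alls[y]) == a1[i] && max(alls[x], alls[y]) == a2[i])
          pr <- pr + f[x] * f[y]
      }
      ll <- ll + log(pr)
    }
    ll
  }
  f_or <- simplex_mle(loglik, 4, restarts = 5, seed = 42)
  names(f_or) <- paste(alls, bits)
  expect_equal(unname(fit$freq[order(key_fit)]),
               unname(f_or[order(names(f_or))]), tolerance = 1e-6)
})

test_that("posteriors are normalized and the call threshold is respected", {
  m <- hla_ab_train(dt_cohort$gm, dt_cohort$typing, "HLA-A", 4,
                    n_classifiers = 3, seed = 4)
  cl <- m$classifiers[[1]]
  G <- dt_cohort$gm$dosage[1:20, match(cl$snp_id, dt_cohort$gm$variants$id),
                           drop = FALSE]
  post <- hlapheno:::.classifier_posteriors(
    list(pattern = cl$pattern, allele = cl$allele, freq = cl$freq), G)
  for (v in post) expect_equal(sum(v), 1, tolerance = 1e-9)
  calls_hi <- predict(m, dt_cohort$gm, call_threshold = 0.999999)
  expect_true(all(calls_hi$called == (calls_hi$posterior >= 0.999999)))
})

test_that("lowering the call threshold never decreases the call rate", {
  pool <- simulate_reference_pool(400, 20, c(4), 0.85, seed = 33)
  coh <- simulate_cohort(pool, 250, seed = 34)
  m <- hla_ab_train(coh$genotypes, coh$typing, "HLA-A", 4,
                    n_classifiers = 4, seed = 5)
  rates <- vapply(c(0.9, 0.7, 0.5, 0.3, 0), function(thr) {
    mean(predict(m, coh$genotypes, call_threshold = thr)$called)
  }, 1.0)
  expect_true(all(diff(rates) >= 0))
})

test_that("training rejects untyped samples and low-resolution typings", {
  ty <- dt_cohort$typing
  expect_error(hla_ab_train(dt_cohort$gm, ty[-1, ], "HLA-A", 4,
                            n_classifiers = 2, seed = 1),
               "without")
  ty2 <- ty
  ty2$allele1 <- truncate_allele(ty2$allele1, 2)
  ty2$allele2 <- truncate_allele(ty2$allele2, 2)
  expect_error(hla_ab_train(dt_cohort$gm, ty2, "HLA-A", 4,
                            n_classifiers = 2, seed = 1),
               "resolution")
})

test_that("a monomorphic flank is rejected", {
  gm <- dt_cohort$gm
  gm$dosage[] <- 1L
  expect_error(hla_ab_train(gm, dt_cohort$typing, "HLA-A", 4,
                            n_classifiers = 2, seed = 1),
               "monomorphic")
})

test_that("the 7:3 internal-validation split uses round()", {
  expect_equal(hlapheno:::.validation_split(845),
               c(train = 592, validation = 253))
  expect_equal(hlapheno:::.validation_split(10),
               c(train = 7, validation = 3))
})

test_that("internal validation is exact on a deterministic-tagging cohort", {
  v <- hla_internal_validation(dt_cohort$gm, dt_cohort$typing, "HLA-A", 4,
                               seed = 6, n_classifiers = 4)
  expect_equal(v$accuracy, 1.0)
  expect_equal(v$call_rate, 1.0)
  expect_equal(v$n_train + v$n_validation, length(dt_cohort$gm$samples))
})

test_that("a half-right heterozygote contributes 1/2 to per-allele accuracy", {
  calls <- data.frame(sample = "s1", gene = "HLA-A",
                      allele1 = "A*01:01", allele2 = "A*03:01",
                      posterior = 1, called = TRUE)
  truth <- data.frame(sample = "s1", gene = "HLA-A",
                      allele1 = "A*01:01", allele2 = "A*02:01")
  expect_equal(call_accuracy(calls, truth, "HLA-A"), 0.5)
})

test_that("models survive a JSON round-trip bit-for-bit in behaviour", {
  m <- hla_ab_train(dt_cohort$gm, dt_cohort$typing, "HLA-A", 4,
                    n_classifiers = 3, seed = 7)
  f <- withr::local_tempfile(fileext = ".json")
  write_hla_model(m, f)
  m2 <- read_hla_model(f)
  expect_equal(m2$alleles, m$alleles)
  expect_equal(m2$classifiers[[1]]$freq, m$classifiers[[1]]$freq)
  c1 <- predict(m, dt_cohort$gm); c2 <- predict(m2, dt_cohort$gm)
  expect_identical(c1$allele1, c2$allele1)
  expect_identical(c1$allele2, c2$allele2)
  expect_identical(c1$called, c2$called)
  expect_equal(c1$posterior, c2$posterior, tolerance = 1e-12)
})

test_that("truncated or version-less model files error cleanly", {
  m <- hla_ab_train(dt_cohort$gm, dt_cohort$typing, "HLA-A", 4,
                    n_classifiers = 2, seed = 8)
  f <- withr::local_tempfile(fileext = ".json")
  write_hla_model(m, f)
  txt <- readLines(f, warn = FALSE)
  half <- substr(paste(txt, collapse = ""), 1, 200)
  f2 <- withr::local_tempfile(fileext = ".json")
  writeLines(half, f2)
  expect_error(read_hla_model(f2), "parse|version")
  f3 <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(gene = "HLA-A"), f3, auto_unbox = TRUE)
  expect_error(read_hla_model(f3), "version")
})

test_that("ensemble averaging is no worse than the weakest classifier", {
  pool <- simulate_reference_pool(400, 20, c(4), 0.85, seed = 35)
  coh <- simulate_cohort(pool, 250, seed = 36)
  m <- hla_ab_train(coh$genotypes, coh$typing, "HLA-A", 4,
                    n_classifiers = 6, seed = 9)
  ens <- predict(m, coh$genotypes, call_threshold = 0)
  acc_ens <- call_accuracy(ens, coh$typing, "HLA-A")
  worst <- min(vapply(m$classifiers, `[[`, 1.0, "oob_accuracy"))
  expect_gte(acc_ens, worst)
})
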