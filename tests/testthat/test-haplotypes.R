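test_that("phase-unambiguous cohorts reduce EM to direct counting", {
  ty <- rbind(
    data.frame(sample = sprintf("s%d", 1:6), gene = "HLA-A",
               allele1 = rep(c("A*01:01", "A*02:01"), c(4, 2)),
               allele2 = rep(c("A*01:01", "A*02:01"), c(4, 2))),
    data.frame(sample = sprintf("s%d", 1:6), gene = "HLA-B",
               allele1 = rep(c("B*01:01", "B*02:01"), c(4, 2)),
               allele2 = rep(c("B*01:01", "B*02:01"), c(4, 2))))
  hf <- em_haplotype_frequencies(ty, c("HLA-A", "HLA-B"))
  expect_equal(hf$haplotypes$haplotype,
               c("A*01:01-B*01:01", "A*02:01-B*02:01"))
  expect_equal(hf$haplotypes$frequency, c(4 / 6, 2 / 6), tolerance = 1e-9)
})

test_that("two-gene EM matches the brute-force likelihood oracle to 1e-6", {
  set.seed(121)
  freqs <- c(0.4, 0.3, 0.2, 0.1)
  haps <- expand.grid(A = c("A*01:01", "A*02:01"),
                      B = c("B*01:01", "B*02:01"),
                      stringsAsFactors = FALSE)
  n <- 30
  i1 <- sample(4, n, TRUE, freqs); i2 <- sample(4, n, TRUE, freqs)
  ty <- rbind(
    data.frame(sample = sprintf("s%02d", 1:n), gene = "HLA-A",
               allele1 = pmin(haps$A[i1], haps$A[i2]),
               allele2 = pmax(haps$A[i1], haps$A[i2])),
    data.frame(sample = sprintf("s%02d", 1:n), gene = "HLA-B",
               allele1 = pmin(haps$B[i1], haps$B[i2]),
               allele2 = pmax(haps$B[i1], haps$B[i2])))
  hf <- em_haplotype_frequencies(ty, c("HLA-A", "HLA-B"), tol = 1e-13,
                                 max_iter = 10000)
  em_freq <- setNames(hf$haplotypes$frequency, hf$haplotypes$haplotype)
  obsA1 <- ty$allele1[ty$gene == "HLA-A"]
  obsA2 <- ty$allele2[ty$gene == "HLA-A"]
  obsB1 <- ty$allele1[ty$gene == "HLA-B"]
  obsB2 <- ty$allele2[ty$gene == "HLA-B"]
  loglik <- function(f) {
    ll <- 0
    for (i in seq_len(n)) {
      pr <- 0
      for (a in 1:4) for (b in 1:4) {
        if (min(haps$A[a], haps$A[b]) == obsA1[i] &&
            max(haps$A[a], haps$A[b]) == obsA2[i] &&
            min(haps$B[a], haps$B[b]) == obsB1[i] &&
            max(haps$B[a], haps$B[b]) == obsB2[i])
          pr <- pr + f[a] * f[b]
      }
      ll <- ll + log(pr)
    }
    ll
  }
  f_or <- simplex_mle(loglik, 4, restarts = 5, seed = 122)
  names(f_or) <- paste(haps$A, haps$B, sep = "-")
  common <- names(em_freq)
  expect_equal(unname(em_freq[common]), unname(f_or[common]),
               tolerance = 1e-6)
})

test_that("frequencies sum to one and the log-likelihood never decreases", {
  pool <- simulate_reference_pool(500, 20, c(3, 3, 3), 0.9, seed = 123)
  coh <- simulate_cohort(pool, 400, seed = 124)
  hf <- em_haplotype_frequencies(coh$typing, pool$genes)
  expect_equal(sum(hf$haplotypes$frequency), 1, tolerance = 1e-6)
  # per-insertion final log-likelihoods are recorded; each EM pass also
  # asserts monotonicity internally and would stop() on a decrease
  expect_true(all(is.finite(hf$ll_trace)))
})

test_that("subject order does not change the EM fixed point", {
  pool <- simulate_reference_pool(400, 16, c(3, 3), 0.9, seed = 125)
  coh <- simulate_cohort(pool, 300, seed = 126)
  ty <- coh$typing
  hf1 <- em_haplotype_frequencies(ty, pool$genes, tol = 1e-12)
  set.seed(127)
  samp_perm <- sample(unique(ty$sample))
  ty2 <- ty[order(match(ty$sample, samp_perm)), ]
  hf2 <- em_haplotype_frequencies(ty2, pool$genes, tol = 1e-12)
  m <- match(hf1$haplotypes$haplotype, hf2$haplotypes$haplotype)
  expect_false(anyNA(m))
  expect_equal(hf2$haplotypes$frequency[m], hf1$haplotypes$frequency,
               tolerance = 1e-6)
})

test_that("uncalled subjects are excluded with a warning; none is an error", {
  ty <- rbind(
    data.frame(sample = c("s1", "s2", "s3"), gene = "HLA-A",
               allele1 = "A*01:01", allele2 = "A*01:01"),
    data.frame(sample = c("s1", "s2"), gene = "HLA-B",
               allele1 = "B*01:01", allele2 = "B*01:01"))
  expect_warning(hf <- em_haplotype_frequencies(ty, c("HLA-A", "HLA-B")),
                 "excluded")
  expect_equal(hf$n_subjects, 2L)
  only_a <- ty[ty$gene == "HLA-A", ]
  only_a$sample <- paste0("x", seq_len(nrow(only_a)))
  both <- rbind(only_a, data.frame(sample = "x1", gene = "HLA-B",
                                   allele1 = "B*01:01",
                                   allele2 = "B*01:01"))
  expect_error(
    suppressWarnings(em_haplotype_frequencies(both, c("HLA-A", "HLA-B"))),
    "fewer than 2")
})

test_that("top_haplotypes ranks totally with cumulative frequencies", {
  pool <- simulate_reference_pool(400, 16, c(3, 3), 0.9, seed = 128)
  coh <- simulate_cohort(pool, 300, seed = 129)
  hf <- em_haplotype_frequencies(coh$typing, pool$genes)
  top <- top_haplotypes(hf, k = 3)
  expect_equal(top$rank, 1:3)
  expect_true(all(diff(top$frequency) <= 0))
  expect_equal(top$cumulative, cumsum(top$frequency))
  expect_match(top$haplotype[1], "^A\\*[0-9:]+-C\\*[0-9:]+$")
  all_h <- top_haplotypes(hf, k = 10000)
  expect_equal(nrow(all_h), nrow(hf$haplotypes))
})

test_that("a single-haplotype cohort reports frequency 1", {
  ty <- rbind(
    data.frame(sample = sprintf("s%d", 1:3), gene = "HLA-A",
               allele1 = "A*33:03", allele2 = "A*33:03"),
    data.frame(sample = sprintf("s%d", 1:3), gene = "HLA-B",
               allele1 = "B*58:01", allele2 = "B*58:01"))
  hf <- em_haplotype_frequencies(ty, c("HLA-A", "HLA-B"))
  top <- top_haplotypes(hf, 1)
  expect_equal(top$haplotype, "A*33:03-B*58:01")
  expect_equal(top$frequency, 1.0)
})
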