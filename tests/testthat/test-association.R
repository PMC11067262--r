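test_that("inverse-normal transform has the promised rank properties", {
  set.seed(51)
  x <- rnorm(11)
  t <- inverse_normal_transform(x)
  expect_equal(t[which(rank(x) == 6)], 0, tolerance = 1e-12)  # odd-n median
  expect_equal(order(t), order(x))                            # monotone
  x2 <- c(x, NA)
  t2 <- inverse_normal_transform(x2)
  expect_true(is.na(t2[12]))
  expect_equal(t2[1:11], t)
  big <- inverse_normal_transform(rnorm(10000))
  expect_lt(abs(mean(big)), 0.01)
  expect_lt(abs(sd(big) - 1), 0.02)
  expect_error(inverse_normal_transform(rep(3, 5)), "identical")
  expect_error(inverse_normal_transform(c(1, NA, NA)), "non-missing")
})

test_that("logistic association matches an independent Newton MLE oracle", {
  set.seed(52)
  n <- 20
  d <- rbinom(n, 2, 0.4)
  cov <- data.frame(z = rnorm(n))
  y <- rbinom(n, 1, plogis(-0.5 + 0.6 * d))
  r <- logistic_assoc(d, y, cov)
  X <- cbind(1, d, cov$z)
  b_or <- newton_logistic(X, y)
  expect_equal(r$beta, unname(b_or[2]), tolerance = 1e-6)
  expect_equal(r$or, exp(r$beta))
  expect_equal(r$ci_lower, exp(r$beta - 1.96 * r$se))
})

test_that("logistic association rejects degenerate inputs", {
  y <- rbinom(50, 1, 0.3)
  expect_error(logistic_assoc(rep(1, 50), y), "zero variance")
  expect_error(logistic_assoc(rbinom(50, 2, 0.3), rep(1, 50)),
               "single class")
})

test_that("separation triggers the Firth fallback with a finite estimate", {
  # perfectly separated fixture: every carrier is a case
  d <- c(rep(0, 30), rep(1, 10))
  y <- c(rep(0, 30), rep(1, 10))
  r <- logistic_assoc(d, y)
  expect_equal(r$method, "firth")
  expect_true(is.finite(r$beta) && is.finite(r$se))
  expect_gt(r$beta, 0)
})

test_that("logistic type-I error is calibrated at the 5 percent level", {
  set.seed(53)
  n <- 500; reps <- 10000
  hits <- 0L
  d_all <- matrix(rbinom(n * reps, 2, 0.3), n, reps)
  y_all <- matrix(rbinom(n * reps, 1, 0.3), n, reps)
  for (i in seq_len(reps)) {
    r <- logistic_assoc(d_all[, i], y_all[, i])
    hits <- hits + (r$p < 0.05)
  }
  expect_gte(hits / reps, 0.04)
  expect_lte(hits / reps, 0.06)
})

test_that("quantitative association equals the normal-equations oracle", {
  set.seed(54)
  n <- 60
  d <- rbinom(n, 2, 0.4)
  cov <- toy_covariates(n, seed = 55)
  y <- 0.4 * d + 0.1 * cov$sex + rnorm(n)
  r <- quantitative_assoc(d, y, cov)
  # oracle: residualize, transform, then closed-form OLS
  C <- cbind(1, as.matrix(cov))
  res <- y - C %*% solve(crossprod(C), crossprod(C, y))
  t_res <- qnorm((rank(res) - 3 / 8) / (n + 1 / 4))
  X <- cbind(1, d)
  b_or <- solve(crossprod(X), crossprod(X, t_res))
  expect_equal(r$beta, unname(b_or[2]), tolerance = 1e-8)
  s2 <- sum((t_res - X %*% b_or)^2) / (n - 2)
  se_or <- sqrt(diag(solve(crossprod(X))) * s2)[2]
  expect_equal(r$se, unname(se_or), tolerance = 1e-8)
})

test_that("quantitative association is invariant to affine rescaling of y", {
  set.seed(56)
  n <- 120
  d <- rbinom(n, 2, 0.3)
  cov <- toy_covariates(n, seed = 57)
  y <- 0.2 * d + rnorm(n)
  r1 <- quantitative_assoc(d, y, cov)
  r2 <- quantitative_assoc(d, 100 + 7 * y, cov)
  expect_equal(r1$beta, r2$beta, tolerance = 1e-10)
  expect_equal(r1$p, r2$p, tolerance = 1e-10)
})

test_that("null quantitative p-values are uniform (KS over 2000 reps)", {
  set.seed(58)
  n <- 300; reps <- 2000
  cov <- toy_covariates(n, seed = 59)
  ps <- vapply(seq_len(reps), function(i) {
    quantitative_assoc(rbinom(n, 2, 0.3), rnorm(n), cov)$p
  }, 1.0)
  expect_gt(suppressWarnings(ks.test(ps, "punif"))$p.value, 0.01)
})

test_that("quantitative association rejects constant dosage and collinearity", {
  cov <- toy_covariates(40, seed = 60)
  y <- rnorm(40)
  expect_error(quantitative_assoc(rep(2, 40), y, cov), "zero variance")
  cov2 <- cov
  cov2$dup <- cov2$sex
  expect_error(quantitative_assoc(rbinom(40, 2, 0.3), y, cov2), "collinear")
})

test_that("omnibus df equals residues minus one", {
  set.seed(61)
  n <- 400
  cov <- toy_covariates(n, seed = 62)
  y <- rnorm(n)
  for (k in 2:4) {
    idx <- replicate(2, sample(k, n, TRUE))
    D <- sapply(seq_len(k), function(r) rowSums(idx == r))
    colnames(D) <- LETTERS[seq_len(k)]
    r <- omnibus_test(D, y, cov, "quantitative")
    expect_equal(r$df, k - 1L)
    expect_equal(r$n_residues, k)
    expect_gte(r$stat, 0)
  }
})

test_that("the df-1 omnibus agrees with the biallelic LRT on the same residue", {
  set.seed(63)
  n <- 500
  cov <- toy_covariates(n, seed = 64)
  idx <- replicate(2, sample(2, n, TRUE, prob = c(0.7, 0.3)))
  D <- sapply(1:2, function(r) rowSums(idx == r))
  colnames(D) <- c("A", "Q")
  y <- 0.1 * D[, "Q"] + rnorm(n)
  r_omni <- omnibus_test(D, y, cov, "quantitative")
  # direct biallelic LRT on the minor residue over the same transformed trait
  t_res <- hlapheno:::.int_residuals(y, cov)
  rss0 <- sum((t_res - mean(t_res))^2)
  X <- cbind(1, D[, "Q"])
  rss1 <- sum(qr.resid(qr(X), t_res)^2)
  lrt <- n * log(rss0 / rss1)
  p_or <- pchisq(lrt, 1, lower.tail = FALSE)
  expect_equal(r_omni$p, p_or, tolerance = 1e-9)
})

test_that("binary omnibus uses the logistic deviance difference", {
  set.seed(65)
  n <- 600
  cov <- toy_covariates(n, seed = 66)
  idx <- replicate(2, sample(3, n, TRUE))
  D <- sapply(1:3, function(r) rowSums(idx == r))
  colnames(D) <- c("A", "Q", "H")
  y <- rbinom(n, 1, 0.2)
  r <- omnibus_test(D, y, cov, "binary")
  expect_equal(r$df, 2L)
  expect_gte(r$stat, 0)
  expect_true(r$p > 0 && r$p <= 1)
})

test_that("run_phewas finds a planted effect as the trait's top signal", {
  set.seed(67)
  n <- 3000
  pheno <- toy_pheno_base(n, seed = 68)
  cat0 <- toy_catalogue(n, 30, seed = 69)
  d <- cat0$dosage[, "rs010"]
  pheno$dz <- rbinom(n, 1, plogis(qlogis(0.1) + log(2) * d))
  pheno$qt <- 0.15 * cat0$dosage[, "rs020"] + rnorm(n)
  pheno <- as_pheno(pheno, binary = "dz", quantitative = "qt")
  res <- run_phewas(cat0, pheno)
  bb <- res$biallelic
  top_dz <- bb$variant[bb$trait == "dz"][which.min(bb$p[bb$trait == "dz"])]
  top_qt <- bb$variant[bb$trait == "qt"][which.min(bb$p[bb$trait == "qt"])]
  expect_equal(top_dz, "rs010")
  expect_equal(top_qt, "rs020")
  expect_equal(nrow(bb), 2L * 30L)  # variants x traits accounting
})

test_that("single-class traits are skipped with a warning", {
  n <- 200
  pheno <- toy_pheno_base(n, seed = 70)
  pheno$dead <- 0
  pheno <- as_pheno(pheno, binary = "dead")
  cat0 <- toy_catalogue(n, 3, seed = 71)
  expect_warning(res <- run_phewas(cat0, pheno), "single class")
  expect_equal(nrow(res$biallelic), 0L)
})
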