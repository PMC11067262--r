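# Shared fixture builders and independent oracles. Everything is generated
# in code; no binary fixtures.

# tiny genotype matrix with known dosages
tiny_gm <- function() {
  v <- data.frame(chrom = "6",
                  pos = c(28510120L, 30000000L, 33480577L, 33480578L),
                  id = c("v1", "v2", "v3", "v4"),
                  ref = "A", alt = "G", stringsAsFactors = FALSE)
  d <- rbind(c(0L, 1L, 2L, 0L),
             c(NA, 0L, 1L, 1L),
             c(2L, 2L, 0L, 2L))
  genotype_matrix(d, v, c("sA", "sB", "sC"))
}

# brute-force HWE oracle: enumerate heterozygote counts consistent with the
# allele counts, exact conditional probabilities via log-factorials
hwe_oracle <- function(n_hom_ref, n_het, n_hom_alt) {
  n <- n_hom_ref + n_het + n_hom_alt
  r <- 2 * min(n_hom_ref, n_hom_alt) + n_het
  if (r == 0) return(1)
  hs <- seq(r %% 2, min(r, 2 * n - r), by = 2)
  w <- vapply(hs, function(h) {
    exp(lfactorial(n) - lfactorial((r - h) / 2) - lfactorial(h) -
          lfactorial(n - (r + h) / 2) + h * log(2))
  }, 1.0)
  w <- w / sum(w)
  obs <- w[hs == n_het]
  min(1, sum(w[w <= obs + 1e-12 * obs]))
}

# independent logistic MLE: straight Newton-Raphson on the score equations
newton_logistic <- function(X, y, tol = 1e-12, max_iter = 100) {
  beta <- rep(0, ncol(X))
  for (i in seq_len(max_iter)) {
    mu <- plogis(drop(X %*% beta))
    W <- mu * (1 - mu)
    step <- solve(crossprod(X, X * W), crossprod(X, y - mu))
    beta <- beta + drop(step)
    if (max(abs(step)) < tol) break
  }
  beta
}

# direct likelihood maximization over the haplotype simplex (softmax
# parameterization, BFGS with restarts); loglik_fn maps a frequency vector
# to the data log-likelihood
simplex_mle <- function(loglik_fn, k, restarts = 5, seed = 1) {
  set.seed(seed)
  nll <- function(theta) {
    f <- exp(c(theta, 0)); f <- f / sum(f)
    -loglik_fn(f)
  }
  best <- NULL
  for (s in seq_len(restarts)) {
    o <- optim(rnorm(k - 1), nll, method = "BFGS",
               control = list(maxit = 2000, reltol = 1e-16))
    if (is.null(best) || o$value < best$value) best <- o
  }
  f <- exp(c(best$par, 0))
  f / sum(f)
}

# standard covariate table for simulation-based tests
toy_covariates <- function(n, seed = 1) {
  set.seed(seed)
  cov <- data.frame(sex = rbinom(n, 1, 0.4), age = rnorm(n, 50, 10))
  cov$age2 <- cov$age^2
  cov
}

# catalogue with independent SNVs and optional planted columns
toy_catalogue <- function(n, m, seed = 1, extra = NULL) {
  set.seed(seed)
  X <- sapply(runif(m, 0.2, 0.4), function(p) rbinom(n, 2, p))
  meta <- data.frame(id = sprintf("rs%03d", seq_len(m)), source = "snv",
                     gene = "-", stringsAsFactors = FALSE)
  if (!is.null(extra)) {
    X <- cbind(X, extra$dosage)
    meta <- rbind(meta, extra$meta)
  }
  samples <- sprintf("s%04d", seq_len(n))
  rownames(X) <- samples
  colnames(X) <- meta$id
  structure(list(dosage = X, meta = meta, positions = list(),
                 samples = samples), class = "variant_catalogue")
}

# phenotype table wrapper with the attributes run_phewas expects
as_pheno <- function(df, binary = character(0), quantitative = character(0)) {
  attr(df, "binary_traits") <- binary
  attr(df, "quantitative_traits") <- quantitative
  df
}

# full covariate set (sex, age, age2, 10 PCs) plus sample ids
toy_pheno_base <- function(n, seed = 1) {
  set.seed(seed)
  pcs <- matrix(rnorm(n * 10), n, 10, dimnames = list(NULL, paste0("PC", 1:10)))
  df <- data.frame(sample = sprintf("s%04d", seq_len(n)),
                   sex = rbinom(n, 1, 0.5), age = rnorm(n, 50, 10),
                   stringsAsFactors = FALSE)
  df$age2 <- df$age^2
  cbind(df, as.data.frame(pcs))
}

# per-allele accuracy between a call table and a truth typing table
call_accuracy <- function(calls, typing, gene) {
  ty <- typing[typing$gene == gene, , drop = FALSE]
  ty <- ty[match(calls$sample, ty$sample), , drop = FALSE]
  ok <- calls$called
  sum(mapply(hlapheno:::.pair_match,
             calls$allele1[ok], calls$allele2[ok],
             ty$allele1[ok], ty$allele2[ok])) / (2 * sum(ok))
}
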