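#' Rank-based inverse-normal transform
#'
#' Blom transform: qnorm((rank - 3/8) / (n + 1/4)) with average ranks for
#' ties; missing values are preserved in place.
#'
#' @param x numeric vector (at least 2 non-missing, not all identical).
#' @return transformed vector, same length and NA pattern as `x`.
#' @export
inverse_normal_transform <- function(x) {
  ok <- !is.na(x)
  if (sum(ok) < 2L) stop("need at least 2 non-missing values")
  if (length(unique(x[ok])) == 1L) stop("all values identical")
  r <- rank(x[ok], ties.method = "average")
  out <- x
  out[ok] <- stats::qnorm((r - 3 / 8) / (sum(ok) + 1 / 4))
  out
}

# Firth penalized logistic regression (Jeffreys-prior score adjustment),
# Newton-Raphson with step halving. Used as the separation fallback.
.firth_logistic <- function(X, y, max_iter = 100L, tol = 1e-8) {
  p <- ncol(X)
  beta <- rep(0, p)
  pll <- function(beta) {
    eta <- drop(X %*% beta)
    mu <- stats::plogis(eta)
    W <- mu * (1 - mu)
    XW <- X * sqrt(W)
    I <- crossprod(XW)
    sum(y * eta - log1p(exp(eta))) + 0.5 * determinant(I)$modulus
  }
  ll_old <- pll(beta)
  for (it in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    mu <- stats::plogis(eta)
    W <- mu * (1 - mu)
    XW <- X * W
    I <- crossprod(X, XW)
    Iinv <- solve(I)
    h <- rowSums((X %*% Iinv) * XW)  # hat diagonal
    U <- crossprod(X, y - mu + h * (0.5 - mu))
    step <- drop(Iinv %*% U)
    lam <- 1
    repeat {
      bn <- beta + lam * step
      ll_new <- pll(bn)
      if (ll_new >= ll_old - 1e-10 || lam < 1e-4) break
      lam <- lam / 2
    }
    conv <- max(abs(bn - beta)) < tol
    beta <- bn; ll_old <- ll_new
    if (conv) break
  }
  eta <- drop(X %*% beta)
  W <- stats::plogis(eta) * (1 - stats::plogis(eta))
  se <- sqrt(diag(solve(crossprod(X, X * W))))
  list(coef = beta, se = se, loglik = as.numeric(ll_old))
}

.as_covmatrix <- function(covariates, n) {
  if (is.null(covariates)) return(matrix(numeric(0), n, 0L))
  C <- as.matrix(as.data.frame(covariates))
  storage.mode(C) <- "double"
  C
}

#' Additive logistic association for a binary trait
#'
#' Maximum-likelihood fit of logit P(y = 1) = a + b dosage + covariates, on
#' complete cases. On separation or non-convergence the fit falls back to
#' Firth penalized logistic regression (flagged in `method`). Reports the
#' per-copy log-odds, Wald SE and p, and the odds ratio with 95 CI.
#'
#' @param dosage additive dosage vector.
#' @param y binary 0/1 trait.
#' @param covariates optional data.frame/matrix of covariates.
#' @param gws genome-wide significance threshold (default 5e-8).
#' @return one-row data.frame: `beta` (log-OR), `se`, `or`, `ci_lower`,
#'   `ci_upper`, `p`, `n`, `method`, `gws`.
#' @export
logistic_assoc <- function(dosage, y, covariates = NULL, gws = 5e-8) {
  C <- .as_covmatrix(covariates, length(y))
  ok <- !is.na(dosage) & !is.na(y)
  if (ncol(C)) ok <- ok & stats::complete.cases(C)
  d <- dosage[ok]; yy <- y[ok]
  if (length(unique(yy)) < 2L) stop("trait has a single class after missing-data removal")
  if (stats::var(d) == 0) stop("zero variance in dosage")
  X <- cbind(`(Intercept)` = 1, dosage = d,
             if (ncol(C)) C[ok, , drop = FALSE])
  fit <- suppressWarnings(stats::glm.fit(X, yy, family = stats::binomial()))
  # Wald statistics from the usual information matrix
  mu <- fit$fitted.values
  W <- mu * (1 - mu)
  info <- crossprod(X, X * W)
  se <- tryCatch(sqrt(diag(solve(info))), error = function(e) rep(NA_real_, ncol(X)))
  beta <- fit$coefficients
  method <- "ml"
  bad <- !fit$converged || anyNA(beta) || anyNA(se) ||
    abs(beta[2L]) > 15 || se[2L] > 10
  if (bad) {
    ff <- .firth_logistic(X, yy)
    beta <- ff$coef; se <- ff$se
    method <- "firth"
  }
  b <- unname(beta[2L]); s <- unname(se[2L])
  p <- 2 * stats::pnorm(-abs(b / s))
  data.frame(beta = b, se = s, or = exp(b),
             ci_lower = exp(b - 1.96 * s), ci_upper = exp(b + 1.96 * s),
             p = p, n = sum(ok), method = method, gws = p < gws,
             stringsAsFactors = FALSE)
}

# stage-1/2 of the quantitative pipeline: covariate residuals, then INT
.int_residuals <- function(y, covariates) {
  C <- .as_covmatrix(covariates, length(y))
  ok <- !is.na(y)
  if (ncol(C)) {
    ok <- ok & stats::complete.cases(C)
    X <- cbind(1, C[ok, , drop = FALSE])
    qr_x <- qr(X)
    if (qr_x$rank < ncol(X)) {
      drop <- colnames(X)[-seq_len(qr_x$rank)]
      stop("collinear covariates: ",
           paste(colnames(X)[qr_x$pivot[(qr_x$rank + 1):ncol(X)]],
                 collapse = ", "))
    }
    res <- qr.resid(qr_x, y[ok])
  } else {
    res <- y[ok] - mean(y[ok])
  }
  out <- rep(NA_real_, length(y))
  out[ok] <- res
  inverse_normal_transform(out)
}

#' Additive linear association for a quantitative trait
#'
#' Three-stage procedure: (1) OLS of the raw trait on the covariates,
#' keeping residuals; (2) rank-based inverse-normal transform of the
#' residuals; (3) OLS of the transformed residuals on the dosage (with
#' intercept, plus any conditioning covariates). The reported beta is in SD
#' units of the transformed trait.
#'
#' @param dosage additive dosage vector.
#' @param y quantitative trait.
#' @param covariates covariates for stage 1.
#' @param condition_on optional matrix of conditioning dosages entering
#'   stage 3 alongside the test dosage.
#' @param gws significance threshold (default 5e-8).
#' @return one-row data.frame: `beta`, `se`, `p`, `n`, `gws`.
#' @export
quantitative_assoc <- function(dosage, y, covariates = NULL,
                               condition_on = NULL, gws = 5e-8) {
  t_res <- .int_residuals(y, covariates)
  ok <- !is.na(dosage) & !is.na(t_res)
  Z <- if (is.null(condition_on)) NULL else as.matrix(condition_on)
  if (!is.null(Z)) ok <- ok & stats::complete.cases(Z)
  d <- dosage[ok]
  if (stats::var(d) == 0) stop("zero variance in dosage")
  X <- cbind(1, dosage = d, if (!is.null(Z)) Z[ok, , drop = FALSE])
  fit <- stats::lm.fit(X, t_res[ok])
  if (fit$rank < ncol(X)) stop("collinear regressors in stage-3 model")
  rdf <- length(d) - fit$rank
  sigma2 <- sum(fit$residuals^2) / rdf
  se <- sqrt(diag(chol2inv(chol(crossprod(X)))) * sigma2)
  b <- unname(fit$coefficients["dosage"])
  s <- unname(se[2L])
  p <- 2 * stats::pt(-abs(b / s), rdf)
  data.frame(beta = b, se = s, p = p, n = sum(ok), gws = p < gws,
             stringsAsFactors = FALSE)
}

#' Multiallelic omnibus likelihood-ratio test
#'
#' Tests one amino-acid position: the full model carries the dosages of all
#' residues but the reference (the most frequent residue; ties broken
#' lexicographically) on top of the covariates, the null model carries the
#' covariates alone. Binary traits use the logistic likelihood; quantitative
#' traits use the Gaussian likelihood on covariate-residualized,
#' inverse-normal transformed values (so the null matches the biallelic
#' scan). The statistic is 2(ll_full - ll_null) ~ chi-squared with df =
#' (number of residues - 1), reduced if collinear residues must be dropped.
#'
#' @param residue_dosage subjects x residues dosage matrix (colnames =
#'   residues).
#' @param y trait vector.
#' @param covariates covariate data.frame/matrix.
#' @param trait_type "binary" or "quantitative".
#' @param condition_on optional conditioning dosage matrix.
#' @param gws significance threshold.
#' @return one-row data.frame: `n_residues`, `stat`, `df`, `p`, `n`, `gws`.
#' @export
omnibus_test <- function(residue_dosage, y, covariates = NULL,
                         trait_type = c("quantitative", "binary"),
                         condition_on = NULL, gws = 5e-8) {
  trait_type <- match.arg(trait_type)
  D <- as.matrix(residue_dosage)
  stopifnot(ncol(D) >= 2L)
  freq <- colMeans(D, na.rm = TRUE)
  ref <- colnames(D)[order(-freq, colnames(D))][1L]
  Dt <- D[, setdiff(colnames(D), ref), drop = FALSE]
  n_res <- ncol(D)
  Z <- if (is.null(condition_on)) NULL else as.matrix(condition_on)

  if (trait_type == "quantitative") {
    t_res <- .int_residuals(y, covariates)
    ok <- !is.na(t_res) & stats::complete.cases(Dt)
    if (!is.null(Z)) ok <- ok & stats::complete.cases(Z)
    yy <- t_res[ok]
    X0 <- cbind(rep(1, sum(ok)), if (!is.null(Z)) Z[ok, , drop = FALSE])
    X1 <- cbind(X0, Dt[ok, , drop = FALSE])
    q1 <- qr(X1)
    dropped <- ncol(X1) - q1$rank
    if (dropped > 0L) warning("dropped ", dropped, " collinear residue column(s)")
    n <- length(yy)
    rss0 <- sum(qr.resid(qr(X0), yy)^2)
    rss1 <- sum(qr.resid(q1, yy)^2)
    stat <- n * log(rss0 / rss1)
    df <- q1$rank - qr(X0)$rank
  } else {
    ok <- !is.na(y) & stats::complete.cases(Dt)
    C <- .as_covmatrix(covariates, length(y))
    if (ncol(C)) ok <- ok & stats::complete.cases(C)
    if (!is.null(Z)) ok <- ok & stats::complete.cases(Z)
    yy <- y[ok]
    X0 <- cbind(rep(1, sum(ok)), if (ncol(C)) C[ok, , drop = FALSE],
                if (!is.null(Z)) Z[ok, , drop = FALSE])
    Xd <- Dt[ok, , drop = FALSE]
    q_full <- qr(cbind(X0, Xd))
    dropped <- ncol(X0) + ncol(Xd) - q_full$rank
    if (dropped > 0L) warning("dropped ", dropped, " collinear residue column(s)")
    f0 <- suppressWarnings(stats::glm.fit(X0, yy, family = stats::binomial()))
    f1 <- suppressWarnings(stats::glm.fit(cbind(X0, Xd), yy,
                                          family = stats::binomial()))
    stat <- f0$deviance - f1$deviance
    df <- f1$rank - f0$rank
    n <- length(yy)
  }
  stat <- max(stat, 0)
  p <- stats::pchisq(stat, df = df, lower.tail = FALSE)
  data.frame(n_residues = n_res, stat = stat, df = df, p = p, n = n,
             gws = p < gws, stringsAsFactors = FALSE)
}

#' Phenome-wide association scan
#'
#' Runs every biallelic catalogue variant against every trait (logistic for
#' binary, the three-stage linear procedure for quantitative) and every
#' multiallelic amino-acid position through the omnibus likelihood-ratio
#' test. Traits with a single observed class are skipped with a warning.
#'
#' @param cat a QCed `variant_catalogue`.
#' @param pheno phenotype table from [simulate_phenotypes()] or equivalent
#'   (attributes `binary_traits` / `quantitative_traits`, covariate columns
#'   `sex`, `age`, `age2`, `PC*`).
#' @param gws genome-wide significance threshold (default 5e-8).
#' @return list of class `phewas_result`: `biallelic` (variant x trait
#'   rows), `omnibus` (position x trait rows), `gws` threshold.
#' @export
run_phewas <- function(cat, pheno, gws = 5e-8) {
  stopifnot(inherits(cat, "variant_catalogue"))
  idx <- match(cat$samples, pheno$sample)
  stopifnot(!anyNA(idx))
  ph <- pheno[idx, , drop = FALSE]
  covars <- .pheno_covariates(ph)
  btr <- attr(pheno, "binary_traits")
  qtr <- attr(pheno, "quantitative_traits")
  rows <- list(); orows <- list()
  for (trait in c(btr, qtr)) {
    y <- ph[[trait]]
    type <- if (trait %in% btr) "binary" else "quantitative"
    if (type == "binary" && length(unique(y[!is.na(y)])) < 2L) {
      warning("trait ", trait, " has a single class; skipped")
      next
    }
    for (j in seq_len(ncol(cat$dosage))) {
      d <- cat$dosage[, j]
      res <- tryCatch({
        if (type == "binary") {
          r <- logistic_assoc(d, y, covars, gws = gws)
          data.frame(variant = cat$meta$id[j], trait = trait,
                     class = cat$meta$source[j], gene = cat$meta$gene[j],
                     effect = r$beta, se = r$se, or = r$or,
                     ci_lower = r$ci_lower, ci_upper = r$ci_upper,
                     p = r$p, n = r$n, gws = r$gws, stringsAsFactors = FALSE)
        } else {
          r <- quantitative_assoc(d, y, covars, gws = gws)
          data.frame(variant = cat$meta$id[j], trait = trait,
                     class = cat$meta$source[j], gene = cat$meta$gene[j],
                     effect = r$beta, se = r$se, or = NA_real_,
                     ci_lower = NA_real_, ci_upper = NA_real_,
                     p = r$p, n = r$n, gws = r$gws, stringsAsFactors = FALSE)
        }
      }, error = function(e) NULL)
      if (!is.null(res)) rows[[length(rows) + 1L]] <- res
    }
    for (pn in names(cat$positions)) {
      pp <- cat$positions[[pn]]
      res <- tryCatch({
        r <- omnibus_test(pp$dosage, y, covars, trait_type = type, gws = gws)
        data.frame(position = pn, gene = pp$gene, trait = trait,
                   n_residues = r$n_residues, stat = r$stat, df = r$df,
                   p = r$p, n = r$n, gws = r$gws, stringsAsFactors = FALSE)
      }, error = function(e) NULL)
      if (!is.null(res)) orows[[length(orows) + 1L]] <- res
    }
  }
  empty_b <- data.frame(variant = character(0), trait = character(0),
                        class = character(0), gene = character(0),
                        effect = numeric(0), se = numeric(0), or = numeric(0),
                        ci_lower = numeric(0), ci_upper = numeric(0),
                        p = numeric(0), n = integer(0), gws = logical(0))
  empty_o <- data.frame(position = character(0), gene = character(0),
                        trait = character(0), n_residues = integer(0),
                        stat = numeric(0), df = integer(0), p = numeric(0),
                        n = integer(0), gws = logical(0))
  structure(list(biallelic = if (length(rows)) do.call(rbind, rows) else empty_b,
                 omnibus = if (length(orows)) do.call(rbind, orows) else empty_o,
                 gws = gws),
            class = "phewas_result")
}

#' @export
print.phewas_result <- function(x, ...) {
  cat("PheWAS scan:", nrow(x$biallelic), "biallelic tests,",
      nrow(x$omnibus), "omnibus tests\n")
  cat("  genome-wide significant (p <", format(x$gws), "):",
      sum(x$biallelic$gws) + sum(x$omnibus$gws), "\n")
  invisible(x)
}

# standard covariate set: sex, age, age2 and all PCs present
.pheno_covariates <- function(pheno) {
  pcs <- grep("^PC[0-9]+$", names(pheno), value = TRUE)
  pheno[, c("sex", "age", "age2", pcs), drop = FALSE]
}
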