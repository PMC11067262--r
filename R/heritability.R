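#' Genetic relationship matrix over catalogue variants
#'
#' Standardizes each dosage column to mean 0 / variance 1 using the observed
#' allele frequency (mean 2p, variance 2p(1-p)), then averages per-pair
#' products over non-missing variants. On HWE data the diagonal averages
#' about 1. Monomorphic variants are skipped; an all-monomorphic input is an
#' error.
#'
#' @param dosage subjects x variants matrix (0/1/2/NA), e.g.
#'   `catalogue$dosage`.
#' @return list of class `grm`: `K` (symmetric subjects x subjects matrix),
#'   `n_variants`, `pair_counts`.
#' @export
compute_grm <- function(dosage) {
  X <- as.matrix(dosage)
  p <- colSums(X, na.rm = TRUE) / (2 * pmax(colSums(!is.na(X)), 1L))
  v <- apply(X, 2L, stats::var, na.rm = TRUE)
  keep <- p > 0 & p < 1 & !is.na(v) & v > 0
  if (sum(keep) < 2L) stop("need at least 2 polymorphic variants")
  X <- X[, keep, drop = FALSE]; p <- p[keep]
  Z <- sweep(X, 2L, 2 * p, "-")
  Z <- sweep(Z, 2L, sqrt(2 * p * (1 - p)), "/")
  miss <- is.na(Z)
  Z[miss] <- 0
  cnt <- tcrossprod((!miss) * 1)
  K <- tcrossprod(Z) / pmax(cnt, 1L)
  dimnames(K) <- list(rownames(X), rownames(X))
  structure(list(K = K, n_variants = ncol(Z), pair_counts = cnt),
            class = "grm")
}

#' @export
print.grm <- function(x, ...) {
  cat("GRM over", x$n_variants, "variants;", nrow(x$K), "subjects; mean",
      "diagonal", sprintf("%.3f", mean(diag(x$K))), "\n")
  invisible(x)
}

# regression-through-sums helpers for HE on all pairs i<j. The slope of
# z ~ 1 + x over pairs is computed from the pair sums; jackknife blocks
# subtract per-subject row contributions.
.he_slope <- function(Sx, Sz, Sxx, Sxz, np) {
  (np * Sxz - Sx * Sz) / (np * Sxx - Sx^2)
}

.he_pair_sums <- function(Xm, Zm) {
  # Xm, Zm symmetric with zero diagonal; sums over unordered pairs
  list(Sx = sum(Xm) / 2, Sz = sum(Zm) / 2,
       Sxx = sum(Xm^2) / 2, Sxz = sum(Xm * Zm) / 2,
       np = nrow(Xm) * (nrow(Xm) - 1) / 2)
}

# jackknife over subject blocks: recompute the slope with all pairs that
# involve a block removed
.he_jackknife <- function(Xm, Zm, n_blocks) {
  n <- nrow(Xm)
  blk <- rep(seq_len(n_blocks), length.out = n)
  full <- .he_pair_sums(Xm, Zm)
  X2 <- Xm^2; XZ <- Xm * Zm
  rx <- rowSums(Xm); rz <- rowSums(Zm); rxx <- rowSums(X2); rxz <- rowSums(XZ)
  theta <- numeric(n_blocks)
  for (b in seq_len(n_blocks)) {
    ib <- which(blk == b)
    nb <- length(ib)
    # pairs inside the block are double-subtracted by the row sums
    inx <- sum(Xm[ib, ib]) / 2; inz <- sum(Zm[ib, ib]) / 2
    inxx <- sum(X2[ib, ib]) / 2; inxz <- sum(XZ[ib, ib]) / 2
    Sx <- full$Sx - sum(rx[ib]) + inx
    Sz <- full$Sz - sum(rz[ib]) + inz
    Sxx <- full$Sxx - sum(rxx[ib]) + inxx
    Sxz <- full$Sxz - sum(rxz[ib]) + inxz
    np <- full$np - nb * (n - nb) - nb * (nb - 1) / 2
    theta[b] <- .he_slope(Sx, Sz, Sxx, Sxz, np)
  }
  theta
}

#' Univariate Haseman-Elston regression
#'
#' Estimates the variance fraction explained by the variants behind the GRM
#' by regressing phenotype cross-products y_i y_j on the relatedness K_ij
#' over all subject pairs i < j (diagonal excluded). The phenotype should
#' already be covariate-residualized and inverse-normal transformed (see
#' [inverse_normal_transform()]); it is centred and scaled here so the slope
#' is a variance fraction. The SE comes from a block jackknife over
#' subjects.
#'
#' @param y phenotype vector (no missing values).
#' @param grm a [compute_grm()] result.
#' @param n_blocks jackknife block count (default 100, capped at n).
#' @return object of class `he_fit`: `h2`, `se`, `n`, `method`.
#' @export
he_univariate <- function(y, grm, n_blocks = 100L) {
  stopifnot(inherits(grm, "grm"), !anyNA(y), length(y) == nrow(grm$K))
  K <- grm$K
  off <- K[upper.tri(K)]
  if (stats::var(off) < 1e-12) stop("no relatedness contrast in the GRM")
  y <- as.numeric(scale(y))
  Xm <- K; diag(Xm) <- 0
  Zm <- tcrossprod(y); diag(Zm) <- 0
  s <- .he_pair_sums(Xm, Zm)
  h2 <- .he_slope(s$Sx, s$Sz, s$Sxx, s$Sxz, s$np)
  B <- min(n_blocks, length(y))
  theta <- .he_jackknife(Xm, Zm, B)
  se <- sqrt((B - 1) / B * sum((theta - mean(theta))^2))
  structure(list(h2 = h2, se = se, n = length(y), n_blocks = B,
                 method = "HE-univariate"),
            class = "he_fit")
}

#' @export
print.he_fit <- function(x, ...) {
  cat(x$method, ": h2 =", sprintf("%.2f%%", 100 * x$h2),
      sprintf("(SE %.2f%%)", 100 * x$se), "on", x$n, "subjects\n")
  invisible(x)
}

#' Bivariate Haseman-Elston regression
#'
#' Estimates the genetic covariance between two traits by regressing
#' symmetrized cross-products (y1_i y2_j + y1_j y2_i)/2 on K_ij over pairs
#' i < j, and the genetic correlation r_g = cov_g / sqrt(h2_1 h2_2). The
#' estimate is clamped to [-1, 1] (clamping recorded); p-value from the
#' jackknife SE of r_g. r_g is undefined (NA) when either h2 is
#' non-positive.
#'
#' @param y1,y2 phenotype vectors on the shared subject set (prepared as in
#'   [he_univariate()]).
#' @param grm a [compute_grm()] result.
#' @param n_blocks jackknife block count.
#' @return object of class `he_rg`: `rg`, `cov_g`, `h2_1`, `h2_2`, `se`,
#'   `p`, `clamped`.
#' @export
he_bivariate <- function(y1, y2, grm, n_blocks = 100L) {
  stopifnot(length(y1) == length(y2))
  f1 <- he_univariate(y1, grm, n_blocks)
  f2 <- he_univariate(y2, grm, n_blocks)
  y1 <- as.numeric(scale(y1)); y2 <- as.numeric(scale(y2))
  Xm <- grm$K; diag(Xm) <- 0
  Zm <- (outer(y1, y2) + outer(y2, y1)) / 2; diag(Zm) <- 0
  s <- .he_pair_sums(Xm, Zm)
  cov_g <- .he_slope(s$Sx, s$Sz, s$Sxx, s$Sxz, s$np)
  if (f1$h2 <= 0 || f2$h2 <= 0) {
    return(structure(list(rg = NA_real_, cov_g = cov_g, h2_1 = f1$h2,
                          h2_2 = f2$h2, se = NA_real_, p = NA_real_,
                          clamped = FALSE), class = "he_rg"))
  }
  rg_raw <- cov_g / sqrt(f1$h2 * f2$h2)
  clamped <- abs(rg_raw) > 1
  rg <- max(-1, min(1, rg_raw))
  # jackknife r_g: recompute the three slopes per block
  B <- min(n_blocks, length(y1))
  Z1 <- tcrossprod(y1); diag(Z1) <- 0
  Z2 <- tcrossprod(y2); diag(Z2) <- 0
  t_cov <- .he_jackknife(Xm, Zm, B)
  t_h1 <- .he_jackknife(Xm, Z1, B)
  t_h2 <- .he_jackknife(Xm, Z2, B)
  ok <- t_h1 > 0 & t_h2 > 0
  t_rg <- ifelse(ok, t_cov / sqrt(pmax(t_h1 * t_h2, 1e-12)), rg)
  t_rg <- pmax(-1, pmin(1, t_rg))
  se <- sqrt((B - 1) / B * sum((t_rg - mean(t_rg))^2))
  p <- if (se > 0) 2 * stats::pnorm(-abs(rg / se)) else
    as.numeric(abs(rg) == 0)
  structure(list(rg = rg, cov_g = cov_g, h2_1 = f1$h2, h2_2 = f2$h2,
                 se = se, p = p, clamped = clamped),
            class = "he_rg")
}

#' @export
print.he_rg <- function(x, ...) {
  cat("HE-bivariate: rg =", sprintf("%.3f", x$rg),
      sprintf("(SE %.3f, p %.3g)", x$se, x$p),
      "; h2 =", sprintf("%.2f%% / %.2f%%", 100 * x$h2_1, 100 * x$h2_2), "\n")
  invisible(x)
}

#' FDR-filtered genetic-correlation network
#'
#' Benjamini-Hochberg FDR across all tested trait pairs; pairs with q below
#' `alpha` become signed, r_g-weighted edges; nodes are traits with at least
#' one edge.
#'
#' @param correlations data.frame with columns `trait1`, `trait2`, `rg`,
#'   `p`.
#' @param alpha FDR threshold (default 0.05).
#' @return list of class `rg_network`: `edges` (with `q`), `graph` (igraph,
#'   edge attribute `weight` = r_g).
#' @export
correlation_network <- function(correlations, alpha = 0.05) {
  stopifnot(all(c("trait1", "trait2", "rg", "p") %in% names(correlations)))
  correlations$q <- stats::p.adjust(correlations$p, method = "BH")
  edges <- correlations[!is.na(correlations$q) & correlations$q < alpha, ,
                        drop = FALSE]
  g <- igraph::graph_from_data_frame(
    edges[, c("trait1", "trait2")], directed = FALSE,
    vertices = unique(c(edges$trait1, edges$trait2)))
  if (nrow(edges)) igraph::E(g)$weight <- edges$rg
  structure(list(edges = edges, graph = g, alpha = alpha),
            class = "rg_network")
}

#' @export
print.rg_network <- function(x, ...) {
  cat("genetic-correlation network:", igraph::vcount(x$graph), "traits,",
      igraph::ecount(x$graph), "edges at FDR <", x$alpha, "\n")
  invisible(x)
}
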