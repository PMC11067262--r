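#' EM estimation of multilocus HLA haplotype frequencies
#'
#' Maximum-likelihood haplotype frequencies across several HLA genes from
#' unphased typings, by the standard EM for multilocus phase ambiguity:
#' the E-step distributes each subject's mass over all haplotype-pair
#' resolutions of their unordered genotypes, the M-step re-estimates
#' frequencies. Genes are inserted progressively in the given order with
#' pruning between insertions, so the haplotype support stays restricted to
#' combinations compatible with at least one subject. Initialization is the
#' product of marginal allele frequencies. Subjects missing a call at any
#' requested gene are excluded with a warning.
#'
#' @param typing typing/call table (`sample`, `gene`, `allele1`, `allele2`,
#'   optional logical `called`).
#' @param genes ordered character vector of genes to phase, e.g.
#'   `c("HLA-A", "HLA-C", "HLA-B", "HLA-DRB1", "HLA-DQB1")`.
#' @param tol log-likelihood convergence tolerance (default 1e-8).
#' @param max_iter EM iteration cap per insertion (default 1000).
#' @param prune frequency pruning threshold between insertions (default
#'   1e-7); haplotypes below 1e-6 are pruned from the output.
#' @return object of class `haplotype_freq`: data.frame `haplotypes`
#'   (`haplotype` as '-'-joined allele names, `frequency`), plus `genes`,
#'   `loglik`, `iterations`, `n_subjects`.
#' @export
em_haplotype_frequencies <- function(typing, genes, tol = 1e-8,
                                     max_iter = 1000L, prune = 1e-7) {
  if (!"called" %in% names(typing)) typing$called <- TRUE
  ty <- typing[typing$gene %in% genes & typing$called, , drop = FALSE]
  samples <- unique(typing$sample)
  p1 <- matrix(NA_character_, length(samples), length(genes))
  p2 <- p1
  for (gi in seq_along(genes)) {
    tg <- ty[ty$gene == genes[gi], , drop = FALSE]
    m <- match(samples, tg$sample)
    p1[, gi] <- tg$allele1[m]
    p2[, gi] <- tg$allele2[m]
  }
  complete <- stats::complete.cases(p1) & stats::complete.cases(p2)
  if (any(!complete)) {
    warning(sum(!complete), " subject(s) missing a call at a requested gene; excluded")
  }
  if (sum(complete) < 2L) stop("fewer than 2 subjects typed at all requested genes")
  fit <- .progressive_em(p1[complete, , drop = FALSE],
                         p2[complete, , drop = FALSE],
                         tol = tol, max_iter = max_iter,
                         prune = prune, final_prune = 1e-6)
  hap <- apply(fit$hap, 1L, paste, collapse = "-")
  ord <- order(-fit$freq, hap)
  structure(list(haplotypes = data.frame(haplotype = hap[ord],
                                         frequency = fit$freq[ord],
                                         stringsAsFactors = FALSE),
                 genes = genes, loglik = fit$loglik,
                 ll_trace = fit$ll_trace,
                 iterations = fit$iterations, n_subjects = fit$n_used),
            class = "haplotype_freq")
}

#' @export
print.haplotype_freq <- function(x, ...) {
  cat("haplotype frequencies over", paste(x$genes, collapse = "-"),
      "(", x$n_subjects, "subjects,", nrow(x$haplotypes), "haplotypes )\n")
  cat("  log-likelihood", sprintf("%.4f", x$loglik), "after",
      x$iterations, "EM iterations\n")
  print(utils::head(x$haplotypes, 5L), row.names = FALSE)
  invisible(x)
}

#' Top haplotypes by frequency
#'
#' Ranks haplotypes by decreasing frequency (ties broken by lexicographic
#' haplotype string — the ranking is total) and adds cumulative
#' frequencies. Requests beyond the table return all haplotypes.
#'
#' @param x a [em_haplotype_frequencies()] result.
#' @param k number of haplotypes (default 10).
#' @return data.frame: `rank`, `haplotype`, `frequency`, `cumulative`.
#' @export
top_haplotypes <- function(x, k = 10L) {
  stopifnot(inherits(x, "haplotype_freq"))
  h <- x$haplotypes
  h <- h[order(-h$frequency, h$haplotype), , drop = FALSE]
  k <- min(k, nrow(h))
  out <- h[seq_len(k), , drop = FALSE]
  data.frame(rank = seq_len(k), haplotype = out$haplotype,
             frequency = out$frequency,
             cumulative = cumsum(out$frequency),
             stringsAsFactors = FALSE)
}
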