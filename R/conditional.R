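#' Forward-type conditional association analysis
#'
#' The modified forward stepwise procedure for one trait: at each iteration
#' every remaining variant (biallelic via the single-variant tests,
#' multiallelic amino-acid positions via the omnibus test) is tested
#' conditioning on the accumulated covariate set. If the minimum p-value no
#' longer reaches `gws` the procedure stops; otherwise the top variant (ties
#' broken by smaller p, then lexicographic id) is selected and added to the
#' covariate set together with every HLA allele and amino-acid polymorphism
#' in high LD (r-squared at or above `r2_threshold`) with it. SNV/indel
#' companions are reported but not conditioned on. Variants in complete LD
#' (r-squared = 1) with the selected variant are reported alongside it.
#' Selected variants and their conditioned companions are never re-tested.
#'
#' For quantitative traits the covariate residualization and inverse-normal
#' transform are done once; conditioning dosages enter the stage-3
#' regression, keeping the null model fixed across iterations.
#'
#' @param trait trait name (column of `pheno`).
#' @param cat a QCed `variant_catalogue`.
#' @param pheno phenotype table (see [run_phewas()]).
#' @param r2_threshold LD threshold for companion covariates (default 0.7).
#' @param gws significance threshold (default 5e-8).
#' @param max_iter safety cap on iterations (default 20).
#' @return data.frame of class `conditional_steps`, one row per step:
#'   `iteration`, `variant`, `kind` ("biallelic"/"position"), `p`, `effect`,
#'   `companions_conditioned` (comma-joined), `complete_ld` (comma-joined
#'   r2 = 1 companions), `truncated` attribute if `max_iter` was hit.
#' @export
forward_conditional <- function(trait, cat, pheno, r2_threshold = 0.7,
                                gws = 5e-8, max_iter = 20L) {
  stopifnot(inherits(cat, "variant_catalogue"))
  idx <- match(cat$samples, pheno$sample)
  stopifnot(!anyNA(idx))
  ph <- pheno[idx, , drop = FALSE]
  covars <- .pheno_covariates(ph)
  y <- ph[[trait]]
  type <- if (trait %in% attr(pheno, "binary_traits")) "binary"
          else "quantitative"

  remaining_b <- cat$meta$id
  remaining_p <- names(cat$positions)
  cond <- NULL        # conditioning dosage matrix
  steps <- list()
  truncated <- FALSE
  hla_idx <- cat$meta$source %in% c("hla_allele", "aa_residue")

  for (it in seq_len(max_iter)) {
    best <- NULL
    for (v in remaining_b) {
      j <- match(v, cat$meta$id)
      r <- tryCatch({
        if (type == "binary") {
          cv <- if (is.null(cond)) covars else cbind(covars, cond)
          logistic_assoc(cat$dosage[, j], y, cv, gws = gws)
        } else {
          quantitative_assoc(cat$dosage[, j], y, covars,
                             condition_on = cond, gws = gws)
        }
      }, error = function(e) NULL)
      if (is.null(r)) next
      if (is.null(best) || r$p < best$p ||
          (r$p == best$p && v < best$variant)) {
        best <- list(variant = v, kind = "biallelic", p = r$p,
                     effect = r$beta, dosage = cat$dosage[, j, drop = FALSE])
      }
    }
    for (pn in remaining_p) {
      pp <- cat$positions[[pn]]
      r <- tryCatch(
        omnibus_test(pp$dosage, y, covars, trait_type = type,
                     condition_on = cond, gws = gws),
        error = function(e) NULL)
      if (is.null(r)) next
      if (is.null(best) || r$p < best$p ||
          (r$p == best$p && pn < best$variant)) {
        ref <- colnames(pp$dosage)[order(-colMeans(pp$dosage, na.rm = TRUE),
                                         colnames(pp$dosage))][1L]
        dd <- pp$dosage[, setdiff(colnames(pp$dosage), ref), drop = FALSE]
        best <- list(variant = pn, kind = "position", p = r$p,
                     effect = NA_real_, dosage = dd)
      }
    }
    if (is.null(best) || best$p >= gws) break
    if (it == max_iter) truncated <- TRUE

    # companions by LD with the selected dosage(s)
    sel_d <- rowMeans(best$dosage, na.rm = TRUE)
    r2 <- vapply(seq_len(ncol(cat$dosage)), function(k) {
      r <- tryCatch(ld_r2(sel_d, cat$dosage[, k]), error = function(e) NA_real_)
      if (is.na(r)) -1 else r
    }, 1.0)
    if (best$kind == "biallelic") {
      r2[match(best$variant, cat$meta$id)] <- -1  # not its own companion
    }
    comp_hla <- cat$meta$id[hla_idx & r2 >= r2_threshold]
    comp_full <- cat$meta$id[r2 >= 1 - 1e-12]
    add <- cbind(best$dosage,
                 cat$dosage[, match(comp_hla, cat$meta$id), drop = FALSE])
    add <- add[, !duplicated(colnames(add)), drop = FALSE]
    # drop columns collinear with what is already conditioned on
    trial <- cbind(if (is.null(cond)) NULL else cond, add)
    trial[is.na(trial)] <- 0
    qr_t <- qr(cbind(1, trial))
    keep <- qr_t$pivot[seq_len(qr_t$rank)] - 1L
    keep <- keep[keep > 0L]
    if (length(keep) < ncol(trial)) {
      warning("dropped ", ncol(trial) - length(keep),
              " collinear conditioning column(s) at step ", it)
    }
    cond <- trial[, sort(keep), drop = FALSE]

    steps[[it]] <- data.frame(
      iteration = it, variant = best$variant, kind = best$kind,
      p = best$p, effect = best$effect,
      companions_conditioned = paste(comp_hla, collapse = ","),
      complete_ld = paste(setdiff(comp_full, best$variant), collapse = ","),
      stringsAsFactors = FALSE)
    remaining_b <- setdiff(remaining_b, c(best$variant, comp_hla))
    remaining_p <- setdiff(remaining_p, best$variant)
  }
  out <- if (length(steps)) do.call(rbind, steps) else
    data.frame(iteration = integer(0), variant = character(0),
               kind = character(0), p = numeric(0), effect = numeric(0),
               companions_conditioned = character(0),
               complete_ld = character(0), stringsAsFactors = FALSE)
  attr(out, "truncated") <- truncated
  class(out) <- c("conditional_steps", "data.frame")
  out
}
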