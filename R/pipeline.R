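#' Pipeline run configuration
#'
#' Collects every stage toggle and threshold with defaults matching the
#' package's standard analysis settings: array QC 0.98 / 0.05 / 1e-6,
#' relatedness 0.1875; 100 classifiers over a 500 kb flank with call
#' threshold 0.5; post-imputation QC missing rate 0.05 and MAF 0.01; GWS
#' 5e-8; LD threshold 0.7; FDR 0.05. A configuration echo is written into
#' the run manifest.
#'
#' @param out_dir output directory.
#' @param seed master seed; each stage derives its own sub-seed
#'   deterministically (`seed + 101 * stage index`, kept in integer range).
#' @param stages character vector of stages to run, a subset (in order) of
#'   simulate, qc, train, impute, encode, phewas, conditional, heritability,
#'   haplotypes, pgx.
#' @param n_subjects,n_classifiers,tagging_strength,alleles_per_gene,n_snps
#'   simulation/training sizes.
#' @param flank_bp,call_threshold,gws,r2_threshold,fdr_alpha,post_missing_max,post_maf_min
#'   analysis thresholds (defaults above).
#' @param qc a [qc_thresholds()] list.
#' @return list of class `run_config`.
#' @export
run_config <- function(out_dir = tempfile("hlapheno_run_"), seed = 1L,
                       stages = c("simulate", "qc", "train", "impute",
                                  "encode", "phewas", "conditional",
                                  "heritability", "haplotypes", "pgx"),
                       n_subjects = 500L, n_classifiers = 10L,
                       tagging_strength = 0.95,
                       alleles_per_gene = c(3L, 3L), n_snps = 30L,
                       flank_bp = 500000L, call_threshold = 0.5,
                       gws = 5e-8, r2_threshold = 0.7, fdr_alpha = 0.05,
                       post_missing_max = 0.05, post_maf_min = 0.01,
                       qc = qc_thresholds()) {
  all_stages <- c("simulate", "qc", "train", "impute", "encode", "phewas",
                  "conditional", "heritability", "haplotypes", "pgx")
  stopifnot(all(stages %in% all_stages))
  structure(list(out_dir = out_dir, seed = as.integer(seed),
                 stages = all_stages[all_stages %in% stages],
                 n_subjects = n_subjects, n_classifiers = n_classifiers,
                 tagging_strength = tagging_strength,
                 alleles_per_gene = alleles_per_gene, n_snps = n_snps,
                 flank_bp = flank_bp, call_threshold = call_threshold,
                 gws = gws, r2_threshold = r2_threshold,
                 fdr_alpha = fdr_alpha,
                 post_missing_max = post_missing_max,
                 post_maf_min = post_maf_min, qc = qc),
            class = "run_config")
}

.stage_seed <- function(config, stage_index) {
  as.integer((config$seed + 101L * stage_index) %% .Machine$integer.max)
}

#' Run the analysis pipeline end to end
#'
#' Executes the enabled stages in order on a synthetic cohort: simulate ->
#' qc -> train -> impute -> encode -> phewas -> conditional -> heritability
#' -> haplotypes -> pgx. Each stage writes its outputs under
#' `config$out_dir` and the run manifest records the configuration, stage
#' seeds and per-file MD5 digests; a rerun with the same configuration and
#' seed reproduces identical digests for deterministic stages. A stage whose
#' upstream output is missing (because the upstream stage was disabled)
#' raises an error naming the stage to run first.
#'
#' @param config a [run_config()].
#' @return list of class `run_manifest`.
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  state <- new.env(parent = emptyenv())
  manifest <- list(config = unclass(config), stages = list())
  need <- function(what, stage) {
    if (!exists(what, envir = state)) {
      stop("stage '", stage, "' needs output of a disabled upstream stage; ",
           "run '", .stage_provider(what), "' first")
    }
    get(what, envir = state)
  }
  files <- character(0)
  for (st in config$stages) {
    si <- match(st, c("simulate", "qc", "train", "impute", "encode",
                      "phewas", "conditional", "heritability",
                      "haplotypes", "pgx"))
    sseed <- .stage_seed(config, si)
    out <- switch(st,
      simulate = {
        pool <- simulate_reference_pool(
          n_haplotypes = 1000L, n_snps = config$n_snps,
          alleles_per_gene = config$alleles_per_gene,
          tagging_strength = config$tagging_strength, seed = sseed)
        coh <- simulate_cohort(pool, config$n_subjects, seed = sseed + 1L)
        aa <- make_aa_table(pool, seed = sseed + 2L)
        eff <- list(effect_spec("trait_bin", "binary",
                                pool$allele_names[[1L]][1L], effect = 0.7,
                                prevalence = 0.05),
                    effect_spec("trait_qt", "quantitative",
                                pool$allele_names[[2L]][1L], effect = 0.15))
        pheno <- simulate_phenotypes(coh$typing, coh$genotypes, eff,
                                     traits = c("null_qt"), seed = sseed + 3L)
        assign("pool", pool, state); assign("cohort", coh, state)
        assign("aa_table", aa, state); assign("pheno", pheno, state)
        f <- file.path(config$out_dir, "cohort.vcf")
        write_genotypes(coh$genotypes, f, "vcf")
        ft <- file.path(config$out_dir, "truth_typing.tsv")
        utils::write.table(coh$typing, ft, sep = "\t", quote = FALSE,
                           row.names = FALSE)
        c(f, ft)
      },
      qc = {
        coh <- need("cohort", st)
        vq <- variant_qc(coh$genotypes, config$qc)
        gm <- extract_region(vq$genotypes, mhc_region())
        assign("gm_qc", gm, state)
        f <- file.path(config$out_dir, "variant_qc.tsv")
        write_qc_report(vq$report, f)
        f
      },
      train = {
        coh <- need("cohort", st); gm <- need("gm_qc", st)
        pool <- need("pool", st)
        models <- lapply(pool$genes, function(g) {
          hla_ab_train(gm, coh$typing, g, resolution = 4L,
                       n_classifiers = config$n_classifiers,
                       flank_bp = config$flank_bp, seed = sseed)
        })
        names(models) <- pool$genes
        assign("models", models, state)
        fs <- vapply(pool$genes, function(g) {
          f <- file.path(config$out_dir, paste0("model_", gsub("HLA-", "", g),
                                                ".json"))
          write_hla_model(models[[g]], f)
          f
        }, "")
        fs
      },
      impute = {
        models <- need("models", st); gm <- need("gm_qc", st)
        calls <- do.call(rbind, lapply(models, function(m) {
          predict(m, gm, call_threshold = config$call_threshold)
        }))
        rownames(calls) <- NULL
        assign("calls", calls, state)
        f <- file.path(config$out_dir, "imputed_calls.tsv")
        utils::write.table(calls, f, sep = "\t", quote = FALSE,
                           row.names = FALSE)
        f
      },
      encode = {
        calls <- need("calls", st); gm <- need("gm_qc", st)
        aa <- need("aa_table", st)
        hla <- allele_dosages(calls, samples = gm$samples)
        aat <- translate_amino_acids(calls, aa, samples = gm$samples)
        catg <- build_catalogue(gm, hla, aat)
        catg <- post_imputation_qc(catg, config$post_missing_max,
                                   config$post_maf_min)
        catg <- assign_to_gene(catg, config$r2_threshold)
        assign("catalogue", catg, state)
        f <- file.path(config$out_dir, "catalogue_meta.tsv")
        utils::write.table(catg$meta, f, sep = "\t", quote = FALSE,
                           row.names = FALSE)
        f
      },
      phewas = {
        catg <- need("catalogue", st); pheno <- need("pheno", st)
        res <- run_phewas(catg, pheno, gws = config$gws)
        assign("phewas", res, state)
        f1 <- file.path(config$out_dir, "phewas_biallelic.tsv")
        f2 <- file.path(config$out_dir, "phewas_omnibus.tsv")
        utils::write.table(res$biallelic, f1, sep = "\t", quote = FALSE,
                           row.names = FALSE)
        utils::write.table(res$omnibus, f2, sep = "\t", quote = FALSE,
                           row.names = FALSE)
        c(f1, f2)
      },
      conditional = {
        catg <- need("catalogue", st); pheno <- need("pheno", st)
        res <- need("phewas", st)
        hits <- unique(res$biallelic$trait[res$biallelic$gws])
        steps <- lapply(hits, function(tr) {
          s <- forward_conditional(tr, catg, pheno,
                                   r2_threshold = config$r2_threshold,
                                   gws = config$gws)
          if (nrow(s)) cbind(trait = tr, s) else NULL
        })
        steps <- do.call(rbind, steps[!vapply(steps, is.null, TRUE)])
        assign("conditional", steps, state)
        f <- file.path(config$out_dir, "conditional_steps.tsv")
        utils::write.table(steps %||% data.frame(), f, sep = "\t",
                           quote = FALSE, row.names = FALSE)
        f
      },
      heritability = {
        catg <- need("catalogue", st); pheno <- need("pheno", st)
        grm <- compute_grm(catg$dosage)
        covars <- .pheno_covariates(pheno[match(catg$samples, pheno$sample), ])
        qtr <- attr(pheno, "quantitative_traits")
        fits <- lapply(qtr, function(tr) {
          yy <- .int_residuals(pheno[[tr]][match(catg$samples, pheno$sample)],
                               covars)
          if (anyNA(yy)) return(NULL)
          he_univariate(yy, grm)
        })
        names(fits) <- qtr
        assign("heritability", fits, state)
        f <- file.path(config$out_dir, "heritability.tsv")
        hdf <- do.call(rbind, lapply(qtr, function(tr) {
          ft <- fits[[tr]]
          if (is.null(ft)) return(NULL)
          data.frame(trait = tr, h2_pct = round(100 * ft$h2, 2),
                     se_pct = round(100 * ft$se, 2), method = ft$method)
        }))
        utils::write.table(hdf, f, sep = "\t", quote = FALSE,
                           row.names = FALSE)
        f
      },
      haplotypes = {
        calls <- need("calls", st)
        pool <- need("pool", st)
        hf <- em_haplotype_frequencies(calls, pool$genes)
        assign("haplotypes", hf, state)
        f <- file.path(config$out_dir, "haplotype_freqs.tsv")
        utils::write.table(top_haplotypes(hf, k = nrow(hf$haplotypes)), f,
                           sep = "\t", quote = FALSE, row.names = FALSE)
        f
      },
      pgx = {
        calls <- need("calls", st)
        pool <- need("pool", st)
        rep <- carrier_report(calls,
                              unlist(pool$allele_names, use.names = FALSE))
        assign("pgx", rep, state)
        f <- file.path(config$out_dir, "carrier_report.tsv")
        utils::write.table(rep, f, sep = "\t", quote = FALSE,
                           row.names = FALSE)
        f
      })
    files <- c(files, out)
    manifest$stages[[st]] <- list(seed = sseed, files = out,
                                  md5 = unname(tools::md5sum(out)))
  }
  manifest$created <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S")
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       force = TRUE)
  class(manifest) <- "run_manifest"
  invisible(manifest)
}

.stage_provider <- function(what) {
  switch(what,
         pool = , cohort = , aa_table = , pheno = "simulate",
         gm_qc = "qc", models = "train", calls = "impute",
         catalogue = "encode", phewas = "phewas", "an upstream stage")
}

#' @export
print.run_manifest <- function(x, ...) {
  cat("pipeline run:", length(x$stages), "stages ->",
      x$config$out_dir, "\n")
  for (st in names(x$stages)) {
    cat(" ", st, ":", length(x$stages[[st]]$files), "file(s)\n")
  }
  invisible(x)
}
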