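#' Simulate a phased SNP/HLA haplotype reference pool
#'
#' Builds a pool of phased haplotypes on a single pseudo-chromosome ("6")
#' inside the MHC interval. Each simulated gene carries a set of HLA alleles
#' with decreasing frequencies (for k alleles, proportional to k:1, so four
#' alleles give 0.4/0.3/0.2/0.1 — a dominant allele near 0.2 or above, as in
#' real HLA data). Every allele is assigned a one-hot core SNP signature on
#' signature SNPs placed within 200 kb of the gene body; a haplotype carrying
#' the allele matches each signature bit with probability `tagging_strength`,
#' and otherwise draws the bit from the background frequency, giving tunable
#' LD between SNPs and alleles. Remaining SNPs are background noise with
#' frequencies uniform in [0.05, 0.5].
#'
#' @param n_haplotypes pool size (each haplotype has frequency
#'   1/n_haplotypes).
#' @param n_snps total SNP count; must cover the signature SNPs
#'   (`sum(alleles_per_gene)`).
#' @param alleles_per_gene integer vector, alleles per simulated gene (>= 2
#'   each); genes are taken in order from the eight classical HLA genes.
#' @param tagging_strength per-SNP probability of matching the core
#'   signature, in [0, 1].
#' @param seed integer seed; same seed gives an identical pool.
#' @return object of class `reference_pool`: `snps` (haplotypes x SNPs 0/1
#'   matrix), `alleles` (haplotypes x genes allele labels), `frequencies`,
#'   `variants` metadata, `genes`, `allele_freqs`.
#' @export
simulate_reference_pool <- function(n_haplotypes = 1000L, n_snps = 40L,
                                    alleles_per_gene = c(4L, 4L),
                                    tagging_strength = 0.95, seed = 1L) {
  stopifnot(all(alleles_per_gene >= 2L), tagging_strength >= 0,
            tagging_strength <= 1, n_haplotypes >= 2L)
  set.seed(seed)
  gc <- hla_gene_coords()
  n_genes <- length(alleles_per_gene)
  stopifnot(n_genes <= nrow(gc))
  genes <- gc$gene[seq_len(n_genes)]
  n_sig <- sum(alleles_per_gene)
  if (n_snps < n_sig) {
    stop("n_snps (", n_snps, ") is below the ", n_sig,
         " signature SNPs required")
  }

  # allele labels and frequencies per gene
  allele_names <- list(); allele_freqs <- list()
  for (g in seq_len(n_genes)) {
    k <- alleles_per_gene[g]
    short <- sub("^HLA-", "", genes[g])
    allele_names[[g]] <- sprintf("%s*%02d:01", short, seq_len(k))
    allele_freqs[[g]] <- (k:1) / sum(k:1)
  }
  names(allele_names) <- names(allele_freqs) <- genes

  # SNP placement: signature SNPs near their gene, background spread over MHC
  mhc <- mhc_region()
  pos <- integer(0); is_sig <- logical(0); sig_gene <- character(0)
  sig_allele <- character(0)
  for (g in seq_len(n_genes)) {
    k <- alleles_per_gene[g]
    centre <- (gc$start[g] + gc$end[g]) %/% 2L
    p <- centre + sort(sample(seq(-200000L, 200000L), k))
    pos <- c(pos, p); is_sig <- c(is_sig, rep(TRUE, k))
    sig_gene <- c(sig_gene, rep(genes[g], k))
    sig_allele <- c(sig_allele, allele_names[[g]])
  }
  n_bg <- n_snps - n_sig
  if (n_bg > 0L) {
    pos <- c(pos, sort(sample(seq(mhc$start, mhc$end), n_bg)))
    is_sig <- c(is_sig, rep(FALSE, n_bg))
    sig_gene <- c(sig_gene, rep(NA_character_, n_bg))
    sig_allele <- c(sig_allele, rep(NA_character_, n_bg))
  }
  ord <- order(pos)
  pos <- pos[ord]; is_sig <- is_sig[ord]
  sig_gene <- sig_gene[ord]; sig_allele <- sig_allele[ord]
  bg_freq <- ifelse(is_sig, NA_real_, stats::runif(n_snps, 0.05, 0.5))

  # per-haplotype gene alleles
  hap_alleles <- matrix("", n_haplotypes, n_genes, dimnames = list(NULL, genes))
  for (g in seq_len(n_genes)) {
    hap_alleles[, g] <- sample(allele_names[[g]], n_haplotypes, replace = TRUE,
                               prob = allele_freqs[[g]])
  }

  # SNP bits
  snps <- matrix(0L, n_haplotypes, n_snps)
  for (j in seq_len(n_snps)) {
    if (is_sig[j]) {
      target <- hap_alleles[, match(sig_gene[j], genes)] == sig_allele[j]
      sig_bit <- as.integer(target)
      p_bg <- allele_freqs[[sig_gene[j]]][match(sig_allele[j],
                                                allele_names[[sig_gene[j]]])]
      follow <- stats::runif(n_haplotypes) < tagging_strength
      random_bit <- as.integer(stats::runif(n_haplotypes) < p_bg)
      snps[, j] <- ifelse(follow, sig_bit, random_bit)
    } else {
      snps[, j] <- as.integer(stats::runif(n_haplotypes) < bg_freq[j])
    }
  }

  variants <- data.frame(chrom = "6", pos = pos,
                         id = sprintf("rs_sim%05d", seq_len(n_snps)),
                         ref = "A", alt = "G",
                         signature_gene = sig_gene,
                         signature_allele = sig_allele,
                         stringsAsFactors = FALSE)
  structure(list(snps = snps, alleles = hap_alleles,
                 frequencies = rep(1 / n_haplotypes, n_haplotypes),
                 variants = variants, genes = genes,
                 allele_names = allele_names, allele_freqs = allele_freqs,
                 tagging_strength = tagging_strength, seed = seed),
            class = "reference_pool")
}

#' @export
print.reference_pool <- function(x, ...) {
  cat("reference_pool:", nrow(x$snps), "haplotypes,", ncol(x$snps), "SNPs,",
      length(x$genes), "genes (", paste(x$genes, collapse = ", "), ")\n")
  cat("  tagging strength:", x$tagging_strength, "\n")
  invisible(x)
}

#' Simulate an unphased cohort from a reference pool
#'
#' Each subject is the union of two haplotypes drawn independently with the
#' pool frequencies, so Hardy-Weinberg equilibrium holds at the haplotype
#' level by construction. Returns unphased SNP dosages and the true HLA
#' typing.
#'
#' @param pool a [simulate_reference_pool()] result.
#' @param n_subjects cohort size (0 gives empty outputs).
#' @param seed integer seed.
#' @return list: `genotypes` (a [genotype_matrix()]), `typing` (truth table:
#'   sample, gene, allele1, allele2).
#' @export
simulate_cohort <- function(pool, n_subjects, seed = 1L) {
  stopifnot(inherits(pool, "reference_pool"), n_subjects >= 0L)
  set.seed(seed)
  samples <- if (n_subjects > 0L) sprintf("S%05d", seq_len(n_subjects))
             else character(0)
  H <- nrow(pool$snps)
  i1 <- sample.int(H, n_subjects, replace = TRUE, prob = pool$frequencies)
  i2 <- sample.int(H, n_subjects, replace = TRUE, prob = pool$frequencies)
  dosage <- pool$snps[i1, , drop = FALSE] + pool$snps[i2, , drop = FALSE]
  gm <- genotype_matrix(dosage, pool$variants[, c("chrom", "pos", "id",
                                                  "ref", "alt")], samples)
  typing <- do.call(rbind, lapply(seq_along(pool$genes), function(g) {
    if (n_subjects == 0L) return(NULL)
    a <- pool$alleles[i1, g]; b <- pool$alleles[i2, g]
    sw <- a > b
    tmp <- a[sw]; a[sw] <- b[sw]; b[sw] <- tmp
    data.frame(sample = samples, gene = pool$genes[g],
               allele1 = a, allele2 = b, stringsAsFactors = FALSE)
  }))
  if (is.null(typing)) {
    typing <- data.frame(sample = character(0), gene = character(0),
                         allele1 = character(0), allele2 = character(0),
                         stringsAsFactors = FALSE)
  }
  list(genotypes = gm, typing = typing)
}

#' Specify a phenotype effect for simulation
#'
#' @param trait trait name.
#' @param type "binary" or "quantitative".
#' @param target the dosage the effect acts on: an HLA allele name (e.g.
#'   `"B*01:01"`) resolved against the typing, or a SNP id resolved against
#'   the genotype matrix.
#' @param effect log-odds per dosage copy (binary) or per-copy shift in SD
#'   units (quantitative).
#' @param prevalence baseline case probability for binary traits.
#' @param sd residual SD for quantitative traits.
#' @return list of class `effect_spec`.
#' @export
effect_spec <- function(trait, type = c("binary", "quantitative"), target,
                        effect, prevalence = 0.05, sd = 1) {
  type <- match.arg(type)
  if (type == "binary") stopifnot(prevalence > 0, prevalence < 1)
  structure(list(trait = trait, type = type, target = target,
                 effect = effect, prevalence = prevalence, sd = sd),
            class = "effect_spec")
}

# resolve an effect target to a dosage vector
.resolve_target <- function(target, typing, gm, samples) {
  if (!is.null(gm)) {
    j <- match(target, gm$variants$id)
    if (!is.na(j)) return(gm$dosage[match(samples, gm$samples), j])
  }
  if (!is.null(typing) && grepl("\\*", target)) {
    gene <- parse_allele(target)$gene
    ty <- typing[typing$gene == gene, , drop = FALSE]
    ty <- ty[match(samples, ty$sample), , drop = FALSE]
    if (!all(is.na(ty$sample))) {
      return((ty$allele1 == target) + (ty$allele2 == target))
    }
  }
  stop("cannot resolve effect target: ", sQuote(target))
}

#' Simulate phenotypes with configurable HLA effects
#'
#' Binary traits follow a logistic model: logit P(case) = intercept
#' (matching the requested prevalence at zero effects) + sum(effect x
#' dosage) + covariate terms. Quantitative traits are additive with Gaussian
#' residuals. Covariates are sex (Bernoulli), age (Gaussian), age^2 and
#' standard-normal principal components, with small fixed coefficients so
#' covariate adjustment is exercised downstream.
#'
#' @param typing truth or imputed typing table (may be NULL if all targets
#'   are SNPs).
#' @param gm genotype matrix (may be NULL if all targets are HLA alleles).
#' @param effects list of [effect_spec()] objects; traits named in no effect
#'   are not created.
#' @param traits optional character vector of extra null trait names to
#'   simulate with no genetic effect; give binary traits as
#'   `c(binary = "name")` entries, others are quantitative.
#' @param covariate_spec list: `p_male`, `age_mean`, `age_sd`, `n_pcs`.
#' @param seed integer seed.
#' @return data.frame: `sample`, `sex` (0/1), `age`, `age2`, `PC1..PCk`,
#'   then one column per trait, with attributes `binary_traits` and
#'   `quantitative_traits`.
#' @export
simulate_phenotypes <- function(typing = NULL, gm = NULL, effects = list(),
                                traits = character(0),
                                covariate_spec = list(p_male = 0.317,
                                                      age_mean = 50.5,
                                                      age_sd = 10.6,
                                                      n_pcs = 10L),
                                seed = 1L) {
  set.seed(seed)
  samples <- if (!is.null(gm)) gm$samples else unique(typing$sample)
  n <- length(samples)
  cs <- utils::modifyList(list(p_male = 0.317, age_mean = 50.5,
                               age_sd = 10.6, n_pcs = 10L), covariate_spec)
  sex <- stats::rbinom(n, 1L, cs$p_male)
  age <- stats::rnorm(n, cs$age_mean, cs$age_sd)
  pcs <- matrix(stats::rnorm(n * cs$n_pcs), n, cs$n_pcs,
                dimnames = list(NULL, paste0("PC", seq_len(cs$n_pcs))))
  out <- data.frame(sample = samples, sex = sex, age = age, age2 = age^2,
                    stringsAsFactors = FALSE)
  out <- cbind(out, as.data.frame(pcs))

  # small fixed covariate coefficients (on the standardized covariates)
  cov_lin <- 0.2 * sex + 0.01 * (age - cs$age_mean) +
    pcs %*% rep(0.05, cs$n_pcs)
  cov_lin <- as.numeric(cov_lin)

  by_trait <- split(effects, vapply(effects, `[[`, "", "trait"))
  binary <- character(0); quantitative <- character(0)
  for (tn in names(by_trait)) {
    es <- by_trait[[tn]]
    type <- es[[1L]]$type
    eta <- numeric(n)
    for (e in es) {
      d <- .resolve_target(e$target, typing, gm, samples)
      d[is.na(d)] <- 0
      eta <- eta + e$effect * d
    }
    if (type == "binary") {
      prev <- es[[1L]]$prevalence
      lin <- stats::qlogis(prev) + eta + cov_lin
      out[[tn]] <- stats::rbinom(n, 1L, stats::plogis(lin))
      binary <- c(binary, tn)
    } else {
      out[[tn]] <- eta + cov_lin + stats::rnorm(n, 0, es[[1L]]$sd)
      quantitative <- c(quantitative, tn)
    }
  }
  if (length(traits)) {
    isb <- names(traits) == "binary"
    if (is.null(names(traits))) isb <- rep(FALSE, length(traits))
    for (i in seq_along(traits)) {
      tn <- traits[i]
      if (isb[i]) {
        out[[tn]] <- stats::rbinom(n, 1L, stats::plogis(stats::qlogis(0.05) +
                                                          cov_lin))
        binary <- c(binary, tn)
      } else {
        out[[tn]] <- cov_lin + stats::rnorm(n)
        quantitative <- c(quantitative, tn)
      }
    }
  }
  attr(out, "binary_traits") <- binary
  attr(out, "quantitative_traits") <- quantitative
  out
}

#' Build a synthetic allele-to-protein table
#'
#' Assigns each 4-digit allele a residue string such that (a) at least one
#' position is biallelic, (b) when a gene has 3 or more alleles at least one
#' position carries 3 or more residues (exercising omnibus df = n - 1), and
#' (c) alleles sharing a 2-digit family share more of their sequence than
#' alleles from different families.
#'
#' @param alleles character vector of 4-digit allele names (one or more
#'   genes), or a `reference_pool` (its alleles are used).
#' @param n_positions sequence length per gene (default 12).
#' @param seed integer seed.
#' @return data.frame of class `aa_table`: `allele`, `gene`, `offset`,
#'   `sequence`.
#' @export
make_aa_table <- function(alleles, n_positions = 12L, seed = 1L) {
  if (inherits(alleles, "reference_pool")) {
    alleles <- unlist(alleles$allele_names, use.names = FALSE)
  }
  set.seed(seed)
  p <- parse_allele(alleles)
  stopifnot(all(table(p$gene) >= 2L))
  aa <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K", "M",
          "F", "P", "S", "T", "W", "Y", "V")
  rows <- list()
  for (g in unique(p$gene)) {
    idx <- which(p$gene == g)
    k <- length(idx)
    consensus <- sample(aa, n_positions, replace = TRUE)
    seqs <- matrix(rep(consensus, k), nrow = k, byrow = TRUE)
    fam <- p$field1[idx]
    # family-level variation: one position per distinct family
    fams <- unique(fam)
    fam_pos <- sample(seq_len(n_positions), length(fams))
    for (fi in seq_along(fams)) {
      res <- sample(setdiff(aa, consensus[fam_pos[fi]]), 1L)
      seqs[fam == fams[fi], fam_pos[fi]] <- res
    }
    # a guaranteed biallelic position: split alleles in two groups
    bi_pos <- setdiff(seq_len(n_positions), fam_pos)[1L]
    grp2 <- seq_len(k) > k / 2
    seqs[grp2, bi_pos] <- sample(setdiff(aa, consensus[bi_pos]), 1L)
    # a >= 3 residue position when possible
    if (k >= 3L) {
      tri_pos <- setdiff(seq_len(n_positions), c(fam_pos, bi_pos))[1L]
      res3 <- sample(setdiff(aa, consensus[tri_pos]), 2L)
      seqs[2L, tri_pos] <- res3[1L]
      seqs[3L, tri_pos] <- res3[2L]
    }
    rows[[g]] <- data.frame(allele = p$allele[idx], gene = g, offset = 1L,
                            sequence = apply(seqs, 1L, paste, collapse = ""),
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("aa_table", "data.frame")
  out
}
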