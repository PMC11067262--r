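#' Train an attribute-bagging HLA imputation model
#'
#' Fits an ensemble of classifiers that predict the unordered HLA allele pair
#' at one gene from unphased SNP dosages in the gene's flanking region. Each
#' classifier is built on a bootstrap sample of subjects: a SNP subset is
#' grown greedily, at each step sampling `mtry` candidate SNPs and keeping
#' the candidate that maximizes out-of-bag allele-prediction accuracy, until
#' no candidate improves accuracy or `max_snps` is reached. The classifier's
#' parameter is a frequency table over (SNP-haplotype pattern, HLA allele)
#' joint haplotypes estimated by EM from the unphased bootstrap data.
#'
#' @param gm a [genotype_matrix()] covering the gene's flank.
#' @param typing HLA typing table (`sample`, `gene`, `allele1`, `allele2`);
#'   all training subjects must be typed at `gene` to at least `resolution`.
#' @param gene gene name, e.g. `"HLA-B"`.
#' @param resolution 2, 4 or 6 (digits).
#' @param n_classifiers ensemble size (default 100).
#' @param flank_bp flank width around the gene (default 500000): SNPs within
#'   `flank_bp` of the gene body are eligible.
#' @param mtry candidate SNPs sampled per growth step; default
#'   `ceiling(sqrt(m))` for `m` flank SNPs.
#' @param max_snps cap on SNPs per classifier (default 15, bounding the EM
#'   state space).
#' @param gene_coords optional data.frame (`gene`, `start`, `end`) overriding
#'   [hla_gene_coords()].
#' @param seed integer seed for bootstrap and candidate sampling.
#' @return object of class `hla_ab_model`.
#' @export
hla_ab_train <- function(gm, typing, gene, resolution = 4L,
                         n_classifiers = 100L, flank_bp = 500000L,
                         mtry = NULL, max_snps = 15L,
                         gene_coords = NULL, seed = NULL) {
  stopifnot(inherits(gm, "genotype_matrix"), n_classifiers >= 1L)
  if (!is.null(seed)) set.seed(seed)
  ty <- typing[typing$gene == gene, , drop = FALSE]
  ty <- ty[match(gm$samples, ty$sample), , drop = FALSE]
  miss <- gm$samples[is.na(ty$sample)]
  if (length(miss)) {
    stop("samples without ", gene, " typing: ",
         paste(utils::head(miss, 5L), collapse = ", "),
         if (length(miss) > 5L) ", ...")
  }
  res_have <- pmin(parse_allele(ty$allele1)$resolution,
                   parse_allele(ty$allele2)$resolution)
  low <- gm$samples[res_have < resolution]
  if (length(low)) {
    stop("typing resolution below ", resolution, " digits for: ",
         paste(utils::head(low, 5L), collapse = ", "),
         if (length(low) > 5L) ", ...")
  }
  a1 <- truncate_allele(ty$allele1, resolution)
  a2 <- truncate_allele(ty$allele2, resolution)

  flank_idx <- .flank_snps(gm, gene, flank_bp, gene_coords)
  G <- gm$dosage[, flank_idx, drop = FALSE]
  poly <- which(apply(G, 2L, function(d) {
    d <- d[!is.na(d)]; length(unique(d)) > 1L
  }))
  if (!length(poly)) stop("flank of ", gene, " is monomorphic; cannot train")
  G <- G[, poly, drop = FALSE]
  flank_idx <- flank_idx[poly]
  m <- ncol(G)
  if (is.null(mtry)) mtry <- max(1L, ceiling(sqrt(m)))

  n <- nrow(G)
  classifiers <- vector("list", n_classifiers)
  for (k in seq_len(n_classifiers)) {
    boot <- sample.int(n, n, replace = TRUE)
    oob <- setdiff(seq_len(n), unique(boot))
    if (!length(oob)) oob <- sample.int(n, max(1L, round(0.3 * n)))
    classifiers[[k]] <- .grow_classifier(G, a1, a2, boot, oob, mtry, max_snps)
  }
  model <- structure(list(
    gene = gene, resolution = as.integer(resolution),
    classifiers = lapply(classifiers, function(cl) {
      list(snp_id = gm$variants$id[flank_idx[cl$snps]],
           snp_pos = gm$variants$pos[flank_idx[cl$snps]],
           pattern = cl$pattern, allele = cl$allele, freq = cl$freq,
           oob_accuracy = cl$oob_accuracy)
    }),
    flank_bp = as.integer(flank_bp),
    n_train = n,
    alleles = sort(unique(c(a1, a2))),
    seed = seed,
    version = "hla_ab_model/1"), class = "hla_ab_model")
  model
}

# SNPs within flank_bp of the gene body
.flank_snps <- function(gm, gene, flank_bp, gene_coords = NULL) {
  gc <- if (is.null(gene_coords)) hla_gene_coords() else gene_coords
  row <- gc[gc$gene == gene, , drop = FALSE]
  if (!nrow(row)) stop("unknown gene (no coordinates): ", gene)
  idx <- which(gm$variants$pos >= row$start[1L] - flank_bp &
               gm$variants$pos <= row$end[1L] + flank_bp)
  if (!length(idx)) stop("no SNPs within ", flank_bp, " bp flank of ", gene)
  idx
}

# greedy OOB-driven growth of one classifier's SNP subset
.grow_classifier <- function(G, a1, a2, boot, oob, mtry, max_snps) {
  sel <- integer(0)
  best_fit <- NULL
  best_acc <- -Inf
  avail <- seq_len(ncol(G))
  repeat {
    if (length(sel) >= max_snps || !length(avail)) break
    cand <- if (length(avail) <= mtry) avail else sample(avail, mtry)
    accs <- rep(NA_real_, length(cand))
    fits <- vector("list", length(cand))
    for (ci in seq_along(cand)) {
      ss <- c(sel, cand[ci])
      fit <- .fit_freq_table(G[boot, ss, drop = FALSE], a1[boot], a2[boot],
                             tol = 1e-4, max_iter = 60L)
      accs[ci] <- .score_subjects(fit, G[oob, ss, drop = FALSE],
                                  a1[oob], a2[oob])
      fits[[ci]] <- fit
    }
    bi <- which.max(accs)
    if (accs[bi] >= best_acc) {
      if (accs[bi] == best_acc && length(sel) >= 3L) break  # plateau guard
      best_acc <- accs[bi]
      sel <- c(sel, cand[bi])
      best_fit <- fits[[bi]]
      avail <- setdiff(avail, cand[bi])
    } else break
  }
  if (is.null(best_fit)) {  # degenerate; fall back to the first SNP
    sel <- 1L
    best_fit <- .fit_freq_table(G[boot, sel, drop = FALSE], a1[boot], a2[boot],
                                tol = 1e-7, max_iter = 500L)
    best_acc <- .score_subjects(best_fit, G[oob, sel, drop = FALSE],
                                a1[oob], a2[oob])
  } else {
    # refit the chosen subset to full convergence
    best_fit <- .fit_freq_table(G[boot, sel, drop = FALSE], a1[boot], a2[boot],
                                tol = 1e-7, max_iter = 500L)
    best_acc <- .score_subjects(best_fit, G[oob, sel, drop = FALSE],
                                a1[oob], a2[oob])
  }
  list(snps = sel, pattern = best_fit$pattern, allele = best_fit$allele,
       freq = best_fit$freq, oob_accuracy = best_acc)
}

# EM frequency table over (SNP pattern, allele) joint haplotypes.
# Locus 1 = the observed allele pair; remaining loci = SNP bits.
.fit_freq_table <- function(G, a1, a2, tol = 1e-7, max_iter = 500L) {
  dp <- .dosage_pairs(as.matrix(G))
  p1 <- cbind(a1, dp$p1); p2 <- cbind(a2, dp$p2)
  fit <- .progressive_em(p1, p2, tol = tol, max_iter = max_iter,
                         prune = 1e-8, final_prune = 1e-8)
  allele <- fit$hap[, 1L]
  pattern <- if (ncol(fit$hap) > 1L) {
    apply(fit$hap[, -1L, drop = FALSE], 1L, paste, collapse = "")
  } else rep("", nrow(fit$hap))
  list(pattern = pattern, allele = allele, freq = fit$freq)
}

# mean per-allele OOB accuracy of a single frequency table
.score_subjects <- function(fit, G, a1, a2) {
  post <- .classifier_posteriors(fit, as.matrix(G))
  pred <- .best_pairs(post)
  mean(mapply(.pair_match, pred$allele1, pred$allele2, a1, a2)) / 2
}

# number of allele matches (0..2) between two unordered pairs
.pair_match <- function(x1, x2, y1, y2) {
  if (is.na(x1) || is.na(x2)) return(0)
  best <- 0L
  truth <- c(y1, y2)
  for (perm in list(c(x1, x2), c(x2, x1))) {
    best <- max(best, sum(perm == truth))
  }
  best
}

# P(unordered allele pair | SNP genotype) for one classifier.
# Pattern pairs are weighted f_i * f_j * eps^d where d is the total allele
# mismatch between the implied genotype and the observed one over non-missing
# SNPs; missing SNPs are marginalized (contribute no mismatch). eps > 0 keeps
# genotype patterns unseen in training from receiving zero posterior mass.
.classifier_posteriors <- function(fit, G, eps = 0.01) {
  K <- length(fit$freq)
  m <- nchar(fit$pattern[1L])
  patm <- if (m > 0L) {
    matrix(as.integer(unlist(strsplit(fit$pattern, ""), use.names = FALSE)),
           nrow = K, byrow = TRUE)
  } else matrix(0L, K, 0L)
  ii <- rep(seq_len(K), each = K); jj <- rep(seq_len(K), K)
  base_w <- fit$freq[ii] * fit$freq[jj]
  pairsum <- if (m > 0L) patm[ii, , drop = FALSE] + patm[jj, , drop = FALSE]
             else matrix(0L, K * K, 0L)
  pa <- ifelse(fit$allele[ii] <= fit$allele[jj],
               paste(fit$allele[ii], fit$allele[jj], sep = "/"),
               paste(fit$allele[jj], fit$allele[ii], sep = "/"))
  # group subjects by identical genotype pattern at the classifier SNPs
  gkey <- apply(G, 1L, paste, collapse = ",")
  ug <- unique(gkey)
  out <- vector("list", length(ug))
  names(out) <- ug
  for (u in ug) {
    g <- G[match(u, gkey), , drop = TRUE]
    if (m > 0L) {
      d <- abs(sweep(pairsum, 2L, as.integer(g), "-"))
      d[, is.na(g)] <- 0L
      mis <- rowSums(d)
    } else mis <- rep(0, K * K)
    w <- base_w * eps^mis
    tw <- tapply(w, pa, sum)
    out[[u]] <- tw / sum(tw)
  }
  lapply(gkey, function(k) out[[k]])
}

# argmax unordered pair from a list of named posterior vectors
.best_pairs <- function(post_list) {
  a1 <- character(length(post_list)); a2 <- a1
  pp <- numeric(length(post_list))
  for (i in seq_along(post_list)) {
    v <- post_list[[i]]
    nm <- names(v)[order(-v, names(v))][1L]  # ties: lexicographic pair key
    al <- strsplit(nm, "/", fixed = TRUE)[[1L]]
    a1[i] <- al[1L]; a2[i] <- al[2L]; pp[i] <- max(v)
  }
  list(allele1 = a1, allele2 = a2, posterior = pp)
}

#' Impute HLA alleles with a trained model
#'
#' Per subject, each classifier yields a posterior over unordered allele
#' pairs (summing phase-consistent haplotype-pattern products, normalized);
#' posteriors are averaged across classifiers. The best pair is the argmax
#' (ties broken lexicographically) and a call is made when its averaged
#' posterior reaches `call_threshold`. Missing SNP genotypes are
#' marginalized over the classifier's frequency table.
#'
#' @param object a fitted `hla_ab_model`.
#' @param gm a [genotype_matrix()] containing the model's SNPs (by id).
#' @param call_threshold minimum posterior for a call (default 0.5).
#' @param ... unused.
#' @return data.frame of class `hla_calls`: `sample`, `gene`, `allele1`,
#'   `allele2`, `posterior`, `called`.
#' @export
predict.hla_ab_model <- function(object, gm, call_threshold = 0.5, ...) {
  stopifnot(inherits(gm, "genotype_matrix"))
  n <- length(gm$samples)
  acc <- vector("list", n)
  used <- 0L
  for (cl in object$classifiers) {
    idx <- match(cl$snp_id, gm$variants$id)
    if (all(is.na(idx))) next
    used <- used + 1L
    G <- matrix(NA_integer_, n, length(idx))
    ok <- !is.na(idx)
    G[, ok] <- gm$dosage[, idx[ok], drop = FALSE]
    post <- .classifier_posteriors(list(pattern = cl$pattern,
                                        allele = cl$allele, freq = cl$freq), G)
    for (i in seq_len(n)) {
      v <- post[[i]]
      if (is.null(acc[[i]])) acc[[i]] <- v
      else {
        keys <- union(names(acc[[i]]), names(v))
        a <- acc[[i]][keys]; a[is.na(a)] <- 0; names(a) <- keys
        b <- v[keys]; b[is.na(b)] <- 0
        acc[[i]] <- a + b
      }
    }
  }
  if (used == 0L) stop("no overlap between model SNPs and genotype matrix")
  acc <- lapply(acc, function(v) v / used)
  best <- .best_pairs(acc)
  out <- data.frame(sample = gm$samples, gene = object$gene,
                    allele1 = best$allele1, allele2 = best$allele2,
                    posterior = best$posterior,
                    called = best$posterior >= call_threshold,
                    stringsAsFactors = FALSE)
  class(out) <- c("hla_calls", "data.frame")
  out
}

#' @export
print.hla_ab_model <- function(x, ...) {
  cat("Attribute-bagging HLA imputation model\n")
  cat("  gene:", x$gene, " resolution:", x$resolution, "digits\n")
  cat("  classifiers:", length(x$classifiers),
      " trained on", x$n_train, "subjects\n")
  cat("  alleles:", length(x$alleles), "\n")
  cat("  mean OOB accuracy:",
      sprintf("%.3f", mean(vapply(x$classifiers, `[[`, 1.0, "oob_accuracy"))),
      "\n")
  invisible(x)
}

#' @export
summary.hla_ab_model <- function(object, ...) {
  oob <- vapply(object$classifiers, `[[`, 1.0, "oob_accuracy")
  nsnp <- vapply(object$classifiers, function(cl) length(cl$snp_id), 1L)
  structure(list(gene = object$gene, resolution = object$resolution,
                 n_classifiers = length(object$classifiers),
                 oob = summary(oob), snps_per_classifier = summary(nsnp),
                 alleles = object$alleles),
            class = "summary.hla_ab_model")
}

#' @export
print.summary.hla_ab_model <- function(x, ...) {
  cat("Model for", x$gene, "at", x$resolution, "digits;",
      x$n_classifiers, "classifiers\n")
  cat("OOB accuracy:\n"); print(x$oob)
  cat("SNPs per classifier:\n"); print(x$snps_per_classifier)
  invisible(x)
}

# deterministic train/validation sizes for a 7:3-style split
.validation_split <- function(n, train_fraction = 0.7) {
  n_train <- round(train_fraction * n)
  c(train = n_train, validation = n - n_train)
}

#' Internal validation of an imputation model
#'
#' Randomly splits typed subjects into training and validation sets
#' (training size = `round(train_fraction * n)`), trains on the first and
#' imputes the second. Accuracy is per-allele — each called subject
#' contributes two allele comparisons under the best matching of unordered
#' pairs — among called subjects only; call rate is called / validation
#' subjects. Validation alleles absent from training still count (against
#' accuracy), with a warning.
#'
#' @param gm,typing,gene,resolution,seed as in [hla_ab_train()].
#' @param train_fraction training proportion (default 0.7).
#' @param call_threshold posterior call threshold (default 0.5).
#' @param ... further arguments passed to [hla_ab_train()]
#'   (`n_classifiers`, `flank_bp`, `mtry`, ...).
#' @return list: `accuracy`, `call_rate`, `n_train`, `n_validation`,
#'   `model`, `calls`.
#' @export
hla_internal_validation <- function(gm, typing, gene, resolution = 4L,
                                    train_fraction = 0.7, call_threshold = 0.5,
                                    seed = NULL, ...) {
  n <- length(gm$samples)
  if (n < 10L) stop("need at least 10 typed subjects")
  if (!is.null(seed)) set.seed(seed)
  sz <- .validation_split(n, train_fraction)
  tr <- sample.int(n, sz["train"])
  va <- setdiff(seq_len(n), tr)
  model <- hla_ab_train(subset_gm(gm, samples = tr), typing, gene, resolution,
                        ...)
  calls <- predict(model, subset_gm(gm, samples = va),
                   call_threshold = call_threshold)
  ty <- typing[typing$gene == gene, , drop = FALSE]
  ty <- ty[match(gm$samples[va], ty$sample), , drop = FALSE]
  t1 <- truncate_allele(ty$allele1, resolution)
  t2 <- truncate_allele(ty$allele2, resolution)
  unseen <- setdiff(unique(c(t1, t2)), model$alleles)
  if (length(unseen)) {
    warning("validation allele(s) absent from training: ",
            paste(unseen, collapse = ", "))
  }
  called <- calls$called
  acc <- if (any(called)) {
    sum(mapply(.pair_match, calls$allele1[called], calls$allele2[called],
               t1[called], t2[called])) / (2 * sum(called))
  } else NA_real_
  list(accuracy = acc, call_rate = mean(called),
       n_train = unname(sz["train"]), n_validation = unname(sz["validation"]),
       model = model, calls = calls)
}

#' Serialize an imputation model to versioned JSON
#'
#' @param model a `hla_ab_model`.
#' @param path output path.
#' @export
write_hla_model <- function(model, path) {
  stopifnot(inherits(model, "hla_ab_model"))
  jsonlite::write_json(unclass(model), path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Load an imputation model from JSON
#'
#' @param path path written by [write_hla_model()].
#' @return a `hla_ab_model`.
#' @export
read_hla_model <- function(path) {
  raw <- tryCatch(jsonlite::read_json(path, simplifyVector = FALSE),
                  error = function(e) stop("cannot parse model file ", path,
                                           ": ", conditionMessage(e)))
  if (is.null(raw$version) || !identical(raw$version, "hla_ab_model/1")) {
    stop("model file version mismatch (expected hla_ab_model/1): ", path)
  }
  cls <- lapply(raw$classifiers, function(cl) {
    list(snp_id = as.character(unlist(cl$snp_id)),
         snp_pos = as.integer(unlist(cl$snp_pos)),
         pattern = as.character(unlist(cl$pattern)),
         allele = as.character(unlist(cl$allele)),
         freq = as.numeric(unlist(cl$freq)),
         oob_accuracy = as.numeric(cl$oob_accuracy))
  })
  structure(list(gene = raw$gene, resolution = as.integer(raw$resolution),
                 classifiers = cls, flank_bp = as.integer(raw$flank_bp),
                 n_train = as.integer(raw$n_train),
                 alleles = as.character(unlist(raw$alleles)),
                 seed = if (is.null(raw$seed)) NULL else as.integer(raw$seed),
                 version = raw$version),
            class = "hla_ab_model")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
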