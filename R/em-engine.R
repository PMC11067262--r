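# Progressive-insertion EM for multilocus haplotype frequencies from
# unphased data. Each subject contributes, per locus, an unordered token
# pair (alleles for HLA genes, 0/1 for SNP haplotype bits; NA = locus
# unobserved, marginalized over the token universe). Loci are inserted one
# at a time, with an EM pass and low-frequency pruning between insertions,
# so the haplotype support stays restricted to combinations compatible with
# the data (standard progressive EM practice; the full Cartesian product is
# infeasible for many loci).
#
# p1, p2: n x L character matrices of token pairs (both NA when missing).
# Returns: hap (H x L token matrix), freq, loglik, iterations, n_used.
.progressive_em <- function(p1, p2, tol = 1e-8, max_iter = 1000L,
                            prune = 1e-7, final_prune = 1e-6) {
  stopifnot(all(dim(p1) == dim(p2)), ncol(p1) >= 1L)
  n <- nrow(p1); L <- ncol(p1)
  # canonical unordered pairs, then collapse identical subjects into groups
  swap <- !is.na(p1) & !is.na(p2) & p1 > p2
  tmp <- p1[swap]; p1[swap] <- p2[swap]; p2[swap] <- tmp
  key <- apply(cbind(p1, p2), 1L, paste, collapse = "\x1f")
  grp_of <- match(key, unique(key))
  G <- max(grp_of)
  wt <- as.numeric(tabulate(grp_of, G))
  first <- match(seq_len(G), grp_of)
  U1 <- p1[first, , drop = FALSE]; U2 <- p2[first, , drop = FALSE]

  universe <- lapply(seq_len(L), function(l) sort(unique(c(U1[, l], U2[, l]))))
  universe <- lapply(universe, function(u) u[!is.na(u)])
  marg <- lapply(seq_len(L), function(l) {
    tok <- c(U1[!is.na(U1[, l]), l], U2[!is.na(U2[, l]), l])
    w2 <- c(wt[!is.na(U1[, l])], wt[!is.na(U2[, l])])
    tt <- tapply(w2, tok, sum)
    tt / sum(tt)
  })

  # ---- initialize with locus 1 ----
  ext_pairs <- function(g, l) {
    u <- U1[g, l]; v <- U2[g, l]
    if (is.na(u)) {
      tks <- universe[[l]]
      cbind(rep(tks, each = length(tks)), rep(tks, length(tks)))
    } else if (u == v) cbind(u, v) else rbind(c(u, v), c(v, u))
  }
  asn <- do.call(rbind, lapply(seq_len(G), function(g) {
    pp <- ext_pairs(g, 1L)
    cbind(g, pp)
  }))
  hap <- matrix(sort(unique(c(asn[, 2L], asn[, 3L]))), ncol = 1L)
  grp <- as.integer(asn[, 1L])
  h1 <- match(asn[, 2L], hap[, 1L])
  h2 <- match(asn[, 3L], hap[, 1L])
  freq <- as.numeric(marg[[1L]][hap[, 1L]])
  freq <- freq / sum(freq)

  total_iters <- 0L
  ll_trace <- numeric(0)

  run_em <- function(freq, grp, h1, h2, wt, tol, max_iter) {
    ll_old <- -Inf; it <- 0L
    H <- length(freq)
    tot2 <- 2 * sum(wt)
    repeat {
      it <- it + 1L
      aw <- freq[h1] * freq[h2]
      den <- as.vector(rowsum(aw, grp, reorder = TRUE))
      den[den <= 0] <- .Machine$double.xmin
      ll <- sum(wt * log(den))
      w <- aw / den[grp] * wt[grp]
      cnt <- numeric(H)
      t1 <- rowsum(w, h1); cnt[as.integer(rownames(t1))] <- t1
      t2 <- rowsum(w, h2)
      cnt[as.integer(rownames(t2))] <- cnt[as.integer(rownames(t2))] + t2
      freq <- cnt / tot2
      if (ll < ll_old - 1e-8 * max(1, abs(ll_old))) {
        stop("EM log-likelihood decreased; this is a bug")
      }
      if (it >= max_iter || abs(ll - ll_old) < tol) break
      ll_old <- ll
    }
    list(freq = freq, ll = ll, iters = it)
  }

  prune_state <- function(freq, hap, grp, h1, h2, thr) {
    keep <- freq >= thr
    # never let a group lose all of its assignments
    ok <- keep[h1] & keep[h2]
    alive <- unique(grp[ok])
    for (g in setdiff(unique(grp), alive)) {
      rows <- which(grp == g)
      best <- rows[which.max(freq[h1[rows]] * freq[h2[rows]])]
      keep[h1[best]] <- TRUE; keep[h2[best]] <- TRUE
    }
    ok <- keep[h1] & keep[h2]
    newid <- cumsum(keep)
    list(freq = freq[keep] / sum(freq[keep]),
         hap = hap[keep, , drop = FALSE],
         grp = grp[ok], h1 = newid[h1[ok]], h2 = newid[h2[ok]])
  }

  st <- list(freq = freq, hap = hap, grp = grp, h1 = h1, h2 = h2)
  fit <- run_em(st$freq, st$grp, st$h1, st$h2, wt, tol, max_iter)
  st$freq <- fit$freq; total_iters <- total_iters + fit$iters
  ll_trace <- c(ll_trace, fit$ll)

  for (l in seq_len(L)[-1L]) {
    # extend every assignment by the new locus
    nh1 <- integer(0); nh2 <- integer(0); ngrp <- integer(0)
    e1 <- character(0); e2 <- character(0)
    per_g <- lapply(seq_len(G), function(g) ext_pairs(g, l))
    rows <- split(seq_along(st$grp), st$grp)
    for (g in names(rows)) {
      gi <- as.integer(g)
      pp <- per_g[[gi]]
      rr <- rows[[g]]
      k <- nrow(pp)
      ngrp <- c(ngrp, rep(st$grp[rr], each = k))
      nh1 <- c(nh1, rep(st$h1[rr], each = k))
      nh2 <- c(nh2, rep(st$h2[rr], each = k))
      e1 <- c(e1, rep(pp[, 1L], length(rr)))
      e2 <- c(e2, rep(pp[, 2L], length(rr)))
    }
    k1 <- paste(nh1, e1, sep = "\x1f")
    k2 <- paste(nh2, e2, sep = "\x1f")
    uk <- unique(c(k1, k2))
    parent <- as.integer(sub("\x1f.*", "", uk))
    tok <- sub("^[0-9]+\x1f", "", uk)
    hap <- cbind(st$hap[parent, , drop = FALSE], tok)
    freq <- st$freq[parent] * as.numeric(marg[[l]][tok])
    freq[is.na(freq)] <- 1e-12
    freq <- freq / sum(freq)
    st <- list(freq = freq, hap = hap,
               grp = ngrp, h1 = match(k1, uk), h2 = match(k2, uk))
    fit <- run_em(st$freq, st$grp, st$h1, st$h2, wt, tol, max_iter)
    st$freq <- fit$freq; total_iters <- total_iters + fit$iters
    ll_trace <- c(ll_trace, fit$ll)
    if (l < L) st <- c(prune_state(st$freq, st$hap, st$grp, st$h1, st$h2, prune),
                       list())
  }

  keep <- st$freq >= final_prune
  if (!any(keep)) keep <- st$freq == max(st$freq)
  freq <- st$freq[keep] / sum(st$freq[keep])
  hap <- st$hap[keep, , drop = FALSE]
  ord <- order(apply(hap, 1L, paste, collapse = "\x1f"))
  colnames(hap) <- NULL
  list(hap = hap[ord, , drop = FALSE], freq = freq[ord],
       loglik = ll_trace[length(ll_trace)], ll_trace = ll_trace,
       iterations = total_iters, n_used = n)
}

# convert a 0/1/2/NA dosage matrix into the engine's token-pair form
.dosage_pairs <- function(G) {
  p1 <- matrix(NA_character_, nrow(G), ncol(G))
  p2 <- p1
  p1[!is.na(G) & G == 0L] <- "0"; p2[!is.na(G) & G == 0L] <- "0"
  p1[!is.na(G) & G == 1L] <- "0"; p2[!is.na(G) & G == 1L] <- "1"
  p1[!is.na(G) & G == 2L] <- "1"; p2[!is.na(G) & G == 2L] <- "1"
  list(p1 = p1, p2 = p2)
}
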