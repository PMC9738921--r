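# Independent brute-force oracles used by the test-suite; deliberately
# naive implementations, kept separate from the package code paths.

# AUC by explicit pair counting: concordant + 0.5 * ties over all
# (positive, negative) pairs
auc_pairs <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (n in neg)
    tot <- tot + (p > n) + 0.5 * (p == n)
  tot / (length(pos) * length(neg))
}

# Benjamini-Hochberg by the direct min-over-j formula
bh_brute <- function(p) {
  m <- length(p)
  ord <- order(p)
  q <- numeric(m)
  for (i in seq_len(m)) {
    js <- i:m
    q[ord[i]] <- min(1, min(m * p[ord[js]] / js))
  }
  q
}

# naive agglomerative complete-linkage clustering on a distance matrix,
# merging while the smallest complete-linkage distance is <= h
complete_linkage_naive <- function(D, h) {
  n <- nrow(D)
  clusters <- as.list(seq_len(n))
  repeat {
    best <- NULL; best_d <- Inf
    for (a in seq_along(clusters)) for (b in seq_along(clusters)) {
      if (a >= b) next
      d_ab <- max(D[clusters[[a]], clusters[[b]]])
      if (d_ab < best_d) { best_d <- d_ab; best <- c(a, b) }
    }
    if (is.null(best) || best_d > h) break
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  lab <- integer(n)
  for (g in seq_along(clusters)) lab[clusters[[g]]] <- g
  lab
}

# symmetric merged GLCM counts by enumerating every ordered neighbour pair
# over all 26 offsets (equivalent to 13 offsets symmetrized)
glcm_brute <- function(lev, n_levels) {
  d <- dim(lev)
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, ]
  P <- matrix(0, n_levels, n_levels)
  for (i in 1:d[1]) for (j in 1:d[2]) for (k in 1:d[3]) {
    if (is.na(lev[i, j, k])) next
    for (r in seq_len(nrow(offs))) {
      ii <- i + offs[r, 1]; jj <- j + offs[r, 2]; kk <- k + offs[r, 3]
      if (ii < 1 || ii > d[1] || jj < 1 || jj > d[2] || kk < 1 || kk > d[3])
        next
      if (is.na(lev[ii, jj, kk])) next
      P[lev[i, j, k], lev[ii, jj, kk]] <- P[lev[i, j, k], lev[ii, jj, kk]] + 1
    }
  }
  P
}

# a small single-lesion phantom spec used across tests
test_phantom <- function(ttp = 7.5, amp = 2.5, slope = 1.0, fwhm = 0,
                         noise = list(type = "none"), semi = c(7, 7, 6),
                         center = c(14, 24, 12), label = 0L, seed = 1L) {
  phantom_spec(psf_fwhm_mm = fwhm, noise_model = noise, seed = seed,
               lesions = list(lesion_spec(center, semi, label, amp, ttp,
                                          slope)))
}
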