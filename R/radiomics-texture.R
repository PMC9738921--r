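# Texture feature families on a discretized VOI: grey level co-occurrence
# (GLCM), run length (GLRLM), size zone (GLSZM), dependence (GLDM/NGLDM)
# and neighbourhood grey tone difference (NGTDM) matrices. All families use
# 3-D 26-neighbourhoods at distance 1; directional matrices are merged
# (summed) over the 13 unique offsets before features are computed.

texture_offsets <- function() {
  g <- as.matrix(expand.grid(di = -1:1, dj = -1:1, dk = -1:1))
  g <- g[rowSums(abs(g)) > 0, , drop = FALSE]
  # keep one of each +/- pair: first nonzero component positive
  keep <- apply(g, 1, function(o) o[match(TRUE, o != 0)] > 0)
  g[keep, , drop = FALSE]
}

# shift with NA fill; L is a 3-D array (NA outside the VOI)
shift_arr <- function(L, off) {
  d <- dim(L)
  out <- array(NA_integer_, d)
  src <- lapply(1:3, function(ax) {
    i <- seq_len(d[ax]) + off[ax]
    i[i >= 1 & i <= d[ax]]
  })
  dst <- lapply(1:3, function(ax) src[[ax]] - off[ax])
  out[dst[[1]], dst[[2]], dst[[3]]] <- L[src[[1]], src[[2]], src[[3]]]
  out
}

glcm_matrix <- function(L, n_levels) {
  counts <- numeric(n_levels^2)
  for (r in seq_len(nrow(texture_offsets()))) {
    off <- texture_offsets()[r, ]
    B <- shift_arr(L, off)
    ok <- !is.na(L) & !is.na(B)
    if (!any(ok)) next
    idx <- (L[ok] - 1L) * n_levels + B[ok]
    counts <- counts + tabulate(idx, n_levels^2)
  }
  P <- matrix(counts, n_levels, n_levels, byrow = TRUE)
  P + t(P)
}

glcm_features <- function(L, n_levels) {
  P <- glcm_matrix(L, n_levels)
  if (sum(P) == 0) {
    # isolated voxels: degenerate co-occurrence of each voxel with itself
    lev <- L[!is.na(L)]
    P <- matrix(0, n_levels, n_levels)
    for (g in lev) P[g, g] <- P[g, g] + 1
  }
  p <- P / sum(P)
  Ng <- n_levels
  i <- row(p); j <- col(p)
  px <- rowSums(p)
  mux <- sum(seq_len(Ng) * px)
  sigx <- sqrt(sum((seq_len(Ng) - mux)^2 * px))
  # diagonal and cross-diagonal distributions
  pxy_sum <- vapply(2:(2 * Ng), function(k) sum(p[i + j == k]), numeric(1))
  pxy_dif <- vapply(0:(Ng - 1), function(k) sum(p[abs(i - j) == k]), numeric(1))
  ks <- 2:(2 * Ng); kd <- 0:(Ng - 1)
  ent <- function(q) { q <- q[q > 0]; -sum(q * log2(q)) }
  da <- sum(kd * pxy_dif)
  sa <- sum(ks * pxy_sum)
  hxy <- ent(p)
  pxpy <- outer(px, px)
  hxy1 <- -sum(p[pxpy > 0] * log2(pxpy[pxpy > 0]))
  hxy2 <- ent(pxpy)
  hx <- ent(px)
  corr <- if (sigx > 0) (sum(i * j * p) - mux^2) / sigx^2 else 1
  imc1 <- if (hx > 0) (hxy - hxy1) / hx else 0
  imc2 <- sqrt(max(0, 1 - exp(-2 * (hxy2 - hxy))))
  offd <- i != j
  c(glcm_autocorrelation = sum(i * j * p),
    glcm_joint_average = mux,
    glcm_cluster_prominence = sum((i + j - 2 * mux)^4 * p),
    glcm_cluster_shade = sum((i + j - 2 * mux)^3 * p),
    glcm_cluster_tendency = sum((i + j - 2 * mux)^2 * p),
    glcm_contrast = sum((i - j)^2 * p),
    glcm_correlation = corr,
    glcm_difference_average = da,
    glcm_difference_entropy = ent(pxy_dif),
    glcm_difference_variance = sum((kd - da)^2 * pxy_dif),
    glcm_joint_energy = sum(p^2),
    glcm_joint_entropy = hxy,
    glcm_imc1 = imc1,
    glcm_imc2 = imc2,
    glcm_idm = sum(p / (1 + (i - j)^2)),
    glcm_idmn = sum(p / (1 + ((i - j) / Ng)^2)),
    glcm_id = sum(p / (1 + abs(i - j))),
    glcm_idn = sum(p / (1 + abs(i - j) / Ng)),
    glcm_inverse_variance = sum(p[offd] / (i[offd] - j[offd])^2),
    glcm_max_probability = max(p),
    glcm_sum_squares = sum((i - mux)^2 * p),
    glcm_sum_average = sa,
    glcm_sum_entropy = ent(pxy_sum),
    glcm_sum_variance = sum((ks - sa)^2 * pxy_sum))
}

# runs along the 13 directions, merged into one Ng x Nr matrix
glrlm_matrix <- function(L, n_levels) {
  d <- dim(L)
  co <- arrayInd(seq_len(prod(d)), d)
  vals_all <- as.vector(L)
  acc <- list()
  for (r in seq_len(nrow(texture_offsets()))) {
    off <- texture_offsets()[r, ]
    lead <- match(TRUE, off != 0)
    t <- co[, lead]
    key <- co - outer(t, off)
    ord <- order(key[, 1], key[, 2], key[, 3], t)
    vals <- vals_all[ord]
    k2 <- key[ord, , drop = FALSE]
    n <- length(vals)
    newgrp <- c(TRUE, (k2[-1, 1] != k2[-n, 1]) | (k2[-1, 2] != k2[-n, 2]) |
                      (k2[-1, 3] != k2[-n, 3]))
    prev <- c(NA, vals[-n])
    same <- !newgrp & !is.na(vals) & !is.na(prev) & vals == prev
    run_id <- cumsum(!same)
    run_val <- vals[!same]
    run_len <- tabulate(run_id)
    keep <- !is.na(run_val)
    acc[[r]] <- cbind(run_val[keep], run_len[keep])
  }
  runs <- do.call(rbind, acc)
  nr <- max(runs[, 2])
  R <- matrix(0, n_levels, nr)
  for (q in seq_len(nrow(runs)))
    R[runs[q, 1], runs[q, 2]] <- R[runs[q, 1], runs[q, 2]] + 1
  R
}

# shared feature formulas for run-length-like matrices (rows = grey level,
# cols = run length / zone size / dependence size)
series_features <- function(Rm, n_vox, prefix, size_name, norm_runs) {
  Ns <- sum(Rm)
  p <- Rm / Ns
  i <- row(p); j <- col(p)
  ri <- rowSums(Rm); rj <- colSums(Rm)
  mui <- sum(i * p); muj <- sum(j * p)
  pnz <- p[p > 0]
  out <- c(
    sum(p / j^2), sum(p * j^2),
    sum(ri^2) / Ns, sum(ri^2) / Ns^2,
    sum(rj^2) / Ns, sum(rj^2) / Ns^2,
    Ns / norm_runs,
    sum((i - mui)^2 * p), sum((j - muj)^2 * p),
    -sum(pnz * log2(pnz)),
    sum(p / i^2), sum(p * i^2),
    sum(p / (i^2 * j^2)), sum(p * i^2 / j^2),
    sum(p * j^2 / i^2), sum(p * i^2 * j^2))
  names(out) <- paste0(prefix, c(
    paste0("small_", size_name, "_emphasis"),
    paste0("large_", size_name, "_emphasis"),
    "gl_nonuniformity", "gl_nonuniformity_norm",
    paste0(size_name, "_nonuniformity"),
    paste0(size_name, "_nonuniformity_norm"),
    paste0(size_name, "_percentage"),
    "gl_variance", paste0(size_name, "_variance"),
    paste0(size_name, "_entropy"),
    "low_gl_emphasis", "high_gl_emphasis",
    paste0("small_", size_name, "_low_gl_emphasis"),
    paste0("small_", size_name, "_high_gl_emphasis"),
    paste0("large_", size_name, "_low_gl_emphasis"),
    paste0("large_", size_name, "_high_gl_emphasis")))
  out
}

glszm_matrix <- function(L, n_levels) {
  sizes <- list()
  for (g in seq_len(n_levels)) {
    m <- !is.na(L) & L == g
    if (!any(m)) { sizes[[g]] <- integer(0); next }
    lab <- label_components(m)
    sizes[[g]] <- tabulate(lab[lab > 0])
  }
  nz <- max(1L, max(unlist(lapply(sizes, function(s) if (length(s)) max(s) else 0L))))
  Z <- matrix(0, n_levels, nz)
  for (g in seq_len(n_levels)) for (s in sizes[[g]]) Z[g, s] <- Z[g, s] + 1
  Z
}

gldm_matrix <- function(L, n_levels) {
  cnt <- array(0L, dim(L))
  for (r in seq_len(nrow(neighbor_offsets_26()))) {
    off <- neighbor_offsets_26()[r, ]
    B <- shift_arr(L, off)
    eq <- !is.na(L) & !is.na(B) & L == B
    cnt <- cnt + eq
  }
  ok <- !is.na(L)
  # dependence size includes the centre voxel (column = count + 1)
  Dmax <- max(cnt[ok]) + 1L
  Dm <- matrix(0, n_levels, Dmax)
  ij <- cbind(L[ok], cnt[ok] + 1L)
  for (q in seq_len(nrow(ij))) Dm[ij[q, 1], ij[q, 2]] <- Dm[ij[q, 1], ij[q, 2]] + 1
  Dm
}

gldm_features <- function(L, n_levels) {
  Dm <- gldm_matrix(L, n_levels)
  f <- series_features(Dm, sum(!is.na(L)), "gldm_", "dep", norm_runs = 1)
  # GLDM keeps a canonical 14 of the series formulas (drop the two
  # normalized-by-N^2 duplicates' counterparts used by run/zone families)
  keep <- c("gldm_small_dep_emphasis", "gldm_large_dep_emphasis",
            "gldm_gl_nonuniformity", "gldm_dep_nonuniformity",
            "gldm_dep_nonuniformity_norm", "gldm_gl_variance",
            "gldm_dep_variance", "gldm_dep_entropy",
            "gldm_low_gl_emphasis", "gldm_high_gl_emphasis",
            "gldm_small_dep_low_gl_emphasis", "gldm_small_dep_high_gl_emphasis",
            "gldm_large_dep_low_gl_emphasis", "gldm_large_dep_high_gl_emphasis")
  f[keep]
}

ngtdm_features <- function(L, n_levels) {
  num <- array(0, dim(L))
  den <- array(0L, dim(L))
  for (r in seq_len(nrow(neighbor_offsets_26()))) {
    off <- neighbor_offsets_26()[r, ]
    B <- shift_arr(L, off)
    v <- !is.na(B)
    num <- num + ifelse(v, B, 0L)
    den <- den + v
  }
  ok <- !is.na(L) & den > 0
  Nv <- sum(ok)
  if (Nv == 0)
    return(c(ngtdm_coarseness = 1e6, ngtdm_contrast = 0, ngtdm_busyness = 0,
             ngtdm_complexity = 0, ngtdm_strength = 0))
  Abar <- num[ok] / den[ok]
  lev <- L[ok]
  s <- vapply(seq_len(n_levels), function(g) sum(abs(g - Abar)[lev == g]),
              numeric(1))
  ni <- tabulate(lev, n_levels)
  p <- ni / Nv
  act <- p > 0
  Ngp <- sum(act)
  ii <- seq_len(n_levels)
  coars_den <- sum(p * s)
  coarseness <- if (coars_den > 0) 1 / coars_den else 1e6
  contrast <- if (Ngp > 1)
    sum(outer(p[act], p[act]) * outer(ii[act], ii[act], `-`)^2) /
      (Ngp * (Ngp - 1)) * sum(s) / Nv else 0
  bus_den <- sum(abs(outer(ii[act] * p[act], ii[act] * p[act], `-`)))
  busyness <- if (bus_den > 0) sum(p * s) / bus_den else 0
  cx <- 0; st <- 0
  for (a in ii[act]) for (b in ii[act]) {
    cx <- cx + abs(a - b) * (p[a] * s[a] + p[b] * s[b]) / (p[a] + p[b])
    st <- st + (p[a] + p[b]) * (a - b)^2
  }
  complexity <- cx / Nv
  strength <- if (sum(s) > 0) st / sum(s) else 0
  c(ngtdm_coarseness = coarseness, ngtdm_contrast = contrast,
    ngtdm_busyness = busyness, ngtdm_complexity = complexity,
    ngtdm_strength = strength)
}

#' Texture features of a discretized VOI
#'
#' GLCM (24), GLRLM (16), GLSZM (16), GLDM (14) and NGTDM (5) features --
#' 75 in all -- computed from matrices merged over the 13 unique 3-D
#' offsets at distance 1, using min-anchored fixed-bin-width levels.
#'
#' @param lev integer 3-D array of grey levels, NA outside the VOI.
#' @param n_levels number of levels.
#' @param spacing voxel spacing mm (carried for interface symmetry).
#' @return named numeric vector of length 75.
#' @export
extract_texture <- function(lev, n_levels, spacing = c(1, 1, 1)) {
  n_vox <- sum(!is.na(lev))
  glcm <- glcm_features(lev, n_levels)
  glrlm <- series_features(glrlm_matrix(lev, n_levels), n_vox, "glrlm_",
                           "run", norm_runs = n_vox * 13)
  glszm <- series_features(glszm_matrix(lev, n_levels), n_vox, "glszm_",
                           "zone", norm_runs = n_vox)
  gldm <- gldm_features(lev, n_levels)
  ngtdm <- ngtdm_features(lev, n_levels)
  c(glcm, glrlm, glszm, gldm, ngtdm)
}
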