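# Internal numerical utilities shared across modules: separable Gaussian
# blurring with reflective boundaries, 3-D connected components, trilinear
# resampling, sphere-neighbourhood means and a rank-based AUC.

#' @keywords internal
gaussian_kernel_1d <- function(sigma_vox) {
  if (sigma_vox <= 0) return(1)
  h <- max(1L, ceiling(4 * sigma_vox))
  x <- seq(-h, h)
  w <- exp(-x^2 / (2 * sigma_vox^2))
  w / sum(w)
}

# Fold an out-of-range index into 1..n by mirror reflection (edge repeated),
# so no mass leaves the grid and column sums of the blur matrix stay 1.
reflect_index <- function(i, n) {
  if (n == 1L) return(rep(1L, length(i)))
  p <- 2L * n
  j <- ((i - 1L) %% p + p) %% p  # 0 .. 2n-1
  ifelse(j < n, j + 1L, p - j)
}

# n x n matrix applying a reflected 1-D Gaussian along one axis.
blur_matrix <- function(n, sigma_vox) {
  K <- diag(n)
  if (sigma_vox <= 0) return(K)
  w <- gaussian_kernel_1d(sigma_vox)
  h <- (length(w) - 1L) / 2L
  K <- matrix(0, n, n)
  for (k in seq_along(w)) {
    off <- k - h - 1L
    src <- reflect_index(seq_len(n) + off, n)
    K[cbind(seq_len(n), src)] <- K[cbind(seq_len(n), src)] + w[k]
  }
  K
}

apply_along_axis1 <- function(arr, K) {
  d <- dim(arr)
  array(K %*% matrix(arr, d[1], prod(d[-1])), dim = d)
}

#' Gaussian blur of a 3-D array
#'
#' Separable Gaussian smoothing with mirror-reflected boundaries, so the
#' global sum is conserved to machine precision. The kernel full width at
#' half maximum is given in millimetres and converted per-axis using the
#' voxel spacing.
#'
#' @param arr numeric array with >= 3 dimensions; the first three are the
#'   spatial axes (a 4th frame axis is blurred frame-wise in one pass).
#' @param fwhm_mm kernel FWHM in mm (scalar).
#' @param spacing voxel spacing in mm, length 3.
#' @return blurred array, same dimensions.
#' @keywords internal
gaussian_blur3d <- function(arr, fwhm_mm, spacing) {
  nd <- length(dim(arr))
  stopifnot(nd >= 3L, fwhm_mm >= 0, length(spacing) == 3L)
  if (fwhm_mm == 0) return(arr)
  sigma_mm <- fwhm_mm / (2 * sqrt(2 * log(2)))
  sig <- sigma_mm / spacing
  Ks <- lapply(1:3, function(ax) blur_matrix(dim(arr)[ax], sig[ax]))
  # cycle the leading axis so each 1-D transform is a single matrix product
  rest <- if (nd > 3) 4:nd else integer(0)
  arr <- apply_along_axis1(arr, Ks[[1]])
  arr <- apply_along_axis1(aperm(arr, c(2, 1, 3, rest)), Ks[[2]])
  arr <- apply_along_axis1(aperm(arr, c(3, 2, 1, rest)), Ks[[3]])
  aperm(arr, c(2, 3, 1, rest))
}

# 26-connected neighbour offsets as a 26 x 3 integer matrix.
neighbor_offsets_26 <- function() {
  g <- as.matrix(expand.grid(di = -1:1, dj = -1:1, dk = -1:1))
  g[rowSums(abs(g)) > 0, , drop = FALSE]
}

#' Label 26-connected components of a logical 3-D mask
#'
#' @param mask logical 3-D array.
#' @return integer array of the same shape; 0 outside the mask, components
#'   numbered from 1 in decreasing size order.
#' @keywords internal
label_components <- function(mask) {
  d <- dim(mask)
  lab <- array(0L, d)
  offs <- neighbor_offsets_26()
  idx <- which(mask)
  if (!length(idx)) return(lab)
  coord <- arrayInd(idx, d)
  in_mask <- array(FALSE, d); in_mask[idx] <- TRUE
  comp <- 0L
  for (s in idx) {
    if (lab[s] != 0L) next
    comp <- comp + 1L
    lab[s] <- comp
    frontier <- matrix(arrayInd(s, d), ncol = 3)
    while (nrow(frontier)) {
      nb <- do.call(rbind, lapply(seq_len(nrow(offs)), function(o)
        sweep(frontier, 2, offs[o, ], "+")))
      keep <- nb[, 1] >= 1 & nb[, 1] <= d[1] &
              nb[, 2] >= 1 & nb[, 2] <= d[2] &
              nb[, 3] >= 1 & nb[, 3] <= d[3]
      nb <- nb[keep, , drop = FALSE]
      if (!nrow(nb)) break
      lin <- nb[, 1] + (nb[, 2] - 1L) * d[1] + (nb[, 3] - 1L) * d[1] * d[2]
      fresh <- in_mask[lin] & lab[lin] == 0L
      lin <- unique(lin[fresh])
      if (!length(lin)) break
      lab[lin] <- comp
      frontier <- arrayInd(lin, d)
    }
  }
  # renumber so component 1 is the largest
  if (comp > 1L) {
    sizes <- tabulate(lab[lab > 0L], comp)
    ord <- order(sizes, decreasing = TRUE)
    remap <- integer(comp); remap[ord] <- seq_len(comp)
    lab[lab > 0L] <- remap[lab[lab > 0L]]
  }
  lab
}

#' Mean of an image over a 1-cm3 sphere around given voxels
#'
#' Used for the IBSI intensity-peak features and the SUVpeak convention:
#' the sphere has a volume of 1 cm^3 (radius ~6.204 mm); for each centre
#' voxel the mean is taken over the in-grid voxels whose centre lies within
#' the radius.
#'
#' @param img numeric 3-D array.
#' @param centers integer matrix (n x 3) of voxel coordinates.
#' @param spacing voxel spacing mm.
#' @keywords internal
sphere_means <- function(img, centers, spacing) {
  r <- (3 * 1000 / (4 * pi))^(1 / 3)  # mm, 1 cm^3 sphere
  d <- dim(img)
  hw <- pmin(ceiling(r / spacing), d - 1L)
  g <- as.matrix(expand.grid(di = -hw[1]:hw[1], dj = -hw[2]:hw[2],
                             dk = -hw[3]:hw[3]))
  dist <- sqrt((g[, 1] * spacing[1])^2 + (g[, 2] * spacing[2])^2 +
               (g[, 3] * spacing[3])^2)
  g <- g[dist <= r, , drop = FALSE]
  vapply(seq_len(nrow(centers)), function(i) {
    nb <- sweep(g, 2, centers[i, ], "+")
    keep <- nb[, 1] >= 1 & nb[, 1] <= d[1] & nb[, 2] >= 1 & nb[, 2] <= d[2] &
            nb[, 3] >= 1 & nb[, 3] <= d[3]
    nb <- nb[keep, , drop = FALSE]
    mean(img[nb])
  }, numeric(1))
}

#' Area under the ROC curve by the rank (Mann-Whitney) formula
#'
#' Ties contribute 1/2 through midranks.
#'
#' @param scores numeric prediction scores.
#' @param labels 0/1 labels.
#' @return AUC in [0, 1].
#' @export
auc_rank <- function(scores, labels) {
  labels <- as.integer(labels)
  stopifnot(length(scores) == length(labels), all(labels %in% 0:1))
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L) stop("both classes required for AUC")
  r <- rank(scores)
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Local-quadratic (Savitzky-Golay style) smoother matrix for points `t`
# (strictly increasing): window `w` points, polynomial order `ord`;
# one-sided windows at the edges, each row evaluates the local fit at its
# own abscissa, so polynomials of degree <= ord are reproduced exactly.
sg_smoother_matrix <- function(t, w = 7L, ord = 2L) {
  n <- length(t)
  stopifnot(n >= w, w > ord)
  S <- matrix(0, n, n)
  half <- (w - 1L) %/% 2L
  for (i in seq_len(n)) {
    lo <- max(1L, min(i - half, n - w + 1L))
    win <- lo:(lo + w - 1L)
    X <- outer(t[win] - t[i], 0:ord, `^`)
    S[i, win] <- (solve(crossprod(X)) %*% t(X))[1, ]
  }
  S
}

# deterministic RNG scope helper
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}
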