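# First-order / intensity features, including the two IBSI intensity-peak
# features (1-cm^3 sphere means) that pyradiomics-style extractors lack.

# zero-padded FFT convolution of a 3-D array with an arbitrary 3-D kernel
conv3d_fft <- function(arr, kern) {
  da <- dim(arr); dk <- dim(kern)
  ds <- da + dk - 1L
  A <- array(0, ds); A[1:da[1], 1:da[2], 1:da[3]] <- arr
  K <- array(0, ds); K[1:dk[1], 1:dk[2], 1:dk[3]] <- kern
  full <- Re(fft(fft(A) * fft(K), inverse = TRUE)) / prod(ds)
  off <- (dk - 1L) %/% 2L
  full[off[1] + (1:da[1]), off[2] + (1:da[2]), off[3] + (1:da[3])]
}

sphere_kernel <- function(spacing) {
  r <- (3 * 1000 / (4 * pi))^(1 / 3)
  hw <- ceiling(r / spacing)
  g <- expand.grid(x = -hw[1]:hw[1], y = -hw[2]:hw[2], z = -hw[3]:hw[3])
  k <- array(as.numeric(sqrt((g$x * spacing[1])^2 + (g$y * spacing[2])^2 +
                             (g$z * spacing[3])^2) <= r),
             2L * hw + 1L)
  k
}

# sphere-mean image with partial spheres at the grid edge renormalized
sphere_mean_image <- function(img, spacing) {
  k <- sphere_kernel(spacing)
  num <- conv3d_fft(img, k)
  den <- conv3d_fft(array(1, dim(img)), k)
  num / pmax(den, 1)
}

#' Intensity (first-order) features of a VOI
#'
#' The canonical 19: mean, variance, skewness, excess kurtosis, median,
#' minimum, 10th/90th percentiles, maximum, interquartile range, range,
#' mean absolute deviation, robust MAD (within the 10-90 percentile band),
#' median absolute deviation, root mean square, discretized-histogram
#' entropy (log2) and uniformity, plus the local and global intensity peaks
#' (1-cm^3 sphere means; local at the hottest voxel, global the maximum
#' over the VOI).
#'
#' @param img 3-D intensity array the VOI lives in.
#' @param voi logical 3-D mask.
#' @param disc a [discretize_fbw()] result on the VOI values.
#' @param spacing voxel spacing mm.
#' @return named numeric vector of length 19.
#' @export
extract_intensity <- function(img, voi, disc, spacing) {
  x <- img[voi]
  n <- length(x)
  if (!n) stop("empty VOI")
  mu <- mean(x)
  v <- mean((x - mu)^2)
  sk <- if (v > 0) mean((x - mu)^3) / v^1.5 else 0
  ku <- if (v > 0) mean((x - mu)^4) / v^2 - 3 else 0
  q <- unname(stats::quantile(x, c(0.10, 0.25, 0.75, 0.90)))
  band <- x[x >= q[1] & x <= q[4]]
  rmad <- if (length(band)) mean(abs(band - mean(band))) else 0
  p <- tabulate(disc$levels, disc$n_levels) / n
  pnz <- p[p > 0]
  pk <- sphere_mean_image(img, spacing)
  hot <- which(voi)[which.max(x)]
  c(stat_mean = mu, stat_variance = v, stat_skewness = sk,
    stat_kurtosis = ku, stat_median = stats::median(x), stat_min = min(x),
    stat_p10 = q[1], stat_p90 = q[4], stat_max = max(x),
    stat_iqr = q[3] - q[2], stat_range = max(x) - min(x),
    stat_mad = mean(abs(x - mu)), stat_rmad = rmad,
    stat_medad = mean(abs(x - stats::median(x))),
    stat_rms = sqrt(mean(x^2)),
    stat_entropy = -sum(pnz * log2(pnz)),
    stat_uniformity = sum(pnz^2),
    stat_local_peak = pk[hot],
    stat_global_peak = max(pk[voi]))
}
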