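# Segmentation, time-activity-curve (TAC) handling, and the two parametric
# maps the analysis revolves around: the static tumour-to-background ratio
# (TBR) and the dynamic voxel time-to-peak (TTP).

#' Time-activity curve
#' @param times frame-midpoint minutes, strictly increasing.
#' @param values SUV or ratio values, same length.
#' @param fitted logical: has the curve been smoothed by [fit_tac()]?
#' @export
tac <- function(times, values, fitted = FALSE) {
  stopifnot(length(times) == length(values), all(diff(times) > 0))
  structure(list(times = as.numeric(times), values = as.numeric(values),
                 fitted = isTRUE(fitted)), class = "tac")
}

#' Parametric map container
#' @param kind "TBR" (unitless) or "TTP" (minutes).
#' @param values 3-D numeric array.
#' @param spacing voxel spacing mm.
#' @export
parametric_map <- function(kind = c("TBR", "TTP"), values, spacing) {
  kind <- match.arg(kind)
  structure(list(kind = kind, values = values, spacing = spacing),
            class = "parametric_map")
}

#' Healthy-brain reference value
#'
#' Arithmetic mean of the static image over the crescent-shaped healthy
#' brain VOI (white + gray matter).
#'
#' @param static 3-D static image.
#' @param crescent a [voi_mask()] with role "brain".
#' @return scalar SUVmean.
#' @export
brain_reference <- function(static, crescent) {
  m <- crescent$mask
  if (!any(m)) stop("empty brain reference mask")
  mean(static[m])
}

#' Threshold tumour segmentation
#'
#' Voxels at or above `factor` times the healthy-brain SUVmean, restricted
#' to a search region (which excludes the striatum), keeping the largest
#' 26-connected component.
#'
#' @param static 3-D static image.
#' @param brain_mean healthy-brain reference, > 0.
#' @param search_region a [voi_mask()] limiting the candidate voxels.
#' @param factor threshold multiplier (default 1.6).
#' @return tumour [voi_mask()].
#' @export
segment_tumor <- function(static, brain_mean, search_region, factor = 1.6) {
  stopifnot(brain_mean > 0)
  cand <- (static >= factor * brain_mean) & search_region$mask
  if (!any(cand)) stop("no voxels above threshold")
  lab <- label_components(cand)
  voi_mask(lab == 1L, search_region$spacing, "tumor")
}

#' Striatum segmentation by fractional-max threshold
#'
#' Keeps the voxels of the seed region at or above `fraction` of the
#' region's maximum uptake.
#'
#' @param static 3-D static image.
#' @param seed_region a [voi_mask()].
#' @param fraction threshold fraction of SUVmax (default 0.70).
#' @export
segment_striatum <- function(static, seed_region, fraction = 0.70) {
  m <- seed_region$mask
  if (!any(m)) stop("empty striatum seed region")
  thr <- fraction * max(static[m])
  voi_mask(m & (static >= thr), seed_region$spacing, "striatum")
}

#' Static TBR parametric map
#'
#' Voxelwise division of the static image by the healthy-brain SUVmean;
#' normalizing out global uptake differences (e.g. Carbidopa premedication
#' effects).
#'
#' @param static 3-D static image with `spacing` attribute.
#' @param brain_mean healthy-brain reference, > 0.
#' @export
tbr_map <- function(static, brain_mean) {
  stopifnot(brain_mean > 0)
  parametric_map("TBR", static / brain_mean, attr(static, "spacing"))
}

#' Smooth a TAC by local quadratic regression
#'
#' Deterministic Savitzky-Golay style smoothing (window 7 frames, order 2,
#' one-sided windows at the edges), evaluated at the frame midpoints.
#' Reproduces polynomials of degree <= 2 exactly and has no convergence
#' failure modes, which suits the piecewise-smooth curves seen here.
#'
#' @param x a [tac()] with >= 7 frames.
#' @return fitted [tac()].
#' @export
fit_tac <- function(x) {
  stopifnot(inherits(x, "tac"))
  if (length(x$times) < 7) stop("need at least 7 frames to fit a TAC")
  S <- sg_smoother_matrix(x$times, w = 7L, ord = 2L)
  tac(x$times, drop(S %*% x$values), fitted = TRUE)
}

#' Fit the rise/washout kinetic model to a TAC
#'
#' Least-squares fit of a continuous two-segment piecewise-linear curve
#' `b0 + b1 t + b2 (t - t_knot)+`, scanning the knot over the frame
#' midpoints and keeping the smallest residual sum of squares (ties by the
#' earliest knot). A small positive post-knot slope (below half the rise
#' rate) is treated as a noise-flipped plateau and replaced by the
#' rise-plateau submodel `b0 + b1 min(t, t_knot)` for that knot; a
#' genuinely continuing rise (post-knot slope at least half the rise rate)
#' is kept, with its maximum at the end of the window. Curves of the
#' rise-then-washout family are reproduced exactly, so the time of the
#' fitted maximum recovers the true time-to-peak on noise-free data, while
#' the 3-parameter fit averages out frame noise.
#'
#' @param x a [tac()].
#' @return fitted [tac()].
#' @export
fit_tac_kinetic <- function(x) {
  stopifnot(inherits(x, "tac"))
  km <- kinetic_hat_matrices(x$times)
  best <- NULL; best_sse <- Inf
  for (b in seq_along(km$H3)) {
    co <- drop(km$B3[[b]] %*% x$values)
    post <- co[2] + co[3]
    plateau <- post > 0 && !(co[2] > 0 && post >= 0.5 * co[2])
    f <- if (plateau) drop(km$H2[[b]] %*% x$values)
         else drop(km$H3[[b]] %*% x$values)
    sse <- sum((x$values - f)^2)
    if (sse < best_sse - 1e-12) { best_sse <- sse; best <- f }
  }
  tac(x$times, best, fitted = TRUE)
}

# hat and coefficient matrices of the knot-model least squares, one per
# candidate knot (interior midpoints, so each segment has >= 2 points):
# H3/B3 for the full two-slope model, H2 for the rise-plateau submodel
kinetic_hat_matrices <- function(times) {
  n <- length(times)
  ks <- 2:(n - 1)
  B3 <- H3 <- H2 <- vector("list", length(ks))
  for (i in seq_along(ks)) {
    b <- ks[i]
    X <- cbind(1, times, pmax(times - times[b], 0))
    B3[[i]] <- solve(crossprod(X), t(X))
    H3[[i]] <- X %*% B3[[i]]
    X2 <- cbind(1, pmin(times, times[b]))
    H2[[i]] <- X2 %*% solve(crossprod(X2), t(X2))
  }
  list(B3 = B3, H3 = H3, H2 = H2)
}

#' Ratio of two fitted TACs
#'
#' Pointwise division of a (fitted) tumour TAC by the fitted mean-brain TAC
#' on the same time grid.
#'
#' @param tumor,brain fitted [tac()] objects on identical time grids.
#' @export
tac_ratio <- function(tumor, brain) {
  stopifnot(identical(tumor$times, brain$times))
  if (any(brain$values <= 0)) stop("brain TAC must be strictly positive")
  tac(tumor$times, tumor$values / brain$values,
      fitted = tumor$fitted && brain$fitted)
}

#' Time-to-peak of a fitted TAC ratio
#'
#' Frame midpoint (minutes from acquisition start) at which the curve
#' attains its maximum; ties (within a 1e-9 numerical tolerance, so exact
#' plateaus are treated as ties in floating point) broken by the earliest
#' frame.
#'
#' @param x a fitted [tac()].
#' @return minutes.
#' @export
ttp <- function(x) {
  stopifnot(inherits(x, "tac"))
  if (!x$fitted) stop("ttp expects a fitted TAC")
  x$times[which(x$values >= max(x$values) - 1e-9)[1]]
}

#' Dynamic TTP parametric map
#'
#' For every voxel inside the bounding box of the tumour region: smooth the
#' voxel TAC, divide by the fitted crescent-mean brain TAC, and record the
#' time of the maximum. Voxels outside the region are NaN.
#'
#' @param study a denoised `dynamic_study`.
#' @param brain_crescent brain reference [voi_mask()].
#' @param tumor_region [voi_mask()] delimiting where to compute the map.
#' @return [parametric_map()] of kind "TTP" (minutes).
#' @export
ttp_map <- function(study, brain_crescent, tumor_region) {
  d <- dim(study$data)
  mids <- frame_midpoints(study$schedule)
  S <- sg_smoother_matrix(mids, 7L, 2L)
  nvox <- prod(d[1:3])
  fm <- matrix(study$data, nvox, d[4])
  brain_tac_raw <- colMeans(fm[which(brain_crescent$mask), , drop = FALSE])
  brain_fit <- drop(S %*% brain_tac_raw)
  if (any(brain_fit <= 0)) stop("non-positive fitted brain TAC")
  idx <- which(tumor_region$mask)
  if (!length(idx)) stop("empty tumour region")
  # normalize the raw voxel TACs by the fitted brain TAC, then kinetic-fit
  # the ratio curves so the fitted maximum is read off a single smooth
  # rise/washout model per voxel
  V <- sweep(fm[idx, , drop = FALSE], 2, brain_fit, `/`)
  # voxelwise rise/washout kinetic fit: pick the knot with least SSE,
  # substituting the rise-plateau submodel where the post-knot slope
  # would be positive
  km <- kinetic_hat_matrices(mids)
  Fbest <- NULL; sse_best <- rep(Inf, nrow(V))
  for (b in seq_along(km$H3)) {
    co <- V %*% t(km$B3[[b]])
    Fb <- V %*% t(km$H3[[b]])
    post <- co[, 2] + co[, 3]
    viol <- post > 0 & !(co[, 2] > 0 & post >= 0.5 * co[, 2])
    if (any(viol))
      Fb[viol, ] <- (V %*% t(km$H2[[b]]))[viol, , drop = FALSE]
    sse <- rowSums((V - Fb)^2)
    upd <- sse < sse_best - 1e-12
    if (any(upd)) {
      if (is.null(Fbest)) Fbest <- Fb
      else Fbest[upd, ] <- Fb[upd, , drop = FALSE]
      sse_best[upd] <- sse[upd]
    }
  }
  # earliest index within numerical tolerance of the row maximum
  rmax <- do.call(pmax, as.data.frame(Fbest))
  ttp_vox <- mids[max.col(Fbest >= rmax - 1e-9, ties.method = "first")]
  vals <- array(NaN, d[1:3])
  vals[idx] <- ttp_vox
  parametric_map("TTP", vals, study$spacing)
}

#' Region-based conventional and dynamic features
#'
#' Nine values per subject: mean, maximum and 1-cm^3-sphere peak of TBR;
#' the same three statistics divided by the striatum SUVmean
#' (tumour-to-striatum ratios); metabolic tumour volume (MTV, mm^3); the
#' region TTP of the tumour-mean TAC ratio; and the late slope of that
#' ratio (least squares over t >= 10 min, per hour).
#'
#' @param tbr a TBR [parametric_map()].
#' @param study the denoised `dynamic_study`.
#' @param vois list with elements `tumor`, `striatum`, `brain`
#'   ([voi_mask()] objects).
#' @return named numeric vector of length 9.
#' @export
region_features <- function(tbr, study, vois) {
  tm <- vois$tumor$mask; sm <- vois$striatum$mask
  if (!any(tm) || !any(sm)) stop("tumour and striatum VOIs must be nonempty")
  v <- tbr$values
  tvals <- v[tm]
  hot <- which(tm)[which.max(tvals)]
  peak <- sphere_means(v, matrix(arrayInd(hot, dim(v)), ncol = 3), tbr$spacing)
  stri_mean <- mean(v[sm])
  mtv <- sum(tm) * prod(vois$tumor$spacing)

  mids <- frame_midpoints(study$schedule)
  d <- dim(study$data)
  fm <- matrix(study$data, prod(d[1:3]), d[4])
  tum_tac <- tac(mids, colMeans(fm[which(tm), , drop = FALSE]))
  brain_tac <- fit_tac(tac(mids, colMeans(fm[which(vois$brain$mask), , drop = FALSE])))
  r <- fit_tac_kinetic(tac_ratio(tum_tac, brain_tac))
  late <- r$times >= 10
  slope_per_min <- stats::coef(stats::lm(r$values[late] ~ r$times[late]))[2]

  c(TBR_mean = mean(tvals), TBR_max = max(tvals), TBR_peak = peak,
    TSR_mean = mean(tvals) / stri_mean, TSR_max = max(tvals) / stri_mean,
    TSR_peak = peak / stri_mean, MTV = mtv,
    TTP_region = ttp(r), slope_region = unname(slope_per_min) * 60)
}
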