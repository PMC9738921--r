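# IBSI-style feature extraction from parametric maps: isotropic
# resampling, fixed-bin-width discretization, and the canonical
# 105-feature set (11 morphology + 19 intensity + 75 texture).

#' Resample a parametric map and its VOI to an isotropic grid
#'
#' Trilinear interpolation for intensities; the mask is interpolated
#' linearly and thresholded at 0.5. The output grid is aligned to the
#' input origin (voxel centre of the first voxel).
#'
#' @param map a [parametric_map()].
#' @param voi a [voi_mask()] on the same grid.
#' @param target target voxel size mm (default 1).
#' @return list(map, voi) on the new grid.
#' @export
resample_isotropic <- function(map, voi, target = 1) {
  sp <- map$spacing
  stopifnot(all(sp > 0), target > 0)
  if (all(abs(sp - target) < 1e-12))
    return(list(map = map, voi = voi))
  d <- dim(map$values)
  interp <- function(arr) {
    axes <- lapply(1:3, function(ax) {
      n_out <- floor((d[ax] - 1) * sp[ax] / target) + 1
      p <- (seq_len(n_out) - 1) * target / sp[ax] + 1
      i0 <- pmin(pmax(floor(p), 1), max(d[ax] - 1, 1))
      list(i0 = as.integer(i0), i1 = as.integer(pmin(i0 + 1, d[ax])),
           f = p - i0)
    })
    gx <- axes[[1]]; gy <- axes[[2]]; gz <- axes[[3]]
    out <- 0
    for (cx in 0:1) for (cy in 0:1) for (cz in 0:1) {
      ii <- if (cx) gx$i1 else gx$i0
      jj <- if (cy) gy$i1 else gy$i0
      kk <- if (cz) gz$i1 else gz$i0
      wx <- if (cx) gx$f else 1 - gx$f
      wy <- if (cy) gy$f else 1 - gy$f
      wz <- if (cz) gz$f else 1 - gz$f
      w <- outer(outer(wx, wy), wz)
      out <- out + arr[ii, jj, kk] * w
    }
    out
  }
  vals <- interp(map$values)
  mres <- interp(voi$mask + 0) >= 0.5
  list(map = parametric_map(map$kind, vals, rep(target, 3)),
       voi = voi_mask(mres, rep(target, 3), voi$role))
}

#' Fixed-bin-width discretization
#'
#' Levels are anchored at the VOI minimum: `floor((x - min) / w) + 1`,
#' with the top edge clamped into the last bin; `n_levels =
#' floor((max - min) / w) + 1`.
#'
#' @param values numeric vector of VOI intensities.
#' @param bin_width bin width (> 0): 0.1 for TBR maps, 1 min for TTP maps.
#' @return list(levels, n_levels, bin_width) of class `discretized_voi`.
#' @export
discretize_fbw <- function(values, bin_width) {
  stopifnot(bin_width > 0, length(values) > 0)
  mn <- min(values)
  n_levels <- as.integer(floor((max(values) - mn) / bin_width)) + 1L
  lev <- pmin(as.integer(floor((values - mn) / bin_width)) + 1L, n_levels)
  structure(list(levels = lev, n_levels = n_levels, bin_width = bin_width),
            class = "discretized_voi")
}

#' Extract the full 105-feature radiomics vector from a parametric map
#'
#' Pipeline: crop to the VOI bounding box (with margin for the peak
#' sphere), resample to 1 mm isotropic, discretize with the kind-specific
#' bin width (0.1 for TBR, 1 min for TTP), then extract 11 morphological,
#' 19 intensity and 75 texture features. For TTP maps the undefined
#' out-of-region voxels (NaN) are filled with the in-region median before
#' interpolation so the peak neighbourhoods are defined.
#'
#' @param map a [parametric_map()].
#' @param voi tumour [voi_mask()] on the same grid.
#' @param kind "tbr" or "ttp"; TTP feature names get a "_TTP" suffix.
#' @return named numeric vector of length 105 with attribute `kind`.
#' @export
extract_all <- function(map, voi, kind = c("tbr", "ttp")) {
  kind <- match.arg(kind)
  stopifnot(identical(dim(map$values), dim(voi$mask)))
  if (!any(voi$mask)) stop("empty VOI")
  vals <- map$values
  if (anyNA(vals)) {
    fill <- stats::median(vals[!is.na(vals)])
    vals[is.na(vals)] <- fill
  }
  # crop to bounding box plus margin for the 1-cm^3 sphere support
  d <- dim(vals)
  co <- arrayInd(which(voi$mask), d)
  marg <- ceiling(8 / map$spacing)
  lo <- pmax(apply(co, 2, min) - marg, 1L)
  hi <- pmin(apply(co, 2, max) + marg, d)
  sub_map <- parametric_map(map$kind,
                            vals[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]],
                            map$spacing)
  sub_voi <- voi_mask(voi$mask[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]],
                      map$spacing, voi$role)
  rs <- resample_isotropic(sub_map, sub_voi, target = 1)
  img <- rs$map$values; m <- rs$voi$mask
  if (!any(m)) stop("VOI vanished under resampling")
  w <- if (kind == "tbr") 0.1 else 1.0
  disc <- discretize_fbw(img[m], w)
  lev <- array(NA_integer_, dim(img))
  lev[m] <- disc$levels
  out <- c(extract_morphology(rs$voi),
           extract_intensity(img, m, disc, rs$map$spacing),
           extract_texture(lev, disc$n_levels, rs$map$spacing))
  if (kind == "ttp") names(out) <- paste0(names(out), "_TTP")
  if (any(!is.finite(out))) stop("non-finite feature value produced")
  attr(out, "kind") <- kind
  out
}

#' Canonical feature manifest
#'
#' @return data.frame with columns `name` and `family` listing the 105
#'   features in extraction order (11 morphological + 94 map features).
#' @export
feature_manifest <- function() {
  cube <- voi_mask(array(TRUE, c(3, 3, 3)), c(1, 1, 1))
  img <- array(seq_len(27) / 10, c(3, 3, 3))
  fv <- extract_all(parametric_map("TBR", img, c(1, 1, 1)), cube, "tbr")
  fam <- sub("_.*", "", names(fv))
  data.frame(name = names(fv), family = fam, stringsAsFactors = FALSE)
}
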