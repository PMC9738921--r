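# Morphological features from a binary VOI: voxel-count volume, a
# closed-surface mesh volume and area from marching tetrahedra at the 0.5
# iso-level, shape ratios, maximum 3-D diameter and principal axis lengths.

# 6-tetrahedra decomposition of a unit cell; corners numbered by bit
# pattern c = x + 2y + 4z. Each tet is a monotone path 0 -> 7.
tet_table <- rbind(c(0L, 1L, 3L, 7L), c(0L, 1L, 5L, 7L),
                   c(0L, 2L, 3L, 7L), c(0L, 2L, 6L, 7L),
                   c(0L, 4L, 5L, 7L), c(0L, 4L, 6L, 7L))
corner_offsets <- cbind(x = bitwAnd(0:7, 1L),
                        y = bitwAnd(bitwShiftR(0:7, 1L), 1L),
                        z = bitwAnd(bitwShiftR(0:7, 2L), 1L))

row_cross <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}
tri_area_rows <- function(p1, p2, p3) {
  cr <- row_cross(p2 - p1, p3 - p1)
  0.5 * sqrt(rowSums(cr^2))
}

# Mesh volume and surface area of {mask interpolated > 0.5}. The mask is
# zero-padded so the surface closes; binary node values put every surface
# vertex at an edge midpoint, which makes the clipped-tet volume fractions
# exact: 0, 1/8, 1/2, 7/8, 1 of a tet for 0..4 inside corners.
mesh_volume_area <- function(mask, spacing) {
  d <- dim(mask)
  P <- array(0, d + 2L)
  P[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- mask + 0
  nc <- dim(P) - 1L
  corner_val <- function(b) P[(1:nc[1]) + corner_offsets[b, 1],
                              (1:nc[2]) + corner_offsets[b, 2],
                              (1:nc[3]) + corner_offsets[b, 3]]
  S <- Reduce(`+`, lapply(1:8, corner_val))
  vcell <- prod(spacing)
  vol <- sum(S == 8) * vcell
  mixed <- which(S > 0 & S < 8)
  if (!length(mixed)) return(c(volume = vol, area = 0))
  org <- arrayInd(mixed, nc)                      # cell origin (padded grid)
  M <- length(mixed)
  fvals <- vapply(1:8, function(b) corner_val(b)[mixed] > 0.5, logical(M))
  fvals <- matrix(fvals, nrow = M)
  # coords (mm) of the 8 corners of every mixed cell: M x 3 x 8
  CC <- array(0, c(M, 3, 8))
  for (b in 1:8)
    CC[, , b] <- sweep(sweep(org - 1, 2, corner_offsets[b, ] + 0, "+"),
                       2, spacing, "*")
  pick <- function(rows, corners) {
    ix <- cbind(rep(rows, times = 3), rep(1:3, each = length(rows)),
                rep(corners, times = 3))
    matrix(CC[ix], ncol = 3)
  }
  area <- 0
  vtet <- vcell / 6
  for (tt in 1:6) {
    ti <- tet_table[tt, ] + 1L
    f <- fvals[, ti, drop = FALSE]
    nin <- rowSums(f)
    vol <- vol + vtet * sum(c(0, 1 / 8, 1 / 2, 7 / 8, 1)[nin + 1])
    # one corner isolated on its side -> triangle through 3 edge midpoints
    for (mode in c(1L, 3L)) {
      sel <- which(nin == mode)
      if (!length(sel)) next
      fs <- if (mode == 1L) f[sel, , drop = FALSE] else !f[sel, , drop = FALSE]
      solo <- max.col(fs, "first")
      oth <- t(vapply(seq_along(sel), function(r) setdiff(1:4, solo[r]),
                      integer(3)))
      A <- pick(sel, ti[solo])
      B1 <- pick(sel, ti[oth[, 1]]); B2 <- pick(sel, ti[oth[, 2]])
      B3 <- pick(sel, ti[oth[, 3]])
      area <- area + sum(tri_area_rows((A + B1) / 2, (A + B2) / 2,
                                       (A + B3) / 2))
    }
    # two in, two out -> quad between the four cut edges
    sel <- which(nin == 2L)
    if (length(sel)) {
      fin <- f[sel, , drop = FALSE]
      ia <- max.col(fin, "first")
      ib <- 5L - max.col(fin[, 4:1, drop = FALSE], "first")
      oc <- t(vapply(seq_along(sel), function(r) setdiff(1:4, c(ia[r], ib[r])),
                     integer(2)))
      A <- pick(sel, ti[ia]); B <- pick(sel, ti[ib])
      C <- pick(sel, ti[oc[, 1]]); D <- pick(sel, ti[oc[, 2]])
      m_ac <- (A + C) / 2; m_ad <- (A + D) / 2
      m_bc <- (B + C) / 2; m_bd <- (B + D) / 2
      area <- area + sum(tri_area_rows(m_ac, m_ad, m_bd)) +
                     sum(tri_area_rows(m_ac, m_bd, m_bc))
    }
  }
  c(volume = vol, area = area)
}

#' Morphological VOI features
#'
#' The canonical 11: mesh volume, voxel-count volume, surface area,
#' surface-to-volume ratio, sphericity, compactness, spherical
#' disproportion, maximum 3-D diameter (between voxel centres of the VOI
#' boundary), and major/minor/least principal axis lengths (4 sqrt of the
#' coordinate-covariance eigenvalues).
#'
#' @param voi a [voi_mask()].
#' @param spacing voxel spacing mm (defaults to the VOI's own).
#' @return named numeric vector of length 11.
#' @export
extract_morphology <- function(voi, spacing = voi$spacing) {
  m <- voi$mask
  if (!any(m)) stop("empty VOI")
  d <- dim(m)
  n <- sum(m)
  va <- mesh_volume_area(m, spacing)
  V <- unname(va["volume"]); A <- unname(va["area"])
  co <- arrayInd(which(m), d)
  mm <- sweep(co - 1, 2, spacing, "*")
  # boundary voxels: at least one missing 6-neighbour (includes grid edge)
  bmask <- rep(FALSE, n)
  for (ax in 1:3) for (s in c(-1L, 1L)) {
    nb <- co; nb[, ax] <- nb[, ax] + s
    out <- nb[, ax] < 1L | nb[, ax] > d[ax]
    lin <- pmin(pmax(nb[, 1], 1L), d[1]) +
      (pmin(pmax(nb[, 2], 1L), d[2]) - 1L) * d[1] +
      (pmin(pmax(nb[, 3], 1L), d[3]) - 1L) * d[1] * d[2]
    bmask <- bmask | out | !m[lin]
  }
  bd <- mm[bmask, , drop = FALSE]
  dmax <- 0
  if (nrow(bd) > 1) {
    for (i in seq_len(nrow(bd) - 1)) {
      dd <- sweep(bd[(i + 1):nrow(bd), , drop = FALSE], 2, bd[i, ], "-")
      dmax <- max(dmax, sqrt(max(rowSums(dd^2))))
    }
  }
  if (n > 1) {
    cv <- stats::cov(mm) * (n - 1) / n
    ev <- sort(eigen(cv, symmetric = TRUE, only.values = TRUE)$values,
               decreasing = TRUE)
    ev <- pmax(ev, 0)
  } else ev <- c(0, 0, 0)
  sph <- if (A > 0) (36 * pi * V^2)^(1 / 3) / A else 0
  c(morph_mesh_volume = V,
    morph_voxel_volume = n * prod(spacing),
    morph_surface_area = A,
    morph_surface_to_volume = if (V > 0) A / V else 0,
    morph_sphericity = sph,
    morph_compactness = if (A > 0) 36 * pi * V^2 / A^3 else 0,
    morph_spherical_disproportion = if (sph > 0) 1 / sph else 0,
    morph_max_diameter = dmax,
    morph_major_axis = 4 * sqrt(ev[1]),
    morph_minor_axis = 4 * sqrt(ev[2]),
    morph_least_axis = 4 * sqrt(ev[3]))
}
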