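# Synthetic dynamic FDOPA-like brain phantoms.
#
# A subject is an ellipsoidal "head" holding a brain compartment at
# SUV-equivalent 1.0, a striatum with an early-peaking time-activity curve
# (TAC), and one tumour lesion whose kinetic class (early peak + washout
# versus late peak + increasing uptake) and contrast encode a binary
# molecular label. The noiseless scene is degraded by a known Gaussian
# point-spread function and post-reconstruction noise, which is what the
# enhancement and parametric stages then have to undo or tolerate.

#' Frame schedule of a dynamic acquisition
#'
#' Contiguous frames given by start and end times in minutes. The default is
#' 30 frames of 1 minute, i.e. a 30-min dynamic acquisition.
#'
#' @param start_times,end_times numeric vectors, minutes.
#' @return object of class `frame_schedule`.
#' @export
frame_schedule <- function(start_times = 0:29, end_times = 1:30) {
  stopifnot(length(start_times) == length(end_times),
            all(end_times > start_times))
  if (length(start_times) > 1) {
    if (any(abs(end_times[-length(end_times)] - start_times[-1]) > 1e-9))
      stop("frames must be contiguous")
    if (any(diff(start_times) <= 0)) stop("frames must be increasing")
  }
  structure(list(start = as.numeric(start_times),
                 end = as.numeric(end_times)),
            class = "frame_schedule")
}

#' Frame midpoints in minutes
#' @param schedule a `frame_schedule`.
#' @export
frame_midpoints <- function(schedule) (schedule$start + schedule$end) / 2

#' Lesion specification
#'
#' Ground-truth description of one ellipsoidal lesion: geometric placement
#' plus the kinetic parameters of its TAC expressed as a ratio to brain.
#'
#' @param center voxel coordinates (length 3).
#' @param semi_axes ellipsoid semi-axes in mm (length 3).
#' @param class_label 0 or 1 (molecular class).
#' @param amplitude_ratio true peak tumour-to-brain contrast, > 1.
#' @param ttp_true true time-to-peak, minutes.
#' @param washout_slope_true post-peak decline, ratio units per hour, >= 0.
#' @export
lesion_spec <- function(center, semi_axes, class_label, amplitude_ratio,
                        ttp_true, washout_slope_true) {
  stopifnot(length(center) == 3, length(semi_axes) == 3, all(semi_axes > 0),
            class_label %in% 0:1, amplitude_ratio > 1, ttp_true > 0,
            washout_slope_true >= 0)
  structure(list(center = center, semi_axes = semi_axes,
                 class_label = as.integer(class_label),
                 amplitude_ratio = amplitude_ratio, ttp_true = ttp_true,
                 washout_slope_true = washout_slope_true),
            class = "lesion_spec")
}

#' Phantom specification
#'
#' @param grid_dim integer length-3 voxel grid.
#' @param spacing voxel spacing mm.
#' @param lesions list of [lesion_spec()].
#' @param psf_fwhm_mm Gaussian blur FWHM applied frame-wise, >= 0.
#' @param noise_model list(type = "none" | "gaussian" | "poisson",
#'   sigma/scale). "poisson" is Poisson-like Gaussian noise with
#'   sd = scale * sqrt(intensity), the character of post-reconstruction PET
#'   noise.
#' @param schedule a [frame_schedule()].
#' @param seed integer RNG seed for the noise realisation.
#' @export
phantom_spec <- function(grid_dim = c(48L, 48L, 24L), spacing = c(2, 2, 2),
                         lesions = list(), psf_fwhm_mm = 4.5,
                         noise_model = list(type = "poisson", scale = 0.05),
                         schedule = frame_schedule(), seed = 1L) {
  stopifnot(psf_fwhm_mm >= 0, length(grid_dim) == 3, length(spacing) == 3)
  margin_mm <- 2 * psf_fwhm_mm
  for (les in lesions) {
    lo_mm <- (les$center - 1) * spacing - les$semi_axes
    hi_mm <- (les$center - 1) * spacing + les$semi_axes
    if (any(lo_mm < margin_mm) || any(hi_mm > (grid_dim - 1) * spacing - margin_mm))
      stop("grid too small: lesion needs a margin of 2*FWHM from the edge")
  }
  structure(list(grid_dim = as.integer(grid_dim), spacing = spacing,
                 lesions = lesions, psf_fwhm_mm = psf_fwhm_mm,
                 noise_model = noise_model, schedule = schedule,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Piecewise-linear lesion time-activity curve
#'
#' Linear rise from 0 at t = 0 to `amplitude_ratio` at `ttp_true`, then
#' linear decline at `washout_slope_true` (per hour), clipped below at half
#' the amplitude. A piecewise-linear model keeps the time-to-peak and slope
#' ground truth exact. Evaluated at frame midpoints.
#'
#' @param lesion a [lesion_spec()].
#' @param schedule a [frame_schedule()].
#' @return numeric vector of ratio-to-brain values, one per frame.
#' @export
tac_model <- function(lesion, schedule) {
  t <- frame_midpoints(schedule)
  ttp <- lesion$ttp_true
  if (ttp < min(t) - 0.5 || ttp > max(schedule$end))
    stop("ttp_true outside the acquisition window")
  amp <- lesion$amplitude_ratio
  v <- ifelse(t <= ttp, amp * t / ttp,
              pmax(amp - lesion$washout_slope_true * (t - ttp) / 60,
                   0.5 * amp))
  v
}

ellipsoid_mask <- function(grid_dim, spacing, center_vox, semi_axes_mm) {
  i <- (seq_len(grid_dim[1]) - center_vox[1]) * spacing[1] / semi_axes_mm[1]
  j <- (seq_len(grid_dim[2]) - center_vox[2]) * spacing[2] / semi_axes_mm[2]
  k <- (seq_len(grid_dim[3]) - center_vox[3]) * spacing[3] / semi_axes_mm[3]
  outer(outer(i^2, j^2, `+`), k^2, `+`) <= 1
}

# Geometry of the default head model, in voxel units of the given grid.
phantom_geometry <- function(grid_dim, spacing) {
  ctr <- (grid_dim + 1) / 2
  brain_ax <- (grid_dim - 1) * spacing * 0.38
  striatum_ctr <- ctr + c(round(0.12 * grid_dim[1]), 0, 0)
  list(center = ctr, brain_semi_axes = brain_ax,
       striatum_center = striatum_ctr,
       striatum_semi_axes = c(8, 10, 6))
}

#' Render one phantom subject
#'
#' Builds the noiseless dynamic truth (background 0.2 outside the head,
#' brain 1.0, striatum contrast 2.5 with an early peak, lesion TACs),
#' applies the Gaussian PSF frame-wise, adds noise, and recomputes the
#' static image as the time-average of the degraded frames whose midpoints
#' fall at or after 10 min (the "last 20 min" of a 30-min study).
#'
#' @param spec a [phantom_spec()].
#' @return list with `study` (class `dynamic_study`: 4-D SUV array, spacing,
#'   schedule), `static` (3-D array with spacing attribute), `masks`
#'   (crescent-shaped brain reference mask on three consecutive slices,
#'   striatum seed mask, tumour search region), and `truth` (lesion specs,
#'   noiseless unblurred 4-D array, label).
#' @export
render_subject <- function(spec) {
  d <- spec$grid_dim; sp <- spec$spacing
  geo <- phantom_geometry(d, sp)
  brain <- ellipsoid_mask(d, sp, geo$center, geo$brain_semi_axes)
  striatum <- ellipsoid_mask(d, sp, geo$striatum_center, geo$striatum_semi_axes)
  striatum <- striatum & brain
  nt <- length(spec$schedule$start)

  striatum_tac <- tac_model(
    lesion_spec(geo$striatum_center, geo$striatum_semi_axes, 0L,
                amplitude_ratio = 2.5, ttp_true = 5.5,
                washout_slope_true = 0.6),
    spec$schedule)

  truth <- array(0.2, c(d, nt))
  lesion_masks <- vector("list", length(spec$lesions))
  frame_ix <- function(t) (t - 1L) * prod(d)
  brain_idx <- which(brain); stri_idx <- which(striatum)
  for (t in seq_len(nt)) {
    fr <- array(0.2, d)
    fr[brain_idx] <- 1.0
    fr[stri_idx] <- striatum_tac[t]
    truth[frame_ix(t) + seq_len(prod(d))] <- fr
  }
  for (li in seq_along(spec$lesions)) {
    les <- spec$lesions[[li]]
    m <- ellipsoid_mask(d, sp, les$center, les$semi_axes)
    if (any(m & striatum)) stop("lesion overlaps the striatum")
    lesion_masks[[li]] <- m
    tac <- tac_model(les, spec$schedule)
    mi <- which(m)
    for (t in seq_len(nt)) truth[frame_ix(t) + mi] <- tac[t]
  }

  degraded <- if (spec$psf_fwhm_mm > 0)
    gaussian_blur3d(truth, spec$psf_fwhm_mm, sp) else truth
  nm <- spec$noise_model
  if (!identical(nm$type, "none")) {
    degraded <- with_seed(spec$seed, {
      eps <- switch(nm$type,
        gaussian = rnorm(length(degraded), 0, nm$sigma),
        poisson = rnorm(length(degraded), 0, nm$scale) * sqrt(pmax(degraded, 0)),
        stop("unknown noise model"))
      pmax(degraded + eps, 0)
    })
  }

  mids <- frame_midpoints(spec$schedule)
  late <- mids >= 10
  static <- array(0, d)
  for (t in which(late)) static <- static + array(degraded[frame_ix(t) + seq_len(prod(d))], d)
  static <- static / sum(late)
  attr(static, "spacing") <- sp

  # crescent reference VOI: an in-slice annular band of healthy brain in the
  # hemisphere opposite the lesions, on three consecutive slices; a 12-mm
  # exclusion margin around striatum and lesions keeps PSF/low-pass leakage
  # of non-brain kinetics out of the reference TAC
  k0 <- round(d[3] / 2) + c(-1L, 0L, 1L)
  inner <- ellipsoid_mask(d, sp, geo$center, geo$brain_semi_axes * 0.45)
  outer_b <- ellipsoid_mask(d, sp, geo$center, geo$brain_semi_axes * 0.8)
  stri_dil <- ellipsoid_mask(d, sp, geo$striatum_center,
                             geo$striatum_semi_axes + 12)
  crescent <- outer_b & !inner & !stri_dil
  ii <- slice.index(crescent, 1); kk <- slice.index(crescent, 3)
  crescent <- crescent & (ii > geo$center[1] + 2) & (kk %in% k0)
  for (li in seq_along(spec$lesions)) {
    les <- spec$lesions[[li]]
    crescent <- crescent & !ellipsoid_mask(d, sp, les$center,
                                           les$semi_axes + 12)
  }

  # striatum seed region: striatum dilated by one voxel-box margin
  seed_reg <- ellipsoid_mask(d, sp, geo$striatum_center,
                             geo$striatum_semi_axes + 2 * sp)
  # tumour search region: union of lesion bounding boxes padded 4 voxels
  tumor_reg <- array(FALSE, d)
  for (m in lesion_masks) {
    co <- arrayInd(which(m), d)
    lo <- pmax(apply(co, 2, min) - 4L, 1L)
    hi <- pmin(apply(co, 2, max) + 4L, d)
    tumor_reg[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- TRUE
  }
  tumor_reg <- tumor_reg & !seed_reg

  study <- structure(list(data = degraded, spacing = sp,
                          schedule = spec$schedule),
                     class = "dynamic_study")
  label <- if (length(spec$lesions)) spec$lesions[[1]]$class_label else NA_integer_
  list(study = study, static = static,
       masks = list(brain = voi_mask(crescent, sp, "brain"),
                    striatum_seed = voi_mask(seed_reg & brain, sp, "striatum"),
                    tumor_region = voi_mask(tumor_reg, sp, "tumor"),
                    lesion_truth = voi_mask(Reduce(`|`, lesion_masks,
                                                   array(FALSE, d)), sp, "tumor")),
       truth = list(lesions = spec$lesions, noiseless = truth, label = label))
}

#' VOI mask constructor
#' @param mask logical 3-D array.
#' @param spacing voxel spacing mm.
#' @param role one of "brain", "striatum", "tumor".
#' @export
voi_mask <- function(mask, spacing, role = c("tumor", "brain", "striatum")) {
  role <- match.arg(role)
  structure(list(mask = mask, spacing = spacing, role = role),
            class = "voi_mask")
}

#' Generate a labelled synthetic cohort
#'
#' Per subject one supra-centimetric lesion (semi-axes 5-10 mm) is drawn
#' with randomized position, size and contrast. Class-1 subjects (emulating
#' IDH-mutant-like kinetics) receive a late time-to-peak (12-25 min,
#' snapped to the nearest frame midpoint), lower contrast (2.2-2.8) and
#' little washout (0-0.3 h^-1); class-0 subjects an early peak (2-8 min),
#' higher contrast (2.8-3.6) and clear washout (0.5-1.5 h^-1). Label
#' counts are exact: `round(n * class_balance)` subjects of class 1.
#'
#' @param n_subjects number of subjects, >= 4.
#' @param class_balance fraction of class-1 subjects, in (0, 1).
#' @param spec_template a [phantom_spec()] supplying grid, blur, noise and
#'   schedule; its `lesions` field is ignored.
#' @param seed integer; all cohort randomness derives from it.
#' @return list with `subjects` (list of [render_subject()] outputs),
#'   `labels` (integer vector) and `specs`.
#' @export
generate_cohort <- function(n_subjects, class_balance,
                            spec_template = phantom_spec(), seed = 1L) {
  stopifnot(n_subjects >= 4, class_balance > 0, class_balance < 1)
  n1 <- round(n_subjects * class_balance)
  if (n1 < 1 || n1 > n_subjects - 1) stop("degenerate class balance")
  d <- spec_template$grid_dim; sp <- spec_template$spacing
  geo <- phantom_geometry(d, sp)
  mids <- frame_midpoints(spec_template$schedule)
  snap <- function(t) mids[which.min(abs(mids - t))]
  with_seed(seed, {
    labels <- sample(c(rep(1L, n1), rep(0L, n_subjects - n1)))
    specs <- vector("list", n_subjects)
    subjects <- vector("list", n_subjects)
    for (s in seq_len(n_subjects)) {
      lab <- labels[s]
      semi <- runif(3, 5, 10)  # supra-centimetric lesions (10-20 mm)
      # place in the hemisphere away from the striatum, inside the brain
      ctr <- c(geo$center[1] - round(runif(1, 0.10, 0.20) * d[1]),
               geo$center[2] + round(runif(1, -0.10, 0.10) * d[2]),
               geo$center[3] + round(runif(1, -0.05, 0.05) * d[3]))
      amp <- if (lab == 1L) runif(1, 2.2, 2.8) else runif(1, 2.8, 3.6)
      ttp <- snap(if (lab == 1L) runif(1, 12, 25) else runif(1, 2, 8))
      slope <- if (lab == 1L) runif(1, 0, 0.3) else runif(1, 0.5, 1.5)
      les <- lesion_spec(ctr, semi, lab, amp, ttp, slope)
      specs[[s]] <- phantom_spec(d, sp, list(les), spec_template$psf_fwhm_mm,
                                 spec_template$noise_model,
                                 spec_template$schedule,
                                 seed = sample.int(2^30, 1))
      subjects[[s]] <- render_subject(specs[[s]])
    }
    list(subjects = subjects, labels = labels, specs = specs)
  })
}

#' @export
print.dynamic_study <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<dynamic_study> %d x %d x %d voxels, %d frames, spacing %s mm\n",
              d[1], d[2], d[3], d[4],
              paste(x$spacing, collapse = "x")))
  invisible(x)
}

#' Write a rendered subject to disk (NIfTI + sidecars)
#'
#' Writes the 4-D dynamic study, 3-D static image and mask volumes as
#' compressed NIfTI, the frame schedule as a CSV (start_min, end_min), and
#' the ground truth as a JSON sidecar.
#'
#' @param subject output of [render_subject()].
#' @param dir output directory, created if needed.
#' @export
write_subject <- function(subject, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sp <- subject$study$spacing
  wr <- function(arr, name) {
    img <- RNifti::asNifti(arr, internal = FALSE)
    RNifti::pixdim(img) <- c(sp, rep(1, length(dim(arr)) - 3))
    RNifti::writeNifti(img, file.path(dir, name))
  }
  wr(subject$study$data, "dynamic.nii.gz")
  wr(subject$static, "static.nii.gz")
  for (nm in names(subject$masks))
    wr(subject$masks[[nm]]$mask + 0, paste0("mask_", nm, ".nii.gz"))
  utils::write.csv(data.frame(start_min = subject$study$schedule$start,
                              end_min = subject$study$schedule$end),
                   file.path(dir, "frames.csv"), row.names = FALSE)
  gt <- list(label = subject$truth$label,
             lesions = lapply(subject$truth$lesions, unclass))
  jsonlite::write_json(gt, file.path(dir, "truth.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}
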