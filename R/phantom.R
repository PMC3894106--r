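#' Phantom specification
#'
#' Geometry and simulation settings for the synthetic cylindrical dosimeter.
#' Defaults reproduce the measurement setup the package targets: a 9.5 cm
#' diameter x 9.2 cm height cylinder with a 0.35 cm diameter channel drilled
#' along the axis from one flat face to mid-height, voxelized at (0.5 mm)^3,
#' and a prescription of 5.3 Gy at the TG-43 reference point
#' (r = 1 cm, theta = 90 degrees).
#'
#' @param cylinder_diameter_cm,cylinder_height_cm Dosimeter dimensions, cm.
#' @param channel_diameter_cm Drilled channel diameter, cm.
#' @param channel_depth_frac Channel depth as a fraction of the height
#'   (0.5 = "to midline").
#' @param voxel_mm Isotropic voxel size, mm.
#' @param prescription_gy Dose delivered at (r0, theta0), Gy.
#' @param noise `list(model, sigma)` with model one of `"none"`,
#'   `"gaussian_constant"` (sigma in Gy; default 1% of the prescription) or
#'   `"gaussian_proportional"` (sigma as a fraction of local dose).
#' @param pose_perturbation `list(translation_cm, tilt_deg, tilt_azimuth_deg)`
#'   applied to the source pose relative to its nominal channel-tip seating
#'   (models imperfect source placement; the drilled channel itself stays put).
#' @param imperfections List of `list(center_cm, radius_cm, value)` spherical
#'   blobs whose intensity is overwritten with `value` (<= 0, e.g. an
#'   occlusion or void reading).
#' @param source_orientation `"normal"` (tip pointing into the material) or
#'   `"reversed"` (axis sign flipped, as when re-irradiating a flipped
#'   dosimeter to fill the angular region shadowed by the channel).
#' @param seed Integer seed for the noise stream (NULL = leave RNG alone).
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(cylinder_diameter_cm = 9.5,
                         cylinder_height_cm = 9.2,
                         channel_diameter_cm = 0.35,
                         channel_depth_frac = 0.5,
                         voxel_mm = 0.5,
                         prescription_gy = 5.3,
                         noise = list(model = "gaussian_constant", sigma = NULL),
                         pose_perturbation = NULL,
                         imperfections = list(),
                         source_orientation = c("normal", "reversed"),
                         seed = NULL) {
  if (is.character(noise)) noise <- list(model = noise)
  noise$model <- match.arg(noise$model %||% "none",
                           c("none", "gaussian_constant", "gaussian_proportional"))
  if (noise$model == "gaussian_constant" && is.null(noise$sigma)) {
    noise$sigma <- 0.01 * prescription_gy
  }
  if (noise$model == "gaussian_proportional" && is.null(noise$sigma)) {
    noise$sigma <- 0.01
  }
  source_orientation <- match.arg(source_orientation)
  if (channel_diameter_cm >= cylinder_diameter_cm) {
    stopf("channel must be narrower than the cylinder")
  }
  if (voxel_mm <= 0) stopf("voxel size must be positive")
  if (prescription_gy <= 0) stopf("prescription dose must be positive")
  if (channel_depth_frac <= 0 || channel_depth_frac >= 1) {
    stopf("channel_depth_frac must lie in (0, 1)")
  }
  structure(list(cylinder_diameter_cm = cylinder_diameter_cm,
                 cylinder_height_cm = cylinder_height_cm,
                 channel_diameter_cm = channel_diameter_cm,
                 channel_depth_frac = channel_depth_frac,
                 voxel_mm = voxel_mm,
                 prescription_gy = prescription_gy,
                 noise = noise,
                 pose_perturbation = pose_perturbation,
                 imperfections = imperfections,
                 source_orientation = source_orientation,
                 seed = seed),
            class = "phantom_spec")
}

## distance (cm) from points P (n x 3) to the active segment of a pose
dist_to_segment <- function(P, pose, L) {
  d <- sweep(P, 2L, pose$center_cm)
  t <- d %*% pose$axis
  t <- pmin(pmax(t, -L / 2), L / 2)
  sqrt(rowSums((d - t %*% t(pose$axis))^2))
}

#' Build a synthetic dosimeter phantom
#'
#' Voxelizes the cylinder on a grid whose physical origin is the cylinder's
#' geometric center (a voxel center sits exactly there), carves out the
#' channel and the source line, evaluates the TG-43 dose of `model` at every
#' material voxel center, then applies noise and imperfections.  The true
#' source pose is returned alongside the volume for recovery experiments.
#'
#' A voxel belongs to the cylinder iff its center is inside the analytic
#' cylinder; channel voxels (centers within the channel bore, from the
#' drilled face down to the channel tip at mid-height) and voxels whose
#' centers fall within half a voxel of the active line segment are excluded
#' from `inside_mask`.
#'
#' @param spec A [phantom_spec()].
#' @param model A [source_model()].
#' @param seed Overrides `spec$seed` when given.
#' @return A list of class `tg43_phantom` with elements `volume`
#'   ([dose_volume()]), `pose` ([source_pose()], the true perturbed pose),
#'   and `spec`.
#' @export
build_phantom <- function(spec, model, seed = spec$seed) {
  if (model$physical_diameter_cm > spec$channel_diameter_cm + 1e-9) {
    stopf("source capsule (%.3g cm) does not fit the %.3g cm channel",
          model$physical_diameter_cm, spec$channel_diameter_cm)
  }
  vox <- spec$voxel_mm / 10                       # cm
  R <- spec$cylinder_diameter_cm / 2
  H <- spec$cylinder_height_cm
  chR <- spec$channel_diameter_cm / 2
  ## grid symmetric about the cylinder center with voxel centers at
  ## +/- (k - 1/2) * vox: no voxel center (or center column) coincides with
  ## the cylinder axis, so the voxel lattice samples radii about the source
  ## the way an arbitrarily seated physical dosimeter does, instead of the
  ## degenerate axis-on-voxel-center alignment whose coherent radius
  ## quantization biases thin annular bins
  nh_xy <- ceiling(R / vox - 0.5)
  nh_z <- ceiling(H / 2 / vox - 0.5)
  x <- (seq_len(2 * nh_xy) - nh_xy - 0.5) * vox
  z <- (seq_len(2 * nh_z) - nh_z - 0.5) * vox
  nx <- length(x); nz <- length(z)

  rho2 <- outer(x^2, x^2, `+`)                    # nx x nx, xy plane
  eps <- 1e-9
  cyl_xy <- rho2 <= R^2 + eps
  chan_xy <- rho2 <= chR^2 + eps
  zin <- abs(z) <= H / 2 + eps
  z_tip <- H / 2 - spec$channel_depth_frac * H    # channel tip height (cm)

  inside <- array(FALSE, c(nx, nx, nz))
  for (k in seq_len(nz)) {
    if (!zin[k]) next
    sl <- cyl_xy
    if (z[k] >= z_tip - eps) sl <- sl & !chan_xy  # channel bore above the tip
    inside[, , k] <- sl
  }

  ## true pose: active-length midpoint at the channel tip, axis along the
  ## channel pointing from the drilled opening (top face) toward the tip
  axis0 <- if (spec$source_orientation == "reversed") c(0, 0, 1) else c(0, 0, -1)
  center <- c(0, 0, z_tip)
  if (!is.null(spec$pose_perturbation)) {
    pp <- spec$pose_perturbation
    center <- center + (pp$translation_cm %||% c(0, 0, 0))
    tilt <- pp$tilt_deg %||% 0
    if (tilt != 0) {
      azim <- (pp$tilt_azimuth_deg %||% 0) * DEG2RAD
      fr <- frame3(axis0)
      tdir <- cos(azim) * fr$u + sin(azim) * fr$v
      axis0 <- cos(tilt * DEG2RAD) * fr$w + sin(tilt * DEG2RAD) * tdir
    }
    if (sqrt(sum(center[1:2]^2)) > chR + 1e-9) {
      stopf("perturbed source center lies outside the channel bore")
    }
    if (abs(center[3] - z_tip) > H / 4) {
      stopf("perturbed source center is far from the channel tip")
    }
  }
  pose <- source_pose(center, axis0)

  idx <- which(inside)
  P <- voxel_coords_cm_grid(idx, x, x, z)
  dseg <- dist_to_segment(P, pose, model$active_length_cm)
  on_line <- dseg < vox / 2 * (1 + 1e-9)
  if (any(on_line)) {
    inside[idx[on_line]] <- FALSE
    idx <- idx[!on_line]
    P <- P[!on_line, , drop = FALSE]
  }
  if (!length(idx)) stopf("phantom grid contains no material voxels")

  d <- sweep(P, 2L, pose$center_cm)
  r <- sqrt(rowSums(d^2))
  ct <- pmin(pmax((d %*% pose$axis) / r, -1), 1)
  theta <- acos(ct) / DEG2RAD

  dose <- tg43_dose(model, spec$prescription_gy, r, theta)

  if (spec$noise$model != "none") {
    if (!is.null(seed)) set.seed(as.integer(seed))
    sd_vec <- if (spec$noise$model == "gaussian_constant") spec$noise$sigma
              else spec$noise$sigma * abs(dose)
    dose <- dose + stats::rnorm(length(dose), 0, sd_vec)
  }

  intensity <- array(0, dim(inside))
  intensity[idx] <- dose

  for (imp in spec$imperfections) {
    if ((imp$value %||% 0) > 0) stopf("imperfection fill values must be <= 0")
    hit <- idx[rowSums(sweep(P, 2L, imp$center_cm)^2) <= imp$radius_cm^2]
    intensity[hit] <- imp$value
  }

  vol <- dose_volume(intensity,
                     spacing_mm = rep(spec$voxel_mm, 3),
                     origin_mm = c(x[1], x[1], z[1]) * 10,
                     inside_mask = inside)
  structure(list(volume = vol, pose = pose, spec = spec),
            class = "tg43_phantom")
}

## coordinates (cm) for linear indices on an axis-aligned grid given center
## vectors (cm) -- faster than voxel_coords_cm during phantom construction
voxel_coords_cm_grid <- function(idx, x, y, z) {
  nx <- length(x); ny <- length(y)
  i <- (idx - 1L) %% nx
  j <- ((idx - 1L) %/% nx) %% ny
  k <- (idx - 1L) %/% (nx * ny)
  cbind(x[i + 1L], y[j + 1L], z[k + 1L])
}

#' Write a phantom (volume, mask and ground-truth pose sidecar)
#'
#' @param phantom A `tg43_phantom` from [build_phantom()].
#' @param path Volume output path (`.nii`, `.nii.gz` or `.mhd`); the mask goes
#'   to `<stem>_mask.<ext>` and the true pose to `<stem>_pose.json`.
#' @return `path`, invisibly.
#' @export
write_phantom <- function(phantom, path) {
  write_volume(phantom$volume, path, write_mask = TRUE)
  pose_path <- sub("(\\.nii\\.gz|\\.nii|\\.mhd)$", "_pose.json", path,
                   ignore.case = TRUE)
  write_pose(phantom$pose, pose_path)
  invisible(path)
}
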