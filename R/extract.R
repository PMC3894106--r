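#' Per-voxel polar coordinates about a source pose
#'
#' Computes, for every ROI voxel, the radius r (cm) from the source center,
#' the polar angle theta (degrees) from the source long axis, and the signed
#' axial coordinate (cm, positive toward the tip) whose absolute value is
#' the distance to the transverse plane.  Voxels exactly at the source
#' center (r = 0, theta undefined) are dropped and counted in the
#' `n_flagged` attribute.
#'
#' @param volume A [dose_volume()].
#' @param mask A [build_roi()] result, a logical array, or NULL to use the
#'   volume's `inside_mask`.
#' @param pose A [source_pose()].
#' @return An object of class `polar_field`: list with `idx` (linear voxel
#'   indices), `intensity`, `r_cm`, `theta_deg`, `axial_cm`.
#' @export
polar_field <- function(volume, mask, pose) {
  m <- roi_as_logical(mask, volume)
  idx <- which(m)
  if (!length(idx)) stopf("mask selects no voxels")
  P <- voxel_coords_cm(volume, idx)
  d <- sweep(P, 2L, pose$center_cm)
  r <- sqrt(rowSums(d^2))
  ax <- as.numeric(d %*% pose$axis)
  keep <- r > 0
  n_flagged <- sum(!keep)
  idx <- idx[keep]; r <- r[keep]; ax <- ax[keep]
  theta <- acos(pmin(pmax(ax / r, -1), 1)) / DEG2RAD
  structure(list(idx = idx,
                 intensity = volume$intensity[idx],
                 r_cm = r,
                 theta_deg = theta,
                 axial_cm = ax),
            class = "polar_field", n_flagged = n_flagged)
}

roi_as_logical <- function(mask, volume) {
  if (is.null(mask)) {
    if (is.null(volume$inside_mask)) stopf("no mask given and volume has no inside_mask")
    return(volume$inside_mask)
  }
  if (inherits(mask, "roi_mask")) return(mask$mask)
  if (is.logical(mask)) return(mask)
  stopf("mask must be a roi_mask, a logical array, or NULL")
}

#' Mean intensity in the TG-43 reference bin
#'
#' Averages the intensity of ROI voxels within `tol_r_mm` of r0 that lie on
#' the transverse plane, where plane membership means the polar angle is
#' within `tol_theta_deg` of theta0 *or* the perpendicular distance to the
#' plane is within `slab_mm` (the angular criterion alone selects no voxel
#' centers when the source axis is not aligned with the grid).
#'
#' @param field A [polar_field()].
#' @param r0_cm,theta0_deg Reference point (defaults 1 cm, 90 degrees).
#' @param tol_r_mm Radial half-width of the bin, mm (default 0.5).
#' @param tol_theta_deg Angular half-width, degrees (default 0.1).
#' @param slab_mm Transverse-plane slab half-thickness, mm (default 0.5).
#' @return List with `mean` (Gy), `n`, and `idx` (member voxel indices).
#' @export
reference_intensity <- function(field, r0_cm = 1.0, theta0_deg = 90.0,
                                tol_r_mm = 0.5, tol_theta_deg = 0.1,
                                slab_mm = 0.5) {
  sel <- abs(field$r_cm - r0_cm) <= tol_r_mm / 10 &
    (abs(field$theta_deg - theta0_deg) <= tol_theta_deg |
       abs(field$axial_cm) <= slab_mm / 10)
  if (!any(sel)) {
    stopf(paste("empty reference bin at r0 = %g cm: no ROI voxel within",
                "%.3g mm / %.3g deg; check the registration or coarsen the",
                "tolerances"), r0_cm, tol_r_mm, tol_theta_deg)
  }
  list(mean = mean(field$intensity[sel]), n = sum(sel), idx = field$idx[sel])
}

#' Transverse-plane samples for the radial dose fit
#'
#' Selects ROI voxels on the transverse plane (polar angle within
#' `tol_theta_deg` of 90 degrees *or* perpendicular distance to the plane
#' within `slab_mm`) and forms the geometry-corrected, reference-normalized
#' sample for each voxel i:
#' y_i = I(r_i, theta_i) / Ibar(r0, theta0) * G_L(r0, theta0) / G_L(r_i, theta0),
#' with the geometry function evaluated at the voxel's radius but the
#' reference angle.  Noise-free, y_i tracks g_L(r_i).
#'
#' @param field A [polar_field()].
#' @param model A [source_model()].
#' @param ref Output of [reference_intensity()] (computed here when NULL).
#' @param tol_theta_deg,slab_mm Transverse-plane tolerances (defaults
#'   0.1 degrees, 0.5 mm).
#' @return A data.frame with columns `r_cm` and `y`; attributes `ref`
#'   (the reference-bin summary) and `n`.
#' @export
radial_samples <- function(field, model, ref = NULL,
                           tol_theta_deg = 0.1, slab_mm = 0.5) {
  if (is.null(ref)) {
    ref <- reference_intensity(field, model$r0_cm, model$theta0_deg,
                               tol_theta_deg = tol_theta_deg, slab_mm = slab_mm)
  }
  sel <- abs(field$theta_deg - model$theta0_deg) <= tol_theta_deg |
    abs(field$axial_cm) <= slab_mm / 10
  if (!any(sel)) stopf("no voxels on the transverse plane")
  r <- field$r_cm[sel]
  G0 <- geometry_function_line(model$r0_cm, model$theta0_deg,
                               model$active_length_cm)
  G <- geometry_function_line(r, model$theta0_deg, model$active_length_cm)
  y <- field$intensity[sel] / ref$mean * (G0 / G)
  out <- data.frame(r_cm = r, y = y)
  attr(out, "ref") <- ref
  attr(out, "n") <- nrow(out)
  out
}

#' Fit the radial dose function
#'
#' Ordinary (unweighted) least-squares degree-5 polynomial through the
#' per-voxel transverse samples, then renormalized so that the fitted curve
#' equals 1 at r0.  The per-voxel samples are used directly; 1-mm binning
#' (see [bin_radial()]) is for reporting only.
#'
#' @param samples Data frame from [radial_samples()] (columns `r_cm`, `y`).
#' @param degree Polynomial degree (default 5).
#' @param r0_cm Normalization radius (default 1 cm).
#' @return An object of class `radial_fit`: normalized `coefficients`
#'   (ascending powers of r), `r_range`, `rms_residual` (dimensionless, on
#'   the normalized scale), `n_voxels`, `ref_intensity` (Gy, when the
#'   samples carry one).
#' @export
fit_radial <- function(samples, degree = 5L, r0_cm = 1.0) {
  r <- samples$r_cm; y <- samples$y
  if (length(r) < degree + 2L) {
    stopf("need at least %d samples for a degree-%d fit", degree + 2L, degree)
  }
  if (length(unique(round(r, 1L))) < 3L) {
    stopf("samples span fewer than 3 distinct 1-mm radius bins")
  }
  X <- outer(r, 0:degree, `^`)
  qr_X <- qr(X)
  if (qr_X$rank < degree + 1L) {
    stopf("degenerate radii: polynomial design matrix is rank-deficient")
  }
  beta <- qr.coef(qr_X, y)
  res <- y - X %*% beta
  g0 <- sum(beta * r0_cm^(0:degree))
  if (!is.finite(g0) || g0 <= 0) stopf("fit is non-positive at r0")
  structure(list(coefficients = as.numeric(beta / g0),
                 r_range = range(r),
                 rms_residual = sqrt(mean(res^2)) / g0,
                 n_voxels = length(r),
                 ref_intensity = attr(samples, "ref")$mean %||% NA_real_),
            class = "radial_fit")
}

#' Evaluate a fitted radial dose function
#'
#' @param fit A [fit_radial()] result.
#' @param r Radii in cm.
#' @return Fitted g values; attribute `outside` flags radii outside the
#'   range of the data that produced the fit (values are still returned,
#'   callers decide whether to trust them).
#' @export
predict_radial <- function(fit, r) {
  co <- fit$coefficients
  out <- rep(co[length(co)], length(r))
  for (k in rev(seq_len(length(co) - 1L))) out <- out * r + co[k]
  attr(out, "outside") <- r < fit$r_range[1] | r > fit$r_range[2]
  out
}

#' Bin transverse samples radially
#'
#' Half-open bins `[c - w/2, c + w/2)` centered on integer multiples of the
#' bin width; per bin the mean, standard deviation, standard error
#' (SD / sqrt(n)) and voxel count are reported.  Bins with a single voxel
#' report `NA` SD/SE.
#'
#' @param samples Data frame from [radial_samples()].
#' @param bin_width_mm Bin width in mm (default 1).
#' @return Data frame with columns `bin_center_cm`, `mean`, `sd`, `se`,
#'   `count`.
#' @export
bin_radial <- function(samples, bin_width_mm = 1.0) {
  if (bin_width_mm <= 0) stopf("bin width must be positive")
  w <- bin_width_mm / 10
  k <- floor(samples$r_cm / w + 0.5)
  ks <- sort(unique(k))
  grp <- match(k, ks)
  n <- tabulate(grp, length(ks))
  s1 <- rowsum(samples$y, grp)[, 1]
  s2 <- rowsum(samples$y^2, grp)[, 1]
  mu <- s1 / n
  ss <- pmax(s2 - n * mu^2, 0)
  sd <- ifelse(n > 1L, sqrt(ss / (n - 1L)), NA_real_)
  data.frame(bin_center_cm = ks * w, mean = mu, sd = sd,
             se = sd / sqrt(n), count = n, row.names = NULL)
}

#' Default anisotropy reporting grid
#'
#' Polar angles every 10 degrees plus a finer ladder approaching the channel
#' side of the long axis, and radii from 0.75 to 4 cm.
#' @return List with `r_cm` and `theta_deg`.
#' @export
default_anisotropy_grid <- function() {
  list(r_cm = c(0.75, 1, 1.5, 2, 3, 4),
       theta_deg = c(seq(10, 170, 10), 172, 174, 175, 176))
}

#' Estimate the 2D anisotropy function
#'
#' For each grid node (r_j, theta_k), averages over the ROI voxels within
#' `tol_r_mm` and `tol_theta_deg` of the node the per-voxel term
#' I(r_i, theta_i) / Ibar(r0, theta0) * G_L(r0, theta0) / G_L(r_i, theta_i)
#'   / g_hat(r_i),
#' where g_hat is the fitted radial dose function.  The per-bin SD of the
#' terms, SE = SD / sqrt(n) and voxel count are recorded.  Bins with fewer
#' than `n_min` voxels, or containing radii outside the radial fit's data
#' range, are flagged (tables leave them blank).
#'
#' @param field A [polar_field()].
#' @param model A [source_model()].
#' @param radial_fit A [fit_radial()] result.
#' @param r_cm,theta_deg Grid nodes (defaults: [default_anisotropy_grid()]).
#' @param tol_r_mm,tol_theta_deg Bin half-widths (defaults 1.0 mm,
#'   0.5 degrees).
#' @param n_min Minimum voxels for a reported bin (default 5).
#' @param ref Output of [reference_intensity()] (computed here when NULL).
#' @return An object of class `anisotropy_grid`: matrices `f_hat`, `sd`,
#'   `se`, `count`, `flagged` with one row per theta and one column per r.
#' @export
anisotropy <- function(field, model, radial_fit,
                       r_cm = NULL, theta_deg = NULL,
                       tol_r_mm = 1.0, tol_theta_deg = 0.5,
                       n_min = 5L, ref = NULL) {
  grid <- default_anisotropy_grid()
  r_cm <- r_cm %||% grid$r_cm
  theta_deg <- theta_deg %||% grid$theta_deg
  if (is.null(ref)) {
    ref <- reference_intensity(field, model$r0_cm, model$theta0_deg)
  }
  nr <- length(r_cm); nt <- length(theta_deg)

  br <- bin_assign(field$r_cm, r_cm, tol_r_mm / 10)
  bt <- bin_assign(field$theta_deg, theta_deg, tol_theta_deg)
  mem <- !is.na(br) & !is.na(bt)
  key <- (br[mem] - 1L) * nt + bt[mem]           # bins laid out theta-fastest

  r_i <- field$r_cm[mem]
  G0 <- geometry_function_line(model$r0_cm, model$theta0_deg,
                               model$active_length_cm)
  G <- geometry_function_line(r_i, field$theta_deg[mem],
                              model$active_length_cm)
  ghat <- predict_radial(radial_fit, r_i)
  term <- field$intensity[mem] / ref$mean * (G0 / G) / as.numeric(ghat)
  outside <- attr(ghat, "outside")

  nbin <- nr * nt
  n <- tabulate(key, nbin)
  s1 <- numeric(nbin); s2 <- numeric(nbin); nout <- numeric(nbin)
  if (length(key)) {
    agg <- rowsum(cbind(term, term^2, as.numeric(outside)), key)
    at <- as.integer(rownames(agg))
    s1[at] <- agg[, 1]; s2[at] <- agg[, 2]; nout[at] <- agg[, 3]
  }
  mu <- ifelse(n > 0L, s1 / n, NA_real_)
  sd <- ifelse(n > 1L, sqrt(pmax(s2 - n * mu^2, 0) / (n - 1L)), NA_real_)

  shape <- function(v) matrix(v, nrow = nt, ncol = nr,
                              dimnames = list(theta = format(theta_deg),
                                              r = format(r_cm)))
  structure(list(r_cm = r_cm, theta_deg = theta_deg,
                 f_hat = shape(mu), sd = shape(sd),
                 se = shape(sd / sqrt(pmax(n, 1L))),
                 count = shape(n),
                 flagged = shape(n < n_min | nout > 0),
                 n_min = n_min,
                 tol_r_mm = tol_r_mm, tol_theta_deg = tol_theta_deg),
            class = "anisotropy_grid")
}

#' Compare an anisotropy estimate to the reference model
#'
#' Percent difference of the estimated anisotropy from the reference table,
#' cell layout mirroring the estimate (theta rows, r columns), with flagged
#' bins blanked.
#'
#' @param grid An [anisotropy()] result.
#' @param model A [source_model()] providing the reference F.
#' @return An object of class `comparison_table`: matrices `percent_diff`
#'   (100 * (F_hat / F_ref - 1)), `se_percent` (100 * SE / F_ref), `count`,
#'   `flagged`.
#' @export
compare_to_reference <- function(grid, model) {
  Fref <- t(vapply(grid$theta_deg,
                   function(th) as.numeric(eval_anisotropy(model, grid$r_cm, th)),
                   numeric(length(grid$r_cm))))
  pd <- 100 * (grid$f_hat / Fref - 1)
  sp <- 100 * grid$se / Fref
  pd[grid$flagged] <- NA_real_
  sp[grid$flagged] <- NA_real_
  structure(list(r_cm = grid$r_cm, theta_deg = grid$theta_deg,
                 percent_diff = pd, se_percent = sp,
                 count = grid$count, flagged = grid$flagged,
                 f_ref = Fref),
            class = "comparison_table")
}

#' Format a comparison table as strings
#'
#' Cells look like `"4.7±4.3% (16)"`; flagged/empty bins render as `"-"`.
#'
#' @param x A [compare_to_reference()] result.
#' @return Character matrix (theta rows, r columns).
#' @export
format_comparison <- function(x) {
  out <- matrix("-", nrow = length(x$theta_deg), ncol = length(x$r_cm),
                dimnames = dimnames(x$percent_diff))
  ok <- !x$flagged & is.finite(x$percent_diff)
  out[ok] <- sprintf("%.1f±%.1f%% (%d)", x$percent_diff[ok],
                     x$se_percent[ok], x$count[ok])
  out
}

#' @export
print.comparison_table <- function(x, ...) {
  cat("Anisotropy comparison: percent difference from reference ± SE (n voxels)\n")
  print(format_comparison(x), quote = FALSE)
  invisible(x)
}

#' @export
print.anisotropy_grid <- function(x, ...) {
  cat(sprintf("anisotropy_grid: %d radii x %d angles, %d reported bins (n_min = %d)\n",
              length(x$r_cm), length(x$theta_deg), sum(!x$flagged), x$n_min))
  invisible(x)
}
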