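#' TG-43 source model
#'
#' A `source_model` bundles the source-specific quantities of the AAPM TG-43
#' formalism: the active length L of the line source, a reference radial dose
#' function g_L(r) (either a polynomial in r or an interpolated table) and a
#' reference 2D anisotropy function F(r, theta) given as a table over radii
#' (cm) and polar angles (degrees, measured from the source long axis).  Both
#' reference curves are renormalized on construction so that g_L(r0) = 1 and
#' F(r, theta0) = 1, with r0 = 1 cm and theta0 = 90 degrees by default.
#'
#' @param active_length_cm Active source length L in cm (> 0).
#' @param radial_dose A list describing g_L(r): either
#'   `list(type = "poly", coefficients = c(c0, ..., c5), r_range = c(min, max))`
#'   (ascending powers of r in cm) or
#'   `list(type = "table", r_cm = ..., g = ...)` interpolated with a
#'   monotone (Fritsch--Carlson) piecewise cubic.
#' @param anisotropy A list `list(theta_deg = ..., r_cm = ..., values = ...)`
#'   where `values` is a matrix with `length(r_cm)` rows and
#'   `length(theta_deg)` columns, interpolated bilinearly.
#' @param physical_diameter_cm Outer diameter of the source capsule in cm;
#'   must fit the channel of any phantom the source is placed in.
#' @param r0_cm,theta0_deg TG-43 reference point (defaults 1 cm, 90 degrees).
#' @return An object of class `source_model`.
#' @export
source_model <- function(active_length_cm,
                         radial_dose,
                         anisotropy,
                         physical_diameter_cm = 0.3,
                         r0_cm = 1.0,
                         theta0_deg = 90.0) {
  if (!is.numeric(active_length_cm) || length(active_length_cm) != 1L ||
      active_length_cm <= 0) {
    stopf("active_length_cm must be a positive scalar")
  }
  if (physical_diameter_cm <= 0) stopf("physical_diameter_cm must be positive")

  rd <- validate_radial_dose(radial_dose)
  an <- validate_anisotropy(anisotropy)

  model <- structure(
    list(active_length_cm = active_length_cm,
         physical_diameter_cm = physical_diameter_cm,
         radial_dose = rd,
         anisotropy = an,
         r0_cm = r0_cm,
         theta0_deg = theta0_deg),
    class = "source_model")

  ## renormalize on load: g(r0) and F(., theta0) must equal 1
  g0 <- eval_radial_raw(model, r0_cm)
  if (!is.finite(g0) || g0 <= 0) stopf("radial dose curve is not positive at r0")
  if (abs(g0 - 1) > 1e-6) {
    if (rd$type == "poly") {
      model$radial_dose$coefficients <- rd$coefficients / g0
    } else {
      model$radial_dose$g <- rd$g / g0
    }
  }
  f0 <- interp_aniso_raw(model, an$r_cm, rep(theta0_deg, length(an$r_cm)))
  if (any(!is.finite(f0)) || any(f0 <= 0)) {
    stopf("anisotropy table is not positive at theta0")
  }
  if (any(abs(f0 - 1) > 1e-6)) {
    model$anisotropy$values <- an$values / f0  # recycles by row (r)
  }
  model
}

validate_radial_dose <- function(rd) {
  if (!is.list(rd) || is.null(rd$type)) {
    stopf("radial_dose must be a list with a 'type' field ('poly' or 'table')")
  }
  if (rd$type == "poly") {
    if (is.null(rd$coefficients) || !is.numeric(rd$coefficients)) {
      stopf("radial_dose poly form requires numeric 'coefficients'")
    }
    if (is.null(rd$r_range) || length(rd$r_range) != 2L ||
        rd$r_range[1] <= 0 || diff(rd$r_range) <= 0) {
      stopf("radial_dose poly form requires r_range = c(min, max) with 0 < min < max")
    }
    list(type = "poly", coefficients = as.numeric(rd$coefficients),
         r_range = as.numeric(rd$r_range))
  } else if (rd$type == "table") {
    r <- as.numeric(rd$r_cm); g <- as.numeric(rd$g)
    if (length(r) < 2L || length(r) != length(g)) {
      stopf("radial_dose table requires r_cm and g of equal length >= 2")
    }
    if (any(diff(r) <= 0)) stopf("radial_dose table r_cm must be strictly increasing")
    if (any(g <= 0)) stopf("radial_dose table values must be positive")
    list(type = "table", r_cm = r, g = g, r_range = range(r))
  } else {
    stopf("unknown radial_dose type '%s'", rd$type)
  }
}

validate_anisotropy <- function(an) {
  th <- as.numeric(an$theta_deg); r <- as.numeric(an$r_cm)
  v <- an$values
  if (is.list(v)) v <- do.call(rbind, lapply(v, as.numeric))
  v <- as.matrix(v)
  if (any(diff(th) <= 0) || any(diff(r) <= 0)) {
    stopf("anisotropy grids must be strictly increasing")
  }
  if (th[1] <= 0 || th[length(th)] >= 180) {
    stopf("anisotropy theta grid must lie strictly inside (0, 180) degrees")
  }
  if (nrow(v) != length(r) || ncol(v) != length(th)) {
    stopf("anisotropy values must be a %d x %d matrix (r by theta); got %d x %d",
          length(r), length(th), nrow(v), ncol(v))
  }
  if (any(v <= 0)) stopf("anisotropy values must be positive")
  list(theta_deg = th, r_cm = r, values = v)
}

#' Read a source model from a YAML/JSON config file
#'
#' The file must contain exactly the keys `active_length_cm`,
#' `physical_diameter_cm` (optional), `radial_dose`, `anisotropy`, and
#' optionally `r0_cm` and `theta0_deg`.  Unknown keys are rejected.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A [source_model()].
#' @export
read_source_model <- function(path) {
  if (!file.exists(path)) stopf("source model file not found: %s", path)
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  allowed <- c("active_length_cm", "physical_diameter_cm", "radial_dose",
               "anisotropy", "r0_cm", "theta0_deg", "name", "synthetic")
  extra <- setdiff(names(cfg), allowed)
  if (length(extra)) stopf("unknown keys in source model config: %s",
                           paste(extra, collapse = ", "))
  for (req in c("active_length_cm", "radial_dose", "anisotropy")) {
    if (is.null(cfg[[req]])) stopf("source model config missing '%s'", req)
  }
  source_model(active_length_cm = cfg$active_length_cm,
               radial_dose = cfg$radial_dose,
               anisotropy = cfg$anisotropy,
               physical_diameter_cm = cfg$physical_diameter_cm %||% 0.3,
               r0_cm = cfg$r0_cm %||% 1.0,
               theta0_deg = cfg$theta0_deg %||% 90.0)
}

#' TG-43 line-source geometry function
#'
#' G_L(r, theta) = beta / (L r sin(theta)) where beta is the angle subtended
#' at the calculation point by the active length; on the long axis
#' (theta = 0 or 180 degrees) the limit (r^2 - L^2/4)^-1 is used.  As L -> 0
#' this tends to the point-source inverse square law 1/r^2.
#'
#' @param r Radius in cm (> 0), vectorized.
#' @param theta_deg Polar angle from the source long axis, degrees in
#'   \[0, 180\], vectorized.
#' @param L Active length in cm (>= 0; 0 gives the point-source form).
#' @return Geometry function values in cm^-2 (strictly positive).
#' @export
geometry_function_line <- function(r, theta_deg, L) {
  if (any(!is.finite(r)) || any(r <= 0)) stopf("geometry function requires r > 0")
  if (any(theta_deg < 0 | theta_deg > 180)) {
    stopf("theta must lie in [0, 180] degrees")
  }
  if (L < 0) stopf("active length must be >= 0")
  if (L == 0) return(1 / r^2)
  n <- max(length(r), length(theta_deg))
  r <- rep_len(r, n); theta_deg <- rep_len(theta_deg, n)
  th <- theta_deg * DEG2RAD
  s <- sin(th)
  rho <- r * s                      # distance from the long axis
  D <- r^2 - L^2 / 4                # dot product of end-point vectors
  onaxis <- s == 0 | theta_deg == 0 | theta_deg == 180
  if (any(onaxis & D <= 0)) {
    stopf("point on the active source segment (theta on axis with r <= L/2)")
  }
  beta <- atan2(rho * L, D)         # subtended angle, exact for all quadrants
  out <- numeric(n)
  out[!onaxis] <- beta[!onaxis] / (L * rho[!onaxis])
  out[onaxis] <- 1 / D[onaxis]
  out
}

## raw (pre-normalization-ratio) evaluation of the radial curve
eval_radial_raw <- function(model, r) {
  rd <- model$radial_dose
  if (rd$type == "poly") {
    co <- rd$coefficients
    out <- rep(co[length(co)], length(r))
    for (k in rev(seq_len(length(co) - 1L))) out <- out * r + co[k]
    out
  } else {
    f <- stats::splinefun(rd$r_cm, rd$g, method = "monoH.FC")
    f(r)
  }
}

#' Evaluate the reference radial dose function g_L(r)
#'
#' Polynomial models are evaluated by Horner's rule; tables with a
#' shape-preserving monotone cubic interpolant.  The curve is expressed as a
#' ratio to its value at r0 so that `eval_radial_dose(model, r0)` is exactly 1.
#' No extrapolation: radii outside the model's valid range raise an error.
#'
#' @param model A [source_model()].
#' @param r Radii in cm, vectorized.
#' @return Dimensionless g_L(r).
#' @export
eval_radial_dose <- function(model, r) {
  rng <- model$radial_dose$r_range
  bad <- r < rng[1] - 1e-12 | r > rng[2] + 1e-12
  if (any(bad)) {
    stopf("radius outside the radial dose curve's valid range [%.3g, %.3g] cm (first offender: %.4g)",
          rng[1], rng[2], r[which(bad)[1]])
  }
  g <- eval_radial_raw(model, r) / eval_radial_raw(model, model$r0_cm)
  if (any(g <= 0)) stopf("radial dose curve non-positive inside its valid range")
  g
}

## bilinear interpolation on the anisotropy table with clamping outside the
## hull (nearest r row / nearest theta column); returns raw table units
interp_aniso_raw <- function(model, r, theta_deg) {
  an <- model$anisotropy
  rg <- an$r_cm; tg <- an$theta_deg; V <- an$values
  rc <- pmin(pmax(r, rg[1]), rg[length(rg)])
  tc <- pmin(pmax(theta_deg, tg[1]), tg[length(tg)])
  i <- findInterval(rc, rg, all.inside = TRUE)
  j <- findInterval(tc, tg, all.inside = TRUE)
  wr <- (rc - rg[i]) / (rg[i + 1L] - rg[i])
  wt <- (tc - tg[j]) / (tg[j + 1L] - tg[j])
  v00 <- V[cbind(i, j)]; v10 <- V[cbind(i + 1L, j)]
  v01 <- V[cbind(i, j + 1L)]; v11 <- V[cbind(i + 1L, j + 1L)]
  (1 - wr) * ((1 - wt) * v00 + wt * v01) + wr * ((1 - wt) * v10 + wt * v11)
}

#' Evaluate the reference 2D anisotropy function F(r, theta)
#'
#' Bilinear interpolation inside the table hull; outside it the nearest
#' r row (or theta column) is used and the result carries an `extrapolated`
#' attribute flagging those points.  Values are expressed as a ratio to the
#' interpolated value at theta0 for the same radius, so F(r, theta0) is
#' exactly 1.
#'
#' @param model A [source_model()].
#' @param r Radii in cm, vectorized.
#' @param theta_deg Angles in degrees within \[0, 180\], vectorized.
#' @return Dimensionless F(r, theta) with attribute `extrapolated`.
#' @export
eval_anisotropy <- function(model, r, theta_deg) {
  if (any(theta_deg < 0 | theta_deg > 180)) {
    stopf("theta must lie in [0, 180] degrees")
  }
  n <- max(length(r), length(theta_deg))
  r <- rep_len(r, n); theta_deg <- rep_len(theta_deg, n)
  an <- model$anisotropy
  f <- interp_aniso_raw(model, r, theta_deg) /
    interp_aniso_raw(model, r, rep_len(model$theta0_deg, n))
  outside <- r < an$r_cm[1] | r > an$r_cm[length(an$r_cm)] |
    theta_deg < an$theta_deg[1] | theta_deg > an$theta_deg[length(an$theta_deg)]
  attr(f, "extrapolated") <- outside
  f
}

#' TG-43 dose at a point
#'
#' dose = D_ref * G_L(r, theta) / G_L(r0, theta0) * g_L(r) * F(r, theta),
#' the TG-43 product with the dose-rate-constant-and-strength factor folded
#' into the reference dose `D_ref` delivered at (r0, theta0).  At the
#' reference point the result equals `D_ref` exactly.
#'
#' @param model A [source_model()].
#' @param D_ref Reference dose in Gy at (r0, theta0) (> 0).
#' @param r Radii in cm, vectorized.
#' @param theta_deg Angles in degrees, vectorized.
#' @return Dose in Gy.
#' @export
tg43_dose <- function(model, D_ref, r, theta_deg) {
  if (D_ref <= 0) stopf("D_ref must be positive")
  G <- geometry_function_line(r, theta_deg, model$active_length_cm)
  G0 <- geometry_function_line(model$r0_cm, model$theta0_deg,
                               model$active_length_cm)
  D_ref * (G / G0) * eval_radial_dose(model, r) *
    as.numeric(eval_anisotropy(model, r, theta_deg))
}

#' @export
print.source_model <- function(x, ...) {
  cat("TG-43 source model\n")
  cat(sprintf("  active length L: %.3f cm, capsule diameter: %.3f cm\n",
              x$active_length_cm, x$physical_diameter_cm))
  cat(sprintf("  radial dose: %s over [%.3g, %.3g] cm\n", x$radial_dose$type,
              x$radial_dose$r_range[1], x$radial_dose$r_range[2]))
  cat(sprintf("  anisotropy table: %d radii x %d angles\n",
              length(x$anisotropy$r_cm), length(x$anisotropy$theta_deg)))
  cat(sprintf("  reference point: r0 = %g cm, theta0 = %g deg\n",
              x$r0_cm, x$theta0_deg))
  invisible(x)
}
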