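## Shared fixtures, built once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.fixture_cache[[key]])) assign(key, expr, envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

test_model <- function() cached("model", synthetic_source_model())

## near-point source with flat g and F: dose is pure inverse square
flat_model <- function() {
  cached("flat_model", source_model(
    active_length_cm = 1e-7,
    radial_dose = list(type = "poly", coefficients = c(1, 0, 0, 0, 0, 0),
                       r_range = c(0.01, 10)),
    anisotropy = list(theta_deg = c(5, 90, 175), r_cm = c(0.25, 1, 5),
                      values = matrix(1, 3, 3)),
    physical_diameter_cm = 0.3))
}

## realistic g/F but coarse voxels and a small cylinder: fast unit tests
tiny_phantom <- function() {
  cached("tiny_phantom", build_phantom(
    phantom_spec(cylinder_diameter_cm = 3.6, cylinder_height_cm = 3.2,
                 voxel_mm = 1, noise = "none"),
    test_model()))
}

## half-scale cylinder at full voxel resolution, noise-free
small_phantom <- function() {
  cached("small_phantom", build_phantom(
    phantom_spec(cylinder_diameter_cm = 5, cylinder_height_cm = 4.8,
                 noise = "none"),
    test_model()))
}

small_roi <- function() cached("small_roi", build_roi(small_phantom()$volume, 1.5))

small_field <- function() {
  cached("small_field",
         polar_field(small_phantom()$volume, small_roi(), small_phantom()$pose))
}

small_fit <- function() {
  cached("small_fit", {
    s <- radial_samples(small_field(), test_model())
    fit_radial(s)
  })
}

## the full default phantom (paper geometry) -- expensive, built once
default_phantom <- function() {
  cached("default_phantom",
         build_phantom(phantom_spec(noise = "none"), test_model()))
}

default_roi <- function() cached("default_roi", build_roi(default_phantom()$volume, 1.5))

default_field <- function() {
  cached("default_field",
         polar_field(default_phantom()$volume, default_roi(),
                     default_phantom()$pose))
}

angle_between_deg <- function(a, b) {
  acos(pmin(pmax(sum(a * b), -1), 1)) * 180 / pi
}

## brute-force erosion oracle: voxel survives iff all mask voxels whose
## centers lie within radius_mm are set (O(N * k), small grids only)
erode_brute <- function(mask, radius_mm, spacing_mm) {
  spacing_mm <- rep_len(spacing_mm, 3L)
  dims <- dim(mask)
  nmax <- floor(radius_mm / spacing_mm)
  off <- expand.grid(i = -nmax[1]:nmax[1], j = -nmax[2]:nmax[2],
                     k = -nmax[3]:nmax[3])
  d2 <- (off$i * spacing_mm[1])^2 + (off$j * spacing_mm[2])^2 +
    (off$k * spacing_mm[3])^2
  off <- as.matrix(off[d2 <= radius_mm^2 + 1e-9, ])
  out <- array(FALSE, dims)
  for (v in which(mask)) {
    ai <- arrayInd(v, dims)
    nb <- sweep(off, 2L, as.integer(ai), `+`)
    ok <- nb[, 1] >= 1 & nb[, 1] <= dims[1] &
      nb[, 2] >= 1 & nb[, 2] <= dims[2] &
      nb[, 3] >= 1 & nb[, 3] <= dims[3]
    out[v] <- all(ok) && all(mask[nb])
  }
  out
}

## numeric line-integration oracle for the TG-43 line-source geometry
## function: G = integral over the active segment of dl / (L * d(l)^2)
geometry_oracle <- function(r, theta_deg, L) {
  th <- theta_deg * pi / 180
  rho <- r * sin(th); z <- r * cos(th)
  stats::integrate(function(l) 1 / (L * (rho^2 + (z - l)^2)),
                   lower = -L / 2, upper = L / 2,
                   rel.tol = 1e-12, abs.tol = 0)$value
}

`%||%` <- function(a, b) if (is.null(a)) b else a
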