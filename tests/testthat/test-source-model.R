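test_that("line-source geometry function matches the line-integration oracle", {
  L <- 1.48
  for (r in seq(0.8, 4, length.out = 20)) {
    for (th in seq(5, 175, length.out = 20)) {
      expect_equal(geometry_function_line(r, th, L), geometry_oracle(r, th, L),
                   tolerance = 1e-8)
    }
  }
  ## off-axis points closer in than L/2 are still valid
  expect_equal(geometry_function_line(0.5, 60, L), geometry_oracle(0.5, 60, L),
               tolerance = 1e-8)
  ## spec'd spot checks
  expect_equal(geometry_function_line(2, 45, 0.5), geometry_oracle(2, 45, 0.5),
               tolerance = 1e-9)
  beta <- 2 * atan(1.48 / 2)
  expect_equal(geometry_function_line(1, 90, 1.48), beta / 1.48,
               tolerance = 1e-12)
})

test_that("geometry function has the point-source limit and mirror symmetry", {
  for (r in c(0.5, 1, 2, 4)) {
    for (th in c(1, 30, 90, 179)) {
      expect_lt(abs(geometry_function_line(r, th, 1e-6) * r^2 - 1), 1e-6)
      expect_equal(geometry_function_line(r, th, 1.48),
                   geometry_function_line(r, 180 - th, 1.48),
                   tolerance = 1e-12)
    }
  }
  expect_equal(geometry_function_line(1, 90, 0), 1)
  ## continuity across the on-axis branch
  expect_equal(geometry_function_line(2, 1e-6, 1.48),
               geometry_function_line(2, 0, 1.48), tolerance = 1e-6)
})

test_that("geometry function rejects points on the source line", {
  expect_error(geometry_function_line(0.5, 0, 1.48), "segment")
  expect_error(geometry_function_line(0.74, 180, 1.48), "segment")
  expect_error(geometry_function_line(0, 90, 1.48), "r > 0")
  expect_error(geometry_function_line(1, 181, 1.48), "180")
})

test_that("radial dose evaluation is normalized, interpolates, and refuses extrapolation", {
  tbl <- source_model(1.48,
                      radial_dose = list(type = "table",
                                         r_cm = c(0.5, 1, 2), g = c(1.04, 1.0, 0.92)),
                      anisotropy = list(theta_deg = c(10, 90, 170),
                                        r_cm = c(0.5, 2), values = matrix(1, 2, 3)))
  expect_equal(eval_radial_dose(tbl, 1), 1)
  expect_equal(eval_radial_dose(tbl, c(0.5, 2)), c(1.04, 0.92))
  ## monotone interpolant stays between neighboring nodes and close to an
  ## independent shape-preserving evaluation
  v <- eval_radial_dose(tbl, 1.5)
  expect_gt(v, 0.92); expect_lt(v, 1.0)
  skip_if_not_installed("pracma")
  expect_equal(v, pracma::pchip(c(0.5, 1, 2), c(1.04, 1.0, 0.92), 1.5),
               tolerance = 0.01)
  expect_error(eval_radial_dose(tbl, 2.5), "valid range")
  expect_error(eval_radial_dose(tbl, 0.4), "valid range")
})

test_that("constant polynomial radial curve is identically 1", {
  m <- flat_model()
  expect_equal(eval_radial_dose(m, c(0.1, 1, 5)), c(1, 1, 1))
})

test_that("radial curve not equal to 1 at r0 is renormalized on load", {
  m <- source_model(1.0,
                    radial_dose = list(type = "poly", coefficients = c(2, 0.1),
                                       r_range = c(0.1, 5)),
                    anisotropy = list(theta_deg = c(10, 90, 170),
                                      r_cm = c(0.5, 2),
                                      values = matrix(2, 2, 3)))
  expect_equal(eval_radial_dose(m, 1), 1)
  expect_equal(as.numeric(eval_anisotropy(m, 1, 90)), 1)
  expect_equal(eval_radial_dose(m, 2), 2.2 / 2.1)
})

test_that("anisotropy evaluation is normalized at theta0 and exact at nodes", {
  m <- test_model()
  an <- m$anisotropy
  expect_equal(as.numeric(eval_anisotropy(m, c(0.5, 1, 3, 6), 90)),
               rep(1, 4))
  ## a node value is reproduced exactly
  i <- which(an$r_cm == 2); j <- which(an$theta_deg == 30)
  expect_equal(as.numeric(eval_anisotropy(m, 2, 30)), an$values[i, j],
               tolerance = 1e-12)
  expect_error(eval_anisotropy(m, 1, -5), "180")
  expect_error(eval_anisotropy(m, 1, 190), "180")
  ## beyond the radial hull: nearest-r, flagged
  f <- eval_anisotropy(m, 20, 45)
  expect_true(attr(f, "extrapolated"))
  expect_equal(as.numeric(f), as.numeric(eval_anisotropy(m, 7, 45)))
})

test_that("tg43 dose is the product of its factors and exact at the reference point", {
  m <- test_model()
  expect_identical(tg43_dose(m, 5.3, 1, 90), 5.3)
  ## inverse square for the near-point flat source
  expect_equal(tg43_dose(flat_model(), 1, 2, 37), 0.25, tolerance = 1e-10)
  ## factor-by-factor oracle at an arbitrary point
  r <- 2; th <- 45
  expected <- 5.3 * geometry_oracle(r, th, m$active_length_cm) /
    geometry_oracle(1, 90, m$active_length_cm) *
    eval_radial_dose(m, r) * as.numeric(eval_anisotropy(m, r, th))
  expect_equal(tg43_dose(m, 5.3, r, th), expected, tolerance = 1e-8)
  expect_error(tg43_dose(m, -1, 1, 90), "positive")
})

test_that("source model config files are strictly validated", {
  m <- read_source_model(synthetic_source_path())
  expect_s3_class(m, "source_model")
  expect_equal(m$active_length_cm, 1.48)

  bad <- tempfile(fileext = ".yaml")
  yaml::write_yaml(list(active_length_cm = 1, radial_dose = list(
    type = "poly", coefficients = c(1), r_range = c(0.1, 5)),
    anisotropy = list(theta_deg = c(10, 90, 170), r_cm = c(0.5, 2),
                      values = list(c(1, 1, 1), c(1, 1, 1))),
    surprise = 1), bad)
  expect_error(read_source_model(bad), "unknown keys")

  bad2 <- tempfile(fileext = ".yaml")
  yaml::write_yaml(list(active_length_cm = 1), bad2)
  expect_error(read_source_model(bad2), "missing")

  expect_error(source_model(-1, list(type = "poly", coefficients = 1,
                                     r_range = c(0.1, 5)),
                            list(theta_deg = c(10, 90), r_cm = c(0.5, 2),
                                 values = matrix(1, 2, 2))),
               "positive")
  ## theta grid must stay inside (0, 180)
  expect_error(source_model(1, list(type = "poly", coefficients = 1,
                                    r_range = c(0.1, 5)),
                            list(theta_deg = c(0, 90, 180), r_cm = c(0.5, 2),
                                 values = matrix(1, 2, 3))),
               "strictly inside")
})
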