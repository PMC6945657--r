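# The gamma-index engine, cross-checked against brute-force oracles.

test_that("identical distributions give gamma zero and full passing", {
  pos <- seq(0, 10, by = 0.2)
  ref <- raw_curve(pos, 50 + 40 * sin(pos / 3))
  res <- gamma_curve(ref, ref, gamma_criteria(1, 1))
  expect_true(all(res$gamma_values < 1e-9))
  expect_equal(res$passing_rate, 100)
  expect_equal(multi_criteria_report(ref, ref),
               c(rate_3_3 = 100, rate_2_2 = 100, rate_1_1 = 100))
})

test_that("a pure dose offset of exactly the tolerance sits on the gamma boundary", {
  pos <- seq(-5, 5, by = 0.2)
  ref <- raw_curve(pos, rep(100, length(pos)))
  ev <- raw_curve(pos, rep(102, length(pos)))
  res <- gamma_curve(ref, ev, gamma_criteria(2, 2))
  expect_true(all(abs(res$gamma_values - 1) < 1e-9))
  expect_equal(res$passing_rate, 100)  # "equal to or less than 1" passes
})

test_that("a 1 mm shift of a steep ramp scores gamma about 1 at 1%/1 mm", {
  pos <- seq(0, 2, by = 0.1)
  ref <- raw_curve(pos, 50 * pos)             # 5% of max per mm
  ev <- raw_curve(pos, 50 * pos + 5)          # = ref shifted by exactly -1 mm
  res <- gamma_curve(ref, ev, gamma_criteria(1, 1))
  interior <- 5:17
  expect_true(all(abs(res$gamma_values[interior] - 1) <= 0.05))
  # brute-force oracle at 1/1000 of the spacing agrees
  brute <- brute_gamma_1d(ref, ev, gamma_criteria(1, 1), refine = 1000)
  expect_true(all(abs(res$gamma_values[interior] - brute[interior]) <= 0.05))
})

test_that("one displaced point out of fifty fails alone", {
  pos <- seq(0, by = 0.2, length.out = 50)
  ref <- raw_curve(pos, rep(100, 50))
  vals <- rep(100, 50); vals[25] <- 200
  ev <- raw_curve(pos, vals)
  res <- gamma_curve(ref, ev, gamma_criteria(1, 1))
  expect_equal(res$passing_rate, 98.0)
})

test_that("criteria nest pointwise: passing 1%/1 mm implies passing the looser pairs", {
  pos <- seq(0, 12, by = 0.2)
  for (s in 1:5) {
    set.seed(100 + s)
    base <- 60 + 35 * sin(pos / 2.5) + 0.3 * pos
    ref <- raw_curve(pos, base)
    ev <- raw_curve(pos, base * (1 + rnorm(length(pos), 0, 0.02)) +
                           rnorm(length(pos), 0, 1))
    g11 <- gamma_curve(ref, ev, gamma_criteria(1, 1))$gamma_values
    g22 <- gamma_curve(ref, ev, gamma_criteria(2, 2))$gamma_values
    g33 <- gamma_curve(ref, ev, gamma_criteria(3, 3))$gamma_values
    expect_true(all(g22[g11 <= 1] <= 1))
    expect_true(all(g33[g22 <= 1] <= 1))
  }
})

test_that("search window is five times the DTA, capped at 1.5 cm", {
  expect_equal(gamma_search_window(gamma_criteria(1, 1)), 0.5)
  expect_equal(gamma_search_window(gamma_criteria(3, 3)), 1.5)
  expect_equal(gamma_search_window(gamma_criteria(2, 2)), 1.0)
  # behavioural check: a reference point 0.6 cm beyond the evaluated extent is
  # uncovered at 1%/1 mm (window 0.5 cm) but covered at 3%/3 mm (window 1.5 cm)
  ev <- raw_curve(seq(0, 4, 0.2), rep(100, 21))
  expect_true(is.na(gamma_point(4.6, 100, ev, gamma_criteria(1, 1))))
  expect_false(is.na(gamma_point(4.6, 100, ev, gamma_criteria(3, 3))))
})

test_that("uncovered reference points are excluded from the denominator", {
  ref <- raw_curve(seq(0, 10, 0.2), rep(100, 51))
  ev <- raw_curve(seq(0, 8, 0.2), rep(100, 41))
  res <- gamma_curve(ref, ev, gamma_criteria(1, 1))
  # points beyond 8.5 cm have an empty 0.5 cm search window: uncovered
  expect_equal(res$n_uncovered, 8)
  expect_equal(res$n_points, 43)
  # points at 8.2 and 8.4 cm are covered but fail on pure distance
  expect_equal(res$n_pass, 41)
  expect_equal(res$passing_rate, 100 * 41 / 43)
})

test_that("gamma is invariant under mirroring both curves", {
  pos <- seq(0, 10, by = 0.2)
  set.seed(5)
  ref <- raw_curve(pos, 60 + 30 * cos(pos / 2))
  ev <- raw_curve(pos, (60 + 30 * cos(pos / 2)) * (1 + rnorm(51, 0, 0.02)))
  mirror <- function(cu) raw_curve(rev(-cu$positions), rev(cu$values),
                                   kind = cu$kind)
  cr <- gamma_criteria(2, 2)
  expect_equal(sort(gamma_curve(mirror(ref), mirror(ev), cr)$gamma_values),
               sort(gamma_curve(ref, ev, cr)$gamma_values), tolerance = 1e-12)
})

test_that("passing rates match a 50-fold-refinement brute-force oracle within 1 point", {
  pos <- seq(0, 19.8, by = 0.2)  # 100 reference points
  for (s in 1:4) {
    base <- 55 + 40 * sin(pos / 3 + s) + 0.2 * pos
    ref <- raw_curve(pos, base)
    # smooth random-phase perturbation: dose tilt plus a short-wavelength wobble
    ev <- raw_curve(pos, base * (1 + 0.012 * sin(pos * 1.3 + 2 * s)) +
                           0.6 * cos(pos * 2.1 + s))
    for (cr in list(gamma_criteria(1, 1), gamma_criteria(2, 2),
                    gamma_criteria(3, 3))) {
      engine <- gamma_curve(ref, ev, cr)$passing_rate
      oracle <- brute_rate_1d(ref, ev, cr, refine = 50)
      expect_lte(abs(engine - oracle), 1.0)
    }
  }
})

test_that("curve comparisons enforce matching conventions and overlap", {
  pos <- seq(0, 10, 0.2)
  a <- raw_curve(pos, rep(100, 51))
  b <- scan_curve("lateral", positions = pos - 5, values = rep(100, 51),
                  depth = 5, normalization = "none")
  expect_error(gamma_curve(a, b, gamma_criteria(1, 1)), "kind")
  shifted <- raw_curve(pos + 8, rep(100, 51))
  expect_error(gamma_curve(a, shifted, gamma_criteria(1, 1)), "overlap")
})

test_that("3D gamma matches trivial cases and the exhaustive oracle", {
  ph <- phantom_spec(size_x = 3, size_y = 3, size_z = 3, bin = 0.2,
                     field_x = 2, field_y = 2)
  cfg <- beam_config(6.26, 0.15, 0.1, 0)
  k0 <- dose_model_constants(kappa = 0)
  g <- generate_dose_grid(cfg, ph, 1e6, seed = 1, constants = k0)
  g$dose <- g$dose / max(g$dose) * 100
  ax <- list(x = (1:15 - 0.5) * 0.2 - 1.5, z = (1:15 - 0.5) * 0.2)

  # reference points sampled exactly from the grid: gamma 0
  pts <- data.frame(x = ax$x[c(3, 8, 12)], y = 0,
                    z = ax$z[c(4, 8, 11)])
  pts$dose <- vapply(seq_len(3), function(i) {
    ix <- c(3, 8, 12)[i]; iz <- c(4, 8, 11)[i]
    g$dose[ix, 8, iz]
  }, numeric(1))
  res <- gamma_grid(pts, g, gamma_criteria(2, 2))
  expect_true(all(abs(res$gamma_values) < 1e-9))

  # uniform grid with a dose offset of exactly the tolerance: gamma 1
  gu <- g; gu$dose[] <- 102
  centre <- data.frame(x = 0, y = 0, z = 1.5, dose = 100)
  expect_equal(gamma_grid(centre, gu, gamma_criteria(2, 2))$gamma_values, 1)

  # ten-point toy case: voxel centres with perturbed doses, checked against
  # the exhaustive 1/50-bin search (small cap keeps the oracle tractable)
  set.seed(9)
  # points across the depth range but inside the flat top, where the dose
  # surface is resolvable at the compared refinements
  ivox <- cbind(sample(6:10, 10, TRUE), sample(6:10, 10, TRUE),
                sample(3:13, 10, TRUE))
  toy <- data.frame(x = ax$x[ivox[, 1]], y = ax$x[ivox[, 2]],
                    z = ax$z[ivox[, 3]])
  toy$dose <- g$dose[ivox] * (1 + rnorm(10, 0, 0.015))
  # high engine refinement so the comparison probes the search machinery, not
  # the lattice quantisation of the steep penumbra
  cr <- gamma_criteria(2, 2, search_cap_cm = 0.25, resample_factor = 25)
  engine <- gamma_grid(toy, g, cr)$gamma_values
  oracle <- brute_gamma_3d(toy, g, cr, refine = 50)
  expect_true(all(abs(engine - oracle) <= 0.05))
})
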