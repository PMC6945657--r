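# Trend rule, serial stages and their decision contracts.

test_that("pearson obeys the textbook identities and error contracts", {
  x <- c(1, 2, 3, 5, 8)
  expect_equal(pearson(x, 2 * x + 3), 1)
  y <- c(4, 1, 6, 2, 9)
  expect_equal(pearson(x, y), pearson(y, x))
  expect_equal(pearson(10 - 2 * x, y), -pearson(x, y))
  expect_error(pearson(x, y[-1]), "equal length")
  expect_error(pearson(1:2, 2:3), "at least 3")
  expect_error(pearson(c(1, 1, 1), y[1:3]), "zero variance")
})

test_that("trend records validate their sweep and expose the decision quantities", {
  sweep <- data.frame(n_histories = c(2e6, 1e7, 5e7),
                      avg_uncertainty = c(20, 9, 4),
                      rate_3_3 = c(80, 90, 99), rate_2_2 = c(50, 70, 90),
                      rate_1_1 = c(10, 40, 85))
  tr <- build_trend("test", sweep, energy = 6.26)
  expect_equal(tr$final_rate_1_1, 85)
  expect_equal(tr$pearson_r, stats::cor(sweep$avg_uncertainty, sweep$rate_1_1))
  expect_error(build_trend("bad", sweep[c(2, 1, 3), ]), "increasing")
  flat <- sweep; flat$rate_1_1 <- 50
  expect_error(build_trend("flat", flat), "zero variance")
  expect_error(build_trend("short", sweep[1:2, ]), "3")
})

test_that("energy selection applies both thresholds and the tie rules", {
  mk <- function(label, r, final) {
    sweep <- data.frame(n_histories = c(1e6, 2e6, 4e6),
                        avg_uncertainty = c(30, 20, 10),
                        rate_3_3 = 99:101 - 1, rate_2_2 = 90:92,
                        rate_1_1 = c(1, 2, 3))
    tr <- build_trend(label, sweep, energy = 1)
    tr$pearson_r <- r; tr$final_rate_1_1 <- final
    tr
  }
  sole <- select_energy(list(mk("a", -0.9, 85)))
  expect_equal(sole$selected, "a")
  none <- select_energy(list(mk("a", -0.5, 85), mk("b", -0.95, 40)))
  expect_true(is.na(none$selected))
  expect_equal(nrow(none$diagnostics), 2)
  best <- select_energy(list(mk("a", -0.85, 90), mk("b", -0.95, 81)))
  expect_equal(best$selected, "b")   # more negative correlation wins
  tie <- select_energy(list(mk("a", -0.9, 82), mk("b", -0.9, 95)))
  expect_equal(tie$selected, "b")    # equal r: higher final rate wins
  expect_error(select_energy(list()), "at least one")
})

test_that("stage argmax scores candidates by their best depth, ties to the smaller value", {
  m <- rbind(c(50, 71, 60), c(40, 65, 71), c(30, 20, 10))
  st <- stage_argmax("energy_fwhm", c(0.10, 0.14, 0.18), m)
  expect_equal(st$best_depth_rates, c(71, 71, 30))
  expect_equal(st$chosen_value, 0.10)  # tie at 71 -> smaller parameter
  expect_equal(st$chosen_rate, 71)
  single <- stage_argmax("divergence", 2, 55)
  expect_equal(single$chosen_value, 2)
  expect_error(stage_argmax("divergence", c(1, 2), 1), "per candidate")
})

test_that("cross-depth comparison counts strict wins with the documented tie-breaks", {
  allwin <- cross_depth_compare("A", c(9, 9, 9, 9, 9), "B", c(1, 1, 1, 1, 1))
  expect_equal(allwin$wins_a, 5)
  expect_equal(allwin$winner, "A")
  tie <- cross_depth_compare("A", c(5, 5), "B", c(5, 5))
  expect_equal(tie$ties, 2)
  expect_equal(tie$winner, "A")     # complete tie -> declaration order
  bymax <- cross_depth_compare("A", c(9, 1), "B", c(2, 8))
  expect_equal(bymax$winner, "A")   # 1-1 on depths, higher single-depth rate
  expect_error(cross_depth_compare("A", 1:3, "B", 1:2), "equal length")
})

test_that("staged tuning runs serially and reports a complete audit trail", {
  ph <- tiny_phantom()
  truth <- beam_config(6.0, 0.2, 0.2, 0)
  k0 <- dose_model_constants(kappa = 0)
  ref <- generate_reference_scans(truth, ph, scan_depths = c(1.5, 5.1, 10.1),
                                  constants = k0)
  # singleton grids: the sole configuration is returned
  one <- run_staged_tuning(ref, 6.0,
                           list(energy_fwhm = 0.2, focal_spot_fwhm = 0.2,
                                divergence = 0),
                           n_histories = 1e6, phantom = ph, constants = k0)
  expect_equal(one$final_config$energy_fwhm, 0.2)
  expect_equal(one$final_config$focal_spot_fwhm, 0.2)
  expect_length(one$stages, 3)
  expect_null(one$depth_comparison)

  grids <- list(energy_fwhm = c(0, 0.2, 0.4), focal_spot_fwhm = c(0, 0.2, 0.4),
                divergence = c(0, 2, 4))
  audit <- run_staged_tuning(ref, 6.0, grids, n_histories = 1e6, phantom = ph,
                             constants = k0, cross_depth_check = TRUE)
  # serial contract: each stage's winner feeds the final configuration
  expect_equal(vapply(audit$stages, `[[`, "", "parameter_name"),
               c("energy_fwhm", "focal_spot_fwhm", "divergence"))
  expect_equal(audit$final_config$energy_fwhm, audit$stages[[1]]$chosen_value)
  expect_equal(audit$final_config$focal_spot_fwhm, audit$stages[[2]]$chosen_value)
  expect_equal(audit$final_config$divergence, audit$stages[[3]]$chosen_value)
  expect_s3_class(audit$depth_comparison, "depth_comparison")
})

test_that("staged tuning recovers on-grid truth exactly in the noiseless limit", {
  ph <- phantom_spec()
  truth <- beam_config(6.26, 0.15, 0.20, 0)
  k0 <- dose_model_constants(kappa = 0)
  ref <- generate_reference_scans(truth, ph, constants = k0)
  grids <- list(energy_fwhm = c(0, 0.15, 0.30),
                focal_spot_fwhm = c(0, 0.20, 0.40),
                divergence = c(0, 2, 4))
  a <- run_staged_tuning(ref, 6.26, grids, n_histories = 1e6, phantom = ph,
                         constants = k0)
  expect_equal(a$final_config$energy_fwhm, 0.15)
  expect_equal(a$final_config$focal_spot_fwhm, 0.20)
  expect_equal(a$final_config$divergence, 0)
})

test_that("staged tuning recovers on-grid truth at verification-level statistics", {
  ph <- phantom_spec()
  truth <- beam_config(6.26, 0.15, 0.20, 0)
  ref <- generate_reference_scans(truth, ph)
  grids <- list(energy_fwhm = c(0, 0.15, 0.30),
                focal_spot_fwhm = c(0, 0.20, 0.40),
                divergence = c(0, 2, 4))
  for (s in 1:3) {
    a <- run_staged_tuning(ref, 6.26, grids, n_histories = 1e9,
                           phantom = ph, seed = s)
    expect_equal(a$final_config$energy_fwhm, 0.15)
    expect_equal(a$final_config$focal_spot_fwhm, 0.20)
    expect_equal(a$final_config$divergence, 0)
  }
})

test_that("zero-noise self-match gives gamma zero at every reference point", {
  ph <- tiny_phantom()
  truth <- beam_config(6.0, 0.15, 0.15, 2)
  k0 <- dose_model_constants(kappa = 0)
  # scan depths on bin centres so the reference and the extracted curve align
  ref <- generate_reference_scans(truth, ph, scan_depths = c(1.5, 5.1, 9.9),
                                  constants = k0)
  g <- generate_dose_grid(truth, ph, 1e6, seed = 1, constants = k0)
  res <- gamma_curve(ref$pdd, extract_pdd(g), gamma_criteria(1, 1))
  expect_true(all(res$gamma_values < 1e-9))
  for (p in ref$profiles) {
    res <- gamma_curve(p$curve, extract_profile(g, p$depth), gamma_criteria(1, 1))
    expect_true(all(res$gamma_values < 1e-9))
  }
})

test_that("energy sweeps validate the ladder and keep criteria nesting row-wise", {
  ph <- tiny_phantom()
  truth <- beam_config(6.0, 0, 0, 0)
  ref <- generate_reference_scans(truth, ph, scan_depths = c(1.5, 5.1),
                                  constants = dose_model_constants())
  expect_error(run_energy_sweep(ref, 6.0, history_ladder = c(1e6, 2e6)),
               "3 rungs")
  trends <- run_energy_sweep(ref, c(matched = 6.0, low = 5.1),
                             history_ladder = c(1e6, 4e6, 1.6e7),
                             phantom = ph, seed = 3)
  expect_length(trends, 2)
  for (tr in trends) {
    expect_s3_class(tr, "trend_record")
    expect_true(all(tr$rows$rate_3_3 >= tr$rows$rate_2_2))
    expect_true(all(tr$rows$rate_2_2 >= tr$rows$rate_1_1))
    expect_true(all(diff(tr$rows$avg_uncertainty) < 0))
  }
})

test_that("matched-config comparison at huge statistics passes 3%/3 mm fully", {
  ph <- phantom_spec()
  truth <- beam_config(6.26, 0.15, 0.15, 3)
  ref <- generate_reference_scans(truth, ph)
  g <- generate_dose_grid(truth, ph, 1e9, seed = 4)
  expect_equal(gamma_curve(ref$pdd, extract_pdd(g),
                           gamma_criteria(3, 3))$passing_rate, 100)
  pr <- ref$profiles[[3]]
  expect_equal(gamma_curve(pr$curve, extract_profile(g, pr$depth),
                           gamma_criteria(3, 3))$passing_rate, 100)
})
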