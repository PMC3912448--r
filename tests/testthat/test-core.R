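# Hand-evaluated reference values for the individual flux equations (pure
# substitution into the linear/exponential forms) use 1e-9 relative
# tolerance; values chained through the whole model use 1e-3.

test_that("leaf proportion and leaf area index follow the compensation curves", {
  expect_equal(proportion_leaf(0), 0.60, tolerance = 1e-9)
  expect_equal(proportion_leaf(1), 0.84, tolerance = 1e-9)
  expect_equal(proportion_leaf(0.5), 0.72, tolerance = 1e-9)
  expect_error(proportion_leaf(1.2), "gi")
  expect_error(proportion_leaf(-0.1), "gi")

  expect_equal(leaf_area_index(0), 1 - 0.015, tolerance = 1e-9)
  expect_equal(leaf_area_index(0.7),
               1.28 - 0.015 * exp(3.22), tolerance = 1e-9)
  # raw curve is -0.092 at gi = 1; a leaf area cannot be negative
  expect_identical(leaf_area_index(1), 0)
  expect_error(leaf_area_index(2), "gi")

  # fitted-intercept form of the alternative set
  k2 <- snap_coefficients("table2-mc")
  expect_equal(leaf_area_index(0, k2), 1.15 - 0.015, tolerance = 1e-9)
})

test_that("production terms match hand evaluation and refuse extrapolation", {
  expect_equal(adjusted_whc(25), 1.1425, tolerance = 1e-9)
  expect_equal(adjusted_whc(44), 1.0, tolerance = 1e-9)
  expect_equal(adjusted_whc(100), 0.58, tolerance = 1e-9)
  expect_error(adjusted_whc(101), "sand_pct")

  expect_equal(anpp_max(450, 25), 350.5 * 1.1425, tolerance = 1e-9)
  expect_equal(anpp_max(721, 51), 547.788, tolerance = 1e-3)
  expect_error(anpp_max(30, 25), "rainfall below model support")

  expect_equal(anpp_est(450, 25, 0), 350.5 * 1.1425 * 0.985,
               tolerance = 1e-9)
  expect_equal(anpp_est(721, 51, 0.32), 582.096, tolerance = 1e-3)
  expect_identical(anpp_est(450, 25, 1), 0)

  expect_equal(bnpp_est(450), 917.4 - 0.763 * 450, tolerance = 1e-9)
  expect_equal(bnpp_est(721), 367.277, tolerance = 1e-3)
  expect_error(bnpp_est(1210), "belowground-production support")
})

test_that("soil carbon input fluxes follow the lignin+cellulose accounting", {
  # full grazing consumption or no lignin means no plant-derived carbon
  # from shoots; complete fire leaves only the root term
  expect_equal(plant_derived_soc(500, 300, gi = 0, fire = 1, ligcell = 0.3),
               0.45 * 0.35 * 300, tolerance = 1e-9)
  expect_equal(plant_derived_soc(500, 0, gi = 0.2, fire = 0, ligcell = 1e-12),
               0, tolerance = 1e-9)
  expect_equal(
    plant_derived_soc(582.096, 367.277, 0.32, 4 / 9, 0.341),
    98.37, tolerance = 1e-3)
  expect_error(plant_derived_soc(500, 300, 0, 0, 0.96),
               "root_ligcell_offset")

  expect_identical(dung_derived_soc(582.096, 0, 0.341), 0)
  expect_equal(dung_derived_soc(582.096, 0.32, 0.341), 28.58,
               tolerance = 1e-3)
  expect_equal(dung_derived_soc(100, 1, 0.3), 13.5, tolerance = 1e-9)
})

test_that("wet days and microbial respiration are clamped at their zeros", {
  expect_equal(wetdays(0.025 / 0.00044), 0, tolerance = 1e-9)
  expect_identical(wetdays(40), 0)  # below the regression root
  expect_equal(wetdays(721), 70.138, tolerance = 1e-3)
  expect_equal(wetdays(472), 43.85, tolerance = 1e-3)
  expect_lte(wetdays(5000), 240)  # season length cap

  expect_equal(microbial_respiration(0.579 / 0.00044, 51, 70.14), 0,
               tolerance = 1e-9)
  expect_equal(microbial_respiration(6139, 51, 70.138), 127.0,
               tolerance = 1e-3)
  expect_identical(microbial_respiration(5000, 51, 0), 0)
  # the clamp is what distinguishes transient from closed-form use
  expect_identical(microbial_respiration(100, 51, 70), 0)
  expect_lt(microbial_respiration(100, 51, 70, clamp = FALSE), 0)
})

test_that("the annual flux identity holds exactly for random states", {
  set.seed(71)
  for (i in 1:50) {
    site <- generate_synthetic_sites(1)[[1]]
    soc <- runif(1, 0, 20000)
    fl <- snap_fluxes(site, soc)
    expect_identical(fl$delta_soc, fl$pdsoc + fl$ddsoc - fl$mresp)
    expect_gte(fl$lai, 0)
    expect_gte(fl$pdsoc, 0)
    expect_gte(fl$ddsoc, 0)
    expect_gte(fl$wetdays, 0)
  }
})

test_that("grazing compensation produces the hump and the collapse", {
  gi <- seq(0, 0.6, by = 0.01)
  ratio <- anpp_est(450, 25, gi) / anpp_max(450, 25)
  expect_true(any(ratio > 1))  # overcompensation at intermediate grazing
  expect_lt(anpp_est(450, 25, 0.98) / anpp_max(450, 25), 0.1)
  expect_identical(anpp_est(450, 25, 1), 0)

  # LAI declines monotonically beyond the compensation range
  lai <- leaf_area_index(seq(0.6, 1, by = 0.005))
  expect_true(all(diff(lai) <= 0))
})

test_that("input fluxes scale linearly in the carbon fraction", {
  k <- snap_coefficients()
  k2 <- k
  k2$value[k2$name == "carbon_frac"] <- 0.9
  pd1 <- plant_derived_soc(500, 300, 0.3, 0.2, 0.34, k)
  pd2 <- plant_derived_soc(500, 300, 0.3, 0.2, 0.34, k2)
  expect_equal(pd2, 2 * pd1, tolerance = 1e-12)
  dd1 <- dung_derived_soc(500, 0.3, 0.34, k)
  dd2 <- dung_derived_soc(500, 0.3, 0.34, k2)
  expect_equal(dd2, 2 * dd1, tolerance = 1e-12)
})

test_that("site constructors validate their domains field by field", {
  expect_error(site_conditions(-5, 0.3, 0.2, 0.3, 50), "rain")
  expect_error(site_conditions(500, 1.2, 0.2, 0.3, 50), "gi")
  expect_error(site_conditions(500, 0.3, -0.1, 0.3, 50), "fire")
  expect_error(site_conditions(500, 0.3, 0.2, 0, 50), "ligcell")
  expect_error(site_conditions(500, 0.3, 0.2, 1, 50), "ligcell")
  expect_error(site_conditions(500, 0.3, 0.2, 0.3, 101), "sand_pct")
  expect_error(site_conditions(500, 0.3, 0.2, 0.3, 50, se_gi = -1), "se_gi")
})

test_that("site tables round-trip through CSV", {
  sites <- list(balanites(), barafu())
  path <- withr::local_tempfile(fileext = ".csv")
  write_sites(sites, path)
  back <- read_sites(path)
  expect_length(back, 2)
  expect_equal(back[[1]]$rain, 721)
  expect_equal(back[[2]]$gi, 0.65)
  expect_equal(back[[1]]$se_rain, 86)
  expect_identical(back[[2]]$name, "Barafu")
})
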