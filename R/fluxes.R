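#' @title Annual carbon-flux equations of the SNAP model
#' @description
#' The model tracks stable (lignin + cellulose) carbon through one annual
#' wet/dry cycle. Grazing removes biomass but shifts allocation from stem to
#' leaf, so leaf area -- and with it carbon assimilation -- is maintained up
#' to high grazing intensities (compensation). Inputs to soil organic carbon
#' (SOC) come from decomposing plant tissue and from dung; the only loss
#' from the stable pool is microbial respiration on days the soil is moist
#' enough for microbes to be active.
#'
#' All areal quantities are g/m^2; SOC is integrated to 40 cm depth.
#' @name snap-fluxes
NULL

#' Proportion of aboveground biomass in leaves
#'
#' Linear increase with grazing intensity: grazed swards trade stem for
#' leaf, raising the leaf fraction from 0.6 (ungrazed) to 0.84 at complete
#' grazing.
#'
#' @param gi grazing intensity, proportion in \[0, 1\] (vectorised).
#' @param coeffs a [snap_coefficients()] set.
#' @return proportion of biomass as leaf.
#' @export
proportion_leaf <- function(gi, coeffs = snap_coefficients()) {
  .check_vec(gi, "gi", 0, 1)
  k <- .coef_vec(coeffs)
  unname(k["pl_intercept"] + k["pl_slope"] * gi)
}

#' Leaf area index under grazing
#'
#' The compensation response: LAI is near 1 and roughly flat across low to
#' intermediate grazing, then collapses as grazing off-take outruns the
#' plants' ability to trade stem for leaf. Two parameterisations are
#' supported, selected by the coefficient set: the leaf-proportion ratio
#' form `P_L / pl_intercept - b1 * exp(b2 * gi)` (default) and the directly
#' fitted intercept form `b0 - b1 * exp(b2 * gi)`. The raw curve goes
#' negative as `gi` approaches 1; a leaf area cannot be negative, so the
#' result is clamped at 0.
#'
#' @inheritParams proportion_leaf
#' @return dimensionless LAI, >= 0.
#' @export
leaf_area_index <- function(gi, coeffs = snap_coefficients()) {
  .check_vec(gi, "gi", 0, 1)
  k <- .coef_vec(coeffs)
  unname(pmax(0, .lai_raw(gi, k)))
}

.lai_raw <- function(gi, k) {
  b0 <- if (k["use_lai_b0"] > 0) k["lai_b0"] else
    (k["pl_intercept"] + k["pl_slope"] * gi) / k["pl_intercept"]
  b0 - k["lai_b1"] * exp(k["lai_b2"] * gi)
}

#' Water-holding-capacity adjustment for soil texture
#'
#' Dimensionless coefficient scaling potential aboveground production:
#' sandy soils hold less water, so production at a given rainfall falls
#' with sand content. Unity near 44% sand for the default set.
#'
#' @param sand_pct soil sand content, percent in \[0, 100\] (vectorised).
#' @inheritParams proportion_leaf
#' @export
adjusted_whc <- function(sand_pct, coeffs = snap_coefficients()) {
  .check_vec(sand_pct, "sand_pct", 0, 100)
  k <- .coef_vec(coeffs)
  unname(k["awhc_intercept"] + k["awhc_slope"] * sand_pct)
}

#' Potential (ungrazed) aboveground production
#'
#' Linear in rainfall, scaled by the texture adjustment [adjusted_whc()].
#' The regression has a positive-production root near 33 mm/yr; rainfall at
#' or below it is refused rather than extrapolated.
#'
#' @param rain mean annual rainfall, mm/yr (vectorised).
#' @inheritParams adjusted_whc
#' @return g m^-2 yr^-1.
#' @export
anpp_max <- function(rain, sand_pct, coeffs = snap_coefficients()) {
  .check_vec(sand_pct, "sand_pct", 0, 100)
  k <- .coef_vec(coeffs)
  root <- -k["anpp_intercept"] / k["anpp_slope"]
  if (any(rain <= root))
    stop(sprintf("rainfall below model support (rain must exceed %.1f mm/yr)",
                 root), call. = FALSE)
  unname((k["anpp_slope"] * rain + k["anpp_intercept"]) *
           (k["awhc_intercept"] + k["awhc_slope"] * sand_pct))
}

#' Grazing-modified aboveground production
#'
#' `anpp_est = LAI * anpp_max`. Because of compensation this can exceed the
#' ungrazed potential at low to intermediate grazing intensities, and it
#' approaches 0 as grazing intensity approaches 1.
#'
#' @inheritParams anpp_max
#' @inheritParams proportion_leaf
#' @return g m^-2 yr^-1.
#' @export
anpp_est <- function(rain, sand_pct, gi, coeffs = snap_coefficients()) {
  leaf_area_index(gi, coeffs) * anpp_max(rain, sand_pct, coeffs)
}

#' Belowground production
#'
#' Declines linearly with rainfall (wetter tropical grasslands allocate
#' less to roots). Rainfall beyond the zero root (~1202 mm/yr for the
#' default set) is refused rather than extrapolated to negative production.
#'
#' @inheritParams anpp_max
#' @return g m^-2 yr^-1.
#' @export
bnpp_est <- function(rain, coeffs = snap_coefficients()) {
  k <- .coef_vec(coeffs)
  root <- -k["bnpp_intercept"] / k["bnpp_slope"]
  if (any(rain >= root))
    stop(sprintf(
      "rainfall outside belowground-production support (rain must be below %.1f mm/yr)",
      root), call. = FALSE)
  unname(k["bnpp_intercept"] + k["bnpp_slope"] * rain)
}

#' Plant-derived input of stable carbon to soil
#'
#' The carbon fraction of lignin + cellulose in roots, plus that in the
#' aboveground biomass neither consumed by grazers nor burned. Fire can
#' only burn what grazers left, hence the `(1 - gi) * (1 - fire)` product.
#' Root tissue is assumed 5 percentage points richer in lignin + cellulose
#' than shoots.
#'
#' @param anpp,bnpp above-/belowground production, g m^-2 yr^-1.
#' @param ligcell lignin + cellulose fraction of aboveground biomass.
#' @param fire fire frequency, proportion of years burning.
#' @inheritParams proportion_leaf
#' @return gC m^-2 yr^-1.
#' @export
plant_derived_soc <- function(anpp, bnpp, gi, fire, ligcell,
                              coeffs = snap_coefficients()) {
  .check_vec(gi, "gi", 0, 1)
  .check_vec(fire, "fire", 0, 1)
  .check_vec(ligcell, "ligcell", 0, 1, open_upper = TRUE)
  k <- .coef_vec(coeffs)
  if (any(ligcell + k["root_ligcell_offset"] >= 1))
    stop("ligcell + root_ligcell_offset must stay below 1", call. = FALSE)
  unname(k["carbon_frac"] *
           (ligcell * anpp * (1 - gi) * (1 - fire) +
              (ligcell + k["root_ligcell_offset"]) * bnpp))
}

#' Dung-derived input of stable carbon to soil
#'
#' The lignin + cellulose fraction of the biomass consumed by grazers,
#' returned to the soil as dung (incorporated by termites and dung
#' beetles). Zero when nothing is grazed.
#'
#' @inheritParams plant_derived_soc
#' @return gC m^-2 yr^-1.
#' @export
dung_derived_soc <- function(anpp, gi, ligcell,
                             coeffs = snap_coefficients()) {
  .check_vec(gi, "gi", 0, 1)
  .check_vec(ligcell, "ligcell", 0, 1, open_upper = TRUE)
  k <- .coef_vec(coeffs)
  unname(ligcell * k["carbon_frac"] * gi * anpp)
}

#' Microbially active days per year
#'
#' The fraction of the 240-day wet season in which soil moisture exceeds
#' the 10% gravimetric threshold for microbial activity, regressed on
#' annual rainfall. The regression goes negative at very low rainfall;
#' the result is clamped to \[0, season_days\].
#'
#' @inheritParams anpp_max
#' @return days per year.
#' @export
wetdays <- function(rain, coeffs = snap_coefficients()) {
  .check_vec(rain, "rain", 0, open_lower = TRUE)
  k <- .coef_vec(coeffs)
  raw <- (k["wet_slope"] * rain + k["wet_intercept"]) * k["season_days"]
  unname(pmin(pmax(raw, 0), k["season_days"]))
}

#' Annual microbial respiration loss from the SOC stock
#'
#' Daily maximum respiration rate is linear in the SOC stock; it is scaled
#' by a sand-access factor (microbes reach organic matter more easily in
#' coarse soils) and by the number of microbially active days. The linear
#' rate is negative for small stocks (below ~1316 gC/m^2 with default
#' coefficients); by default it is clamped at 0 so that respiration can
#' never create carbon. `clamp = FALSE` evaluates the regression as
#' printed, which is the form the closed-form equilibrium inverts.
#'
#' @param soc SOC stock, gC/m^2 to 40 cm (vectorised).
#' @param wetdays microbially active days per year (see [wetdays()]).
#' @param clamp clamp the daily rate at 0 for low stocks (default `TRUE`).
#' @inheritParams adjusted_whc
#' @return gC m^-2 yr^-1.
#' @export
microbial_respiration <- function(soc, sand_pct, wetdays,
                                  coeffs = snap_coefficients(),
                                  clamp = TRUE) {
  .check_vec(soc, "soc", 0)
  .check_vec(sand_pct, "sand_pct", 0, 100)
  .check_vec(wetdays, "wetdays", 0)
  k <- .coef_vec(coeffs)
  rate <- k["mresp_slope"] * soc + k["mresp_intercept"]
  if (clamp) rate <- pmax(rate, 0)
  unname(wetdays * (k["sand_access_base"] +
                      k["sand_access_span"] * sand_pct / 100) * rate)
}

#' One annual evaluation of every model flux
#'
#' Evaluates the full flux chain for a site at a given SOC state and
#' returns the intermediate quantities as a `snap_fluxes` object. The net
#' annual SOC change is `delta_soc = pdsoc + ddsoc - mresp`, exactly.
#'
#' @param site a [site_conditions()] object.
#' @param soc current SOC stock, gC/m^2 to 40 cm.
#' @param clamp_resp clamp the respiration rate at 0 for low stocks.
#' @inheritParams proportion_leaf
#' @return a list of class `snap_fluxes` with elements `p_leaf, lai,
#'   anpp_max, anpp_est, bnpp_est, pdsoc, ddsoc, wetdays, mresp,
#'   delta_soc`.
#' @export
snap_fluxes <- function(site, soc, coeffs = snap_coefficients(),
                        clamp_resp = TRUE) {
  stopifnot(inherits(site, "snap_site"))
  .check_num(soc, "soc", 0)
  am <- anpp_max(site$rain, site$sand_pct, coeffs)
  ae <- anpp_est(site$rain, site$sand_pct, site$gi, coeffs)
  be <- bnpp_est(site$rain, coeffs)
  pd <- plant_derived_soc(ae, be, site$gi, site$fire, site$ligcell, coeffs)
  dd <- dung_derived_soc(ae, site$gi, site$ligcell, coeffs)
  wd <- wetdays(site$rain, coeffs)
  mr <- microbial_respiration(soc, site$sand_pct, wd, coeffs,
                              clamp = clamp_resp)
  structure(
    list(p_leaf = proportion_leaf(site$gi, coeffs),
         lai = leaf_area_index(site$gi, coeffs),
         anpp_max = am, anpp_est = ae, bnpp_est = be,
         pdsoc = pd, ddsoc = dd, wetdays = wd, mresp = mr,
         delta_soc = pd + dd - mr),
    class = "snap_fluxes"
  )
}

#' @export
print.snap_fluxes <- function(x, ...) {
  cat("SNAP annual fluxes (g/m^2/yr; LAI and proportions dimensionless):\n")
  v <- unlist(x)
  for (n in names(v)) cat(sprintf("  %-9s %10.3f\n", n, v[[n]]))
  invisible(x)
}

#' @export
as.data.frame.snap_fluxes <- function(x, ...) {
  as.data.frame(unclass(x), stringsAsFactors = FALSE)
}

# Vectorised whole-model evaluator used by grids, Monte Carlo and
# sensitivity sweeps. No range errors: cells outside the model's validity
# envelope come back NaN, with clamp events flagged. `k` is a named
# coefficient vector so that perturbed draws can be passed directly.
.snap_eval <- function(rain, gi, fire, ligcell, sand_pct, k) {
  n <- max(length(rain), length(gi), length(fire), length(ligcell),
           length(sand_pct))
  rain <- rep_len(rain, n); gi <- rep_len(gi, n); fire <- rep_len(fire, n)
  ligcell <- rep_len(ligcell, n); sand_pct <- rep_len(sand_pct, n)

  lai_raw <- .lai_raw(gi, k)
  lai <- pmax(0, lai_raw)
  am <- (k[["anpp_slope"]] * rain + k[["anpp_intercept"]]) *
    (k[["awhc_intercept"]] + k[["awhc_slope"]] * sand_pct)
  ae <- lai * am
  be <- k[["bnpp_intercept"]] + k[["bnpp_slope"]] * rain
  pd <- k[["carbon_frac"]] *
    (ligcell * ae * (1 - gi) * (1 - fire) +
       (ligcell + k[["root_ligcell_offset"]]) * be)
  dd <- ligcell * k[["carbon_frac"]] * gi * ae
  wd_raw <- (k[["wet_slope"]] * rain + k[["wet_intercept"]]) *
    k[["season_days"]]
  wd <- pmin(pmax(wd_raw, 0), k[["season_days"]])
  sfac <- k[["sand_access_base"]] + k[["sand_access_span"]] * sand_pct / 100
  soc_eq <- (pd + dd - wd * sfac * k[["mresp_intercept"]]) /
    (k[["mresp_slope"]] * wd * sfac)

  invalid <- !is.finite(rain) | rain <= 0 |
    gi < 0 | gi > 1 | fire < 0 | fire > 1 |
    ligcell <= 0 | ligcell + k[["root_ligcell_offset"]] >= 1 |
    sand_pct < 0 | sand_pct > 100 |
    am <= 0 | be < 0 | wd <= 0 |
    k[["mresp_slope"]] <= 0 | !is.finite(soc_eq) | soc_eq <= 0
  soc_eq[invalid] <- NaN

  list(lai = lai, anpp_max = am, anpp_est = ae, bnpp_est = be,
       pdsoc = pd, ddsoc = dd, wetdays = wd, soc_eq = soc_eq,
       invalid = invalid,
       lai_clamped = lai_raw < 0,
       wetdays_clamped = wd_raw < 0 | wd_raw > k[["season_days"]])
}
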