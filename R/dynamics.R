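#' Net annual change in the SOC stock
#'
#' `delta_soc = pdsoc + ddsoc - mresp` at the given stock. Respiration is
#' clamped at 0 below the stock at which the linear daily-rate regression
#' crosses zero, so transient simulations can never create carbon through
#' "negative respiration".
#'
#' @param soc current SOC stock, gC/m^2 to 40 cm.
#' @param site a [site_conditions()] object.
#' @param coeffs a [snap_coefficients()] set.
#' @param clamp_resp clamp the respiration rate at 0 (default `TRUE`).
#' @return gC m^-2 yr^-1.
#' @export
delta_soc <- function(soc, site, coeffs = snap_coefficients(),
                      clamp_resp = TRUE) {
  snap_fluxes(site, soc, coeffs, clamp_resp = clamp_resp)$delta_soc
}

#' Closed-form equilibrium SOC stock
#'
#' Setting the annual change to zero and solving the respiration term for
#' the stock gives
#' `SOC_eq = [PDSOC + DDSOC + WETDAYS * 0.579 * sandfactor] /
#'           [0.00044 * WETDAYS * sandfactor]`
#' (default coefficients), i.e. a floor of ~1316 gC/m^2 set by the
#' respiration intercept plus the annual carbon inputs divided by the
#' per-unit-stock respiration loss. The annual map is affine and
#' contracting in the stock, so this fixed point is the global attractor
#' of [simulate_trajectory()].
#'
#' @inheritParams delta_soc
#' @return equilibrium stock, gC/m^2 to 40 cm (strictly positive).
#' @export
soc_equilibrium <- function(site, coeffs = snap_coefficients()) {
  stopifnot(inherits(site, "snap_site"))
  wd <- wetdays(site$rain, coeffs)
  if (wd <= 0)
    stop("no microbially active days; equilibrium undefined", call. = FALSE)
  # validate the envelope with informative errors
  anpp_max(site$rain, site$sand_pct, coeffs)
  bnpp_est(site$rain, coeffs)
  k <- .coef_vec(coeffs)
  ev <- .snap_eval(site$rain, site$gi, site$fire, site$ligcell,
                   site$sand_pct, k)
  if (!is.finite(ev$soc_eq))
    stop("site is outside the model's validity envelope", call. = FALSE)
  ev$soc_eq
}

#' Iterate the annual SOC update from an initial stock
#'
#' Applies `soc[t+1] = max(0, soc[t] + delta_soc(soc[t]))` for up to
#' `years` years, stopping early once `|delta_soc|` falls below `tol`
#' relative to the closed-form equilibrium. The respiration clamp makes
#' the map piecewise affine; above the clamp point it is a contraction, so
#' convergence is geometric.
#'
#' @param soc0 initial stock, gC/m^2 (>= 0).
#' @param years maximum number of annual steps (>= 1).
#' @param tol relative convergence tolerance on the final annual change.
#' @inheritParams delta_soc
#' @return a `snap_trajectory`: a list with `years` (0-based), `soc`,
#'   per-year flux columns, `converged` and `final_soc`.
#' @export
simulate_trajectory <- function(site, soc0, years = 1000,
                                coeffs = snap_coefficients(), tol = 1e-6) {
  stopifnot(inherits(site, "snap_site"))
  .check_num(soc0, "soc0", 0)
  .check_num(years, "years", 1)
  years <- min(as.integer(years), 1e5L)
  eq <- soc_equilibrium(site, coeffs)

  # Input fluxes and the respiration coefficients are constant over the
  # trajectory; only the stock-dependent respiration term changes by year.
  fl0 <- snap_fluxes(site, 0, coeffs)
  k <- .coef_vec(coeffs)
  inputs <- fl0$pdsoc + fl0$ddsoc
  resp_fac <- fl0$wetdays *
    (k[["sand_access_base"]] + k[["sand_access_span"]] * site$sand_pct / 100)

  soc <- numeric(years + 1)
  mr <- dl <- numeric(years)
  soc[1] <- soc0
  converged <- FALSE
  t_used <- years
  for (t in seq_len(years)) {
    mr[t] <- resp_fac *
      max(0, k[["mresp_slope"]] * soc[t] + k[["mresp_intercept"]])
    dl[t] <- inputs - mr[t]
    soc[t + 1] <- max(0, soc[t] + dl[t])
    if (abs(dl[t]) < tol * eq) {
      converged <- TRUE
      t_used <- t
      break
    }
  }
  idx <- seq_len(t_used)
  pd <- rep(fl0$pdsoc, t_used)
  dd <- rep(fl0$ddsoc, t_used)
  structure(
    list(years = 0:t_used, soc = soc[seq_len(t_used + 1)],
         pdsoc = pd[idx], ddsoc = dd[idx], mresp = mr[idx],
         delta_soc = dl[idx],
         converged = converged, final_soc = soc[t_used + 1],
         equilibrium = eq, site = site),
    class = "snap_trajectory"
  )
}

#' @export
print.snap_trajectory <- function(x, ...) {
  cat(sprintf(
    "SNAP trajectory: %d years, soc0 = %.1f -> final %.1f gC/m^2 (%s; closed-form equilibrium %.1f)\n",
    length(x$years) - 1, x$soc[1], x$final_soc,
    if (x$converged) "converged" else "not converged", x$equilibrium))
  invisible(x)
}

#' @export
as.data.frame.snap_trajectory <- function(x, ...) {
  n <- length(x$years)
  data.frame(year = x$years,
             soc = x$soc,
             pdsoc = c(x$pdsoc, NA),
             ddsoc = c(x$ddsoc, NA),
             mresp = c(x$mresp, NA),
             delta_soc = c(x$delta_soc, NA))[seq_len(n), ]
}

#' @export
plot.snap_trajectory <- function(x, ...) {
  graphics::plot(x$years, x$soc, type = "l", xlab = "year",
                 ylab = expression(SOC ~ (gC ~ m^-2 ~ to ~ 40 ~ cm)), ...)
  graphics::abline(h = x$equilibrium, lty = 2, col = "grey40")
  invisible(x)
}
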