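#' Load the packaged eight-site Serengeti exclosure-experiment table
#'
#' The package ships the grazed-plot site means of the 9-year, eight-site
#' grazing exclosure experiment (grazing intensity, lignin + cellulose,
#' rainfall, fire counts over the 2000-2008 monitoring window, soil
#' composition, soil %C and bulk density). This is the model's validation
#' data set: every cell used by the model is transcribed once and guarded
#' by a checksum.
#'
#' Percentages are converted to proportions and fire counts to an annual
#' frequency (`fires / 9`).
#'
#' @return a list of 8 `snap_experiment_site` objects. Each extends
#'   [site_conditions()] with `fires_2000_2008`, `soil_c_pct`,
#'   `bulk_density`, `soil_n_pct`, `soil_p_permil`, `silt_pct`, `clay_pct`.
#' @export
load_experiment_sites <- function() {
  path <- system.file("extdata", "serengeti_sites.csv", package = "snapsoc",
                      mustWork = TRUE)
  tab <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  checksum <- sum(unlist(tab[vapply(tab, is.numeric, TRUE)]))
  if (abs(checksum - 10363.57) > 1e-6)
    stop("fixture checksum mismatch: serengeti_sites.csv has been altered",
         call. = FALSE)
  if (nrow(tab) != 8)
    stop("fixture checksum mismatch: expected 8 sites", call. = FALSE)
  lapply(seq_len(nrow(tab)), function(i) {
    s <- site_conditions(
      rain = tab$rain_mm[i],
      gi = tab$gi_pct[i] / 100,
      fire = tab$fires_2000_2008[i] / 9,
      ligcell = tab$ligcell_pct[i] / 100,
      sand_pct = tab$sand_pct[i],
      name = tab$name[i],
      se_gi = tab$gi_se_pct[i] / 100,
      se_ligcell = tab$ligcell_se_pct[i] / 100,
      se_rain = tab$rain_se_mm[i]
    )
    s$fires_2000_2008 <- tab$fires_2000_2008[i]
    s$soil_c_pct <- tab$soil_c_pct[i]
    s$bulk_density <- tab$bulk_density[i]
    s$soil_n_pct <- tab$soil_n_pct[i]
    s$soil_p_permil <- tab$soil_p_permil[i]
    s$silt_pct <- tab$silt_pct[i]
    s$clay_pct <- tab$clay_pct[i]
    class(s) <- c("snap_experiment_site", "snap_site")
    s
  })
}

#' Observed SOC stock from soil %C and bulk density
#'
#' `(soil_c_pct / 100) * bulk_density * depth * 1e4`, in gC/m^2 -- the
#' product formula used to turn Walkley-Black carbon content and core bulk
#' density into an areal stock over the sampled depth.
#'
#' @param soil_c_pct soil organic carbon content, percent by mass.
#' @param bulk_density g/cm^3.
#' @param depth sampling depth, cm (default 40).
#' @return gC/m^2 (vectorised).
#' @export
observed_soc <- function(soil_c_pct, bulk_density, depth = 40) {
  .check_vec(soil_c_pct, "soil_c_pct", 0)
  .check_vec(bulk_density, "bulk_density", 0, open_lower = TRUE)
  .check_vec(depth, "depth", 0, open_lower = TRUE)
  soil_c_pct / 100 * bulk_density * depth * 1e4
}

#' Site-level predicted-vs-observed validation regression
#'
#' Predicts the equilibrium SOC stock for each of the eight experimental
#' sites, reconstructs the observed stock from soil %C and bulk density to
#' 40 cm, and fits the ordinary least-squares regression
#' `observed ~ predicted`. The hypotheses slope = 1 and intercept = 0 are
#' evaluated with two-sided z-tests on the OLS coefficient standard
#' errors. Optionally attaches a per-site Monte Carlo s.e.m. on the
#' predictions.
#'
#' @param coeffs a [snap_coefficients()] set (default `"text-equations"`).
#' @param mc also run [monte_carlo_soc_eq()] per site (default `FALSE`).
#' @param n_draws,seed Monte Carlo settings when `mc = TRUE`.
#' @param sites the validation sites; defaults to the packaged fixture.
#' @return a `snap_validation` object: list with `sites` (per-site data
#'   frame: `name, predicted, observed, residual`, plus `mc_sem` when
#'   requested), `slope`, `slope_se`, `intercept`, `intercept_se`,
#'   `r_squared`, `z_slope`, `p_slope`, `z_intercept`, `p_intercept`, `n`.
#' @export
validate_site_level <- function(coeffs = snap_coefficients(), mc = FALSE,
                                n_draws = 100, seed = NULL,
                                sites = load_experiment_sites()) {
  pred <- vapply(sites, soc_equilibrium, 0, coeffs = coeffs)
  obs <- vapply(sites, function(s) {
    if (is.null(s$soil_c_pct) || is.null(s$bulk_density))
      stop("validation sites need soil_c_pct and bulk_density", call. = FALSE)
    observed_soc(s$soil_c_pct, s$bulk_density)
  }, 0)
  if (stats::sd(pred) == 0)
    stop("degenerate regression: predictions have zero variance",
         call. = FALSE)
  fit <- stats::lm(obs ~ pred)
  sm <- summary(fit)
  slope <- sm$coefficients["pred", "Estimate"]
  slope_se <- sm$coefficients["pred", "Std. Error"]
  intercept <- sm$coefficients["(Intercept)", "Estimate"]
  intercept_se <- sm$coefficients["(Intercept)", "Std. Error"]
  z_slope <- (slope - 1) / slope_se
  z_intercept <- intercept / intercept_se
  per_site <- data.frame(
    name = vapply(sites, function(s) s$name, ""),
    predicted = pred, observed = obs,
    residual = stats::residuals(fit),
    stringsAsFactors = FALSE, row.names = NULL)
  if (mc) {
    per_site$mc_sem <- vapply(seq_along(sites), function(i) {
      monte_carlo_soc_eq(sites[[i]], coeffs, n_draws = n_draws,
                         seed = if (is.null(seed)) NULL else seed + i
                         )$sem_soc_eq
    }, 0)
  }
  structure(
    list(sites = per_site,
         slope = slope, slope_se = slope_se,
         intercept = intercept, intercept_se = intercept_se,
         r_squared = sm$r.squared,
         z_slope = z_slope,
         p_slope = 2 * stats::pnorm(-abs(z_slope)),
         z_intercept = z_intercept,
         p_intercept = 2 * stats::pnorm(-abs(z_intercept)),
         n = length(sites),
         coefficient_set = attr(coeffs, "set") %||% "custom"),
    class = "snap_validation"
  )
}

#' @export
print.snap_validation <- function(x, ...) {
  cat(sprintf("SNAP site-level validation (n = %d, coefficients: %s)\n",
              x$n, x$coefficient_set))
  cat(sprintf("  observed = %.3f (+/- %.3f) * predicted + %.1f (+/- %.1f)\n",
              x$slope, x$slope_se, x$intercept, x$intercept_se))
  cat(sprintf("  R^2 = %.3f\n", x$r_squared))
  cat(sprintf("  z(slope = 1) = %.2f, p = %.3f; z(intercept = 0) = %.2f, p = %.3f\n",
              x$z_slope, x$p_slope, x$z_intercept, x$p_intercept))
  print.data.frame(x$sites, row.names = FALSE, digits = 5)
  invisible(x)
}

#' @export
plot.snap_validation <- function(x, ...) {
  rng <- range(x$sites$predicted, x$sites$observed)
  graphics::plot(x$sites$predicted, x$sites$observed, xlim = rng, ylim = rng,
                 xlab = expression(predicted ~ SOC[eq] ~ (gC ~ m^-2)),
                 ylab = expression(observed ~ SOC ~ (gC ~ m^-2)), ...)
  graphics::abline(0, 1, lty = 2, col = "grey50")
  graphics::abline(x$intercept, x$slope)
  invisible(x)
}
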