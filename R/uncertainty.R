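#' Monte Carlo propagation of parameter errors into equilibrium SOC
#'
#' Each draw perturbs every registry coefficient with a nonzero standard
#' error -- and, when the site carries driver standard errors, the measured
#' drivers (grazing intensity, lignin + cellulose, rainfall) -- by sampling
#' independent normal distributions centred on the stored values. Draws
#' that violate the model's domain (proportions outside \[0, 1\], rainfall
#' outside the production regressions' support, no microbially active days,
#' non-positive equilibrium) are rejected rather than clipped, so that the
#' retained sample is not distorted; the retained count is reported and
#' `retained + rejected = n_draws`.
#'
#' In the leaf-proportion ratio form of the LAI curve the divisor is the
#' drawn leaf intercept itself, so its error largely cancels in the ratio.
#'
#' The reported `sem` is `sd(draws) / sqrt(retained)`, i.e. the standard
#' error of the Monte Carlo mean over `n_draws` repetitions; `cv` is
#' `sd(draws) / mean(draws)` (so `cv = sem * sqrt(retained) / mean`).
#'
#' @param site a [site_conditions()] object (its `se_*` fields supply the
#'   driver errors; they default to 0, i.e. drivers treated as exact).
#' @param coeffs a [snap_coefficients()] set carrying standard errors.
#' @param n_draws number of Monte Carlo draws (>= 2; default 100).
#' @param seed integer seed; the summary is bit-reproducible for a fixed
#'   seed. The caller's RNG state is preserved.
#' @param perturb_coefficients,perturb_drivers toggles for the two error
#'   sources (both `TRUE` by default).
#' @return a `snap_mc` object: list with `site`, `mean_soc_eq`,
#'   `sem_soc_eq`, `cv`, `n_draws`, `retained`, `rejected`, `seed`,
#'   `draws`.
#' @export
monte_carlo_soc_eq <- function(site, coeffs = snap_coefficients(),
                               n_draws = 100, seed = NULL,
                               perturb_coefficients = TRUE,
                               perturb_drivers = TRUE) {
  stopifnot(inherits(site, "snap_site"))
  .check_num(n_draws, "n_draws", 2)
  n_draws <- as.integer(n_draws)
  .with_seed(seed, {
    val <- .coef_vec(coeffs)
    se <- .coef_vec(coeffs, "se")
    if (!perturb_coefficients) se[] <- 0
    draws <- rep(NaN, n_draws)
    for (i in seq_len(n_draws)) {
      k <- val + stats::rnorm(length(val)) * se
      k[["use_lai_b0"]] <- val[["use_lai_b0"]]  # structural switch, not sampled
      gi <- site$gi; lig <- site$ligcell; rain <- site$rain
      if (perturb_drivers) {
        gi <- stats::rnorm(1, gi, site$se_gi)
        lig <- stats::rnorm(1, lig, site$se_ligcell)
        rain <- stats::rnorm(1, rain, site$se_rain)
      }
      if (k[["pl_intercept"]] <= 0 || k[["carbon_frac"]] <= 0 ||
          k[["carbon_frac"]] >= 1)
        next
      ev <- .snap_eval(rain, gi, site$fire, lig, site$sand_pct, k)
      draws[i] <- ev$soc_eq
    }
    keep <- draws[is.finite(draws)]
    if (length(keep) < 2)
      stop("parameter errors incompatible with model support", call. = FALSE)
    structure(
      list(site = if (is.na(site$name)) "<unnamed>" else site$name,
           mean_soc_eq = mean(keep),
           sem_soc_eq = stats::sd(keep) / sqrt(length(keep)),
           cv = stats::sd(keep) / mean(keep),
           n_draws = n_draws,
           retained = length(keep),
           rejected = n_draws - length(keep),
           seed = if (is.null(seed)) NA_integer_ else as.integer(seed),
           draws = keep),
      class = "snap_mc"
    )
  })
}

#' @export
print.snap_mc <- function(x, ...) {
  cat(sprintf(
    "SNAP Monte Carlo for %s: SOC_eq = %.1f +/- %.1f (s.e.m.) gC/m^2, cv %.1f%%, %d/%d draws retained\n",
    x$site, x$mean_soc_eq, x$sem_soc_eq, 100 * x$cv, x$retained, x$n_draws))
  invisible(x)
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`
# (NULL = use, and advance, the current RNG state).
.with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has_old) assign(".Random.seed", old, envir = globalenv())
          else rm(".Random.seed", envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  expr
}

#' Default driver levels for the sensitivity analysis
#'
#' Low/medium/high values of the five drivers spanning the conditions of
#' the Serengeti grazing-experiment sites.
#'
#' @return a named list of length-3 numeric vectors (`low, medium, high`)
#'   for `rain`, `fire`, `gi`, `ligcell`, `sand_pct`.
#' @export
snap_sensitivity_levels <- function() {
  list(rain = c(450, 650, 900),
       fire = c(0.25, 0.50, 0.75),
       gi = c(0.25, 0.60, 0.90),
       ligcell = c(0.15, 0.25, 0.35),
       sand_pct = c(25, 45, 70))
}

#' One-at-a-time sensitivity of equilibrium SOC
#'
#' For each focal driver at each of its three levels, the focal value is
#' perturbed by `+perturbation` (default +10%) and the absolute percent
#' change in equilibrium SOC is computed against the unperturbed
#' equilibrium of the same background. Backgrounds are either the full
#' factorial of the other four drivers' levels (default; the spread across
#' backgrounds gives the reported standard error) or their medium levels
#' only. Perturbed proportions that would leave \[0, 1\] are clipped, with
#' a warning.
#'
#' @param coeffs a [snap_coefficients()] set.
#' @param levels a named list as returned by [snap_sensitivity_levels()].
#' @param perturbation fractional perturbation (> 0; default 0.10).
#' @param background `"factorial"` (default) or `"medium"`.
#' @return a `snap_sensitivity` data frame with one row per
#'   (parameter, level): `parameter`, `level`, `base_value`,
#'   `perturbed_value`, `mean_abs_pct_change`, `se_pct_change`,
#'   `n_backgrounds`.
#' @export
sensitivity_analysis <- function(coeffs = snap_coefficients(),
                                 levels = snap_sensitivity_levels(),
                                 perturbation = 0.10,
                                 background = c("factorial", "medium")) {
  background <- match.arg(background)
  .check_num(perturbation, "perturbation", 0, open_lower = TRUE)
  stopifnot(is.list(levels), length(levels) == 5,
            all(lengths(levels) == 3))
  k <- .coef_vec(coeffs)
  lev_names <- c("low", "medium", "high")
  pars <- names(levels)
  clipped <- 0L
  rows <- list()
  for (p in pars) {
    others <- setdiff(pars, p)
    bg <- if (background == "factorial") {
      expand.grid(levels[others], KEEP.OUT.ATTRS = FALSE)
    } else {
      as.data.frame(lapply(levels[others], `[`, 2))
    }
    for (li in 1:3) {
      base_val <- levels[[p]][li]
      pert_val <- base_val * (1 + perturbation)
      if (p %in% c("fire", "gi") && pert_val > 1) {
        pert_val <- 1
        clipped <- clipped + 1L
      }
      args <- bg
      args[[p]] <- base_val
      soc0 <- .snap_eval(args$rain, args$gi, args$fire, args$ligcell,
                         args$sand_pct, k)$soc_eq
      args[[p]] <- pert_val
      soc1 <- .snap_eval(args$rain, args$gi, args$fire, args$ligcell,
                         args$sand_pct, k)$soc_eq
      pct <- abs(soc1 - soc0) / soc0 * 100
      rows[[length(rows) + 1L]] <- data.frame(
        parameter = p, level = lev_names[li],
        base_value = base_val, perturbed_value = pert_val,
        mean_abs_pct_change = mean(pct),
        se_pct_change = if (nrow(bg) > 1)
          stats::sd(pct) / sqrt(length(pct)) else 0,
        n_backgrounds = nrow(bg),
        stringsAsFactors = FALSE)
    }
  }
  if (clipped > 0)
    warning(clipped, " perturbed value(s) clipped to stay within [0, 1]",
            call. = FALSE)
  out <- do.call(rbind, rows)
  structure(out, class = c("snap_sensitivity", "data.frame"),
            perturbation = perturbation, background = background)
}

#' @export
print.snap_sensitivity <- function(x, ...) {
  cat(sprintf(
    "SNAP sensitivity analysis: +%.0f%% perturbation, %s background\n",
    100 * attr(x, "perturbation"), attr(x, "background")))
  print.data.frame(x, row.names = FALSE, digits = 4, ...)
  invisible(x)
}
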