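#' Fit the leaf-area compensation curve to new data
#'
#' Fits `lai = b0 - b1 * exp(b2 * gi)` by nonlinear least squares, the
#' functional form of the grazing-compensation response (flat LAI at low
#' grazing, collapse at high grazing; `b1, b2 > 0`). Exponential-rate fits
#' are sensitive to their starting values, so the fit is multi-started
#' over a grid of rates (`b2` in 1, 3, 5, 8 by default) and the converged
#' fit with the lowest residual sum of squares is kept.
#'
#' @param data a data frame with numeric columns `gi` and `lai`
#'   (>= 6 rows, non-constant `gi`).
#' @param starts optional numeric vector of starting values for `b2`.
#' @return a `snap_lai_fit`: list with `coefficients` (b0, b1, b2), `se`,
#'   `r_squared` (vs the mean-only model), `converged`, `flat_fit`
#'   (constant-response data), `fitted`, `residuals`, `n`.
#' @export
fit_lai_response <- function(data, starts = c(1, 3, 5, 8)) {
  stopifnot(is.data.frame(data), all(c("gi", "lai") %in% names(data)))
  data <- data[stats::complete.cases(data[c("gi", "lai")]), ]
  if (nrow(data) < 6)
    stop("need at least 6 observations for the 3-parameter fit",
         call. = FALSE)
  if (stats::var(data$gi) == 0)
    stop("predictor variance is zero", call. = FALSE)
  tss <- sum((data$lai - mean(data$lai))^2)
  if (tss == 0) {
    # Degenerate constant response: the curve reduces to its intercept.
    return(structure(
      list(coefficients = c(b0 = mean(data$lai), b1 = 0, b2 = 0),
           se = c(b0 = 0, b1 = NA_real_, b2 = NA_real_),
           r_squared = NA_real_, converged = TRUE, flat_fit = TRUE,
           fitted = rep(mean(data$lai), nrow(data)),
           residuals = rep(0, nrow(data)), n = nrow(data)),
      class = "snap_lai_fit"))
  }
  best <- NULL
  for (b2_start in starts) {
    # start b0 at the low-grazing plateau, b1 from the range of the decline
    b0_start <- max(data$lai)
    b1_start <- max(1e-4, (b0_start - min(data$lai)) /
                      exp(b2_start * max(data$gi)))
    fit <- tryCatch(
      minpack.lm::nlsLM(
        lai ~ b0 - b1 * exp(b2 * gi), data = data,
        start = list(b0 = b0_start, b1 = b1_start, b2 = b2_start),
        lower = c(-Inf, 0, 0),
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (!is.null(fit)) {
      rss <- sum(stats::residuals(fit)^2)
      if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
    }
  }
  if (is.null(best))
    stop("leaf-area fit failed to converge from any starting value",
         call. = FALSE)
  fit <- best$fit
  est <- stats::coef(fit)
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) rep(NA_real_, 3))
  r2 <- 1 - best$rss / tss
  structure(
    list(coefficients = c(b0 = unname(est["b0"]), b1 = unname(est["b1"]),
                          b2 = unname(est["b2"])),
         se = c(b0 = unname(se[1]), b1 = unname(se[2]), b2 = unname(se[3])),
         r_squared = r2, converged = TRUE,
         flat_fit = r2 < 1e-6 || est["b1"] < 1e-8,
         fitted = stats::fitted(fit), residuals = stats::residuals(fit),
         n = nrow(data)),
    class = "snap_lai_fit"
  )
}

#' @export
print.snap_lai_fit <- function(x, ...) {
  cat("Leaf-area compensation fit: lai = b0 - b1 * exp(b2 * gi)\n")
  tab <- data.frame(estimate = x$coefficients, se = x$se)
  print(tab, digits = 5)
  cat(sprintf("  R^2 = %.3f, n = %d%s\n",
              x$r_squared, x$n, if (x$flat_fit) " (flat response)" else ""))
  invisible(x)
}

# Mapping from sub-model role to the coefficient-registry slots its
# intercept and slope refill.
.submodel_slots <- list(
  anpp = c("anpp_intercept", "anpp_slope"),
  awhc = c("awhc_intercept", "awhc_slope"),
  bnpp = c("bnpp_intercept", "bnpp_slope"),
  wetdays_prop = c("wet_intercept", "wet_slope"),
  mresp_max = c("mresp_intercept", "mresp_slope"),
  p_leaf = c("pl_intercept", "pl_slope")
)

#' Fit one of the model's linear sub-models to new data
#'
#' Ordinary least squares `y ~ x` for the named sub-model role: potential
#' aboveground production vs rainfall (`"anpp"`), the water-holding
#' capacity adjustment vs sand (`"awhc"`), belowground production vs
#' rainfall (`"bnpp"`), the wet-day proportion vs rainfall
#' (`"wetdays_prop"`), the maximum daily respiration rate vs SOC stock
#' (`"mresp_max"`) or the leaf proportion vs grazing intensity
#' (`"p_leaf"`). The result names the registry slots it refills, so a
#' re-fitted coefficient set plugs straight back into the model via
#' [update_coefficients()].
#'
#' @param data a data frame with numeric columns `x` and `y` (>= 4 rows,
#'   non-constant `x`).
#' @param role sub-model name (see Details).
#' @return a `snap_linear_fit`: list with `role`, `slots`, `intercept`,
#'   `slope`, their standard errors, and `r_squared`.
#' @export
fit_linear_submodel <- function(data, role = names(.submodel_slots)) {
  role <- match.arg(role)
  stopifnot(is.data.frame(data), all(c("x", "y") %in% names(data)))
  data <- data[stats::complete.cases(data[c("x", "y")]), ]
  if (nrow(data) < 4)
    stop("need at least 4 observations for a linear sub-model fit",
         call. = FALSE)
  if (stats::var(data$x) == 0)
    stop("rank-deficient fit: predictor variance is zero", call. = FALSE)
  fit <- stats::lm(y ~ x, data = data)
  sm <- summary(fit)
  structure(
    list(role = role, slots = .submodel_slots[[role]],
         intercept = unname(stats::coef(fit)[1]),
         slope = unname(stats::coef(fit)[2]),
         intercept_se = sm$coefficients[1, "Std. Error"],
         slope_se = sm$coefficients[2, "Std. Error"],
         r_squared = sm$r.squared, n = nrow(data)),
    class = "snap_linear_fit"
  )
}

#' @export
print.snap_linear_fit <- function(x, ...) {
  cat(sprintf("Linear sub-model fit [%s]: y = %.6g + %.6g x (R^2 = %.3f, n = %d)\n",
              x$role, x$intercept, x$slope, x$r_squared, x$n))
  invisible(x)
}

#' Install re-fitted sub-model coefficients into a coefficient set
#'
#' @param coeffs a [snap_coefficients()] set.
#' @param fit a `snap_linear_fit` from [fit_linear_submodel()] or a
#'   `snap_lai_fit` from [fit_lai_response()].
#' @return the updated `snap_coefficients` object (set name suffixed with
#'   `"+refit"`).
#' @export
update_coefficients <- function(coeffs, fit) {
  if (inherits(fit, "snap_linear_fit")) {
    slots <- fit$slots
    vals <- c(fit$intercept, fit$slope)
    ses <- c(fit$intercept_se, fit$slope_se)
  } else if (inherits(fit, "snap_lai_fit")) {
    slots <- c("lai_b0", "lai_b1", "lai_b2")
    vals <- unname(fit$coefficients)
    ses <- ifelse(is.na(fit$se), 0, unname(fit$se))
    coeffs$value[coeffs$name == "use_lai_b0"] <- 1
  } else {
    stop("fit must come from fit_linear_submodel() or fit_lai_response()",
         call. = FALSE)
  }
  i <- match(slots, coeffs$name)
  coeffs$value[i] <- vals
  coeffs$se[i] <- ses
  coeffs$source[i] <- "refit"
  attr(coeffs, "set") <- paste0(attr(coeffs, "set") %||% "custom", "+refit")
  .check_coefficients(coeffs)
  structure(coeffs, class = c("snap_coefficients", "data.frame"))
}

#' Generate random sites within the model's validity envelope
#'
#' Independent uniform draws per driver, for property tests and scenario
#' exploration. Default ranges stay inside the support of the production
#' and wet-day regressions, so every generated site has a well-defined
#' equilibrium.
#'
#' @param n number of sites (>= 0).
#' @param seed integer seed (the caller's RNG state is preserved).
#' @param ranges named list of `c(min, max)` intervals for `rain`, `gi`,
#'   `fire`, `ligcell`, `sand_pct`.
#' @return a list of `n` [site_conditions()] objects.
#' @export
generate_synthetic_sites <- function(n, seed = NULL,
                                     ranges = list(rain = c(100, 1100),
                                                   gi = c(0, 0.95),
                                                   fire = c(0, 1),
                                                   ligcell = c(0.05, 0.5),
                                                   sand_pct = c(0, 100))) {
  .check_num(n, "n", 0)
  need <- c("rain", "gi", "fire", "ligcell", "sand_pct")
  miss <- setdiff(need, names(ranges))
  if (length(miss))
    stop("ranges is missing: ", paste(miss, collapse = ", "), call. = FALSE)
  for (nm in need) {
    r <- ranges[[nm]]
    if (length(r) != 2 || !all(is.finite(r)) || r[1] >= r[2])
      stop("empty or inverted range for ", nm, call. = FALSE)
  }
  if (n == 0) return(list())
  .with_seed(seed, {
    draw <- function(nm) stats::runif(n, ranges[[nm]][1], ranges[[nm]][2])
    rain <- draw("rain"); gi <- draw("gi"); fire <- draw("fire")
    ligcell <- draw("ligcell"); sand <- draw("sand_pct")
    lapply(seq_len(n), function(i) {
      site_conditions(rain = rain[i], gi = gi[i], fire = fire[i],
                      ligcell = ligcell[i], sand_pct = sand[i],
                      name = sprintf("synthetic-%03d", i))
    })
  })
}

#' Generate a synthetic leaf-area response data set
#'
#' Draws grazing intensities uniformly on \[0, 1\] and adds Gaussian noise
#' to the compensation curve `b0 - b1 * exp(b2 * gi)` -- the generating
#' model for the parameter-recovery tests of [fit_lai_response()].
#'
#' @param n number of observations (default 36, the size of a two-season
#'   paired-quadrat campaign).
#' @param b generating coefficients `c(b0, b1, b2)`.
#' @param sigma Gaussian noise standard deviation on LAI (default 0.05).
#' @param gi optional vector of grazing intensities to use instead of
#'   uniform draws.
#' @param seed integer seed (the caller's RNG state is preserved).
#' @return a data frame with columns `gi` and `lai`.
#' @export
generate_lai_response <- function(n = 36, b = c(b0 = 1.15, b1 = 0.015,
                                                b2 = 4.6),
                                  sigma = 0.05, gi = NULL, seed = NULL) {
  .check_num(n, "n", 1)
  .check_num(sigma, "sigma", 0)
  .with_seed(seed, {
    if (is.null(gi)) gi <- stats::runif(n)
    lai <- b[[1]] - b[[2]] * exp(b[[3]] * gi) + stats::rnorm(length(gi), 0, sigma)
    data.frame(gi = gi, lai = lai)
  })
}
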