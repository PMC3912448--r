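#' Coefficient registry for the SNAP model
#'
#' The SNAP model is built from empirical sub-models (leaf allocation,
#' leaf-area response to grazing, production-rainfall and respiration-SOC
#' regressions) whose fitted constants carry standard errors. A
#' `snap_coefficients` object is a small registry holding every such
#' constant as a `(name, value, se, source)` row.
#'
#' Two named sets ship with the package:
#' \describe{
#'   \item{`"text-equations"`}{the canonical deterministic constants as they
#'     appear in the model equations (e.g. leaf intercept 0.6, belowground
#'     production 917.4 - 0.763 * RAIN). Standard errors are attached from
#'     the Monte Carlo parameter table so the set can be used directly for
#'     error propagation. This is the default everywhere.}
#'   \item{`"table2-mc"`}{the Monte Carlo parameter-table variants, which
#'     differ slightly (0.597 vs 0.6, 958.8/-0.82 vs 917.4/-0.763,
#'     1.04/-0.0070 vs 1.33/-0.0075, 0.00043 vs 0.00044) and use the fitted
#'     leaf-area intercept form (B0 = 1.15) rather than the leaf-proportion
#'     ratio form. Kept selectable by name; the two sets are never merged.}
#' }
#'
#' Structural constants (wet-season length, the root lignin+cellulose
#' offset, the sand-access factor of respiration, the 10% gravimetric
#' moisture threshold) have zero standard error.
#'
#' @param set name of a packaged coefficient set, or a path to a registry
#'   file written by [write_coefficients()].
#' @return an object of class `snap_coefficients` (a data frame with columns
#'   `name`, `value`, `se`, `source` and a `set` attribute).
#' @seealso [coef_value()], [read_coefficients()], [update_coefficients()]
#' @examples
#' k <- snap_coefficients()
#' coef_value(k, "pl_slope")
#' @export
snap_coefficients <- function(set = c("text-equations", "table2-mc")) {
  if (length(set) == 1 && file.exists(set)) {
    return(read_coefficients(set))
  }
  set <- match.arg(set)
  tab <- if (set == "text-equations") .coef_text_equations else .coef_table2_mc
  structure(tab, class = c("snap_coefficients", "data.frame"), set = set)
}

.coef_row <- function(name, value, se, source) {
  data.frame(name = name, value = value, se = se, source = source,
             stringsAsFactors = FALSE)
}

.coef_common <- rbind(
  .coef_row("season_days",         240,     0, "structural"),
  .coef_row("root_ligcell_offset", 0.05,    0, "structural"),
  .coef_row("moisture_threshold",  10,      0, "structural"),
  .coef_row("sand_access_base",    0.7,     0, "structural"),
  .coef_row("sand_access_span",    0.3,     0, "structural"),
  .coef_row("carbon_frac",         0.45, 0.02, "tissue-analysis")
)

.coef_text_equations <- rbind(
  .coef_row("pl_intercept",    0.6,     0.061,   "equation"),
  .coef_row("pl_slope",        0.24,    0.023,   "equation"),
  .coef_row("lai_b0",          1.15,    0.027,   "fit"),
  .coef_row("lai_b1",          0.015,   0.0011,  "equation"),
  .coef_row("lai_b2",          4.6,     0.2,     "equation"),
  .coef_row("use_lai_b0",      0,       0,       "structural"),
  .coef_row("anpp_intercept", -27.5,    17.6,    "equation"),
  .coef_row("anpp_slope",      0.84,    0.07,    "equation"),
  .coef_row("awhc_intercept",  1.33,    0.05,    "equation"),
  .coef_row("awhc_slope",     -0.0075,  0.0008,  "equation"),
  .coef_row("bnpp_intercept",  917.4,   165.0,   "equation"),
  .coef_row("bnpp_slope",     -0.763,   0.27,    "equation"),
  .coef_row("wet_intercept",  -0.025,   0.033,   "equation"),
  .coef_row("wet_slope",       0.00044, 0.00006, "equation"),
  .coef_row("mresp_intercept", -0.579,  0.45,    "equation"),
  .coef_row("mresp_slope",     0.00044, 0.00007, "equation"),
  .coef_common
)

.coef_table2_mc <- rbind(
  .coef_row("pl_intercept",    0.597,   0.061,   "mc-table"),
  .coef_row("pl_slope",        0.24,    0.023,   "mc-table"),
  .coef_row("lai_b0",          1.15,    0.027,   "mc-table"),
  .coef_row("lai_b1",          0.015,   0.0011,  "mc-table"),
  .coef_row("lai_b2",          4.6,     0.2,     "mc-table"),
  .coef_row("use_lai_b0",      1,       0,       "structural"),
  .coef_row("anpp_intercept", -27.5,    17.6,    "mc-table"),
  .coef_row("anpp_slope",      0.84,    0.07,    "mc-table"),
  .coef_row("awhc_intercept",  1.04,    0.05,    "mc-table"),
  .coef_row("awhc_slope",     -0.0070,  0.0008,  "mc-table"),
  .coef_row("bnpp_intercept",  958.8,   165.0,   "mc-table"),
  .coef_row("bnpp_slope",     -0.82,    0.27,    "mc-table"),
  .coef_row("wet_intercept",  -0.025,   0.033,   "mc-table"),
  .coef_row("wet_slope",       0.00043, 0.00006, "mc-table"),
  .coef_row("mresp_intercept", -0.58,   0.45,    "mc-table"),
  .coef_row("mresp_slope",     0.00044, 0.00007, "mc-table"),
  .coef_common
)

.check_coefficients <- function(x) {
  stopifnot(is.data.frame(x),
            all(c("name", "value", "se", "source") %in% names(x)))
  if (anyDuplicated(x$name)) stop("duplicate coefficient names", call. = FALSE)
  if (!all(is.finite(x$value)) || !all(is.finite(x$se)))
    stop("every coefficient needs a finite value and standard error",
         call. = FALSE)
  if (any(x$se < 0)) stop("standard errors must be >= 0", call. = FALSE)
  cf <- x$value[x$name == "carbon_frac"]
  if (length(cf) && (cf <= 0 || cf >= 1))
    stop("carbon_frac must be in (0, 1)", call. = FALSE)
  sd <- x$value[x$name == "season_days"]
  if (length(sd) && sd <= 0) stop("season_days must be > 0", call. = FALSE)
  invisible(x)
}

#' Look up a coefficient value or standard error
#'
#' @param coeffs a [snap_coefficients()] object.
#' @param name coefficient name.
#' @param what `"value"` (default) or `"se"`.
#' @return a single numeric.
#' @export
coef_value <- function(coeffs, name, what = c("value", "se")) {
  what <- match.arg(what)
  i <- match(name, coeffs$name)
  if (anyNA(i)) stop("unknown coefficient: ", name[is.na(i)][1], call. = FALSE)
  coeffs[[what]][i]
}

# Named numeric vector view, used by the flux evaluators.
.coef_vec <- function(coeffs, what = "value") {
  stats::setNames(coeffs[[what]], coeffs$name)
}

#' Write a coefficient registry to a flat text file
#'
#' One coefficient per line: `name value se source`, whitespace-separated,
#' values printed with full (17 significant digit) precision so that a
#' write/read round trip is bit-exact. Lines starting with `#` are comments.
#'
#' @param coeffs a [snap_coefficients()] object.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_coefficients <- function(coeffs, path) {
  .check_coefficients(coeffs)
  lines <- c(
    paste0("# snapsoc coefficient registry: ", attr(coeffs, "set") %||% "custom"),
    "# name value se source",
    sprintf("%s %.17g %.17g %s", coeffs$name, coeffs$value, coeffs$se,
            coeffs$source)
  )
  writeLines(lines, path)
  invisible(path)
}

#' Read a coefficient registry written by [write_coefficients()]
#'
#' @param path registry file.
#' @return a [snap_coefficients()] object.
#' @export
read_coefficients <- function(path) {
  lines <- readLines(path)
  set <- sub("^# snapsoc coefficient registry: *", "",
             grep("^# snapsoc coefficient registry:", lines, value = TRUE)[1])
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  parts <- strsplit(trimws(lines), "\\s+")
  bad <- lengths(parts) != 4
  if (any(bad))
    stop("malformed registry line: ", lines[bad][1], call. = FALSE)
  tab <- data.frame(
    name = vapply(parts, `[`, "", 1),
    value = as.numeric(vapply(parts, `[`, "", 2)),
    se = as.numeric(vapply(parts, `[`, "", 3)),
    source = vapply(parts, `[`, "", 4),
    stringsAsFactors = FALSE
  )
  .check_coefficients(tab)
  structure(tab, class = c("snap_coefficients", "data.frame"),
            set = if (is.na(set)) "custom" else set)
}

#' @export
print.snap_coefficients <- function(x, ...) {
  cat("SNAP coefficient set:", attr(x, "set") %||% "custom",
      sprintf("(%d entries)\n", nrow(x)))
  print.data.frame(x, row.names = FALSE, ...)
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
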