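#' Site drivers for the SNAP model
#'
#' Bundles the five environmental drivers the model needs for one
#' site or scenario, with optional standard errors of the measured drivers
#' for Monte Carlo propagation.
#'
#' @param rain mean annual rainfall, mm/yr (> 0).
#' @param gi grazing intensity, 1 - (grazed biomass / ungrazed biomass),
#'   a proportion in \[0, 1\].
#' @param fire fire frequency: expected fraction of years the site burns,
#'   in \[0, 1\].
#' @param ligcell lignin + cellulose fraction of aboveground biomass,
#'   a proportion in (0, 1).
#' @param sand_pct soil sand content, percent in \[0, 100\].
#' @param name optional site label.
#' @param se_gi,se_ligcell,se_rain optional standard errors of the measured
#'   drivers (>= 0; default 0, i.e. treated as known exactly).
#' @return an object of class `snap_site`.
#' @examples
#' site_conditions(rain = 721, gi = 0.32, fire = 4 / 9,
#'                 ligcell = 0.341, sand_pct = 51, name = "Balanites")
#' @export
site_conditions <- function(rain, gi, fire, ligcell, sand_pct, name = NULL,
                            se_gi = 0, se_ligcell = 0, se_rain = 0) {
  .check_num(rain, "rain", lower = 0, open_lower = TRUE)
  .check_num(gi, "gi", 0, 1)
  .check_num(fire, "fire", 0, 1)
  .check_num(ligcell, "ligcell", 0, 1, open_lower = TRUE, open_upper = TRUE)
  .check_num(sand_pct, "sand_pct", 0, 100)
  for (f in c("se_gi", "se_ligcell", "se_rain"))
    .check_num(get(f), f, lower = 0)
  structure(
    list(name = if (is.null(name)) NA_character_ else as.character(name),
         rain = rain, gi = gi, fire = fire, ligcell = ligcell,
         sand_pct = sand_pct, se_gi = se_gi, se_ligcell = se_ligcell,
         se_rain = se_rain),
    class = "snap_site"
  )
}

# Domain check that names the offending field in its error message.
.check_num <- function(x, field, lower = -Inf, upper = Inf,
                       open_lower = FALSE, open_upper = FALSE) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x))
    stop(field, " must be a single finite number", call. = FALSE)
  lo_bad <- if (open_lower) x <= lower else x < lower
  hi_bad <- if (open_upper) x >= upper else x > upper
  if (lo_bad || hi_bad)
    stop(sprintf("%s = %g is outside its valid range %s%g, %g%s", field, x,
                 if (open_lower) "(" else "[", lower, upper,
                 if (open_upper) ")" else "]"),
         call. = FALSE)
  invisible(x)
}

.check_vec <- function(x, field, lower = -Inf, upper = Inf,
                       open_lower = FALSE, open_upper = FALSE) {
  if (!is.numeric(x) || anyNA(x))
    stop(field, " must be numeric with no missing values", call. = FALSE)
  lo_bad <- if (open_lower) x <= lower else x < lower
  hi_bad <- if (open_upper) x >= upper else x > upper
  if (any(lo_bad | hi_bad))
    stop(sprintf("%s = %g is outside its valid range %s%g, %g%s", field,
                 x[lo_bad | hi_bad][1],
                 if (open_lower) "(" else "[", lower, upper,
                 if (open_upper) ")" else "]"),
         call. = FALSE)
  invisible(x)
}

#' @export
print.snap_site <- function(x, ...) {
  cat("SNAP site:", if (is.na(x$name)) "<unnamed>" else x$name, "\n")
  cat(sprintf("  rain %g mm/yr, gi %.3g, fire %.3g, ligcell %.3g, sand %g%%\n",
              x$rain, x$gi, x$fire, x$ligcell, x$sand_pct))
  if (x$se_gi > 0 || x$se_ligcell > 0 || x$se_rain > 0)
    cat(sprintf("  driver SEs: gi %.3g, ligcell %.3g, rain %.3g\n",
                x$se_gi, x$se_ligcell, x$se_rain))
  invisible(x)
}

#' @export
as.data.frame.snap_site <- function(x, ...) {
  data.frame(name = x$name, rain = x$rain, gi = x$gi, fire = x$fire,
             ligcell = x$ligcell, sand_pct = x$sand_pct, se_gi = x$se_gi,
             se_ligcell = x$se_ligcell, se_rain = x$se_rain,
             stringsAsFactors = FALSE)
}

#' Read a site table from CSV
#'
#' Expects header columns `name, rain, gi, fire, ligcell, sand_pct` and
#' optional `se_gi, se_ligcell, se_rain`. Lines beginning with `#` are
#' treated as comments.
#'
#' @param path CSV file.
#' @return a list of [site_conditions()] objects.
#' @export
read_sites <- function(path) {
  tab <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("rain", "gi", "fire", "ligcell", "sand_pct")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("site table is missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  lapply(seq_len(nrow(tab)), function(i) {
    site_conditions(
      rain = tab$rain[i], gi = tab$gi[i], fire = tab$fire[i],
      ligcell = tab$ligcell[i], sand_pct = tab$sand_pct[i],
      name = if ("name" %in% names(tab)) tab$name[i] else NULL,
      se_gi = if ("se_gi" %in% names(tab)) tab$se_gi[i] else 0,
      se_ligcell = if ("se_ligcell" %in% names(tab)) tab$se_ligcell[i] else 0,
      se_rain = if ("se_rain" %in% names(tab)) tab$se_rain[i] else 0
    )
  })
}

#' Write a list of sites to CSV
#'
#' @param sites a list of [site_conditions()] objects.
#' @param path output CSV file.
#' @return `path`, invisibly.
#' @export
write_sites <- function(sites, path) {
  tab <- do.call(rbind, lapply(sites, as.data.frame))
  utils::write.csv(tab, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}
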