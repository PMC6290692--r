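#' Age-by-year surface of death rates
#'
#' Container for period death rates m(x, t) for one population and sex on a
#' Lexis grid: ages in rows, calendar years in columns.  Ages are exact
#' integers and intervals are half-open `[x, x + n)`; the last age opens the
#' open-ended interval (110+ for single-year grids, 85+ for the abridged
#' cause-of-death work).
#'
#' @param mx numeric matrix of death rates per person-year,
#'   `length(ages)` rows by `length(years)` columns.  A vector is accepted
#'   for a single year.
#' @param ages strictly increasing integer age grid; the last entry is the
#'   start of the open interval.
#' @param years ordered calendar years, one per column of `mx`.
#' @param sex one of `"male"`, `"female"`, `"total"`.
#' @param population_id label for the population (country code or fixture
#'   name).
#'
#' @return An object of class `mortality_surface`: a list with elements
#'   `mx`, `ages`, `years`, `open_age`, `sex`, `population_id`.
#' @examples
#' mu <- siler_hazard(0:110, cee_male_params())
#' surf <- mortality_surface(matrix(mu, ncol = 1), 0:110, 2000)
#' surf
#' @export
mortality_surface <- function(mx, ages, years, sex = "total",
                              population_id = "synthetic") {
  if (is.vector(mx)) mx <- matrix(mx, ncol = 1L)
  ages <- as.integer(ages)
  years <- as.integer(years)
  sex <- match.arg(sex, c("male", "female", "total"))
  if (nrow(mx) != length(ages) || ncol(mx) != length(years))
    stop("mx must be length(ages) x length(years) (",
         length(ages), " x ", length(years), "), got ",
         nrow(mx), " x ", ncol(mx))
  if (any(diff(ages) <= 0)) stop("age grid must be strictly increasing")
  bad <- which(!is.finite(mx) | mx < 0, arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop("non-finite or negative rate at age ", ages[bad[1, 1]],
         ", year ", years[bad[1, 2]])
  if (any(mx[nrow(mx), ] <= 0))
    stop("open-interval rate must be positive in every year")
  dimnames(mx) <- list(age = ages, year = years)
  structure(
    list(mx = mx, ages = ages, years = years,
         open_age = ages[length(ages)], sex = sex,
         population_id = population_id),
    class = "mortality_surface")
}

#' @export
print.mortality_surface <- function(x, ...) {
  cat("Mortality surface: ", x$population_id, " (", x$sex, ")\n", sep = "")
  cat("  ages  ", min(x$ages), "-", x$open_age, "+ (",
      length(x$ages), " groups)\n", sep = "")
  cat("  years ", min(x$years), "-", max(x$years), " (",
      length(x$years), ")\n", sep = "")
  cat("  m(x,t) range ", format(min(x$mx), digits = 3), " .. ",
      format(max(x$mx), digits = 3), "\n", sep = "")
  invisible(x)
}

#' Extract one year's rate column from a surface
#'
#' @param surface a `mortality_surface`.
#' @param year calendar year present in the surface.
#' @return named numeric vector of rates by age.
#' @export
surface_year <- function(surface, year) {
  stopifnot(inherits(surface, "mortality_surface"))
  j <- match(as.integer(year), surface$years)
  if (is.na(j)) stop("year ", year, " not in surface")
  stats::setNames(surface$mx[, j], surface$ages)
}

#' Inflate infant mortality by a year-specific factor
#'
#' Robustness scenario for under-registration of early-life deaths: the
#' age-0 rate is multiplied by a schedule of factors, 2.0 before
#' `full_until`, decreasing linearly to `tail_factor` at `taper_to`, and
#' constant at `tail_factor` thereafter.  Only age 0 is touched.
#'
#' @param surface a `mortality_surface` whose first age is 0.
#' @param full_until last year (exclusive) of full doubling. Default 1990.
#' @param taper_to year at which the factor reaches `tail_factor`.
#'   Default 2000.
#' @param peak_factor multiplier before `full_until`. Default 2.
#' @param tail_factor multiplier at and after `taper_to`. Default 1.1.
#' @return a new `mortality_surface` with inflated age-0 rates.
#' @export
inflate_infant_rates <- function(surface, full_until = 1990, taper_to = 2000,
                                 peak_factor = 2, tail_factor = 1.1) {
  stopifnot(inherits(surface, "mortality_surface"))
  if (surface$ages[1] != 0L) stop("surface must start at age 0")
  if (peak_factor <= 0 || tail_factor <= 0) stop("multipliers must be > 0")
  f <- infant_inflation_factor(surface$years, full_until, taper_to,
                               peak_factor, tail_factor)
  mx <- surface$mx
  mx[1, ] <- mx[1, ] * f
  mortality_surface(mx, surface$ages, surface$years, surface$sex,
                    surface$population_id)
}

# Year -> multiplier schedule for the infant-inflation scenario.
infant_inflation_factor <- function(years, full_until = 1990, taper_to = 2000,
                                    peak_factor = 2, tail_factor = 1.1) {
  ifelse(years < full_until, peak_factor,
         ifelse(years >= taper_to, tail_factor,
                peak_factor + (tail_factor - peak_factor) *
                  (years - full_until) / (taper_to - full_until)))
}
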