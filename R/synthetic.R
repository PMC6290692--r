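#' Siler hazard with a young-adult hump
#'
#' Parametric baseline hazard
#' `mu(x) = a1 exp(-b1 x) + c + a2 exp(b2 x) + h exp(-(x - kappa)^2 / (2 sigma^2))`:
#' declining infant component, background level, Gompertz senescence, and
#' a Gaussian young-adult excess emulating the external-cause mortality
#' hump of male schedules in Central and Eastern Europe.
#'
#' @param x ages (years).
#' @param params list with elements `a1`, `b1`, `c`, `a2`, `b2` (Siler)
#'   and `h`, `kappa`, `sigma` (hump); all non-negative, `b2 > 0`.
#' @return hazard per person-year at each age.
#' @examples
#' plot(0:100, siler_hazard(0:100, cee_male_params()), log = "y", type = "l")
#' @export
siler_hazard <- function(x, params) {
  p <- params
  stopifnot(p$b2 > 0)
  mu <- p$a1 * exp(-p$b1 * x) + p$c + p$a2 * exp(p$b2 * x)
  if (p$h > 0) mu <- mu + p$h * exp(-(x - p$kappa)^2 / (2 * p$sigma^2))
  if (any(mu <= 0)) stop("hazard must be positive everywhere")
  mu
}

#' Baseline hazard parameters emulating a CEE male schedule
#'
#' Pinned calibration giving life expectancy at birth around 66 years and
#' life disparity around 15 years on the 0-110+ grid - the levels of the
#' region's male populations during the stagnation decades (e0 between
#' roughly 63 and 70, e-dagger between 13 and 19).
#'
#' @return parameter list for [siler_hazard()].
#' @export
cee_male_params <- function() {
  list(a1 = 0.045, b1 = 1.1, c = 0.0006,
       a2 = 4.5e-05, b2 = 0.098,
       h = 0.0016, kappa = 35, sigma = 13)
}

#' Regime schedule of age-band rate multipliers
#'
#' Defines time-varying multipliers m(x, t) -> factor(x, t) * mu(x) as a
#' set of episodes, each an (age band, year, factor) triple; factors of
#' overlapping episodes multiply.  Every year carries a regime label from
#' stagnation / improvement / crisis / recovery.
#'
#' @param years calendar years covered.
#' @param episodes data frame with columns `year`, `age_lo`, `age_hi`
#'   (inclusive band), `factor` (> 0).
#' @param regime character vector of regime labels, one per year.
#' @return An object of class `scenario_schedule`.
#' @export
scenario_schedule <- function(years, episodes, regime) {
  years <- as.integer(years)
  if (length(regime) != length(years))
    stop("one regime label per year required")
  ok <- regime %in% c("stagnation", "improvement", "crisis", "recovery")
  if (any(!ok))
    stop("unknown regime label: ", paste(unique(regime[!ok]), collapse = ", "))
  if (any(episodes$factor <= 0)) stop("factors must be positive")
  if (any(!episodes$year %in% years))
    stop("episode year outside the schedule span")
  structure(list(years = years, episodes = episodes,
                 regime = stats::setNames(regime, years)),
            class = "scenario_schedule")
}

#' Flat schedule (all factors 1)
#' @param years calendar years.
#' @param regime single regime label for every year.
#' @return a [scenario_schedule()].
#' @export
flat_schedule <- function(years, regime = "stagnation") {
  scenario_schedule(years,
                    data.frame(year = integer(0), age_lo = integer(0),
                               age_hi = integer(0), factor = numeric(0)),
                    rep(regime, length(years)))
}

#' Crisis-and-recovery schedule emulating the FSU mortality upheaval
#'
#' Deterministic five-regime scenario over `years` (default 1960-2014):
#' slow working-age worsening during stagnation (1960-1979), improvement
#' in the 1980s, a sharp working-age crisis jump in `crisis_start` rising
#' to `crisis_factor` and held through the divergence years, and a step
#' recovery from `recovery_start` onward decaying back toward baseline.
#' Transitions at `crisis_start` and `recovery_start` are deliberately
#' abrupt so that change-point detection on derived series has a sharp
#' target.
#'
#' @param years calendar years (must cover the regime boundaries).
#' @param age_lo,age_hi working-age band hit by the crisis. Default 20-60.
#' @param crisis_factor peak multiplier. Default 1.5.
#' @param crisis_start,recovery_start first year of the crisis and of the
#'   recovery regimes.
#' @return a [scenario_schedule()].
#' @export
fsu_crisis_schedule <- function(years = 1960:2014, age_lo = 20, age_hi = 60,
                                crisis_factor = 1.5, crisis_start = 1988,
                                recovery_start = 2000) {
  years <- as.integer(years)
  regime <- ifelse(years < 1980, "stagnation",
            ifelse(years < crisis_start, "improvement",
            ifelse(years < recovery_start, "crisis", "recovery")))
  fac <- function(y) {
    if (y < 1980)                       # drift up to +12 % by 1979
      1 + 0.12 * (y - min(years)) / max(1, 1979 - min(years))
    else if (y < crisis_start)          # anti-alcohol-campaign-style dip
      1.12 - 0.17 * (y - 1980) / (crisis_start - 1 - 1980)
    else if (y < recovery_start) {      # jump, then climb to the peak
      ramp <- min(1, (y - crisis_start) / 4)
      (crisis_factor - 0.25) + 0.25 * ramp
    } else                              # step down, then decay to 0.95
      max(0.95, 1.15 - 0.02 * (y - recovery_start))
  }
  episodes <- data.frame(year = years, age_lo = age_lo, age_hi = age_hi,
                         factor = vapply(years, fac, numeric(1)))
  scenario_schedule(years, episodes, regime)
}

#' Steadily improving schedule emulating a Central European country
#'
#' Working-age and old-age mortality decline of about `rate` percent per
#' year throughout, with no crisis.
#'
#' @param years calendar years.
#' @param rate annual improvement in percent. Default 0.7.
#' @return a [scenario_schedule()].
#' @export
ce_improvement_schedule <- function(years = 1960:2014, rate = 0.7) {
  years <- as.integer(years)
  episodes <- data.frame(year = years, age_lo = 0, age_hi = 110,
                         factor = exp(-rate / 100 * (years - min(years))))
  scenario_schedule(years, episodes,
                    rep("improvement", length(years)))
}

#' Build a deterministic mortality surface from a hazard and a schedule
#'
#' `m(x, t) = mu(x) * factor(x, t)` with `mu` the [siler_hazard()] of
#' `params` and the factors taken from the schedule's episodes (factors of
#' overlapping episodes multiply; ages outside every episode keep factor
#' 1).
#'
#' @param params hazard parameters, see [siler_hazard()].
#' @param schedule a [scenario_schedule()] (or `NULL` for all factors 1).
#' @param ages integer age grid (default 0:110, open interval 110+).
#' @param years calendar years; defaults to the schedule's.
#' @param ... passed to [mortality_surface()] (`sex`, `population_id`).
#' @return a [mortality_surface()].
#' @export
make_surface <- function(params, schedule = NULL, ages = 0:110,
                         years = NULL, ...) {
  if (is.null(years))
    years <- if (is.null(schedule)) 2000L else schedule$years
  mu <- siler_hazard(ages, params)
  fac <- matrix(1, length(ages), length(years))
  if (!is.null(schedule)) {
    stopifnot(inherits(schedule, "scenario_schedule"))
    ep <- schedule$episodes
    for (i in seq_len(nrow(ep))) {
      j <- match(ep$year[i], years)
      if (is.na(j)) next
      rows <- ages >= ep$age_lo[i] & ages <= ep$age_hi[i]
      fac[rows, j] <- fac[rows, j] * ep$factor[i]
    }
  }
  mortality_surface(mu * fac, ages, years, ...)
}

#' Sample Poisson death counts from a surface
#'
#' Independent counts with mean `m(x, t) * exposure(x, t)`, reproducible
#' given the seed.  Intended as optional noise for robustness tests; the
#' deterministic rate surfaces are the primary fixtures.
#'
#' @param surface a [mortality_surface()].
#' @param exposures positive scalar or matrix of person-years matching the
#'   surface.
#' @param seed integer seed.
#' @return list with matrices `deaths` and `exposures`, and `rates` =
#'   deaths / exposures.
#' @export
sample_death_counts <- function(surface, exposures, seed) {
  stopifnot(inherits(surface, "mortality_surface"))
  if (length(exposures) == 1)
    exposures <- matrix(exposures, nrow(surface$mx), ncol(surface$mx))
  if (any(exposures <= 0)) stop("exposures must be positive")
  old_seed <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, globalenv()))
  set.seed(as.integer(seed))
  deaths <- matrix(stats::rpois(length(surface$mx),
                                surface$mx * exposures),
                   nrow(surface$mx), dimnames = dimnames(surface$mx))
  list(deaths = deaths, exposures = exposures,
       rates = deaths / exposures)
}

# Parametric cause-of-death age profiles (relative intensities by age).
cause_profiles <- function() {
  list(
    alcohol = function(x) 0.10 * exp(-(x - 45)^2 / (2 * 15^2)),
    circulatory = function(x) 0.65 / (1 + exp(-(x - 60) / 11)),
    transport = function(x) 0.12 * exp(-(x - 30)^2 / (2 * 15^2)),
    other_external = function(x) 0.22 * exp(-(x - 35)^2 / (2 * 18^2)),
    infectious_respiratory = function(x) 0.05 + 0.25 * exp(-x / 25),
    cancers = function(x) 0.30 / (1 + exp(-(x - 55) / 9)),
    rest = function(x) rep(0.22, length(x)))
}

#' Synthetic cause-proportion table
#'
#' Derives the seven-cause fraction matrix for one year from parametric
#' age profiles: logistic rises for circulatory disease and cancers,
#' working-age Gaussian humps for the alcohol-attributable, transport and
#' other-external groups, a declining profile for infectious and
#' respiratory disease, and a flat residual.  Profiles are scaled by
#' per-cause `weights` (emulating, e.g., a crisis inflating external
#' causes), normalized within each age group, and forced entirely into
#' `"rest"` at and above the truncation age.
#'
#' @param year calendar year recorded on the table.
#' @param ages5 starting ages of the 5-year groups (default
#'   `seq(0, 85, 5)`, open at 85).
#' @param weights named multipliers for a subset of [cause_categories()].
#' @param truncation_age see [cause_table()]. Default 85.
#' @return a [cause_table()].
#' @export
make_cause_table <- function(year, ages5 = seq(0, 85, by = 5),
                             weights = NULL, truncation_age = 85) {
  prof <- cause_profiles()
  w <- stats::setNames(rep(1, 7), cause_categories())
  if (!is.null(weights)) {
    bad <- setdiff(names(weights), cause_categories())
    if (length(bad)) stop("unknown cause: ", paste(bad, collapse = ", "))
    w[names(weights)] <- weights
  }
  mid <- ages5 + 2.5
  raw <- vapply(cause_categories(),
                function(cc) w[[cc]] * prof[[cc]](mid),
                numeric(length(ages5)))
  if (any(rowSums(raw) <= 0)) stop("all-zero profile row")
  props <- raw / rowSums(raw)
  open <- ages5 >= truncation_age
  props[open, ] <- 0
  props[open, "rest"] <- 1
  rownames(props) <- ages5
  cause_table(props, year, truncation_age)
}

#' Aggregate a single-age surface onto an abridged grid
#'
#' Groups single-year rates into wider intervals using that year's
#' life-table person-years Lx as weights, so the abridged rates reproduce
#' the deaths-to-exposure ratio of the stationary population.  The last
#' group is the new open interval.
#'
#' @param surface a single-age [mortality_surface()].
#' @param ages5 starting ages of the target groups (default
#'   `seq(0, 85, 5)`).
#' @param ... passed to [lifetable()] for the weighting tables.
#' @return a `mortality_surface` on the abridged grid.
#' @export
abridge_surface <- function(surface, ages5 = seq(0, 85, by = 5), ...) {
  stopifnot(inherits(surface, "mortality_surface"))
  grp <- findInterval(surface$ages, ages5)
  mx5 <- sapply(seq_along(surface$years), function(j) {
    lt <- lifetable(surface$mx[, j], surface$ages, ...)
    w <- lt$Lx
    vapply(seq_along(ages5), function(g) {
      i <- grp == g
      sum(w[i] * surface$mx[i, j]) / sum(w[i])
    }, numeric(1))
  })
  mortality_surface(mx5, ages5, surface$years, surface$sex,
                    surface$population_id)
}

#' Two-country crisis fixture
#'
#' The package's standard synthetic study set: a steadily improving
#' Central-European-style country ("CE-A") and an FSU-style country
#' ("FSU-B") whose working ages undergo the stagnation / improvement /
#' crisis / recovery regimes of [fsu_crisis_schedule()].  Both share the
#' [cee_male_params()] baseline hazard.  Deterministic.
#'
#' @param years calendar years. Default 1960:2014.
#' @return named list of two [mortality_surface()]s with attached
#'   schedules in attribute `"schedule"`.
#' @export
two_country_crisis <- function(years = 1960:2014) {
  sched <- list(`CE-A` = ce_improvement_schedule(years),
                `FSU-B` = fsu_crisis_schedule(years))
  out <- lapply(names(sched), function(nm)
    structure(make_surface(cee_male_params(), sched[[nm]],
                           sex = "male", population_id = nm),
              schedule = sched[[nm]]))
  names(out) <- names(sched)
  out
}

#' Write a synthetic fixture set to disk
#'
#' Emits, for each country of [two_country_crisis()] (or any named list of
#' surfaces), an HMD-dialect Mx 1x1 file, a cause-of-death count CSV for
#' the cause-analysis years, optionally a Poisson-sampled death-count
#' file, and a JSON manifest recording the regimes and seed.  Files
#' round-trip through [read_hmd_mx()] and [read_cause_table()].
#'
#' @param dir output directory (created if needed).
#' @param surfaces named list of surfaces; default the two-country crisis
#'   fixture.
#' @param cause_years years for which cause tables are written.
#' @param seed seed for the optional sampled counts.
#' @param sample_counts also write Poisson death counts at exposure 1e5.
#' @return invisibly, the manifest list.
#' @export
write_fixture_set <- function(dir, surfaces = two_country_crisis(),
                              cause_years = c(1994, 2000, 2010),
                              seed = 1, sample_counts = FALSE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(seed = seed, countries = list())
  for (nm in names(surfaces)) {
    surf <- surfaces[[nm]]
    mx_path <- file.path(dir, paste0(nm, "_Mx_1x1.txt"))
    write_hmd_mx(surf, mx_path)
    sched <- attr(surf, "schedule")
    cause_path <- file.path(dir, paste0(nm, "_causes.csv"))
    tabs <- lapply(cause_years, function(y)
      make_cause_table(y, weights = crisis_cause_weights(sched, y)))
    write_cause_table(tabs, cause_path, country = nm, sex = surf$sex)
    entry <- list(mx_file = basename(mx_path),
                  cause_file = basename(cause_path),
                  regime = if (is.null(sched)) NULL else
                    as.list(sched$regime))
    if (sample_counts) {
      counts <- sample_death_counts(surf, 1e5, seed)
      cpath <- file.path(dir, paste0(nm, "_deaths.csv"))
      utils::write.csv(data.frame(
        age = rep(surf$ages, length(surf$years)),
        year = rep(surf$years, each = length(surf$ages)),
        deaths = as.vector(counts$deaths)), cpath, row.names = FALSE)
      entry$deaths_file <- basename(cpath)
    }
    manifest$countries[[nm]] <- entry
  }
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

# Cause weights tied to the crisis intensity: the schedule's working-age
# factor in a year inflates the alcohol / external profiles, so cause
# change concentrates where the rate change happens.
crisis_cause_weights <- function(schedule, year) {
  if (is.null(schedule)) return(NULL)
  ep <- schedule$episodes
  f <- ep$factor[ep$year == year & ep$age_lo <= 40 & ep$age_hi >= 40]
  if (length(f) == 0) return(NULL)
  intensity <- prod(f)
  excess <- max(0, intensity - 1)
  c(alcohol = 1 + 2.0 * excess, other_external = 1 + 2.5 * excess,
    transport = 1 + 1.5 * excess)
}
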