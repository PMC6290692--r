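#' Build a period life table from age-specific death rates
#'
#' Converts a schedule of central death rates m(x) on a single-year or
#' abridged age grid into the full set of period life-table columns with
#' radix 1.  Conversion uses the standard closure
#' `q(x) = n m(x) / (1 + (n - a(x)) m(x))`, capped at 1 (an interval whose
#' capped probability reaches 1 absorbs all remaining deaths), and the open
#' interval is closed with `q = 1`, `e(open) = 1 / m(open)`.
#'
#' The mean person-years lived in the interval by those dying in it, a(x),
#' defaults to a Coale-Demeny-style infant rule
#' `a(0) = 0.07 + 1.7 m(0)` (capped at 0.5 years) when the first interval
#' starts at age 0 and is one year wide, and to the interval midpoint
#' elsewhere.
#'
#' @param mx numeric vector of death rates, one per age group, all finite
#'   and non-negative with a positive open-interval rate.
#' @param ages strictly increasing integer age grid; the last entry starts
#'   the open interval.
#' @param a0_rule `"cd"` for the Coale-Demeny-style infant adjustment or
#'   `"midpoint"` for a(x) = n/2 everywhere.
#' @param radix survivorship at the first age; columns scale linearly with
#'   it.  Default 1.
#'
#' @return An object of class `lifetable`: a data frame with columns
#'   `age`, `n`, `mx`, `ax`, `qx`, `lx`, `dx`, `Lx`, `Tx`, `ex` (one row per
#'   age group, the last being the open interval) and attributes `open_age`
#'   and `radix`.
#' @examples
#' lt <- lifetable(siler_hazard(0:110, cee_male_params()), 0:110)
#' summary(lt)
#' @seealso [e_dagger()], [threshold_age()], [keyfitz_entropy()],
#'   [gini_lifetable()]
#' @export
lifetable <- function(mx, ages, a0_rule = c("cd", "midpoint"), radix = 1) {
  a0_rule <- match.arg(a0_rule)
  ages <- as.numeric(ages)  # fine fractional grids allowed for quadrature
  k <- length(ages)
  if (length(mx) != k) stop("mx and ages lengths differ")
  if (any(diff(ages) <= 0)) stop("age grid must be strictly increasing")
  bad <- which(!is.finite(mx) | mx < 0)
  if (length(bad) > 0)
    stop("non-finite or negative rate at age ", ages[bad[1]])
  if (mx[k] <= 0) stop("open-interval rate must be positive")

  cc <- lt_compute(mx, ages, a0_rule)
  out <- data.frame(age = ages, n = cc$n, mx = mx, ax = cc$ax, qx = cc$qx,
                    lx = radix * cc$lx, dx = radix * cc$dx,
                    Lx = radix * cc$Lx, Tx = radix * cc$Tx, ex = cc$ex,
                    row.names = NULL)
  structure(out, class = c("lifetable", "data.frame"),
            open_age = ages[k], radix = radix)
}

# Vector core of the life-table closure (radix 1, no validation); shared
# by lifetable() and the hot decomposition path.
lt_compute <- function(mx, ages, a0_rule = "cd") {
  k <- length(ages)
  n <- c(diff(ages), Inf)
  ax <- ifelse(is.finite(n), n / 2, 1 / mx[k])
  if (a0_rule == "cd" && ages[1] == 0L && k > 1 && n[1] == 1)
    ax[1] <- min(0.07 + 1.7 * mx[1], 0.5)
  qx <- numeric(k)
  cl <- seq_len(k - 1L)
  qx[cl] <- n[cl] * mx[cl] / (1 + (n[cl] - ax[cl]) * mx[cl])
  qx[qx > 1] <- 1
  qx[k] <- 1
  lx <- cumprod(c(1, 1 - qx[cl]))
  dx <- lx * qx
  Lx <- numeric(k)
  Lx[cl] <- n[cl] * (lx[cl] - dx[cl]) + ax[cl] * dx[cl]
  Lx[k] <- if (lx[k] > 0) lx[k] / mx[k] else 0
  Tx <- rev(cumsum(rev(Lx)))
  ex <- ifelse(lx > 0, Tx / lx, 0)
  list(n = n, ax = ax, qx = qx, lx = lx, dx = dx, Lx = Lx, Tx = Tx,
       ex = ex)
}

# e-dagger from the vector core (radix 1).
edag_compute <- function(cc) {
  k <- length(cc$ex)
  cl <- seq_len(k - 1L)
  w <- cc$ax[cl] / cc$n[cl]
  sum(cc$dx[cl] * ((1 - w) * cc$ex[cl] + w * cc$ex[cl + 1L])) +
    cc$dx[k] * cc$ex[k]
}

#' Life tables for every year of a mortality surface
#'
#' @param surface a [mortality_surface()].
#' @param ... passed to [lifetable()].
#' @return named list of `lifetable` objects, one per year.
#' @export
lifetable_series <- function(surface, ...) {
  stopifnot(inherits(surface, "mortality_surface"))
  out <- lapply(seq_along(surface$years),
                function(j) lifetable(surface$mx[, j], surface$ages, ...))
  names(out) <- surface$years
  out
}

#' Condition a mortality schedule on survival to a given age
#'
#' Rebuilds the life table from rates at ages >= `age` with the radix reset
#' there (l(age) = 1), the robustness scenario that removes early-life
#' mortality from the dispersion measures.
#'
#' @param mx,ages as in [lifetable()].
#' @param age starting age; must be on the grid and below the open interval.
#' @param ... passed to [lifetable()].
#' @return a `lifetable` starting at `age`.
#' @export
lifetable_conditional <- function(mx, ages, age, ...) {
  i <- match(as.numeric(age), as.numeric(ages))
  if (is.na(i)) stop("starting age ", age, " not on the grid")
  if (i == length(ages)) stop("starting age cannot be the open interval")
  lifetable(mx[i:length(mx)], ages[i:length(ages)], ...)
}

#' @export
print.lifetable <- function(x, digits = 4, ...) {
  cat("Period life table, ages ", x$age[1], "-", attr(x, "open_age"),
      "+, radix ", attr(x, "radix"), "\n", sep = "")
  cat("  e(", x$age[1], ") = ", format(x$ex[1], digits = 6), " years\n",
      sep = "")
  print.data.frame(utils::head(as.data.frame(x), 5), digits = digits)
  if (nrow(x) > 5) cat("  ... ", nrow(x) - 5, " more rows\n")
  invisible(x)
}

#' Dispersion summary of a life table
#'
#' @param object a `lifetable`.
#' @param ... ignored.
#' @return An object of class `summary.lifetable`: list with `e0`
#'   (expectancy at the first age), `e_dagger`, `entropy`, `gini`, and
#'   `threshold_age`.
#' @export
summary.lifetable <- function(object, ...) {
  th <- tryCatch(threshold_age(object)$threshold,
                 error = function(e) NA_real_)
  structure(list(e0 = object$ex[1],
                 e_dagger = e_dagger(object),
                 entropy = keyfitz_entropy(object),
                 gini = gini_lifetable(object),
                 threshold_age = th,
                 start_age = object$age[1]),
            class = "summary.lifetable")
}

#' @export
print.summary.lifetable <- function(x, ...) {
  cat(sprintf("e(%d)          %8.3f years\n", x$start_age, x$e0))
  cat(sprintf("e-dagger      %8.3f years\n", x$e_dagger))
  cat(sprintf("entropy H     %8.4f\n", x$entropy))
  cat(sprintf("Gini          %8.4f\n", x$gini))
  if (is.finite(x$threshold_age))
    cat(sprintf("threshold age %8.2f years\n", x$threshold_age))
  invisible(x)
}

#' @export
plot.lifetable <- function(x, which = c("lx", "dx", "mx"), ...) {
  which <- match.arg(which)
  closed <- seq_len(nrow(x) - 1L)
  ylab <- switch(which, lx = "survivorship l(x)",
                 dx = "life-table deaths d(x)", mx = "death rate m(x)")
  y <- x[[which]][closed]
  graphics::plot(x$age[closed], y, type = "l", xlab = "age", ylab = ylab,
                 log = if (which == "mx") "y" else "", ...)
  invisible(x)
}
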