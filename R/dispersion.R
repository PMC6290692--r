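#' Life disparity (e-dagger)
#'
#' Average remaining life expectancy at the ages people die, equivalently
#' the average life-years lost per death: the integral of d(a) e(a) over
#' age.  On the table grid each closed interval contributes
#' `dx * ((1 - ax/n) * e(x) + (ax/n) * e(x + n))` - remaining expectancy
#' linearly interpolated at the mean age at death within the interval - and
#' the open interval contributes `d(open) * e(open)`.
#'
#' @param lt a [lifetable()].
#' @return life disparity in years (per unit radix).
#' @examples
#' lt <- lifetable(siler_hazard(0:110, cee_male_params()), 0:110)
#' e_dagger(lt)
#' @export
e_dagger <- function(lt) {
  stopifnot(inherits(lt, "lifetable"))
  k <- nrow(lt)
  radix <- attr(lt, "radix")
  cl <- seq_len(k - 1L)
  w <- lt$ax[cl] / lt$n[cl]
  e_next <- lt$ex[cl + 1L]
  contrib <- lt$dx[cl] * ((1 - w) * lt$ex[cl] + w * e_next)
  (sum(contrib) + lt$dx[k] * lt$ex[k]) / radix
}

#' Keyfitz life-table entropy
#'
#' Relative dispersion of the age-at-death distribution, computed
#' independently of [e_dagger()] as `H = -integral(l ln l) / e0` by
#' trapezoid over the closed grid plus an exponential open-interval tail.
#' `H = 1` for a constant hazard, `H -> 0` as survival becomes rectangular,
#' and `H = e_dagger / e0` up to discretization.
#'
#' @param lt a [lifetable()].
#' @return dimensionless entropy.
#' @export
keyfitz_entropy <- function(lt) {
  stopifnot(inherits(lt, "lifetable"))
  k <- nrow(lt)
  l <- lt$lx / attr(lt, "radix")
  f <- ifelse(l > 0, -l * log(l), 0)
  cl <- seq_len(k - 1L)
  num <- sum(lt$n[cl] * (f[cl] + f[cl + 1L]) / 2)
  den <- sum(lt$n[cl] * (l[cl] + l[cl + 1L]) / 2)
  # open tail: l(x) = l_w exp(-m (x - w)) with m the open-interval rate
  lw <- l[k]; m <- lt$mx[k]
  if (lw > 0) {
    num <- num + lw * (1 - log(lw)) / m
    den <- den + lw / m
  }
  num / den
}

#' Life-table Gini coefficient
#'
#' Inter-individual inequality of ages at death,
#' `G = 1 - (1/e0) integral(l(x)^2 dx)` with radix 1, evaluated by
#' trapezoid over the closed grid with an exponential open-interval tail.
#' Equals 1/2 under a constant hazard and approaches 0 as everyone dies at
#' the same age.
#'
#' @param lt a [lifetable()].
#' @return Gini coefficient in `[0, 1)`.
#' @export
gini_lifetable <- function(lt) {
  stopifnot(inherits(lt, "lifetable"))
  k <- nrow(lt)
  l <- lt$lx / attr(lt, "radix")
  cl <- seq_len(k - 1L)
  i2 <- sum(lt$n[cl] * (l[cl]^2 + l[cl + 1L]^2) / 2)
  e0 <- sum(lt$n[cl] * (l[cl] + l[cl + 1L]) / 2)
  lw <- l[k]; m <- lt$mx[k]
  if (lw > 0) {
    i2 <- i2 + lw^2 / (2 * m)
    e0 <- e0 + lw / m
  }
  1 - i2 / e0
}

#' Threshold age for lifespan variation
#'
#' The age at which a marginal mortality improvement has zero effect on
#' life disparity: saving lives below it compresses the age-at-death
#' distribution (e-dagger falls), saving lives above it expands it.
#' Located by the sign change of a finite-difference sensitivity: rates in
#' a band of width `bandwidth` centred at a trial age are reduced by
#' `reduction` (a 1 percent cut by default, applied pro rata to the overlap
#' of each age interval with the band), the table rebuilt, and the change
#' in e-dagger recorded.  The crossing is refined by root finding; when
#' several crossings exist the oldest below the open interval is returned
#' and all are reported.
#'
#' @param lt a [lifetable()] built from rates (its `mx` column is
#'   perturbed and the table reconstructed with the same closure rules).
#' @param bandwidth width in years of the perturbation band. Default 1.
#' @param reduction proportional rate reduction. Default 0.01.
#' @return list with `threshold` (years), `crossings` (all zero-crossing
#'   ages, youngest first), and `sensitivity` (data frame of band centre
#'   ages and the e-dagger change per perturbation).
#' @examples
#' lt <- lifetable(siler_hazard(0:110, cee_male_params()), 0:110)
#' threshold_age(lt)$threshold
#' @export
threshold_age <- function(lt, bandwidth = 1, reduction = 0.01) {
  stopifnot(inherits(lt, "lifetable"))
  mx <- lt$mx
  ages <- lt$age
  a0_rule <- if (isTRUE(all.equal(lt$ax[1], lt$n[1] / 2))) "midpoint" else "cd"
  base <- e_dagger(lt)
  sens <- function(centre) {
    pm <- perturb_band(mx, ages, centre, bandwidth, reduction)
    edag_compute(lt_compute(pm, ages, a0_rule)) - base
  }
  centres <- ages[-length(ages)] + diff(ages) / 2
  s <- vapply(centres, sens, numeric(1))
  sgn <- sign(s)
  idx <- which(sgn[-length(sgn)] < 0 & sgn[-1] >= 0 |
               sgn[-length(sgn)] <= 0 & sgn[-1] > 0)
  if (length(idx) == 0)
    stop("sensitivity of e-dagger never changes sign: ",
         "schedule has no threshold age")
  crossings <- vapply(idx, function(i) {
    stats::uniroot(sens, c(centres[i], centres[i + 1]),
                   tol = .Machine$double.eps^0.5)$root
  }, numeric(1))
  list(threshold = crossings[length(crossings)],
       crossings = crossings,
       sensitivity = data.frame(age = centres, d_edagger = s))
}

# Multiply rates down by `reduction` inside [centre - w/2, centre + w/2],
# pro rata to each interval's overlap with the band.
perturb_band <- function(mx, ages, centre, bandwidth, reduction) {
  k <- length(ages)
  lo <- centre - bandwidth / 2
  hi <- centre + bandwidth / 2
  upper <- c(ages[-1], ages[k] + bandwidth)  # open interval: nominal width
  width <- upper - ages
  overlap <- pmax(0, pmin(hi, upper) - pmax(lo, ages)) / width
  mx * (1 - reduction * overlap)
}

#' Dispersion summary for one rate schedule
#'
#' One-call wrapper computing life expectancy, life disparity, the
#' entropy/Gini relative measures, and the threshold age from a vector of
#' rates.
#'
#' @inheritParams lifetable
#' @param ... passed to [lifetable()].
#' @return a [summary.lifetable] object.
#' @export
dispersion_summary <- function(mx, ages, ...) {
  summary(lifetable(mx, ages, ...))
}

#' Coefficient of variation across populations
#'
#' Cross-sectional relative spread of a summary measure (for instance e0 or
#' e-dagger in one calendar year) over the study populations, using the
#' population (n-denominator) standard deviation since the populations are
#' the complete study set.
#'
#' @param values numeric vector, one summary value per population
#'   (length >= 2, positive mean).
#' @return dimensionless coefficient of variation.
#' @examples
#' cv_across_populations(c(10, 20))  # 0.3333
#' @export
cv_across_populations <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 2) stop("need at least 2 populations")
  m <- mean(values)
  if (m <= 0) stop("mean must be positive")
  sqrt(mean((values - m)^2)) / m
}

#' Quadrant analysis of paired first differences
#'
#' Classifies year-over-year changes in life expectancy and life disparity
#' by sign pair, pooling consecutive-year pairs across populations within
#' each analysis period.  A pair falls in quadrant `(-,-)` when both
#' measures fell, `(+,+)` when both rose, and so on; exact-zero differences
#' are counted separately as "no change" and excluded from the quadrant
#' denominator unless `drop_zero = FALSE`.  Proportions carry
#' normal-approximation 95 percent confidence intervals
#' `p +/- 1.96 sqrt(p(1-p)/n)`, truncated to `[0, 1]`.
#'
#' @param e0 numeric matrix of life expectancy, years in rows (named by
#'   calendar year) and populations in columns; or a vector for one
#'   population.
#' @param edagger matching matrix of life disparity.
#' @param breaks ordered interior break years partitioning the span;
#'   a period covers year pairs `(t, t+1)` with `t + 1 <= break`.
#' @param scale `"absolute"` (differences in years) or `"relative"`
#'   (differences divided by the previous value).
#' @param drop_zero exclude exact-zero differences from denominators.
#' @return An object of class `quadrant_summary`: data frame with one row
#'   per period and quadrant, columns `period`, `quadrant`, `n_pairs`,
#'   `count`, `prop`, `ci_low`, `ci_high`, plus attribute `n_zero`.
#' @export
quadrant_analysis <- function(e0, edagger, breaks = NULL,
                              scale = c("absolute", "relative"),
                              drop_zero = TRUE) {
  scale <- match.arg(scale)
  if (is.vector(e0)) e0 <- as.matrix(e0)
  if (is.vector(edagger)) edagger <- as.matrix(edagger)
  if (!identical(dim(e0), dim(edagger)))
    stop("e0 and edagger must have identical dimensions")
  years <- as.integer(rownames(e0) %||% seq_len(nrow(e0)))
  if (nrow(e0) < 2) stop("need at least 2 years")
  d0 <- diff(e0)
  dd <- diff(edagger)
  if (scale == "relative") {
    d0 <- d0 / e0[-nrow(e0), , drop = FALSE]
    dd <- dd / edagger[-nrow(edagger), , drop = FALSE]
  }
  end_year <- years[-1]  # pair (t, t+1) indexed by its later year
  breaks <- sort(unique(as.integer(breaks)))
  edges <- c(min(end_year) - 1L, breaks, max(end_year))
  labels <- paste0(c(years[1], breaks), "-", c(breaks, max(end_year)))
  period <- cut(end_year, edges, labels = labels)
  quadrants <- c("-/-", "-/+", "+/-", "+/+")
  rows <- list()
  n_zero <- 0L
  for (p in levels(period)) {
    sel <- period == p
    x <- as.vector(d0[sel, , drop = FALSE])
    y <- as.vector(dd[sel, , drop = FALSE])
    ok <- is.finite(x) & is.finite(y)
    x <- x[ok]; y <- y[ok]
    zero <- x == 0 | y == 0
    n_zero <- n_zero + sum(zero)
    if (drop_zero) { x <- x[!zero]; y <- y[!zero] }
    n <- length(x)
    q <- paste0(ifelse(x < 0, "-", "+"), "/", ifelse(y < 0, "-", "+"))
    cnt <- vapply(quadrants, function(qq) sum(q == qq), integer(1))
    prop <- if (n > 0) cnt / n else rep(NA_real_, 4)
    se <- sqrt(prop * (1 - prop) / n)
    rows[[p]] <- data.frame(period = p, quadrant = quadrants,
                            n_pairs = n, count = cnt, prop = prop,
                            ci_low = pmax(0, prop - 1.96 * se),
                            ci_high = pmin(1, prop + 1.96 * se),
                            row.names = NULL)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, class = c("quadrant_summary", "data.frame"),
            scale = scale, n_zero = n_zero)
}

#' @export
print.quadrant_summary <- function(x, ...) {
  cat("Quadrant analysis of yearly (d e0, d e-dagger) pairs [",
      attr(x, "scale"), " scale]\n", sep = "")
  df <- as.data.frame(x)
  df$prop <- sprintf("%.1f%%", 100 * df$prop)
  df$ci <- sprintf("[%.1f, %.1f]", 100 * df$ci_low, 100 * df$ci_high)
  print.data.frame(df[, c("period", "quadrant", "n_pairs", "count",
                          "prop", "ci")])
  if (attr(x, "n_zero") > 0)
    cat("(", attr(x, "n_zero"), " exact-zero differences excluded)\n",
        sep = "")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
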