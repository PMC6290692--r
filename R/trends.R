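# Second-order difference matrix for k points.
diff_matrix2 <- function(k) diff(diag(k), differences = 2)

#' Smooth a mortality surface on the log scale
#'
#' Two-dimensional penalized least squares (Whittaker-style) fit to log
#' death rates with second-order difference penalties along both age and
#' year.  The solution is computed exactly via eigendecomposition of the
#' two penalty matrices; when the smoothing parameters are not supplied
#' they are chosen by generalized cross-validation over a log-spaced grid.
#' The penalty null space contains all surfaces bilinear in age and year,
#' which therefore pass through untouched.  Zero rates are floored at
#' `eps` before logging.
#'
#' @param surface a [mortality_surface()] with at least 3 ages and 3
#'   years.
#' @param lambda_age,lambda_year optional non-negative smoothing
#'   parameters; `NULL` selects them by GCV.
#' @param eps floor applied to rates before logging. Default `1e-6`.
#' @return a `mortality_surface` of strictly positive smoothed rates on
#'   the same grid, with attributes `lambda_age`, `lambda_year`, `gcv`.
#' @export
smooth_mortality <- function(surface, lambda_age = NULL, lambda_year = NULL,
                             eps = 1e-6) {
  stopifnot(inherits(surface, "mortality_surface"))
  na <- length(surface$ages); ny <- length(surface$years)
  if (na < 3 || ny < 3)
    stop("need at least 3 ages and 3 years for second-difference smoothing")
  Y <- log(pmax(surface$mx, eps))
  ea <- eigen(crossprod(diff_matrix2(na)), symmetric = TRUE)
  ey <- eigen(crossprod(diff_matrix2(ny)), symmetric = TRUE)
  la <- pmax(ea$values, 0); ly <- pmax(ey$values, 0)
  Yt <- crossprod(ea$vectors, Y) %*% ey$vectors
  shrink <- function(lam_a, lam_y) {
    den <- 1 + outer(lam_a * la, lam_y * ly, `+`)
    list(Z = ea$vectors %*% (Yt / den) %*% t(ey$vectors),
         edf = sum(1 / den))
  }
  if (is.null(lambda_age) || is.null(lambda_year)) {
    grid <- 10^seq(-2, 6, length.out = 9)
    best <- NULL
    for (lam_a in grid) for (lam_y in grid) {
      fit <- shrink(lam_a, lam_y)
      rss <- sum((Y - fit$Z)^2)
      n <- length(Y)
      gcv <- n * rss / (n - fit$edf)^2
      if (is.null(best) || gcv < best$gcv)
        best <- list(lam_a = lam_a, lam_y = lam_y, gcv = gcv, Z = fit$Z)
    }
    lambda_age <- best$lam_a; lambda_year <- best$lam_y
    Z <- best$Z; gcv <- best$gcv
  } else {
    fit <- shrink(lambda_age, lambda_year)
    Z <- fit$Z
    gcv <- length(Y) * sum((Y - Z)^2) / (length(Y) - fit$edf)^2
  }
  out <- mortality_surface(exp(Z), surface$ages, surface$years,
                           surface$sex, surface$population_id)
  attr(out, "lambda_age") <- lambda_age
  attr(out, "lambda_year") <- lambda_year
  attr(out, "gcv") <- gcv
  out
}

#' Annual rates of mortality improvement
#'
#' Year-over-year log decline of the (typically smoothed) death rates,
#' `rho(x, t) = -100 (ln m(x, t+1) - ln m(x, t))` in percent per year:
#' positive where mortality improves, negative where it worsens.  Cells
#' are categorized as improvement, worsening, or little change inside the
#' `+/- band` percent band.
#'
#' @param surface a [mortality_surface()] with at least 2 years (usually
#'   the output of [smooth_mortality()]).
#' @param band half-width in percent of the little-change band.
#'   Default 0.5.
#' @return An object of class `improvement_surface`: list with `rho`
#'   (ages x year-pairs matrix, columns named by the pair's first year),
#'   `category` (character matrix), `ages`, `years`, `band`.
#' @export
improvement_rates <- function(surface, band = 0.5) {
  stopifnot(inherits(surface, "mortality_surface"))
  ny <- length(surface$years)
  if (ny < 2) stop("need at least 2 years")
  lm_ <- log(surface$mx)
  rho <- -100 * (lm_[, -1, drop = FALSE] - lm_[, -ny, drop = FALSE])
  yrs <- surface$years[-ny]
  dimnames(rho) <- list(age = surface$ages, year = yrs)
  category <- matrix("little_change", nrow(rho), ncol(rho),
                     dimnames = dimnames(rho))
  category[rho > band] <- "improvement"
  category[rho < -band] <- "worsening"
  structure(list(rho = rho, category = category, ages = surface$ages,
                 years = yrs, band = band),
            class = "improvement_surface")
}

#' @export
print.improvement_surface <- function(x, ...) {
  cat("Rates of mortality improvement (% per year), ",
      length(x$ages), " ages x ", length(x$years), " year pairs\n",
      sep = "")
  tab <- table(factor(x$category,
                      c("improvement", "little_change", "worsening")))
  print(round(100 * tab / sum(tab), 1))
  invisible(x)
}

#' @export
plot.improvement_surface <- function(x, ...) {
  lim <- max(abs(range(x$rho, finite = TRUE)))
  graphics::image(x$years, x$ages, t(x$rho), zlim = c(-lim, lim),
                  col = grDevices::hcl.colors(64, "Blue-Red 2", rev = TRUE),
                  xlab = "year", ylab = "age", ...)
  invisible(x)
}

# Two-sample energy statistic, scaled, from the 2-D cumulative sum C of
# the pairwise-distance matrix of the whole (standardized) series.
# Segment [l, r] split after position k (left l..k, right (k+1)..r).
block_sum <- function(C, a, b, c, d) {
  C[b, d] - (if (a > 1) C[a - 1, d] else 0) -
    (if (c > 1) C[b, c - 1] else 0) +
    (if (a > 1 && c > 1) C[a - 1, c - 1] else 0)
}

energy_split_stat <- function(C, l, k, r) {
  m <- k - l + 1; n <- r - k
  between <- block_sum(C, l, k, k + 1, r)
  within_l <- block_sum(C, l, k, l, k)
  within_r <- block_sum(C, k + 1, r, k + 1, r)
  e <- 2 * between / (m * n) - within_l / m^2 - within_r / n^2
  m * n / (m + n) * e
}

# Best admissible split over a set of segments; returns the max statistic
# and its location.
best_split <- function(C, segments, min_segment) {
  best <- list(stat = -Inf, segment = NA, k = NA)
  for (s in seq_len(nrow(segments))) {
    l <- segments[s, 1]; r <- segments[s, 2]
    if (r - l + 1 < 2 * min_segment) next
    for (k in (l + min_segment - 1):(r - min_segment)) {
      q <- energy_split_stat(C, l, k, r)
      if (q > best$stat) best <- list(stat = q, segment = s, k = k)
    }
  }
  best
}

dist_cumsum <- function(x) {
  D <- abs(outer(x, x, `-`))
  t(apply(apply(D, 2, cumsum), 1, cumsum))
}

#' Divisive energy-statistic change-point detection
#'
#' Hierarchical divisive segmentation of a yearly series: at each stage
#' the binary split (over all current segments) maximizing the scaled
#' two-sample energy-distance statistic
#' `mn/(m+n) * (2 E|X-Y| - E|X-X'| - E|Y-Y'|)` (exponent 1) is tested
#' against a permutation null obtained by permuting observations within
#' the current segments; accepted splits recurse until no candidate is
#' significant at `alpha`.  The series is standardized first, making the
#' segmentation invariant to affine transforms.  Results are deterministic
#' given `seed`.
#'
#' @param series numeric vector of yearly values.
#' @param years calendar years (default names of `series`, else a unit
#'   sequence).
#' @param min_segment minimum segment length in years. Default 5.
#' @param alpha significance level for accepting a split. Default 0.05.
#' @param n_permutations permutations per test. Default 199.
#' @param seed integer seed for the permutation null.
#' @return An object of class `period_segmentation`: list with `breaks`
#'   (years starting each new segment, ordered), `stats` and `p_values`
#'   per accepted break, `years`, and `n_permutations`.
#' @examples
#' y <- c(rep(0, 10), rep(3, 10)) + sin(1:20)
#' detect_changepoints(y, years = 1991:2010, seed = 1)$breaks
#' @export
detect_changepoints <- function(series, years = NULL, min_segment = 5,
                                alpha = 0.05, n_permutations = 199,
                                seed = 1) {
  x <- as.numeric(series)
  n <- length(x)
  if (is.null(years))
    years <- as.integer(names(series) %||% seq_len(n))
  if (length(years) != n) stop("years and series lengths differ")
  if (n < 2 * min_segment)
    stop("series shorter than 2 * min_segment (", 2 * min_segment, ")")
  s <- stats::sd(x)
  z <- if (is.finite(s) && s > 0) (x - mean(x)) / s else x * 0
  old_seed <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)

  segments <- matrix(c(1L, n), nrow = 1)
  breaks <- integer(0); stats_out <- numeric(0); pvals <- numeric(0)
  repeat {
    C <- dist_cumsum(z)
    obs <- best_split(C, segments, min_segment)
    if (!is.finite(obs$stat)) break
    exceed <- 0L
    for (b in seq_len(n_permutations)) {
      zp <- z
      for (s_i in seq_len(nrow(segments))) {
        idx <- segments[s_i, 1]:segments[s_i, 2]
        zp[idx] <- zp[sample(idx)]
      }
      qb <- best_split(dist_cumsum(zp), segments, min_segment)$stat
      if (qb >= obs$stat) exceed <- exceed + 1L
    }
    p <- (1 + exceed) / (1 + n_permutations)
    if (p > alpha) break
    l <- segments[obs$segment, 1]; r <- segments[obs$segment, 2]
    breaks <- c(breaks, obs$k + 1L)
    stats_out <- c(stats_out, obs$stat)
    pvals <- c(pvals, p)
    segments <- rbind(segments[-obs$segment, , drop = FALSE],
                      c(l, obs$k), c(obs$k + 1L, r))
  }
  ord <- order(breaks)
  structure(list(breaks = years[breaks[ord]], stats = stats_out[ord],
                 p_values = pvals[ord], years = years,
                 min_segment = min_segment, alpha = alpha,
                 n_permutations = n_permutations, seed = seed),
            class = "period_segmentation")
}

#' @export
print.period_segmentation <- function(x, ...) {
  cat("Divisive energy change-point segmentation, ",
      min(x$years), "-", max(x$years), "\n", sep = "")
  if (length(x$breaks) == 0) {
    cat("  no significant breaks\n")
  } else {
    df <- data.frame(break_year = x$breaks,
                     statistic = round(x$stats, 3),
                     p_value = round(x$p_values, 4))
    if (!is.null(x$labels)) {
      cat("  periods: ", paste(x$labels, collapse = ", "), "\n", sep = "")
      df$canonical <- x$canonical
    }
    print(df, row.names = FALSE)
  }
  invisible(x)
}

#' Map statistical breaks to canonical analysis periods
#'
#' Snaps detected break years to the canonical period boundaries
#' (1980, 1988, 1994, 2000 by default) when close enough, keeping distant
#' breaks as they are, and emits period labels.  A break `b` is snapped to
#' boundary `c` when `|b - (c - 1)| <= snap` - the boundary's closing
#' period runs through year `c - 1`, so the comparison is against the last
#' complete year before the boundary.  When the snapped boundaries are
#' exactly the canonical four, the five periods carry their standard names
#' (stagnation, improvements, deterioration, divergence, convergence);
#' otherwise generic labels are used and non-snapped breaks flagged
#' non-canonical.
#'
#' @param breaks ordered break years, or a `period_segmentation`.
#' @param canonical canonical boundary years.
#' @param snap snapping tolerance in years. Default 3.
#' @param span optional `c(first, last)` year of the series, used in the
#'   period labels.
#' @return a `period_segmentation` with elements `breaks` (snapped),
#'   `original_breaks`, `canonical` (logical per break), and `labels`
#'   (one per period).
#' @examples
#' assign_periods(c(1976, 1986, 1993, 2001), span = c(1960, 2014))$labels
#' @export
assign_periods <- function(breaks, canonical = c(1980, 1988, 1994, 2000),
                           snap = 3, span = NULL) {
  seg <- NULL
  if (inherits(breaks, "period_segmentation")) {
    seg <- breaks
    if (is.null(span)) span <- range(seg$years)
    breaks <- seg$breaks
  }
  breaks <- sort(as.integer(breaks))
  if (any(duplicated(breaks))) stop("duplicate break years")
  snapped <- vapply(breaks, function(b) {
    d <- abs(b - (canonical - 1L))
    if (min(d) <= snap) as.integer(canonical[which.min(d)]) else b
  }, integer(1))
  is_canon <- snapped %in% canonical
  if (any(duplicated(snapped)))
    stop("two breaks snapped to the same boundary")
  k <- length(snapped)
  canonical_names <- c("stagnation", "improvements", "deterioration",
                       "divergence", "convergence")
  labels <- if (k == 4 && all(snapped == canonical)) canonical_names
            else paste0("period_", seq_len(k + 1),
                        ifelse(c(TRUE, is_canon), "", " (non-canonical)"))
  lo <- if (is.null(span)) NA_integer_ else span[1]
  hi <- if (is.null(span)) NA_integer_ else span[2]
  bounds <- paste0(c(lo, snapped), "-", c(snapped, hi))
  out <- if (is.null(seg)) list(years = if (is.null(span)) breaks else span)
         else seg
  out$original_breaks <- breaks
  out$breaks <- snapped
  out$canonical <- is_canon
  out$labels <- labels
  out$period_bounds <- bounds
  class(out) <- "period_segmentation"
  out
}
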