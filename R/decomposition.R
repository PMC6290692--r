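#' Line-integral (Horiuchi) decomposition of a change in a functional
#'
#' Attributes the change `f(x_end) - f(x_start)` in a scalar functional of
#' a rate vector additively to each covariate.  The covariate vector is
#' moved along the straight line between the endpoints in `n_steps` equal
#' segments; at each segment midpoint covariate i is advanced and retarded
#' by half a step and the difference of the functional accumulated into its
#' contribution.  The sum of contributions reproduces the total change up
#' to a numerical-integration residual that shrinks roughly quadratically
#' in `n_steps`.
#'
#' @param f function mapping a rate vector (same length and order as the
#'   endpoints) to a scalar, e.g. life expectancy of the table built from
#'   the rates.
#' @param x_start,x_end numeric endpoint vectors; names, if present, must
#'   agree and label the contributions.
#' @param n_steps number of integration segments (default 20).
#' @param functional_label label stored on the result for printing.
#' @return An object of class `decomp_result`: list with `contributions`
#'   (named numeric), `total` = `f(x_end) - f(x_start)`, `residual`
#'   = `|sum(contributions) - total|`, `n_steps`, and `functional_label`.
#' @examples
#' f <- function(x) sum(x^2)
#' horiuchi_decompose(f, c(a = 1, b = 2), c(a = 2, b = 1), n_steps = 40)
#' @export
horiuchi_decompose <- function(f, x_start, x_end, n_steps = 20,
                               functional_label = deparse(substitute(f))) {
  if (length(x_start) != length(x_end))
    stop("endpoint vectors differ in length")
  if (!is.null(names(x_start)) && !is.null(names(x_end)) &&
      !identical(names(x_start), names(x_end)))
    stop("endpoint labels differ")
  n_steps <- as.integer(n_steps)
  if (n_steps < 1) stop("n_steps must be positive")
  p <- length(x_start)
  delta <- (x_end - x_start) / n_steps
  contrib <- numeric(p)
  for (s in seq_len(n_steps)) {
    mid <- x_start + (s - 0.5) * delta
    for (i in seq_len(p)) {
      if (delta[i] == 0) next
      up <- mid; up[i] <- up[i] + delta[i] / 2
      dn <- mid; dn[i] <- dn[i] - delta[i] / 2
      fu <- f(up); fd <- f(dn)
      if (!is.finite(fu) || !is.finite(fd))
        stop("functional non-finite at integration step ", s,
             ", covariate ", i)
      contrib[i] <- contrib[i] + (fu - fd)
    }
  }
  names(contrib) <- names(x_start)
  total <- f(x_end) - f(x_start)
  structure(list(contributions = contrib, total = total,
                 residual = abs(sum(contrib) - total),
                 n_steps = n_steps, functional_label = functional_label),
            class = "decomp_result")
}

#' @export
print.decomp_result <- function(x, ...) {
  cat("Decomposition of change in ", x$functional_label,
      " (", x$n_steps, " steps)\n", sep = "")
  cat("  total change ", format(x$total, digits = 6),
      ", residual ", format(x$residual, digits = 3), "\n", sep = "")
  top <- sort(abs(x$contributions), decreasing = TRUE)
  show <- names(top)[seq_len(min(8, length(top)))]
  print(round(x$contributions[show], 5))
  if (length(x$contributions) > 8)
    cat("  ... ", length(x$contributions) - 8, " more covariates\n")
  invisible(x)
}

#' @export
plot.decomp_result <- function(x, ...) {
  graphics::barplot(x$contributions, las = 2,
                    ylab = paste("contribution to", x$functional_label),
                    ...)
  invisible(x)
}

# Functional factory shared by the age and age-cause decompositions;
# uses the lean vector core rather than full lifetable objects.
lifetable_functional <- function(functional = c("e0", "edagger"), ages,
                                 a0_rule = "cd") {
  functional <- match.arg(functional)
  switch(functional,
         e0 = function(mx) lt_compute(mx, ages, a0_rule)$ex[1],
         edagger = function(mx) edag_compute(lt_compute(mx, ages, a0_rule)))
}

#' Age decomposition of a change in e0 or e-dagger
#'
#' Applies [horiuchi_decompose()] with the single-age (or age-group) death
#' rates of two years as covariates, giving the contribution of mortality
#' change at every age to the change in the chosen life-table functional
#' between the years.
#'
#' @param surface a [mortality_surface()].
#' @param year1,year2 calendar years in the surface.
#' @param functional `"e0"` or `"edagger"`.
#' @param n_steps integration segments (default 20).
#' @param ... passed to [lifetable()].
#' @return a `decomp_result` whose contributions are named by age.
#' @export
decompose_by_age <- function(surface, year1, year2,
                             functional = c("e0", "edagger"),
                             n_steps = 20, ...) {
  functional <- match.arg(functional)
  f <- lifetable_functional(functional, surface$ages, ...)
  horiuchi_decompose(f, surface_year(surface, year1),
                     surface_year(surface, year2), n_steps,
                     functional_label = functional)
}

#' The seven cause-of-death categories
#'
#' Broad groups used throughout the cause analysis: conditions wholly
#' attributable to alcohol; circulatory disease; transport accidents; other
#' external causes; infectious and respiratory diseases; cancers; and all
#' remaining causes (which also absorb all mortality above the cause
#' truncation age).
#' @return character vector of the 7 category labels.
#' @export
cause_categories <- function() {
  c("alcohol", "circulatory", "transport", "other_external",
    "infectious_respiratory", "cancers", "rest")
}

# ICD-10 range table, in priority order (first match wins).  Codes are
# encoded as letter-index * 100 + numeric part so ranges may span letters.
icd10_ranges <- local({
  enc <- function(code) {
    (match(substr(code, 1, 1), LETTERS) - 1) * 100 +
      as.numeric(substr(code, 2, nchar(code)))
  }
  rng <- function(cat, from, to = from)
    data.frame(category = cat, from = enc(from), to = enc(to))
  rbind(
    rng("alcohol", "F10"), rng("alcohol", "K70"), rng("alcohol", "K74"),
    rng("alcohol", "X45"),
    rng("circulatory", "I20", "I25"), rng("circulatory", "I60", "I67"),
    rng("circulatory", "G45"), rng("circulatory", "I00", "I09"),
    rng("circulatory", "I10", "I15"), rng("circulatory", "I26", "I28"),
    rng("circulatory", "I34", "I38"), rng("circulatory", "I46"),
    rng("circulatory", "I50"), rng("circulatory", "I30", "I33"),
    rng("circulatory", "I40", "I45"), rng("circulatory", "I47", "I49"),
    rng("circulatory", "I51"), rng("circulatory", "I69"),
    rng("circulatory", "I70", "I78"), rng("circulatory", "I80", "I99"),
    rng("transport", "V01", "V99"),
    rng("other_external", "X00", "X09"), rng("other_external", "X40", "X44"),
    rng("other_external", "X46", "X49"), rng("other_external", "X60", "X84"),
    rng("other_external", "X85", "Y09"), rng("other_external", "Y35", "Y36"),
    rng("other_external", "Y10", "Y34"), rng("other_external", "Y40", "Y84"),
    rng("other_external", "W00", "W19"), rng("other_external", "W65", "W74"),
    rng("other_external", "W75", "W84"), rng("other_external", "W20", "W64"),
    rng("other_external", "W85", "W99"), rng("other_external", "X10", "X39"),
    rng("other_external", "X50", "X59"), rng("other_external", "Y85", "Y91"),
    rng("other_external", "Y95", "Y98"),
    rng("infectious_respiratory", "A00", "B99"),
    rng("infectious_respiratory", "J00", "J99"),
    rng("cancers", "C00", "C97"))
})

#' Classify an ICD-10 code into the seven broad cause categories
#'
#' Routes a code (letter, two digits, optional decimal subcode) to exactly
#' one of [cause_categories()].  Alcohol-attributable conditions (F10, K70,
#' K74, X45) take priority, then circulatory disease (including G45),
#' transport accidents (V01-V99), other external causes, infectious and
#' respiratory diseases (A00-B99, J00-J99), and cancers (C00-C97); any
#' other valid code falls into `"rest"`.  The infectious/respiratory and
#' cancer ranges are package conventions for the otherwise unlisted groups.
#'
#' @param code character vector of ICD-10 codes, e.g. `"F10"`, `"V42.1"`.
#' @return character vector of category labels.
#' @examples
#' classify_icd10(c("F10", "V42", "Z99"))
#' @export
classify_icd10 <- function(code) {
  code <- toupper(trimws(as.character(code)))
  ok <- grepl("^[A-Z][0-9]{2}(\\.[0-9]{1,2})?$", code)
  if (any(!ok))
    stop("malformed ICD-10 code: ", paste(code[!ok], collapse = ", "))
  val <- (match(substr(code, 1, 1), LETTERS) - 1) * 100 +
    as.numeric(substr(code, 2, 3))
  vapply(val, function(v) {
    hit <- which(icd10_ranges$from <= v & v <= icd10_ranges$to)
    if (length(hit) == 0) "rest" else icd10_ranges$category[hit[1]]
  }, character(1))
}

#' Cause-proportion table for one year
#'
#' Validating constructor for the matrix of within-age-group cause-of-death
#' fractions: 5-year age groups in rows up to the truncation age, the seven
#' [cause_categories()] in columns, every row summing to 1.  At and above
#' the truncation age (default 85) all mass must sit in `"rest"`.
#'
#' @param props numeric matrix, age groups x 7 causes; rows named by the
#'   starting age of the group, columns by category.
#' @param year calendar year the table describes.
#' @param truncation_age first age group whose causes are not resolved.
#' @return An object of class `cause_table`.
#' @export
cause_table <- function(props, year, truncation_age = 85) {
  props <- as.matrix(props)
  if (is.null(colnames(props))) colnames(props) <- cause_categories()
  if (!identical(sort(colnames(props)), sort(cause_categories())))
    stop("columns must be the 7 cause categories")
  props <- props[, cause_categories(), drop = FALSE]
  ages <- as.integer(rownames(props))
  if (any(is.na(ages))) stop("rows must be named by age-group start")
  if (any(props < -1e-12 | props > 1 + 1e-12))
    stop("proportions must lie in [0, 1]")
  rs <- rowSums(props)
  if (any(abs(rs - 1) > 1e-9))
    stop("age-group rows must sum to 1 (worst deviation ",
         format(max(abs(rs - 1)), digits = 3), ")")
  open <- ages >= truncation_age
  if (any(open) && any(props[open, setdiff(cause_categories(), "rest")]
                       > 1e-12))
    stop("ages >= ", truncation_age, " must carry all mass in 'rest'")
  structure(list(props = props, ages = ages, year = as.integer(year),
                 truncation_age = as.integer(truncation_age)),
            class = "cause_table")
}

#' @export
print.cause_table <- function(x, ...) {
  cat("Cause-proportion table, year ", x$year, ", ", length(x$ages),
      " age groups (causes resolved below ", x$truncation_age, ")\n",
      sep = "")
  print(round(utils::head(x$props, 4), 3))
  if (length(x$ages) > 4) cat("  ...\n")
  invisible(x)
}

#' Split all-cause rates into cause-specific rates
#'
#' Multiplies abridged all-cause rates by cause fractions,
#' `m(x, c) = m(x) p(x, c)`, so that summing over causes reproduces the
#' all-cause schedule exactly.
#'
#' @param mx all-cause rates on the abridged grid of `props`.
#' @param props a [cause_table()] whose age groups match `mx`.
#' @return numeric matrix of rates, age groups x causes, with `dimnames`;
#'   flattening it column-major gives the covariate vector used by
#'   [decompose_by_age_cause()].
#' @export
split_rates_by_cause <- function(mx, props) {
  stopifnot(inherits(props, "cause_table"))
  if (length(mx) != length(props$ages))
    stop("rate vector and cause table disagree on age groups")
  m <- props$props * mx
  dimnames(m) <- list(age = props$ages, cause = cause_categories())
  m
}

#' Age-by-cause decomposition of a change in e0 or e-dagger
#'
#' Covariates are the age-group x cause death rates obtained by splitting
#' the two years' all-cause schedules with their cause tables; the
#' functional is evaluated on the abridged grid (truncated at the cause
#' table's open age) so covariates and functional share one grid.  Per-
#' cause totals are sums of each cause's age contributions; the grand total
#' is the change in the functional.
#'
#' @param surface a [mortality_surface()] on the abridged grid of the
#'   cause tables (open interval at the truncation age).
#' @param props1,props2 [cause_table()]s for `year1` and `year2`.
#' @param year1,year2 calendar years in the surface.
#' @inheritParams decompose_by_age
#' @return a `decomp_result` with an additional `by_cause` element (named
#'   per-cause totals) and a `by_age_cause` contribution matrix.
#' @export
decompose_by_age_cause <- function(surface, props1, props2, year1, year2,
                                   functional = c("e0", "edagger"),
                                   n_steps = 20, ...) {
  functional <- match.arg(functional)
  stopifnot(inherits(props1, "cause_table"), inherits(props2, "cause_table"))
  if (!identical(props1$ages, surface$ages) ||
      !identical(props2$ages, surface$ages))
    stop("cause tables and surface disagree on the age grid")
  m1 <- split_rates_by_cause(surface_year(surface, year1), props1)
  m2 <- split_rates_by_cause(surface_year(surface, year2), props2)
  ages <- surface$ages
  k <- length(ages)
  f_lt <- lifetable_functional(functional, ages, ...)
  f <- function(x) f_lt(rowSums(matrix(x, nrow = k)))
  labs <- as.vector(outer(ages, cause_categories(),
                          function(a, c) paste0(c, ":", a)))
  x1 <- stats::setNames(as.vector(m1), labs)
  x2 <- stats::setNames(as.vector(m2), labs)
  res <- horiuchi_decompose(f, x1, x2, n_steps, functional_label = functional)
  cm <- matrix(res$contributions, nrow = k,
               dimnames = list(age = ages, cause = cause_categories()))
  res$by_age_cause <- cm
  res$by_cause <- colSums(cm)
  res
}
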