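#' Write a mortality surface as an HMD-style Mx 1x1 file
#'
#' Header block, blank line, then whitespace-aligned columns
#' `Year  Age  Female  Male  Total`; the open interval is written as
#' `"110+"` (or the surface's open age).  The surface's own sex column
#' carries its rates; the other sex columns carry `"."` (the missing
#' marker) unless matching surfaces are supplied.  Rates are printed with
#' 15 significant digits so that files round-trip to within floating-point
#' noise.
#'
#' @param surface a [mortality_surface()] (used for the `Total` column if
#'   its sex is `"total"`).
#' @param path output file.
#' @param female,male optional surfaces for the other columns, same grid.
#' @return invisibly, `path`.
#' @export
write_hmd_mx <- function(surface, path, female = NULL, male = NULL) {
  stopifnot(inherits(surface, "mortality_surface"))
  cols <- list(Female = female, Male = male, Total = NULL)
  cols[[c(female = "Female", male = "Male",
          total = "Total")[[surface$sex]]]] <- surface
  fmt <- function(s, i, j)
    if (is.null(s)) "." else sprintf("%.15g", s$mx[i, j])
  k <- length(surface$ages)
  age_lab <- c(as.character(surface$ages[-k]),
               paste0(surface$open_age, "+"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0(surface$population_id,
                    ", Death rates (period 1x1)"), con)
  writeLines("", con)
  writeLines(sprintf("%6s %10s %22s %22s %22s",
                     "Year", "Age", "Female", "Male", "Total"), con)
  for (j in seq_along(surface$years))
    for (i in seq_len(k))
      writeLines(sprintf("%6d %10s %22s %22s %22s",
                         surface$years[j], age_lab[i],
                         fmt(cols$Female, i, j), fmt(cols$Male, i, j),
                         fmt(cols$Total, i, j)), con)
  invisible(path)
}

#' Read an HMD-style Mx 1x1 file
#'
#' Parses the period death-rate dialect: a header block, then columns
#' `Year Age Female Male Total` with ages 0..109 plus an open interval
#' written `"110+"` and missing values as `"."`.  Returns one
#' [mortality_surface()] per sex column that contains any data.  In strict
#' mode (default) a `"."` in an otherwise present sex column is an error;
#' in lenient mode the affected years are dropped from that sex's surface
#' and reported in the `flagged_years` attribute.
#'
#' @param path input file.
#' @param strict reject missing cells instead of dropping their years.
#' @return named list of `mortality_surface` objects (subset of
#'   `female`, `male`, `total`).
#' @export
read_hmd_mx <- function(path, strict = TRUE) {
  lines <- readLines(path)
  hdr <- grep("\\bYear\\b.*\\bAge\\b", lines)[1]
  if (is.na(hdr)) stop("no 'Year Age ...' header line found in ", path)
  pop_id <- sub(",.*$", "", lines[1])
  body <- lines[(hdr + 1):length(lines)]
  body <- body[nzchar(trimws(body))]
  tok <- strsplit(trimws(body), "[[:space:]]+")
  nt <- lengths(tok)
  if (any(nt != 5))
    stop("malformed row (expected 5 columns) at line ",
         hdr + which(nt != 5)[1])
  tok <- do.call(rbind, tok)
  year <- as.integer(tok[, 1])
  age_raw <- tok[, 2]
  open <- grepl("\\+$", age_raw)
  age <- suppressWarnings(as.integer(sub("\\+$", "", age_raw)))
  if (any(is.na(age) | is.na(year)))
    stop("malformed age or year token at line ",
         hdr + which(is.na(age) | is.na(year))[1])
  if (any(duplicated(paste(year, age))))
    stop("duplicate (year, age) at line ",
         hdr + which(duplicated(paste(year, age)))[1])
  ages <- sort(unique(age))
  years <- sort(unique(year))
  if (length(age) != length(ages) * length(years))
    stop("non-rectangular year blocks in ", path)
  open_age <- unique(age[open])
  if (length(open_age) > 1) stop("multiple open-interval ages")
  if (length(open_age) == 1 && open_age != max(ages))
    stop("open interval is not the last age")

  parse_col <- function(j, sex) {
    v <- tok[, j]
    if (all(v == ".")) return(NULL)
    miss <- v == "."
    val <- suppressWarnings(as.numeric(v))
    if (any(is.na(val) & !miss))
      stop("malformed rate at line ", hdr + which(is.na(val) & !miss)[1])
    m <- matrix(NA_real_, length(ages), length(years))
    m[cbind(match(age, ages), match(year, years))] <- val
    flagged <- years[apply(is.na(m), 2, any)]
    if (length(flagged) > 0 && strict)
      stop("missing values ('.') for ", sex, " in year(s) ",
           paste(flagged, collapse = ", "),
           " (use strict = FALSE to drop them)")
    keep <- !years %in% flagged
    if (!any(keep)) return(NULL)
    out <- mortality_surface(m[, keep, drop = FALSE], ages, years[keep],
                             sex, pop_id)
    attr(out, "flagged_years") <- flagged
    out
  }
  res <- list(female = parse_col(3, "female"),
              male = parse_col(4, "male"),
              total = parse_col(5, "total"))
  res[!vapply(res, is.null, logical(1))]
}

#' Write cause-of-death tables as a long-format CSV
#'
#' Columns `country, year, sex, cause, age, value`: one row per (year,
#' age group, cause), `value` being the within-age-group proportion (15
#' significant digits).
#'
#' @param tables list of [cause_table()]s (or a single one).
#' @param path output file.
#' @param country,sex labels written on every row.
#' @return invisibly, `path`.
#' @export
write_cause_table <- function(tables, path, country = "synthetic",
                              sex = "male") {
  if (inherits(tables, "cause_table")) tables <- list(tables)
  rows <- do.call(rbind, lapply(tables, function(tb) {
    data.frame(country = country, year = tb$year, sex = sex,
               cause = rep(colnames(tb$props), each = length(tb$ages)),
               age = rep(tb$ages, ncol(tb$props)),
               value = sprintf("%.15g", as.vector(tb$props)))
  }))
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read cause-of-death tables from a delimited file
#'
#' Accepts the package's long CSV dialect: columns `country`, `year`,
#' `sex`, `cause`, `age`, `value`, where `value` holds death counts or
#' within-age-group proportions and `cause` holds either one of the seven
#' pre-grouped [cause_categories()] or an ICD-10 code (routed through
#' [classify_icd10()]).  Values are normalized to proportions within each
#' (year, age group); rows at or above the truncation age are collapsed
#' into `"rest"`.
#'
#' @param path input file.
#' @param truncation_age see [cause_table()]. Default 85.
#' @return named list (by year) of [cause_table()]s.
#' @export
read_cause_table <- function(path, truncation_age = 85) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("year", "cause", "age", "value")
  if (!all(need %in% names(df)))
    stop("cause file must have columns ", paste(need, collapse = ", "))
  pre <- df$cause %in% cause_categories()
  df$category <- df$cause
  if (any(!pre))
    df$category[!pre] <- classify_icd10(df$cause[!pre])
  out <- lapply(split(df, df$year), function(dy) {
    ages <- sort(unique(dy$age))
    m <- matrix(0, length(ages), 7,
                dimnames = list(ages, cause_categories()))
    agg <- stats::aggregate(value ~ age + category, dy, sum)
    m[cbind(match(agg$age, ages), match(agg$category,
                                        cause_categories()))] <- agg$value
    open <- ages >= truncation_age
    if (any(open)) {
      m[open, "rest"] <- rowSums(m[open, , drop = FALSE])
      m[open, setdiff(colnames(m), "rest")] <- 0
    }
    rs <- rowSums(m)
    if (any(rs <= 0))
      stop("all-zero age group (year ", dy$year[1], ", age ",
           ages[which(rs <= 0)[1]], ")")
    cause_table(m / rs, dy$year[1], truncation_age)
  })
  names(out) <- vapply(out, function(tb) as.character(tb$year),
                       character(1))
  out
}
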