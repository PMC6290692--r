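#' Configuration for a full pipeline run
#'
#' Collects every knob of [run_pipeline()] with the canonical defaults:
#' period boundaries 1980 / 1988 / 1994 / 2000, 20 integration steps for
#' the decompositions, cause truncation at 85, open interval at 110, and a
#' fixed seed for the permutation tests.
#'
#' @param preset name of a built-in fixture (`"two-country-crisis"`), or
#'   `NULL` when `input_dir` is given.
#' @param input_dir directory of Mx 1x1 and cause CSV files written by
#'   [write_fixture_set()] (or downloaded in the same dialects).
#' @param sex which sex column to analyse from input files.
#' @param boundaries interior period boundary years.
#' @param n_steps decomposition integration steps.
#' @param truncation_age open age of the cause analysis.
#' @param cause_years years at which cause tables are taken; the first
#'   pair and last pair define the two cause-decomposition periods.
#' @param seed seed for permutation tests (and any sampling).
#' @param output_dir where [run_pipeline()] writes its files.
#' @return list of class `run_config`.
#' @export
run_config <- function(preset = "two-country-crisis", input_dir = NULL,
                       sex = "male",
                       boundaries = c(1980, 1988, 1994, 2000),
                       n_steps = 80, truncation_age = 85,
                       cause_years = c(1994, 2000, 2010),
                       seed = 1, output_dir = tempfile("lifedisp_run_")) {
  if (is.null(preset) && is.null(input_dir))
    stop("either a fixture preset or an input directory is required")
  if (any(diff(boundaries) <= 0)) stop("boundaries must be ordered")
  if (truncation_age > 110) stop("truncation age above the open age")
  structure(list(preset = preset, input_dir = input_dir, sex = sex,
                 boundaries = as.integer(boundaries),
                 n_steps = as.integer(n_steps),
                 truncation_age = as.integer(truncation_age),
                 cause_years = as.integer(cause_years),
                 seed = as.integer(seed), output_dir = output_dir),
            class = "run_config")
}

write_stage <- function(df, path, units) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# units: ", units), con)
  utils::write.table(format(df, digits = 15, trim = TRUE, scientific = NA),
                     con, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Run the full lifespan-variation analysis pipeline
#'
#' Executes, in order: period life tables for every country-year;
#' e0 / e-dagger / entropy / Gini / threshold-age series; change-point
#' segmentation of the cross-country coefficient-of-variation series of
#' e0; smoothed improvement surfaces; quadrant summaries per period on
#' both absolute and relative scales; single-age decompositions of the
#' change in e0 and e-dagger across each period; and age-by-cause
#' decompositions for the cause-era periods.  Each stage writes one
#' tab-separated file (with a units header line) into the output
#' directory, plus a JSON manifest carrying the config, seed and all
#' decomposition residuals.  A second run with the same config reproduces
#' every output byte for byte.
#'
#' @param config a [run_config()].
#' @return invisibly, a list with all in-memory stage results
#'   (`measures`, `segmentation`, `improvement`, `quadrants`,
#'   `age_decomp`, `cause_decomp`, `manifest`).
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)

  surfaces <- pipeline_inputs(config)
  run_pipeline_stages(config, surfaces)
}

pipeline_inputs <- function(config) {
  if (!is.null(config$input_dir)) {
    files <- list.files(config$input_dir, pattern = "Mx_1x1", full.names = TRUE)
    if (length(files) == 0)
      stop("stage 'read': no Mx 1x1 files in ", config$input_dir)
    out <- lapply(files, function(f) read_hmd_mx(f)[[config$sex]])
    names(out) <- vapply(out, function(s) s$population_id, character(1))
    attr(out, "cause_files") <- stats::setNames(
      file.path(config$input_dir,
                sub("_Mx_1x1\\.txt$", "_causes.csv", basename(files))),
      names(out))
    return(out)
  }
  if (config$preset != "two-country-crisis")
    stop("unknown fixture preset: ", config$preset)
  two_country_crisis()
}

run_pipeline_stages <- function(config, surfaces) {
  countries <- names(surfaces)
  out_dir <- config$output_dir
  residuals <- c()

  # --- life tables and dispersion measures -------------------------------
  lts <- lapply(surfaces, lifetable_series)
  measures <- do.call(rbind, lapply(countries, function(nm) {
    yrs <- surfaces[[nm]]$years
    do.call(rbind, lapply(seq_along(yrs), function(j) {
      lt <- lts[[nm]][[j]]
      th <- tryCatch(threshold_age(lt)$threshold,
                     error = function(e) NA_real_)
      data.frame(country = nm, year = yrs[j], e0 = lt$ex[1],
                 e_dagger = e_dagger(lt),
                 entropy = keyfitz_entropy(lt),
                 gini = gini_lifetable(lt), threshold_age = th)
    }))
  }))
  write_stage(measures, file.path(out_dir, "measures.tsv"),
              "e0, e_dagger, threshold_age in years; entropy, gini dimensionless")

  # --- change-point segmentation of the cross-country CV of e0 -----------
  years <- sort(Reduce(intersect, lapply(surfaces, `[[`, "years")))
  e0_mat <- sapply(countries, function(nm)
    measures$e0[measures$country == nm][match(years,
      measures$year[measures$country == nm])])
  rownames(e0_mat) <- years
  ed_mat <- sapply(countries, function(nm)
    measures$e_dagger[measures$country == nm][match(years,
      measures$year[measures$country == nm])])
  rownames(ed_mat) <- years
  cv_series <- apply(e0_mat, 1, cv_across_populations)
  seg <- detect_changepoints(cv_series, years = years,
                             seed = config$seed)
  seg <- assign_periods(seg)
  seg_df <- data.frame(break_year = seg$breaks,
                       statistical_break = seg$original_breaks,
                       canonical = seg$canonical,
                       statistic = seg$stats, p_value = seg$p_values)
  write_stage(seg_df, file.path(out_dir, "segmentation.tsv"),
              "break_year calendar years; statistic dimensionless")

  # --- improvement surfaces ----------------------------------------------
  improvement <- lapply(surfaces, function(s)
    improvement_rates(smooth_mortality(s)))
  imp_df <- do.call(rbind, lapply(countries, function(nm) {
    im <- improvement[[nm]]
    data.frame(country = nm,
               age = rep(im$ages, length(im$years)),
               year = rep(im$years, each = length(im$ages)),
               rho = as.vector(im$rho),
               category = as.vector(im$category))
  }))
  write_stage(imp_df, file.path(out_dir, "improvement.tsv"),
              "rho in % per year")

  # --- quadrant summaries -------------------------------------------------
  quad <- list(
    absolute = quadrant_analysis(e0_mat, ed_mat, config$boundaries,
                                 scale = "absolute"),
    relative = quadrant_analysis(e0_mat, ed_mat, config$boundaries,
                                 scale = "relative"))
  quad_df <- rbind(cbind(scale = "absolute", as.data.frame(quad$absolute)),
                   cbind(scale = "relative", as.data.frame(quad$relative)))
  write_stage(quad_df, file.path(out_dir, "quadrants.tsv"),
              "prop, ci_low, ci_high dimensionless proportions")

  # --- single-age decompositions per period -------------------------------
  edges <- unique(pmin(pmax(c(min(years), config$boundaries, max(years)),
                            min(years)), max(years)))
  age_rows <- list()
  for (nm in countries) for (i in seq_len(length(edges) - 1)) {
    for (fun in c("e0", "edagger")) {
      d <- decompose_by_age(surfaces[[nm]], edges[i], edges[i + 1],
                            functional = fun, n_steps = config$n_steps)
      if (d$residual > 1e-6 * max(1, abs(d$total)))
        stop("stage 'age_decomp': residual ", format(d$residual),
             " above tolerance (", nm, ", ", edges[i], "-", edges[i + 1],
             ", ", fun, ")")
      residuals <- c(residuals, d$residual)
      age_rows[[length(age_rows) + 1]] <-
        data.frame(country = nm, period = paste0(edges[i], "-", edges[i + 1]),
                   functional = fun, age = surfaces[[nm]]$ages,
                   contribution = unname(d$contributions),
                   total = d$total)
    }
  }
  age_decomp <- do.call(rbind, age_rows)
  write_stage(age_decomp, file.path(out_dir, "age_decomposition.tsv"),
              "contribution, total in years")

  # --- age x cause decompositions for the cause-era periods ---------------
  cause_files <- attr(surfaces, "cause_files")
  cyrs <- config$cause_years
  cyrs <- cyrs[cyrs >= min(years) & cyrs <= max(years)]
  cause_rows <- list()
  for (nm in countries) {
    ab <- abridge_surface(surfaces[[nm]],
                          seq(0, config$truncation_age, by = 5))
    tabs <- if (!is.null(cause_files)) {
      read_cause_table(cause_files[[nm]], config$truncation_age)
    } else {
      sched <- attr(surfaces[[nm]], "schedule")
      stats::setNames(
        lapply(cyrs, function(y)
          make_cause_table(y, weights = crisis_cause_weights(sched, y),
                           truncation_age = config$truncation_age)),
        cyrs)
    }
    for (i in seq_len(length(cyrs) - 1)) {
      y1 <- cyrs[i]; y2 <- cyrs[i + 1]
      d <- decompose_by_age_cause(ab, tabs[[as.character(y1)]],
                                  tabs[[as.character(y2)]], y1, y2,
                                  functional = "edagger",
                                  n_steps = config$n_steps)
      if (d$residual > 1e-6 * max(1, abs(d$total)))
        stop("stage 'cause_decomp': residual above tolerance (", nm, ")")
      residuals <- c(residuals, d$residual)
      cause_rows[[length(cause_rows) + 1]] <-
        data.frame(country = nm, period = paste0(y1, "-", y2),
                   cause = names(d$by_cause),
                   contribution = unname(d$by_cause), total = d$total)
    }
  }
  cause_decomp <- do.call(rbind, cause_rows)
  write_stage(cause_decomp, file.path(out_dir, "cause_decomposition.tsv"),
              "contribution, total in years")

  # --- manifest -----------------------------------------------------------
  analysis_periods <- assign_periods(config$boundaries,
                                     span = range(years))
  manifest <- list(config = unclass(config),
                   countries = countries,
                   period_labels = analysis_periods$labels,
                   statistical_breaks = seg$original_breaks,
                   max_residual = max(residuals),
                   n_residuals = length(residuals))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  invisible(list(measures = measures, segmentation = seg,
                 improvement = improvement, quadrants = quad,
                 age_decomp = age_decomp, cause_decomp = cause_decomp,
                 e0 = e0_mat, e_dagger = ed_mat, cv_e0 = cv_series,
                 manifest = manifest))
}
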