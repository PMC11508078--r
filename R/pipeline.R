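# Reporting pipeline: configuration, stage orchestration, TSV rendering and
# a provenance log. Stages are the exported functions of the other modules;
# each stage's output is the next stage's input, so every stage is
# independently testable.

#' Build a run configuration
#'
#' @param measurements path to a measurements CSV, or `NULL` to simulate a
#'   campaign under `seed`.
#' @param budget path to a time-budget CSV, or `NULL` for the shipped default.
#' @param profiles path to an activity-profile CSV, or `NULL` for the shipped
#'   registry.
#' @param toxicology path to a toxicology CSV, or `NULL` for the shipped
#'   registry.
#' @param rounding `"paper"` (published-table rounding) or `"exact"`.
#' @param rfd_source `"annual"` or `"guideline"` PM reference dose.
#' @param dermal_cancer `"sf_over_g"` or `"sf_times_g"`.
#' @param bdl below-detection substitution: `"half_mdl"`, `"zero"`, `"mdl"`.
#' @param ed_source `"table"` (registry ED) or `"formula"`.
#' @param lcr_inh_basis `"dose"` or `"air"` inhalation cancer-risk basis.
#' @param seed integer seed; mandatory, echoed into the provenance log.
#' @param out_dir output directory for the report bundle.
#' @return list of class `merisk_config`.
#' @export
run_config <- function(measurements = NULL, budget = NULL, profiles = NULL,
                       toxicology = NULL,
                       rounding = c("paper", "exact"),
                       rfd_source = c("annual", "guideline"),
                       dermal_cancer = c("sf_over_g", "sf_times_g"),
                       bdl = c("half_mdl", "zero", "mdl"),
                       ed_source = c("table", "formula"),
                       lcr_inh_basis = c("dose", "air"),
                       seed = 1L, out_dir = tempfile("merisk_run_")) {
  cfg <- list(
    measurements = measurements, budget = budget, profiles = profiles,
    toxicology = toxicology,
    rounding = match.arg(rounding), rfd_source = match.arg(rfd_source),
    dermal_cancer = match.arg(dermal_cancer), bdl = match.arg(bdl),
    ed_source = match.arg(ed_source), lcr_inh_basis = match.arg(lcr_inh_basis),
    seed = as.integer(seed), out_dir = out_dir
  )
  for (f in c("measurements", "budget", "profiles", "toxicology")) {
    if (!is.null(cfg[[f]]) && !file.exists(cfg[[f]])) {
      stop_merisk("config file '%s' does not exist: %s", f, cfg[[f]])
    }
  }
  class(cfg) <- "merisk_config"
  cfg
}

#' Read a run configuration from JSON or YAML
#'
#' @param path a `.json` or `.yml`/`.yaml` document whose fields mirror the
#'   arguments of [run_config()].
#' @return a `merisk_config`.
#' @export
read_run_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  fields <- if (ext == "json") {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else if (ext %in% c("yml", "yaml")) {
    yaml::read_yaml(path)
  } else {
    stop_merisk("config must be .json or .yaml, got '%s'", path)
  }
  do.call(run_config, fields)
}

#' Run the full exposure-to-risk pipeline
#'
#' Stages: measurement input (file or simulated campaign), per-ME summaries,
#' time-weighted combined exposures, PM dose/hazard chain, element three-route
#' risk chain, TSV rendering and a provenance log. The bundle written to
#' `config$out_dir` is byte-identical across runs with the same configuration
#' and seed.
#'
#' @param config a [run_config()].
#' @return invisibly, a list with the stage tables and the bundle file paths.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "merisk_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop_merisk("stage '%s' failed: %s", name, conditionMessage(e))
    })
  }

  measurements <- stage("input", {
    if (is.null(config$measurements)) simulate_campaign(config$seed)
    else read_measurements(config$measurements)
  })
  budget <- stage("input", {
    if (is.null(config$budget)) default_time_budget()
    else read_time_budget(config$budget)
  })
  profiles <- stage("input", {
    if (is.null(config$profiles)) me_activity_profiles()
    else read_activity_profiles(config$profiles)
  })
  tox <- stage("input", {
    if (is.null(config$toxicology)) tox_registry()
    else read_tox_registry(config$toxicology)
  })

  summaries <- stage("summarize", summarize_measurements(measurements))

  pollutants <- unique(summaries$pollutant)
  exposures <- stage("expose", do.call(rbind, lapply(pollutants, function(p) {
    combine_profile(summaries, budget, p)
  })))

  pm <- exposures[exposures$pollutant %in% pm_pollutants, , drop = FALSE]
  pm_in <- data.frame(code = pm$combined_code, pollutant = pm$pollutant,
                      exposure_ugm3 = pm$exposure, stringsAsFactors = FALSE)
  pm_risk <- stage("pm-risk", pm_risk_table(
    pm_in, profiles, rfd_source = config$rfd_source,
    rounding = config$rounding, ed_source = config$ed_source))

  el <- exposures[!exposures$pollutant %in% pm_pollutants, , drop = FALSE]
  el_in <- data.frame(element = el$pollutant, code = el$combined_code,
                      mean_ugm3 = el$exposure, stringsAsFactors = FALSE)
  el_risk <- if (nrow(el_in)) {
    stage("element-risk", element_risk_table(
      el_in, tox, profiles,
      lcr_inh_basis = config$lcr_inh_basis,
      dermal_cancer = config$dermal_cancer))
  } else NULL
  el_summary <- if (!is.null(el_risk)) element_risk_summary(el_risk) else NULL

  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    summaries = write_tsv_file(render_table(summaries, "long"),
                               file.path(config$out_dir, "summaries.tsv")),
    exposure = write_tsv_file(render_table(exposures, "long"),
                              file.path(config$out_dir, "exposure.tsv")),
    pm_dose = write_tsv_file(render_table(pm_risk$doses, "table3"),
                             file.path(config$out_dir, "pm_dose.tsv")),
    pm_hazard = write_tsv_file(render_table(pm_risk, "table4"),
                               file.path(config$out_dir, "pm_hazard.tsv"))
  )
  if (!is.null(el_risk)) {
    el_exp_wide <- el_in
    names(el_exp_wide) <- c("element", "code", "mean_ugm3")
    paths <- c(paths,
      element_exposure = write_tsv_file(render_table(el_exp_wide, "table5"),
                                        file.path(config$out_dir, "element_exposure.tsv")),
      element_risk = write_tsv_file(render_table(el_risk, "long"),
                                    file.path(config$out_dir, "element_risk.tsv")),
      element_summary = write_tsv_file(render_table(el_summary, "table6_7"),
                                       file.path(config$out_dir, "element_summary.tsv")))
  }
  paths <- c(paths, provenance = write_provenance(
    config, measurements, file.path(config$out_dir, "provenance.txt")))

  invisible(list(
    measurements = measurements, summaries = summaries, exposures = exposures,
    pm_risk = pm_risk, element_risk = el_risk, element_summary = el_summary,
    paths = paths
  ))
}

#' Render a result table as TSV text
#'
#' Stable column order per layout; absent cells (missing reference doses or
#' potency factors) render as blank fields, never as zero; mean and SD stay
#' in separate machine-readable columns.
#'
#' @param rows a data.frame (or, for `"table4"`, the list returned by
#'   [pm_risk_table()]).
#' @param layout one of `"table3"` (dose + exposure per ME), `"table4"` (HQ
#'   rows and HI row, one column per ME), `"table5"` (element exposure, one
#'   column per ME), `"table6_7"` (per-route and grand HI/LCR totals),
#'   `"long"` (as-is).
#' @return a single TSV string (embedded newlines, trailing newline).
#' @export
render_table <- function(rows, layout = c("long", "table3", "table4", "table5", "table6_7")) {
  layout <- match.arg(layout)
  fmt_col <- function(col) {
    s <- if (is.numeric(col)) {
      vapply(col, function(x) format(x, trim = TRUE, scientific = FALSE, digits = 10),
             character(1))
    } else {
      as.character(col)
    }
    ifelse(is.na(col), "", s)
  }
  fmt <- function(df) {
    m <- vapply(df, fmt_col, character(nrow(df)))
    if (nrow(df) == 1) m <- matrix(m, nrow = 1, dimnames = list(NULL, names(df)))
    paste0(paste(colnames(m), collapse = "\t"), "\n",
           paste(apply(m, 1, paste, collapse = "\t"), collapse = "\n"), "\n")
  }
  if (layout == "table4") {
    if (!is.list(rows) || is.null(rows$doses) || is.null(rows$hi)) {
      stop_merisk("layout 'table4' expects the list returned by pm_risk_table()")
    }
    codes <- unique(rows$doses$code)
    lines <- c(paste(c("quantity", codes), collapse = "\t"))
    for (p in unique(rows$doses$pollutant)) {
      d <- rows$doses[rows$doses$pollutant == p, ]
      lines <- c(lines, paste(c(paste0("HQ ", p),
                                fmt_col(d$hq[match(codes, d$code)])),
                              collapse = "\t"))
    }
    lines <- c(lines, paste(c("HI", fmt_col(rows$hi$hi[match(codes, rows$hi$code)])),
                            collapse = "\t"))
    return(paste0(paste(lines, collapse = "\n"), "\n"))
  }
  if (layout == "table3") {
    wide <- stats::reshape(
      rows[, c("code", "pollutant", "exposure_ugm3", "add")],
      direction = "wide", idvar = "code", timevar = "pollutant")
    return(fmt(wide))
  }
  if (layout == "table5") {
    wide <- stats::reshape(rows, direction = "wide", idvar = "element",
                           timevar = "code")
    return(fmt(wide))
  }
  # long and table6_7: already in final shape
  fmt(rows)
}

write_tsv_file <- function(text, path) {
  con <- file(path, open = "wb") # fixed newline convention across platforms
  on.exit(close(con))
  writeLines(text, con, sep = "", useBytes = TRUE)
  path
}

# Provenance: config echo, seed, versions, record counts, and the known
# internal inconsistencies of the shipped published tables that a run may
# touch. Deliberately timestamp-free so identical runs are byte-identical.
write_provenance <- function(config, measurements, path) {
  cfg <- config
  class(cfg) <- NULL
  cfg$out_dir <- NULL
  cfg_lines <- vapply(sort(names(cfg)), function(n) {
    v <- cfg[[n]]
    sprintf("  %s: %s", n, if (is.null(v)) "<default>" else as.character(v))
  }, character(1))
  lines <- c(
    "merisk run provenance",
    sprintf("package version: %s", as.character(utils::packageVersion("merisk"))),
    "configuration:",
    cfg_lines,
    sprintf("records: %d (censored: %d, fraction %.4f)",
            nrow(measurements), sum(measurements$censored),
            mean(measurements$censored)),
    "known inconsistencies in the shipped published tables:",
    "  - registry ED for bundles A-I differs from EF*TA*EL/24 (e.g. A: 2209 vs 2188)",
    "  - registry TA for CC (9.07 h) implies ED 6897; the registry ED 6904 matches 9.08 h",
    "  - reported PM2.5 dose at CC (1.42) is inconsistent with its exposure 17.6 (chain: 2.19)",
    "  - reported PM10 dose at I (7.53) is inconsistent with its exposure 185 (chain: 7.67)",
    "  - published element risk tables are not reproducible from the stated parameters;",
    "    element results here follow the documented dose conventions instead"
  )
  write_tsv_file(paste0(paste(lines, collapse = "\n"), "\n"), path)
}
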