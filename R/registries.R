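# Shipped registries: activity profiles, PM reference doses, element
# toxicology, and the published exposure summaries they are applied to.
# All are plain CSV under inst/extdata so they double as format examples
# for user-supplied inputs.

me_codes_component <- c("LR", "EF", "KF", "CS", "RS", "CF", "IS", "TS")
me_codes_combined <- c("A", "B", "C", "D", "E", "F", "G", "H", "I", "AA", "BB", "CC")
pm_pollutants <- c("PM2.5", "PM10")

extdata <- function(file) {
  path <- system.file("extdata", file, package = "merisk", mustWork = TRUE)
  path
}

#' Activity profiles for the twelve combined microenvironments
#'
#' One row per combined microenvironment (ME) code: nine bundles that include
#' flatbread baking (A--I) and three that exclude it (AA--CC). Columns are the
#' daily activity time `ta_h` (h/day), exposure frequency `ef_dpy` (days/year),
#' exposure longevity `el_y` (years), exposure duration `ed_d` (days),
#' averaging time `at_d` (days), inhalation rate `ir_m3pd` (m3/day) and adult
#' body weight `bw_kg` (kg).
#'
#' The shipped `ed_d` values are the published registry values; for the A--I
#' bundles they differ slightly from the `ef * ta * el / 24` formula (see
#' [exposure_duration()]), so both are kept available and the choice is a
#' pipeline option.
#'
#' @return data.frame with 12 rows.
#' @export
me_activity_profiles <- function() {
  read_activity_profiles(extdata("activity_profiles.csv"))
}

#' Read an activity-profile table
#'
#' @param path CSV with header `code,ta_h,ef_dpy,el_y,ed_d,at_d,ir_m3pd,bw_kg`.
#' @return validated data.frame.
#' @export
read_activity_profiles <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("code", "ta_h", "ef_dpy", "el_y", "ed_d", "at_d", "ir_m3pd", "bw_kg")
  if (!all(need %in% names(df))) {
    stop_merisk("activity profile file must have columns %s", paste(need, collapse = ","))
  }
  for (col in need[-1]) check_number(df[[col]], col, positive = TRUE)
  if (any(df$ta_h > 24)) stop_merisk("ta_h must be <= 24 h/day")
  if (any(df$ef_dpy > 365)) stop_merisk("ef_dpy must be <= 365 days/year")
  df
}

#' Reference doses for particulate matter
#'
#' Guideline concentrations (10 and 20 ug/m3 for PM2.5 and PM10) and the
#' annual-average reference doses (3.24 and 6.56 ug/kg/day) against which the
#' published hazard quotients were computed. [pm_hazard_quotient()] defaults
#' to the annual values; see the methods vignette for the rationale.
#'
#' @return data.frame with one row per PM pollutant.
#' @export
pm_reference <- function() {
  data.frame(
    pollutant = pm_pollutants,
    rfd_guideline_ugm3 = c(10, 20),
    rfd_annual = c(3.24, 6.56),
    stringsAsFactors = FALSE
  )
}

#' Published PM exposure summaries per combined microenvironment
#'
#' Time-activity-weighted exposure concentration (mean, SD, ug/m3) and the
#' reported average daily dose for PM2.5 and PM10 in each of the twelve
#' combined MEs. Two reported dose cells are internally inconsistent with
#' their own exposure concentrations (PM2.5 at CC; PM10 at I); the risk
#' pipeline flags them and can recompute the chain-consistent values.
#'
#' @return data.frame with columns `code`, `pollutant`, `exposure_ugm3`,
#'   `sd_ugm3`, `add_reported`.
#' @export
pm_exposure_table <- function() {
  df <- utils::read.csv(extdata("pm_exposure.csv"), stringsAsFactors = FALSE)
  df
}

#' Published PM hazard quotients and hazard indices
#'
#' The hazard quotient rows for PM2.5 and PM10 and the hazard-index row, as
#' reported, for the twelve combined MEs. Used as input for hazard-index
#' reproduction and as a comparison surface in tests.
#'
#' @return data.frame with columns `code`, `hq_pm25`, `hq_pm10`, `hi`.
#' @export
pm_hq_table <- function() {
  utils::read.csv(extdata("pm_hq_reported.csv"), stringsAsFactors = FALSE)
}

#' Toxicology registry for trace elements in PM10
#'
#' Route-specific reference doses (mg/kg/day), inhalation unit risk
#' ((ug/m3)^-1), oral cancer slope factor ((mg/kg/day)^-1), gastrointestinal
#' absorption fraction `g`, and dermal absorption fraction `abs` for the ten
#' elements with registry entries. Blank cells propagate as `NA` ("no metric
#' defined"), never as zero. `carcinogen` is TRUE where a cancer potency
#' factor (IUR or SF) exists: Pb, Cr, Cd, As, Ni.
#'
#' Sn and Co are measured in the exposure tables but have no registry entry;
#' they yield exposure output but no risk output.
#'
#' @return data.frame with one row per element.
#' @export
tox_registry <- function() {
  read_tox_registry(extdata("tox_registry.csv"))
}

#' Read a toxicology table
#'
#' @param path CSV with header `element,rfd_inh,rfd_ing,rfd_der,iur,sf,g,abs`;
#'   blank cells are allowed and read as `NA`.
#' @return validated data.frame with a derived `carcinogen` column.
#' @export
read_tox_registry <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(element = "character"))
  need <- c("element", "rfd_inh", "rfd_ing", "rfd_der", "iur", "sf", "g", "abs")
  if (!all(need %in% names(df))) {
    stop_merisk("toxicology file must have columns %s", paste(need, collapse = ","))
  }
  for (col in need[-1]) {
    v <- df[[col]]
    if (any(!is.na(v) & v <= 0)) stop_merisk("'%s' entries must be > 0 or blank", col)
  }
  if (any(!is.na(df$abs) & df$abs > 1)) stop_merisk("'abs' must lie in (0, 1]")
  df$carcinogen <- !is.na(df$iur) | !is.na(df$sf)
  df
}

#' Published element exposure summaries per combined microenvironment
#'
#' Arithmetic mean and SD (ug/m3) of twelve trace elements bound to PM10 for
#' each combined ME. These feed both the element risk chain and the default
#' synthetic element generator.
#'
#' @return long data.frame with columns `element`, `code`, `mean_ugm3`,
#'   `sd_ugm3`.
#' @export
element_exposure_table <- function() {
  utils::read.csv(extdata("element_exposure.csv"), stringsAsFactors = FALSE,
                  colClasses = c(element = "character", code = "character"))
}

#' Default time budget for the combined microenvironments
#'
#' Hours per day spent in each component ME (living room LR, roadside RS,
#' stew-cooking kitchens EF/KF/CS, flatbread-baking kitchens CF/IS/TS) for
#' every combined code. Per-activity splits are not published, only the
#' daily totals; this shipped default reproduces those totals row-for-row
#' while using a fixed 7 h living room + 1 h roadside allocation.
#'
#' @return data.frame with columns `combined_code`, `me_code`, `hours`.
#' @export
default_time_budget <- function() {
  read_time_budget(extdata("time_budget_default.csv"))
}

#' Read a time-budget table
#'
#' @param path CSV with header `combined_code,me_code,hours`.
#' @return validated data.frame.
#' @export
read_time_budget <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("combined_code", "me_code", "hours")
  if (!all(need %in% names(df))) {
    stop_merisk("time budget file must have columns %s", paste(need, collapse = ","))
  }
  check_number(df$hours, "hours", positive = TRUE)
  df
}
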