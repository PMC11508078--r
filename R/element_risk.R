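# Three-route risk chain for trace elements bound to PM10: inhalation,
# ingestion and dermal doses, hazard quotients/indices, lifetime cancer risk.

#' Exposure context for the element risk chain
#'
#' Bundles the receptor parameters of the route dose equations. Defaults are
#' the adult receptor of the shipped study design: inhalation rate 20 m3/day,
#' ingestion rate 100 mg/day, skin surface area 2011 cm2, adherence factor
#' 0.07 mg/cm2/day, body weight 60.5 kg, exposure duration 50 years,
#' noncancer averaging time 18250 days (50 y x 365) and cancer averaging
#' time 25550 days (70 y x 365).
#'
#' `basis` declares what the concentration `c` means for the ingestion and
#' dermal equations: `"mass"` expects `c_mass` in mg of element per kg of
#' particulate (the conventional basis for the 1e-6 unit factor those
#' equations carry); `"literal"` feeds the air concentration (ug/m3) into all
#' three equations unchanged, mirroring the published usage. Inhalation
#' always uses the air concentration (converted to mg/m3 internally).
#'
#' @param c_air element concentration in air, ug/m3 (>= 0).
#' @param c_mass element content of particulate, mg/kg (required for
#'   `basis = "mass"`).
#' @param basis `"literal"` or `"mass"`.
#' @param inhr inhalation rate, m3/day.
#' @param ingr ingestion rate, mg/day.
#' @param sa exposed skin surface area, cm2.
#' @param af skin adherence factor, mg/cm2/day.
#' @param ef exposure frequency, days/year.
#' @param ed_years exposure duration, years.
#' @param bw body weight, kg.
#' @param at_noncancer,at_cancer averaging times, days.
#' @return list of class `exposure_context`.
#' @export
exposure_context <- function(c_air, c_mass = NULL, basis = c("literal", "mass"),
                             inhr = 20, ingr = 100, sa = 2011, af = 0.07,
                             ef = 365, ed_years = 50, bw = 60.5,
                             at_noncancer = 18250, at_cancer = 25550) {
  basis <- match.arg(basis)
  check_number(c_air, "c_air", nonnegative = TRUE)
  if (basis == "mass") {
    if (is.null(c_mass)) stop_merisk("basis 'mass' requires c_mass (mg element per kg particulate)")
    check_number(c_mass, "c_mass", nonnegative = TRUE)
  }
  for (nm in c("inhr", "ingr", "sa", "af", "ef", "ed_years", "bw",
               "at_noncancer", "at_cancer")) {
    check_number(get(nm), nm, positive = TRUE)
  }
  structure(list(c_air = c_air, c_mass = c_mass, basis = basis, inhr = inhr,
                 ingr = ingr, sa = sa, af = af, ef = ef, ed_years = ed_years,
                 bw = bw, at_noncancer = at_noncancer, at_cancer = at_cancer),
            class = "exposure_context")
}

at_days <- function(ctx, at = c("noncancer", "cancer")) {
  at <- match.arg(at)
  if (at == "noncancer") ctx$at_noncancer else ctx$at_cancer
}

ingestion_basis_conc <- function(ctx) {
  switch(ctx$basis,
    literal = ctx$c_air,
    mass = ctx$c_mass)
}

#' Inhalation dose
#'
#' D_inh = C_mg x InhR x EF x ED / (BW x AT), mg/kg/day, where the air
#' concentration in ug/m3 is converted to mg/m3 internally.
#'
#' @param ctx an [exposure_context()].
#' @param at `"noncancer"` (default) or `"cancer"` averaging time.
#' @return dose, mg/kg/day.
#' @export
inhalation_dose <- function(ctx, at = c("noncancer", "cancer")) {
  (ctx$c_air / 1000) * ctx$inhr * ctx$ef * ctx$ed_years / (ctx$bw * at_days(ctx, at))
}

#' Ingestion dose
#'
#' D_ing = C x IngR x EF x ED / (BW x AT) x 1e-6, mg/kg/day. `C` follows the
#' context's declared basis (see [exposure_context()]).
#'
#' @inheritParams inhalation_dose
#' @return dose, mg/kg/day.
#' @export
ingestion_dose <- function(ctx, at = c("noncancer", "cancer")) {
  ingestion_basis_conc(ctx) * ctx$ingr * ctx$ef * ctx$ed_years /
    (ctx$bw * at_days(ctx, at)) * 1e-6
}

#' Dermal dose
#'
#' D_der = C x AF x SA x ABS x EF x ED / (BW x AT) x 1e-6, mg/kg/day, with
#' ABS the element-specific dermal absorption fraction (0.001 Cd, 0.030 As,
#' 0.010 otherwise).
#'
#' @inheritParams inhalation_dose
#' @param abs_dermal dermal absorption fraction in (0, 1].
#' @return dose, mg/kg/day.
#' @export
dermal_dose <- function(ctx, abs_dermal, at = c("noncancer", "cancer")) {
  check_number(abs_dermal, "abs_dermal", nonnegative = TRUE)
  if (any(abs_dermal > 1)) stop_merisk("abs_dermal must lie in [0, 1]")
  ingestion_basis_conc(ctx) * ctx$af * ctx$sa * abs_dermal * ctx$ef *
    ctx$ed_years / (ctx$bw * at_days(ctx, at)) * 1e-6
}

#' Hazard quotient for one route
#'
#' HQ = D / RfD. A missing reference dose (blank registry cell) yields `NA`
#' ("no metric defined"), never zero, and is excluded from index sums.
#'
#' @param dose route dose, mg/kg/day (>= 0).
#' @param rfd route-specific reference dose, mg/kg/day, or `NA`.
#' @return hazard quotient, or `NA` where no RfD exists.
#' @export
route_hazard_quotient <- function(dose, rfd) {
  check_number(dose, "dose", nonnegative = TRUE)
  if (length(rfd) == 1) rfd <- rep_len(rfd, length(dose))
  if (any(!is.na(rfd) & rfd <= 0)) stop_merisk("rfd must be > 0")
  ifelse(is.na(rfd), NA_real_, dose / rfd)
}

#' Aggregate a hazard-quotient table over its margins
#'
#' @param hq_table numeric matrix or data.frame, elements x routes, `NA` for
#'   absent cells.
#' @param mode `"element_all_routes"` (per-element sum over routes),
#'   `"route_all_elements"` (per-route sum over elements),
#'   `"all_elements_all_routes"` (grand total), or `"single"` (the one cell of
#'   a 1x1 table).
#' @return named vector (margin modes) or scalar.
#' @export
aggregate_hi <- function(hq_table,
                         mode = c("element_all_routes", "route_all_elements",
                                  "all_elements_all_routes", "single")) {
  mode <- match.arg(mode)
  m <- as.matrix(hq_table)
  if (!is.numeric(m)) stop_merisk("hq_table must be numeric")
  switch(mode,
    element_all_routes = apply(m, 1, function(r) sum(r, na.rm = TRUE)),
    route_all_elements = apply(m, 2, function(r) sum(r, na.rm = TRUE)),
    all_elements_all_routes = sum(m, na.rm = TRUE),
    single = {
      if (length(m) != 1) stop_merisk("mode 'single' needs a 1x1 table")
      m[[1]]
    })
}

#' Lifetime cancer risk for one element in one microenvironment
#'
#' LCR_inh = D_inh x IUR (or C_air x IUR under the concentration convention,
#' where the unit risk's (ug/m3)^-1 units apply directly);
#' LCR_ing = D_ing x SF; LCR_der = D_der x SF / GIABS by default (the dermal
#' slope-factor adjustment), or D_der x SF x G under the literal alternate.
#' Routes whose potency factor is absent yield `NA` and are excluded from the
#' total.
#'
#' @param ctx an [exposure_context()]; cancer averaging time is used.
#' @param tox one row of [tox_registry()] (a list or one-row data.frame).
#' @param lcr_inh_basis `"dose"` (literal equation) or `"air"` (concentration
#'   convention).
#' @param dermal_cancer `"sf_over_g"` (default) or `"sf_times_g"`.
#' @return list with `lcr_inh`, `lcr_ing`, `lcr_der`, `lcr_total`, `band`.
#' @export
lifetime_cancer_risk <- function(ctx, tox,
                                 lcr_inh_basis = c("dose", "air"),
                                 dermal_cancer = c("sf_over_g", "sf_times_g")) {
  lcr_inh_basis <- match.arg(lcr_inh_basis)
  dermal_cancer <- match.arg(dermal_cancer)
  if (!isTRUE(tox$carcinogen)) {
    stop_merisk("no cancer metrics defined for element '%s'", tox$element)
  }
  lcr_inh <- if (is.na(tox$iur)) NA_real_ else {
    if (lcr_inh_basis == "dose") inhalation_dose(ctx, "cancer") * tox$iur
    else ctx$c_air * tox$iur
  }
  lcr_ing <- if (is.na(tox$sf)) NA_real_ else ingestion_dose(ctx, "cancer") * tox$sf
  lcr_der <- if (is.na(tox$sf) || is.na(tox$g)) NA_real_ else {
    d <- dermal_dose(ctx, tox$abs, "cancer")
    if (dermal_cancer == "sf_over_g") d * tox$sf / tox$g else d * tox$sf * tox$g
  }
  parts <- c(lcr_inh, lcr_ing, lcr_der)
  total <- if (all(is.na(parts))) NA_real_ else sum(parts, na.rm = TRUE)
  list(lcr_inh = lcr_inh, lcr_ing = lcr_ing, lcr_der = lcr_der,
       lcr_total = total,
       band = if (is.na(total)) NA_character_ else classify_lcr(total))
}

#' Classify a lifetime cancer risk value
#'
#' The conventional regulatory bands: below 1e-6 negligible, 1e-6 to 1e-4
#' (closed interval) tolerable, above 1e-4 unacceptable.
#'
#' @param lcr lifetime cancer risk (>= 0), vectorized.
#' @return character band.
#' @export
classify_lcr <- function(lcr) {
  check_number(lcr, "lcr", nonnegative = TRUE)
  ifelse(lcr < 1e-6, "negligible",
         ifelse(lcr <= 1e-4, "tolerable", "unacceptable"))
}

#' Full element risk chain for a set of microenvironments
#'
#' Runs the three route doses, per-route hazard quotients, per-element hazard
#' index and lifetime cancer risk for every (element, code) in an element
#' exposure table. Elements without a toxicology entry (here Sn and Co) are
#' silently dropped from the risk output; their exposure rows remain in the
#' input table.
#'
#' @param exposure data.frame with columns `element`, `code`, `mean_ugm3`
#'   (air concentrations); defaults to [element_exposure_table()].
#' @param tox toxicology registry, defaults to [tox_registry()].
#' @param profiles activity profiles supplying the per-code exposure
#'   frequency; defaults to [me_activity_profiles()].
#' @param basis,bw,ed_years,at_noncancer,at_cancer receptor settings passed to
#'   [exposure_context()] (`basis = "literal"` feeds air concentrations to all
#'   routes; no particulate mass data ship with the package).
#' @param lcr_inh_basis,dermal_cancer cancer-mode settings, see
#'   [lifetime_cancer_risk()].
#' @return long data.frame: one row per (code, element) with doses, route
#'   HQs, `hi_element`, route LCRs, `lcr_total` and `band`.
#' @export
element_risk_table <- function(exposure = element_exposure_table(),
                               tox = tox_registry(),
                               profiles = me_activity_profiles(),
                               basis = "literal", bw = 60.5, ed_years = 50,
                               at_noncancer = 18250, at_cancer = 25550,
                               lcr_inh_basis = "dose",
                               dermal_cancer = "sf_over_g") {
  keep <- exposure$element %in% tox$element
  exposure <- exposure[keep, , drop = FALSE]
  rows <- lapply(seq_len(nrow(exposure)), function(k) {
    el <- exposure$element[k]
    code <- exposure$code[k]
    t <- as.list(tox[tox$element == el, , drop = FALSE])
    ef <- profiles$ef_dpy[match(code, profiles$code)]
    if (is.na(ef)) stop_merisk("no activity profile for ME '%s'", code)
    ctx <- exposure_context(c_air = exposure$mean_ugm3[k], basis = basis,
                            ef = ef, ed_years = ed_years, bw = bw,
                            at_noncancer = at_noncancer, at_cancer = at_cancer)
    d_inh <- inhalation_dose(ctx)
    d_ing <- ingestion_dose(ctx)
    d_der <- dermal_dose(ctx, t$abs)
    hq <- c(inh = route_hazard_quotient(d_inh, t$rfd_inh),
            ing = route_hazard_quotient(d_ing, t$rfd_ing),
            der = route_hazard_quotient(d_der, t$rfd_der))
    lcr <- if (isTRUE(t$carcinogen)) {
      lifetime_cancer_risk(ctx, t, lcr_inh_basis, dermal_cancer)
    } else {
      list(lcr_inh = NA_real_, lcr_ing = NA_real_, lcr_der = NA_real_,
           lcr_total = NA_real_, band = NA_character_)
    }
    data.frame(
      code = code, element = el,
      d_inh = d_inh, d_ing = d_ing, d_der = d_der,
      hq_inh = hq[["inh"]], hq_ing = hq[["ing"]], hq_der = hq[["der"]],
      hi_element = sum(hq, na.rm = TRUE),
      lcr_inh = lcr$lcr_inh, lcr_ing = lcr$lcr_ing, lcr_der = lcr$lcr_der,
      lcr_total = lcr$lcr_total, band = lcr$band,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Aggregate an element risk table the way the published summaries are laid out
#'
#' @param risk output of [element_risk_table()].
#' @return data.frame per code: route HI totals, grand HI (all elements, all
#'   routes), route LCR totals and grand LCR, with noncancer/cancer
#'   classifications.
#' @export
element_risk_summary <- function(risk) {
  rows <- lapply(split(risk, risk$code), function(r) {
    hq <- as.matrix(r[, c("hq_inh", "hq_ing", "hq_der")])
    rownames(hq) <- r$element
    route_hi <- aggregate_hi(hq, "route_all_elements")
    grand_hi <- aggregate_hi(hq, "all_elements_all_routes")
    lcr_total <- sum(r$lcr_total, na.rm = TRUE)
    data.frame(
      code = r$code[1],
      hi_inh = route_hi[["hq_inh"]], hi_ing = route_hi[["hq_ing"]],
      hi_der = route_hi[["hq_der"]], hi_total = grand_hi,
      hi_class = classify_noncancer(grand_hi),
      lcr_inh = sum(r$lcr_inh, na.rm = TRUE),
      lcr_ing = sum(r$lcr_ing, na.rm = TRUE),
      lcr_der = sum(r$lcr_der, na.rm = TRUE),
      lcr_total = lcr_total,
      lcr_band = classify_lcr(lcr_total),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  out <- out[match(unique(risk$code), out$code), , drop = FALSE]
  rownames(out) <- NULL
  out
}
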