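# Element three-route doses, hazard aggregation and cancer risk.

ctx_cd_a <- exposure_context(c_air = 0.013, ef = 104, ed_years = 50,
                             bw = 60.5, at_noncancer = 18250)

test_that("route doses match hand arithmetic and are linear in C", {
  # Cd at ME A: 1.3e-5 mg/m3 * 20 * 104 * 50 / (60.5 * 18250)
  expect_equal(inhalation_dose(ctx_cd_a), 1.224499038e-06, tolerance = 1e-9)
  expect_equal(inhalation_dose(exposure_context(0, ef = 104)), 0)

  ctx_mass <- exposure_context(c_air = 0, c_mass = 100, basis = "mass",
                               ef = 365, ed_years = 50, bw = 60.5,
                               at_noncancer = 18250)
  expect_equal(ingestion_dose(ctx_mass), 1.652892562e-04, tolerance = 1e-9)
  expect_equal(dermal_dose(ctx_mass, 0.010), 2.32677686e-06, tolerance = 1e-9)
  expect_equal(dermal_dose(ctx_mass, 0), 0)

  set.seed(31)
  for (i in 1:15) {
    c0 <- runif(1, 0.001, 0.5); k <- runif(1, 0.2, 5)
    ef <- sample(c(104, 365), 1)
    ctx1 <- exposure_context(c_air = c0, ef = ef)
    ctxk <- exposure_context(c_air = k * c0, ef = ef)
    expect_equal(inhalation_dose(ctxk), k * inhalation_dose(ctx1))
    expect_equal(ingestion_dose(ctxk), k * ingestion_dose(ctx1))
    expect_equal(dermal_dose(ctxk, 0.01), k * dermal_dose(ctx1, 0.01))
    # halving body weight doubles every dose
    ctx_half <- exposure_context(c_air = c0, ef = ef, bw = 60.5 / 2)
    expect_equal(ingestion_dose(ctx_half),
                 2 * ingestion_dose(exposure_context(c_air = c0, ef = ef)))
  }
  expect_error(exposure_context(c_air = 1, basis = "mass"), "c_mass")
})

test_that("route HQ propagates absent reference doses as NA, never zero", {
  expect_equal(route_hazard_quotient(1e-6, 1e-5), 0.1)
  expect_equal(route_hazard_quotient(0, 0.5), 0)
  tox <- tox_registry()
  fe <- tox[tox$element == "Fe", ]
  expect_true(is.na(fe$rfd_inh))
  expect_true(is.na(route_hazard_quotient(1e-6, fe$rfd_inh)))
  expect_error(route_hazard_quotient(1e-6, -2), "rfd")
})

test_that("aggregate_hi margins agree with brute-force summation", {
  m <- matrix(c(0.1, NA, 0.02,
                0.3, 0.04, NA,
                NA, 0.005, 0.6), nrow = 3, byrow = TRUE,
              dimnames = list(c("Cr", "Cd", "As"), c("inh", "ing", "der")))
  o <- oracle_margin_sums(m)
  expect_equal(unname(aggregate_hi(m, "element_all_routes")), o$by_element)
  expect_equal(unname(aggregate_hi(m, "route_all_elements")), o$by_route)
  expect_equal(aggregate_hi(m, "all_elements_all_routes"), o$grand)
  # margin consistency: both margins sum to the grand total
  expect_equal(sum(aggregate_hi(m, "element_all_routes")), o$grand)
  expect_equal(sum(aggregate_hi(m, "route_all_elements")), o$grand)

  zero <- matrix(0, 2, 3)
  expect_equal(aggregate_hi(zero, "all_elements_all_routes"), 0)
  one <- matrix(0.42, 1, 1)
  expect_equal(aggregate_hi(one, "single"), 0.42)
  expect_equal(aggregate_hi(one, "all_elements_all_routes"), 0.42)
  expect_error(aggregate_hi(m, "diagonal"))

  # summing the ten published per-element totals for ME A gives 1.2399
  # (the source prints 1.2398 as its own grand total)
  tab_a <- c(9.8e-05, 0.0007, 0.6527, 0.0008, 0.0007, 0.0143, 0.0159,
             0.2462, 0.2374, 0.0711)
  expect_equal(aggregate_hi(matrix(tab_a, ncol = 1), "all_elements_all_routes"),
               1.239898, tolerance = 1e-10)
})

test_that("lifetime cancer risk applies the route potency factors", {
  tox <- tox_registry()
  as_row <- as.list(tox[tox$element == "As", ])
  cr_row <- as.list(tox[tox$element == "Cr", ])
  fe_row <- as.list(tox[tox$element == "Fe", ])

  ctx0 <- exposure_context(c_air = 0, ef = 104)
  z <- lifetime_cancer_risk(ctx0, as_row)
  expect_equal(z$lcr_inh, 0)
  expect_equal(z$lcr_ing, 0)
  expect_equal(z$lcr_der, 0)
  expect_equal(z$lcr_total, 0)

  # ingestion: dose times slope factor (As SF = 1.5)
  ctx <- exposure_context(c_air = 0.02, ef = 104)
  r <- lifetime_cancer_risk(ctx, as_row)
  expect_equal(r$lcr_ing, ingestion_dose(ctx, "cancer") * 1.5)
  # dermal default divides by GIABS: Cr sf 0.5 / g 0.025 = 20x
  rc <- lifetime_cancer_risk(ctx, cr_row)
  expect_equal(rc$lcr_der, dermal_dose(ctx, 0.010, "cancer") * 0.5 / 0.025)
  rl <- lifetime_cancer_risk(ctx, cr_row, dermal_cancer = "sf_times_g")
  expect_equal(rl$lcr_der, dermal_dose(ctx, 0.010, "cancer") * 0.5 * 0.025)
  # direct products at the spec'd magnitudes
  expect_equal(1e-5 * 1.5, 1.5e-5)
  expect_equal(rc$lcr_der / dermal_dose(ctx, 0.010, "cancer"), 20)

  # air-concentration convention for the inhalation unit risk
  ra <- lifetime_cancer_risk(ctx, as_row, lcr_inh_basis = "air")
  expect_equal(ra$lcr_inh, 0.02 * 0.043)

  expect_error(lifetime_cancer_risk(ctx, fe_row), "no cancer metrics")
})

test_that("LCR bands partition with a closed tolerable interval", {
  expect_equal(classify_lcr(5e-5), "tolerable")
  expect_equal(classify_lcr(1e-7), "negligible")
  expect_equal(classify_lcr(2e-4), "unacceptable")
  expect_equal(classify_lcr(1e-6), "tolerable")
  expect_equal(classify_lcr(1e-4), "tolerable")
  expect_equal(classify_lcr(0.999e-6), "negligible")
  expect_equal(classify_lcr(1.001e-4), "unacceptable")
  expect_error(classify_lcr(-1e-6), "lcr")
})

test_that("the shipped toxicology registry matches the source cell for cell", {
  tox <- tox_registry()
  expect_equal(tox$element, expected_tox$element)
  for (col in names(expected_tox)[-1]) {
    expect_equal(tox[[col]], expected_tox[[col]], info = col)
  }
  expect_equal(tox$element[tox$carcinogen], c("Pb", "Cr", "Cd", "As", "Ni"))
})

test_that("elements without registry entries yield exposure but no risk rows", {
  exp_tab <- element_exposure_table()
  expect_true(all(c("Sn", "Co") %in% exp_tab$element))
  risk <- element_risk_table()
  expect_false(any(c("Sn", "Co") %in% risk$element))
  expect_setequal(unique(risk$element), expected_tox$element)
  # Fe/B lack inhalation and dermal reference doses; Fe/B/Zn lack cancer
  # potency, so inhalation LCR is absent for them
  expect_true(all(is.na(risk$hq_inh[risk$element %in% c("Fe", "B")])))
  expect_true(all(is.na(risk$lcr_inh[risk$element %in% c("Fe", "B", "Zn")])))
  # per-element HI equals the exact sum of its present route HQs
  hq_sum <- rowSums(risk[, c("hq_inh", "hq_ing", "hq_der")], na.rm = TRUE)
  expect_equal(risk$hi_element, hq_sum)
})

test_that("element_risk_summary margins are mutually consistent", {
  risk <- element_risk_table()
  s <- element_risk_summary(risk)
  expect_equal(s$hi_total, s$hi_inh + s$hi_ing + s$hi_der)
  for (code in c("A", "CC")) {
    r <- risk[risk$code == code, ]
    expect_equal(s$hi_total[s$code == code], sum(r$hi_element))
  }
  expect_true(all(s$lcr_band %in% c("negligible", "tolerable", "unacceptable")))
})
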