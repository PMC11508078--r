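# PM dose and hazard chain against the published twelve-ME tables.

test_that("exposure_duration follows EF*TA*EL/24 and exposes the registry gap", {
  expect_equal(exposure_duration(365, 8.85, 50)$days, 6730)
  expect_equal(exposure_duration(365, 24, 1)$days, 365)
  # baking bundles: the formula and the shipped registry disagree; the
  # registry keeps the published 2209 for A while the formula gives 2188
  ed_a <- exposure_duration(104, 10.1, 50)
  expect_equal(ed_a$days, 2188)
  expect_equal(ed_a$exact, 104 * 10.1 * 50 / 24)
  prof <- me_activity_profiles()
  expect_equal(prof$ed_d[prof$code == "A"], 2209)
  expect_error(exposure_duration(-1, 8, 50), "ef")
})

test_that("average_daily_dose reproduces the dose table where consistent", {
  prof <- me_activity_profiles()
  exp_tab <- pm_exposure_table()
  chain <- function(code, pollutant) {
    p <- prof[prof$code == code, ]
    e <- exp_tab[exp_tab$code == code & exp_tab$pollutant == pollutant, ]
    average_daily_dose(e$exposure_ugm3, p$ir_m3pd, p$ed_d, p$at_d, p$bw_kg)
  }
  expect_equal(signif_half_up(chain("A", "PM2.5"), 3), 0.423)
  expect_equal(signif_half_up(chain("CC", "PM10"), 3), 19.4)
  expect_equal(chain("D", "PM2.5") * 0, 0) # zero concentration gives zero
  expect_equal(average_daily_dose(0, 20, 2209, 18250, 60.7), 0)

  # cells whose published value equals the chain at 3 s.f.
  consistent <- list(c("A", "PM2.5"), c("F", "PM2.5"), c("G", "PM2.5"),
                     c("I", "PM2.5"), c("AA", "PM2.5"), c("BB", "PM2.5"),
                     c("A", "PM10"), c("C", "PM10"), c("G", "PM10"),
                     c("CC", "PM10"))
  for (cell in consistent) {
    reported <- exp_tab$add_reported[exp_tab$code == cell[1] &
                                       exp_tab$pollutant == cell[2]]
    expect_equal(signif_half_up(chain(cell[1], cell[2]), 3), reported,
                 info = paste(cell, collapse = " "))
  }
  # two cells are irreconcilable with their own exposure concentrations;
  # the chain-consistent values are asserted instead
  expect_equal(signif_half_up(chain("CC", "PM2.5"), 3), 2.19) # reported 1.42
  expect_equal(signif_half_up(chain("I", "PM10"), 3), 7.67)   # reported 7.53
})

test_that("dose is linear in concentration/intake and monotone in bw/at", {
  set.seed(7)
  for (i in 1:20) {
    c0 <- runif(1, 1, 200); ir <- runif(1, 5, 30); ed <- runif(1, 100, 7000)
    at <- runif(1, 1000, 30000); bw <- runif(1, 40, 90); k <- runif(1, 0.1, 4)
    base <- average_daily_dose(c0, ir, ed, at, bw)
    expect_equal(average_daily_dose(k * c0, ir, ed, at, bw), k * base)
    expect_equal(average_daily_dose(c0, k * ir, ed, at, bw), k * base)
    expect_lt(average_daily_dose(c0, ir, ed, at, bw * 1.5), base)
    expect_lt(average_daily_dose(c0, ir, ed, at * 1.5, bw), base)
    expect_equal(base, oracle_add(c0, ir, ed, at, bw))
  }
})

test_that("pm_hazard_quotient supports annual and guideline reference doses", {
  expect_equal(round_half_up(pm_hazard_quotient(5.10, "PM10"), 3), 0.777)
  expect_equal(pm_hazard_quotient(0, "PM2.5"), 0)
  expect_equal(pm_hazard_quotient(3.24, "PM2.5"), 1)
  expect_equal(pm_hazard_quotient(20, "PM10", rfd_source = "guideline"), 1)
  expect_error(pm_hazard_quotient(1, "O3"), "unknown pollutant")
  # the published 0.130 for (0.423, PM2.5) only follows from the unrounded
  # dose chain: from the printed dose the quotient is 0.1306
  expect_equal(round_half_up(pm_hazard_quotient(0.423, "PM2.5"), 3), 0.131)
  expect_equal(round_half_up(pm_hazard_quotient(10.6 * 20 * 2209 / (18250 * 60.7),
                                                "PM2.5"), 3), 0.130)
})

test_that("hazard_index sums exactly and reproduces the published row", {
  expect_equal(hazard_index(numeric(0)), 0)
  expect_equal(hazard_index(c(0.2, 0.3, 0.1)), 0.6)
  expect_equal(hazard_index(c(0.130, 0.777), rounding = "paper"), 0.907)
  expect_equal(hazard_index(c(1.522, 1.15), rounding = "paper"), 2.67)
  hq <- pm_hq_table()
  for (i in seq_len(nrow(hq))) {
    expect_equal(hazard_index(c(hq$hq_pm25[i], hq$hq_pm10[i]), "paper"),
                 hq$hi[i], info = hq$code[i])
  }
  expect_error(hazard_index(c(0.1, -0.2)), "hqs")
})

test_that("noncancer classification treats unity as acceptable", {
  expect_equal(classify_noncancer(0.907), "acceptable")
  expect_equal(classify_noncancer(1.0), "acceptable")
  expect_equal(classify_noncancer(2.67), "significant risk")
  expect_error(classify_noncancer(-0.1), "value")
})

test_that("pm_risk_table runs the chain for all twelve MEs", {
  res <- pm_risk_table(pm_exposure_table())
  expect_equal(nrow(res$doses), 24)
  expect_equal(nrow(res$hi), 12)
  expect_setequal(res$hi$code, c("A", "B", "C", "D", "E", "F", "G", "H", "I",
                                 "AA", "BB", "CC"))
  a <- res$doses[res$doses$code == "A", ]
  expect_equal(a$add[a$pollutant == "PM2.5"], 0.423)
  # exact mode: HI equals the exact HQ sum
  exact <- pm_risk_table(pm_exposure_table(), rounding = "exact")
  for (code in exact$hi$code) {
    expect_equal(exact$hi$hi[exact$hi$code == code],
                 sum(exact$doses$hq[exact$doses$code == code]))
  }
})
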