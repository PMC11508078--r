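# Independent oracles and small fixtures built in code.

# spreadsheet-style one-liners, kept deliberately separate from the package
# implementations they check
oracle_weighted_mean <- function(conc, hours, total) sum(conc * hours) / total
oracle_add <- function(c, ir, ed, at, bw) c * ir * ed / (at * bw)

# brute-force margin summation over an elements x routes matrix
oracle_margin_sums <- function(m) {
  by_el <- sapply(seq_len(nrow(m)), function(i) sum(m[i, ], na.rm = TRUE))
  by_rt <- sapply(seq_len(ncol(m)), function(j) sum(m[, j], na.rm = TRUE))
  list(by_element = by_el, by_route = by_rt, grand = sum(m, na.rm = TRUE))
}

# the published toxicology registry, independently transcribed for
# cell-for-cell fidelity checks (element order Fe Cu Mn B Zn Pb Cr Cd As Ni)
expected_tox <- data.frame(
  element = c("Fe", "Cu", "Mn", "B", "Zn", "Pb", "Cr", "Cd", "As", "Ni"),
  rfd_inh = c(NA, 0.040, 0.00005, NA, 0.040, 0.0035, 0.0004, 0.00001, 0.000015, 0.00005),
  rfd_ing = c(0.070, 0.040, 0.140, 0.200, 0.300, 0.0035, 0.0003, 0.001, 0.015, 0.050),
  rfd_der = c(NA, 1.00, 1.00, NA, 1.00, 1.00, 0.025, 0.025, 1.00, 0.040),
  iur = c(NA, NA, NA, NA, NA, 0.00008, 0.012, 0.0018, 0.043, 0.0024),
  sf = c(NA, NA, NA, NA, NA, 0.280, 0.50, 0.640, 1.50, 0.084),
  g = c(NA, NA, NA, NA, NA, 1.00, 0.025, 0.025, 1.00, 0.040),
  abs = c(0.010, 0.010, 0.010, 0.010, 0.010, 0.010, 0.010, 0.001, 0.030, 0.010),
  stringsAsFactors = FALSE
)

# a tiny deterministic summary/budget pair for composition checks
toy_summaries <- function() {
  data.frame(
    me_code = c("LR", "RS", "CS", "TS"),
    pollutant = "PM2.5",
    n = 5L, gm = c(17, 55, 95, 190), gsd = 1.5,
    am = c(20, 60, 100, 200), sd = 5,
    stringsAsFactors = FALSE
  )
}
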