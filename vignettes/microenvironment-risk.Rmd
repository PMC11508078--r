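---
title: "Microenvironment exposure and health-risk modelling with merisk"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Microenvironment exposure and health-risk modelling with merisk}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(merisk)
```

## The model

People do not breathe one air. Over a day an adult moves through a handful of
*microenvironments* (MEs) — the living room, the kitchen while cooking stew or
baking flatbread on different stove types, the roadside while commuting — each
with its own pollutant concentration and occupancy time. The exposure
concentration of an individual over an activity bundle is the
occupancy-time-weighted mean

$$E = \frac{1}{T}\sum_{j=1}^{m} C_j\, t_j,$$

where $C_j$ is the concentration in ME $j$ (µg/m³), $t_j$ the time spent
there, and $T$ the total time in the bundle. `merisk` models twelve such
bundles: nine (A–I) crossing three stew-cooking fuels (electricity, kerosene,
charcoal) with three flatbread-baking stoves (clean, improved, traditional),
and three (AA–CC) without baking. $T$ is the bundle's own daily activity
time (8.85–10.5 h), not the 24-h day: the exposures are within-bundle
averages, not daywide dilutions.

On top of the exposure model sits the standard risk-characterization chain.
For PM2.5 and PM10:

$$\mathrm{ED} = \frac{\mathrm{EF}\cdot \mathrm{TA}\cdot \mathrm{EL}}{24},
\qquad
\mathrm{ADD} = \frac{C\cdot \mathrm{IR}\cdot \mathrm{ED}}{\mathrm{AT}\cdot \mathrm{BW}},
\qquad
\mathrm{HQ} = \frac{\mathrm{ADD}}{\mathrm{RfD}},
\qquad
\mathrm{HI} = \sum \mathrm{HQ},$$

with exposure frequency EF (days/yr), daily activity time TA (h/day),
longevity EL (yr), averaging time AT (days), inhalation rate IR (m³/day) and
body weight BW (kg). For trace elements bound to PM10 the chain splits into
three routes (mg·kg⁻¹·day⁻¹):

$$D_\mathrm{inh} = \frac{C\cdot \mathrm{InhR}\cdot \mathrm{EF}\cdot \mathrm{ED}}{\mathrm{BW}\cdot \mathrm{AT}},\quad
D_\mathrm{ing} = \frac{C\cdot \mathrm{IngR}\cdot \mathrm{EF}\cdot \mathrm{ED}}{\mathrm{BW}\cdot \mathrm{AT}}\times 10^{-6},\quad
D_\mathrm{der} = \frac{C\cdot \mathrm{AF}\cdot \mathrm{SA}\cdot \mathrm{ABS}\cdot \mathrm{EF}\cdot \mathrm{ED}}{\mathrm{BW}\cdot \mathrm{AT}}\times 10^{-6},$$

with route hazard quotients $D/\mathrm{RfD}_{\mathrm{route}}$, a hazard index
summed over any margin (per element across routes, per route across elements,
or grand total), and lifetime cancer risk
$\mathrm{LCR} = D_\mathrm{inh}\cdot\mathrm{IUR}
 = D_\mathrm{ing}\cdot\mathrm{SF}
 = D_\mathrm{der}\cdot \mathrm{SF}/\mathrm{GIABS}$
for the five elements with potency factors (Pb, Cr, Cd, As, Ni). LCR below
10⁻⁶ is negligible, 10⁻⁶–10⁻⁴ (closed interval) tolerable, above 10⁻⁴
unacceptable; HQ/HI strictly above 1 flags potential noncancer risk (ties at
1 are acceptable).

## Parameters that matter

* **Receptor** — an adult: IR = 20 m³/day, IngR = 100 mg/day, SA = 2011 cm²,
  AF = 0.07 mg·cm⁻²·day⁻¹, EL = 50 yr. Body weight is 60.7 kg in the PM
  registry and 60.5 kg in the element chain; the source uses both and so does
  the package, each where the corresponding results were produced.
* **Averaging time** — 18 250 days (50 yr × 365) for noncancer endpoints and
  25 550 days (70 yr × 365) for cancer. The source's prose also mentions a
  67-yr life expectancy; 18 250 is what its tables use, so that is the
  registry value.
* **PM reference doses** — `pm_hazard_quotient()` defaults to the
  annual-average RfDs 3.24 / 6.56 µg·kg⁻¹·day⁻¹ because every published
  hazard quotient divides by them; the 10 / 20 µg/m³ guideline concentrations
  are available via `rfd_source = "guideline"`. The derivation of 3.24/6.56
  from the guidelines is not stated in the source (10·20/60.7 ≈ 3.30).
* **Dermal absorption** — 0.001 for Cd, 0.030 for As, 0.010 otherwise.
* **Below-detection values** — substituted at MDL/2 by default
  (`"zero"`/`"mdl"` selectable); the source reports BDL entries without a
  substitution rule.

## Design choices where the design was open

* **ED source.** The published activity registry prints ED values for the
  baking bundles (A–I) that the ED formula cannot produce (A: 2209 vs 2188
  days from EF = 104, TA = 10.1, EL = 50). Since the published doses flow
  from the printed EDs, the registry keeps them and `ed_source = "formula"`
  is an explicit option. For the daily bundles the formula agrees (AA: 6730).
* **Rounding.** Published tables are printed at 3 significant figures
  (doses, HI) and 3 decimals (HQ) with *half-up* ties, the spreadsheet
  convention — `round_half_up()`/`signif_half_up()` reproduce it (banker's
  rounding would give 2.64 where 2.65 is printed). "Paper" rounding mode
  applies these at the reporting step; "exact" mode carries full precision,
  in which HI is exactly the sum of its HQs.
* **Reproduction limits.** Because the published exposure concentrations are
  themselves rounded to 3 s.f., downstream cells can differ from any single
  recomputation path by one unit in their last printed digit, and the source
  evidently mixed rounded and unrounded intermediates (its HQ of 0.130 at
  bundle A follows only from the unrounded dose 0.4227, while its 1.522 at I
  follows only from the printed dose 4.93). Two dose cells are inconsistent
  outright with their own exposure concentrations (PM2.5 at CC: printed 1.42,
  chain 2.19 — the printed HQ 0.677 confirms the chain; PM10 at I: printed
  7.53, chain 7.67). The pipeline flags all of these in its provenance log;
  tests assert exact equality where the printed chain supports it and the
  chain-consistent value where it does not.
* **Element dose basis.** The route equations carry a 10⁻⁶ factor that
  belongs to a mg-of-element-per-kg-of-particulate basis for ingestion and
  dermal contact, yet only air concentrations (µg/m³) are published. The
  context object therefore declares its basis: `"mass"` for true particulate
  content, or `"literal"` (default in the pipeline) feeding the air
  concentration into all three equations as the source did. The published
  element risk tables are not reproducible from the stated parameters under
  either reading (they imply an undocumented time factor ≈ 0.55), so the
  element chain is guaranteed by properties — linearity in concentration,
  exact margin additivity, registry fidelity, absent-value propagation —
  rather than cell-by-cell table matching.
* **Dermal cancer term.** The potency notation "(SF G)" is read as
  SF/GIABS, the standard dermal slope-factor adjustment; `sf_times_g` is
  retained as a literal alternate. Likewise the inhalation unit risk is
  applied to the inhalation dose by default (`lcr_inh_basis = "dose"`, the
  literal equation) with the concentration convention (`"air"`, dimensionally
  the native use of a (µg/m³)⁻¹ factor) selectable.
* **Absent toxicology.** Blank registry cells (e.g. no inhalation RfD for Fe
  or B, no potency for Fe/Cu/Mn/B/Zn) propagate as `NA` and are skipped by
  sums — never coerced to zero. Sn and Co are measured but have no registry
  entry, so they appear in exposure output only.

## What the synthetic generator emulates

`simulate_campaign()` produces a full measurement campaign without any
external data: lognormal PM series per component ME (the GM/GSD reporting
convention implies lognormality, though the source never names its
distribution) and zero-truncated normal element series (matching mean ± SD
reporting), with sub-MDL draws censored and substituted by policy. The PM
geometric means are anchored to the published range endpoints (PM2.5 17.0
µg/m³ in the living room to 190 at the traditional baking stove; PM10 77.6
to 547, reading the stray '%' signs in the source as µg/m³) and to the
published ordering of the eight component MEs; interior values, all GSDs
(1.8), element SDs where unstated (40 % of the mean) and the uniform
0.0001–0.003 µg/m³ MDL draw are placeholders chosen once as field-plausible.
Sample sizes default to 45 indoor / 30 roadside locations, the study's
design. Per-activity durations within a bundle are not published (only
totals), so the shipped time budget fixes 7 h living room + 1 h roadside and
assigns the remainder to cooking/baking so that every bundle total is
reproduced row-for-row.

Passing tests on synthetic campaigns therefore show that the pipeline is
correct and deterministic under the assumed distributions — not that real
kitchens are lognormal, that concentrations across MEs are independent (real
households correlate), or that the placeholder spreads match the field data.

## Numerical notes

* Generator determinism comes from a single user seed; parameter-recovery
  tests run at n = 5000 (PM) and n = 2000 (elements), inside 3 % and
  3·sd/√n respectively.
* Zero-truncated normal draws use rejection sampling; at the concentration
  scales involved (mean/sd ≥ 2.5) rejection rates are negligible.
* `geometric_summary()` refuses nonpositive values (log moments undefined)
  and returns `NA` spreads for n = 1; constant series give GSD exactly 1.
* Degenerate inputs error early with the offending record or stage named:
  empty measurement sets ("no data"), nonpositive durations, unknown ME
  codes, missing config files.
* Report bundles are TSV (mean and SD in separate machine-readable columns,
  blanks for absent cells) and carry a timestamp-free provenance log, so a
  rerun under the same configuration and seed is byte-identical.

## Known limitations

One adult receptor only (no children or elderly profiles); no probabilistic
treatment of reference doses; no speciation or bioavailability modelling for
elements; no spatial handling of sampling sites. The published element risk
tables are documented as non-reproducible rather than matched.
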