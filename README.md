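# derepnet

Dereplication of glycosylated aromatic polyketides — anthracyclines
(cosmomycins) and angucyclines (kidamycin, hedamycin) — from centroided
LC-MS/MS data, for natural-product chemists screening actinobacterial
extracts.

Known compounds in a crude extract must be identified *before* isolation
effort is spent on them. `derepnet` implements the computational core of
that workflow:

* **Molecular networking.** Modified-cosine spectral similarity — fragment
  pairs match either directly or offset by the precursor-mass difference
  `|m_a − m_b − (P_A − P_B)| ≤ τ` — scored as an exact maximum-weight
  one-to-one peak matching, assembled into a network with the standard
  thresholds (cosine ≥ 0.6, fragment/parent tolerance 0.02 Da, ≥ 4 matched
  peaks, minimum cluster size 2).
* **Deoxysugar neutral-loss ladders.** Depth-first detection of the
  sequential glycosidic losses that fingerprint anthracycline glycosides:
  rhodinose (−114), 2-deoxy-L-fucose (−130), rhodosamine (−157 Da), plus
  the `(mh + m_proton)/2` arithmetic of the \[M+2H\]²⁺ charge companion.
* **Formula assignment.** Exhaustive CHNOS enumeration for accurate ion
  masses with ppm, RDBE (`C − H/2 + N/2 + 1`) and H/C filters.
* **Analog propagation.** Seed-library matching plus breadth-first
  propagation of "analog of" labels along edges whose parent-mass delta
  matches a chemical transform (O, H₂, H₂O, CH₂, acetyl, or a sugar
  residue) within 0.01 Da.
* **Plate screening.** The turbidometric 96-well statistic
  `Inhibition % = [1 − (t24 − t0)/(C24 − C0)] × 100` with control
  validation and the strict 60 % activity threshold.
* **Synthetic data.** A ground-truthed generator for glycoside spectra,
  analog families and OD600 plates, so every stage is testable end to end
  without raw instrument files.

## Worked example

The published cosmomycin D MS2 peak list ships as a fixture:

```r
library(derepnet)

s <- read_peaklist_tsv(system.file("extdata", "cosmomycin_d.tsv",
                                   package = "derepnet"))
s
#> <msms_spectrum> cosmomycin_D  precursor m/z 1189.6000 (1+)  7 peaks

best <- best_ladder(detect_ladders(s, tol = 0.5, mode = "nominal"))
best
#> <nl_ladder> cosmomycin_D: 1189.6000 -> 544.3000  [5 steps: -rho -defuc -rho -defuc -RhN]
glycan_composition(best)
#> defuc   RhN   rho
#>     2     1     2
```

The detector recovers the full dissociation cascade
1189.6 → 1075.5 → 945.3 → 831.3 → 701.3 → 544.3 — losses of
114/130/114/130/157 Da, i.e. two rhodinoses, two deoxyfucoses and one
rhodosamine peeled from the \[M+H\]⁺ ion down to the aglycone-related
fragment at m/z 544.3. The doubly protonated companion of this ion:

```r
round(charge_companion_mz(1189.5878), 4)
#> [1] 595.2975
```

Formula candidates for an accurate mass, tightest ppm error first:

```r
head(enumerate_formulas(1187.5710, ppm_tol = 10)[, c("formula", "ppm_error", "rdbe")], 3)
#>         formula  ppm_error rdbe
#> 1  C69H83N6O8S2 -0.1419235 31.5
#> 2   C70H81N3O14  0.2574406 32.0
#> 3 C56H91N4O19S2  0.2901247 13.5
```

And the screening statistic — a test well growing 0.07 OD against a control
growing 0.50 OD is 86 % inhibited, hence active:

```r
inhibition_percent(t0 = 0.05, t24 = 0.12, c0 = 0.05, c24 = 0.55)
#> [1] 86
```

`run_pipeline(pipeline_config(...))` chains all stages (network, ladders,
formulas, seeds, propagation, report + JSON manifest); the same stages are
exposed as shell subcommands in `inst/scripts/derepnet`
(`run`, `network`, `ladders`, `formulas`, `screen`, `simulate`).

## Layout

* `R/` — spectra I/O, cosine/network, ladders, formulas, annotation,
  bioassay, simulation, pipeline
* `inst/extdata/` — published peak-list fixtures and the seed compound
  library (TSV)
* `tests/testthat/` — unit, property and end-to-end suites with
  brute-force oracles
* `vignettes/dereplication-methods.Rmd` — the model, parameter rationale
  and known limitations
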