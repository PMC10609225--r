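---
title: "Dereplicating glycosylated polyketides: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dereplicating glycosylated polyketides: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(derepnet)
```

## The problem

Actinobacterial extracts are crowded with known metabolites, and isolating a
compound only to rediscover it is the most expensive mistake in natural-product
chemistry. *Dereplication* — deciding from MS/MS data alone which ions are
known compounds and which are new analogs — is therefore the gatekeeping step.
`derepnet` implements the computational core of that workflow for glycosylated
aromatic polyketides (anthracyclines such as the cosmomycins, and
angucyclines of the kidamycin/hedamycin class), together with the
turbidometric plate statistic used to prioritize producing strains.

## Spectral similarity and the molecular network

Two MS/MS spectra of structural analogs share most fragments, except that
fragments retaining the modified substructure shift by the difference of the
two precursor masses. The *modified cosine* accommodates this: a peak pair
$(a, b)$ is a match candidate when

$$|m_a - m_b| \le \tau \quad\text{or}\quad
  |(m_a - m_b) - (P_A - P_B)| \le \tau,$$

with fragment tolerance $\tau$ and precursor masses $P_A, P_B$. The score is
the maximum total product of L2-normalized intensities over one-to-one
matchings of candidate pairs. `derepnet` computes this optimum *exactly* by
linear assignment (a Jonker–Volgenant solver) rather than by the greedy
pairing common in networking tools: candidate sets are small, the exact
optimum is never below the greedy one, and it is deterministic. A brute-force
enumeration oracle over all matchings pins the implementation down in the
test suite. Ties between equally heavy matchings are broken toward the
smaller absolute m/z difference by an infinitesimal (1e-12-scale) weight
perturbation, which is orders of magnitude below the score tolerances used
anywhere in the package.

Preprocessing before scoring (`preprocess_spectrum()`):

* peaks within 17 Da of the precursor are removed — the surviving precursor,
  its isotopes and small neutral losses carry no fragment information but
  dominate intensity;
* peaks within 8.5 Da of the doubly protonated companion
  $(P + m_p)/2$ of a singly charged precursor are removed for the same
  reason. Glycoside spectra routinely show this \[M+2H\]²⁺ ion as the base
  peak; because it shifts by only *half* the parent-mass delta between
  analogs, the modified cosine can never match it, and leaving it in the
  L2 norm systematically depresses analog similarity. This removal is a
  design choice of this package (flag `remove_charge_companion`);
* within every 50 Da window only the six locally most intense peaks are
  kept, and intensities are square-root transformed.

The network (`build_network()`) keeps an edge when the score is at least
0.6 and at least 4 peak pairs matched; an edge must rank in the top 10 by
score at both endpoints; components larger than 100 nodes are pared down by
removing their weakest edges; components below 2 nodes (singletons) are
dropped. These defaults are the GNPS-style parameter set used in
anthracycline dereplication practice, and every one of them is a
`network_params()` field.

## Deoxysugar neutral-loss ladders

Anthracycline glycosides carry short deoxysugar chains that peel off one
residue at a time under collision-induced dissociation, producing fragment
cascades separated by the residue masses:

| residue | loss formula | monoisotopic (Da) | nominal (Da) |
|---|---|---|---|
| rhodinose (`rho`) | C6H10O2 | 114.0681 | 114 |
| 2-deoxy-L-fucose (`defuc`) | C6H10O3 | 130.0630 | 130 |
| rhodosamine (`RhN`) | C8H15NO2 | 157.1103 | 157 |

`detect_ladders()` runs a depth-first search from the precursor m/z (or the
most intense peak within tolerance of it, when one is present): at each
level, each library residue whose subtraction lands within `tol` of an
unused peak opens a branch; *every* peak in tolerance is explored,
closest-mass first, and each maximal root-to-leaf path with at least one
step becomes a ladder. Branching over all candidates (not only the single
closest peak) matters when near-duplicate centroids occur; the closest-first
order still makes the result deterministic, and ladders are ranked by step
count, then total absolute error, then a lexicographic key.

Two matching modes exist because published fragment tables print one-decimal
masses against integer losses: `nominal` mode (integer residue masses,
tolerances around 0.5 Da — occasionally 0.75 Da where printed roundings are
internally inconsistent, as in the cosmomycin C isomer cascade whose first
printed step is 114.5) and `exact` mode (monoisotopic masses, tolerances of
0.02–0.03 Da for accurate-mass data). Intensities are deliberately ignored
in ladder matching; a flag in the synthetic generator randomizes intensities
to prove nothing depends on them.

Mass-identical residues cannot be distinguished — a rhodinose and a
dehydroxylated fucose both lose 114 Da — so compositions report mass
classes, not positional identities, and no attempt is made to assign
residues between the two chains.

## Formula enumeration

`enumerate_formulas()` scans the bounded CHNOS lattice (defaults C ≤ 70,
H ≤ 130, N ≤ 6, O ≤ 26, S ≤ 2 — generous for glycosylated polyketides up to
~1200 Da) for compositions whose theoretical cation m/z,

$$m/z = \Big(\sum_e n_e M_e - z\,m_e\Big)/z,$$

falls within a ppm window of the query, then filters by
rings-plus-double-bond equivalents (RDBE $= C - H/2 + N/2 + 1$, allowed
range 0–40) and H/C ratio (0.2–3.2). Only even-electron positive ions
(\[M+H\]⁺, \[M+2H\]²⁺) are modeled; element counts describe the ion as
written, protons included, and the electron mass is subtracted — a
0.00055 Da correction below instrument reporting precision, kept for
correctness. The scan iterates over (C, N, O, S) and solves for hydrogen,
which is exact because the ppm window is far narrower than the 1.008 Da
hydrogen spacing; the tests verify equality with an unpruned brute force
over the full lattice. Published experimental masses can sit 10–13 ppm from
theory, so matching reported ions needs windows of that order.

## Seed matching and analog propagation

`match_seeds()` labels nodes whose precursor lies within 0.02 Da (the
parent-mass tolerance) of a library compound. `propagate()` then walks the
network breadth-first from those anchors: an unannotated neighbor inherits
an "analog of" label when the edge's absolute parent-mass difference matches
a transform — oxygenation (O, 15.9949), saturation (H₂, 2.0157), hydration
(H₂O, 18.0106), methylenation (CH₂, 14.0157), acetylation (C₂H₂O, 42.0106),
or a sugar residue (114.0681/130.0630/157.1103) — within a *propagation*
tolerance of 0.01 Da. That tolerance is deliberately tighter than the
0.02 Da networking tolerance: the closest pair of distinct transforms is
about 2 Da apart, but chained assignments accumulate error, and manual
amu-difference reasoning in the literature operates at four-decimal
precision. Shorter hop counts win; within a hop the smallest transform error
wins; two hops is the default reach, and composite (two-term) transforms are
off by default because single deltas explain every reported assignment in
this compound family. Labels report both the exact and the field-style
nominal delta (e.g. `-O(16)`).

## The plate-screening statistic

Growth inhibition is computed from OD600 readings as

$$\text{Inhibition \%} = \Big[1 - \frac{t_{24} - t_0}{C_{24} - C_0}\Big]
  \times 100,$$

with the negative-control growth $C_{24} - C_0$ taken as the mean (median by
flag) of the plate's own row-12 wells. Values above 100 (lysis) and below 0
(growth promotion) are preserved, and the statistic is invariant under
affine rescaling of all four readings — both properties are tested. A
sample is *active* when its replicate-mean inhibition strictly exceeds 60%.
Exact equality with the threshold is therefore inactive; note that 60.0
cannot even arise in binary floating point from a growth ratio of 2/5, so
the strictness test uses an exactly representable boundary (ratio 1/2
against a 50% threshold). Plates are validated before calling: any
sterility well gaining more than 0.05 OD flags contamination, and mean
positive-control (levofloxacin) inhibition below 60% flags assay failure.
The plate is addressed as 12 rows × 8 columns (row 1: 4 sterility + 4
positive wells; rows 2–11: test wells; row 12: negative controls); standard
landscape A–H × 1–12 CSVs are transposed on read.

Replicates are aggregated by the mean of per-replicate inhibition values,
each computed against its own plate's control — the replicate design
(triplicate plates) is standard, the combiner is this package's choice.

## The synthetic-data generator

`simulate_glycoside_spectrum()` builds an \[M+H\]⁺ ion from an aglycone
mass (uniform in 350–600 Da) plus two trisaccharide chains
(`rho`–`defuc`–`RhN`, outermost first), then peels each chain
outermost-to-innermost, emitting every chain ordering since dissociation
does not fix which chain fragments first. Intensities decay geometrically
(ratio 0.7) down the ladder — an invented model, as intensities are never
reported for these cascades, which is exactly why ladder logic ignores them.
Every peak receives Gaussian m/z jitter; a \[M+2H\]²⁺ companion appears with
probability 0.5 at 1.2× the precursor-peak intensity; 20 uniform noise
peaks, each weaker than twice the weakest true peak, keep detection
non-trivial. `simulate_family()` derives analogs by applying one random
signed aglycone transform (O, H₂, H₂O, CH₂) so that all fragments shift
with the precursor. `simulate_plate()` draws control growth from
N(0.45, 0.03) OD units truncated at zero and gives each test well an
independent control draw scaled by $1 - \text{effect}$ plus N(0, 0.01)
noise, across three replicate plates.

Two jitter levels are used deliberately. Ladder recovery is exercised at
σ = 0.01 Da — a stress level at which a 0.03 Da step tolerance is only about
two standard deviations of a step delta — while networking and propagation
experiments use σ = 0.003 Da, the accuracy a modern QTOF actually delivers
at m/z ~1000 and the level consistent with the 0.02 Da networking
tolerances. At the stress level, 10 ppm jitter with 0.02 Da tolerances
would be physically self-contradictory.

What the generator does *not* emulate — and what passing tests therefore do
not demonstrate — includes: aglycone-side fragmentation (real analog spectra
share many more peaks than the sugar ladder, so real cosine scores are, if
anything, easier); isotope envelopes; chromatographic coelution and chimeric
spectra; intensity-dependent centroid accuracy; media/solvent background
ions; and plate artifacts such as edge effects or drift.

## Numerical choices and degenerate inputs

* Tolerance comparisons use `<= tol + 1e-9` to guard representation error
  at printed-value boundaries (e.g. a 0.5 Da step computed from one-decimal
  masses).
* Peak lists are canonical: sorted strictly ascending, near-duplicates
  (within 1e-6 Th) merged by intensity sum at the intensity-weighted mean
  m/z; canonicalization is idempotent.
* Zero-intensity or empty spectra score 0 with 0 matched peaks; an empty
  spectrum yields no ladders; an empty network yields valid empty exports.
* Seed-match ties at identical mass distance resolve by library order;
  edge-removal ties during component splitting resolve by (score, from, to).
* All randomness flows through R's global RNG; fixed seeds make every
  simulation, test and pipeline run reproducible, and identical
  configurations produce byte-identical TSV outputs.

## Problem sizes in the shipped experiments

The packaged validation experiments are sized for interactive runs: 200
simulated spectra for ladder recovery, 100 four-spectrum families for
propagation recovery, four five-spectrum families plus five random spectra
for clustering, 500 test wells across ten triplicate plates for the
screening statistic, and 20 random masses against the full-lattice formula
oracle. These sizes give binomial confidence intervals comfortably inside
the asserted bounds (≥ 95% ladder recovery, ≥ 90% analog recovery with zero
false transforms, ≥ 99% sensitivity and specificity).

## Known limitations

* Chain-position isomers and mass-identical residues are indistinguishable
  by construction; annotation strings are mass-class claims, not structures.
* Propagated labels are hypotheses: a matching parent-mass delta is
  necessary, not sufficient, and two-hop chains can be chemically
  equivalent to a single transform (+O then +H₂ equals +H₂O); downstream
  interpretation should treat the cumulative delta as the load-bearing
  quantity.
* The formula engine covers CHNOS only and does not score isotope patterns;
  outside even-electron positive ions it is silent by design.
* Network topology depends on acquisition coverage: a compound absent from
  the spectra cannot anchor its family, and min-cluster filtering hides
  singletons entirely.
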