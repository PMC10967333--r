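---
title: "Methods: glycopeptide-centric Fc N-glycan profiling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: glycopeptide-centric Fc N-glycan profiling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fcglycoscope)
```

## The problem

IgG antibodies carry a conserved N-glycosylation sequon in the heavy-chain
CH2 domain (Asn297 in the usual numbering). Which glycan sits there — and
on what fraction of antibody copies the site is occupied at all — shapes
Fc-receptor binding and therefore effector functions such as
antibody-dependent cellular phagocytosis. Manufacturing platform strongly
influences this glycosylation state, so comparing the Fc glycan profile of
the same antibody expressed in, say, a glyco-engineered tobacco plant
versus mRNA-transfected human cells is a routine quality-control and
characterization task.

`fcglycoscope` implements the complete desk-side analysis for this task
from tandem-MS data:

1. **In-silico digestion** (Glu-C + trypsin, shared missed-cleavage
   budget) and **sequon discovery** (N-X-S/T, X ≠ P).
2. **Oxonium-ion triage** of HCD MS2 spectra: a spectrum is treated as
   glycopeptide-derived when at least two of the seven diagnostic
   carbohydrate B ions (HexNAc m/z 204.0867 and its satellites, HexNAcHex,
   NeuAc and its water loss) match within 15 ppm. The instrument this
   emulates used the same rule as a real-time acquisition trigger; here it
   is an offline filter with identical logic.
3. **Glycopeptide-spectrum matching (GPSM)**: candidates are generated by
   precursor mass (10 ppm) over digested peptides × glycan library
   compositions, scored against the spectrum at 20 ppm, and the site is
   localized via glycosylated backbone ions (b/y fragments retaining
   HexNAc1–2).
4. **MS1 glycoform profiling**: per composition, the precursor's
   monoisotopic height (apex within ±30 s of the MS2 trigger, summed over
   charge states), normalized over occupied compositions.
5. **¹⁸O site-occupancy quantification**: PNGase F deglycosylation in
   heavy-oxygen water stamps formerly occupied sites with +2.98826 Da
   (deamidation +0.98402 plus ¹⁸O−¹⁶O +2.00425); occupancy is the labeled
   fraction of the peptide's MS1 signal.

A worked anchor ties the mass calculus to reality: the doubly protonated
CH2 glycopeptide EEQYNSTYR + HexNAc₄Hex₃ must come out at m/z 1244.4976.

```{r anchor}
gp <- glycopeptide(peptide("EEQYNSTYR", 293, 301), site = 5,
                   glycan = glycan_composition(hexnac = 4, hex = 3))
glycopeptide_mz(gp, charge = 2)
```

## Mass conventions

* Monoisotopic masses throughout; the packaged JSON mass table is derived
  from CHNOS elemental formulas and NIST atomic masses, so the mass path
  and the isotope-envelope path cannot drift apart.
* Charged species use the proton mass 1.007276 Da; the electron mass is
  not separately subtracted. This choice reproduces the worked precursor
  to four decimals.
* Monosaccharides carry dehydrated residue masses and attachment to Asn
  adds no water (validated by the same anchor).
* The published oxonium panel values are treated as reference values with
  a ±0.001 Da band: several differ from first-principles values in the
  fourth decimal, so the package computes its own values
  (`oxonium_mz()`) and the triage panel carries the published ones.
* Fucose and sialic acid are modeled generically as dHex and NeuAc;
  NeuGc and plant xylose are out of scope (the emulated plant platform is
  a ΔXF knockout line).

## The GPSM score

Commercial search engines score glycopeptides with closed-source models.
The package's score is deliberately simple, deterministic, and documented:

* backbone term: matched distinct b/y ions over 2(n−1), × 50;
* glycan term: 8 × min(matched Y remnants, 5) × (matched / theoretical
  Y remnants);
* oxonium term: +10 when ≥ 2 distinct oxonium ions match.

The completeness weighting in the glycan term matters: a candidate whose
composition overshoots the true glycan shares most of its truncated
Y-ladder with the truth, and an unweighted "count up to 5" rule would tie
the two at the top score. Weighting by the matched fraction of the
candidate's own ladder makes the true composition win strictly on clean
data, which is the behavior the search relies on. Ranking ties are broken
by smaller |precursor ppm|, then fewer glycan residues, then
lexicographic composition, so output order is reproducible bit for bit.

No FDR machinery is attached: the emulated study verified assignments by
manual inspection, and the reports carry the matched-ion evidence needed
for exactly that.

## Occupancy estimation details

At Orbitrap-class resolving power (120,000 at m/z 200, scaling as
1/√(m/z)), the ¹⁸O-labeled monoisotopic peak and the M+3 isotopologue of
the unlabeled envelope differ by only ~0.022 Da/z and are not reliably
resolved — at z = 2 they coalesce into one centroid, at z = 3 they sit at
the edge of separation. The estimator therefore:

1. reads the unlabeled monoisotopic height within tolerance;
2. sums all signal across the narrow bracket spanning the labeled
   monoisotopic and unlabeled-M+3 positions (robust to merged and
   unmerged centroids alike);
3. subtracts the predicted M+3 contribution, `isotope_envelope()`'s
   M+3/M ratio times the observed unlabeled height (configurable off);
4. forms occupancy = corrected labeled / (corrected labeled + unlabeled)
   per charge state, and combines charge states by intensity weighting.

Per charge state, centroid *heights* (never areas) are summed over the
run's MS1 scans — an intensity-weighted mean across scans. An earlier
apex-scan rule (take the single most intense scan) was rejected: under
independent per-scan intensity noise it preferentially selects scans
where the dominant species drew high, biasing recovered occupancy by up
to ~2.5 percentage points; summed heights recover the whole test curve
(10–96% occupancy) with |bias| ≤ 0.2 points.

The 97% isotopic purity of the heavy water is modeled in the generator
(3% of labeled molecules appear at the ¹⁶O-deamidation position +0.98402)
but deliberately ignored by the estimator; the resulting bias is under
one percentage point across the range and is smaller than run-to-run
noise. Natural deamidation is excluded from both numerator and
denominator; a diagnostic flag is raised when unexplained signal at that
position exceeds 5% of the unlabeled height.

## What the synthetic generator emulates — and what it does not

`generate_glyco_run()` and `generate_deglyco_run()` state a world and
stick to it:

* **Glycoform profiles**: the `"hca-n"` preset has 13 compositions
  (G0-dominant, all three glycan classes, ~1% fucosylated, monoHexNAc
  present) with site occupancy 49.1%; `"hca-mrna"` has 11 compositions
  (fairly even, biased to fucosylated complex types with G0F/G1F/G2F on
  top, G2S1F and monoHexNAc present) with occupancy 96.0%. Counts,
  dominance structure, fucosylation level and occupancies are the stated
  platform characteristics; the individual filler weights are package
  constants documented here and in `platform_preset()`, chosen once to
  respect those statements.
* **Spectra**: MS1 isotope envelopes from the same `isotope_envelope()`
  code path the estimator uses; MS2 content from the same
  `theoretical_fragments()` the scorer uses; centroids only. Peak m/z
  jitter is Gaussian with σ = 2 ppm; intensities carry 10% lognormal
  noise; 30 uniform noise peaks per spectrum; 5% peptide-only decoy MS2
  scans with no oxonium content.
* **Centroider**: peaks closer than 1.5 × FWHM (from the resolving-power
  model) merge into one intensity-weighted centroid. This single rule is
  what makes the labeled/M+3 overlap physical rather than assumed.
* **Protein context**: the universal human IgG1 CH2 region around
  EEQYNSTYR, shipped as `synthetic_protein()` and labelled synthetic —
  the real antibody's chains are not published.

Not emulated: chromatographic peak shapes and co-elution, chimeric
spectra, profile-mode data, charge states beyond the configured set, ion
mobility, and real glycan isomerism. A green test on synthetic data
therefore establishes the *internal consistency and statistical behavior*
of the pipeline (triage logic, search correctness against ground truth,
quantification bias and variance at stated noise), not instrument-level
performance on raw deposited data.

## Numerical choices and degenerate inputs

* Peak-match ties within tolerance: highest intensity, then smaller
  |Δppm|.
* The Y-ion remnant ladder grows chitobiose-core-first (HexNAc₂, then
  Hex₃, then remaining units) and is truncated at 8 remnants by default —
  deep enough to separate presets' compositions, shallow enough to keep
  search time linear.
* `classify_glycan()` is a pure count heuristic; compositions the rule
  does not reach (HexNAc₂ with fewer than five hexoses, e.g. the
  paucimannose core) fall into "other", and reports flag the
  classification as composition-based.
* Duplicate m/z values within a spectrum merge by intensity summation at
  construction; empty runs, empty candidate lists and unquantifiable
  sites return empty/NA results rather than errors.
* Digestion treats the missed-cleavage budget over the union of both
  enzymes' sites; trypsin respects the K/R-P block, Glu-C cleaves E-P
  (both configurable), and Glu-C specificity is E only.
* Variable modifications searched: Met oxidation (≤ 2 simultaneous) and
  protein N-terminal acetylation; Cys carbamidomethylation is fixed.
  Deamidation is handled only inside the occupancy workflow, where it is
  the signal.

## Known limitations

* Composition-level identification cannot distinguish glycan isomers;
  "hybrid" vs "bisected complex" calls from counts are heuristic.
* The score has no decoy-based calibration; it is a ranking device with
  evidence reporting, not a posterior probability.
* The mzML reader supports centroided 32/64-bit, zlib-or-none spectra
  only; MGF is the canonical interchange format.
* Printed sequence-coverage values from the emulated study depend on its
  deposited raw runs and are not reproduced here; the coverage operation
  itself is exact (interval union) and oracle-tested.
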