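---
title: "Methods: glycoproteomics target prioritization with glycotarget"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: glycoproteomics target prioritization with glycotarget}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glycotarget)
```

## The problem

Shotgun proteomics of tumor tissue yields thousands of protein
identifications, very few of which are useful as *targetable* biomarkers: a
good target sits on the plasma membrane (reachable by antibodies), is
abundant in tumor but scarce in healthy tissue, and marks aggressive
disease. Truncated O-glycosylation — in particular the sialyl-Tn (STn)
antigen, NeuAc-α2,6-GalNAc on Ser/Thr — can add the missing cancer
specificity, because STn is rare in healthy tissue and common in aggressive
gastrointestinal tumors. `glycotarget` implements the computational side of
this discovery workflow: O-glycome readout by mass, identification-list
selection, Target Score ranking, STn glycosite mapping, and the clinical
association statistics.

## Permethylated benzyl glycoside masses

The cellular O-glycome reporter strategy feeds cells benzyl-GalNAc; the
glycans elongated on it are secreted as benzyl glycosides, permethylated and
measured by LC-ESI-MS/MS. For a composition with counts $c_k$ of residue
classes $k \in \{\mathrm{Hex}, \mathrm{HexNAc}, \mathrm{dHex},
\mathrm{NeuAc}\}$ and $R = \sum_k c_k$ residues, the neutral monoisotopic
mass is

$$
M = \sum_k c_k\, m_k + m_{\mathrm{H_2O}} + m_{\mathrm{C_7H_6}}
  + n_{\mathrm{sites}} \cdot m_{\mathrm{CH_2}}, \qquad
n_{\mathrm{sites}} = \sum_k c_k\, s_k - (R - 1),
$$

with residue masses $m_k$ (Hex 162.052824, HexNAc 203.079373, dHex
146.057909, NeuAc 291.095417 Da) and base methylation-site counts $s_k$
(4, 4, 3, 6). Each glycosidic bond consumes one hydroxyl, hence one
methylation site, regardless of branching — site bookkeeping is
topology-free, which suffices because only compositions, not linkages, are
ever read from peak m/z. NeuAc contributes six sites because
permethylation also esterifies the carboxyl and methylates the amide N-H.

Peaks are interpreted as singly protonated $[M+H]^+$. This adduct/charge
convention, and the inclusion of the carboxyl methyl ester, are the only
conventions under which the full set of published reference peaks (T
572.31, sialyl-T 933.48, STn 729.4, core 3 613.33, the core 2 series
817.43–1470.76, di-sialyl-T 1294.7) is reproduced to the printed decimals;
the package fixes them and the test suite asserts all ten values.
Composition assignment (`assign_composition()`) inverts the formula by
exhaustive enumeration within per-class bounds (default ≤ 6) and a mass
tolerance (default 0.05 Da — the source tables print 2 decimals, so 0.05 Da
separates all compositions in the bounded space; both are configurable).
Ambiguity is resolved by smaller |error|, then fewer residues, then class
order. Relative abundances are intensities normalized to the summed
intensity of the annotated glycome.

A free-reducing-end (non-benzyl) mode exists behind `benzyl = FALSE` for
conventional permethylated glycomes; it is not used by the reference
values.

## Selection of membrane identifications

The selection module reproduces the downstream logic applied to a
double-fractionated (RPS/SCX) identification export: restrict to a
plasma-membrane registry (a GO-derived accession list), order by posterior
error probability, cut to the top N (default 250) per method, and intersect
methods. Conventions the export format leaves open are fixed
deterministically: lower PEP is better (standard PEP semantics); ties break
by higher PSM count then accession; duplicate accessions collapse to their
best-PEP record; isoform suffixes are stripped before registry matching
(registries are canonical-accession keyed; `collapse_isoforms = FALSE`
disables this). The pipeline order is fixed as filter → rank → cut →
intersect. The published counts for the original repository dataset
(773/795 membrane proteins, 213 common) depend on that raw data and a 2020
database snapshot; they are context, not reproducible quantities, so the
module is validated against brute-force sort/intersect oracles on seeded
fixtures instead.

## The Target Score

For a protein with plasma-membrane flag $m \in \{0,1\}$, ordinal tumor
expression level $e \in \{0,1,2,3\}$ (not detected/low/medium/high),
unfavorable-prognosis flag $p \in \{0,1\}$ and healthy-tissue levels
$h_t$ over tissues $t$:

$$
S = w_m m + w_e e + w_p p \;-\;
\operatorname{agg}_t \big( w_h \cdot \mu(t) \cdot h_t \big),
$$

where $\mu(t)$ is a penalty multiplier (default 2) for tissues of the
reproductive, immune and nervous systems and 1 otherwise, and
$\operatorname{agg}$ is the mean (default) or sum.

The qualitative structure — reward membrane location, tumor abundance and
poor prognosis; penalize healthy expression, with extra weight on the three
sensitive systems — is the published design. The concrete linear form and
the default weights ($w_m = 3$, $w_e = 1$ per level, $w_p = 2$, $w_h = 1$
per level, multiplier 2) are this package's choices: defaults were set so
that each qualitative factor can overturn one expression level of another
(membrane location outweighs any single-tissue penalty at the default
multiplier; prognosis outweighs a low-level penalty) while no single factor
dominates the sum. The mean aggregation makes the penalty insensitive to
how many tissues an atlas happens to profile; `healthy_aggregation = "sum"`
gives the stricter alternative. All weights live in `score_weights()` (or a
YAML `targetscore:` block) so a different published weighting can be
dropped in without code change. Missing tissue annotations count as not
detected. When the tumor of interest is not profiled in the expression
atlas, a histologically related tumor column can be designated via
`read_annotations(tumor_column = ...)` — e.g. head-and-neck squamous
carcinoma as a proxy for esophageal squamous carcinoma. Ranking is by
descending score with dense ranks and accession-order tie-breaks, so output
is permutation-invariant.

## STn glycopeptide search and site localization

The second search finds STn-modified tryptic peptides in MS/MS peak lists:

* **Digestion**: cleave after K/R, not before P, up to 2 missed cleavages;
  peptides shorter than 5 residues are not searched.
* **Modifications**: fixed carbamidomethyl-C (+57.02146); variable
  oxidation-M (+15.9949, ≤ 2) and STn (+494.174790 on S/T, ≤ 3 per
  peptide). The STn delta is exactly the HexNAc + NeuAc residue-mass sum.
  The per-peptide caps bound the placement combinatorics; spectra needing
  more sites than that are outside the intended use.
* **Oxonium gate**: an STn interpretation is considered only when the
  spectrum shows both a HexNAc-type oxonium ion (204.0866) and a NeuAc-type
  one (292.1027 or its water loss 274.0921), each within the fragment
  tolerance. This is the package's reading of "typical GalNAc and sialic
  acid oxonium ions"; the three masses are fixed constants derived from the
  residue formulas.
* **Matching**: precursor within 10 ppm (default), fragments within
  0.01 Da (default; the first-search convention of 0.02 Da is simply a
  different argument value). Candidates are scored by the count of matched
  singly-charged b/y ions, where an STn-carrying fragment matches either
  with the intact glycan or after full glycan loss — HCD frequently strips
  O-glycans from backbone fragments. A transparent matched-ion count
  replaces the proprietary score of commercial glyco search engines; ties
  prefer fewer modifications, then lexicographic peptide order. Spectra
  without a charge state are tried at 2+ and 3+.
* **Localization**: among all placements of the matched number of STn over
  the peptide's S/T positions, count matched *site-determining* ions (ions
  whose m/z differs between placements). A unique maximum localizes the
  site(s); ties report the union of tied sites with `localized = FALSE`.

On noiseless synthetic spectra with complete fragment coverage this search
recovers every peptide and site exactly (asserted in the tests); under peak
dropout it loses sensitivity but never reports a site outside the
candidate S/T set, and without oxonium ions it never reports STn at all.

## Clinical statistics

Cross-tabulations of marker status against clinicopathological variables
are tested with the uncorrected Pearson chi-square ($\sum (O-E)^2/E$,
df $=(r-1)(c-1)$): the uncorrected form reproduces both printed p-values
that can be checked from published counts (0.026 for high-vs-low marker
expression against distant recurrence; 0.414 for positivity across four
stages), while the Yates-corrected form reproduces neither, so no
continuity correction is applied. Some published table p-values are not
reproducible from the printed counts by any uncorrected Pearson test
(e.g. a published 0.167 where the printed counts give 0.194) and
presumably come from a
different variant; they are documented context only. Survival is handled by
the Kaplan-Meier product-limit estimator and the two-group log-rank test
(df = 1), delegated to the `survival` package behind this module's
readers/report shape; the test suite validates both against a hand-rolled
product-limit oracle and by simulation (type-I error under a null hazard
ratio, power under a planted hazard ratio of 3), because per-patient
survival times are not published. p-values are reported to 3 decimals,
matching the source tables.

## Synthetic data generators

Each generator is a pure function of its configuration including the seed
(asserted byte-identical across runs) and restores the caller's RNG state.

* `make_identifications()` — PEPs from Beta(1, 20), a right-skewed
  distribution concentrating mass near confident zero; a planted accession
  set receives the smallest PEPs of each method *by construction*, making
  the expected intersection exact rather than probabilistic; membrane
  fraction 0.4 by default, sized after the roughly 40% share of membrane
  annotations in identification lists of this kind.
* `make_annotations()` — random expression levels over a tissue panel that
  always covers the three penalized systems; the planted target profile
  (membrane, tumor-high, unfavorable prognosis, a single low-level healthy
  tissue outside the penalized systems) mirrors the published top hit's
  pattern of sparse healthy expression.
* `make_glyco_spectra()` — complete singly-charged b/y series (glycan-intact
  and glycan-stripped forms), the three oxonium ions, exact precursor at
  charge 2; optional uniform peak dropout and uniform-m/z decoy peaks. A
  bundled synthetic three-protein FASTA (`toy_fasta()`; S/T-rich,
  membrane-protein-like, invented sequences) removes any need for sequence
  downloads.
* `make_cohort()` — exponential event times with a group hazard ratio
  applied to group B and independent exponential censoring calibrated to
  the requested censored fraction; baseline hazard 0.05/month, a
  median survival near 14 months as is typical for aggressive
  gastrointestinal cancer cohorts.

What the generators deliberately do not emulate: chromatographic retention,
isotope envelopes, intensity models, correlated tissue expression, and
protein inference ambiguity. Green tests therefore demonstrate algorithmic
correctness on well-posed inputs, not end-to-end performance on real
instrument data.

## Problem sizes and numerics

The shipped tests run the selection oracle at 1,000 proteins, Target Score
panels at 100 proteins, the glycopeptide search at 50 noiseless spectra
against the three-protein FASTA, and the log-rank null calibration at
1,000 replicates of 30 + 30 subjects — sizes at which every property is
already fully exercised while the whole suite stays interactive
(seconds, not minutes). Mass comparisons against printed values use the
printed precision (2 decimals, 1 where the source prints 1); internal mass
arithmetic is double precision throughout; fragment matching uses absolute
Da windows and precursor matching ppm windows, per mass-spectrometry
convention.

## Known limitations

* The exact published Target Score weighting is not public; rankings from
  this implementation agree with it qualitatively (monotonicity, planted
  recovery) but are not guaranteed to match it protein-for-protein.
* The glycopeptide score is a matched-ion count; it has no calibrated
  false-discovery control (a reversed-decoy option would be the natural
  extension).
* Composition assignment reports the best composition within tolerance; at
  coarser tolerances or wider bounds than the defaults, isobaric
  near-collisions would need retention-time or MS/MS evidence, which the
  package does not model.
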