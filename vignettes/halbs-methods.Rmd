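---
title: "Detecting and scoring ligand-protein halogen bonds"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting and scoring ligand-protein halogen bonds}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(halbs)
```

## The interaction and its descriptors

A halogen bond forms because the σ-bond from carbon to a halogen atom X
polarises the halogen, leaving a belt of negative potential around its
equator and a positive cap — the σ-hole — opposite the C–X bond. An
electron-rich acceptor Y (an oxygen or sulfur lone pair, or the π cloud
of an aromatic ring) binds into that cap. The geometry is therefore
directional and can be summarised by a handful of descriptors:

* `d` — the X···Y distance (Å); for π acceptors, the distance from X to
  the unweighted centroid of the ring atoms. Genuine halogen bonds are
  often shorter than the sum of the Van der Waals radii, which we report
  as the overlap `(r_X + r_Y) − d`.
* `theta1` — the C–X···Y angle at the halogen (degrees). Values near
  180° place the acceptor in the σ-hole; below 90° the σ-hole is
  geometrically unreachable, so such pairs are discarded.
* `theta2` — the X···Y–neighbour angle at an atomic acceptor, where the
  neighbour is the acceptor's covalent partner (the backbone C for a
  carbonyl O, CB for a thiol S, ...). Lone-pair geometry puts the
  expected range around 90–120°. For a π acceptor there is no covalent
  neighbour of the centroid, so `theta2` (and the Van der Waals overlap)
  are undefined — this is also why waters are never accepted as
  acceptors: with no resolvable hydrogen positions their `theta2` cannot
  be computed.

## Candidate enumeration

Detection scans a structure model for halogen atoms (F, Cl, Br, I) that
are covalently bonded to carbon, using the compound dictionary when one
is available (a full CCD-style file, or the `chem_comp_*` categories
embedded in the input; embedded definitions win so fixtures are
self-contained) and a 1.9 Å nearest-carbon fallback otherwise. Single
halide ions and compounds whose halogen sits on a metal or nitrogen are
excluded via a packaged identifier list plus the dictionary's
connectivity. Halogens in alternate conformations are excluded; we apply
the same rule to acceptor atoms so that a two-conformer acceptor cannot
contribute duplicate candidates.

Atomic acceptors are O/S atoms of canonical amino acids whose considered
heavy-atom neighbours are all carbon (classes `O-C` and `S-C`) within
4.0 Å of the halogen; π acceptors are His/Phe/Tyr/Trp rings whose
centroid lies within 6.0 Å. Both shells are inclusive at the cutoff.
Contacts within the halogen's own residue are not candidates: the method
targets compound-to-protein interactions. Symmetry mates are not
generated; only atoms present in the file are scanned, which matches how
deposited asymmetric units are analysed. For multi-model files only
model 1 is scored by default (`all_models = TRUE` iterates), since the
method is calibrated on crystallographic models and an NMR ensemble
would need per-model treatment anyway.

Three enumeration choices deserve a note because the problem leaves them
genuinely open:

* **Tryptophan rings.** The indole has a 5- and a 6-membered ring. We
  emit one candidate per ring by default and let best-bond selection
  keep the better-scoring one; `trp_rings = "indole"` switches to a
  single whole-indole centroid. Emitting both avoids silently preferring
  one reading.
* **Multi-neighbour acceptors.** Methionine SD is bonded to CG and CE
  and there is no principled single choice of `theta2` neighbour.
  Detection emits one row per neighbour; scoring keeps the row with the
  lower `theta2` score, so a valid geometry is never penalised by an
  arbitrary neighbour pick. Calibration, which must store one value,
  keeps the first-listed neighbour deterministically.
* **The θ₁ boundary.** We cull at strictly `theta1 > 90°` everywhere, so
  a candidate at exactly 90.0° is removed.

## Scoring

Each defined parameter is scored against the quartiles of its
(halogen × acceptor class) reference cell:

$$\mathrm{Score}_{geom} = \max\!\left(\frac{v - Q3}{IQR},\;
  \frac{Q1 - v}{IQR},\; 0\right)$$

and the bond's HalBS is the maximum over its defined parameter scores —
the least favourable feature. Classification is `preferred` at exactly
0 (the box is closed: a value on Q1 or Q3 scores 0), `allowed` up to and
including 1.5 (the whisker endpoint), and `outlier` strictly above 1.5.
The 1.5 comparison is an exact floating-point comparison; we do not add
a tolerance, and the tests exercise the boundary on both sides. Scores
are computed in double precision and `acos` arguments are clamped to
[−1, 1] so collinear geometries are exact.

A category without reference statistics — C–I···Trp in the shipped
table, where the corpus had too few observations — yields `halbs = NA`
with an explicit reason; such candidates are reported with their
geometry but never enter the per-model mean. When several bonds are
possible for one halogen, the lowest HalBS wins; exact ties prefer the
atomic acceptor over the π acceptor, then the shorter distance, then
acceptor order, purely for determinism. The per-model summary is the
count and arithmetic mean of the *selected* bonds' HalBS (not of all
candidates), reported missing for zero bonds.

Scoring accepts any halogen-bearing compound class — ligands, modified
residues, nucleotides — while calibration restricts itself to
ligand-to-protein pairs, so a scored population is slightly broader than
the calibrated one by design.

## Calibration

`calibrate()` rebuilds the reference table from a corpus: detect, keep
ligand→canonical-amino-acid pairs, apply the quality filter, keep one
acceptor per halogen (θ₁ closest to 180°, ties by shorter distance then
residue order), pool per category, and compute `n`, mean, median, Q1,
Q3 and the unscaled MAD. The quality thresholds default to the values
used to assemble the reference corpus: halogen B-factor ≤ 100 Å², RSCC
≥ 0.9 for both the halogen-bearing and the acceptor-bearing compound
(we apply the RSCC rule to π-acceptor residues too, reading "compound
containing the acceptor" inclusively), and resolution ≤ 2.5 Å. All
three are boundary-inclusive keeps; candidates with missing metadata
are rejected as `unverifiable` rather than waved through, because a
calibration set must be verified. RSCC values are consumed from a
sidecar table — this package never computes density fit.

Quartiles use linear interpolation between closest ranks
(`stats::quantile` type 7), the most common convention; the estimator
is a `quartile_type` argument because Q1/Q3 feed the score directly and
users matching an external table may need a different type. Cells with
fewer than `min_category_n = 5` observations, or zero IQR (constant
values), are omitted — the score is undefined there.

### The packaged reference table is synthetic

The shipped `reference_stats_synthetic.tsv` is constructed from
published per-category medians, expected angle ranges and observation
counts for the ligand–protein halogen-bond corpus; the quartile spreads
around those medians are plausible choices, not measurements. It makes
every scoring path exercisable offline (including the absent C–I···Trp
cell) and gives sensible demonstration scores, but absolute HalBS values
under it should not be quoted for real structures. Research use should
recalibrate on a corpus with `calibrate()` and pass the result to
`score_bonds()` / `run_score()`.

Similarly, the Van der Waals radii ship as an editable table
(`vdw_radii()`: Bondi-compilation values, F 1.47, Cl 1.75, Br 1.85,
I 1.98, O 1.52, S 1.80 Å). The overlap is descriptive output only — no
filter or score depends on it — so substituting another compilation
changes reports, not decisions.

## What the fixture generator emulates

`fixture_structure()` builds a minimal ligand (parent carbon + halogen,
with embedded connectivity) and a protein fragment — a backbone
carbonyl, a cysteine thiol, or an ideal planar ring (1.39 Å edges,
1.37 Å for the imidazole) perpendicular to the halogen–centroid axis —
positioned so the recomputed descriptors equal the prescription to
8-decimal coordinate precision. Real residue and atom names are used so
categorisation code paths run. `fixture_corpus()` draws i.i.d.
geometries from truncated normal laws (distance within the detection
shell, θ₁ in (90°, 180°)) with R's Mersenne–Twister generator under a
fixed seed, and returns both the analytic quartiles of the laws and the
sample quartiles of the draws.

What fixtures deliberately do not emulate: chemically refined ligand
geometry beyond the atoms the method touches, coordinate noise and
refinement artefacts, crowded binding sites with correlated contacts,
occupancy disorder, or symmetry-related neighbours. Passing tests
therefore demonstrate the correctness of the geometry, bookkeeping and
statistics on exactly specified inputs — not robustness to the full
messiness of experimental models, which only a real-corpus calibration
and inspection can probe.

## Test problem sizes

The suite checks the score analytics exhaustively (they are closed
form), equivalence of the end-to-end pipeline with an independent
scalar recomputation on 200 seeded fixtures at 10⁻⁹, equality of the
candidate enumeration with an O(n²) brute-force scan on 30 fuzzed
multi-acceptor fixtures, and quartile recovery in calibration on
corpora of 50 and 500 synthetic bonds (within three Monte-Carlo
standard errors of the generating laws). These sizes give stable
verdicts while keeping the default test run quick.

## Known limitations

* Nitrogen acceptors (histidine) are out of scope: their availability
  depends on protonation states this package does not model.
* Water-mediated contacts are excluded by construction, although some
  real halogen contacts are to ordered waters.
* π descriptors are limited to centroid distance and θ₁; the
  perpendicular offset from the ring plane and a θ₂-analogue at the
  centroid are not computed, so edge-on ring contacts score the same as
  face-on ones at equal centroid geometry.
* HalBS is an empirical-geometric score — no energy model, no
  quantum-chemical treatment of the σ-hole — and is best read as an
  indication, not a verdict.
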