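---
title: "Annotating xyloglucan oligosaccharide MALDI-ToF spectra with olimpr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Annotating xyloglucan oligosaccharide MALDI-ToF spectra with olimpr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(olimpr)
```

## The measurement and the model

Oligosaccharide mass profiling (OLIMP) digests a cell-wall preparation with
an endo-xyloglucanase and records the released xyloglucan oligosaccharides
(XGOs) by MALDI-ToF. Underivatized neutral glycans fly almost exclusively as
singly charged sodium adducts, so every peak is an [M+Na]+ ion and the whole
analysis reduces to integer arithmetic over five residue-class masses:
hexose (162), pentose (132), deoxy-hexose (146), hexuronic acid (176) and
the O-acetyl ester (42). A peak's m/z determines its monosaccharide
*composition* (a count vector over those classes) up to a mass tolerance; a
composition determines a set of candidate *structures* — assignments of
one-letter sidechain codes (G, X, L, F, S, D, E, B, Y, P) to backbone
glucosyl positions — which mass alone cannot distinguish. Everything beyond
composition therefore comes from orthogonal evidence: residue-mass ladders
between related peaks, and mass shifts produced by exo-glycosidases of known
specificity.

The package models exactly this chain: grammar and composition arithmetic
(`parse_structure()`, `composition_of()`), mass and adduct arithmetic
(`neutral_mass()`, `adduct_mz()`), exhaustive candidate enumeration
(`enumerate_compositions()`, `enumerate_structures()`), in-silico digestion
(`digest_endo()`, `exo_trim()`, `driselase_digest()`), ladder detection
(`find_series()`), differential pre/post-enzyme analysis (`diff_spectra()`),
tandem-MS neutral-loss interpretation (`fragment_ions()`,
`infer_terminals()`), and the assembled annotation pipeline
(`annotate_peaks()`).

Three modeling assumptions are global. Charge is fixed at one (MALDI of
neutral glycans). Peaks are centroids; profile-shape, isotope envelopes and
deisotoping are out of scope. Intensity is semi-quantitative and used only
for presence and fold-change decisions, never for quantification.

## Mass conventions

Integer m/z values reported for XGOs arise from two different conventions,
and both occur in practice: the monoisotopic [M+Na]+ mass truncated to an
integer (the fucosylated series 1099/1393/1555 and the acidic series
1129/1423), and the average [M+Na]+ mass rounded to the nearest integer (the
sparsely branched series 1146/1322/1440/1616). `mass_convention()` makes the
residue table (`monoisotopic`, `average`, `nominal`) and the rounding
(`none`, `nearest`, `truncate`) explicit, and every result records which
convention produced it. The electron mass is neglected in cation m/z
(≈0.0005 Da, far below reflectron accuracy at m/z 200–4000, the modeled
acquisition range).

```{r conventions}
adduct_mz("XXFG", mass_convention("monoisotopic", rounding = "truncate"))
adduct_mz("LGGGG", mass_convention("average", rounding = "nearest"))
```

## The sidechain grammar

The registry (`sidechain_registry()`) records each letter's residue content,
its exo-glycosidase-accessible terminal residue and the letter left after
trimming it: F→L and E→D under α-fucosidase (one deoxy-hexose),
L→X and P→Y under β-galactosidase (one hexose; F is resistant because its
galactose is capped by the fucose). S, D and B all contain two pentoses and
are mass-degenerate: they are kept as distinct letters, collapse to one
composition, and annotation reports the whole degeneracy group. Epimer
identity within a class (Gal vs Glc, GalA vs GlcA) is not modeled — mass
cannot see it. The registry is extensible through a plain-text table
(`read_sidechain_registry()`); the Q sidechain is omitted from the default
registry because its full residue content is not established, and can be
added via configuration once it is.

The P sidechain is modeled as *branched* on its xylose — a galactosyl and a
galacturonosyl side by side — so in tandem MS both its hexose and its uronic
acid are terminal. This is what makes an XPG-type precursor show three
simultaneous depth-1 neutral losses (pentose, hexose, uronic acid), and it
is why `exo_trim()` under galactosidase takes P to Y while the MS/MS model
additionally allows the HexA loss (P to L).

Acetylation is carried as a count with a `+nAc` suffix (e.g. `LPGGG+1Ac`)
because MALDI resolves the +42 mass but not the ester's position.
`saponify()` models alkaline de-esterification by zeroing the count.

## Enumeration

`enumerate_compositions()` is a brute-force sweep of all count vectors
within per-class bounds (defaults: Hex ≤ 10, Pent ≤ 6, dHex ≤ 2, HexA ≤ 3,
Ac ≤ 2), keeping those whose theoretical adduct m/z falls within the
tolerance (default ±0.5 Da, matching integer-reported peaks). The default
grid has 2 772 cells, so exhaustiveness is cheap and is cross-checked in the
tests against an independently coded nested-loop oracle.
`enumerate_structures()` then solves the exact cover of a composition by
sidechain codes over backbone lengths 2–6 (depth-first with residue-budget
pruning), optionally requiring the unsubstituted reducing-end glucose that
endo-xyloglucanase products carry. One arrangement per composition is
flagged canonical, following the conventions by which such structures are
named: no unsubstituted glucose before the reducing end where the
composition allows it (XLG, not GXXG), the most plain-X positions (the
XXXG-core convention: XXFG, not BFGG), decoration weight non-decreasing
toward the reducing end (XXFG, not XFXG), decorated positions early in
G-rich sparse oligos (LGGGG, LPGGG), and lexicographic order last for
determinism. This hierarchy reproduces the published names of all fourteen
assigned XGO compositions.

## Ranking candidates: why mass error alone cannot decide

The residue-class masses are linearly near-dependent:

* Hex + dHex = Pent + HexA + **0.0364 Da**
* Hex + 2 Pent = 2 dHex + HexA − Ac **exactly** (same elemental formula)

so two different compositions can sit 0.036 Da apart — an order of magnitude
below external-calibration MALDI-ToF accuracy. With 0.1 Da peak jitter,
ranking candidates by raw |mass error| alone would assign such peaks
essentially at random. `annotate_peaks()` therefore treats errors within a
`mass_accuracy` parameter (default 0.2 Da, typical reflectron accuracy at
m/z 1000–2000) as indistinguishable and resolves such groups by evidence,
in order:

1. candidates admitting at least one grammar-valid structure;
2. candidates whose structures explain an observed enzyme shift, graded up
   when subtracting the removed residue lands exactly on the established
   composition of the observed product peak;
3. candidates consistent with detected residue-mass series, counted per
   supporting ladder edge;
4. fewer distinct residue classes, fewer total residues, and a fixed
   lexicographic key for determinism.

Series consistency is evaluated by *anchored propagation*. A peak anchors
its ladder neighbors only when its own identity is settled — a single
candidate within the mass accuracy, or a single candidate singled out by
enzyme or (in a second pass) series evidence. Support then flows from
anchors along edges labeled with residue steps: a candidate is supported
when it equals an anchored neighbor's composition plus or minus the edge's
step. Propagating from merely top-ranked but ambiguous neighbors would be
circular: because of the near-degeneracy above, every true XGO series has a
phantom parallel series shifted by 0.036 Da, and binary support from
unsettled neighbors lets that phantom support itself. For the same reason
only single-residue enzyme-shift pairs act as edges or validate candidates:
a two-residue window (−324 Da) is wide enough to land on unrelated
compositions.

This evidence-first resolution of mass-indistinguishable groups is the
package's own design choice where raw-error ranking proved unstable; it
mirrors how such spectra are read by hand — an assignment that would break
an established series is rejected even when its mass error is marginally
smaller.

Peaks whose only candidates are pure hexose oligomers are flagged as the
contaminating hexose ladder that untreated cell-wall extracts carry; the
flag is computed from the composition, never matched against a stored list.

An aside the adduct machinery makes easy: a galactosidase-sensitive peak at
1445 differing from 1423 by ~22 is consistent with the di-sodiated acidic
XGO ([M+2Na−H]+ of the XXPG-type composition); the `+2Na-H` adduct is
available for exactly this check, and such peaks remain reported as
unassigned candidates rather than assignments.

## In-silico digestion

Endo rules are purely positional predicates on adjacent backbone positions:
XEG cleaves after an unsubstituted glucose; the XcXGHA-type activity cleaves
between two substituted units. Real enzymes have subsite requirements, so a
minimum product backbone length is configurable (default 1, i.e. all cuts);
digestion here serves to rationalize observed oligosaccharide pools, not to
model kinetics. Hydrolysis adds one water per cut, and mass conservation
(Σ products = substrate + cuts × water, to 1e−6 Da) is enforced by a
property test over random structures. Acetyls, position-unresolved, ride on
the reducing-end product. Partial digestion is represented at the spectrum
level — precursor and product co-present — not kinetically;
`simulate_digestion_experiment()`'s `completeness` fraction produces it.
Whether XXG-type cores arise from XEG acting on GXX-type regions or from a
second activity is left open; both rule sets are available.

Driselase reduces everything to monosaccharides except the α-1,6 xylose,
which stays on its glucose as isoprimeverose — the diagnostic disaccharide
of xyloglucan. `driselase_digest()` does the per-position bookkeeping;
residue counts reconcile exactly with `composition_of()`.

For exo-glycosidases, `predict_shift_pairs()` projects each observed peak
down by 1..k residue masses (k = 1 for fucosidase; k = 2 for galactosidase,
since XLLG-type oligos carry two removable galactoses), and
`diff_spectra()` pairs peaks that disappear (pre/post fold-change ≥ 5,
configurable) or shrink (≥ 1.5, "partial") with products present in the
post spectrum. Products need only be present, not new: fucosidase products
of XXFG-type oligos typically pre-exist as native XGOs.

## Tandem MS

Only neutral losses from the sodiated parent are modeled (the charge stays
on the large fragment), plus the two cross-ring neutrals of 60.021 and
120.042 Da: that is what reflectron MALDI-ToF/ToF spectra of sodiated
glycans show. The reducing-end glucose is removable only when unsubstituted
and not the last remaining unit (so a lone `G` yields only cross-ring
ions); the non-reducing terminal backbone unit can leave with its sidechain
as a composite loss whose depth cost is its residue count. Branching order
is generally not determined by these losses, so `infer_terminals()` returns
residue-class evidence (and ordered depth-2 pairs), never a position
assignment: the ambiguity set is preserved deliberately.

## The synthetic-data generator

`simulate_spectrum()` emulates the features of the real spectra this
pipeline targets: sodiated XGO peaks from a known structure mixture, the
contaminating hexose-oligomer ladder (default Hex3–Hex7), uniform-random
decoy peaks in the 200–4000 acquisition window, Gaussian m/z jitter in Da
(reflectron error is approximately mass-independent at the integer-reporting
scale; default sd 0.1 Da) and lognormal intensity noise (default CV 0.3).
Decoys are deliberately adversarial: uniform in m/z, some land within
tolerance of real compositions. The default 20-structure panel spans the
assignments made for charophycean green algae — XXG/XXXG-type neutral
cores, the galactosylated XLG…XLLG family, the fucosylated XFG/XXFG/XLFG
family including branching isomers, the acidic XPG/XXPG family, and the
sparsely branched LGGGG/PGGGG/LLGGG/LPGGG family — with mass-degenerate
isomers included on purpose (they collapse onto shared peaks, as in real
spectra). All randomness derives from the configuration seed; the paired
pre/post experiment derives the post-spectrum noise stream from seed + 10^6
so the two spectra are independently noisy yet jointly reproducible.

What the generator does **not** emulate: isotope envelopes, detector
saturation, matrix clusters, ppm-scaled mass error, chemical background
correlated across spectra. A passing recovery test therefore demonstrates
the logic of the evidence combination under realistic centroid-level noise,
not robustness to raw-spectrum artifacts.

## Numerical choices and problem sizes

Peak identity within a spectrum is 1e−6 Da (duplicate centroids merge);
peak matching across spectra and to theory uses the 0.5 Da tolerance;
mass-indistinguishability uses 0.2 Da; series steps match within 0.5 Da;
MS/MS terminal inference uses 0.3 Da by default (0.01 Da in the exhaustive
self-tests, where no noise exists). Structure enumeration caps at 500
arrangements per composition (attribute `truncated` marks the cut). The
test suite sizes its sweeps to be exhaustive where the space is small (all
registry structures to backbone 3–4 for round-trip and terminal-inference
checks; 11 110 structures at the largest) and seeded-random elsewhere (100
oracle m/z values, 200 conservation substrates, 50 simulated experiments of
~35 peaks each for recovery).

## Known limitations

* Composition bounds and backbone range are tuned to XGO pools; exotic
  polymers need wider bounds, at quadratic-to-combinatorial cost.
* The grammar admits every letter at every substituted position; organisms
  use restricted repertoires, so enumerated structure lists overstate the
  true ambiguity. The canonical flag and degeneracy groups mitigate, not
  remove, this.
* Enzyme rules are specificity idealizations: no subsite preferences beyond
  the minimum-length option, no incomplete-digestion kinetics.
* With a single companion enzyme, compositions insensitive to that enzyme
  are resolved only by series evidence; peaks outside any series and any
  shift remain ranked by parsimony among mass-tied candidates.
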