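---
title: "Melting-curve identification of species and haplotypes: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Melting-curve identification of species and haplotypes: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hrmelt)
library(dplyr)
```

This vignette documents the models, parameters and design choices
behind `hrmelt`, in the spirit of a methods section: what each stage
assumes, where the knobs are, and what the synthetic data do and do not
demonstrate.

## From raw fluorescence to melting curves

A high-resolution melting experiment records, per well, relative
fluorescence `F(T)` on a fine temperature ramp — canonically 65 °C to
95 °C in 0.1 °C steps, i.e. 301 grid points. The package stores this as
a long tibble (`sample_id`, `temperature`, `rfu`) and never assumes a
uniform grid at parse time: instruments drop steps, and the operations
that require uniform spacing (smoothing) check it explicitly and direct
the caller to `regrid_curves()` rather than resampling silently.

**Smoothing.** Raw fluorescence is smoothed with a Savitzky–Golay
filter (local least-squares polynomial fit) before differentiation,
never after: smoothing the derivative would bias peak shape directly.
Defaults are a 7-point window with a quadratic fit — on a 0.1 °C grid
the window spans 0.6 °C, comparable to one transition width, which
suppresses point noise while leaving the peak position of a symmetric
melt transition unchanged (a quadratic fit reproduces any quadratic
exactly, so a locally parabolic peak is not displaced). The window must
be odd and at least `poly_order + 2`; smoothing can be disabled.

**Differentiation.** The melting curve is `−dF/dT`, computed by central
finite differences at interior points and one-sided differences at the
two boundary points. Central differences on a uniform grid are
second-order accurate; the trapezoidal integral of the result recovers
`F(T_a) − F(T_b)` to `O(step²)`, a property the test suite checks on
smooth synthetic inputs.

**Tm calling.** The melting temperature is the temperature of the
global maximum of `−dF/dT` restricted to interior grid points, refined
by the vertex of the parabola through the peak and its two neighbours.
Ties break toward lower temperature (`which.max`). If the global
maximum sits on a boundary point there is no interior melt peak — no
amplification, or a transition outside the ramp — and the sample is
flagged `no_peak` with `tm = NA` instead of reporting a misleading
number. If the fitted parabola is degenerate (non-negative curvature)
or its vertex escapes the three-point bracket, the grid-point maximum
is returned unrefined. On noiseless two-state curves the called Tm is
within 0.05 °C of the model Tm for transition widths ≥ 0.3 °C on the
0.1 °C grid.

**Difference curves.** Following the convention of subtracting each
curve from the mean of the comparison set, the difference curve is
`d_i(T) = m(T) − c_i(T)` with `m` the mean over the reference set only;
curves outside the set are differenced against the same `m`. The sign
choice is cosmetic (it flips the plot); the substantive property —
`Σ_i d_i(T) = 0` pointwise over the generating set — is independent of
it and holds to machine precision. Difference curves are computed on
`−dF/dT` curves by default. Commercial HRM software often differences
*normalized raw fluorescence* instead; that mode is available
explicitly via `normalize_fluorescence()` (linear baselines fitted in
pre-melt 65–70 °C and post-melt 90–95 °C windows, rescaled to 0–100 %)
and is off by default because the derivative-curve convention keeps the
whole pipeline scale-equivariant and offset-invariant, properties the
tests verify end to end.

## Classification, ambiguity, and the multiplex fallback

Reference wells are averaged per label into an `hrm_library`. Distances
between curves are Euclidean by default, computed on an **analysis
window** of 70–85 °C rather than the full ramp: outside the transition
region the derivative is baseline noise, and including 150 near-zero
noisy points would dilute the signal. The window is configurable and
recorded in the library object. The within-replicate spread — the
median Euclidean distance of each replicate curve to its label mean
over the window — is recorded as the library's noise scale.

Classification of a query computes distances to all entries and applies
two thresholds:

* `reject` (default 5× spread): best distance above it →
  **unassigned**; no reference taxon melts like this sample.
* `margin` (default 2× spread): runner-up within it of the best →
  **ambiguous**, with every label inside the margin listed as a
  candidate.

The multipliers are a design choice, made once: 2× leaves essentially
no chance that two same-species replicates straddle the margin, while
5× tolerates a query noisier than the library without rejecting it.
With a noiseless library the spread is zero and the automatic
thresholds degenerate to `reject = Inf`, `margin = 0` (assign
everything to its nearest entry); supply numeric thresholds when
calibrating against real instrument variability. Exact distance ties
are ordered lexicographically by label and reported ambiguous, so the
procedure is deterministic. Increasing the margin can only move calls
from assigned to ambiguous, never the reverse (abstention
monotonicity).

Species whose amplicons melt within instrument resolution of each other
— the motivating case is a congeneric pair whose main-assay Tms differ
by a few hundredths of a degree — come back ambiguous by design. The
resolution is a secondary **multiplex assay**: two primer pairs, each
amplifying only one of the candidates (a 116-bp 16S product for one, a
213-bp COI product for the other), whose product Tms fall in disjoint
windows. `multiplex_resolve()` calls the multiplex well's Tm: inside
exactly one candidate's window the sample is assigned (method
`"multiplex"`); a missing peak means neither product amplified and the
sample is unassigned; a Tm outside every window, or inside overlapping
windows, is inconclusive and preserves the ambiguity rather than
guessing. The windows are shipped configuration
(`default_multiplex_rule()`, bracketing the simulator's model Tms for
the two products), not hard-coded biology — real assays should supply
windows calibrated on their own instrument, e.g. via a YAML file and
`read_multiplex_rule()`.

## Haplotype groups from difference curves

Melt-based haplotype screening clusters difference curves with average
linkage under the Euclidean distance. Average linkage was chosen over
single (chains through noise) and complete (splits elongated noise
clouds) for robustness to single noisy replicates; the choice is
recorded in the result object. The cut height is the genuinely open
design point — the underlying experiment decided group membership
visually — so the automatic rule is deliberately simple and always
reported alongside the group count: cut at **3× the within-replicate
spread** when replicate structure is available, else 3× the median
nearest-neighbour distance. The rationale: within-group distances on
replicate-averaged curves are of the order of the replicate noise,
while between-group distances correspond to Tm shifts of several tenths
of a degree and are an order of magnitude larger, so any multiplier in
the 2–5 range separates them; 3 sits in the middle. Group indices are
relabeled by first occurrence, making the partition invariant to input
order.

## In-silico PCR

The degenerate-primer engine defines matching set-wise: an IUPAC symbol
matches a template base iff the base is in the symbol's set. A template
`N` matches nothing by default — conservative, because a primer cannot
be relied on to bind an unknown base — with a permissive
set-intersection mode behind a flag. The 3′-terminal 3 bases of the
primer must match exactly (polymerase extension requires a paired 3′
end); the mismatch budget (default 0) applies only outside that anchor.
How many non-degenerate mismatches the original assay tolerated is not
documented, hence the explicit default-0 flag rather than a guess.

Product length includes both primer footprints, the standard PCR
convention (a 158-bp product = 23-bp forward footprint + 115-bp core +
20-bp reverse footprint). Coordinates are 0-based half-open internally.
Amplicon prediction pairs every + strand forward hit with every
downstream − strand reverse hit within a 2 kb limit and reports all of
them — off-target products are a finding, not an error. Because primer
sites are fixed loci on a template, the nine product lengths of a
3 × 3 primer panel satisfy offset additivity (`L(F_i,R_j) − L(F_i,R_k)`
independent of `i`, and vice versa); the published length table
satisfies this, and `simulate_coi_reference()` builds a synthetic
template whose planted sites reproduce the full table, which the tests
and the acceptance script verify.

Haplotypes are defined on the **inter-primer core** by default: in a
real amplicon the primer-footprint bases are overwritten by the primers
and carry no specimen information. Full-amplicon mode exists for
comparison. Collapse is exact identity after uppercasing; equal length
is enforced, because primer-anchored extraction of a subregion without
indels must return constant-length cores — a length difference signals
a failed extraction or an indel, which is reported rather than aligned
away. No multiple sequence alignment is performed anywhere. The tree
over haplotypes is UPGMA on p-distances (ambiguous sites excluded
pairwise; a pair with no comparable sites is `NA`, never 0). UPGMA —
not maximum likelihood — is the shipped method: it is deterministic,
dependency-light, ultrametric by construction, and sufficient to
recover the topology class of a short subregion; branch lengths are not
comparable to an ML tree's.

## The melt simulator

Synthetic plates come from a deliberately minimal two-state model:

* helicity `θ(T) = 1 / (1 + exp((T − Tm)/s))` with transition width
  `s` (default 0.6 °C, a typical short-amplicon transition);
* fluorescence `F(T) = b0 + b1·T + A·θ(T) + ε`, with a linear baseline
  (defaults `b0 = 2`, `b1 = −0.01` RFU/°C, a mild downward dye drift),
  unit amplitude, and i.i.d. Gaussian noise per well and temperature
  step (default SD 0.002 RFU, i.e. 0.2 % of amplitude — a clean but
  not noise-free instrument);
* amplicon Tm from the classic salt-adjusted GC/length rule
  `Tm = 81.5 + 16.6·log10([Na+]) + 0.41·GC% − 600/N` at 50 mM salt.

For this model the `−dF/dT` peak sits exactly at Tm, which is what
makes the Tm-recovery bound testable. The GC/length rule is the
simulator's *definition*, not a physical prediction: it ignores
sequence order entirely, so A↔T and G↔C substitutions are exactly
Tm-neutral. That is a feature — it reproduces, mechanically, the
empirical phenomenon of haplotypes that HRM cannot distinguish, and
lets fixtures plant melt groups with known membership. What the
simulator does **not** emulate: multi-domain melting of longer
amplicons, heteroduplexes, plate-position effects, correlated drift,
amplification-phase variability. Passing tests therefore demonstrate
the pipeline's correctness and calibration on idealized two-state data,
not instrument-grade performance on real plates.

The packaged scenarios fix the study conditions: `eight_species`
(8 species at core-GC steps of 3, i.e. ~0.78 °C Tm spacing; 5
technical replicates per reference; 200 single-well queries),
`caliginosa_longa_ambiguity` (two labels 0.04 °C apart — below the
0.1 °C ramp step — plus per-query multiplex wells), and
`chlorotica_haplotypes` (28 individuals, 8 haplotypes planted as +3 and
+7 G+C between groups and GC-neutral substitutions within, collapsing
to 3 melt groups with membership 1 / 4 / 3). Sizes follow the
experimental layout they emulate: 5 replicates, 301-point ramps,
28 individuals; the 200-query classification set is the package's
choice of a round, statistically comfortable sample. All generators are
seeded and byte-reproducible.

## Degenerate inputs and numerical edges

* Temperature grids: strictly increasing enforced everywhere;
  duplicated rows are an error at parse time, not silently dropped.
* Melt tables are written with 6 significant digits; round-trips are
  exact to that precision.
* `curve_distance` requires identical grids and refuses to interpolate
  implicitly.
* Clustering a set of identical curves yields one group (the automatic
  cut falls back to a tiny positive height when the noise scale is
  zero).
* The parabola refinement falls back to the grid maximum when the
  three-point fit is degenerate.
* `expand_degenerate` counts by per-position set-size product;
  enumeration (lexicographic) is capped at 10⁴ variants and equals the
  count wherever it is allowed to run.

## Known limitations

* The two-state simulator cannot generate curve *shape* differences at
  equal Tm, so shape-based discrimination (which real HRM sometimes
  achieves) is untested.
* Automatic thresholds are calibrated from replicate spread; libraries
  built from single wells need user-supplied thresholds.
* The multiplex Tm windows shipped as defaults match the simulator,
  not any instrument; recalibrate before real use.
* p-distance and UPGMA are adequate for grouping near-identical cores;
  they are not a substitute for model-based phylogenetics on divergent
  sequences.
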