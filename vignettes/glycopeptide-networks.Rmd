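---
title: "Glycopeptide networks from LC-MS1 feature tables: method and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Glycopeptide networks from LC-MS1 feature tables: method and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glyconet)
```

## The problem

N-glycosylation is a critical quality attribute of antibodies: the glycans
on the conserved Fc site (tryptic peptides EEQYNSTYR for IgG1, EEQFNSTFR
for IgG2) modulate effector function, clearance and immunogenicity.
Conventional glycan characterisation releases the glycans, labels them
fluorescently and assigns structures from separate LC runs — accurate, but
slow and expertise-heavy. An attractive alternative for multi-attribute
monitoring is to work directly from a deconvoluted LC-MS1 feature table:
one row per detected species with its neutral monoisotopic mass, retention
time and summed intensity, as exported by standard deconvolution software.

The difficulty is identification. A single neutral mass at TOF accuracy
rarely pins down a glycopeptide on its own, and database lookups cannot see
glycan compositions that the database lacks. `glyconet` exploits the fact
that glycoforms of one peptide backbone form a *mass ladder*: they differ
from each other by sums of monosaccharide residue masses and co-elute
within narrow retention windows. Treating features as nodes and
residue-mass differences as edges turns each peptide's glycoform family
into a connected subgraph that can be identified as a unit: only one node
per subgraph — the *reference node* — is ever matched against a database,
and every other member is assigned by arithmetic along the edges.

## The procedure

1. **Mass floor.** Features lighter than the smallest conceivable
   glycopeptide — the lightest configured backbone plus one HexNAc, 1359.594
   Da for the IgG Fc peptides — cannot be glycopeptides of interest and are
   removed (`mass_floor_filter()`; retention is inclusive at the boundary).
2. **Edges.** Every feature pair whose mass difference matches a residue
   delta within `mass_tol` (default 0.02 Da) *and* whose retention gap is
   within that residue's window becomes an edge (`detect_edges()`). The
   residue set is HexNAc 203.07937, Hex 162.05282, Fuc 146.05791, NeuAc
   291.09542, and the composite HexHexNAc 365.13219 which bridges a missing
   intermediate glycoform; NeuGc 307.09033 is available but off by default.
   Windows are 30 s (HexNAc, Hex, Fuc), 50 s (HexHexNAc) and 500 s (NeuAc
   — sialylation shifts retention strongly). A pair matching several
   residues keeps only the smallest-ppm-error match.
3. **Networks.** Connected components of the edge graph
   (`cluster_subgraphs()`). Features without any edge are reported as
   singletons, never as one-node networks: an isolated mass has no ladder
   evidence and is left unidentified.
4. **Reference matching.** The candidate database is the Cartesian product
   of backbone masses and a glycan composition library
   (`build_candidate_db()`). Only each network's lowest-mass node is
   matched against it (`match_reference()`, default tolerance 0.02 Da,
   ranked by absolute error, ties broken toward the smaller composition).
   Networks whose reference matches nothing are excluded from
   quantitation — this is the graph filter that removes non-glycopeptide
   clusters.
5. **Propagation.** From an accepted reference composition, crossing an
   edge toward higher mass adds the edge residue's composition increment
   and toward lower mass subtracts it (`propagate()`). Every reached node
   inherits the reference peptide plus the accumulated composition —
   deliberately *without* re-matching the library, so glycoforms absent
   from any database are still assigned. Each assignment is verified
   against the node's observed mass (default 0.03 Da).
6. **Quantitation.** Features sharing (peptide, composition) — retention-
   split peaks — are merged by intensity sum (`merge_split_peaks()`), then
   relative abundance is `100 x intensity / total intensity` within the
   peptide backbone (`relative_abundance()`), and attribute roll-ups sum
   the percentages of glycoforms satisfying each composition predicate
   (`attribute_rollup()`).

`glyconet()` runs all of this and returns one object with `print()`,
`summary()`, `plot()` (the retention-vs-mass bubble chart, unassigned
features in grey) and `residuals()` (per-node mass errors in Da) methods;
`run_pipeline()` wraps it for batch use with a YAML configuration and CSV
reports, and `inst/cli/glyconet` is a thin command-line front end.

## Parameters that matter

| parameter | default | unit | rationale |
|---|---|---|---|
| `mass_tol` (edges) | 0.02 | Da | benchtop-TOF accuracy at 1.3–4 kDa; ppm mode available |
| `match_tol` (reference) | 0.02 | Da | same scale as edge matching |
| `verify_tol` (propagation) | 0.03 | Da | edge errors accumulate along paths |
| RT windows | 30 / 50 / 500 | s | co-elution of single-residue steps; composite steps looser; sialylation much looser |
| mass floor | min backbone + HexNAc | Da | smallest possible glycopeptide |

The NeuAc window deserves a note: single-residue windows are 30 s, but a
NeuAc addition changes hydrophilicity enough to shift elution by minutes,
so NeuAc uses the wide 500 s window. All windows are per-residue
configurable (`default_residue_set(rt_windows = ...)`).

The default glycan library is generated combinatorially rather than taken
from any commercial list: 2–7 HexNAc, 3–12 Hex, 0–2 Fuc, and 0–4 NeuAc
constrained by antenna count (NeuAc ≤ HexNAc − 2), which covers complex,
hybrid and high-mannose (2 HexNAc, 4–12 Hex) mammalian N-glycans — 600
compositions. What the algorithm needs from the library is only that
plausible *reference* compositions are present; propagated nodes are never
looked up. A user library is a one-column CSV of short forms
(`read_glycan_library()`).

### Assignment modes

Reference confirmation is the one human step of the semi-automated design.
Three modes exist: `"interactive"` prompts per network on the console;
`"from-file"` replays a decisions CSV (`network_id, accept`), which is the
auditable route for validated workflows; `"auto"` accepts the best-ranked
candidate and warns when alternatives fall inside the tolerance. The R
function defaults to `"auto"` because programmatic use is itself the batch
case; an interactive R session can opt into the prompt mode.

### Attribute predicates

Composition data cannot prove topology, so attribute rules are documented
naming conventions, configurable per run: fucosylation `Fuc ≥ 1`;
sialylation `NeuAc + NeuGc ≥ 1`; high mannose `HexNAc = 2 and Hex ≥ 5`;
galactosylation `HexNAc ≥ 3 and Hex ≥ 4` (complex/hybrid carrying at least
one galactose); bisecting `HexNAc ≥ 5 and Hex ≤ 5` (the extra HexNAc of a
biantennary IgG glycan is conventionally read as bisecting GlcNAc).
Roll-ups are computed from **all** assigned rows; any display threshold
(for example hiding sub-0.5 % glycoforms in a table) is applied at print
time only, via `summary(fit, threshold = 0.5)`, and never changes the
roll-up denominators.

## The synthetic data generator

Because raw instrument data cannot ship with a package, every claim the
test suite makes is established on synthetic feature tables with planted
ground truth (`synthetic_spec()` / `generate_features()`). The generator
emulates exactly the structure the method consumes: per-glycoform features
at exact glycopeptide mass plus Gaussian error (default SD 0.002 Da),
retention as backbone base time plus per-residue shifts (defaults: 2 s per
HexNAc, 3 s per Hex, 5 s per Fuc, 120 s per NeuAc — inside the edge
windows) plus jitter (SD 2 s), intensity proportional to the planted
fraction with optional multiplicative lognormal noise, retention-split
peaks with configurable probability (intensity split 0.65/0.35), and two
kinds of decoys: scatter features and decoy *ladders* that cluster like
glycopeptide families but match no candidate. Decoy masses are
rejection-sampled at least 0.1 Da away from every residue offset of every
planted or previously placed node, so decoys can never join a planted
network by construction — tests of decoy safety are therefore exact, not
probabilistic.

`fig_fixture_serum_igg()` is the canned benchmark: two assignable networks
(IgG1 on EEQYNSTYR near 12 min, IgG2 on EEQFNSTFR near 18 min) among 16
decoy ladders — 18 connectable clusters of which exactly 2 match the
candidate database. The planted IgG1 profile fixes the two dominant
glycoforms at N4H4F1 = 36.782 % and N4H5F1 = 19.284 % and distributes the
remainder over the usual serum-IgG1 minor species (agalacto N4H3F1,
afucosylated N4H3/N4H5, bisecting-type N5H3F1/N5H4F1, mono-sialylated
forms, Man5) with one deliberate subtlety: a trace hybrid N3H5 (0.434 %)
bridges Man5 (N2H5) into the residue ladder. On real data such
low-abundance intermediates are what connect the high-mannose arm to the
complex-type ladder; without the bridge N2H5 would be an isolated node and
correctly remain unassigned. The IgG2 profile (N4H4F1 = 33.368 %, N4H5F1 =
14.222 %) places the truncated N3H3F1 as its lowest-mass, reference
glycoform.

```{r fixture, eval = FALSE}
sim <- generate_features(fig_fixture_serum_igg(seed = 1))
fit <- glyconet(sim$features, c("EEQYNSTYR", "EEQFNSTFR"))
summary(fit, threshold = 0.5)
plot(fit)
```

What the generator does **not** emulate — and what green tests therefore do
not demonstrate about real data: chromatographic peak shapes and tailing,
charge-state deconvolution artefacts, isotope-cluster errors (off-by-1.003
Da masses), adducts, in-source fragmentation, co-eluting isobaric
backbones, and intensity nonlinearity. Problem sizes in the suite
(~100–500 features per table, 50 randomised tables for the brute-force
equivalence checks, 100 replicates for noisy-recovery statistics) were
chosen as the smallest sizes at which every code path — decoy rejection,
split peaks, multi-network tables — is exercised.

## Numerical choices and degenerate inputs

* **Tie-breaks.** Edge residue assignment: minimum |ppm error|. Reference
  ranking: |mass error|, then composition size, then lexicographic — fully
  deterministic.
* **Propagation order-independence.** Compositions are relaxed to a
  fixpoint over the component's edges rather than taken from a single BFS
  tree, so the result cannot depend on visit order; a node reached with two
  *different* compositions is flagged `ambiguous` (and excluded from every
  quantitation denominator), while agreeing multi-path diamonds are
  ordinary assignments. Subtracting below a zero residue count prunes that
  path. A near-degenerate arithmetic fact worth knowing: 2×Hex − 2×Fuc =
  31.98982 Da equals the EEQYNSTYR/EEQFNSTFR backbone difference to 0.1
  mDa, so cross-backbone candidate masses can collide; reference matching
  reports all within-tolerance candidates precisely so such collisions are
  visible rather than silent.
* **Floor boundary** is inclusive (a feature exactly at the floor mass is
  kept).
* **Empty inputs.** An edgeless table yields zero networks and all
  singletons; a table empty after the floor terminates the pipeline cleanly
  with its log written; zero total intensity in a quantitation scope is an
  error, not a NaN.
* **Determinism.** The analysis path contains no randomness; the generator
  is seeded. Re-running a pipeline configuration reproduces every report
  byte for byte.

## Known limitations

Compositions, not structures: linkage, arm position and true bisection are
outside what MS1 masses can show. Single glycosylation site per backbone is
assumed (true for IgG Fc tryptic peptides); multiply glycosylated peptides
would need site-resolved fragment data. Quantitation treats deconvoluted
intensity as an opaque non-negative weight — ionisation-efficiency
differences between glycoforms are not corrected. Networks whose true
reference glycoform is absent from the library are dropped entirely;
extending the library is the remedy. Inferential statistics across
conditions are out of scope by design: `longitudinal_table()` emits a tidy
long table (with group means and standard errors) intended for standard
statistical tooling downstream.
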