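---
title: "Methods: transport-function analysis for reduced-genome endosymbionts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: transport-function analysis for reduced-genome endosymbionts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(symbiotrans)
```

`symbiotrans` quantifies the transport function of obligate intracellular
bacteria from three directions: the topology of the metabolic network
(which compounds must cross the envelope), the annotated transporter
repertoire (which carriers remain), and membrane ultrastructure (what the
envelope those carriers sit in actually looks like). This vignette is the
package's account of the underlying models, the parameters that matter,
and the design decisions taken where the design was genuinely open.

## 1. Qualitative network model

A network is a set of compounds and reactions; each reaction has non-empty
substrate and product lists with positive coefficients and a
reversibility flag. Two modelling commitments shape everything downstream:

* **Stoichiometry is stored but ignored.** All topology and producibility
  operations are qualitative. This is deliberate: boundary detection and
  precursor semantics are graph-theoretic questions, and no mass-balance
  information is assumed to be reliable in draft annotations of reduced
  genomes.
* **Reversible reactions are expanded to two oriented reactions** before
  any downstream operation (`orient_reactions()`); this is the single
  point where direction semantics live.

**Side (currency) compounds.** Hub metabolites like ATP and water connect
nearly everything and would otherwise flood the compound graph with
spurious paths. `filter_side_compounds()` removes them before topology
analysis; reactions left one-sided are dropped and logged. The default
list (`default_side_compounds()`: H2O, H+, ATP, ADP, AMP, Pi, PPi, NAD(P)
and NAD(P)H, FAD, FADH2, CoA, CO2, NH3, O2) is a package decision — the
standard currency set used in metabolic graph analysis — and is
overridable everywhere it is used, because no canonical published list
exists for this system. Filtering is idempotent and order-independent
(filtering with S then T equals filtering with S ∪ T), which the test
suite checks as a property.

**Compound graph.** Nodes are compounds; a directed edge (u, v) exists iff
some oriented reaction consumes u and produces v, deduplicated with the
inducing reaction ids kept as provenance.

## 2. Boundary compounds

* an **input** is a node with in-degree 0 and out-degree ≥ 1 (a source);
* an **output** is a node with in-degree ≥ 1 and out-degree 0 (a sink);
* **isolated nodes belong to neither list** — both definitions presuppose
  participation in the network — and are reported separately.

Inputs are computed on the side-filtered graph and the filtered currency
compounds are then *restored* into the input list with provenance
`restored_side`: a filtered hub compound is, by construction, consumed by
the pruned network but not produced within it. Curation
(`apply_curation()`) emulates expert refinement: manual additions carry
provenance `manual_add`, false-positive removals are logged with reasons,
and disjointness conflicts resolve in favour of the manual action with a
warning, because curation models an expert override of the automatic
lists. A subgraph-level reading of "no incoming edge" (connected
components) was considered and rejected: the node-level definition is the
one the source definitions support, and it is what the package implements.

## 3. Producibility and minimal precursor sets

Producibility is the least fixpoint of network expansion: starting from a
seed set, fire any oriented reaction whose substrates are all available,
add its products, repeat. A compound inside a directed cycle is producible
only if the cycle can be entered from outside — there is no
bootstrapping. This strict forward-closure semantics is the standard
reading when no stoichiometric criterion is given.

A **minimal precursor set** for target `t` is a subset-minimal `S` of the
declared inputs with `t ∈ closure(S)`. Precursor sets are subsets of
*declared inputs only*; internal compounds never appear in them. The
enumerator works by increasing set size over the inputs that are
graph-ancestors of the target (no other input can occur in a minimal set,
since removing a member must break production along some path), skipping
supersets of sets already found; the size-increasing order makes every
accepted set automatically minimal, and each returned set is nevertheless
re-verified (producible, and not producible after any single-member
removal). Output order is canonical: by size, then lexicographic.
Correctness is defined by agreement with `brute_force_precursor_sets()`,
which tests all `2^n` subsets; the suite checks exact agreement on 260
seeded random networks (up to 25 compounds, up to 8 declared inputs,
cycles and reversible reactions allowed), plus monotonicity, idempotence
and antichain properties.

Resource limits (`max_inputs` 20, `max_sets` 10 000) are hard errors,
never silent truncation: an incomplete enumeration that looks complete is
worse than a refusal.

## 4. The transporter repertoire

The packaged fixture transcribes a four-strain *Buchnera* transporter
repertoire (BAp, BSg, BBp, BCc) with TC class, family, best-hit
expectation exponent, substrates, direction, membrane, transmembrane
domains, functional category, and per-strain gene lists with pseudogene
flags. Binding counting conventions:

* **Gene counts** sum intact (non-pseudogene) genes only, with complex
  multiplicities as printed (8 for the F-ATPase chain, 28 for the BAp
  type-III secretion apparatus). Under this convention the fixture yields
  90/92/79/35 intact genes for BAp/BSg/BBp/BCc.
* **CvpA is flagged pseudogene in BSg**: the running text describes the
  shared single-base deletion even though the table cell carries no
  pseudogene mark; the text wins. Without this flag the BSg gene total
  would not reproduce.
* **System totals** count grouping-column groups with ≥ 1 intact gene.
  The grouping convention: GroES/GroEL form one GroESL chaperonin group
  that is *listed but not counted* as a transporter system (cytosolic
  chaperonins with no TC hit, carried as transport facilitators), and the
  PTS energy-coupling factors (PtsI, PtsH; TC class 8) attach to their
  parent PTS group. Under exactly this convention the fixture reproduces
  the summary totals 33/34/30/12. This is the one place where several
  defensible conventions existed; the chosen one is recorded in the
  fixture's `group_id` column so it is data, not code.
* **Confidence**: a substrate prediction is `confident` iff its best-hit
  exponent is ≤ −40 (including perfect hits), else `speculative`.
  Explicit per-system overrides are allowed and flagged in the fixture;
  the only rule override is YnfM (exponent −116, confident by rule) which
  the source's ten-gene caution list nevertheless labels speculative —
  the explicit list wins. Multimeric complexes identified by orthology
  rather than a single Blast hit (F-ATPase, Rnf, Sec, T3) carry no
  exponent and are marked non-speculative as systems.
* `functional_category` assigns DnaK, GroESL, Sec, T3, YidC/OxaA, HtpX,
  YfgM, YaeT, Lol and Pal to `protein_processing`; this makes the
  conserved-core query deterministic: the four-strain core outside
  protein processing is {YggB, YoaE, Mdl, YciC}.

## 5. Comparative statistics

`ks_two_sample()` computes D = sup |ECDF_x − ECDF_y| directly. The
p-value uses the asymptotic Kolmogorov distribution with the standard
effective-sample-size correction (λ = (√n_eff + 0.12 + 0.11/√n_eff)·D,
n_eff = nm/(n+m)); for samples of ≤ 10 observations each the exact
permutation distribution is used instead (via `stats::psmirnov`), and the
tests verify the exact path against a full enumeration oracle written
independently in the test helpers. `linear_fit_r2()` is ordinary least
squares through `stats::lm` with R² = 1 − SS_res/SS_tot and the slope
t-test at n − 2 df; a constant response is defined to have R² = 0.

`generate_lifestyle_dataset()` draws transporter-gene fractions uniformly
within each lifestyle group's range (defaults: intracellular-obligate
1–4 %, n = 12; parasitic 2.5–7.1 %, n = 26; free-living 2.8–10.7 %,
n = 146). Uniform sampling within ranges is an emulation — only ranges
and group sizes are available, not the underlying distributions — so
passing tests demonstrate that the statistics detect separation under
these conditions, not that real fractions are uniform.

## 6. Compound-to-transporter assignment

Rules (packaged JSON, editable) map each repertoire system to the
compound classes it moves, or to named substrates for narrowly specific
carriers (PitA → phosphate; Znu → zinc), with a match level, allowed
directions and a membrane. Broad channels are `general` matchers whose
class coverage is enumerated explicitly (the OmpF porin passes all
small-solute classes); systems with direction `nd` match nothing unless
explicitly ruled. Passive-diffusion compounds (CO2, O2, H2O, NH3,
glycerol, formaldehyde) carry a diffusion flag and are never counted as
orphans. Membrane models: inner+outer for BAp, BSg and BCc; inner only
for BBp (its outer-membrane protein complement is absent); the
symbiosomal membrane is represented but carries no bacterial transporter.
Outer-only coverage of an import compound leaves it an inner-membrane
orphan (the headline deficiency metric is the fraction of non-diffusion
import compounds with no non-speculative inner-membrane candidate);
whether porin-only coverage should count as partial import is a
configurable reading, and the stricter default is used throughout.

## 7. Image analysis

**FFT bandpass.** Feature-size band [small_px, large_px] implemented as a
fourth-order Gaussian annulus in frequency space,
H(f) = exp(−(f·small)⁴)·(1 − exp(−(f·large)⁴)). The kernel order is a
package decision (only the filter class is given by the source
procedure); fourth order gives a flat passband (mid-band amplitude within
5 %) with ≥ 80 % attenuation one octave outside the band and
near-idempotence, all checked analytically on sinusoidal gratings in the
tests. The DC term is removed by the band and re-added by default so a
uniform image passes unchanged.

**Profiles and detection.** An ROI crosses the membranes along its row
axis; the profile is the per-row mean across the ROI columns. Membranes
are electron-dense, hence dark: detection runs on the inverted profile
(polarity configurable). A trough is accepted when its prominence is
≥ `min_prominence_sd` (default 1.0) profile standard deviations and it
lies ≥ `min_separation_px` (default 4 px) from any stronger accepted
trough; sub-pixel positions come from a 3-point parabolic fit with the
interpolation step clamped to ±0.5 px and ties broken toward the smaller
index. Spacings are reported in nm only when a pixel size is calibrated,
otherwise in px with an explicit unit tag — never silently unitless.
Layer classification is purely by count (2 → two-layer, 3 → three-layer,
else other). The 20 nm contact-point threshold sits between the two
reference regimes for intermembrane distances (mitochondrial contact
sites near 15 nm versus symbiosomal spacings near 37–41 nm) and uses a ≤
convention at the boundary.

**Ratiometric check.** ratio = weight·a/(b + offset), coefficient of
variation over a mask, and contrast regions as connected components
(EBImage labelling) where |ratio − mean| > k·SD (default k = 3, minimum
region 9 px). Identical inputs give an exactly constant ratio with
CV = 0.

## 8. Synthetic data: what it emulates and what it does not

Every generator is a pure function of (spec, seed) and returns a manifest
sufficient to score the downstream operation without re-derivation;
manifest claims are themselves verified in the suite (network inputs
against the degree scan, planted precursor sets against the subset
oracle, planted repertoire cores against `conserved_core()`, line centres
against the detector). The network generator builds layered networks with
optional alternative routes, entered cycles and reversible reactions, and
guarantees the target is producible from the full input set. The image
generator plants Gaussian-profile dark lines (blur, then additive
Gaussian noise; SNR = depth/noise). These emulations omit real-data
features — annotation errors and missing reactions, curved or broken
membranes, detector artefacts, uneven illumination — so green tests
certify the algorithms under controlled conditions, not performance on
raw micrographs or draft networks.

Problem sizes used by the default suite and the acceptance script were
chosen to exercise the contracts at full strength while staying quick:
200 networks for oracle equivalence, 100 images per geometry at SNR 5,
100 lifestyle simulations, 25-replicate property loops elsewhere.

## 9. Known limitations

* Boundary semantics are purely topological; flux, kinetics,
  compartments and mass balance are out of scope by design.
* The repertoire fixture is a transcription with documented conventions,
  not a re-annotation; recomputing repertoires from genome sequences or
  live homology searches is out of scope.
* The enumerator's exact search is exponential in the number of declared
  inputs (hence the hard `max_inputs` limit); networks with hundreds of
  inputs need a different algorithmic approach.
* The membrane detector assumes lines roughly parallel to ROI rows;
  strongly curved membranes require ROI placement by the user.
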