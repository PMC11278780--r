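---
title: "Boolean pathway reachability for endophyte chemotype inference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Boolean pathway reachability for endophyte chemotype inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chemotypeR)
```

## The problem

*Epichloë* endophytes of cool-season grasses synthesize up to four alkaloid
classes, each encoded by a gene cluster (EAS for ergot alkaloids, IDT/LTM
for indole–diterpenes, LOL for lolines) or a single multi-domain gene
(`ppzA` for peramine). Which alkaloids a strain can make — its chemotype —
is determined, to first order, by which pathway genes its genome retains.
PCR presence/absence profiling of those genes is the standard low-cost
assay, and the inference from profile to chemotype is purely logical:
a metabolite is producible when every gene its synthesis step needs is
present and its pathway precursor is itself producible.

chemotypeR makes that inference reproducible: declarative pathway models,
a deterministic reachability engine, strain-level calls (mating type,
`ppzA` allele, pattern codes, chemotype type, livestock-safety category),
survey arithmetic, and a simulator that generates profiles with known
ground truth.

## The model and its assumptions

A pathway model is a list of steps `product <- genes {...} [+ precursor]`
whose precursor references form a DAG. Producibility is the least fixed
point of the gating relation — computed once in topological order by the
engine, and by naive fixed-point iteration in the independent oracle
(`producible_fixed_point()`); a property test holds the two routes equal
on thousands of random profiles.

The assumptions this encodes, and their limits:

* **Presence implies function.** A positive PCR band is taken as a
  functional gene. Point mutations, silencing, or regulatory loss are
  invisible to the assay and the model.
* **All-of gates.** Every gene listed for a step is required; there is no
  partial redundancy. Where the literature only constrains a gene set in
  aggregate, the bundled defaults use the coarsest assignment consistent
  with the observed genotype-to-chemotype facts: the EAS terminal trio is
  split as `lpsC` → ergonovine and `easO`/`easP` → lysergic acid
  α-hydroxyacetamide, and the six LOL genes downstream of the AcAP gate
  act as one block. Both choices are configurable in the model files
  (`inst/extdata/models/`, schema in
  `inst/extdata/pathway_model_schema.json`) and neither affects any
  result on the bundled strains.
* **No quantities.** The engine predicts what can be made, not how much;
  toxicity thresholds and expression levels are out of scope.

Toxicity flags follow the livestock-safety framing of the field: all EAS
and IDT products are toxic; peramine, the pyrrolopyrazine-1,4-diones of
the ΔR allele, and all lolines are insect-active but livestock-safe.
Category I is defined as an empty intersection between the producible set
and the union of toxic products — so an all-absent profile is vacuously
category I, which is why the pipeline attaches a warning to profiles with
no detected alkaloid gene at all.

## Calls on top of reachability

* **`ppzA` allele** — the R and ΔR segments are mutually exclusive
  alleles: R without ΔR is *ppzA-1* (peramine), ΔR without R is *ppzA-2*
  (pyrrolopyrazine-1,4-diones). Both absent gives `none`; both present is
  a `conflict`, which never aborts the pipeline: a warning is attached and
  producibility falls back to the raw domain gates.
* **Mating type** — mtAC only → A, mtBA only → B, neither →
  `undetermined`, both → `conflict` (warning).
* **Pattern codes** — compact per-cluster letters (PPZ A/B, EAS A/B,
  IDT A/B/C, LOL A) defined as fixed presence/absence signatures and
  always derived from the raw calls. This matters: published summary
  tables occasionally mislabel a cluster (e.g. printing the
  idtP-containing code for a strain whose own gene row shows idtP
  absent); deriving from the calls keeps the code, the producible set and
  the type mutually consistent. Signatures matching no letter get `"X"`
  plus a warning rather than a forced fit.
* **Type 1–4** — defined over producible sets, not pattern codes:
  type 1 = peramine only; type 2 = peramine + {CC, D-LC, ERV} +
  {PAS, PAX, TDK}; type 3 = {CC, D-LC, ERV} + paspaline only;
  type 4 = {CC, D-LC, ERV} + {PAS, PAX, TDK} without peramine. Anything
  else is `unclassified` with a warning — the classifier never guesses.

## Unknown calls

Real re-use will have untested markers, so `unknown` is a first-class
state distinct from `absent`. The engine resolves it by policy:
`strict` (default) counts unknown as absent — conservative for safety
screening, and monotone: masking calls to unknown can only shrink
producible sets; `optimistic` counts unknown as present and exists for
sensitivity analysis (an upper bound on what the strain might make).
Either way the consulted unknown markers are reported as warnings.

## The bundled study tables

`inst/extdata/` carries a transcription of a 20-strain *E. bromicola*
survey from five *Elymus* species of Northwest China: the marker table
(mating type, eight `ppzA` segments, 14 EAS, 11 IDT, 11 LOL genes — the
LOL cluster reduced to `lolC` alone in all strains) and the six-row
infection survey. Both files are pinned by checksum in the test suite.
Two transcription conventions are worth noting: the ΔR segment is stored
ASCII-safe as `ppzA-dR` (readers accept the delta spellings), and `idtO`,
which appears in some running text as a synonym of the `idtQ` column, is
accepted as an alias with a warning rather than silently or fatally.

On these tables the pipeline partitions the strains 4/6/5/5 across types
1–4 and 4/16 across categories I/II, with all 20 strains mating type A
and the `ppzA` alleles split 10/10 — exactly the published chemotype
analysis, derived here from the raw gene calls alone.

## Survey arithmetic

Infection frequency is `100 * n_infected / n_samples` rounded half-up at
two decimals. The rounding is done in exact integer arithmetic (half-up
carry on the remainder of `10000 * n_infected / n_samples`) because the
half-up convention is what reproduces the printed two-decimal values
(e.g. 36/44 → 81.82, 2/12 → 16.67) and binary floating point cannot be
trusted at the .005 boundary. Roll-ups are key-sorted, making aggregates
invariant to record order; the location roll-up counts five distinct
sites while the host-by-site table keeps six rows (one site contributes
two hosts).

## The simulator

`simulate_profiles()` draws profiles under a two-level loss model chosen
to mirror the two modes of loss the real data exhibit: whole-cluster
absence (retention probability π per cluster) and per-gene dropout
(probability δ within a retained cluster) — the bundled strains show both
modes (four strains lack the EAS and IDT clusters entirely; five others
lack only `idtP`). The `ppzA` R/ΔR pair and the mating idiomorphs are
drawn mutually exclusively. Defaults are the observed study conditions:
π = 1, 0.8, 0.8, 1 for PPZ, EAS, IDT, LOL (the observed retention
fractions), δ = 0.15, allele-R probability 0.5 (the observed 10/20
split), mating-type-A probability 1 (all observed strains), and no
unknown masking. The terminal EAS trio and `idtE`/`idtJ` get ordinary
dropout draws — no special-casing — so type-2/4-like truths arise
naturally.

Ground truth is computed at generation time with the fixed-point oracle
and an independent re-implementation of the type/category rules, so a
simulate-then-predict round trip crosses two fully independent routes.
With δ = 0 and no masking the engine must recover 100% of ground-truth
chemotypes — the profile-to-chemotype map is deterministic — and the test
suite checks exactly that, plus seed-pinned byte-identical reruns. Each
simulation call uses a private RNG stream restored on exit, so it neither
disturbs nor depends on the caller's random state.

What passing these tests does *not* show about real data: the simulator
draws genes independently within clusters, has no linkage between
clusters, no PCR dropout correlated by primer, and no sequence-level
events — it validates the logic, not the assay.

## Numerical and scale choices

Everything here is discrete logic on at most dozens of markers, so all
checks run in seconds: the oracle-equivalence property uses 1000 random
profiles per pathway model, the recovery checks use 100–500 simulated
strains, and the whole suite stays well under a minute on one CPU. Those
sizes are comfortable saturation points for models with at most five
steps — every gate combination is hit many times over — not a statistical
compromise.

## Known limitations

* The per-step gene assignments inside the EAS terminal trio and below
  the LOL AcAP gate are the coarsest consistent choice, not an
  experimentally resolved one; both are model-file configuration.
* Whether `easH` is strictly required for ergovaline cannot be decided
  from presence/absence data in which every ERV-positive strain carries
  it; it is kept required by default and is configurable.
* Pattern codes are descriptive signatures for reporting; classification
  never depends on them.
* The package predicts genetic capability. Field toxicity depends on
  expression, concentration and grazing pressure, which are outside the
  model.
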