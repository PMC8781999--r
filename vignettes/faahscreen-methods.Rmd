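---
title: "Scaffold enrichment and repurposing screens: models and conventions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scaffold enrichment and repurposing screens: models and conventions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette documents the models behind `faahscreen`, the conventions
and parameter choices that were genuinely open, and what the synthetic
validation does and does not show. It states no empirical result that the
test suite or `scripts/acceptance.R` does not itself compute.

## The screening problem

Fatty acid amide hydrolase (FAAH) terminates anandamide signalling;
inhibiting it is a candidate analgesic strategy. A ligand-based
repurposing screen asks: given ~10^3 known FAAH inhibitors with measured
IC50 and a ~10^4 property-matched decoy background, which structural
features separate the two, and which already-approved drugs carry those
features? The package casts this as scaffold enrichment plus a
discretized QSAR model, followed by a cascade over a candidate library.

## Curation conventions

* **Deduplication** keys on Open Babel canonical SMILES after keeping the
  largest organic fragment of salts/mixtures (the identity criterion and
  the standardization protocol are conventions of this package; largest
  fragment and no charge neutralization). Merged entries average IC50 in
  molar units, then pIC50 = −log10(IC50). Qualified measurements
  (">", "<", "~") are dropped at parse time.
* **Labels** use strict inequalities: strong means pIC50 *above* 8, weak
  *under* 5. Boundary compounds stay unlabeled rather than being forced
  into a class.
* **Property window** (MW 150–620 g/mol, logP −0.8–9.2, HBA 1–12,
  HBD 0–4) uses closed intervals: a compound exactly at a bound is
  matched, not excluded. HBA/HBD are Lipinski-style counts (N+O atoms;
  N–H/O–H hydrogens from a valence model with charge adjustment); logP is
  the same Crippen-type atomic-contribution estimate everywhere
  (curation, descriptors), so the filter and the classifier never
  disagree about a compound's lipophilicity.
* **Organometallic** means any atom outside
  {H, B, C, N, O, F, Si, P, S, Cl, Se, Br, I}. Metal-bearing entries are
  absent from the inhibitor set and break descriptor computation, so they
  are removed from candidate libraries too.

## Scaffold definitions

* **Murcko framework (MF)**: the 2-core of the heavy-atom bond graph
  (rings plus all ring–ring linkers) extended by exocyclic
  multiple-bonded atoms attached to retained atoms (a ring carbonyl
  oxygen stays; an acetyl side chain does not). Element identity and bond
  orders are preserved. Acyclic molecules map to the null framework.
* **Bemis–Murcko skeleton (BM)**: the rings + linkers only, every atom
  relabeled to carbon, every bond set to single. Exocyclic
  multiple-bonded atoms are *not* part of the skeleton: after bond
  flattening they are indistinguishable from side chains, and excluding
  them is what makes the transform idempotent
  (`bm(bm(m)) = bm(m)`) and consistent with `bm(m) = bm(mf(m))`. The
  null skeleton (acyclic compounds) is a first-class skeleton and is
  counted and scored like any other.
* **Plain rings (PR)**: one fragment per fused ring system — rings
  sharing an atom or a bond form one system, so spiro junctions fuse —
  with all single-bonded substituents erased and double-bonded
  heteroatoms directly on the ring retained (2-pyridone keeps its
  carbonyl oxygen). Duplicate fragments within a molecule collapse.
* **Side chains**: SC = MW(molecule) − MW(hydrogen-completed MF), both
  masses from the same Open Babel convention. For acyclic molecules SC
  equals the molecular weight and an `acyclic` flag is set. The
  substitution-group counts (halogens, OH, COOH, CONH2, NH2, NO2) are
  SMARTS queries documented in the source code; all these groups are
  terminal, so whole-molecule counts equal side-chain counts.

## Enrichment and potency scores

With `a` of `n_FI` inhibitors and `b` of `n_DCY` decoys containing a
scaffold, and `prior = n_FI/(n_FI + n_DCY)`:

`P = (a/(a + b)) / prior`.

This is the posterior probability that a compound containing the scaffold
is an inhibitor, normalized by the prior: `P = 1` is random expectation,
`P = 1/prior` (11 at ratio 10) means inhibitor-exclusive, `P = 0` means
absent from inhibitors. A plausible alternative reading — the plain count
ratio `a/b` divided by the prior — was rejected because it does not have
the stated unit-at-random-expectation property and contradicts the
worked null-skeleton value the formula above reproduces (48 vs 57
compounds gives `P = 5.03`). Significance uses Pearson's chi-square on
the 2×2 containment × set table, without continuity correction, at
α = 0.05; no multiple-testing correction is applied across scaffolds,
matching standard practice for scaffold profiling. The potency score `I` is the mean pIC50 of
the inhibitors containing the scaffold (decoys have no measured
activity by construction).

Two filter-selection modes mirror the two scaffold families: skeletons
are kept when significantly enriched (`P > 1`, chi-square p < 0.05);
rings are kept above a fixed `P ≥ 3`.

## Repurposing score and thresholding

`RpS = mean(I-PR over contained filter rings) + I-BM(skeleton)`. A
missing term contributes 0 — a compound containing no scored scaffold
scores 0 rather than being undefined, which keeps the cascade total. The
ROC threshold for RpS picks the largest cutoff (midpoint between
adjacent observed scores) that keeps the positive fraction *strictly
above* the cutoff at or over the target sensitivity (default 0.9); the
rank-statistic AUC (Mann–Whitney, ties at 1/2) and the achieved
specificity are reported alongside. All cascade comparisons phrased
"higher than"/"over" are strict: RpS > threshold, probability > 0.7.

## Descriptors and the 3D embedding

The classifier consumes eleven descriptors: Crippen-type logP (Open
Babel's Wildman–Crippen-style atomic contributions), the spectral mean
absolute deviation of the topological distance matrix, the 5th-largest
absolute eigenvalue of an ionization-weighted Burden matrix (diagonal =
relative first ionization potentials, off-diagonal 0.1 × bond order,
+0.01 for terminal bonds, 0.001 otherwise), the WHIM total size indices
A under five weightings (unit, Sanderson electronegativity, ionization
potential, Kier–Hall intrinsic state, van der Waals volume; A =
λ1λ2 + λ1λ3 + λ2λ3 of the weighted covariance of centered coordinates),
the radial distribution function at r = 8.5 Å with β = 100 Å⁻² weighted
by relative mass (the conventional reading of descriptor code 085), and
the charge-weighted positive surface areas WPSA1/WPSA2 (solvent-
accessible areas, Bondi radii, 1.4 Å probe, 256 deterministic
Fibonacci-sphere points per atom; EEM partial charges with hydrogen
charges condensed onto their heavy atom).

Conformers come from the package's deterministic distance-geometry
embedding: bond lengths from covalent radii with bond-order contraction,
1–3 distances by the law of cosines with hybridization-typed angles,
through-bond path lengths as upper bounds and a 2.5 Å steric floor;
a distance matrix drawn reproducibly inside the bounds (fixed seed) is
embedded by classical multidimensional scaling, hydrogen-completed, and
relaxed by MMFF94s steepest descent (1500 steps, the standard
ligand-preparation recipe). The same input and seed give bit-identical
coordinates; all 3D descriptors are invariant under rigid motion and
atom renumbering, which the suite checks. Embedding quality is
descriptor-grade, not pose-grade: global fold errors that survive local
minimization are acceptable because only size/shape/surface summaries
are consumed.

**Calibration caveat.** The published flag cutoffs (e.g. CrippenLogP >
4.582, WPSA1 > 382.111) were derived with a different descriptor stack;
applied to this package's descriptor values they are approximate, and
nothing here re-derives them. The published logistic model itself is
exact arithmetic and ships verbatim; `roc_cutoff`/`fit_flag_logistic`
re-derive cutoffs and coefficients from data when you have training
sets. The reduction from eleven flags to the published four is not itself
prescribed; optional backward elimination at p < 0.05 is provided, and
the published four-flag model is available independently of any
selection heuristic, so reproducing it never depends on our heuristic.

## Docking post-filter

Docking is consumed, never executed: results arrive as tables of ligand
id and binding energy ΔG (kcal/mol). Ligand efficiency is |ΔG| divided
by the heavy-atom count — ΔG is negative for binders while LE is
conventionally positive. The filter keeps 0.25 ≤ LE ≤ 0.4 and
ΔG ≤ −6: the lower LE bound and the energy cutoff drop weak binders, the
upper LE bound drops small fragments whose per-atom efficiency
overstates potency. Covalent poses score poorly on non-covalent energy
terms, so rows flagged covalent can be exempted from the ΔG cutoff; the
exemption is off by default because covalent flags are engine-specific.

## The synthetic generator

`generate_library()` assembles structures as prefix + ring core + suffix
from fixed pools (twelve cores including the benzene, piperazine,
piperidine and pyridine chemotypes prominent among real FAAH inhibitors;
acyclic substituents with at least one N/O per molecule so every product
satisfies the property window by construction). Enrichment is planted by
over-sampling enriched cores in the inhibitor-like set proportionally to
their odds and under-sampling them (1/odds) among decoys; the default
plants piperazine at odds 20. Potency is scaffold-dependent: compounds
on an enriched core draw pIC50 from N(8.5, 0.6), the rest from
N(4.5, 0.4), so the strong/weak thresholds at 8 and 5 capture most of
each class and the inhibitor set spans pIC50 ≈ 4–10. Defaults use 200
inhibitors and a 10:1 decoy ratio — large enough for stable scaffold
counts and chi-square tests, small enough that a twenty-seed validation
sweep runs in minutes. The prefix/suffix pools are split between the two
sets, which guarantees FI/DCY structural disjointness (symmetric cores
could otherwise produce the same molecule from swapped substituents);
any residual collision is resampled. Simulated docking draws
ΔG = −8.12 − 1.59·shift + noise with shift 1 for strong and 0 for weak
compounds (interpolated in pIC50 otherwise) and class noise SDs of 1.44
and 1.14 kcal/mol, reproducing the reported class energy distributions
(−8.12 ± 1.44 weak, −9.71 ± 1.14 strong).

What passing tests on these libraries shows: the scoring recovers
planted enrichment, the filters behave monotonically, the cascade
short-circuits correctly, and every pipeline contract holds under known
ground truth. What it does not show: behavior on real chemical space —
the generator's diversity is combinatorial, its decoys are idealized
(inverted odds rather than merely property-matched), its molecules are
smaller than typical drug-like FAAH inhibitors (so the published 3D flag
cutoffs rarely fire on them), and measurement noise in IC50 is absent.
In this synthetic world a 0.9-sensitivity RpS threshold is degenerate
(≈13% of inhibitor-like compounds sit on unscored five-membered-ring
cores with RpS = 0), so the reported operating points on synthetic data
are not estimates of the real screen's operating points.

## Numerical choices and degenerate inputs

* Ties in ROC cutoff selection break toward higher sensitivity; cutoff
  candidates are midpoints between adjacent observed values.
* The flag transform is `value ≥ cutoff → 1` (boundary inclusive);
  orientation-inverted rules negate value and cutoff first.
* Empty filter sets evaluate to sensitivity 0 / specificity 1, with a
  warning. Scaffolds absent from both sets are not emitted.
* Molecules with fewer than five heavy atoms return the smallest
  available Burden eigenvalue, flagged `degenerate`; single atoms give
  SpMAD = RDF = 0 and sit at the origin after centering; planar
  conformers legitimately have λ3 = 0.
* Complete separation in the logistic fit is a fatal error naming the
  separating flag; constant flags are dropped with a warning.
* Unparsable structures are skipped with positional warnings; a batch
  with zero parsable structures is fatal.

## Known limitations

* Descriptor values are not numerically interchangeable with other
  stacks (PaDEL, RDKit); only trends and the package's own cutoff
  machinery transfer. Cross-stack agreement is asserted only where it is
  meaningful (Crippen logP to ±0.1 on reference molecules).
* The distance-geometry embedding produces one conformer; flexible
  molecules' 3D descriptors are single-conformer estimates.
* Charged-species implicit-hydrogen handling covers the common organic
  cases (ammonium, carboxylate, nitro); exotic charge states may count
  donors approximately.
* Chirality is ignored throughout (scaffold analysis and the descriptor
  panel are constitution-level).
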