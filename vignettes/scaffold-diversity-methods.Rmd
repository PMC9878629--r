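---
title: "Quantifying scaffold and chemical-space diversity with scafdiv"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying scaffold and chemical-space diversity with scafdiv}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scafdiv)
```

`scafdiv` answers one question about a compound collection: *how
structurally diverse is it, and compared to what?* This vignette explains
the models and conventions behind each stage of the pipeline, the
parameters that matter, and the choices made where the methodology leaves
room for interpretation.

## Preprocessing: what counts as "one chemical"

All metrics are defined on cleaned, non-redundant libraries, produced by
`clean_and_deduplicate()`:

1. **Stereochemistry is disregarded.** Stereo descriptors are stripped
   before canonicalization, so enantiomers and E/Z isomers collapse to one
   record. Scaffold and fingerprint analyses are constitution-level
   notions; keeping stereoisomers apart would double-count identical
   frameworks.
2. **Largest covalent fragment.** Salts and solvates are reduced to their
   largest fragment by heavy-atom count (ties broken by molecular weight).
   This is the standard convention; the counter-ion is chemically
   irrelevant to scaffold or fingerprint diversity.
3. **Canonicalization and first-occurrence dedup.** Structures are
   canonicalized with Open Babel; among duplicates the first record's
   identifier is kept, which makes cleaning deterministic.

Two deliberate *non*-steps: no charge neutralization and no tautomer
canonicalization. Both are registration-grade standardizations whose rules
vary between toolkits; applying neither keeps the cleaning contract simple
and reproducible. Consequently, protonation-state variants of the same
parent are counted as distinct chemicals — a documented dialect choice.

## Bemis–Murcko scaffolds and the three abstraction levels

The scaffold of a cyclic molecule is the union of its ring systems and the
linker paths connecting them, obtained by iteratively pruning terminal
side-chain atoms (graph-theoretically, the 2-core of the molecular graph).
Three levels of abstraction are exposed:

* **GNB** (graph/node/bond) keeps elements and bond orders. Terminal atoms
  attached to the framework by a double or triple bond — exocyclic
  carbonyl oxygens, imine nitrogens — are retained, following the dominant
  toolkit convention for Murcko frameworks: these atoms are part of the
  ring system's electronic identity, not decorations.
* **GN** keeps elements but collapses every bond to single order.
* **GRAPH** additionally mutates every atom to carbon, leaving the
  anonymous ring-and-linker skeleton.

At GN and GRAPH the bond collapse happens *before* pruning, so a former
exocyclic carbonyl oxygen becomes an ordinary single-bonded terminal atom
and is pruned. This ordering is what makes scaffold keys *idempotent at
their level* — re-deriving the scaffold of a key returns the key — and
makes the GRAPH scaffold of a molecule equal the GRAPH scaffold of its GNB
scaffold. Both properties are enforced by tests.

Scaffold keys are canonical SMILES. Aromaticity is re-perceived by the
toolkit when a scaffold is serialized; since element substitution can
break aromaticity rules, GRAPH keys come out as saturated carbocycles,
which is exactly the intended "graph" reading.

Acyclic molecules have no Murcko scaffold; they are assigned one shared
pseudo-scaffold (`"ACYCLIC"`) that participates in all counts. A single
pooled pseudo-scaffold (rather than one per molecule) means an
all-acyclic library has N = 1 — acyclic chemicals contribute bulk, not
scaffold diversity.

The default analysis level is GNB, the most informative of the three; GN
and GRAPH are available for coarser comparisons.

## CSR curves, AUC, and P50

Scaffolds are ranked by descending frequency (ties broken
lexicographically by key, so all derived numbers are deterministic; AUC
and P50 are tie-invariant because cumulative sums are, but the top-*n*
membership used by the entropy is not, hence the fixed rule). The CSR
curve plots cumulative % of compounds against cumulative % of scaffolds,
with the origin prepended. The AUC is computed by the trapezoidal rule on
unit-normalized axes, which yields exactly 0.5 on the uniform
one-molecule-per-scaffold case — the diagonal limit of maximal scaffold
diversity — and approaches 1 as a single scaffold absorbs the library.

P50 is read off the curve by linear interpolation between the bracketing
points of the first crossing of y = 50%. Interpolation (rather than the
discrete rank) is required for P50 to be a percentage on a continuous
scale; discrete steps could only produce multiples of 100/N.

## Scaled Shannon entropy

For the top *n* scaffolds holding *P* compounds with counts `c_i`,

SE = −Σ p\_i log2 p\_i, p\_i = c\_i / P, SSE = SE / log2(n).

SSE ranges from 0 (all *P* compounds on one scaffold) to 1 (even spread).
Base-2 logarithms are used throughout, consistently in SE and in the
normalization. The default grid n ∈ {5, 10, 20, 30, 40, 50, 60, 70}
covers the "most populated scaffolds" range usually tabulated. If a
library has fewer than *n* scaffolds, all are used but the normalization
stays log2(n) and the value is flagged (`truncated` attribute); real
libraries rarely hit this case, but synthetic extremes do, and silently
renormalizing would make values across libraries incomparable.

SSE and AUC deliberately measure different things: SSE sees only the head
of the frequency distribution, AUC integrates over all scaffolds. A
library can have a low AUC (diverse overall) and a low SSE (uneven head)
at the same time.

## Library distances

**Fingerprints.** Each molecule gets the public 166-bit MACCS key vector.
The pairwise distance is the Soergel distance `1 − T` with Tanimoto
`T = |x∧y| / |x∨y|`. For a pair of all-zero vectors T is 0/0; the package
defines the distance as 0, since two structurally featureless, identical
bit vectors should not register as maximally distant. Inter-library
distance is the mean over all U×V cross pairs; intra-library distance is
the mean over the U(U−1)/2 unordered distinct pairs (self-pairs excluded).
Note the resulting identity `inter(A, A) = intra(A) · (U−1)/U`: the
self-distance of a library against itself is diluted by its U zero
self-pairs.

**Properties.** Each molecule gets the six drug-likeness properties HBD,
HBA (N+O-style acceptor count), LogP (Wildman–Crippen), MW, TPSA (Ertl),
and RTB (single non-ring bonds between non-terminal atoms). The toolkit
conventions behind these names differ slightly between cheminformatics
packages (LogP most visibly); the package fixes the Open Babel
definitions and documents that cross-toolkit numeric drift of a few
percent is expected. Pairwise distance is the Euclidean norm after
z-standardizing each property with mean/SD pooled over **all molecules of
all libraries in the comparison**. Standardization is essential — raw MW
(hundreds of g/mol) would otherwise drown TPSA and the counts — and
pooling, rather than per-library scaling, keeps every cell of the distance
matrix on one scale. With six standardized dimensions, typical
intra-library distances land around 3 (the expected distance between two
independent standard 6-D Gaussians is ≈ 3.3), which is the natural
magnitude scale for these values.

Distances are exact O(U·V) by default. For very large libraries a
per-library cap with seeded uniform subsampling is available
(`max_molecules`); the cap and seed are recorded in the run log.

## Consensus diversity plot

Each library condenses to one point: x = intra-library Soergel distance,
y = CSR AUC, color = intra-library property distance, size = library
size (area-proportional with a floor). The plane splits into quadrants at
x = median of the plotted libraries' Soergel distances and y = 0.75:
quadrant IV (x ≥ median, y ≤ 0.75) is diverse by both criteria, I is
fingerprint-diverse, III scaffold-diverse, II comparatively redundant.
Boundary ties go to the higher-diversity side (≥ median, ≤ 0.75) — a
deterministic rule chosen so that a library sitting exactly on a
threshold is not demoted. The median is computed over all plotted
libraries; adding a library exactly at the median leaves everyone's
quadrant unchanged.

## Chemical-space embeddings

**PCA** projects onto the first two principal axes, with a deterministic
sign convention (largest-magnitude loading of each axis positive).
Property matrices should be unit-scaled (`scale. = TRUE`); binary
fingerprints are conventionally fed as 0/1 reals without scaling.

**GTM** is implemented from scratch as the standard EM algorithm: a k×k
grid of latent 2D nodes (default 16×16) is mapped into data space through
an m×m grid of Gaussian RBFs (default 4×4, width 0.3× the center spacing)
plus a bias term; a shared noise precision β and the mapping weights are
fitted by EM, with a Gaussian weight prior (relative precision 0.1) for
regularization. The mapping is initialized from the first two principal
components, which makes the fit fully deterministic — the `seed` argument
is recorded for provenance. These defaults mirror the documented defaults
of the commonly used GTM implementations. Per-iteration the penalized
log-likelihood is tracked and must be non-decreasing (a property the test
suite asserts to 1e−8); molecules embed at the posterior-mean latent
position, so all coordinates lie in the latent square. The Gaussian noise
model is retained for binary fingerprints — a documented approximation
that is standard practice for MACCS-key GTMs.

When several libraries are visualized together the model is fitted once
on the pooled matrix and all molecules are projected through that single
model; statements about overlap between libraries are only meaningful
under a joint fit, so `run_full_report()` never fits per-library models.

## The synthetic library generator

`generate_library()` emits chemically valid libraries with a known
census, used throughout the test suite in place of real (non-bundleable)
compound collections. Molecules are built by decorating scaffolds drawn
from a bundled vocabulary of 896 ring systems (monocycles, fused
bicyclics, spiro systems, and linked ring pairs with varied heteroatom
content, each verified to be its own canonical GNB scaffold) with random
acyclic substituents at positions with spare valence. The generator's
core correctness requirement is that decoration can never change the
assigned scaffold: substituents are acyclic trees attached by single
bonds, which the Murcko pruning removes entirely. Scaffold frequencies
follow a Zipf law with exponent `skew` subject to the singleton
constraint (singleton scaffolds get exactly one molecule, all others at
least two, so the realized singleton count equals the requested one);
frequency allocation uses deterministic largest-remainder rounding.
Acyclic molecules are random carbon chains with occasional O/N atoms.
Duplicate decorations are resolved by re-decoration with a bounded retry
counter; an impossible specification errors rather than silently
degrading.

Default composition values (singleton fraction 0.5, skew 1, acyclic
fraction 0.05) sit in the range observed for real natural-product
libraries, where roughly half to two-thirds of scaffolds are singletons
and a few percent of molecules are acyclic.

What the generator does *not* emulate: realistic synthesizability,
property distributions of any particular real library, and fingerprint
correlation structure between related analogue series. Passing tests
therefore demonstrate the correctness of the census, metric, and distance
machinery on structurally controlled inputs — not that any real library
has a particular diversity value.

## Numerical choices and degenerate inputs

* Scaffold-frequency ties: lexicographic key order everywhere.
* P50: linear interpolation; the uniform library gives exactly 50%.
* All-zero fingerprint pairs: distance 0 (see above).
* Zero-variance property columns: SD set to 1 after centering, so the
  column contributes nothing rather than producing NaN.
* Molecules that fail scaffold generation are logged and excluded from
  the census (with M decremented); in practice only unparseable input
  triggers this.
* `sse()` requires n ≥ 2 (log2(1) = 0 would divide by zero);
  `csr_curve()` rejects empty count tables; `fit_pca()` rejects inputs of
  rank < 2; `fit_gtm()` requires ≥ 10 molecules and flags
  non-convergence in its diagnostics instead of failing.

## Problem sizes

The shipped tests and the acceptance script run on synthetic libraries of
25–300 molecules and 20 randomized generator specifications, sizes at
which every distance computation is exact and the full suite completes in
about a minute. All operations scale to real libraries of 10^4–10^5
molecules, with the optional subsampling cap recommended for the
all-pairs distance stage beyond ~10^4 molecules per library.

## Known limitations

* Open Babel's canonical SMILES, MACCS key definitions, and property
  conventions differ in detail from other toolkits; absolute values of
  LogP and some sparsely populated MACCS bits are toolkit-dialects,
  though within-package comparisons are unaffected.
* No charge/tautomer standardization (see Preprocessing).
* The GN level drops exocyclic multiple-bond atoms by construction; if a
  use case requires retaining them at GN, compute GNB scaffolds and
  post-process.
* GTM uses a spherical Gaussian noise model for binary fingerprints.
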