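---
title: "Interaction-fingerprint screening: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Interaction-fingerprint screening: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plifscreen)
```

## The problem this package addresses

Leucine-rich repeat kinase 2 (LRRK2) is a prominent therapeutic target in
Parkinson's disease: its most common pathogenic variant, G2019S, increases
kinase activity, and small-molecule inhibition is a plausible and
apparently safe therapeutic strategy. Because de-novo drug development is
slow and expensive, an attractive alternative is *drug repositioning*:
finding an already-approved drug that also inhibits the new target.

`plifscreen` implements a structure-based route to such candidates. The
premise is that drugs engage different targets through *similar
three-dimensional interaction patterns*. Given one protein–ligand complex
of a known inhibitor (the query), the package detects its non-covalent
interactions, encodes their mutual geometry as a binary fingerprint, and
ranks a library of other complexes by fingerprint similarity. Library
complexes whose interaction pattern is improbably similar to the query
(by an empirical p-value) and whose ligand is an approved drug become
repositioning candidates.

When no experimental complex of the target itself exists — the LRRK2 case,
where crystallography long yielded only homologs such as the slime-mold
kinase Roco4, "humanized" by two binding-site phenylalanine-to-leucine
mutations — the same toolbox quantifies whether a surrogate complex is an
acceptable query template: global sequence identity, iterative structural
superposition of the kinase domains, and an explicit residue-by-residue
correspondence map of the binding site.

## Interaction detection

Detection is purely geometric, over heavy atoms only, because deposited
X-ray and cryo-EM structures usually carry no hydrogens. Three interaction
types are implemented; they are the ones that populate ATP-competitive
kinase binding sites of the kind this screen targets (hinge hydrogen
bonds, halogen bonds to backbone carbonyls, hydrophobic pocket contacts):

* **Hydrogen bond** — donor D and acceptor A (N/O) with
  `dist(D, A) ≤ 4.1 Å`; for every known heavy antecedent X of the donor,
  the angle X–D⋯A must be at least 100°. Requiring the *minimum* over
  antecedents keeps only geometries where a hydrogen could plausibly point
  at the acceptor regardless of which substituent carries it; this is the
  conservative resolution of an ambiguity that hydrogen-free detection
  cannot avoid.
* **Hydrophobic contact** — carbons bonded only to carbon (or hydrogen) on
  both sides at `≤ 4.0 Å`. Contacts are clustered per (ligand atom,
  protein residue), keeping the shortest, so a single leucine sidechain
  cannot flood the fingerprint with near-duplicate pairs.
* **Halogen bond** — ligand halogen X (F/Cl/Br/I) bound to carbon, protein
  acceptor A (O/N/S with an antecedent Y): `dist(X, A) ≤ 4.0 Å`, donor
  angle C–X⋯A within 165° ± 30°, acceptor angle Y–A⋯X within 120° ± 30°
  for at least one antecedent.

These thresholds are the published defaults of geometric interaction
profilers; they ship as an editable `interaction_config()` rather than as
constants, since they are conventions, not laws.

Donor/acceptor roles on the protein side come from a residue/atom-name
table (backbone N donates except proline, backbone O accepts, sidechain
chemistry per amino acid). Ligand atoms carry no bond orders in PDB input,
so typing is heuristic from heavy-atom connectivity: O always accepts and
additionally donates when terminal — unless its carbon has three or more
heavy neighbours, the carbonyl-like case; N donates up to heavy degree 2
and accepts up to degree 3. Ambiguity is resolved *in favour of
reporting*, then deduplicated per ordered (donor, acceptor) pair. Covalent
bonds are inferred by distance (sum of covalent radii × 1.3), separately
within protein and ligand; protein–ligand pairs are never bonded by
assumption.

Multi-chain queries matter: a ligand can straddle a dimer interface, as
kinase inhibitors bound between two chains do. The `scope` parameter
(`"all-chains"`, the default, vs `"single-chain"`) makes this choice
explicit instead of burying it.

## The fingerprint

A fingerprint feature is a *pair* of interactions, described by:

* the canonicalised (sorted) pair of interaction types,
* the Euclidean distance between the two ligand-side anchor atoms,
* the angle between the two protein→ligand direction vectors.

Distance and angle are binned — by default 1 Å bins over [0, 20) and 30°
bins over [0, 180] — and the key space is fully enumerated:
6 type pairs × 20 distance bins × 6 angle bins = 720 bits, collision-free,
so every on-bit decodes back to a human-readable feature (this decoding is
what the screening report prints for visual inspection of shared key
features). Patterns with fewer than two interactions encode to the zero
vector; pairs outside the binned range are dropped and counted.

The bin widths, and the specific pair-geometry definitions (anchor–anchor
distance, direction–direction angle), are design choices of this package:
the original fingerprints of this kind are proprietary and their binning
unpublished. All of it is parameterised in `fingerprint_schema()`, and the
tests only rely on properties that hold for any sane binning (permutation
invariance, popcount bounds, refinement monotonicity).

Similarity is Tanimoto over on-bits, `|A∩B| / (|A|+|B|−|A∩B|)`; two empty
fingerprints compare as 0 with a warning rather than 0/0.

## Screening statistics

The background model is the empirical distribution of Tanimoto
similarities between library entries themselves: by default 10^6 uniformly
sampled entry pairs (all pairs when the library is small enough), sorted
and stored with the library. The p-value of an observed similarity `s` is
add-one smoothed,

    p = (1 + #{background ≥ s}) / (1 + N),

which is conservative, never zero, and monotone non-increasing in `s`.
Whether the original screen used all-vs-all or query-vs-library pairs as
background is unknowable from the outside; library all-vs-all is the
default here because it is query-independent and reusable.

Ranking breaks ties by complex identifier (ascending) so runs are
reproducible to the byte. The query's own complex is excluded from the
ranking *by identifier only* — a deliberate choice: true duplicates of the
query under other identifiers should surface, as repeated complexes of
the same drug do in real screens. Hit filtering keeps entries with
`p ≤ p_max` (default 0.001) whose het code maps to an approved drug; the
manual clinical-judgment step of a real campaign is represented only by an
empty `exclusion_reason` column, not automated.

## Chemical triage

Candidates are characterised, not re-scored:

* **ECFP similarity** (`ecfp()`, `chem_similarity_matrix()`): circular
  Morgan fingerprints, 16384 bits, radius 2 (diameter 4), computed through
  the rdkit toolkit and compared by Tanimoto. Low chemical similarity
  between query and hits is the *desired* outcome — it shows the
  interaction-pattern screen finds scaffolds a chemical-similarity search
  would miss. Bit-level identity across fingerprint toolkits is not
  promised, only within-run consistency and rank-level statements.
* **BOILED-Egg** (`boiled_egg()`): the published two-ellipse model in the
  (TPSA, WLOGP) plane — the white ellipse for passive gastrointestinal
  absorption, the yolk for blood–brain-barrier permeation, the property a
  Parkinson's drug must have. WLOGP (Wildman–Crippen, with per-atom
  contributions) and TPSA are computed locally so the classification is
  offline-testable; the ellipse constants are packaged and the
  point-in-ellipse test is implemented in both the parametric and the
  implicit-quadratic form, which must agree.

The packaged `compounds_demo.csv` carries the six candidate drugs and the
assay control with SMILES transcribed from their published structures (see
its provenance column). The two query tool compounds are deliberately
absent: their structures could not be sourced reliably offline, and a
wrong SMILES would be worse than a missing one.

## Homolog suitability

* `humanize()` applies author-numbered point mutations with strict
  from-residue validation — a silent off-by-one here would invalidate
  everything downstream.
* `global_align()` wraps Needleman–Wunsch with affine gaps
  (BLOSUM62, open 10, extend 0.5, end gaps free — the defaults of the
  standard web service for global identity). Identity is identical
  columns over the *full* alignment length including end gaps; the
  aligned strings are reassembled to full length for exactly this reason.
* `superpose()` is the closed-form Kabsch fit with the reflection guard
  (`det(R) = +1` always; a mirror-image pair fits worse, never
  impossibly well). Collinear or undersized point sets are errors, not
  NaNs.
* `iterative_superpose()` replicates refinement-style structural
  alignment: CA pairs seeded by sequence alignment, then up to 5 cycles of
  fit → reject pairs deviating > 2.0 Å → refit, stopping early at
  convergence. This is not a re-implementation of any specific program's
  internals; it reproduces the *behaviour* that matters — the final RMSD
  reflects the conserved core, with flexible segments rejected — which is
  why agreement with published RMSDs of this procedure should be judged
  with a tolerance of a few tenths of an Ångström.
* `map_binding_site_residues()` answers the decisive question for a
  surrogate template: does each binding-site residue of the homolog land
  on a residue of the target after superposition (nearest CA within
  3.0 Å), and is it the same amino acid? Unmapped residues are reported
  explicitly — a residue with no counterpart is a finding, not a missing
  value.

## The synthetic-data generator

`make_complex()` builds complexes in which the *interaction geometry is
the ground truth*: a small aliphatic ligand core with one anchor atom per
planted interaction, and per interaction one protein residue placed so
that the requested distance and angles are realised exactly. Arms radiate
at ≥ 60° azimuthal separation (at most six), which keeps every unintended
atom pair outside all detection cutoffs — this is proven by construction
geometry, and re-checked by a steric guard (inter-residue contacts
< 1.5 Å abort generation). Decoy residues, a water and a small buffer
molecule sit far outside every cutoff to exercise the exclusion logic.

The manifest records the realised geometry and the *expected* detection
counts, computed by threshold arithmetic over the planted parameters —
never by running the detectors — so generator and detector can serve as
independent witnesses of each other. A planted geometry beyond a cutoff
is generated anyway and expected to go undetected: manifests are ground
truth, not wish lists.

What the generator does **not** emulate: realistic backbone geometry
(no Ramachandran statistics), crowded binding sites where interactions
share residues, waters, metals, π-systems, alternate conformations, or
experimental noise beyond an optional uniform distance jitter. Passing the
closure tests therefore demonstrates that the detectors implement their
geometric definitions exactly; it does not demonstrate agreement with any
particular profiler on real, messy depositions.

`make_fingerprint_library()` generates the null world for the screening
statistics: independent Bernoulli bits at a chosen density (default 0.01
over 720 bits ≈ 7 on-bits, the sparse regime real interaction
fingerprints live in), with optional planted near-duplicates of a query
(bit-flip distance 2 by default) standing in for genuinely similar
complexes hidden in a large library.

## Numerical conventions worth knowing

* Distance bins are right-open, the angle range is closed at 180° (an
  exactly antiparallel direction pair is binned, not dropped).
* Altloc selection: highest occupancy, ties to altloc "A"; model 1 only;
  author residue numbering preserved end-to-end so residue labels match
  the literature's.
* Ranking ties: lexicographic by complex id. Background sampling: seeded,
  with the seed stored in the library object.
* The success-rate and potency counts treat censored assay values by
  comparator semantics: a ">bound" measurement never passes a
  "below threshold" test; the packaged potency table records one value
  whose two printed sources disagreed (the table's comment header
  documents the resolution).
* All validation problem sizes are chosen to make the suite complete in
  about two minutes on one core: 100 closure complexes, 1000 Tanimoto
  oracle pairs, 1000 null screens against a 200-entry library, a
  10,000-entry planted-hit library, 25 exhaustively enumerated alignment
  pairs, 20 random rigid transforms.

## Known limitations

Only the three interaction types above are detected; water bridges, salt
bridges, π-stacking, π-cation and metal coordination are out of scope (the
type enum is closed but the fingerprint schema is parameterised, so adding
a type is a config change, not a redesign). No protonation or tautomer
handling; no symmetry expansion (the asymmetric unit is screened as
deposited); covalent ligands are not modelled. The packaged het-code → drug
map is a small demonstration table, not a registry. The pipeline cannot
rebuild the proprietary full-PDB fingerprint library that motivated this
design; it builds libraries from whatever structure set the user supplies.
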