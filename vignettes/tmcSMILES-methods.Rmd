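---
title: "From xyz coordinates to transition-metal-complex SMILES: models and choices"
author: "tmcSMILES"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From xyz coordinates to transition-metal-complex SMILES}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tmcSMILES)
```

# The problem

A mononuclear transition metal complex (TMC) is a single d-block atom
surrounded by ligands. Databases and quantum-chemistry pipelines usually
carry TMCs as Cartesian geometries plus an overall charge $Q$; most
cheminformatics machinery instead wants a molecular graph — ideally a
SMILES string. For organic molecules that conversion is routine. For TMCs
it is not: metal–ligand bonding has no universally agreed line notation,
ligand formal charges are not printed anywhere in an xyz file, and the
metal's oxidation state follows from those charges rather than from any
local valence rule.

`tmcSMILES` converts `(xyz, Q)` into a canonical SMILES in which every
metal–ligand bond is dative (written with the directional `->` / `<-`
tokens, the ligand atom donating), every ligand carries integer formal
charges, and the metal's formal charge equals its oxidation state

$$M_{ox} = Q - \sum_i q_i ,$$

so that the chemistry (ligand charges, oxidation state, coordination
environment) can be read directly off the string.

# The pipeline

## Connectivity from distances

Two atoms are bonded when their distance is below the sum of their
covalent radii (Cordero-type values, see `elementTables()`) plus a
tolerance of 0.45 Å. The tolerance is deliberately generous; the cost is
occasional over-perception, handled by two repair passes:

* **Valence trimming.** Non-metal atoms have hard neighbor-count caps
  (H 1, C 4, N 4, O 3, S 6, P 6, halogens 1, ...). While an atom exceeds
  its cap, its *weakest* bond — the longest relative to the sum of the
  covalent radii — is cut, worst violator first, one bond per atom per
  pass. Metals are exempt. Every cut is logged with its relative length.
  The halogen cap of one neighbor is what shreds perceived perchlorate
  ions into a kept Cl–O fragment plus stranded oxygen atoms; that is
  intentional, because it reproduces a known, documented artifact of this
  family of methods (see *Failure modes* below) rather than hiding it.
* **Spurious-haptic pruning.** When a coordinating atom's neighbor is
  also, barely, within the distance criterion of the metal, the result
  looks like an η²-patch with one long bond. Within every connected patch
  of mutually bonded coordinating atoms, metal bonds longer than
  `hapticRatioCutoff` (default 1.3) times the patch's shortest metal bond
  are cut. A genuine η⁵-cyclopentadienyl, whose five metal distances are
  nearly equal, is untouched; the shortest bond of a patch can never be
  cut. The 1.3 ratio is this package's choice (the qualitative rule —
  "much longer than its haptic neighbors" — does not fix a number); it is
  configurable and every cut is logged. Pruning runs after valence
  trimming.

Deleting the single d-block atom then splits the graph into connected
components: ligands (with at least one metal bond) and counter-ions
(without). Exactly one d-block atom is required; anything else is
rejected as non-mononuclear.

## Ligand charges from extended Hückel occupancies

Each isolated ligand gets a molecular-orbital ladder from an extended
Hückel calculation: a minimal Slater basis (one s and one p shell per
main-group atom), diagonal elements from the classic valence-state
ionization potential table, off-diagonals from the weighted
Wolfsberg–Helmholz formula, and two-center overlaps evaluated in prolate
spheroidal coordinates with 48-point Gauss–Laguerre × Gauss–Legendre
quadrature (exact to ~10⁻⁹ for these basis sizes; the 1s–1s case is
checked against its closed form in the tests). The engine is validated
orbital-by-orbital against an independent extended Hückel implementation
on fixed geometries; frozen reference ladders live in the test suite.

The initial ligand charge counts doubly occupied orbitals below a cutoff
$E_C$ = 10 eV:

$$q = \sum_i V_i \; - \sum_{k:\,E(\psi_k) < E_C} 2 ,$$

with $V_i$ the valence-electron count of atom $i$. Because weakly
antibonding orbitals often sit below +10 eV, this guess is deliberately
too negative (NH₃ starts at −4); two iterative frontier rules then walk
it to a sensible value **without recomputing anything** — the frontier is
re-read from the fixed ladder at each new filling:

* while $q > 0$ and $E_{LUMO} < -9$ eV: add two electrons;
* while $q \le -2$ and $E_{HOMO} > -10.2$ eV: remove two electrons.

The iteration cap defaults to 50. This is purely a runaway guard: real
ligands legitimately need several steps (pyridine starts at −10 and needs
five two-electron removals to reach 0), so any small cap would silently
corrupt charges.

Two consequences of taking these rules seriously are worth knowing:

* An even-electron ligand always ends at an even charge, odd at odd
  (electrons move in pairs). Odd-electron fragments are allowed —
  radicals exist as ligands — and end at odd charges.
* Strong π-acceptors can keep extra electron pairs. 4-nitropyridine's
  filled π* sits at −10.83 eV, below the −10.2 eV threshold, so the rules
  stop at $q=-2$ and the complex is assigned a reduced ligand and a
  correspondingly higher $M_{ox}$. This is the method's genuine output
  (verified against the independent Hückel engine), not a bug in the
  implementation; the fixture suite pins it as such. When trusted charges
  exist (e.g. from a natural-bond-orbital analysis), the fixed-charge
  assembly path `assembleFromFixedCharges()` bypasses the guess entirely.

## Lewis structures by valence enumeration

Given the fragment connectivity and a target charge, the solver assigns
each atom an admissible (bond-order sum, formal charge) state — e.g. C:
(4, 0), (3, −1), (3, +1); N: (3, 0), (4, +1), (2, −1), (0, −3); O:
(2, 0), (1, −1), (3, +1), (0, −2) — and searches for integer bond orders
(1–3) realizing those sums on the fixed connectivity with the charges
summing to the target. Atoms are visited in index order and states in
table order, so the first solution is deterministic; bond-order
realizations are found by backtracking over edges in lexicographic order
with capacity pruning, and realizations are cached per valence pattern.

A **carbene** is admitted as an extra carbon state — exactly two σ
neighbors, both bonds single, charge 0, one lone pair — only when the
carbene pass is active. Restricting the state to two-neighbor carbons is
what keeps carbon monoxide in its classical [C−]≡[O+] form (a
one-neighbor carbon may not become a carbene) while letting
N-heterocyclic carbenes be drawn uncharged.

If no solution exists at the adjusted charge, exactly one retry is made
two electrons away ($q-2$ if $q \ge 0$, else $q+2$). If that also fails,
the complex produces no SMILES and the failure names the stage.

## Resonance forms and their scoring

All Lewis solutions at the chosen charge — up to a cap of 500, with the
cap hit logged — form the resonance set, enumerated twice (carbenes
allowed and disallowed) and pooled. The winner is chosen by, in order:

1. **larger aromatic system** (more atoms flagged aromatic);
2. **fewer penalized formal charges**, where negative charges on
   metal-coordinating atoms are free — this is what puts the carboxylate
   and sulfonate −1 on the oxygen that actually binds the metal;
3. fewer charged atoms overall (the non-zwitterionic, i.e. carbene,
   preference);
4. canonical SMILES string order, as a deterministic tie-break.

Aromaticity uses a deliberately simple Hückel model: smallest rings (≤7
atoms) from the graph; per-atom π contributions (1 for an atom with any
multiple bond, 2 for a usable lone pair, 0 for an empty p orbital or a
carbene's in-plane lone pair, none for saturated blockers); a ring is
aromatic when all atoms are π-capable and the count is 4n+2. This scores
benzene, pyridine, pyrrole, imidazol-2-ylidenes, cyclopentadienide and
naphthalene correctly; it underestimates delocalized edge cases
(pyridones, fused heterocycles with exocyclic carbonyls). Since the model
is only a *ranking* device between resonance forms of the same ligand,
such misses at worst pick a different but equally valid resonance form.

## Assembly, fixes, emission

The complex is rebuilt on the originally perceived connectivity: ligand
graphs plus one dative bond per (coordinating atom, metal) pair, donor on
the ligand side, and the metal's formal charge set to $M_{ox}$ so that
formal charges sum to $Q$. Counter-ions ride along as disconnected
components and enter the charge bookkeeping. Oxidation states below 0 or
above 10 are flagged as unusual, never rejected.

Two structural fixes run after assembly, before emission (equivalent to
fixing the string and re-parsing, without the re-parse):

* **Oxyanion charge placement**: if a coordinating terminal oxygen is
  neutral (double-bonded to its central atom) while a non-coordinating
  sibling carries the −1, charge and bond orders are swapped. With this
  package's exhaustive resonance enumeration the scoring rule above
  already prevents the defect, so the fix is a safety net; it matters for
  inputs built by other tools.
* **Nitro normalization**: every charge-separated nitro group
  ([N⁺](=O)[O⁻]) is rewritten to the uncharged two-double-bond form
  N(=O)=O, and the metal charge is rebalanced if a ligand total changed.
  The package's sanitizer accepts the pentavalent neutral nitro nitrogen
  (and the carbene carbon) on top of the enumeration states; the
  enumeration itself never produces them. Note that toolkits which
  normalize nitro groups the other way will redraw this form on import;
  within this package the representation round-trips unchanged.

Sanitization then checks every non-metal atom against the admissible
states (dative bonds do not count toward the donor's valence), and the
canonical SMILES is emitted.

## The SMILES dialect and canonicalization

Output is Kekulé (no lowercase aromatic atoms), with explicit charges,
implicit hydrogens folded into heavy atoms, and `->`/`<-` dative tokens
(including through ring closures, which chelates require). Unbracketed
atoms imply hydrogens up to the element's first default valence (C 4,
N 3, O 2, S 2, ...); atoms at or above it imply none, which mirrors how
common toolkits treat hypervalent input and is what the CSD fixer's
hypervalence rules key on.

Canonical atom order comes from canonical labeling (BLISS, via
`igraph::canonical_permutation`) of a vertex-colored graph: atoms colored
by (element, charge, implicit-H count) and one dummy vertex per bond
colored by bond type, which encodes edge colors in a vertex-colored
canonization. Writing then follows a depth-first traversal in canonical
rank order. All internal string orderings use byte-wise (radix) sorting,
so the emitted string is independent of atom input order, platform and
locale; `parse(write(m))` re-canonicalizes to the same string, and the
test suite asserts both properties across the whole fixture set.

## Repairing raw CSD-style SMILES

Database SMILES for TMCs typically draw metal–ligand bonds covalently and
omit charges, which breaks kekulization and valence checking. The fixer's
rules, each logged:

1. every covalent metal–ligand bond becomes dative; if the ligand atom's
   valence only makes sense *with* the metal bond counted (a "true"
   covalent bond), the bond order is transferred as charge — metal up,
   ligand atom down. A neutral trivalent amine bound to a metal thus
   converts with no transfer, while a metal-bound chloride becomes
   Cl⁻ / M⁺;
2. hypervalent uncharged N atoms away from the metal get +1 (metal −1),
   hypervalent B atoms −1 (metal +1);
3. special cases: aromatic nitrogen σ-bonded to the metal kekulizes
   pyridine-like if possible and falls back to pyrrolide-like (gaining
   the −1 through rule 1); metal-bound divalent carbons with a terminal
   oxygen are rewritten to [C−]≡[O+]; metal–nitrogen triples become
   nitride bookkeeping ([N³⁻]→M³⁺).

Every rule moves charge in balanced pairs, so the net formal charge of
the output equals the input's; the fixer is idempotent; no covalent metal
bond survives in a successful output. Structures whose raw SMILES lack
hydrogens cannot be *corrected*, but they are *caught*: materializing
implicit hydrogens and comparing element counts against a reference Hill
formula (`checkFormula`) flags the deficit.

## Three-level SMILES agreement

Two conversions of the same complex can disagree for reasons of different
severity, so equality is graded:

* **direct** — canonical strings match;
* **resonance** — the complexes share a resonance form. Because this
  package's resonance set is *all* Lewis solutions at fixed connectivity
  and charge, two complexes share a form exactly when their bond-order-
  erased graphs (with dative topology), per-fragment charges and metal
  oxidation state agree; that is how it is computed, via canonical forms
  of the erased colored graphs;
* **disconnect-resonance** — after deleting all metal–ligand bonds, the
  ligand multisets match with the same charges and the same oxidation
  state; only the coordination topology differed.

Equality is monotone across the three levels and symmetric; both
properties are asserted over every pair of fixture outputs.

# The fixture suite: what it emulates and what it does not

`fixtureSuite()` builds fifteen idealized complexes — octahedral, square
planar, linear and sandwich coordination; σ-donors (ammine, carbonyl,
pyridine), anions (chloride, acetate, mesylate), chelates (bipyridine,
acetylacetonate), an N-heterocyclic carbene, a nitro-substituted
pyridine, a spurious-haptic geometry, an η⁵-cyclopentadienyl, a
perchlorate complex and a closo-borane cage — from pure arithmetic at
typical bond lengths, with fixed 6-decimal formatting (bit-stable across
platforms). Expected ligand charges and oxidation states are fixed by
construction; expected SMILES are pinned from verified output as
regression oracles.

Two fixtures pin *failure* modes on purpose. The perchlorate complex
exercises the halogen valence cap: the ClO₄⁻ is shredded into a Cl–O
fragment and stranded O²⁻ atoms, inflating the oxidation state far past
+10 and raising the unusual-oxidation-state flag. The borane cage cannot
be described with two-center two-electron bonds at any reachable charge
and fails at the Lewis stage — bridged/cluster bonding is out of scope by
design.

What passing these tests shows: the rules are implemented as stated, the
bookkeeping identities hold, and the pipeline is deterministic and robust
to 0.03 Å coordinate noise on idealized geometries. What it does not
show: behavior on thermal, disordered or poorly resolved experimental
geometries, on polynuclear complexes, or metal-centered stereochemistry
(not represented at all). Conversion rates on real databases cannot be
inferred from a 15-complex suite.

# Numerical and design choices, collected

| choice | value | why |
|---|---|---|
| distance tolerance | 0.45 Å | the method's stated criterion |
| orbital cutoff $E_C$ | +10 eV | stated; negative energies are bound orbitals |
| frontier thresholds | −9 / −10.2 eV | stated; strict inequalities |
| adjustment cap | 50 | runaway guard only (pyridine needs 5 steps) |
| haptic ratio | 1.3 | unspecified qualitatively; configurable, logged |
| halogen max valence | 1 | required to reproduce the perchlorate behavior |
| resonance cap | 500 | unbounded in principle; capped + logged |
| EHT quadrature | 48 × 48 nodes | overlap error ≪ 10⁻⁸ |
| overlap orthogonalization | eigenvalues > 10⁻⁸ kept | near-singular bases |
| tie-breaks | radix string order | locale-independent determinism |

# Limitations

Three-center two-electron bonds (boranes, bridging hydrides) are out of
scope and fail loudly. Metal stereo-descriptors are not emitted. The
aromaticity model is a ranking heuristic, not a perception engine. The
extended Hückel charge rules inherit the method's artifacts (π-acceptor
over-reduction, perchlorate shredding); the fixed-charge path exists
precisely so that better charges can be injected when available.
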