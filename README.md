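# tmcSMILES

SMILES generation for mononuclear transition metal complexes (TMCs) from
Cartesian coordinates and an overall charge — in R, with no external
cheminformatics toolkit.

Chemical databases and quantum-chemistry pipelines store TMCs as xyz
geometries plus a total charge `Q`. Machine-learning and screening
workflows want molecular graphs and SMILES instead, but TMC SMILES are
awkward: metal–ligand bonding has no standard line notation, ligand
formal charges are not stored anywhere, and the metal oxidation state
follows from those charges. `tmcSMILES` produces canonical SMILES in
which

* every metal–ligand bond is **dative** (`->` / `<-`, ligand atom
  donating),
* every ligand carries integer formal charges found by the pipeline, and
* the metal formal charge equals its oxidation state,
  `M_ox = Q − Σ q_i`.

The pipeline: bond perception from covalent radii (+0.45 Å tolerance)
with valence trimming and spurious-haptic pruning; per-ligand charges by
counting doubly occupied extended Hückel orbitals below +10 eV,
`q = Σ V_i − 2·#{E(ψ) < E_C}`, corrected by two iterative frontier rules
(add 2e while `q > 0` and LUMO < −9 eV; remove 2e while `q ≤ −2` and
HOMO > −10.2 eV); ligand Lewis structures by valence enumeration with a
one-shot ±2-electron fallback; resonance forms scored by aromatic-system
size, then formal charges (negative charges on coordinating atoms are
free), with the neutral carbene form preferred over zwitterions;
reassembly with dative bonds, oxyanion and nitro normalization, and
canonical emission. The package also repairs raw CSD-style SMILES with
covalent metal bonds (`fixCSDSmiles`), compares SMILES at three agreement
levels (`compareSmiles`), and profiles oxidation states and coordination
environments.

Everything is implemented in R: the extended Hückel engine (VSIP
parameters, Slater-orbital overlaps by quadrature), the Lewis/resonance
solver, the dative-aware SMILES writer/parser (canonicalized through
colored-graph canonical labeling), and a deterministic toy-complex
fixture generator used throughout the tests.

## Worked example

```r
library(tmcSMILES)

# a square-planar tetrachloro complex, overall charge -2
fx <- makeFixture("tetrachloro_platinum2")
res <- xyzToSmiles(fx$xyz, Q = -2)
res$smiles
#> [1] "[Cl-]->[Pt+2](<-[Cl-])(<-[Cl-])<-[Cl-]"
res$oxidationState
#> [1] 2
res$ligandCharges
#> [1] -1 -1 -1 -1
```

Each chloride was assigned −1 by the Hückel occupancy rules, so the
platinum carries `+2 = (−2) − 4·(−1)`: the string encodes Pt(II) with
four dative chlorides. An N-heterocyclic carbene complex keeps the
carbene carbon uncharged (the `[C]` atom below has two bonds and a lone
pair) instead of the N⁺/C⁻ zwitterion:

```r
xyzToSmiles(makeFixture("nhc_silver1")$xyz, Q = 0)$smiles
#> [1] "[Ag+](<-[Cl-])<-[C]1N(C=CN1C)C"
```

Descriptors come straight off the strings:

```r
smis <- vapply(Filter(function(f) is.null(f$expected$failureStage),
                      fixtureSuite()),
               function(f) xyzToSmiles(f$xyz, f$charge)$smiles, "")
head(coordinationEnvironments(smis), 4)
#>   environment count
#> 1           N    39
#> 2          Cl    12
#> 3        C(O)     9
#> 4      C(c,c)     5
```

Repairing a raw database-style SMILES with covalent metal bonds:

```r
fixCSDSmiles("[Pt](Cl)(Cl)(Cl)Cl")@outputSmiles
#> [1] "[Cl-]->[Pt+4](<-[Cl-])(<-[Cl-])<-[Cl-]"
```

A command-line front end (`convert`, `batch`, `fix-csd`, `compare`,
`profile`, `fixtures`) is installed at `inst/scripts/tmc-smiles.R`:

```sh
Rscript inst/scripts/tmc-smiles.R convert complex.xyz --charge -2
```

## Scope

Mononuclear complexes only; three-center two-electron bonding (boranes,
bridging hydrides) is out of scope and fails with a named stage;
metal-centered stereochemistry is not emitted. See the methods vignette
(`vignettes/tmcSMILES-methods.Rmd`) for the models, parameter choices and
limitations in detail.
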