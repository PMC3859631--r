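---
title: "Methods and design decisions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design decisions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clcimpact)
```

`clcimpact` classifies missense mutations on a dimeric chloride-channel
structural model by where they sit (dimer interface, ion pathway, buried
core, surface) and what they change (side-chain volume, charge class,
polarity class, side-chain contacts), and computes disease-allele
statistics from phased patient cohorts. This vignette documents the model
behind each stage, every numeric default, and the reasoning behind the
less obvious design decisions.

## The structural model

A structure is a flat table of heavy atoms (`clc_structure`): identifiers,
coordinates, occupancy and an assigned van der Waals radius, with residues
defined as groups sharing `(chain, resno, insertion)`. Hydrogens are
dropped on input because the intended inputs are homology models and
crystal structures without reliable hydrogen positions; all downstream
geometry (surface, clearance, contacts) is defined on heavy atoms only.
Radii come from a packaged element table (C 1.70, N 1.55, O 1.52, S 1.80 Å
and the common heteroatoms).

A dimer can be assembled from a monomer model with `assemble_dimer()`:
two copies of the monomer are rigidly superposed (closed-form Kabsch fit
on mapped CA atoms, proper rotation enforced via the determinant
correction) onto the two chains of a dimeric template. This mirrors the
standard way a dimeric channel model is produced from a monomer model and
a dimeric crystal structure of a homologue.

## Solvent accessibility (surface module)

Surface areas use the Shrake–Rupley method: each atom is inflated by the
probe radius (default **1.4 Å**, a water molecule) and sampled with a
point lattice; the accessible fraction of sample points, scaled by the
inflated sphere's area, is the atom's solvent-accessible surface area
(SASA). Two deliberate choices:

* The lattice is a **golden-spiral (Fibonacci) lattice of 960 points**,
  not random sampling. It is quasi-uniform, so the accuracy matches
  random sampling at equal point count, and it is fully deterministic, so
  identical inputs give byte-identical reports. 960 points put single-atom
  areas within a fraction of a percent of the closed form; doubling the
  lattice changes totals by well under 1% (verified in the test suite).
* Relative accessibility (RSA) divides a residue's SASA by a
  maximal-exposure reference. The default is the **theoretical Gly-X-Gly
  maxima (Tien et al.)**, with the older Miller set available via
  `analysis_config(max_asa = "miller")`. A residue is **buried when RSA
  < 15%** (strict inequality), the conventional buried/exposed cut.

```{r}
fx <- make_spheres(rbind(c(0, 0, 0)))
sum(shrake_rupley(fx$structure)$per_atom)   # vs 4*pi*(1.7+1.4)^2
fx$analytic$sasa
```

## Dimer interface (interface module)

"Forming the dimer interface" has two common operationalizations, and the
package implements both:

* `delta_sasa` (default): a residue is at the interface when it buries
  more than **1.0 Å²** of surface on complexation (SASA alone minus SASA
  in the assembly).
* `distance`: any heavy atom within **4.5 Å** of the other chain.

The buried-surface definition is the principled one (it is how interfaces
are defined in the protein-protein interaction literature); the distance
definition is cheaper and exactly recoverable from coordinates, which the
test suite exploits against a fixture with brute-force ground truth. On
that fixture the two definitions agree on ≥ 90% of residues, with the
distance-contact core always contained in the buried-surface set.

`near_interface()` additionally marks residues whose minimum heavy-atom
distance to an interface residue of the *other* chain is within **6 Å** —
positions at the channel mouth that sit close to the subunit boundary
without burying surface themselves.

## Ion pathway (pore module)

The pathway is found on a cubic grid (spacing **0.8 Å**) anchored at the
structure centroid. Each node's clearance is its distance to the nearest
atom surface; nodes with clearance ≤ **0.8 Å** (`probe_min`, roughly a
dehydrated chloride's lower bound) are blocked. Open nodes form a
26-connected graph with edge cost `mean(1/clearance²) × edge length`, and
the tunnel is the least-cost path between the nodes nearest two
user-supplied seed points — the inverse-square weighting pulls the path
onto the locally widest centerline, as in grid/graph channel-finding
tools of the MOLE family. The path is smoothed with a 3-point moving
average and clearances are recomputed on the smoothed samples; the
reported **bottleneck** is the minimum sample clearance.

Two details matter in practice:

* The grid is padded by only 1 Å beyond the structure's bounding box, so
  bulk solvent outside the structure cannot offer a cheap detour around
  it. Seeds may sit slightly outside the box (up to 5 Å).
* "No tunnel" (seeds not connected through open nodes) is a valid result,
  not an error — a constriction below `probe_min` legitimately blocks the
  pathway.

A residue **lines** the tunnel when one of its heavy atoms lies within
(local clearance + **3.0 Å**) of a path sample, i.e. within a margin of
the local tunnel surface rather than a fixed ball around the centerline;
this keeps the lining tight at narrow points and inclusive at vestibules.
On the barrel fixture the computed bottleneck sits within the grid
resolution of the analytic value, and the lining is exactly the wall
rings:

```{r}
b <- make_barrel()
p <- find_pore(b$structure, b$seed_start, b$seed_end)
c(computed = p$bottleneck, analytic = b$bottleneck)
```

## Contacts (contacts module)

Hydrogen bonds use a heavy-atom criterion suited to models without
hydrogens: a polar side-chain N/O of the focus residue and any N/O of
another residue at ≤ **3.5 Å**, with the angle at the focus atom (bonded
antecedent → focus atom → partner) required to be ≥ **90°** so the
partner cannot sit "behind" the donor/acceptor. Aromatic interactions are
ring-centroid distance ≤ **7 Å** with ring normals within 60° of parallel
or antiparallel, covering stacked and strongly tilted geometries;
histidine is counted aromatic, and tryptophan's six-membered ring defines
its centroid.

The contact-loss rule after a substitution is by atom identity: a
hydrogen bond is lost when the mutant side chain has no atom of the
wild-type contact's name, and an aromatic contact is lost when
aromaticity is lost. Chemically conservative substitutions (Glu/Asp,
Gln/Asn, Ser/Thr) flag the loss as `possibly_preserved`, since the
analogue can often form an equivalent bond.

## Impact classification (impact module)

Per-mutation report (`annotate_mutation()`):

* **ΔV** from the Zamyatnin residue-volume set; **destabilizing when
  |ΔV| ≥ 30 Å³** (boundary inclusive). Printed values round half away
  from zero, with inputs pre-rounded to 9 decimals so decimal ties
  (e.g. 60.1 − 88.6 = −28.5) are not mis-rounded through binary
  floating-point representation.
* **Charge change** over three classes (Asp/Glu negative; Arg/Lys/His
  positive; the rest neutral) and **polarity change** over a three-way
  polarity partition.
* **Localization** with the precedence *outside the modelled range* →
  *interface* → *pore* → *near interface* → *buried elsewhere* →
  *surface*. Precedence encodes specificity: interface and pore
  membership are mechanistically more informative than mere buriedness.
* For exposed positions the report carries an explicit note that the
  buried-residue destabilization heuristics are not applied — a surface
  volume change rarely destabilizes the fold.

The packaged reference table (`clcn1_functional_table()`) transcribes
published structural/functional annotations for 29 channel mutations at
the interface and along the chloride pathway, including the experimental
dominant-negative effect of each interface mutation in the
wild-type/mutant heterodimer. Recomputing the ΔV/charge/polarity triples
from the packaged constant set reproduces 18 of the 21 printed triples;
the three divergences are transcribed as such in the table and asserted
in the tests: the printed ΔV for p.(Tyr302His) (−35 vs −40 from the
volume set), the printed ΔV sign for p.(Met485Val) (+23 vs −23), and the
printed charge flag for p.(Ile556Asn) (Yes vs No — neither Ile nor Asn is
charged under the three-class scheme). They are preserved, not corrected,
because the package's job is to report what the constant set implies and
to document disagreements rather than silently overwrite either side.
Published per-residue interface/pore lists and printed RSA values depend
on the authors' unreleased homology model and are therefore regression
anchors only if an equivalent model is supplied; the analytic fixtures
stand in for them.

## Cohort statistics (cohort module)

`parse_variant()` reads the HGVS-like grammar found in clinical variant
tables: substitutions with optional intronic offsets, deletions and
deletion-insertions. Classification precedence: protein `fs` →
frameshift (large deletion when the cDNA span exceeds 100 bases), protein
`*` → nonsense, intronic offset → splice, `Xxx→Yyy` → missense. One
transcription quirk is handled explicitly: a dash between two exonic
coordinates (`c.1044-1156del`) is read as a *range* separator when the
second number exceeds the first by more than 100 — favouring a multi-exon
deletion — and as an intronic offset otherwise; the normalized
underscore form is used as the counting key while the verbatim spelling
is preserved.

Allele counting follows clinical-genetics convention: **two disease
alleles per proband, one for probands with a single detected variant**
(the second pathogenic allele is unproven), variants in cis on one allele
count as one disease allele while each member of the cis pair credits its
own mutation type, and homozygotes contribute two. Percentages are
reported to one decimal, half away from zero. For probands with three
variants and no recorded phase the loader defaults to the two most-5'
variants in cis and warns.

```{r}
s <- suppressWarnings(allele_frequencies(load_cohort(clcn1_cohort_path())))
s$n_disease_alleles
head(s$frequencies, 3)
```

The packaged transcription of a published 51-proband myotonia congenita
cohort reproduces the published statistics exactly: 96 disease alleles,
p.(Arg894*) on 38 (39.6%), c.1437_1450del on 18 (18.8%), p.(Phe413Cys)
at 6% after integer rounding, and 14 novel mutation types (8
truncating/splice, 6 missense). The raw distinct-type count over the
table is 35; the published summary accompanying the source table reports
34 types without stating its merging rule, so the package reports the raw
count and leaves the discrepancy documented rather than guessed at.

## Synthetic fixtures (synthetic_data module)

Every generator returns ground truth computed *independently of the code
under test*: closed-form sphere areas; a helix-bundle dimer whose
interface set comes from a brute-force double loop at generation time; a
barrel whose bottleneck is `inner_radius − r_C` by construction (built as
a perforated slab — wall rings plus a sealed filler annulus — so the
cylinder is the only open route between the faces); hydrogen-bond and
aromatic micro-fixtures with exact distances; and synthetic cohorts with
exact allele bookkeeping recorded during sampling. `simulate_fixture()`
writes each fixture with a `.truth.json` sidecar. All generators are
deterministic given their arguments (the cohort generator given its
seed), down to the written bytes.

What the generators deliberately do **not** emulate: real protein
stereochemistry (the helix is an idealized poly-Ala trace), crystal
artefacts (altlocs, gaps), or realistic mutation spectra beyond a small
configurable catalog. They are accuracy instruments, not simulators.

## Numerical and testing choices

* Determinism end to end: no random numbers anywhere in the analysis
  path; reports embed the package version, a configuration hash and all
  thresholds, and identical inputs give byte-identical files.
* Threshold comparisons that encode published conventions (RSA 15%,
  |ΔV| ≥ 30) are made on values pre-rounded to 9 decimals, so results on
  the boundary follow the decimal convention rather than binary
  representation accidents.
* The test suite cross-checks against independent implementations where
  they exist in the environment: biotite's Shrake–Rupley for SASA
  (agreement within 2% on totals) and bio3d's least-squares fit for
  superposition.
* Steric-clash scoring is intentionally absent: the reference annotations
  mark one mutation as clashing without stating a criterion, and
  inventing one would produce unverifiable numbers.

## Limitations

* Heavy-atom geometry only; protonation states, explicit hydrogens and
  electrostatics are out of scope.
* The pore search is grid-based: bottlenecks are resolved to roughly the
  grid spacing, and strongly non-axial tunnels in open, highly exposed
  structures may require tighter seeds.
* Impact classification is rule-based (volume/charge/polarity/contacts),
  not an energy model; it reproduces the published annotation scheme
  rather than predicting ΔΔG.
* The cohort parser covers the variant grammar that occurs in the
  packaged table plus common simple forms; it is not a general HGVS
  engine (no duplications, inversions, or complex rearrangements).
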