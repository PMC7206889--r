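---
title: "Aromatic clusters in protein-drug and protein-protein complexes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Aromatic clusters in protein-drug and protein-protein complexes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aroclust)
```

## The problem

Aromatic rings — the side chains of Phe, Tyr, Trp and His, and the ring
systems of most drug-like molecules — form π–π contacts (parallel
stacking and perpendicular T-shape arrangements) that contribute to both
protein stability and molecular recognition. Beyond isolated pairs,
aromatic rings organise into *clusters*: connected components of the
graph whose nodes are rings and whose edges are detected ring–ring
contacts. This package measures those contacts and clusters in
protein–drug (PD) and protein–protein (PP) complexes and derives the
downstream structural statistics: solvent exposure, secondary-structure
preference, distance/angle distributions and their Boltzmann-inverted
free-energy maps, and binding-affinity strata.

## Geometry of a ring pair

Every ring is reduced to a centroid and a unit normal from a
least-squares plane fit (SVD of the centered member-atom coordinates;
the normal's sign is canonicalised to z ≥ 0 so downstream angles are
deterministic). A ring pair is described by three quantities:

* **d** — the Euclidean distance between centroids (Å);
* **α** — the planar angle between the two normals, folded into
  [0°, 90°] (ring normals are axial: n and −n are the same plane);
* **θ** — the orientational angle between a ring normal and the
  centroid–centroid vector, folded the same way.

A contact is *detected* purely by distance, d ≤ 7.0 Å; the angles are
descriptive. The cutoff and all angle boundaries are arguments with
these defaults.

The pair has two orientational angles, one per ring; the paper-style
descriptor does not say which ring defines θ, so the package takes the
minimum of the two, which makes θ symmetric in the pair; both per-ring
values (`theta_a`, `theta_b`) are retained in the output for
transparency.

Conformation classes are assigned from (α, θ): near-parallel rings
(α ≤ 30°) are *face-to-face* when θ ≤ 45° and *edge-to-edge* otherwise;
near-perpendicular rings (α ≥ 60°) are *edge-to-face* (the T-shape);
the remaining wedge is *oblique*. The literature names these classes
without fixing boundaries; 30°/45°/60° were chosen once so that the two
empirical density maxima — stacking near (d ≈ 3.75 Å, α ≈ 0°) and
T-shape near (d ≈ 5 Å, α ≈ 75°) — fall well inside their classes, and
they are exposed as arguments.

Two rings sharing an atom (the two rings of a Trp indole, fused ligand
ring systems) or belonging to the same residue/ligand instance never
form an interaction: a fused system is one chemical unit. Detection
computes all pairwise centroid distances directly; structures at this
scale carry tens of rings, so no spatial-pruning structure is used —
the all-pairs evaluation is exact by construction.

## Ring detection

Protein rings are template-based: Phe/Tyr contribute one benzene
(CG–CD1–CE1–CZ–CE2–CD2), His one imidazole (CG–ND1–CE1–NE2–CD2), Trp a
pyrrole and a benzene counted individually. Incomplete templates are
skipped with a warning rather than fitted partially.

Ligand rings are perceived from the heavy-atom bond graph (CONECT
records when present, otherwise covalent-radii inference with a 0.40 Å
tolerance). The smallest rings (per-edge shortest cycles, deduplicated)
of size 5–6 are kept when every member is C/N/O/S with at most three
heavy-atom neighbours and the plane fit has rms out-of-plane deviation
≤ 0.10 Å. This deterministic planarity-plus-valence proxy stands in for
toolkit aromaticity perception: it has no electron counting, so it
accepts any flat, conjugation-compatible ring and rejects puckered
saturated rings (an ideal cyclohexane chair has rms 0.25 Å). On a panel
of ten common fragments it reproduces toolkit aromatic-ring counts; for
exotic heterocycles a JSON override (component id → ring atom names)
injects externally perceived rings verbatim. Ring chemical type is
assigned by composition (all-C 6-ring → benzene; 5-ring with one/two N →
pyrrole-/imidazole-like; anything else → other-aromatic), so e.g.
pyridine is counted but typed "other-aromatic".

## Cluster enumeration: detection vs counting edges

Clusters are connected components of the interaction graph under a
context-specific *detection* edge set, while interaction totals come
from a possibly larger *counting* edge set:

* **PD** — detection on drug–residue plus all residue–residue edges;
  only components containing at least one drug ring are kept (a
  residue–residue edge may chain a residue into a cluster without it
  touching the drug directly). Counting uses the same edges.
* **PP** — detection on inter-chain residue–residue edges only;
  counting additionally includes intra-chain residue–residue edges
  among member rings.
* **intra** — intra-chain edges only.

Singleton rings are not clusters. Three-ring clusters fall into exactly
two motifs, because the only connected 3-node graphs have two or three
edges: *Lad* (ladder/path) and *Sym* (triangle, maximizing interactions
at 3 for 3 rings).

Dataset summaries follow the conventions that make the published
Table-1-style arithmetic internally consistent: *clusters per complex*
averages over complexes with at least one cluster (7236/5908 = 1.22,
7717/3048 = 2.53, 73312/9760 = 7.51), and *interactions per cluster*
over all clusters (23303/7236 = 3.22, 15309/7717 = 1.98). Residue
composition counts each interacting aromatic residue once per cluster
membership — a Trp contributes one residue though it carries two rings
(switchable to per-ring). His is included in every context.
One printed intra-protein ratio, 277797/73312, equals 3.789; a
two-decimal display of 3.78 is consistent only with truncation, and the
package rounds.

## Solvent exposure

SASA uses the Shrake–Rupley construction: each atom's sphere of radius
vdW + probe (probe 1.4 Å, water) is sampled on a deterministic
Fibonacci lattice (960 points by default; no RNG, bit-reproducible) and
scaled by the accessible fraction. The vdW table is fixed (C 1.70,
N 1.55, O 1.52, S 1.80 Å) and hydrogens are ignored throughout, as
crystal structures rarely record them. Single atoms reproduce
4π(r+probe)² exactly and the two-sphere case matches the spherical-cap
closed form within 2% at 960 points.

Per-residue exposure uses three contexts — the side chain alone
(iSASA), within its own protein monomer (eSASA), and within the entire
complex (nSASA) — giving

> %Exposed = 100 · eSASA / iSASA,  %inContact = 100 · (eSASA − nSASA) / eSASA.

The side chain is CB and beyond (CB switchable); glycines are skipped.
The monomer context is the residue's own chain for two-chain PP
complexes and the whole protein for PD, so the contact ratio isolates
partner-induced burial. Hetero atoms enter only nSASA; whether waters
or ligands were present in the original eSASA computations is not
recoverable, so this choice is documented as a divergence risk. The
reference implementations in this field often use a Connolly surface;
Shrake–Rupley was chosen for its closed-form testability, and a bundled
fixture bounds the divergence against an external Shrake–Rupley
implementation at the per-atom level.

## Secondary structure

The internal mode is a Kabsch–Sander-style approximation: the amide H
is placed 1.01 Å from N anti to the previous residue's carbonyl, bonds
satisfy E = 27.888·(1/r_ON + 1/r_CH − 1/r_OH − 1/r_CN) < −0.5 kcal/mol,
two consecutive n→n+4 turns make a minimal helix, parallel/antiparallel
bridge patterns make sheet (isolated bridges included), everything else
is loop, and helix wins ties. Chain breaks (C–N > 2.5 Å) sever all
neighbour-dependent patterns; residues with missing backbone atoms
become Loop with a warning. The approximation targets the 3-class
collapse (H/G/I → Helix, E/B → Sheet), not 8-state fidelity; on the
bundled synthetic fixture protein it agrees with an external reference
assignment at 93%, and exact agreement is available by supplying a
classic DSSP output file (`mode = "dssp"`) or header records
(`mode = "header"`).

The preference statistic is the log odds ratio
log₁₀(P(partner class | context class) / P(partner class)), zero under
independence, positive for enrichment. Base 10 is the default (the
statistic is unitless either way; the base is an argument). The
background is estimated from the partner marginal of the dataset under
analysis rather than whole-PDB frequencies — the scope of the published
background is unstated, and the within-dataset choice makes the
statistic self-contained; a user-supplied background overrides it. Zero
cells trigger Jeffreys +0.5 smoothing of the whole table, with a
message, so log-odds stay finite without distorting well-populated
tables.

## Ensemble statistics

The radial distribution function over ring–ring distances uses 0.1 Å
bins to 7 Å. The default normalization is *frequency* (bins sum to 1),
which makes curves from datasets of different size comparable; *shell*
mode divides by 4πr²Δr and renormalizes to mean 1, so uniform-in-volume
points give a flat profile.

The (d, α) free-energy map is a Boltzmann inversion of the 2-D
histogram (0.25 Å × 5° bins): ΔG = −RT ln(N/N_max) at 298 K with
R = 1.987×10⁻³ kcal/(mol·K). The most populated bin is the reference
(ΔG = 0) and empty bins are masked, matching the relative colour scales
such maps are displayed with; ΔG depends only on population ratios, so
the map is invariant under duplication of the sample set. A 10:1 bin
ratio costs RT ln 10 = 1.363 kcal/mol.

Affinity stratification groups complexes by (1 or 2 clusters) ×
interaction bins {2–3, 4–5, ≥6}, and separately by side-chain exposure
(strictly greater than 20% vs at most 20%) and by the secondary
structure of contacted residues. The published binning "2 or 3, 4 or 5,
5 or more" overlaps at five; the package resolves it to disjoint bins
{2–3}, {4–5}, {≥6}. Complexes with more than two clusters are reported
but excluded from the 1-vs-2-cluster contrast, which is how the
published comparison is framed. Group contrasts use a two-sided
Mann–Whitney test on log Ki — the published analysis reports
significance without naming a test, and the rank-sum test is the
standard nonparametric choice for skewed affinity data; median-based
group ordering is invariant to log-scaling. Ki ingestion converts
nM/µM/mM to molar and resolves duplicate complex entries by geometric
mean.

## The synthetic-fixture generator

Every stage is testable without downloads because the fixture module
writes standard PDB text (the full parsing path is exercised, and
ligand fixtures always carry CONECT records):

* `makeDimer(d, alpha, theta)` — one Phe and one benzene ligand whose
  measured descriptors equal the request exactly: the centroid vector
  makes angle θ with ring A's normal, and ring B's normal is tilted by
  α in the perpendicular plane, which guarantees ring B's own
  orientational angle is never the smaller one. Round-trip through the
  written file agrees to PDB fixed-width precision (1e−3 Å, < 0.1°).
* `makeTrimer("Sym" | "Lad")` — equilateral (side 5 Å) vs collinear
  (spacing 5 Å, ends beyond the cutoff) Phe triplets.
* `makeComplexFixture("PD" | "PP", ...)` — rigid aromatic units at
  requested centers/normals on one or two chains, with a 1.5 Å
  inter-unit clash gate that aborts unsatisfiable geometry.
* `buildPeptide` / `makeSheetFixture` / `makeReferenceProtein` — ideal
  poly-alanine backbones from internal coordinates (N–CA 1.458,
  CA–C 1.525, C–N 1.329 Å, trans peptides). Helices use (−57°, −47°).
  Strands use (−138.27°, 135.70°): the canonical antiparallel values
  adjusted so the residue repeat is an exact two-fold screw under the
  builder's bond geometry, i.e. the strand is flat and every residue
  can hydrogen-bond to the partner strand, whose placement is selected
  by maximizing inter-strand Kabsch–Sander bonds over a rigid offset
  scan.
* `sampleEnsemble` — a seeded Gaussian mixture over (d, α) emulating
  the two-mode geometry of real contact ensembles: a broad T-shape mode
  (5.0 Å, 75°; sd 0.3 Å, 8°) and a narrow stacking mode (3.75 Å, 0°;
  sd 0.15 Å, 8°), with angles folded into [0°, 90°] by reflection.

What the fixtures deliberately do not emulate: side-chain rotamer
statistics, crystallographic noise and disorder, realistic packing
environments, or chemically diverse ligand scaffolds. Tests that pass
on them establish the correctness of the geometry, graph and statistics
machinery — not the field-scale distributional claims, which depend on
a structure-database snapshot.

## A worked pipeline

```{r pipeline}
pdb <- makeComplexFixture("PD",
  proteinRings = list(
    list(chain = "A", center = c(0, 0, 0),  normal = c(0, 0, 1)),
    list(chain = "A", center = c(5, 0, 0),  normal = c(0, 0, 1))),
  ligandRings = list(list(center = c(0, 0, 3.75), normal = c(0, 0, 1))))
s  <- resolveAltLoc(readStructure(pdb))
rs <- detectRings(s)
is <- detectInteractions(rs)
interactions(is)[, c("d", "alpha", "theta", "conformation", "context")]
cs <- enumerateClusters(rs, is, mode = "PD")
clusters(cs)
summarizeDataset(list(fixture = list(rings = rs, clusters = cs)))$averages
```

## Numerical choices and limitations

* Degenerate inputs error early: collinear points in a plane fit,
  coincident ring centers, coincident atoms in SASA.
* Occupancy absent means 1.0; altLoc ties resolve to the
  lexicographically smallest code after the occupancy criterion.
* Molecular weight is computed over recorded heavy atoms only (no
  implicit hydrogens) — the 100 Da drug-likeness gate is coarse and
  crystal structures rarely record H; the convention is documented at
  the function. Whether the original gate included hydrogens is
  unstated; the ~6–8 Da difference only matters within a few Da of the
  boundary. For the same reason the bundled benzene fixture ligand
  (72 Da) is *not* drug-like at default settings.
* Multi-model (NMR-style) files use the first model, with a message.
* Sequence-identity clustering of targets is accepted as a precomputed
  membership file; the package performs no alignment.
* Problem sizes in the test-suite simulations — 100 dimer recipes, 200
  random graphs of up to 50 rings, 5×10⁴ ensemble samples — were chosen
  as the smallest sizes at which the checked statistics are stable to
  well within their tolerances.
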