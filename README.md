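# aroclust

Aromatic rings — the side chains of Phe, Tyr, Trp and His and the ring
systems of most drug-like molecules — form π–π contacts that shape both
protein–protein interfaces and drug binding sites. Beyond isolated
pairs, rings organise into **aromatic clusters**: connected components
of the graph whose nodes are rings and whose edges are ring–ring
contacts within 7.0 Å. `aroclust` is an R package for structural
bioinformaticians and medicinal chemists that detects those rings,
measures their interaction geometry, enumerates clusters under
context-specific edge rules, and computes the downstream structural and
statistical summaries.

## What it computes

For a ring pair with centroids **c₁**, **c₂** and unit plane normals
**n₁**, **n₂** (least-squares plane fits):

- **d** = ‖c₂ − c₁‖, the centroid distance (detection cutoff 7.0 Å);
- **α** = ∠(n₁, n₂) folded into [0°, 90°], the planar angle;
- **θ** = min over the two rings of the angle between that ring's
  normal and c₂ − c₁, folded the same way.

Conformations: face-to-face (α ≤ 30°, θ ≤ 45°; the π-stacking optimum
near d ≈ 3.75 Å), edge-to-face/T-shape (α ≥ 60°; optimum near d ≈ 5 Å,
α ≈ 75°), edge-to-edge, oblique.

Clusters are enumerated per analysis context — protein–drug (PD),
protein–protein (PP, detection restricted to inter-chain edges) and
intra-protein — distinguishing the *detection* edges that define
connectivity from the *counting* edges that enter interaction totals.
Downstream statistics: Table-style dataset summaries, Shrake–Rupley
solvent exposure (%Exposed = 100·eSASA/iSASA, %inContact =
100·(eSASA−nSASA)/eSASA), Kabsch–Sander-style secondary structure with
preference log-odds log₁₀(P(partner|context)/P(partner)), radial
distribution functions, Boltzmann-inverted (d, α) free-energy maps at
298 K (ΔG = −RT ln N/N_max), and Ki stratification by cluster count,
interaction count, exposure and secondary structure.

A synthetic-fixture module (`makeDimer`, `makeTrimer`,
`makeComplexFixture`, `buildPeptide`, `sampleEnsemble`) writes valid
toy PDB complexes with exactly controlled ring geometry, so the entire
pipeline is testable offline.

## Worked example

```r
library(aroclust)

pdb <- makeDimer(d = 3.75, alpha = 0, theta = 0)   # Phe + stacked benzene
s   <- readStructure(pdb)
rs  <- detectRings(resolveAltLoc(s))
is  <- detectInteractions(rs)
interactions(is)[, c("d", "alpha", "theta", "conformation", "context")]
#>      d alpha theta conformation      context
#> 1 3.75     0     0 face-to-face drug-residue

cs <- enumerateClusters(rs, is, mode = "PD")
clusters(cs)
#>   cluster_id size n_detection n_counting motif
#> 1          1    2           1          1  <NA>

et <- exposureTable(s)
round(et[, c("iSASA", "eSASA", "nSASA", "pct_exposed", "pct_in_contact")], 1)
#>   iSASA eSASA nSASA pct_exposed pct_in_contact
#> 1 238.1 187.8 133.8        78.9           28.7
```

The dimer is detected exactly at the requested geometry and classified
as face-to-face stacking; the minimal PD cluster has two rings and one
counting edge (trimers would carry a Sym/Lad motif). The exposure row
reads: the Phe side chain alone would expose 238 Å²; within its own
residue context 188 Å² remain (79% exposed); the stacked ligand buries
a further 54 Å², so 29% of the exposed surface is in contact.

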