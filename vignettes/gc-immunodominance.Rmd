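---
title: "Modeling germinal center immunodominance with a lattice-protein affinity engine"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling germinal center immunodominance with a lattice-protein affinity engine}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(latticeGC)
```

## The model

`latticeGC` couples two models: a **structural affinity model** that scores
antibody-antigen binding on a cubic lattice, and an **agent-based model of
the germinal center (GC)** in which B cells proliferate, hypermutate, and
compete for antigen and T-cell help.  The purpose of the combination is to
let immunodominance — the suppression of the response to one antigen domain
by the response to another — *emerge* from structure and repertoire rather
than being imposed by hand.

### Structural affinity model

Antigens are self-avoiding chains on the cubic lattice, one residue per
node, with the 6-neighborhood as the only adjacency.  A B-cell receptor
(BCR) is reduced to a short peptide — by default 9 residues, standing in
for the central part of the heavy-chain CDR3 loop that dominates binding
specificity.  The affinity of a BCR sequence for an antigen is defined by
**exhaustive docking**: every self-avoiding conformation of the BCR chain
around the antigen that makes at least `min_contacts` non-covalent
BCR-antigen adjacencies is enumerated, and each conformation is scored as

    E = sum_inter U(b_i, a_j)  +  s * sum_intra U(b_i, b_j)

where `U` is an empirical amino-acid contact potential (the packaged
default is the Miyazawa-Jernigan 1996 statistical potential, in kT units;
the resource file documents its origin and any 20x20 symmetric table can be
swapped in), the first sum runs over lattice-adjacent BCR-antigen residue
pairs, and the second over non-covalent intra-BCR adjacencies weighted by a
stabilization factor `s` (default 1; its magnitude is not fixed by the
model's sources, so it is exposed as a parameter).  The minimum energy over
all conformations is the binding energy; ties are resolved toward the
smallest conformation index in a canonical enumeration order (sorted by
start node, then move codes), making the optimal pose reproducible.

Energies map to unitless affinities through

    Aff = exp((Emax - E) / C),      Emax = -100 kT,  C = 2.8 kT.

With this orientation affinity **increases** as binding grows stronger,
equals 1 at `E = Emax`, and can exceed 1 for rarer, stronger binders; since
`Emax` sits below the commonly reachable energy range, affinities typically
lie in (0, 1).  The same formula is sometimes printed with the opposite
sign convention; both orientations are implemented
(`affinity_params(mode = "literal")`), the strength-increasing one is the
default because it is the only one consistent with the founder
(`1e-4`) and capture (`1e-8`) affinity floors meaning *at least this much
binding*.

Two implementation choices matter for scale.  First, enumeration is
geometric: conformations are reduced to *contact profiles* (which BCR
position touches which antigen node, plus intra-BCR contacts), enumerated
once per antigen **shape** and reused across residue reassignments of that
shape.  Second, profiles that coincide after mapping antigen nodes to
residue letters are merged, since they yield identical energies for every
sequence; scoring a sequence is then a table-lookup sum over merged
profiles with a branch-and-bound early stop (profiles are visited in
decreasing contact-count order; once no remaining profile can undercut the
current minimum, scanning stops).  These are exact optimizations — the
test suite checks them against a naive enumerator that keeps every pose
explicitly.

### Antigen design and immunogenicity classes

Synthetic antigen structures are generated as self-avoiding growth walks
with a compactness bias (`generate_structure()`); a text importer accepts
externally discretized lattice structures in a one-residue-per-line format.
Residues are assigned uniformly at random to *all* positions — burial is
emergent from adjacency, so assigning buried residues is harmless and
simpler than classifying the surface.

The **immunogenicity** of an antigen is operationalized as the mean binding
energy of a panel of random naive BCR sequences (200 by default) against
it.  Mean panel energies are binned into classes A through H: class A below
-75 kT, then 2.5-kT steps up to class H at -60 kT and above.  Interval
boundaries belong to the less-immunogenic side; the partition covers the
whole axis, so every antigen gets exactly one label.  Antigen libraries
(`antigen_library()`) randomize residues on a fixed scaffold repeatedly and
classify each variant — the screening route by which antigens of a desired
class are obtained.

### The germinal center agent-based model

Space is a sphere of 5-µm lattice nodes (default radius 160 µm) split into
a dark zone (DZ, upper hemisphere, 300 stromal cells) and a light zone (LZ,
lower hemisphere, 250 Tfh cells and 200 follicular dendritic cells, each
FDC extending 6 dendrite arms of 40 µm along the axes).  Every node holds
at most one motile cell; FDC somas and dendrites do not block.  A total of
3000 antigen units is divided equally among domains and spread uniformly
(as integer units, remainder scattered randomly one unit at a time) over
dendrite nodes.  Two static guidance fields — one sourced by FDC dendrites,
one by stromal cells — are precomputed by iterative relaxation (120 Jacobi
sweeps, sources clamped to 1, zero outside the sphere) and bias movement:
cells perform a persistent random walk (speed 7.5 µm/min, persistence 1.5
min) and, at each direction redraw, follow the steepest ascent of their
target field with probability `chemo_weight` (default 0.5).  Centroblasts
ascend the stromal field, centrocytes and Tfh the FDC field.

The B-cell life cycle follows the standard GC program:

1. **Influx**: founders arrive as a Poisson stream (2 cells/h for 96 h) at
   random free nodes, drawing their BCR from a precomputed founder pool,
   and proliferate 6 times.
2. **Proliferation + SHM**: division requires a free neighbor node (else
   it is deferred); cycle lengths are Normal(7.5, 1.25) h truncated
   positive.  At each division both daughters independently pass through
   the SHM operator: every residue is replaced with probability 0.055 by a
   uniform draw among the 19 *other* residues, so replacements are
   guaranteed changes and the replacement count is Binomial(L, p) — at
   L = 9 a mean of 0.495 ≈ 0.5 mutations per division.  On any change the
   BCR is re-docked against **all** domains present.
3. **Antigen capture**: after its divisions a cell becomes an unselected
   centrocyte with a 0.7-h search clock.  Every 0.001 h, a centrocyte on
   an antigen-bearing dendrite node targets the stocked domain of highest
   affinity and captures one unit with probability `min(1, Aff)`, provided
   `Aff >= 1e-8`.  Cells that captured nothing by the end of the search
   time die; the rest enter the Tfh phase.
4. **Tfh selection**: within a 3-h window, a B cell adjacent to a Tfh
   forms a 0.6-h contact.  Per time step each Tfh polarizes only its
   contacted B cell with the *most* internalized antigen; accumulating
   0.5 h of polarization selects the cell, window expiry kills it.
5. **Recycling and output**: selected cells return to the DZ with a number
   of divisions given by a Hill map of internalized antigen,
   `Nmin + round((Nmax - Nmin) a^h / (a^h + K^h))` with defaults
   `Nmin = 1, Nmax = 6, K = 9, h = 2` (the functional form is our design
   choice; only the dependence on internalized antigen is fixed by the
   model's sources).  During divisions antigen is shared asymmetrically
   (all units to one daughter) in 72% of divisions, evenly otherwise (odd
   unit by fair coin).  After the last division, antigen-retaining cells
   leave the GC as output cells; empty-handed ones return to the LZ and
   recycle.  Output cells differentiate into antibody-secreting cells with
   a 24-h half-life; each secretes 3e-8 mol/h of antibody.

Events within a step execute in a fixed, documented order (influx,
movement, DZ dynamics, capture, search resolution, Tfh phase, output
dynamics), which together with per-subsystem RNG streams (placement,
influx, movement, division/SHM, capture, Tfh, output — all derived from
the single run seed) makes runs bit-reproducible and keeps subsystems'
draws independent of each other.

### Conservation and audits

Antigen is an exactly conserved integer ledger: units on FDC nodes + units
inside living B cells + units removed with dead or egressed cells equals
the initial total at every step.  The engine tracks the three pools
incrementally and, when `audit_every_step = TRUE`, additionally recomputes
them from scratch each step and counts violations (the test suite requires
zero over a 10-day run, along with zero node-sharing violations among
motile cells).

## Reduced-scale operating point

The published operating point (9-mer BCRs, PDB-derived antigens of 95-159
residues, `dt = 1e-4` h, 21 days, ~5 CPU hours per antigen) is not suitable
for a test suite, so the package ships a calibrated reduced preset
(`gc_toy_config()`) used throughout the tests: an 80-µm GC (25 Tfh, 40
FDCs with 20-µm arms, 30 stromal), 5-mer BCRs against ~10-residue
synthetic antigens, `dt = 0.01` h with capture checks every step, and a
10-day horizon.  Three quantities were recalibrated to the smaller energy
scale, with the published values retained for everything biological
(inflow, cycle, SHM, search/selection clocks, asymmetric division, dose):

* `Emax = -50 kT`: random 5-mer optima on 10-residue antigens span roughly
  -20 to -50 kT, so -50 plays the same "chosen very low" role that
  -100 kT plays at full scale.
* founder floor `1e-3`, capture floor `1e-5`: with 70 capture checks per
  0.7-h search instead of 700, a floor-affinity founder retains the same
  order of expected captures per search as at full scale.
* `div_K = 2`: the Hill half-saturation is set at the typical
  per-selection capture count of the reduced scale so that well-binding
  selected cells obtain 3-4 divisions and recycling sustains the reaction;
  at the published capture economics the default `K = 9` plays that role.

The preset was frozen on a survival criterion (a GC that persists and
produces output cells through the horizon), before any comparative
experiment was run.

Problem sizes used by the packaged checks: the docking oracle comparison
uses antigens of 4-6 residues with 4-mer BCRs and 510 random sequences;
founder-pool construction at the published threshold (affinity >= 1e-4,
1000 founders, 500 per antigen) uses two screened compact 24-residue
antigens with 9-mer BCRs — at ~12 residues the threshold is physically
unreachable (random 9-mer optima stay above about -63 kT), while screened
24-mers reach ~10% founder acceptance; the immunodominance trend checks
use 5 replicates per condition at the reduced preset.

## What the synthetic data does and does not emulate

The synthetic generator reproduces the *mechanisms* that give rise to
immunodominance in the model — structure-dependent binding, composition-
driven immunogenicity, shared Tfh help, antigen consumption — at a reduced
scale.  It does not reproduce: the geometry of real discretized proteins
(PDB-derived scaffolds with pockets at 5.25-Å lattice constant; our walks
are smaller and smoother, so absolute energies and pose counts differ from
the published figures), glycosylation or other post-translational
modifications, antibody feedback or epitope masking, domain-specific Tfh
help, affinity-dependent mutation rates, or memory re-entry beyond the
optional injection of founder sequences into the pool.  Passing trend
checks therefore demonstrates that the implemented mechanisms produce the
reported *directions* (GC dynamics follow the most immunogenic domain;
half-dose increases affinity; added low-immunogenicity domains shrink the
GC), not that the package reproduces the published figures numerically.

## Numerical choices and degenerate inputs

* Pose-set construction is deterministic; equal-energy optima resolve to
  the smallest canonical pose index.
* The branch-and-bound scoring bound uses the most negative potential
  entry; it is exact for any `s >= 0` and any (possibly positive) entries.
* The potential loader enforces symmetry to 1e-9 and rejects unknown
  residues by name; an all-zero matrix is legal (every energy 0).
* Antigen doses are integers; equal division distributes the remainder one
  unit at a time to random distinct dendrite nodes.
* `pool_total` not divisible by the number of antigens floors the quota
  and warns.
* Empty pose sets ("antigen unbindable at this min_contacts") are an
  error wherever an energy is required.
* Founder sampling fails after `max_attempts` with the best affinity seen,
  which distinguishes "unlucky" from "physically unreachable threshold".
* Division with no free neighbor node is deferred, not forced; GCs at
  carrying capacity slow down rather than overlap.
* The cell-snapshot lookup accepts times within 1 h of a recorded
  snapshot; anything farther is an error rather than a silent nearest
  match.

## Known limitations

* The movement model is a persistent walk with field-following direction
  redraws; it is fitted to nothing — speeds and persistence are exposed
  parameters with literature-typical defaults.
* Output cells leave the lattice immediately on differentiation; transit
  time to the GC boundary is ignored.
* A Tfh polarizes at most one B cell per time step; simultaneous contacts
  queue behind the antigen ranking rather than sharing signal.
* The search clock starts when a cell becomes an unselected centrocyte
  (possibly still inside the DZ), so transit to the LZ consumes search
  time; at the default speeds transit is short relative to 0.7 h.
* Sequence space at the reduced scale (20^5) is small enough that distinct
  lineages can converge on identical sequences; diversity metrics count
  distinct sequences, not clones.
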