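---
title: "Detecting surface-directed ligand diffusion from MD trajectories"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting surface-directed ligand diffusion from MD trajectories}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Unbiased molecular dynamics of an enzyme surrounded by tens of free substrate
molecules produces an overwhelming volume of data: tens of molecules, tens of
replicates, ten thousand frames each. Buried in that volume may be a
*surface channel* — a contiguous region of the protein exterior along which
substrate molecules preferentially travel before entering the active site.
`surfchannel` implements a centroid-based reduction and an iterative merge
clustering that make such channels visible, together with per-residue
occupancy scoring, active-site arrival detection, and a synthetic trajectory
generator with planted ground truth for validating every stage.

The package operates entirely at the level of *substrate centroids*: each
molecule in each frame is replaced by the unweighted spatial mean of its
atoms. For a typical 22–24 atom substrate this is a roughly 25-fold data
reduction, and it is the representation every downstream stage consumes.

## The clustering model

The core algorithm reduces a pooled centroid cloud (all frames of all
molecules of one substrate type) to "the most populated positions in space".
One iteration, with cutoff $c$ (default $c = 10$ Å):

1. **Isolated-point removal.** Any point with no neighbour strictly within
   $c$ is removed. These are low-density, "false" positions that would
   otherwise generate merged centroids not representing genuinely co-located
   substrate.
2. **Greedy nearest-unique-neighbour matching.** All remaining pairs with
   distance $< c$ are sorted ascending; pairs are accepted in that order
   whenever both members are still unmatched, so each point merges with at
   most one partner, beginning with the closest pair and ending with the
   pair closest to the cutoff.
3. **Merging.** Each matched pair is replaced by its unweighted midpoint —
   the spatial average of the two points — carrying the summed count of
   original centroids as a weight.
4. **Carry.** Points that had neighbours but found no free partner are
   carried forward unchanged.

Iterating this shrinks the cloud strictly monotonically until an iteration
performs no merge (all survivors mutually beyond $c$), a single point
remains, or an iteration cap (64) is hit. Every surviving point is an
explicit convex combination of input centroids, and the whole procedure is
deterministic: distance ties are broken lexicographically by point index.

### Choices the model description leaves open

* **Carry versus drop.** A literal reading of "a new list generated from
  each unique centroid pair" could discard unmatched points wholesale, but
  the cutoff is explicitly there to remove *isolated* centroids; dropping
  neighboured-but-unmatched points would throw away density signal. We carry
  by default and expose `carry_unmatched = FALSE` for comparison.
* **Zero-merge termination.** When an iteration would merge nothing, its
  only possible effect is to delete all survivors as "isolated" (they are
  mutually beyond the cutoff). That final deletion would destroy the result —
  e.g. two well-separated condensed clusters are the *answer*, not noise —
  so the zero-merge iteration terminates the loop and its output is
  discarded. A two-point input 12 Å apart still yields an empty cloud from a
  *single* `cluster_iteration()` call, which is the documented per-iteration
  contract.
* **Midpoint versus weighted mean.** The merged point is the plain midpoint
  of the two merged points regardless of their accumulated weights,
  matching the "spatial average of the two points" description;
  `weight_average = TRUE` switches to the weight-aware mean.
* **Strict cutoff.** The neighbour criterion is strictly $< c$.
* **Pooling.** Clustering pools all frames of one trajectory into a single
  iteration-0 cloud and runs per trajectory; substrate types are never
  mixed, since each point pairs with its nearest unique neighbour *of the
  same type*.

## Trajectory conditioning

Before centroid extraction the trajectory is conditioned in the canonical
order: translate each frame so the geometric centroid of an anchor selection
(a short stretch of core residues, e.g. `"protein and resid 138-140"`) is at
the origin; superpose every frame onto the first frame by a Kabsch
least-squares fit (SVD with reflection correction, det $= +1$); re-center on
the whole protein; strip everything but substrate atoms. Centroids are
geometric, never mass-weighted — nothing in the pipeline invokes masses.
The fit selection defaults to all protein atoms; backbone-only fits are
expressible through the selection language. No periodic-boundary re-imaging
is performed: **inputs are assumed re-imaged upstream** by the MD engine's
own tooling.

## Per-residue scoring

The headline per-residue scalar is a *contact population score*: for residue
$r$,
$$s(r) = \frac{1}{N_\mathrm{frames}}\sum_{\mathrm{frames}\ t}\;
  \#\{\text{centroids within } c_\mathrm{contact} \text{ of any atom of } r
  \text{ at } t\},$$
a time-averaged occupancy with default $c_\mathrm{contact} = 5$ Å. One
centroid may score several residues in a frame. This is deliberately a
single number per residue so it can be written into the PDB B-factor column
(rescaled min–max onto 0–99.99 by default) and used to colour a structure in
any molecular viewer. A textbook radial distribution function
$g(r)$ — frame-averaged counts in shells around the nearest reference atom,
normalised by $4\pi r^2\,\mathrm{d}r\,\rho$ — is provided separately for
users wanting the distance-resolved quantity; its binning (1 Å), reference
convention (nearest anchor atom) and density handling (supplied, or
estimated as molecules per bounding-box volume and recorded) are our own
declared defaults, not inferred from any external tool. Scores from
replicate simulations are combined by an arithmetic per-residue mean.

## Arrival detection

An active site is a labelled anchor selection (typically the cofactor, e.g.
`resname PLP` for the unoccupied site and the aldimine-bearing residue for
the occupied one — the distinction is purely labelling, no chemistry is
modelled). A molecule *arrives* at the first frame its centroid comes within
`arrival_cutoff` of the nearest anchor atom; 3.5 Å by default, a typical
hydrogen-bond donor–acceptor heavy-atom distance, since the phenomenon being
operationalised is "within hydrogen-bonding distance" and detection works on
centroids rather than polar atoms. *Retention* is the fraction of frames
from the arrival frame onward spent within `site_region_cutoff` (6 Å); the
window includes the arrival frame, so retention is defined even for an
arrival on the last frame, and a molecule held at the site scores 1. A
molecule counts as "retained" at the conventional threshold of 0.95.
Only distances and retention are reported; no superficial-versus-deep
penetration classification is attempted. Restricting the centroid series to
arriving molecules (`filter_arriving()`) before clustering is what turns
diffuse occupancy into visible channel paths, with per-site subsets
available for colouring clusters by destination.

## The synthetic generator

`decoy_spec()` / `make_decoy_system()` / `simulate_walkers()` build
validation fixtures with exactly known answers. They emulate the *shape* of
a substrate-competition study — one protein, two recessed cofactor-anchored
sites, twenty substrate molecules of each of two types (the study condition
the defaults mirror), rigid 22- and 24-atom molecules so the ~23-fold
centroid reduction is exercised — while making no attempt to be a physical
model: there is no force field, no solvent, no electrostatics.

* **Free walkers** perform a reflected Gaussian random walk (per-axis step
  `step_sigma`, default 1 Å/frame) inside a cubic box, with hard-sphere
  reflection off the protein shell. Site anchors are recessed 5 Å below the
  shell, so a free walker can never come within the 3.5 Å arrival cutoff:
  free walkers are an exact negative control.
* **Channeled walkers** traverse the planted surface polyline
  arc-length-uniformly with 0.35 Å jitter, reach the last surface waypoint
  one frame before their scripted arrival frame, sit on the site anchor at
  exactly that frame, and then relax around the anchor (OU-style pull with
  0.3 Å noise) so they are retained for the rest of the run. Detection must
  therefore recover *exactly* the scripted molecules at *exactly* the
  scripted frames.
* **Channel-lining residues** are defined as those with any atom within 8 Å
  of the polyline, giving planted truth for enrichment checks.

Defaults the generator fixes once (no field convention exists for them):
200 shell residues of 3 atoms on a radius-30 Å sphere — a sphere rather than
a flattened ellipsoid keeps the hard-sphere reflection exact — a 60 Å
half-width box, 2,000 frames, and 3 channeled walkers. Structure and
starting positions derive from `placement_seed`, dynamics from `seed`, so
different "systems" can share identical starting substrate coordinates.

What passing tests on these fixtures show — and what they do not: they
demonstrate that the analysis recovers planted signal of realistic geometry
and ignores planted noise; they cannot certify behaviour on real MD output,
where substrate motion is correlated, solvent-mediated and
periodic-boundary-wrapped. The conditioning stage in particular assumes
upstream re-imaging.

## Numerical and testing choices

* All coordinates are Å; residue numbering is 1-based PDB numbering
  preserved verbatim; frames are 1-based.
* Trajectory interchange is multi-model PDB plus a CSV centroid dialect
  (6-decimal coordinates, header `frame,molecule_tag,substrate_type,x,y,z`);
  all writers emit LF endings and fixed-width PDB columns, so outputs are
  byte-comparable across runs. Substrate instances get a `molecule_tag`
  synthesised from residue name, chain and residue number, because PDB has
  no molecule-instance concept.
* The clustering is validated against an independently coded brute-force
  implementation (sequential minimum-search matching) on 200 random
  instances of up to 60 points — identical points, weights and ordering —
  and on planted-polyline instances where all surviving points must fall
  within 6 Å of the truth.
* Problem sizes in the test-suite and acceptance script (80–200 residues,
  100–2,000 frames, 200 oracle instances, one 400-molecule × 1,500-frame
  ideal-gas control) are the package's own validation choices: large enough
  that every statistical check has comfortable Monte-Carlo margin, small
  enough that the whole suite runs in about a minute.

## Known limitations

* No periodic-boundary handling, velocities, or binary trajectory formats
  (DCD/XTC/NetCDF); conversion to multi-model PDB is assumed upstream.
* Arrival detection is centroid-level; a long molecule's functional group
  can be nearer the cofactor than its centroid.
* Channel identification is the centroid-cloud geometry itself; no explicit
  path-graph extraction is attempted beyond the per-iteration clouds.
* The generator's walkers are controls with known answers, not physics.
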