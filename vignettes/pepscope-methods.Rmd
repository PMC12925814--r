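---
title: "Methods: trajectory, conservation and assay analyses in pepscope"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: trajectory, conservation and assay analyses in pepscope}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pepscope)
```

pepscope analyses the interaction repertoire of short host-defense
peptides — self-assembly in solution, adsorption onto lipid A
aggregates, and binding in a CD14-style receptor groove — together with
the evolutionary conservation of the residues involved and the scalar
assay metrics used to rank peptide variants. This vignette documents
the models, the parameters that matter, the numerical choices, and
what the synthetic generators do and do not emulate.

## Data model and geometry

A `molecular_system` is a flat particle table (molecule id and kind,
1-based residue index, residue/site names, chemical group tag, optional
radius); a `trajectory` adds ordered coordinate frames with an optional
orthorhombic box. The internal length unit is nanometres everywhere;
PDB files are converted from Ångström at the I/O boundary, GRO and the
package's plain-text XYZ-table format are nm-native. Only orthorhombic
boxes are supported — triclinic input raises an explicit error —
because the systems this package targets are cubic solution or
complex boxes. Residue numbering is taken verbatim from input files
and never rewritten, so reference positions such as CD14 W45/F69/Y82
keep their conventional numbers.

All cutoff-based metrics use minimum-image distances under the box
(`d_k -> d_k - L_k * round(d_k / L_k)` per axis), and all cutoff
comparisons are **inclusive** (`<=`), a deliberate, documented
tie-break. Whether contacts should use minimum-image or whole-molecule
mapped distances is genuinely open for this kind of analysis; the
package computes minimum-image distances, and input can be pre-wrapped
by the caller if molecule-contiguous coordinates are wanted.

Chemical groups (lipid head group/phosphate/tail, guanidinium and
ammonium cation groups, aromatic rings, backbone) are assigned by
ordered pattern rules — first match wins — shipped as an overridable
default table covering both coarse-grained bead names and atomistic
side-chain atoms.

## Aggregation analysis

Two peptides are linked in a frame when **any** inter-peptide particle
pair lies within the contact cutoff (default 0.6 nm, the same cutoff
used for all contact metrics; no separate clustering cutoff is
defined). Clusters are connected components of that link graph, i.e.
single-linkage clustering at the contact cutoff. Any-particle linkage,
rather than centroid distance, matches the contact-based definition of
the other metrics.

Per-residue inter-peptide contact propensity counts contact events
over all frames and both orderings of each pair, attributes each event
to the residue of the first particle, and normalises to percentages
summing to 100. Normalising over events (not frames) is the default
because the profile is a percentage-of-contacts quantity; a
frames-in-contact mode is available and labelled.

## Lipid-interface analysis

Per-residue head-group and tail contact profiles follow the same
event-counting convention against lipid particles carrying the target
tag.

SASA uses the Shrake–Rupley construction with a deterministic golden
spiral quadrature: for particle *i*, points are placed on the sphere of
radius `r_i + probe`; a point strictly inside any other particle's
expanded sphere is buried (a point exactly on an occluding sphere
counts as exposed — a deterministic tie-break), and the exposed
fraction scales `4*pi*(r_i + probe)^2`. The probe radius defaults to
0.26 nm, the radius of a coarse-grained water particle. Solvent
particles never occlude (the probe represents solvent). Default
radii: 0.23 nm for coarse-grained beads, standard van der Waals radii
for atomistic elements; both are configurable and recorded. The
default 96-point quadrature reproduces an isolated sphere exactly and
agrees with a 10^5-point Monte-Carlo surface oracle within 2% on
random 20-particle clusters (see the test suite); 384 points are used
where tighter agreement is wanted.

Ion "displacement" has no single operational definition; the package
defines it relative to the first frame's bound count (an ion is bound
when within the cutoff of any phosphate-tagged particle), floored at
zero, and always reports the full bound-count series so alternative
definitions can be derived.

Whether averages should exclude an equilibration window is left to the
caller: series are returned per frame and the pipeline summarises over
a configurable final-fraction window.

## Complex-interface analysis

Superposition uses the Kabsch SVD construction restricted to proper
rotations (det = +1); collinear fit sets raise a degeneracy error.
RMSD series fit each frame on one selection (typically the receptor)
and measure on another (typically the whole peptide), against frame 1.

Geometric interaction criteria are not printed in most structural
papers, so the defaults follow common structural-biology practice and
are configuration-exposed; every occupancy result records the criteria
used:

| interaction | distance | angle |
|---|---|---|
| cation-π | centroid–centroid ≤ 0.6 nm | ring normal vs. centroid–cation ≤ 45° |
| π-stacking (parallel) | ≤ 0.55 nm | inter-plane ≤ 30° |
| hydrogen bond | D–A ≤ 0.35 nm | D–H–A ≥ 120° (distance-only in CG mode, flagged) |
| salt bridge | group centroids ≤ 0.45 nm | — |

Cation positions are centroids of the tagged cation-group particles
(guanidinium NH1/NH2/CZ, ammonium NZ); ring normals come from the
smallest principal axis of the ring coordinates, with the sign
ambiguity folded out of all angles.

Contact maps against a chemical group are normalised to percentages
over receptor residues (raw counts retained; per-event normalisation
is the default, as above). Profile comparison uses Spearman ρ with
fractional mid-ranks, joining the two maps on the union of receptor
residues with zero-fill — comparing "all contacts made with the
receptor" requires a common residue axis — and is computed on
percentages (ranks are identical for raw counts of the same
trajectory length).

## Conservation and selection

Column conservation is `1 − H/ln 20` with `H` the Shannon entropy of
non-gap residue frequencies; `X` is treated as missing, like a gap.
Columns are classed `identical` (one residue type), `similar` (all
residues within one similarity group: {KRH} {DE} {STNQ} {FWY} {LIVM}
{AG} {C} {P}, configurable), `masked` (gap fraction above 0.5,
configurable) or `variable`. The consensus takes the plurality
non-gap residue, writes `-` where gaps exceed half the column, and
breaks ties lexicographically with an explicit tie flag — conventions
chosen here and documented, not inferred from any external tool.
Reference-position mapping treats numbering as a property of the
chosen reference row (the 1-based ungapped count in that row) and
never re-derives it; this is how a full-precursor position such as
prothrombin H605 (numbered including the signal peptide) is carried
onto alignment columns.

Selection pressure is measured with Nei–Gojobori (1986) equal-weight
pathway counting: synonymous site fractions per codon position,
differences averaged over all mutational pathway orderings
(stop-passing pathways excluded; mutations **to** stop codons count as
nonsynonymous sites), pairwise deletion for gapped codons, and
Jukes–Cantor correction `d = −(3/4) ln(1 − (4/3) p)`. ω = dN/dS is
flagged undefined when dS = 0. Per-codon summaries pool site and
difference counts over all sequence pairs without Jukes–Cantor
correction (proportions only are meaningful at single-codon scale) and
flag codons with zero observed substitutions. This is a deliberate
desk-scale metric: maximum-likelihood codon models and per-site
likelihood tests are out of scope, and outputs are labelled with the
counting method. NG86 counting is known to compress ω toward
moderate values at higher divergence; the ω-recovery test therefore
checks rank (monotone) agreement with the planted grid, not equality.

## Assay metrics

Hemolysis uses the standard control-normalised form
`100 (A − A_neg)/(A_pos − A_neg)`, clipped to [0, 100] with a clip
flag. The 4PL fit
`y = bottom + (top − bottom)/(1 + (x/ic50)^hill)` and the 1:1
isotherm `y = baseline + amplitude · x/(kd + x)` both use
Levenberg–Marquardt with a deterministic multi-start over a log-spaced
grid (and both slope signs for the 4PL), so fits are deterministic
given the data. Orientation is normalised after fitting so the Hill
slope is positive and `ic50` always denotes the half-effect
concentration, with the response direction reported. Honesty flags:
a fit whose span is within the residual noise, or whose IC50/KD falls
far outside the measured concentration range (including
saturation-only binding data), is marked unidentified rather than
silently reported. The 1:1 isotherm is the default binding model; a
Hill-type curve can be fitted with the 4PL routine when cooperative
binding is suspected. The therapeutic index is the exact ratio
IC50(hemolysis)/IC50(TNF-α).

## Synthetic data: what is and is not emulated

The generators plant structure geometrically and combinatorially —
never via force fields. They emulate the *statistical signatures* the
analyses must recover, not physical dynamics:

- `gen_aggregation`: rigid bead-rod peptides (10 copies of an 18-bead
  rod in a 15 nm box by default) with random-walk moves; with
  stickiness on, bodies drift toward their nearest neighbour at
  0.2 nm/frame and merge irreversibly at the contact cutoff (capture
  radius = 0.6 nm, so a detected contact is always already a merge —
  this removes transient contact/uncontact flicker around the cutoff).
  Ground truth: the merge log and final cluster size.
- `gen_lipid_interface`: a spherical aggregate (61 lipids by default)
  with head/phosphate surface shell and tail core; peptide residues
  contact the shell independently per frame with probability
  proportional to planted weights, with the geometry arranged so each
  contact produces exactly one counted pair event. Ions sit 0.3 nm
  off phosphates and a planted subset is released at a chosen frame.
- `gen_complex`: a static receptor grid (1.5 nm spacing) with six-bead
  aromatic rings where needed; each planted interaction is satisfied
  in exactly `round(p · n_frames)` evenly spaced frames; optional
  linear peptide drift plants a strictly increasing RMSD; an optional
  planted categorical mixture over receptor residues drives contact
  maps.
- `gen_msa` / `gen_codon_msa`: per-column sampling from planted
  residue distributions (with a conserved-histidine preset), and
  star-tree codon evolution where synonymous proposals are accepted
  with probability 1 and nonsynonymous with probability ω (for ω > 1
  the synonymous acceptance is down-weighted to 1/ω so probabilities
  stay in [0, 1]); stop codons are rejected. Realised substitution
  counts are recorded.
- `gen_dose_response`: log-spaced concentrations over 0.015–500 μM
  (the usual thermophoresis assay range) with Gaussian noise.

Every generator is seed-deterministic, restores the caller's RNG
state, and serialises its ground truth next to the data. Because the
planted structure is geometric, passing tests demonstrate that the
*analyses* are correct and sensitive at realistic scales; they say
nothing about force-field realism, kinetics, or the behaviour of real
μs-scale trajectories, which are far noisier than these constructions.

## Problem sizes and determinism

The test suite and the acceptance script run at deliberately modest
sizes chosen to exercise every code path with tight statistics: 100
random frames for the geometry oracles, 20-particle clusters against a
10^5-point Monte-Carlo SASA oracle, 6–10 peptides over 120–200 frames
for the aggregation contrast, 500 random codon pairs against the
exhaustive Nei–Gojobori oracle, 20 seeds for the ω-recovery grid and
50 seeds for the fit-noise studies. All randomness in the pipeline and
the acceptance script flows from a single recorded seed, and reruns
with the same configuration reproduce byte-identical numeric outputs
(manifests record package version, seed, and output digests).

## Known limitations

- No binary trajectory formats (XTC/TRR/DCD) and no triclinic boxes.
- Neighbour search is vectorised all-pairs, appropriate for the
  10³-particle systems targeted here, not for million-particle ones.
- NG86 dN/dS is a counting method; it is not expected to agree
  numerically with maximum-likelihood codon models, and saturation
  (p ≥ 3/4) yields infinite distances.
- The hydrogen-bond detector in coarse-grained mode is distance-only
  and flagged as such.
- Contact-map normalisation offers per-event and per-frame modes;
  which one an external study used must be known for quantitative
  comparison.
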