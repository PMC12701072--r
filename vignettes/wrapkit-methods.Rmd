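---
title: "Methods: quantifying DNA wrapping by tetrameric bacterial histones"
author: "wrapkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying DNA wrapping by tetrameric bacterial histones}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wrapkit)
```

## The scientific problem

Bacterial histones of the face-to-face (FtF) subfamily, exemplified by HLp
from *Leptospira perolatii*, form stable homotetramers whose perimeter is
ringed by a continuous band of positive charge. Crystal structures of such
tetramers bound to short DNA duplexes show two complementary, overlapping
protein-DNA interfaces, which raises the central question this package
quantifies: does the tetramer *bridge* two separate duplexes across opposite
faces, or does a single DNA segment *wrap* around its circumference
(roughly 60 bp, compared with ~147 bp around a eukaryotic nucleosome)?

wrapkit implements the full downstream analysis by which that question is
answered from structures, molecular-dynamics trajectories and in vitro
assays: crystallographic symmetry expansion, construction of wrapping and
bridging starting models from crystal interfaces, heavy-atom contact and
binding-site analytics over trajectories, geometric descriptors (backbone
RMSD, tetramer planarity, helix crossing angles, wrap coverage,
free-energy landscapes), post-processing of steered unwrapping runs, and
quantitation of the supporting biochemistry (masses and stoichiometry,
Shine-Dalgarno positioning, nuclease protection ladders, tethered-particle
compaction curves, binding isotherms). It deliberately does **not** run
molecular dynamics, refine crystal structures or process gel images: its
inputs are coordinates, frame series, pull data and densitometric profiles.

## Contact analytics

A binding contact is any pair of heavy atoms (element other than H or D)
within 4.0 Å; the comparison is inclusive (`<=`) so that the boundary case
is deterministic. Contacts are counted as atom pairs, not residue pairs; a
per-residue aggregation (mean contacts per protein residue) is emitted
alongside. The cutoff and the heavy-atom restriction live in
`contact_params()` and can be changed in one place.

Four canonical binding sites decompose the tetramer surface
(`define_canonical_sites()`): the two **A-sites** each combine two
beta-bridge motifs (T27/G29 in loop l1, T56/T57 in loop l2) with the
flanking l2 DNA-binding residues (K54, R59) at a tetramerization interface;
the two **B-sites** are each centered on a paired-end-of-helices motif
(A13, S14, K15) with the adjacent alpha1 residues (K17, K21) across a
dimer. With dimer-ordered chains (c1, c2 | c3, c4), B-site 1 spans (c1,
c2), B-site 2 spans (c3, c4), A-site 1 spans (c2, c3) and A-site 2 spans
(c4, c1); the four (chain, residue) sets are pairwise disjoint. The exact
per-site residue inventory is configurable, since the defaults are
assembled from the main-text motif residues rather than a full
supplementary table.

The **binding fluctuation** of a trajectory is the per-frame deviation of
the total contact count from its mean over all frames; it sums to zero by
construction and is reported together with a centered moving-average
smoother (window 100 frames by default; even windows are bumped to the next
odd integer so the window centers, and edge windows are truncated rather
than padded).

Hydrogen bonds use a 3.5 Å donor-acceptor distance with a 120 degree
D-H...A angle when hydrogens are present (distance-only otherwise), and
salt bridges a 4.0 Å charged-group N/O distance; a pair is *persistent* at
occupancy >= 0.5. These values are common MD practice, are not dictated by
any single data set, and are configurable in `hbond_criteria()`.

Contact counting offers a dense all-pairs path and a cell-list
(spatial-hash) path; both are exact and are cross-checked against an
independent brute-force oracle in the test suite. Distances use plain
Euclidean geometry; inputs are expected to be whole molecules (periodic
images re-wrapped upstream).

## Building models

`build_bdna()` places rigid idealized nucleotides on successive base-pair
frames: rise 3.4 Å/bp and twist 36 deg/bp by default (a 10.5 bp/turn
dialect, twist ~34.3 deg, is one argument away), along a straight axis or a
circular arc of curvature kappa (1/Å). Base atoms follow the standard
base-pair reference frame to ~0.05 Å; the sugar-phosphate template is an
approximate fiber geometry whose O3'(i)-P(i+1) virtual bond closes under
the default step. This is sufficient by design: every downstream metric
uses heavy-atom positions, never covalent energetics. 5'-terminal
nucleotides carry no phosphate. `measure_duplex_params()` recovers each
base-pair frame by Kabsch superposition of the ideal template, so rise and
twist round-trip to machine precision — the builder's key invariant.

`assemble_wrapping_model()` realizes the "symmetry expansion, trimming and
reconnection" workflow: each crystal-derived interface template is
superposed onto the tetramer through its shared protein atoms; the
transformed template base-pair centers define the wrapping plane, a
least-squares circle (center and radius) and the starting phase; and a
single idealized B-DNA arc of the requested length (67 bp by default) is
laid through the interfaces. The helical twist phase of the arc is chosen
by scanning against the template C1' atoms (both plane orientations are
scanned, since a flipped normal would build a left-handed duplex). Rather
than literally splicing template fragments and healing the joints, the
common circle fit absorbs overlapping coverage and bridges gaps in one
step — an equivalent end state (a continuous uniform-rise duplex through
the crystal interfaces) that is far more robust to noisy or partially
overlapping templates. Templates whose radial scatter exceeds 35% of the
mean radius are rejected as geometrically inconsistent (they would require
kinks beyond DNA stiffness). If the arc would clash with the protein
(any protein-DNA heavy-atom pair under 2.0 Å), its radius is inflated in
0.25 Å steps up to +5 Å, then the assembly fails loudly.

`assemble_bridging_model()` gives each of two opposing templates its own
straight duplex (32 bp by default) extended along the template DNA axis;
segments must stay clash-free and more than 4 Å apart from each other. In
both modes the tetramer coordinates pass through bit-exactly.

The 67-bp and 32-bp lengths and the step parameters are exposed as
arguments; the sequences are explicit inputs (a repeating ACGT filler by
default) because the binding under study is not sequence-specific.

## Geometry

* `superpose()` is a standard Kabsch (SVD) solver constrained to proper
  rotations; it is cross-checked in the tests against both a brute-force
  minimization over rotation parameterizations and an independent library
  implementation.
* `dna_backbone_rmsd_series()` fits each frame on protein heavy atoms and
  measures over the DNA backbone, defined as phosphate plus sugar heavy
  atoms (bases excluded) — the standard nucleic backbone, and the moiety
  that dominates the binding interface.
* `tetramer_planarity()` concretizes "the dihedral between the two dimers"
  as the torsion over the four monomer heavy-atom centroids in the order
  (dimer1.monA, dimer1.monB, dimer2.monA, dimer2.monB). Pass the second
  dimer in ring-reversed order for the trans convention (planar reads
  180 deg), or use `convention = "zero"` to read deviation from planarity.
  Collinear centroids yield `NA` for the frame.
* `helix_crossing_angle()` fits each helix axis by the
  perpendicular-bisector construction (cross products of successive
  second-difference vectors), which is exact for ideal helices and needs
  no full-turn alignment; the angle is folded to [0, 90] degrees with the
  antiparallel flag reported separately.
* `wrap_coverage()` counts a base pair as wrapped when any heavy atom of
  either nucleotide is within the contact cutoff of any protein heavy
  atom; the angular coverage is 360 degrees minus the largest azimuthal
  gap between wrapped base-pair centers about the normal of their best-fit
  plane. Unpaired DNA falls back to per-nucleotide counting with a
  warning.
* `free_energy_landscape()` histograms two collective variables and maps
  probabilities to F = -kT ln(P/Pmax), so the global minimum is exactly 0
  and empty bins are `NA` rather than infinite. kT defaults to
  2.577 kJ/mol (310 K). The minimum basin is summarized by its location,
  depth and area below a threshold (1 kT by default). No collective
  variables are imposed; the natural default pair for this problem is
  (DNA backbone RMSD, total contact count). Note that the Pmax anchoring
  makes F invariant under rescaling all counts, which is the
  normalization invariance the tests check.

## Steered-unwrapping post-processing

`work_profile()` integrates force over the pulling coordinate by the
trapezoid rule (units are declared once on the series and carried through);
the profile is raw cumulative work from a single trajectory, deliberately
not a Jarzynski/Crooks free-energy estimate. `detect_barriers()` segments
the smoothed slope dW/dxi at a threshold (10% of the maximum slope by
default): each maximal rising stretch, anchored at the midpoints of its
flanking plateaus, contributes its rise in W as one barrier if it exceeds
`min_height`; a monotone profile therefore yields its total rise as a
single barrier. When per-site contact series over the same coordinate are
available, each barrier is attributed to the site whose contacts drop most
across its interval. `release_order()` declares a site released at the
first coordinate where its smoothed contacts fall below a threshold
fraction (0.5) of the initial mean and stay below for a dwell window —
the threshold-sensitivity of this definition is itself exercised in the
tests (release coordinates move monotonically earlier as the threshold
rises).

`residue_energy_decomposition()` computes, per protein residue, the mean
over frames of the cutoff-truncated nonbonded energy (Coulomb with
configurable relative dielectric, 12 Å cutoff, plus Lennard-Jones when
parameters are supplied) against all DNA atoms, with fractions reported on
the magnitude of the attractive residues. Decomposition schemes are
method-sensitive; the published "top five residues carry 52%" style of
statement is treated as a planted-share recovery problem in the synthetic
fixtures, not as an exact physical constant.

## Assay quantitation

* Masses are average (not monoisotopic): peptides as residue masses plus
  one water; DNA as 5'-monophosphate nucleotide residues minus
  condensation water, with the 5' end chemistry configurable — 5'-OH is
  the default, appropriate for synthesized oligos, and the two conventions
  differ by one HPO3 (~80 Da) per strand, which matters when comparing a
  tetramer + 2 duplex complex against a SEC-MALS figure.
* `sd_scan()` slides the Shine-Dalgarno core (AGGAGG, the complement of
  the anti-SD CCUCCU) over a 4-14 nt spacing window upstream of candidate
  start codons and scores the longest contiguous match, supporting the
  choice between alternative annotated start positions.
* `ladder_sizing()` detects lane peaks above a noise floor (median + 3 MAD
  of the profile, with a 5% of maximum guard against baseline spikes),
  calibrates log10(size) against migration from a marker lane by least
  squares, checks monotonicity, and propagates the calibration residual
  into a per-fragment uncertainty; peaks outside the marker range are
  flagged as extrapolated, never silently reported.
* `tpm_logistic_fit()` fits the four-parameter decreasing logistic
  RMS(c) = RMSmin + (RMS0 - RMSmin) / (1 + (c/c50)^k) by
  Levenberg-Marquardt least squares (optionally weighted by replicate
  SDs); the saturation concentration is where 95% of the total drop is
  reached, i.e. c50 * 19^(1/k). Constant input yields a flagged degenerate
  fit rather than a failure.
* `isotherm_fit()` fits both a 1:1 model (depletion-aware quadratic when
  the probe concentration is given) and a Hill variant and reports an
  AIC-based selection, a no-binding verdict for flat responses, and a
  narrow-span flag when the titration covers under two decades.

## Synthetic study conditions

The generators in this package are first-class, tested code; they define
the conditions under which the pipeline is validated.

`gen_toy_complex()` builds a coarse tetramer of four pseudo-monomer chains
carrying the canonical site residues (real residue and atom names, so the
production selection code runs unchanged) around idealized B-DNA: a closed
67-bp circle for wrapping, two straight 32-bp duplexes for bridging.
Engaged sites receive contact atoms planted at exactly 3.5 Å from their
nearest DNA heavy atom (inside the 3.0-3.9 Å band); disengaged site atoms
sit at least 6 Å from all DNA. In wrapping mode a surface ring of
pseudo-atoms tracks a chosen number of contiguous base pairs at 3.6 Å
(with a 3.2 Å clearance floor against all other DNA), so per-base-pair
wrap coverage has an exact, brute-force-verified ground truth; 60 of 67 bp
is the wrapped-state condition used in the acceptance computation, and the
per-frame DNA displacement amplitude (6 Å) sets the backbone-RMSD plateau
the wrapped ensemble is expected to hold. Frames add isotropic Gaussian
jitter (0.3-0.5 Å in routine use). Requesting A-site engagement from two
separate straight segments is rejected as impossible geometry.

`gen_smd_series()` plants Gaussian force bumps whose integrals are the
barrier heights — 500 kJ/mol at B-site 2 followed by 400 kJ/mol at
A-site 2 by default, matching the two-phase unwrapping picture — and
co-generates per-site contact series that collapse sigmoidally at each
barrier, so both attribution and release order have ground truth.
`gen_gel_lane()` places Gaussian bands through a monotone log-linear
migration model (planted protection-fragment sizes 35/46/72 bp; an
ultra-low-range 10-300 bp marker lane is co-generated). `gen_titration()`
draws logistic TPM curves (RMS 140 -> 80 nm, midpoint 1500 nM, slope 2 —
saturation then falls near 6000 nM) or 1:1/Hill isotherms (Kd 2 uM)
with Gaussian replicate noise. All generators are bitwise-deterministic
under a fixed seed, and every fixture carries its ground truth, which
serializes losslessly to plain text (`write_ground_truth()`).

What the toys emulate is the *statistical structure* the analysis assumes:
planted contact geometry, engagement patterns, staircase work, log-linear
migration, logistic compaction. What they do not emulate is physics — no
force field, no thermal ensembles, no sequence effects, no correlated
motions. A passing suite therefore demonstrates that the measurement
machinery is correct and calibrated, not that any particular biological
system wraps DNA; conclusions about real systems still require the real
structures and trajectories, for which the same functions are the entry
points.

## Numerical choices and degenerate inputs

Distances at the contact boundary compare inclusively with a 1e-12
absolute guard; altloc resolution keeps the highest-occupancy conformer
(ties: first in file); deuterium counts as hydrogen for the heavy-atom
flag; residue and sequence numbering is 1-based author numbering exactly
as deposited. Symmetry expansion measures atom-to-atom distances (not
centers of mass) with a default 20 Å radius, always retains the identity
copy first, renames generated chains uniquely, and records each copy's
operator; it searches lattice translations to +/-2 cells with a bounding
prune. Kabsch superposition refuses fewer than 3 non-collinear points;
degenerate planarity frames return `NA`; empty atom selections are empty
results, not errors, while unknown selection classes and absent residues
are errors that name the offender. Fits never fail silently: degenerate
TPM input, non-converged fits, no-binding isotherms and extrapolated
ladder sizes are all flagged in the return value.

Problem sizes in the test and acceptance runs (tens of frames, a few
thousand atoms, 20 classification replicates) were chosen as the smallest
ensembles at which every recovery check is statistically comfortable; all
of them are package choices and scale up linearly for real data.

## Known limitations

The B-DNA builder uses rigid nucleotides and idealized base-pair planes:
no sequence-dependent step parameters, no minimization, no solvation. The
wrapping assembler fits one circular arc; strongly non-planar or
superhelical wrapping paths would need a generalization. The free-energy
landscapes are raw -kT ln P histograms without reweighting (no
WHAM/MBAR), and the unwrapping "energy landscape" is raw cumulative work
from a single pull. The energy decomposition is a cutoff nonbonded sum,
not a polar/nonpolar solvation decomposition. Gel densitometry starts
from lane profiles; image processing is out of scope.
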