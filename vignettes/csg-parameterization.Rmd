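---
title: "Parameterizing and validating S-glutathionylated cysteines"
author: "csgkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Parameterizing and validating S-glutathionylated cysteines}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(csgkit)
```

## The problem

S-glutathionylation attaches glutathione (GSH, the tripeptide
gamma-Glu--Cys--Gly) to a protein cysteine through a disulfide bond. The
modified residue, CSG, does not exist in standard protein force fields, so
simulating glutathionylated proteins requires (i) a residue definition --
partial charges, atom types, connectivity, chain-link atoms -- compatible
with the host force field, (ii) a way to introduce the modification into
unmodified structures, and (iii) descriptors to judge whether simulations
started from such models reproduce experimental structures. csgkit
implements all three as desk-scale, fully testable components. The
quantum-chemistry steps that produce electrostatic-potential (ESP) grids,
and the molecular dynamics engine itself, are deliberately out of scope:
csgkit consumes ESP grids and coordinate ensembles, it does not create
physics.

## RESP charge fitting

Atomic charges are fit to reproduce a molecular ESP sampled at $P$ points
around the molecule. The objective is the standard restrained electrostatic
potential (RESP) form

$$\chi^2(q) \;=\; \sum_{i=1}^{P}\Big(V_i - \sum_{j=1}^{M} \frac{q_j}{r_{ij}}\Big)^2
\;+\; \sum_j a_j\big(\sqrt{q_j^2 + b^2} - b\big),$$

minimized subject to $\sum_j q_j = Q$ (the integer molecular charge), any
frozen charges, and within-group equality for symmetry-equivalent atoms.
Everything is in atomic units (Bohr, Hartree/e). The hyperbolic restraint is
re-linearized each pass -- its gradient contributes $a_j/\sqrt{q_j^2+b^2}$
to the normal-equation diagonal -- and the constrained linear system is
solved repeatedly until no charge moves by more than $10^{-8}$ e (hard error
after 200 passes, or on a singular system).

Tunable parameters, with defaults chosen to match common practice:

* `a1 = 0.0005` e$^2$ -- stage-1 restraint on all non-hydrogen atoms;
  hydrogens are never restrained.
* `a2 = 0.001` e$^2$ -- stage-2 restraint.
* `b = 0.1` e -- restraint width.
* `stage2_refit_set` -- the canonical two-stage protocol refits only sp3
  carbons carrying two or more equivalent hydrogens, plus those hydrogens,
  with everything else frozen at stage-1 values;
  `stage2_set_from_template()` derives this set (and the hydrogen
  equivalence groups) from a residue template's bond graph. When the set is
  empty a single restrained stage is performed. Equivalencing is treated as
  a stage-2 device: it constrains stage 1 only when no second stage follows.
* Equivalence detection: hydrogens bonded to the same carbon are considered
  topologically equivalent. This is coarser than a full graph-isomorphism
  treatment but matches what matters for methyl/methylene groups;
  user-supplied groups override it.

With the restraint switched off and an ESP generated exactly from point
charges, the fit recovers the generating charges to machine precision; the
test suite asserts recovery to $10^{-6}$, rigid-motion invariance to
$10^{-8}$, and bit-identical charges within equivalence groups.

## Charge normalization for a spliceable residue

Charges fit on a capped model compound must be turned into a residue that
splices into a protein chain without changing the total charge. The
bookkeeping, applied by `normalize_charges()`:

1. capping-group charges are discarded (not redistributed);
2. backbone atoms (N, H, CA, HA, C, O) take the host force field's cysteine
   backbone charges verbatim, so the residue is electrostatically seamless
   with its neighbors;
3. the residual needed to reach the integer target (here $-1$ e: a $+1$
   amino terminus and two $-1$ carboxylates on the GSH moiety) is spread
   uniformly over the side-chain atoms,
   $\Delta = (Q - \sum q_\mathrm{bb} - \sum q_\mathrm{sc})/n_\mathrm{sc}$.

A residual of $-0.009$ e over five side-chain atoms, for example, gives
$\Delta = -0.0018$ e per atom. The output sum is asserted to the target
within $10^{-9}$ e.

The CSG template shipped with the package (`csg_template()`) is synthetic:
ff14SB cysteine backbone charges, analogy-based side-chain charges run
through this normalization, GSH-entry atom names (SG2/CB2/O2/OE1/N1/C1/C3,
amide hydrogens H2 and H4), ff14SB-style atom types, and ideal-geometry
coordinates built from canonical internal coordinates. It is a working,
integer-charge, fully connected residue meant to exercise the pipeline and
to be replaced atom-for-atom by charges fit from a user's own QM ESP.

## Grafting glutathione onto a cysteine

`graft_glutathione()` converts a cysteine in place: the residue is renamed
CSG, the thiol hydrogen removed, and the 35 GSH-moiety atoms placed by
running the template's internal-coordinate table (a z-matrix seeded from the
cysteine's N/CA/C/CB/SG) with natural-extension (NeRF) placement. Two
torsions are exposed because they control the modification's orientation:

* `chi_ss` -- the disulfide torsion CB--SG--SG2--CB2, default $+90^\circ$;
  disulfides cluster near $\pm 90^\circ$ and experimental CSG sites do the
  same, so both wells matter.
* `chi2` -- CA--CB--SG--SG2, default the template value ($180^\circ$).

Geometry constants (S--S 2.04 Å, C--S--S 104°, trans amides) are canonical
values; they relax in any downstream minimization, which is why the builder
does not attempt energy refinement. All pre-existing atoms are left
bit-identical -- the graft is purely additive after the HG deletion -- and
the three GSH residues are built as L-amino acids (asserted as a signed
volume around each alpha carbon).

Because a modification grafted onto an unmodified model can land in the
wrong side-chain orientation and stay trapped there, `enumerate_rotamers()`
generates starting structures covering both `chi_ss` wells first, then a
`360/k`-spaced `chi2` grid, each annotated with a steric-clash report
(heavy--heavy contacts under 2.0 Å, bonded and 1--3 pairs excluded;
permissive by design since minimization follows). The list is sorted by
clash count so the first entries are the useful starting points.

## The descriptor panel

All ensemble descriptors run on a trajectory container (fixed topology,
$F \times N \times 3$ coordinates, one frame per PDB `MODEL`):

* **RMSD series** -- each frame is superposed on the reference by weighted
  Kabsch SVD (proper rotation, det $= +1$) over a *fit* selection, then the
  RMSD is computed over a *calc* selection without refitting. The CSG-site
  protocol superposes on the protein backbone and measures over all CSG
  atoms: a local fit would hide exactly the side-chain-reversal signal one
  wants to detect. "Backbone" means N, CA, C, O plus the amide H; HA is
  excluded.
* **Radius of gyration** -- mass-weighted, over all atoms present
  (experimental structures usually lack hydrogens; their reference values
  are then heavy-atom values by construction, which is the consistent
  comparison).
* **S--S dihedral series** -- the torsion CB--SG--SG2--CB2 with circular
  mean and circular standard deviation (mean resultant vector), because
  wrapped angular data near $\pm 180^\circ$ makes linear moments
  meaningless.
* **Native interactions** -- hydrogen-bond partners of the CSG polar
  moieties (amide O2/OE1 and H2/H4, the glycine-end carboxylate C3, the
  glutamate-end carboxylate C1, the free amino N1) within 3.5 Å
  heavy--heavy, with a D--H⋯A $\ge 120^\circ$ filter when the donor
  hydrogen is present; distance-only monitoring along the ensemble, as
  distances are what distributions are plotted from. Carboxylate distances
  are the minimum over the two oxygens, making them invariant to the
  arbitrary crystallographic O-naming. Cation--$\pi$ contacts are measured
  from N1 to TYR/PHE/TRP ring centroids within 6.0 Å.
* **Occupancy** -- percent of frames with the monitored distance at or
  under a cutoff (default 3.5 Å).

Summary exports mirror boxplot statistics (median, quartiles, 1.5·IQR
whiskers) plus mean and sd; histograms use 0.1 Å bins.

## Conformational clustering

`pairwise_rmsd_matrix()` computes all-vs-all best-fit RMSD over a selection
(best-fit via the covariance singular values with a proper-rotation sign
correction; near-identical pairs, where the trace formula cancels
catastrophically, are recomputed through the explicit superposition).
`cluster_frames()` applies average-linkage agglomerative clustering,
stopping when the smallest inter-cluster distance exceeds `eps` (default
2.0 Å, the common recipe for conformational ensembles) or at a requested
`k`; occupancies are reported as percentages in descending order and each
cluster's representative is the frame minimizing the mean distance to its
co-members. The $O(F^2)$ matrix is the practical size limit; a `stride`
option subsamples long ensembles.

## Synthetic fixtures, and what they do not show

Every input class has a deterministic generator, so the full pipeline runs
and is tested without downloads:

* `make_toy_peptide()` -- chemically complete extended-chain peptides over
  {A, G, C} from ideal internal coordinates, optionally glutathionylated.
* `make_wobble_trajectory()` -- reference plus i.i.d. Gaussian noise of sd
  $\sigma$ per coordinate; the expected unfitted RMSD is $\sigma\sqrt{3}$,
  which calibrates the RMSD machinery (at $\sigma = 0.2$ Å, 511 atoms, 200
  frames the suite requires agreement within 5%).
* `make_two_state_trajectory()` -- a labelled two-conformer mixture with
  exact deterministic allocation (e.g. 300/200 frames at 60/40), used as a
  planted-partition oracle for clustering.
* `make_esp_grid()` -- Merz--Singh--Kollman-style shells (Fibonacci-lattice
  points on {1.4, 1.6, 1.8, 2.0} × Bondi-radius spheres, points inside
  another atom's shell removed) with the exact Coulomb potential of known
  point charges.

All generators are pure functions of their arguments: a fixed seed
reproduces output bit for bit, and the Mersenne--Twister state of the
caller is restored afterwards.

These fixtures emulate the *statistical* structure the analyses consume --
not force-field physics. Gaussian wobble has no correlated motions, no
solvent, no barriers; a passing wobble calibration therefore validates the
estimator, not any claim about real conformational dynamics. Conversely the
experimental-reference checks (radius of gyration of curated crystal
structures of glutathionylated proteins) do test against reality, but need
the PDB entries locally (`inst/extdata/crystal/README.md`); they are not
redistributed with the package.

## Numerical and design choices

* Alternate locations: highest occupancy wins, ties to the lexicographically
  first altloc -- deterministic and matching common preparation practice.
* Masses come from a built-in IUPAC table keyed by element (mass-weighted
  Rg must work without a topology file); unknown elements are a hard error.
* Coordinates are Å everywhere; atom indices are 1-based everywhere a user
  sees them.
* Hydrogens are read if present and never added outside the grafting
  template; protonation assignment belongs to upstream tools.
* The ESP file dialect is the whitespace antechamber form (counts line,
  nucleus lines, then `V x y z` point lines), Bohr and Hartree/e, with
  1 Bohr = 0.529177210903 Å.
* Parameter-coverage checking canonicalizes type tuples as the
  lexicographically smaller of the forward/reverse forms and falls back to
  the `X-B-C-X` wildcard for dihedrals -- the frcmod matching order.
* Torsions use the atan2 formulation (stable near $\pm 180^\circ$), IUPAC
  sign convention, range $(-180, 180]$. Note the torsion is invariant under
  reading the four atoms backwards; its sign flips under mirror reflection.
* Problem sizes in the shipped tests (10--200 frame fixtures, a 500-frame
  clustering problem, ESP grids of a few hundred points) were chosen as the
  smallest sizes at which the statistical assertions are stable.

## Known limitations

* Terminal reconstruction of incomplete chains is not implemented; inputs
  are assumed complete.
* The shipped CSG template geometry and charges are synthetic stand-ins
  built in code (ideal internal coordinates; normalized analogy charges);
  production work should refit charges from a real QM ESP of the capped
  model compound and keep everything else.
* The grafting builder always places every template atom; partially
  occupied experimental side chains are not reproduced.
* Clustering is average-linkage only, by design; no density-based variants
  and no automatic cluster-number selection.
* Cluster occupancies from other tools depend on their linkage/cutoff
  settings and are not expected to transfer numerically.
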