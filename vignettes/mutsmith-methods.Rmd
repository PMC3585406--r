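---
title: "Methods: conservation-guided variant engineering at desk scale"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: conservation-guided variant engineering at desk scale}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mutsmith)
```

mutsmith implements an in-silico protocol for engineering enhanced-activity
enzyme variants by sequence-information transfer between homologs, with each
analysis stage — alignment-based candidate selection, structure handling,
folding/binding energetics, continuum electrostatics, and elastic-network
dynamics — as a separately testable function. This vignette records the
models, the parameters that matter, and the design decisions taken where the
protocol left the choice open.

## The selection cascade

The candidate list starts from all aligned, non-gap columns where the donor
and acceptor sequences differ (`pairwise_candidates()`). Three filters and
one augmentation follow:

1. **Manual exclusion** (`exclude`, default site 149): sites adjacent to the
   active site or to known disease-causing positions are removed, mirroring
   the structure-based triage a protein engineer applies by hand. Expressed
   as a config list rather than re-deriving the judgment.
2. **Conservation context** (`conservation_context()`): a candidate is kept
   only if its column is not conserved; a column counts as conserved when
   its modal residue frequency (gap included as a 21st category) reaches
   `conservation_threshold`. Sites within `window` (± 2 columns) of a
   conserved column get a `near_conserved` ranking flag but are not
   filtered.
3. **Majority rule** (`frequency_rule()`, threshold 0.5): the donor residue
   must appear in at least half of the homolog sequences. The denominator is
   the full sequence count including gaps — the published per-site counts
   use n = 500 with gaps listed as a category, so percentages are taken on
   the same basis. The rule deletes strictly-below-threshold candidates, so
   a residue at exactly 50% survives.
4. **Coevolving partners** (`correlated_pairs()`): survivors recruit dropped
   sites whose columns covary with them. How the original protocol measured
   "correlated" is not recorded; we use mutual information with
   average-product correction (APC), the standard coevolution statistic,
   with gaps as a 21st symbol. Significance is judged against a
   column-shuffle permutation null (default 200 shuffles), which absorbs
   the finite-sample MI bias (~(k−1)²/2n nats for k symbols) without an
   explicit correction. Because that null is right-skewed, a normal
   mean-plus-z·sd cutoff understates the tail; instead a gamma
   distribution is moment-fitted to the shuffled values and the partner
   must exceed its upper 1e-6 quantile (on the APC-corrected scale). The
   tail probability is set so that the dozen anchor-by-partner tests of a
   cascade run, times generous allowance for tail mis-calibration, keep
   the chance of admitting a spurious partner well below 1% per run,
   while a genuinely coupled pair scores an order of magnitude above any
   such quantile. Below 30 sequences scores are flagged unreliable. With
   only two columns APC is undefined and raw MI is used.

**Why the conserved cutoff is 0.95.** The protocol retained a site whose
modal homolog frequency is 85.6% as "non-conserved", so the conserved
cutoff must sit clearly above 0.856 — including the sampling noise of a
500-sequence alignment, where an 85.6% column's empirical modal frequency
has a standard deviation of ~1.6 points and crosses 0.90 in roughly 0.3% of
draws. The default 0.95 is more than six standard deviations above 0.856
while remaining below typical background conservation (0.97 in the bundled
scenario); a cutoff of 0.90 would sporadically misclassify a site the
protocol kept. Both values remain configurable.

## Structures, mutants, exposure

Structures are atom tibbles read and written through bio3d; alternate
locations resolve to the highest-occupancy copy. Residue numbering follows
the crystal structure; `renumber()` applies the +15 offset to full-sequence
numbering (S165 ↔ S180). The biological dimer is chosen by keeping the
requested chain pair and reporting inter-chain van der Waals overlaps
(`clash_scan()`, tolerance 0.4 Å) — the clash-ridden crystallographic pair
is thereby excluded. The N-terminal dimerization domain (residues 2–109) can
be removed before energy work (`truncate_domain()`); all four engineered
sites lie in the catalytic domain.

`mutate_residue()` performs ideal-geometry side-chain replacement: backbone
atoms never move, Cβ is rebuilt at canonical internal coordinates (Cα–Cβ
1.53 Å, N–Cα–Cβ 110.5°, C–N–Cα–Cβ torsion +122.5°, the L-configuration),
and the target side chain is grown from bundled internal-coordinate
templates. Rotatable χ angles are set by a greedy deterministic scan on a
15° grid minimizing hard-sphere clashes against all atoms outside the
residue (ties break toward the smaller angle). This is adequate for the
solvent-exposed sites the protocol targets; it does not sample backbone
relaxation, and proline (a ring backbone) is refused.

Solvent accessibility uses Shrake–Rupley with a deterministic golden-spiral
point set (default 960 points, probe 1.4 Å); relative SASA divides by a
bundled Gly-X-Gly maximum table and `surface` means rSASA ≥ 0.25. Doubling
the point density moves a helix total by < 0.2%.

`hbond_geometry()` measures H···acceptor distance and donor–H–acceptor
angle, placing missing polar hydrogens by ideal geometry; hydroxyl/thiol
torsions are scanned at 10° toward the nearest acceptor, amide N–H along
the external bisector of the nitrogen's neighbors. Contacts under 3.5 Å
are classified bonded.

## The energy framework

`total_energy()` evaluates five components in kcal/mol: harmonic bonds over
covalent connectivity detected by distance (equilibrium lengths from
covalent radii, k = 300 kcal mol⁻¹ Å⁻²), Lennard-Jones 12-6 with per-element
parameters, Coulomb at internal dielectric 1.0 with the constant
332.0637 kcal Å mol⁻¹ e⁻², a Still-type generalized-Born polar term with
Hawkins–Cramer–Truhlar pairwise-descreened Born radii, and a nonpolar term
γ·SASA. 1-2 and 1-3 pairs are excluded from the nonbonded sums. The GB
intrinsic radius equals the van der Waals radius (no offset), so the
isolated-ion limit is exactly the Born expression
−(332.0637 q²/2a)(1 − 1/ε_out) — the analytic anchor the tests use. Partial
charges come from a compact per-residue scheme: backbone atoms sum to zero
and side chains carry the formal charge on the chemically relevant atoms.

Three bundled parameterizations (`setA`–`setC`, differing in LJ radii/depths
and γ_np) stand in for independent force fields; downstream results are
arithmetic means across the parameterizations used, preserving the
averaging semantics of the original multi-force-field protocol. The raw
magnitudes of the published tables were produced by full force fields after
minimization and are deliberately **not** comparable; only the protocol's
bookkeeping (averages, sums, calibration) is reproduced exactly from the
bundled printed values.

`minimize()` is L-BFGS (via `stats::optim`) over the differentiable vacuum
terms — bonds, LJ, Coulomb, optional harmonic restraints — with analytic
gradients, converging to an RMS per-atom gradient ≤ 0.01 kcal mol⁻¹ Å⁻¹
(cap 5000 iterations). Badly clashed starts first relax under a soft-core
LJ with the interatomic distance floored at 0.8 r_min. GB and the SASA term
are evaluated single-point on the final geometry: their Cartesian gradients
(through the descreening integrals and the surface measure) would dominate
the code for no accuracy gain at this level of theory.

**Folding changes** use the three-residue-segment unfolded proxy: for each
monomer, ΔG_fold = G(folded) − Σ G₃(segments), where G₃ is the energy of the
tripeptide centered on each mutated site, cut from the same coordinates with
neutral (uncapped) termini; the sequence-independent remainder of the
unfolded state cancels between wild type and mutant and is never evaluated.
The reported ΔΔG is ΔG_fold(WT) − ΔG_fold(mut), so **positive = mutant more
stable**, matching the published convention. **Binding changes** are
ΔG_bind = E(dimer) − E(C) − E(D) with monomers either rigidly extracted
(default) or re-minimized, and ΔΔΔ = ΔG_bind(WT) − ΔG_bind(mut), positive =
tighter mutant dimer. Changes within a ±2 kcal/mol neutral band are
classified "no-effect". The two-parameter calibration (`fit_adjustment()`)
is an affine least-squares fit, the only two-parameter family consistent
with the published footnote, and verified against the printed
(raw, adjusted) pairs: fitting the two single mutants and predicting the
third reproduces its printed value to the printed precision.

## Continuum electrostatics

`solve_lpbe()` discretizes ∇·(ε∇φ) − κ̄²φ = −4π l_B ρ on a uniform grid with
φ in kT/e (l_B = e²/4πε₀kT = 560.46 Å at 298.15 K). Defaults are the
published protocol's: 1 grid/Å, 70% fill, ε = 2 (solute) / 80 (solvent),
0.15 M 1:1 salt, probe 1.4 Å, Stern layer 2.0 Å. Choices taken here:

* **Dielectric map**: probe-inflated atom spheres mark the solute; no
  reentrant molecular surface is built (a simplification relative to
  DelPhi-class solvers — thin crevices read as solvent).
* **Ion accessibility**: excluded within atom radius + Stern layer;
  κ̄² = ε_s/λ_D² elsewhere.
* **Charges**: trilinear node spreading. **Boundary**: the sum of
  Debye–Hückel monopoles, so the uniform-dielectric, zero-salt case reduces
  to exact Coulomb boundary data.
* **Iteration**: red-black successive over-relaxation (ω = 2/(1+sin(π/n)))
  to a maximum update below 1e-4 kT/e; exceeding 10,000 iterations is an
  error, not a warning.

Verification uses the two closed forms: a point charge in uniform ε = 80
(relative error < 1% at 5–9 Å off-axis on a 29³ grid) and the dielectric
sphere with Stern layer in salt, whose exterior is
φ(r) = (l_B q/ε_s) e^{−κ(r−a−s)} / ((1+κ(a+s)) r) (error ≲ 2.5% at scale 2).
CUBE files are written with the header in bohr (1 Å = 1.8897259886 bohr) and
values z-fastest; non-orthogonal axes are rejected on read. Surface patches
(the substrate-path regions) are residue lists; their statistics are taken
over grid points within the probe-inflated patch surface plus a 2 Å shell,
excluding solute interior points.

## Elastic network modes

`enm_modes()` builds the standard Cα anisotropic-network Hessian: for node
pairs within the cutoff (default 15 Å, distance-weight exponent 0 = uniform
springs), the 3×3 super-element −γ d̂d̂ᵀ/|d|²·|d|², i.e. the unit-bond outer
product. Eigenvalues below 1e-8·λ_max are rigid-body modes; any valid 3-D
network has six. Perfectly collinear input leaves the transverse directions
without stiffness, so the six-mode bookkeeping cannot apply; the package
warns and reports the degenerate spectrum rather than refusing, since the
spectrum itself is still well-defined (and the linear-chain case is a
useful analytic fixture). Frequencies are
ν = (1/2π)√(γλ/m) with γ in kcal mol⁻¹ Å⁻² (× 0.6947695 → N/m) and the node
mass in Da (× 1.66053907e-27 → kg), reported in GHz. The node mass the
original webserver assumed is not recoverable, so absolute GHz values of our
solver are not compared against the published table; the published
per-force-field values ship as a fixture and only their arithmetic-mean
bookkeeping is reproduced. The default 110 Da is the average residue mass.

Dense eigendecomposition is used throughout: the pipeline's systems are a
few hundred nodes at most, where `eigen()` on the 3N×3N symmetric matrix is
both the implementation and, at small N, the oracle the tests compare
against an independently assembled Hessian.

## The synthetic generators

`synth_msa()` samples alignments column-independently from specified residue
distributions, except for one jointly sampled column pair. The bundled
scenario (`table1_msa_spec()`) emulates the published study conditions: 500
homologs over acceptor sites 145–230; the four engineered sites follow the
printed per-residue counts exactly (with an explicit "other" category where
the printed rows list only the top residues); decoy candidate sites whose
donor residue is in the minority; a gap-dominated column (the published
protocol deleted a site for being gap); and a 175/178 joint distribution
whose integer marginals equal the printed counts while concentrating Glu175
with His178 (all 167 His co-occur with Glu). The reference sequence itself
is one of the 500, as in a real homolog search. The acceptor window
sequence is invented — only the engineered-site residues and the column
statistics are constrained by the study.

What the generator does **not** emulate: phylogenetic correlation between
sequences (each row is independent), indel structure beyond per-column gap
frequencies, and any coupling other than the single specified pair. Passing
the recovery test therefore shows the cascade recovers planted signal under
multinomial sampling noise — not that it would be robust to tree-structured
correlation in real homolog sets.

Toy structures carry exact parameters for the analytic fixtures: ideal-
geometry helices (φ = −57°, ψ = −47°), two-domain dimers with a root-found
cleft width, charged spheres for the Born/Debye–Hückel limits, and spring
chains for the elastic-network oracle.

## Orchestration and problem sizes

`run_pipeline()` runs select → mutate → ddg → bind → pbmap → anm on
immutable inputs; any stage can be skipped, failures abort naming the stage,
and a config + seed pair determines the report byte-for-byte (reports carry
the seed, a config hash and the package version, not timestamps). The test
and demonstration configuration uses 8-residue-per-domain dimers, two
energy parameterizations, a coarse 0.75 grid/Å map and 100-seed recovery
runs — sizes chosen so the full suite exercises every stage in a few
minutes on one CPU while leaving every tolerance analytically justified.

## Known limitations

* Raw folding/binding magnitudes are not comparable to full-force-field
  results; only protocol bookkeeping and sign/limit behavior are validated.
* Rotamer placement is hard-sphere greedy; no backbone relaxation, no
  proline targets, approximate ring closure for aromatics.
* The dielectric map has no reentrant surface; potentials inside narrow
  clefts are systematically closer to solvent values than a molecular-
  surface solver would give.
* The pKa stage only bookkeeps externally supplied titration tables
  (`pka_shift_table()`); no Poisson–Boltzmann titration is attempted.
* Collinear elastic networks are degenerate (warned, not refused).
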