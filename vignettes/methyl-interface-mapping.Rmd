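---
title: "Mapping binding interfaces from methyl-TROSY titration intensities"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping binding interfaces from methyl-TROSY titration intensities}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methylmap)
library(dplyr)
```

## The problem

When a small transcription factor binds a very large partner such as RNA
polymerase (about 400 kDa), classical chemical-shift-perturbation mapping
fails: the complex tumbles too slowly and most signals broaden away.
Methyl-TROSY spectroscopy of [I,L,V]-labeled proteins — only the Ile-δ1,
Leu-δ1/δ2 and Val-γ1/γ2 methyl groups carry ¹H,¹³C on an otherwise
deuterated background — keeps methyl signals observable even in such
complexes. Upon titration with the unlabeled partner, all signals lose
intensity (the complex is simply much larger), but methyls *in the binding
surface* lose more: their protons sit close to partner protons, and the
intermolecular dipole–dipole interactions add relaxation. Intensity losses
therefore encode the binding interface.

`methylmap` implements this analysis as a tested pipeline:

1. **Normalization** — raw peak intensities are divided by labeled-protein
   concentration × number of scans, making points with different
   acquisition settings comparable.
2. **Relative intensities** — for each titration point, $r_i =
   I^{norm}_i(\mathrm{point}) / I^{norm}_i(\mathrm{free})$ per methyl
   probe. Only unambiguously assigned peaks with a usable free-state
   intensity participate; everything else is excluded with a recorded
   reason.
3. **Classification** — at one evaluation point the mean $\mu$ of all
   included $r_i$ is formed and two experiment-specific thresholds are set
   as fractions of it: strongly affected if $r_i < f_s\mu$, slightly
   affected if $f_s\mu \le r_i < f_l\mu$. The fractions are free
   parameters; the shipped profiles are 55 %/75 % (evaluated at the 1:1
   point), 60 %/80 % (at 1:2) and 65 %/85 % (at 1:1), the settings used in
   published RNAP titrations of NusG-NTD, NusE and NusA-NTD respectively.
   Because both thresholds scale with $\mu$, the classification is
   invariant under any common rescaling of intensities, concentrations or
   scan counts.
4. **Residue aggregation** — a Leu or Val counts as affected when at least
   one of its two methyl signals shows the decrease; a residue takes the
   most severe class among its probes; residues with only excluded probes,
   and residue types that carry no probes, are "no-data".
5. **Sequence extension (±2 rule)** — methyl mapping reports only on
   Ile/Leu/Val, so the displayed surface is extended by the two residues
   on either side of each affected Ile/Leu/Val residue, *unless* the
   neighbor is itself an Ile/Leu/Val classified unaffected (direct
   evidence beats proximity). Extensions never seed further extensions and
   never downgrade an affected residue.
6. **Patches** — flagged residues are clustered into spatial patches by
   single-linkage on minimal heavy-atom distance (default cutoff 5 Å, a
   standard atomic-contact scale; configurable). The classification is
   also written onto the structure as B-factor codes (strong = 4,
   slight = 3, extension = 2, unaffected = 1, no-data = 0) so any viewer
   reproduces the colored-surface figure.
7. **Docking preparation** — affected *and* solvent-exposed residues
   (relative SASA ≥ 0.40 by default, the common docking-server practice)
   become "active"; exposed residues with heavy atoms within 6.5 Å of an
   active become "passive"; one ambiguous interaction restraint per active
   residue is written against the partner's active+passive union with a
   2.0 Å effective-distance bound. The 0.40/6.5/2.0 values follow the
   published defaults of data-driven docking servers, which the original
   analyses delegated to; all are configurable.

A second group of functions handles NMR restraint bookkeeping: NOESY
cross-peak classes map to upper distance limits (strong 3.0 Å, medium
4.0 Å, weak 5.0 Å, very weak 6.0 Å), hydrogen bonds contribute a ≤ 2.3 Å
H···acceptor and a ≤ 3.1 Å N···acceptor restraint, restraints are
categorized by residue separation (|Δ| = 0 intraresidual, 1 sequential,
2–4 medium-range, ≥ 5 long-range — the universal convention, which the
published tables use without defining), violations are measured with
$(\sum r^{-6})^{-1/6}$ effective distances for pseudo-atom groups, and
ensemble precision is the mean rmsd to the iteratively superposed mean
structure.

## A worked run on synthetic data

```{r simulate}
scenario <- binding_scenario(seed = 42)
scenario
sim <- simulate_titration(scenario)
```

```{r classify}
mc <- relative_intensities(sim$series) |>
  classify_methyls(f_strong = 0.55, f_slight = 0.75, point = "1:1")
glance(mc)
```

```{r map}
rc <- aggregate_residues(mc, structure_residues(scenario$structure)) |>
  extend_classification()
patches <- cluster_patches(rc, scenario$structure)
glance(patches)
score_recovery(rc, sim$truth)
```

```{r plot, fig.width = 7, fig.height = 3.5}
autoplot(mc)
```

## The synthetic-data generator

Real titration spectra are not recomputable at desk scale, so the package
ships a generator whose defaults define the reference conditions under
which the pipeline is tested.

**Structure.** `toy_fold()` builds an idealized four-helix bundle
(60–130 residues; default 100) with backbone, Cβ and the Ile/Leu/Val
methyl carbons, and a sequence carrying at least 25 methyl-bearing
residues. It is a geometric stand-in, not a refined structure: helices are
ideal (1.5 Å rise, 100°/residue), loops are interpolated, and side chains
point along the outward normal.

**Partner.** The default partner is a shell of carbon atoms molded at
3.0 Å clearance against every heavy atom of the bundle's +x face band
(`partner_shell()`). This emulates the surface complementarity of a much
larger partner enveloping one face. A flat wall (`partner_wall()`) is also
available, but a plane touching only the most protruding side chain makes
the ground-truth interface a handful of scattered tips — a geometry in
which no surface-based classification could succeed, and not what contact
with a 30-fold larger binding partner looks like.

**Ground truth and signal model.** The interface is every ligand residue
with a heavy atom within 5 Å of the partner. Each methyl probe carries a
contact score $s_i = \sum_j (r_0 / r_{ij})^6$ over partner atoms within
10 Å of the methyl carbon ($r_0 = 4$ Å). At a titration point with bound
fraction $p_b$ (two-state binding, solved from the quadratic with
`fraction_bound()`), the noise-free relative intensity is

$$ r_i = (1 - p_b) + p_b \, A \, e^{-\lambda s_i} $$

with a uniform bound-state attenuation $A = 0.5$ (size-dependent signal
loss on complex formation) and broadening amplitude $\lambda = 1$.
Observed intensities multiply in a per-peak gain (log-normal, sd 0.1,
fixed across points — so the normalization and ratio steps are genuinely
exercised) and per-point log-normal noise (sd 0.05), then scale with
concentration and scan count. A tenth of the probes is marked ambiguous to
exercise the exclusion rules. The methyl carbon stands proxy for its three
protons (the background is deuterated, and a single site keeps the model
transparent).

**Binding constants.** The labeled protein is at 20 µM with partner added
at ratios 0/1/2, as in the titrations the package models. The default
dissociation constant is 2 µM: the titrations being emulated show strong
intensity losses already at the equimolar point at 20 µM, which requires
binding well below the sample concentration, and with $K_D = 2$ µM the
bound fraction at 1:1 is 0.73 and interface probes lose 43–73 % of their
intensity — the behavior the generator is meant to caricature. A weak-bind
setting (say $K_D = 50$ µM at the same concentrations) caps the bound
fraction at 0.23, so *no* probe can drop below 75 % of the mean and every
classification is empty; that regime tests nothing and is deliberately not
the default, though `binding_scenario(kd = ...)` accepts any value.

**What the generator does not model.** Chemical exchange in the
intermediate regime — one of the real causes of intensity loss — is not
simulated; the model is a fast-exchange/broadening caricature. Neither are
lineshapes, frequency dimensions, peak overlap, nor relaxation-matrix NOE
effects. Passing the end-to-end tests therefore shows that the *analysis
chain* is correct and recovers a planted interface under realistic noise,
gains and partial binding; it does not validate the spectroscopy itself.

**NOE and ensemble fixtures.** `simulate_noe_peaks()` emits cross peaks
for atom pairs between 1.8 Å (the van der Waals lower bound used for all
generated restraints — closer contacts do not occur in real structures and
would contradict the restraint they generate) and 5.5 Å, binned at
2.7/3.3/4.2 Å so each class's upper limit strictly exceeds the true
distance; restraints generated from a structure are therefore satisfied on
it by construction, which anchors the violation statistics at an exact
zero. `jitter_ensemble()` adds per-atom Gaussian noise plus a random rigid
motion per model, so precision calculations must actually superpose.

## Numerical choices and degenerate inputs

* Classification needs at least 3 included probes; fewer is an analysis
  error (the mean would be dominated by single peaks).
* Ties at a threshold fall into the milder class: the rule is strictly
  "below the threshold".
* The classification mean is computed per evaluation point over included
  probes only; excluded probes can shift $\mu$ only by their absence,
  never resurrect themselves.
* SASA uses Shrake–Rupley sampling with 120 Fibonacci-lattice points per
  atom (doubling changes residue values by < 2 %), probe radius 1.4 Å,
  hydrogens and heteroatoms excluded; relative SASA divides by the Tien
  et al. (2013) theoretical maxima. Unknown residue types get an absolute
  value and an `NA` relative value with a warning.
* Ensemble precision superposes models onto their mean iteratively
  (convergence 10⁻⁶ Å); the backbone set is N/Cα/C′. Both the atom set and
  the rmsd-to-mean convention are configurable because published tables
  use the labels without defining them.
* The rms violation averages over *all* restraints, violated or not, per
  model, then over models — the convention of structure-calculation
  software.
* PDB reading keeps HETATM records, hydrogens and alternate locations but
  flags them; only the highest-occupancy altloc survives. Ensembles must
  have identical atom sets across models. Malformed coordinate fields
  abort with the line number.
* Dihedral restraints are carried as a count in the tally only; deriving
  them from chemical shifts is out of scope.
* The combined distance-restraint total counts hydrogen-bond restraints
  together with NOE restraints; the tally reports both numbers separately
  because published counts quote them both ways.

## Open choices made here

* Sequence extension does not chain, and neighbors that are Ile/Leu/Val
  *without data* (unassigned or excluded) are extended by default — the
  exclusion rule names only *unaffected* ILV neighbors. A switch
  (`include_no_data_ilv = FALSE`) restores the stricter reading.
* Only strong/slight residues seed docking actives; extension-flagged
  residues do not (published active lists contain only directly affected
  ILV residues).
* When a multi-model structure is used for surface figures or docking,
  model 1 is the default.
* The NOE lower bound is fixed at 1.8 Å (van der Waals contact); the
  published rules give only upper limits.

## Problem sizes

The test-suite and acceptance computations use 60–100-residue toy folds,
around 43 methyl probes, ensembles of 3–20 models and a few dozen
restraints — sizes chosen so a full run of every stage, including 20
repeated end-to-end simulations, completes in well under a minute while
still exercising every code path at realistic density.
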