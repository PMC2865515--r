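---
title: "Deciding the zwitterionic character of gas-phase peptide ions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deciding the zwitterionic character of gas-phase peptide ions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(protomerscan)
```

## The problem and the model

A peptide ion in vacuo at net charge $z$ can realize that charge with many
different assignments of protons to its ionizable sites. Each assignment —
a *protomer* — may be a plain state (exactly $|z|$ ionized groups) or a
zwitterion (extra acid/base pairs ionized simultaneously). Which protomer
dominates is decided by the balance of two terms.

**The intrinsic charge-separation penalty.** Transferring a proton from an
acid AH to a base B in the gas phase costs
$$\Delta\Delta G_{\mathrm{sep}} = \mathrm{GA}(\mathrm{AH}) -
\mathrm{GPB}(\mathrm{B}),$$
where GA is the gas-phase acidity of the acid (the gas-phase basicity of
its conjugate base) and GPB the gas-phase basicity of the base, both
positive and of order $10^3$ kJ/mol. The package treats the penalty of a
protomer as additive over its ionized sites,
$$\Delta\Delta G_{\mathrm{sep}}(p) = \sum_{\mathrm{acids}^-}
\mathrm{GA}_i - \sum_{\mathrm{bases}^+} \mathrm{GPB}_j,$$
and reports it relative to the protomer of the same charge state with the
lowest raw penalty (ties all map to zero). The same bookkeeping applies to
proton affinities (PA, the enthalpic part) and bare protonation energies
($\Delta U$). Additivity neglects site–site coupling of the intrinsic
values; that coupling is part of what the conformer energies supplied by
external engines capture, which is why the penalty is a descriptor and not
an energy model.

**Internal solvation.** Ionized groups are stabilized by intramolecular
salt bridges and hydrogen bonds. The census module quantifies this from
3-D conformers: a salt bridge is an ionized acid/base site pair whose
closest acid-O to protonatable-N contact is strictly below 4.0 Å; hydrogen
bonds are (donor, H, acceptor) triples with N/O donor carrying the
hydrogen, N/O acceptor, donor–acceptor distance $\le d_{\max}$ and
D–H$\cdots$A angle $\ge \theta_{\min}$, classified with precedence
sHB (both groups form a detected bridge pair) > iHB (either group
ionized) > HB (neutral).

## Tunable parameters

| Parameter | Default | Units | Rationale |
|---|---|---|---|
| `d_max` | 3.5 | Å | common gas-phase H-bond distance criterion |
| `angle_min` | 120 | deg | excludes incidental contacts, keeps bent bonds |
| salt-bridge cutoff | 4.0 (strict `<`) | Å | contact-pair convention for O···N |
| `window_ps` | 5 | ps | annealing-candidate harvesting window |
| `delta_threshold` | 100 (60 for Trp-cage) | kJ/mol | force-field filter validated by the cross-level retention statistic |
| `n_select` | 60 (35 for Trp-cage) | — | refinement budget, one conformer per energy bin |
| `qm_window` | 10 | kJ/mol | sampling-uncertainty scale at the refined level |

The hydrogen-bond thresholds are deliberately configurable (and recorded
in every census report header): reasonable analyses vary them by a few
tenths of an ångström and tens of degrees, and the classifier isolates
that uncertainty in two arguments.

All energies in the package are kJ/mol; comparisons against printed
integer tables use a ±1 kJ/mol tolerance, since printed values are
rounded.

## The intrinsic tables

`intrinsic_free_amino_acids()` ships GPB/PA/$\Delta U$ of the Lys, Arg,
His and Gln side-chain bases and the Asp and Glu side-chain conjugate
bases, in two limiting conformations: the lowest-energy ("folded")
conformer, in which internal hydrogen bonding stabilizes the charge, and
the extended all-trans ("linear") conformer with that stabilization
removed. `conformer_shift()` exposes the linear-minus-folded differences
(bases lose basicity when unfolded, acids gain acidity cost), and
`entropic_dispersion()` verifies that GPB − PA is nearly constant across
entries (standard deviation below 6 kJ/mol under both the population and
sample conventions), which justifies using energy-based rankings as
free-energy surrogates.

`intrinsic_peptide_scale()` adds terminal-group entries
(`NTER_amine`, `CTER_carboxyl`). These are *reconstructed*: terminal
values are not free-amino-acid observables, so they are solved from the
single-pair anchor rows of the packaged benchmark tables under the
additive model and labelled `reconstructed` in the `source` column. With
this one scale, the package reproduces the relative
$\Delta\Delta U$/$\Delta$PA/$\Delta$GPB columns of the benchmark protomer
tables of all three packaged systems.

The identity of the two acid rows is worth a note: the first acid row is
assigned to Asp because its folded values agree, in all three quantities
independently, with the values implied by the peptide anchor rows that
involve the Asp side chain; the second acid row is assigned to Glu, the
only other acidic side chain in scope.

**Anchor calibration.** `calibrate_anchors()` solves the additive model
from printed relative-penalty rows by least squares. The absolute scale is
not identifiable from relative penalties — within each connected component
of site types co-occurring in rows there is one free additive gauge — so
one site per component is pinned (to 0, or to a supplied prior such as the
free-amino-acid value). Relative penalties of any fixed-charge set are
invariant under that gauge because the ionized acid/base count difference
is fixed at $-z$. Rank deficiency beyond the gauge is reported as an
error naming the unresolved site types rather than silently regularized.

## The selection protocol

The protocol consumes per-conformer energies produced by external engines
via TSV adapters; the force-field and refined stages themselves are out of
scope.

1. `window_minima()` keeps the lowest-energy record of each 5-ps window
   (ties to the earliest time).
2. `threshold_filter()` keeps candidates within `delta_threshold` of the
   minimum (boundary inclusive; the minimum always survives).
3. `stratified_select()` divides $[\min, \min + \Delta_{\mathrm{th}}]$
   into `n_select` equal bins — the bin span is the threshold width by
   default, the observed range as an option, since either reading of
   "equally spaced energy windows" is defensible — and draws one uniform
   member per non-empty bin from a single seeded generator whose seed is
   recorded in run manifests. Bin edges are half-open with the last bin
   closed; empty bins contribute nothing.
4. `rank_protomers()` takes per-protomer minima of the refined energies
   and reports gaps $\Delta E$ to the charge-state minimum. It refuses
   mixed charge states and mixed provenance levels.

`cross_level_retention()` validates the threshold: among refined
conformers within `qm_window` of the refined minimum, the fraction whose
force-field energy exceeds the threshold. A protocol is trustworthy when
this is a few percent at most.

Geometry-optimization convergence metadata (e.g. residual-force criteria)
is carried on records as provenance, never recomputed.

## What the synthetic fixtures emulate — and what they do not

`build_conformer()` realizes a prescribed census with ideal ammonium,
carboxylate, amide and carbonyl templates on a glycine scaffold, one
interaction unit per 25 Å so units cannot cross-talk, contacts placed with
at least 0.25 Å margin to every threshold so a jitter of up to 0.05 Å
cannot flip a classification. `build_landscape()` emulates an 8-ns
annealing energy series as a per-protomer floor plus half a scaled squared
AR(1) process (autocorrelation time 2 ps, amplitude 50 kJ/mol by default):
strictly non-negative above the floor, smooth on the ps scale, with the
series minimum approaching the floor for long durations.

These fixtures prove the *bookkeeping*: that the classifier partitions
correctly, that the pipeline recovers known floor separations (a 0 vs 40
kJ/mol two-protomer landscape is resolved within the protocol's 10 kJ/mol
sampling uncertainty across seeds), and that file round trips are stable.
They do not emulate real conformational ensembles: no Boltzmann
statistics, no rotamer realism, no correlated multi-site geometry. Passing
tests therefore certify the analysis layer, not the physics of any
particular force field or functional.

## Numerical and design choices

* **Enumeration order** is depth-first over sites in declared order with
  states in declared order (first site most significant), so protomer
  lists, downstream seeds and reports are reproducible. Charge states with
  a single protomer are returned as singleton lists; restricting attention
  to charge states with several protomers is a reporting-layer choice.
* **State labels** follow force-field nomenclature (HID/HIE/HIP, ASH/GLH,
  `+`/`0`/`-`), which makes protonation states round-trip through PDB
  residue naming; hydrogen counting on the titratable heavy atoms is the
  fallback inference, and an explicit sidecar file overrides both.
* **Ties** in normalization all receive zero relative penalty; ties in
  window minima resolve to the earliest time; report rows sort by energy
  gap with the pattern string as a stable tiebreak.
* **Degenerate inputs**: empty protomer sets, empty record sets and
  zero-mass structures raise errors rather than returning silent zeros;
  a donor group stripped of hydrogens is skipped with a warning and a QC
  record.
* **sHB membership** is decided at the site-pair level: any hydrogen bond
  whose donor group and acceptor group form a detected bridge pair counts,
  even if the specific atoms differ from the minimal-distance pair. The
  alternative (atom-level) reading would undercount bifurcated bridge
  geometries.
* The benchmark tables include a solution-state reference row in the
  Trp-cage +1 block; it is a reference annotation, not a gas-phase
  protomer, and is excluded from protomer counts.

## Problem sizes

The shipped tests enumerate the full 100-protomer space of the three
packaged systems, verify the census on 200 randomized fixtures and random
50–200-atom structures against an exhaustive all-triples oracle, and run
the pipeline on 8-ns/0.5-ps mock trajectories (16 000 samples per
protomer, 1 600 windows) across 10 seeds. These sizes keep the whole suite
well under a minute on one core while exercising every code path at the
scale the protocol is designed for.

## Known limitations

* The additive penalty ignores conformational coupling between sites and
  uses one intrinsic value per site type; tautomer-specific intrinsic
  differences for neutral His are not modelled.
* Donor/acceptor typing covers the standard ionizable groups and backbone
  N/O; π-interactions, cation–π and C–H···O contacts are out of scope.
* Terminal-group intrinsic values are reconstructions under the additive
  model, not measurements; they are clearly labelled and trivially
  replaceable by a user-supplied table.
* The selection protocol assumes the external refined energies are
  comparable across protomers of one charge state (same level of theory,
  same system composition); it checks provenance tags, not physics.
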