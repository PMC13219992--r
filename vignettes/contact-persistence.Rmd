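---
title: "Contact-persistence analysis of protein–ligand MD trajectories"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Contact-persistence analysis of protein-ligand MD trajectories}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ligstab)
```

## The model

A docking pose tells you where a ligand *can* sit; it does not tell you
whether it *stays* there. ligstab scores the second question from a
molecular-dynamics trajectory of the complex, typically one run at elevated
temperature (e.g. 400 K) as a stress test of the binding mode. The score is
the **R-value**, a smoothed fraction of native contacts:

$$R \;=\; \frac{1}{N}\sum_{ij}
  \frac{1}{1 + \exp\!\big[\beta\,(r_{ij}^{X} - \Lambda\, r_{ij}^{0})\big]}$$

where the sum runs over the $N$ **native contacts** — protein heavy-atom /
ligand heavy-atom pairs closer than 4.5 Å in a chosen reference structure —
$r_{ij}^{0}$ is the pair distance in that reference, and $r_{ij}^{X}$ the
distance in the frame being scored. Each term is a logistic switch: it is
$1$ while the pair stays near its reference separation, crosses $0.5$
exactly at $r^{X} = \Lambda r^{0}$, and decays to $0$ once the contact is
lost. $\beta$ (default 5.0 Å$^{-1}$) sets how sharp the switch is;
$\Lambda$ (default 1.8, dimensionless) sets how much relative stretching a
contact may absorb before it stops counting. The per-frame values are
averaged, unweighted, over the analysis window to give the trajectory
R-value in $(0,1)$: higher means the reference's interaction network
persists.

Because $N$ is fixed for a given reference, averaging per-frame means over
frames equals the mean over the full frames × pairs term matrix; the
implementation exploits this, and a test asserts the commutation.

### Reference modes

The reference that defines the native contacts is a modelling choice, and
the package keeps it explicit:

* `dock` — the initial docking pose: measures whether the *input* pose's
  contacts survive;
* `exp` — an experimental structure: measures retention of the
  experimentally observed network;
* `repr` — the trajectory's own representative frame: measures *intrinsic*
  stability without any external reference, which is what makes the score
  usable in prospective docking where no crystal structure exists.

Contacts are re-identified at the 4.5 Å cutoff on whichever reference is
named; the cutoff is strict (`<`), so a pair at exactly 4.5 Å is not a
native contact.

### Representative-frame selection

For `repr` mode the package must first pick the frame that best represents
the bound ensemble. Every protein–ligand heavy-atom pair is a candidate;
its distance is averaged over the windowed, pooled trajectory, and pairs
with mean distance ≤ 6.75 Å (inclusive) are retained. Each frame's
retained-pair distances form a vector, and the frame minimizing the
Euclidean distance to the ensemble-averaged vector is the representative.
Ties go to the lowest pooled frame index, which makes the selection
deterministic; a test pins this on an all-identical-frames trajectory.

### Analysis window and replica pooling

High-temperature runs need an equilibration prefix discarded. The window is
expressed as a *fraction* (default 0.6 dropped per replica, mirroring the
common practice of analysing the last 40 ns of 100-ns runs) so the method
applies to trajectories of any length. Replicas are windowed individually
and then pooled in file order; all ensemble statistics (contact means,
per-frame R-values, RMSF) are computed over the pooled frames. Pooling
before averaging is the reading consistent with reporting a single
representative per system from a multi-replica campaign; the alternative
(per-replica averages, then averaging those) differs only when replicas
have unequal lengths, and the windowing keeps them equal in the common
case.

## Stability decomposition

Grouping the native contacts by the protein residue owning the
protein-side atom gives the per-residue R-value $R_i$ (mean sigmoid term
over that residue's frames × pairs). Since residues with one persistent
contact and residues with ten are not equally load-bearing, the package
also reports the **contribution** $R_i \times n_i$ (the unnormalized
per-residue R-value, $n_i$ = contact count) and its percentage share.
Two identities hold by construction and are asserted to $10^{-9}$ in the
tests: contributions sum to $N \times R$, and percentage shares sum
to 100.

The same grouping by *ligand* heavy atom produces an atom-level stability
map for lead optimization: each atom is categorized `stable`,
`less_stable`, `unstable`, or `no_contact`. The category cutoffs (0.85 and
0.70 on the atom's mean term) are package defaults chosen to give a
conventional three-color rendering of "holds", "loosens", "lost"; they are
not derived quantities, and both are configurable and echoed in the
output. `no_contact` atoms report a null R-value rather than zero — an
atom with no native contact carries no evidence, which is different from
an atom whose contacts broke.

## Geometry: RMSD and RMSF

Pose similarity is ligand heavy-atom RMSD after optimal (Kabsch)
superposition of the *protein* onto the reference — the ligand is never
re-fitted, so genuine ligand displacement survives the alignment. The fit
selection defaults to protein Cα; Cα is also the RMSF alignment
convention, and reusing it keeps the two measures consistent. (Backbone
fitting is available through the selection argument; on the synthetic
fixtures the difference is nil because the generator keeps the protein
rigid.) No ligand-symmetry correction is applied — a known limitation for
ligands with topological symmetry, where the reported RMSD is an upper
bound.

RMSF aligns every frame to the representative structure, then reports the
per-residue root-mean-square fluctuation of each Cα about its
time-averaged position. Isotropic Gaussian jitter of width $\sigma$ per
coordinate gives RMSF $= \sigma\sqrt{3}$, which the tests recover within
5% at 2000 frames.

## Pose classification and ensemble metrics

Crossing stability with similarity gives four classes: **SS** (stable and
similar), **SD** (stable but dissimilar), **US** (unstable but similar),
**UD** (unstable and dissimilar). The rule is strict on both axes —
stable means $R > 0.70$, similar means RMSD $< 3.0$ Å — so boundary values
fall in the unfavorable class. Both thresholds are configurable, and
`threshold_grid()` reports how global and per-system %SS move as they are
varied, with $\Delta$%SS defined as per-system %SS minus global %SS (the
absolute value is reported alongside, since dispersion in either direction
matters).

Within a docking ensemble, poses are ranked by R-value (ties: lower RMSD,
then pose id — explicit so reruns agree). Ensemble metrics then follow
directly: *top-1 hit* (the docking-score top pose was already native-like
by its initial docking RMSD), *dock success* (any ensemble pose was), and
*rescued* (top-1 failed but the R-ranked pose is SS after MD).

## Stability–affinity correlation

For ligand series binding one site in comparable modes, contact
persistence tracks the dissociation rate, and hence $K_d$; the package
quantifies this as the Pearson correlation between R-value and
$\mathrm{p}K_d = -\log_{10} K_d[\mathrm{M}]$. Three guardrails: complexes
with $R < 0.70$ are excluded as non-native-like before correlating (their
simulated pose no longer represents the binding mode the affinity was
measured for; exactly 0.70 is retained); IC50/Ki values are accepted only
behind an explicit flag, because those assays are not directly comparable
to equilibrium $K_d$; and outlier exclusion is only ever a user-supplied
list, never automatic, so sensitivity analyses with and without an
influential compound are both one call. Per-residue correlations are
computed for both the per-residue R-value and its contribution — figures
in this area are not consistent about which is plotted, so both are always
reported side by side. Residues observed in fewer than three ligands, or
with zero variance, are flagged instead of scored.

## The synthetic generators

No desk-scale test can rerun a millisecond-scale MD campaign, so the
package ships two generator tiers whose ground truth is known by
construction:

* **Distance-level** (`simulate_distance_series()`): each native contact
  is independently *intact* per frame with probability $p$ (distance
  $r^0 + \mathcal N(0,\sigma)$, truncated positive) or *broken* (distance
  $\Lambda r^0 + \Delta + |\mathcal N(0,\sigma)|$, $\Delta$ =
  `broken_offset`). The expected R-value has a closed form — the emission
  densities pushed through the sigmoid, evaluated by quadrature
  (`expected_r_value()`) — and recovery tests require the measured R to
  land within ±0.03 of it at 500 frames for $p \in \{0.2, 0.5, 0.8\}$.
* **Coordinate-level** (`simulate_trajectory()`): a deterministic toy
  pocket (pseudo-residues on a sphere around a small ligand cluster)
  whose ligand undergoes rigid-body jitter plus excursion events with
  probability $1-p$ per frame. The excursion displacement is
  $\Lambda c + \Delta + c$ ($c$ = native cutoff): the tightest translation
  guaranteeing every native contact lands beyond $\Lambda r^0 + \Delta$,
  i.e. the same broken-distance floor the distance tier plants. This tier
  exercises the full pipeline — file round trips, windowing,
  superposition, representative selection.

Exact realization of an arbitrary distance matrix in 3D is infeasible,
which is why the coordinate tier plants persistence via excursions rather
than per-pair distances. Default conditions are 12 replicas × 100 frames
(one frame per ns of a 100-ns run), persistence 0.8 — a mostly-stable
pose, matching the regime the method is designed to discriminate —
in-pocket jitter $\sigma = 0.05$ Å and $\Delta = 5$ Å. All randomness
derives from one seed through named substreams, so adding a generator
never perturbs existing fixtures, and identical configs are bit-identical.

What the generators deliberately do *not* emulate: force-field energetics,
correlated contact breaking (contacts break independently here; in real
unbinding they break cooperatively), protein flexibility (the pocket is
rigid, so superposition is exact and RMSF of protein residues is zero
unless jitter is added), partial-unbinding intermediates, and solvent.
Passing tests therefore demonstrate that the *estimators* are correct on
data with known truth — not that any particular real system is stable.

## Numerical choices

* The sigmoid is evaluated through the logistic CDF (`plogis`), which
  underflows to 0 / saturates to 1 cleanly; the naive `1/(1+exp(x))` form
  overflows once $\beta(r^X - \Lambda r^0) > 710$, which unbound frames
  reach easily. The midpoint anchor $R = 0.5$ at $r^X = \Lambda r^0$ is
  exact, not approximate.
* Kabsch superposition uses the SVD with the determinant sign corrected,
  so reflections are excluded; near-collinear fit selections are rejected
  rather than silently producing an ill-conditioned rotation.
* Representative ties (and ranking ties) are broken deterministically, as
  described above.
* Degenerate inputs fail loudly with typed conditions: zero native
  contacts is an error (`NoNativeContacts`-style), never a silent
  $R = 0$; an empty atom selection is a warning, because some callers
  legitimately probe for emptiness.
* TSV numerics are written with 17 significant digits so a write/read
  round trip is exact to well below $10^{-12}$ relative.

## Problem sizes used in the shipped checks

The test suite and the acceptance script run entirely on the synthetic
generators: toy systems of ≤ 30 atoms and ≤ 20 frames for the
oracle-equivalence sweeps (50 random systems), 500-frame single-replica
series for persistence recovery, 2000 frames for the RMSF sampling check,
and the default 12 × 100-frame coordinate study for the end-to-end run.
These sizes make every statistical tolerance comfortably tight while the
whole suite completes in well under a minute.

## Known limitations

* XTC trajectories are not read; convert to DCD or multi-model PDB
  upstream. (PDB and DCD are read natively, in Å.)
* Frames are assumed whole-molecule imaged by the MD pipeline; no
  periodic minimum-image correction is applied to distances.
* No ligand-symmetry-corrected RMSD.
* The R-value is a contact-persistence descriptor, not a free energy: it
  carries no entropic or solvent terms, and correlations with affinity
  are expected to degrade for flexible pockets or heterogeneous ligand
  series.
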