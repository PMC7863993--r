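---
title: "Benchmarking force fields against QM conformer ensembles: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Benchmarking force fields against QM conformer ensembles: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ffbench)
```

## The problem

A general small-molecule force field (FF) should reproduce, for every
molecule, the optimized geometries and the *relative* energies of its
conformers as computed by a trustworthy quantum-chemical (QM) reference.
`ffbench` takes a QM-optimized conformer ensemble and one re-minimized
ensemble per force field, and quantifies the disagreement molecule by
molecule: in energies, in geometries, and — through a parameter
overrepresentation analysis — in which force-field parameters co-occur with
the worst geometric failures.

## Molecule identity and grouping

Structures are grouped into molecules by the labeled-graph identity of the
QM-optimized connectivity: element, formal charge, bond order, and
(optionally) per-atom stereo flags. Two records belong to the same molecule
exactly when their graphs are isomorphic under these labels, which is
decided by canonical labeling (BLISS, via igraph) of an auxiliary graph in
which every bond is subdivided by a vertex colored with its order. A
tautomer differs in bond orders and hydrogen placement, so it receives a
different key and is analyzed as a distinct molecule — QM optimization can
change tautomeric state, and the pipeline treats the post-optimization
connectivity as authoritative.

Identity comes from the explicit SDF bond table, never from 3-D bond
perception: the same input always produces the same grouping regardless of
toolkit. Whether stereocenters that invert during optimization should split
molecules is genuinely open (upstream pipelines differ); `use_stereo` is a
documented switch, `TRUE` by default so that stereoisomers stay distinct
when flags are present.

Records lacking results for any dataset-wide force field are dropped and
reported, so every downstream comparison runs on the same structure set for
every force field.

## Relative conformer energies

With conformer 0 the molecule's lowest-QM-energy conformer,

$$\mathrm{ddE}_i \;=\; \mathrm{dE}_{FF,i}-\mathrm{dE}_{QM,i}
\;=\;[FF(i)-FF(0)]\;-\;[QM(i)-QM(0)],$$

so any constant offset between energy scales cancels; the reference row is
exactly zero and is excluded from histograms and fraction-within summaries.
Per molecule, the mean signed deviation over the $N$ matched conformers
(reference excluded) is

$$\mathrm{MSD}=\frac{1}{N-1}\sum_{i=1}^{N-1}
\left(\mathrm{dE}_{FF,i}-\mathrm{dE}_{QM,i}\right).$$

Whether $N$ should count conformers before or after matching is a genuine
design choice; here $N$ is the matched count, and the summands are the
matched pairs' deviations. The "fraction within" summary reports the share
of non-reference conformers with $|\mathrm{ddE}|$ at or below a window
(default 1 kcal/mol) with a binomial standard error
$\sqrt{p(1-p)/n}$; the binomial SE is this package's documented
uncertainty convention for these fractions.

Rows with a non-finite FF energy, or with $|\mathrm{ddE}|$ at or above a
pathological cutoff (default $10^4$ kcal/mol), are excluded from all
summaries but retained in a dedicated listing: this is how
hydrogen-collapse-type minimization failures (a polar hydrogen falling into
its parent atom under a missing van der Waals term, with absurd energies)
surface without poisoning the statistics.

## Geometry agreement

**RMSD.** The reported RMSD is the minimum over the molecular symmetry
group of the least-squares (Kabsch) superposition RMSD, hydrogens included,
proper rotations only. Symmetry means graph automorphisms: atom
permutations preserving element, charge and bond order, enumerated by VF2
with a default cap of 10,000; on truncation the identity permutation is
always retained, so a capped result is a valid upper bound and is flagged
as such. For large automorphism groups the minimum is located by a
vectorized closed-form Kabsch evaluation (analytic singular values of the
3×3 cross-covariance) and then confirmed with the exact SVD on the leading
candidates, so reported values are exact, not approximate.

**TFD.** The torsion fingerprint deviation compares internal torsions
only, normalized to $[0,1]$. Published TFD implementations differ in their
selection, period and weighting recipes; this package fixes its own and
claims only the contract, not numeric equality with any other tool:

* one dihedral per non-ring bond whose endpoints are both non-terminal,
  with representative end atoms chosen by highest atomic number then
  lowest index;
* a symmetry period per torsion from terminal-group topology: $360/k$
  degrees when either end carries $k \ge 2$ identical terminal substituents
  (120° for a methyl), otherwise 360°;
* one pseudo-torsion per ring system (fused rings sharing bonds count
  once): the mean signed wrapped deviation over the system's internal
  dihedrals, period 360°; three-membered rings have no internal dihedral
  and contribute nothing;
* per-entry deviation
  $\min(|\Delta\theta| \bmod P,\,P-|\Delta\theta| \bmod P)/(P/2)$;
* Gaussian weights in the topological distance $d$ of the entry's central
  bond from the center of the bond graph (line graph),
  $w\propto e^{-d^2/2\sigma^2}$ with $\sigma=\max(1,\text{bond-graph
  radius})$, normalized to sum to 1.

Degenerate (colinear) quadruples contribute deviation 0 with a warning;
molecules with no torsion entries have undefined TFD and are skipped in
TFD-based analyses.

## Conformer matching

Minimization can hop conformers, so FF conformers are paired to QM
references before the MSD: each FF conformer goes to its nearest QM
reference if that symmetry-aware RMSD is at most the threshold (default
1.0 Å), otherwise it is dropped; when several FF conformers claim one
reference only the lowest-RMSD claimant survives (ties to the lower index);
references left unpartnered are dropped from the matched analysis. This is
deliberately the greedy procedure as described, not an optimal assignment —
an $O(n^3)$ Hungarian assignment is available behind
`method = "optimal"` for sensitivity checks. The matching RMSD is
symmetry-aware with hydrogens included, for self-consistency with the
geometry metrics; heavy-atom-only matching is a conceivable alternative
convention and is deliberately not the default.

## Parameter enrichment

A molecule enters the high-TFD subset when any of its analyzed structures
exceeds the TFD cutoff (default 0.12, a visually chosen boundary between
the bulk of well-reproduced geometries and the deviant tail); molecule-level
TFD is thus the max over that molecule's structures.
For each parameter the representation ratio is the fraction of molecules in
a set applying it at least once (multiplicity within a molecule never
counts). The subset ratio $\hat p$ is tested against the full-set ratio
$p_0$ with the one-sample Z-test for proportions,

$$z=\frac{\hat p - p_0}{\sqrt{p_0(1-p_0)/n}},$$

two-sided p-value, with a Wald interval
$\hat p \pm z_{1-\alpha/2}\sqrt{\hat p(1-\hat p)/n}$ on the sample
proportion (several interval constructions exist for this test; Wald is the
documented choice). A parameter is flagged *significant* only when it is overrepresented
($\hat p > p_0$) — the question is one-directional even though the p-value
is two-sided — and is excluded outright when 20 or fewer subset molecules
apply it, a small-sample rule that avoids significance calls from
inconclusive counts. Substructure tagging
(shipped defaults: N–N single bond, azetidine ring) uses labeled subgraph
isomorphism on elements and bond orders, ignoring charges.

## The synthetic world

`synth_config()` defaults describe the world the tests assert about:

| parameter | default | why |
|---|---|---|
| molecules | 200 | enough groups for stable means, minutes not hours |
| heavy atoms | 4–8 | keeps automorphism groups small, chemistry varied |
| conformers/molecule | 2–10 | matches the few-to-tens regime of curated ensembles |
| energy bias $b$ (kcal/mol) | −1, 0, +2 per FF | the planted signal MSD must recover |
| energy noise $s$ (kcal/mol) | 0.5 | conformer-level scatter around the bias |
| Cartesian noise $\sigma$ (Å) | 0.05 | "minimization barely moves atoms" regime |
| torsion kicks | 3° sd; 60° sd for a 30% high-deviation set | separates TFD below/above the 0.12 cutoff |
| tautomer-flip rate | 2% | occasional identity changes, at most one per molecule |
| collapse rate | 2% | rare pathological records, never a reference conformer |
| planted parameters | 3 ids at 80% vs 30% background | overrepresentation the Z-test must find |

Molecules are random valence-legal graphs grown around a keto fragment
O=C–C(H), which makes the keto→enol tautomer flip (move the alpha hydrogen
onto the oxygen, swap the C=O / C–C orders) always well defined. Geometry
comes from a toy spring-plus-repulsion relaxation — deliberately minimal,
because the analysis contracts, not chemistry, are under test. Conformers
are random torsion draws; rigid molecules emit a single conformer and
near-duplicate draws (< 0.25 Å) are rejected, because the emulated datasets
are explicitly non-redundant and duplicate geometries would be deduplicated
by the matcher by construction. The FF energy bias is planted on *relative*
energies, $FF(i)=QM(i)+C_{mol}+(b+\varepsilon_i)\,[i\neq \mathrm{ref}]$:
planting it on absolute energies would cancel identically in every ddE and
no bias-recovery statement could hold. All randomness flows from one
mandatory seed through named substreams, so reruns are byte-identical.

What a green test therefore establishes: the metrics, matching, accounting
and statistics behave as specified on ensembles with this statistical
structure. What it does not establish: agreement with any real force
field's error distribution, transferability of the TFD recipe's numeric
values to other implementations, or performance on molecules far larger or
more symmetric than the generator produces.

## Numerical choices and edge cases

* Dihedrals are computed in degrees and wrapped to (−180, 180].
* Kabsch uses proper rotations only; reflections are never considered.
* QM-energy ties for the reference conformer break to the lowest input
  index; matching ties break to the lower FF index.
* The bias-recovery acceptance criterion runs on a world without planted
  high-TFD kicks: large kicks make matching cross-pair conformers, which
  injects QM-spread noise that is no part of the $b+\varepsilon$ model the
  criterion states.
* The KDE behind the ddE-vs-TFD scatter density uses a product Gaussian
  kernel with Scott's-rule bandwidths, degenerate (zero-variance)
  directions falling back to unit bandwidth.

## Limitations

No real minimizers, charges, or parameter assignment engines are involved
anywhere; assignment tables are consumed, not produced. Published
benchmarks of this kind run on tens of thousands of structures with
proprietary minimizers and are out of desk-scale reach; nothing here
claims to reproduce any such campaign numerically — the package validates
its machinery on synthetic ensembles with known ground truth.
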