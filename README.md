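# ffbench

Benchmarking small-molecule force fields against quantum-chemical (QM)
conformer ensembles.

Given one SDF file of QM-optimized conformers (with per-record energies)
and one SDF per force field of the corresponding re-minimized conformers,
`ffbench` answers, per force field and per molecule:

* **Energy agreement** — the relative conformer-energy difference
  `ddE_i = [FF(i) − FF(0)] − [QM(i) − QM(0)]`, anchored at the molecule's
  lowest-QM-energy conformer; per-molecule mean signed deviations (MSD)
  over matched conformers; fraction of conformers within an energy window;
  per-force-field extrema with a separate listing of pathological records
  (e.g. hydrogen-collapse minimization failures with absurd energies).
* **Geometry agreement** — symmetry-aware minimum RMSD (Kabsch over the
  graph automorphism group, hydrogens included) and a torsion fingerprint
  deviation (TFD) in [0, 1].
* **Conformer matching** — each FF conformer is paired to its nearest QM
  reference within an RMSD threshold (default 1.0 Å), duplicates
  deduplicated, unmatched references dropped — so energy comparisons are
  made between corresponding minima.
* **Parameter enrichment** — which force-field parameters are
  overrepresented among molecules with poorly reproduced geometries
  (TFD above a cutoff, default 0.12), via representation ratios and a
  one-sample Z-test for proportions (`z = (p̂ − p₀)/√(p₀(1−p₀)/n)`), with
  Wald confidence intervals and a ≤20-molecule small-sample exclusion.

Molecules are grouped by canonical labeled-graph identity (element, charge,
bond order, optional stereo flags) of the *post-optimization* connectivity,
so tautomers are distinct molecules. A seeded synthetic-data generator
emits complete benchmark datasets — molecules, QM ensembles, per-FF
perturbed geometries and biased energies, parameter assignments — with
known ground truth, so the entire pipeline is testable offline.

## Worked example

```r
library(ffbench)

cfg <- synth_config(n_molecules = 30L, conformers = c(2L, 6L), seed = 1L)
dataset <- generate_benchmark(cfg, out_dir = "demo")   # qm.sdf, ff_*.sdf, ...
bundle  <- run_pipeline(dataset$records,
                        assignments = dataset$assignments, seed = 1L)
bundle
#> <report_bundle> 32 group(s), 3 force field(s); 345 energy rows, 0 dropped record(s)
```

32 groups from 30 molecules: two records changed tautomer and are analyzed
as distinct molecules. The three synthetic force fields carry planted
energy biases of −1, 0 and +2 kcal/mol (noise 0.5 kcal/mol), which the
summaries recover:

```r
bundle$within_table
#>     ff threshold   fraction         se  n
#> 1 ff_a         1 0.50000000 0.05590170 80
#> 2 ff_b         1 0.90361446 0.03239355 83
#> 3 ff_c         1 0.02409639 0.01683218 83

aggregate(msd ~ ff, bundle$msd_table, function(x) round(mean(x, na.rm = TRUE), 3))
#>     ff    msd
#> 1 ff_a -0.882
#> 2 ff_b -0.053
#> 3 ff_c  2.147
```

The unbiased field keeps 90% of conformers within 1 kcal/mol of QM; the
+2 kcal/mol field keeps almost none, and the per-molecule MSDs sit near
each planted bias. The extrema table isolates the three planted
hydrogen-collapse records instead of letting them poison the ranges:

```r
bundle$extrema$summary
#>     ff    min_dde   max_dde n_pathological
#> 1 ff_a -2.3522421 0.1204088              3
#> 2 ff_b -1.3831371 1.2952514              0
#> 3 ff_c  0.9570413 3.4547259              0
```

At 30 molecules the high-TFD subset is too small for significance calls —
every parameter falls under the ≤20-molecule exclusion, by design. The test
statistic itself on a realistic subset size:

```r
proportion_z_test(p_hat = 0.5, p0 = 0.2, n = 25)
#> $z
#> [1] 3.75
#> $p_value
#> [1] 0.0001768346
#> $ci_low
#> [1] 0.3040036
#> $ci_high
#> [1] 0.6959964
```

At the default scale (200 molecules, ~60 high-TFD molecules) the pipeline
flags the generator's three planted parameters as significantly
overrepresented and none of the 25 background parameters — this is
asserted by the acceptance suite.

## Command line

```sh
Rscript exec/ffbench synth --config cfg.yaml --out data/ --seed 7
Rscript exec/ffbench run --qm data/qm.sdf --ff ff_a=data/ff_ff_a.sdf \
    --assignments data/assignments.csv --rmsd-threshold 1.0 \
    --tfd-cutoff 0.12 --within 1.0 --out report/ --seed 7
```

The report directory contains CSV tables (energy table, geometry metrics,
match report, per-molecule MSD, ddE histograms, ddE-vs-TFD scatter with
KDE densities, enrichment report) plus `metadata.json` with thresholds and
versions.

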