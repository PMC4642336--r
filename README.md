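# methylmap

Mapping protein binding interfaces from methyl-TROSY titration
intensities.

## What it does, and for whom

When a small protein (a transcription factor, say) binds a very large
partner such as RNA polymerase, the complex is too big for classical NMR
chemical-shift mapping — but the methyl signals of an [I,L,V]-labeled,
deuterated protein (Ile-δ1, Leu-δ1/δ2, Val-γ1/γ2) survive. On titration
with the unlabeled partner every signal weakens, and methyls **in the
binding surface weaken more**, because intermolecular dipole–dipole
contacts add relaxation. `methylmap` turns per-peak intensity tables from
such titrations into a residue-level map of the binding surface, and
carries the result through to docking restraints. It is written for NMR
spectroscopists and structural bioinformaticians doing interface mapping
of protein complexes that are too large for conventional approaches.

The core statistic: after normalizing intensities by protein
concentration and scan count, relative intensities
*r*<sub>i</sub> = *I*<sub>i</sub>(point)/*I*<sub>i</sub>(free) are formed
per methyl probe, their mean *µ* over all unambiguously assigned probes
is taken at one evaluation point, and probes are classified

* **strongly affected** if *r*<sub>i</sub> < *f*<sub>s</sub>·*µ*,
* **slightly affected** if *f*<sub>s</sub>·*µ* ≤ *r*<sub>i</sub> <
  *f*<sub>l</sub>·*µ*,

with experiment-specific fractions (*f*<sub>s</sub>, *f*<sub>l</sub>),
e.g. (0.55, 0.75). A Leu/Val residue is affected when at least one of its
two signals is. The surface is extended by the two residues on either
side of each affected Ile/Leu/Val (unless that neighbor is an unaffected
Ile/Leu/Val), clustered into spatial patches, written onto the structure
as B-factor codes, and converted — together with Shrake–Rupley solvent
accessibilities — into active/passive residue selections and ambiguous
interaction restraints for data-driven docking.

The package also covers NMR restraint bookkeeping: NOE class → upper
bound (3.0/4.0/5.0/6.0 Å), hydrogen-bond restraints (H···A < 2.3 Å,
N···A < 3.1 Å), sequence-separation categories, r⁻⁶ effective-distance
violation statistics against multi-model ensembles, and ensemble
coordinate precision (rmsd to the iteratively superposed mean). A
synthetic-data generator (toy fold, molded partner surface, two-state
binding, contact-dependent broadening, per-peak gains, noise) makes every
stage testable without external data.

## Worked example

```r
library(methylmap)

scenario <- binding_scenario(seed = 42)   # synthetic ground truth
scenario
#> <binding_scenario> 100 residues, 48 methyl probes, 48 interface residues
#>   Kd 2 uM, 20 uM labeled, ratios 0/1/2, lambda 1, A 0.5, sigma 0.05, seed 42

sim <- simulate_titration(scenario)
mc <- relative_intensities(sim$series) |>
  classify_methyls(f_strong = 0.55, f_slight = 0.75, point = "1:1")
glance(mc)
#>   point n_probes n_included n_excluded    mu t_strong t_slight n_strong n_slight n_unaffected
#> 1 1:1         48         43          5 0.520    0.286    0.390        9        4           30
```

Of 48 methyl probes, 43 are usable; the mean relative intensity at the
1:1 point is 0.52 (the complex is large, so everything dims), and probes
below 0.286 (55 % of the mean) are called strongly affected — 9 of them,
plus 4 slight.

```r
rc <- aggregate_residues(mc, structure_residues(scenario$structure)) |>
  extend_classification()
glance(cluster_patches(rc, scenario$structure))
#>   patch n_residues    x    y    z
#> 1     1         37 5.64 1.31 17.6

score_recovery(rc, sim$truth)
#>   precision recall    f1 n_predicted n_truth
#> 1         1  0.771 0.871          37      48
```

The affected-plus-extension residues form a single contiguous patch of 37
residues, all of which lie in the planted 48-residue interface
(precision 1.00, recall 0.77, F1 0.87). `autoplot(mc)` draws the
per-residue intensity profile with the mean and both thresholds;
`annotate_classification()` writes the class-coded structure for any
molecular viewer.

Restraint bookkeeping reproduces published-style totals directly from
per-category counts:

```r
restraint_tally(counts = c(intraresidual = 329, sequential = 386,
                           medium_range = 321, long_range = 471),
                n_hbond = 58, n_dihedral = 193)
#>   intraresidual sequential medium_range long_range noe_total hbond distance_total dihedral
#> 1           329        386          321        471      1507    58           1565      193
```

A command-line interface wraps the same pipeline
(`inst/scripts/methylmap simulate|map-surface|prep-docking|gen-restraints|validate-ensemble`,
with `--config`/`--seed`/`--profile`/`--out` flags and YAML
configuration).

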