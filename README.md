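# pacedys

In silico comparison of left bundle branch pacing (LBBP) and leadless
right-ventricular septal pacing (LCPM) on ventricular dyssynchrony.

Patients with high-degree AV block need ventricular pacing, and the two
modern options enter the ventricles very differently: LBBP recruits the
specialized His–Purkinje system, while a leadless pacemaker stimulates
working septal myocardium. `pacedys` simulates single-beat biventricular
activation for both families of protocols — proximal/distal left bundle
pacing and leadless pacing at the RVOT-septum, mid-septum and apical
septum — under three conduction substrates: intact left bundle conduction,
proximal left bundle branch block (LBBB), and a transmural septal scar that
deactivates the overlapping His–Purkinje fibres. It is intended for
computational electrophysiology work at "desk scale": a full 19-heart
synthetic cohort crossed with 18 scenarios runs in minutes on one core.

## The model in brief

Activation is first arrival under transversely isotropic conduction.
With fibre direction $f$, conduction velocities $v_f = 0.6$ m/s along and
$v_t = 0.24$ m/s across the fibre, a mesh edge of length $L$ and direction
$d$ costs

$$ t = L\,\sqrt{(d\cdot f)^2/v_f^2 + \bigl(1-(d\cdot f)^2\bigr)/v_t^2}, $$

the path-metric (dual) form of the anisotropic Eikonal equation. A
fascicular His–Purkinje tree (three LV fascicles, RV septal fascicle and
moderator band) conducts at 3 m/s and couples to the endocardium through
Purkinje–myocardial junctions with anterograde/retrograde delays
(10/3 ms defaults), in both directions — paced wavefronts can re-enter the
tree and travel retrogradely. The coupled problem is solved exactly as one
shortest-path pass over the union graph.

Per heart and scenario the package reports, in ms:

* **VEU** — mean LV minus mean RV epicardial activation time (positive:
  LV later);
* **absolute VEU** — |VEU|, per heart before any averaging;
* **LVDI** — SD of LV activation times;
* **BIVAT-90** — shortest interval activating 90% of both ventricles;

with valve-ring and RV outflow regions excluded from all measures, and
cohort statistics (mean ± SD, Shapiro–Wilk-routed t / Wilcoxon rank-sum
tests, combined LBBP vs combined LCPM groups).

## Worked example

```r
library(pacedys)

spec  <- cohort_spec(n_hearts = 19, seed = 1)    # 2 mm target edge length
heart <- generate_heart(spec, 1)                 # mesh + UVC + fibres
tree  <- build_tree(heart$mesh, heart$uvc, tree_params(seed = 98))
regions <- metric_regions(heart$mesh, heart$uvc)

# junctional-escape baseline: stimulate the His root
act <- solve_coupled(heart$mesh, tree, conduction_config(),
                     data.frame(kind = "tree", node = tree$root, onset = 0))
compute_metrics(act, regions)
#> VEU 19.2 ms | |VEU| 19.2 ms | LVDI 20.0 ms | BIVAT-90 63.9 ms (0 unreached)

# proximal LBBP with proximal LBBB: the tree cannot reach the right bundle,
# the RV activates late through myocardium, and VEU flips negative
lb <- run_scenario(heart, tree, "LBBB", "PLBBP", conduction_config())
compute_metrics(lb$act, regions)
#> VEU -22.3 ms | |VEU| 22.3 ms | LVDI 18.5 ms | BIVAT-90 76.2 ms (0 unreached)

# mid-septal leadless pacing under the same substrate delays the LV instead
ms <- run_scenario(heart, tree, "LBBB", "MS", conduction_config())
compute_metrics(ms$act, regions)
#> VEU 30.0 ms | |VEU| 30.0 ms | LVDI 29.6 ms | BIVAT-90 92.7 ms (0 unreached)
```

The signs carry the physiology: under LBBB, left bundle pacing leaves the
RV waiting on slow cell-to-cell conduction (negative VEU, RBBB-like),
while septal myocardial pacing leaves the LV waiting (positive VEU), and
LBBP keeps LV activation far more homogeneous (LVDI 18.5 vs 29.6 ms).

A full cohort experiment — 19 hearts × 18 scenarios, with a metrics table,
a protocol-by-substrate summary shaped like a clinical results table, and
group comparisons — is one call:

```r
res <- run_cohort(default_config(), out_dir = "cohort_out")
```

`cohort_out/` then contains `metrics.csv` (one row per heart × scenario),
`summary_table.csv`, `comparisons.csv`, the resolved `config.yaml`, a run
log and a JSON manifest; re-running the same config reproduces the CSVs
byte for byte. A thin CLI with `run`, `validate` and `metrics` subcommands
is installed at `inst/cli/pacedys`.

The methods vignette
(`vignettes/pacing-dyssynchrony-model.Rmd`) documents the geometry
generator, the Purkinje growth rule, the solver's metrization error bound,
the scar model and the statistical conventions.

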