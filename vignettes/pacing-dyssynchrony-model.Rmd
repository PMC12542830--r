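---
title: "Simulating ventricular activation under conduction-system and leadless septal pacing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating ventricular activation under conduction-system and leadless septal pacing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The question the package addresses

Patients with high-degree atrioventricular block need ventricular pacing.
Two modern strategies differ in where the wavefront enters the ventricles:
left bundle branch pacing (LBBP) stimulates the specialized His–Purkinje
conduction system directly, while a leadless pacemaker (LCPM) screwed into
the right-ventricular septal endocardium stimulates working myocardium.
`pacedys` simulates single-beat biventricular activation for both families
of protocols across three conduction substrates — intact left bundle
conduction, proximal left bundle branch block (LBBB), and a transmural
septal scar involving the His–Purkinje system — and quantifies the
resulting interventricular and intraventricular dyssynchrony on a seeded
synthetic cohort of hearts.

Four measures are computed per heart and scenario, all in milliseconds:

* **VEU** (ventricular electrical uncoupling): mean LV epicardial minus
  mean RV epicardial activation time. Positive values mean the LV
  activates later (an LBBB-like pattern), negative values an RBBB-like
  pattern.
* **absolute VEU**: |VEU|, always taken per heart *before* cohort
  averaging, so that opposite-signed hearts do not cancel.
* **LVDI**: the standard deviation of activation times within the LV
  (population form, N denominator — the simulated field is exhaustive, not
  a sample; a sample-SD switch exists).
* **BIVAT-90**: the shortest interval containing activation of 90% of the
  biventricular nodes, read literally as a sliding-window minimum over the
  sorted times. A "90th percentile minus minimum" variant is available
  (`method = "quantile"`), as is inverse-density volume weighting; the
  windowed, unweighted form is the default.

Nodes around the AV valve ring and the RV outflow tract are excluded from
every region before any metric is computed. These regions still *conduct* —
only the measurement ignores them. Under the scar substrate the
non-conducting core is likewise excluded: infarcted tissue never activates
and is not part of the viable myocardium the measures describe.

## The activation model

Myocardium is a transversely isotropic conduction medium: 0.6 m/s along
the local fibre direction and 0.24 m/s across it, with the His–Purkinje
tree conducting at 3 m/s. Activation is first arrival. On the mesh this
is computed as a shortest path over the element edge graph, where an edge
of length $L$ and direction $d$ against local fibre $f$ costs

$$ t(L, d) = L \sqrt{\frac{(d \cdot f)^2}{v_f^2} + \frac{1 - (d\cdot f)^2}{v_t^2}}. $$

This is the Riemannian (dual-metric) edge length consistent with a front
that propagates at $v_f$ along and $v_t$ across the fibre. The distinction
matters: using the front-normal speed profile
$v(d)^2 = v_f^2 (d\cdot f)^2 + v_t^2 (1-(d\cdot f)^2)$ directly as an edge
speed lets zig-zag paths outrun the physical transverse wave by over 30%,
because that expression is the speed of a *plane front* whose normal is
$d$, not the cost of *travelling* along $d$. Both forms agree exactly
along and across the fibre, which are the two calibrated directions.

### Mesh metrization error

A graph geodesic can only overestimate the continuum first arrival, and
the overestimate depends on how well the edge direction set covers the
sphere. The Kuhn (six-tetrahedra) subdivision used by the generator is
directionally asymmetric — each cube face carries one diagonal — which
alone would cost up to $\sqrt{2}$ in unfavourable directions. The solver
therefore augments the edge graph with each complete lattice cell's
complementary face and body diagonals, recovering the full
26-neighbourhood direction set, whose worst-direction overestimate is
$\sqrt{1 + (\sqrt2-1)^2 + (\sqrt3-\sqrt2)^2} \approx 1.128$. Along lattice
axes the times are exact, which is why planar-wave speed recovery along
and across the fibre reproduces the configured velocities to well within
5% (see `tests/testthat/test-acceptance.R` and `scripts/acceptance.R`).
Augmented diagonals conduct only when *every* element of their cell
conducts, so they can never leak across a scar-core boundary.

### Tree–myocardium coupling

Purkinje–myocardial junctions (PMJs) couple the tree to the endocardium
with an anterograde (tree-to-muscle) delay of 10 ms and a retrograde delay
of 3 ms by default. These delays are not reported by clinical pacing
studies; the defaults are typical of Eikonal–His-Purkinje modelling and
are configurable, including to zero. Coupling is bidirectional: a paced
myocardial wavefront that touches a PMJ re-enters the tree and can travel
retrogradely — this is what lets a wavefront climb the left bundle into
the right bundle when the left fascicles are destroyed by scar.

The default coupled solver runs one Dijkstra pass over the union graph
(mesh arcs, unblocked tree arcs, directed PMJ arcs), which is exactly the
fixed point of the physically intuitive alternating scheme
(tree solve → anterograde transfer → myocardial solve → retrograde
transfer, repeated). The alternating scheme is also implemented
(`method = "alternating"`); it decreases times monotonically and converges
in at most #PMJ + 2 rounds, and the test suite checks both that bound and
exact agreement between the two methods, plus exact agreement with an
independent brute-force Dijkstra on randomized small instances.

## The synthetic cohort

The experiment is run on a cohort of healthy adult biventricular
anatomies. The generator builds each heart from truncated nested
ellipsoids sharing a septal wall: an LV shell, an RV shell displaced
toward +x whose cavity is the part of its endocardial ellipsoid beyond the
LV septal surface, a basal truncation plane, a valve-ring exclusion band
(4 mm below the base) and a supero-anterior RV outflow exclusion region.
Shape parameters (cavity radii and lengths, wall and septal thicknesses,
truncation fraction) are drawn per heart from configurable normal
distributions with means in the normal adult range (LV cavity radius
22 mm, long axis 50 mm, LV wall 9 mm, septum 10 mm, RV wall 4 mm) and
~5–8% coefficients of variation, seeded so a cohort is bit-reproducible.
Meshing is a regular lattice with Kuhn subdivision; the lattice spacing is
0.75× the requested edge length so the *median* edge (axes plus
diagonals) matches the target. The default target is 2 mm — coarser than
the ~1 mm resolution typical of patient-specific electrophysiology
meshes, chosen so a full 19-heart, 18-scenario cohort runs in minutes on
a laptop core.

Universal ventricular coordinates (UVCs) are assigned at generation time:
apicobasal ρ is linear in the long-axis coordinate (0 apex, 1 base);
rotational φ is the angle about the LV long axis with the septal centre at
0 and the branch cut (±π) on the LV lateral free wall; transmural τ is the
normalized geodesic wall depth between the tagged endocardial and
epicardial surfaces (for the septum: LV endocardium → RV septal
endocardium). The geodesic construction was preferred over a purely
analytic transmural coordinate because lattice boundary nodes do not lie
exactly on the analytic ellipsoids, and the wall-depth form guarantees
τ = 0 and τ = 1 exactly on the tagged surfaces — which the scar
transmurality predicate and the fibre rule rely on.

Fibres follow a rule-based transmural helix: the helix angle varies
linearly from +60° at the endocardium to −60° at the epicardium in the
local circumferential–longitudinal frame. The linear helix is the
standard rule-based stand-in for unavailable patient-specific fibre
architecture, and its angles are exposed as parameters.

What the synthetic cohort deliberately does **not** emulate: atria and AV
valve anatomy (every protocol simulates complete AV block, so atrial
geometry is electrically inert), trabeculation and papillary muscles,
patient-specific septal curvature, and image-derived scar geometry. Cohort
results are therefore read as *orderings and signs* across protocols and
substrates — which protocol uncouples more, in which direction — never as
patient-level millisecond predictions.

## The His–Purkinje network

The tree is grown on the endocardial surfaces. The His trunk enters high
on the RV septal endocardium (ρ ≈ 0.92) and descends to the
His–left-bundle junction (ρ ≈ 0.85); the left bundle crosses the septum
and descends the LV septal endocardium to a split point (ρ ≈ 0.78) where
the three LV fascicles (anterior, septal, posterior) originate; the right
bundle continues down the RV septal endocardium to a moderator-band
take-off (ρ ≈ 0.74) from which a free-running segment crosses to the RV
free wall; the RV septal fascicle continues down the septum. The anterior
and posterior fascicles first run along a basal corridor (above the
default scar's upper edge, as proximal bundles run superficially and
superiorly) to φ ≈ ±0.95 rad and then plunge toward their territories.
Each fascicle ends in a peripheral arbor: a shortest-path tree from the
fascicle's territory centre to seeded target nodes in its UVC territory,
each terminal becoming a PMJ (default ≥ 40 per fascicle). The growth rule
is deliberately simple and parameter-compatible with fractal-growth
generators from the literature; territories, waypoints and densities are
configuration, not anatomy claims.

Lesions act on this graph. Proximal LBBB blocks the single edge joining
the His trunk to the left bundle, bidirectionally — pacing the left bundle
then cannot reach the right bundle through the tree, reproducing the
delayed RV activation that makes LBBP-under-LBBB uncouple negatively.
Scar deactivation blocks every tree edge whose midpoint lies inside a
scar-core element (point-in-tetrahedron, boundary ties resolved into the
core) and removes PMJs anchored at nodes fully inside the core.

## Substrates, protocols and the scar

The scenario matrix crosses three substrates with six protocols
(junctional-escape baseline plus five pacing configurations), 18 scenarios
per heart. Pacing sites: PLBBP at 10% of the left bundle (just distal to
the junction, hence distal to a proximal block — left bundle capture is
selective), DLBBP at the posterior-fascicle origin, and the three leadless
sites on the RV septal endocardium at ρ = 0.90 (RVOT-S), 0.50 (MS) and
0.15 (AS). All sites are configurable; mesh sites resolve to the nearest
tagged surface node in UVC space with lowest-index tie-breaking, and the
resolved nodes are recorded in the run output.

The default scar core spans ρ ∈ [0.10, 0.68] over the septal angular range
φ ∈ [−1.3, 1.3] and transmural depth τ ∈ [0, 0.85] — from the LV septal
endocardium deep into the septum, sparing a thin RV subendocardial rim.
The rim reflects the clinical situation being modelled: septal leadless
pacing remains feasible in patients with septal scar, so the scar model
must not abolish the RV septal subendocardium where the device screws in. A
fully transmural predicate (τ up to 1) is available and is exercised in
the tests; with it, mid-septal pacing is correctly rejected as infeasible.
The border zone is the core predicate dilated by 0.07 in ρ (0.21 in φ)
and conducts at native velocity by default; a CV multiplier exists for
sensitivity analyses. With the default geometry the scar severs all three
LV fascicle plunge routes; narrowing the angular range to
φ ∈ [−1.3, 0.45] spares the anterior route (which plunges at φ ≈ 0.95),
and LBBP then recovers much of its effect — the package reproduces this
viability split as a configured variant rather than as emergent
patient-to-patient anatomy.

## Statistics

Cohort summaries are mean ± SD over hearts (sample SD). "Combined LBBP"
pools PLBBP and DLBBP, "combined LCPM" pools RVOT-S, MS and AS; pooling
averages the member protocols within each heart first, then summarises
across hearts (the alternative flat pooling is available and recorded in
the output when chosen). Comparisons run Shapiro–Wilk on both groups and
use a two-tailed unpaired Student's t-test when both pass (α = 0.05),
otherwise a Wilcoxon rank-sum test; groups smaller than three, or
constant, go straight to the rank-sum test with a warning, and a
completely tied comparison reports p = 1. The tests are unpaired even
though scenarios share hearts, as is conventional when protocol groups
are treated as independent arms; a paired option is provided and clearly
marked as the non-default alternative.

## Numerical choices and degenerate inputs

* Unreached nodes carry an `Inf` sentinel, exported as empty CSV fields
  and as −1 in VTK scalars; metrics refuse to compute over unreached
  viable nodes rather than impute.
* Stimuli inside non-conducting tissue are dropped with a warning; if none
  remain the map is all-unreached.
* The coupled fixed point is declared converged when no time improves by
  more than 1e-9 ms; exceeding #PMJ + 2 rounds is an internal error, not a
  tolerance failure.
* Mesh-site resolution breaks UVC-distance ties by lowest node index;
  branch-fraction sites take the first node at or beyond the requested
  fraction, so fraction 0 is the branch origin.
* Degenerate shape draws (wall ≥ cavity radius, no RV cavity) abort heart
  generation with an actionable message rather than producing a sliver
  mesh.
* Edge fibre direction is the mean of the conducting incident elements'
  fibres; an antiparallel degenerate mean falls back to the first
  incident element.

## Problem sizes

The shipped configuration runs 19 hearts at a 2 mm target edge
(~50,000 nodes, ~300,000 structural edges per heart) through 18 scenarios
each, in roughly three minutes on one core; the validation suite's
randomized solver-equivalence instances use ~150-node slabs where an
O(n²) reference Dijkstra is convenient. These sizes were chosen as the
smallest at which the cohort orderings are stable and mesh-convergence
effects are documented, not as limits of the implementation.

## Known limitations

* Activation only: no repolarization, no ECG, no membrane kinetics, and
  no mechanics — conclusions are about activation-time dyssynchrony.
* The synthetic anatomy supports cohort-level orderings, not
  patient-level magnitudes; at the default 2 mm resolution absolute LVDI
  and BIVAT-90 run systematically higher than at 1 mm because Purkinje
  coverage is sparser and the chamfer overestimate adds a few percent.
* The fibre rule and Purkinje layout are standard stand-ins with exposed
  parameters, not reconstructions of any specific heart.
* Scar is binary (core/border) in UVC space; heterogeneous conductivity
  within the core is out of scope.
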