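---
title: "Modelling a kinetic skull as a multi-loop spatial linkage"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling a kinetic skull as a multi-loop spatial linkage}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(skullkin)
```

## The model

`skullkin` treats a kinetic skull as a spatial parallel mechanism: a
connected graph of rigid links (skeletal elements and soft-tissue struts)
joined by idealized joints. Four joint primitives are available — revolute
(1 DoF), universal (2), spherical (3) and prismatic (1) — and compliant
elements such as ligaments and muscles are modelled as struts: two
half-links joined by a prismatic slide with a spherical joint at each end,
so a strut transmits a length constraint while leaving the connected bones
otherwise free and contributing one internal long-axis twist DoF.

The analytic mobility of a mechanism with $n$ links, $j$ joints and summed
joint freedoms $\sum f_i$ is the spatial Chebychev–Grübler–Kutzbach count

$$ M = 6\,(n - 1 - j) + \sum_i f_i , $$

and the number of independent loops of the connected link/joint graph is
$j - n + 1$. Because the CGK formula undercounts for overconstrained
geometries (the classic example being a planar four-bar evaluated with the
spatial formula), the package carries an independent numeric oracle:
`numeric_mobility()` evaluates the loop-closure constraint Jacobian over all
joint coordinates and reports its null-space dimension (singular values,
relative threshold $10^{-8}$). Where the two disagree, the geometry is
special and the numeric answer is the physically meaningful one.

### The catfish-like fixture

`build_catfish_fixture()` constructs a bilaterally symmetric skull linkage
with eleven bones — a fixed neurocranium; left and right suspensorium,
mandible, operculum and hyoid; a midline urohyal; and a pectoral-girdle
unit — plus three struts: the left and right interoperculomandibular (IOM)
ligaments (mandible to operculum) and the sternohyoideus (urohyal to
girdle). Its census is 17 links (11 bones + 3 struts × 2 half-links),
21 joints (12 bone joints + 3 × 3 strut joints), summed joint DoFs 49
(28 + 21), five independent loops, and CGK mobility 19, which the numeric
oracle confirms at the reference and at random nearby conformations. The
five loops are anatomically interpretable: the two jaw–ligament–operculum
circuits, the mandibular-symphysis circuit, the hyoid–urohyal midline ring,
and the sternohyoideus circuit through the girdle.

The joint-type assignment is a design choice of the fixture (real
assignments would be estimated per articulation with
`fit_joint_model()`/`select_joint_model()`): hinges at the
cranio-suspensorial and cranio-girdle articulations, spherical joints at the
jaw, symphysis, suspensorium–hyoid and hyoid–urohyal articulations, and
universal (2-DoF) opercular joints. Two alternative assignments we explored
(universal jaws with a revolute symphysis, or spherical cranio-suspensorial
joints) satisfy the same census arithmetic but are kinematically
pathological: either the input chart loses rank at the symmetric reference
or the ligament loops become overdetermined and the mechanism locks at tiny
amplitudes. The shipped assignment keeps the input chart full-rank
(condition number about $10^4$) and leaves a physiologically wide feasible
motion range.

Two geometric details matter and are deliberate. First, joint axes are
tilted off the anatomical axes, as in real skulls; perfectly axis-aligned
axes place the bilaterally symmetric reference posture near a kinematic
singularity. Second, the IOM ligament attachment sites are placed (by a
small optimization run once during design) so that opercular rotations and
mandibular depression are first-order *tangential* to the ligament line —
rotation swings rather than stretches the ligament — while the mandible's
spin about its jaw-to-symphysis axis retains a ~3 mm/rad lever on ligament
length. Without this property the ligament-length DoFs are effectively
frozen and realistic gape cycles have no closed assembly.

### Parameterization

The 19 DoFs carry the labels A–S, grouped as: three strut length changes
(A, L: the IOM ligaments; B: the sternohyoideus), four midline asymmetries
(C, D: urohyal pitch/yaw against the sternohyoideus line; E: girdle
rotation; F: urohyal pitch against the right hyoid), four opercular
rotations (G, H left; M, N right), mandibular depression (I), suspensorial
abduction (J), hyoid depression (K), and five long-axis twists (O–S) of the
links with spherical joints at both ends: the three struts and the two
hyoid bars. Which joint coordinates serve as inputs is itself a numerical
design decision: among the label-respecting choices we selected the chart
that maximizes the smallest singular value of the dependent-coordinate
Jacobian at the reference, because a poorly chosen chart (even a full-rank
one) makes the dependent solve ill-conditioned and folds appear at small
amplitudes.

Forward kinematics (`forward_kinematics()`) sets the 19 labelled inputs and
solves the 30 dependent coordinates from the five loops' closure equations
(an axis-angle rotation residual and a translation residual per loop) by
Levenberg–Marquardt with an analytic screw-based Jacobian, warm-started
from the previous conformation; assembly branches are therefore selected by
continuation, never by global search. The closure tolerance is $10^{-8}$
(mm and rad). Failed cold starts fall back to ramped continuation from the
initial conformation.

## Fitting the mechanism to motion

`fit_mechanism_frame()` estimates the free input parameters of one frame by
minimizing the RMS distance between model-animated fit points (three
landmarks per marked element) and their observed positions. The optimizer
is Levenberg–Marquardt with an analytic Jacobian obtained from the implicit
function theorem on loop closure: if $A$ and $B$ are the closure Jacobians
with respect to dependent and free coordinates, the sensitivity of the
dependent coordinates is $-A^{-1}B$, and fit-point sensitivities chain
through the joint screws. Two numerical safeguards matter in practice:

* a tiny ridge penalty (weight $10^{-4}$) tethers the parameters to their
  warm-start values; it is orders of magnitude below the fit-point
  sensitivities, so identified parameters are unaffected, but it pins
  combinations the fit points barely constrain, which otherwise
  random-walk along near-null directions from frame to frame;
* a fit is skipped (or discarded in favour of its initialization) when the
  initial residual is already at numerical zero, because a refit there only
  injects differentiation noise.

`sequential_freeze()` implements the DoF-importance scan: starting from the
parameterization's a-priori freeze mask, it fits the full trajectory once
(each frame warm-started from the previous), sets every parameter's freeze
value to its mean over that trajectory, selects the most disparate frames
by greedy maximin on the observed fit-point configurations, and then
repeatedly freezes whichever remaining free DoF increases the error
statistic the least, refitting the sampled frames after each freeze, down
to the zero-DoF (akinetic) model. Ties break in label order, so runs are
reproducible. The greedy cost defaults to the median pointwise error
(matching box-plot style summaries) and can be switched to the mean. Each
step records one error per fit point, marked element and sampled frame —
with three fit points, five reported elements and fifteen frames, 225
measures per step. The default frame-sample size is 15; in our synthetic
experiments larger samples did not change the ranking. Note one subtlety:
the nested-model argument guarantees that each frame's *summed squared*
error cannot decrease as DoFs are frozen, so the per-step overall RMS is
monotone; the median of pointwise errors can redistribute slightly and is
reported rather than asserted.

Three benchmarks judge how many DoFs suffice (`sufficient_dofs()`): the
tracking precision of the marker data (`precision_metric()`: RMS deviation
of each element's marker configuration from its consensus over 50 random
frames, after rigid alignment), the inter-individual variation
(`procrustes_consensus()`: RMS deviation of homologous landmarks from a
generalized least-squares consensus, reported in mm — scaling is off by
default), and the percent-of-error-range scale (`percent_scale()`)
anchored at the best (highest-parameter) and worst (akinetic) models.
`sufficient_dofs()` also reports the bilateral-equivalent count: a
unilateral model whose retained opercular DoFs have unmeasured right-side
twins counts those twins when expressed bilaterally (a 5-DoF unilateral
model is bilaterally a 7-DoF model).

## Motion patterns

The five primary traces (mandibular depression, suspensorial abduction,
hyoid depression, opercular abduction, opercular flaring out) are scanned
for event windows of 0.5 s around gape and/or flaring peaks
(`detect_events()`; peaks closer than half a window merge). Event
classification (`classify_event()`) is an explicit quantitative surrogate
for what is, in practice, expert labelling; all thresholds live in
`classify_thresholds()`:

* *rostrocaudal*: substantial gape, peak order mandible then
  suspensorium/hyoid then operculum;
* *caudorostral*: flaring leads and the order reverses;
* *compressive*: gape below 10% of the other amplitudes and hyoid
  elevation preceding flaring;
* *slow open*: gape rise time above 250 ms (measured on the full trace,
  since slow openings begin before the event window);
* *unknown* otherwise.

Peak times use the centroid of the half-maximum lobe after zero-phase
10 Hz smoothing, which keeps the ordering decisions stable under in-band
noise of up to ~20% of each trace's amplitude. Classified events are
aligned at peak gape (rostrocaudal, slow open) or peak flaring
(caudorostral, compressive) and aggregated pointwise
(`align_and_aggregate()`), optionally together with the rostrocaudal prey
velocity (`prey_velocity_rc()`: zero-phase smoothing then central
differences; positive is caudally directed).

## The synthetic-data generator

`generate_wave_trajectories()` produces Gaussian bump-train trajectories
for all 19 parameters, with class-specific amplitudes, stage lags (default
20 ms) and widths (default 80 ms), per-event amplitude (5%) and timing
(3 ms) jitter, and a class-matched prey-velocity template: a sharp caudal
pulse at peak gape for rostrocaudal waves, a slower rostral pulse ~100 ms
after peak flaring for caudorostral waves, and an order-of-magnitude
smaller caudal pulse for compressive waves. The peak amplitudes (0.3 rad
gape, 0.15 rad flaring, 0.12 rad hyoid depression and opercular abduction,
0.04 rad suspensorial abduction, −0.5 mm sternohyoideus shortening, 0.2 mm
ligament length change, 0.005 rad for the residual DoFs) are
order-of-magnitude choices fixed once from the fixture's feasible motion
range with a 1.3× margin — the source traces for real fish are not
available numerically, so these values are explicitly *not* measurements.

`simulate_recording()` runs forward kinematics over a trajectory, rigidly
attaches markers (the three fit points plus offset markers) to the marked
left-side and midline elements, and observes them with isotropic Gaussian
noise and optional missingness; a single seed determines everything. The
study-like noise level is 0.08 mm. `make_individual()` scales the geometry
isotropically and adds bilaterally symmetric landmark jitter to emulate
inter-individual variation.

What the generator deliberately does not emulate: skeletal non-rigidity,
tracking outliers and gap structure from occlusion, asymmetric behaviour,
soft-tissue wobble of markers, and hydrodynamic coupling between skull
motion and prey motion (the prey track is a kinematic template, not a flow
solution). Passing tests on synthetic data therefore validate the
*machinery* — geometry, solvers, bookkeeping, classification rules — not
the biological fidelity of any particular real recording.

## Problem sizes and runtime choices

The shipped tests and examples use one to two feeding events at 300 Hz
(a few hundred frames), subsampled threefold for trajectory fits, 15
disparate frames per freeze-scan step, and 200 events for the
classification-robustness property. A full 11-DoF freeze scan at these
sizes runs in about a minute on one core; forward kinematics costs a few
milliseconds per warm-started frame.

## Known limitations

* The fixture's joint-type assignment and geometry are one defensible
  choice among several; census invariants are enforced, but alternative
  assignments require re-checking chart conditioning.
* Strut lengths and girdle rotation are only weakly identified unless the
  girdle carries markers; the fixture therefore marks it, and the ridge
  penalty keeps the weakly identified directions anchored.
* The dependent-coordinate chart loses validity at folds of the
  configuration space; large uncoordinated parameter jumps can fail even
  though a solution exists on another branch. Warm-started trajectories
  are unaffected.
* Classification thresholds are a documented surrogate for expert
  labelling, not estimates of any published rule.
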