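# skullkin

Fish skulls are not simple lever systems: a suction-feeding catfish moves
more than a dozen skeletal elements — suspensoria, mandibles, opercula,
hyoid bars, urohyal and pectoral girdle — that are wired together by joints
and soft-tissue links into a single multi-loop *parallel mechanism*.
`skullkin` is an R toolkit for modelling that kind of system from
marker-based motion data: it fits joint models to the relative motion of
bone pairs, assembles link/joint graphs, counts loops and degrees of
freedom, poses the whole mechanism by constrained forward kinematics, asks
which degrees of freedom a recorded behaviour actually uses, and classifies
the cranial expansion-wave patterns that accompany prey transport.

It is aimed at comparative biomechanists working with XROMM-style rigid-body
data, and at anyone who needs a tested, pure-R implementation of multi-loop
spatial linkage analysis.

## The model in brief

A mechanism with `n` links, `j` joints and summed joint freedoms `Σf` has
the spatial Chebychev–Grübler–Kutzbach mobility

    M = 6 (n − 1 − j) + Σf

and `j − n + 1` independent loops. Ligaments and muscles enter as struts —
spherical–prismatic–spherical chains — so each contributes a length DoF and
a long-axis twist. Built in is a catfish-like five-loop skull fixture: 11
bones + 3 struts = 17 links, 21 joints, `Σf = 49`, 5 loops, mobility 19,
with its 19 DoFs labelled A–S (strut lengths, midline asymmetries,
opercular rotations, mandibular depression, suspensorial abduction, hyoid
depression, and five long-axis twists). An independent numeric oracle
(the null space of the loop-closure constraint Jacobian) confirms the
analytic count and flags overconstrained special geometries where the CGK
formula undercounts, such as a planar four-bar evaluated spatially.

On top of the kinematics sit the analysis tools: a sequential DoF-freezing
scan that fits the mechanism to motion data and freezes, one at a time, the
degree of freedom whose loss costs the least fit error (producing an
error-versus-DoF curve down to the akinetic model), benchmarks for judging
sufficiency (tracking precision, Procrustes inter-individual variation, and
a percent-of-error-range scale), and a rule-based classifier for
rostrocaudal, caudorostral, compressive and slow-open cranial waves with
their associated rostrocaudal prey-velocity profiles. A seeded
synthetic-data generator emulates the whole observation chain — wave-
patterned DoF trajectories, forward kinematics, unilateral markers with
0.08 mm noise — so every stage is testable without animal data.

## Worked example

```r
library(skullkin)

fx <- build_catfish_fixture()
fx$mechanism
#> Mechanism: 17 links (fixed: neurocranium), 21 joints, 5 loops
#>   summed joint DoFs: 49; CGK mobility: 19
#>   strut half-links: iom_L_a, iom_L_b, iom_R_a, iom_R_b, sh_a, sh_b
numeric_mobility(fx$mechanism)
#> [1] 19

# a seeded synthetic feeding bout: three wave classes, 0.08 mm marker noise
traj <- generate_wave_trajectories(
  lapply(c("rostrocaudal", "caudorostral", "compressive"), wave_spec),
  n_events = 3, fs = 300, seed = 42)
rec <- simulate_recording(fx, traj, sigma = 0.08, seed = 43)

round(precision_metric(rec$markers, n_frames = 50, seed = 44), 4)
#>     mandible_L suspensorium_L    operculum_L        hyoid_L        urohyal
#>         0.0911         0.0999         0.1006         0.0990         0.1002
#>         girdle
#>         0.0941

traces <- dof_traces(rec$truth, fs = rec$fs, prey_velocity = traj$prey_velocity)
ev <- classify_events(traces)
ev[, c("event_id", "class", "t_ref_s")]
#>   event_id        class   t_ref_s
#> 1        1 rostrocaudal 0.8947195
#> 2        2 caudorostral 2.0978251
#> 3        3  compressive 3.3469953
```

The precision benchmark reads the injected 0.08 mm marker noise back at the
expected scale (with four markers per element the per-landmark RMS after
rigid alignment is about 1.2 sigma), and the three events are recovered
with their generating classes and alignment times. Aggregating the
rostrocaudal events confirms the constructed prey kinematics — a caudal
velocity pulse peaking at peak gape:

```r
ag <- align_and_aggregate(traces, ev, "rostrocaudal")
ag$t_rel_s[which.max(ag$mean_preyvel)]
#> [1] 0    # peak prey velocity at the gape-aligned origin, +250 mm/s
```

For the DoF-usage analysis, freeze the eight unmeasurable DoFs (the five
twists O–S and the right-side L–N, as a unilateral marker set dictates) and
run the scan:

```r
param <- freeze_parameters(fx$param, c("L","M","N","O","P","Q","R","S"))
curve <- sequential_freeze(fx$mechanism, param, rec$targets_by_frame,
                           fx$fit_points, n_sample = 15,
                           head_length = fx$head_length,
                           error_bodies = fx$error_bodies)
summary(curve)   # error (mm and %HL) and percent scale per freezing step
plot(curve)      # box plots of the 225 error measures per step
```

A command-line wrapper with `simulate`, `mobility`, `freeze-scan`,
`classify` and `run` subcommands is installed at `inst/cli/skullkin`.

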