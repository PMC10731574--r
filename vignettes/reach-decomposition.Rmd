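---
title: "Decomposing reaching movements with a simplified marker set"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decomposing reaching movements with a simplified marker set}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(reachcomp)
```

## The model

`reachcomp` quantifies *how* a seated person achieves a reach, not just how
far. Two tasks are analyzed: a forward reach (hand transported anteriorly
to a target) and a hand-to-mouth reach (hand raised toward the chin). Both
are described purely at the marker level — no joint angles are estimated,
which is exactly what makes a 10-marker clinical setup sufficient.

The primitive is the **pelvis-calibrated displacement**: for marker $m$ and
task axis $a$ (Y = anterior for forward reach, Z = vertical for
hand-to-mouth),

$$D(m) = \big[p_m(t_{end}) - p_m(t_{start})\big]_a -
         \big[p_{troch}(t_{end}) - p_{troch}(t_{start})\big]_a$$

with the reaching-side greater trochanter as pelvis reference. Any motion
shared by the whole body (the chair shifting, the pelvis sliding) cancels
exactly; the test suite asserts this invariance to 1e-9 mm.

The total reach is then split *telescopically* along the marker chain:
each component is the displacement of one chain marker relative to the next
more proximal one, so the components sum to the total as an algebraic
identity, not as an empirical approximation. Components are signed: a
negative cervical-flexion contribution simply means the chin moved away
from the hand. Percentages are the components over the measured total, and
therefore sum to 100.

Two modelling approximations are inherited from the method and worth
keeping in mind:

* **Shoulder abduction** is read as the *vertical elevation of the humeral
  epicondyle relative to the acromion*, assuming a constant
  acromion–epicondyle distance. Shoulder *flexion* also elevates the
  epicondyle (by $L(1-\cos\theta_{flex})$), so part of a flexion-driven
  movement is attributed to "abduction". The suite quantifies this leakage
  rather than hiding it (`test-simulator.R`).
* **Trunk flexion** moves the whole arm chain; on a deeply leaning trunk
  the hanging arm's forward extent relative to the acromion can shrink, so
  the shoulder/elbow component of a trunk-dominated reach can be small or
  negative. This is the marker-level definition working as designed.

## Percent denominator

The protocol description normalizes contributions "by arm length", but each
group's published percentage set sums to 100.0–100.1, which is only
guaranteed when the denominator is the trial's own measured total. The
package defaults to `denominator_mode = "measured_total"` and keeps
`"arm_length"` (using the subject's upper-extremity-length metadata) as an
option for protocol fidelity; in that mode percentages do not sum to 100.

## Pipeline parameters

| parameter | default | units | rationale |
|---|---|---|---|
| low-pass cutoff | 6 | Hz | conventional for reaching kinematics at 60 Hz capture; zero-phase 4th-order Butterworth, so no temporal lag in endpoints |
| window threshold | 0.05 | fraction of peak speed | standard velocity-threshold onset/offset rule |
| sustain | 3 | frames | crossings shorter than this (50 ms) are jitter |
| peak-speed floor | 20 | mm/s | below this the trial is declared motionless |
| gap interpolation | 0.2 | s | short optical occlusions are filled linearly at read time and flagged; longer gaps stay `NaN` |
| degenerate-total floor | 20 | mm | percentages of a near-zero total are meaningless |

Window detection is *peak-anchored*: the reach is the sustained
above-threshold run of end-effector speed that contains the global speed
peak. A plain "first sustained crossing" rule proved fragile — filtered
marker noise near the trial boundary can exceed 5% of peak for a few
frames — whereas the peak-anchored variant is identical on clean data and
robust at the device's stated noise levels. Because the decomposition uses
only the *endpoint positions* (the published quantities are start-to-end
differences; speed and smoothness are explicitly out of scope), small
window misplacements land in the rest padding and barely move any
component.

Numerical notes: the Butterworth design uses the bilinear transform with
prewarping; zero-phase filtering runs forward and backward with odd
extension and steady-state initial conditions, so constant signals pass
through unchanged to machine precision and no startup transient
contaminates the window endpoints. The filter's measured frequency
response is checked against its analytic $|H|^2$ in the tests. Ties in
window detection resolve to the earliest qualifying frame.

## The simulator: what it emulates, and what a green test proves

The generator is a seated kinematic chain — trunk (trochanter→C7), lateral
shoulder offset (C7→acromion, plus a pure vertical girdle-elevation
translation), upper arm, forearm, and a chin offset off C7 — driven by
minimum-jerk rest-to-rest programs over seven degrees of freedom. Default
segment lengths (trunk 450, shoulder offset 180, upper arm 300, forearm
330, chin (60, 120) mm) put the acromion→MP distance at 630 mm, about 88%
of a 717 mm upper-extremity length, i.e. the MP joint sits ~88% of the way
to the fingertip — consistent with adult anthropometry; all lengths are
overridable and are rescaled per simulated subject. Marker noise is
i.i.d. Gaussian per frame/axis at the capture device's stated error
(defaults 2.0/1.1/1.65 mm on X/Y/Z; worst case 2.4/1.7/1.7 used in the
robustness tests).

Cohort presets draw per-subject DOF end values from truncated normals. The
*healthy* preset is arm-dominant; the *stroke* preset reduces
shoulder/elbow excursion and elevates trunk flexion (forward task,
end angle ~N(18°, 10°) truncated to [0°, 45°]) and abduction + girdle
elevation (hand-to-mouth). These numeric ranges are design constants: no
subject-level kinematics were ever published, so calibrating them to
reproduce the published group means would be circular. Only the
*direction* of the group differences is anchored to the published pattern,
and that is all the acceptance criterion asserts.

Consequently a green cohort test establishes that the pipeline *recovers a
known strategy difference at realistic noise*, not that the simulator
reproduces real stroke kinematics. Real data differ in ways the generator
does not model: soft-tissue marker artifact (non-Gaussian, correlated),
sub-movements and corrective jerks, inter-trial variability within a
subject, trunk-restraint effects, and actual clavicular kinematics (girdle
elevation is modelled as pure translation).

The simulator also provides the independent oracle: evaluating the chain
at a program's exact start/end poses and applying the component formulas
directly, bypassing sampling, filtering and windowing. Noise-free pipeline
runs must match it to 1e-6 mm — for that comparison the pipeline runs with
filtering off and threshold 0 (both documented limiting cases), because a
5% velocity threshold by construction trims the first and last ~0.02% of a
minimum-jerk ramp (~0.04 mm of a 300 mm reach): well inside the ≥99%
displacement-capture property, but far above 1e-6 mm.

## Design choices on genuinely open points

* **Marker count**: the protocol names six anatomical sites but ten
  markers; bilateral placement of the four paired sites (6 + 4 = 10) is the
  only consistent reading and is what the vocabulary implements.
* **Calibration side**: "the greater trochanter" is not sided in the
  protocol; the reaching-side trochanter is used, for proximity to the
  measured chain.
* **Start/end events**: whether the original start position was an event
  marker or a quiet-stance frame is unstated; the velocity rule is a
  documented substitute, and the window object records its detection rule.
* **Statistics**: the pooled-variance Student test is the default because
  it is the named method, despite unequal group sizes; Welch is available
  and recommended for real analyses. No multiplicity correction by default
  (per-component α = 0.05), Holm optional.
* **One row per subject per task**: whether repeated trials were averaged
  upstream is unstated; averaging is left to the caller.
* **Axis signs**: only axis *names* are fixed by convention (X lateral,
  Y anterior, Z vertical); signs are chosen so forward distance and
  elevation are positive, and X positive toward the reaching side after
  canonicalization (left-side trials are mirrored; the decomposition uses
  only Y and Z, so mirroring is exactly neutral).

## Limitations

No joint angles, no speed/smoothness/accuracy metrics, no inverse
dynamics — by design, these need richer marker sets. C3D support covers
little-endian float-data files (the modern default); integer-scaled or
DEC-era files raise an explicit error. The stacked-bar figure is a
reporting aid, not a statistical display: error structure lives in the
comparison table.
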