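---
title: "Methods: a static-equilibrium bite model from dissection data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a static-equilibrium bite model from dissection data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(jawforce)
```

## The model and its assumptions

`jawforce` treats the mandible as a rigid third-class lever in static
equilibrium. Each masticatory muscle is a single force vector from the
centroid of its mandibular insertion towards the centroid of its cranial
origin; its magnitude is the architecturally maximal tetanic force,

$$F^{3D}_i = \frac{F_{MS}\, MM_i\, c}{FL_i\, d_M},$$

i.e. muscle stress $F_{MS}$ times PCSA, with a mass correction $c$ for
preservation loss. The force is projected into the sagittal plane
($F^{2D}_i = F^{3D}_i \sin\varphi_i$, with $\varphi_i$ the angle to the
mediolateral axis), the moment of the projected force about the condyle
is balanced against a reaction at the bite point, and the jaw-closing
contributions of both body sides are summed:

$$F_{calc} = 2 \sum_{i\,\in\,\text{closers}}
  \frac{D_{I\!-\!C,i}\,\sin\theta_i\,F^{2D}_i}{D_{C\!-\!BP}}.$$

Assumptions worth keeping in mind: purely rotational temporomandibular
joint (no translation), mirror-symmetric bilateral activation (hence
the factor 2 and the cancellation of mediolateral components), full
simultaneous tetanic activation of all closers, no force–length or
pennation (RPCSA) effects, rigid bone. Whether a muscle is a closer is
decided by the sign of its computed moment about the condyle at the
current gape — in the shipped didelphid example the lateral pterygoid
emerges as the single jaw opener among the modelled muscles and is
excluded from the sum, as is the digastric by its architectural role
whenever it is present.

## Parameters, units, defaults

| parameter | unit | default | why |
|---|---|---|---|
| muscle stress $F_{MS}$ | N·cm⁻² | 30 | classical vertebrate specific tension |
| density $d_M$ | g·cm⁻³ | 1.0518 | head-muscle estimate; 1.0597 / 1.0564 / 1.0582 / 1.0558 are documented alternatives, override via `model_constants()` |
| mass correction $c$ | — | 1.692 | average mass loss after formalin fixation and long ethanol storage |
| gape step | degrees | 0.5 | resolution of the optimal-gape search |
| sensitivity fraction | — | 0.05 | one-at-a-time ±5% perturbations |

Masses stay in g and fibre lengths in mm at every interface; fibre
lengths are converted to cm inside the formulas so that areas come out
in cm² and forces in N at the magnitudes practitioners expect. Angles
are degrees at every interface and radians internally.

A deliberate asymmetry: `pcsa()` reports the *preserved* cross-section
(no mass correction), while `f3dmax()` applies the correction. This is
the combination under which both the recorded PCSA table and the
recorded force table of the example dissection are reproduced
simultaneously, and it keeps PCSA a property of the measured specimen
rather than of a reconstruction.

## Geometry, rotation, and the two input pathways

The skull frame is x = anteroposterior (+ anterior), y = dorsoventral
(+ dorsal), z = mediolateral; the sagittal plane is x–y. Gape changes
are rigid rotations of the mandibular landmarks (insertions, bite
points) about the mediolateral axis through the condyle; positive
rotation opens the jaw (the tooth row swings ventrally). After every
rotation *all* action lines are re-derived from the rotated
coordinates, so both $\theta_i$ and $\varphi_i$ evolve with gape: the
3D pull direction changes as the insertion moves relative to the fixed
origin. (At 0° the two conceivable conventions — re-deriving $\varphi$
or freezing it — coincide, so closed-mouth results are unaffected by
this choice; we re-derive because the physics says the vector changes.)

When no landmark coordinates exist — the common case for published
records, which print angles and resultants but not coordinates —
`bite_model()` accepts a geometry-free table of $(\varphi_i, \theta_i,
D_{I-C,i})$ plus out-levers. Rotation is then unavailable, and moment
signs must be supplied (default: closer) or overridden with `exclude`.

## The synthetic-geometry generator

`generate_geometry()` inverts the angle derivation: insertions are
placed at their in-lever distance from the condyle, the sagittal pull
direction is the in-lever direction rotated by $\theta$ in the closing
(or opening) sense, and the 3D direction is tilted out of plane to meet
$\varphi$; the origin sits a fixed distance along that direction. Two
quantities are unconstrained by the targets and are fixed a priori:
the insertion–origin distance (10 mm — a plausible centroid separation
for a ~30 mm skull) and the insertion placement rays, which provably
cannot affect any model output because the whole construction is
equivariant under rotation about the mediolateral axis. Optional
relative Gaussian jitter (`noise_sd`, seeded) perturbs every landmark
proportionally to its distance from the condyle.

`marmosa_synthetic_geometry()` applies this to the shipped *Marmosa
murina* record: the recorded tables fix the angles and, through the
per-muscle resultants, the ratio in-lever/out-lever and the
incisor/m4 out-lever ratio (2.337) — but no absolute length. We set
the incisor out-lever to 14 mm, a realistic condyle–incisor distance
for this species, and back-solve the in-levers (≈2–4 mm, anatomically
sensible). At 0° gape this fixture reproduces the recorded mechanics
exactly by construction. Away from 0° its behaviour is *emergent*: with
the a priori 10 mm origin distance the bite force rises to a peak at
12.5° gape, about 2.5% above the closed-mouth force — qualitatively the
single-digit-degrees optimum reported for the real animal, though the
recorded optima (5.5–6.5°) depend on true coordinates that were
never released and are therefore not reproduction targets. What passing
tests show is that the pipeline recovers prescribed geometry exactly
and behaves correctly under rotation; they cannot validate the
unpublished skull shape itself.

`generate_architecture()` draws masses and fibre lengths from
log-normals centred on the example dissection's scale (median mass
0.02 g, sd(log) 0.5; median fibre length 3.5 mm, sd(log) 0.2), chosen
so that simulated PCSAs fall overwhelmingly inside the observed
0.011–0.149 cm² range.

## Gape sweep, calibration, sensitivity

The sweep evaluates the model every 0.5° (configurable) and by default
stops at the first decrease, reporting the previous angle — a rule
that presumes a unimodal profile. `full_sweep = TRUE`
scans to `max_gape` (default 60°) as a guard against early local
maxima; on plateaus the smallest maximising gape wins, a deterministic
tie-break. Architecture-derived forces are gape-independent (no
force–length relation); only geometry changes with gape.

Calibration exploits the exact linearity of $F_{calc}$ in $F_{MS}$:
the closed form $F_{MS}^* = F_{MS}\,F_{alive}/F_{calc}$ is the default,
and a bisection mode (interval 0.1–200 N·cm⁻², force tolerance
0.001 N) reproduces the iterative increase/decrease search; linearity
makes the two agree to the loop tolerance regardless of starting
point. Calibration is performed at the optimal gape by default
(`at = "closed"` for comparison).

Sensitivity perturbs, per muscle, each of the six parameters (in-lever,
$\theta$, mass, fibre length, $\varphi$, and the out-lever *within that
muscle's term only*) multiplicatively by ±5% and reports the percent
change of $F_{calc}$. The structure is analytic: linear parameters move
the force by exactly ±5% of that muscle's force share, angle entries
follow sine ratios, and the fibre-length column necessarily duplicates
the per-muscle out-lever column (both are pure denominators). The
default evaluation is at the model's current gape with its current
mechanics; recorded sensitivity magnitudes evaluated at an undisclosed
configuration are not reproducible from printed data, so only these
structural signatures — plus the top-three ranking (superficial
masseter, medial deep temporal, superficial temporal) — are asserted.

## Numerical choices and degenerate inputs

* Angle extraction clamps cosines to [−1, 1] before `acos`.
* A purely mediolateral pull (zero sagittal projection) or an insertion
  on the condyle raises an error naming the muscle; it cannot be
  assigned a sagittal moment.
* An action line through the condyle ($\theta \in \{0°, 180°\}$) has
  moment sign 0 and is excluded (it contributes nothing either way).
* Out-of-domain sensitivity perturbations (an angle scaled past 180°)
  are flagged `NA`, never fatal.
* Printed-style rounding (3 decimals for forces) appears only in text
  reports; CSV/JSON outputs carry full precision, which is what makes
  pipeline reruns byte-identical.
* Suite problem sizes: property tests use 10–100 random geometries of
  2–6 muscles and fine-grid oracles at 0.01°; these run in seconds and
  are statistically ample for exact-identity checks.

## Known limitations

No joint translation, no unilateral biting, no pennation correction,
no force–length or activation dynamics, single uniform muscle stress
and density across muscles, bilateral symmetry enforced. The example
geometry is synthetic (consistent with, not identical to, the dissected
animals), so gape-dependent quantities computed from it characterise
the model, not the specimens.
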