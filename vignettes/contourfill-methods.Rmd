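---
title: "Contour facilitation and brightness filling-in: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Contour facilitation and brightness filling-in: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(contourfill)
```

## The scientific problem

A gray patch completely surrounded by white can look *brighter* than an
identical patch surrounded by black, provided high-contrast inducing
elements in the neighbourhood are collinear or parallel with the patch's
contours (dungeon illusion, reduced cube illusion, grating illusion,
bullseye displays, ring patterns). This is assimilation — the opposite
direction from simultaneous brightness contrast — and it defeats models
built on lateral inhibition alone. The hypothesis implemented here is
geometric: a low-contrast contour that is aligned with a high-contrast
contour is *facilitated* in the oriented boundary system; the boundary
gate then compares the local signal with the facilitated (global) signal
and, where the ratio is low, deletes the boundary. A deleted boundary no
longer blocks filling-in, so the surround's surface signal floods the
target: brightness assimilates from white in the ON system, darkness
from black in the OFF system.

## Architecture

Six modules mirror the processing stages:

1. **`stimuli`** — seed-free parametric generators for the 16-case
   battery, each bundled with eroded target masks and the predicted
   relation.
2. **`maxcircuit`** — the recurrent MAX microcircuit. Each unit's
   recurrent collaterals terminate on distinct dendrites; a dendritic
   interneuron subtracts the unit's own momentary activity, so a
   collateral passes only the rectified difference `[x_j − x_i]₊`. The
   soma relaxes with unit leak toward
   `max(ff_i, x_i + max_j [x_j − x_i]₊)`. The fixed point of a connected
   set of supported units is the maximum feedforward drive in the set;
   facilitation is asymmetric (activity never drops below feedforward).
   Both the Euler dynamics (`relax_dynamics`, dt = 0.1) and the
   equivalent monotone fixed-point iteration (`relax_fixed_point`, used
   by all downstream stages for speed) are provided and cross-validated
   against a brute-force component-maximum oracle.
3. **`fcs_pathways`** — ON/OFF Contrast Pathways (balanced
   difference-of-Gaussians, σ_center = 1 px, σ_surround = 3 px, unit-mass
   lobes, shunting floor 0.5) and ON/OFF Luminance Pathways (surround
   lobe down-weighted by 0.5). The OFF member of each pair is *defined*
   as the ON operator applied to `1 − I`, which makes the ON/OFF duality
   of the whole model exact rather than approximate. Feature input to
   filling-in: `2·contrast + 1·luminance`; more contrast weight produces
   stronger contrast and weaker assimilation.
4. **`bcs`** — oriented boundary processing in two orientations (every
   battery stimulus is rectilinear; the cube illusion is used in its
   reduced corner-bracket form). Simple nodes: two 3-px rectangular
   lobes offset by 1 px perpendicular to the orientation, one combining
   `+ON − OFF`, the other `+OFF − ON`; opposite-polarity pairs sum into
   polarity-invariant complex nodes, dilated by a feedforward 3×3 MAX so
   corners and junctions are not attenuated. Global facilitation links
   supported sites within 15 px along the contour orientation and 5 px
   orthogonal to it, and relaxes to the component maximum. The L/G gate
   keeps a supported site iff `LBD ≥ 0.65 · GBD` (and LBD exceeds an
   absolute floor).
5. **`filling_in`** — ON and OFF filling-in layers: recurrent MAX over
   4-neighbours, edges cut where the relevant-orientation mask is set at
   either endpoint, relay restricted to nodes at ≥ 0.1 of the layer's
   maximum feature input. Steady state equals the flood-fill region
   maximum (validated against an independent oracle). Brightness is the
   min–max normalized `ON − OFF`; a constant difference map maps to 0.5.
6. **`cli_eval`** — battery driver, per-target statistics over the
   eroded masks (mean difference, or RMS contrast for the
   contrast-contrast case), relation scoring with δ = 0.01 and
   δ_eq = 0.005 on the normalized scale, panel/CSV export and a CLI.

## Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| `sigma_center`, `sigma_surround` | 1, 3 | px | resolve 4-px features; surround ≈ 3× center as in retinal ganglion fits |
| `shunt_floor` | 0.5 | luminance | keeps the shunting ratio well-behaved on the [0,1] scale |
| `w_contrast`, `w_luminance` | 2, 1 | – | contrast-vs-assimilation balance; fixed for the whole battery |
| `collinear_reach`, `parallel_reach` | 15, 5 | px @128 | must bridge the 8-px dungeon/cube gaps and one 4-px ring/bar spacing, but not whole surfaces; scaled with grid size |
| `support_eps` | 0.15 | fraction of LBD max | sites below it, or off the oriented crest, carry no contour support |
| `lg_threshold` | 0.65 | ratio | see calibration below |
| `lg_eps` | 0.02 | fraction of LBD max | absolute floor under which no boundary is emitted |
| `fill_threshold_frac` | 0.1 | fraction of feature max | black (≈0 after rectification) below, every gray above |
| `delta`, `delta_eq` | 0.01, 0.005 | normalized brightness | reporting conventions for direction/equality |

## Numerical choices and calibration

**Where the L/G threshold can live.** Under the default palette
{0, 0.5, 1}, a facilitated half-contrast edge settles at a
local-to-global ratio of ≈ 0.56–0.60; an unfacilitated contour is not at
ratio exactly 1, because the center–surround kernels amplify responses
at contour corners (≈ 1.37×) and the recurrent MAX equalizes each
contour to its own corner level, leaving mid-edge ratios of ≈ 0.73. The
threshold must separate these bands; 0.65 does, and
`check_lg_calibration()` errors on any configuration where it does not.
A consequence worth knowing: erased contours may retain sub-segment
"crumbs" near corners (ratio locally above threshold). They do not seal
the region — filling-in only needs an opening — and the acceptance tests
assert openness of the mid-edges rather than pixel-free outlines.

**Contour support is the crest.** A site supports facilitation only if
its oriented response exceeds `support_eps` of the global maximum *and*
is a local maximum perpendicular to its orientation. Without the crest
condition, the smooth kernel tails flanking every contour (10–25% of
the maximum up to ~8 px away) act as relay corridors between nearby
contours and facilitation leaks across the very gaps the model says are
empty. Two contours closer than ~14 px can still fuse their tails into
a ridge that survives the crest test; the stimulus geometry therefore
keeps contours that must remain distinct at least 16 px apart.

**Relay threshold.** The filling threshold is relative to the layer's
maximum feature input (palette independence). That maximum is carried by
edge contrast peaks, roughly twice the uniform white-level input, while
a small gray target's interior input is surround-depressed to 0.12–0.19
of it; 0.1 puts every gray above and everything black-side below (deep
black is exactly 0 after rectification).

**Fixed point, not wall clock.** All recurrent stages are solved by
monotone fixed-point iteration, which provably terminates (values are
drawn from a finite set and never decrease). The microcircuit's slow
dynamics are kept as a separately tested implementation; iteration
counts (reported in `model_outputs$on_fill$iterations` and the timing
table) stand in for the "slow spreading" story — filling-in takes tens
of sweeps, boundary facilitation a handful.

**Degenerate inputs.** A constant image yields zero contrast, identical
ON/OFF luminance, no boundaries, and a flat brightness map of 0.5. Where
GBD is zero, LBD is below the support floor and no boundary is emitted,
so the L/G ratio is never evaluated at 0/0.

## The stimulus battery as a stated world

The source accounts state no grid resolution, element sizes or gray
levels; this package fixes them once: 128×128, palette black = 0,
gray = 0.5, white = 1 (the symmetric gray makes the ON and OFF networks
exact mirrors). Geometry follows two rules derived from the boundary
system's physics: weak edges that must be erased are ≥ 12 px long (so
they have a true mid-segment below the corner-amplified level) and
contours that must stay distinct are ≥ 16 px apart (so their kernel
tails cannot fuse into a facilitation bridge). Concretely: dungeon uses
12-px lattice squares with 8-px gaps; the cube is rendered as two hollow
square outlines with 12-px bands, corner brackets and 8-px gaps (4-px
bars are unusable: a thin strip's two edges reinforce each other into an
unerasable compound edge); ring patterns and the bullseye are nested
squares with 4-px rings; the White-family stimuli use 8-px bars with
24-px targets. The Anderson and Howe variants share one construction — a
grating with a phase-reversed band whose strong horizontal edges are
collinear with the target's horizontal borders — differing in the
vertical offset of the targets from the band (0 for Howe, 40 for
Anderson). The Howe rendition adds a white frame stripe on top and a
black one at the bottom; these connect all white regions into a single
brightness system and all black regions into a single darkness system,
so the predicted ON/OFF cancellation draws on identical component maxima
and is exact rather than approximate. Contrast-contrast uses 12-px
checks at amplitudes ±0.1 (both centres), ±0.5 (left surround) and
±0.05 (right surround); these satisfy the mechanism's inequalities
(centre erasable by the left surround, not by its own right surround,
and both check luminances above the relay threshold), which the often
quoted larger amplitudes do not.

What a green battery does and does not establish: it shows the model
reproduces the *direction* of each effect from crisp, pixel-aligned,
two-level geometry. It says nothing about magnitudes (the boundary gate
is binary, so all assimilation effects have the same strength), about
anti-aliased or natural images, oblique contours, luminance gradients,
or depth/transparency phenomena — all outside this model's scope.

## Known limitations

- Qualitative only: the binary gate cannot modulate illusion strength
  with stimulus size or separation.
- Two orientations (H, V); oblique or curved contours are unsupported.
- Corner amplification in the front end is managed (calibration band,
  geometry rules) rather than eliminated; displays with dense fine
  structure near strong borders can still show facilitation bridging.
- No anchoring: brightness is normalized per image, so absolute values
  are comparable only within one run.
- The global boundary network is purely excitatory; inhibitory lateral
  interactions are deliberately absent.
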