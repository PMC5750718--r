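---
title: "Counting neurons along the early visual pathway"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Counting neurons along the early visual pathway}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neurocensus)
```

## The problem

How many neurons does a small visual stimulus engage at each stage of the
primate early visual pathway — retina, thalamus, cortex? These numbers set the
stage for any population-coding argument (how much information each stage could
carry, how efficient the cortical read-out can be), yet they are rarely stated
explicitly. `neurocensus` chains published anatomical and physiological
summaries of the macaque visual system into per-stage counts for a stimulus of
given area and eccentricity, with every anatomical assumption exposed as a
parameter.

The method is entirely closed-form: no data are fitted, no randomness enters
anywhere, and two runs with the same configuration are byte-identical. What the
package adds over a back-of-envelope calculation is a validated parameter
surface, a reporting convention that separates full-precision values from the
rounded figures such estimates are conventionally quoted at, and a sensitivity
module for exploring how conclusions move with the assumptions.

## The model chain

**V1 (upper bound).** The cortical surface activated by a stimulus of area $A$
deg$^2$ centered at eccentricity $E$ is $A \cdot M(E)$, where the areal
cortical magnification factor is a power law

$$M(E) = 103\,(0.82 + E)^{-2.28} \quad \text{mm}^2/\text{deg}^2 .$$

Only neurons projecting to higher cortex are assumed usable for a
discrimination task: pyramidal neurons of layers 2/3/4B, which span about
0.75 mm of depth, of which about 80% of neurons are excitatory, giving an
effective depth of $0.8 \times 0.75 = 0.6$ mm. Surface × effective depth ×
cortical density (≈120,000 neurons/mm$^3$) is the **upper bound**: every neuron
in the activated volume counts, tuned or not.

**V1 (lower bounds).** If only orientation-selective neurons matter, the count
is discounted by the fraction with orientation bandwidth below 30 deg —
about 75% across layers 2/3/4B (**tuned lower bound**). Extracellular
recordings cannot see neurons that never fire; calcium imaging suggests about
55% of neurons in a small volume respond to at least one stimulus. Discounting
by both fractions ($0.75 \times 0.55$) gives the **loose lower bound**.

**LGN.** Parvocellular and magnocellular cell densities (cells/deg$^2$) follow

$$N_P(E) = 1{,}011{,}688\,(2.9144 + E)^{-2.6798}, \qquad
  N_M(E) = 2{,}620.2\,(5.5638 + (E - 1.8322)^2)^{-0.8012}.$$

$N_P$ decreases monotonically; $N_M$ is unimodal with its peak at 1.8322 deg.
Stimulus area times density gives each count; their sum is the LGN total.

**RGC.** Retinal ganglion cell densities are available only as tabulated
values — 8,500 cells/deg$^2$ at 2 deg and 3,000 cells/deg$^2$ at 5 deg
eccentricity (binocular viewing, 90% of RGCs projecting to LGN) — so the
package interpolates linearly between anchors. By default it *refuses*
eccentricities outside the anchor range: a two-point table carries no
information there, and failing loudly beats silently extrapolating. An
`extrapolate` flag extends the boundary segments linearly, with a warning, for
users who accept that risk.

**Expansion ratios.** The LGN:V1 and RGC:V1 ratios divide the V1 bounds by the
upstream counts. The high ratio uses the upper bound, the low ratio the loose
lower bound, each computed from the *rounded* counts and reported to the
nearest integer. With the defaults: LGN:V1 17:1–40:1, RGC:V1 23:1–55:1.

## The rounding convention

Estimates of this kind are quoted as "approximately" figures. The quoted chain
(5 mm² → 3 mm³ → 360,000 → 270,000 → 150,000) only reproduces if rounded
intermediates propagate: carried at full precision the same chain gives
4.84990 mm² → 2.90994 mm³ → 349,193 neurons. The package therefore reports
**both** columns everywhere. Rounding is half-up (so 148,500 at a 10,000 grain
becomes 150,000, where banker's rounding would not) with stage-specific
grains: 1 mm² for surface, 1 mm³ for volume, 10,000 for V1 counts, 1,000 for
LGN, 500 for RGC, and 1 for ratios. The grains are a reverse-engineered
reporting convention, exposed in the `rounding` config section, not an
anatomical claim. V1 rounded fields propagate rounded intermediates; surface,
volume, LGN and RGC rounded fields are direct half-up roundings of their raw
values — the tests pin down exactly this distinction.

```{r}
est <- estimate_pathway()
est
```

## Parameters

All defaults ship in a YAML constants file
(`system.file("extdata", "default_config.yaml", package = "neurocensus")`):
the coefficients are data, not code, so fits for another species (or a better
macaque fit) can be substituted wholesale via `load_config()`, which merges a
partial user file onto the defaults and rejects unknown keys.

| parameter | default | units | meaning |
|---|---|---|---|
| `stimulus.area` | 1 | deg² | stimulus area |
| `stimulus.eccentricity` | 3 | deg | stimulus center (radial; no meridian anisotropy is modeled, as the magnification fits are meridian-free) |
| `v1.laminar_depth` | 0.75 | mm | depth of layers 2/3/4B |
| `v1.excitatory_fraction` | 0.8 | — | excitatory (pyramidal) share |
| `v1.density` | 120,000 | neurons/mm³ | cortical density |
| `v1.tuned_fraction` | 0.75 | — | bandwidth < 30 deg |
| `v1.responsive_fraction` | 0.55 | — | non-silent share |
| `lgn.parvo`, `lgn.magno` | see file | — | density model coefficients |
| `rgc.anchors` | (2, 8500), (5, 3000) | deg, cells/deg² | interpolation anchors |

Stimulus eccentricity is taken as the *center* of the stimulus. Whether the
tuned discount applies before or after the silent-neuron discount is
numerically moot (multiplication commutes); the package applies tuned first
purely for presentation.

## Numerical choices

* **Point vs integrated surface.** By default the magnification is evaluated
  at the center eccentricity and multiplied by the area — the convention the
  headline figures assume. `mode = "integrated"` instead treats the footprint
  as an eccentricity band of the stimulus height and integrates $M$ across it
  (adaptive quadrature, relative tolerance 1e-10), times the stimulus width.
  This is a documented approximation of the true retinotopic footprint, whose
  geometry the closed forms do not specify; for a 1×1 deg² patch at 3 deg the
  two modes differ by about 2%, and they converge as the extent shrinks. A
  band reaching below 0 deg eccentricity is refused.
* **Validity range.** The density fits derive from parafoveal/peripheral data
  of unstated extent; any $E \ge 0$ is accepted, with a warning beyond 20 deg.
  Foveal ($E < 0.5$ deg) specializations are out of scope.
* **Counts are real numbers.** Densities are continuous estimates, so raw
  counts are not forced to integers; only the rounded reporting column is.
* **Degenerate inputs.** Zero area yields zero counts and a warning that the
  expansion ratios are undefined; a zero upstream count makes
  `expansion_ratios()` error rather than return infinity.

## Sensitivity analysis

`sweep_pathway()` evaluates one parameter over a grid with everything else
held fixed; `one_at_a_time()` applies ±relative perturbations per parameter.
Both are exhaustive, deterministic grid evaluations — the method is
closed-form, so Monte Carlo uncertainty propagation would add noise without
information and is deliberately out of scope (as are factorial interaction
designs).

```{r}
sweep_pathway(parameter = "stimulus.eccentricity",
              grid = c(2, 3, 4, 5))[, c("grid_value", "rgc_raw",
                                        "lgn_total_raw", "v1_upper_raw")]
```

Because every stage count is multiplicative in area, density and the
fractions, relative output changes equal relative parameter changes exactly
for those parameters — a useful self-check that the sweep machinery exercises
in the test suite.

## What the tests do and do not show

The suite checks the closed forms against independent log-domain re-evaluation
(to 1e-10 relative), the interpolation against its anchors, the rounding
against an integer-arithmetic oracle, monotonicity/unimodality over dense
grids, bound ordering over sampled fractions, linearity in area, quadrature
convergence, and the complete quoted worked example. All of this validates the
*arithmetic chain*, not the anatomy: the confidence in the counts themselves
is bounded by the summary fractions and fitted coefficients that enter as
inputs. The package deliberately treats those as replaceable data.

## Known limitations

* The macaque defaults blend sources with different viewing conditions; it is
  unknown whether the LGN density fits fold in binocular viewing and the 90%
  RGC→LGN projection fraction the way the RGC anchors do. The coefficients are
  used as published.
* No receptive-field overlap, tuning-curve shape, correlated variability, or
  decoding efficiency is modeled — the counts are inputs to such analyses, not
  substitutes for them.
* The RGC table has two anchors; between them linearity is an assumption, and
  outside them the package refuses to guess by default.
* Parvo/magno RGC subclasses are not distinguished.
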