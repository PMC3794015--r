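---
title: "Methods: paleophylogeographic range hindcasting"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: paleophylogeographic range hindcasting}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(paleoniche)
```

# The model

A paleophylogeographic model (PPGM) hindcasts a species' geographic range
through glacial–interglacial cycles in four coupled steps.

**1. Continuous paleoclimate.** Two end-member bioclimatic grids — an
interglacial (modern) and a glacial state on one equal-area lattice — are
blended per cell and per variable, with the blend weight read off an
isotope-proxy curve of global mean annual temperature (MAT) at uniform
4-ky slices:

$$X_t = \alpha\,X_{\mathrm{modern}} + (1-\alpha)\,X_{\mathrm{glacial}},
\qquad
\alpha = \frac{\mathrm{MAT}(t) - \mathrm{MAT}_{\mathrm{glacial}}}
             {\mathrm{MAT}_{\mathrm{modern}} - \mathrm{MAT}_{\mathrm{glacial}}}.$$

The blend is linear by assumption — the simplest model in which every
local climate variable scales with the global temperature state — and
$\alpha$ is allowed to exceed 1 so that interglacials warmer than the
present extrapolate rather than saturate. `interpolate_slice()` requires
exact slice membership; mapping arbitrary ages onto slices is a separate,
explicit step (`slices_in_window()`), so no age is ever silently snapped.

**2. Niche envelopes.** The potential niche is a rectilinear BIOCLIM
envelope: per-variable bounds around the modern occurrence climates.
Because the bounds depend only on marginals, the envelope is unbiased by
correlations between climate variables — important here because those
correlations differ between glacial and modern climates. Two trim levels
are supported: 0 (min/max, contains every training point) and 0.10
(per-variable 5th/95th percentiles). "Excluding the outlying 10%" is
ambiguous between a multivariate and a per-variable reading; we use
symmetric per-variable percentile trimming (the standard BIOCLIM
percentile envelope) because it is deterministic and matches the
rectilinear framing. Percentiles use the linear-interpolation convention
(`quantile` type 7). With fewer than 10 training vectors the 10% trim is
poorly defined; the fit falls back to min/max with a warning recorded in
the envelope's provenance.

The realized niche is operationalized as the convex hull of the
occurrence climates. The hull is strictly nested inside the trim-0
envelope fitted on the same points, which gives the within-realized ≤
within-potential ordering that fossil summaries require. Whether a
published "within realized niche" test is hull-based cannot be inferred
from summary tables alone; the hull is our design choice, recorded here,
chosen because it is parameter-free and strictly tighter than the box.
Membership is decided by a nearest-point-in-hull quadratic program
(`quadprog`) in range-standardized coordinates with a residual tolerance
of `1e-4` (standardized units); reference clouds with fewer than $d+1$
points or deficient rank fall back to bounding-box membership with a
warning.

**3. Phylogenetic correction.** Each envelope bound (lower and upper, per
variable) is treated as an independent continuous trait evolving by
Brownian motion on the time-calibrated tree (branch lengths in My; the
package owns the 1 My = 1000 ky conversion). Ancestral values at internal
nodes are generalized-least-squares estimates under the Brownian
covariance of shared path lengths; the root estimate is the GLS grand
mean, and standard errors propagate the estimated mean and the
maximum-likelihood rate. The envelope at age $t$ along a terminal branch
is the linear interpolation between the tip bounds (at $t=0$) and the
parent-node estimate (at the node's age). We interpolate once per branch
rather than re-fitting the reconstruction at every slice: a single GLS
fit per trait already determines the along-branch expectation under
Brownian motion, and re-fitting per slice would change nothing but the
runtime. If interpolation ever makes a lower bound cross its upper bound
(possible only when some GLS weights are negative), both are collapsed to
their midpoint and a warning is recorded — validity is preserved without
inventing width.

**4. Projection and refugia.** The range at a slice is the set of
accessible cells whose climate vector falls inside the (corrected or
uncorrected) envelope. Accessibility is the union of Level-1 drainage
basins holding at least one modern occurrence — large-scale geographic
barriers — while Level-2 basins define each species' available climate
space. Range area is cell count × cell area; the centroid is the
unweighted mean of presence-cell centres, which on an equal-area lattice
is the area-weighted centroid; fragments are counted with 4-connectivity
(conservative and deterministic). When a projected range is empty the
five accessible cells with least-negative combined MESS score (SIM5)
stand in as the most parsimonious refugium, flagged as substituted and
excluded from richness maps by default. SIM5 candidates are restricted to
the species' Level-1 mask — a refugium must be reachable — and whether
the original procedure searched continent-wide cannot be determined from
the text; the mask restriction is our recorded choice. The empty-slice
census is likewise computed inside Level-1 space.

**MESS scores.** For a reference interval of width $w$: inside, the score
is $200\,d_{\mathrm{in}}/w$ where $d_{\mathrm{in}}$ is the distance to
the nearest boundary (equivalently $100(1 - 2|x-\mathrm{mid}|/w)$, but
exactly 0 on a boundary in floating point); outside it is
$-100\,d_{\mathrm{out}}/w$. The combined score is the minimum across
variables — a point is non-analogue as soon as one variable is outside —
with arg-min ties broken by canonical BIO ordering. This is the
literal width-normalized boundary-distance definition (including the
"−100 at one full width" anchor), not the percentile-rank MESS variant
used elsewhere in the SDM literature.

**Fossils.** A fossil's reported age window is resolved to the modeled
slice(s) inside it whose paleoclimate at the fossil's cell is most
compatible with the species' potential niche (maximal combined MESS);
exact ties are all retained as equally likely. Paleoclimate is read from
the single containing cell — consistent with the per-cell niche
arithmetic everywhere else — and classification uses the resolved-slice
paleoclimate rather than the site's modern climate, consistent with the
E-space framing of fossil tests. When resolved slices disagree, the most
favorable slice is the headline classification and the full set is kept.
Per-species summary percentages are pooled count-weighted *before* the
single 1-decimal rounding.

**Response partitioning.** Pairwise changes between slices in range area
(PC_RS, km²), centroid position (PC_GC, km, non-negative) and mean annual
temperature (PC_MAT, °C) feed simple linear regressions of response
magnitude on $|$PC_MAT$|$. "Pairwise" is ambiguous between consecutive
slices and all slice pairs; both modes exist and consecutive is the
default (conservative, no inflation of n by correlated pairs). Magnitude
regression is the default because rate-of-response summaries are
magnitude statements; signed mode is available. PC_MAT defaults to the
range-local mean of BIO1 over the species' accessibility mask (each
species responds to its own region), with the global proxy curve as
fallback. Subtracting uncorrected from corrected records partitions each
response into a climate-tracking and an adaptive (phylogenetic)
component; the partition is additive by construction, exactly.

# Tunable parameters

| parameter | default | units | why |
|---|---|---|---|
| cell area | 50 | km² | equal-area cells avoid latitudinal bias |
| slice step | 4 | ky | resolution of the isotope proxy |
| slices | 80 | — | three ~100-ky cycles (320-ky window) |
| trim | 0 | — | reduced envelopes are often too restrictive |
| thinning resolution | 18.5 | km | ten arc-minute grid equivalent |
| SIM5 k | 5 | cells | minimal refugium (250 km²) |
| watershed level | 1 (mask) / 2 (climate) | — | barrier vs training scale |
| hull tolerance | 1e-4 | standardized | QP residual cut-off |

A naming caveat: published variable lists for the 8-variable modeling
subset sometimes label the warm-month maximum "BIO6"; conventionally BIO5
is the warm-month maximum and BIO6 the cold-month minimum. The package
defaults to the conventional definitions (`MODELING_VARS`) and the subset
is configurable everywhere.

# The synthetic generator

`synthetic_world()` emulates every input with known ground truth. Climate
fields are sums of low-frequency cosine modes over a meridional gradient
(cheap, controllable autocorrelation); the glacial end-member subtracts a
uniform offset (default 6 °C, mid-range for glacial–interglacial MAT
swings) from temperature *level* variables plus a smooth anomaly.
Temperature range-type variables (BIO2, BIO3, BIO4, BIO7) are differences
of temperatures and are left unshifted by the uniform cooling — cooling
them would make every glacial climate globally non-analogue. The isotope
curve is a cosine cycle (period 100 ky) anchored at the modern MAT at
t = 0 and the glacial MAT at cycle minima, with an optional sin⁴
interglacial overshoot peaking one period before present. The clade is a
Yule tree conditioned on the species count (rescaled, if needed, so the
320-ky window fits inside every terminal branch), with envelope midpoints
and log-widths evolving by Brownian motion; displacements are simulated
from zero so that zero rates reproduce the root envelope bit-exactly.
Occurrences are sampled from suitable cells, optionally confined to a few
"home" Level-1 basins (default 2) so that realized ranges are nested
inside potential ranges and northern-basin species can lose all suitable
climate during glacials. Fossils are planted at known slices with
ground-truth niche-membership labels that analysis code never reads;
"inside" fossils are planted inside the envelope the pipeline will fit
from the sampled occurrences (nested in the truth envelope), so the
zero-blur round trip classifies them correctly by construction.

What the generator does **not** emulate: real North American geography,
WorldClim's covariance structure among the 19 variables, spatially
structured sampling bias, dated-fossil taphonomy, or non-Brownian niche
evolution. Passing tests therefore demonstrate internal consistency and
correctness of the machinery under the stated model, not predictive
performance on real turtle data.

# Numerical choices

- Thinning retains the first point per cell in input order (deterministic
  without a seed).
- Point-to-cell lookup is half-open (left/bottom edge inclusive).
- Envelope membership is bounds-inclusive.
- Slice interpolation computes `alpha*modern + (1-alpha)*glacial`, which
  reproduces the end-members bit-exactly at `alpha` 1 and 0.
- SIM5 ties are broken by ascending cell id.
- Degenerate inputs: zero-width MESS reference with an off-bound value is
  an error (on-bound scores 0); constant traits give Brownian rate 0 with
  a warning; a constant response gives a regression with slope 0 and
  R² 0 rather than 0/0.
- The ML Brownian rate divides by n, so its expectation is (n−1)/n σ²;
  tests compare simulation means against that expectation.

# Problem sizes

The shipped test-and-verification runs use a 50 × 50-cell lattice, 10
species, 80 slices at 4 ky, 60 occurrences and 40 fossils — large enough
to exercise fragmentation, empty-slice censuses and SIM5 substitution
while keeping the full suite under half a minute. All sizes are
arguments.

# Package shape

The package follows the classic R modelling idiom: `ppgm()` is the single
fitting function returning a classed object with `print`, `summary`,
`coef`, `predict` and `plot` methods, while every pipeline stage
(generation, interpolation, envelope fitting, reconstruction, projection,
MESS, fossil evaluation, partitioning) remains an exported function so
stages can be run, tested and replaced independently.

# Known limitations

Range filling is instantaneous per slice (no dispersal kinetics), there
is no sea-level or coastline dynamics, niche evolution is single-rate
Brownian (no Ornstein–Uhlenbeck or rate shifts), and the linear
two-end-member blend cannot produce spatial climate patterns absent from
both end-members. The hull-based realized-niche test and the Level-1 SIM5
restriction are design decisions, not assertions about any published
procedure.
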