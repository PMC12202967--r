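---
title: "Methods: beauty-frame midline analysis, facial proportions, and the smile framework"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: beauty-frame midline analysis, facial proportions, and the smile framework}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(smileframe)
```

## The measurement problem

Clinical aesthetic analysis of the face asks three nested questions, from
macro- to micro-aesthetics: are the vertical and transverse proportions of
the face harmonious (conventionally, close to the divine ratio 1.618)?
How do the midline landmarks — nasion, nose tip, philtrum tip, dental
midline, mouth midline — sit relative to the facial midline? And how is the
smile framed: the smile arc, lip curvature, gingival display, smile width,
and the shape and proportions of the maxillary central incisor?

The difficulty is that "the facial midline" is not directly observable on a
photograph. This package operationalises it with a **beauty frame**: the
rectangle bounded above by the line through the two external canthi,
laterally by perpendiculars through each canthus, and below by the parallel
line through the lowest point of the lower lip (LLI). The frame's vertical
bisector is the working facial midline. Because the frame is anchored to the
canthi, slight head roll in the photograph rotates the frame with the face,
and every quantity the package reports is invariant under rotation,
translation and uniform scaling of the image (this is tested to 1e-9
relative error).

## Relative midline values

Let $u(\cdot)$ be the perpendicular distance of a point from the
subject-right lateral frame border, and $F$ half the intercanthal width, so
the facial midline is $u = F$. For the nasion $n$, nose tip $t$, philtrum
tip $p$, dental midline $d$ and commissure midpoint $C_x$ (all measured as
$u$-coordinates), the **relative facial-midline values** are

$$\mathrm{RFV}_1 = n/F,\quad \mathrm{RFV}_2 = t/F,\quad
  \mathrm{RFV}_3 = p/F,\quad \mathrm{RFV}_4 = d/F,\quad
  \mathrm{RFV}_5 = C_x/F,$$

and the **relative commissural-midline values** normalise the same four
landmarks by the mouth midline instead:
$\mathrm{RCV}_i = u_i / C_x$. A value of exactly 1 means coincidence with
the respective midline; values below 1 lie toward the subject's right,
above 1 toward the left. Two identities follow directly from the
definitions and are enforced by tests:

* perfect bilateral symmetry gives all five RFVs and four RCVs equal to 1;
* $\mathrm{RCV}_i \cdot \mathrm{RFV}_5 = \mathrm{RFV}_i$ exactly.

The RCV denominator deserves a note: the definitions admit two readings
(distance of the commissure midline from the lateral border, or from the
canthus). Only the lateral-border reading makes RCV equal 1 under perfect
symmetry and yields the product identity above, so that is the reading
implemented.

A genuinely mirrored subject (coordinates reflected *and* anatomical
`_R`/`_L` labels swapped — reflection alone is an isometry that changes
nothing) maps every RFV to $2 - \mathrm{RFV}$; this antisymmetry is also
tested.

## Facial proportions

Nine vertical spans between the trichion (TR), external canthus (LC),
lateral nose border (LN), mouth corner (CH) and menton (ME) levels, and
four right–left widths (TS, LC, LN, CH), combine into ten ratios, each also
expressed as a percentage of the divine proportion
($1.618 = 100\%$, so `golden_percent(r) = r/1.618 * 100`). The constant is
fixed at 1.618 exactly rather than $\phi$ to machine precision, matching
the arithmetic convention of clinical golden-ratio analyses.

Vertical spans are measured along the canthal frame's v-axis (bilateral
landmarks contribute their pair-mean level), which equals the raw vertical
pixel distance on an un-rotated photograph but stays well-defined on
rotated input. Transverse widths are straight Euclidean distances between
the sided pair, as they are drawn on measurement diagrams. One deliberate
extension: the width ratio CH(r-l):LN(r-l) requires the LN right–left
width, so LN(r-l) is measured alongside the three widths the distance list
would otherwise contain.

## The smile framework

* **Smile arc** — a least-squares quadratic $v = au^2 + bu + c$ (frame
  coordinates, $v$ downward) is fitted to the maxillary incisal-edge points
  and to the lower-lip border points. The arc is *consonant* when both
  curvatures dip centrally, i.e. both $a < -\texttt{flatness\_tol}$.
  No numeric consonance rule is standard, so the package uses the minimal
  quantification — curvature *direction* agreement only; magnitudes need
  not match. The default `flatness_tol = 1e-4` px$^{-1}$ corresponds to
  under ~0.4 px of central sag across a typical 120 px incisal span, i.e.
  visually flat.
* **Upper lip curvature** — sign of
  $\Delta = v(\mathrm{ULC}) - \overline{v}(\mathrm{CH})$, the upper-lip
  centre relative to the mouth corners, with a dead band of
  `lip_tol_frac = 0.02` of frame height so sub-pixel differences classify
  as *straight*. The reference point is the centre of the upper lip's lower
  margin: comparing the corners to the lower lip's own margin would make
  the comparison circular.
* **Smile line** — *high* requires the full clinical crown plus a
  continuous gingival band; *medium* 75–100% of the crown (papilla only);
  *low* below 75%. The rule is monotone in the exposure fraction.
* **Smile width** — the most posterior exposed maxillary tooth type, coded
  by the FDI tooth-type digit (4 = first premolar … 7 = second molar).
  Anterior-only smiles are rejected as unsupported input.
* **Tooth shape** — $\mathrm{DP}\% = \text{length}/\text{width} \times 100$
  with classes triangular (< 43), oval (43–57, boundaries inclusive) and
  square (> 57), exactly as the index is printed in the clinical
  literature this implements. Taken literally the thresholds imply crowns
  about twice as wide as long, which is anatomically atypical and
  inconsistent with the companion width-to-length statistics (mean 1.1845,
  i.e. DP ≈ 84); the package implements the printed definition, exposes a
  `dp_definition = "width_over_length"` switch for the conventional
  reading, and does not silently correct either. A 1e-9 guard keeps
  measurement quotients that land exactly on a printed boundary (e.g.
  5.7/10) from being pushed across it by floating-point rounding.
* **Tooth size** — the width-to-length ratio and its percent of 1.618.

## Cohort statistics

Sex associations of categorical attributes use the chi-square test of
independence without continuity correction, switching to the Fisher exact
test when more than 33% of expected cell counts fall below five.
Continuous comparisons use the Mann-Whitney U test (exact enumeration when
the combined sample is ≤ 12 and tie-free; otherwise the normal
approximation with tie-corrected variance and no continuity correction).
Correlations are Pearson with the $t$ transform. Test–retest reliability is
ICC(2,1) — two-way random effects, absolute agreement, single measurement —
computed from the two-way ANOVA mean squares; this is the conventional
form for repeated digitisations, and the form had to be chosen here since
reliability conventions vary. Categorical tables use the grand total as the
percent denominator, with within-sex percents in the per-sex columns;
display rounding is one decimal for percents, all internal arithmetic
unrounded.

## The synthetic cohort generator

No landmark coordinates are distributed with the package, so the generator
produces cohorts with the statistical structure the analysis assumes. The
defaults describe a reference adult population of 637 subjects (350
female, 287 male, ages 18–40):

* **Midline offsets.** Each subject's five true RFVs are drawn from
  normals with means (0.9981, 0.9964, 0.9924, 0.9851, 0.9917) and SDs
  (0.086, 0.079, 0.071, 0.089, 0.074), truncated at ±4 SD to avoid
  degenerate geometry. Landmarks are placed at $u = \mathrm{RFV}\cdot F$,
  so the drawn values are realised exactly. The same values are used for
  both sexes: the available sex-stratified figures for these quantities are
  not mutually consistent with their pooled values (their 350:287-weighted
  average disagrees with the pooled means and would invert the landmark
  ordering), so the pooled column is taken as the generating truth and the
  stratified figures are kept under `reference` for inspection only. RCVs
  are not independently parameterised — they are implied by
  $\mathrm{RFV}_i/\mathrm{RFV}_5$, consistent with the product identity.
* **Face geometry.** Per-sex vertical landmark levels are calibrated by
  least squares on log ratios from the per-sex proportion targets: seven
  targets constrain three free gap proportions, so the system is
  over-determined and the optimiser (Nelder-Mead followed by a damped
  Gauss-Newton polish) reports its residual (~0.03 on the default
  targets; 0 to machine precision when the targets are mutually
  consistent, which the tests exploit as a forward-then-invert oracle).
  Transverse widths follow in closed form from the width-ratio chain,
  anchored at an intercanthal width of 600 px on a 1000 px
  trichion–menton template. Per-landmark Gaussian jitter (SD 4 px) gives
  between-subject proportion variation.
* **Smile attributes.** The five categorical attributes are drawn from
  per-sex multinomials (frequencies of the reference population), and each
  drawn category is *realised geometrically* — lip $\Delta$ sign and
  magnitude, arc curvature signs, crown exposure band, last visible tooth,
  and a DP% value inside the drawn shape-class band — so that analysing
  noise-free coordinates reproduces every drawn category exactly. Because
  the printed shape classes and the printed width-to-length statistics are
  mutually contradictory (see above), the shape multinomial is treated as
  the generating truth and the square band is centred at DP = 84.4
  (= 100/1.1845) so the square-majority cohort still lands near the
  reference width-to-length mean.
* **Nuisance transforms.** Each photograph (rest and smile views
  separately) receives a random similarity transform — head roll ±5°,
  scale 0.9–1.1, translation ±100 px — plus 0.5 px Gaussian coordinate
  noise, emulating residual positioning error and digitisation jitter in a
  controlled photographic protocol.
* **Reproducibility.** A single global seed spawns per-subject sub-streams
  (a seeded draw of per-subject seeds), so cohorts are byte-identical
  across runs and the first $k$ subjects do not change when $n$ grows.

What the generator does **not** emulate: correlation between different
landmarks' deviations (no covariance information is available, so offsets
are independent); age effects; asymmetric soft-tissue shape; anything
photometric. Passing tests therefore demonstrate the correctness and
invariances of the measurement pipeline and the self-consistency of the
generator — not that the generator reproduces the full dependence
structure of real faces.

## Validation design and problem sizes

The test suite checks each operation against an independent oracle
(closed-form arithmetic, enumeration of rank assignments for the exact
Mann-Whitney distribution, `aov` mean squares for the ICC, brute-force
quotients for ratios), plus property-style invariants: similarity
invariance (rotation ±15°, scale 0.5–2) and mirror antisymmetry across 100
simulated subjects, the RCV×RFV5 identity across 1,000, and parameter
recovery on cohorts of n = 2000 over three seeds — sizes chosen so the
standard errors are small enough to be informative while the whole suite
runs in a couple of minutes.

One recovery property is statistically marginal by construction: the
reference ordering of the five landmarks by mean RFV (nasion, nose tip,
philtrum, commissure midline, dental midline) involves an adjacent-mean
gap of 0.0007 (philtrum vs commissure midline) against a standard error of
the mean difference of ≈ 0.0023 at n = 2000. The probability of recovering
the full ordering in one simulated cohort of this size is therefore only
≈ 0.4 — adjacent swaps are the expected behaviour, a property of the
reference values themselves rather than of the estimator, and the
hierarchy check in the acceptance tests should be read with that in mind.

## Degenerate inputs and numerical choices

Coincident canthi, an LLI on the canthal line, commissures above the
canthal line, a commissure midline on the lateral border (RCV denominator
0), fewer than three curve points, curve points collinear in $u$, and
non-positive tooth measurements all raise targeted errors rather than
producing values. Side classification uses `tol = 0` by default — the
strict reading in which any deviation from 1 counts — and is configurable.
Quadratic fits centre the $u$ coordinate before solving for numerical
stability. All classifier dead bands are dimensionless or scale with frame
height, keeping every decision scale-free.
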