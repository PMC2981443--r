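---
title: "Structural and aerodynamic models of giant pterosaur flight"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Structural and aerodynamic models of giant pterosaur flight}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pterosoar)
```

## The question

Whether the largest pterosaurs — the 10–11 m span azhdarchids
*Quetzalcoatlus* and *Hatzegopteryx*, and the 7 m ornithocheiroid
*Pteranodon* — could fly has been argued both ways, usually by applying
avian biomechanical limits to animals that were not birds. `pterosoar`
implements the quantitative side of that argument as a reproducible
pipeline: beam-theory strength of the flight skeleton compared against
avian structural scaling, glide-polar flight performance, anaerobic
burst climb-out range, and the mass/size rescaling corrections on which
those analyses depend.

## Bone strength as a hollow elliptical beam

Pterosaur long-bone midshafts closely approach true ellipses, so a
hollow-ellipse beam model applies. For semi-axes $a$ (dorsoventral) and
$b$ (anteroposterior), the polar second moment of area of the solid
section is

$$J = \frac{\pi a b (a^2 + b^2)}{4},$$

computed for both the outer contour and the medullary cavity; their
difference is the cortical $J$. The polar section modulus is

$$Z_p = \frac{J_\mathrm{cort}}{(a_\mathrm{out}+b_\mathrm{out})/2},$$

a proxy for torsional and (twice) average bending strength in any two
perpendicular planes. Treating the whole element as a cantilever (total
length = moment arm) with a breaking stress $\sigma_\mathrm{max}$, the
failure force is $F = \sigma_\mathrm{max}\,(c\,Z_p)/L$ and the
**relative failure force** (RFF) is $F$ in multiples of body weight —
a size-corrected robustness index.

Parameter choices:

* `sigma_max = 175` MPa: the experimental breaking limit of avian bone,
  deliberately conservative (most vertebrate long bone fails higher).
* `bending_share = 0.5`: $Z_p$ measures *twice* average bending
  strength, so half of it is credited to single-plane bending. This
  convention affects absolute failure forces only; every comparative
  quantity in the analysis (RFF ratios across masses and taxa) is
  invariant to it, which is why the package's acceptance surface is the
  ratio columns of the published strength table rather than absolute
  forces. Back-calculating the published RFFs from the table's
  length-corrected modulus column does not succeed under any single
  unit convention, so absolute forces are parameterised and documented
  as such.
* `g = 9.81` m/s² (consistent with the published weight column, e.g.
  70.00 kg → 686.70 N).
* Cortical geometry may be given as inner radii or as a uniform wall
  thickness (fossil cortices are usually measured from broken
  elements); thickness is subtracted from both outer radii and floored
  at zero.

The **avian expectation** — the RFF a bird of equal mass would have —
is a power law $\widehat{\mathrm{RFF}} = 10^{\,c_0 + c_1 \log_{10} M}$.
The original avian regression coefficients are not republished in the
source table, so the packaged models are calibrated by least squares to
the table's own (mass, expectation) pairs: the humerus fit
(intercept 0.682, slope −0.320, six pairs) reproduces the printed
expectation column to within 0.2 %. The femur appears once, so its
intercept is anchored through that single point using the humerus
slope; this is a calibration convention of this package, exposed via
`fit_avian_scaling()` so literature coefficients can be substituted.

```{r bone}
models <- packaged_avian_scaling()
t2 <- azhdarchid_strength_table()
round_half_up(rff_ratio(t2$rff, t2$avian_expectation), 2)
```

Azhdarchid humeri come out 1.9–2.8 times stronger than the avian
expectation while the *Quetzalcoatlus* femur sits at 0.30 of it — the
signature of a forelimb-launching animal, not a flightless one.

## The glide polar

For a static planform (span $b$, area $S$, mass $M$, weight $W = Mg$)
total drag decomposes into profile, body and induced terms:

$$D(V) = \underbrace{\tfrac12 \rho V^2 (S\,C_{D,pro} + S_b\,C_{D,body})}_{A V^2}
       + \underbrace{\frac{k\,W^2}{\tfrac12 \rho V^2 \pi b^2}}_{B/V^2},$$

with body frontal area closed allometrically as
$S_b = 0.00813\,M^{0.666}$ m². The closed-form optima of this two-term
polar are

* best glide speed $V_{bg} = (B/A)^{1/4}$ — the most robust quantity in
  the whole flight analysis, since it depends only on planform, mass
  and wing efficiency, never on physiology;
* minimum sink speed $V_{ms} = (B/3A)^{1/4} = 3^{-1/4} V_{bg}$, with
  sink rate $D\,V/W$.

Defaults ($\rho = 1.23$ kg/m³, $k = 1.1$, $C_{D,pro} = 0.014$,
$C_{D,body} = 0.1$) are the standard flight-mechanics conventions for
animal glide polars; none are printed in the source, which is why
reproduction of its glide speeds is banded at ±5 % rather than exact.

```{r glide}
chatterjee <- planform(span = 10.39, area = 9.55, mass = 70,
                       label = "Quetzalcoatlus, narrow")
witton <- planform(span = 9.64, area = 11.36, mass = 259.06,
                   label = "Quetzalcoatlus, broad")
c(best_glide_speed(chatterjee), best_glide_speed(witton))
```

Membrane-wing specifics enter through the lift ceilings — compliant
membranes reach higher maximum lift coefficients than feathered wings,
so `cl_max_unsteady = 2.2` (about a third above the avian maximum) with
a steady ceiling of 1.8 — and through span control: membranes flutter
when slack, so effective span declines only linearly from 100 % at
stall speed to a hard 80 % floor at twice stall speed
(`effective_span_fraction()`). The endpoint behaviour is specified by
the source; the linear interior is this package's choice, the simplest
curve through both endpoints. The flap:glide ratio 0.2 is carried as
report metadata; no intermittent-flight energy model is attached to it
because the analysis publishes no intermediate results to anchor one.

**A known formulation gap.** The published minimum-sink speeds
(8.80 m/s narrow, 16.3 m/s broad) imply $V_{bg}/V_{ms} \approx 1.51$,
which no two-term polar can produce (the analytic ratio is
$3^{1/4} \approx 1.316$; the original software evidently computes sink
differently). The printed sink speeds are therefore treated as
reference metadata: the test suite asserts the analytic ratio and flags
the discrepancy instead of chasing the printed values.

## Anaerobic burst climb-out

Giant pterosaurs were likely incapable of sustained flapping; the model
instead asks how far an anaerobic burst carries the animal toward
external lift. Available power is
$P = M \cdot \texttt{muscle\_fraction} \cdot \texttt{specific\_power}$;
the burst (maximum range) speed is the larger root of

$$D(V)\,V + W\,\dot h = P,$$

found by bracketed root search (`uniroot`, relative tolerance $10^{-6}$)
between the minimum-sink speed — where required power is minimal, so
the power-required curve is U-shaped and a feasible budget has exactly
two roots — and a configurable ceiling. Burst range is speed times
burst duration, with climb losses reported separately rather than
subtracted. The default burst model (30 % of body mass as flight
muscle, 400 W/kg anaerobic output, 60 s, 1 m/s climb) reflects the
large flight-muscle fractions reconstructed for azhdarchids and
measured burst outputs of galliform flight muscle; the muscle
parameters behind the published 48.3 m/s figure are not stated, so
burst speed is validated against its defining power balance and a grid
oracle, not against that number.

## Planform metrics and ecomorphospace

`wing_metrics()` returns the derived planform columns (weight $Mg$,
aspect ratio $b^2/S$, wing loading $Mg/S$). `ecomorph_pca()` projects
$\log_{10}$(mass, span, area) onto principal components of the
covariance matrix: component 1 is a pure size axis (all loadings one
sign; the sign convention points it at larger animals), components 2–3
are the shape axes used for ecomorphospace plots, and log space makes
scores invariant to uniform unit changes. The original figure's
variable set and rotation are unstated, so this projection is a
faithful convention rather than a bit-level reproduction; the external
bird/bat morphometric datasets it drew on are not bundled, and the
packaged wing-attribute table plus synthetic clusters exercise the
machinery at fixture scale. `region_membership()` is an exact
point-in-convex-polygon test with boundary counted as inside.

## Mass and size rescaling

* `segmentwise_correction()`: axial volume scales linearly with torso
  length at fixed cross-section, so a volumetric model whose torso is
  too long by factor $f$ corrects to $\mathrm{axial}/f +
  \mathrm{appendicular}$. The 544 kg *Quetzalcoatlus* model with its
  474 kg axial segment and torso factor 2.77 corrects to ≈241 kg.
* `span_mass_regression()`: the default power law is the unique curve
  through the anchors (6.65 m, 70 kg) and (4.2 m, 22 kg), giving
  exponent ≈2.52 — hence a 13 m animal masses ~1.94× a 10 m one.
  Alternative published regressions substitute via the constructor.
* `density_check()`: mass/volume in g/cm³ against an open (0.6, 1.0)
  band spanning measured bird densities and the ≈1 g/cm³ of non-volant
  animals. The check reports the computed density; for the well-known
  93 kg-in-40 L case that is 2.325 g/cm³ (the source prints 2.235, an
  apparent digit transposition the package does not reproduce).

## Synthetic data: what it emulates and what it does not

`generate_bone_dataset()` draws masses log-uniformly, builds hollow
elliptical sections with eccentricity $b/a \in (0.6, 1)$ and wall
thickness a fraction of the outer radius in $(0.1, 0.5)$ (draws that
would exhaust the anteroposterior cortex are rejected and redrawn), and
scales each section so the realised length-corrected modulus follows
$Z_p/L = 10^{c}\,M^{\alpha}$ with multiplicative lognormal noise.
Element length scales with $M^{1/3}$ (85 mm at 1 kg, matching the
proportions of mid-sized azhdarchid humeri). The geometry is therefore
arbitrary but the strength allometry is exactly the one specified —
which is the property the estimation pipeline
(`estimate_allometry()`, OLS on log–log axes) is validated against.
`generate_planforms()` similarly hits target aspect ratio and wing
loading with lognormal noise. All generators take an explicit seed and
are deterministic given the spec; no global RNG state leaks
(`withr::with_seed`).

What passing these tests shows: the estimators and the analysis chain
are unbiased and correctly plumbed under the assumed noise model. What
it does not show: robustness to phylogenetic autocorrelation,
measurement error beyond lognormal, taphonomic distortion of fossil
sections, or planform reconstruction uncertainty — all of which affect
real specimens.

## Numerical choices and problem sizes

Half-up rounding (`round_half_up()`) is used wherever computed values
are compared with printed table cells. Degenerate inputs fail loudly:
negative radii, inner radii exceeding outer, non-positive masses,
lengths, areas or volumes, infeasible burst power, and collinear hulls
all raise errors naming the violated constraint. The validation suite
runs at deliberately modest sizes — 200 random sections against the
numerical integration oracle, 100 random planforms against grid-search
optima, $n = 50$–100 specimens for allometry recovery — chosen so the
full suite completes in seconds while the sampling error of each check
stays an order of magnitude below its tolerance.

## Limitations

Sections are modelled as true ellipses (exact only for symmetric
sections); torsional failure is represented only through the $Z_p$
proxy; the glide polar is quasi-steady with no aeroelastic membrane
simulation; launch kinematics are out of scope; and the
ecomorphospace projection is a convention, not a reconstruction of any
published figure. Within those bounds the pipeline reproduces every
internally consistent derived cell of the published strength and
wing-attribute tables and the banded glide speeds.
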