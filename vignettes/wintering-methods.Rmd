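---
title: "Methods: sex-specific wintering costs and resource partitioning"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sex-specific wintering costs and resource partitioning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(godwitwinter)
```

## The scientific problem

Bar-tailed godwits are strongly dimorphic: females are about 20% heavier
and have about 25% longer bills than males, and the sexes winter in
different proportions at different sites along the northwest-European
coast. Two mechanisms could produce that segregation:

* **Energetics (Bergmann's rule).** Northern sites are colder but closer
  to the Arctic breeding grounds. The larger sex loses less heat per unit
  body mass, so females could be relatively better off at cold northern
  sites.
* **Resource partitioning.** Benthic prey live at different depths.
  Short-billed males peck prey from roughly the top 4 cm of sediment;
  long-billed females probe down to 30 cm. If sites differ in how deeply
  their biomass is buried, each sex should go where *its* food is.

The package implements the full chain needed to confront these
hypotheses: a per-site, per-sex wintering-cost model; processing of
two-layer benthic cores into ash-free dry-mass (AFDM) densities; sex-ratio
estimation from flock scans; the statistical battery; and a synthetic
study generator that can produce data under either mechanism (or neither).

## The wintering-cost model

Maintenance power is basal metabolic rate plus thermoregulation:

$$M_{maint} = BMR + H_{sm} \quad (\mathrm{W})$$

BMR uses the temperate-wintering shorebird allometry
$BMR = 5.06\,BM^{0.729}$ (BM in kg), giving 1.95 W for a 0.270 kg male and
2.22 W for a 0.323 kg female. The exponent below one is the energetic core
of the Bergmann argument: cost per kilogram falls as birds get bigger.

Standardized heat loss is

$$H_{sm} = \max\{0,\; K_{es}\,(T_b - T_a)\,(1 + K_u u^{exp}) - K_r R_g\}$$

with the live-bird thermal conductance $K_{es}$ (0.0914 W/°C males,
0.1111 W/°C females), body temperature $T_b = 41$ °C for both sexes, mean
winter air temperature $T_a$, wind speed $u$ (m/s) and global radiation
$R_g$ (W/m²). Wind inflates the conductive term; solar radiation offsets
part of it. The output is floored at zero because $H_{sm}$ is an *extra*
cost on top of BMR — a warm, sunny, calm site cannot subsidise basal
metabolism.

The wind and radiation coefficients of the original regression fit are not
in the public record. They are therefore explicit configuration fields
with documented placeholder defaults — $K_u = 0.30$ with $exp = 0.5$
(convective transfer growing roughly with the square root of wind speed)
and $K_r = 0.002$ — and every cost table carries the values actually used
as a `"parameters"` attribute. Any quantity that depends on the absolute
scale of $H_{sm}$ (for example the pooled cost-versus-distance $R^2$)
inherits this placeholder character and should be read as
model-conditional, not as a reproduction of any published value.

Migration cost is the round trip at fixed speed with a sex-specific hourly
rate:

$$C_{flight} = \frac{2D}{S}\,C_{sex}, \qquad S = 75\ \mathrm{km/h},\quad
C_{sex} = 67\ (\mathrm{female}),\ 55\ (\mathrm{male})\ \mathrm{kJ/h}.$$

Distances use a spherical haversine ($R$ = 6371 km) from each site to the
fixed breeding-grounds reference (70°16′ N, 24°05′ E). The packaged site
table also carries a per-site distance override column holding the
recorded route distances, which exceed the haversine values from the
site coordinates by a consistent ~80–160 km (a different measuring tool
and unknown exact endpoints); when present the override wins, so recorded
geographies are reproduced exactly.

The seasonal total integrates maintenance over a configurable winter of
182 days (October–March, matching the averaging window of the climate
forcing): `seasonal_total = maintenance * 182 * 86.4 + migration` in kJ.
On the packaged six-site table migration is about 3% of maintenance —
a small correction that does not change the picture.

## Benthos processing

Each core (0.0177 m², 30 cm deep) is split into a top layer (0–4 cm, the
pecking horizon) and a bottom layer (5–30 cm, probing only). AFDM is dry
mass minus ash mass; densities are per m². Two numerical conventions
matter:

* The site bottom-layer percentage is the **mean of per-core ratios**, not
  the ratio of pooled means. The two differ whenever core totals vary; the
  package demonstrates this with a two-core example (shares 100% and 60%:
  mean of ratios 80%, pooled ratio 63.6%).
* Sample SDs use the n−1 denominator; a single observation reports SD 0.
  Cores missing a layer still contribute to the other layer's summary
  (which is why the two layers can end up with different ANOVA degrees of
  freedom), but not to the percentage; all-zero cores are excluded from
  the percentage as undefined.

Records with ash mass exceeding dry mass are physically impossible, and
are dropped with a warning rather than silently clamped.

## Sex ratios and their tests

The scan session is the unit of replication. Each session's female
proportion is transformed with the empirical logit
$\mathrm{logit}\!\left((y + 0.5)/(n + 1)\right)$, which stays finite for
all-male and all-female flocks and keeps 50:50 exactly at zero. Site
estimates are the back-transformed session means with 95% t-intervals on
the logit scale (the interval choice of scale is an assumption; the
back-transform keeps estimates strictly inside (0, 100)%). Sessions are
equally weighted regardless of flock size, matching session-level
inference; a flock-size-weighted variant sits behind a flag for
sensitivity analysis.

The site-effect test compares Gaussian linear models on session logits
with and without a site factor. With one observation per session a
session-level random intercept is confounded with the residual, so the
fixed-effects Gaussian model *is* the identifiable form of the
session-level mixed model; the likelihood-ratio χ² (df = sites − 1) is
reported as the statistic. Because the Gaussian LRT is a monotone
transform of the exact F statistic, the p-value is computed from the
finite-sample F distribution rather than the asymptotic χ²: at six sites
by ten sessions the asymptotic version rejects a true null about 7% of the
time at α = 0.05, while the exact form holds the nominal rate (the
package's null-calibration tests verify 3–7% empirically).

The remaining battery is classical and delegated to base R behind thin
wrappers: one-way ANOVA (`aov`), Tukey HSD (`TukeyHSD`, Tukey–Kramer for
unbalanced groups), Pearson correlation (`cor.test`), and least-squares
fits (`lm`). p-values below 1e−16 are reported as that bound, never as
zero.

### The four-correlation panel

The head-to-head comparison correlates percent female per site with:
(i) seasonal wintering cost (site level, cost averaged over the sexes —
the two sexes' costs are affinely related so the correlation is
insensitive to this choice); (ii) bottom-layer AFDM at the sample level,
each core paired with its site's percent female (this is what gives the
~60-core degrees of freedom); (iii) top-layer AFDM, likewise; and (iv) the
site mean bottom percentage. Under resource partitioning the expected
signature is bottom positive, top negative, cost near zero; under the
energetic hypothesis the cost correlation should dominate. A site-level
variant of the biomass correlations is available behind a flag.

## The synthetic study generator

The generator exists so that every stage is testable end to end without
field data. Its defaults emulate the study conditions: six sites spanning
0–7 °C with one-way distances 1940–3093 km co-varying so that colder
sites are closer, ten cores and ten scan sessions per site, and flock
sizes from a truncated normal (mean 117, SD 108.4, floor 10 — the floor
avoids degenerate logits from tiny flocks). Wind (4–8 m/s) and radiation
(40–80 W/m²) are drawn uniformly from winter-typical coastal ranges and
recorded in the output.

**Benthos.** Each site draws a latent *depth-resource factor* that
simultaneously raises the bottom-layer share (logit-linear, centred on
80%), raises bottom-layer density, and lowers top-layer density — sites
rich in deep-living prey such as lugworms are exactly the sites where
little biomass sits near the surface. This one factor is what makes the
resource-partitioning signature (bottom +, top −) emerge mechanistically
rather than by construction. Within a site, a core's two layers share a
local-richness factor with loading 0.76, calibrated analytically so the
within-site core-level top/bottom correlation is about 0.5 at the default
coefficients of variation (0.8 top, 0.9 bottom, the scale seen across the
six study sites). The *pooled* cross-site correlation is lower because the
site-level coupling is negative; the two observed facts — positively
correlated layers at core level, negatively associated top biomass and
female share at site level — cannot both be driven by a single positive
coupling, and the within-site reading is the one the generator preserves.
Explicit per-site moments can be supplied instead (used in tests to
moment-match an observed site). Dry and ash masses are synthesized around
the AFDM with ash fractions of 70–90% of dry mass.

**Counts.** The named hypothesis sets each site's true probability that a
scanned bird is female: `resource_partitioning` links it to the generated
bottom-share (slope 8, intercept −6.4, chosen once so site percentages
span roughly 25–75% — the spread actually observed across the study
sites); `bergmann` links it to the standardized site cost (slope 1);
`null` is 50:50 everywhere. Noise is binomial by default; a logit-normal
session-level overdispersion parameter exists but defaults to 0 because
no within-site session variance is on record.

**Abdominal profiles.** Ordinal 1–5 scores discretize a latent Gaussian
(SD 1) whose mean is linear in standardized site × sex cost, sex, and
their interaction (defaults 3, 0.4, −0.2, +0.2: scores rise with cost and
rise *faster* for males, the smaller sex carrying relatively larger
stores at expensive sites). Rounding-and-clamping to 1–5 slightly
attenuates the latent coefficients; parameter-recovery tests therefore
compare fitted coefficients with the exact least-squares estimand of the
discretized model, computed in closed form from the cell probabilities,
rather than with the latent coefficients themselves.

**Determinism.** A study is a pure function of its scenario: the root seed
derives four fixed per-stage streams (sites, benthos, counts, profiles),
so any stage can be regenerated independently and full runs are
byte-identical across repetitions.

### What the generator does not emulate

No spatial autocorrelation within mudflats, no temporal turnover across
the winter, no observer error in sexing (the 97.3% validation accuracy is
treated as support for ignoring it), no double counting, and no
taxon-level prey structure. Passing tests therefore show that the
*pipeline* recovers what the generative model encodes at realistic sample
sizes — not that real flocks or real sediment behave this simply.

## Problem sizes and calibration checks

The test suite's simulation studies use the default design (6 × 10 × 10)
throughout: 2000 null replicates for type-I calibration of the site-effect
and sex-bias tests (accepting 3–7% at α = 0.05), 200 replicates per
hypothesis for the panel-signature experiment (requiring the
resource-partitioning signature, and its absence under the energetic
generator, in ≥90% of runs), and 500 replicates of 600 scored birds for
profile-model coefficient recovery within two standard errors. The
two-standard-error criterion has a nominal coverage of 95.45%, so its
long-run pass rate against a 95% bar is close to a coin flip by
construction; the recovery experiment's long-run coverage was measured at
about 95.2% over 4000 independent replicates.

## Known limitations

* The heat-loss wind/radiation coefficients are placeholders; absolute
  cost levels (and statistics mixing between-sex and between-site cost
  variance, such as the pooled cost–distance $R^2$) move with them.
  Within-sex orderings, monotonicities and the female-above-male gap do
  not.
* The site-level correlations run on six sites (df = 4); only very strong
  associations can reach significance there, which is faithful to the
  design but worth remembering when reading the panel.
* The single fixed breeding-grounds endpoint ignores within-population
  breeding spread.
* Scores, counts and masses are validated structurally, but no
  field-protocol modelling (detectability, flock turnover) is attempted.
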