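---
title: "Integrated biomarker indexes: models, choices and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Integrated biomarker indexes: models, choices and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ibrkit)
```

## The problem

Biomonitoring studies measure a handful of biomarkers — typically enzyme
activities such as catalase, glutathione S-transferase or
acetylcholinesterase — in organisms sampled at several sites or exposure
treatments. Each biomarker responds on its own scale and in its own
direction (some are induced by stress, some inhibited), so site-level
comparison needs a composite index. `ibrkit` implements the two indexes
in common use, for tables of 3–9 biomarkers measured at 2 or more sites
with replicate samples per site.

Replicates are averaged to per-site arithmetic means (over non-missing
values) before either index is computed: both indexes are defined on
site-level values, and averaging first makes the pipeline insensitive to
the number and order of replicate rows. If your rows are already site
means, the averaging is a no-op.

## The IBR model

Per biomarker $j$ with site means $m_{ij}$:

1. **Standardize across sites** with the sample SD ($n-1$ denominator):
   $Y_{ij} = (m_{ij} - \bar m_j) / s_j$. A biomarker whose site means are
   all equal cannot be standardized and raises an error naming the
   biomarker; it is never silently dropped, because dropping could push
   the biomarker count below three and silently change the index
   definition.
2. **Apply the direction coefficient** $c_j \in \{+1, -1\}$:
   $Z_{ij} = c_j Y_{ij}$. With $c_j = -1$ for inhibited biomarkers
   (e.g. acetylcholinesterase), stronger inhibition points outward on the
   star plot like stronger induction does. Without a coefficient table,
   every biomarker uses $+1$.
3. **Shift non-negative** per biomarker:
   $S_{ij} = Z_{ij} + |\min_i Z_{ij}|$, so each axis is anchored at 0 at
   the least-responding site of the same dataset. The minimum is global
   within the analysis, which is what makes radar charts of $S$
   comparable across sites.

A site's index is the area of the star polygon of its $S$ scores on $k$
equally spaced axes. The area depends on which biomarkers end up adjacent,
so it is computed for **every distinct circular arrangement** and reported
as mean and sample SD over arrangements. Orderings that differ by rotation
or reflection trace congruent polygons, so the distinct set has
$(k-1)!/2$ members ($k=5$: 12; $k=9$: 20160). Enumerating all $k!$
orderings instead would repeat each area $2k$ times — the mean would be
unchanged, and a sample-SD over the duplicated set would differ from the
deduplicated one only through the $n-1$ denominator; we report the SD over
the distinct arrangements, which are the genuinely different index values.
With $k=3$ there is a single arrangement and the SD is reported as 0.

Two properties worth knowing when reading IBR values:

* The area scales **quadratically**: doubling a site's scores quadruples
  its IBR.
* Standardization **saturates**: in a study with $n$ sites a z-score
  cannot exceed $(n-1)/\sqrt{n}$, so once one site is far from the others
  its standardized score stops growing, and the scores of the remaining
  sites compress. Past that point a stronger perturbation no longer
  increases — and can slightly decrease — the site's mean IBR. The
  synthetic-data tests therefore assert dose monotonicity for IBRv2,
  which has no such ceiling on its log-ratio scale, and not for IBR.

## The IBRv2 model

IBRv2 compares every site to a designated **reference site** $S_0$
(default: the first site in file order, overridable). Per biomarker:

$$Y_{ij} = \log(m_{ij} / m_{0j}), \qquad
  Z_{ij} = (Y_{ij} - \mu_j)/\sigma_j, \qquad
  A_{ij} = Z_{ij} - Z_{0j},$$

with $\mu_j, \sigma_j$ the mean and sample SD of $Y$ over **all** sites
including the reference. The site index is
$\mathrm{IBRv2}_i = \sum_j |A_{ij}|$; the reference scores exactly 0.

Numerical choices:

* **Natural logarithm.** Any log base would give identical $Z$, $A$ and
  IBRv2 — the base change is a positive rescaling of $Y$ that cancels in
  the standardization — so the choice is documented for transparency, not
  consequential.
* **Zero-variance biomarkers** ($\sigma_j = 0$, all sites identical) get
  $Z = A = 0$ rather than an error: the deviation genuinely is zero
  everywhere. This deliberately differs from the IBR path, where zero
  variance leaves the index undefined.
* **Non-positive site means are errors** naming the site and biomarker:
  the log-ratio does not exist, and imputing around a zero enzyme
  activity would silently fabricate a deviation.

Useful invariances, all covered by tests: multiplying one biomarker by a
positive constant at every site (a unit change) leaves IBRv2 unchanged;
the reference row of $A$ is exactly zero; and
$\mathrm{IBRv2}_i \le \sum_j (|Z_{ij}| + |Z_{0j}|)$.

Note that because each biomarker is standardized by the spread of its own
log-ratios, biomarkers that barely vary (replicate noise only) still
contribute $|A|$ values on the z scale. IBRv2 values are therefore most
interpretable when compared within one dataset, not across studies.

## Radar charts

`ibr_chart()` overlays one closed polygon of $S$ scores per site on $k$
axes (axis minimum 0); the enclosed areas are what `ibr_index()`
integrates. `ibrv2_chart()` draws one site's $A$ values as a solid polygon
with point markers over the reference's zero line as a dashed polygon —
vertices outside the dashed line are upregulated, inside downregulated.
The first biomarker sits at 12 o'clock and axes proceed clockwise; this is
presentation only and affects no index value.

The per-site axis range defaults to $[\min(A, 0), \max(A, 0)]$ with 4
rings, and `axis_ticks(lo, hi, segments)` reproduces the usual manual
construction of ring labels (`segments + 1` equally spaced values rounded
to 2 decimals) for overriding them. SVG is the default output; it is
written directly by the package with fixed fonts and number formatting, so
identical inputs give byte-identical files and the polygons and labels are
plainly parseable. PNG and PDF are rendered through the standard graphics
devices (PDF embeds a creation date, so only SVG output is byte-stable).
A site drawn with all-zero scores degenerates to the chart center and a
zero-deviation site coincides with the baseline; both render without
error. Fill transparency and palette are free choices; the default
palette is the Okabe–Ito qualitative set.

## The synthetic data generator

`simulate_biomarkers()` generates the multi-site enzyme-activity tables
the rest of the package consumes:

$$x_{ijr} = \mathrm{baseline}_j \times \mathrm{effect}_{ij}
           \times \varepsilon_{ijr},$$

with $\varepsilon$ lognormal with unit mean and coefficient of variation
`cv`. Lognormal noise keeps every value positive, so the IBRv2 log path is
defined for all generated data. The first site is the reference and its
effects are fixed at 1. Defaults model a 4-site, 5-biomarker, 8-replicate
gradient design: baselines are plausible enzyme activities in arbitrary
assay units (e.g. catalase 18.2, lactate dehydrogenase 240), replicate
noise is `cv = 0.1` (a tight assay), and effects follow a geometric
gradient $\exp(d_j \cdot 0.4 \cdot i)$ away from the reference —
induced biomarkers ($d_j=+1$) rise to $\approx 3.3\times$ at the farthest
site, the inhibited acetylcholinesterase falls correspondingly. These
sizes keep every test and the acceptance script in the seconds range
while leaving the replicate-noise scale clearly visible in the outputs.

Missing-value masking (`miss_prob`) never violates the admissibility
rules: each site/biomarker cell keeps at least one replicate and each
biomarker at least three values overall, so generated tables always pass
validation unless a degenerate fixture (e.g. all effects 1 at `cv = 0`,
which triggers the zero-variance error path) is requested explicitly.

What passing tests on this generator do **not** show: real biomarker data
have correlated biomarkers, season and size covariates, heavier tails and
occasional measurement dropout that is not missing-at-random. The
generator establishes arithmetic correctness and dose-response behavior
of the indexes, not field performance.

## Validation rules

A table must have 3–9 biomarker columns, each with at least three
non-missing values, at least two distinct sites, and no site/biomarker
cell that is entirely missing. `validate_biomarkers()` reports all
violations; the index entry points abort on any of them. A `force` flag
waives only the 3–9 count rule (for exploratory runs with, say, ten
biomarkers); the three-non-NA rule is never waived, because site means
from fewer values would be statistically meaningless while looking
exact.

## Known limitations

* IBR values depend on the site set: adding or removing a site changes
  every site's standardization, shift, and hence index. IBRv2 values
  depend on the choice of reference. Neither index should be compared
  across analyses run on different site sets.
* The arrangement SD quantifies ordering ambiguity only; neither index
  comes with a sampling-error estimate or a between-site test.
* The original (1999) single-arrangement IBR formulation is out of scope;
  only the arrangement-averaged revision and IBRv2 are provided.
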