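---
title: "How fsindex builds a food safety index"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{How fsindex builds a food safety index}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fsindex)
```

## The problem

Regulatory food surveillance programmes accumulate large tables of
sampling-and-inspection records: one laboratory measurement of one analyte
("test project") in one food sample, together with the permissible limit(s)
for that analyte, where the sample was taken (city, sales channel) and where
the food was produced. The usual summary — the fraction of samples that pass
— throws away how close each result sits to its limit and weighs a trace of
a heavy metal in a staple food the same as an additive slightly over the
line in a niche product.

`fsindex` turns such records into a per-sample **comprehensive qualification
degree** and aggregates it into 0–100 **food safety indexes** per city and
per food category, for two methods that differ only in whether a data-driven
correction is applied:

$$\bar{Q} \;=\; \omega_c \cdot \omega_h \cdot \omega_s \cdot \omega_r \cdot
\omega_{\mathrm{FADM}} \cdot Q$$

* $Q \in [0,1]$ — the simple qualification degree (distance of the test
  result from its limit);
* $\omega_c$ — consumption weight of the food category (normalized
  per-capita consumption, sums to 1 over the 8 categories);
* $\omega_h$ — analyte hazard score, an expert 1–5 toxicity rating used raw;
* $\omega_s$ — sales-channel size weight (large 1.0, medium 1.4, small 1.1);
* $\omega_r$ — production-region weight (produced in the sampled city 1.0,
  elsewhere in the home region 0.8, outside it 0.7);
* $\omega_{\mathrm{FADM}}$ — a per-sample correction in $(1, k)$ from a
  factor analysis of mixed auxiliary data (below). The
  **expert-elicitation baseline** fixes $\omega_{\mathrm{FADM}} = 1$.

Group means of $\bar{Q}$ by city or category are min–max scaled to
$[0, 100]$ within a report, and the two methods' index series are compared
with a paired $t$-test.

## The qualification degree

For test result $T \ge 0$ with limits $0 \le \mathrm{Min} \le \mathrm{Max}$:

| limit kind | condition | score |
|---|---|---|
| maximum only | $\mathrm{Min}=0<\mathrm{Max}$ | $1 - T/\mathrm{Max}$ on $[0,\mathrm{Max})$, else 0 |
| band | $0<\mathrm{Min}<\mathrm{Max}$ | $1 - \lvert\frac{T-\mathrm{Min}}{\mathrm{Max}-\mathrm{Min}} - 0.5\rvert$ on $[\mathrm{Min},\mathrm{Max})$, else 0 |
| point target | $0<\mathrm{Min}=\mathrm{Max}$ | $\max(0,\, 2 - T/\mathrm{Min})$ for $T \ge \mathrm{Min}$, 0 below |
| must be absent | $\mathrm{Min}=\mathrm{Max}=0$ | 1 iff $T = 0$, else 0 |

Two of these branches are typographically ambiguous in their original
formulation, and the parses above are deliberate choices:

* **Point target.** The printed expression can be read several ways; we use
  $Q = 2 - T/\mathrm{Min}$ clamped to $[0,1]$, which is 1 exactly at the
  target and decreases with relative deviation, preserving the stated
  $[0,1]$ range and the "deviation from the limit" semantics. The
  alternative decreasing-reciprocal reading ($Q = \mathrm{Min}/T$) is
  available via `point_parse = "reciprocal"`. Note the clamped parse marks
  $T \ge 2\,\mathrm{Min}$ as non-qualified ($Q = 0$) even though the branch
  condition admits it.
* **Band.** Without the absolute value the printed form exceeds 1 at
  $T = \mathrm{Min}$; the absolute-deviation-from-midpoint form keeps
  $Q \in [0.5, 1]$ inside the band (safest at the midpoint) and 0 outside.
* **Pure lower bound** ($\mathrm{Min} > 0$, no maximum): no graded branch
  exists for it, so these rare records score pass/fail
  ($Q \in \{0, 1\}$). None are produced by the default generator.

Records whose analyte has no usable limit at all cannot be scored; they are
excluded and counted in the run log. Units mg/kg and mg/L are treated as
numerically interchangeable, as in the source data conventions; no density
conversion is attempted.

## The mixed-data factor analysis

Each record also carries ~25 auxiliary variables of mixed type (shelf life,
sampling link, region type, ...). To let this information modify the index
without hand-picked weights, the package performs a factor analysis of
mixed data:

1. **Encoding.** Quantitative columns are standardized — centered and
   divided by the *population* ($1/n$) standard deviation, so a
   standardized column has first eigenvalue exactly 1 under the
   $X^\top X/n$ convention. Qualitative columns are one-hot expanded (one
   indicator per observed level) and centered. Constant columns and
   single-level variables are dropped with a log entry.
2. **Block scaling and SVD.** With $\lambda_1^{(i)}$ the first eigenvalue
   of block $i$, the global matrix
   $G = [\,X_1/\lambda_1^{(1)} \;|\; X_2^{\mathrm{ind}}/\lambda_1^{(2)}\,]$
   is decomposed as $G = U \Sigma V^\top$. Dividing each block by its first
   eigenvalue stops whichever block happens to have more columns (or more
   levels) from dominating the joint factors — the same idea as multiple
   factor analysis block weighting.
3. **Factor scores.** With the uniform mass matrix $M = (1/n) I$,
   $F = M^{-1/2} U \Sigma = \sqrt{n}\, U \Sigma$; row $j$ holds sample
   $j$'s scores on the principal factors. The variance contribution of
   factor $i$ is $\omega_i = \sigma_i^2 / \sum_j \sigma_j^2$ (sums to 1
   over all factors).
4. **Bounded transform.** Factor scores are deviations from a mean, so they
   are mapped into $(1, k)$ before use as weights:
   $$f(F) = \begin{cases} k - \frac{k-1}{2} e^{-F} & F \ge 0 \\
   1 + \frac{k-1}{2} e^{F} & F < 0 \end{cases}$$
   continuous ($f(0) = (k+1)/2$), strictly increasing, asymptoting to $k$
   above and 1 below. The printed source formula is ambiguous here too: its
   literal upper branch grows without bound, contradicting the stated
   ceiling $k$, and the accompanying remark about the minimum becoming zero
   contradicts the $(1,k)$ range; our orientation makes higher factor
   scores raise the transformed score. The mirrored decreasing orientation
   is available via `transform = "decreasing"`.
5. **The weight.** Over the $r$ retained factors,
   $\omega_{\mathrm{FADM}} = \sum_{i \le r} f(F_i)\,\omega_i \big/
   \sum_{i \le r} \omega_i \in (1, k)$, computed per sample.

Numerical choices worth knowing:

* **Sign convention.** SVD factor signs are arbitrary; we flip each factor
  so its largest-magnitude loading in $V$ is positive. Because $V$ depends
  on $G$ only through $G^\top G$, this makes factor scores (hence
  $\omega_{\mathrm{FADM}}$) well-defined and exactly equivariant under
  reordering of samples.
* **Retention.** The number of principal factors is not fixed by the
  method; the default keeps the smallest $r$ with cumulative variance
  contribution $\ge 0.80$. `kaiser` (eigenvalue above the mean) and
  `fixed(r)` are available. The weighted mean in step 5 runs over retained
  factors only.
* **k.** Default 100, so indexes modified by $\omega_{\mathrm{FADM}}$ have
  a natural "percent-like" scale; any $k > 1$ is accepted.

## Aggregation, scaling, comparison

Group means of $\bar{Q}$ per city and per category are min–max scaled
within each report: the best unit maps to 100, the worst to 0, ties all to
100 when every unit is equal (including single-unit reports). The mapping
from raw means to the published-style 0–100 indexes is a package choice —
the source material reports indexes without stating it — so **indexes are
comparable in rank within a report, not in absolute value across
reports**; `scaling = "raw"` disables it.

The FADM and expert index series, aligned by unit, are compared with a
two-sided paired $t$-test ($n-1$ degrees of freedom, $\alpha = 0.05$).
Degenerate series are handled totally: identical series give $p = 1$, a
constant nonzero difference gives $p = 0$, both with warnings.

## The synthetic generator — what it does and does not establish

Real provincial inspection databases are not public, so
`generate_campaign()` emulates their *structure*: 15 cities, 8 food
categories, a pool of test projects with limit pairs (80% maximum-only,
10% band, 5% point, 5% must-be-absent) and 1–5 hazard scores, 16 named
sales channels in three size classes, production-region labels
(local city / home region / outside, 0.5/0.3/0.2), and 25 auxiliary
variables (10 quantitative, 15 qualitative with 2–5 levels).

Stated-world defaults, chosen once: contamination rate 0.05 (a typical
national non-conformity rate for routine sampling), exceedance magnitude
$\mathrm{Max} \times (1 + s)$ with $s$ exponential of mean 0.5, and a
project pool of 40 (real programmes track ~200 analytes; 40 keeps every
project observed at desk-scale $n$). Safe results are uniform on the safe
interval. Auxiliaries share one latent factor shifted by city and category
(strength `aux_structure`, default 1; 0 gives independent noise), so the
factor analysis has recoverable structure.

A green test on this generator establishes that the *pipeline machinery*
behaves as specified — scores bounded, decompositions correct against
brute-force oracles, contamination monotonically depressing the index,
planted structure recovered. It does **not** establish anything about real
data: real campaigns have correlated project/category incidence, censored
measurements at the method detection limit (the `method_test_limit` column
is carried through but not modeled), non-uniform sampling designs and
multi-year drift, none of which are emulated.

## Limitations

* The two ambiguous scoring branches and the transform orientation are
  documented choices, not certainties about the original method's intent;
  both alternatives ship behind switches.
* Hazard scores enter raw (1–5), so they dominate the product's scale;
  an optional normalization was considered and deliberately left off to
  stay faithful to the source formulation.
* No missing-data imputation: rows enter the factor analysis as-is after
  exclusion logging; no varimax rotation or supplementary projection.
* The paired comparison is per report; no multiple-testing correction
  across strata.
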