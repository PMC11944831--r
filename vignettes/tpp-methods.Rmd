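---
title: "Melting-curve models, NPARC inference and design choices in tppshift"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Melting-curve models, NPARC inference and design choices in tppshift}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tppshift)
```

## The melting model

Thermal proteome profiling quantifies, for each protein, the fraction
remaining soluble after heating to a series of temperatures. tppshift
models the relative (reference-normalized) abundance with the standard
three-parameter sigmoid

$$f(T) = \frac{1 - p}{1 + e^{\,b - a/T}} + p,$$

where $T$ is in degrees Celsius, $a > 0$ (°C-scaled) and $b > 0$ set the
location and steepness of the transition, and $p \in [0, 1)$ is the
non-denaturing plateau. Two properties matter in practice:

* the curve is strictly decreasing in $T$, from $\approx 1$ at the
  reference temperature towards the plateau (the exact high-$T$ asymptote
  is $(1-p)/(1+e^b) + p$, indistinguishable from $p$ for typical
  $b \approx 10$);
* the half-denaturation point has the closed form
  $T_m = a / (b - \log[0.5/(0.5 - p)])$, defined only when $p < 0.5$.

Because the exponent contains $a/T$, the parameters are specific to the
Celsius convention used here; Kelvin-parameterised values from other
software are not interchangeable. `compute_tm()` additionally declares a
$T_m$ undefined when the crossing lies outside an extrapolation window of
the measured grid ± 5 °C (configurable), so that a fit whose nominal
crossing sits far beyond the data is not reported as a melting
temperature.

## Fitting

`fit_melt_curve()` estimates $(a, b, p)$ by bounded least squares
(Levenberg–Marquardt via minpack.lm) with $a \in (0, 5000]$,
$b \in (0, 100]$, $p \in [0, 0.999]$. Initialisation is data-driven: the
temperature where the profile first crosses halfway between its maximum
and its floor seeds $a \approx 10\,T_{mid}$ with $b = 10$ and
$p = \min(y)$; three deterministic perturbations of that start plus one
fixed fallback are also run and the lowest-RSS solution kept. Multistart
matters beyond fit quality: a per-condition fit stuck in a local optimum
inflates the alternative-model RSS and distorts the downstream F-test.

Degenerate inputs are values, not errors: a constant profile (no decay)
has zero total sum of squares, leaves $R^2$ undefined and returns
`valid = FALSE`; fewer than five distinct temperatures is an input error,
since a three-parameter model on fewer points is not meaningfully
constrained. Quality filtering (`curve_quality_filter()`) defaults to
$R^2 \ge 0.8$, plateau $< 0.3$ and a defined $T_m$ — common practice for
calling a "valid sigmoidal melting curve"; both thresholds are exposed
because conventions differ between laboratories.

$\Delta T_m$ is computed per replicate (treatment minus vehicle), whereas
the NPARC test pools replicates within each condition's fit: the shift
estimate benefits from replicate resolution, while the hypothesis test is
about condition-level curves.

## NPARC inference

For each protein the null model fits one sigmoid to both conditions
pooled (3 parameters); the alternative fits one sigmoid per condition
(6). With $RSS_0$ and $RSS_1$ their residual sums of squares,

$$F = \frac{(RSS_0 - RSS_1)/(p_1 - p_0)}{RSS_1/(n - p_1)}.$$

The models are nested, so $RSS_1 \le RSS_0$ up to solver tolerance; the
implementation guarantees this structurally by adding the null solution
to the start set of each per-condition fit (Levenberg–Marquardt never
accepts an uphill step, so the alternative can only improve on it).
Negative differences within tolerance clamp $F$ to zero. An exactly zero
$RSS_1$ (possible only on noiseless data) gives a floored p-value of
1e-300 with a warning rather than NaN.

**Degrees of freedom.** The package offers two p-value modes:

* `"theoretical"`: $F \sim F(p_1 - p_0,\; n - p_1)$, the textbook choice.
* `"empirical"` (default): the distributions of $RSS_0 - RSS_1$ and
  $RSS_1$ across the proteome are each matched to a scaled
  $\chi^2(d)$ — the interquartile ratio $q_{75}/q_{25}$ depends only on
  $d$ and pins it, the median then pins the scale — and the rescaled
  ratio is referred to $F(d_1, d_2)$.

The empirical mode is the default as a deliberate design choice. The
theoretical reference assumes i.i.d. homoscedastic Gaussian residuals,
which relative-abundance data violate: noise scales with the signal, so
residual variance falls along the melt. Under such heteroscedasticity the
theoretical F-test is mis-calibrated (conservative), and the established
remedy in the NPARC literature is to estimate effective degrees of
freedom from the proteome-wide ensemble. Quartile-based matching makes
the estimate robust to the minority of true shifters in the upper tail,
so it does not require knowing which proteins are null. The test suite
verifies the calibration claim directly on simulated data: under a global
null (1000 proteins, 5% multiplicative noise, fixed seed) the empirical
mode's rejection rate at $\alpha = 0.05$ lies in [0.03, 0.07] and its
p-value distribution is near-uniform (Kolmogorov–Smirnov statistic
< 0.05); no such guarantee is made for the theoretical mode, which is
retained for comparability. With fewer than 20 testable proteins the
ensemble is too small to characterise and the empirical mode falls back
to theoretical with a warning.

Proteins whose fits fail, that lack a condition, or that have too few
observations are flagged untestable and excluded *before*
Benjamini–Hochberg adjustment, so the multiplicity correction runs over
the number of hypotheses actually tested. Hit tiers follow the common
reporting pattern — nominal $p < 0.05$, nominal $p < 0.01$, adjusted
$p < 0.1$ ("prime") — with the adjusted tier computed independently of
the nominal ones.

## The synthetic-data generator

`simulate_tpp()` emulates the quantitative structure of a two-condition,
two-replicate TMT experiment over ten temperatures from 37 to 67 °C.
Baseline parameters are drawn uniformly ($a \sim U(430, 680)$,
$b \sim U(9, 11)$, $p \sim U(0, 0.15)$) with rejection until the implied
$T_m$ falls in 45–70 °C, the range reported for the human proteome. A
configurable fraction of proteins (default 10%) are true shifters whose
treatment-condition $a$ is re-derived so the closed-form $T_m$ moves by
exactly the injected shift ($\Delta T_m \sim N(3, 0.5)$ °C by default)
while $b$ and $p$ are held — the ground truth is therefore exact, not
approximate. Observations are the true curve times $(1 + \epsilon)$,
$\epsilon \sim N(0, \sigma)$ truncated at zero; $\sigma = 0.05$ by
default, a choice we document as an assumption about replicate-level
measurement noise rather than a value fitted to any particular dataset.
Replicates are independent noise redraws around the same true curve.

What the generator deliberately does **not** emulate: TMT reporter-ion
intensities and their ratio compression, isotopic impurity, peptide-to-
protein rollup, missing channels, co-isolation interference, or
between-replicate biological variance in the true curves. Passing the
simulation-based tests therefore demonstrates correctness of the
estimators and calibration of the inference under the stated noise model
— not robustness to every artefact of real LC-MS data.

## Compound annotation

Monoisotopic masses use C = 12 (exact), H = 1.00782503, N = 14.00307401,
O = 15.99491462, S = 31.97207117, P = 30.97376200 Da; singly charged
adducts add or subtract a proton (1.007276 Da). Besides [M+H]⁺ and
[M−H]⁻, the calculator supports the formate adduct [M+HCOO]⁻
(+44.998203 Da): with formic-acid mobile phases, neutral glycosides
commonly ionise as formate adducts in negative mode, and two glycosides
in the packaged negative-mode table (hastatoside, atractyloside A) match
[M+HCOO]⁻ within 1 ppm while being ~78 ppm off [M−H]⁻. The packaged
binding-component table prints no per-row ion mode; the fixture carries a
mode and adduct inferred as the assignment minimizing ppm error, under
which every row of all three tables agrees with theory within 5 ppm
(most within 1 ppm). The default agreement tolerance is 5 ppm,
typical for Orbitrap mass accuracy, and configurable.

All component-table thresholds are strict inequalities — score "over 80",
ratio "exceeding 20", binding score "exceeded 70" — so records exactly at
a threshold are dropped; boundary tests pin this behaviour.
Deduplication and blank-control subtraction match names case-insensitively
after whitespace normalization, with no synonym resolution: identity of
the reported name is the deduplication key, and conflating distinct
flavonoids that differ by one letter (scutellarin vs scutellarein) would
be an error a synonym service could easily introduce.

## Evidence integration

Interaction networks are undirected simple graphs: duplicate, reversed
and self edges collapse on load, symbols are uppercased. Degree ranking
breaks ties alphabetically so output order is deterministic. The docking
rule flags a compound when XP GScore < −6 **or** MM-GBSA ΔG < −30
kcal/mol, both strict; applied to the packaged docking table it flags
narirutin (by both criteria), berberrubine and sinensetin, but not
jatrorrhizine (−2.447, −22.11), which fails both.

## Problem sizes and tolerances used in the test suite

The simulation-based checks use sizes chosen to make their statistical
margins comfortable at interactive runtimes: 1000 proteins for null
calibration, 150 per shift level for power monotonicity at
$\Delta T_m \in \{1, 2, 4\}$ °C, 20 × 100 proteins for realized
false-discovery proportion, 100 random draws for noiseless parameter
recovery (tolerance $10^{-4}$ relative), bisection agreement for $T_m$ to
$10^{-6}$ °C, and 1000 random vectors against a brute-force BH oracle.

## Known limitations

* The sigmoid family is fixed; proteins with non-sigmoidal melting
  behaviour (multi-domain transitions, precipitation artefacts) are
  handled only by the validity/quality flags, not by alternative models.
* Isothermal dose–response (ITDR) designs and spline-based NPARC
  variants are out of scope.
* Empirical df estimation characterises the ensemble globally; strong
  heterogeneity of noise across proteins (e.g. abundance-dependent CV)
  would call for per-protein variance modelling that the package does not
  attempt.
* The evidence-integration step operates on user-supplied edge lists and
  score tables; it performs no database queries, enrichment analyses or
  identifier mapping.
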