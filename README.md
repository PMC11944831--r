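# tppshift

Thermal proteome profiling (TPP) melting-curve analysis and drug-target
deconvolution in R.

TPP identifies the protein targets of a compound proteome-wide: cell
lysate aliquots treated with the compound or vehicle are heated across a
temperature gradient, the soluble (non-denatured) fraction at each
temperature is quantified by multiplexed mass spectrometry, and proteins
whose thermal stability shifts under treatment are candidate binders. The
package is aimed at analysts of such experiments — particularly of complex
interventions such as multi-component herbal extracts, where the melting
analysis is combined with compound identification and network evidence —
and at methodologists who need a fully simulated test bed with known
ground truth.

## What it computes

**Melting curves and Tm.** Each protein × condition × replicate profile of
relative abundances over temperature is fitted with the standard
three-parameter sigmoid

    f(T) = (1 − plateau) / (1 + exp(b − a/T)) + plateau,

decreasing from ≈1 at the reference temperature (37 °C) to `plateau` at
high temperature. The melting temperature is the half-denaturation point,
available in closed form as `Tm = a / (b − log(0.5/(0.5 − plateau)))` when
`plateau < 0.5`, and `ΔTm = Tm(treatment) − Tm(vehicle)` measures the
treatment-induced stabilisation. Temperatures are in °C throughout.

**NPARC hypothesis testing.** For each protein, a null model (one sigmoid
for all conditions pooled) is compared with an alternative model (one
sigmoid per condition) via the residual-sum-of-squares F-statistic

    F = [(RSS0 − RSS1)/(p1 − p0)] / [RSS1/(n − p1)],   p0 = 3, p1 = 6,

with p-values from the cumulative F-distribution, Benjamini–Hochberg FDR
control across all tested proteins, and three nested hit tiers
(p < 0.05, p < 0.01, adjusted p < 0.1). P-values use either theoretical
degrees of freedom or (default) empirically moment-matched ones estimated
robustly from the proteome-wide ensemble — see the methods vignette for
why the empirical mode is the calibrated default.

**Compound annotation.** A formula parser and monoisotopic-mass/adduct
m/z calculator ([M+H]⁺, [M−H]⁻, [M+HCOO]⁻) validates MS component
identifications by ppm error, applies the component-table filters
(spectral-library score, sample/control enrichment ratio, blank-control
subtraction) and deduplicates identifications across ionisation modes.
The published component tables ship as plain-text fixtures.

**Evidence integration.** Target-list merging with provenance, degree
ranking on a user-supplied protein–protein interaction edge list, and the
docking-score rule (XP GScore < −6 or MM-GBSA ΔG < −30 kcal/mol) for
flagging stable binders.

**Synthetic data.** `simulate_tpp()` generates TMT-style datasets — ten
temperatures 37–67 °C, two conditions, two replicates, baseline Tm in
45–70 °C, a configurable fraction of true shifters with exactly known
injected ΔTm, multiplicative noise — so that every stage above is testable
against ground truth without any external data.

## Worked example

```r
library(tppshift)

sim <- simulate_tpp(sim_config(n_proteins = 300, shift_fraction = 0.1,
                               seed = 42))
res <- nparc_test(sim$profiles)
glance(res)
#> # A tibble: 1 × 6
#>   n_proteins n_tested n_significant n_marked n_prime df_mode
#>        <int>    <int>         <int>    <int>   <int> <chr>
#> 1        300      300            42       33      34 empirical
```

300 simulated proteins, 10% carrying a true ΔTm shift of about +3 °C.
All 300 are testable; 42 reach nominal p < 0.05, 33 the stricter p < 0.01,
and 34 pass the adjusted-p < 0.1 prime tier — of which 97% are true
shifters in this run (the realized false-discovery proportion matches the
0.1 FDR target).

```r
fits <- fit_melt_curves(sim$profiles)
replicate_tm_correlation(fits)
#> # A tibble: 2 × 3
#>   condition     r n_pairs
#>   <chr>     <dbl>   <int>
#> 1 treatment 0.994     290
#> 2 vehicle   0.994     294
```

Replicate Tm estimates correlate at r ≈ 0.99 under the default 5%
noise — the same reproducibility check used on real experiments.

```r
neg <- read_compound_table(tppshift_example("table1_negative.tsv"))
pos <- read_compound_table(tppshift_example("table2_positive.tsv"))
uniq <- deduplicate_across_modes(filter_main_components(neg),
                                 filter_main_components(pos))
nrow(uniq)
#> [1] 54
```

The packaged component tables (32 negative-mode and 30 positive-mode
identifications) pass the score > 80 and ratio > 20 filters and collapse
to 54 unique compounds; `annotate_theoretical_mz()` confirms every printed
m/z against its formula within 5 ppm.

A thin command-line wrapper over the same functions is installed at
`system.file("scripts", "tppshift-cli.R", package = "tppshift")` with
`simulate`, `fit`, `nparc`, `annotate`, `integrate` and `run` subcommands.

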