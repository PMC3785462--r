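# haplopower

Monte-Carlo power analysis for case-control association studies over
2×k contingency tables, with mtDNA haplogroup studies as the motivating
application.

## The problem

A case-control association study of k marker categories (haplogroups,
haplotypes, mtSNP classes) compares the category frequency vectors of
`N_co` controls and `N_ca` cases in a 2×k table. Most published mtDNA
association studies never report their statistical power, partly because
the available tools handle only 2×2 tables or designs with equal numbers
of cases and controls — while real studies usually recruit more controls
than cases. `haplopower` estimates power for arbitrary k and arbitrary
arm sizes, and solves the inverse problems a study planner actually
faces: how many subjects, and how small an effect is detectable.

## The method

Tables are simulated as two independent multinomial draws: the control
row from the null spectrum **q**, the case row from an effect-shifted
vector in which one "risky" category's frequency rises from `p0` to
`p1 = p0 (1 + δ)` and the difference is redistributed proportionally over
the other categories. Power is the fraction of simulated tables whose
homogeneity p-value falls below α. Three p-value calibrations of the
Pearson statistic are available:

* **asymptotic** — the χ²(k′−1) upper tail (k′ = non-empty columns);
  anti-conservative in small samples when Cochran's rule fails;
* **permutation** — B tables resampled with both margins fixed
  (sequential conditional hypergeometric columns, equivalent to
  Patefield's algorithm), `p = (1 + #{χ²* ≥ χ²}) / (B + 1)`;
* **fisher_mc** — a Monte-Carlo Fisher exact test on the same
  margin-fixed resamples.

Designs of any shape are summarized by the scaled noncentrality
statistic

    N_sc = (p1 − p0)² / ( p̄ (1 − p̄) · (1/N_ca + 1/N_co) ),   p̄ = (p0 + p1)/2,

which reduces at equal arms to `N_scaled = N (p1 − p0)² / (2 p̄ (1 − p̄))`
and, divided by `k^0.37`, collapses power curves across different
numbers of categories onto a single curve. `calibrate_nsc()` fits that
curve (local-linear Gaussian-kernel regression of simulated power on
`N_sc / k^0.37`, cross-validated bandwidth) and inverts it to thresholds
`N_sc*(α, β)`; the sample-size and minimum-detectable-effect solvers
then search for the smallest integer design whose corrected statistic
reaches the threshold.

## Worked example

Power to detect a doubling of haplogroup J (11% in European controls)
with 300 cases and 600 controls:

```r
library(haplopower)
sp <- euro11_spectrum()                  # 11-haplogroup example spectrum
eff <- effect_spec("J", deviation = 1)   # case frequency doubles (OR = 2.25)
d <- study_design(n_cases = 300, ratio = 2, alpha = 0.05,
                  method = "permutation", n_sim = 2000, n_perm = 2000,
                  seed = 1)
estimate_power(sp, eff, d)
#> Monte-Carlo power estimate: 0.8155 (MC SE 0.0087)
#>   300 cases / 600 controls, alpha = 0.05, method = permutation
#>   n_sim = 2000, n_perm = 2000, seed = 1
```

So this design would detect a doubling of J in about 82% of studies.
The smallest equal-arm design reaching 80% power for the same effect
(J's renormalized control frequency is 0.10):

```r
star <- nsc_star(default_calibration(), alpha = 0.05, beta = 0.80)
min_cases_given_ratio(star, ratio = 1, p0 = sp$freqs[3], eff,
                      n_categories = 11)
#> Minimum design: 412 cases, 412 controls
#>   (achieved statistic 6.653 >= threshold 6.648)
```

And the smallest effect detectable with 500 cases and 1500 controls at
80% power:

```r
min_detectable_effect(star, n_cases = 500, n_controls = 1500,
                      p0 = sp$freqs[3], n_categories = 11)
#> Minimum detectable effect: delta = 0.7101 (case frequency 0.1710, OR = 1.857)
```

The same operations are available from the shell via the installed
script (`system.file("cli", "haplopower", package = "haplopower")`),
with subcommands `power`, `posthoc`, `samplesize`, `mindetect`,
`calibrate` and `fixture`; results are emitted as JSON run records.

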