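# cbrisk

Regression-based estimation of **odds ratios, absolute risks and relative
risks from case-base studies**.

In a case-base study, cases are sampled from incident diseased subjects
(with probability γ) and a *base* (control) sample is drawn from the whole
study population regardless of disease status (with probability τ). Because
the base sample represents everyone, absolute risks are identifiable — not
just odds ratios, as in a classical case-control study. `cbrisk` fits a
logistic model to the recruited subjects and corrects its intercept with
ρ̂ = n₁/n_D, the observed fraction of recruited diseased subjects that
belong to the base sample:

```
alpha_hat = alpha* + log(rho_hat)
```

From the corrected model it reports ORs, absolute risks and relative risks
for arbitrary covariate profiles, with delta-method Wald confidence
intervals that carry the extra variance of log ρ̂. The package also
provides:

* closed-form comparison estimators: **Sato** (`sato_rr()`, exactly
  equivalent to the regression estimator for one binary exposure),
  **Miettinen** (`miettinen_rr()`, with an overlap-corrected variance) and
  **case duplication** (`duplication_rr()`);
* a synthetic-population simulator (`solve_baseline_odds()`,
  `simulate_population()`, `draw_case_base_sample()`);
* a Monte-Carlo study runner with built-in published scenarios
  (`run_scenario()`, `builtin_scenarios()`, `write_report()`);
* a design-precision calculator (`casebase_plan()`);
* YAML/CSV/JSON I/O and a command-line interface
  (`inst/cli/casebase`, `casebase_cli()`).

## Worked example

```r
library(cbrisk)

# A population with one binary exposure (prevalence 0.3, OR 2.5) whose
# baseline odds are solved so that the marginal disease prevalence is 0.1.
model <- solve_baseline_odds(list(cb_binary("x", 0.3)), ~ x,
                             c(x = log(2.5)), target_prevalence = 0.1)
truth_table(model, data.frame(x = c(0, 1)))
#>   x      risk logit_risk       rr    log_rr
#> 1 0 0.0726590  -2.546544 1.000000 0.0000000
#> 2 1 0.1637957  -1.630253 2.254307 0.8128424

# Simulate a case-base study: gamma = 0.05, tau = 0.005, N = 100,000.
pop <- simulate_population(model, 100000, seed = 1)
ds  <- draw_case_base_sample(pop, sampling_design(100000, 0.05, 0.005),
                             seed = 2)

fit <- fit_casebase(ds, ~ x)
fit
#> Case-base logistic risk model
#>
#> Case-base recruitment counts
#>   recruited subjects:        981
#>   distinct diseased (n_D):   527
#>   diseased in base (n1):     46
#>   ...
#> rho_hat = 0.0873 (var(log rho_hat) = 0.01984)
#> corrected intercept alpha_hat = -2.6543

estimate_rr(fit, data.frame(x = 1), data.frame(x = 0))
#>   kind  label    point transformed        se   ci_low  ci_high level
#> 1   RR 1 vs 0 2.413184   0.8809471 0.1212982 1.902573 3.060834  0.95

estimate_risk(fit, data.frame(x = c(0, 1)))
#>   kind label      point transformed        se     ci_low    ci_high level
#> 1 risk     1 0.06572646   -2.654268 0.1628815 0.04863707 0.08826338  0.95
#> 2 risk     2 0.15861005   -1.668607 0.1792652 0.11712314 0.21127565  0.95
```

Running a published scenario end to end:

```r
report <- run_scenario("table1", replicates = 2000, seed = 1)
write_report(report, "table1.csv", "csv")
```

Or from the shell:

```sh
inst/cli/casebase study --config scenario.yaml --seed 1 --out report.csv
inst/cli/casebase plan --n-distinct 900 --prevalence 0.1
```

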