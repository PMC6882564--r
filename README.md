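# hepaticCE

Bayesian analysis of contrast enhancement in hepatic dynamic CT.

## The problem

On contrast-enhanced hepatic CT, lesion detection needs *optimal*
enhancement: more than 280 HU in the abdominal aorta during the hepatic
arterial phase (HAP) and more than 50 HU in the hepatic parenchyma during
the portal venous phase (PVP). With a weight-adjusted injection (2.0 mL/kg
of 300 mgI/mL contrast, i.e. 600 mgI/kg), mean enhancement is usually
adequate — but patients vary, and the clinically relevant quantity is the
*probability* that a patient reaches the threshold under a given
tube-voltage protocol (120 kVp vs the iodine-friendlier 100 kVp).
Frequentist summaries of mean enhancement do not answer that directly;
a Bayesian posterior does.

`hepaticCE` implements that analysis end to end for radiology physicists
and biostatisticians:

1. **Synthetic cohorts** (`generate_cohort()`): seeded two-arm patient
   cohorts whose enhancement moments can be matched exactly to published
   summary statistics.
2. **Enhancement metrics** (`compute_enhancement()`, `attainment_rate()`,
   `two_sample_t()`, `chi_square_2x2()`): per-patient ΔHU and the standard
   descriptive/frequentist comparisons.
3. **Required-volume transform** (`required_volume()`,
   `transform_cohort()`): each patient's enhancement *E* under
   administered dose *a* (mL/kg) is converted to the volume needed to just
   reach threshold *T*, via the dose–enhancement proportionality
   `v = a·T / E`.
4. **Bayesian model** (`sample_posterior()` and friends): required volumes
   are modelled as `v_i ~ Normal(μ, σ²)` with a uniform prior on `(μ, σ)`.
   A conjugate Gibbs sampler (default: 5 chains × 21,000 draws, burn-in
   1,000 → 100,000 retained draws) yields per-draw derived quantities
   - attainment probability `p_k = Φ((a − μ_k)/σ_k)` — the modelled
     fraction of patients whose required volume does not exceed the
     administered dose, and
   - coverage dose `q_k = μ_k + z(c)·σ_k` — the dose at which a fraction
     *c* (default 95%, `z = 1.6449`) of patients reach threshold,

   each reported as posterior mean ± SD, with split-chain R-hat
   diagnostics (`gelman_rubin()`) and a closed-form flat-prior posterior
   (`analytic_posterior()`) as an exact cross-check.
5. **Pipeline** (`run_study()`): the whole two-arm study from a config
   file, with CSV/JSON/markdown outputs. A thin command-line wrapper ships
   in `inst/scripts/hepaticce.R`.

## Worked example

The 120 kVp arm at the study conditions (n = 100, aortic HAP enhancement
moment-matched to 340.9 ± 51.4 HU, 2.0 mL/kg administered):

```r
library(hepaticCE)

cohort <- generate_cohort(default_arm_spec(120, seed = 7))
enh    <- compute_enhancement(cohort)
attainment_rate(enh$aorta_enh_hu, 280)
#> Attainment: 91/100 (91.0%) above 280 HU

vols  <- transform_cohort(enh, "aorta", quiet = TRUE)
draws <- sample_posterior(vols$required_ml_per_kg, mcmc_config(seed = 8))
exceedance_probability(draws, 2.0)
#> P(required volume <= 2 mL/kg): 0.8926 +/- 0.02468 (95% CrI 0.8389-0.9353)
coverage_dose(draws, 0.95)
#> dose covering 95% of patients (mL/kg): 2.103 +/- 0.03999 (95% CrI 2.03-2.187)
gelman_rubin(draws)
#>        mu     sigma
#> 0.9999813 1.0000050
```

Reading: 91 of the 100 synthetic patients exceeded 280 HU empirically; the
posterior says a randomly drawn patient attains optimal aortic enhancement
at 2.0 mL/kg with probability ≈ 89 ± 2.5%, and ≈ 2.10 mL/kg would be
needed to cover 95% of patients. R-hat ≈ 1 confirms the five chains agree.
`run_study(default_study_config(seed = 1))` produces the full 2-arm × 2-site
report, including the 100 kVp cells (where the attainment probability rises
above 95% for both sites) and the cross-arm t and chi-square tests.

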