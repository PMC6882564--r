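# Default two-arm study configuration: moment-matched synthetic cohorts at
# the published enhancement moments, 2.0 mL/kg administered (600 mgI/kg at
# 300 mgI/mL), thresholds 280 HU (aorta, HAP) and 50 HU (liver, PVP).
arms:
  "120":
    protocol_kvp: 120
    n: 100
    aorta_enh_mean: 340.9
    aorta_enh_sd: 51.4
    liver_enh_mean: 57.8
    liver_enh_sd: 11.8
    administered_volume: 2.0
    seed: 2
  "100":
    protocol_kvp: 100
    n: 100
    aorta_enh_mean: 395.9
    aorta_enh_sd: 65.1
    liver_enh_mean: 73.9
    liver_enh_sd: 15.5
    administered_volume: 2.0
    seed: 3
thresholds:
  aorta: 280.0
  liver: 50.0
administered_volume: 2.0
coverage: 0.95
moment_match: true
fit_enhancement: true
mcmc:
  n_chains: 5
  draws_per_chain: 21000
  burn_in: 1000
  mu_bounds: [0.0, 10.0]
  sigma_bounds: [1.0e-6, 5.0]
  seed: 4
  sampler: gibbs
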