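# Default exposure-assessment configuration (units in comments)
ptmi: 25            # provisional tolerable monthly intake, ug/kg-bw/month
body_weight: 60     # kg
ptdi: 49.5          # provisional tolerable daily intake, ug/day
tobacco_conc: 1.5   # ug Cd per g tobacco
cigarette_mass: 1.0 # g tobacco per cigarette
water_conc: 0.025   # ug/L (half the LOD of 0.05 ug/L)
water_volume: 1.2   # L/day
lod: 0.05           # ug/L, detection limit for Cd in water/urine/blood
n_iterations: 100000
seed: 20130618
smoking_prevalence:
  male: 0.662
  female: 0.033
  total: 0.295
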