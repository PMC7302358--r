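# Base-case configuration: cost-utility of xanthan-gum food thickening vs
# routine clinical practice in post-stroke dysphagia (GUSS 10-14 aspirators),
# Polish public-payer perspective, PLN.
#
# Fields listed under `assumed_fields` have no published main-source base
# value (their source data live in supplementary material we do not ship);
# the values here are clearly-flagged synthetic placeholders chosen once to
# be clinically plausible. Everything else is a published base-case value.

meta:
  currency: PLN
  threshold_per_qaly: 147024

static:
  dysphagia_weeks: 8
  ap_weeks: 2
  ap_counts:                       # 8-week aspiration-pneumonia risks
    aspirators: {events: 10, n_patients: 82}        # 12.2%
    non_aspirators: {events: 1, n_patients: 57}     # 1.75%
  u_aspiration: 0.15
  u_no_aspiration: 0.37
  du_ap: 0.13
  cost_ap_episode: 1924.0
  nutilis_daily_g: 37.96
  tin_g: 175.0
  tin_price: 77.05                 # payer price per tin (copayment excluded)

dynamic:
  horizon_weeks: 52
  baseline_ap_ir_weekly: 0.004036  # weekly AP incidence, no dysphagia
  rr_ap_no_asp: 2.77               # dysphagia without aspirations
  rr_ap_asp: 8.27                  # dysphagia with aspirations
  rr_death_ap: 2.99                # mortality during an AP episode
  deterioration_weekly: 0.0011     # weekly onset of aspirations
  mortality:
    p30_weekly: 0.046              # weeks 1-4 (first 30 days)
    p90_weekly: 0.0096             # weeks 5-13 (days 31-90)
    rest_weekly: 0.0024            # weeks 14-52
  prevalence_anchors:              # synthetic placeholder (see assumed_fields)
    - {day: 0, fraction: 1.0}
    - {day: 7, fraction: 0.5}
    - {day: 28, fraction: 0.25}
    - {day: 180, fraction: 0.08}
  u_no_dysphagia: 0.46             # synthetic placeholder (see assumed_fields)
  u_dys_no_asp: 0.37
  u_dys_asp: 0.15
  du_ap: 0.13
  cost_ap_episode: 1924.0
  cost_monitoring_visit: 186.0
  monitoring_weeks: [1, 4, 12, 26, 39, 52]
  nutilis_daily_g: 37.96
  tin_g: 175.0
  tin_price: 77.05

psa:
  n_iterations: 10000
  ap_cost_sd_frac: 0.20            # assumed: cost SD = 20% of mean

assumed_fields:
  - dynamic.prevalence_anchors
  - dynamic.u_no_dysphagia
  - psa.ap_cost_sd_frac
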