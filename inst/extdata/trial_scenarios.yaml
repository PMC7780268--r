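# Default study configuration: the censoring/accrual parameters of the four
# reference trials (per-month rates, months for durations), with the two
# exponential-source scenarios fully specified.  Exponential rates are
# calibrated so the source RMST at the economic-model horizon equals the
# published true RMST (pembrolizumab: 5.6 mo at horizon 420; pertuzumab:
# 376.8 mo at horizon 624); see calibrate_exponential_rate().
#
# Source-distribution parameters for Weibull and generalized-gamma scenarios
# are a required user input: add entries with `family: weibull` /
# `family: gengamma` and your own `params`.  The `templates` block below
# records the accrual/censoring settings of all four trials and is ignored
# by the reader.  Trial-end times are set so simulated follow-up maturity
# matches each trial's observed event fraction (e.g. KEYNOTE-045: 18-month
# maximum follow-up, ~79% of patients with events).
study:
  mode: trial
  bic_variant: standard
  seed: 20201207
scenarios:
  - label: pembrolizumab_exponential
    family: exponential
    params:
      rate: 0.17857142857142858
    n_patients: 542
    recruit_period: 12.0
    recruit_rate: 0.2
    ltf_rate: 0.002
    max_followup: 18.0
    horizon: 420.0
    n_sim: 10000
  - label: pertuzumab_exponential
    family: exponential
    params:
      rate: 0.0017798504397959
    n_patients: 2400
    recruit_period: 23.0
    recruit_rate: 0.1
    ltf_rate: 0.002
    max_followup: 46.0
    horizon: 624.0
    n_sim: 10000
templates:
  - trial: ARCHER-1050 (dacomitinib, overall survival)
    n_patients: 227
    recruit_period: 21.0
    recruit_rate: 0.1
    ltf_rate: 0.002
    max_followup: 48.0
    horizon: 180.0
  - trial: KEYNOTE-045 (pembrolizumab, progression-free survival)
    n_patients: 542
    recruit_period: 12.0
    recruit_rate: 0.2
    ltf_rate: 0.002
    max_followup: 18.0
    horizon: 420.0
  - trial: APHINITY (pertuzumab + trastuzumab, invasive disease-free survival)
    n_patients: 2400
    recruit_period: 23.0
    recruit_rate: 0.1
    ltf_rate: 0.002
    max_followup: 46.0
    horizon: 624.0
  - trial: MURANO (venetoclax + rituximab, overall survival)
    n_patients: 194
    recruit_period: 18.0
    recruit_rate: 0.1
    ltf_rate: 0.002
    max_followup: 38.0
    horizon: 240.0
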