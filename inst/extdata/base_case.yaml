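# Base-case inputs for the one-year suicide risk assessment
# cost-effectiveness model. Probabilities are annual; costs are GBP.
p_high_oxmis: 0.25
p_high_clinical: 0.5
p_suicide_high: 0.017
p_suicide_overall: 0.008
hrm_risk_reduction: 0.10
cost_oxmis: 57
cost_clinical_assessment: 253
cost_hrm: 1615
cost_lrm: 0
cost_suicide: 260
utility_smi: 0.77
utility_decrement_hrm: 0.05
utility_death: 0
time_horizon_years: 1
wtp_threshold: 20000
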