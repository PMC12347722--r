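# Conditional probability table of the published sepsis network,
# transcribed as printed. Only four of the eight parent-state columns
# were published (the all-low and all-high CRP/WBC combinations, each
# for both sTREM-1 strata); the remaining columns are absent here and
# load as NA, flagged "not_printed".
scheme:
  crp_breaks: [70]
  wbc_breaks: [14000]
  strem1_breaks: [283.53]
columns:
  - crp_state: "<=70"
    wbc_state: "<=14000"
    strem1_state: "<=283.53"
    p_with: 0.00
  - crp_state: "<=70"
    wbc_state: "<=14000"
    strem1_state: ">283.53"
    p_with: 0.20
  - crp_state: ">70"
    wbc_state: ">14000"
    strem1_state: "<=283.53"
    p_with: 0.67
  - crp_state: ">70"
    wbc_state: ">14000"
    strem1_state: ">283.53"
    p_with: 1.00
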