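# Planning dose constraints. "PTV3" resolves to the plan's active boost
# volume (PTV3_1/2/3). Thresholds in Gy for D-metrics.
constraints:
  - {structure: PTV2,        metric: "D98%", bound: ">=", threshold: 58.8}
  - {structure: PTV2,        metric: "D2%",  bound: "<=", threshold: 70.0}
  - {structure: PTV3,        metric: "D98%", bound: ">=", threshold: 68.6}
  - {structure: PTV3,        metric: "D2%",  bound: "<=", threshold: 71.4}
  - {structure: URETHRA,     metric: "D2%",  bound: "<=", threshold: 62.4}
  - {structure: PRV_URETHRA, metric: "D2%",  bound: "<=", threshold: 62.4}
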