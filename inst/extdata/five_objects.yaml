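# schema + run configuration for five_objects.csv
id_col: id
decision_col: d
positive_label: "1"
engine: gseq
xi: [0.59, 0.60, 0.70]
thresholds:
  - alpha: 0.8
    beta: 0.2
  - alpha: 0.7
    beta: 0.3
  - alpha: 0.5
    beta: 0.4
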