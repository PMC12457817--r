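{
  "aipw_oracle_6.csv": "c3dc58646dfdb16133098fb7801c2f48",
  "zero_residual.csv": "26c33fde691f64303c7fbb55c6cfbb2b",
  "demo_simple1.csv": "3cdf59ac0e8a659b809b8c8e0df388dd"
}
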