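"month","value"
"2020-01",101.71
"2020-02",105.55
"2020-03",106.25
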