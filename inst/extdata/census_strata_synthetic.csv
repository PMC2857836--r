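age_band,sex,proportion
25-34,male,0.18
35-44,male,0.135
45-54,male,0.105
55-64,male,0.08
25-34,female,0.18
35-44,female,0.135
45-54,female,0.105
55-64,female,0.08
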