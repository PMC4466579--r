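# Soluble-VEGF colocalization protocol, PAECs co-expressing VEGFR2 and NRP1.
study: trafficking_study
mode: soluble
vegf_ng_ml: 50
duration_min: 30
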