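# Reference HUVEC configuration used for model predictions; dose varies.
study: other
mode: soluble
vegf_ng_ml: 20
duration_min: 60
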