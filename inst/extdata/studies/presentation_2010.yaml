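# High-dose immobilized-VEGF protocol: 200 ng/mL VEGF pre-bound in a
# collagen/fibrinogen gel, HUVEC receptor numbers.
study: presentation_2010
mode: immobilized
vegf_ng_ml: 200
duration_min: 60
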