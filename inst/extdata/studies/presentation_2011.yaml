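# Low-dose surface-immobilized VEGF (heparin linker), HUVEC receptor numbers.
study: presentation_2011
mode: immobilized
vegf_ng_ml: 2
duration_min: 60
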