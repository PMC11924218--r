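"sample_id","c_tccho_gC_per_L","toc_gC_per_L"
"T-striatum-like",0.0012,0.003
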