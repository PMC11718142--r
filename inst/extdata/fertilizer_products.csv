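product_id,n_fraction
urea,0.46
dap,0.18
ammonium_sulphate,0.21
can,0.27
superphosphate,0
potash,0
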