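# Example parameter override file for rhocycle (uM, min).
# Keys are the rho_params field names; Inf disables a GDI interaction.
Ki_GAP_GDI = 0.01
GDI_free_excess = 1.2
GAP_total = 0.1
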