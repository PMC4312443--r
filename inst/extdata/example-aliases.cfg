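# Example species alias table for import_sbml(): alias = canonical species id.
# Matching ignores case and the characters - _ / . and spaces.
GDP-Rho = RhoGDP
GTP-Rho = RhoGTP
RhoGDIalpha = GDI
GTP-Rho/Effector = RhoGTP_Effector
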