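#! FIELDS time cv1 sigma_cv1 height
# synthetic 1D hill ledger authored by hand for parser tests:
# 3 hills at t = 10/20/30 ps, centers 0.53/0.76/1.12 nm,
# sigma 0.05 nm each, heights 0.5/0.2/0.05 kcal/mol
10.0 0.53 0.05 0.5
20.0 0.76 0.05 0.2
30.0 1.12 0.05 0.05
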