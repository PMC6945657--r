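# 10 MV energy-FWHM comparison: 1%/1 mm rates at each scan depth, 10.5 MeV, focal spot and divergence 0, 2.5e7 histories
energy_fwhm_mev,avg_uncertainty,d2.4,d5,d10,d20,d30
0.120,5.9,59.0,74.5,39.8,78.3,45.3
0.140,5.9,80.1,36.6,14.3,36.0,9.9
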