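# 10 MV stage 3: divergence sweep at 10.5 MeV, energy FWHM 0.120 MeV, focal spot 0.12 cm, 2.5e7 histories
divergence_deg,avg_uncertainty,rate_3_3,rate_2_2,rate_1_1
1,6.0,100.0,100.0,81.4
2,6.0,100.0,95.0,74.5
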