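compound,mu_eV,eta_eV,softness_eVinv,electrophilicity_eV
1a,-4.6761,5.4932,0.1820,1.9903
1b,-4.6608,5.4494,0.1835,1.9931
1c,-4.9587,5.6360,0.1774,2.1814
1d,-4.5300,5.0529,0.1979,2.0306
1e,-4.5975,5.2009,0.1923,2.0320
1f,-4.5529,5.3625,0.1864,1.9327
2,-4.5953,5.2243,0.1914,2.0210
3d,-4.5229,5.0523,0.1979,2.0245
3e,-4.5296,5.3177,0.1880,1.9292
GDM,-4.8982,5.5895,0.1789,2.1462
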