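wavelength_nm,eps_hbo2,eps_hb
730,390.0,1102.2
810,864.0,717.1
855,1036.0,691.3
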