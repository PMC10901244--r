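# basis=log10_cm_M units=cm^-1.M^-1 source=compiled-in-vivo-hemoglobin
wavelength_nm,eps_hbo,eps_hbr
690,276,2051.96
830,974,693.04
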