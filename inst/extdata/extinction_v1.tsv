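# dvos hemoglobin extinction table, version 1
# source: synthetic working values approximating a published compilation of
#   adult human oxy-/deoxyhemoglobin molar extinction spectra (base-10
#   decadic coefficients), interpolated at the four device wavelengths.
# units: eps_* in L / (mmol * cm)
wavelength_nm	eps_hbo	eps_hbd
670	0.32	2.80
780	0.74	1.08
808	0.86	0.78
850	1.06	0.69
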