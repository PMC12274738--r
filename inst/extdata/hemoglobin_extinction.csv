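# Molar extinction coefficients of human hemoglobin (cm^-1 / M per heme),
# compiled from the tabulation of S. Prahl, "Optical absorption of
# hemoglobin", Oregon Medical Laser Center (1999); the 558 nm row is
# linearly interpolated between the tabulated 556 and 560 nm entries.
wavelength,epsHbO2,epsHb,source
532,44480,40584,"Prahl OMLC 1999 tabulation"
558,33209,53412,"Prahl OMLC 1999 tabulation, interpolated 556-560 nm"
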