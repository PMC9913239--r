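# Published thermal-injury kinetic coefficients, fitted from viability
# measured 24 h post hyperthermia (murine cell lines).
#   activation_energy    Ea, J/mol
#   ln_frequency_factor  ln A, A in 1/s
#   delay_intercept_b    shoulder delay intercept b, s
#   delay_slope_m        shoulder delay slope m, s/K
#   r_cem                per-degree isoeffect factor above 43 degC
STO:
  activation_energy: 455630
  ln_frequency_factor: 164.79
  delay_intercept_b: 127460
  delay_slope_m: 400
  r_cem: 0.607
KPC:
  activation_energy: 383112
  ln_frequency_factor: 137.63
  delay_intercept_b: 254920
  delay_slope_m: 800
  r_cem: 0.588
Pan02:
  activation_energy: 427712
  ln_frequency_factor: 153.63
  delay_intercept_b: 127460
  delay_slope_m: 400
  r_cem: 0.596
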