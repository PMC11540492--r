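# Example configuration: hub-only electrodes with the working electrode
# raised to 1.7 V vs Ag/AgCl, everything else at tabulated defaults.
scenario: S1
electrodes:
  we:
    potential: 1.7
controls:
  rtol: 1.0e-6
  atol: 1.0e-9
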