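# Calibration windows for control biomarkers at 1 Hz.
# APD50/APD90/dVdtMax/APA/TOP: human in-silico control mean +/- 2 SD.
# APD10/APD25/APD75/EOP: bundled-model baseline value +/- 50% (no published
# human ranges for these; wide by construction).
APD10: {min: 0.81, max: 2.43}
APD25: {min: 1.69, max: 5.07}
APD50: {min: 110, max: 310}
APD75: {min: 108.2, max: 324.7}
APD90: {min: 171, max: 391}
dVdtMax: {min: 261, max: 577}
APA: {min: 104, max: 120}
TOP: {min: -89, max: -85}
EOP: {min: -130.1, max: -43.4}
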