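biomarker,arm,pacing,frequency_hz,mean,sd
APD90,rabbit_invitro,slow,0.25,432,119
APD90,human_insilico,slow,0.25,292,65
APD90,rabbit_invitro,normal,1,310,52
APD90,human_insilico,normal,1,281,55
APD90,rabbit_invitro,fast,3,216,24
APD90,human_insilico,fast,3,212,27
APD50,rabbit_invitro,slow,0.25,311,107
APD50,human_insilico,slow,0.25,215,59
APD50,rabbit_invitro,normal,1,239,53
APD50,human_insilico,normal,1,210,50
APD50,rabbit_invitro,fast,3,162,24
APD50,human_insilico,fast,3,149,22
dVdtMax,rabbit_invitro,slow,0.25,627,80
dVdtMax,human_insilico,slow,0.25,363,73
dVdtMax,rabbit_invitro,normal,1,616,72
dVdtMax,human_insilico,normal,1,419,79
dVdtMax,rabbit_invitro,fast,3,595,62
dVdtMax,human_insilico,fast,3,391,79
APA,rabbit_invitro,slow,0.25,128,3
APA,human_insilico,slow,0.25,107,4
APA,rabbit_invitro,normal,1,129,3
APA,human_insilico,normal,1,112,4
APA,rabbit_invitro,fast,3,129,3
APA,human_insilico,fast,3,113,4
TOP,rabbit_invitro,slow,0.25,-89,1
TOP,human_insilico,slow,0.25,-84,1
TOP,rabbit_invitro,normal,1,-91,1
TOP,human_insilico,normal,1,-87,1
TOP,rabbit_invitro,fast,3,-92,1
TOP,human_insilico,fast,3,-88,1
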