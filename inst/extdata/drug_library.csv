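name,ic50_INa,ic50_ICaL,ic50_Ito,ic50_IKr,hill,concentrations,frequencies,n_fibers,tdp_class
astemizole,2.8,0.59,22,0.017,1,0.01;0.1;1;3,0.25;1;3,6,1
bepridil,3.1,6,13,0.19,1,0.1;0.3;1;3,0.2;1;3,6,1
cisapride,,33,,0.015,1,0.003;0.01;0.03,0.25;1;3,6,1
clarithromycin,163,103,,62.5,1,1;2.4;10;30,0.25;1;3,5,1
diltiazem,15,0.76,84,16.6,1,0.1;1;3;10;30,0.25;1;3,6,NC
disopyramide,,114,,14.4,1,0.3;1;3;10;30;100,0.2;1,5,1
dofetilide,94,204,,0.047,1,0.0003;0.001;0.003;0.01,0.2;1;3,7,1
nifedipine,23,0.051,31,92,1,0.03;0.3;1;10,0.25;1;3,6,NC
quinidine,35,2.9,15,1.26,1,0.1;1;3;10,0.25;1;3,6,1
ranolazine,101,156,,24.5,1,0.3;3;10;30,0.25;1;3,4,2
risperidone,102,138,43,0.41,1,0.003;0.03;0.3,0.25;1,6,2
sotalol,,,,86.4,1,0.3;1;3;10;30,0.25;1;3,6,1
terfenadine,3.3,2.2,68,0.17,1,0.03;0.32;1.44;5.34,0.25;1;3,6,1
verapamil,29,0.2,58,0.6,1,0.1;1;3,0.25;1;3,6,NC
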