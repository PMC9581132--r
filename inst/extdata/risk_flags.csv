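drug,tdp_class,ead_insilico,ead_invitro,apd90_insilico,apd90_invitro,note
astemizole,1,TRUE,TRUE,TRUE,TRUE,EADs in both arms; APD90 prolongation above threshold in both arms
bepridil,1,TRUE,FALSE,TRUE,TRUE,EADs in simulations only; no EADs observed in rabbit fibers despite wide concentration range
cisapride,1,TRUE,TRUE,TRUE,TRUE,EADs in both arms up to the highest tested concentration
clarithromycin,1,TRUE,TRUE,TRUE,TRUE,dose-dependent prolongation in both arms; larger in rabbit
diltiazem,NC,FALSE,FALSE,TRUE,FALSE,no EADs in either arm; significant prolongation at high concentration in silico (false positive)
disopyramide,1,TRUE,TRUE,TRUE,TRUE,risky in both arms
dofetilide,1,TRUE,TRUE,TRUE,TRUE,prolongation in both arms; much larger in rabbit
nifedipine,NC,FALSE,FALSE,FALSE,FALSE,safe in both arms by both metrics
quinidine,1,TRUE,TRUE,TRUE,TRUE,risky in both arms
ranolazine,2,TRUE,FALSE,TRUE,TRUE,EADs in simulations only at the highest concentration; none in rabbit
risperidone,2,TRUE,TRUE,TRUE,TRUE,risky in both arms
sotalol,1,TRUE,TRUE,TRUE,TRUE,prolongation in both arms; much larger in rabbit
terfenadine,1,TRUE,FALSE,TRUE,FALSE,EADs in simulations only; little rabbit prolongation at all concentrations (false negative in vitro)
verapamil,NC,FALSE,FALSE,TRUE,TRUE,no EADs; above-threshold prolongation at high multiples of therapeutic concentration in both arms (false positive)
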