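pathway_id	required	optional
sulfate_route	cysP;cysA;cysU;cysW;cysD;cysN;cysC	cysE;cysK;cysQ
sulfonate_route	ssuA;ssuB;ssuC;ssuD
taurine_route	tauA;tauB;tauC;tauD
ectoine	ectA;ectB;ectC	ectD
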