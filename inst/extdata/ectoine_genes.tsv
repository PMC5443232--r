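genome_id	symbols
AP12	tauD
P6W	ectA;tauD
NBRC15208	ectB;tauD
LL02	ectA;ectB;tauD
KN65.2	ectA;ectB;ectC;tauD
LE124	tauD
NBRC102051	tauD
ST904	ectA;ectB;tauD
AAP1	tauD
AAP83	tauD
AAP93	tauD
FNE08-7	tauD
DSM12444	tauD
DSM19966	tauD
MBES04	tauD
Musc273	ectA;ectB;ectC;tauD
DSM12447	tauD
US6-1	ectA;ectB;ectC;tauD
PP1Y	ectA;ectB;ectC;tauD
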