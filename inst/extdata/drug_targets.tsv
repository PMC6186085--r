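gene	drug
FEN1	Epinephrine
FEN1	Gentian violet
FEN1	Methyldopa
FEN1	Dopamine
FEN1	Idarubicin
FEN1	Norepinephrine
FEN1	Masoprocol
FEN1	Quinacrine
FEN1	Mitoxantrone
FEN1	Levodopa
MMP2	Captopril
MMP2	Marimastat
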