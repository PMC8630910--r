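locus	rsid	gene	method	cell_type	direction
ITGAM	rs1143679	TLR7	logistic	CL	+
ITGAM	rs1143683	JAK1	logistic	CL	+
TNFAIP3	rs2230926	IRF8	proportion_anova	CL	+
SPP1	rs9138	ARG1	logistic	CL	+
SPP1	rs9138	IRF1	logistic	CL	+
SPP1	rs9138	IRF4	logistic	CL	+
IRF5	rs10488631	IRF1	logistic	NCL	+
IRF7	rs1061502	IRF1	logistic	NCL	+
ITGAM	rs1143679	ARG1	gaussian_nonzero	NCL	+
ITGAM	rs1143679	TCF4	logistic	NCL	+
ITGAM	rs1143683	IL1B	gaussian_nonzero	NCL	+
ITGAM	rs1143683	TNFA	gaussian_nonzero	NCL	+
TNFAIP3	rs2230926	CD274	logistic	NCL	+
TNFAIP3	rs2230926	FCER1G	proportion_anova	NCL	+
TNFAIP3	rs2230926	IL7R	proportion_anova	NCL	+
TNFAIP3	rs2230926	STAT1	proportion_anova	NCL	+
TNFAIP3	rs2230926	STAT2	tweedie	NCL	+
TNFAIP3	rs2230926	TNFA	logistic	NCL	+
TNFAIP3	rs2230926	TYK2	proportion_anova	NCL	+
PTPN22	rs2476601	IL5	logistic	NCL	+
SPP1	rs9138	IFIT5	proportion_anova	NCL	+
SPP1	rs9138	IL1A	proportion_anova	NCL	+
SPP1	rs9138	IRF1	logistic	NCL	+
SPP1	rs9138	TLR3	proportion_anova	NCL	+
SPP1	rs9138	TYK2	proportion_anova	NCL	+
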