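[Header]
GSGT Version	example export
Num SNPs	18
Num Samples	2
[Data]
Sample ID	SNP Name	Chr	Position	GType	B Allele Freq	Log R Ratio
HM01	exm870797	1	1000001	BB	0.9841
HM01	exm2271913	1	1000002	AB	0.4887
HM01	exm1163669	1	1000003	BB	0.9737
HM01	exm151810	1	1000004	AB	0.4712
HM01	exm363078	1	1000005	BB	0.9788
HM01	exm1588790	1	1000006	BB	0.9921
HM01	exm717089	1	1000007	AA	0.0089
HM01	exm1436659	1	1000008	AA	0.0058
HM01	exm747290	1	1000009	AB	0.4611
HM01	exm2265754	1	1000010	AA	0.0042
HM01	exm779139	1	1000011	AB	0.5202
HM01	exm1083876	1	1000012	AA	0.0022
HM01	exm-rs6929796	1	1000013	AB	0.585
HM01	exm1021627	1	1000014	BB	0.9553
HM01	exm44591	1	1000015	BB	0.9822
HM01	exm2259465	1	1000016	AA	0.0043
HM01	exm2267990	1	1000017	AA	0.0102
HM01	exm-rs10472828	1	1000018	AB	0.467
HM01_PT	exm870797	1	1000001	BB	0.9865
HM01_PT	exm2271913	1	1000002	AB	0.4551
HM01_PT	exm1163669	1	1000003	BB	0.9901
HM01_PT	exm151810	1	1000004	AB	0.4921
HM01_PT	exm363078	1	1000005	AB	0.4917
HM01_PT	exm1588790	1	1000006	AB	0.4467
HM01_PT	exm717089	1	1000007	AA	0.0002
HM01_PT	exm1436659	1	1000008	AA	0.001
HM01_PT	exm747290	1	1000009	BB	0.9738
HM01_PT	exm2265754	1	1000010	BB	0.987
HM01_PT	exm779139	1	1000011	AA	0.0056
HM01_PT	exm1083876	1	1000012	AB	0.4597
HM01_PT	exm-rs6929796	1	1000013	AA	0.0076
HM01_PT	exm1021627	1	1000014	AA	0.0156
HM01_PT	exm44591	1	1000015	AA	0.0233
HM01_PT	exm2259465	1	1000016	AB	0.4864
HM01_PT	exm2267990	1	1000017	BB	0.9968
HM01_PT	exm-rs10472828	1	1000018	BB	0.9919
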