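model_name	model_type	lnL	k	delta_aic	weight
X	Divergences, migrations, and expansions	-5262.392335	14	0	1
III	Divergences and migrations	-5261.258098	16	1.731526292	0.420730351
IV	Divergences and migrations	-5480.279081	18	443.7734919	4.32E-97
IX	Divergences, migrations, and expansions	-5262.817181	16	4.84969321	0.088491692
II	Divergences and migrations	-5275.603138	12	22.42160665	1.35E-05
XII	Divergences, migrations, expansions, and bottleneck	-5279.918669	16	39.05266805	3.31E-09
I	Divergences	-5309.276383	8	81.76809762	1.76E-18
VI	Divergences and migrations	-5486.576572	18	456.3684745	7.96E-100
V	Divergences and migrations	-5407.541805	18	298.2989407	1.68E-65
VII	Divergences, migrations, and expansions	-5491.428656	22	474.0726424	1.14E-103
VIII	Divergences, migrations, and expansions	-7152.90404	22	3797.023411	0
XI	Divergences, migrations, and expansions	-18294.94633	22	26081.10799	0
XIII	Divergences, migrations, expansions, and bottleneck	-9709.965268	22	8911.145868	0
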